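#' Build a genomic interval tibble
#'
#' All coordinates in the package are 0-based, half-open (BED convention):
#' `start` is the first base of the interval and `end` is one past the last.
#' Intervals are plain tibbles so they compose with dplyr verbs; every
#' function in the package that consumes regions accepts any tibble with at
#' least `chrom`, `start`, `end` columns.
#'
#' @param chrom Chromosome identifiers (character).
#' @param start,end Integer coordinates, `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` per interval. Footprints and DHSs
#'   are strandless (`"."`); cleavage events are stranded.
#' @param name Optional labels.
#' @param score Optional numeric scores.
#' @return A tibble with columns `chrom, start, end, name, score, strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                              score = NA_real_) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand)
  )
  validate_intervals(out)
  out
}

#' Validate an interval tibble
#'
#' Checks the invariants every region table must satisfy: `0 <= start < end`
#' and strand in `{+, -, .}`. When an assembly is supplied, also checks that
#' every chromosome exists and every interval is in bounds.
#'
#' @param x Interval tibble.
#' @param assembly Optional [genome_assembly()] to bind coordinates against.
#' @return `x`, invisibly, or an error.
#' @export
validate_intervals <- function(x, assembly = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop("invalid interval at row ", bad[1], ": need 0 <= start < end, got [",
         x$start[bad[1]], ", ", x$end[bad[1]], ")", call. = FALSE)
  }
  if ("strand" %in% names(x)) {
    bad_s <- which(!x$strand %in% c("+", "-", "."))
    if (length(bad_s) > 0) stop("invalid strand at row ", bad_s[1], call. = FALSE)
  }
  if (!is.null(assembly)) {
    lens <- assembly_lengths(assembly)
    missing_chrom <- setdiff(unique(x$chrom), names(lens))
    if (length(missing_chrom) > 0) {
      stop("chromosome not in assembly: ", missing_chrom[1], call. = FALSE)
    }
    oob <- which(x$end > lens[x$chrom])
    if (length(oob) > 0) {
      stop("interval out of assembly bounds at row ", oob[1], call. = FALSE)
    }
  }
  invisible(x)
}

empty_intervals <- function() {
  genomic_intervals(character(), integer(), integer(), character())
}

#' Midpoint of each interval (0-based position)
#' @param x Interval tibble.
#' @return Integer vector of floor((start+end)/2).
#' @export
interval_midpoint <- function(x) {
  as.integer(floor((as.numeric(x$start) + as.numeric(x$end)) / 2))
}

## Overlap machinery: thin tibble-facing wrappers over IRanges. Coordinates
## are shifted to 1-based closed form at this boundary only.
iranges_of <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Pairs of overlapping intervals between two tables
#'
#' @param a,b Interval tibbles.
#' @param min_overlap Minimum number of overlapping bases (default 1).
#' @return Tibble with columns `a` and `b`: row indices into each input.
#' @export
interval_overlap_pairs <- function(a, b, min_overlap = 1L) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(a = integer(), b = integer()))
  }
  res <- purrr::map(split(seq_len(nrow(a)), a$chrom), function(ia) {
    ib <- which(b$chrom == a$chrom[ia[1]])
    if (length(ib) == 0) return(tibble::tibble(a = integer(), b = integer()))
    hits <- IRanges::findOverlaps(iranges_of(a[ia, ]), iranges_of(b[ib, ]),
                                  minoverlap = min_overlap)
    tibble::tibble(a = ia[S4Vectors_from(hits)], b = ib[S4Vectors_to(hits)])
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$a, .data$b)
}

# queryHits/subjectHits without importing S4Vectors wholesale
S4Vectors_from <- function(h) methods::slot(h, "from")
S4Vectors_to <- function(h) methods::slot(h, "to")

#' Logical vector: does each interval in `a` overlap anything in `b`?
#' @inheritParams interval_overlap_pairs
#' @export
interval_overlaps_any <- function(a, b, min_overlap = 1L) {
  out <- rep(FALSE, nrow(a))
  hits <- interval_overlap_pairs(a, b, min_overlap)
  out[unique(hits$a)] <- TRUE
  out
}

#' Base-level intersection of two interval sets
#'
#' Returns the per-base intersection of `a` with `b` as disjoint intervals.
#' Empty intersections are dropped. Metadata columns from `a` rows are kept
#' for each clipped piece.
#' @inheritParams interval_overlap_pairs
#' @export
interval_intersect <- function(a, b) {
  hits <- interval_overlap_pairs(a, b)
  if (nrow(hits) == 0) return(empty_intervals())
  piece <- tibble::tibble(
    chrom = a$chrom[hits$a],
    start = pmax(a$start[hits$a], b$start[hits$b]),
    end = pmin(a$end[hits$a], b$end[hits$b]),
    name = if ("name" %in% names(a)) a$name[hits$a] else NA_character_,
    score = if ("score" %in% names(a)) a$score[hits$a] else NA_real_,
    strand = if ("strand" %in% names(a)) a$strand[hits$a] else "."
  )
  # merge pieces coming from the same `a` row so output is disjoint
  piece |>
    dplyr::mutate(.arow = hits$a) |>
    dplyr::group_by(.data$.arow, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(.grp = cumsum(dplyr::lag(cummax(.data$end), default = -1L) < .data$start)) |>
    dplyr::group_by(.data$.arow, .data$chrom, .data$.grp) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      name = dplyr::first(.data$name), score = dplyr::first(.data$score),
      strand = dplyr::first(.data$strand), .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::select("chrom", "start", "end", "name", "score", "strand")
}

#' Subtract the bases of `b` from `a`
#' @inheritParams interval_overlap_pairs
#' @return Disjoint intervals covering bases of `a` not in `b`.
#' @export
interval_subtract <- function(a, b) {
  if (nrow(a) == 0) return(empty_intervals())
  bm <- interval_merge(b)
  out <- purrr::pmap(list(a$chrom, a$start, a$end, seq_len(nrow(a))), function(ch, s, e, i) {
    cuts <- bm[bm$chrom == ch & bm$end > s & bm$start < e, , drop = FALSE]
    if (nrow(cuts) == 0) {
      return(tibble::tibble(chrom = ch, start = s, end = e, row = i))
    }
    cuts <- cuts[order(cuts$start), ]
    starts <- c(s, pmin(cuts$end, e))
    ends <- c(pmax(cuts$start, s), e)
    keep <- starts < ends
    tibble::tibble(chrom = ch, start = starts[keep], end = ends[keep], row = i)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty_intervals())
  genomic_intervals(out$chrom, out$start, out$end,
                    strand = if ("strand" %in% names(a)) a$strand[out$row] else ".",
                    name = if ("name" %in% names(a)) a$name[out$row] else NA_character_)
}

#' Merge overlapping or bookended intervals
#' @param x Interval tibble.
#' @param gap Merge intervals separated by at most `gap` bases (default 0:
#'   overlapping or touching).
#' @export
interval_merge <- function(x, gap = 0L) {
  if (nrow(x) == 0) return(empty_intervals())
  x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(.grp = cumsum(dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf) + gap < .data$start)) |>
    dplyr::group_by(.data$chrom, .data$.grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::transmute(.data$chrom, .data$start, .data$end,
                     name = NA_character_, score = NA_real_, strand = ".")
}

#' Total bases covered by an interval set (after merging)
#' @param x Interval tibble.
#' @export
interval_bases <- function(x) {
  m <- interval_merge(x)
  sum(as.numeric(m$end) - as.numeric(m$start))
}

#' Reciprocal-overlap fraction between two specific intervals
#' @keywords internal
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}
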