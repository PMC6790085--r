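#' Map an interval through ungapped alignment blocks
#'
#' Bases of the interval covered by blocks are translated by the per-block
#' offset (orientation-aware). The mapped interval is the span of translated
#' bases on the target assembly, provided the covered fraction is at least
#' `min_frac` and all covered bases map to a single target chromosome and
#' orientation; otherwise the interval is unmappable.
#'
#' @param iv One-row interval tibble (`chrom, start, end`).
#' @param blocks Alignment-block tibble (see [read_blocks()]).
#' @param min_frac Minimum covered fraction (default 0.5).
#' @return One-row tibble `chrom, start, end, covered_frac`, or `NULL`.
#' @export
map_interval <- function(iv, blocks, min_frac = 0.5) {
  b <- blocks[blocks$chromA == iv$chrom[1] & blocks$endA > iv$start[1] &
                blocks$startA < iv$end[1], ]
  if (nrow(b) == 0) return(NULL)
  os <- pmax(b$startA, iv$start[1])
  oe <- pmin(b$endA, iv$end[1])
  covered <- sum(oe - os)
  if (covered / (iv$end[1] - iv$start[1]) < min_frac) return(NULL)
  if (length(unique(b$chromB)) > 1 || length(unique(b$orient)) > 1) return(NULL)
  # translate the first and last covered base of each overlapping block
  first_b <- ifelse(b$orient == "+", b$startB + (os - b$startA),
                    b$endB - 1L - (oe - 1L - b$startA))
  last_b <- ifelse(b$orient == "+", b$startB + (oe - 1L - b$startA),
                   b$endB - 1L - (os - b$startA))
  tibble::tibble(chrom = b$chromB[1],
                 start = min(first_b, last_b),
                 end = max(first_b, last_b) + 1L,
                 covered_frac = covered / (iv$end[1] - iv$start[1]))
}

#' Invert an alignment-block set (swap assemblies A and B)
#' @param blocks Block tibble.
#' @export
invert_blocks <- function(blocks) {
  validate_blocks(tibble::tibble(
    chromA = blocks$chromB, startA = blocks$startB, endA = blocks$endB,
    chromB = blocks$chromA, startB = blocks$startA, endB = blocks$endA,
    orient = blocks$orient
  ))
}

#' Classify cross-species footprint conservation
#'
#' Each source footprint is `not_conserved` when it cannot be mapped through
#' the blocks at `min_frac`, `conserved_occupied` when its mapped interval
#' overlaps a target-species footprint by at least 1 bp, and
#' `conserved_unoccupied` otherwise.
#'
#' @param dgfs_a Source footprints (interval tibble).
#' @param dgfs_b Target-species footprints.
#' @param blocks Alignment blocks A -> B.
#' @param min_frac Mapping threshold (default 0.5).
#' @return `dgfs_a` with added `mapped_chrom, mapped_start, mapped_end,
#'   category` columns.
#' @export
classify_conservation <- function(dgfs_a, dgfs_b, blocks, min_frac = 0.5) {
  n <- nrow(dgfs_a)
  out <- dgfs_a
  out$mapped_chrom <- NA_character_
  out$mapped_start <- NA_integer_
  out$mapped_end <- NA_integer_
  out$category <- "not_conserved"
  mapped_rows <- list()
  for (i in seq_len(n)) {
    m <- map_interval(dgfs_a[i, ], blocks, min_frac)
    if (is.null(m)) next
    out$mapped_chrom[i] <- m$chrom
    out$mapped_start[i] <- m$start
    out$mapped_end[i] <- m$end
    mapped_rows[[length(mapped_rows) + 1L]] <- tibble::tibble(
      i = i, chrom = m$chrom, start = m$start, end = m$end
    )
  }
  mapped <- dplyr::bind_rows(mapped_rows)
  if (nrow(mapped) > 0 && nrow(dgfs_b) > 0) {
    occ <- interval_overlaps_any(mapped, dgfs_b)
    out$category[mapped$i] <- ifelse(occ, "conserved_occupied", "conserved_unoccupied")
  } else if (nrow(mapped) > 0) {
    out$category[mapped$i] <- "conserved_unoccupied"
  }
  out
}

#' Multi-species hyperconserved footprints
#'
#' Classifies the reference footprints against every other species and keeps
#' those `conserved_occupied` in all of them; per-species mapped coordinates
#' are attached, and a per-feature-class breakdown is reported when gene
#' models are supplied.
#'
#' @param dgfs_ref Reference-species footprints.
#' @param others Named list; each element a list with `dgfs` and `blocks`
#'   (reference -> that species).
#' @param min_frac Mapping threshold.
#' @param genes Optional gene models for the feature breakdown.
#' @return List: `hyperconserved` tibble (with per-species mapped coordinate
#'   columns), `feature_breakdown` (or NULL).
#' @export
multiway_conserved <- function(dgfs_ref, others, min_frac = 0.5, genes = NULL) {
  if (length(others) == 0) stop("need at least one comparison species", call. = FALSE)
  if (is.null(names(others)) || any(names(others) == "")) {
    stop("comparison species must be named", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(dgfs_ref))
  res <- dgfs_ref
  for (sp in names(others)) {
    o <- others[[sp]]
    if (is.null(o$blocks)) stop("missing alignment blocks for ", sp, call. = FALSE)
    cls <- classify_conservation(dgfs_ref, o$dgfs, o$blocks, min_frac)
    keep <- keep & cls$category == "conserved_occupied"
    res[[paste0("mapped_", sp)]] <- ifelse(
      is.na(cls$mapped_chrom), NA_character_,
      paste0(cls$mapped_chrom, ":", cls$mapped_start, "-", cls$mapped_end)
    )
  }
  hyper <- res[keep, ]
  breakdown <- if (!is.null(genes) && nrow(hyper) > 0) {
    feature_distribution(hyper, genes)
  } else NULL
  list(hyperconserved = hyper, feature_breakdown = breakdown)
}

#' Fraction of one region set overlapped by another
#'
#' @param set_a,set_b Interval tibbles.
#' @param symmetric Also require the fraction computed from B and average
#'   the two (default FALSE).
#' @return Fraction of A intervals with >= 1 bp overlap in B.
#' @export
overlap_fraction <- function(set_a, set_b, symmetric = FALSE) {
  if (nrow(set_a) == 0) stop("overlap fraction undefined for empty A", call. = FALSE)
  fa <- mean(interval_overlaps_any(set_a, set_b))
  if (!symmetric) return(fa)
  if (nrow(set_b) == 0) stop("overlap fraction undefined for empty B", call. = FALSE)
  (fa + mean(interval_overlaps_any(set_b, set_a))) / 2
}

# overlap count used by the permutation machinery
overlap_count <- function(a, b) {
  sum(interval_overlaps_any(a, b))
}

#' Permutation test of region-set overlap with a local z profile
#'
#' The observed count of A intervals overlapping B is compared with the
#' counts from `n_perm` random placements of A (interval lengths and
#' chromosome assignment preserved, uniform placement, no overlap
#' enforcement): `z = (obs - mean) / sd` and
#' `p_emp = (1 + #{perm >= obs}) / (n_perm + 1)`. The local z profile shifts
#' all of A by each offset in `-shift_window ... +shift_window` (step
#' `shift_step`) and recomputes the observed count against the same
#' permutation null (random placement is shift-invariant).
#'
#' @param set_a,set_b Interval tibbles.
#' @param lengths Named chromosome lengths.
#' @param n_perm Number of permutations (>= 20; default 100).
#' @param seed Seed.
#' @param shift_window Half-width of the local profile in bp (0 disables).
#' @param shift_step Profile step in bp.
#' @return A `perm_overlap` object: `observed, perm_mean, perm_sd, z, p_emp,
#'   n_perm, profile` (tibble `shift, observed, z`).
#' @export
permutation_overlap <- function(set_a, set_b, lengths, n_perm = 100L, seed = 1L,
                                shift_window = 0L, shift_step = 50L) {
  if (n_perm < 20) stop("need n_perm >= 20", call. = FALSE)
  obs <- overlap_count(set_a, set_b)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      w <- set_a$end - set_a$start
      ns <- vapply(seq_len(nrow(set_a)), function(j) {
        sample.int(lengths[[set_a$chrom[j]]] - w[j], 1) - 1L
      }, integer(1))
      overlap_count(tibble::tibble(chrom = set_a$chrom, start = ns, end = ns + w),
                    set_b)
    }, numeric(1))
  })
  mu <- mean(perm)
  sdv <- stats::sd(perm)
  z <- if (sdv > 0) (obs - mu) / sdv else NA_real_
  p_emp <- (1 + sum(perm >= obs)) / (n_perm + 1)
  profile <- NULL
  if (shift_window > 0) {
    shifts <- seq(-shift_window, shift_window, by = shift_step)
    obs_s <- vapply(shifts, function(d) {
      a <- set_a
      a$start <- pmax(0L, pmin(a$start + d, lengths[a$chrom] - (a$end - a$start)))
      a$end <- a$start + (set_a$end - set_a$start)
      overlap_count(a, set_b)
    }, numeric(1))
    profile <- tibble::tibble(shift = shifts, observed = obs_s,
                              z = if (sdv > 0) (obs_s - mu) / sdv else NA_real_)
  }
  structure(list(observed = obs, perm_mean = mu, perm_sd = sdv, z = z,
                 p_emp = p_emp, n_perm = n_perm, profile = profile),
            class = "perm_overlap")
}

#' @export
print.perm_overlap <- function(x, ...) {
  cat(sprintf("<perm_overlap> observed %d vs permuted %.2f +/- %.2f | z = %s | p_emp = %.4g (%d perms)\n",
              x$observed, x$perm_mean, x$perm_sd,
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)), x$p_emp, x$n_perm))
  invisible(x)
}

#' @export
tidy.perm_overlap <- function(x, ...) {
  if (is.null(x$profile)) {
    tibble::tibble(shift = 0, observed = x$observed, z = x$z)
  } else x$profile
}

#' @export
glance.perm_overlap <- function(x, ...) {
  tibble::tibble(observed = x$observed, perm_mean = x$perm_mean,
                 perm_sd = x$perm_sd, z = x$z, p_emp = x$p_emp, n_perm = x$n_perm)
}
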