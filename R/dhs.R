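#' Call DNaseI-hypersensitive sites with a sliding-window Poisson model
#'
#' Strand-summed counts are evaluated in sliding windows; a window is
#' significant when its one-sided Poisson upper-tail p-value against
#' `lambda = max(genome-wide rate, local 5 kb rate)` falls below `p_thresh`.
#' Significant windows within `gap` bases of each other (including
#' bookended) are merged; merged peaks narrower than `min_width` are
#' discarded. Peak score is the `-log10` Poisson p-value of the peak's total
#' count against the same background; the summit is the position of the
#' maximum window count.
#'
#' @param profile A `cut_profile`.
#' @param window Window width in bp (default 150).
#' @param step Window step in bp (default 20).
#' @param p_thresh Per-window significance threshold (default 1e-5).
#' @param gap Maximum separation for merging significant windows (default 150).
#' @param min_width Minimum reported peak width (default 150).
#' @param local_bg Width of the local background window (default 5000).
#' @return Tibble of peaks: `chrom, start, end, name, score, strand, summit`,
#'   sorted by coordinate; `score` is `-log10 p`.
#' @export
call_dhs <- function(profile, window = 150L, step = 20L, p_thresh = 1e-5,
                     gap = 150L, min_width = 150L, local_bg = 5000L) {
  tot <- total_cuts(profile)
  if (tot == 0) return(dhs_empty())
  glen <- sum(vapply(profile$chroms, function(ch) length(ch$plus), numeric(1)))
  global_rate <- tot / glen
  peaks <- purrr::imap(profile$chroms, function(chv, ch) {
    y <- chv$plus + chv$minus
    L <- length(y)
    if (L < window) return(NULL)
    cs <- cumsum(as.numeric(y))
    starts <- seq(0L, L - window, by = step) # 0-based window starts
    wc <- cs[starts + window] - c(0, cs)[starts + 1L]
    # local lambda over +-local_bg/2 around the window center
    ls <- pmax(0L, starts + window %/% 2L - local_bg %/% 2L)
    le <- pmin(L, starts + window %/% 2L + local_bg %/% 2L)
    local_rate <- (cs[le] - c(0, cs)[ls + 1L]) / (le - ls)
    lambda <- pmax(global_rate, local_rate) * window
    p <- stats::ppois(wc - 1, lambda, lower.tail = FALSE)
    sig <- which(p <= p_thresh)
    if (length(sig) == 0) return(NULL)
    iv <- tibble::tibble(chrom = ch, start = starts[sig], end = starts[sig] + window,
                         count = wc[sig])
    merged <- interval_merge(iv, gap = gap)
    merged <- merged[merged$end - merged$start >= min_width, ]
    if (nrow(merged) == 0) return(NULL)
    merged$summit <- NA_integer_
    merged$score <- NA_real_
    for (i in seq_len(nrow(merged))) {
      inside <- iv$start >= merged$start[i] & iv$end <= merged$end[i]
      best <- which(inside)[which.max(iv$count[inside])]
      merged$summit[i] <- as.integer(iv$start[best] + window %/% 2L)
      n_pk <- cs[merged$end[i]] - c(0, cs)[merged$start[i] + 1L]
      lam_pk <- global_rate * (merged$end[i] - merged$start[i])
      merged$score[i] <- -stats::ppois(n_pk - 1, lam_pk, lower.tail = FALSE,
                                       log.p = TRUE) / log(10)
    }
    merged
  })
  out <- dplyr::bind_rows(peaks)
  if (nrow(out) == 0) return(dhs_empty())
  out |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::transmute(.data$chrom, .data$start, .data$end,
                     name = paste0("dhs_", dplyr::row_number()),
                     score = .data$score, strand = ".", summit = .data$summit)
}

dhs_empty <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = double(), strand = character(),
                 summit = integer())
}

#' Replicate-consistent peaks by reciprocal overlap
#'
#' Keeps peaks from replicate 1 that have a replicate-2 peak with reciprocal
#' overlap of at least `min_overlap_frac`; each kept peak is reported as the
#' union span of the matched pair. The Spearman rank correlation of matched
#' scores is attached as attribute `score_cor` as a consistency diagnostic.
#'
#' @param peaks1,peaks2 Peak tibbles from [call_dhs()], coordinate-sorted.
#' @param min_overlap_frac Minimum reciprocal overlap fraction (default 0.5).
#' @return Tibble of consistent peaks (non-overlapping, sorted), with
#'   attribute `score_cor`.
#' @export
replicate_consistency <- function(peaks1, peaks2, min_overlap_frac = 0.5) {
  hits <- interval_overlap_pairs(peaks1, peaks2)
  if (nrow(hits) > 0) {
    ro <- reciprocal_overlap(peaks1$start[hits$a], peaks1$end[hits$a],
                             peaks2$start[hits$b], peaks2$end[hits$b])
    hits <- hits[ro >= min_overlap_frac, ]
  }
  if (nrow(hits) == 0) {
    out <- dhs_empty()[, c("chrom", "start", "end", "name", "score", "strand")]
    attr(out, "score_cor") <- NA_real_
    return(out)
  }
  # best match per rep1 peak (largest reciprocal overlap)
  hits$ro <- reciprocal_overlap(peaks1$start[hits$a], peaks1$end[hits$a],
                                peaks2$start[hits$b], peaks2$end[hits$b])
  hits <- hits |>
    dplyr::group_by(.data$a) |>
    dplyr::slice_max(.data$ro, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  merged <- genomic_intervals(
    chrom = peaks1$chrom[hits$a],
    start = pmin(peaks1$start[hits$a], peaks2$start[hits$b]),
    end = pmax(peaks1$end[hits$a], peaks2$end[hits$b]),
    name = peaks1$name[hits$a],
    score = peaks1$score[hits$a]
  )
  merged <- interval_merge(merged) |>
    dplyr::mutate(name = paste0("cdhs_", dplyr::row_number()),
                  score = NA_real_)
  sc <- suppressWarnings(stats::cor(peaks1$score[hits$a], peaks2$score[hits$b],
                                    method = "spearman"))
  attr(merged, "score_cor") <- sc
  merged
}
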