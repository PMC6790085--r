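#' SPOT score (signal proportion of tags)
#'
#' Fraction of a uniform subsample of mapped reads that overlap a DNaseI-
#' hypersensitive site by at least 1 bp. Reads are subsampled without
#' replacement; the conventional subsample is 5 million reads, configurable
#' down for small libraries.
#'
#' @param reads Interval tibble of mapped reads.
#' @param dhs Interval tibble of DHSs (may be empty).
#' @param subsample Number of reads to subsample (capped at `nrow(reads)`).
#' @param seed Seed for the subsample.
#' @return Fraction in `[0, 1]`.
#' @export
spot_score <- function(reads, dhs, subsample = 5e6, seed = 1L) {
  if (nrow(reads) == 0) stop("SPOT score undefined for an empty read set", call. = FALSE)
  n <- min(subsample, nrow(reads))
  idx <- with_seed(seed, sample.int(nrow(reads), n))
  sub <- reads[idx, ]
  if (nrow(dhs) == 0) return(0)
  mean(interval_overlaps_any(sub, dhs))
}

#' PCR bottleneck coefficient (PBC1)
#'
#' `N1 / Ndistinct`: the number of genomic positions covered by exactly one
#' read 5' end divided by the number of positions covered by at least one.
#' Positions are (chrom, strand, 5' coordinate) triples.
#'
#' @param reads Interval tibble of mapped reads with `strand`.
#' @return Fraction in `[0, 1]`.
#' @export
pbc1 <- function(reads) {
  if (nrow(reads) == 0) stop("PBC undefined for an empty read set", call. = FALSE)
  five_prime <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  key <- paste(reads$chrom, reads$strand, five_prime)
  tab <- table(key)
  sum(tab == 1) / length(tab)
}

#' Library-quality report
#'
#' @inheritParams spot_score
#' @return A `qc_report` list with `spot`, `pbc1`, `n_reads_used`,
#'   `subsample_size`.
#' @export
qc_report <- function(reads, dhs, subsample = 5e6, seed = 1L) {
  structure(list(
    spot = spot_score(reads, dhs, subsample, seed),
    pbc1 = pbc1(reads),
    n_reads_used = nrow(reads),
    subsample_size = as.integer(min(subsample, nrow(reads)))
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> SPOT %.4f | PBC1 %.4f | reads %d (subsample %d)\n",
              x$spot, x$pbc1, x$n_reads_used, x$subsample_size))
  invisible(x)
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(spot = x$spot, pbc1 = x$pbc1, n_reads_used = x$n_reads_used,
                 subsample_size = x$subsample_size)
}
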