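FEATURE_LEVELS <- c("five_prime_utr", "cds_exon", "intron", "three_prime_utr",
                    "promoter", "downstream", "intergenic")

#' Classify regions against gene models
#'
#' Each region is assigned exactly one feature label by its midpoint:
#' `five_prime_utr`, `cds_exon`, `intron`, `three_prime_utr` (genic, in that
#' precedence), then `promoter` (up to 2000 bp upstream of the TSS,
#' strand-aware), then `downstream` (up to 1000 bp past the TTS), else
#' `intergenic`. When several genes offer a label of the same precedence the
#' gene with the nearest TSS wins (ties by gene id).
#'
#' @param regions Interval tibble.
#' @param genes Gene-model tibble.
#' @param promoter_bp Promoter extent upstream of the TSS (default 2000).
#' @param downstream_bp Downstream extent past the TTS (default 1000).
#' @return `regions` with added columns `feature` (factor) and `feature_gene`.
#' @export
classify_regions <- function(regions, genes, promoter_bp = 2000L, downstream_bp = 1000L) {
  mids <- interval_midpoint(regions)
  feats <- gene_feature_table(genes, promoter_bp, downstream_bp)
  labs <- character(nrow(regions))
  gids <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- feats[feats$chrom == regions$chrom[i] &
                   feats$start <= mids[i] & feats$end > mids[i], ]
    if (nrow(hit) == 0) {
      labs[i] <- "intergenic"
      gids[i] <- NA_character_
      next
    }
    hit$rank <- match(hit$feature, FEATURE_LEVELS)
    hit$tss_dist <- abs(mids[i] - hit$tss)
    hit <- hit[order(hit$rank, hit$tss_dist, hit$gene_id), ]
    labs[i] <- hit$feature[1]
    gids[i] <- hit$gene_id[1]
  }
  regions$feature <- factor(labs, levels = FEATURE_LEVELS)
  regions$feature_gene <- gids
  regions
}

# flat table of labelled feature intervals for all genes
gene_feature_table <- function(genes, promoter_bp, downstream_bp) {
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    parts <- list(
      five_prime_utr = gene_utr(g, five_prime = TRUE),
      cds_exon = g$cds[[1]],
      three_prime_utr = gene_utr(g, five_prime = FALSE),
      intron = {
        ex <- g$exons[[1]]
        if (nrow(ex) < 2) tibble::tibble(start = integer(), end = integer())
        else tibble::tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
      },
      promoter = if (g$strand == "+") {
        tibble::tibble(start = max(0L, g$start - promoter_bp), end = g$start)
      } else {
        tibble::tibble(start = g$end, end = g$end + promoter_bp)
      },
      downstream = if (g$strand == "+") {
        tibble::tibble(start = g$end, end = g$end + downstream_bp)
      } else {
        tibble::tibble(start = max(0L, g$start - downstream_bp), end = g$start)
      }
    )
    dplyr::bind_rows(purrr::imap(parts, function(iv, nm) {
      if (nrow(iv) == 0) return(NULL)
      tibble::tibble(chrom = g$chrom, start = iv$start, end = iv$end,
                     feature = nm, gene_id = g$gene_id, tss = g$tss)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Distribution of regions across genomic feature classes
#'
#' @inheritParams classify_regions
#' @return Tibble `feature, n, fraction`; counts sum to `nrow(regions)` and
#'   fractions to 1.
#' @export
feature_distribution <- function(regions, genes, promoter_bp = 2000L,
                                 downstream_bp = 1000L) {
  if (nrow(regions) == 0) {
    return(tibble::tibble(feature = factor(FEATURE_LEVELS, levels = FEATURE_LEVELS),
                          n = 0L, fraction = 0))
  }
  cls <- classify_regions(regions, genes, promoter_bp, downstream_bp)
  tab <- table(cls$feature)
  tibble::tibble(
    feature = factor(names(tab), levels = FEATURE_LEVELS),
    n = as.integer(tab),
    fraction = as.integer(tab) / nrow(regions)
  )
}

#' Region density relative to the nearest TSS
#'
#' Signed, strand-aware distance (negative upstream of the TSS) from each
#' region midpoint to the nearest gene TSS, binned; density is normalized
#' per kb and per region.
#'
#' @inheritParams classify_regions
#' @param window_kb Half-window around the TSS in kb.
#' @param bin_bp Bin width in bp.
#' @return Tibble `bin_start, bin_mid, n, density` (regions per kb per
#'   region).
#' @export
tss_density <- function(regions, genes, window_kb = 5, bin_bp = 200L) {
  stopifnot(window_kb > 0, nrow(genes) > 0)
  mids <- interval_midpoint(regions)
  dist <- vapply(seq_len(nrow(regions)), function(i) {
    g <- genes[genes$chrom == regions$chrom[i], ]
    if (nrow(g) == 0) return(NA_real_)
    d <- mids[i] - g$tss
    j <- which.min(abs(d))
    # negative means upstream of the gene
    if (g$strand[j] == "+") d[j] else -d[j]
  }, numeric(1))
  W <- window_kb * 1000
  breaks <- seq(-W, W, by = bin_bp)
  inside <- !is.na(dist) & dist >= -W & dist < W
  h <- hist(dist[inside], breaks = breaks, plot = FALSE)
  out <- tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_mid = breaks[-length(breaks)] + bin_bp / 2,
    n = h$counts
  )
  out$density <- if (nrow(regions) > 0) {
    out$n / (bin_bp / 1000) / nrow(regions)
  } else 0
  structure(out, class = c("tss_density", class(out)))
}
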