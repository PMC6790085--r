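#' Gene-model tibbles
#'
#' A gene model table has one row per gene: `gene_id`, `chrom`, `strand`,
#' `start`, `end` (transcript span, 0-based half-open), derived `tss`/`tts`
#' (0-based positions of the first/last transcribed base, strand-aware), the
#' reading-frame `phase` of the first CDS base, and list-columns `exons` and
#' `cds`, each a tibble of `start`, `end` sorted by genomic coordinate.
#'
#' @param gene_id,chrom,strand,start,end Scalars describing the gene.
#' @param exons,cds Tibbles with `start`, `end` columns (genomic order).
#' @param phase Phase (0/1/2) of the first CDS base in translation order.
#' @return One-row gene-model tibble.
#' @export
gene_model_row <- function(gene_id, chrom, strand, start, end, exons, cds, phase = 0L) {
  tss <- if (strand == "+") start else end - 1L
  tts <- if (strand == "+") end - 1L else start
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    tss = as.integer(tss), tts = as.integer(tts), phase = as.integer(phase),
    exons = list(tibble::tibble(start = as.integer(exons$start),
                                end = as.integer(exons$end))),
    cds = list(tibble::tibble(start = as.integer(cds$start),
                              end = as.integer(cds$end)))
  )
}

empty_gene_models <- function() {
  gene_model_row("x", "x", "+", 0L, 1L, tibble::tibble(start = 0L, end = 1L),
                 tibble::tibble(start = integer(), end = integer()))[0, ]
}

#' Validate a gene-model tibble
#'
#' Exons must be sorted and non-overlapping; CDS bases must be a subset of
#' exon bases; TSS/TTS must respect strand.
#' @param genes Gene-model tibble.
#' @export
validate_gene_models <- function(genes) {
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    cd <- genes$cds[[i]]
    if (nrow(ex) == 0) stop("gene ", genes$gene_id[i], ": no exons", call. = FALSE)
    if (is.unsorted(ex$start) || any(ex$end[-nrow(ex)] > ex$start[-1])) {
      stop("gene ", genes$gene_id[i], ": exons unsorted or overlapping", call. = FALSE)
    }
    if (nrow(cd) > 0) {
      within <- vapply(seq_len(nrow(cd)), function(j) {
        any(ex$start <= cd$start[j] & ex$end >= cd$end[j])
      }, logical(1))
      if (!all(within)) stop("gene ", genes$gene_id[i], ": CDS outside exons",
                             call. = FALSE)
    }
  }
  genes
}

#' Interval tibble of one feature across all genes
#' @param genes Gene-model tibble.
#' @param what `"exons"`, `"cds"`, `"introns"`, `"utr5"` or `"utr3"`.
#' @return Interval tibble with a `name` column of gene ids.
#' @export
gene_feature_intervals <- function(genes, what = c("exons", "cds", "introns", "utr5", "utr3")) {
  what <- match.arg(what)
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    iv <- switch(
      what,
      exons = g$exons[[1]],
      cds = g$cds[[1]],
      introns = {
        ex <- g$exons[[1]]
        if (nrow(ex) < 2) tibble::tibble(start = integer(), end = integer())
        else tibble::tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
      },
      utr5 = gene_utr(g, five_prime = TRUE),
      utr3 = gene_utr(g, five_prime = FALSE)
    )
    if (nrow(iv) == 0) return(NULL)
    tibble::tibble(chrom = g$chrom, start = iv$start, end = iv$end,
                   name = g$gene_id, score = NA_real_, strand = g$strand)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_intervals() else out
}

# UTR bases = exon bases outside [cds_start, cds_end), 5'/3' by strand
gene_utr <- function(g, five_prime) {
  ex <- g$exons[[1]]
  cd <- g$cds[[1]]
  if (nrow(cd) == 0) return(tibble::tibble(start = integer(), end = integer()))
  cs <- min(cd$start)
  ce <- max(cd$end)
  left <- tibble::tibble(start = pmin(ex$start, cs), end = pmin(ex$end, cs))
  left <- left[left$start < left$end, ]
  right <- tibble::tibble(start = pmax(ex$start, ce), end = pmax(ex$end, ce))
  right <- right[right$start < right$end, ]
  want_left <- (g$strand == "+") == five_prime
  if (want_left) left else right
}

#' Per-gene CDS coordinate map
#'
#' Maps each CDS base to its genomic position in translation order (5' to 3'
#' of the coding strand). Used by FFDS enumeration and variant classification.
#' @param g One-row gene-model tibble.
#' @return Integer vector of 0-based genomic positions; element `k` is the
#'   k-th coding base. The first `phase` bases of a partial codon are skipped.
#' @export
cds_genomic_positions <- function(g) {
  cd <- g$cds[[1]]
  if (nrow(cd) == 0) return(integer())
  pos <- unlist(lapply(seq_len(nrow(cd)), function(j) cd$start[j]:(cd$end[j] - 1L)))
  if (g$strand == "-") pos <- rev(pos)
  if (g$phase > 0) pos <- pos[-seq_len(g$phase)]
  pos
}

#' Coding sequence of a gene
#' @param g One-row gene-model tibble.
#' @param assembly A [genome_assembly()].
#' @return Character scalar: the coding-strand CDS sequence in translation
#'   order (phase-trimmed).
#' @export
coding_sequence <- function(g, assembly) {
  cd <- g$cds[[1]]
  if (nrow(cd) == 0) return("")
  segs <- assembly_seq(assembly, rep(g$chrom, nrow(cd)), cd$start, cd$end)
  s <- paste0(segs, collapse = "")
  if (g$strand == "-") s <- revcomp(s)
  if (g$phase > 0) s <- substring(s, g$phase + 1)
  s
}
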