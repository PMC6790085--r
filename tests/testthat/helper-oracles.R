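# Independent brute-force oracles used to validate the package's vectorized
# implementations. These deliberately share no code with the package paths
# they check.

# O(n*m) pairwise overlap check
oracle_overlap_any <- function(a, b, min_overlap = 1L) {
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
}

# binomial upper tail by direct summation of the pmf
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

# FFDS by trying all three substitutions at every CDS base and translating
oracle_ffds <- function(genes, assembly) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    pos <- cds_genomic_positions(g)
    if (length(pos) %% 3 != 0) next
    cseq <- strsplit(coding_sequence(g, assembly), "")[[1]]
    for (b in seq_along(cseq)) {
      cstart <- 3 * ((b - 1) %/% 3) + 1
      codon <- paste0(cseq[cstart:(cstart + 2)], collapse = "")
      if (grepl("N", codon)) next
      inpos <- b - cstart + 1
      all_syn <- TRUE
      for (alt in setdiff(bases, cseq[b])) {
        mut <- codon
        substr(mut, inpos, inpos) <- alt
        if (code[[mut]] != code[[codon]]) {
          all_syn <- FALSE
          break
        }
      }
      if (all_syn) {
        out[[length(out) + 1L]] <- data.frame(chrom = g$chrom, pos = pos[b])
      }
    }
  }
  if (length(out) == 0) return(data.frame(chrom = character(), pos = integer()))
  do.call(rbind, out)
}

# Kendall tau-b by explicit pair counting
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Pearson chi-square from first principles
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# hypergeometric upper tail by direct summation
oracle_hyper_upper <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# midpoint feature classification by exhaustive feature enumeration
oracle_classify <- function(region, genes, promoter_bp = 2000, downstream_bp = 1000) {
  mid <- floor((region$start + region$end) / 2)
  prec <- c("five_prime_utr", "cds_exon", "intron", "three_prime_utr",
            "promoter", "downstream")
  found <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != region$chrom) next
    inside <- function(iv) any(iv$start <= mid & iv$end > mid)
    labs <- character()
    if (inside(gene_utr(g, TRUE))) labs <- c(labs, "five_prime_utr")
    if (inside(g$cds[[1]])) labs <- c(labs, "cds_exon")
    ex <- g$exons[[1]]
    if (nrow(ex) > 1 &&
        inside(data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1]))) {
      labs <- c(labs, "intron")
    }
    if (inside(gene_utr(g, FALSE))) labs <- c(labs, "three_prime_utr")
    prom <- if (g$strand == "+") c(g$start - promoter_bp, g$start) else c(g$end, g$end + promoter_bp)
    if (prom[1] <= mid && mid < prom[2]) labs <- c(labs, "promoter")
    dn <- if (g$strand == "+") c(g$end, g$end + downstream_bp) else c(g$start - downstream_bp, g$start)
    if (dn[1] <= mid && mid < dn[2]) labs <- c(labs, "downstream")
    for (l in labs) {
      found[[length(found) + 1L]] <- data.frame(lab = l, tss_dist = abs(mid - g$tss))
    }
  }
  if (length(found) == 0) return("intergenic")
  f <- do.call(rbind, found)
  f$rank <- match(f$lab, prec)
  f <- f[order(f$rank, f$tss_dist), ]
  f$lab[1]
}

# recall/precision of footprint calls vs truth (center within `tol` bp)
match_footprints <- function(calls, truth, tol = 10) {
  if (nrow(truth) == 0 || nrow(calls) == 0) {
    return(list(recall = NA_real_, precision = NA_real_))
  }
  cc <- (calls$start + calls$end) / 2
  tc <- (truth$start + truth$end) / 2
  recall <- mean(vapply(seq_len(nrow(truth)), function(i) {
    any(calls$chrom == truth$chrom[i] & abs(cc - tc[i]) <= tol)
  }, logical(1)))
  precision <- mean(vapply(seq_len(nrow(calls)), function(i) {
    any(truth$chrom == calls$chrom[i] & abs(tc - cc[i]) <= tol)
  }, logical(1)))
  list(recall = recall, precision = precision)
}
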