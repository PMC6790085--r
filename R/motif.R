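#' Position weight matrix
#'
#' Wraps a 4 x L position frequency (count) matrix with an id. Log-odds
#' scores against a 0-order background are derived at scan time with a
#' pseudocount, so the same motif can be scanned against different
#' backgrounds.
#'
#' @param id Motif identifier.
#' @param counts 4 x L numeric matrix (rows A, C, G, T), counts >= 0.
#' @return A `pwm` object.
#' @export
pwm <- function(id, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PFM must have 4 rows (A,C,G,T)", call. = FALSE)
  if (any(counts < 0)) stop("PFM counts must be >= 0", call. = FALSE)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(id = id, counts = counts), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$id, " (", ncol(x$counts), " positions), consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus string of a PWM (most frequent base per column)
#' @param p A `pwm`.
#' @export
pwm_consensus <- function(p) {
  paste0(c("A", "C", "G", "T")[apply(p$counts, 2, which.max)], collapse = "")
}

#' Build a PWM from a consensus string
#' @param id Motif id.
#' @param consensus DNA string.
#' @param weight Count given to the consensus base per column (others get 1).
#' @export
consensus_pwm <- function(id, consensus, weight = 20) {
  b <- strsplit(toupper(consensus), "")[[1]]
  m <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(b, c("A", "C", "G", "T")), seq_along(b))] <- weight
  pwm(id, m)
}

# log-odds matrix and per-column score support for a background composition
pwm_logodds <- function(p, background, pseudocount = 0.1) {
  probs <- sweep(p$counts + pseudocount, 2, colSums(p$counts + pseudocount), "/")
  log2(probs / background)
}

#' Exact null distribution of PWM scores
#'
#' Dynamic programming over motif columns: the per-column score distribution
#' under the 0-order background is convolved across positions, with scores
#' discretized to `bin`-wide steps. Returns a function mapping a score to
#' its exact upper-tail p-value `P(S >= s)` under the background.
#'
#' @param lo Log-odds matrix (4 x L).
#' @param background Background base probabilities (A, C, G, T).
#' @param bin Score discretization (default 1e-3).
#' @return Function `score -> p`.
#' @export
pwm_null_distribution <- function(lo, background, bin = 1e-3) {
  q <- round(lo / bin)
  offset <- -sum(apply(q, 2, min))
  dist <- 1 # probability mass over shifted integer scores, index 1 = min score
  for (j in seq_len(ncol(q))) {
    col <- q[, j] - min(q[, j])
    width <- max(col)
    new <- numeric(length(dist) + width)
    for (b in 1:4) {
      sh <- col[b]
      new[(1 + sh):(length(dist) + sh)] <- new[(1 + sh):(length(dist) + sh)] +
        dist * background[b]
    }
    dist <- new
  }
  sf <- rev(cumsum(rev(dist))) # P(shifted score >= k)
  function(score) {
    k <- round(score / bin) + offset + 1
    k <- pmin(pmax(k, 1), length(sf) + 1)
    ifelse(k > length(sf), 0, sf[pmax(k, 1)])
  }
}

#' Scan sequences or regions with a PWM
#'
#' Scores every position on both strands with the motif's log-odds against a
#' 0-order background (the scanned set's base composition unless supplied),
#' and reports matches whose exact null p-value is at or below `p_thresh`.
#'
#' @param regions Interval tibble (requires `assembly`) or `NULL`.
#' @param assembly A [genome_assembly()] (with `regions`).
#' @param sequences Alternatively, a character vector of sequences.
#' @param p A `pwm`.
#' @param p_thresh Match p-value threshold (default 1e-4).
#' @param background Optional background probabilities (A,C,G,T).
#' @param pseudocount PWM pseudocount per cell (default 0.1).
#' @return Tibble of hits: `seq_index, chrom, start, end, strand, motif,
#'   score, p`. Coordinates are genomic when regions are scanned, else
#'   0-based within each sequence.
#' @export
scan_pwm <- function(p, regions = NULL, assembly = NULL, sequences = NULL,
                     p_thresh = 1e-4, background = NULL, pseudocount = 0.1) {
  if (is.null(sequences)) {
    stopifnot(!is.null(regions), !is.null(assembly))
    sequences <- assembly_seq(assembly, regions$chrom, regions$start, regions$end)
  }
  L <- ncol(p$counts)
  if (is.null(background)) {
    all_b <- table(factor(strsplit(paste0(sequences, collapse = ""), "")[[1]],
                          levels = c("A", "C", "G", "T")))
    background <- as.numeric(all_b) / sum(all_b)
    background[background == 0] <- 1e-6
    background <- background / sum(background)
  }
  lo <- pwm_logodds(p, background, pseudocount)
  pfun <- pwm_null_distribution(lo, background)
  hits <- list()
  for (si in seq_along(sequences)) {
    s <- sequences[si]
    if (nchar(s) < L) next
    code <- base_codes(s)
    n <- nchar(s) - L + 1L
    sc_f <- numeric(n)
    sc_r <- numeric(n)
    lo_rc <- lo[4:1, L:1] # scanning reverse strand = RC'd matrix on forward seq
    ok <- rep(TRUE, n)
    for (j in seq_len(L)) {
      cj <- code[j:(j + n - 1L)]
      ok <- ok & !is.na(cj)
      cj[is.na(cj)] <- 1L
      sc_f <- sc_f + lo[cbind(cj + 1L, j)]
      sc_r <- sc_r + lo_rc[cbind(cj + 1L, j)]
    }
    for (str in c("+", "-")) {
      sc <- if (str == "+") sc_f else sc_r
      pv <- pfun(sc)
      m <- which(ok & pv <= p_thresh)
      if (length(m) > 0) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          seq_index = si, offset = m - 1L, strand = str,
          motif = p$id, score = sc[m], p = pv[m]
        )
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(seq_index = integer(), chrom = character(),
                          start = integer(), end = integer(), strand = character(),
                          motif = character(), score = double(), p = double()))
  }
  if (!is.null(regions)) {
    out$chrom <- regions$chrom[out$seq_index]
    out$start <- regions$start[out$seq_index] + out$offset
  } else {
    out$chrom <- NA_character_
    out$start <- out$offset
  }
  out$end <- out$start + L
  out[, c("seq_index", "chrom", "start", "end", "strand", "motif", "score", "p")]
}

#' Annotate footprints with motif hits
#'
#' Scans each footprint with every motif in the library; a footprint is
#' annotated when at least one hit overlaps it.
#'
#' @param dgfs Interval tibble of footprints.
#' @param motifs List of `pwm` objects.
#' @param assembly A [genome_assembly()].
#' @param p_thresh Match threshold (default 1e-4).
#' @param flank Bases of context added around each footprint before scanning
#'   (default 5), so motifs on the footprint edge are still found.
#' @return List: `hits` tibble, `per_dgf` tibble (`name`, `motifs`,
#'   `annotated`), `annotated_fraction` (NA for an empty footprint set).
#' @export
annotate_dgfs <- function(dgfs, motifs, assembly, p_thresh = 1e-4, flank = 5L) {
  if (nrow(dgfs) == 0) {
    return(list(hits = NULL, per_dgf = NULL, annotated_fraction = NA_real_))
  }
  if (length(motifs) == 0) {
    return(list(hits = NULL,
                per_dgf = tibble::tibble(name = region_names(dgfs),
                                         motifs = "", annotated = FALSE),
                annotated_fraction = 0))
  }
  lens <- assembly_lengths(assembly)
  scan_regions <- dgfs
  scan_regions$start <- pmax(0L, dgfs$start - flank)
  scan_regions$end <- pmin(lens[dgfs$chrom], dgfs$end + flank)
  hits <- dplyr::bind_rows(lapply(motifs, scan_pwm, regions = scan_regions,
                                  assembly = assembly, p_thresh = p_thresh))
  annotated <- rep(FALSE, nrow(dgfs))
  per_motifs <- rep("", nrow(dgfs))
  if (nrow(hits) > 0) {
    ov <- hits$start < dgfs$end[hits$seq_index] & hits$end > dgfs$start[hits$seq_index]
    hits <- hits[ov, ]
    agg <- hits |>
      dplyr::group_by(.data$seq_index) |>
      dplyr::summarise(motifs = paste(sort(unique(.data$motif)), collapse = ","))
    annotated[agg$seq_index] <- TRUE
    per_motifs[agg$seq_index] <- agg$motifs
  }
  list(
    hits = hits,
    per_dgf = tibble::tibble(name = region_names(dgfs), motifs = per_motifs,
                             annotated = annotated),
    annotated_fraction = mean(annotated)
  )
}

region_names <- function(x) {
  if ("name" %in% names(x) && !all(is.na(x$name))) x$name
  else paste0(x$chrom, ":", x$start, "-", x$end)
}

#' Simplified de novo motif discovery (k-mer seed and extend)
#'
#' Counts k-mers on both strands in foreground and background sequence sets
#' (reverse-complement pairs merged onto a canonical form), tests each
#' foreground count against the background rate with a one-sided binomial
#' test, BH-adjusts, and turns the top seeds into PWMs from their aligned
#' foreground occurrences extended by 2 bp of context.
#'
#' @param foreground,background Character vectors of DNA sequences.
#' @param k_range k-mer sizes searched (default 6:10).
#' @param top_n Maximum number of seeds reported (default 5).
#' @param q_thresh BH threshold for reported motifs (default 0.01).
#' @return List of `pwm` objects, ranked by seed significance, each with
#'   attributes `seed`, `p`, `q`.
#' @export
denovo_motifs <- function(foreground, background, k_range = 6:10, top_n = 5L,
                          q_thresh = 0.01) {
  if (length(foreground) < 50) stop("need >= 50 foreground sequences", call. = FALSE)
  if (sum(nchar(background)) < sum(nchar(foreground))) {
    warning("background smaller than foreground; rates will be noisy", call. = FALSE)
  }
  seeds <- list()
  for (k in k_range) {
    fg <- canonical_kmer_counts(foreground, k)
    bg <- canonical_kmer_counts(background, k)
    shared <- names(fg)
    nf <- sum(fg)
    rate <- (bg[shared] + 1) / (sum(bg) + length(bg))
    rate[is.na(rate)] <- 1 / (sum(bg) + length(bg))
    pv <- stats::pbinom(fg - 1, nf, rate, lower.tail = FALSE)
    seeds[[length(seeds) + 1L]] <- tibble::tibble(
      kmer = shared, k = k, count = as.integer(fg), p = as.numeric(pv)
    )
  }
  seeds <- dplyr::bind_rows(seeds)
  seeds$q <- stats::p.adjust(seeds$p, method = "BH")
  seeds <- seeds[seeds$q < q_thresh, ]
  if (nrow(seeds) == 0) return(list())
  seeds <- seeds[order(seeds$p, -seeds$count, seeds$kmer), ]
  # drop seeds contained in (or containing) an already-accepted stronger seed
  chosen <- list()
  for (i in seq_len(nrow(seeds))) {
    km <- seeds$kmer[i]
    redundant <- any(vapply(chosen, function(ch) {
      grepl(km, ch$kmer, fixed = TRUE) || grepl(ch$kmer, km, fixed = TRUE) ||
        grepl(revcomp(km), ch$kmer, fixed = TRUE) ||
        grepl(ch$kmer, revcomp(km), fixed = TRUE)
    }, logical(1)))
    if (!redundant) chosen[[length(chosen) + 1L]] <- seeds[i, ]
    if (length(chosen) >= top_n) break
  }
  purrr::imap(chosen, function(sd, i) {
    m <- seed_to_pwm(sd$kmer, foreground, flank = 2L)
    p <- pwm(paste0("denovo_", i, "_", sd$kmer), m)
    attr(p, "seed") <- sd$kmer
    attr(p, "p") <- sd$p
    attr(p, "q") <- sd$q
    p
  })
}

# canonical (min of kmer, revcomp) k-mer counts over both strands
canonical_kmer_counts <- function(seqs, k) {
  ss <- Biostrings::DNAStringSet(seqs[nchar(seqs) >= k])
  if (length(ss) == 0) return(stats::setNames(integer(0), character(0)))
  cnt <- colSums(Biostrings::oligonucleotideFrequency(ss, width = k, step = 1L))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(names(cnt))))
  both <- cnt + cnt[rc]
  canon <- pmin(names(cnt), rc)
  keep <- names(cnt) == canon
  both[keep]
}

# align all foreground occurrences of a seed (either strand) into a count matrix
seed_to_pwm <- function(seed, seqs, flank = 2L) {
  k <- nchar(seed)
  w <- k + 2L * flank
  counts <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  rc_seed <- revcomp(seed)
  for (s in seqs) {
    for (pat in unique(c(seed, rc_seed))) {
      occ <- gregexpr(pat, s, fixed = TRUE)[[1]]
      if (occ[1] == -1) next
      for (o in occ) {
        frag_start <- o - flank
        frag <- substring(s, max(1, frag_start), min(nchar(s), o + k - 1 + flank))
        if (pat == rc_seed) frag <- revcomp(frag)
        off <- if (pat == rc_seed) {
          # right-flank truncation becomes left offset after RC
          flank - (min(nchar(s), o + k - 1 + flank) - (o + k - 1))
        } else {
          flank - (o - max(1, frag_start))
        }
        b <- strsplit(frag, "")[[1]]
        for (j in seq_along(b)) {
          col <- j + off
          if (col >= 1 && col <= w && b[j] %in% rownames(counts)) {
            counts[b[j], col] <- counts[b[j], col] + 1
          }
        }
      }
    }
  }
  counts
}

#' Hypergeometric motif enrichment in a footprint subset
#'
#' For each motif annotated in `K` of the `N` universe footprints and `k` of
#' the `n` subset footprints, the upper-tail hypergeometric p-value
#' `P(X >= k)` is computed; BH q-values are attached and motifs at
#' `p < p_thresh` flagged enriched.
#'
#' @param subset_names,universe_names Footprint identifiers (subset must be
#'   contained in the universe).
#' @param annotations Tibble `name, motif` of motif annotations per
#'   footprint (one row per pair).
#' @param p_thresh Enrichment threshold (default 0.001).
#' @return Tibble `motif, K, k, N, n, p, q, enriched`.
#' @export
motif_enrichment <- function(subset_names, universe_names, annotations,
                             p_thresh = 0.001) {
  if (!all(subset_names %in% universe_names)) {
    stop("subset is not contained in the universe", call. = FALSE)
  }
  N <- length(unique(universe_names))
  n <- length(unique(subset_names))
  ann <- annotations[annotations$name %in% universe_names, ]
  ann <- dplyr::distinct(ann, .data$name, .data$motif)
  per <- ann |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$name),
                     k = dplyr::n_distinct(.data$name[.data$name %in% subset_names]))
  per$N <- N
  per$n <- n
  per$p <- stats::phyper(per$k - 1, per$K, N - per$K, n, lower.tail = FALSE)
  per$q <- stats::p.adjust(per$p, method = "BH")
  per$enriched <- per$p < p_thresh
  dplyr::arrange(per, .data$p)
}

#' Kendall rank correlation of motif frequency vectors
#'
#' Motifs are ranked by frequency in each sample; agreement is summarized by
#' Kendall's tau-b (tie-corrected), with a p-value from the normal
#' approximation when ties are present (exact otherwise).
#'
#' @param freq_a,freq_b Named numeric vectors of per-motif frequencies.
#' @return Tibble `tau, p, n_motifs`.
#' @export
rank_correlation <- function(freq_a, freq_b) {
  shared <- intersect(names(freq_a), names(freq_b))
  if (length(shared) < 2) stop("need >= 2 shared motifs", call. = FALSE)
  ht <- suppressWarnings(stats::cor.test(freq_a[shared], freq_b[shared],
                                         method = "kendall"))
  tibble::tibble(tau = unname(ht$estimate), p = ht$p.value,
                 n_motifs = length(shared))
}
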