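#' Hexamer bias table
#'
#' Relative cleavage preference for each of the 4096 DNA hexamers: the
#' frequency of the hexamer among cleavage-site contexts divided by its
#' frequency in the genome (both strands), after adding a pseudocount to
#' both. Entries whose hexamer never occurs (or contains N) are NA and are
#' treated as preference 1 where the table is applied.
#'
#' @param preference Named numeric vector of length 4096 (names = hexamers in
#'   lexicographic order).
#' @param cleavage_freq Optional normalized cleavage-context frequencies
#'   (sum 1).
#' @param pseudocount Pseudocount used during estimation.
#' @return A `hexamer_bias` object.
#' @export
hexamer_bias <- function(preference, cleavage_freq = NULL, pseudocount = NA_real_) {
  stopifnot(length(preference) == N_HEX)
  if (is.null(names(preference))) names(preference) <- hexamer_names()
  if (any(preference <= 0, na.rm = TRUE)) stop("bias preferences must be > 0", call. = FALSE)
  structure(list(preference = preference, cleavage_freq = cleavage_freq,
                 pseudocount = pseudocount), class = "hexamer_bias")
}

#' @export
print.hexamer_bias <- function(x, ...) {
  cat("<hexamer_bias> 4096 hexamers, preference range [",
      sprintf("%.3f", min(x$preference, na.rm = TRUE)), ", ",
      sprintf("%.3f", max(x$preference, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' Estimate hexamer cleavage bias from a naked-DNA profile
#'
#' For every cleavage event at position `c` on strand `s`, the hexamer
#' covering offsets `[c-3, c+3)` on that strand (reverse-complemented window
#' for minus-strand cuts) is counted, weighted by the cut count, so the
#' cleavage falls between the hexamer's third and fourth bases. Counts are
#' normalized to frequencies (sum 1), then divided by the genome's hexamer
#' frequencies over both strands; a pseudocount is added to both numerator
#' and genome counts. Hexamers never observed in the genome (e.g. windows
#' containing N only) get NA.
#'
#' @param naked A `cut_profile` from deproteinized DNA.
#' @param assembly The matching [genome_assembly()].
#' @param pseudocount Pseudocount added to cut and genome hexamer counts.
#' @return A `hexamer_bias`.
#' @export
estimate_bias <- function(naked, assembly, pseudocount = 1) {
  if (!setequal(names(naked$chroms), names(assembly$sequences))) {
    stop("profile and assembly chromosomes do not match", call. = FALSE)
  }
  cut_counts <- numeric(N_HEX)
  for (ch in names(naked$chroms)) {
    ctx <- hexamer_context(assembly$sequences[[ch]])
    pv <- naked$chroms[[ch]]$plus
    mv <- naked$chroms[[ch]]$minus
    ip <- !is.na(ctx$plus) & pv > 0
    im <- !is.na(ctx$minus) & mv > 0
    cut_counts <- cut_counts +
      as.numeric(unname(tapply2(ctx$plus[ip], pv[ip]))) +
      as.numeric(unname(tapply2(ctx$minus[im], mv[im])))
  }
  cleavage_freq <- (cut_counts) / sum(cut_counts)
  genome_counts <- genome_hexamer_counts(assembly)
  genome_freq <- (genome_counts + pseudocount) / sum(genome_counts + pseudocount)
  pref <- (cut_counts + pseudocount) / sum(cut_counts + pseudocount) / genome_freq
  pref[genome_counts == 0] <- NA_real_
  hexamer_bias(stats::setNames(pref, hexamer_names()),
               cleavage_freq = stats::setNames(cleavage_freq, hexamer_names()),
               pseudocount = pseudocount)
}

# weighted tabulate over 1..4096
tapply2 <- function(idx, w) {
  out <- numeric(N_HEX)
  agg <- rowsum(as.numeric(w), group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Strand-imbalance footprint score for one candidate window
#'
#' The footprint statistic: on the plus strand, cuts in the upstream shoulder
#' (`F`) are tested against cuts inside the candidate footprint (`f`) with a
#' one-sided binomial test, `p_fwd = P(X >= F)`,
#' `X ~ Binomial(F + f, shoulder_len / (shoulder_len + fp_len))`; the minus
#' strand is tested symmetrically with the downstream shoulder. The score is
#' `-(log10 p_fwd + log10 p_rev)`. A strand with no cuts in shoulder or
#' footprint contributes p = 1 (no evidence).
#'
#' @param plus,minus Integer cut vectors covering
#'   `[fp_start - shoulder_len, fp_start + fp_len + shoulder_len)`; element 1
#'   is the first shoulder base.
#' @param fp_len Footprint length.
#' @param shoulder_len Shoulder length.
#' @return List with `score`, `p_fwd`, `p_rev`.
#' @export
wellington_candidate_score <- function(plus, minus, fp_len, shoulder_len) {
  stopifnot(length(plus) == fp_len + 2 * shoulder_len,
            length(minus) == fp_len + 2 * shoulder_len)
  Fu <- sum(plus[seq_len(shoulder_len)])
  f <- sum(plus[shoulder_len + seq_len(fp_len)])
  Rd <- sum(minus[shoulder_len + fp_len + seq_len(shoulder_len)])
  r <- sum(minus[shoulder_len + seq_len(fp_len)])
  pr <- shoulder_len / (shoulder_len + fp_len)
  p_fwd <- binom_upper_tail(Fu, Fu + f, pr)
  p_rev <- binom_upper_tail(Rd, Rd + r, pr)
  list(score = -(log10(p_fwd) + log10(p_rev)), p_fwd = p_fwd, p_rev = p_rev)
}

# P(X >= k), X ~ Binomial(n, p); k = 0 or n = 0 give 1
binom_upper_tail <- function(k, n, p) {
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Call footprints inside DHSs
#'
#' Every start and footprint length in `fp_len_range` within each DHS is
#' scored with [wellington_candidate_score()] (best score over the shoulder
#' set); the two strand p-values are combined by Fisher's method
#' (chi-square, 4 df) into one p per candidate. Candidates are reduced to a
#' non-overlapping set by greedy selection in descending score order (ties
#' to the leftmost start). Because each selected region is the best of the
#' hundreds of overlapping (start, width) candidates it was maximized over,
#' its p-value is Sidak-corrected for that search space before
#' Benjamini-Hochberg adjustment across regions; regions at `q <= fdr` are
#' retained.
#'
#' @param dhs Peak tibble (e.g. from [call_dhs()]).
#' @param profile A `cut_profile` on the same assembly.
#' @param fp_len_range Footprint widths searched (default 11:25).
#' @param shoulders Set of shoulder lengths (default 35).
#' @param fdr BH false-discovery-rate threshold (default 0.01).
#' @param prefilter Raw combined-p cap applied before greedy selection;
#'   candidates above it can never survive the corrected threshold.
#' @return Tibble of footprint calls: `chrom, start, end, name, score,
#'   strand, p_fwd, p_rev, combined_p, q, source_dhs`.
#' @export
call_footprints <- function(dhs, profile, fp_len_range = 11:25, shoulders = 35L,
                            fdr = 0.01, prefilter = 0.05) {
  cand <- footprint_candidates(dhs, profile, fp_len_range, shoulders)
  if (nrow(cand) == 0) return(footprint_empty())
  keep <- cand[cand$combined_p <= prefilter, ]
  if (nrow(keep) == 0) return(footprint_empty())
  sel <- greedy_nonoverlap(keep)
  # search-space size per region: candidates overlapping an interval of
  # width w number ~ (w + fl - 1) per footprint length fl
  w <- sel$end - sel$start
  T_search <- vapply(w, function(wi) sum(wi + fp_len_range - 1L), numeric(1))
  p_search <- -expm1(T_search * log1p(-pmin(sel$combined_p, 1 - 1e-15)))
  sel$q <- stats::p.adjust(p_search, method = "BH")
  sel <- sel[sel$q <= fdr, ]
  if (nrow(sel) == 0) return(footprint_empty())
  sel |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(name = paste0("fp_", dplyr::row_number()), strand = ".") |>
    dplyr::select("chrom", "start", "end", "name", "score", "strand",
                  "p_fwd", "p_rev", "combined_p", "q", "source_dhs")
}

footprint_empty <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = double(), strand = character(),
                 p_fwd = double(), p_rev = double(), combined_p = double(),
                 q = double(), source_dhs = character())
}

# exhaustive candidate table for all DHSs (vectorized over cumulative sums)
footprint_candidates <- function(dhs, profile, fp_len_range, shoulders) {
  rows <- list()
  for (ch in unique(dhs$chrom)) {
    chv <- profile$chroms[[ch]]
    if (is.null(chv)) stop("profile lacks chromosome ", ch, call. = FALSE)
    L <- length(chv$plus)
    cp <- c(0, cumsum(as.numeric(chv$plus)))
    cm <- c(0, cumsum(as.numeric(chv$minus)))
    d <- dhs[dhs$chrom == ch, ]
    for (i in seq_len(nrow(d))) {
      grid <- tidyr::expand_grid(
        s = seq.int(d$start[i], max(d$start[i], d$end[i] - min(fp_len_range))),
        fl = as.integer(fp_len_range)
      )
      grid <- grid[grid$s + grid$fl <= d$end[i], ]
      if (nrow(grid) == 0) next
      best <- NULL
      for (sh in shoulders) {
        g <- grid[grid$s - sh >= 0 & grid$s + grid$fl + sh <= L, ]
        if (nrow(g) == 0) next
        Fu <- cp[g$s + 1L] - cp[g$s - sh + 1L]
        f <- cp[g$s + g$fl + 1L] - cp[g$s + 1L]
        Rd <- cm[g$s + g$fl + sh + 1L] - cm[g$s + g$fl + 1L]
        r <- cm[g$s + g$fl + 1L] - cm[g$s + 1L]
        pr <- sh / (sh + g$fl)
        p_fwd <- binom_upper_tail(Fu, Fu + f, pr)
        p_rev <- binom_upper_tail(Rd, Rd + r, pr)
        res <- tibble::tibble(
          chrom = ch, start = g$s, end = g$s + g$fl,
          shoulder = sh, score = -(log10(p_fwd) + log10(p_rev)),
          p_fwd = p_fwd, p_rev = p_rev, source_dhs = d$name[i]
        )
        best <- if (is.null(best)) res else {
          better <- res$score > best$score
          best[better, ] <- res[better, ]
          best
        }
      }
      if (!is.null(best)) rows[[length(rows) + 1L]] <- best
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  chi <- -2 * (log(out$p_fwd) + log(out$p_rev))
  out$combined_p <- stats::pchisq(chi, df = 4, lower.tail = FALSE)
  out
}

# greedy non-overlapping selection by descending score, ties to leftmost
# start; per-chromosome occupancy bitmaps keep this linear in total width
greedy_nonoverlap <- function(cand) {
  cand <- cand[order(-cand$score, cand$chrom, cand$start, cand$end), ]
  occ <- lapply(split(cand$end, cand$chrom), function(e) logical(max(e)))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- (cand$start[i] + 1L):cand$end[i]
    if (!any(occ[[cand$chrom[i]]][idx])) {
      keep[i] <- TRUE
      occ[[cand$chrom[i]]][idx] <- TRUE
    }
  }
  cand[keep, ]
}

#' Footprint log-likelihood ratio filter (bias mixture model)
#'
#' Each retained candidate is extended by one shoulder on both sides and its
#' strand-summed counts are aggregated into a fixed set of window bins
#' (`shoulder_bins` per shoulder, `fp_bins` across the interior), so that
#' candidates of different widths align on the same shoulder/interior
#' structure. The binned counts `y` are modelled as a two-component
#' multinomial mixture: a bias component `B` whose bin probabilities are the
#' summed hexamer preferences of the local sequence (both strands), and a
#' footprint component `F` with a shared shape `theta` estimated by EM
#' across all candidates. The footprint log-likelihood ratio is
#' `flr = log L(y | F) - log L(y | B)`; candidates with `flr < 0` are flagged
#' as bias artifacts (`retained = FALSE`) but kept in the table.
#'
#' @param candidates Footprint tibble from [call_footprints()].
#' @param profile The `cut_profile` the candidates were called from.
#' @param assembly The matching assembly.
#' @param bias A `hexamer_bias` (typically from [estimate_bias()] on the
#'   naked-DNA control).
#' @param shoulder Shoulder used to extend candidate windows (default 35).
#' @param shoulder_bins,fp_bins Bins per shoulder and across the footprint
#'   interior.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return `candidates` with added columns `flr`, `retained`, and attributes
#'   `em` (list: `pi`, `theta`, `loglik`, `iterations`, `converged`).
#' @export
footprint_flr <- function(candidates, profile, assembly, bias, shoulder = 35L,
                          shoulder_bins = 7L, fp_bins = 5L,
                          max_iter = 200L, tol = 1e-6) {
  if (nrow(candidates) == 0) {
    candidates$flr <- double()
    candidates$retained <- logical()
    return(candidates)
  }
  K <- 2L * shoulder_bins + fp_bins
  lens <- assembly_lengths(assembly)
  Y <- matrix(0, nrow(candidates), K)
  B <- matrix(0, nrow(candidates), K)
  bias_by_chrom <- list()
  for (ch in unique(candidates$chrom)) {
    ctx <- hexamer_context(assembly$sequences[[ch]])
    bp <- bias$preference[ctx$plus]
    bm <- bias$preference[ctx$minus]
    bp[is.na(bp)] <- 1
    bm[is.na(bm)] <- 1
    bias_by_chrom[[ch]] <- bp + bm
  }
  for (i in seq_len(nrow(candidates))) {
    ch <- candidates$chrom[i]
    s <- candidates$start[i]
    e <- candidates$end[i]
    if (s - shoulder < 0 || e + shoulder > lens[[ch]]) {
      s <- max(shoulder, min(s, lens[[ch]] - shoulder - (e - s)))
      e <- s + (candidates$end[i] - candidates$start[i])
    }
    idx <- (s - shoulder + 1L):(e + shoulder) # R indices of the window
    fl <- e - s
    bin <- c(
      rep(seq_len(shoulder_bins), each = shoulder %/% shoulder_bins,
          length.out = shoulder),
      shoulder_bins + 1L + floor((seq_len(fl) - 1L) * fp_bins / fl),
      shoulder_bins + fp_bins +
        rep(seq_len(shoulder_bins), each = shoulder %/% shoulder_bins,
            length.out = shoulder)
    )
    y <- profile$chroms[[ch]]$plus[idx] + profile$chroms[[ch]]$minus[idx]
    b <- bias_by_chrom[[ch]][idx]
    Y[i, ] <- as.numeric(rowsum(y, bin))
    B[i, ] <- as.numeric(rowsum(b, bin))
  }
  B <- B / rowSums(B)
  em <- multinomial_mixture_em(Y, B, max_iter = max_iter, tol = tol)
  lF <- Y %*% log(em$theta)
  lB <- rowSums(Y * log(B))
  candidates$flr <- as.numeric(lF - lB)
  candidates$retained <- candidates$flr >= 0
  attr(candidates, "em") <- em
  candidates
}

# two-component multinomial mixture with one shared footprint shape
multinomial_mixture_em <- function(Y, B, max_iter = 200L, tol = 1e-6) {
  eps <- 1e-10
  theta <- colSums(Y / pmax(rowSums(Y), 1)) + eps
  theta <- theta / sum(theta)
  pi_f <- 0.5
  lB <- rowSums(Y * log(B))
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  pi_trace <- numeric()
  for (it in seq_len(max_iter)) {
    lF <- as.numeric(Y %*% log(theta))
    m <- pmax(lF, lB)
    wF <- pi_f * exp(lF - m)
    wB <- (1 - pi_f) * exp(lB - m)
    ll <- sum(m + log(wF + wB))
    resp <- wF / (wF + wB)
    pi_f <- mean(resp)
    pi_f <- min(max(pi_f, eps), 1 - eps)
    pi_trace <- c(pi_trace, pi_f)
    theta <- colSums(resp * Y) + eps
    theta <- theta / sum(theta)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) warning("footprint mixture EM did not converge in ", max_iter,
                          " iterations", call. = FALSE)
  list(pi = pi_f, theta = theta, loglik = ll_old, iterations = it,
       converged = converged, pi_trace = pi_trace)
}

#' Differential footprint occupancy between two samples
#'
#' For each candidate footprint the deeper profile is first downsampled to
#' the shallower profile's total depth by seeded binomial thinning; the
#' statistic is `delta = score_A - score_B` (footprint scores from
#' [wellington_candidate_score()]). The null is built by `n_boot` random
#' 50/50 re-assignments of the pooled per-base cuts within the candidate
#' window; `z = (delta - mean delta*) / sd delta*` and
#' `p_emp = (1 + #{|delta*| >= |delta|}) / (n_boot + 1)`.
#'
#' @param profile_a,profile_b `cut_profile`s on the same assembly.
#' @param candidates Footprint tibble (`chrom, start, end`).
#' @param shoulder Shoulder length (default 35).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed for thinning and bootstrap.
#' @param p_cut Significance level for labelling `enriched_in` (default 0.01).
#' @return Tibble: candidate coordinates plus `delta, z, p_emp, enriched_in`
#'   (`NA` when not significant); candidates with zero pooled cuts are
#'   dropped with a `skipped` attribute listing them.
#' @export
differential_footprints <- function(profile_a, profile_b, candidates,
                                    shoulder = 35L, n_boot = 200L, seed = 1L,
                                    p_cut = 0.01) {
  tot_a <- total_cuts(profile_a)
  tot_b <- total_cuts(profile_b)
  thin <- if (max(tot_a, tot_b) == 0) 1 else min(tot_a, tot_b) / max(tot_a, tot_b)
  thin_a <- tot_a > tot_b
  with_seed(seed, {
    out <- vector("list", nrow(candidates))
    skipped <- character()
    for (i in seq_len(nrow(candidates))) {
      ch <- candidates$chrom[i]
      s <- candidates$start[i]
      e <- candidates$end[i]
      fl <- e - s
      L <- length(profile_a$chroms[[ch]]$plus)
      if (s - shoulder < 0 || e + shoulder > L) next
      idx <- (s - shoulder + 1L):(e + shoulder)
      ap <- profile_a$chroms[[ch]]$plus[idx]
      am <- profile_a$chroms[[ch]]$minus[idx]
      bp <- profile_b$chroms[[ch]]$plus[idx]
      bm <- profile_b$chroms[[ch]]$minus[idx]
      if (thin < 1) {
        if (thin_a) {
          ap <- stats::rbinom(length(ap), ap, thin)
          am <- stats::rbinom(length(am), am, thin)
        } else {
          bp <- stats::rbinom(length(bp), bp, thin)
          bm <- stats::rbinom(length(bm), bm, thin)
        }
      }
      pooled_p <- ap + bp
      pooled_m <- am + bm
      if (sum(pooled_p) + sum(pooled_m) == 0) {
        skipped <- c(skipped, paste0(ch, ":", s, "-", e, " zero pooled cuts"))
        next
      }
      delta <- wellington_candidate_score(ap, am, fl, shoulder)$score -
        wellington_candidate_score(bp, bm, fl, shoulder)$score
      dstar <- numeric(n_boot)
      W <- length(idx)
      for (b in seq_len(n_boot)) {
        xp <- stats::rbinom(W, pooled_p, 0.5)
        xm <- stats::rbinom(W, pooled_m, 0.5)
        dstar[b] <- wellington_candidate_score(xp, xm, fl, shoulder)$score -
          wellington_candidate_score(pooled_p - xp, pooled_m - xm, fl, shoulder)$score
      }
      sd_star <- stats::sd(dstar)
      z <- if (sd_star > 0) (delta - mean(dstar)) / sd_star else NA_real_
      p_emp <- (1 + sum(abs(dstar) >= abs(delta))) / (n_boot + 1)
      out[[i]] <- tibble::tibble(
        chrom = ch, start = s, end = e,
        name = if ("name" %in% names(candidates)) candidates$name[i] else NA_character_,
        delta = delta, z = z, p_emp = p_emp,
        enriched_in = if (p_emp <= p_cut) {
          if (delta > 0) "A" else "B"
        } else NA_character_
      )
    }
    res <- dplyr::bind_rows(out)
    attr(res, "skipped") <- skipped
    res
  })
}
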