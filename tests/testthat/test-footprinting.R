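test_that("strand-imbalance scores follow the exact binomial tail", {
  # no cuts anywhere: no evidence, score 0
  z <- rep(0L, 20 + 2 * 10)
  res <- wellington_candidate_score(z, z, fp_len = 20, shoulder_len = 10)
  expect_equal(res$p_fwd, 1)
  expect_equal(res$p_rev, 1)
  expect_equal(res$score, 0)

  # shoulder_len = fp_len, F = 8, f = 2: P(X >= 8), X ~ Bin(10, 0.5)
  plus <- c(rep(1L, 8), rep(0L, 2), c(1L, 1L, rep(0L, 8)), rep(0L, 10))
  minus <- rep(0L, 30)
  res <- wellington_candidate_score(plus, minus, fp_len = 10, shoulder_len = 10)
  expect_equal(res$p_fwd, 0.0546875, tolerance = 1e-12)
  expect_equal(res$p_rev, 1)

  # binomial tails match direct summation to 1e-12 for n <= 50
  set.seed(2)
  for (i in 1:200) {
    n <- sample(0:50, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(binom_upper_tail(k, n, p), oracle_binom_upper(k, n, p),
                 tolerance = 1e-12)
  }
})

test_that("adding shoulder cuts never decreases the score", {
  base_plus <- c(rep(2L, 35), rep(1L, 15), rep(0L, 35))
  minus <- c(rep(0L, 35), rep(1L, 15), rep(2L, 35))
  s0 <- wellington_candidate_score(base_plus, minus, 15, 35)$score
  for (extra in c(1L, 5L, 20L)) {
    bp <- base_plus
    bp[1] <- bp[1] + extra
    expect_gte(wellington_candidate_score(bp, minus, 15, 35)$score, s0)
    s0 <- wellington_candidate_score(bp, minus, 15, 35)$score
  }
})

test_that("a protected footprint outscores a flat window at equal depth", {
  cfg <- small_cfg(bias_sd = 0, protection = 1, shoulder_boost = 4)
  base <- generate_assembly(cfg)
  tr <- plant_regulatory_truth(base, cfg)
  prof <- simulate_cuts(tr$assembly, tr[c("dhs", "footprints")], NULL, cfg, 23)
  fp <- tr$footprints[tr$footprints$tissue_a, ][1:5, ]
  flat <- simulate_naked(base$assembly, NULL, cfg, 24) # uniform depth
  for (i in seq_len(nrow(fp))) {
    idx <- (fp$start[i] - 35 + 1L):(fp$end[i] + 35)
    fl <- fp$end[i] - fp$start[i]
    s_fp <- wellington_candidate_score(prof$chroms[[fp$chrom[i]]]$plus[idx],
                                       prof$chroms[[fp$chrom[i]]]$minus[idx],
                                       fl, 35)$score
    s_flat <- wellington_candidate_score(flat$chroms[[fp$chrom[i]]]$plus[idx],
                                         flat$chroms[[fp$chrom[i]]]$minus[idx],
                                         fl, 35)$score
    expect_gt(s_fp, s_flat)
  }
})

test_that("footprint calls respect the width range and recover truth", {
  study <- small_study()
  dhs <- call_dhs(study$cuts_a1)
  fp <- call_footprints(dhs, study$cuts_a1)
  expect_true(all(fp$end - fp$start >= 11 & fp$end - fp$start <= 25))
  expect_true(all(fp$q <= 0.01))
  # non-overlapping greedy selection
  fp_s <- dplyr::arrange(fp, chrom, start)
  expect_true(all(fp_s$start[-1] >= fp_s$end[-nrow(fp_s)] |
                    fp_s$chrom[-1] != fp_s$chrom[-nrow(fp_s)]))
  truth_a <- study$truth$footprints[study$truth$footprints$tissue_a, ]
  m <- match_footprints(fp, truth_a)
  expect_gte(m$recall, 0.8)
  expect_gte(m$precision, 0.8)
})

test_that("hexamer bias estimation recovers the generating table", {
  cfg <- sim_config(seed = 30, genome_length = 1000000L, n_chromosomes = 1L,
                    n_genes = 0L, gc_content = 0.5, bias_sd = 0.25, depth = 1)
  base <- generate_assembly(cfg)
  bias <- generate_bias_table(cfg)
  naked <- simulate_naked(base$assembly, bias, cfg, 31)
  est <- estimate_bias(naked, base$assembly)
  expect_equal(sum(est$cleavage_freq, na.rm = TRUE), 1, tolerance = 1e-9)
  ok <- !is.na(est$preference)
  expect_gte(cor(log(est$preference[ok]), log(bias$preference[ok])), 0.9)

  # bias-free naked DNA gives a near-flat table at depth 1
  cfg0 <- sim_config(seed = 30, genome_length = 1000000L, n_chromosomes = 1L,
                     n_genes = 0L, gc_content = 0.5, bias_sd = 0, depth = 1)
  naked0 <- simulate_naked(base$assembly, generate_bias_table(cfg0), cfg0, 32)
  est0 <- estimate_bias(naked0, base$assembly)
  pref <- est0$preference[!is.na(est0$preference)]
  expect_true(all(pref > 0.8 & pref < 1.25))

  # chromosome mismatch is an error
  other <- genome_assembly(c(weird = "ACGTACGTACGT"))
  expect_error(estimate_bias(naked, other), "do not match")
})

test_that("windows drawn from the bias model itself get flr <= 0 on average", {
  cfg <- small_cfg(bias_sd = 0.5)
  base <- generate_assembly(cfg)
  bias <- generate_bias_table(cfg)
  W <- 95L
  ctx <- hexamer_context(base$assembly$sequences$chr1)
  bp <- bias$preference[ctx$plus]
  bm <- bias$preference[ctx$minus]
  bp[is.na(bp)] <- 1
  bm[is.na(bm)] <- 1
  per_base <- bp + bm
  set.seed(41)
  starts <- sample.int(150000L, 200) + 1000L
  cand <- genomic_intervals("chr1", starts, starts + 15L)
  # profile whose counts are multinomial draws from the bias shape
  pv <- integer(length(per_base))
  for (s in starts) {
    win <- (s - 40L + 1L):(s - 40L + W)
    pv[win] <- pv[win] + as.integer(rmultinom(1, 60, per_base[win]))
  }
  prof <- new_cut_profile(list(chr1 = list(plus = pv, minus = integer(length(pv)))))
  res <- footprint_flr(cand, prof, base$assembly, bias)
  expect_lte(mean(res$flr), 0)
  em <- attr(res, "em")
  expect_true(all(em$pi_trace >= 0 & em$pi_trace <= 1))
})

test_that("true footprints survive the flr filter under strong bias", {
  cfg <- small_cfg(bias_sd = 0.5)
  base <- generate_assembly(cfg)
  bias <- generate_bias_table(cfg)
  tr <- plant_regulatory_truth(base, cfg)
  truth <- tr[c("dhs", "footprints")]
  prof <- simulate_cuts(tr$assembly, truth, bias, cfg, 51)
  naked <- simulate_naked(tr$assembly, bias, cfg, 52)
  est <- estimate_bias(naked, tr$assembly)
  fp <- call_footprints(call_dhs(prof), prof)
  fp <- footprint_flr(fp, prof, tr$assembly, est)
  truth_a <- truth$footprints[truth$footprints$tissue_a, ]
  is_true_call <- vapply(seq_len(nrow(fp)), function(i) {
    any(truth_a$chrom == fp$chrom[i] &
          abs((truth_a$start + truth_a$end) / 2 - (fp$start[i] + fp$end[i]) / 2) <= 10)
  }, logical(1))
  expect_gte(mean(fp$retained[is_true_call]), 0.8)
})

test_that("differential z flips sign when samples are swapped", {
  study <- small_study()
  truth <- study$truth
  fp_a_only <- truth$footprints[truth$footprints$tissue_a & !truth$footprints$tissue_b, ]
  skip_if(nrow(fp_a_only) == 0)
  d1 <- differential_footprints(study$cuts_a1, study$cuts_b1, fp_a_only, seed = 3)
  d2 <- differential_footprints(study$cuts_b1, study$cuts_a1, fp_a_only, seed = 3)
  expect_equal(d1$delta, -d2$delta)
  strong <- which(d1$p_emp <= 0.01)
  expect_true(all(sign(d1$z[strong]) == -sign(d2$z[strong])))
})

test_that("identical profiles produce no differential calls", {
  study <- small_study()
  fp <- study$truth$footprints[1:10, ]
  d <- differential_footprints(study$cuts_a1, study$cuts_a1, fp, seed = 4)
  expect_true(all(d$p_emp == 1))
  expect_true(all(is.na(d$enriched_in)))
})

test_that("empty windows are skipped with a reason", {
  prof <- new_cut_profile(list(chr1 = list(plus = integer(1000), minus = integer(1000))))
  cand <- genomic_intervals("chr1", 500L, 515L)
  d <- differential_footprints(prof, prof, cand, seed = 5)
  expect_equal(nrow(d), 0)
  expect_match(attr(d, "skipped"), "zero pooled cuts")
})
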