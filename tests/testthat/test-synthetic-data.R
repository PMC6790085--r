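test_that("generated genomes hit the configured GC content", {
  cfg <- sim_config(seed = 21, genome_length = 100000L, n_chromosomes = 1L,
                    n_genes = 0L, gc_content = 0.5)
  base <- generate_assembly(cfg)
  expect_equal(nrow(base$genes), 0)
  gc <- gc_fraction(genomic_intervals("chr1", 0, 100000L), base$assembly)
  sd3 <- 3 * sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(gc - 0.5), sd3)
})

test_that("gene models satisfy their structural contract", {
  base <- generate_assembly(sim_config(seed = 3, genome_length = 150000L,
                                       n_chromosomes = 1L, n_genes = 15L))
  expect_equal(nrow(base$genes), 15)
  for (i in seq_len(15)) {
    g <- base$genes[i, ]
    cseq <- coding_sequence(g, base$assembly)
    expect_equal(nchar(cseq) %% 3, 0)
    expect_equal(substr(cseq, 1, 3), "ATG")
    codons <- substring(cseq, seq(1, nchar(cseq), 3), seq(3, nchar(cseq), 3))
    internal <- codons[-length(codons)]
    expect_false(any(internal %in% c("TAA", "TAG", "TGA")))
  }
  # non-overlapping genes
  gv <- base$genes
  expect_true(all(gv$start[-1] >= gv$end[-nrow(gv)] | gv$chrom[-1] != gv$chrom[-nrow(gv)]))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_cfg()
  a1 <- generate_assembly(cfg)
  a2 <- generate_assembly(cfg)
  expect_identical(a1$assembly$sequences, a2$assembly$sequences)
  expect_identical(a1$genes, a2$genes)
  b1 <- generate_bias_table(cfg)
  b2 <- generate_bias_table(cfg)
  expect_identical(b1$preference, b2$preference)
  t1 <- plant_regulatory_truth(a1, cfg)
  t2 <- plant_regulatory_truth(a2, cfg)
  expect_identical(t1$footprints, t2$footprints)
  c1 <- simulate_cuts(t1$assembly, t1[c("dhs", "footprints")], b1, cfg, 5)
  c2 <- simulate_cuts(t2$assembly, t2[c("dhs", "footprints")], b2, cfg, 5)
  expect_identical(c1$chroms, c2$chroms)
})

test_that("bias tables are lognormal with mean one", {
  expect_true(all(generate_bias_table(sim_config(bias_sd = 0))$preference == 1))
  b <- generate_bias_table(sim_config(seed = 8, bias_sd = 0.5))
  expect_equal(mean(b$preference), 1, tolerance = 1e-12)
  expect_lt(abs(sd(log(b$preference)) - 0.5) / 0.5, 0.1)
})

test_that("cut simulation realizes protection, openness and shoulders", {
  cfg <- small_cfg(protection = 1, bias_sd = 0, shoulder_boost = 1)
  base <- generate_assembly(cfg)
  tr <- plant_regulatory_truth(base, cfg)
  truth <- tr[c("dhs", "footprints")]
  prof <- simulate_cuts(tr$assembly, truth, NULL, cfg, 99)
  # full protection: zero cuts strictly inside every tissue-A footprint
  fp <- truth$footprints[truth$footprints$tissue_a, ]
  for (i in seq_len(nrow(fp))) {
    idx <- (fp$start[i] + 1L):fp$end[i]
    expect_equal(sum(prof$chroms[[fp$chrom[i]]]$plus[idx]) +
                   sum(prof$chroms[[fp$chrom[i]]]$minus[idx]), 0)
  }

  # open_fold: mean cuts in DHS ~ open_fold x background, within 3 sd
  cfg2 <- small_cfg(protection = 0, bias_sd = 0, shoulder_boost = 1, open_fold = 10)
  tr2 <- plant_regulatory_truth(generate_assembly(cfg2), cfg2)
  prof2 <- simulate_cuts(tr2$assembly, tr2[c("dhs", "footprints")], NULL, cfg2, 100)
  y <- prof2$chroms$chr1$plus + prof2$chroms$chr1$minus
  in_dhs <- rep(FALSE, length(y))
  for (i in seq_len(nrow(tr2$dhs))) in_dhs[(tr2$dhs$start[i] + 1L):tr2$dhs$end[i]] <- TRUE
  mu_in <- mean(y[in_dhs])
  mu_out <- mean(y[!in_dhs])
  expect_lt(abs(mu_in - 2 * cfg2$depth), 3 * sqrt(2 * cfg2$depth / sum(in_dhs)))
  expect_lt(abs(mu_out - 2 * cfg2$depth / 10), 3 * sqrt(2 * cfg2$depth / 10 / sum(!in_dhs)))

  # replicates differ but share the expected total
  cfg3 <- small_cfg()
  tr3 <- plant_regulatory_truth(generate_assembly(cfg3), cfg3)
  truth3 <- tr3[c("dhs", "footprints")]
  bias3 <- generate_bias_table(cfg3)
  r1 <- simulate_cuts(tr3$assembly, truth3, bias3, cfg3, 1)
  r2 <- simulate_cuts(tr3$assembly, truth3, bias3, cfg3, 2)
  expect_false(identical(r1$chroms, r2$chroms))
  expect_lt(abs(total_cuts(r1) - total_cuts(r2)),
            3 * sqrt(total_cuts(r1) + total_cuts(r2)))
})

test_that("upstream shoulders out-cut footprint interiors on the plus strand", {
  study <- small_study()
  fp <- study$truth$footprints[study$truth$footprints$tissue_a, ]
  sh <- study$config$shoulder
  shoulder_cuts <- interior_cuts <- shoulder_n <- interior_n <- 0
  for (i in seq_len(nrow(fp))) {
    pv <- study$cuts_a1$chroms[[fp$chrom[i]]]$plus
    up <- (fp$start[i] - sh + 1L):fp$start[i]
    inside <- (fp$start[i] + 1L):fp$end[i]
    shoulder_cuts <- shoulder_cuts + sum(pv[up])
    interior_cuts <- interior_cuts + sum(pv[inside])
    shoulder_n <- shoulder_n + length(up)
    interior_n <- interior_n + length(inside)
  }
  expect_gt(shoulder_cuts / shoulder_n, interior_cuts / interior_n)
})

test_that("naked-DNA simulation carries bias but no regulatory structure", {
  cfg <- small_cfg(bias_sd = 0)
  base <- generate_assembly(cfg)
  nk <- simulate_naked(base$assembly, generate_bias_table(cfg), cfg, 5)
  y <- nk$chroms$chr1$plus
  # flat Poisson field at the configured depth
  expect_lt(abs(mean(y) - cfg$depth), 3 * sqrt(cfg$depth / length(y)))
  expect_identical(nk$chroms,
                   simulate_naked(base$assembly, generate_bias_table(cfg), cfg, 5)$chroms)
})

test_that("species divergence produces the three conservation categories", {
  cfg0 <- small_cfg(species_divergence = 0, footprint_turnover = 0,
                    deletion_fraction = 0)
  base <- generate_assembly(cfg0)
  tr <- plant_regulatory_truth(base, cfg0)
  sim <- list(assembly = tr$assembly, truth = tr[c("dhs", "footprints")])
  sp0 <- diverge_species(sim, cfg0)
  expect_true(all(sp0$labels$category == "conserved_occupied"))
  expect_identical(sp0$assembly_b$sequences[[1]], tr$assembly$sequences[[1]])

  cfg1 <- small_cfg(footprint_turnover = 1)
  sp1 <- diverge_species(sim, cfg1)
  expect_false(any(sp1$labels$category == "conserved_occupied"))

  # categories partition the footprint set and match the mapped truth
  sp <- diverge_species(sim, small_cfg())
  expect_equal(nrow(sp$labels), nrow(tr$footprints))
  expect_equal(sum(table(sp$labels$category)), nrow(tr$footprints))
  expect_equal(sum(sp$labels$category == "conserved_occupied"),
               nrow(sp$truth_b$footprints))
})

test_that("variant simulation respects per-class rates", {
  gr <- gene_rich()
  duons <- plant_duons(gr$genes, 400)
  cfg0 <- sim_config(snp_rate_unconstrained = 0, snp_rate_duon = 0,
                     snp_rate_nonsyn = 0)
  expect_equal(nrow(simulate_variants(gr$assembly, gr$genes, duons, cfg0, 1,
                                      sites = gr$sites)), 0)

  v <- simulate_variants(gr$assembly, gr$genes, duons, gr$cfg, 31, sites = gr$sites)
  ffds <- gr$sites[gr$sites$class == "ffds", ]
  in_duon <- interval_overlaps_any(
    tibble::tibble(chrom = ffds$chrom, start = ffds$pos, end = ffds$pos + 1L), duons)
  poly <- paste(ffds$chrom, ffds$pos) %in% paste(v$chrom, v$pos)
  n_d <- sum(in_duon)
  rate_d <- sum(poly[in_duon]) / n_d
  expect_lt(abs(rate_d - gr$cfg$snp_rate_duon),
            3 * sqrt(gr$cfg$snp_rate_duon * (1 - gr$cfg$snp_rate_duon) / n_d))
  rate_u <- mean(poly[!in_duon])
  expect_lt(abs(rate_u - gr$cfg$snp_rate_unconstrained),
            3 * sqrt(gr$cfg$snp_rate_unconstrained / sum(!in_duon)))
  # every simulated variant is a real substitution against the assembly
  expect_silent(validate_variants(v, gr$assembly))
})
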