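identity_blocks <- function(len = 10000L) {
  tibble::tibble(chromA = "chr1", startA = 0L, endA = len,
                 chromB = "chr1b", startB = 0L, endB = len, orient = "+")
}

test_that("interval mapping translates through blocks orientation-aware", {
  iv <- genomic_intervals("chr1", 100L, 150L)
  m <- map_interval(iv, identity_blocks())
  expect_equal(c(m$chrom, m$start, m$end), c("chr1b", 100L, 150L))

  shifted <- identity_blocks()
  shifted$startB <- 100L
  shifted$endB <- 10100L
  m2 <- map_interval(iv, shifted)
  expect_equal(c(m2$start, m2$end), c(200L, 250L))

  # inverted block: coordinates reflect
  inv <- tibble::tibble(chromA = "chr1", startA = 0L, endA = 1000L,
                        chromB = "chr1b", startB = 0L, endB = 1000L, orient = "-")
  m3 <- map_interval(iv, inv)
  expect_equal(c(m3$start, m3$end), c(1000L - 150L, 1000L - 100L))

  # 40% covered at min_frac 0.5: unmappable (per-base coverage oracle)
  part <- tibble::tibble(chromA = "chr1", startA = 100L, endA = 120L,
                         chromB = "chr1b", startB = 0L, endB = 20L, orient = "+")
  covered <- sum(vapply(100:149, function(p) p >= 100 && p < 120, logical(1)))
  expect_equal(covered / 50, 0.4)
  expect_null(map_interval(iv, part, min_frac = 0.5))
  expect_false(is.null(map_interval(iv, part, min_frac = 0.4)))
})

test_that("mapping round-trips through inverted blocks", {
  study <- small_study()
  blocks <- study$species$blocks
  inv <- invert_blocks(blocks)
  fp <- study$truth$footprints
  for (i in seq_len(min(nrow(fp), 30))) {
    m <- map_interval(fp[i, ], blocks, min_frac = 1)
    if (is.null(m)) next
    back <- map_interval(m, inv, min_frac = 1)
    expect_equal(c(back$chrom, back$start, back$end),
                 c(fp$chrom[i], fp$start[i], fp$end[i]))
  }
})

test_that("conservation categories partition the footprint set", {
  study <- small_study()
  fp_a <- genomic_intervals(study$truth$footprints$chrom,
                            study$truth$footprints$start,
                            study$truth$footprints$end,
                            name = study$truth$footprints$fp_id)
  fp_b <- study$species$truth_b$footprints
  cls <- classify_conservation(fp_a, fp_b, study$species$blocks)
  expect_equal(nrow(cls), nrow(fp_a))
  expect_true(all(cls$category %in% c("conserved_occupied", "conserved_unoccupied",
                                      "not_conserved")))
  expect_true(all(is.na(cls$mapped_start[cls$category == "not_conserved"])))
  # truth-level classification reproduces the generator's labels exactly
  expect_equal(cls$category, study$species$labels$category)
})

test_that("two-species multiway reduces to pairwise conservation", {
  study <- small_study()
  fp_a <- genomic_intervals(study$truth$footprints$chrom,
                            study$truth$footprints$start,
                            study$truth$footprints$end,
                            name = study$truth$footprints$fp_id)
  fp_b <- study$species$truth_b$footprints
  cls <- classify_conservation(fp_a, fp_b, study$species$blocks)
  mw <- multiway_conserved(fp_a, list(sp2 = list(dgfs = fp_b,
                                                 blocks = study$species$blocks)))
  expect_setequal(mw$hyperconserved$name,
                  cls$name[cls$category == "conserved_occupied"])
  # adding a species can only shrink the set
  mw2 <- multiway_conserved(fp_a, list(
    sp2 = list(dgfs = fp_b, blocks = study$species$blocks),
    sp3 = list(dgfs = fp_b[0, ], blocks = study$species$blocks)
  ))
  expect_lte(nrow(mw2$hyperconserved), nrow(mw$hyperconserved))
  expect_error(multiway_conserved(fp_a, list(sp2 = list(dgfs = fp_b))), "blocks")
})

test_that("overlap fractions match the quadratic oracle", {
  lens <- c(chr1 = 20000L)
  a <- random_regions(40, lens, seed = 81)
  b <- random_regions(40, lens, seed = 82)
  expect_equal(overlap_fraction(a, a), 1.0)
  far <- b
  far$start <- far$start + 100000L
  far$end <- far$end + 100000L
  expect_equal(overlap_fraction(a, far), 0.0)
  expect_equal(overlap_fraction(a, b), mean(oracle_overlap_any(a, b)))
  expect_error(overlap_fraction(a[0, ], b), "empty")
})

test_that("self-overlap permutation tests are maximally significant", {
  lens <- c(chr1 = 50000L)
  a <- random_regions(30, lens, seed = 83)
  pt <- permutation_overlap(a, a, lens, n_perm = 100, seed = 84)
  expect_equal(pt$observed, 30)
  expect_equal(pt$p_emp, 1 / 101, tolerance = 1e-12)
  expect_gt(pt$z, 3)
})

test_that("degenerate permutation spread is reported without a z-score", {
  lens <- c(chr1 = 1000L)
  a <- genomic_intervals("chr1", 0L, 900L) # every placement overlaps itself
  pt <- permutation_overlap(a, a, lens, n_perm = 20, seed = 85)
  expect_true(is.na(pt$z))
  expect_equal(pt$p_emp, 1)
})

test_that("local z profiles decay faster for exact-match narrow features", {
  lens <- c(chr1 = 200000L)
  with_seed(86, {
    centers <- sort(sample.int(190000L, 40) + 4000L)
  })
  b <- genomic_intervals("chr1", centers - 10L, centers + 10L)       # narrow targets
  a_broad <- genomic_intervals("chr1", centers - 500L, centers + 500L)
  a_narrow <- genomic_intervals("chr1", centers - 10L, centers + 10L)
  p_broad <- permutation_overlap(a_broad, b, lens, n_perm = 50, seed = 87,
                                 shift_window = 400L, shift_step = 100L)
  p_narrow <- permutation_overlap(a_narrow, b, lens, n_perm = 50, seed = 88,
                                  shift_window = 400L, shift_step = 100L)
  rel <- function(pt) {
    pr <- pt$profile
    mean(pr$z[abs(pr$shift) == 400]) / pr$z[pr$shift == 0]
  }
  expect_lt(rel(p_narrow), rel(p_broad))
  expect_equal(p_narrow$profile$z[p_narrow$profile$shift == 0], p_narrow$z)
})
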