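test_that("duons are the base-level footprint/CDS intersection", {
  study <- small_study()
  genes <- study$genes
  cds <- gene_feature_intervals(genes, "cds")

  inside <- genomic_intervals(cds$chrom[1], cds$start[1] + 2L, cds$start[1] + 20L)
  expect_equal(find_duons(inside, genes)[, c("chrom", "start", "end")],
               inside[, c("chrom", "start", "end")])

  introns <- gene_feature_intervals(genes, "introns")
  intronic <- genomic_intervals(introns$chrom[1], introns$start[1],
                                introns$start[1] + 10L)
  expect_equal(nrow(find_duons(intronic, genes)), 0)

  # straddling footprint is clipped to the CDS part (per-base oracle)
  straddle <- genomic_intervals(cds$chrom[1], cds$start[1] - 7L, cds$start[1] + 9L)
  duon <- find_duons(straddle, genes)
  for (pos in straddle$start:(straddle$end - 1L)) {
    pt <- tibble::tibble(chrom = straddle$chrom, start = pos, end = pos + 1L)
    in_cds <- any(oracle_overlap_any(pt, cds))
    in_duon <- nrow(duon) > 0 && any(oracle_overlap_any(pt, duon))
    expect_equal(in_duon, in_cds)
  }
})

test_that("duons and the exon remainder partition the selected exons", {
  gr <- gene_rich()
  duons <- plant_duons(gr$genes, 200)
  surrounding <- surrounding_exon_regions(duons, gr$genes)
  sel <- attr(surrounding, "selected_exons")
  expect_false(any(interval_overlaps_any(surrounding, duons)))
  dn_in_sel <- interval_intersect(duons, sel)
  expect_equal(interval_bases(dn_in_sel) + interval_bases(surrounding),
               interval_bases(sel))
  # exons without duons are excluded
  expect_true(all(interval_overlaps_any(sel, duons)))
})

test_that("FFDS enumeration matches codon-table facts and the brute-force oracle", {
  # GCT (Ala): third base fourfold degenerate; ATG: none
  asm <- genome_assembly(c(c1 = "ATGGCTTTTTAA")) # ATG GCT TTT TAA
  g <- gene_model_row("g", "c1", "+", 0L, 12L,
                      exons = tibble::tibble(start = 0L, end = 12L),
                      cds = tibble::tibble(start = 0L, end = 12L))
  ffds <- enumerate_ffds(g, asm)
  expect_true(5L %in% ffds$pos)           # third base of GCT
  expect_false(any(ffds$pos %in% 0:2))    # ATG start codon
  expect_false(any(ffds$pos %in% 6:8))    # TTT (Phe) twofold only

  gr <- gene_rich()
  got <- gr$sites[gr$sites$class == "ffds", c("chrom", "pos")]
  want <- oracle_ffds(gr$genes, gr$assembly)
  expect_setequal(paste(got$chrom, got$pos), paste(want$chrom, want$pos))
})

test_that("variant effect classification translates alternate codons", {
  asm <- genome_assembly(c(c1 = "ATGGCTTGGTAA")) # ATG GCT TGG TAA
  g <- gene_model_row("g", "c1", "+", 0L, 12L,
                      exons = tibble::tibble(start = 0L, end = 12L),
                      cds = tibble::tibble(start = 0L, end = 12L))
  v <- tibble::tibble(
    chrom = "c1", pos = c(5L, 8L, 4L),
    ref = c("T", "G", "C"), alt = c("C", "A", "A"), af = 0.2
  )
  cls <- classify_variants(v, g, asm)
  expect_equal(cls$site_class, c("ffds", "nonsynonymous", "nonsynonymous"))
  # GCT->GCC stays Ala at an FFDS; TGG->TGA introduces a stop; GCT->GAT changes aa

  # minus-strand gene: same logic through the reverse complement
  asm2 <- genome_assembly(c(c1 = revcomp("ATGGCTTGGTAA")))
  g2 <- gene_model_row("g2", "c1", "-", 0L, 12L,
                       exons = tibble::tibble(start = 0L, end = 12L),
                       cds = tibble::tibble(start = 0L, end = 12L))
  # genomic position of GCT third base = 12 - 1 - 5 = 6; C on minus = G on plus
  v2 <- tibble::tibble(chrom = "c1", pos = 6L, ref = "A", alt = "G", af = 0.2)
  expect_equal(classify_variants(v2, g2, asm2)$site_class, "ffds")

  # random variants agree with a translation oracle
  gr <- gene_rich()
  duons <- plant_duons(gr$genes, 100)
  vr <- simulate_variants(gr$assembly, gr$genes, duons, gr$cfg, 61, sites = gr$sites)
  set.seed(62)
  vr <- vr[sample.int(nrow(vr), 60), ]
  cls <- classify_variants(vr, gr$genes, gr$assembly)
  ffds_pos <- paste(gr$sites$chrom[gr$sites$class == "ffds"],
                    gr$sites$pos[gr$sites$class == "ffds"])
  zf_pos <- paste(gr$sites$chrom[gr$sites$class == "zerofold"],
                  gr$sites$pos[gr$sites$class == "zerofold"])
  key <- paste(cls$chrom, cls$pos)
  expect_true(all(cls$site_class[key %in% ffds_pos] == "ffds"))
  expect_true(all(cls$site_class[key %in% zf_pos] == "nonsynonymous"))
})

test_that("chi-square statistic matches the closed form", {
  tab <- rbind(c(10, 990), c(40, 960))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(unname(ht$statistic), oracle_chisq(tab), tolerance = 1e-9)
  # (10-25)^2/25 * 2 + (15)^2/975 * 2
  expect_equal(oracle_chisq(tab), 2 * 225 / 25 + 2 * 225 / 975, tolerance = 1e-12)
})

test_that("constraint test reports densities per eligible kb and a 2x2 test", {
  gr <- gene_rich()
  duons <- plant_duons(gr$genes, 1200)
  surrounding <- surrounding_exon_regions(duons, gr$genes)
  v <- simulate_variants(gr$assembly, gr$genes, duons, gr$cfg, 71, sites = gr$sites)
  res <- duon_constraint_test(v, duons, surrounding, gr$genes, gr$assembly,
                              sites = gr$sites)
  cnt <- tidy(res)
  expect_true(all(cnt$polymorphic <= cnt$eligible))
  expect_equal(cnt$per_kb, 1000 * cnt$polymorphic / cnt$eligible)
  # chi2 agrees with the direct formula on the same table
  expect_equal(res$ffds_chi2, oracle_chisq(res$ffds_table), tolerance = 1e-9)
  # constrained duons: lower FFDS density, similar nonsyn density
  expect_lt(cnt$per_kb[cnt$region == "duon" & cnt$site_class == "ffds"],
            cnt$per_kb[cnt$region == "surrounding" & cnt$site_class == "ffds"])
  expect_lt(res$ffds_p, 0.01)
  expect_gt(res$nonsyn_p, 0.01)
  # GC composition control: both arms drawn from the same gene space
  expect_lt(abs(res$gc_duon - res$gc_surrounding), 0.05)
  # degenerate input: no eligible sites
  empty <- duon_constraint_test(v, duons[0, ], surrounding, gr$genes, gr$assembly,
                                sites = gr$sites)
  expect_true(is.na(empty$ffds_p))
  expect_match(empty$note, "zero eligible")
})
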