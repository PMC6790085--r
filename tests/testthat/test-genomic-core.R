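test_that("BED fields map directly and round-trip is the identity", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t25\tdgf1\t5.2\t+", tmp)
  iv <- read_bed(tmp)
  expect_equal(iv$chrom, "chr1")
  expect_equal(iv$start, 10L)
  expect_equal(iv$end, 25L)
  expect_equal(iv$name, "dgf1")
  expect_equal(iv$score, 5.2)
  expect_equal(iv$strand, "+")

  # empty file
  writeLines(character(), tmp)
  expect_equal(nrow(read_bed(tmp)), 0)

  # 50-record round trip, field-wise
  set.seed(4)
  x <- genomic_intervals(
    chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
    start = s <- sample.int(10000, 50),
    end = s + sample.int(500, 50),
    name = paste0("r", 1:50),
    score = round(runif(50), 3),
    strand = sample(c("+", "-", "."), 50, replace = TRUE)
  )
  write_bed(x, tmp)
  expect_equal(read_bed(tmp), x)

  # strand "." serialized verbatim
  write_bed(genomic_intervals("c", 0, 5), tmp)
  expect_match(readLines(tmp), "\\.$")
})

test_that("malformed BED lines are rejected with the line number", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t10", "chr1\tbroken"), tmp)
  expect_error(read_bed(tmp), "line 2")
  writeLines(c("chr1\t5\t5"), tmp)
  expect_error(read_bed(tmp), "start < end")
})

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\tsrc\tCDS\t111\t190\t.\t+\t0\tID=c1;Parent=t1"
  ), tmp)
  g <- read_gff_genes(tmp)
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  expect_equal(g$tss, 100L)
  expect_equal(g$cds[[1]]$start, 110L)
  expect_equal(g$cds[[1]]$end, 190L)

  # minus-strand gene: TSS is the rightmost transcribed base
  writeLines(c(
    "chr1\tsrc\tgene\t101\t200\t.\t-\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t-\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t-\t.\tID=e1;Parent=t1"
  ), tmp)
  expect_equal(read_gff_genes(tmp)$tss, 199L)

  # orphan CDS
  writeLines(c("chr1\tsrc\tCDS\t1\t9\t.\t+\t0\tID=c;Parent=ghost"), tmp)
  expect_error(read_gff_genes(tmp), "parent mRNA")
})

test_that("generated gene models survive a GFF round trip", {
  genes <- small_study()$genes
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gff_genes(genes, tmp)
  back <- read_gff_genes(tmp)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$tss, genes$tss)
  expect_equal(back$phase, genes$phase)
  for (i in seq_len(nrow(genes))) {
    expect_equal(back$exons[[i]], genes$exons[[i]])
    expect_equal(back$cds[[i]], genes$cds[[i]])
  }
})

test_that("cut profiles round-trip through bedGraph with totals conserved", {
  p1 <- withr::local_tempfile(fileext = ".bg")
  m1 <- withr::local_tempfile(fileext = ".bg")
  # dense expansion of a single record
  writeLines("chr1\t0\t3\t2", p1)
  writeLines(character(), m1)
  prof <- read_cut_profile(p1, m1, c(chr1 = 10L))
  expect_equal(prof$chroms$chr1$plus[1:4], c(2L, 2L, 2L, 0L))
  expect_equal(total_cuts(prof), 6)
  expect_equal(sum(prof$chroms$chr1$minus), 0)

  # random profile round trip
  set.seed(7)
  rp <- new_cut_profile(list(chr1 = list(plus = rpois(500, 0.4), minus = rpois(500, 0.4))))
  write_cut_profile(rp, p1, m1)
  back <- read_cut_profile(p1, m1, c(chr1 = 500L))
  expect_identical(back$chroms$chr1$plus, as.integer(rp$chroms$chr1$plus))
  expect_identical(back$chroms$chr1$minus, as.integer(rp$chroms$chr1$minus))
  expect_equal(total_cuts(back), total_cuts(rp))

  # overlapping records on one strand are rejected
  writeLines(c("chr1\t0\t5\t1", "chr1\t3\t8\t1"), p1)
  writeLines(character(), m1)
  expect_error(read_cut_profile(p1, m1, c(chr1 = 10L)), "overlap")
})

test_that("variant and block tables are validated on read", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 3L, ref = "AT", alt = "A",
                                  af = 0.1), tmp)
  expect_error(read_variants(tmp), "indel")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 3L, ref = "A", alt = "A",
                                  af = 0.1), tmp)
  expect_error(read_variants(tmp), "ref == alt")
  asm <- genome_assembly(c(chr1 = "ACGTACGT"))
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = 0L, ref = "C", alt = "G",
                                  af = 0.1), tmp)
  expect_error(read_variants(tmp, asm), "mismatch")
  v <- tibble::tibble(chrom = "chr1", pos = 2L, ref = "G", alt = "A", af = 0.25)
  write_variants(v, tmp)
  expect_equal(read_variants(tmp, asm), v)

  readr::write_tsv(tibble::tibble(chromA = "c", startA = 0L, endA = 10L,
                                  chromB = "d", startB = 0L, endB = 9L,
                                  orient = "+"), tmp)
  expect_error(read_blocks(tmp), "length-mismatched")
  readr::write_tsv(tibble::tibble(chromA = "c", startA = c(0L, 5L), endA = c(10L, 15L),
                                  chromB = "d", startB = c(0L, 20L), endB = c(10L, 30L),
                                  orient = "+"), tmp)
  expect_error(read_blocks(tmp), "overlap")
})

test_that("FASTA assemblies round-trip through Biostrings", {
  asm <- genome_assembly(c(chrA = "ACGTN", chrB = paste(rep("ACGT", 30), collapse = "")))
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(asm, tmp)
  back <- read_fasta(tmp)
  expect_equal(back$sequences, asm$sequences)
  expect_equal(assembly_seq(asm, "chrB", 2, 6), "GTAC")
  expect_equal(assembly_seq(asm, "chrB", 2, 6, strand = "-"), "GTAC") # palindrome
  expect_equal(assembly_seq(asm, "chrA", 0, 4, strand = "-"), "ACGT")
})

test_that("interval algebra matches the brute-force oracle", {
  lens <- c(chr1 = 5000L, chr2 = 3000L)
  a <- random_regions(60, lens, seed = 11)
  b <- random_regions 	(40, lens, seed = 12)
  expect_equal(interval_overlaps_any(a, b), oracle_overlap_any(a, b))

  isect <- interval_intersect(a, b)
  # every intersect base is in both sets
  for (i in seq_len(min(nrow(isect), 20))) {
    pt <- tibble::tibble(chrom = isect$chrom[i], start = isect$start[i],
                         end = isect$start[i] + 1L)
    expect_true(all(oracle_overlap_any(pt, a)) && all(oracle_overlap_any(pt, b)))
  }
  sub <- interval_subtract(a, b)
  expect_false(any(interval_overlaps_any(sub, b)))
  expect_equal(interval_bases(sub) + interval_bases(isect), interval_bases(a))
})
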