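#' Duons: footprints within coding sequence
#'
#' Base-level intersection of footprint intervals with CDS intervals; empty
#' intersections are dropped.
#'
#' @param dgfs Interval tibble of footprints.
#' @param genes Gene-model tibble.
#' @return Interval tibble of duon pieces.
#' @export
find_duons <- function(dgfs, genes) {
  interval_intersect(dgfs, gene_feature_intervals(genes, "cds"))
}

#' Surrounding exonic sequence for the duon comparison
#'
#' For every CDS exon containing at least one duon base, the duon bases are
#' subtracted, leaving the rest of that exon as the comparison territory.
#' Exons without duons are excluded; an exon fully covered by duons
#' contributes no remainder but still counts as selected.
#'
#' @param duons Interval tibble from [find_duons()].
#' @param genes Gene-model tibble.
#' @return Interval tibble of remainder pieces, with attribute
#'   `selected_exons` (the CDS exons that contained duons).
#' @export
surrounding_exon_regions <- function(duons, genes) {
  cds <- gene_feature_intervals(genes, "cds")
  sel <- cds[interval_overlaps_any(cds, duons), ]
  out <- interval_subtract(sel, duons)
  attr(out, "selected_exons") <- sel
  out
}

## codon-degeneracy lookup: for each codon (1..64) and position (1..3), is the
## site fourfold degenerate (all substitutions synonymous) or zero-fold
## (all substitutions nonsynonymous)?
codon_tables <- function() {
  if (!is.null(.hex_cache$codon)) return(.hex_cache$codon)
  gc_map <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc_map)
  deg4 <- matrix(FALSE, 64, 3, dimnames = list(codons, NULL))
  deg0 <- matrix(FALSE, 64, 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    aa <- gc_map[[cd]]
    for (p in 1:3) {
      subs <- vapply(setdiff(bases, substr(cd, p, p)), function(b) {
        alt <- cd
        substr(alt, p, p) <- b
        gc_map[[alt]]
      }, character(1))
      deg4[cd, p] <- all(subs == aa)
      deg0[cd, p] <- all(subs != aa)
    }
  }
  .hex_cache$codon <- list(code = gc_map, deg4 = deg4, deg0 = deg0)
  .hex_cache$codon
}

#' Enumerate site degeneracy classes over all CDS bases
#'
#' A CDS base is `ffds` (fourfold degenerate) when substituting it to each of
#' the other three bases leaves the encoded amino acid unchanged, `zerofold`
#' when every substitution changes it, otherwise `partial`. Codon reading is
#' strand-aware; genes whose phase-trimmed CDS length is not divisible by 3
#' are skipped with a warning.
#'
#' @param genes Gene-model tibble.
#' @param assembly A [genome_assembly()].
#' @return Tibble `chrom, pos, gene_id, codon, codon_pos, class`.
#' @export
enumerate_site_classes <- function(genes, assembly) {
  tabs <- codon_tables()
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    pos <- cds_genomic_positions(g)
    if (length(pos) == 0) return(NULL)
    if (length(pos) %% 3 != 0) {
      warning("gene ", g$gene_id, ": CDS length not divisible by 3, skipped",
              call. = FALSE)
      return(NULL)
    }
    cseq <- coding_sequence(g, assembly)
    if (grepl("N", cseq, fixed = TRUE)) return(NULL)
    codons <- substring(cseq, seq(1, nchar(cseq), 3), seq(3, nchar(cseq), 3))
    codon_of_base <- rep(codons, each = 3)
    codon_pos <- rep(1:3, length(codons))
    ci <- match(codon_of_base, rownames(tabs$deg4))
    is4 <- tabs$deg4[cbind(ci, codon_pos)]
    is0 <- tabs$deg0[cbind(ci, codon_pos)]
    tibble::tibble(
      chrom = g$chrom, pos = pos, gene_id = g$gene_id,
      codon = codon_of_base, codon_pos = codon_pos,
      class = ifelse(is4, "ffds", ifelse(is0, "zerofold", "partial"))
    )
  })
  dplyr::bind_rows(rows)
}

#' Enumerate fourfold-degenerate sites
#' @inheritParams enumerate_site_classes
#' @return Tibble of FFDS positions (`chrom, pos, gene_id, codon, codon_pos`).
#' @export
enumerate_ffds <- function(genes, assembly) {
  s <- enumerate_site_classes(genes, assembly)
  s[s$class == "ffds", c("chrom", "pos", "gene_id", "codon", "codon_pos")]
}

#' Classify a variant's coding effect
#'
#' Substitutes the alternate allele into its codon (strand-aware) and
#' translates: a changed amino acid is `nonsynonymous`; an unchanged one is
#' `ffds` when the site is fourfold degenerate and `other_synonymous`
#' otherwise; positions outside CDS are `noncoding`.
#'
#' @param variants Variant tibble (`chrom, pos, ref, alt`).
#' @param genes Gene-model tibble.
#' @param assembly A [genome_assembly()].
#' @return `variants` with an added `site_class` column.
#' @export
classify_variants <- function(variants, genes, assembly) {
  validate_variants(variants, assembly)
  tabs <- codon_tables()
  sites <- enumerate_site_classes(genes, assembly)
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(variants$chrom, variants$pos), key)
  out <- rep("noncoding", nrow(variants))
  coding <- which(!is.na(idx))
  for (i in coding) {
    s <- sites[idx[i], ]
    g <- genes[genes$gene_id == s$gene_id, ]
    alt <- if (g$strand == "-") chartr("ACGT", "TGCA", variants$alt[i]) else variants$alt[i]
    alt_codon <- s$codon
    substr(alt_codon, s$codon_pos, s$codon_pos) <- alt
    same_aa <- tabs$code[[alt_codon]] == tabs$code[[s$codon]]
    out[i] <- if (!same_aa) "nonsynonymous"
    else if (s$class == "ffds") "ffds" else "other_synonymous"
  }
  variants$site_class <- out
  variants
}

#' Test for reduced polymorphism at FFDS in duons
#'
#' Counts eligible fourfold-degenerate sites and the polymorphic ones among
#' them inside duons and in the surrounding exonic remainder, reports per-kb
#' densities (1000 x polymorphic / eligible), and tests the 2x2 table
#' `[polymorphic, non-polymorphic] x [duon, surrounding]` with a Pearson
#' chi-square (1 df, no continuity correction by default). The same
#' machinery is reported for zero-fold (nonsynonymous) sites, and the GC
#' fraction of both region sets is attached as a composition control.
#'
#' @param variants Variant tibble.
#' @param duons Duon intervals ([find_duons()]).
#' @param surrounding Remainder intervals ([surrounding_exon_regions()]).
#' @param genes Gene-model tibble.
#' @param assembly A [genome_assembly()].
#' @param correct Apply Yates continuity correction (default FALSE).
#' @param per_region_length Normalize densities by region length instead of
#'   eligible sites (default FALSE).
#' @param sites Optional precomputed [enumerate_site_classes()] table (saves
#'   recomputation across repeated tests on the same gene set).
#' @return A `duon_test` object.
#' @export
duon_constraint_test <- function(variants, duons, surrounding, genes, assembly,
                                 correct = FALSE, per_region_length = FALSE,
                                 sites = NULL) {
  if (is.null(sites)) sites <- enumerate_site_classes(genes, assembly)
  var_pos <- paste(variants$chrom, variants$pos)

  arm <- function(regions) {
    if (nrow(regions) == 0) {
      return(list(ffds = c(poly = 0L, eligible = 0L),
                  nonsyn = c(poly = 0L, eligible = 0L), bases = 0))
    }
    site_iv <- tibble::tibble(chrom = sites$chrom, start = sites$pos,
                              end = sites$pos + 1L)
    inside <- interval_overlaps_any(site_iv, regions)
    s_in <- sites[inside, ]
    poly <- paste(s_in$chrom, s_in$pos) %in% var_pos
    list(
      ffds = c(poly = sum(poly & s_in$class == "ffds"),
               eligible = sum(s_in$class == "ffds")),
      nonsyn = c(poly = sum(poly & s_in$class == "zerofold"),
                 eligible = sum(s_in$class == "zerofold")),
      bases = interval_bases(regions)
    )
  }
  d <- arm(duons)
  s <- arm(surrounding)

  density <- function(cell, bases) {
    denom <- if (per_region_length) bases else cell[["eligible"]]
    if (denom == 0) NA_real_ else 1000 * cell[["poly"]] / denom
  }
  test_cells <- function(cd, cs) {
    if (cd[["eligible"]] == 0 || cs[["eligible"]] == 0) {
      return(list(chi2 = NA_real_, p = NA_real_, table = NULL,
                  note = "undefined: zero eligible sites in one arm"))
    }
    tab <- rbind(duon = c(poly = cd[["poly"]], non = cd[["eligible"]] - cd[["poly"]]),
                 surrounding = c(poly = cs[["poly"]], non = cs[["eligible"]] - cs[["poly"]]))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(chi2 = unname(ht$statistic), p = unname(ht$p.value), table = tab, note = NA)
  }
  ffds_test <- test_cells(d$ffds, s$ffds)
  nonsyn_test <- test_cells(d$nonsyn, s$nonsyn)

  structure(list(
    counts = tibble::tibble(
      region = rep(c("duon", "surrounding"), each = 2),
      site_class = rep(c("ffds", "nonsynonymous"), 2),
      polymorphic = c(d$ffds[["poly"]], d$nonsyn[["poly"]],
                      s$ffds[["poly"]], s$nonsyn[["poly"]]),
      eligible = c(d$ffds[["eligible"]], d$nonsyn[["eligible"]],
                   s$ffds[["eligible"]], s$nonsyn[["eligible"]]),
      per_kb = c(density(d$ffds, d$bases), density(d$nonsyn, d$bases),
                 density(s$ffds, s$bases), density(s$nonsyn, s$bases))
    ),
    ffds_chi2 = ffds_test$chi2, ffds_p = ffds_test$p, ffds_table = ffds_test$table,
    nonsyn_chi2 = nonsyn_test$chi2, nonsyn_p = nonsyn_test$p,
    nonsyn_table = nonsyn_test$table,
    gc_duon = gc_fraction(duons, assembly),
    gc_surrounding = gc_fraction(surrounding, assembly),
    note = ffds_test$note
  ), class = "duon_test")
}

#' @export
print.duon_test <- function(x, ...) {
  cat("<duon_test>\n")
  print(x$counts)
  cat(sprintf("FFDS:   chi2 = %.4g, p = %.4g\n", x$ffds_chi2, x$ffds_p))
  cat(sprintf("nonsyn: chi2 = %.4g, p = %.4g\n", x$nonsyn_chi2, x$nonsyn_p))
  cat(sprintf("GC duon %.3f vs surrounding %.3f\n", x$gc_duon, x$gc_surrounding))
  invisible(x)
}

#' @export
tidy.duon_test <- function(x, ...) {
  x$counts
}

#' @export
glance.duon_test <- function(x, ...) {
  tibble::tibble(
    ffds_chi2 = x$ffds_chi2, ffds_p = x$ffds_p,
    nonsyn_chi2 = x$nonsyn_chi2, nonsyn_p = x$nonsyn_p,
    gc_duon = x$gc_duon, gc_surrounding = x$gc_surrounding
  )
}
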