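# Shared fixtures, built once per test run and cached in an environment so
# independent test files can reuse the same synthetic study.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# compact study for module-level tests: 200 kb, 12 genes, 10 DHSs
small_cfg <- function(...) {
  sim_config(genome_length = 200000L, n_chromosomes = 1L, n_genes = 12L,
             n_dhs = 10L, ...)
}

small_study <- function() {
  memo("small_study", simulate_study(small_cfg()))
}

# gene-rich set for duon/FFDS tests: CDS-heavy, no regulatory structure
gene_rich <- function() {
  memo("gene_rich", {
    cfg <- sim_config(genome_length = 1200000L, n_chromosomes = 1L,
                      n_genes = 300L, n_dhs = 0L, footprints_per_dhs = 0L)
    base <- generate_assembly(cfg)
    sites <- enumerate_site_classes(base$genes, base$assembly)
    list(cfg = cfg, assembly = base$assembly, genes = base$genes, sites = sites)
  })
}

# duon intervals planted directly into a gene set's CDS (width bp pieces)
plant_duons <- function(genes, n, width = 24L, seed = 9L) {
  cds <- gene_feature_intervals(genes, "cds")
  wide <- cds[cds$end - cds$start >= width + 10L, ]
  with_seed(seed, {
    duons <- wide[sample(nrow(wide), n, replace = TRUE), ]
    off <- vapply(duons$end - duons$start - width, function(m) sample.int(m, 1),
                  integer(1))
    duons$start <- duons$start + off
    duons$end <- duons$start + width
    interval_merge(duons)
  })
}

random_regions <- function(n, lengths, width_range = c(20L, 200L), seed = 1L) {
  with_seed(seed, {
    ch <- sample(names(lengths), n, replace = TRUE)
    w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
    s <- vapply(seq_len(n), function(i) sample.int(lengths[[ch[i]]] - w[i], 1) - 1L,
                integer(1))
    genomic_intervals(ch, s, s + w)
  })
}
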