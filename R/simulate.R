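#' Simulation configuration
#'
#' Defaults define the package's reference synthetic study: a 1 Mb two-
#' chromosome genome with 60 genes and 40 DNaseI-hypersensitive sites, three
#' transcription-factor footprints per DHS, strand-polarized shoulder signal,
#' a lognormal hexamer cutting bias shared with a naked-DNA control, two
#' tissues with partial footprint turnover, a diverged second species related
#' by ungapped alignment blocks, and coding polymorphisms depleted at
#' constrained duon sites.
#'
#' @param ... Overrides for any default field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome_length = 1000000L,
    n_chromosomes = 2L,
    gc_content = 0.45,
    n_genes = 60L,
    n_dhs = 40L,
    dhs_width_range = c(300L, 1200L),
    footprints_per_dhs = 3L,
    footprint_width_range = c(11L, 25L),
    duon_fraction = 0.25,
    depth = 0.5,
    open_fold = 10,
    protection = 0.9,
    shoulder_boost = 2,
    shoulder = 35L,
    bias_sd = 0.25,
    snp_rate_unconstrained = 0.05,
    snp_rate_duon = 0.025,
    snp_rate_nonsyn = 0.01,
    species_divergence = 0.05,
    footprint_turnover = 0.3,
    deletion_fraction = 0.1,
    dup_rate = 0,
    read_length = 36L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config key: ", unknown[1], call. = FALSE)
  cfg[names(over)] <- over
  fracs <- c("gc_content", "duon_fraction", "protection", "bias_sd",
             "snp_rate_unconstrained", "snp_rate_duon", "snp_rate_nonsyn",
             "species_divergence", "footprint_turnover", "deletion_fraction",
             "dup_rate")
  for (f in setdiff(fracs, "bias_sd")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]", call. = FALSE)
  }
  if (cfg$bias_sd < 0) stop("bias_sd must be >= 0", call. = FALSE)
  if (cfg$snp_rate_duon > cfg$snp_rate_unconstrained) {
    stop("snp_rate_duon must not exceed snp_rate_unconstrained", call. = FALSE)
  }
  if (cfg$species_divergence >= 0.3) stop("species_divergence must be < 0.3", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Write / read a configuration as flat key-value text
#' @param config A `sim_config`.
#' @param path Output path.
#' @rdname sim_config_io
#' @export
write_sim_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], scientific = FALSE, trim = TRUE),
                           collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname sim_config_io
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num))) v else num
  })
  do.call(sim_config, stats::setNames(vals, trimws(keys)))
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derived from a base seed and a label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

random_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# m sense codons at the target GC (stop codons redrawn)
random_codons <- function(m, gc) {
  draw <- function(k) {
    b <- matrix(random_dna(3 * k, gc), ncol = 3)
    paste0(b[, 1], b[, 2], b[, 3])
  }
  cod <- draw(m)
  while (any(cod %in% STOP_CODONS)) {
    i <- cod %in% STOP_CODONS
    cod[i] <- draw(sum(i))
  }
  cod
}

#' Generate a random genome assembly with gene models
#'
#' Bases are i.i.d. at the configured GC content. Genes are non-overlapping
#' single-transcript models with 1-3 exons, UTRs, an ATG start codon, no
#' internal stop codons, a terminal stop, and CDS length divisible by 3.
#'
#' @param config A [sim_config()].
#' @return List with `assembly` ([genome_assembly()]) and `genes`
#'   (gene-model tibble).
#' @export
generate_assembly <- function(config) {
  with_seed(derive_seed(config$seed, "assembly"), {
    chrom_len <- as.integer(config$genome_length / config$n_chromosomes)
    if (chrom_len < 10000) stop("need >= 10 kb per chromosome", call. = FALSE)
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    seqs <- lapply(chroms, function(ch) random_dna(chrom_len, config$gc_content))
    names(seqs) <- chroms

    genes <- NULL
    if (config$n_genes > 0) {
      per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
      gi <- 0L
      rows <- list()
      for (ci in seq_along(chroms)) {
        ng <- per_chrom[ci]
        if (ng == 0) next
        layouts <- lapply(seq_len(ng), function(i) gene_layout(config))
        spans <- vapply(layouts, function(l) l$span, integer(1))
        min_gap <- 2500L # room for promoters and downstream regions
        free <- chrom_len - sum(spans) - (ng + 1L) * min_gap
        if (free < 0) stop("cannot pack ", ng, " genes into ", chrom_len, " bp",
                           call. = FALSE)
        extra <- as.vector(stats::rmultinom(1, free, rep(1, ng + 1L)))
        gaps <- min_gap + extra
        starts <- cumsum(gaps[seq_len(ng)]) + cumsum(c(0L, spans[-ng]))
        for (i in seq_len(ng)) {
          gi <- gi + 1L
          strand <- sample(c("+", "-"), 1)
          g <- realize_gene(paste0("gene", gi), chroms[ci], strand,
                            starts[i], layouts[[i]])
          # write the coding sequence into the genome
          pos <- cds_genomic_positions(g)
          bases <- layouts[[i]]$coding_bases
          if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
          seqs[[chroms[ci]]][pos + 1L] <- bases
          rows[[gi]] <- g
        }
      }
      genes <- dplyr::bind_rows(rows)
    } else {
      genes <- empty_gene_models()
    }
    assembly <- genome_assembly(lapply(seqs, paste0, collapse = ""))
    list(assembly = assembly, genes = validate_gene_models(genes))
  })
}

# draw a gene's internal structure (lengths only, plus its coding bases)
gene_layout <- function(config) {
  n_exons <- sample(1:3, 1)
  m <- sample(80:250, 1) # sense codons incl. start
  codons <- c("ATG", random_codons(m - 1L, config$gc_content),
              sample(STOP_CODONS, 1))
  cds_len <- 3L * (m + 1L)
  piece_min <- 30L
  if (n_exons == 1) {
    pieces <- cds_len
  } else {
    cuts <- sort(sample(seq(piece_min, cds_len - piece_min, by = 3L), n_exons - 1L))
    pieces <- diff(c(0L, cuts, cds_len))
  }
  u5 <- sample(50:150, 1)
  u3 <- sample(80:200, 1)
  introns <- if (n_exons > 1) sample(80:300, n_exons - 1L, replace = TRUE) else integer()
  span <- u5 + u3 + cds_len + sum(introns)
  list(n_exons = n_exons, pieces = as.integer(pieces), u5 = u5, u3 = u3,
       introns = as.integer(introns), span = as.integer(span),
       coding_bases = strsplit(paste0(codons, collapse = ""), "")[[1]])
}

# place a layout at a genomic start; mirror the layout for minus-strand genes
realize_gene <- function(gene_id, chrom, strand, start, layout) {
  # exon/intron walk with UTR5 leftmost
  ex_start <- integer()
  ex_end <- integer()
  cd_start <- integer()
  cd_end <- integer()
  p <- start
  for (k in seq_len(layout$n_exons)) {
    exon_len <- layout$pieces[k] +
      (if (k == 1) layout$u5 else 0L) + (if (k == layout$n_exons) layout$u3 else 0L)
    ex_start <- c(ex_start, p)
    ex_end <- c(ex_end, p + exon_len)
    cs <- p + (if (k == 1) layout$u5 else 0L)
    cd_start <- c(cd_start, cs)
    cd_end <- c(cd_end, cs + layout$pieces[k])
    p <- p + exon_len
    if (k < layout$n_exons) p <- p + layout$introns[k]
  }
  end <- p
  if (strand == "-") {
    mirror <- function(s, e) list(start = rev(start + (end - e)), end = rev(start + (end - s)))
    ex <- mirror(ex_start, ex_end)
    cd <- mirror(cd_start, cd_end)
    ex_start <- ex$start; ex_end <- ex$end
    cd_start <- cd$start; cd_end <- cd$end
  }
  gene_model_row(gene_id, chrom, strand, start, end,
                 exons = tibble::tibble(start = ex_start, end = ex_end),
                 cds = tibble::tibble(start = cd_start, end = cd_end))
}

#' Generate a hexamer cleavage-bias table
#'
#' 4096 positive multiplicative preferences, lognormal on the log scale with
#' the configured standard deviation, normalized to mean 1. `bias_sd = 0`
#' gives a flat (bias-free) table.
#'
#' @param config A [sim_config()].
#' @return A `hexamer_bias` object (see [hexamer_bias()]).
#' @export
generate_bias_table <- function(config) {
  with_seed(derive_seed(config$seed, "bias"), {
    f <- stats::rlnorm(N_HEX, meanlog = 0, sdlog = config$bias_sd)
    f <- f / mean(f)
    hexamer_bias(stats::setNames(f, hexamer_names()))
  })
}

#' Plant DNaseI-hypersensitive sites and footprints (ground truth)
#'
#' Places `n_dhs` non-overlapping DHSs, a configured fraction of them centered
#' on coding exons so that their footprints fall in CDS (duons). Each DHS
#' receives `footprints_per_dhs` non-overlapping footprints with room for
#' their shoulders. Non-duon footprints carry a planted motif consensus
#' written into the assembly; each footprint is assigned to tissues A/B
#' (shared, A-only or B-only by the turnover probability).
#'
#' @param sim Output of [generate_assembly()].
#' @param config A [sim_config()].
#' @return List: possibly modified `assembly`, `dhs` interval tibble,
#'   `footprints` tibble with `fp_id, dhs_id, motif, in_cds, tissue_a,
#'   tissue_b` columns.
#' @export
plant_regulatory_truth <- function(sim, config) {
  with_seed(derive_seed(config$seed, "truth"), {
    assembly <- sim$assembly
    genes <- sim$genes
    lens <- assembly_lengths(assembly)
    sh <- config$shoulder
    wr <- config$footprint_width_range
    dr <- config$dhs_width_range

    n_fp <- config$n_dhs * config$footprints_per_dhs
    n_duon_dhs <- if (n_fp == 0) 0L else {
      min(config$n_dhs,
          ceiling(config$duon_fraction * n_fp / config$footprints_per_dhs))
    }

    cds_iv <- gene_feature_intervals(genes, "cds")
    wide_cds <- cds_iv[cds_iv$end - cds_iv$start >= max(wr) + 10L, ]

    placed <- empty_intervals()
    dhs_rows <- list()
    fp_rows <- list()
    fp_i <- 0L
    for (d in seq_len(config$n_dhs)) {
      w <- sample(dr[1]:dr[2], 1)
      ok <- FALSE
      for (try in 1:200) {
        if (d <= n_duon_dhs && nrow(wide_cds) > 0) {
          # center the DHS on a coding exon
          ci <- sample(nrow(wide_cds), 1)
          center <- sample(wide_cds$start[ci]:(wide_cds$end[ci] - 1L), 1)
          ch <- wide_cds$chrom[ci]
          s <- max(0L, center - w %/% 2L)
        } else {
          ch <- sample(names(lens), 1)
          s <- sample.int(lens[[ch]] - w, 1) - 1L
        }
        cand <- tibble::tibble(chrom = ch, start = s, end = s + w)
        if (!any(interval_overlaps_any(cand, placed))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("cannot place ", config$n_dhs, " non-overlapping DHSs", call. = FALSE)
      placed <- dplyr::bind_rows(placed, genomic_intervals(ch, s, s + w,
                                                           name = paste0("dhs", d)))
      dhs_rows[[d]] <- placed[nrow(placed), ]

      # footprints inside this DHS, shoulders included, mutually separated
      target_cds <- d <= n_duon_dhs
      occupied <- tibble::tibble(chrom = character(), start = integer(), end = integer())
      for (k in seq_len(config$footprints_per_dhs)) {
        fw <- sample(wr[1]:wr[2], 1)
        lo <- s + sh
        hi <- s + w - sh - fw
        if (hi <= lo) next
        fp <- NULL
        for (try in 1:100) {
          fs <- sample(lo:hi, 1)
          cand <- tibble::tibble(chrom = ch, start = fs - sh, end = fs + fw + sh)
          if (any(interval_overlaps_any(cand, occupied))) next
          fp_iv <- tibble::tibble(chrom = ch, start = fs, end = fs + fw)
          in_cds <- nrow(cds_iv) > 0 && any(interval_overlaps_any(fp_iv, cds_iv))
          fully_in_cds <- nrow(cds_iv) > 0 &&
            any(cds_iv$chrom == ch & cds_iv$start <= fs & cds_iv$end >= fs + fw)
          if (target_cds && !fully_in_cds) next
          fp <- list(start = fs, end = fs + fw, in_cds = in_cds)
          break
        }
        if (is.null(fp)) next
        fp_i <- fp_i + 1L
        occupied <- dplyr::bind_rows(occupied,
                                     tibble::tibble(chrom = ch, start = fp$start - sh,
                                                    end = fp$end + sh))
        motif <- NA_character_
        if (!fp$in_cds) {
          motif <- sample(names(builtin_motif_consensus()), 1)
          cons <- builtin_motif_consensus()[[motif]]
          ms <- fp$start + (fp$end - fp$start - nchar(cons)) %/% 2L
          assembly <- plant_sequence(assembly, ch, ms, cons)
        }
        u <- stats::runif(1)
        shared <- u < 1 - config$footprint_turnover
        a_only <- !shared && u < 1 - config$footprint_turnover / 2
        fp_rows[[fp_i]] <- tibble::tibble(
          chrom = ch, start = fp$start, end = fp$end,
          fp_id = paste0("fp", fp_i), dhs_id = paste0("dhs", d),
          motif = motif, in_cds = fp$in_cds,
          tissue_a = shared || a_only, tissue_b = shared || !a_only
        )
      }
    }
    list(assembly = assembly,
         dhs = dplyr::arrange(placed, .data$chrom, .data$start),
         footprints = dplyr::bind_rows(fp_rows))
  })
}

plant_sequence <- function(assembly, chrom, start, seq) {
  s <- assembly$sequences[[chrom]]
  assembly$sequences[[chrom]] <- paste0(
    substring(s, 1, start), seq, substring(s, start + nchar(seq) + 1, nchar(s))
  )
  assembly
}

#' Built-in planted motif consensi
#'
#' Five plant-style consensus elements used by the generator, built around
#' the I-box, G-box, W-box, GCC-box and TATC cores. Each is 8 bp so that an
#' exact match is resolvable at the default scan threshold (the best
#' attainable p-value of a short motif is the background probability of its
#' consensus word, which for 6-mers sits above 1e-4).
#' @return Named character vector.
#' @export
builtin_motif_consensus <- function() {
  c(ibox = "AGATAAGG", gbox = "GCACGTGG", wbox = "TTTGACCT",
    gccbox = "TAGCCGCC", tatc = "TATCCATC")
}

# per-base Poisson rate matrices for one chromosome, both strands
cut_rates <- function(assembly, truth, bias, config, tissue = NULL) {
  sh <- config$shoulder
  lapply(stats::setNames(names(assembly$sequences), names(assembly$sequences)), function(ch) {
    L <- nchar(assembly$sequences[[ch]])
    base <- rep(config$depth / config$open_fold, L)
    if (!is.null(truth)) {
      d <- truth$dhs[truth$dhs$chrom == ch, ]
      for (i in seq_len(nrow(d))) base[(d$start[i] + 1L):d$end[i]] <- config$depth
    }
    rp <- base
    rm_ <- base
    if (!is.null(truth) && nrow(truth$footprints) > 0) {
      fp <- truth$footprints[truth$footprints$chrom == ch, ]
      if (!is.null(tissue)) {
        fp <- fp[fp[[paste0("tissue_", tissue)]], ]
      }
      for (i in seq_len(nrow(fp))) {
        inside <- (fp$start[i] + 1L):fp$end[i]
        rp[inside] <- rp[inside] * (1 - config$protection)
        rm_[inside] <- rm_[inside] * (1 - config$protection)
        up <- max(1L, fp$start[i] - sh + 1L):fp$start[i]
        rp[up] <- rp[up] * config$shoulder_boost
        dn <- (fp$end[i] + 1L):min(L, fp$end[i] + sh)
        rm_[dn] <- rm_[dn] * config$shoulder_boost
      }
    }
    if (!is.null(bias)) {
      ctx <- hexamer_context(assembly$sequences[[ch]])
      bp <- bias$preference[ctx$plus]
      bm <- bias$preference[ctx$minus]
      bp[is.na(bp)] <- 1
      bm[is.na(bm)] <- 1
      rp <- rp * bp
      rm_ <- rm_ * bm
    }
    list(plus = rp, minus = rm_)
  })
}

#' Simulate a stranded cleavage profile for one library
#'
#' Per-base per-strand counts are independent Poisson draws. The rate is
#' `depth` inside DHSs and `depth / open_fold` outside; footprint interiors
#' are reduced by the protection factor; upstream shoulders are boosted on
#' the plus strand and downstream shoulders on the minus strand; everything
#' is multiplied by the strand-aware hexamer bias at each cut position.
#'
#' @param assembly A [genome_assembly()].
#' @param truth Output of [plant_regulatory_truth()] (or `NULL` for no
#'   regulatory structure).
#' @param bias A `hexamer_bias` table (or `NULL` for no bias).
#' @param config A [sim_config()].
#' @param seed Replicate seed.
#' @param tissue `"a"` or `"b"`: which tissue's footprints protect.
#' @return A `cut_profile`.
#' @export
simulate_cuts <- function(assembly, truth, bias, config, seed, tissue = "a") {
  rates <- cut_rates(assembly, truth, bias, config, tissue)
  with_seed(seed, {
    prof <- lapply(rates, function(r) {
      list(plus = stats::rpois(length(r$plus), r$plus),
           minus = stats::rpois(length(r$minus), r$minus))
    })
    new_cut_profile(prof)
  })
}

#' Simulate a naked-DNA (deproteinized) control library
#'
#' Rate is `depth x bias(hexamer)` at every base on each strand: no DHS and
#' no footprint structure, only sequence-specific cutting preference.
#' @inheritParams simulate_cuts
#' @export
simulate_naked <- function(assembly, bias, config, seed) {
  lens <- assembly_lengths(assembly)
  with_seed(seed, {
    prof <- lapply(stats::setNames(names(lens), names(lens)), function(ch) {
      L <- lens[[ch]]
      rp <- rep(config$depth, L)
      rm_ <- rep(config$depth, L)
      if (!is.null(bias)) {
        ctx <- hexamer_context(assembly$sequences[[ch]])
        bp <- bias$preference[ctx$plus]
        bm <- bias$preference[ctx$minus]
        bp[is.na(bp)] <- 1
        bm[is.na(bm)] <- 1
        rp <- rp * bp
        rm_ <- rm_ * bm
      }
      list(plus = stats::rpois(L, rp), minus = stats::rpois(L, rm_))
    })
    new_cut_profile(prof)
  })
}

#' Derive a second species by substitution, deletion and footprint turnover
#'
#' Copies the assembly with i.i.d. substitutions at `species_divergence`,
#' deletes a configured fraction of the sequence in chunks (creating
#' unalignable gaps), and records the remaining colinear correspondence as
#' ungapped alignment blocks. Each footprint is labelled with its
#' conservation category: `not_conserved` when most of it falls in deleted
#' sequence, otherwise `conserved_occupied` (retained in the second species,
#' probability `1 - footprint_turnover`) or `conserved_unoccupied`.
#'
#' @param sim List with `assembly` and `truth` (from
#'   [plant_regulatory_truth()]).
#' @param config A [sim_config()].
#' @param min_frac Mappable fraction below which a footprint counts as not
#'   conserved (matches the mapping threshold downstream).
#' @return List: `assembly_b`, `blocks`, `truth_b` (DHS + footprints mapped
#'   to B coordinates, with occupancy), and `labels` (per-A-footprint
#'   category tibble).
#' @export
diverge_species <- function(sim, config, min_frac = 0.5) {
  with_seed(derive_seed(config$seed, "species"), {
    assembly <- sim$assembly
    truth <- sim$truth
    lens <- assembly_lengths(assembly)

    blocks <- list()
    seqs_b <- list()
    del_all <- list()
    for (ch in names(lens)) {
      L <- lens[[ch]]
      # deletions: chunks of ~1-3 kb until the target fraction is reached
      target <- config$deletion_fraction * L
      dels <- tibble::tibble(start = integer(), end = integer())
      deleted <- 0
      guard <- 0
      while (deleted < target && guard < 10000) {
        guard <- guard + 1
        dl <- sample(1000:3000, 1)
        ds <- sample.int(L - dl, 1) - 1L
        cand <- tibble::tibble(chrom = ch, start = ds, end = ds + dl)
        if (nrow(dels) > 0 &&
            any(interval_overlaps_any(
              cand, tibble::tibble(chrom = ch, start = dels$start, end = dels$end)))) next
        dels <- dplyr::bind_rows(dels, tibble::tibble(start = ds, end = ds + dl))
        deleted <- deleted + dl
      }
      dels <- dplyr::arrange(dels, .data$start)
      del_all[[ch]] <- dels
      seg_start <- c(0L, dels$end)
      seg_end <- c(dels$start, L)
      keep <- seg_start < seg_end
      seg_start <- seg_start[keep]
      seg_end <- seg_end[keep]
      seg_len <- seg_end - seg_start
      offs <- cumsum(c(0L, seg_len[-length(seg_len)]))
      chb <- paste0(ch, "_b")
      blocks[[ch]] <- tibble::tibble(
        chromA = ch, startA = seg_start, endA = seg_end,
        chromB = chb, startB = offs, endB = offs + seg_len, orient = "+"
      )
      # substituted copy of the retained sequence
      bases <- strsplit(assembly$sequences[[ch]], "")[[1]]
      nsub <- stats::rbinom(1, L, config$species_divergence)
      if (nsub > 0) {
        at <- sample.int(L, nsub)
        shift <- sample(1:3, nsub, replace = TRUE)
        cur <- match(bases[at], c("A", "C", "G", "T"))
        ok <- !is.na(cur)
        bases[at[ok]] <- c("A", "C", "G", "T")[((cur[ok] - 1L + shift[ok]) %% 4L) + 1L]
      }
      seqs_b[[chb]] <- paste0(unlist(lapply(seq_along(seg_start), function(i) {
        bases[(seg_start[i] + 1L):seg_end[i]]
      })), collapse = "")
    }
    blocks <- dplyr::bind_rows(blocks)
    assembly_b <- genome_assembly(seqs_b)

    fp <- sim$truth$footprints
    labels <- character(nrow(fp))
    fp_b <- list()
    retained <- stats::runif(nrow(fp)) < 1 - config$footprint_turnover
    for (i in seq_len(nrow(fp))) {
      m <- map_interval(fp[i, ], blocks, min_frac = min_frac)
      if (is.null(m)) {
        labels[i] <- "not_conserved"
      } else if (retained[i]) {
        labels[i] <- "conserved_occupied"
        fp_b[[length(fp_b) + 1L]] <- tibble::tibble(
          chrom = m$chrom, start = m$start, end = m$end,
          fp_id = fp$fp_id[i], source_fp = fp$fp_id[i]
        )
      } else {
        labels[i] <- "conserved_unoccupied"
      }
    }
    dhs_b <- list()
    for (i in seq_len(nrow(sim$truth$dhs))) {
      m <- map_interval(sim$truth$dhs[i, ], blocks, min_frac = 0.3)
      if (!is.null(m)) {
        dhs_b[[length(dhs_b) + 1L]] <- tibble::tibble(
          chrom = m$chrom, start = m$start, end = m$end,
          name = sim$truth$dhs$name[i]
        )
      }
    }
    fp_b <- dplyr::bind_rows(fp_b)
    if (nrow(fp_b) > 0) {
      fp_b$tissue_a <- TRUE
      fp_b$tissue_b <- TRUE
      fp_b$in_cds <- FALSE
      fp_b$motif <- NA_character_
      fp_b$dhs_id <- NA_character_
    }
    list(
      assembly_b = assembly_b,
      blocks = blocks,
      truth_b = list(dhs = dplyr::bind_rows(dhs_b), footprints = fp_b),
      labels = tibble::tibble(fp_id = fp$fp_id, category = labels)
    )
  })
}

#' Simulate coding polymorphisms with duon constraint
#'
#' Fourfold-degenerate sites (FFDS) inside duons are polymorphic with
#' probability `snp_rate_duon`, FFDS elsewhere in CDS with
#' `snp_rate_unconstrained`; zero-fold (nonsynonymous) sites are polymorphic
#' at `snp_rate_nonsyn` regardless of duon membership.
#'
#' @param assembly A [genome_assembly()].
#' @param genes Gene-model tibble.
#' @param duons Interval tibble of duon bases (footprint within CDS).
#' @param config A [sim_config()].
#' @param seed Seed.
#' @param sites Optional precomputed [enumerate_site_classes()] table.
#' @return Variant tibble `chrom, pos, ref, alt, af`.
#' @export
simulate_variants <- function(assembly, genes, duons, config, seed, sites = NULL) {
  if (is.null(sites)) sites <- enumerate_site_classes(genes, assembly)
  with_seed(seed, {
    ffds <- sites[sites$class == "ffds", ]
    zf <- sites[sites$class == "zerofold", ]
    in_duon <- interval_overlaps_any(
      tibble::tibble(chrom = ffds$chrom, start = ffds$pos, end = ffds$pos + 1L), duons
    )
    rate <- ifelse(in_duon, config$snp_rate_duon, config$snp_rate_unconstrained)
    pick_f <- stats::runif(nrow(ffds)) < rate
    pick_z <- stats::runif(nrow(zf)) < config$snp_rate_nonsyn
    chosen <- dplyr::bind_rows(ffds[pick_f, c("chrom", "pos")],
                               zf[pick_z, c("chrom", "pos")])
    if (nrow(chosen) == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(), af = double()))
    }
    ref <- assembly_seq(assembly, chosen$chrom, chosen$pos, chosen$pos + 1L)
    shift <- sample(1:3, nrow(chosen), replace = TRUE)
    alt <- c("A", "C", "G", "T")[((match(ref, c("A", "C", "G", "T")) - 1L + shift) %% 4L) + 1L]
    out <- tibble::tibble(chrom = chosen$chrom, pos = chosen$pos, ref = ref, alt = alt,
                          af = stats::runif(nrow(chosen), 0.01, 0.5))
    dplyr::arrange(out, .data$chrom, .data$pos)
  })
}

#' Expand a cut profile into read intervals
#'
#' Each cleavage event becomes one read of `read_length` whose 5' end is the
#' cut position (clipped at chromosome ends).
#' @param profile A `cut_profile`.
#' @param read_length Read length in bases.
#' @return Interval tibble with strand.
#' @export
profile_to_reads <- function(profile, read_length = 36L) {
  rows <- purrr::imap(profile$chroms, function(chv, ch) {
    L <- length(chv$plus)
    pp <- which(chv$plus > 0)
    mp <- which(chv$minus > 0)
    tibble::tibble(
      chrom = ch,
      start = c(rep(pp - 1L, chv$plus[pp]),
                rep(pmax(0L, mp - read_length), chv$minus[mp])),
      end = c(rep(pmin(L, pp - 1L + read_length), chv$plus[pp]),
              rep(mp, chv$minus[mp])),
      strand = c(rep("+", sum(chv$plus[pp])), rep("-", sum(chv$minus[mp])))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$name <- NA_character_
  out$score <- NA_real_
  out[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Add PCR-style duplicate reads
#'
#' Appends `round(dup_rate * n)` reads drawn with replacement from the input,
#' emulating PCR bottlenecking for complexity metrics.
#' @param reads Interval tibble.
#' @param dup_rate Expected duplicates as a fraction of input reads.
#' @param seed Seed.
#' @export
add_duplicate_reads <- function(reads, dup_rate, seed) {
  with_seed(seed, {
    n_dup <- round(dup_rate * nrow(reads))
    if (n_dup == 0) return(reads)
    dplyr::bind_rows(reads, reads[sample.int(nrow(reads), n_dup, replace = TRUE), ])
  })
}

#' Run the complete synthetic study
#'
#' Generates the assembly, gene models, bias table, regulatory ground truth,
#' two replicate cleavage profiles per tissue, a naked-DNA control, a
#' diverged second species with its own profile and control, and a
#' constrained variant table; returns everything with a ground-truth
#' manifest.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list.
#' @export
simulate_study <- function(config = sim_config()) {
  base <- generate_assembly(config)
  bias <- generate_bias_table(config)
  truth <- plant_regulatory_truth(base, config)
  assembly <- truth$assembly
  truth <- truth[c("dhs", "footprints")]

  cuts_a1 <- simulate_cuts(assembly, truth, bias, config,
                           derive_seed(config$seed, "cuts_a1"), tissue = "a")
  cuts_a2 <- simulate_cuts(assembly, truth, bias, config,
                           derive_seed(config$seed, "cuts_a2"), tissue = "a")
  cuts_b1 <- simulate_cuts(assembly, truth, bias, config,
                           derive_seed(config$seed, "cuts_b1"), tissue = "b")
  naked <- simulate_naked(assembly, bias, config, derive_seed(config$seed, "naked"))

  sp <- diverge_species(list(assembly = assembly, truth = truth), config)
  cuts_sp <- simulate_cuts(sp$assembly_b, sp$truth_b, bias, config,
                           derive_seed(config$seed, "cuts_sp"), tissue = "a")
  naked_sp <- simulate_naked(sp$assembly_b, bias, config,
                             derive_seed(config$seed, "naked_sp"))

  duons <- interval_intersect(
    genomic_intervals(truth$footprints$chrom, truth$footprints$start,
                      truth$footprints$end, name = truth$footprints$fp_id),
    gene_feature_intervals(base$genes, "cds")
  )
  variants <- simulate_variants(assembly, base$genes, duons, config,
                                derive_seed(config$seed, "variants"))

  structure(list(
    config = config, assembly = assembly, genes = base$genes, bias = bias,
    truth = truth, cuts_a1 = cuts_a1, cuts_a2 = cuts_a2, cuts_b1 = cuts_b1,
    naked = naked, species = sp, cuts_sp = cuts_sp, naked_sp = naked_sp,
    duons = duons, variants = variants
  ), class = "sim_study")
}

#' Write a study's ground-truth manifest as JSON
#' @param study A `sim_study`.
#' @param path Output path.
#' @export
write_manifest <- function(study, path) {
  manifest <- list(
    config = unclass(study$config),
    dhs = study$truth$dhs,
    footprints = study$truth$footprints,
    conservation_labels = study$species$labels,
    blocks = study$species$blocks,
    n_variants = nrow(study$variants)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
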