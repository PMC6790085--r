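#' Run the end-to-end footprinting pipeline on a synthetic study
#'
#' Executes simulate -> qc -> dhs -> footprint (with bias correction) ->
#' differential -> annotate -> duon -> motif -> conserve in dependency
#' order, writing each stage's outputs into `out_dir`. A stage is skipped
#' when all of its outputs exist and are newer than its inputs, so deleting
#' an intermediate regenerates only that stage and everything downstream.
#' All randomness derives from the config seed (per-stage sub-seeds from the
#' stage name), so identical configs reproduce identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param force Re-run every stage regardless of timestamps.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir, force = FALSE,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, paste0(...))
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s: %s",
                                format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
  stage_done <- character()
  run_stage <- function(stage, inputs, outputs, fun) {
    fresh <- all(file.exists(outputs)) &&
      (length(inputs) == 0 ||
         max(file.mtime(inputs)) <= min(file.mtime(outputs)))
    if (!force && fresh) {
      log_line(stage, "up to date, skipped")
    } else {
      log_line(stage, "running")
      tryCatch(fun(), error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
      log_line(stage, "done")
    }
    stage_done <<- c(stage_done, stage)
  }

  files <- list(
    config = pth("config.txt"), genome = pth("genome.fa"), genes = pth("genes.gff3"),
    truth = pth("truth.json"),
    a1p = pth("cuts_a1_plus.bg"), a1m = pth("cuts_a1_minus.bg"),
    a2p = pth("cuts_a2_plus.bg"), a2m = pth("cuts_a2_minus.bg"),
    b1p = pth("cuts_b1_plus.bg"), b1m = pth("cuts_b1_minus.bg"),
    nkp = pth("naked_plus.bg"), nkm = pth("naked_minus.bg"),
    genome_b = pth("genome_b.fa"),
    spp = pth("cuts_sp_plus.bg"), spm = pth("cuts_sp_minus.bg"),
    nsp = pth("naked_sp_plus.bg"), nsm = pth("naked_sp_minus.bg"),
    blocks = pth("blocks.tsv"), variants = pth("variants.tsv"),
    qc = pth("qc.json"), dhs = pth("dhs.bed"), dhs_b = pth("dhs_sp.bed"),
    fp = pth("footprints.tsv"), fp_bed = pth("footprints.bed"),
    fp_sp = pth("footprints_sp.tsv"),
    diff = pth("differential.tsv"), annot = pth("annotation.tsv"),
    duon = pth("duon_test.json"), motif = pth("motif_annotation.tsv"),
    conserve = pth("conservation.tsv"), permtest = pth("permtest.json")
  )

  run_stage("simulate", character(), unlist(files[c(
    "config", "genome", "genes", "truth", "a1p", "a1m", "a2p", "a2m", "b1p", "b1m",
    "nkp", "nkm", "genome_b", "spp", "spm", "nsp", "nsm", "blocks", "variants")]), function() {
    study <- simulate_study(config)
    write_sim_config(config, files$config)
    write_fasta(study$assembly, files$genome)
    write_gff_genes(study$genes, files$genes)
    write_manifest(study, files$truth)
    write_cut_profile(study$cuts_a1, files$a1p, files$a1m)
    write_cut_profile(study$cuts_a2, files$a2p, files$a2m)
    write_cut_profile(study$cuts_b1, files$b1p, files$b1m)
    write_cut_profile(study$naked, files$nkp, files$nkm)
    write_fasta(study$species$assembly_b, files$genome_b)
    write_cut_profile(study$cuts_sp, files$spp, files$spm)
    write_cut_profile(study$naked_sp, files$nsp, files$nsm)
    write_blocks(study$species$blocks, files$blocks)
    write_variants(study$variants, files$variants)
  })

  lens <- function(fa) assembly_lengths(read_fasta(fa))
  load_profile <- function(p, m, fa) read_cut_profile(p, m, lens(fa))

  run_stage("qc", unlist(files[c("a1p", "a1m", "genome", "truth")]), files$qc, function() {
    prof <- load_profile(files$a1p, files$a1m, files$genome)
    truth <- jsonlite::read_json(files$truth, simplifyVector = TRUE)
    reads <- profile_to_reads(prof, config$read_length)
    reads <- add_duplicate_reads(reads, config$dup_rate,
                                 derive_seed(config$seed, "qcdup"))
    rep <- qc_report(reads, tibble::as_tibble(truth$dhs), subsample = 100000,
                     seed = derive_seed(config$seed, "qc"))
    jsonlite::write_json(unclass(rep), files$qc, auto_unbox = TRUE, digits = NA)
  })

  run_stage("dhs", unlist(files[c("a1p", "a1m", "a2p", "a2m", "genome")]),
            files$dhs, function() {
    prof1 <- load_profile(files$a1p, files$a1m, files$genome)
    prof2 <- load_profile(files$a2p, files$a2m, files$genome)
    cons <- replicate_consistency(call_dhs(prof1), call_dhs(prof2))
    write_bed(cons, files$dhs)
  })

  run_stage("footprint", unlist(files[c("dhs", "a1p", "a1m", "nkp", "nkm", "genome")]),
            c(files$fp, files$fp_bed), function() {
    genome <- read_fasta(files$genome)
    prof <- load_profile(files$a1p, files$a1m, files$genome)
    naked <- load_profile(files$nkp, files$nkm, files$genome)
    dhs <- read_bed(files$dhs)
    calls <- call_footprints(dhs, prof)
    bias <- estimate_bias(naked, genome)
    calls <- footprint_flr(calls, prof, genome, bias)
    readr::write_tsv(calls, files$fp)
    write_bed(calls[calls$retained, ], files$fp_bed)
  })

  run_stage("differential", unlist(files[c("fp_bed", "a1p", "a1m", "b1p", "b1m", "genome")]),
            files$diff, function() {
    prof_a <- load_profile(files$a1p, files$a1m, files$genome)
    prof_b <- load_profile(files$b1p, files$b1m, files$genome)
    fp <- read_bed(files$fp_bed)
    dd <- differential_footprints(prof_a, prof_b, fp,
                                  seed = derive_seed(config$seed, "diff"))
    readr::write_tsv(dd, files$diff)
  })

  run_stage("annotate", unlist(files[c("fp_bed", "genes")]), files$annot, function() {
    fp <- read_bed(files$fp_bed)
    genes <- read_gff_genes(files$genes)
    cls <- classify_regions(fp, genes)
    readr::write_tsv(cls, files$annot)
  })

  run_stage("duon", unlist(files[c("fp_bed", "genes", "genome", "variants")]),
            files$duon, function() {
    fp <- read_bed(files$fp_bed)
    genes <- read_gff_genes(files$genes)
    genome <- read_fasta(files$genome)
    variants <- read_variants(files$variants, genome)
    duons <- find_duons(fp, genes)
    surrounding <- surrounding_exon_regions(duons, genes)
    res <- duon_constraint_test(variants, duons, surrounding, genes, genome)
    jsonlite::write_json(list(counts = res$counts, ffds_chi2 = res$ffds_chi2,
                              ffds_p = res$ffds_p, nonsyn_chi2 = res$nonsyn_chi2,
                              nonsyn_p = res$nonsyn_p, gc_duon = res$gc_duon,
                              gc_surrounding = res$gc_surrounding),
                         files$duon, auto_unbox = TRUE, digits = NA, na = "null")
  })

  run_stage("motif", unlist(files[c("fp_bed", "genome")]), files$motif, function() {
    fp <- read_bed(files$fp_bed)
    genome <- read_fasta(files$genome)
    lib <- purrr::imap(builtin_motif_consensus(), ~consensus_pwm(.y, .x))
    ann <- annotate_dgfs(fp, lib, genome)
    readr::write_tsv(ann$per_dgf, files$motif)
  })

  run_stage("conserve",
            unlist(files[c("spp", "spm", "nsp", "nsm", "genome_b", "fp_bed", "blocks")]),
            c(files$dhs_b, files$fp_sp, files$conserve, files$permtest), function() {
    genome_b <- read_fasta(files$genome_b)
    prof_b <- load_profile(files$spp, files$spm, files$genome_b)
    naked_b <- load_profile(files$nsp, files$nsm, files$genome_b)
    dhs_b <- call_dhs(prof_b)
    write_bed(dhs_b, files$dhs_b)
    calls_b <- call_footprints(dhs_b, prof_b)
    bias_b <- estimate_bias(naked_b, genome_b)
    calls_b <- footprint_flr(calls_b, prof_b, genome_b, bias_b)
    readr::write_tsv(calls_b, files$fp_sp)
    fp <- read_bed(files$fp_bed)
    blocks <- read_blocks(files$blocks)
    cls <- classify_conservation(fp, calls_b[calls_b$retained, ], blocks)
    readr::write_tsv(cls, files$conserve)
    dhs <- read_bed(files$dhs)
    pt <- permutation_overlap(fp, dhs, lens(files$genome), n_perm = 100,
                              seed = derive_seed(config$seed, "permtest"))
    jsonlite::write_json(glance(pt), files$permtest, auto_unbox = TRUE, digits = NA)
  })

  outputs <- unlist(files)
  manifest <- list(
    config = unclass(config),
    stages = stage_done,
    checksums = as.list(stats::setNames(
      tools::md5sum(outputs[file.exists(outputs)]),
      basename(outputs[file.exists(outputs)])))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
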