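#' Read a BED file into an interval tibble
#'
#' Accepts BED3 to BED6; columns 4-6 populate `name`, `score`, `strand` when
#' present. Input order is preserved.
#'
#' @param path BED file path.
#' @return Interval tibble (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns",
         call. = FALSE)
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], ": non-integer coordinates", call. = FALSE)
  }
  badc <- which(start >= end | start < 0)
  if (length(badc) > 0) {
    stop("invalid interval on BED line ", badc[1], ": need 0 <= start < end",
         call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(get(5, NA)))
  genomic_intervals(
    chrom = get(1, NA),
    start = start, end = end,
    name = dplyr::na_if(get(4, NA_character_), "."),
    score = score,
    strand = dplyr::coalesce(dplyr::na_if(get(6, NA_character_), ""), ".")
  )
}

#' Write an interval tibble as BED6
#' @param intervals Interval tibble.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name else NA
  score <- if ("score" %in% names(intervals)) intervals$score else NA
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  lines <- paste(intervals$chrom,
                 format(intervals$start, scientific = FALSE, trim = TRUE),
                 format(intervals$end, scientific = FALSE, trim = TRUE),
                 ifelse(is.na(name), ".", name),
                 ifelse(is.na(score), "0", format(score, scientific = FALSE, trim = TRUE)),
                 strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene`, `mRNA`, `exon` and `CDS` features (one mRNA per gene).
#' GFF3 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention; CDS phase is taken from column 8 of the first CDS
#' segment in translation order.
#'
#' @param path GFF3 file path.
#' @return A gene-model tibble: one row per gene with columns `gene_id, chrom,
#'   strand, tss, tts, start, end, phase` and list-columns `exons`, `cds`
#'   (each a tibble of `start`, `end`).
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_gene_models())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) {
    stop("malformed GFF line ", which(lengths(f) < 9)[1], call. = FALSE)
  }
  rec <- tibble::tibble(
    chrom = vapply(f, `[`, "", 1),
    type = vapply(f, `[`, "", 3),
    start = as.integer(vapply(f, `[`, "", 4)) - 1L, # to 0-based half-open
    end = as.integer(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7),
    phase = vapply(f, `[`, "", 8),
    attr = vapply(f, `[`, "", 9)
  )
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]+"), a))
    out <- rep(NA_character_, length(a))
    out[lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "="), a))) > 0] <-
      sub(paste0(".*", key, "="), "", m)
    out
  }
  rec$id <- attr_field(rec$attr, "ID")
  rec$parent <- attr_field(rec$attr, "Parent")

  mrna <- rec[rec$type == "mRNA", ]
  mrna_gene <- stats::setNames(mrna$parent, mrna$id)
  sub_feats <- rec[rec$type %in% c("exon", "CDS"), ]
  orphan <- which(!sub_feats$parent %in% mrna$id)
  if (length(orphan) > 0) {
    stop(sub_feats$type[orphan[1]], " feature without parent mRNA: parent=",
         sub_feats$parent[orphan[1]], call. = FALSE)
  }
  genes <- rec[rec$type == "gene", ]
  models <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tr <- mrna$id[mrna$parent == g$id]
    ex <- sub_feats[sub_feats$type == "exon" & sub_feats$parent %in% tr, c("start", "end")]
    cd <- sub_feats[sub_feats$type == "CDS" & sub_feats$parent %in% tr,
                    c("start", "end", "phase")]
    ex <- dplyr::arrange(ex, .data$start)
    cd <- dplyr::arrange(cd, .data$start)
    first_cds <- if (nrow(cd) == 0) NA_character_ else if (g$strand == "+") {
      cd$phase[1]
    } else cd$phase[nrow(cd)]
    gene_model_row(
      gene_id = g$id, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end,
      exons = tibble::as_tibble(ex),
      cds = tibble::as_tibble(cd[, c("start", "end")]),
      phase = if (is.na(first_cds)) 0L else as.integer(first_cds)
    )
  })
  validate_gene_models(dplyr::bind_rows(models))
}

#' Write gene models as GFF3 (inverse of [read_gff_genes()])
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    row9 <- function(type, s, e, phase, attrs) {
      paste(g$chrom, "footprintr", type, s + 1L, e, ".", g$strand, phase, attrs,
            sep = "\t")
    }
    lines <- c(lines,
               row9("gene", g$start, g$end, ".", paste0("ID=", gid)),
               row9("mRNA", g$start, g$end, ".", paste0("ID=", tid, ";Parent=", gid)))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, row9("exon", ex$start[j], ex$end[j], ".",
                             paste0("ID=", tid, ".exon", j, ";Parent=", tid)))
    }
    cd <- g$cds[[1]]
    phases <- cds_phases(cd, g$strand, g$phase)
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines, row9("CDS", cd$start[j], cd$end[j], phases[j],
                             paste0("ID=", tid, ".cds", j, ";Parent=", tid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# phase of each CDS segment (in genomic order) given the phase of the first
# base in translation order
cds_phases <- function(cds, strand, phase0 = 0L) {
  if (nrow(cds) == 0) return(integer())
  lens <- cds$end - cds$start
  ord <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  ph <- integer(nrow(cds))
  acc <- phase0
  for (k in ord) {
    ph[k] <- acc %% 3L
    acc <- (3L - ((lens[k] - acc) %% 3L)) %% 3L
  }
  ph
}

#' Read / write stranded per-base cleavage profiles (bedGraph pair)
#'
#' A cut profile stores the number of DNaseI 5' cleavage events at every base
#' on each strand. On disk it is a pair of bedGraph files (plus, minus);
#' in memory a `cut_profile` object: per chromosome a list with integer
#' vectors `plus` and `minus` of length equal to the chromosome.
#'
#' @param plus_path,minus_path bedGraph paths for the two strands.
#' @param lengths Named chromosome lengths (required to build dense vectors).
#' @return A `cut_profile` object.
#' @export
read_cut_profile <- function(plus_path, minus_path, lengths) {
  read_one <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    df <- utils::read.table(path, sep = "\t", col.names = c("chrom", "start", "end", "value"),
                            colClasses = c("character", "integer", "integer", "numeric"))
    if (nrow(df) > 0) {
      ov <- df |>
        dplyr::group_by(.data$chrom) |>
        dplyr::arrange(.data$start, .by_group = TRUE) |>
        dplyr::summarise(bad = any(dplyr::lag(.data$end, default = -1L) > .data$start))
      if (any(ov$bad)) {
        stop("overlapping bedGraph records on ", ov$chrom[ov$bad][1], call. = FALSE)
      }
    }
    df
  }
  plus <- read_one(plus_path)
  minus <- read_one(minus_path)
  prof <- lapply(stats::setNames(names(lengths), names(lengths)), function(ch) {
    dense <- function(df) {
      v <- integer(lengths[[ch]])
      d <- df[df$chrom == ch, , drop = FALSE]
      if (nrow(d) > 0) {
        if (any(d$end > lengths[[ch]])) {
          stop("bedGraph record beyond chromosome end on ", ch, call. = FALSE)
        }
        runs <- d$end - d$start
        v[sequence(runs, from = d$start + 1L)] <- rep(as.integer(d$value), runs)
      }
      v
    }
    list(plus = dense(plus), minus = dense(minus))
  })
  new_cut_profile(prof)
}

new_cut_profile <- function(chroms) {
  structure(list(chroms = chroms), class = "cut_profile")
}

#' @export
print.cut_profile <- function(x, ...) {
  cat("<cut_profile> ", length(x$chroms), " chromosome(s), ",
      format(total_cuts(x), big.mark = ","), " cuts\n", sep = "")
  invisible(x)
}

#' Total cleavage events in a profile (both strands, all chromosomes)
#' @param profile A `cut_profile`.
#' @export
total_cuts <- function(profile) {
  sum(vapply(profile$chroms, function(ch) sum(as.numeric(ch$plus)) + sum(as.numeric(ch$minus)),
             numeric(1)))
}

#' @param profile A `cut_profile`.
#' @rdname read_cut_profile
#' @export
write_cut_profile <- function(profile, plus_path, minus_path) {
  write_one <- function(path, strand) {
    con <- file(path, "w")
    on.exit(close(con))
    for (ch in names(profile$chroms)) {
      v <- profile$chroms[[ch]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        writeLines(paste(ch, starts[keep], ends[keep], r$values[keep], sep = "\t"), con)
      }
    }
  }
  write_one(plus_path, "plus")
  write_one(minus_path, "minus")
  invisible(c(plus_path, minus_path))
}

#' Read / write biallelic SNP tables
#'
#' TSV with header `chrom pos ref alt af`; positions 0-based. Indels (alleles
#' longer than one base) are rejected.
#' @param path TSV path.
#' @param assembly Optional assembly to check `ref` alleles against.
#' @return Tibble `chrom, pos, ref, alt, af`.
#' @export
read_variants <- function(path, assembly = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    af = readr::col_double()
  ))
  validate_variants(df, assembly)
  df
}

validate_variants <- function(df, assembly = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(nchar(df$ref) != 1 | nchar(df$alt) != 1)) {
    stop("indel alleles not supported (row ",
         which(nchar(df$ref) != 1 | nchar(df$alt) != 1)[1], ")", call. = FALSE)
  }
  if (any(df$ref == df$alt)) stop("ref == alt at row ", which(df$ref == df$alt)[1],
                                  call. = FALSE)
  if (any(!(df$af > 0 & df$af <= 1))) stop("allele frequency outside (0,1]", call. = FALSE)
  if (!is.null(assembly)) {
    obs <- assembly_seq(assembly, df$chrom, df$pos, df$pos + 1L)
    bad <- which(obs != df$ref)
    if (length(bad) > 0) {
      stop("ref allele mismatch with assembly at row ", bad[1], call. = FALSE)
    }
  }
  invisible(df)
}

#' @param variants Variant tibble.
#' @rdname read_variants
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants[, c("chrom", "pos", "ref", "alt", "af")], path)
  invisible(path)
}

#' Read / write ungapped pairwise alignment blocks
#'
#' TSV with header `chromA startA endA chromB startB endB orient`. Blocks are
#' ungapped and length-matched; they must not overlap on assembly A.
#' @param path TSV path.
#' @return Tibble of blocks, sorted on A.
#' @export
read_blocks <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chromA = readr::col_character(), startA = readr::col_integer(),
    endA = readr::col_integer(), chromB = readr::col_character(),
    startB = readr::col_integer(), endB = readr::col_integer(),
    orient = readr::col_character()
  ))
  validate_blocks(df)
}

validate_blocks <- function(df) {
  if (nrow(df) > 0) {
    if (any(df$endA - df$startA != df$endB - df$startB)) {
      stop("length-mismatched alignment block", call. = FALSE)
    }
    if (!all(df$orient %in% c("+", "-"))) stop("invalid block orientation", call. = FALSE)
    df <- dplyr::arrange(df, .data$chromA, .data$startA)
    ov <- df |>
      dplyr::group_by(.data$chromA) |>
      dplyr::summarise(bad = any(dplyr::lag(.data$endA, default = -1L) > .data$startA))
    if (any(ov$bad)) stop("alignment blocks overlap on assembly A", call. = FALSE)
  }
  df
}

#' @param blocks Block tibble.
#' @rdname read_blocks
#' @export
write_blocks <- function(blocks, path) {
  readr::write_tsv(blocks[, c("chromA", "startA", "endA", "chromB", "startB",
                              "endB", "orient")], path)
  invisible(path)
}

#' Read JASPAR-style position frequency matrices
#'
#' Accepts the `>id name` header followed by four rows `A [ n n n ... ]` (the
#' brackets are optional). Multiple motifs per file are supported.
#' @param path PFM text file.
#' @return List of `pwm` objects (see [pwm()]).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no motif headers in ", path, call. = FALSE)
  bounds <- c(heads, length(lines) + 1L)
  purrr::map(seq_along(heads), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- block[grepl(paste0("^", b, "\\b"), block)]
      if (length(ln) != 1) stop("motif ", id, ": missing/duplicate row ", b, call. = FALSE)
      as.numeric(strsplit(gsub("[][A-Za-z]", " ", ln), "\\s+")[[1]] |>
                   (\(x) x[nzchar(x)])())
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("motif ", id, ": ragged matrix", call. = FALSE)
    }
    pwm(id, do.call(rbind, rows))
  })
}

#' Write motifs in JASPAR PFM format
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$id),
      vapply(1:4, function(r) {
        paste0(c("A", "C", "G", "T")[r], " [ ",
               paste(format(p$counts[r, ], trim = TRUE), collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}
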