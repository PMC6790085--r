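#' Genome assembly container
#'
#' A genome assembly is a named list of uppercase DNA strings over
#' `{A,C,G,T,N}`, one per chromosome, wrapped in a light S3 class.
#'
#' @param sequences Named character vector or list of DNA strings.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(sequences) {
  sequences <- as.list(sequences)
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("assembly sequences must be named by chromosome", call. = FALSE)
  }
  sequences <- lapply(sequences, function(s) toupper(as.character(s)))
  bad <- vapply(sequences, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) stop("non-ACGTN character in chromosome ", names(sequences)[bad][1],
                     call. = FALSE)
  if (any(nchar(unlist(sequences)) < 1)) stop("empty chromosome sequence", call. = FALSE)
  structure(list(sequences = sequences), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  lens <- assembly_lengths(x)
  cat("<genome_assembly> ", length(lens), " chromosome(s), ",
      format(sum(as.numeric(lens)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of an assembly
#' @param assembly A [genome_assembly()].
#' @return Named integer vector.
#' @export
assembly_lengths <- function(assembly) {
  vapply(assembly$sequences, nchar, integer(1))
}

#' Extract the sequence of an interval (plus strand unless `strand = "-"`)
#'
#' @param assembly A [genome_assembly()].
#' @param chrom,start,end 0-based half-open coordinates (vectorized).
#' @param strand `"+"`/`"."` returns the forward sequence, `"-"` its reverse
#'   complement.
#' @return Character vector of sequences, each of length `end - start`.
#' @export
assembly_seq <- function(assembly, chrom, start, end, strand = "+") {
  lens <- assembly_lengths(assembly)
  stopifnot(all(chrom %in% names(lens)), all(start >= 0), all(end <= lens[chrom]))
  n <- max(length(chrom), length(start), length(end))
  strand <- rep_len(strand, n)
  out <- substring(unlist(assembly$sequences[chrom], use.names = FALSE), start + 1, end)
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  out
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA (`ACGTN`).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Read / write FASTA assemblies
#'
#' Thin wrappers over Biostrings; sequences are uppercased on read.
#' @param path FASTA file path.
#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome_assembly(stats::setNames(as.character(ss), names(ss)))
}

#' @param assembly A [genome_assembly()].
#' @rdname fasta_io
#' @export
write_fasta <- function(assembly, path) {
  ss <- Biostrings::DNAStringSet(unlist(assembly$sequences))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

## ---- hexamer machinery ----------------------------------------------------

HEX_K <- 6L
N_HEX <- 4096L

base_codes <- function(seq) {
  # A=0 C=1 G=2 T=3, N -> NA
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  code
}

#' All 4096 hexamer strings in index order
#' @keywords internal
hexamer_names <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  apply(g, 1, paste0, collapse = "")
}

.hex_cache <- new.env(parent = emptyenv())

# index (1..4096) of the reverse complement of each hexamer index
hexamer_rc_index <- function() {
  if (!is.null(.hex_cache$rc)) return(.hex_cache$rc)
  idx0 <- 0:(N_HEX - 1L)
  digits <- sapply(0:(HEX_K - 1L), function(j) (idx0 %/% 4L^j) %% 4L) # last base first
  # reverse complement: reverse base order and complement (0<->3, 1<->2)
  comp <- 3L - digits
  rc <- rowSums(comp * matrix(rep(4L^((HEX_K - 1L):0), each = N_HEX), ncol = HEX_K))
  .hex_cache$rc <- as.integer(rc + 1L)
  .hex_cache$rc
}

#' Per-position hexamer indices for cleavage-site context
#'
#' For a cut whose 5' end maps to 0-based position `c` on the plus strand, the
#' cleavage falls between bases `c-1` and `c`; the hexamer context is the
#' window `[c-3, c+3)` so the cleavage sits between its third and fourth
#' bases. For a minus-strand cut at `c` the cleavage falls between `c` and
#' `c+1` and the context is the reverse complement of `[c-2, c+4)`.
#'
#' @param seq One chromosome sequence (string).
#' @return List with integer vectors `plus` and `minus`, length `nchar(seq)`,
#'   giving the 1..4096 hexamer index of the context at each cut position
#'   (NA near chromosome ends or where the window contains N).
#' @export
hexamer_context <- function(seq) {
  L <- nchar(seq)
  code <- base_codes(seq)
  if (L < HEX_K) {
    return(list(plus = rep(NA_integer_, L), minus = rep(NA_integer_, L)))
  }
  nwin <- L - HEX_K + 1L
  v <- integer(nwin)
  ok <- rep(TRUE, nwin)
  for (j in 0:(HEX_K - 1L)) {
    cj <- code[(1L + j):(nwin + j)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 0L
    v <- v + cj * 4L^(HEX_K - 1L - j)
  }
  widx <- ifelse(ok, v + 1L, NA_integer_) # hexamer index of window starting at 1-based i
  plus <- rep(NA_integer_, L)
  # cut at 0-based c uses window starting 1-based at c-2  (c in 3..L-3)
  cpos <- 3:(L - 3L)
  plus[cpos + 1L] <- widx[cpos - 2L]
  minus <- rep(NA_integer_, L)
  rc <- hexamer_rc_index()
  # cut at 0-based c uses RC of window starting 1-based at c-1 (c in 2..L-4)
  cpos_m <- 2:(L - 4L)
  minus[cpos_m + 1L] <- rc[widx[cpos_m - 1L]]
  list(plus = plus, minus = minus)
}

#' Genome-wide hexamer counts (both strands)
#'
#' Counts every overlapping hexamer on the forward strand and its reverse
#' complement; windows containing N are skipped.
#' @param assembly A [genome_assembly()].
#' @return Integer vector of length 4096 named by hexamer.
#' @export
genome_hexamer_counts <- function(assembly) {
  ss <- Biostrings::DNAStringSet(unlist(assembly$sequences))
  fwd <- colSums(Biostrings::oligonucleotideFrequency(ss, width = HEX_K, step = 1L))
  # both strands: add reverse-complement counts
  counts <- fwd + fwd[revcomp(names(fwd))]
  counts[hexamer_names()]
}

#' GC fraction of an interval set
#' @param regions Interval tibble.
#' @param assembly A [genome_assembly()].
#' @return Fraction of non-N bases that are G or C.
#' @export
gc_fraction <- function(regions, assembly) {
  if (nrow(regions) == 0) return(NA_real_)
  seqs <- assembly_seq(assembly, regions$chrom, regions$start, regions$end)
  s <- paste0(seqs, collapse = "")
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_at <- nchar(gsub("[^AT]", "", s))
  n_gc / (n_gc + n_at)
}
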