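#' Genome records
#'
#' A `genome_record` holds one taxon's nucleotide sequence (all contigs of a
#' multi-record FASTA concatenated), its length `g` in bases, and its
#' A/C/G/T composition computed over unambiguous residues only.
#'
#' @param sequence Single character string of nucleotide residues
#'   (case-insensitive; IUPAC ambiguity codes and `N` are kept but excluded
#'   from the composition).
#' @param name Taxon label.
#' @return An object of class `genome_record` with fields `name`, `sequence`
#'   (uppercase), `g` (total length in bases) and `freqs` (named A/C/G/T
#'   fractions summing to 1, or all `NA` if the sequence has no unambiguous
#'   residue).
#' @examples
#' gr <- genome_record("ACGTACGT", "toy")
#' gr$freqs
#' @export
genome_record <- function(sequence, name = "genome") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  g <- nchar(sequence)
  if (g < 1L) stop("empty genome: '", name, "' has no residues")
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    g - nchar(gsub(b, "", sequence, fixed = TRUE))
  }, numeric(1))
  tot <- sum(counts)
  freqs <- if (tot > 0) counts / tot else rep(NA_real_, 4)
  names(freqs) <- c("A", "C", "G", "T")
  structure(list(name = name, sequence = sequence, g = g, freqs = freqs),
            class = "genome_record")
}

#' Read a genome assembly from a FASTA file
#'
#' All records of the file are concatenated into a single taxon: contigs share
#' one composition vector, but k-mer windows never span contig boundaries
#' (record breaks are preserved internally as window breaks).
#'
#' @param path FASTA file, plain or gzip-compressed.
#' @param name Taxon label; defaults to the file name without extensions.
#' @return A [genome_record()]. Contig boundaries are retained in attribute
#'   `"contig_breaks"` consumed by [bottom_sketch()].
#' @export
read_genome <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty genome: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) stop("not FASTA: ", path, " does not start with '>'")
  rec_id <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], rec_id[!is_hdr]),
                 paste0, character(1), collapse = "")
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L)
    stop("empty genome: ", path, " has no residues")
  if (is.null(name)) name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                 basename(path), ignore.case = TRUE)
  rec <- genome_record(paste0(seqs, collapse = ""), name)
  attr(rec, "contig_breaks") <- cumsum(nchar(seqs))
  rec
}

#' @export
print.genome_record <- function(x, ...) {
  cat("Genome record:", x$name, "\n")
  cat("  length g =", x$g, "bases\n")
  if (anyNA(x$freqs)) cat("  composition: no unambiguous residues\n")
  else cat("  composition:",
           paste(sprintf("%s=%.4f", names(x$freqs), x$freqs), collapse = " "),
           "\n")
  invisible(x)
}

# Contig-aware residue chunks: k-mer windows must not span record boundaries.
.genome_chunks <- function(rec) {
  brk <- attr(rec, "contig_breaks")
  if (is.null(brk) || length(brk) <= 1L) return(rec$sequence)
  start <- c(1L, head(brk, -1L) + 1L)
  substring(rec$sequence, start, brk)
}
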