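#' Choose a k-mer size from a random-match probability
#'
#' The k-mer size is set large enough that the probability `q` of two genomes
#' of length `g` sharing a random k-mer by chance alone stays below the
#' requested level: `k = ceil(log4(g (1 - q) / q) - 0.5)`, never below 1.
#'
#' @param g Genome length in bases (the largest genome under comparison).
#' @param q Acceptable random-match probability, in (0, 1).
#' @return Integer k-mer size.
#' @examples
#' choose_k(5e6, 1e-9)  # 26
#' @export
choose_k <- function(g, q) {
  stopifnot(g >= 1)
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  pmax(1L, as.integer(ceiling(log(g * (1 - q) / q, base = 4) - 0.5)))
}

#' Canonical k-mers of a genome
#'
#' Every window of length `k` made only of A/C/G/T contributes the
#' lexicographically smaller of the k-mer and its reverse complement; windows
#' containing any other symbol are skipped, windows never span contig
#' boundaries, and the result is deduplicated.  This reference implementation
#' is string-based and intended for small inputs and verification; the sketch
#' path ([bottom_sketch()]) uses an independent packed-integer implementation.
#'
#' @param rec A [genome_record()] or a plain character string.
#' @param k k-mer size.
#' @return Character vector of distinct canonical k-mers (unsorted order not
#'   guaranteed).
#' @export
canonical_kmers <- function(rec, k) {
  stopifnot(k >= 1)
  chunks <- if (inherits(rec, "genome_record")) .genome_chunks(rec)
            else toupper(rec)
  out <- character(0)
  for (ch in chunks) {
    n <- nchar(ch)
    if (n < k) next
    kmers <- substring(ch, 1:(n - k + 1L), k:n)
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    if (!length(kmers)) next
    rc <- .revcomp(kmers)
    out <- c(out, ifelse(kmers <= rc, kmers, rc))
  }
  unique(out)
}

.revcomp <- function(x) {
  flipped <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(flipped, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

#' Bottom-sketch MinHash signature of a genome
#'
#' Hashes every canonical k-mer with a seeded 64-bit MurmurHash3-finalizer
#' over the 2-bit-packed k-mer (truncated to 53 bits so values are exact in
#' doubles) and keeps the `sigma` smallest distinct values.  Two sketches
#' built with the same `k`, `sigma` and `seed` estimate the Jaccard index of
#' the genomes' full canonical k-mer sets via [estimate_jaccard()].
#'
#' @param rec A [genome_record()].
#' @param k k-mer size, at most 31.
#' @param sigma Sketch size (number of hashes retained).
#' @param seed Hash seed (any integer); sketches are only comparable across
#'   identical seeds.
#' @return An object of class `genome_sketch`: fields `taxon`, `k`, `sigma`,
#'   `seed`, `g`, `freqs` and `hashes` (strictly increasing numeric vector of
#'   at most `sigma` values; shorter only when the genome has fewer distinct
#'   canonical k-mers).
#' @export
bottom_sketch <- function(rec, k, sigma, seed = 42L) {
  stopifnot(inherits(rec, "genome_record"), k >= 1, k <= 31, sigma >= 1)
  if (anyNA(rec$freqs))
    stop("no unambiguous residues: cannot sketch '", rec$name, "'")
  chunks <- .genome_chunks(rec)
  hashes <- sort(unique(unlist(lapply(chunks, .sketch_hashes_cpp,
                                      k = as.integer(k), sigma = -1,
                                      seed = as.double(seed)))))
  if (length(hashes) == 0L)
    stop("no k-mers: '", rec$name, "' has no unambiguous window of length ",
         k)
  structure(list(taxon = rec$name, k = as.integer(k),
                 sigma = as.integer(sigma), seed = as.integer(seed),
                 g = rec$g, freqs = rec$freqs,
                 hashes = hashes[seq_len(min(sigma, length(hashes)))]),
            class = "genome_sketch")
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat("MinHash bottom sketch:", x$taxon, "\n")
  cat(sprintf("  k = %d, sigma = %d (holding %d), seed = %d, g = %d\n",
              x$k, x$sigma, length(x$hashes), x$seed, x$g))
  invisible(x)
}

#' Sketch a set of genomes with shared parameters
#'
#' Resolves the k-mer size from `q` against the largest genome of the set
#' (unless `k` is given) and the sketch size from the fraction `s` of the
#' mean genome length (unless `sigma` is given), then sketches every genome
#' with the shared parameters.
#'
#' @param recs List of [genome_record()]s, or character vector of FASTA paths.
#' @param k,q Exactly one of: explicit k-mer size, or random-match
#'   probability from which k is derived via [choose_k()].
#' @param sigma,s Exactly one of: explicit sketch size, or fraction of the
#'   mean genome length (default `s = 0.5`).
#' @param seed Hash seed shared by all sketches.
#' @return List of `genome_sketch` objects.
#' @export
sketch_genomes <- function(recs, k = NULL, q = 1e-9, sigma = NULL, s = 0.5,
                           seed = 42L) {
  if (is.character(recs)) recs <- lapply(recs, read_genome)
  stopifnot(length(recs) >= 1)
  g <- vapply(recs, `[[`, numeric(1), "g")
  if (is.null(k)) k <- choose_k(max(g), q)
  if (is.null(sigma)) {
    stopifnot(s > 0, s <= 1)
    sigma <- max(1L, round(s * mean(g)))
  }
  lapply(recs, bottom_sketch, k = k, sigma = sigma, seed = seed)
}

#' Estimate a Jaccard index from two sketches
#'
#' Merged bottom-sketch estimator: pool both hash lists, keep the `sigma`
#' smallest distinct values `U` of the union (fewer if the sketches jointly
#' hold fewer), and count how many elements of `U` occur in both sketches.
#'
#' @param a,b `genome_sketch` objects built with identical `k`, `sigma` and
#'   `seed`.
#' @return Object of class `jaccard_estimate`: `j_hat = shared / denom`,
#'   with integer fields `shared` and `denom` (`denom <= sigma`).
#' @export
estimate_jaccard <- function(a, b) {
  stopifnot(inherits(a, "genome_sketch"), inherits(b, "genome_sketch"))
  if (a$k != b$k || a$seed != b$seed || a$sigma != b$sigma)
    stop("incompatible sketches: k, sigma and seed must match (",
         a$taxon, " vs ", b$taxon, ")")
  u <- sort(unique(c(a$hashes, b$hashes)))
  u <- u[seq_len(min(a$sigma, length(u)))]
  shared <- sum((u %in% a$hashes) & (u %in% b$hashes))
  structure(list(j_hat = shared / length(u), shared = shared,
                 denom = length(u)),
            class = "jaccard_estimate")
}

#' @export
print.jaccard_estimate <- function(x, ...) {
  cat(sprintf("Jaccard estimate: j_hat = %.6f (%d / %d)\n",
              x$j_hat, x$shared, x$denom))
  invisible(x)
}

#' Sketch persistence in a flat text format
#'
#' One header line (`taxon k sigma seed g piA piC piG piT`, tab-separated)
#' followed by one decimal hash value per line.  Round-trips are bit-exact:
#' hash values are 53-bit integers stored exactly in doubles.
#'
#' @param sk A `genome_sketch`.
#' @param path Output file.
#' @return `path`, invisibly (`write_sketch`); the restored `genome_sketch`
#'   (`read_sketch`).
#' @export
write_sketch <- function(sk, path) {
  stopifnot(inherits(sk, "genome_sketch"))
  hdr <- paste(c(sk$taxon, sk$k, sk$sigma, sk$seed, sk$g,
                 sprintf("%.17g", sk$freqs)), collapse = "\t")
  writeLines(c("#skimer-sketch\tv1", hdr, sprintf("%.0f", sk$hashes)), path)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#skimer-sketch"))
    stop("not a skimer sketch file: ", path)
  f <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  freqs <- as.numeric(f[6:9])
  names(freqs) <- c("A", "C", "G", "T")
  structure(list(taxon = f[1L], k = as.integer(f[2L]),
                 sigma = as.integer(f[3L]), seed = as.integer(f[4L]),
                 g = as.numeric(f[5L]), freqs = freqs,
                 hashes = as.numeric(lines[-(1:2)])),
            class = "genome_sketch")
}
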