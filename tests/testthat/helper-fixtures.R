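# Shared fixtures: random genomes, mutated relatives, brute-force oracles.

random_genome <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# substitute a fraction of positions with a different base
mutate_genome <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  idx <- which(runif(length(ch)) < rate)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# independent exact Jaccard on the full canonical k-mer sets (string route)
exact_jaccard <- function(rec_a, rec_b, k) {
  ka <- canonical_kmers(rec_a, k)
  kb <- canonical_kmers(rec_b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

fasta_file <- function(records, path = tempfile(fileext = ".fa"),
                       gz = FALSE) {
  lines <- unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]])))
  if (gz) {
    path <- paste0(path, ".gz")
    con <- gzfile(path, "wt")
    writeLines(lines, con)
    close(con)
  } else writeLines(lines, path)
  path
}

# additive distance matrix from a tree (patristic distances)
additive_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[sort(rownames(d)), sort(rownames(d))]
}
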