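test_that("FASTA reading concatenates contigs and computes composition", {
  p <- fasta_file(list(c1 = "ACGT", c2 = "AC"))
  g <- read_genome(p)
  expect_equal(g$g, 6)
  expect_equal(unname(g$freqs), c(1/3, 1/3, 1/6, 1/6))

  pgz <- fasta_file(list(c1 = "ACGT", c2 = "AC"), gz = TRUE)
  ggz <- read_genome(pgz, name = g$name)
  expect_equal(ggz[c("sequence", "g", "freqs")],
               g[c("sequence", "g", "freqs")])

  pn <- fasta_file(list(x = "NNNN"))
  gn <- read_genome(pn)
  expect_equal(gn$g, 4)
  expect_true(all(is.na(gn$freqs)))
  expect_error(bottom_sketch(gn, 2, 10), "no unambiguous")

  pe <- tempfile()
  writeLines(character(0), pe)
  expect_error(read_genome(pe), "empty")
  pb <- tempfile()
  writeLines("ACGT no header", pb)
  expect_error(read_genome(pb), "not FASTA")
})

test_that("choose_k follows the random-match rule and its monotonicities", {
  expect_equal(choose_k(5e6, 1e-3), 16L)
  expect_equal(choose_k(5e6, 1e-6), 21L)
  expect_equal(choose_k(5e6, 1e-9), 26L)
  expect_equal(choose_k(5e6, 1e-12), 31L)
  # stable over the whole simulated genome-length range
  for (g in c(3.38e6, 4e6, 4.99e6))
    expect_equal(sapply(c(1e-3, 1e-6, 1e-9, 1e-12), choose_k, g = g),
                 c(16L, 21L, 26L, 31L))
  expect_equal(choose_k(4, 0.5), 1L)
  # non-decreasing in g, non-increasing in q
  gs <- c(1e3, 1e4, 1e6, 1e8)
  expect_false(is.unsorted(choose_k(gs, 1e-6)))
  qs <- c(1e-12, 1e-9, 1e-6, 1e-3)   # ascending q -> non-increasing k
  expect_false(is.unsorted(rev(sapply(qs, choose_k, g = 1e6))))
  expect_error(choose_k(100, 0), "q must")
  expect_error(choose_k(100, 1), "q must")
})

test_that("canonical k-mers use the min of k-mer and reverse complement", {
  expect_equal(canonical_kmers("ACGT", 4), "ACGT") # palindrome
  expect_setequal(canonical_kmers("AAAC", 2), c("AA", "AC"))
  expect_equal(canonical_kmers("ANGT", 2), "AC")   # ambiguity voids windows
  expect_length(canonical_kmers("ACG", 4), 0)      # k > g
  # windows never span contig boundaries
  p <- fasta_file(list(c1 = "ACG", c2 = "TTT"))
  expect_setequal(canonical_kmers(read_genome(p), 3),
                  c("ACG", "AAA"))
})

test_that("bottom sketches are deterministic, strand-symmetric, saturating", {
  set.seed(101)
  g <- genome_record(random_genome(300), "t")
  s1 <- bottom_sketch(g, 9, 50, seed = 42)
  s2 <- bottom_sketch(g, 9, 50, seed = 42)
  expect_identical(s1$hashes, s2$hashes)
  expect_false(identical(s1$hashes, bottom_sketch(g, 9, 50, seed = 1)$hashes))
  expect_false(is.unsorted(s1$hashes, strictly = TRUE))

  # saturation: sigma above the number of distinct k-mers keeps all of them
  nk <- length(canonical_kmers(g, 9))
  sat <- bottom_sketch(g, 9, nk + 100, seed = 42)
  expect_length(sat$hashes, nk)
  # bottom-1 is the global minimum
  expect_equal(bottom_sketch(g, 9, 1, seed = 42)$hashes, min(sat$hashes))

  # reverse complement gives the identical sketch
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", g$sequence), "")[[1L]]),
              collapse = "")
  expect_identical(bottom_sketch(genome_record(rc, "t"), 9, 50, 42)$hashes,
                   s1$hashes)
})

test_that("merged sketch estimator matches brute-force Jaccard when saturated", {
  set.seed(202)
  for (rep in 1:5) {
    a <- genome_record(random_genome(2000), "a")
    b <- genome_record(mutate_genome(a$sequence, 0.05), "b")
    sk <- sketch_genomes(list(a, b), k = 11, sigma = 10000, seed = 42)
    est <- estimate_jaccard(sk[[1]], sk[[2]])
    expect_equal(est$j_hat, exact_jaccard(a, b, 11), tolerance = 1e-12)
    expect_equal(est$j_hat, est$shared / est$denom)
  }
  # identity and disjointness
  a <- genome_record(random_genome(1000), "a")
  ska <- bottom_sketch(a, 11, 200, 42)
  expect_equal(estimate_jaccard(ska, ska)$j_hat, 1)
  b <- genome_record(paste(rep("ACCCT", 200), collapse = ""), "b")
  skb <- bottom_sketch(b, 11, 200, 42)
  ej <- estimate_jaccard(ska, skb)
  expect_lt(ej$j_hat, 0.05) # near-disjoint k-mer sets
  expect_lte(ej$denom, 200)
})

test_that("incompatible sketches are rejected", {
  g <- genome_record(random_genome(500), "g")
  s_k9 <- bottom_sketch(g, 9, 50, 42)
  expect_error(estimate_jaccard(s_k9, bottom_sketch(g, 11, 50, 42)),
               "incompatible")
  expect_error(estimate_jaccard(s_k9, bottom_sketch(g, 9, 60, 42)),
               "incompatible")
  expect_error(estimate_jaccard(s_k9, bottom_sketch(g, 9, 50, 7)),
               "incompatible")
})

test_that("sketch accuracy is non-increasing in sketch size", {
  set.seed(303)
  n_pairs <- 50
  sigmas <- c(64, 128, 256, 512, 1024)
  err <- matrix(NA_real_, n_pairs, length(sigmas))
  for (i in seq_len(n_pairs)) {
    a <- genome_record(random_genome(10000), "a")
    b <- genome_record(mutate_genome(a$sequence, runif(1, 0.02, 0.10)), "b")
    # exact Jaccard from the saturated hash route
    full_a <- bottom_sketch(a, 13, 2e5, 42)$hashes
    full_b <- bottom_sketch(b, 13, 2e5, 42)$hashes
    jex <- length(intersect(full_a, full_b)) /
      length(union(full_a, full_b))
    for (s in seq_along(sigmas)) {
      sk <- sketch_genomes(list(a, b), k = 13, sigma = sigmas[s], seed = 42)
      err[i, s] <- abs(estimate_jaccard(sk[[1]], sk[[2]])$j_hat - jex)
    }
  }
  m <- colMeans(err)
  # allow 10% sampling slack on each doubling
  expect_true(all(diff(m) <= 0.1 * m[-length(m)] + 1e-9))
  expect_lt(m[length(sigmas)], m[1]) # strictly better overall
})

test_that("sketch set resolution: k from largest genome, sigma from s", {
  recs <- list(genome_record(random_genome(1000), "a"),
               genome_record(random_genome(3000), "b"))
  sk <- sketch_genomes(recs, q = 1e-3, s = 0.25, seed = 42)
  expect_equal(sk[[1]]$k, choose_k(3000, 1e-3))
  expect_equal(sk[[1]]$sigma, round(0.25 * 2000))
})

test_that("sketch flat-file persistence round-trips bit-exactly", {
  g <- genome_record(random_genome(800, c(0.3, 0.2, 0.2, 0.3)), "taxonX")
  sk <- bottom_sketch(g, 13, 100, 42)
  p <- tempfile()
  write_sketch(sk, p)
  rt <- read_sketch(p)
  expect_identical(rt$hashes, sk$hashes)
  expect_equal(rt$freqs, sk$freqs)
  expect_equal(rt[c("taxon", "k", "sigma", "seed", "g")],
               sk[c("taxon", "k", "sigma", "seed", "g")])
  expect_equal(estimate_jaccard(rt, sk)$j_hat, 1)
  expect_error(read_sketch(fasta_file(list(a = "ACGT"))), "not a skimer")
})
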