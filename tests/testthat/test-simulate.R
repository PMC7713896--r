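test_that("the GTR generator is normalized and stationary", {
  # equal rates + equal frequencies: Jukes-Cantor closed form
  Q <- build_rate_matrix(evo_model("f1"))
  expect_equal(unname(Q[1, 2]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(diag(Q)), rep(-1, 4), tolerance = 1e-12)
  for (m in list(evo_model("f2", rates = c(1.3, 4.1, 0.7, 1.1, 5, 1)),
                 evo_model("f3", rates = c(0.8, 2.5, 1.2, 1.25, 2.9, 1),
                           alpha = 0.3))) {
    Q <- build_rate_matrix(m)
    expect_equal(max(abs(m$freqs %*% Q)), 0, tolerance = 1e-12) # pi Q = 0
    expect_equal(-sum(m$freqs * diag(Q)), 1, tolerance = 1e-12) # unit rate
    expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  }
  expect_error(build_rate_matrix(evo_model("f1", rates = rep(0, 6))))
})

test_that("analytic p(d) matches closed forms and caps at 1 - sum(pi^2)", {
  jc <- evo_model("f1")
  expect_equal(analytic_p(0, jc), 0)
  d <- c(0.05, 0.1, 0.5, 1)
  expect_equal(analytic_p(d, jc), 0.75 * (1 - exp(-4 * d / 3)),
               tolerance = 1e-12)
  # JC+Gamma eigen-closure equals the textbook formula
  jcg <- evo_model("f1", alpha = 0.314)
  expect_equal(analytic_p(d, jcg),
               0.75 * (1 - (1 + 4 * d / (3 * 0.314))^(-0.314)),
               tolerance = 1e-12)
  # saturation limit is b1 of the composition
  m2 <- evo_model("f2", rates = c(1, 3, 1, 1, 4, 1))
  expect_equal(analytic_p(500, m2), b1_from_freqs(freq_preset("f2")),
               tolerance = 1e-4)
})

test_that("truncated Zipf indel lengths follow the stated law", {
  set.seed(21)
  n <- 1e5
  x <- sample_indel_length(n, 1.5, 50000)
  expect_true(all(x >= 1 & x <= 50000))
  # mass ratio P(1)/P(2) = 2^1.5
  p1 <- mean(x == 1); p2 <- mean(x == 2)
  expect_equal(p1 / p2, 2^1.5, tolerance = 0.1)
  # absolute mass at 1: 1 / zeta_trunc(1.5), within 3 SE
  z <- sum(seq_len(50000)^(-1.5))
  se <- sqrt((1 / z) * (1 - 1 / z) / n)
  expect_lt(abs(p1 - 1 / z), 3 * se)
})

test_that("pair simulation reproduces the analytic divergence", {
  m <- evo_model("f1")
  sp0 <- evolve_pair(0, m, 1000, seed = 1)
  expect_identical(sp0$seq_x, sp0$seq_y)
  expect_equal(sp0$true_p, 0)
  # determinism
  a <- evolve_pair(0.2, m, 2000, seed = 9)
  b <- evolve_pair(0.2, m, 2000, seed = 9)
  expect_identical(a[c("seq_x", "seq_y", "true_p")],
                   b[c("seq_x", "seq_y", "true_p")])
  # binomial agreement with the analytic expectation, JC without indels
  L <- 1e5
  sp <- evolve_pair(0.3, m, L, seed = 2)
  p <- analytic_p(0.3, m)
  expect_lt(abs(sp$true_p - p), 3 * sqrt(p * (1 - p) / L))
  # ungapping the alignment rows reproduces the sequences
  expect_identical(gsub("-", "", sp$aln_x, fixed = TRUE), sp$seq_x)
  expect_identical(gsub("-", "", sp$aln_y, fixed = TRUE), sp$seq_y)
  expect_equal(p_from_alignment(sp$aln_x, sp$aln_y), sp$true_p)
})

test_that("simulation agrees with analytic p across GTR(+Gamma) scenarios", {
  L <- 1e5
  scen <- list(evo_model("f1", rates = c(1, 3.6, 0.85, 0.95, 4.2, 1)),
               evo_model("f2", rates = c(1.3, 4.1, 0.7, 1.1, 5, 1)),
               evo_model("f3", rates = c(1.15, 3.1, 0.95, 1, 3.9, 1),
                         alpha = 0.314))
  for (i in seq_along(scen)) for (d in c(0.1, 0.5, 1.0)) {
    sp <- evolve_pair(d, scen[[i]], L, seed = 100 * i + d * 10)
    p <- analytic_p(d, scen[[i]])
    expect_lt(abs(sp$true_p - p), 3 * sqrt(p * (1 - p) / L))
  }
  # descendant composition stays stationary (JC, 3 SE per base)
  m <- evo_model("f1")
  sp <- evolve_pair(0.5, m, 1e5, seed = 5)
  comp <- genome_record(sp$seq_y, "y")$freqs
  expect_true(all(abs(comp - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
})

test_that("indels drift relative sequence lengths upward with divergence", {
  set.seed(22)
  m <- evo_model("f1", indel_rate = 0.01)
  rel <- function(d, n = 20) {
    mean(replicate(n, {
      sp <- evolve_pair(d, m, 2e4)
      lx <- nchar(sp$seq_x); ly <- nchar(sp$seq_y)
      max(lx, ly) / min(lx, ly)
    }))
  }
  r_small <- rel(0.05)
  r_large <- rel(1.0)
  expect_gt(r_small, 1)
  expect_gt(r_large, r_small) # directional growth with divergence
})

test_that("tree simulation is stationary, deterministic and reversible", {
  m <- evo_model("f1")
  star0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  recs <- evolve_along_tree(star0, m, 500, seed = 3)
  expect_identical(recs$A$sequence, recs$B$sequence)
  expect_identical(recs$A$sequence, recs$C$sequence)

  tr <- ape::read.tree(text = "((A:0.05,B:0.1):0.02,(C:0.04,D:0.08):0.03);")
  r1 <- evolve_along_tree(tr, m, 2000, seed = 4)
  r2 <- evolve_along_tree(tr, m, 2000, seed = 4)
  expect_identical(lapply(r1, `[[`, "sequence"),
                   lapply(r2, `[[`, "sequence"))
  expect_error(evolve_along_tree("((A:1,B:1", m, 100), "Newick|parse")

  # reversibility: a cherry with d/2 + d/2 behaves like a one-branch pair;
  # without indels the leaf sequences stay positionally aligned
  L <- 1e5
  chr <- ape::read.tree(text = "(A:0.15,B:0.15,C:0.0);")
  rc <- evolve_along_tree(chr, m, L, seed = 6)
  p_obs <- p_from_alignment(rc$A$sequence, rc$B$sequence)
  p_exp <- analytic_p(0.3, m)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / L))
})

test_that("alignment p-distance ignores gapped columns", {
  expect_equal(p_from_alignment("ACGT", "ACGA"), 0.25)
  expect_equal(p_from_alignment("AC-T", "ACGT"), 0)
  expect_equal(p_from_alignment("ACGT", "ACGT"), 0)
  expect_error(p_from_alignment("AC", "ACG"), "length")
  expect_error(p_from_alignment("--", "AA"), "no residue")
})
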