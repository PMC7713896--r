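#' Run configuration for the genome-to-tree pipeline
#'
#' Collects the sketching and transformation settings shared by the pipeline
#' drivers.  Mutually exclusive options (`k` vs `q`, `sigma` vs `s`) are
#' resolved here.
#'
#' @param k,q Explicit k-mer size, or random-match probability from which k
#'   is derived per run via [choose_k()] (default `q = 1e-9`).
#' @param sigma,s Explicit sketch size, or fraction of the mean genome
#'   length (default `s = 0.5`).
#' @param model Distance transformation (`"pc"`, `"ei"`, `"ei_gamma"`).
#' @param a Gamma shape for `"ei_gamma"`.
#' @param freq_mode `"global"` or `"per_pair"` (see
#'   [build_distance_matrix()]).
#' @param rounds,perturb Ratchet schedule for [ratchet_search()].
#' @param seed Seed for hashing and the tree search.
#' @return Object of class `run_config`.
#' @export
run_config <- function(k = NULL, q = 1e-9, sigma = NULL, s = 0.5,
                       model = c("ei_gamma", "pc", "ei"), a = 1.5,
                       freq_mode = c("global", "per_pair"),
                       rounds = 100, perturb = 0.2, seed = 42L) {
  if (!is.null(k)) q <- NULL      # explicit k wins over q
  if (!is.null(sigma)) s <- NULL  # explicit sigma wins over s
  structure(list(k = k, q = q, sigma = sigma, s = s,
                 model = match.arg(model), a = a,
                 freq_mode = match.arg(freq_mode),
                 rounds = rounds, perturb = perturb,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Genomes to phylogeny
#'
#' The complete alignment-free pipeline: sketch every genome, estimate all
#' pairwise Jaccard indices, convert to p-distances and evolutionary
#' distances, impute any missing entries, and reconstruct a balanced
#' minimum-evolution tree with the ratchet search.  Deterministic for a
#' fixed configuration.
#'
#' @param genomes List of [genome_record()]s or character vector of FASTA
#'   paths (plain or gzipped), at least 3.
#' @param cfg A [run_config()].
#' @return List with `tree` (`ape::phylo`), `matrix` (`evo_dist` after
#'   imputation) and `sketches`.
#' @export
run_genomes_to_tree <- function(genomes, cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  sk <- tryCatch(
    sketch_genomes(genomes, k = cfg$k, q = if (is.null(cfg$k)) cfg$q,
                   sigma = cfg$sigma, s = if (is.null(cfg$sigma)) cfg$s
                   else NULL, seed = cfg$seed),
    error = function(e) stop("sketch stage: ", conditionMessage(e)))
  m <- tryCatch(
    impute_missing(build_distance_matrix(sk, model = cfg$model, a = cfg$a,
                                         freq_mode = cfg$freq_mode)),
    error = function(e) stop("distance stage: ", conditionMessage(e)))
  tr <- tryCatch(
    ratchet_search(m, rounds = cfg$rounds, perturb = cfg$perturb,
                   seed = cfg$seed),
    error = function(e) stop("tree stage: ", conditionMessage(e)))
  list(tree = tr, matrix = m, sketches = sk)
}

#' Pair-simulation benchmark of sketch-based p-distance estimation
#'
#' Simulates diverged sequence pairs under GTR and GTR+Gamma with the three
#' canonical composition presets, estimates each pair's p-distance from
#' bottom sketches, and summarises: per-scenario accuracy reports
#' ([accuracy_report()]), and the Gamma-shape equivalence parameter fitted
#' to the pooled (true p, true d) relationship of each substitution model
#' ([fit_equiv_a()]), with per-composition fits recorded alongside the
#' pooled ones.
#'
#' @param models Character subset of `c("gtr", "gtr_gamma")`.
#' @param freqs Character subset of `c("f1", "f2", "f3")`.
#' @param d_grid Divergences simulated (expected substitutions per site).
#' @param n_pairs Pairs per divergence value.
#' @param L Ancestor length in bases.
#' @param alpha Gamma shape for the `gtr_gamma` scenarios.
#' @param rates GTR exchangeabilities; default draws per pair from
#'   [gtr_rate_library()].
#' @param indel_rate Indel rate passed to the simulator.
#' @param k,s Sketching parameters.
#' @param seed RNG seed.
#' @return List with `pairs` (data frame: scenario, freqs, d, p_true,
#'   p_hat), `reports` (per scenario) and `fits` (per model: pooled and
#'   per-composition equivalence shapes).
#' @export
run_pair_benchmark <- function(models = c("gtr", "gtr_gamma"),
                               freqs = c("f1", "f2", "f3"),
                               d_grid = seq(0.05, 1.0, by = 0.05),
                               n_pairs = 20, L = 1e5, alpha = 0.314,
                               rates = NULL, indel_rate = 0.01,
                               k = 21, s = 0.2, seed = 1L) {
  set.seed(seed)
  lib <- gtr_rate_library()
  rows <- list()
  for (mod in models) for (fr in freqs) {
    for (d in d_grid) for (i in seq_len(n_pairs)) {
      rset <- if (is.null(rates)) lib[[sample.int(length(lib), 1L)]]$rates
              else rates
      em <- evo_model(fr, rates = rset,
                      alpha = if (mod == "gtr_gamma") alpha else Inf,
                      indel_rate = indel_rate)
      sp <- evolve_pair(d, em, L)
      recs <- list(genome_record(sp$seq_x, "x"),
                   genome_record(sp$seq_y, "y"))
      sk <- sketch_genomes(recs, k = k, s = s, seed = seed)
      jh <- estimate_jaccard(sk[[1L]], sk[[2L]])$j_hat
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = paste(mod, fr, sep = "_"), model = mod,
                   freqs = fr, d = d, p_true = sp$true_p,
                   p_hat = p_from_jaccard(jh, k))
    }
  }
  pairs <- do.call(rbind, rows)
  reports <- lapply(split(pairs, pairs$scenario), function(df)
    accuracy_report(df$p_true, df$p_hat, p_max = 0.35))
  fits <- lapply(split(pairs, pairs$model), function(df) {
    b <- b1_from_freqs(freq_preset(df$freqs[1L]))
    per <- vapply(split(df, df$freqs), function(dd) {
      bb <- b1_from_freqs(freq_preset(dd$freqs[1L]))
      as.numeric(fit_equiv_a(dd$d, b1 = bb, b2 = bb, p = dd$p_true))
    }, numeric(1))
    pooled_b <- mean(vapply(unique(df$freqs), function(f)
      b1_from_freqs(freq_preset(f)), numeric(1)))
    pooled <- as.numeric(fit_equiv_a(df$d, b1 = pooled_b, b2 = pooled_b,
                                     p = df$p_true))
    list(pooled = pooled, per_freqs = per)
  })
  list(pairs = pairs, reports = reports, fits = fits)
}

#' Tree-recovery benchmark of the p-distance transformations
#'
#' For each reference tree: simulate leaf genomes along it, run the
#' sketch-to-tree pipeline once per transformation (Poisson correction,
#' equal-input, and equal-input+Gamma for each shape in `a_grid`), and score
#' the percentage of exactly recovered reference topologies per
#' transformation.
#'
#' @param trees List of `ape::phylo` reference trees with branch lengths.
#' @param model An [evo_model()] used for simulation (its frequencies are
#'   also inherited by the simulated genomes).
#' @param L Root sequence length.
#' @param a_grid Gamma shapes evaluated for the `ei_gamma` transformation.
#' @param cfg Sketch/tree [run_config()]; its `model`/`a` fields are
#'   overridden per transformation.
#' @param seed RNG seed.
#' @return List with `recovery` (named percentages: `pc`, `ei`, and
#'   `ei_gamma_<a>`) and `n_trees`.
#' @export
run_tree_benchmark <- function(trees, model, L = 1e5,
                               a_grid = c(0.5, 1, 1.5, 2),
                               cfg = run_config(rounds = 10),
                               seed = 1L) {
  stopifnot(length(trees) >= 1, inherits(model, "evo_model"))
  transforms <- c(list(pc = list(model = "pc", a = Inf),
                       ei = list(model = "ei", a = Inf)),
                  stats::setNames(
                    lapply(a_grid, function(a) list(model = "ei_gamma",
                                                    a = a)),
                    paste0("ei_gamma_", a_grid)))
  inferred <- lapply(transforms, function(...) vector("list", length(trees)))
  for (ti in seq_along(trees)) {
    recs <- evolve_along_tree(trees[[ti]], model, L, seed = seed + ti)
    sk <- sketch_genomes(recs, k = cfg$k, q = if (is.null(cfg$k)) cfg$q,
                         sigma = cfg$sigma,
                         s = if (is.null(cfg$sigma)) cfg$s else NULL,
                         seed = cfg$seed)
    for (tn in names(transforms)) {
      tf <- transforms[[tn]]
      m <- impute_missing(build_distance_matrix(sk, model = tf$model,
                                                a = tf$a,
                                                freq_mode = cfg$freq_mode))
      inferred[[tn]][[ti]] <- ratchet_search(m, rounds = cfg$rounds,
                                             perturb = cfg$perturb,
                                             seed = cfg$seed)
    }
  }
  recovery <- vapply(inferred, recovery_percentage, numeric(1),
                     reference = trees)
  list(recovery = recovery, n_trees = length(trees))
}
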