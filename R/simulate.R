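#' GTR(+Gamma) evolutionary model with indels
#'
#' Bundles the parameters of a general time-reversible nucleotide
#' substitution model: equilibrium frequencies, six exchangeabilities,
#' optional Gamma-distributed rate heterogeneity across sites, and an indel
#' process whose event rate is expressed relative to the unit substitution
#' rate and whose lengths follow a truncated Zipf law.
#'
#' @param freqs A/C/G/T equilibrium frequencies summing to 1, or one of the
#'   preset labels `"f1"` (equal), `"f2"` (GC-rich: 0.10/0.30/0.40/0.20),
#'   `"f3"` (AT-rich: 0.40/0.10/0.10/0.40).
#' @param rates Six non-negative GTR exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT (scale-free; all equal gives Jukes-Cantor when
#'   frequencies are equal).
#' @param alpha Gamma shape of among-site rate variation (mean-1 rates);
#'   `Inf` for homogeneous rates.
#' @param indel_rate Insertion rate = deletion rate, each per substitution
#'   per site (0 disables indels).
#' @param zipf_a Zipf exponent for indel lengths (> 1).
#' @param indel_max Upper truncation of indel lengths.
#' @return Object of class `evo_model`.
#' @examples
#' jc <- evo_model("f1")                      # Jukes-Cantor
#' gg <- evo_model("f2", alpha = 0.314, indel_rate = 0.01)
#' @export
evo_model <- function(freqs = "f1", rates = rep(1, 6), alpha = Inf,
                      indel_rate = 0, zipf_a = 1.5, indel_max = 50000L) {
  if (is.character(freqs)) freqs <- freq_preset(freqs)
  .check_freqs(freqs)
  names(freqs) <- c("A", "C", "G", "T")
  stopifnot(length(rates) == 6L, all(rates >= 0), any(rates > 0),
            alpha > 0, indel_rate >= 0, zipf_a > 1, indel_max >= 1)
  names(rates) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  structure(list(freqs = freqs, rates = rates, alpha = alpha,
                 indel_rate = indel_rate, zipf_a = zipf_a,
                 indel_max = as.integer(indel_max)),
            class = "evo_model")
}

#' @rdname evo_model
#' @param name Preset label.
#' @export
freq_preset <- function(name = c("f1", "f2", "f3")) {
  name <- match.arg(name)
  switch(name,
         f1 = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
         f2 = c(A = 0.10, C = 0.30, G = 0.40, T = 0.20),
         f3 = c(A = 0.40, C = 0.10, G = 0.10, T = 0.40))
}

#' Representative GTR parameter sets
#'
#' A small synthetic library of transition-biased exchangeability vectors and
#' Gamma shapes spanning the range typical of prokaryotic genus-level
#' phylogenomic estimates (shapes in roughly \[0.16, 0.42\]).  Used by the
#' benchmark drivers when no model parameters are supplied.
#'
#' @return List of lists, each with `rates` (length 6) and `alpha`.
#' @export
gtr_rate_library <- function() {
  list(
    list(rates = c(1.00, 3.60, 0.85, 0.95, 4.20, 1.00), alpha = 0.162),
    list(rates = c(1.30, 4.10, 0.70, 1.10, 5.00, 1.00), alpha = 0.210),
    list(rates = c(0.90, 2.80, 1.05, 0.80, 3.30, 1.00), alpha = 0.260),
    list(rates = c(1.15, 3.10, 0.95, 1.00, 3.90, 1.00), alpha = 0.314),
    list(rates = c(1.05, 4.60, 0.75, 0.90, 4.80, 1.00), alpha = 0.360),
    list(rates = c(0.80, 2.50, 1.20, 1.25, 2.90, 1.00), alpha = 0.422))
}

#' @export
print.evo_model <- function(x, ...) {
  cat("GTR",
      if (is.finite(x$alpha)) sprintf("+Gamma(%.3g)", x$alpha) else "",
      " model\n", sep = "")
  cat("  freqs:", paste(sprintf("%s=%.3g", names(x$freqs), x$freqs),
                        collapse = " "), "\n")
  cat("  rates:", paste(sprintf("%s=%.3g", names(x$rates), x$rates),
                        collapse = " "), "\n")
  if (x$indel_rate > 0)
    cat(sprintf("  indels: rate %.3g, Zipf(%.3g) lengths in [1, %d]\n",
                x$indel_rate, x$zipf_a, x$indel_max))
  invisible(x)
}

#' GTR rate matrix (generator)
#'
#' Builds the 4x4 generator with `Q[i, j] = rate(i, j) pi_j` off-diagonal,
#' rows summing to zero, rescaled so the expected substitution rate at
#' stationarity is one (`-sum(pi_i Q[i, i]) = 1`), i.e. branch lengths are in
#' expected substitutions per site.
#'
#' @param model An [evo_model()].
#' @return 4x4 numeric matrix with A/C/G/T dimnames.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "evo_model"))
  pi <- model$freqs
  r <- model$rates
  R <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  R["A", "C"] <- R["C", "A"] <- r["AC"]
  R["A", "G"] <- R["G", "A"] <- r["AG"]
  R["A", "T"] <- R["T", "A"] <- r["AT"]
  R["C", "G"] <- R["G", "C"] <- r["CG"]
  R["C", "T"] <- R["T", "C"] <- r["CT"]
  R["G", "T"] <- R["T", "G"] <- r["GT"]
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("zero total substitution rate")
  Q / mu
}

# Eigendecomposition of the normalized GTR generator via the symmetrized
# form diag(sqrt(pi)) Q diag(1/sqrt(pi)); eigenvalues are real and <= 0.
.gtr_eigen <- function(model) {
  Q <- build_rate_matrix(model)
  sp <- sqrt(model$freqs)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  V <- diag(1 / sp) %*% e$vectors
  Vinv <- t(e$vectors) %*% diag(sp)
  list(lambda = e$values, V = V, Vinv = Vinv, pi = model$freqs)
}

#' Expected p-distance after divergence d
#'
#' The analytic probability that a site differs after `d` expected
#' substitutions per site: `p(d) = 1 - sum_r pi_r P(d)[r, r]` with
#' `P = exp(Q d)`.  Under Gamma rate heterogeneity the exponential terms
#' `exp(lambda d)` are replaced by their Gamma-mixture closure
#' `(1 - lambda d / alpha)^(-alpha)`.
#'
#' @param d Non-negative divergence(s), expected substitutions per site.
#' @param model An [evo_model()].
#' @return Expected p-distance(s) in \[0, 1).
#' @examples
#' analytic_p(0.1, evo_model("f1"))  # Jukes-Cantor closed form 0.0936
#' @export
analytic_p <- function(d, model) {
  stopifnot(all(d >= 0))
  eig <- .gtr_eigen(model)
  vapply(d, function(t) {
    f <- if (is.finite(model$alpha))
      (1 - eig$lambda * t / model$alpha)^(-model$alpha)
    else exp(eig$lambda * t)
    Pd <- eig$V %*% (f * eig$Vinv)
    1 - sum(eig$pi * diag(Pd))
  }, numeric(1))
}

#' Sample indel lengths from a truncated Zipf distribution
#'
#' `P(L = n)` proportional to `n^(-zipf_a)` on `1..indel_max`, sampled by
#' inverse CDF.
#'
#' @param n Number of draws.
#' @param zipf_a Exponent (> 1).
#' @param indel_max Upper truncation.
#' @return Integer vector of lengths.
#' @export
sample_indel_length <- function(n, zipf_a = 1.5, indel_max = 50000L) {
  stopifnot(zipf_a > 1, indel_max >= 1)
  cdf <- cumsum(seq_len(indel_max)^(-zipf_a))
  cdf <- cdf / cdf[indel_max]
  findInterval(runif(n), cdf) + 1L
}

# --- internal evolution engine (integer-coded sequences, 1=A..4=T) ---------

.draw_root <- function(L, model) {
  sample.int(4L, L, replace = TRUE, prob = model$freqs)
}

.site_rates <- function(L, model) {
  if (is.finite(model$alpha))
    rgamma(L, shape = model$alpha, rate = model$alpha)
  else rep(1, L)
}

# Substitute along one branch of length d; anc and rates are parallel
# vectors. Vectorised by ancestor state: transition probabilities come from
# the spectral form P(t)[a, b] = sum_m V[a, m] exp(lambda_m t) Vinv[m, b].
.substitute <- function(anc, rates, d, eig) {
  if (d == 0) return(anc)
  L <- length(anc)
  E <- exp(outer(d * rates, eig$lambda))
  out <- integer(L)
  u <- runif(L)
  for (a in 1:4) {
    idx <- which(anc == a)
    if (!length(idx)) next
    W <- eig$V[a, ] * eig$Vinv          # W[m, b] = V[a, m] Vinv[m, b]
    P <- E[idx, , drop = FALSE] %*% W   # rows: per-site P(a -> .)
    P[P < 0] <- 0
    c1 <- P[, 1L]; c2 <- c1 + P[, 2L]; c3 <- c2 + P[, 3L]
    uu <- u[idx] * (c3 + P[, 4L])
    out[idx] <- 1L + (uu > c1) + (uu > c2) + (uu > c3)
  }
  out
}

# Draw indel events for a branch: counts are Poisson with mean
# indel_rate * d * L for insertions and deletions separately.
.indel_events <- function(L, d, model) {
  mu <- model$indel_rate * d * L
  n_ins <- if (mu > 0) rpois(1L, mu) else 0L
  n_del <- if (mu > 0) rpois(1L, mu) else 0L
  list(
    ins_pos = if (n_ins) sort(sample.int(L + 1L, n_ins, replace = TRUE) - 1L)
              else integer(0),
    ins_len = if (n_ins) sample_indel_length(n_ins, model$zipf_a,
                                             model$indel_max) else integer(0),
    del_pos = if (n_del) sample.int(L, n_del, replace = TRUE) else integer(0),
    del_len = if (n_del) sample_indel_length(n_del, model$zipf_a,
                                             model$indel_max) else integer(0))
}

# Splice insertions into a sequence (and parallel rate vector); inserted
# residues are drawn from the equilibrium frequencies with fresh site rates.
.apply_insertions <- function(seq, rates, ev, model) {
  if (!length(ev$ins_pos)) return(list(seq = seq, rates = rates,
                                       ins_mask = logical(length(seq))))
  L <- length(seq)
  pieces_s <- vector("list", 2L * length(ev$ins_pos) + 1L)
  pieces_r <- pieces_m <- pieces_s
  last <- 0L; pi_ <- 1L
  for (e in seq_along(ev$ins_pos)) {
    pos <- min(ev$ins_pos[e], L)
    if (pos > last) {
      idx <- (last + 1L):pos
      pieces_s[[pi_]] <- seq[idx]
      pieces_r[[pi_]] <- rates[idx]
      pieces_m[[pi_]] <- rep(FALSE, length(idx))
      pi_ <- pi_ + 1L
    }
    len <- ev$ins_len[e]
    pieces_s[[pi_]] <- .draw_root(len, model)
    pieces_r[[pi_]] <- .site_rates(len, model)
    pieces_m[[pi_]] <- rep(TRUE, len)
    pi_ <- pi_ + 1L
    last <- pos
  }
  if (last < L) {
    idx <- (last + 1L):L
    pieces_s[[pi_]] <- seq[idx]
    pieces_r[[pi_]] <- rates[idx]
    pieces_m[[pi_]] <- rep(FALSE, length(idx))
  }
  list(seq = unlist(pieces_s), rates = unlist(pieces_r),
       ins_mask = unlist(pieces_m))
}

# Deletion mask over a sequence of length L (TRUE = deleted).
.deletion_mask <- function(L, ev) {
  del <- logical(L)
  for (e in seq_along(ev$del_pos)) {
    s <- ev$del_pos[e]
    del[s:min(L, s + ev$del_len[e] - 1L)] <- TRUE
  }
  del
}

.int2char <- function(x) paste(c("A", "C", "G", "T")[x], collapse = "")

#' Simulate a diverged sequence pair with its true alignment
#'
#' Draws an ancestor of length `L` from the model's equilibrium frequencies
#' and evolves a descendant along a single branch of length `d` expected
#' substitutions per site (equivalent, by time reversibility, to two
#' branches of d/2 from a common ancestor).  Substitutions use per-site
#' Gamma rates; insertion and deletion events (each Poisson with mean
#' `indel_rate * d * L`) are then applied to the descendant with uniform
#' positions and Zipf lengths, while the true pairwise alignment is tracked.
#' The true p-distance is computed over columns where both rows hold a
#' residue, so it reflects substitutions only.
#'
#' @param d Branch length (expected substitutions per site).
#' @param model An [evo_model()].
#' @param L Ancestor length in bases.
#' @param seed Optional RNG seed for a reproducible pair.
#' @return Object of class `sim_pair`: `seq_x`, `seq_y` (ungapped character
#'   strings), `aln_x`, `aln_y` (gapped alignment rows), `true_p`,
#'   `true_d = d`.
#' @export
evolve_pair <- function(d, model, L, seed = NULL) {
  stopifnot(inherits(model, "evo_model"), d >= 0, L >= 1)
  if (!is.null(seed)) set.seed(seed)
  eig <- .gtr_eigen(model)
  anc <- .draw_root(L, model)
  rates <- .site_rates(L, model)
  desc <- .substitute(anc, rates, d, eig)

  ev <- .indel_events(L, d, model)
  del <- .deletion_mask(L, ev)
  # alignment rows before insertions: gaps coded 0
  desc_al <- desc
  desc_al[del] <- 0L
  # splice insertions; ancestor row receives gaps at inserted columns
  ins <- .apply_insertions(desc_al, rates, ev, model)
  anc_al <- integer(length(ins$seq))
  anc_al[!ins$ins_mask] <- anc
  both <- anc_al > 0L & ins$seq > 0L
  if (!any(both)) stop("no residue-residue columns in simulated alignment")
  true_p <- mean(anc_al[both] != ins$seq[both])
  gapchar <- function(x) {
    ch <- c("-", "A", "C", "G", "T")[x + 1L]
    paste(ch, collapse = "")
  }
  seq_y <- ins$seq[ins$seq > 0L]
  structure(list(seq_x = .int2char(anc), seq_y = .int2char(seq_y),
                 aln_x = gapchar(anc_al), aln_y = gapchar(ins$seq),
                 true_p = true_p, true_d = d, seed = seed),
            class = "sim_pair")
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf("Simulated pair: d = %.4g, true p = %.5f, lengths %d / %d\n",
              x$true_d, x$true_p, nchar(x$seq_x), nchar(x$seq_y)))
  invisible(x)
}

#' Simulate sequence evolution along a phylogeny
#'
#' Draws a stationary root sequence and applies the branch engine of
#' [evolve_pair()] (substitutions with per-site Gamma rates, then indels)
#' recursively along every edge of the tree.  Site rates are drawn once at
#' the root and inherited; inserted sites receive fresh rates.
#'
#' @param tree An `ape::phylo` tree, or a Newick string/file path.
#' @param model An [evo_model()].
#' @param L Root sequence length.
#' @param seed Optional RNG seed.
#' @return Named list of [genome_record()]s, one per leaf.
#' @export
evolve_along_tree <- function(tree, model, L, seed = NULL) {
  if (is.character(tree)) {
    tree <- suppressWarnings(
      if (file.exists(tree)) ape::read.tree(tree)
      else ape::read.tree(text = tree))
    if (is.null(tree)) stop("malformed Newick input")
  }
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 3)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!is.null(seed)) set.seed(seed)
  eig <- .gtr_eigen(model)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  state <- vector("list", ntip + tree$Nnode)
  state[[root]] <- list(seq = .draw_root(L, model),
                        rates = .site_rates(L, model))
  out <- vector("list", ntip)
  # preorder: every parent is evolved before its children
  ord <- .preorder_edges(tree)
  for (e in ord) {
    par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
    st <- state[[par]]
    chs <- .evolve_branch(st$seq, st$rates, tree$edge.length[e], model, eig)
    if (chi <= ntip) out[[chi]] <- chs else state[[chi]] <- chs
  }
  recs <- lapply(seq_len(ntip), function(i) {
    genome_record(.int2char(out[[i]]$seq), tree$tip.label[i])
  })
  stats::setNames(recs, tree$tip.label)
}

.preorder_edges <- function(tree) {
  root <- length(tree$tip.label) + 1L
  edges_by_parent <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  ord <- integer(0)
  stack <- as.character(root)
  while (length(stack)) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    es <- edges_by_parent[[node]]
    if (is.null(es)) next
    ord <- c(ord, es)
    stack <- c(as.character(tree$edge[es, 2L]), stack)
  }
  ord
}

# one branch: substitutions, then deletions, then insertions
.evolve_branch <- function(seq, rates, d, model, eig) {
  L <- length(seq)
  s <- .substitute(seq, rates, d, eig)
  ev <- .indel_events(L, d, model)
  del <- .deletion_mask(L, ev)
  if (any(del)) {
    s <- s[!del]
    rates <- rates[!del]
  }
  if (!length(s)) stop("simulated sequence deleted entirely")
  ins <- .apply_insertions(s, rates, ev, model)
  list(seq = ins$seq, rates = ins$rates)
}

#' p-distance of a gapped alignment pair
#'
#' Counts mismatches over the columns where both rows hold a residue; columns
#' containing a gap in either row are excluded.
#'
#' @param x,y Equal-length aligned sequences (strings; `-` marks gaps).
#' @return p-distance.
#' @export
p_from_alignment <- function(x, y) {
  cx <- strsplit(toupper(x), "")[[1L]]
  cy <- strsplit(toupper(y), "")[[1L]]
  if (length(cx) != length(cy)) stop("alignment rows differ in length")
  both <- cx != "-" & cy != "-"
  if (!any(both)) stop("no residue-residue column in alignment")
  mean(cx[both] != cy[both])
}
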