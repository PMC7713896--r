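#' Build an evolutionary distance matrix from genome sketches
#'
#' For every pair of sketches: estimate the Jaccard index, convert it to a
#' p-distance, and transform that into an evolutionary distance under the
#' chosen model.  Entries whose Jaccard estimate is zero, or whose p-distance
#' reaches the model ceiling `b2`, are recorded as missing with an explicit
#' reason and can be filled afterwards with [impute_missing()].
#'
#' @param sketches List of at least three compatible `genome_sketch` objects.
#' @param model Distance transformation: `"pc"` (Poisson correction,
#'   `b1 = b2 = 1`), `"ei"` (equal input, [ei_log_distance()]) or
#'   `"ei_gamma"` (equal input with Gamma rate heterogeneity,
#'   [ei_gamma_distance()]).
#' @param a Gamma shape for `model = "ei_gamma"`.
#' @param freq_mode How equal-input coefficients are derived: `"global"`
#'   pools the composition of all genomes (length-weighted) into one
#'   `b1 = b2`; `"per_pair"` uses the mean of the two genomes' `b1` values
#'   and the pair's cross-composition `b2`.
#' @return Object of class `evo_dist`: `taxa`, symmetric numeric matrix `d`
#'   (NA where missing), character matrix `reason` (`"j_zero"`,
#'   `"p_exceeds_b2"`, `"imputed"` or `""`), plus diagnostic matrices `j`
#'   and `p`.
#' @export
build_distance_matrix <- function(sketches,
                                  model = c("pc", "ei", "ei_gamma"),
                                  a = Inf,
                                  freq_mode = c("global", "per_pair")) {
  model <- match.arg(model)
  freq_mode <- match.arg(freq_mode)
  stopifnot(length(sketches) >= 3)
  taxa <- unname(vapply(sketches, `[[`, character(1), "taxon"))
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  n <- length(sketches)
  k <- sketches[[1L]]$k
  g <- vapply(sketches, `[[`, numeric(1), "g")
  pooled <- colSums(do.call(rbind,
                            lapply(sketches, `[[`, "freqs")) * g) / sum(g)
  b1_each <- vapply(sketches, function(s) b1_from_freqs(s$freqs), numeric(1))
  b1_glob <- b1_from_freqs(pooled)

  dm <- jm <- pm <- matrix(0, n, n, dimnames = list(taxa, taxa))
  reason <- matrix("", n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (jj in (i + 1L):n) {
    est <- estimate_jaccard(sketches[[i]], sketches[[jj]])
    p <- p_from_jaccard(est$j_hat, k)
    jm[i, jj] <- jm[jj, i] <- est$j_hat
    pm[i, jj] <- pm[jj, i] <- if (is.na(p)) NA_real_ else p
    if (model == "pc") {
      b1 <- 1; b2 <- 1
    } else if (freq_mode == "global") {
      b1 <- b1_glob; b2 <- b1_glob
    } else {
      b1 <- mean(b1_each[c(i, jj)])
      b2 <- b2_from_freq_pair(sketches[[i]]$freqs, sketches[[jj]]$freqs)
    }
    d <- switch(model,
                pc = ei_log_distance(p, 1, 1),
                ei = ei_log_distance(p, b1, b2),
                ei_gamma = ei_gamma_distance(p, a, b1, b2))
    if (is.na(d)) {
      dm[i, jj] <- dm[jj, i] <- NA_real_
      why <- if (is.na(p)) "j_zero" else "p_exceeds_b2"
      reason[i, jj] <- reason[jj, i] <- why
    } else {
      dm[i, jj] <- dm[jj, i] <- d
    }
  }
  structure(list(taxa = taxa, d = dm, reason = reason, j = jm, p = pm,
                 model = model, a = a, freq_mode = freq_mode),
            class = "evo_dist")
}

#' Construct an `evo_dist` object from a plain matrix
#'
#' @param d Symmetric numeric matrix with zero diagonal; `NA` marks missing
#'   entries.  Row/column names supply taxon labels.
#' @return An `evo_dist` object.
#' @export
evo_dist <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (!isTRUE(all.equal(d, t(d)))) stop("matrix must be symmetric")
  if (any(diag(d) != 0, na.rm = TRUE)) stop("diagonal must be zero")
  reason <- matrix("", nrow(d), ncol(d), dimnames = dimnames(d))
  reason[is.na(d)] <- "missing"
  diag(reason) <- ""
  structure(list(taxa = rownames(d), d = d, reason = reason,
                 j = NULL, p = NULL, model = "external", a = NA,
                 freq_mode = NA_character_),
            class = "evo_dist")
}

#' @export
print.evo_dist <- function(x, ...) {
  n <- length(x$taxa)
  miss <- sum(is.na(x$d[upper.tri(x$d)]))
  imp <- sum(x$reason[upper.tri(x$d)] == "imputed")
  cat(sprintf("Evolutionary distance matrix: %d taxa (%s model)\n",
              n, x$model))
  cat(sprintf("  %d missing, %d imputed of %d pairs\n",
              miss, imp, n * (n - 1) / 2))
  invisible(x)
}

#' Impute missing distances from the triangle inequality
#'
#' Each missing entry `d_uv` is replaced by
#' `min over x of (d_xu + d_xv)` across third taxa `x` for which both legs
#' are present, an upper-bound approximation justified by the triangle
#' inequality for evolutionary distances.  All imputations read only the
#' original (non-imputed) entries, so the result does not depend on entry
#' order.
#'
#' @param m An `evo_dist` matrix.
#' @return The matrix with every missing entry filled and flagged
#'   `"imputed"`; an error names any pair with no resolvable third taxon.
#' @export
impute_missing <- function(m) {
  stopifnot(inherits(m, "evo_dist"))
  d0 <- m$d
  miss <- which(is.na(d0) & upper.tri(d0), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(m)
  for (r in seq_len(nrow(miss))) {
    u <- miss[r, 1L]; v <- miss[r, 2L]
    cand <- d0[, u] + d0[, v]
    cand[c(u, v)] <- NA_real_
    if (all(is.na(cand)))
      stop("cannot impute distance between '", m$taxa[u], "' and '",
           m$taxa[v], "': no third taxon with both distances present")
    val <- min(cand, na.rm = TRUE)
    m$d[u, v] <- m$d[v, u] <- val
    m$reason[u, v] <- m$reason[v, u] <- "imputed"
  }
  m
}

#' Write / read a relaxed square PHYLIP distance matrix
#'
#' First line: number of taxa; then one row per taxon, the label (no
#' whitespace allowed) followed by all distances at full precision.
#'
#' @param m An `evo_dist` with no missing entries (run [impute_missing()]
#'   first if needed).
#' @param path Output file.
#' @return `path` invisibly (`write_phylip`); an `evo_dist`
#'   (`read_phylip`).
#' @export
write_phylip <- function(m, path) {
  stopifnot(inherits(m, "evo_dist"))
  if (anyNA(m$d))
    stop("matrix has missing entries; run impute_missing() first")
  if (any(grepl("[[:space:]]", m$taxa)))
    stop("taxon labels must not contain whitespace")
  rows <- vapply(seq_along(m$taxa), function(i) {
    paste(c(m$taxa[i], sprintf("%.10g", m$d[i, ])), collapse = "  ")
  }, character(1))
  writeLines(c(sprintf("%d", length(m$taxa)), rows), path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1L])
  if (is.na(n) || length(lines) < n + 1L) stop("malformed PHYLIP file")
  parts <- strsplit(trimws(lines[2:(n + 1L)]), "[[:space:]]+")
  taxa <- vapply(parts, `[[`, character(1), 1L)
  d <- t(vapply(parts, function(x) as.numeric(x[-1L]), numeric(n)))
  dimnames(d) <- list(taxa, taxa)
  evo_dist(d)
}
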