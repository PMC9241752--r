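#' SparCC compositional correlation inference
#'
#' Estimates linear correlations between log-scale basis abundances from
#' compositional counts. Each of `n_samplings` draws resamples per-sample
#' fractions from `Dirichlet(counts + 1)` (so zeros never enter a log),
#' computes the log-ratio variation matrix `t_ij = var(log(x_i / x_j))`,
#' solves for basis variances `omega` under the sparsity assumption, and
#' forms `r_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`.
#' The most strongly correlated pair exceeding `exclusion_threshold` is
#' then iteratively excluded from the system and the basis re-solved, up
#' to `n_iterations` times. The reported correlation is the element-wise
#' median over samplings, clipped to \[-1, 1\].
#'
#' @param table an [asv_table()], prevalence-filtered at 10% upstream.
#' @param n_iterations cap on the strong-pair exclusion loop (default 100).
#' @param exclusion_threshold |r| above which the strongest pair is
#'   excluded from the basis system (default 0.1).
#' @param n_samplings number of Dirichlet-posterior resamplings
#'   (default 50).
#' @param seed integer seed.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_iterations = 100L, exclusion_threshold = 0.1,
                   n_samplings = 50L, seed = 1L) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  d <- ncol(m)
  if (d < 4L)
    stop_arg("SparCC needs >= 4 taxa: the basis-variance system is ",
             "underdetermined below that")
  f0 <- m + 1e-6
  f0 <- f0 / rowSums(f0)
  tv0 <- variation_matrix(log(f0))
  if (max(tv0[upper.tri(tv0)]) < 1e-10)
    stop_arg("degenerate input: taxa are in identical proportions in ",
             "every sample (zero log-ratio variance)")
  with_seed(derive_seed(seed, "sparcc"), {
    rs <- lapply(seq_len(n_samplings), function(s) {
      frac <- dirichlet_fractions(m)
      basis_correlations(variation_matrix(log(frac)), n_iterations,
                         exclusion_threshold)
    })
    r <- apply(simplify2array(rs), c(1L, 2L), stats::median)
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    dimnames(r) <- list(colnames(m), colnames(m))
    r
  })
}

# one Dirichlet(counts + 1) fraction draw per sample (rows)
dirichlet_fractions <- function(m) {
  g <- matrix(stats::rgamma(length(m), shape = t(m) + 1, rate = 1),
              nrow = ncol(m))
  sweep(t(g), 1L, colSums(g), "/")
}

# t_ij = var(log x_i - log x_j) from the covariance of the log fractions
variation_matrix <- function(logf) {
  cv <- stats::cov(logf)
  v <- diag(cv)
  outer(v, v, "+") - 2 * cv
}

# solve the sparsity-assumption linear system for basis variances, with
# iterative exclusion of the strongest correlated pair
basis_correlations <- function(tv, n_iterations, threshold) {
  d <- ncol(tv)
  included <- matrix(TRUE, d, d)
  diag(included) <- FALSE
  r <- NULL
  for (it in seq_len(n_iterations + 1L)) {
    A <- (included) * 1
    diag(A) <- rowSums(included)
    b <- rowSums(tv * included)
    omega <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, d))
    if (anyNA(omega)) break
    omega <- pmax(omega, 1e-10)
    denom <- 2 * sqrt(outer(omega, omega))
    r_new <- (outer(omega, omega, "+") - tv) / denom
    r <- pmin(pmax(r_new, -1), 1)
    if (it > n_iterations) break
    # strongest still-included pair above the threshold
    cand <- abs(r) * included
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1L, ]
    # keep every taxon identifiable (>= 3 included partners)
    if (sum(included[idx[1L], ]) <= 3L || sum(included[idx[2L], ]) <= 3L)
      break
    included[idx[1L], idx[2L]] <- included[idx[2L], idx[1L]] <- FALSE
  }
  if (is.null(r)) stop_arg("SparCC basis system could not be solved")
  diag(r) <- 1
  r
}

#' Permutation significance for SparCC correlations
#'
#' Each permutation shuffles every taxon column independently (destroying
#' all covariance while preserving marginal count distributions) and
#' recomputes the SparCC correlation with a reduced number of internal
#' samplings and exclusion iterations for tractability. Two-sided
#' pseudo-P values `(#{|r_perm| >= |r_obs|} + 1)/(n_perm + 1)`,
#' BH-adjusted across the upper triangle.
#'
#' @param table the [asv_table()] `observed_r` was computed from.
#' @param observed_r correlation matrix from [sparcc()].
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param perm_samplings,perm_iterations internal SparCC settings used for
#'   each permutation (defaults 1 and 10).
#' @return list with matrices `P` and `P_FDR`.
#' @export
sparcc_significance <- function(table, observed_r, n_perm = 10000L,
                                seed = 1L, perm_samplings = 1L,
                                perm_iterations = 10L) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  if (n_perm < 100L)
    warning("fewer than 100 permutations gives poor P-value resolution")
  d <- ncol(m)
  stopifnot(all(dim(observed_r) == d))
  obs <- abs(observed_r)
  count_ge <- matrix(0L, d, d)
  with_seed(derive_seed(seed, "sparcc_perm"), {
    for (b in seq_len(n_perm)) {
      perm <- apply(m, 2L, sample)
      r_perm <- tryCatch({
        rs <- lapply(seq_len(perm_samplings), function(s) {
          frac <- dirichlet_fractions(perm)
          basis_correlations(variation_matrix(log(frac)),
                             perm_iterations, 0.1)
        })
        if (perm_samplings == 1L) rs[[1L]]
        else apply(simplify2array(rs), c(1L, 2L), stats::median)
      }, error = function(e) NULL)
      if (!is.null(r_perm))
        count_ge <- count_ge + (abs(r_perm) >= obs - 1e-12)
    }
  })
  P <- (count_ge + 1) / (n_perm + 1)
  diag(P) <- NA_real_
  ut <- upper.tri(P)
  padj <- matrix(NA_real_, d, d, dimnames = dimnames(observed_r))
  padj[ut] <- stats::p.adjust(P[ut], "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  dimnames(P) <- dimnames(observed_r)
  list(P = P, P_FDR = padj)
}
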