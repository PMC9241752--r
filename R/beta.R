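#' Pairwise community distances
#'
#' Three dissimilarities in \[0, 1\]: Bray-Curtis
#' (`sum|x-y| / sum(x+y)`, differential abundance), binary Jaccard
#' (`1 - |A∩B| / |A∪B|` on presence/absence, differential occurrence) and
#' the generalized UniFrac of Chen et al. with branch weighting exponent
#' `alpha` (default `d^0.5`): over tree branches `b` with length `l_b` and
#' per-sample branch proportions `p_b`, `q_b`,
#' `d = sum(l_b (p+q)^a |p-q|/(p+q)) / sum(l_b (p+q)^a)`.
#'
#' @param table an [asv_table()], normally rarefied.
#' @param metric one of `"bray_curtis"`, `"jaccard"`, `"gunifrac"`.
#' @param tree `ape::phylo`, required for `"gunifrac"`.
#' @param alpha generalized UniFrac branch weighting exponent in \[0, 1\].
#' @return a `dist` object with attribute `metric`.
#' @export
distance_matrix <- function(table, metric = c("bray_curtis", "jaccard",
                                              "gunifrac"),
                            tree = NULL, alpha = 0.5) {
  metric <- match.arg(metric)
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(m, method = "bray"),
    jaccard = vegan::vegdist(m > 0, method = "jaccard", binary = TRUE),
    gunifrac = {
      if (is.null(tree)) stop_arg("`gunifrac` requires a tree")
      if (alpha < 0 || alpha > 1) stop_arg("`alpha` must be in [0, 1]")
      gunifrac_dist(m, tree, alpha)
    })
  attr(d, "metric") <- metric
  d
}

# branch-proportion matrix: rows = samples, cols = edges of the tree
branch_proportions <- function(m, tree) {
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop_arg("tree lacks ASVs present in the table: ",
             paste(utils::head(missing, 5L), collapse = ", "))
  tree <- ape::keep.tip(tree, colnames(m))
  ntip <- ape::Ntip(tree)
  rel <- sweep(m[, tree$tip.label, drop = FALSE], 1L, rowSums(m), "/")
  # tips descending from each edge, by postorder accumulation
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  under <- matrix(FALSE, nrow = nnode, ncol = ntip)
  under[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; chd <- po$edge[k, 2L]
    under[par, ] <- under[par, ] | under[chd, ]
  }
  inc <- t(under[tree$edge[, 2L], , drop = FALSE]) # tips x edges
  list(bp = rel %*% inc, len = tree$edge.length)
}

gunifrac_dist <- function(m, tree, alpha) {
  prp <- branch_proportions(m, tree)
  bp <- prp$bp
  len <- prp$len
  n <- nrow(bp)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      p <- bp[i, ]; q <- bp[j, ]
      s <- p + q
      keep <- s > 0
      w <- len[keep] * s[keep]^alpha
      out[i, j] <- out[j, i] <-
        sum(w * abs(p[keep] - q[keep]) / s[keep]) / sum(w)
    }
  }
  stats::as.dist(out)
}

#' Principal coordinate analysis on square-root transformed distances
#'
#' Classical (Gower-centered) scaling of the element-wise square root of
#' the dissimilarities — the square-root transform makes Bray-Curtis and
#' Jaccard matrices Euclidean-embeddable, avoiding negative eigenvalues.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param k number of axes to return (default: all positive).
#' @return list of class `pcoa_result`: `points` (samples x axes),
#'   `eigenvalues`, `proportion` of variation per axis.
#' @export
pcoa_sqrt <- function(d, k = NULL) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop_arg("distance matrix must be symmetric")
  dm <- sqrt(dm)
  n <- nrow(dm)
  fit <- stats::cmdscale(stats::as.dist(dm), k = n - 1L, eig = TRUE)
  pos <- fit$eig > 1e-8 * max(abs(fit$eig))
  npos <- sum(pos[seq_len(ncol(fit$points))])
  k <- min(k %||% npos, npos)
  structure(list(points = fit$points[, seq_len(k), drop = FALSE],
                 eigenvalues = fit$eig,
                 proportion = pmax(fit$eig, 0) / sum(pmax(fit$eig, 0))),
            class = "pcoa_result")
}

#' Permutational multivariate ANOVA (PERMANOVA) on a distance matrix
#'
#' Sequential (Type I) partition of the distance-matrix variance over the
#' listed metadata terms — covariates first, term of interest last — with
#' pseudo-F and free-permutation P values (Anderson's method, via
#' `vegan::adonis2`), `P = (b + 1) / (m + 1)`. Per-term adjusted R² is
#' `1 - (1 - R²)(n - 1)/(n - k - 1)` with `k` the term's degrees of
#' freedom; BH-adjusted P across the model terms. Samples are canonically
#' ordered internally so results do not depend on input row order.
#'
#' @param d a `dist` over samples (names = sample ids).
#' @param metadata data.frame with `sample_id` and the model terms.
#' @param terms character vector of metadata columns, in entry order.
#' @param n_perm number of permutations (default 10000), or a permutation
#'   matrix for exhaustive tests.
#' @param seed integer seed.
#' @return data.frame per term: `df`, `df_resid`, `F`, `R2`, `adj_R2`,
#'   `P`, `P_FDR`.
#' @export
permanova <- function(d, metadata, terms, n_perm = 10000L, seed = 1L) {
  dm <- as.matrix(d)
  ids <- rownames(dm) %||% metadata$sample_id
  ord <- order(ids)
  dm <- dm[ord, ord, drop = FALSE]
  meta <- metadata[match(ids[ord], metadata$sample_id), , drop = FALSE]
  bad <- !terms %in% names(meta)
  if (any(bad)) stop_arg("unknown terms: ", paste(terms[bad], collapse = ", "))
  keep <- terms[vapply(terms, function(t) {
    v <- meta[[t]]
    length(unique(v[!is.na(v)])) > 1L
  }, logical(1L))]
  if (length(keep) < length(terms))
    warning("dropping single-level term(s): ",
            paste(setdiff(terms, keep), collapse = ", "))
  cc <- stats::complete.cases(meta[, keep, drop = FALSE])
  meta <- meta[cc, , drop = FALSE]
  dd <- stats::as.dist(dm[cc, cc, drop = FALSE])
  form <- stats::reformulate(keep, response = quote(dd))
  fit <- with_seed(derive_seed(seed, "permanova"),
    vegan::adonis2(form, data = meta, permutations = n_perm,
                   by = "terms"))
  rows <- seq_len(length(keep))
  n <- sum(cc)
  r2 <- fit$R2[rows]
  k <- fit$Df[rows]
  out <- data.frame(term = rownames(fit)[rows],
                    df = k,
                    df_resid = fit$Df[rownames(fit) == "Residual"],
                    F = fit$F[rows],
                    R2 = r2,
                    adj_R2 = 1 - (1 - r2) * (n - 1) / (n - k - 1),
                    P = fit$`Pr(>F)`[rows],
                    P_FDR = stats::p.adjust(fit$`Pr(>F)`[rows], "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "residual_R2") <- fit$R2[rownames(fit) == "Residual"]
  out
}

#' Pairwise PERMANOVA contrasts between condition levels
#'
#' Runs [permanova()] on each two-condition subset and BH-adjusts the P
#' values across the contrast family.
#'
#' @inheritParams permanova
#' @param group metadata column holding the group labels
#'   (default `"condition"`).
#' @return data.frame per contrast with the [permanova()] columns.
#' @export
pairwise_permanova <- function(d, metadata, group = "condition",
                               n_perm = 10000L, seed = 1L) {
  lev <- sort(unique(metadata[[group]]))
  if (length(lev) < 2L) stop_arg("need at least two groups")
  prs <- utils::combn(lev, 2L, simplify = FALSE)
  dm <- as.matrix(d)
  rows <- lapply(seq_along(prs), function(i) {
    pr <- prs[[i]]
    sel <- metadata[[group]] %in% pr
    ids <- metadata$sample_id[sel]
    sub <- permanova(stats::as.dist(dm[ids, ids, drop = FALSE]),
                     metadata[sel, , drop = FALSE], terms = group,
                     n_perm = n_perm, seed = seed + i)
    cbind(contrast = paste(pr, collapse = "-"), sub)
  })
  out <- do.call(rbind, rows)
  out$P_FDR <- stats::p.adjust(out$P, "BH")
  out
}

#' Goodness-of-fit of a variable on the first two ordination axes
#'
#' Continuous variables: squared multiple correlation (R²) of the variable
#' regressed on axes 1-2, P by permuting the variable. Categorical
#' variables: between-centroid fit, analogously. A constant variable fits
#' nothing (`R² = 0`, `P = 1`).
#'
#' @param ord a [pcoa_sqrt()] result (or matrix of coordinates).
#' @param variable vector over the ordinated samples.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `r2` and `P`.
#' @export
envfit_goodness <- function(ord, variable, n_perm = 10000L, seed = 1L) {
  pts <- if (inherits(ord, "pcoa_result")) ord$points else as.matrix(ord)
  pts <- pts[, seq_len(min(2L, ncol(pts))), drop = FALSE]
  if (length(variable) != nrow(pts))
    stop_arg("variable length does not match ordination")
  if (length(unique(variable[!is.na(variable)])) < 2L)
    return(list(r2 = 0, P = 1))
  env <- data.frame(v = variable)
  fit <- with_seed(derive_seed(seed, "envfit"),
    vegan::envfit(pts ~ v, data = env, permutations = n_perm,
                  na.rm = TRUE))
  if (!is.null(fit$vectors) && length(fit$vectors$r))
    list(r2 = unname(fit$vectors$r), P = unname(fit$vectors$pvals))
  else
    list(r2 = unname(fit$factors$r), P = unname(fit$factors$pvals))
}
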