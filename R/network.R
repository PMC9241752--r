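#' Build the co-abundance network from SparCC output
#'
#' An undirected weighted graph over the taxa. Edge (i, j) is retained iff
#' `P_FDR <= fdr_cutoff` AND `|r|` is strictly above the median of the
#' nonzero off-diagonal correlations (computed before significance
#' filtering by default; `median_of = "significant"` switches to the
#' post-filter set). Isolated nodes stay in the node set. Edges carry the
#' signed correlation `r` and weight `|r|`.
#'
#' @param r correlation matrix from [sparcc()].
#' @param p_fdr matrix of BH-adjusted P values
#'   (from [sparcc_significance()]).
#' @param node_annotations optional data.frame with column `taxon_id` plus
#'   flags (e.g. `indicator`), attached as vertex attributes.
#' @param fdr_cutoff significance cutoff (default 0.05).
#' @param median_of `"all"` (default) or `"significant"` correlations for
#'   the strength threshold.
#' @return an `igraph` graph; retained-edge criteria are recorded as graph
#'   attributes `fdr_cutoff` and `r_threshold`.
#' @export
build_network <- function(r, p_fdr, node_annotations = NULL,
                          fdr_cutoff = 0.05,
                          median_of = c("all", "significant")) {
  median_of <- match.arg(median_of)
  stopifnot(all(dim(r) == dim(p_fdr)))
  d <- ncol(r)
  ut <- upper.tri(r)
  nz <- ut & r != 0
  sig <- ut & !is.na(p_fdr) & p_fdr <= fdr_cutoff
  pool <- if (median_of == "all") abs(r[nz]) else abs(r[sig & nz])
  thr <- if (length(pool)) stats::median(pool) else Inf
  keep <- sig & abs(r) > thr
  if (!any(keep)) warning("network has no edges at the given cutoffs")
  idx <- which(keep, arr.ind = TRUE)
  ids <- colnames(r) %||% paste0("V", seq_len(d))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
               r = r[keep], weight = abs(r[keep]),
               P_FDR = p_fdr[keep]),
    directed = FALSE,
    vertices = data.frame(name = ids))
  if (!is.null(node_annotations)) {
    ann <- node_annotations[match(ids, node_annotations$taxon_id), ,
                            drop = FALSE]
    for (cl in setdiff(names(ann), "taxon_id"))
      g <- igraph::set_vertex_attr(g, cl, value = ann[[cl]])
  }
  g <- igraph::set_graph_attr(g, "fdr_cutoff", fdr_cutoff)
  igraph::set_graph_attr(g, "r_threshold", thr)
}

#' Fast-greedy module detection
#'
#' Agglomerative modularity maximization (Clauset-Newman-Moore) on the
#' edge weights `|r|`; returns the partition at maximal weighted
#' modularity Q. Components of a disconnected graph are partitioned
#' independently (modules never span components).
#'
#' @param net graph from [build_network()].
#' @param weighted use edge weights (default TRUE).
#' @return list of class `module_assignment`: `membership` (named integer
#'   vector), `modularity` (Q), `modules` (list of member id vectors).
#' @export
detect_modules <- function(net, weighted = TRUE) {
  if (igraph::ecount(net) == 0L)
    stop_arg("network has no edges; modules are undefined")
  w <- if (weighted) igraph::E(net)$weight else NULL
  cl <- igraph::cluster_fast_greedy(net, weights = w)
  # cut the merge tree at maximal Q; numerical ties resolved toward the
  # coarser (later-merge) partition so a clique is one module exactly
  qv <- cl$modularity
  i <- max(which(qv >= max(qv) - 1e-10))
  memb <- igraph::cut_at(cl, no = igraph::vcount(net) - (i - 1L))
  names(memb) <- igraph::V(net)$name
  structure(list(membership = memb,
                 modularity = igraph::modularity(net, memb, weights = w),
                 modules = split(names(memb), memb)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("%d modules over %d nodes, Q = %.4f\n",
              length(x$modules), length(x$membership), x$modularity))
  invisible(x)
}

# weighted modularity recomputed from first principles (test oracle lives
# here so the identity is checkable against igraph's value)
modularity_from_partition <- function(net, membership, weighted = TRUE) {
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- if (weighted) igraph::E(net)$weight else rep(1, nrow(el))
  m2 <- 2 * sum(w)
  deg <- igraph::strength(net, weights = w)
  q <- 0
  for (cm in unique(membership)) {
    inside <- names(membership)[membership == cm]
    e_cc <- sum(w[el[, 1L] %in% inside & el[, 2L] %in% inside]) / (m2 / 2)
    a_c <- sum(deg[inside]) / m2
    q <- q + e_cc - a_c^2
  }
  q
}

#' Node centralities of the co-abundance network
#'
#' Degree (unweighted edge count), betweenness (shortest paths with edge
#' length `1/|r|`, so stronger correlations are shorter), PageRank
#' (damping 0.85, weights `|r|`), and eigenvector centrality (weights
#' `|r|`, max-normalized to 1). On a disconnected graph eigenvector
#' centrality is computed per component and a flag is set.
#'
#' @param net graph from [build_network()].
#' @return data.frame per node: `node`, `degree`, `betweenness`,
#'   `pagerank`, `eigenvector`; attribute `disconnected`.
#' @export
node_centralities <- function(net) {
  if (igraph::ecount(net) < 1L) stop_arg("network has no edges")
  w <- igraph::E(net)$weight
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, weights = 1 / w, directed = FALSE)
  pr <- igraph::page_rank(net, damping = 0.85, weights = w)$vector
  comp <- igraph::components(net)
  disconnected <- comp$no > 1L
  if (!disconnected) {
    eig <- igraph::eigen_centrality(net, weights = w)$vector
  } else {
    eig <- stats::setNames(numeric(igraph::vcount(net)),
                           igraph::V(net)$name)
    for (k in seq_len(comp$no)) {
      vs <- names(comp$membership)[comp$membership == k]
      sub <- igraph::induced_subgraph(net, vs)
      if (igraph::ecount(sub) > 0L)
        eig[vs] <- igraph::eigen_centrality(
          sub, weights = igraph::E(sub)$weight)$vector
    }
  }
  out <- data.frame(node = igraph::V(net)$name, degree = unname(deg),
                    betweenness = unname(btw), pagerank = unname(pr),
                    eigenvector = unname(eig[igraph::V(net)$name]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "disconnected") <- disconnected
  out
}

#' Vertex-permutation null test for node centralities
#'
#' Permutes the node labels over the fixed graph structure `n_perm`
#' times; each node's null distribution is the set of centrality values
#' its label receives across permutations. `Z = (obs - null_mean) /
#' null_sd` with a one-sided P (`1 - pnorm(Z)`: "more central than
#' expected"); `two_sided = TRUE` for the two-sided version. BH
#' adjustment per measure. Nodes with zero null spread get `NA`.
#'
#' @param net graph from [build_network()].
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @param two_sided report two-sided P values instead.
#' @return data.frame per node x measure: `node`, `measure`, `observed`,
#'   `null_mean`, `null_sd`, `Z`, `P`, `P_FDR`.
#' @export
centrality_null_test <- function(net, n_perm = 10000L, seed = 1L,
                                 two_sided = FALSE) {
  cent <- node_centralities(net)
  measures <- c("degree", "betweenness", "pagerank", "eigenvector")
  nv <- nrow(cent)
  rows <- list()
  with_seed(derive_seed(seed, "centrality_null"), {
    # label permutation over a fixed topology: each permutation assigns
    # the observed centrality vector to a shuffled set of labels
    perm_idx <- replicate(n_perm, sample.int(nv))
    for (ms in measures) {
      vals <- cent[[ms]]
      nulls <- matrix(vals[perm_idx], nrow = nv) # node x perm
      mu <- rowMeans(nulls)
      sd <- apply(nulls, 1L, stats::sd)
      z <- ifelse(sd > 0, (vals - mu) / sd, NA_real_)
      p <- if (two_sided) 2 * stats::pnorm(abs(z), lower.tail = FALSE)
           else stats::pnorm(z, lower.tail = FALSE)
      rows[[ms]] <- data.frame(node = cent$node, measure = ms,
                               observed = vals, null_mean = mu,
                               null_sd = sd, Z = z, P = p,
                               P_FDR = stats::p.adjust(p, "BH"),
                               row.names = NULL, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Permutative rank-sum comparison of indicator vs non-indicator nodes
#'
#' For each centrality measure, the Wilcoxon rank-sum statistic comparing
#' flagged (indicator/differential) nodes against the rest, with a
#' two-sided P from permuting the flags and BH adjustment across the four
#' measures.
#'
#' @param centralities data.frame from [node_centralities()].
#' @param indicator_flags logical per node, both classes non-empty.
#' @param n_perm number of flag permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame per measure: `measure`, `statistic` (rank sum of
#'   the indicator class), `P`, `P_FDR`.
#' @export
indicator_centrality_comparison <- function(centralities, indicator_flags,
                                            n_perm = 10000L, seed = 1L) {
  stopifnot(length(indicator_flags) == nrow(centralities))
  flags <- as.logical(indicator_flags)
  if (!any(flags) || all(flags))
    stop_arg("both indicator and non-indicator classes must be non-empty")
  measures <- c("degree", "betweenness", "pagerank", "eigenvector")
  n1 <- sum(flags)
  out <- with_seed(derive_seed(seed, "indicator_centrality"), {
    perm_sets <- replicate(n_perm, sample(flags))
    rows <- lapply(measures, function(ms) {
      rk <- rank(centralities[[ms]])
      obs <- sum(rk[flags])
      e0 <- n1 * (length(rk) + 1) / 2
      perm <- colSums(rk * perm_sets)
      b <- sum(abs(perm - e0) >= abs(obs - e0) - 1e-12)
      data.frame(measure = ms, statistic = obs,
                 P = (b + 1) / (n_perm + 1))
    })
    do.call(rbind, rows)
  })
  out$P_FDR <- stats::p.adjust(out$P, "BH")
  out
}

#' Per-subject module completeness
#'
#' For each sample and module, the fraction of the module's member taxa
#' detected (count > 0) in that sample: 0 = no members present, 1 = all
#' present. Computed on the pre-rarefaction table by default, since
#' presence/absence is depth-sensitive.
#'
#' @param table an [asv_table()].
#' @param modules a [detect_modules()] result (or named membership
#'   vector).
#' @param min_size drop modules with fewer members (default 1 keeps all;
#'   the pipeline uses 2 so singleton nodes are not treated as modules).
#' @return numeric matrix samples x modules with attribute
#'   `module_sizes`.
#' @export
module_completeness <- function(table, modules, min_size = 1L) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  memb <- if (inherits(modules, "module_assignment")) modules$membership
          else modules
  mods <- split(names(memb), memb)
  if (any(lengths(mods) == 0L)) stop_arg("empty module")
  mods <- mods[lengths(mods) >= min_size]
  if (!length(mods)) stop_arg("no module with >= ", min_size, " members")
  missing <- setdiff(unlist(mods), colnames(m))
  if (length(missing))
    stop_arg("module members absent from the table: ",
             paste(utils::head(missing, 5L), collapse = ", "))
  out <- vapply(mods, function(members)
    rowMeans(m[, members, drop = FALSE] > 0), numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), names(mods)))
  attr(out, "module_sizes") <- lengths(mods)
  out
}

#' Binomial GLM association of module completeness with a predictor
#'
#' Per module, a logit-link binomial GLM of (members present, members
#' absent) per subject on the predictor: `condition` (Control reference)
#' over the full cohort, or a clinical activity score over its own
#' condition (`sccai` on UC subjects, `cdai` on CD subjects). Wald P per
#' coefficient, BH-adjusted across modules within each coefficient.
#' Complete separation is flagged and refit with a Haldane-style
#' continuity correction (0.5 added to each subject's success and
#' failure counts).
#'
#' @param profile matrix from [module_completeness()].
#' @param metadata data.frame with `sample_id`, `condition`, and the
#'   score columns.
#' @param predictor `"condition"`, `"sccai"` or `"cdai"`.
#' @return data.frame per module x coefficient: `module`, `coef_name`,
#'   `estimate`, `se`, `P`, `P_FDR`, `separation`.
#' @export
completeness_association <- function(profile, metadata,
                                     predictor = c("condition", "sccai",
                                                   "cdai")) {
  predictor <- match.arg(predictor)
  sizes <- attr(profile, "module_sizes")
  if (is.null(sizes)) stop_arg("profile lacks module sizes; use ",
                               "module_completeness()")
  meta <- metadata[match(rownames(profile), metadata$sample_id), ,
                   drop = FALSE]
  if (predictor == "sccai") meta <- meta[meta$condition %in% "UC", ,
                                         drop = FALSE]
  if (predictor == "cdai") meta <- meta[meta$condition %in% "CD", ,
                                        drop = FALSE]
  meta <- meta[!is.na(meta[[predictor]]), , drop = FALSE]
  if (nrow(meta) < 3L) stop_arg("too few subjects with `", predictor, "`")
  prof <- profile[meta$sample_id, , drop = FALSE]
  x <- meta[[predictor]]
  if (predictor == "condition")
    x <- stats::relevel(factor(x), ref = "Control")

  rows <- list()
  for (k in seq_len(ncol(prof))) {
    size <- sizes[k]
    pres <- round(prof[, k] * size)
    # separation symptoms (non-convergence, fitted 0/1) are detected below
    fit <- suppressWarnings(stats::glm(cbind(pres, size - pres) ~ x,
                                       family = stats::binomial()))
    sm <- summary(fit)$coefficients
    separation <- any(abs(sm[, "Estimate"]) > 15 |
                        sm[, "Std. Error"] > 10) || !fit$converged
    if (separation) {
      # Haldane continuity correction against complete separation
      fit <- suppressWarnings(
        stats::glm(cbind(pres + 0.5, size - pres + 0.5) ~ x,
                   family = stats::binomial()))
      sm <- summary(fit)$coefficients
    }
    cf <- rownames(sm)[-1L]
    rows[[k]] <- data.frame(
      module = colnames(prof)[k],
      coef_name = sub("^x", paste0(predictor, ":"), cf),
      estimate = sm[-1L, "Estimate"], se = sm[-1L, "Std. Error"],
      P = 2 * stats::pnorm(abs(sm[-1L, "Estimate"] / sm[-1L, "Std. Error"]),
                           lower.tail = FALSE),
      separation = separation, row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$P_FDR <- NA_real_
  for (cf in unique(out$coef_name)) {
    sel <- out$coef_name == cf
    out$P_FDR[sel] <- stats::p.adjust(out$P[sel], "BH")
  }
  out
}

#' Module differentiation by redundancy analysis (eigengene-style)
#'
#' Per module, the count table is subset to the module members,
#' Hellinger-transformed on the subset's own row sums, and analyzed by
#' redundancy analysis constrained on the condition labels: variance
#' explained (constrained / total inertia), pseudo-F and a permutation P
#' (condition labels shuffled), BH-adjusted across modules.
#'
#' @param table an [asv_table()].
#' @param modules a [detect_modules()] result.
#' @param metadata data.frame with `sample_id` and `condition`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame per module: `module`, `n_members`,
#'   `variance_explained`, `F`, `P`, `P_FDR`.
#' @export
module_rda <- function(table, modules, metadata, n_perm = 10000L,
                       seed = 1L) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  memb <- if (inherits(modules, "module_assignment")) modules$membership
          else modules
  mods <- split(names(memb), memb)
  mods <- mods[lengths(mods) >= 2L]
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  rows <- list()
  for (k in seq_along(mods)) {
    members <- intersect(mods[[k]], colnames(m))
    sub <- m[, members, drop = FALSE]
    keep <- rowSums(sub) > 0
    if (!any(keep)) stop_arg("module ", names(mods)[k],
                             " absent from every sample")
    # samples without any member contribute an all-zero Hellinger row
    H <- matrix(0, nrow(sub), ncol(sub), dimnames = dimnames(sub))
    H[keep, ] <- hellinger_transform(sub[keep, , drop = FALSE])
    cond <- factor(meta$condition)
    if (nlevels(droplevels(cond)) < 2L) next
    fit <- vegan::rda(H ~ cond)
    ve <- fit$CCA$tot.chi / fit$tot.chi
    an <- with_seed(derive_seed(seed, paste0("module_rda", k)),
                    vegan::anova.cca(fit, permutations = n_perm))
    rows[[length(rows) + 1L]] <- data.frame(
      module = names(mods)[k], n_members = length(members),
      variance_explained = ve, F = an$F[1L], P = an$`Pr(>F)`[1L],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(module = character(), n_members = integer(),
                      variance_explained = numeric(), F = numeric(),
                      P = numeric(), P_FDR = numeric()))
  out <- do.call(rbind, rows)
  out$P_FDR <- stats::p.adjust(out$P, "BH")
  out
}

#' Export a network as GraphML and edge-list TSV
#'
#' @param net graph from [build_network()].
#' @param modules optional [detect_modules()] result; module ids are
#'   added to the edge list.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_network <- function(net, dir, modules = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gml <- file.path(dir, "network.graphml")
  tsv <- file.path(dir, "edges.tsv")
  igraph::write_graph(net, gml, format = "graphml")
  el <- igraph::as_data_frame(net, what = "edges")
  if (!is.null(modules)) {
    memb <- modules$membership
    el$module_from <- memb[el$from]
    el$module_to <- memb[el$to]
  }
  utils::write.table(el, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gml, tsv))
}
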