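#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run with the workflow's
#' standard settings: rarefaction to 11,800 reads/sample, prevalence
#' filters of 5% (differential abundance) and 10% (network), 999
#' phylogenetic-null permutations, 10,000 permutations elsewhere, FDR
#' level 0.05, and a single master seed fanned out to per-stage child
#' seeds so stages are independently reproducible.
#'
#' @param rarefaction_depth reads/sample (default 11800).
#' @param prevalence_differential,prevalence_network prevalence filters.
#' @param n_null phylogenetic null draws (default 999).
#' @param n_perm permutations for all permutation tests (default 10000).
#' @param sparcc_samplings,sparcc_iterations SparCC settings (50, 100).
#' @param fdr FDR level (default 0.05).
#' @param seed master seed for every permutation test.
#' @param data_seed seed for the data-level stochastic estimates (the
#'   single rarefaction draw and the SparCC Dirichlet resamplings), kept
#'   separate so changing `seed` changes permutation P values but never
#'   the observed statistics.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(rarefaction_depth = 11800L,
                            prevalence_differential = 0.05,
                            prevalence_network = 0.10,
                            n_null = 999L, n_perm = 10000L,
                            sparcc_samplings = 50L,
                            sparcc_iterations = 100L,
                            fdr = 0.05, seed = 1L, data_seed = 1L) {
  stopifnot(rarefaction_depth >= 1,
            prevalence_differential > 0, prevalence_differential <= 1,
            prevalence_network > 0, prevalence_network <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing (rarefaction, coverage), alpha
#' diversity (indices, NRI/NTI, backward-AIC covariate models), beta
#' diversity (three distances, PCoA, PERMANOVA with pairwise contrasts),
#' differential abundance and indicator analysis, and the co-abundance
#' network layer (SparCC, significance, modules, centralities, module
#' completeness and its associations). Results are returned as a named
#' list and, if `out_dir` is given, written as tidy TSVs together with a
#' manifest recording parameters, seed and stage completion.
#'
#' @param dataset list with `counts`, `taxonomy`, `tree`, `metadata`
#'   (from [load_dataset()] or [simulate_dataset()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return named list of stage results (class `pipeline_result`).
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res$rarefied <- stage("preprocess",
    rarefy_table(dataset$counts, depth = config$rarefaction_depth,
                 seed = config$data_seed))
  res$coverage <- stage("preprocess",
    apply(count_matrix(dataset$counts), 1L, goods_coverage))

  meta <- dataset$metadata
  kept <- rownames(res$rarefied)
  meta_r <- meta[match(kept, meta$sample_id), , drop = FALSE]

  res$alpha <- stage("alpha", {
    a <- alpha_indices(res$rarefied)
    pa <- phylo_alpha(res$rarefied, dataset$tree, n_null = config$n_null,
                      seed = config$seed)
    merge(a, pa, by = "sample_id")
  })
  res$alpha_models <- stage("alpha", {
    dat <- merge(res$alpha, meta_r, by = "sample_id")
    lapply(stats::setNames(nm = c("chao1", "simpson", "nri", "nti")),
           function(v) fit_diversity_models(dat, v))
  })

  res$beta <- stage("beta", {
    lapply(stats::setNames(nm = c("bray_curtis", "jaccard", "gunifrac")),
           function(mt) {
      d <- distance_matrix(res$rarefied, mt, tree = dataset$tree)
      list(metric = mt,
           distance = d,
           ordination = pcoa_sqrt(d, k = 2L),
           permanova = permanova(d, meta_r,
                                 terms = c("age", "bmi", "gender",
                                           "condition"),
                                 n_perm = config$n_perm,
                                 seed = config$seed),
           pairwise = pairwise_permanova(d, meta_r, n_perm = config$n_perm,
                                         seed = config$seed))
    })
  })

  res$differential <- stage("differential", {
    filt <- prevalence_filter(dataset$counts,
                              config$prevalence_differential)
    asv <- nb_wald_test(filt, meta)
    phy <- nb_wald_test(
      prevalence_filter(aggregate_taxa(dataset$counts, dataset$taxonomy,
                                       "phylum"),
                        config$prevalence_differential),
      meta)
    ind <- indval_test(res$rarefied, meta_r$condition,
                       n_perm = config$n_perm, seed = config$seed)
    list(asv = asv, phylum = phy, indicators = ind)
  })

  res$network <- stage("network", {
    net_tab <- prevalence_filter(dataset$counts, config$prevalence_network)
    r <- sparcc(net_tab, n_iterations = config$sparcc_iterations,
                n_samplings = config$sparcc_samplings,
                seed = config$data_seed)
    # network construction (correlations + their significance screen) is
    # part of estimating the observed structure: it follows data_seed
    sig <- sparcc_significance(net_tab, r, n_perm = config$n_perm,
                               seed = config$data_seed)
    ind <- res$differential$indicators
    flags <- data.frame(taxon_id = colnames(r),
                        indicator = colnames(r) %in%
                          ind$taxon_id[ind$P_FDR <= config$fdr])
    net <- build_network(r, sig$P_FDR, node_annotations = flags,
                         fdr_cutoff = config$fdr)
    if (igraph::ecount(net) == 0L)
      return(list(correlations = r, significance = sig, graph = net,
                  modules = NULL, centralities = NULL,
                  centrality_null = NULL, indicator_comparison = NULL,
                  completeness = NULL, associations = NULL,
                  module_rda = NULL))
    mods <- detect_modules(net)
    cent <- node_centralities(net)
    cent_null <- centrality_null_test(net, n_perm = config$n_perm,
                                      seed = config$seed)
    cent_cmp <- if (any(flags$indicator) && !all(flags$indicator))
      indicator_centrality_comparison(
        cent, flags$indicator[match(cent$node, flags$taxon_id)],
        n_perm = config$n_perm, seed = config$seed) else NULL
    prof <- module_completeness(dataset$counts, mods, min_size = 2L)
    assoc <- list(condition = completeness_association(prof, meta,
                                                       "condition"))
    for (sc in c("sccai", "cdai"))
      if (sc %in% names(meta) && any(!is.na(meta[[sc]])))
        assoc[[sc]] <- completeness_association(prof, meta, sc)
    rda <- module_rda(dataset$counts, mods, meta,
                      n_perm = config$n_perm, seed = config$seed)
    list(correlations = r, significance = sig, graph = net,
         modules = mods, centralities = cent,
         centrality_null = cent_null,
         indicator_comparison = cent_cmp,
         completeness = prof, associations = assoc, module_rda = rda)
  })

  res$cohort <- stage("cohort", summarize_cohort(meta))
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

# write tidy TSVs plus a manifest of parameters and stages
write_pipeline_results <- function(res, out_dir) {
  for (sub in c("alpha", "beta", "differential", "network"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE,
               recursive = TRUE)
  wt <- function(x, path) utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$alpha, file.path(out_dir, "alpha", "alpha_diversity.tsv"))
  for (v in names(res$alpha_models)) {
    fitres <- res$alpha_models[[v]]
    wt(fitres$anova, file.path(out_dir, "alpha",
                               paste0("model_", v, "_anova.tsv")))
    wt(fitres$contrasts, file.path(out_dir, "alpha",
                                   paste0("model_", v, "_contrasts.tsv")))
  }
  for (mt in names(res$beta)) {
    b <- res$beta[[mt]]
    dm <- as.matrix(b$distance)
    utils::write.table(
      data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
      file.path(out_dir, "beta", paste0(mt, "_distance.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    wt(b$permanova, file.path(out_dir, "beta",
                              paste0(mt, "_permanova.tsv")))
    wt(b$pairwise, file.path(out_dir, "beta",
                             paste0(mt, "_pairwise.tsv")))
  }
  wt(res$differential$asv,
     file.path(out_dir, "differential", "asv_nb_wald.tsv"))
  wt(res$differential$phylum,
     file.path(out_dir, "differential", "phylum_nb_wald.tsv"))
  wt(res$differential$indicators,
     file.path(out_dir, "differential", "indicators.tsv"))
  nw <- res$network
  write_network(nw$graph, file.path(out_dir, "network"), nw$modules)
  if (is.null(nw$modules)) {
    writeLines("no edges passed the significance and strength cutoffs",
               file.path(out_dir, "network", "EMPTY"))
    cfgempty <- res$config
    manifest <- c(sprintf("seed\t%d", cfgempty$seed),
                  paste0("stages_complete\tpreprocess,alpha,beta,",
                         "differential,network,cohort"))
    writeLines(manifest, file.path(out_dir, "manifest.tsv"))
    return(invisible(out_dir))
  }
  wt(data.frame(node = names(nw$modules$membership),
                module = as.integer(nw$modules$membership)),
     file.path(out_dir, "network", "modules.tsv"))
  wt(nw$centrality_null, file.path(out_dir, "network",
                                   "centrality_null.tsv"))
  utils::write.table(
    data.frame(sample_id = rownames(nw$completeness), nw$completeness,
               check.names = FALSE),
    file.path(out_dir, "network", "module_completeness.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (a in names(nw$associations))
    wt(nw$associations[[a]],
       file.path(out_dir, "network",
                 paste0("completeness_", a, ".tsv")))
  wt(nw$module_rda, file.path(out_dir, "network", "module_rda.tsv"))

  cfg <- res$config
  manifest <- c(
    sprintf("seed\t%d", cfg$seed),
    sprintf("rarefaction_depth\t%d", cfg$rarefaction_depth),
    sprintf("n_perm\t%d", cfg$n_perm),
    sprintf("n_null\t%d", cfg$n_null),
    sprintf("fdr\t%g", cfg$fdr),
    paste0("stages_complete\tpreprocess,alpha,beta,differential,",
           "network,cohort"))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
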