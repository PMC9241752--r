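#' Per-sample alpha diversity indices
#'
#' Computed on a rarefied table so richness is comparable across samples:
#' observed richness, bias-corrected Chao1
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (F1/F2 = singleton/doubleton
#' counts), Gini-Simpson diversity `1 - sum(p_i^2)`, and Pielou evenness
#' `H / ln(S_obs)` (Shannon `H`; undefined, hence `NA`, for single-ASV
#' samples).
#'
#' @param table an [asv_table()], normally rarefied.
#' @return data.frame with one row per sample: `sample_id`,
#'   `observed_richness`, `chao1`, `simpson`, `evenness`.
#' @export
alpha_indices <- function(table) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  res <- t(apply(m, 1L, function(x) {
    x <- x[x > 0]
    s <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    p <- x / sum(x)
    h <- -sum(p * log(p))
    c(observed_richness = s,
      chao1 = s + f1 * (f1 - 1) / (2 * (f2 + 1)),
      simpson = 1 - sum(p^2),
      evenness = if (s > 1) h / log(s) else NA_real_)
  }))
  data.frame(sample_id = rownames(m), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Phylogenetic alpha diversity with a richness null model (NRI/NTI)
#'
#' Mean pairwise distance (MPD) and mean nearest-taxon distance (MNTD) of
#' each sample's taxa on the tree, standardized against null communities
#' that preserve each sample's richness while drawing taxa uniformly from
#' the pool of taxa present anywhere in the table (999 draws by default).
#' The net relatedness index is `NRI = -(MPD_obs - mean_null) / sd_null`
#' and likewise `NTI` from MNTD, so positive values indicate phylogenetic
#' clustering. Metrics are presence-based by default; set
#' `abundance_weighted = TRUE` for the abundance-weighted variants.
#'
#' Samples with fewer than two taxa get `NA` metrics; where the null
#' standard deviation is zero (e.g. every sample holds the full pool) the
#' index is emitted as 0 with `degenerate = TRUE`.
#'
#' @param table an [asv_table()], normally rarefied.
#' @param tree `ape::phylo` containing every ASV present in `table`.
#' @param n_null number of null communities (default 999).
#' @param seed integer seed for the null draws.
#' @param abundance_weighted weight (M)PD/(MN)TD by abundance?
#' @return data.frame per sample: `mpd_obs`, `mntd_obs`, `nri`, `nti`,
#'   null means/sds, `n_null`, `degenerate`.
#' @export
phylo_alpha <- function(table, tree, n_null = 999L, seed = 1L,
                        abundance_weighted = FALSE) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  present <- colSums(m) > 0
  m <- m[, present, drop = FALSE] # pool = taxa present anywhere
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop_arg("tree lacks ASVs present in the table: ",
             paste(utils::head(missing, 5L), collapse = ", "))
  pruned <- ape::keep.tip(tree, colnames(m))
  dis <- stats::cophenetic(pruned)
  dis <- dis[colnames(m), colnames(m)]
  res <- with_seed(derive_seed(seed, "phylo_alpha"), {
    ses_mpd <- picante::ses.mpd(m, dis, null.model = "richness",
                                abundance.weighted = abundance_weighted,
                                runs = n_null)
    ses_mntd <- picante::ses.mntd(m, dis, null.model = "richness",
                                  abundance.weighted = abundance_weighted,
                                  runs = n_null)
    list(mpd = ses_mpd, mntd = ses_mntd)
  })
  std <- function(obs, mu, sd) ifelse(sd > 0, -(obs - mu) / sd, 0)
  degen <- (res$mpd$mpd.rand.sd == 0 | res$mntd$mntd.rand.sd == 0)
  out <- data.frame(
    sample_id = rownames(m),
    mpd_obs = res$mpd$mpd.obs,
    mntd_obs = res$mntd$mntd.obs,
    nri = std(res$mpd$mpd.obs, res$mpd$mpd.rand.mean, res$mpd$mpd.rand.sd),
    nti = std(res$mntd$mntd.obs, res$mntd$mntd.rand.mean,
              res$mntd$mntd.rand.sd),
    mpd_null_mean = res$mpd$mpd.rand.mean,
    mpd_null_sd = res$mpd$mpd.rand.sd,
    mntd_null_mean = res$mntd$mntd.rand.mean,
    mntd_null_sd = res$mntd$mntd.rand.sd,
    n_null = n_null,
    degenerate = !is.na(degen) & degen,
    row.names = NULL, stringsAsFactors = FALSE)
  few <- rowSums(m > 0) < 2
  out[few, c("mpd_obs", "mntd_obs", "nri", "nti")] <- NA_real_
  out
}

#' Covariate models for diversity with backward AIC selection
#'
#' Fits an ordinary least-squares model of a diversity index on the
#' candidate terms (by default `condition * age + condition * bmi +
#' gender`), then removes, one at a time, the term whose deletion most
#' lowers the AIC until no deletion lowers it further — main effects are
#' never removed while a retained interaction contains them. The final
#' model is summarized with sequential ANOVA F-tests, and pairwise
#' condition contrasts are obtained by refitting the final model on
#' two-condition subsets: the subset P of the `condition` term (average
#' differences) and, when an age or BMI interaction was retained, of the
#' interaction term (slope differences, reported as e.g. `Age:Contr.-CD`).
#'
#' @param data data.frame holding the response and covariates (e.g. the
#'   merge of [alpha_indices()] / [phylo_alpha()] with the metadata).
#' @param response name of the response column.
#' @param candidates character vector of model terms.
#' @return list of class `diversity_model`: `response`, `final_formula`,
#'   `anova` (term, df, F, P), `contrasts` (comparison, P), `aic`,
#'   `model` (the `lm` fit).
#' @export
fit_diversity_models <- function(data, response,
                                 candidates = c("condition * age",
                                                "condition * bmi",
                                                "gender")) {
  if (!response %in% names(data)) stop_arg("response `", response,
                                           "` not found")
  if (anyDuplicated(candidates)) {
    warning("duplicated candidate terms collapsed to one copy")
    candidates <- unique(candidates)
  }
  form <- stats::reformulate(candidates, response = response)
  vars <- all.vars(form)
  dat <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
              drop = FALSE]
  if ("condition" %in% names(dat))
    dat$condition <- stats::relevel(factor(dat$condition), ref = "Control")
  full <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(full))))
    warning("rank-deficient candidate model; aliased terms dropped")
  fit <- stats::step(full, direction = "backward", trace = 0)
  an <- stats::anova(fit)
  terms_kept <- rownames(an)[rownames(an) != "Residuals"]
  anova_tab <- if (length(terms_kept)) data.frame(
    term = terms_kept,
    df = an$Df[seq_along(terms_kept)],
    df_resid = an$Df[nrow(an)],
    F = an$`F value`[seq_along(terms_kept)],
    P = an$`Pr(>F)`[seq_along(terms_kept)],
    row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(term = character(), df = integer(),
                  df_resid = integer(), F = numeric(), P = numeric())

  contrasts <- pairwise_condition_contrasts(fit, dat, response)
  structure(list(response = response,
                 final_formula = stats::formula(fit),
                 anova = anova_tab, contrasts = contrasts,
                 aic = stats::AIC(fit), model = fit),
            class = "diversity_model")
}

# refit the selected model on each pair of conditions and report the P of
# the condition term and of any retained condition interaction
pairwise_condition_contrasts <- function(fit, dat, response) {
  tl <- attr(stats::terms(fit), "term.labels")
  if (!"condition" %in% all.vars(stats::formula(fit)) ||
      !"condition" %in% names(dat))
    return(data.frame(comparison = character(), P = numeric()))
  lev <- levels(dat$condition)
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  short <- c(Control = "Contr.", CD = "CD", UC = "UC")
  rows <- list()
  for (pr in pairs) {
    sub <- droplevels(dat[dat$condition %in% pr, , drop = FALSE])
    subfit <- stats::lm(stats::formula(fit), data = sub)
    an <- stats::anova(subfit)
    lab <- paste(short[pr], collapse = "-")
    if ("condition" %in% rownames(an))
      rows[[length(rows) + 1L]] <-
        data.frame(comparison = lab, term = "condition",
                   P = an["condition", "Pr(>F)"])
    for (iv in intersect(c("age", "bmi"), all.vars(stats::formula(fit)))) {
      intn <- intersect(c(paste0("condition:", iv), paste0(iv, ":condition")),
                        rownames(an))
      if (length(intn))
        rows[[length(rows) + 1L]] <-
          data.frame(comparison = paste0(toupper(substr(iv, 1, 1)),
                                         substr(iv, 2, nchar(iv)), ":", lab),
                     term = intn[1L], P = an[intn[1L], "Pr(>F)"])
    }
  }
  if (!length(rows)) return(data.frame(comparison = character(),
                                       term = character(), P = numeric()))
  do.call(rbind, rows)
}

#' @export
print.diversity_model <- function(x, ...) {
  cat("Diversity model for", x$response, "\n")
  cat("  final:", deparse(x$final_formula), sprintf(" (AIC %.2f)\n", x$aic))
  print(x$anova, digits = 4)
  if (nrow(x$contrasts)) {
    cat("  pairwise contrasts:\n")
    print(x$contrasts, digits = 4)
  }
  invisible(x)
}
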