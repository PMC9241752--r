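#' Median-of-ratios size factors
#'
#' Library-size normalization factors in the DESeq tradition: each
#' sample's factor is the median over reference taxa of
#' `count / geometric mean across samples`, where reference taxa are
#' those with no zero count (falling back to a positive-counts geometric
#' mean when no all-nonzero taxon exists). Factors are scaled to
#' geometric mean 1.
#'
#' @param table an [asv_table()] with at least 2 samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(table) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  if (nrow(m) < 2L) stop_arg("need at least 2 samples")
  allpos <- colSums(m == 0) == 0
  if (any(allpos)) {
    sub <- m[, allpos, drop = FALSE]
    gm <- exp(colMeans(log(sub)))
    ratios <- sweep(sub, 2L, gm, "/")
  } else {
    # fallback: geometric mean over positive counts only
    gm <- apply(m, 2L, function(x) exp(mean(log(x[x > 0]))))
    usable <- colSums(m > 0) >= 2L
    if (!any(usable))
      stop_arg("no taxa usable for size-factor estimation; ",
               "consider pooling or pseudocounts")
    ratios <- sweep(m[, usable, drop = FALSE], 2L, gm[usable], "/")
    ratios[m[, usable, drop = FALSE] == 0] <- NA
  }
  sf <- apply(ratios, 1L, stats::median, na.rm = TRUE)
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald tests for differential abundance
#'
#' Per-taxon negative-binomial GLM with log link and log-size-factor
#' offsets on the design `~ gender + age + condition` (Control as the
#' reference level), with maximum-likelihood dispersion and a
#' method-of-moments fallback floored at 1e-8. Wald tests on the contrast
#' coefficients, BH-adjusted across taxa within each contrast.
#' Non-converged taxa are flagged and excluded from the FDR family.
#'
#' This is a transparent simplification of the DESeq2 machinery — no
#' empirical-Bayes dispersion shrinkage or independent filtering — chosen
#' so the model formula, prevalence filter and FDR procedure stay exactly
#' as specified while every fitting step remains inspectable.
#'
#' @param table an [asv_table()], prevalence-filtered at 5% upstream.
#' @param metadata data.frame with `sample_id` and the design columns.
#' @param design one-sided formula over metadata columns; the grouping
#'   column `condition` must be one of them.
#' @param contrasts list of condition pairs `c(level, reference)`;
#'   default CD-vs-Control, UC-vs-Control, UC-vs-CD.
#' @param sf optional size factors (computed from `table` by default).
#' @return data.frame per taxon x contrast: `taxon_id`, `contrast`,
#'   `log2_fold_change`, `se`, `stat`, `P`, `P_FDR`, `converged`.
#' @export
nb_wald_test <- function(table, metadata,
                         design = ~ gender + age + condition,
                         contrasts = list(c("CD", "Control"),
                                          c("UC", "Control"),
                                          c("UC", "CD")),
                         sf = NULL) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  vars <- all.vars(design)
  cc <- stats::complete.cases(meta[, vars, drop = FALSE])
  m <- m[cc, , drop = FALSE]
  meta <- meta[cc, , drop = FALSE]
  if ("condition" %in% vars)
    meta$condition <- stats::relevel(factor(meta$condition),
                                     ref = "Control")
  sf <- sf %||% size_factors(asv_table(m))
  X <- stats::model.matrix(design, data = meta)
  off <- log(sf)

  fits <- lapply(seq_len(ncol(m)), function(j)
    fit_nb_taxon(m[, j], X, off))
  names(fits) <- colnames(m)

  rows <- list()
  for (ct in contrasts) {
    lab <- paste0(ct[1L], "-vs-", ct[2L])
    L <- contrast_vector(colnames(X), "condition", ct)
    est <- t(vapply(fits, function(f) {
      if (is.null(f)) return(c(NA_real_, NA_real_))
      b <- sum(L * f$coef)
      se <- sqrt(drop(t(L) %*% f$vcov %*% L))
      c(b, se)
    }, numeric(2L)))
    lfc <- est[, 1L] / log(2)
    se <- est[, 2L] / log(2)
    stat <- est[, 1L] / est[, 2L]
    p <- 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
    conv <- !vapply(fits, is.null, logical(1L))
    padj <- rep(NA_real_, length(p))
    padj[conv] <- stats::p.adjust(p[conv], "BH")
    rows[[lab]] <- data.frame(taxon_id = colnames(m), contrast = lab,
                              log2_fold_change = lfc, se = se,
                              stat = stat, P = p, P_FDR = padj,
                              converged = conv, row.names = NULL,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Wald contrast vector for `level - reference` of a treatment-coded factor
contrast_vector <- function(coef_names, factor_name, pair) {
  L <- numeric(length(coef_names))
  names(L) <- coef_names
  for (sgn in c(1, -1)) {
    lev <- pair[if (sgn > 0) 1L else 2L]
    nm <- paste0(factor_name, lev)
    if (nm %in% coef_names) L[nm] <- sgn # reference level has no column
  }
  L
}

fit_nb_taxon <- function(y, X, off) {
  dat <- data.frame(y = y, X[, -1L, drop = FALSE], check.names = FALSE)
  form <- y ~ . + offset(off)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = dat,
                                  control = stats::glm.control(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(stats::coef(fit))) {
    # method-of-moments dispersion from a Poisson fit, floored at 1e-8
    pois <- tryCatch(
      suppressWarnings(stats::glm(y ~ . + offset(off), data = dat,
                                  family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(pois)) return(NULL)
    mu <- stats::fitted(pois)
    alpha <- max(sum((y - mu)^2 - mu) / sum(mu^2), 1e-8)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ . + offset(off), data = dat,
                                  family = MASS::negative.binomial(1 / alpha))),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) return(NULL)
    # NB likelihood has no free dispersion once theta is fixed
    return(list(coef = stats::coef(fit),
                vcov = summary(fit, dispersion = 1)$cov.scaled))
  }
  list(coef = stats::coef(fit), vcov = stats::vcov(fit))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' preserving input order; a validated front-end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of P values in \[0, 1\].
#' @return adjusted P values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_arg("P values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Indicator species analysis (IndVal.g)
#'
#' Group-size-corrected indicator value of Dufrêne-Legendre as generalized
#' by De Cáceres: for taxon `k` and group `g`, specificity
#' `A = mean abundance in g / sum over groups of mean abundances` and
#' fidelity `B = occurrence fraction in g`; `IndVal.g = sqrt(A * B)`. Each
#' taxon is associated with its argmax group; significance by permuting
#' group labels, `P = (b + 1)/(m + 1)`, BH-adjusted across taxa. Taxa
#' absent everywhere are skipped.
#'
#' @param table an [asv_table()], normally rarefied.
#' @param groups group label per sample (character or factor).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @param perm_matrix optional matrix of permuted sample indices (rows =
#'   permutations) for exhaustive tests; overrides `n_perm`.
#' @return data.frame per taxon: `taxon_id`, `group`, `indval_g`, `P`,
#'   `P_FDR`.
#' @export
indval_test <- function(table, groups, n_perm = 10000L, seed = 1L,
                        perm_matrix = NULL) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop_arg("need at least 2 groups")
  if (any(table(g) < 2L)) stop_arg("each group needs at least 2 samples")
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]

  stat_fun <- function(gg) {
    mu <- rowsum(m, gg) / as.vector(table(gg)) # group mean abundance
    occ <- rowsum((m > 0) + 0, gg) / as.vector(table(gg))
    A <- sweep(mu, 2L, colSums(mu), "/")
    iv <- sqrt(A * occ)
    list(stat = apply(iv, 2L, max),
         group = rownames(mu)[apply(iv, 2L, which.max)])
  }
  obs <- stat_fun(g)
  perms <- with_seed(derive_seed(seed, "indval"), {
    if (!is.null(perm_matrix)) {
      apply(perm_matrix, 1L, function(ix) stat_fun(g[ix])$stat)
    } else {
      vapply(seq_len(n_perm),
             function(i) stat_fun(sample(g))$stat,
             numeric(ncol(m)))
    }
  })
  perms <- matrix(perms, nrow = ncol(m))
  b <- rowSums(perms >= obs$stat - 1e-12)
  p <- (b + 1) / (ncol(perms) + 1)
  data.frame(taxon_id = colnames(m), group = obs$group,
             indval_g = unname(obs$stat), P = unname(p),
             P_FDR = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
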