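#' Configuration for a synthetic IBD-remission cohort
#'
#' Defaults mirror the cohort structure the analysis assumes: 97 healthy
#' controls, 32 Crohn's disease (CD) and 66 ulcerative colitis (UC)
#' subjects (195 in total), several hundred ASVs, sequencing depths with a
#' floor of 11,800 reads/sample so default rarefaction drops nothing, one
#' tightly correlated "Enterobacteriaceae-like" taxon module planted with
#' pairwise basis correlation 0.8 and enriched in CD, and per-condition
#' abundance shifts on a handful of further taxa.
#'
#' Counts are generated from a multivariate log-normal basis whose
#' log-scale covariance encodes the module correlations and whose log-means
#' carry the condition effects; reads are a multinomial draw of the closed
#' composition at the subject's depth. A Dirichlet-multinomial alternative
#' (`model = "dirichlet"`) is available for robustness checks.
#'
#' @param n_control,n_cd,n_uc subjects per condition.
#' @param n_asv number of taxa.
#' @param depth_mean,depth_sdlog log-normal read-depth parameters
#'   (location on the natural scale, sdlog on the log scale).
#' @param depth_floor minimum depth; draws below it are raised to it.
#' @param module_spec list of planted modules, each
#'   `list(members =, rho =, condition =, log2fc =, meanlog =)`: member
#'   ASV indices, pairwise basis correlation, an optional abundance
#'   enrichment (log2 fold change) in one condition, and an optional
#'   shared baseline log-abundance (set low, e.g. -4, to make module
#'   presence/absence vary across subjects as it does for a rare
#'   pathobiont group; leave `NULL` to keep the members' random
#'   baselines).
#' @param effect_spec list of planted single-taxon effects, each
#'   `list(asv =, condition =, log2fc =)`.
#' @param basis_meanlog_sd spread of baseline log-abundances across taxa
#'   (controls the rank-abundance curve).
#' @param basis_sdlog per-taxon log-scale standard deviation.
#' @param age_evenness named per-condition coefficient shrinking the
#'   log-mean spread with age (plants an age-by-condition diversity trend);
#'   default none.
#' @param model `"lognormal"` (default) or `"dirichlet"`.
#' @param seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_control = 97L, n_cd = 32L, n_uc = 66L,
                       n_asv = 300L,
                       depth_mean = 2e4, depth_sdlog = 0.25,
                       depth_floor = 11800L,
                       module_spec = list(list(members = 1:10, rho = 0.8,
                                               condition = "CD",
                                               log2fc = 3,
                                               meanlog = -4)),
                       effect_spec = default_effect_spec(),
                       basis_meanlog_sd = 1.5,
                       basis_sdlog = 1.0,
                       age_evenness = c(Control = 0, CD = 0, UC = 0),
                       model = c("lognormal", "dirichlet"),
                       seed = 1L) {
  model <- match.arg(model)
  if (min(n_control, n_cd, n_uc) < 1L) stop_arg("group sizes must be > 0")
  if (n_asv < 3L) stop_arg("`n_asv` must be >= 3")
  for (m in module_spec) {
    if (abs(m$rho) >= 1) stop_arg("module |rho| must be < 1")
    if (max(m$members) > n_asv) stop_arg("module member index out of range")
  }
  structure(list(n_control = as.integer(n_control), n_cd = as.integer(n_cd),
                 n_uc = as.integer(n_uc), n_asv = as.integer(n_asv),
                 depth_mean = depth_mean, depth_sdlog = depth_sdlog,
                 depth_floor = as.integer(depth_floor),
                 module_spec = module_spec, effect_spec = effect_spec,
                 basis_meanlog_sd = basis_meanlog_sd,
                 basis_sdlog = basis_sdlog,
                 age_evenness = age_evenness,
                 model = model, seed = as.integer(seed)),
            class = "sim_config")
}

# A small default set of single-taxon condition shifts (indices past the
# planted module) so differential-abundance stages have signal to find.
default_effect_spec <- function() {
  list(list(asv = 21L, condition = "CD", log2fc = 2),
       list(asv = 22L, condition = "UC", log2fc = 2),
       list(asv = 23L, condition = "Control", log2fc = 2),
       list(asv = 24L, condition = "UC", log2fc = -2))
}

#' Simulate a random rooted phylogeny over the ASVs
#'
#' Birth-only (Yule) topology conditioned on `n_tips` tips, with
#' independent exponential branch lengths; tips are labelled
#' `ASV_1 ... ASV_n`. A stand-in for a real 16S ASV tree.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @param branch_rate rate of the exponential branch-length distribution.
#' @return an `ape::phylo` tree.
#' @export
simulate_tree <- function(n_tips, seed = 1L, branch_rate = 10) {
  if (n_tips < 3L) stop_arg("`n_tips` must be >= 3")
  with_seed(derive_seed(seed, "tree"), {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = branch_rate)
    tree$tip.label <- paste0("ASV_", seq_len(n_tips))
    tree
  })
}

#' Simulate subject metadata for the three condition groups
#'
#' Covariates follow the cohort's demographic structure: gender and
#' smoking proportions per condition, adult ages, BMI around the
#' overweight boundary, medication flags (every UC subject receives
#' 5-ASA), Montreal subtype codes within their condition, and clinical
#' activity scores in the remission range (SCCAI for UC, CDAI for CD);
#' condition-specific fields are `NA` elsewhere.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per subject.
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- c(Control = config$n_control, CD = config$n_cd, UC = config$n_uc)
  with_seed(derive_seed(config$seed, "metadata"), {
    condition <- rep(names(n), n)
    ntot <- sum(n)
    p_male <- c(Control = 0.515, CD = 0.563, UC = 0.652)[condition]
    gender <- ifelse(stats::runif(ntot) < p_male, "M", "F")
    age <- pmax(19, round(stats::rnorm(ntot, mean = 45, sd = 16)))
    bmi <- round(stats::rlnorm(ntot, log(26), 0.15), 1)
    smoke_p <- rbind(Control = c(0.835, 0.062, 0.103),
                     CD = c(0.563, 0.188, 0.250),
                     UC = c(0.682, 0.060, 0.258))
    smoking <- vapply(condition, function(cc)
      sample(c("nonsmoker", "smoker", "ex-smoker"), 1L,
             prob = smoke_p[cc, ]), character(1L))
    ibd <- condition != "Control"
    med_5asa <- ifelse(condition == "UC", TRUE,
                       ifelse(condition == "CD", stats::runif(ntot) < 0.75,
                              NA))
    med_thiopurine <- ifelse(ibd, stats::runif(ntot) < 0.40, NA)
    med_antitnf <- ifelse(ibd, stats::runif(ntot) < 0.35, NA)
    montreal_A <- ifelse(condition == "CD",
                         sample(c("A1", "A2", "A3"), ntot, TRUE,
                                prob = c(0.19, 0.66, 0.15)), NA)
    montreal_B <- ifelse(condition == "CD",
                         sample(c("B1", "B2/B3"), ntot, TRUE,
                                prob = c(0.72, 0.28)), NA)
    montreal_L <- ifelse(condition == "CD",
                         sample(c("L1", "L2", "L3"), ntot, TRUE,
                                prob = c(0.34, 0.25, 0.41)), NA)
    montreal_E <- ifelse(condition == "UC",
                         sample(c("E1", "E2", "E3"), ntot, TRUE,
                                prob = c(0.30, 0.36, 0.33)), NA)
    sccai <- ifelse(condition == "UC", stats::rpois(ntot, 1.5), NA)
    cdai <- ifelse(condition == "CD",
                   round(stats::rgamma(ntot, shape = 4, scale = 20), 1), NA)
    data.frame(sample_id = sprintf("S%03d", seq_len(ntot)),
               condition = condition, age = age, gender = gender,
               bmi = bmi, smoking = smoking, med_5asa = med_5asa,
               med_thiopurine = med_thiopurine, med_antitnf = med_antitnf,
               montreal_A = montreal_A, montreal_B = montreal_B,
               montreal_L = montreal_L, montreal_E = montreal_E,
               sccai = sccai, cdai = cdai,
               stringsAsFactors = FALSE)
  })
}

# per-taxon baseline log-abundances; module members are pinned to a low
# baseline so their presence/absence varies between subjects
basis_meanlog <- function(config) {
  mu <- with_seed(derive_seed(config$seed, "meanlog"),
                  stats::rnorm(config$n_asv, 0, config$basis_meanlog_sd))
  for (m in config$module_spec)
    if (!is.null(m$meanlog)) mu[m$members] <- m$meanlog
  mu
}

# log-scale covariance: diagonal basis_sdlog^2 with module blocks at rho
basis_covariance <- function(config) {
  s <- rep(config$basis_sdlog, config$n_asv)
  sigma <- diag(s^2, config$n_asv)
  for (m in config$module_spec) {
    idx <- m$members
    block <- m$rho * outer(s[idx], s[idx])
    diag(block) <- s[idx]^2
    sigma[idx, idx] <- block
  }
  sigma
}

#' Simulate the ASV count table for a cohort
#'
#' Per subject, basis abundances are drawn from a multivariate log-normal
#' whose log-scale covariance encodes the planted module correlations and
#' whose log-means carry the subject's condition effects; the basis is
#' closed to proportions and reads are drawn
#' `multinomial(depth, proportions)` with a log-normal depth floored at
#' `config$depth_floor`. Each sample's counts sum exactly to its drawn
#' depth. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param tree tree from [simulate_tree()] (tip count must equal `n_asv`).
#' @param metadata data.frame from [simulate_metadata()].
#' @return an [asv_table()] (subjects x ASVs).
#' @export
simulate_counts <- function(config, tree, metadata) {
  stopifnot(inherits(config, "sim_config"))
  if (ape::Ntip(tree) != config$n_asv)
    stop_arg("tree tip count does not match `n_asv`")
  if (!all(c("sample_id", "condition", "age") %in% names(metadata)))
    stop_arg("metadata lacks required columns")
  p <- config$n_asv
  nsub <- nrow(metadata)
  mu0 <- basis_meanlog(config)

  # condition-specific log-mean shifts (log2fc on the natural-log scale)
  shift <- matrix(0, nrow = 3L, ncol = p,
                  dimnames = list(c("Control", "CD", "UC"), NULL))
  for (e in config$effect_spec)
    shift[e$condition, e$asv] <- shift[e$condition, e$asv] + log(2) * e$log2fc
  for (m in config$module_spec)
    if (!is.null(m$condition) && !is.null(m$log2fc))
      shift[m$condition, m$members] <-
        shift[m$condition, m$members] + log(2) * m$log2fc

  cholL <- chol(basis_covariance(config))
  with_seed(derive_seed(config$seed, "counts"), {
    depths <- pmax(config$depth_floor,
                   round(stats::rlnorm(nsub, log(config$depth_mean),
                                       config$depth_sdlog)))
    counts <- matrix(0L, nrow = nsub, ncol = p,
                     dimnames = list(metadata$sample_id, tree$tip.label))
    for (i in seq_len(nsub)) {
      cond <- metadata$condition[i]
      mu <- mu0 + shift[cond, ]
      a <- unname(config$age_evenness[cond])
      if (!is.na(a) && a != 0) # shrink spread with age -> more even with age
        mu <- mu * pmax(0.2, 1 - a * (metadata$age[i] - 45))
      if (config$model == "lognormal") {
        z <- mu + drop(crossprod(cholL, stats::rnorm(p)))
        prop <- exp(z - max(z))
      } else { # Dirichlet-multinomial alternative
        prop <- stats::rgamma(p, shape = exp(mu) /
                                sum(exp(mu)) * 50, rate = 1)
        prop[prop <= 0] <- 1e-12
      }
      prop <- prop / sum(prop)
      counts[i, ] <- stats::rmultinom(1L, depths[i], prop)[, 1L]
    }
    asv_table(counts)
  })
}

# synthetic taxonomy: module members get Enterobacteriaceae-style labels,
# the rest are spread over common gut phyla; all below-rank labels "uncl."
simulate_taxonomy <- function(config, tree) {
  p <- config$n_asv
  phyla <- c("Firmicutes", "Bacteroidetes", "Actinobacteria",
             "Proteobacteria", "Verrucomicrobia", "Fusobacteria")
  tax <- data.frame(asv_id = tree$tip.label,
                    kingdom = "Bacteria",
                    phylum = with_seed(derive_seed(config$seed, "taxonomy"),
                                       sample(phyla, p, TRUE,
                                              prob = c(.5, .25, .1, .08,
                                                       .04, .03))),
                    class = "uncl.", order = "uncl.", family = "uncl.",
                    genus = "uncl.", species = "uncl.",
                    stringsAsFactors = FALSE)
  entero <- c("Klebsiella", "Escherichia/Shigella", "Enterobacter",
              "Citrobacter")
  for (m in config$module_spec) {
    idx <- m$members
    tax$phylum[idx] <- "Proteobacteria"
    tax$class[idx] <- "Gammaproteobacteria"
    tax$order[idx] <- "Enterobacteriales"
    tax$family[idx] <- "Enterobacteriaceae"
    tax$genus[idx] <- rep_len(entero, length(idx))
  }
  tax
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper producing the four cross-referenced objects
#' [load_dataset()] would return, from a single [sim_config()].
#'
#' @param config a [sim_config()].
#' @return list with `counts`, `taxonomy`, `tree`, `metadata`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_tree(config$n_asv, seed = config$seed)
  metadata <- simulate_metadata(config)
  counts <- simulate_counts(config, tree, metadata)
  list(counts = counts, taxonomy = simulate_taxonomy(config, tree),
       tree = tree, metadata = metadata)
}
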