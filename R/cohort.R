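#' Demographic cohort summary
#'
#' Per-condition counts and percentages for gender, age bins (<=30,
#' 31-60, >=61 years), smoking status, BMI bins (18.5-24.9, 25-29.9,
#' >=30 kg/m2), Montreal subtype codes and medication flags, plus
#' cohort-level shares (UC fraction of the IBD patients, smoking
#' breakdown over all IBD patients). Percentages are of the condition
#' group (or of the IBD patients for the cohort-level rows), rounded to
#' one decimal.
#'
#' @param metadata data.frame with the cohort fields (see
#'   [simulate_metadata()] for the schema).
#' @return list with `by_condition` (data.frame: condition, category,
#'   level, n, pct) and `ibd` (data.frame: statistic, n, pct).
#' @export
summarize_cohort <- function(metadata) {
  stopifnot(all(c("condition", "age", "gender") %in% names(metadata)))
  conds <- intersect(c("UC", "CD", "Control"), unique(metadata$condition))
  # half-up rounding, as in the published tables (18/32 -> 56.3)
  pct <- function(n, total) floor(1000 * n / total + 0.5) / 10

  level_rows <- function(cond, category, values, levels) {
    total <- sum(metadata$condition == cond)
    vals <- values[metadata$condition == cond]
    n <- vapply(levels, function(l) sum(vals == l, na.rm = TRUE),
                integer(1L))
    data.frame(condition = cond, category = category, level = levels,
               n = unname(n), pct = pct(unname(n), total),
               row.names = NULL, stringsAsFactors = FALSE)
  }

  age_bin <- cut(metadata$age, c(-Inf, 30, 60, Inf),
                 labels = c("<30", "31-60", ">61"))
  bmi_bin <- if ("bmi" %in% names(metadata))
    cut(metadata$bmi, c(-Inf, 24.95, 29.95, Inf),
        labels = c("18.5-24.9", "25-29.9", ">30")) else NULL

  rows <- list()
  for (cond in conds) {
    rows[[length(rows) + 1L]] <-
      level_rows(cond, "gender", metadata$gender, c("M", "F"))
    rows[[length(rows) + 1L]] <-
      level_rows(cond, "age", age_bin, levels(age_bin))
    if ("smoking" %in% names(metadata))
      rows[[length(rows) + 1L]] <-
        level_rows(cond, "smoking", metadata$smoking,
                   c("nonsmoker", "smoker", "ex-smoker"))
    if (!is.null(bmi_bin))
      rows[[length(rows) + 1L]] <-
        level_rows(cond, "bmi", bmi_bin, levels(bmi_bin))
    for (mc in intersect(c("montreal_A", "montreal_B", "montreal_L",
                           "montreal_E", "med_5asa", "med_thiopurine",
                           "med_antitnf"), names(metadata))) {
      vals <- metadata[[mc]][metadata$condition == cond]
      lev <- sort(unique(vals[!is.na(vals)]))
      if (length(lev))
        rows[[length(rows) + 1L]] <-
          level_rows(cond, mc, metadata[[mc]], as.character(lev))
    }
  }
  by_condition <- do.call(rbind, rows)

  n_uc <- sum(metadata$condition == "UC")
  n_cd <- sum(metadata$condition == "CD")
  n_ibd <- n_uc + n_cd
  ibd <- data.frame(statistic = c("UC share of IBD", "CD share of IBD"),
                    n = c(n_uc, n_cd),
                    pct = pct(c(n_uc, n_cd), n_ibd),
                    stringsAsFactors = FALSE)
  if ("smoking" %in% names(metadata)) {
    sm <- metadata$smoking[metadata$condition %in% c("UC", "CD")]
    for (l in c("nonsmoker", "smoker", "ex-smoker"))
      ibd <- rbind(ibd, data.frame(
        statistic = paste("IBD", l), n = sum(sm == l, na.rm = TRUE),
        pct = pct(sum(sm == l, na.rm = TRUE), n_ibd)))
  }
  list(by_condition = by_condition, ibd = ibd)
}
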