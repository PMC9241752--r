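#' Construct an ASV count table
#'
#' An `asv_table` is a non-negative integer matrix of sequence read counts
#' with samples as rows and amplicon sequence variants (ASVs) as columns.
#' Row and column names are the sample and ASV identifiers and must be
#' unique; every sample must contain at least one read.
#'
#' @param counts numeric matrix of non-negative integers, samples x ASVs,
#'   with unique rownames (sample ids) and colnames (ASV ids).
#' @return an object of class `asv_table` (an integer matrix).
#' @export
asv_table <- function(counts) {
  if (!is.matrix(counts)) stop_arg("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_arg("`counts` must carry sample ids (rownames) and ASV ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop_arg("duplicate sample ids in count table")
  if (anyDuplicated(colnames(counts)))
    stop_arg("duplicate ASV ids in count table")
  if (any(is.na(counts))) stop_arg("count table contains missing values")
  if (any(counts < 0)) stop_arg("count table contains negative entries")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop_arg("count table contains non-integer entries")
  if (any(rowSums(counts) == 0))
    stop_arg("samples with zero total reads: ",
             paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(counts, class = c("asv_table", class(unclass(counts))))
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV count table: %d samples x %d ASVs, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  d <- attr(x, "depth")
  if (!is.null(d))
    cat(sprintf("  rarefied to %s reads/sample (%d sample(s) dropped)\n",
                format(d, big.mark = ","),
                length(attr(x, "dropped_samples"))))
  invisible(x)
}

# strip the class but keep dimnames; used before handing to matrix code
count_matrix <- function(table) {
  m <- unclass(table)
  attr(m, "depth") <- NULL
  attr(m, "dropped_samples") <- NULL
  m
}

#' Rarefy samples to a common sequencing depth
#'
#' Each sample's reads are subsampled uniformly *without replacement* to
#' exactly `depth` reads, the standard normalization that makes richness
#' and coverage comparable across samples (the workflow default is
#' 11,800 reads/sample). Samples with fewer than `depth` total reads are
#' dropped, not retained at native depth.
#'
#' @param table an [asv_table()].
#' @param depth target reads per sample (default 11800).
#' @param seed integer seed; the draw is deterministic given
#'   `(table, depth, seed)`.
#' @return an `asv_table` whose retained rows each sum exactly to `depth`,
#'   with attributes `depth` and `dropped_samples`.
#' @export
rarefy_table <- function(table, depth = 11800L, seed = 1L) {
  if (!inherits(table, "asv_table")) table <- asv_table(table)
  if (length(depth) != 1L || is.na(depth) || depth < 1)
    stop_arg("`depth` must be a positive integer")
  depth <- as.integer(depth)
  m <- count_matrix(table)
  keep <- rowSums(m) >= depth
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  out <- with_seed(derive_seed(seed, "rarefy"), {
    t(apply(m, 1L, function(x) {
      n <- sum(x)
      if (n == depth) return(as.integer(x))
      # uniform subsample without replacement of the read multiset
      reads <- rep.int(seq_along(x), x)
      tabulate(reads[sample.int(n, depth)], nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(m)
  res <- asv_table(out)
  attr(res, "depth") <- depth
  attr(res, "dropped_samples") <- dropped
  res
}

#' Good's coverage of a sample
#'
#' Estimates the fraction of the community captured by the sample as
#' `1 - F1/N`, with `F1` the number of singleton ASVs and `N` the total
#' read count.
#'
#' @param sample_counts non-negative integer vector, sum > 0.
#' @return coverage fraction in \[0, 1\].
#' @export
goods_coverage <- function(sample_counts) {
  if (any(sample_counts < 0) || any(sample_counts != round(sample_counts)))
    stop_arg("counts must be non-negative integers")
  n <- sum(sample_counts)
  if (n == 0) stop_arg("sample has zero reads")
  1 - sum(sample_counts == 1) / n
}

#' Filter ASVs by prevalence
#'
#' Retains ASVs observed (count > 0) in at least
#' `ceiling(min_fraction * n_samples)` samples. The workflow uses 5%
#' before differential abundance testing and 10% before network inference.
#'
#' @param table an [asv_table()].
#' @param min_fraction required fraction of samples, in (0, 1\].
#' @return filtered `asv_table`, column order preserved.
#' @export
prevalence_filter <- function(table, min_fraction) {
  if (!inherits(table, "asv_table")) table <- asv_table(table)
  if (length(min_fraction) != 1L || min_fraction <= 0 || min_fraction > 1)
    stop_arg("`min_fraction` must be in (0, 1]")
  m <- count_matrix(table)
  need <- ceiling(min_fraction * nrow(m))
  keep <- colSums(m > 0) >= need
  if (!any(keep)) warning("prevalence filter removed every ASV")
  out <- m[, keep, drop = FALSE]
  res <- asv_table(out)
  attr(res, "depth") <- attr(table, "depth")
  attr(res, "dropped_samples") <- attr(table, "dropped_samples")
  res
}

#' Hellinger transform
#'
#' Square root of relative abundance, `sqrt(count / rowsum)`; each
#' transformed row has unit sum of squares. Makes linear ordination
#' (RDA/PCA) appropriate for count compositions.
#'
#' @param table an [asv_table()] or count matrix with positive row sums.
#' @return numeric matrix of the same shape.
#' @export
hellinger_transform <- function(table) {
  m <- if (inherits(table, "asv_table")) count_matrix(table) else as.matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0)) stop_arg("Hellinger transform undefined for zero rows")
  sqrt(sweep(m, 1L, rs, "/"))
}

#' Aggregate ASV counts to a taxonomic rank
#'
#' Sums counts over ASVs sharing the same label at `rank` (e.g. phylum),
#' the preparation step for rank-level differential abundance tests.
#' Aggregation happens before any prevalence filtering so the filter is
#' applied at the tested level.
#'
#' @param table an [asv_table()].
#' @param taxonomy data.frame with column `asv_id` plus rank columns.
#' @param rank column of `taxonomy` to aggregate by.
#' @return an `asv_table` with one column per distinct rank label.
#' @export
aggregate_taxa <- function(table, taxonomy, rank = "phylum") {
  if (!inherits(table, "asv_table")) table <- asv_table(table)
  if (!rank %in% names(taxonomy)) stop_arg("rank `", rank, "` not in taxonomy")
  m <- count_matrix(table)
  lab <- taxonomy[[rank]][match(colnames(m), taxonomy$asv_id)]
  if (any(is.na(lab))) stop_arg("taxonomy is missing ASVs present in the table")
  grp <- factor(lab, levels = unique(lab))
  out <- sapply(levels(grp), function(g)
    rowSums(m[, grp == g, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(m), levels(grp)))
  asv_table(out)
}
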