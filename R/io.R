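## File formats
##
## counts:   TSV, first column "sample_id", remaining headers = ASV ids.
## taxonomy: TSV, columns asv_id, kingdom, phylum, class, order, family,
##           genus, species; unresolved ranks flagged "uncl.".
## tree:     newick with branch lengths, tips labelled with ASV ids.
## metadata: TSV with the cohort fields; missing values encoded "NA".

TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                    "genus", "species")

#' Load a complete dataset from its four on-disk files
#'
#' Reads the count table, taxonomy, rooted phylogeny and subject metadata,
#' and cross-references them: samples present in the counts but absent from
#' the metadata are an error; ASVs missing from the tree are reported via a
#' warning (phylogenetic metrics would silently lose them otherwise).
#'
#' @param counts_path,taxonomy_path,tree_path,metadata_path file paths.
#' @return list with elements `counts` ([asv_table()]), `taxonomy`
#'   (data.frame), `tree` (`ape::phylo`), `metadata` (data.frame).
#' @export
load_dataset <- function(counts_path, taxonomy_path, tree_path,
                         metadata_path) {
  for (p in c(counts_path, taxonomy_path, tree_path, metadata_path))
    if (!file.exists(p)) stop_arg("file not found: ", p)

  counts <- read_counts(counts_path)
  taxonomy <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  if (!"asv_id" %in% names(taxonomy))
    stop_arg(taxonomy_path, ": missing column `asv_id`")
  if (anyDuplicated(taxonomy$asv_id))
    stop_arg(taxonomy_path, ": duplicate asv_id rows")
  missing_tax <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(missing_tax))
    stop_arg(taxonomy_path, ": no taxonomy for ASVs: ",
             paste(utils::head(missing_tax, 5L), collapse = ", "))

  tree <- tryCatch(ape::read.tree(tree_path), error = function(e)
    stop_arg(tree_path, ": newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop_arg(tree_path, ": no tree could be parsed")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop_arg(tree_path, ": negative branch lengths")
  off_tree <- setdiff(colnames(counts), tree$tip.label)
  if (length(off_tree))
    warning(length(off_tree), " ASV(s) absent from the tree: ",
            paste(utils::head(off_tree, 5L), collapse = ", "))

  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                                na.strings = "NA")
  if (!"sample_id" %in% names(metadata))
    stop_arg(metadata_path, ": missing column `sample_id`")
  if (anyDuplicated(metadata$sample_id))
    stop_arg(metadata_path, ": duplicate sample_id rows")
  orphans <- setdiff(rownames(counts), metadata$sample_id)
  if (length(orphans))
    stop_arg("samples missing from metadata: ",
             paste(orphans, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- metadata$sample_id

  list(counts = counts, taxonomy = taxonomy, tree = tree,
       metadata = metadata)
}

read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    stop_arg(path, ": first column must be `sample_id`")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  tryCatch(asv_table(m),
           error = function(e) stop_arg(path, ": ", conditionMessage(e)))
}

#' Write a dataset to the four on-disk files read by [load_dataset()]
#'
#' @param dataset list with `counts`, `taxonomy`, `tree`, `metadata`.
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "taxonomy.tsv", "tree.nwk",
                            "metadata.tsv"))
  m <- count_matrix(dataset$counts)
  utils::write.table(
    data.frame(sample_id = rownames(m), m, check.names = FALSE),
    paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$taxonomy, paths[2L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, paths[3L])
  utils::write.table(dataset$metadata, paths[4L], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(paths)
}
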