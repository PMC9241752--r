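# Shared fixture builders; everything is generated in code at test time.

# tiny 3-sample x 4-ASV dataset written to disk for IO round-trips
write_tiny_dataset <- function(dir = tempfile("tinyds")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- matrix(c(5L, 3L, 0L, 2L,
                     1L, 4L, 6L, 0L,
                     2L, 2L, 2L, 2L), nrow = 3L, byrow = TRUE,
                   dimnames = list(c("S1", "S2", "S3"),
                                   paste0("ASV_", 1:4)))
  taxonomy <- data.frame(asv_id = paste0("ASV_", 1:4),
                         kingdom = "Bacteria", phylum = "Firmicutes",
                         class = "uncl.", order = "uncl.",
                         family = "uncl.", genus = "uncl.",
                         species = "uncl.")
  tree <- ape::read.tree(
    text = "((ASV_1:0.1,ASV_2:0.1):0.2,(ASV_3:0.1,ASV_4:0.1):0.2):0;")
  metadata <- data.frame(sample_id = c("S1", "S2", "S3"),
                         condition = c("Control", "CD", "UC"),
                         age = c(30L, 45L, 60L),
                         gender = c("M", "F", "M"),
                         bmi = c(24.0, 27.5, 30.1),
                         smoking = c("nonsmoker", "smoker", "ex-smoker"),
                         sccai = c(NA, NA, 2L), cdai = c(NA, 110.5, NA))
  ds <- list(counts = asv_table(counts), taxonomy = taxonomy,
             tree = tree, metadata = metadata)
  paths <- write_dataset(ds, dir)
  list(dir = dir, paths = paths, dataset = ds)
}

# barbell graph: two 4-cliques joined by a single bridge edge, unit weights
barbell_graph <- function() {
  edges <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)),
                 c(4, 5))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:8)
  igraph::E(g)$weight <- 1
  igraph::E(g)$r <- 1
  g
}

# exhaustive search over all 2^(n-1) two-block partitions (plus the trivial
# one-block partition) for the maximal modularity; oracle for fast-greedy
exhaustive_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  best <- igraph::modularity(g, rep(1L, n), weights = igraph::E(g)$weight)
  for (code in seq_len(2^(n - 1L) - 1L)) {
    memb <- as.integer(intToBits(code))[seq_len(n)] + 1L
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    best <- max(best, q)
  }
  best
}

# small planted-pair cohort used by several SparCC tests
sparcc_pair_dataset <- function(n_asv = 50L, seed = 7L) {
  cfg <- sim_config(n_control = 100L, n_cd = 50L, n_uc = 50L,
                    n_asv = n_asv, seed = seed,
                    module_spec = list(list(members = 1:2, rho = 0.8,
                                            meanlog = 0)),
                    effect_spec = list())
  simulate_dataset(cfg)
}

# all distinct permutations of a two-group label vector, as index rows:
# g[row] enumerates every distinct label assignment exactly once
exhaustive_group_perms <- function(g) {
  g <- as.character(g)
  n <- length(g)
  lev1 <- unique(g)[1L]
  i1 <- which(g == lev1)
  i2 <- which(g != lev1)
  pos <- utils::combn(n, length(i1))
  t(apply(pos, 2L, function(p) {
    perm <- integer(n)
    perm[p] <- i1
    perm[-p] <- i2
    perm
  }))
}
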