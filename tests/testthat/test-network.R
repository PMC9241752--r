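test_that("edge retention follows the FDR-and-median rule", {
  ids <- paste0("t", 1:4)
  r <- diag(4); dimnames(r) <- list(ids, ids)
  r[1, 2] <- r[2, 1] <- 0.9
  r[3, 4] <- r[4, 3] <- 0.2
  r[1, 3] <- r[3, 1] <- 0.4 # the median of |0.9, 0.2, 0.4| is 0.4
  p <- matrix(1, 4, 4, dimnames = dimnames(r))
  # everything insignificant -> no edges
  expect_warning(g0 <- build_network(r, p), "no edges")
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 4) # isolated nodes retained
  # significance alone is not enough: |r| must exceed the median strictly
  p[1, 2] <- p[2, 1] <- 0.01
  p[3, 4] <- p[4, 3] <- 0.01
  p[1, 3] <- p[3, 1] <- 0.01
  g <- build_network(r, p)
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 1L)
  expect_equal(el$r, 0.9) # 0.2 below median, 0.4 == median excluded
  expect_equal(igraph::graph_attr(g, "r_threshold"), 0.4)
  # relaxing the FDR cutoff never removes edges
  g2 <- build_network(r, p, fdr_cutoff = 0.5)
  expect_true(all(apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
                  %in% apply(igraph::as_edgelist(g2), 1, paste,
                             collapse = "-")))
})

test_that("fast-greedy equals the exhaustive optimum on the barbell", {
  g <- barbell_graph()
  mods <- detect_modules(g)
  expect_equal(length(mods$modules), 2L)
  expect_setequal(mods$modules[[mods$membership[["n1"]]]],
                  paste0("n", 1:4))
  expect_equal(mods$modularity, 12 / 13 - 1 / 2, tolerance = 1e-10)
  expect_equal(mods$modularity, exhaustive_best_modularity(g),
               tolerance = 1e-10)
  # reported Q matches an independent evaluation of the partition
  expect_equal(mods$modularity,
               dysbionet:::modularity_from_partition(g, mods$membership),
               tolerance = 1e-10)
})

test_that("single cliques and disconnected components partition sanely", {
  clique <- igraph::make_full_graph(5)
  igraph::V(clique)$name <- paste0("c", 1:5)
  igraph::E(clique)$weight <- 1
  m1 <- detect_modules(clique)
  expect_equal(length(m1$modules), 1L)
  expect_equal(m1$modularity, 0, tolerance = 1e-12)

  two <- igraph::disjoint_union(igraph::make_full_graph(4),
                                igraph::make_full_graph(4))
  igraph::V(two)$name <- paste0("v", 1:8)
  igraph::E(two)$weight <- 1
  m2 <- detect_modules(two)
  memb <- m2$membership
  expect_true(all(memb[paste0("v", 1:4)] == memb[["v1"]]))
  expect_true(all(memb[paste0("v", 5:8)] == memb[["v5"]]))
  expect_false(memb[["v1"]] == memb[["v5"]])
})

test_that("centralities match closed forms on canonical graphs", {
  path <- igraph::make_graph(~ A - B, B - C)
  igraph::E(path)$weight <- 1
  pc <- node_centralities(path)
  expect_equal(pc$betweenness[pc$node == "B"], 1)
  expect_equal(pc$betweenness[pc$node == "A"], 0)

  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("r", 1:6)
  igraph::E(ring)$weight <- 0.7
  rc <- node_centralities(ring)
  expect_equal(rc$pagerank, rep(1 / 6, 6), tolerance = 1e-10)
  expect_equal(sum(rc$pagerank), 1, tolerance = 1e-12)

  star <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("s", 1:7)
  igraph::E(star)$weight <- 1
  sc <- node_centralities(star)
  expect_equal(sc$eigenvector[sc$node == "s1"], 1)
  expect_equal(max(sc$degree), sc$degree[sc$node == "s1"])
  # leaves have betweenness zero
  expect_true(all(sc$betweenness[sc$node != "s1"] == 0))
})

test_that("vertex-permutation nulls flag hubs and degenerate symmetry", {
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("r", 1:8)
  igraph::E(ring)$weight <- 1
  st <- centrality_null_test(ring, n_perm = 200, seed = 1)
  # vertex-transitive graph: null sd is 0, Z undefined
  expect_true(all(is.na(st$Z[st$measure == "degree"])))

  hub <- igraph::make_star(20, mode = "undirected", center = 1)
  igraph::V(hub)$name <- paste0("h", 1:20)
  igraph::E(hub)$weight <- 1
  sh <- centrality_null_test(hub, n_perm = 2000, seed = 2)
  hub_deg <- sh[sh$measure == "degree" & sh$node == "h1", ]
  expect_gt(hub_deg$Z, 0)
  expect_lt(hub_deg$P, 0.05)
  # null mean of degree equals the graph's average degree
  expect_equal(hub_deg$null_mean, mean(igraph::degree(hub)),
               tolerance = 0.05)
})

test_that("indicator-centrality comparison finds loaded flags", {
  set.seed(3)
  g <- igraph::sample_gnp(50, 0.15)
  igraph::V(g)$name <- paste0("n", 1:50)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.3, 0.9)
  cent <- node_centralities(g)
  top5 <- rank(-cent$degree) <= 5
  res <- indicator_centrality_comparison(cent, top5, n_perm = 999,
                                         seed = 4)
  expect_lte(res$P[res$measure == "degree"], 0.01)
  expect_true(all(res$P_FDR >= res$P))
  # identical centralities carry no rank signal
  flat <- cent
  for (ms in c("degree", "betweenness", "pagerank", "eigenvector"))
    flat[[ms]] <- 1
  res2 <- indicator_centrality_comparison(flat, top5, n_perm = 99,
                                          seed = 5)
  expect_true(all(res2$P == 1))
  expect_error(indicator_centrality_comparison(cent, rep(TRUE, 50)),
               "non-empty")
})

test_that("module completeness is the fraction of members detected", {
  m <- rbind(S1 = c(1L, 2L, 3L, 4L),
             S2 = c(1L, 2L, 3L, 0L),
             S3 = c(5L, 0L, 0L, 0L))
  colnames(m) <- paste0("t", 1:4)
  memb <- setNames(c(1L, 1L, 1L, 1L), paste0("t", 1:4))
  prof <- module_completeness(asv_table(m), memb)
  expect_equal(unname(prof[, 1]), c(1, 0.75, 0.25))
  expect_error(module_completeness(asv_table(m),
                                   setNames(integer(0), character(0))),
               "module")
})

test_that("completeness association detects a planted condition effect", {
  set.seed(6)
  n <- 120
  cond <- rep(c("Control", "UC"), each = 60)
  size <- 10L
  p <- ifelse(cond == "UC", 0.8, 0.3)
  pres <- rbinom(n, size, p)
  prof <- matrix(pres / size, ncol = 1,
                 dimnames = list(paste0("S", 1:n), "1"))
  attr(prof, "module_sizes") <- c("1" = size)
  meta <- data.frame(sample_id = paste0("S", 1:n), condition = cond)
  res <- completeness_association(prof, meta, "condition")
  uc <- res[res$coef_name == "condition:UC", ]
  expect_gt(uc$estimate, 0)
  expect_lt(uc$P_FDR, 0.01)
})

test_that("constant completeness yields a null association", {
  n <- 80
  prof <- matrix(0.5, n, 1, dimnames = list(paste0("S", 1:n), "1"))
  attr(prof, "module_sizes") <- c("1" = 10L)
  meta <- data.frame(sample_id = paste0("S", 1:n),
                     condition = rep(c("Control", "CD"), each = n / 2))
  res <- completeness_association(prof, meta, "condition")
  expect_equal(res$estimate, 0, tolerance = 1e-8)
  expect_gt(res$P, 0.99)
})

test_that("activity-score associations are fit within their condition", {
  set.seed(7)
  n <- 60
  meta <- data.frame(sample_id = paste0("S", 1:n),
                     condition = rep(c("UC", "CD", "Control"), each = 20),
                     sccai = NA_integer_, cdai = NA_real_)
  meta$sccai[meta$condition == "UC"] <- rpois(20, 3)
  size <- 8L
  pres <- rbinom(n, size, 0.5)
  # completeness rises with SCCAI inside UC
  uc_rows <- meta$condition == "UC"
  pres[uc_rows] <- rbinom(20, size, plogis(-1 + 0.8 * meta$sccai[uc_rows]))
  prof <- matrix(pres / size, ncol = 1,
                 dimnames = list(meta$sample_id, "1"))
  attr(prof, "module_sizes") <- c("1" = size)
  res <- completeness_association(prof, meta, "sccai")
  expect_gt(res$estimate, 0)
  expect_lt(res$P, 0.05)
})

test_that("module RDA separates condition-determined modules", {
  set.seed(8)
  n <- 60
  cond <- rep(c("Control", "CD"), each = 30)
  # module taxa present only in CD (disjoint supports)
  mod <- matrix(0L, n, 4)
  mod[cond == "CD", ] <- matrix(rpois(30 * 4, 20) + 1L, 30, 4)
  mod[cond == "Control", 1] <- 0L
  other <- matrix(rpois(n * 6, 10) + 1L, n, 6)
  m <- cbind(mod, other)
  dimnames(m) <- list(paste0("S", 1:n), paste0("t", 1:10))
  memb <- setNames(c(rep(1L, 4), rep(2L, 6)), paste0("t", 1:10))
  meta <- data.frame(sample_id = rownames(m), condition = cond)
  res <- module_rda(asv_table(m), memb, meta, n_perm = 199, seed = 1)
  m1 <- res[res$module == "1", ]
  expect_gt(m1$variance_explained, 0.9)
  expect_equal(m1$P, 1 / 200, tolerance = 1e-12)
  expect_true(all(res$variance_explained >= 0 &
                    res$variance_explained <= 1))
})

test_that("network export writes GraphML and an edge list", {
  g <- barbell_graph()
  igraph::E(g)$r <- igraph::E(g)$weight
  dir <- tempfile("net")
  mods <- detect_modules(g)
  paths <- write_network(g, dir, mods)
  expect_true(all(file.exists(paths)))
  el <- read.delim(paths[2])
  expect_equal(nrow(el), igraph::ecount(g))
  expect_true(all(c("from", "to", "r", "weight", "module_from") %in%
                    names(el)))
})
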