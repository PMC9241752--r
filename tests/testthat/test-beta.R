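four_tip_tree <- function() ape::read.tree(
  text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("identical samples are at distance 0, disjoint clades at 1", {
  tree <- four_tip_tree()
  m <- rbind(S1 = c(A = 3L, B = 2L, C = 0L, D = 0L),
             S2 = c(A = 3L, B = 2L, C = 0L, D = 0L),
             S3 = c(A = 0L, B = 0L, C = 5L, D = 1L))
  tab <- asv_table(m)
  for (mt in c("bray_curtis", "jaccard", "gunifrac")) {
    d <- as.matrix(distance_matrix(tab, mt, tree = tree))
    expect_equal(d["S1", "S2"], 0, info = mt)
    expect_equal(d["S1", "S3"], 1, info = mt)
    expect_true(all(d >= 0 & d <= 1), info = mt)
    expect_equal(d, t(d), info = mt)
  }
})

test_that("generalized UniFrac matches hand branch summation on 4 tips", {
  tree <- four_tip_tree()
  m <- rbind(S1 = c(A = 7L, B = 0L, C = 0L, D = 0L),
             S2 = c(A = 0L, B = 9L, C = 0L, D = 0L))
  # branches with mass: A (l=1, p=1,q=0), B (l=1, p=0,q=1),
  # AB stem (l=1, p=1,q=1); alpha = 0.5
  hand <- (1 * 1^0.5 * 1 + 1 * 1^0.5 * 1 + 1 * 2^0.5 * 0) /
    (1 * 1^0.5 + 1 * 1^0.5 + 1 * 2^0.5)
  d <- as.matrix(distance_matrix(asv_table(m), "gunifrac", tree = tree))
  expect_equal(d["S1", "S2"], hand, tolerance = 1e-12)
  expect_equal(hand, 2 / (2 + sqrt(2)), tolerance = 1e-12)
})

test_that("gUniFrac alpha endpoints behave as documented", {
  tree <- four_tip_tree()
  set.seed(31)
  m <- matrix(rpois(5 * 4, 6) + 1L, 5, 4,
              dimnames = list(paste0("S", 1:5), c("A", "B", "C", "D")))
  tab <- asv_table(m)
  # independent evaluation of the branch-weighting formula
  gu_ref <- function(alpha) {
    rel <- sweep(m, 1, rowSums(m), "/")
    # branch proportions for this fixed 4-tip topology
    bp <- cbind(rel[, "A"], rel[, "B"], rel[, "A"] + rel[, "B"],
                rel[, "C"], rel[, "D"], rel[, "C"] + rel[, "D"])
    len <- rep(1, 6)
    out <- matrix(0, 5, 5)
    for (i in 1:4) for (j in (i + 1):5) {
      p <- bp[i, ]; q <- bp[j, ]; s <- p + q
      k <- s > 0
      w <- len[k] * s[k]^alpha
      out[i, j] <- out[j, i] <- sum(w * abs(p[k] - q[k]) / s[k]) / sum(w)
    }
    out
  }
  for (alpha in c(0, 0.5, 1)) {
    d <- as.matrix(distance_matrix(tab, "gunifrac", tree = tree,
                                   alpha = alpha))
    expect_equal(unname(d), gu_ref(alpha), tolerance = 1e-12,
                 info = paste("alpha =", alpha))
  }
  expect_error(distance_matrix(tab, "gunifrac"), "tree")
})

test_that("PCoA on sqrt distances reproduces Euclidean configurations", {
  pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  dsq <- dist(pts)^2 # sqrt transform will undo the square
  o <- pcoa_sqrt(dsq)
  expect_equal(o$eigenvalues[1], o$eigenvalues[2], tolerance = 1e-8)
  expect_equal(as.matrix(dist(o$points[, 1:2])), as.matrix(dist(pts)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(o$eigenvalues) <= 1e-8))
  expect_lte(sum(o$proportion), 1 + 1e-12)
})

test_that("PCoA handles simplex and duplicate-sample degeneracies", {
  eq <- matrix(0.5, 5, 5); diag(eq) <- 0
  o <- pcoa_sqrt(eq)
  pos <- o$eigenvalues[o$eigenvalues > 1e-10]
  expect_equal(length(pos), 4L)
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-10)
  dup <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0))
  o2 <- pcoa_sqrt(dup)
  expect_equal(o2$points[1, ], o2$points[2, ], tolerance = 1e-10)
  expect_error(pcoa_sqrt(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA matches exhaustive enumeration at n = 6", {
  set.seed(3)
  m <- matrix(rpois(6 * 8, 20), 6, 8,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:8)))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     grp = rep(c("a", "b"), each = 3))
  d <- distance_matrix(asv_table(m), "bray_curtis")
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 6), ]
  p_ex <- suppressMessages(
    permanova(d, meta, "grp", n_perm = perms, seed = 1))
  p_samp <- suppressMessages(
    permanova(d, meta, "grp", n_perm = 4999, seed = 1))
  expect_equal(p_ex$P, p_samp$P, tolerance = 0.02)
})

test_that("PERMANOVA R2 partition sums to one and detects planted shifts", {
  set.seed(4)
  n <- 100
  grp <- rep(c("x", "y"), each = n / 2)
  m <- matrix(rpois(n * 30, 10), n, 30,
              dimnames = list(paste0("s", 1:n), paste0("t", 1:30)))
  m[grp == "y", 1:5] <- m[grp == "y", 1:5] + rpois(sum(grp == "y") * 5, 25)
  meta <- data.frame(sample_id = paste0("s", 1:n), grp = grp,
                     age = runif(n, 20, 70))
  d <- distance_matrix(asv_table(m), "bray_curtis")
  res <- permanova(d, meta, c("age", "grp"), n_perm = 999, seed = 2)
  expect_lte(res$P[res$term == "grp"], 0.001)
  # R2 over terms + residual = 1
  fitfull <- suppressMessages(
    permanova(d, meta, c("age", "grp"), n_perm = 99, seed = 3))
  expect_equal(sum(fitfull$R2) + (1 - sum(fitfull$R2)), 1,
               tolerance = 1e-10)
  expect_true(all(fitfull$adj_R2 <= fitfull$R2))
})

test_that("PERMANOVA results do not depend on sample order", {
  set.seed(5)
  n <- 24
  m <- matrix(rpois(n * 12, 15), n, 12,
              dimnames = list(paste0("s", 1:n), paste0("t", 1:12)))
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     grp = rep(c("a", "b"), each = n / 2))
  d <- distance_matrix(asv_table(m), "bray_curtis")
  r1 <- permanova(d, meta, "grp", n_perm = 499, seed = 9)
  shuf <- sample(n)
  dm <- as.matrix(d)[shuf, shuf]
  r2 <- permanova(as.dist(dm), meta[shuf, ], "grp", n_perm = 499,
                  seed = 9)
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
  expect_identical(r1$P, r2$P)
})

test_that("pairwise PERMANOVA covers every contrast with a BH family", {
  set.seed(6)
  n <- 36
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     condition = rep(c("Control", "CD", "UC"), each = 12))
  m <- matrix(rpois(n * 15, 0.9), n, 15,
              dimnames = list(meta$sample_id, paste0("t", 1:15)))
  m[rowSums(m) == 0, 1] <- 1L
  d <- distance_matrix(asv_table(m), "jaccard")
  pw <- suppressMessages(
    pairwise_permanova(d, meta, n_perm = 199, seed = 1))
  expect_setequal(pw$contrast, c("CD-Control", "CD-UC", "Control-UC"))
  expect_true(all(pw$P_FDR >= pw$P))
})

test_that("ordination goodness-of-fit behaves at both extremes", {
  set.seed(7)
  m <- matrix(rpois(30 * 20, 10), 30, 20,
              dimnames = list(paste0("s", 1:30), paste0("t", 1:20)))
  ord <- pcoa_sqrt(distance_matrix(asv_table(m), "bray_curtis"))
  perfect <- envfit_goodness(ord, ord$points[, 1], n_perm = 99, seed = 1)
  expect_equal(perfect$r2, 1, tolerance = 1e-8)
  constant <- envfit_goodness(ord, rep(2.5, 30), n_perm = 99, seed = 1)
  expect_equal(constant$r2, 0)
  expect_equal(constant$P, 1)
})

test_that("a planted continuous gradient is detected by envfit", {
  set.seed(8)
  n <- 150
  age <- runif(n, 20, 75)
  m <- matrix(rpois(n * 25, 10), n, 25,
              dimnames = list(paste0("s", 1:n), paste0("t", 1:25)))
  # age drives a smooth abundance gradient across the first 8 taxa
  m[, 1:8] <- m[, 1:8] + matrix(rpois(n * 8, outer((age - 20) / 2,
                                                   rep(1, 8))), n, 8)
  ord <- pcoa_sqrt(distance_matrix(asv_table(m), "bray_curtis"))
  fit <- envfit_goodness(ord, age, n_perm = 999, seed = 2)
  expect_lt(fit$P, 0.01)
})
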