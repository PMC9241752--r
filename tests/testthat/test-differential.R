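test_that("size factors are scale-equivariant and normalized", {
  base <- matrix(c(10L, 20L, 30L, 40L), 1, 4)
  m <- rbind(A = base[1, ], B = 2L * base[1, ])
  colnames(m) <- paste0("t", 1:4)
  sf <- size_factors(asv_table(m))
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # identical samples
  same <- matrix(rep(c(5L, 9L, 2L), each = 3), 3, 3,
                 dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  expect_equal(unname(size_factors(asv_table(same))), rep(1, 3))
  # global rescaling of the table leaves factors unchanged
  expect_equal(size_factors(asv_table(m * 3L)), sf)
})

test_that("size factors track a planted depth gradient", {
  set.seed(41)
  depths <- round(seq(5000, 40000, length.out = 40))
  prop <- runif(60); prop <- prop / sum(prop)
  m <- t(sapply(depths, function(d) rmultinom(1, d, prop)[, 1]))
  dimnames(m) <- list(paste0("s", 1:40), paste0("t", 1:60))
  sf <- size_factors(asv_table(m))
  expect_gt(cor(sf, depths, method = "spearman"), 0.9)
})

test_that("NB-Wald recovers planted fold changes with controlled FDR", {
  set.seed(5)
  n <- 120
  g <- rep(c("Control", "CD"), each = 60)
  sf_true <- exp(rnorm(n, 0, 0.3))
  mu0 <- exp(rnorm(50, log(100), 1))
  lfc <- c(rep(2, 10), rep(0, 40))
  m <- sapply(1:50, function(j)
    rnbinom(n, size = 1 / 0.2, mu = sf_true * mu0[j] *
              2^(lfc[j] * (g == "CD"))))
  dimnames(m) <- list(paste0("S", 1:n), paste0("T", 1:50))
  meta <- data.frame(sample_id = rownames(m), condition = g,
                     age = round(runif(n, 20, 70)),
                     gender = sample(c("M", "F"), n, TRUE))
  res <- nb_wald_test(asv_table(m), meta,
                      contrasts = list(c("CD", "Control")))
  planted <- res[match(paste0("T", 1:10), res$taxon_id), ]
  expect_gte(median(planted$log2_fold_change), 1.5)
  expect_lte(median(planted$log2_fold_change), 2.5)
  expect_gte(sum(planted$P_FDR <= 0.05), 8)
})

test_that("NB-Wald agrees with DESeq2 on a shared fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(6)
  n <- 60
  g <- rep(c("Control", "CD"), each = 30)
  m <- sapply(1:20, function(j)
    rnbinom(n, size = 5, mu = exp(rnorm(1, log(80), 1)) *
              2^(ifelse(j <= 4, 1.5, 0) * (g == "CD"))))
  dimnames(m) <- list(paste0("S", 1:n), paste0("T", 1:20))
  meta <- data.frame(sample_id = rownames(m), condition = g,
                     age = round(runif(n, 20, 70)),
                     gender = sample(c("M", "F"), n, TRUE))
  mine <- nb_wald_test(asv_table(m), meta,
                       contrasts = list(c("CD", "Control")))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = t(m),
    colData = data.frame(condition = factor(g, c("Control", "CD")),
                         age = meta$age, gender = factor(meta$gender)),
    design = ~ gender + age + condition))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("condition", "CD", "Control"))
  est <- mine$log2_fold_change[match(paste0("T", 1:20), mine$taxon_id)]
  expect_gt(cor(est, ref$log2FoldChange), 0.98)
  expect_equal(est, ref$log2FoldChange, tolerance = 0.25)
})

test_that("constant taxa and contrast reversal behave as expected", {
  set.seed(7)
  n <- 40
  g <- rep(c("Control", "CD"), each = 20)
  m <- cbind(sapply(1:10, function(j) rnbinom(n, size = 5, mu = 50)),
             const = rep(7L, n))
  dimnames(m) <- list(paste0("S", 1:n), c(paste0("T", 1:10), "const"))
  meta <- data.frame(sample_id = rownames(m), condition = g,
                     age = round(runif(n, 20, 70)),
                     gender = sample(c("M", "F"), n, TRUE))
  res <- nb_wald_test(asv_table(m), meta, sf = rep(1, n),
                      contrasts = list(c("CD", "Control"),
                                       c("Control", "CD")))
  const_fwd <- res[res$taxon_id == "const" &
                     res$contrast == "CD-vs-Control", ]
  expect_equal(const_fwd$log2_fold_change, 0, tolerance = 1e-6)
  expect_gt(const_fwd$P, 0.99)
  fwd <- res[res$contrast == "CD-vs-Control", "log2_fold_change"]
  rev <- res[res$contrast == "Control-vs-CD", "log2_fold_change"]
  expect_equal(fwd, -rev, tolerance = 1e-12)
})

test_that("BH adjustment matches hand computations and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.01)), c(0.05, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_lte(max(adj), 1)
})

test_that("IndVal.g matches its closed forms on designed tables", {
  set.seed(12)
  g <- rep(c("a", "b"), each = 10)
  m <- cbind(perfect = c(rpois(10, 4) + 1L, rep(0L, 10)),
             shared = rep(6L, 20))
  rownames(m) <- paste0("s", 1:20)
  res <- indval_test(asv_table(m), g, n_perm = 100, seed = 1)
  perf <- res[res$taxon_id == "perfect", ]
  expect_equal(perf$indval_g, 1)
  expect_equal(perf$group, "a")
  expect_equal(perf$P, 1 / 101) # attainable permutation floor
  shr <- res[res$taxon_id == "shared", ]
  expect_equal(shr$indval_g, sqrt(0.5), tolerance = 1e-12)
})

test_that("IndVal permutation P agrees with exhaustive enumeration", {
  set.seed(9)
  g <- rep(c("a", "b"), each = 4)
  m <- matrix(rpois(8 * 5, 3), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  m[rowSums(m) == 0, 1] <- 1L
  ex <- indval_test(asv_table(m), g,
                    perm_matrix = exhaustive_group_perms(g), seed = 1)
  samp <- indval_test(asv_table(m), g, n_perm = 9999, seed = 2)
  expect_equal(ex$P, samp$P, tolerance = 0.02)
  expect_identical(ex$group, samp$group)
})

test_that("IndVal is invariant to sample order within non-focal groups", {
  set.seed(10)
  g <- rep(c("a", "b", "c"), each = 4)
  m <- matrix(rpois(12 * 6, 2), 12, 6,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:6)))
  m[rowSums(m) == 0, 1] <- 1L
  r1 <- indval_test(asv_table(m), g, n_perm = 199, seed = 3)
  shuffle <- c(1:4, sample(5:8), sample(9:12))
  r2 <- indval_test(asv_table(m[shuffle, ]), g[shuffle],
                    n_perm = 199, seed = 3)
  expect_equal(r1$indval_g, r2$indval_g, tolerance = 1e-12)
})
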