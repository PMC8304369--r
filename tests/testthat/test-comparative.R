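test_that("count matrices assemble from per-genome profiles with zero fill", {
  cm <- buildCountMatrix(list(SPA = c(HSF = 2L, C2H2 = 1L),
                              SPB = c(MADS = 4L)))
  m <- tapCounts(cm)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["HSF", "SPA"], 2L)
  expect_equal(m["MADS", "SPA"], 0L)
  expect_equal(m["MADS", "SPB"], 4L)

  expect_equal(ncol(buildCountMatrix(setNames(list(), character(0)))), 0L)
  expect_error(buildCountMatrix(list(SPA = c(HSF = -1L))), "negative")
  expect_error(buildCountMatrix(list(SPA = c(X = 1L)),
                                family_universe = "Y"), "universe")

  # TSV round-trip
  f <- withr::local_tempfile()
  writeCountMatrix(cm, f)
  back <- readCountMatrix(f)
  expect_equal(tapCounts(back), m)
})

test_that("presence filter keeps families seen in a focal species set", {
  set.seed(21)
  m <- matrix(rpois(20 * 6, 0.7), nrow = 20,
              dimnames = list(paste0("fam", 1:20), paste0("SP", 1:6)))
  cm <- buildCountMatrix(apply(m, 2, function(col)
    setNames(as.integer(col), rownames(m)), simplify = FALSE))
  focal <- c("SP1", "SP2", "SP3")
  kept <- selectFamiliesWithPresence(cm, focal)
  # independent per-row any() oracle
  expect_equal(rownames(kept),
               rownames(m)[apply(m[, focal] >= 1, 1, any)])
  expect_equal(ncol(kept), 6L)
  # idempotent, and commutes with species permutation
  expect_equal(tapCounts(selectFamiliesWithPresence(kept, focal)),
               tapCounts(kept))
  perm <- sample(colnames(m))
  kept_perm <- selectFamiliesWithPresence(cm[, perm], focal)
  expect_equal(rownames(kept_perm), rownames(kept))
  expect_error(selectFamiliesWithPresence(cm, "NOPE"), "unknown")
})

test_that("group comparisons follow the normality gate and exact Wilcoxon", {
  cm <- buildCountMatrix(list(
    S1 = c(f = 1L), S2 = c(f = 2L), S3 = c(f = 3L),
    S4 = c(f = 4L), S5 = c(f = 5L), S6 = c(f = 6L)))
  # Wilcoxon route forced via the gate: exact two-sided p = 0.1
  res <- compareGroups(cm, "f", c("S1", "S2", "S3"), c("S4", "S5", "S6"),
                       alpha_normality = 1)
  expect_equal(res$test_used, "Wilcoxon")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, enumWilcoxP(1:3, 4:6))  # enumeration oracle

  # group relabeling leaves the p-value unchanged
  res_swap <- compareGroups(cm, "f", c("S4", "S5", "S6"), c("S1", "S2", "S3"),
                            alpha_normality = 1)
  expect_equal(res_swap$p_value, res$p_value)

  # identical constant groups: perfect symmetry, p = 1
  cm2 <- buildCountMatrix(setNames(lapply(1:6, function(i) c(f = 2L)),
                                   paste0("S", 1:6)))
  res2 <- compareGroups(cm2, "f", paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(res2$p_value, 1)
  expect_true(res2$degenerate)

  # a large planted shift is detected (exact enumeration cross-check)
  a <- c(1, 2, 3, 1.5, 2.5); b <- c(20, 24, 27, 22, 30)
  cm3 <- buildCountMatrix(setNames(
    lapply(c(a, b), function(v) c(f = as.integer(round(v * 2)))),
    paste0("S", 1:10)))
  res3 <- compareGroups(cm3, "f", paste0("S", 1:5), paste0("S", 6:10),
                        alpha_normality = 1)
  expect_lt(res3$p_value, 0.05)
  av <- tapCounts(cm3)[1, 1:5]; bv <- tapCounts(cm3)[1, 6:10]
  expect_equal(res3$p_value, enumWilcoxP(av, bv))

  # normal route: gate passes at conventional alpha -> t-test
  vals <- c(8L, 9L, 10L, 11L, 12L, 28L, 29L, 30L, 31L, 33L)
  cm4 <- buildCountMatrix(setNames(lapply(vals, function(v) c(f = v)),
                                   paste0("S", 1:10)))
  res4 <- compareGroups(cm4, "f", paste0("S", 1:5), paste0("S", 6:10))
  expect_equal(res4$test_used, "t-test")

  # the total across families is compared when asked for "total"
  cm5 <- buildCountMatrix(list(
    S1 = c(x = 1L, y = 1L), S2 = c(x = 2L, y = 1L), S3 = c(x = 3L, y = 1L),
    S4 = c(x = 4L, y = 1L), S5 = c(x = 5L, y = 1L), S6 = c(x = 6L, y = 1L)))
  res5 <- compareGroups(cm5, "total", paste0("S", 1:3), paste0("S", 4:6),
                        alpha_normality = 1)
  expect_equal(res5$mean_a, 3)  # totals 2,3,4
  expect_equal(res5$p_value, 0.1)

  expect_error(compareGroups(cm, "f", c("S1", "S2"), c("S4", "S5", "S6")),
               ">= 3")
  expect_error(compareGroups(cm, "f", c("S1", "S2", "S3"),
                             c("S3", "S4", "S5")), "disjoint")
})

test_that("PCA is centred SVD with fixed signs and unit-sum variance", {
  # exactly one varying family: PC1 carries all the variance
  cm <- buildCountMatrix(list(S1 = c(a = 1L, b = 5L), S2 = c(a = 3L, b = 5L),
                              S3 = c(a = 7L, b = 5L)))
  p <- runPCA(cm)
  expect_equal(p$variance_fraction[1], 1.0)
  expect_equal(sum(p$variance_fraction), 1.0)

  # rank-2 matrix: exactly two nonzero variance fractions, matching an
  # independent eigendecomposition of the covariance matrix
  set.seed(31)
  u <- matrix(sample(0:4, 6 * 2, replace = TRUE), 6)
  v <- matrix(sample(0:3, 2 * 8, replace = TRUE), 2)
  m <- u %*% v  # exact integer rank <= 2
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("s", 1:6), paste0("fam", 1:8))
  cm2 <- buildCountMatrix(apply(m, 1, function(r) r, simplify = FALSE))
  p2 <- runPCA(cm2)
  expect_equal(sum(p2$variance_fraction > 1e-10), 2L)
  ev <- eigen(stats::cov(m), symmetric = TRUE)$values
  expect_equal(p2$variance_fraction[1:2], (ev / sum(ev))[1:2],
               tolerance = 1e-8)

  # scores are invariant under family reordering (sign convention fixed)
  perm <- sample(rownames(tapCounts(cm2)))
  p2b <- runPCA(cm2[perm, ])
  expect_equal(abs(p2b$scores), abs(p2$scores), tolerance = 1e-8)
  expect_equal(p2b$scores[, 1:2], p2$scores[, 1:2], tolerance = 1e-8)

  # reconstruction from all components reproduces the centred matrix
  centred <- scale(t(tapCounts(cm2)), center = TRUE, scale = FALSE)
  recon <- p2$scores %*% t(p2$loadings)
  expect_equal(unname(recon), unname(centred[, rownames(p2$loadings)]),
               tolerance = 1e-8)

  expect_error(runPCA(buildCountMatrix(list(S1 = c(a = 1L)))), "2 species")
})
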