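# Voxelwise statistics and regional group tests.

rmap <- function(d, mu = 0, sd = 1) {
  cm_volume(array(rnorm(prod(d), mu, sd), d), c(1, 1, 1), "map")
}

test_that("voxel t map equals the scalar t-test applied voxel by voxel", {
  set.seed(10)
  d <- c(5, 4, 3)
  A <- replicate(4, rmap(d), simplify = FALSE)
  B <- replicate(5, rmap(d, mu = 0.3), simplify = FALSE)
  sm <- voxel_ttest(A, B)
  for (v in sample(prod(d), 12)) {
    a <- vapply(A, function(m) m[v], numeric(1))
    b <- vapply(B, function(m) m[v], numeric(1))
    tt <- t.test(b, a, var.equal = TRUE)
    expect_equal(sm$statistic[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(sm$p[v], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(sm$df, 7)

  smw <- voxel_ttest(A, B, var_equal = FALSE)
  v <- 7
  a <- vapply(A, function(m) m[v], numeric(1))
  b <- vapply(B, function(m) m[v], numeric(1))
  expect_equal(smw$p[v], t.test(b, a)$p.value, tolerance = 1e-10)
})

test_that("degenerate and separated voxels behave as contracted", {
  d <- c(3, 3, 3)
  A <- replicate(3, cm_volume(array(1, d), c(1, 1, 1), "map"),
                 simplify = FALSE)
  sm <- voxel_ttest(A, A)
  expect_true(all(sm$p == 1))
  expect_equal(sm$flagged, prod(d))

  set.seed(2)
  B <- replicate(3, cm_volume(array(2 + rnorm(prod(d), 0, 1e-6), d),
                              c(1, 1, 1), "map"), simplify = FALSE)
  sm2 <- voxel_ttest(A, B)
  expect_true(all(sm2$p < 0.01))
  expect_true(all(sm2$mean_diff > 0))

  brain <- array(c(TRUE, rep(FALSE, 26)), d)
  sm3 <- voxel_ttest(A, B, brain = brain)
  expect_true(is.nan(sm3$p[27]))
  expect_false(is.nan(sm3$p[1]))
})

test_that("two-way ANOVA genotype map matches per-voxel least squares", {
  set.seed(20)
  d <- c(4, 4, 2)
  genotype <- rep(c("ctl", "cr"), each = 8)
  batch <- rep(rep(c("e1", "e2"), each = 4), 2)
  maps <- lapply(seq_along(genotype), function(i)
    rmap(d, mu = 0.5 * (genotype[i] == "cr") + 0.8 * (batch[i] == "e2")))
  res <- voxel_anova2(maps, genotype, batch)
  for (v in sample(prod(d), 5)) {
    y <- vapply(maps, function(m) m[v], numeric(1))
    fit <- anova(lm(y ~ factor(batch) + factor(genotype)))
    expect_equal(res$genotype$statistic[v], fit$`F value`[2],
                 tolerance = 1e-8)
    expect_equal(res$genotype$p[v], fit$`Pr(>F)`[2], tolerance = 1e-8)
    fitb <- anova(lm(y ~ factor(genotype) + factor(batch)))
    expect_equal(res$batch$statistic[v], fitb$`F value`[2],
                 tolerance = 1e-8)
  }
  expect_equal(res$genotype$df, c(1, 13))
})

test_that("ANOVA detects balanced genotype shifts and rejects bad designs", {
  set.seed(21)
  d <- c(4, 3, 2)
  genotype <- rep(c("ctl", "cr"), each = 6)
  batch <- rep(rep(c("e1", "e2"), each = 3), 2)
  maps <- lapply(seq_along(genotype), function(i)
    rmap(d, mu = 10 * (genotype[i] == "cr"), sd = 0.5))
  res <- voxel_anova2(maps, genotype, batch)
  expect_true(all(res$genotype$p < 0.01))

  expect_error(voxel_anova2(maps[1:6], genotype[c(1:3, 1:3)],
                            c("e1", "e1", "e1", "e2", "e2", "e2")),
               "2 genotypes")
  expect_error(
    voxel_anova2(maps[c(1, 2, 7, 8)], c("ctl", "ctl", "cr", "cr"),
                 c("e1", "e1", "e1", "e1")), "2 batches|empty design cell")
})

test_that("genotype p-values are uniform under a pure batch effect", {
  set.seed(22)
  d <- c(25, 25, 20)   # 12500 voxels
  genotype <- rep(c("ctl", "cr"), each = 8)
  batch <- rep(rep(c("e1", "e2"), each = 4), 2)
  maps <- lapply(seq_along(genotype), function(i)
    rmap(d, mu = 5 * (batch[i] == "e2")))
  res <- voxel_anova2(maps, genotype, batch)
  ks <- ks.test(as.vector(res$genotype$p), "punif")
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$batch$p < 1e-3))
})

test_that("minus-log10 transform is exact and NaN-preserving", {
  p <- array(c(0.01, 1, 0.005, NaN), c(4, 1, 1))
  out <- neglog10_pmap(cm_volume(p, c(1, 1, 1), "map"))
  expect_equal(out[1:3], c(2, 0, 2.301029995663981), tolerance = 1e-12)
  expect_true(is.nan(out[4]))
})

test_that("group volume test matches the pooled-variance formula", {
  res <- group_volume_test(c(1, 2, 3), c(11, 12, 13), n_boot = 200,
                           seed = 5L)
  expect_equal(res$t, 12.247448714, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2.552167494419e-4, tolerance = 1e-9)
  expect_equal(res$mean_diff, 10)
  expect_true(res$ci[1] <= res$mean_diff && res$mean_diff <= res$ci[2])

  same <- group_volume_test(c(1, 2, 3), c(1, 2, 3), n_boot = 200, seed = 1L)
  expect_equal(same$p, 1)
  expect_true(same$ci[1] <= 0 && 0 <= same$ci[2])

  r1 <- group_volume_test(c(1, 2, 3), c(2, 4, 5), n_boot = 500, seed = 9L)
  r2 <- group_volume_test(c(1, 2, 3), c(2, 4, 5), n_boot = 500, seed = 9L)
  expect_identical(r1$ci, r2$ci)
  expect_error(group_volume_test(1, c(1, 2)), "at least 2")
})

test_that("three-condition ANOVA has the right df and matches a
           sums-of-squares oracle", {
  same <- three_group_anova(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                 c = c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  set.seed(6)
  vols <- list(control = rnorm(16, 2), xrcc1 = rnorm(14, 1.6),
               double = rnorm(12, 2))
  res <- three_group_anova(vols)
  expect_equal(res$df[1:2], c(2, 39))

  toy <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  rt <- three_group_anova(toy)
  y <- unlist(toy); g <- rep(names(toy), each = 3)
  grand <- mean(y)
  ssb <- sum(3 * (tapply(y, g, mean) - grand)^2)
  ssw <- sum((y - ave(y, g))^2)
  expect_equal(rt$F, (ssb / 2) / (ssw / 6), tolerance = 1e-12)
  expect_equal(nrow(rt$posthoc), 3)
  tt <- t.test(toy$a, toy$c, var.equal = TRUE)
  i <- which(rt$posthoc$group1 == "a" & rt$posthoc$group2 == "c")
  expect_equal(rt$posthoc$p[i], tt$p.value, tolerance = 1e-12)
  expect_error(three_group_anova(list(a = 1:3, b = 1:3)), "3 conditions")
})
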