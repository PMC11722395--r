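# Jacobian maps, LJD, and volumetrics.

test_that("identity and affine fields give closed-form Jacobians", {
  f <- zero_field(c(6, 7, 8))
  expect_true(all(abs(jacobian_determinant(f) - 1) < 1e-14))

  # affine u = (a x, b y, c z) in physical coords: J = (1+a)(1+b)(1+c)
  # everywhere (finite differences are exact for linear fields)
  a <- 0.05; b <- -0.03; cc <- 0.02
  sp <- c(2, 2.5, 3)
  d <- c(6, 7, 8)
  u <- array(0, c(d, 3))
  x <- (0:(d[1] - 1)) * sp[1]; y <- (0:(d[2] - 1)) * sp[2]
  z <- (0:(d[3] - 1)) * sp[3]
  u[, , , 1] <- array(a * x, d)
  u[, , , 2] <- array(rep(b * y, each = d[1]), d)
  u[, , , 3] <- array(rep(cc * z, each = d[1] * d[2]), d)
  J <- jacobian_determinant(cm_volume(u, sp, "displacement"))
  expect_true(all(abs(J - (1 + a) * (1 + b) * (1 + cc)) < 1e-12))
})

test_that("random smooth fields match the independent Jacobian oracles", {
  at <- small_atlas()
  f <- make_displacement(at, small_cohort_spec(seed = 3L), 31L)
  J <- jacobian_determinant(f)
  dense <- jacobian_oracle_dense(f)
  interior <- !is.na(dense)
  expect_lt(max(abs(J[interior] - dense[interior])), 1e-6)

  set.seed(4)
  vox <- cbind(sample(2:(dim(f)[1] - 1), 40, TRUE),
               sample(2:(dim(f)[2] - 1), 40, TRUE),
               sample(2:(dim(f)[3] - 1), 40, TRUE))
  expect_equal(J[vox], jacobian_oracle(f, vox), tolerance = 1e-10)
})

test_that("non-finite displacements are reported with their voxel", {
  f <- zero_field(c(4, 4, 4))
  f[2, 3, 4, 1] <- NA
  expect_error(jacobian_determinant(f), "voxel \\(1, 2, 3\\)")
})

test_that("log-Jacobian maps clamp folds and obey the sign convention", {
  at <- small_atlas()
  J1 <- jacobian_determinant(zero_field(dim(at$labels),
                                        voxel_spacing(at$labels)))
  expect_true(all(log_jacobian(J1) == 0))

  # implanted contraction: LJD in the atrophied region is negative,
  # approximately ln(0.8)
  f8 <- make_displacement(at, small_cohort_spec(warp_amplitude = 0,
                                                scale = 0.8), 1L)
  ljd <- log_jacobian(jacobian_determinant(f8))
  tm <- truth_region_mask(at)
  expect_lt(mean(ljd[tm]), 0)
  # discrete gradients blend across the core boundary, so allow a small
  # absolute bias relative to ln 0.8
  expect_lt(abs(mean(ljd[tm]) - log(0.8)), 0.02)

  Jf <- J1
  Jf[1:3, 1, 1] <- 1e-9
  cl <- log_jacobian(Jf, min_jacobian = 1e-3)
  expect_equal(attr(cl, "folds"), 3L)
  expect_equal(cl[1, 1, 1], log(1e-3))
  Jbad <- array(as.vector(J1), dim(at$labels))
  Jbad[seq_len(ceiling(0.02 * length(Jbad)))] <- 0
  expect_error(log_jacobian(cm_volume(Jbad, voxel_spacing(J1), "map")),
               "folded")
})

test_that("division volumes integrate the Jacobian over labels", {
  at <- small_atlas()
  lab <- array(as.vector(at$labels), dim(at$labels))
  idJ <- jacobian_determinant(zero_field(dim(lab), voxel_spacing(at$labels)))
  dv <- division_volumes(at, idJ)
  expect_equal(dv$volume_um3, dv$n_voxels * voxel_volume(at$labels))
  expect_equal(sum(dv$percent), 100, tolerance = 1e-9)

  # a global uniform scaling leaves percentages unchanged
  s3 <- cm_volume(array(0.7, dim(lab)), voxel_spacing(at$labels), "map")
  dv2 <- division_volumes(at, s3)
  expect_equal(dv2$percent, dv$percent, tolerance = 1e-9)

  # implanted LCeP contraction: LCeP percent drops, other named
  # divisions' absolute volumes stay within 1 percent (the compensating
  # shell lives in the unannotated remainder)
  f8 <- make_displacement(at, small_cohort_spec(warp_amplitude = 0,
                                                scale = 0.8), 1L)
  dv8 <- division_volumes(at, jacobian_determinant(f8))
  lcep <- dv8$division %in% c("LCeP_L", "LCeP_R")
  expect_true(all(dv8$percent[lcep] < dv$percent[lcep]))
  named <- !lcep & dv8$division != "Rest"
  expect_true(all(abs(dv8$volume_um3[named] / dv$volume_um3[named] - 1)
                  < 0.01))
  expect_lt(abs(sum(dv8$volume_um3) / sum(dv$volume_um3) - 1), 0.01)

  expect_error(division_volumes(at, cm_volume(array(1, c(2, 2, 3)),
                                              c(1, 1, 1), "map")),
               "different grids")
})

test_that("pullback label counting cross-checks Jacobian integration", {
  at <- small_atlas()
  idf <- zero_field(dim(at$labels)[1:3], voxel_spacing(at$labels))
  idJ <- jacobian_determinant(idf)
  dvj <- division_volumes(at, idJ)
  dvp <- division_volumes(at, idJ, field = idf, mode = "pullback")
  expect_equal(dvp$volume_um3, dvj$volume_um3)

  # supra-voxel deformation (label pull-back cannot resolve sub-voxel
  # boundary shifts): global affine contraction by 0.9 per axis
  d <- dim(at$labels)[1:3]
  sp <- voxel_spacing(at$labels)
  ctr <- (d - 1) / 2 * sp
  u <- array(0, c(d, 3))
  u[, , , 1] <- array(-0.1 * ((0:(d[1] - 1)) * sp[1] - ctr[1]), d)
  u[, , , 2] <- array(rep(-0.1 * ((0:(d[2] - 1)) * sp[2] - ctr[2]),
                          each = d[1]), d)
  u[, , , 3] <- array(rep(-0.1 * ((0:(d[3] - 1)) * sp[3] - ctr[3]),
                          each = d[1] * d[2]), d)
  aff <- cm_volume(u, sp, "displacement")
  dvap <- division_volumes(at, jacobian_determinant(aff), field = aff,
                           mode = "pullback")
  # every region shrinks; regions large enough that the boundary moves
  # by more than the half-voxel label quantization track the analytic
  # volume ratio
  expect_true(all(dvap$volume_um3 <= dvj$volume_um3))
  big <- dvj$n_voxels > 5000
  expect_equal(dvap$volume_um3[big] / dvj$volume_um3[big],
               rep(0.9^3, sum(big)), tolerance = 0.03)
  expect_equal(sum(dvap$volume_um3) / sum(dvj$volume_um3), 0.9^3,
               tolerance = 0.04)
})

test_that("mask volume percentages follow the Jacobian", {
  at <- small_atlas()
  lab <- array(as.vector(at$labels), dim(at$labels))
  brain <- lab > 0
  idJ <- jacobian_determinant(zero_field(dim(lab), voxel_spacing(at$labels)))
  expect_equal(mask_volume_pct(brain, idJ, brain), 100)
  tm <- truth_region_mask(at)
  expect_equal(mask_volume_pct(tm, idJ, brain),
               100 * sum(tm) / sum(brain))
  expect_error(mask_volume_pct(array(FALSE, dim(lab)), idJ, brain),
               "empty")
})

test_that("division intensities recover generator means; empty is NA", {
  at <- small_atlas()
  lab <- array(as.vector(at$labels), dim(at$labels))
  const <- cm_volume(array(7.5, dim(lab)), voxel_spacing(at$labels),
                     "intensity")
  di <- division_intensity(at, const)
  expect_true(all(di$mean_ch1 == 7.5))

  di2 <- division_intensity(at, at$image)
  expect_equal(di2$mean_ch1,
               unname(at$spec$channel_means[di2$division, 1]))

  spec <- small_atlas_spec()
  spec$divisions <- rbind(spec$divisions,
                          data.frame(name = "Ghost", cx = 15.5, cy = 200,
                                     cz = 100, rx = 1, ry = 1, rz = 1))
  spec$channel_means <- rbind(spec$channel_means,
                              Ghost = c(1, 1, 1))
  at2 <- make_atlas(spec)
  di3 <- division_intensity(at2, at2$image)
  expect_true(is.na(di3$mean_ch1[di3$division == "Ghost"]))
})
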