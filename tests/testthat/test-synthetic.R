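# Synthetic-data generators: atlas construction, warp fields with
# implanted atrophy, DE count tables, electropherograms.

test_that("atlas labels are bilaterally symmetric with equal twins", {
  at <- small_atlas()
  lab <- array(as.vector(at$labels), dim(at$labels))
  mir <- array(as.vector(mirror_volume(at$labels)), dim(lab))
  # occupancy is exactly mirror-symmetric
  expect_identical(lab > 0, mir > 0)
  # twin divisions swap labels under reflection, midline ones map to
  # themselves
  nm <- at$spec$divisions$name
  twin <- ifelse(grepl("_L$", nm), sub("_L$", "_R", nm),
                 ifelse(grepl("_R$", nm), sub("_R$", "_L", nm), nm))
  swap <- match(twin, nm)
  swapped <- mir
  swapped[mir > 0] <- swap[mir[mir > 0]]
  expect_identical(swapped, lab)
  expect_equal(sum(lab == division_id(at$spec, "LCeP_L")),
               sum(lab == division_id(at$spec, "LCeP_R")))
  expect_equal(sum(lab == division_id(at$spec, "TeO_L")),
               sum(lab == division_id(at$spec, "TeO_R")))
})

test_that("total labeled volume equals the brute-force voxel sum", {
  at <- small_atlas()
  lab <- array(as.vector(at$labels), dim(at$labels))
  counts <- vapply(seq_len(nrow(at$spec$divisions)),
                   function(i) sum(lab == i), numeric(1))
  expect_equal(sum(lab > 0) * voxel_volume(at$labels),
               sum(counts) * voxel_volume(at$labels))
  dv <- division_volumes(at, jacobian_determinant(
    zero_field(dim(lab), voxel_spacing(at$labels))))
  expect_equal(dv$n_voxels, as.integer(counts))
})

test_that("overlapping divisions are rejected naming the pair", {
  spec <- small_atlas_spec()
  bad <- spec$divisions
  bad$cy[bad$name %in% c("TeO_L", "TeO_R")] <- bad$cy[bad$name == "Pallium"]
  bad$cx[bad$name == "TeO_L"] <- bad$cx[bad$name == "Pallium"] - 2
  bad$cx[bad$name == "TeO_R"] <- bad$cx[bad$name == "Pallium"] + 2
  spec2 <- atlas_spec(shape = spec$shape, spacing = spec$spacing,
                      divisions = bad, envelope = spec$envelope)
  expect_error(make_atlas(spec2), "overlap.*Pallium|Pallium.*overlap")
})

test_that("zero-amplitude warps are the identity; implanted contraction
           matches its analytic radial profile", {
  at <- small_atlas()
  spec <- small_cohort_spec(warp_amplitude = 0, scale = 1)
  f <- make_displacement(at, spec, 1L)
  expect_true(all(f == 0))
  J <- jacobian_determinant(f)
  expect_true(all(abs(J - 1) < 1e-12))

  spec8 <- small_cohort_spec(warp_amplitude = 0, scale = 0.8)
  f8 <- make_displacement(at, spec8, 1L)
  J8 <- array(as.vector(jacobian_determinant(f8)), dim(at$labels))
  tm <- truth_region_mask(at)
  # analytic oracle: J(r) = rho'(r) (rho(r)/r)^2 from the contraction
  # profile, averaged over the same voxels
  dv <- at$spec$divisions
  sp <- voxel_spacing(at$labels)
  expected <- numeric(0)
  for (tw in c("LCeP_L", "LCeP_R")) {
    row <- dv[dv$name == tw, ]
    co <- arrayInd(which(array(as.vector(at$labels),
                               dim(at$labels)) == division_id(at$spec, tw)),
                   dim(at$labels))
    r <- sqrt(colSums((t(co - 1) - c(row$cx, row$cy, row$cz))^2)) * sp[1]
    r0 <- row$rx * sp[1]; r1 <- 1.6 * r0
    eps <- 1e-4
    rho1 <- cerebmorph:::radial_profile(r + eps, 0.8, r0, r1)
    rho0 <- cerebmorph:::radial_profile(pmax(r - eps, 0), 0.8, r0, r1)
    drho <- (rho1 - rho0) / (2 * eps)
    rho <- cerebmorph:::radial_profile(r, 0.8, r0, r1)
    expected <- c(expected, drho * ifelse(r > 0, (rho / r)^2, 0.8^(2 / 3)))
  }
  expect_equal(mean(J8[tm]), mean(expected), tolerance = 0.02)
  expect_lt(abs(mean(J8[tm]) - 0.8), 0.05)
})

test_that("warp generation is a pure function of the seed", {
  at <- small_atlas()
  spec <- small_cohort_spec()
  f1 <- make_displacement(at, spec, 7L)
  f2 <- make_displacement(at, spec, 7L)
  expect_identical(as.vector(f1), as.vector(f2))
  f3 <- make_displacement(at, spec, 8L)
  expect_false(identical(as.vector(f1), as.vector(f3)))
  expect_true(all(jacobian_determinant(f1) > 0))
})

test_that("cohorts carry genotype, batch and implanted truth", {
  at <- small_atlas()
  co <- make_cohort(at, small_cohort_spec(scale = 1))
  expect_equal(nrow(co$truth), 8)
  expect_true(all(co$truth$scale == 1))
  expect_true(all(co$truth$atrophy_region == "none"))

  co8 <- make_cohort(at, cohort_spec(
    n_per_group = c(control = 2L, crispant = 3L), scale = 0.8, seed = 3L))
  expect_equal(nrow(co8$truth), 5)
  expect_equal(co8$truth$scale[co8$truth$genotype == "crispant"],
               rep(0.8, 3))
  expect_equal(length(unique(co8$truth$seed)), 5)
  flds <- vapply(co8$samples, function(s) s$field[3, 3, 3, 1], numeric(1))
  expect_equal(length(unique(flds)), 5)

  expect_error(cohort_spec(n_per_group = c(control = 1L, crispant = 3L)),
               "at least 2")
})

test_that("subject channel images are atlas means plus noise", {
  at <- small_atlas()
  co <- make_cohort(at, cohort_spec(
    n_per_group = c(control = 2L, crispant = 2L),
    scale = 1, channel_noise_sd = 4, seed = 11L), channels = TRUE)
  img <- co$samples[[1]]$image
  lab <- array(as.vector(at$labels), dim(at$labels))
  i <- division_id(at$spec, "Pallium")
  ch1 <- array(as.vector(img)[seq_len(prod(dim(lab)))], dim(lab))
  mu <- at$spec$channel_means["Pallium", 1]
  se <- 4 / sqrt(sum(lab == i))
  expect_lt(abs(mean(ch1[lab == i]) - mu), 5 * se)
})

test_that("DE tables implant sign-consistent shared effects", {
  de <- make_de_tables(de_gen_spec(n_genes = 400L, n_shared_de = 20L,
                                   n_unique_de = 10L, lfc_mean = 4,
                                   lfc_sd = 0, mu_meanlog = log(2000),
                                   mu_sdlog = 0.2, seed = 5L))
  shared <- de$truth$gene[de$truth$de_a & de$truth$de_b]
  expect_length(shared, 20)
  la <- de$table_a$log2FoldChange[match(shared, de$table_a$gene)]
  lb <- de$table_b$log2FoldChange[match(shared, de$table_b$gene)]
  sg <- de$truth$sign[match(shared, de$truth$gene)]
  expect_true(all(sign(la) == sg))
  expect_true(all(sign(lb) == sg))

  de0 <- make_de_tables(de_gen_spec(n_genes = 200L, n_shared_de = 0L,
                                    n_unique_de = 5L, seed = 2L))
  expect_equal(sum(de0$truth$de_a & de0$truth$de_b), 0)

  expect_error(de_gen_spec(dispersion = 0), "dispersion")
})

test_that("realized baseMean equals the mean of the simulated counts", {
  de <- make_de_tables(de_gen_spec(n_genes = 50L, n_shared_de = 5L,
                                   n_unique_de = 5L, seed = 9L))
  expect_equal(de$table_a$baseMean, rowMeans(de$counts_a))
  expect_equal(de$table_b$baseMean, rowMeans(de$counts_b))
  # a gene with identical counts in every replicate has baseMean equal
  # to that constant and an undefined (p = 1) test
  const <- which(apply(de$counts_a, 1, function(r) length(unique(r)) == 1))
  if (length(const) > 0) {
    expect_equal(de$table_a$baseMean[const[1]], de$counts_a[const[1], 1])
    expect_equal(de$table_a$pvalue[const[1]], 1)
  }
  expect_true(all(de$table_a$pvalue > 0 & de$table_a$pvalue <= 1))
})

test_that("traces integrate to their analytic area and flag crowding", {
  tr <- make_trace(trace_gen_spec(wt_frac = 1,
                                  indel_offsets_bp = numeric(0),
                                  indel_rel_areas = numeric(0),
                                  noise_sd = 0, seed = 1L))
  with(tr$trace, {
    total <- sum(diff(size_bp) * (head(signal, -1) + tail(signal, -1)) / 2)
    expect_equal(total, 1, tolerance = 0.01)
  })
  expect_false(tr$crowded)

  tr2 <- make_trace(trace_gen_spec(wt_frac = 0.5,
                                   indel_offsets_bp = -6,
                                   indel_rel_areas = 1,
                                   noise_sd = 0, seed = 1L))
  pk <- detect_peaks(tr2)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$area[1] / pk$area[2], 1, tolerance = 0.02)

  tr3 <- make_trace(trace_gen_spec(indel_offsets_bp = c(-0.5),
                                   indel_rel_areas = 1, seed = 1L))
  expect_true(tr3$crowded)
})
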