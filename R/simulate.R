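#' Specify a synthetic morphometry cohort
#'
#' Describes the study design emulated by the warp generator: group sizes
#' per genotype and batch, the smoothness and amplitude of the random
#' per-subject warps, and the implanted regional atrophy. Atrophy is a
#' radially symmetric contraction centred on each twin of the target
#' division with a compensating dilation shell, so the core of the target
#' has Jacobian determinant exactly `scale` while total brain volume is
#' essentially unchanged (the volume removed from the core reappears in
#' the shell).
#'
#' `warp_amplitude` is the maximum displacement magnitude of the smoothed
#' random field in micrometres (default 2 voxel edges); `warp_sigma` is
#' the Gaussian smoothing kernel in micrometres (default 6 voxel edges).
#' These defaults keep per-voxel displacement gradients small enough that
#' Jacobians stay strictly positive.
#'
#' @param genotypes Character vector of group labels, a subset of
#'   `{"control", "crispant", "double"}` (repeated per subject) or set via
#'   `n_per_group`.
#' @param n_per_group Named integer vector of subjects per genotype,
#'   e.g. `c(control = 14, crispant = 17)`.
#' @param batch Batch label applied to the whole cohort (one experiment).
#' @param warp_sigma,warp_amplitude Smoothness / amplitude in um.
#' @param atrophy_region Division name without the `_L`/`_R` suffix
#'   (both twins are contracted), or `"none"`.
#' @param scale Volume scale factor s in (0, 1] implanted in crispants.
#' @param scale_double Scale implanted in double crispants (default 1,
#'   i.e. full rescue).
#' @param channel_noise_sd Per-voxel Gaussian intensity noise SD.
#' @param seed Base RNG seed; subject i uses `seed + i`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(control = 14L, crispant = 17L),
                        batch = "exp1",
                        warp_sigma = 12, warp_amplitude = 4,
                        atrophy_region = "LCeP",
                        scale = 0.8, scale_double = 1,
                        channel_noise_sd = 10,
                        seed = 1L) {
  if (any(n_per_group < 2L))
    stop("need at least 2 subjects per group (group tests undefined below 2)")
  if (!all(names(n_per_group) %in% c("control", "crispant", "double")))
    stop("genotype labels must be control / crispant / double")
  if (scale <= 0 || scale > 1) stop("atrophy scale must lie in (0, 1]")
  if (scale_double <= 0 || scale_double > 1) stop("scale_double must lie in (0, 1]")
  structure(list(n_per_group = n_per_group, batch = batch,
                 warp_sigma = warp_sigma, warp_amplitude = warp_amplitude,
                 atrophy_region = atrophy_region, scale = scale,
                 scale_double = scale_double,
                 channel_noise_sd = channel_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Radial contraction profile: rho(r) maps reference radius to subject
# radius. Inside r0 the map is uniform scaling by s^(1/3) (Jacobian s);
# over [r0, r1] a cubic Hermite blend returns to the identity with unit
# slope, so the volume removed from the core is restored in the shell and
# the map is the identity beyond r1.
radial_profile <- function(r, s, r0, r1) {
  s13 <- s^(1 / 3)
  rho <- r
  core <- r <= r0
  rho[core] <- s13 * r[core]
  shell <- r > r0 & r < r1
  if (any(shell)) {
    t <- (r[shell] - r0) / (r1 - r0)
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    dr <- r1 - r0
    rho[shell] <- h00 * (s13 * r0) + h10 * dr * s13 +
                  h01 * r1 + h11 * dr * 1
  }
  rho
}

# Displacement (um) of the compensated radial contraction centred at
# `center` (0-based voxel coords) for one twin of the target region.
atrophy_displacement <- function(shape, spacing, center, s, r0_um,
                                 shell_factor = 1.6) {
  d <- shape
  r1_um <- shell_factor * r0_um
  cx <- center * spacing   # centre in um
  gx <- (0:(d[1] - 1)) * spacing[1] - cx[1]
  gy <- (0:(d[2] - 1)) * spacing[2] - cx[2]
  gz <- (0:(d[3] - 1)) * spacing[3] - cx[3]
  X <- array(gx, d)
  Y <- array(rep(gy, each = d[1]), d)
  Z <- array(rep(gz, each = d[1] * d[2]), d)
  r <- sqrt(X^2 + Y^2 + Z^2)
  rho <- radial_profile(r, s, r0_um, r1_um)
  fac <- ifelse(r > 1e-9, rho / r - 1, s^(1 / 3) - 1)
  u <- array(0, c(d, 3L))
  u[, , , 1] <- fac * X
  u[, , , 2] <- fac * Y
  u[, , , 3] <- fac * Z
  u
}

#' Generate one subject's displacement field
#'
#' A smooth random warp (independent Gaussian white noise per component,
#' Gaussian-smoothed, rescaled so the maximum displacement magnitude
#' equals `warp_amplitude`) plus, when `scale < 1`, the compensated radial
#' contraction implanted at each twin of the atrophy region. The field
#' follows the convention T(x) = x + u(x), reference to subject, so a
#' contracted subject region has Jacobian determinant below 1. Fields are
#' regenerated (fresh noise) if any Jacobian is non-positive; exhausting
#' the retries is an error.
#'
#' @param atlas Result of [make_atlas()].
#' @param spec A [cohort_spec()].
#' @param subject_seed Integer seed; equal seeds give identical fields.
#' @param scale Overrides `spec$scale` (used for genotype-specific
#'   atrophy).
#' @param max_retries Regeneration attempts for non-positive Jacobians.
#' @return A `cm_volume` of kind `"displacement"` (um).
#' @export
make_displacement <- function(atlas, spec, subject_seed,
                              scale = spec$scale, max_retries = 5L) {
  d <- atlas$spec$shape
  sp <- atlas$spec$spacing
  sigma_vox <- spec$warp_sigma / mean(sp)
  u_atr <- NULL
  if (!identical(spec$atrophy_region, "none") && scale < 1) {
    twins <- paste0(spec$atrophy_region, c("_L", "_R"))
    dv <- atlas$spec$divisions
    if (!all(twins %in% dv$name))
      stop("atrophy region '", spec$atrophy_region, "' not in atlas")
    u_atr <- 0
    for (tw in twins) {
      row <- dv[dv$name == tw, ]
      if (length(unique(unlist(row[, c("rx", "ry", "rz")]))) != 1L)
        stop("atrophy target must be spherical for the radial implant")
      u_atr <- u_atr + atrophy_displacement(
        d, sp, c(row$cx, row$cy, row$cz), scale, row$rx * sp[1])
    }
  }
  for (try in 0:max_retries) {
    set.seed(subject_seed + try * 1000003L)
    if (spec$warp_amplitude > 0) {
      u <- array(0, c(d, 3L))
      for (comp in 1:3)
        u[, , , comp] <- smooth_gaussian3(array(stats::rnorm(prod(d)), d),
                                          sigma_vox)
      mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
      u <- u * (spec$warp_amplitude / max(mag))
    } else {
      u <- array(0, c(d, 3L))
    }
    if (!is.null(u_atr)) u <- u + u_atr
    fld <- cm_volume(u, sp, "displacement")
    J <- jacobian_determinant(fld)
    if (all(J > 0)) return(fld)
  }
  stop("could not generate a diffeomorphic field after ", max_retries,
       " retries (warp amplitude too large for smoothness)")
}

#' Generate a cohort of warped subjects
#'
#' One sample per subject: genotype, batch, seed, displacement field, and
#' (optionally) 3-channel intensity images (atlas means plus per-subject
#' iid Gaussian voxel noise). Controls carry scale 1, crispants
#' `spec$scale`, double crispants `spec$scale_double`. A truth table
#' records the implanted parameters per subject.
#'
#' @param atlas Result of [make_atlas()].
#' @param spec A [cohort_spec()].
#' @param channels Generate per-subject channel images (slower).
#' @return List with `samples` (list of per-subject lists) and `truth`
#'   (data frame: subject, genotype, batch, seed, atrophy_region, scale).
#' @export
make_cohort <- function(atlas, spec, channels = FALSE) {
  genos <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(genos)
  scales <- c(control = 1, crispant = spec$scale,
              double = spec$scale_double)[genos]
  truth <- data.frame(
    subject = sprintf("s%02d", seq_len(n)),
    genotype = genos, batch = spec$batch,
    seed = spec$seed + seq_len(n),
    atrophy_region = ifelse(scales < 1, spec$atrophy_region, "none"),
    scale = unname(scales))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    fld <- make_displacement(atlas, spec, truth$seed[i], scale = scales[i])
    smp <- list(subject = truth$subject[i], genotype = genos[i],
                batch = spec$batch, seed = truth$seed[i], field = fld)
    if (channels) {
      set.seed(truth$seed[i] + 500000L)
      img <- bare(atlas$image) +
        stats::rnorm(length(atlas$image), sd = spec$channel_noise_sd)
      dim(img) <- dim(atlas$image)
      smp$image <- cm_volume(img, atlas$spec$spacing, "intensity")
    }
    samples[[i]] <- smp
  }
  list(samples = samples, truth = truth)
}

#' Ground-truth atrophy mask for a cohort's target region
#' @param atlas Result of [make_atlas()].
#' @param region Region name without twin suffix, e.g. `"LCeP"`.
#' @return Logical array, TRUE over both twins of the target division.
#' @export
truth_region_mask <- function(atlas, region = "LCeP") {
  ids <- vapply(paste0(region, c("_L", "_R")),
                function(nm) division_id(atlas$spec, nm), integer(1))
  arr <- bare(atlas$labels) %in% ids
  dim(arr) <- spatial_dim(atlas$labels)
  arr
}
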