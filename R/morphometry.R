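#' Jacobian determinant of a displacement field
#'
#' For the transform T(x) = x + u(x) (reference to subject), computes
#' J(x) = det(I + grad u(x)) per voxel, with the displacement gradient
#' taken by finite differences in physical units (central on interior
#' voxels, one-sided on the two boundary planes of each axis, so
#' anisotropic spacing is handled). J below 1 marks local contraction of
#' the subject relative to the reference; J of the identity transform is
#' exactly 1.
#'
#' @param field A `cm_volume` of kind `"displacement"` (um).
#' @return A `cm_volume` map of J with attribute `boundary` marking the
#'   one-sided boundary voxels.
#' @export
jacobian_determinant <- function(field) {
  if (!identical(attr(field, "kind"), "displacement"))
    stop("jacobian_determinant needs a displacement field")
  d <- spatial_dim(field)
  if (any(d < 3L)) stop("grid must be at least 3 voxels per axis")
  bad <- which(!is.finite(field))
  if (length(bad) > 0) {
    ix <- arrayInd(bad[1], dim(field))
    stop("non-finite displacement at voxel (",
         paste(ix[1:3] - 1L, collapse = ", "), "), component ", ix[4])
  }
  sp <- voxel_spacing(field)
  g <- vector("list", 9L)  # g[[3*(i-1)+j]] = d u_i / d x_j
  for (i in 1:3) {
    ui <- bare(field)[, , , i]
    dim(ui) <- d
    for (j in 1:3)
      g[[3 * (i - 1) + j]] <- fd_derivative(ui, j, sp[j])
  }
  a11 <- 1 + g[[1]]; a12 <- g[[2]];     a13 <- g[[3]]
  a21 <- g[[4]];     a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]];     a32 <- g[[8]];     a33 <- 1 + g[[9]]
  J <- a11 * (a22 * a33 - a23 * a32) -
       a12 * (a21 * a33 - a23 * a31) +
       a13 * (a21 * a32 - a22 * a31)
  out <- cm_volume(J, sp, "map")
  boundary <- array(FALSE, d)
  boundary[c(1, d[1]), , ] <- TRUE
  boundary[, c(1, d[2]), ] <- TRUE
  boundary[, , c(1, d[3])] <- TRUE
  attr(out, "boundary") <- boundary
  out
}

#' Log-Jacobian-determinant (LJD) map
#'
#' The voxel-volume change map: log J, zero under the identity transform,
#' negative where the subject is locally smaller than the reference.
#' Voxels with J at or below `min_jacobian` are folds (the surrogate for a
#' failed registration); they are clamped to `log(min_jacobian)` and
#' counted, and more than 1 percent folded voxels is an error.
#'
#' @param jmap Jacobian map from [jacobian_determinant()].
#' @param min_jacobian Positive clamping floor.
#' @param subject Optional subject id stored on the map.
#' @return A `cm_volume` map of log J with attributes `folds` (count) and
#'   `subject`.
#' @export
log_jacobian <- function(jmap, min_jacobian = 1e-3, subject = NA_character_) {
  if (min_jacobian <= 0) stop("min_jacobian must be strictly positive")
  J <- bare(jmap)
  folded <- is.finite(J) & J <= min_jacobian
  nf <- sum(folded)
  if (nf > 0.01 * length(J))
    stop(sprintf("%.2f%% of voxels are folded (J <= %g); field is not usable",
                 100 * nf / length(J), min_jacobian))
  J[folded] <- min_jacobian
  out <- cm_volume(log(J), voxel_spacing(jmap), "map")
  attr(out, "folds") <- nf
  attr(out, "subject") <- subject
  out
}

#' Per-division volumes and intensities for one subject
#'
#' Division volume is the integral of the Jacobian determinant over the
#' division's atlas label (`mode = "jacobian"`), i.e. the subject-space
#' volume of the atlas-defined region; percentages are relative to the
#' whole labeled brain. `mode = "pullback"` instead pushes each reference
#' voxel centre through T and counts nearest-voxel label hits in subject
#' space — the discrete label-propagation route, useful as a cross-check
#' but subject to rounding noise.
#'
#' @param atlas Result of [make_atlas()] (or a list with `labels`,
#'   `spec`).
#' @param jmap Jacobian map on the atlas grid.
#' @param image Optional 3-channel image for per-division mean
#'   intensities.
#' @param field Displacement field, required for `mode = "pullback"`.
#' @param mode `"jacobian"` (default) or `"pullback"`.
#' @return Data frame: division, n_voxels, volume_um3, percent, and
#'   mean_ch1..3 when `image` is given. Percentages sum to 100. Empty
#'   divisions report NA means.
#' @export
division_volumes <- function(atlas, jmap, image = NULL, field = NULL,
                             mode = c("jacobian", "pullback")) {
  mode <- match.arg(mode)
  lab <- bare(atlas$labels)
  if (!all(spatial_dim(atlas$labels) == spatial_dim(jmap)))
    stop("atlas and Jacobian map are on different grids")
  nm <- atlas$spec$divisions$name
  vv <- voxel_volume(atlas$labels)
  counts <- tabulate(lab[lab > 0], nbins = length(nm))
  if (mode == "jacobian") {
    J <- bare(jmap)
    vol <- vapply(seq_along(nm),
                  function(i) sum(J[lab == i]) * vv, numeric(1))
  } else {
    if (is.null(field)) stop("pullback mode needs the displacement field")
    vol <- pullback_volumes(atlas, field) * vv
  }
  out <- data.frame(division = nm, n_voxels = counts,
                    volume_um3 = vol,
                    percent = 100 * vol / sum(vol))
  if (!is.null(image)) {
    for (ch in seq_len(dim(image)[4])) {
      chan <- bare(image)[, , , ch]
      out[[paste0("mean_ch", ch)]] <- vapply(seq_along(nm), function(i) {
        if (counts[i] == 0) return(NA_real_)
        mean(chan[lab == i])
      }, numeric(1))
    }
  }
  out
}

# Trilinear sampling of a 3D array at fractional 0-based voxel
# coordinates (matrix n x 3), clamped to the grid.
trilinear3 <- function(arr, pts) {
  d <- dim(arr)
  p <- pmin(pmax(pts, 0), rep(d - 1L, each = nrow(pts)))
  i0 <- floor(p)
  fr <- p - i0
  i0 <- pmin(i0, rep(d - 2L, each = nrow(pts)))
  fr <- p - i0
  lin <- function(dx, dy, dz)
    arr[(i0[, 1] + dx) + (i0[, 2] + dy) * d[1] +
        (i0[, 3] + dz) * d[1] * d[2] + 1]
  w <- function(dx, dy, dz)
    (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
    (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
    (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    out <- out + w(dx, dy, dz) * lin(dx, dy, dz)
  out
}

# Inverse label propagation: for every subject-grid voxel y, solve
# T(x) = x + u(x) = y by fixed-point iteration (x <- y - u(x), trilinear
# u) and take the atlas label at the nearest reference voxel — the
# discrete analogue of inversely registering atlas annotations onto the
# subject scan — then count subject voxels per label.
pullback_volumes <- function(atlas, field, n_iter = 5L) {
  d <- spatial_dim(atlas$labels)
  sp <- voxel_spacing(atlas$labels)
  lab <- bare(atlas$labels)
  nm <- atlas$spec$divisions$name
  u <- bare(field)
  uc <- lapply(1:3, function(j) {
    a <- u[, , , j]; dim(a) <- d; a
  })
  y <- arrayInd(seq_len(prod(d)), d) - 1
  x <- y
  for (it in seq_len(n_iter)) {
    ux <- vapply(1:3, function(j) trilinear3(uc[[j]], x) / sp[j],
                 numeric(nrow(y)))
    x <- y - ux
  }
  xi <- round(x)
  inb <- xi[, 1] >= 0 & xi[, 1] < d[1] &
         xi[, 2] >= 0 & xi[, 2] < d[2] &
         xi[, 3] >= 0 & xi[, 3] < d[3]
  lin <- xi[inb, 1] + xi[inb, 2] * d[1] + xi[inb, 3] * d[1] * d[2] + 1
  tabulate(lab[lin], nbins = length(nm))
}

#' Mask volume as a percentage of total brain volume
#'
#' 100 x (integral of J over the mask) / (integral of J over all brain
#' voxels): the subject-space volume of the masked region relative to the
#' subject's whole labeled brain.
#'
#' @param mask Logical array (or `cm_volume` mask) on the atlas grid.
#' @param jmap Jacobian map for the subject.
#' @param brain Logical array of brain voxels (e.g. atlas labels > 0).
#' @return Scalar percentage.
#' @export
mask_volume_pct <- function(mask, jmap, brain) {
  m <- as.logical(bare(mask)); dim(m) <- spatial_dim(jmap)
  if (!any(m)) stop("mask is empty")
  b <- as.logical(bare(brain)); dim(b) <- spatial_dim(jmap)
  J <- bare(jmap)
  100 * sum(J[m]) / sum(J[b])
}

#' Per-division mean channel intensities
#'
#' @param atlas Result of [make_atlas()].
#' @param image 3D single-channel or 4D multi-channel `cm_volume`.
#' @return Data frame: division, then one mean column per channel; empty
#'   divisions are NA (missing, not zero).
#' @export
division_intensity <- function(atlas, image) {
  if (!all(spatial_dim(atlas$labels) == dim(image)[1:3]))
    stop("atlas and image are on different grids")
  img <- bare(image)
  d <- spatial_dim(atlas$labels)
  if (length(dim(img)) == 3L) dim(img) <- c(d, 1L)
  lab <- bare(atlas$labels)
  nm <- atlas$spec$divisions$name
  counts <- tabulate(lab[lab > 0], nbins = length(nm))
  out <- data.frame(division = nm)
  for (ch in seq_len(dim(img)[4])) {
    chan <- img[, , , ch]; dim(chan) <- d
    out[[paste0("mean_ch", ch)]] <- vapply(seq_along(nm), function(i) {
      if (counts[i] == 0) return(NA_real_)
      mean(chan[lab == i])
    }, numeric(1))
  }
  out
}
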