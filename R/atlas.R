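#' Specify a synthetic labeled reference brain
#'
#' The synthetic atlas stands in for an annotated larval zebrafish
#' reference brain: a set of disjoint ellipsoidal divisions placed
#' bilaterally symmetrically about the mid-sagittal plane of the grid.
#' Divisions whose centre lies off the midline must be listed as
#' left/right twins (`_L`/`_R`) with mirrored centres and equal radii;
#' midline divisions are centred exactly on the mirror plane
#' (x = (nx - 1) / 2, 0-based).
#'
#' Centres and radii are in 0-based voxel units. The default layout places
#' a midline pallium, paired optic tecta, paired lateral cerebellar plate
#' (LCeP) spheres — the atrophy target used throughout the test suite —
#' and a midline medulla, on a 64 x 80 x 48 grid at 2 um isotropic
#' spacing.
#'
#' @param shape Grid extent in voxels (x, y, z).
#' @param spacing Voxel edge lengths in micrometres.
#' @param divisions Data frame with columns `name`, `cx`, `cy`, `cz`,
#'   `rx`, `ry`, `rz` (voxel units, 0-based centres).
#' @param midline_axis Mirror axis (1 = x).
#' @param channel_means Matrix (divisions x 3 channels) of mean
#'   intensities for the pan-neuronal, glutamatergic-like and
#'   GABAergic-like channels; rownames are division names.
#' @param envelope Brain envelope ellipsoid (`center`, `radii`, both in
#'   voxel units): voxels inside it but in no named division become the
#'   unannotated remainder division `"Rest"`, so the brain is a single
#'   contiguous volume and compensation shells around contracted regions
#'   stay inside brain tissue. `NULL` for no envelope.
#' @return An `atlas_spec` list.
#' @export
atlas_spec <- function(shape = c(64L, 80L, 48L),
                       spacing = c(2, 2, 2),
                       divisions = default_divisions(shape),
                       midline_axis = 1L,
                       channel_means = default_channel_means(divisions$name),
                       envelope = list(center = (shape - 1) / 2,
                                       radii = c(28, 38, 22))) {
  stopifnot(length(shape) == 3L, all(shape >= 8L), length(spacing) == 3L)
  need <- c("name", "cx", "cy", "cz", "rx", "ry", "rz")
  if (!all(need %in% names(divisions)))
    stop("divisions must have columns ", paste(need, collapse = ", "))
  mid <- (shape[midline_axis] - 1) / 2
  cc <- as.matrix(divisions[, c("cx", "cy", "cz")])
  for (i in seq_len(nrow(divisions))) {
    ci <- cc[i, midline_axis]
    if (abs(ci - mid) < 1e-9) next
    mirrored <- cc
    mirrored[, midline_axis] <- 2 * mid - mirrored[, midline_axis]
    hit <- which(apply(mirrored, 1, function(r) all(abs(r - cc[i, ]) < 1e-9)))
    twin_ok <- any(hit != i &
                   divisions$rx[hit] == divisions$rx[i] &
                   divisions$ry[hit] == divisions$ry[i] &
                   divisions$rz[hit] == divisions$rz[i])
    if (!twin_ok)
      stop("division '", divisions$name[i],
           "' is off-midline but has no mirrored twin of equal radii")
  }
  if (!is.null(envelope) &&
      abs(envelope$center[midline_axis] - mid) > 1e-9)
    stop("brain envelope must be centred on the midline plane")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 divisions = divisions, midline_axis = as.integer(midline_axis),
                 channel_means = channel_means, envelope = envelope),
            class = "atlas_spec")
}

#' @rdname atlas_spec
#' @export
default_divisions <- function(shape = c(64L, 80L, 48L)) {
  mid <- (shape[1] - 1) / 2
  data.frame(
    name = c("Pallium", "TeO_L", "TeO_R", "LCeP_L", "LCeP_R", "Medulla"),
    cx = c(mid, 15, 2 * mid - 15, 14, 2 * mid - 14, mid),
    cy = c(14, 36, 36, 58, 58, 71),
    cz = c(24, 28, 28, 22, 22, 20),
    rx = c(13, 10, 10, 8, 8, 9),
    ry = c(11, 10, 10, 8, 8, 7),
    rz = c(12, 9, 9, 8, 8, 7))
}

#' @rdname atlas_spec
#' @export
default_channel_means <- function(names) {
  m <- matrix(0, length(names), 3,
              dimnames = list(names, c("pan", "glut", "gaba")))
  base <- cbind(pan = 100, glut = 40, gaba = 40)
  m[] <- rep(base, each = length(names))
  # division-specific contrasts so intensity recovery is testable
  bump <- (seq_along(names) - 1) * 10
  m[, "glut"] <- m[, "glut"] + bump
  m[, "gaba"] <- m[, "gaba"] + rev(bump)
  m
}

#' Build the synthetic atlas
#'
#' Rasterizes the divisions into an integer label volume (labels follow
#' row order of `spec$divisions`, background 0) and a 3-channel intensity
#' image with division-specific means. Division overlap at any voxel is an
#' error naming the pair. The label volume is exactly mirror-symmetric
#' about the grid mid-plane by construction.
#'
#' @param spec An [atlas_spec()].
#' @return List with `labels` (a `cm_volume` of kind `"labels"`),
#'   `image` (4D 3-channel `cm_volume`), and `spec`.
#' @export
make_atlas <- function(spec = atlas_spec()) {
  d <- spec$shape
  lab <- array(0L, d)
  ax <- (0:(d[1] - 1)); ay <- (0:(d[2] - 1)); az <- (0:(d[3] - 1))
  for (i in seq_len(nrow(spec$divisions))) {
    dv <- spec$divisions[i, ]
    ex <- ((ax - dv$cx) / dv$rx)^2
    ey <- ((ay - dv$cy) / dv$ry)^2
    ez <- ((az - dv$cz) / dv$rz)^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    clash <- inside & lab != 0L
    if (any(clash)) {
      other <- spec$divisions$name[lab[which(clash)[1]]]
      stop("divisions overlap: '", dv$name, "' and '", other, "'")
    }
    lab[inside] <- i
  }
  divisions <- spec$divisions
  channel_means <- spec$channel_means
  if (!is.null(spec$envelope)) {
    en <- spec$envelope
    ex <- ((ax - en$center[1]) / en$radii[1])^2
    ey <- ((ay - en$center[2]) / en$radii[2])^2
    ez <- ((az - en$center[3]) / en$radii[3])^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    rest_id <- nrow(divisions) + 1L
    lab[inside & lab == 0L] <- rest_id
    divisions <- rbind(divisions, data.frame(
      name = "Rest", cx = en$center[1], cy = en$center[2],
      cz = en$center[3], rx = en$radii[1], ry = en$radii[2],
      rz = en$radii[3]))
    channel_means <- rbind(channel_means,
                           Rest = c(pan = 80, glut = 25, gaba = 25))
  }
  spec$divisions <- divisions
  spec$channel_means <- channel_means
  img <- array(0, c(d, 3L))
  for (ch in 1:3) {
    plane <- array(0, d)
    for (i in seq_len(nrow(divisions)))
      plane[lab == i] <- channel_means[i, ch]
    img[, , , ch] <- plane
  }
  list(labels = cm_volume(lab, spec$spacing, "labels"),
       image = cm_volume(img, spec$spacing, "intensity"),
       spec = spec)
}

#' Look up a division label id by name
#' @param spec An `atlas_spec`.
#' @param name Division name, e.g. `"LCeP_L"`.
#' @return Integer label id.
#' @export
division_id <- function(spec, name) {
  i <- match(name, spec$divisions$name)
  if (is.na(i)) stop("no division named '", name, "' in atlas")
  i
}
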