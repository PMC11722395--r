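# Conversion of voxelwise p-value maps into validated region masks:
# p-threshold -> small-cluster removal -> bilateral-symmetry filter.
# The filter order is fixed; each filter is idempotent.

#' Threshold a p-value map
#'
#' Keeps voxels with p at or below `alpha` (the boundary p = alpha counts
#' as significant); NaN voxels (outside the brain) are excluded.
#'
#' @param pmap P-value `cm_volume` or array.
#' @param alpha Threshold in (0, 1).
#' @return Logical array.
#' @export
threshold_pmap <- function(pmap, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)")
  p <- bare(pmap)
  keep <- !is.na(p) & p <= alpha
  dim(keep) <- dim(p)[1:3]
  keep
}

#' Remove small connected components from a binary map
#'
#' Labels connected components under the stated 3D connectivity and drops
#' every component with fewer than `min_size` voxels.
#'
#' @param mask Logical array.
#' @param min_size Minimum surviving component size in voxels (>= 1).
#' @param connectivity 6, 18 or 26 (face / edge / corner neighbours).
#' @return Logical array.
#' @export
remove_small_clusters <- function(mask, min_size, connectivity = 26L) {
  if (!is.numeric(min_size) || min_size < 1)
    stop("min_size must be at least 1 voxel")
  m <- as.logical(bare(mask)); dim(m) <- dim(mask)[1:3]
  lab <- label_components(m, connectivity)
  if (max(lab) == 0L) return(m)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep_ids <- which(sizes >= min_size)
  out <- array(lab %in% keep_ids & lab > 0L, dim(m))
  out
}

#' Bilateral-symmetry filter
#'
#' Keeps a voxel only if some set voxel lies within `tolerance_radius`
#' (Chebyshev distance, i.e. a cube window) of its mirror position, the
#' reflection of the voxel's index about the grid mid-plane of the
#' midline axis (0-based x maps to nx - 1 - x). With tolerance 0 a voxel
#' survives only if its exact mirror voxel is set, so a purely unilateral
#' blob is removed entirely while a mirrored pair is untouched.
#'
#' @param mask Logical array.
#' @param midline_axis Axis index of the left-right axis (1 = x).
#' @param tolerance_radius Non-negative integer voxel radius.
#' @return Logical array.
#' @export
bilateral_filter <- function(mask, midline_axis = 1L, tolerance_radius = 2L) {
  if (midline_axis < 1L || midline_axis > 3L)
    stop("midline axis must be 1, 2 or 3")
  if (tolerance_radius < 0) stop("tolerance_radius must be non-negative")
  m <- as.logical(bare(mask)); dim(m) <- dim(mask)[1:3]
  mirrored <- mirror_volume(m, midline_axis)
  m & dilate_cube(mirrored, as.integer(tolerance_radius))
}

#' Build the affected-region mask from a statistic map
#'
#' The fixed filter chain: threshold the p-map at `alpha`, optionally
#' restrict to the direction of the group effect (`"negative"` keeps
#' voxels where the second group's mean is below the first's, i.e. the
#' region *reduced* in crispants when controls are passed first), remove
#' small clusters, apply the bilateral-symmetry filter, and optionally
#' re-run the cluster filter on what survives. Provenance (all filter
#' parameters) is recorded on the mask.
#'
#' @param stat_map A `cm_stat_map` (from [voxel_ttest()] or
#'   [voxel_anova2()]).
#' @param alpha Voxelwise p threshold.
#' @param min_cluster Minimum cluster size (voxels).
#' @param connectivity 6, 18 or 26.
#' @param sym_tol Symmetry tolerance radius (voxels).
#' @param direction `"negative"`, `"positive"` or `"both"`; directions
#'   other than `"both"` need a map with `mean_diff` (t-test maps).
#' @param midline_axis Left-right axis (1 = x).
#' @param recluster Re-run the cluster filter after the symmetry filter.
#' @return A `region_mask`: logical array with attribute `provenance`.
#' @export
make_mask <- function(stat_map, alpha = 0.01, min_cluster = 50L,
                      connectivity = 26L, sym_tol = 2L,
                      direction = c("negative", "positive", "both"),
                      midline_axis = 1L, recluster = FALSE) {
  direction <- match.arg(direction)
  keep <- threshold_pmap(stat_map$p, alpha)
  if (direction != "both") {
    if (is.null(stat_map$mean_diff))
      stop("directional masks need a two-group map with mean_diff")
    md <- bare(stat_map$mean_diff)
    keep <- keep & !is.na(md) &
      (if (direction == "negative") md < 0 else md > 0)
  }
  keep <- remove_small_clusters(keep, min_cluster, connectivity)
  keep <- bilateral_filter(keep, midline_axis, sym_tol)
  if (recluster) keep <- remove_small_clusters(keep, min_cluster, connectivity)
  if (!any(keep))
    stop("no voxels survive the filter chain; review alpha (", alpha,
         "), min_cluster (", min_cluster, ") and sym_tol (", sym_tol, ")")
  structure(keep,
            provenance = list(test = stat_map$test, alpha = alpha,
                              min_cluster = min_cluster,
                              connectivity = connectivity,
                              sym_tol = sym_tol, direction = direction,
                              midline_axis = midline_axis,
                              recluster = recluster,
                              n_voxels = sum(keep)),
            class = c("region_mask", "array"))
}

#' Write / read a region mask with its provenance sidecar
#'
#' The mask is stored as a uint8 0/1 NIfTI volume; provenance goes to a
#' YAML sidecar next to it (`<path>.prov.yaml`).
#'
#' @param mask A `region_mask`.
#' @param path NIfTI destination.
#' @param spacing Voxel spacing for the written volume.
#' @return `write_mask`: `path`, invisibly. `read_mask`: the
#'   `region_mask`.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  arr <- array(as.integer(mask), dim(mask))
  write_volume(cm_volume(arr, spacing, "mask"), path)
  prov <- attr(mask, "provenance")
  if (!is.null(prov))
    yaml::write_yaml(prov, paste0(path, ".prov.yaml"))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  vol <- read_volume(path, kind = "mask")
  arr <- bare(vol) != 0
  dim(arr) <- spatial_dim(vol)
  prov_path <- paste0(path, ".prov.yaml")
  prov <- if (file.exists(prov_path)) yaml::read_yaml(prov_path) else NULL
  structure(arr, provenance = prov, class = c("region_mask", "array"))
}

#' Dice overlap coefficient between two masks
#' @param a,b Logical arrays of equal dimension.
#' @return 2|A n B| / (|A| + |B|); 0 when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
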