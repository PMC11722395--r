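#' Voxel-grid containers
#'
#' All pipeline stages exchange voxel grids as plain R arrays carrying two
#' attributes: `spacing` (micrometres per voxel edge along x, y, z) and
#' `kind`, one of `"intensity"` (3D scalar or 4D multi-channel image),
#' `"labels"` (integer division labels, 0 = background), `"displacement"`
#' (4D array, 4th axis = x/y/z displacement components in micrometres, with
#' the convention that T(x) = x + u(x) maps reference to subject
#' coordinates), `"map"` (3D scalar map such as a log-Jacobian-determinant
#' or p-value volume) or `"mask"` (0/1). Grids live in reference (atlas)
#' space; axis 1 is the left-right axis used by the bilateral-symmetry
#' filter; voxel indexing is 0-based in all user-facing coordinate fields.
#'
#' @param x Numeric array, 3D or 4D.
#' @param spacing Numeric length-3 vector, micrometres per voxel edge.
#' @param kind Grid kind (see above).
#' @return The array with `spacing` and `kind` attributes and class
#'   `cm_volume`.
#' @export
cm_volume <- function(x, spacing, kind = c("intensity", "labels",
                                           "displacement", "map", "mask")) {
  kind <- match.arg(kind)
  if (!is.array(x) || !(length(dim(x)) %in% c(3L, 4L)))
    stop("volume must be a 3D or 4D array, got ", length(dim(x)), " dims")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel edge lengths (micrometres)")
  if (kind == "displacement" &&
      (length(dim(x)) != 4L || dim(x)[4] != 3L))
    stop("displacement field must be 4D with 3 components on axis 4")
  structure(x, spacing = as.numeric(spacing), kind = kind,
            class = c("cm_volume", "array"))
}

#' @export
print.cm_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cm_volume kind=%s dim=%s spacing=%s um>\n",
              attr(x, "kind"), paste(d, collapse = "x"),
              paste(signif(attr(x, "spacing"), 4), collapse = "x")))
  invisible(x)
}

#' Voxel spacing of a grid
#' @param x A `cm_volume`.
#' @return Numeric length-3 vector (micrometres).
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("grid has no spacing attribute")
  sp
}

#' Physical volume of one voxel in cubic micrometres
#' @param x A `cm_volume`.
#' @export
voxel_volume <- function(x) prod(voxel_spacing(x))

spatial_dim <- function(x) dim(x)[1:3]

# strip volume attributes, keep bare array
bare <- function(x) {
  a <- as.vector(x)
  dim(a) <- dim(x)
  a
}

#' Read a volume, label atlas, map or displacement field from NIfTI
#'
#' Displacement fields are stored in the NIfTI vector convention (5D,
#' dim = c(nx, ny, nz, 1, 3), intent code 1007) and come back as 4D arrays
#' with the component axis last. 4D files are multi-channel intensity
#' images; 3D integer files are label volumes; 3D float files are scalar
#' maps or images (`kind` is then taken from the `kind` argument).
#'
#' @param path NIfTI file path.
#' @param kind Optional override for 3D scalar files: `"map"`,
#'   `"intensity"` or `"mask"`.
#' @return A [cm_volume()].
#' @export
read_volume <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) < 3L)
    stop("volume in ", path, " is not a 3D grid (dim = ",
         paste(d, collapse = "x"), ")")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or non-positive voxel spacing in ", path)
  intent <- tryCatch(img$intent_code, error = function(e) 0L)
  arr <- as.array(img)
  if (length(d) == 5L && d[4] == 1L && d[5] == 3L) {
    dim(arr) <- d[c(1, 2, 3, 5)]
    return(cm_volume(arr, sp, "displacement"))
  }
  if (length(d) == 4L) {
    if (identical(intent, 1007L) && d[4] == 3L)
      return(cm_volume(arr, sp, "displacement"))
    return(cm_volume(arr, sp, "intensity"))
  }
  if (length(d) != 3L)
    stop("volume in ", path, " has unsupported dimensionality ", length(d))
  if (is.integer(arr) && is.null(kind)) kind <- "labels"
  if (is.null(kind)) kind <- "map"
  cm_volume(arr, sp, kind)
}

#' Write a volume to NIfTI
#'
#' Label volumes and masks are written as int32/uint8 and round-trip
#' exactly; float maps are written as float64. Displacement fields are
#' written in the 5D NIfTI vector convention with intent code 1007.
#'
#' @param vol A [cm_volume()].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  sp <- voxel_spacing(vol)
  kind <- attr(vol, "kind")
  arr <- bare(vol)
  if (kind == "displacement") dim(arr) <- c(dim(arr)[1:3], 1L, 3L)
  datatype <- switch(kind, labels = "int32", mask = "uint8", "double")
  if (kind == "labels") storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  if (kind == "displacement") img$intent_code <- 1007L
  ok <- tryCatch({
    suppressWarnings(RNifti::writeNifti(img, path, datatype = datatype))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write volume to ", path)
  invisible(path)
}

#' Mirror a grid about the mid-sagittal plane
#'
#' Reflects voxel index i to (nx - 1 - i) along the stated axis (0-based
#' indexing; in R terms index j maps to nx + 1 - j).
#'
#' @param vol A `cm_volume` or bare array.
#' @param axis Midline axis, 1 = x (default).
#' @return Grid of the same kind, mirrored.
#' @export
mirror_volume <- function(vol, axis = 1L) {
  d <- dim(vol)
  if (axis < 1L || axis > 3L) stop("midline axis must be 1, 2 or 3")
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- d[axis]:1
  out <- do.call(`[`, c(list(bare(vol)), idx, list(drop = FALSE)))
  dim(out) <- d
  if (inherits(vol, "cm_volume"))
    out <- cm_volume(out, voxel_spacing(vol), attr(vol, "kind"))
  out
}
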