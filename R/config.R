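#' Default run configuration
#'
#' Central registry of every tunable pipeline parameter with its default.
#' Thresholds: `alpha_voxel` is the uncorrected voxelwise p cutoff used to
#' threshold statistic maps before filtering; `min_cluster` the minimum
#' connected-component size in voxels; `connectivity` the 3D neighbourhood
#' (6, 18 or 26); `sym_tol` the bilateral-symmetry tolerance radius in
#' voxels; `alpha_fdr` the Benjamini-Hochberg FDR level for differential
#' expression (significant iff adjusted p strictly below it);
#' `min_basemean` the expression floor applied to both experiments;
#' `wt_threshold` the wildtype-peak fraction below which a crispant is
#' included; `min_jacobian` the fold-clamping floor for log-Jacobian maps;
#' `size_tolerance_bp` and `min_prominence` govern fragment-peak matching
#' and detection; `tag_offset_bp` is added to declared amplicon sizes to
#' get the detected product size (fluorescent primer tags: 18 bp forward +
#' 7 bp reverse).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed            = 1L,
    alpha_voxel     = 0.01,
    min_cluster     = 50L,
    connectivity    = 26L,
    sym_tol         = 2L,
    mask_direction  = "negative",
    alpha_fdr       = 0.1,
    min_basemean    = 100,
    wt_threshold    = 0.5,
    min_jacobian    = 1e-3,
    size_tolerance_bp = 2,
    min_prominence  = 0.05,
    tag_offset_bp   = 25,
    bootstrap_n     = 5000L,
    indir           = NULL,
    outdir          = NULL
  )
}

config_positive_keys <- function() {
  c("alpha_voxel", "min_cluster", "connectivity", "sym_tol", "alpha_fdr",
    "min_basemean", "wt_threshold", "min_jacobian", "size_tolerance_bp",
    "min_prominence", "tag_offset_bp", "bootstrap_n")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills unset keys from [default_config()], rejects
#' unknown keys, and requires every threshold to be strictly positive
#' (`sym_tol` may be zero: exact mirror matching). A provenance block
#' (seed, package version, config path) is attached as an attribute and is
#' propagated into all stage manifests.
#'
#' @param path YAML config file; `NULL` or an empty file yields defaults.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return Validated config list with attribute `provenance`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  for (k in config_positive_keys()) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config key '", k, "' must be a single strictly positive number, got ",
           deparse(v))
  }
  if (!is.numeric(cfg$sym_tol) || cfg$sym_tol < 0)
    stop("config key 'sym_tol' must be a non-negative number")
  if (cfg$alpha_voxel >= 1 || cfg$alpha_fdr >= 1)
    stop("alpha thresholds must lie in (0, 1)")
  if (!cfg$connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  if (!cfg$mask_direction %in% c("negative", "positive", "both"))
    stop("mask_direction must be 'negative', 'positive' or 'both'")
  cfg$seed <- as.integer(cfg$seed)
  attr(cfg, "provenance") <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("cerebmorph")),
    config_path = if (is.null(path)) NA_character_ else normalizePath(path),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  cfg
}

#' Read / write tab-separated result tables
#'
#' All tabular interchange (manifests, gene tables, peak tables, division
#' stats) uses TSV with a header row and no quoting or row names, so that
#' re-running a stage with the same config and seed reproduces the file
#' byte-identically.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv_table` returns a data frame; `write_tsv_table`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("no such table file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
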