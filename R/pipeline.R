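# Stage orchestration: each stage reads/writes files under a run
# directory and records a manifest (seed, parameters, input/output
# hashes) so any result file is attributable and re-runs are verifiably
# identical.

write_manifest <- function(outdir, stage, params, inputs, outputs, seed) {
  man <- list(stage = stage, seed = seed,
              params = params,
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])),
              package_version = as.character(utils::packageVersion("cerebmorph")))
  path <- file.path(outdir, paste0("manifest_", stage, ".yaml"))
  yaml::write_yaml(man, path)
  invisible(man)
}

#' Run one pipeline stage against a run directory
#'
#' Stages: `"simulate"` (atlas + discovery cohort written as NIfTI with a
#' TSV manifest of subjects), `"morph"` (LJD map per subject),
#' `"voxelstats"` (two-group t map over the cohort), `"filter"` (mask
#' from the t map), `"deg"` (synthetic DE tables + convergence summary),
#' `"fragqc"` (synthetic traces + efficiency report). Every stage writes
#' a YAML manifest with its seed, parameters and file hashes.
#'
#' @param name Stage name.
#' @param config A config list from [load_config()] / [default_config()].
#' @param outdir Run directory (created if missing).
#' @param ... Stage-specific overrides (e.g. `atlas` and `spec` for
#'   `"simulate"`).
#' @return The stage manifest, invisibly.
#' @export
run_stage <- function(name, config = default_config(), outdir, ...) {
  if (!name %in% c("simulate", "morph", "voxelstats", "filter",
                   "deg", "fragqc"))
    stop("unknown stage '", name, "'; usage: simulate | morph | ",
         "voxelstats | filter | deg | fragqc")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
         simulate = stage_simulate(config, outdir, ...),
         morph = stage_morph(config, outdir),
         voxelstats = stage_voxelstats(config, outdir),
         filter = stage_filter(config, outdir),
         deg = stage_deg(config, outdir),
         fragqc = stage_fragqc(config, outdir))
}

stage_simulate <- function(config, outdir, atlas = make_atlas(),
                           spec = cohort_spec(seed = config$seed)) {
  cohort <- make_cohort(atlas, spec)
  write_volume(atlas$labels, file.path(outdir, "atlas_labels.nii.gz"))
  write_volume(atlas$image, file.path(outdir, "atlas_image.nii.gz"))
  for (s in cohort$samples)
    write_volume(s$field,
                 file.path(outdir, paste0("field_", s$subject, ".nii.gz")))
  write_tsv_table(cohort$truth, file.path(outdir, "subjects.tsv"))
  outs <- c(file.path(outdir, c("atlas_labels.nii.gz", "atlas_image.nii.gz",
                                "subjects.tsv")),
            file.path(outdir, paste0("field_", cohort$truth$subject,
                                     ".nii.gz")))
  write_manifest(outdir, "simulate",
                 list(n_per_group = as.list(spec$n_per_group),
                      scale = spec$scale,
                      atrophy_region = spec$atrophy_region),
                 character(0), outs, config$seed)
}

stage_morph <- function(config, outdir) {
  truth <- read_tsv_table(file.path(outdir, "subjects.tsv"))
  ins <- file.path(outdir, paste0("field_", truth$subject, ".nii.gz"))
  outs <- file.path(outdir, paste0("ljd_", truth$subject, ".nii.gz"))
  for (i in seq_len(nrow(truth))) {
    fld <- read_volume(ins[i])
    J <- jacobian_determinant(fld)
    write_volume(log_jacobian(J, config$min_jacobian,
                              subject = truth$subject[i]), outs[i])
  }
  write_manifest(outdir, "morph", list(min_jacobian = config$min_jacobian),
                 ins, outs, config$seed)
}

stage_voxelstats <- function(config, outdir) {
  truth <- read_tsv_table(file.path(outdir, "subjects.tsv"))
  labels <- read_volume(file.path(outdir, "atlas_labels.nii.gz"))
  brain <- bare(labels) > 0
  maps <- lapply(file.path(outdir, paste0("ljd_", truth$subject, ".nii.gz")),
                 read_volume)
  ctl <- truth$genotype == "control"
  sm <- voxel_ttest(maps[ctl], maps[!ctl], brain = brain)
  outs <- file.path(outdir, c("tmap.nii.gz", "pmap.nii.gz",
                              "neglog10p.nii.gz", "mean_diff.nii.gz"))
  write_volume(sm$statistic, outs[1])
  write_volume(sm$p, outs[2])
  write_volume(neglog10_pmap(sm), outs[3])
  write_volume(sm$mean_diff, outs[4])
  write_manifest(outdir, "voxelstats", list(test = sm$test, df = sm$df),
                 file.path(outdir, paste0("ljd_", truth$subject, ".nii.gz")),
                 outs, config$seed)
}

stage_filter <- function(config, outdir) {
  p <- read_volume(file.path(outdir, "pmap.nii.gz"))
  md <- read_volume(file.path(outdir, "mean_diff.nii.gz"))
  sm <- list(p = p, mean_diff = md, test = "student_t")
  class(sm) <- "cm_stat_map"
  mask <- make_mask(sm, alpha = config$alpha_voxel,
                    min_cluster = config$min_cluster,
                    connectivity = config$connectivity,
                    sym_tol = config$sym_tol,
                    direction = config$mask_direction)
  out <- file.path(outdir, "mask.nii.gz")
  write_mask(mask, out, spacing = voxel_spacing(p))
  write_manifest(outdir, "filter", attr(mask, "provenance"),
                 file.path(outdir, c("pmap.nii.gz", "mean_diff.nii.gz")),
                 c(out, paste0(out, ".prov.yaml")), config$seed)
}

stage_deg <- function(config, outdir) {
  de <- make_de_tables(de_gen_spec(seed = config$seed))
  fa <- file.path(outdir, "de_table_a.tsv")
  fb <- file.path(outdir, "de_table_b.tsv")
  write_tsv_table(de$table_a, fa)
  write_tsv_table(de$table_b, fb)
  conv <- run_convergence(de$table_a, de$table_b,
                          min_basemean = config$min_basemean,
                          alpha = config$alpha_fdr)
  fs <- file.path(outdir, "convergence_summary.tsv")
  write_tsv_table(data.frame(N = conv$N, n_a = conv$n_a, n_b = conv$n_b,
                             k = conv$k, concordant = conv$concordant,
                             fisher_p = conv$fisher_p), fs)
  fo <- file.path(outdir, "convergence_overlap.tsv")
  write_tsv_table(conv$overlap_table, fo)
  write_manifest(outdir, "deg",
                 list(min_basemean = config$min_basemean,
                      alpha_fdr = config$alpha_fdr),
                 c(fa, fb), c(fs, fo), config$seed)
}

stage_fragqc <- function(config, outdir) {
  fr <- simulate_fragment_panel(seed = config$seed,
                                tag_offset = config$tag_offset_bp,
                                min_prominence = config$min_prominence,
                                size_tolerance = config$size_tolerance_bp)
  rep <- guide_efficiency_report(fr$results, threshold = config$wt_threshold)
  fg <- file.path(outdir, "fragqc_per_guide.tsv")
  fs <- file.path(outdir, "fragqc_per_subject.tsv")
  write_tsv_table(rep$per_guide, fg)
  write_tsv_table(rep$per_subject, fs)
  write_manifest(outdir, "fragqc",
                 list(wt_threshold = config$wt_threshold,
                      size_tolerance_bp = config$size_tolerance_bp),
                 character(0), c(fg, fs), config$seed)
}

#' Simulate a small CRISPRstat panel and quantify it
#'
#' Four guides of graded efficiency measured in three injected subjects
#' each (plus one uninjected control subject with pure wildtype product):
#' traces are generated, peak-called, and reduced to per-guide wildtype
#' fractions.
#'
#' @param seed RNG seed.
#' @param product_size_bp Declared amplicon size (tags excluded).
#' @param tag_offset Fluorescent-tag size offset added to the declared
#'   size (default 25 bp).
#' @param true_fracs Per-guide true wildtype fractions.
#' @param min_prominence,size_tolerance Peak-calling parameters.
#' @return List: `results` (subject, guide, wt_fraction, true_fraction).
#' @export
simulate_fragment_panel <- function(seed = 1L, product_size_bp = 200,
                                    tag_offset = 25,
                                    true_fracs = c(g1 = 0.15, g2 = 0.3,
                                                   g3 = 0.45, g4 = 0.85),
                                    min_prominence = 0.05,
                                    size_tolerance = 2) {
  expected <- product_size_bp + tag_offset
  rows <- list()
  k <- 0L
  for (g in names(true_fracs)) {
    for (s in 1:3) {
      k <- k + 1L
      tr <- make_trace(trace_gen_spec(wt_size_bp = expected,
                                      wt_frac = true_fracs[[g]],
                                      seed = seed + 100L * k))
      pk <- detect_peaks(tr, min_prominence)
      rows[[k]] <- data.frame(subject = sprintf("inj%02d", s + 10L *
                                                  match(g, names(true_fracs))),
                              guide = g,
                              wt_fraction = wildtype_fraction(pk, expected,
                                                              size_tolerance),
                              true_fraction = true_fracs[[g]])
    }
  }
  k <- k + 1L
  tr <- make_trace(trace_gen_spec(wt_size_bp = expected, wt_frac = 1,
                                  indel_offsets_bp = numeric(0),
                                  indel_rel_areas = numeric(0),
                                  seed = seed + 100L * k))
  pk <- detect_peaks(tr, min_prominence)
  rows[[k]] <- data.frame(subject = "uninj01", guide = "none",
                          wt_fraction = wildtype_fraction(pk, expected,
                                                          size_tolerance),
                          true_fraction = 1)
  list(results = do.call(rbind, rows))
}

#' End-to-end synthetic reproduction of the morphometry study logic
#'
#' Runs the whole discovery / validation / rescue design in memory on
#' synthetic data: (1) discovery cohort -> LJD maps -> voxel t map ->
#' filtered affected-region mask, scored by Dice against the implanted
#' truth region; (2) an independent validation cohort in which the
#' discovery mask's volume is compared between groups (t-test +
#' bootstrap CI) and the implanted volume ratio is recovered; (3) a
#' three-condition rescue cohort (control / crispant / rescued double
#' crispant) analysed by one-way ANOVA with post hoc t-tests; (4)
#' two-experiment DE tables analysed for sign-concordant convergence;
#' (5) a fragment-QC panel with inclusion calls.
#'
#' @param config Config list ([default_config()] / [load_config()]).
#' @param n_discovery,n_validation Named group sizes for the imaging
#'   cohorts.
#' @param n_rescue Named sizes for the three rescue conditions.
#' @param scale Implanted atrophy volume scale.
#' @param outdir Optional directory for TSV reports and manifests.
#' @return List of per-stage results: `mask` (NULL when no voxels
#'   survive the filter chain, with `mask_empty = TRUE`), `dice`,
#'   `p_summary` (fraction of brain voxels at or below the voxel
#'   threshold in the discovery map — near the threshold itself on
#'   effect-free data), `validation`, `rescue` (both NULL when the mask
#'   is empty), `convergence`, `fragqc`.
#' @export
run_all <- function(config = default_config(),
                    n_discovery = c(control = 14L, crispant = 17L),
                    n_validation = c(control = 14L, crispant = 17L),
                    n_rescue = c(control = 16L, crispant = 14L,
                                 double = 12L),
                    scale = 0.8,
                    outdir = NULL) {
  seed <- config$seed
  atlas <- make_atlas()
  brain <- bare(atlas$labels) > 0
  truth_mask <- truth_region_mask(atlas, "LCeP")

  ljd_maps <- function(cohort) lapply(cohort$samples, function(s)
    log_jacobian(jacobian_determinant(s$field), config$min_jacobian,
                 subject = s$subject))

  disc <- make_cohort(atlas, cohort_spec(n_per_group = n_discovery,
                                         batch = "exp1", scale = scale,
                                         seed = seed))
  maps_d <- ljd_maps(disc)
  ctl <- disc$truth$genotype == "control"
  sm <- voxel_ttest(maps_d[ctl], maps_d[!ctl], brain = brain)
  p_disc <- bare(sm$p)
  p_summary <- mean(p_disc[brain] <= config$alpha_voxel)
  mask <- tryCatch(
    make_mask(sm, alpha = config$alpha_voxel,
              min_cluster = config$min_cluster,
              connectivity = config$connectivity,
              sym_tol = config$sym_tol,
              direction = config$mask_direction),
    error = function(e) NULL)
  mask_empty <- is.null(mask)
  dice <- if (mask_empty) 0 else dice_coefficient(mask, truth_mask)

  vres <- NULL; ratio <- NA_real_; rescue <- NULL
  if (!mask_empty) {
    vali <- make_cohort(atlas, cohort_spec(n_per_group = n_validation,
                                           batch = "exp2", scale = scale,
                                           seed = seed + 20000L))
    maps_v <- ljd_maps(vali)
    pct <- vapply(seq_along(maps_v), function(i)
      mask_volume_pct(mask, cm_volume(exp(bare(maps_v[[i]])),
                                      voxel_spacing(maps_v[[i]]), "map"),
                      brain), numeric(1))
    vctl <- vali$truth$genotype == "control"
    vres <- group_volume_test(pct[vctl], pct[!vctl],
                              n_boot = config$bootstrap_n,
                              seed = seed + 30000L)
    ratio <- vres$mean_b / vres$mean_a

    resc <- make_cohort(atlas, cohort_spec(n_per_group = n_rescue,
                                           batch = "exp3", scale = scale,
                                           scale_double = 1,
                                           seed = seed + 40000L))
    maps_r <- ljd_maps(resc)
    pct_r <- vapply(seq_along(maps_r), function(i)
      mask_volume_pct(mask, cm_volume(exp(bare(maps_r[[i]])),
                                      voxel_spacing(maps_r[[i]]), "map"),
                      brain), numeric(1))
    by_cond <- split(pct_r, resc$truth$genotype)
    rescue <- three_group_anova(by_cond[c("control", "crispant", "double")])
  }

  de <- make_de_tables(de_gen_spec(seed = seed))
  conv <- run_convergence(de$table_a, de$table_b,
                          min_basemean = config$min_basemean,
                          alpha = config$alpha_fdr)

  frag <- simulate_fragment_panel(seed = seed,
                                  tag_offset = config$tag_offset_bp,
                                  min_prominence = config$min_prominence,
                                  size_tolerance = config$size_tolerance_bp)
  fq <- guide_efficiency_report(frag$results,
                                threshold = config$wt_threshold)

  out <- list(mask = mask, mask_empty = mask_empty, dice = dice,
              p_summary = p_summary,
              validation = c(vres, list(volume_ratio = ratio)),
              rescue = rescue, convergence = conv, fragqc = fq,
              seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!mask_empty)
      write_mask(mask, file.path(outdir, "mask.nii.gz"),
                 spacing = atlas$spec$spacing)
    write_tsv_table(data.frame(
      mask_empty = mask_empty, dice = dice,
      frac_p_below_alpha = p_summary,
      validation_p = if (mask_empty) NA else vres$p,
      volume_ratio = ratio,
      rescue_F = if (mask_empty) NA else rescue$F,
      rescue_p = if (mask_empty) NA else rescue$p,
      fisher_p = conv$fisher_p, n_included = fq$n_included),
      file.path(outdir, "summary.tsv"))
    write_manifest(outdir, "run_all",
                   list(alpha_voxel = config$alpha_voxel,
                        min_cluster = config$min_cluster,
                        sym_tol = config$sym_tol, scale = scale),
                   character(0),
                   file.path(outdir, c("mask.nii.gz", "summary.tsv")),
                   seed)
  }
  out
}
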