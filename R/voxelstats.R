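# Voxelwise and regional group statistics. Voxelwise operations are
# vectorized across the grid (subjects stacked as a matrix) and are exact
# matches of the corresponding scalar tests applied voxel by voxel.

stack_subject_maps <- function(maps) {
  d <- spatial_dim(maps[[1]])
  for (m in maps)
    if (!all(spatial_dim(m) == d)) stop("subject maps are on different grids")
  do.call(cbind, lapply(maps, function(m) as.vector(bare(m))))
}

new_stat_map <- function(statistic, p, df, test, spacing, extra = list()) {
  out <- c(list(statistic = cm_volume(statistic, spacing, "map"),
                p = cm_volume(p, spacing, "map"),
                df = df, test = test), extra)
  class(out) <- "cm_stat_map"
  out
}

#' @export
print.cm_stat_map <- function(x, ...) {
  cat(sprintf("<cm_stat_map %s df=%s voxels=%d>\n", x$test,
              paste(x$df, collapse = ","), length(x$p)))
  invisible(x)
}

#' Voxelwise two-group t-test
#'
#' Two-sided independent-samples t-test at every voxel across subjects,
#' pooled-variance (Student) by default with a Welch option. Voxels with
#' zero variance in both groups get p = 1 and are flagged; voxels outside
#' `brain` are NaN. The per-voxel mean difference (group B minus group A;
#' pass controls as A) is kept so masks can be restricted to a direction
#' of effect.
#'
#' @param maps_a,maps_b Lists of subject maps (LJD or channel volumes).
#' @param brain Optional logical array restricting the test.
#' @param var_equal Pooled variance (TRUE, default) or Welch.
#' @return A `cm_stat_map` with `statistic`, `p`, `mean_diff`, `df`,
#'   `flagged` (zero-variance voxel count).
#' @export
voxel_ttest <- function(maps_a, maps_b, brain = NULL, var_equal = TRUE) {
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("need at least 2 subjects per group")
  A <- stack_subject_maps(maps_a)
  B <- stack_subject_maps(maps_b)
  d <- spatial_dim(maps_a[[1]])
  sp <- voxel_spacing(maps_a[[1]])
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  diff <- mb - ma
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  flagged <- se == 0
  tstat <- diff / se
  tstat[flagged] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[flagged] <- 1
  p <- pmax(p, .Machine$double.xmin)
  dim(tstat) <- d; dim(p) <- d
  md <- diff; dim(md) <- d
  if (!is.null(brain)) {
    out_of_brain <- !as.logical(bare(brain))
    tstat[out_of_brain] <- NaN; p[out_of_brain] <- NaN; md[out_of_brain] <- NaN
  }
  new_stat_map(tstat, p, if (var_equal) na + nb - 2 else NA,
               if (var_equal) "student_t" else "welch_t", sp,
               list(mean_diff = cm_volume(md, sp, "map"),
                    flagged = sum(flagged)))
}

#' Voxelwise additive two-way ANOVA (genotype x batch)
#'
#' Fits the additive two-factor model (main effects of genotype and
#' experimental batch, no interaction) at every voxel and reports the
#' genotype main-effect F and p with batch controlled for (genotype
#' entered after batch; for the batch map the roles are swapped). All
#' voxels share the design, so the model is fit once by QR projection and
#' applied to the stacked subject matrix.
#'
#' @param maps List of subject maps.
#' @param genotype,batch Factors (or coercible), one entry per subject.
#' @param brain Optional logical array restricting the test.
#' @param interaction Add the genotype:batch interaction to the full
#'   model (the reported effects remain the main effects).
#' @return List with `genotype` and `batch` `cm_stat_map`s.
#' @export
voxel_anova2 <- function(maps, genotype, batch, brain = NULL,
                         interaction = FALSE) {
  genotype <- factor(genotype); batch <- factor(batch)
  if (nlevels(genotype) < 2L || nlevels(batch) < 2L)
    stop("need at least 2 genotypes and 2 batches")
  cells <- table(genotype, batch)
  if (any(cells == 0)) {
    i <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: genotype '", levels(genotype)[i[1]],
         "', batch '", levels(batch)[i[2]], "'")
  }
  Y <- t(stack_subject_maps(maps))   # subjects x voxels
  d <- spatial_dim(maps[[1]]); sp <- voxel_spacing(maps[[1]])
  dat <- data.frame(genotype, batch)
  rss <- function(form) {
    X <- stats::model.matrix(form, dat)
    q <- qr.Q(qr(X))
    list(rss = colSums(Y^2) - colSums((crossprod(q, Y))^2),
         rank = qr(X)$rank)
  }
  full <- rss(~ batch + genotype)
  n <- nrow(Y)
  df_err <- n - full$rank
  to_map <- function(rss_red, rss_full, df_eff, dfe) {
    Fv <- ((rss_red - rss_full) / df_eff) / (rss_full / dfe)
    Fv[!is.finite(Fv)] <- 0
    p <- stats::pf(Fv, df_eff, dfe, lower.tail = FALSE)
    p <- pmax(p, .Machine$double.xmin)
    Fm <- Fv; dim(Fm) <- d; pm <- p; dim(pm) <- d
    if (!is.null(brain)) {
      oob <- !as.logical(bare(brain))
      Fm[oob] <- NaN; pm[oob] <- NaN
    }
    new_stat_map(Fm, pm, c(df_eff, dfe), "anova2_F", sp)
  }
  out <- list(
    genotype = to_map(rss(~ batch)$rss, full$rss,
                      nlevels(genotype) - 1L, df_err),
    batch = to_map(rss(~ genotype)$rss, full$rss,
                   nlevels(batch) - 1L, df_err))
  if (interaction) {
    fint <- rss(~ batch + genotype + batch:genotype)
    df_int_err <- n - fint$rank
    out$interaction <- to_map(full$rss, fint$rss,
                              fint$rank - full$rank, df_int_err)
  }
  out
}

#' Minus-log10 transform of a p-value map
#' @param x A `cm_stat_map` or p-value `cm_volume`/array.
#' @return `cm_volume` map of -log10(p); NaN preserved.
#' @export
neglog10_pmap <- function(x) {
  p <- if (inherits(x, "cm_stat_map")) x$p else x
  sp <- if (inherits(p, "cm_volume")) voxel_spacing(p) else c(1, 1, 1)
  cm_volume(-log10(bare(p)), sp, "map")
}

#' Two-group comparison of regional volumes
#'
#' Two-sided independent-samples t-test on per-subject volume percentages
#' plus a seeded percentile-bootstrap confidence interval of the mean
#' difference (B minus A).
#'
#' @param volumes_a,volumes_b Numeric vectors (e.g. mask volume percent).
#' @param n_boot Bootstrap resamples (default 5000).
#' @param conf Confidence level.
#' @param seed RNG seed for the bootstrap.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return List: group means, `mean_diff`, `ci`, `t`, `df`, `p`.
#' @export
group_volume_test <- function(volumes_a, volumes_b, n_boot = 5000L,
                              conf = 0.95, seed = 1L, var_equal = TRUE) {
  if (length(volumes_a) < 2L || length(volumes_b) < 2L)
    stop("need at least 2 subjects per group")
  tt <- stats::t.test(volumes_b, volumes_a, var.equal = var_equal)
  set.seed(seed)
  boots <- replicate(n_boot,
    mean(sample(volumes_b, replace = TRUE)) -
    mean(sample(volumes_a, replace = TRUE)))
  ci <- unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  list(mean_a = mean(volumes_a), mean_b = mean(volumes_b),
       mean_diff = mean(volumes_b) - mean(volumes_a),
       ci = ci, conf = conf,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_boot = n_boot, seed = seed)
}

#' One-way ANOVA across three or more conditions with post hoc t-tests
#'
#' One-way fixed-effects ANOVA on regional volumes by condition (F with
#' k - 1 and N - k degrees of freedom), followed by unadjusted pairwise
#' two-sided Student t-tests between all condition pairs.
#'
#' @param volumes Named list of numeric vectors, one per condition (e.g.
#'   control, xrcc1, double).
#' @return List: `F`, `df`, `p`, `group_means`, `posthoc` (data frame of
#'   pairwise comparisons).
#' @export
three_group_anova <- function(volumes) {
  if (length(volumes) < 3L) stop("need at least 3 conditions")
  if (any(lengths(volumes) < 2L)) stop("need at least 2 subjects per condition")
  if (is.null(names(volumes)))
    names(volumes) <- paste0("g", seq_along(volumes))
  y <- unlist(volumes, use.names = FALSE)
  g <- factor(rep(names(volumes), lengths(volumes)), levels = names(volumes))
  fit <- stats::anova(stats::lm(y ~ g))
  pairs <- utils::combn(names(volumes), 2)
  posthoc <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    t = NA_real_, df = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    tt <- stats::t.test(volumes[[pairs[1, i]]], volumes[[pairs[2, i]]],
                        var.equal = TRUE)
    posthoc$t[i] <- unname(tt$statistic)
    posthoc$df[i] <- unname(tt$parameter)
    posthoc$p[i] <- tt$p.value
  }
  list(F = fit$`F value`[1], df = fit$Df, p = fit$`Pr(>F)`[1],
       group_means = vapply(volumes, mean, numeric(1)),
       posthoc = posthoc)
}
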