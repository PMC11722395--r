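# CRISPRstat-style fragment-analysis quantification: peak detection on
# capillary-electrophoresis traces, wildtype-peak area fraction, and the
# crispant inclusion rule (<50% wildtype product).

#' Specify a synthetic electropherogram
#'
#' A fragment-analysis trace as a sum of Gaussian peaks over product size
#' (bp) plus baseline Gaussian noise. The wildtype peak carries `wt_frac`
#' of the total area; the remaining area is split across the indel peaks
#' according to `indel_rel_areas` (which must sum to 1).
#'
#' @param wt_size_bp Detected wildtype product size (bp), i.e. declared
#'   amplicon size plus the fluorescent-tag offset.
#' @param wt_frac True wildtype area fraction in [0, 1].
#' @param indel_offsets_bp Indel peak positions relative to the wildtype
#'   size (bp). The default models two dominant indel products; note
#'   that every true peak must clear the detector's prominence floor
#'   (5 percent of the trace maximum by default) to be quantified.
#' @param indel_rel_areas Relative areas of the indel peaks (sum 1).
#' @param peak_width_bp Gaussian SD of each peak (bp).
#' @param noise_sd Baseline noise SD (signal units).
#' @param size_range_bp Trace extent around the peaks.
#' @param step_bp Sampling step of the size axis.
#' @param seed RNG seed.
#' @return A `trace_gen_spec` list.
#' @export
trace_gen_spec <- function(wt_size_bp = 225, wt_frac = 0.5,
                           indel_offsets_bp = c(-7, 7),
                           indel_rel_areas = c(0.5, 0.5),
                           peak_width_bp = 0.8, noise_sd = 5e-4,
                           size_range_bp = 40, step_bp = 0.1,
                           seed = 1L) {
  if (wt_frac < 0 || wt_frac > 1) stop("wt_frac must lie in [0, 1]")
  if (wt_size_bp <= 0 || peak_width_bp <= 0) stop("sizes must be positive")
  if (length(indel_offsets_bp) > 0 &&
      abs(sum(indel_rel_areas) - 1) > 1e-8)
    stop("indel relative areas must sum to 1")
  structure(list(wt_size_bp = wt_size_bp, wt_frac = wt_frac,
                 indel_offsets_bp = indel_offsets_bp,
                 indel_rel_areas = indel_rel_areas,
                 peak_width_bp = peak_width_bp, noise_sd = noise_sd,
                 size_range_bp = size_range_bp, step_bp = step_bp,
                 seed = as.integer(seed)),
            class = "trace_gen_spec")
}

#' Simulate a fragment-analysis trace
#'
#' @param spec A [trace_gen_spec()].
#' @return List: `trace` (data frame size_bp, signal), `truth`
#'   (wt_fraction, peak positions/areas), `crowded` (TRUE when any two
#'   peaks sit closer than one peak width — a warning flag, not an
#'   error).
#' @export
make_trace <- function(spec = trace_gen_spec()) {
  set.seed(spec$seed)
  total_area <- 1
  pos <- spec$wt_size_bp
  areas <- spec$wt_frac * total_area
  if (spec$wt_frac < 1 && length(spec$indel_offsets_bp) > 0) {
    pos <- c(pos, spec$wt_size_bp + spec$indel_offsets_bp)
    areas <- c(areas, (1 - spec$wt_frac) * spec$indel_rel_areas)
  }
  keep <- areas > 0
  pos <- pos[keep]; areas <- areas[keep]
  crowded <- FALSE
  if (length(pos) > 1) {
    dists <- abs(diff(sort(pos)))
    crowded <- any(dists < spec$peak_width_bp)
  }
  x <- seq(min(pos) - spec$size_range_bp, max(pos) + spec$size_range_bp,
           by = spec$step_bp)
  w <- spec$peak_width_bp
  signal <- numeric(length(x))
  for (i in seq_along(pos))
    signal <- signal +
      areas[i] / (w * sqrt(2 * pi)) * exp(-(x - pos[i])^2 / (2 * w^2))
  signal <- signal + stats::rnorm(length(x), sd = spec$noise_sd)
  list(trace = data.frame(size_bp = x, signal = signal),
       truth = list(wt_fraction = spec$wt_frac, positions = pos,
                    areas = areas),
       crowded = crowded)
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Detect peaks in a fragment trace
#'
#' Local maxima with topographic prominence of at least `min_prominence`
#' times the trace maximum. Each peak's area is the trapezoid integral of
#' the signal between its flanking minima (valley bottoms between
#' adjacent kept peaks, trace ends outside the outermost peaks). A flat
#' or all-noise trace yields an empty table, not an error.
#'
#' @param trace Data frame with columns `size_bp` (strictly increasing)
#'   and `signal`, or the list returned by [make_trace()].
#' @param min_prominence Fraction of the maximum signal (default 0.05).
#' @return Data frame: size_bp, height, area (one row per peak).
#' @export
detect_peaks <- function(trace, min_prominence = 0.05) {
  if (is.list(trace) && !is.data.frame(trace) && !is.null(trace$trace))
    trace <- trace$trace
  x <- trace$size_bp; y <- trace$signal
  n <- length(y)
  if (n < 10L) stop("trace needs at least 10 samples")
  if (any(diff(x) <= 0)) stop("size axis must be strictly increasing")
  if (any(!is.finite(y))) stop("non-finite signal in trace")
  empty <- data.frame(size_bp = numeric(0), height = numeric(0),
                      area = numeric(0))
  ymax <- max(y)
  if (ymax <= 0) return(empty)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- if (any(y[seq_len(i - 1)] > h)) {
      j <- max(which(y[seq_len(i - 1)] > h)); min(y[j:i])
    } else min(y[1:i])
    right <- if (any(y[(i + 1):n] > h)) {
      j <- i + min(which(y[(i + 1):n] > h)); min(y[i:j])
    } else min(y[i:n])
    h - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence * ymax]
  if (length(keep) == 0) return(empty)
  keep <- sort(keep)
  # integration boundaries: valley minima between adjacent peaks
  bounds <- c(1L, vapply(seq_len(length(keep) - 1), function(j) {
    seg <- keep[j]:keep[j + 1]
    seg[which.min(y[seg])]
  }, integer(1)), n)
  out <- data.frame(
    size_bp = x[keep],
    height = y[keep],
    area = vapply(seq_along(keep), function(j) {
      seg <- bounds[j]:bounds[j + 1]
      trapezoid_area(x[seg], y[seg])
    }, numeric(1)))
  # noise ripples can sneak past the prominence cut with ~zero net area;
  # they carry no product and are dropped
  out[out$area > 0, , drop = FALSE]
}

#' Wildtype-peak area fraction
#'
#' The fraction of total peak area carried by the peak nearest the
#' expected wildtype product size (within `size_tolerance`); 0 when no
#' peak lies within tolerance (the wildtype product is extinguished).
#' Remember that ABI-detected sizes include the fluorescent primer tags:
#' expected size = declared amplicon size + tag offset (default 25 bp).
#'
#' @param peaks Peak table (size_bp, height, area) — from
#'   [detect_peaks()] or reported directly by the instrument.
#' @param expected_size Expected detected wildtype size (bp).
#' @param size_tolerance Matching tolerance (bp, default 2).
#' @return Fraction in [0, 1].
#' @export
wildtype_fraction <- function(peaks, expected_size, size_tolerance = 2) {
  if (nrow(peaks) == 0) stop("empty peak table: no product detected")
  if (any(peaks$area <= 0)) stop("peak areas must be positive")
  dist <- abs(peaks$size_bp - expected_size)
  i <- which.min(dist)
  if (dist[i] > size_tolerance) return(0)
  peaks$area[i] / sum(peaks$area)
}

#' Crispant inclusion rule
#'
#' A subject is included for phenotype analysis iff at least one guide
#' RNA reduced the wildtype peak to strictly less than `threshold`
#' (default 50 percent) of the total PCR product.
#'
#' @param fractions Per-guide wildtype fractions for one subject.
#' @param threshold Inclusion cutoff (strict).
#' @return TRUE / FALSE.
#' @export
include_crispant <- function(fractions, threshold = 0.5) {
  if (length(fractions) == 0) stop("no guide measurements for subject")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  min(fractions) < threshold
}

#' Guide-efficiency report over a cohort
#'
#' @param results Data frame with columns `subject`, `guide`,
#'   `wt_fraction`.
#' @param threshold Inclusion cutoff.
#' @return List: `per_guide` (guide, n, mean/median wildtype fraction),
#'   `per_subject` (subject, min fraction, included), `n_included`.
#' @export
guide_efficiency_report <- function(results, threshold = 0.5) {
  need <- c("subject", "guide", "wt_fraction")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "))
  per_guide <- do.call(rbind, lapply(split(results, results$guide),
    function(g) data.frame(guide = g$guide[1], n = nrow(g),
                           mean_wt = mean(g$wt_fraction),
                           median_wt = stats::median(g$wt_fraction))))
  per_subject <- do.call(rbind, lapply(split(results, results$subject),
    function(s) data.frame(subject = s$subject[1],
                           min_wt = min(s$wt_fraction),
                           included = include_crispant(s$wt_fraction,
                                                       threshold))))
  rownames(per_guide) <- rownames(per_subject) <- NULL
  list(per_guide = per_guide, per_subject = per_subject,
       n_included = sum(per_subject$included))
}
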