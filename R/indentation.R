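#' Fit a stiffness to a force-displacement indentation record
#'
#' Ordinary least-squares line fit over the loading segment of an
#' indentation record; the slope is the measured stiffness in N/mm.  The
#' loading segment is the longest contiguous run of non-decreasing
#' displacement, and the intercept is left free to absorb the contact-onset
#' offset.
#'
#' @param displacement_mm Indenter displacement series, mm.
#' @param force_n Force series, N, same length.
#' @param min_samples Minimum number of loading samples required.
#' @return List: `k_measured` (N/mm), `intercept_n`, `residual_rms_n`,
#'   `n_used`.
#' @export
fit_stiffness <- function(displacement_mm, force_n, min_samples = 10) {
  if (length(displacement_mm) != length(force_n))
    stop("displacement and force series must have equal length")
  if (length(displacement_mm) < min_samples)
    stop("need at least ", min_samples, " samples")
  # longest contiguous non-decreasing run of displacement
  nd <- c(TRUE, diff(displacement_mm) >= 0)
  r <- rle(nd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a run of TRUEs at position i extends the preceding sample too
  best <- c(1L, 1L)
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    s <- max(1L, starts[j] - 1L)
    if (ends[j] - s > best[2] - best[1]) best <- c(s, ends[j])
  }
  idx <- best[1]:best[2]
  if (length(idx) < min_samples)
    stop("loading segment has fewer than ", min_samples, " samples")
  d <- displacement_mm[idx]
  f <- force_n[idx]
  if (diff(range(d)) <= 0)
    stop("zero displacement range in the loading segment; cannot fit a stiffness")
  fit <- stats::lm(f ~ d)
  list(k_measured = unname(stats::coef(fit)[2]),
       intercept_n = unname(stats::coef(fit)[1]),
       residual_rms_n = sqrt(mean(stats::residuals(fit)^2)),
       n_used = length(idx))
}

#' Correct a measured stiffness for instrument compliance
#'
#' The indenter and the tissue deflect as two springs in series, so the
#' measured slope underestimates the tissue stiffness.  Inverting the
#' series relation gives
#' `k_dorsum = k_measured * k_indenter / (k_indenter - k_measured)`; the
#' round trip `series_elastic(k_dorsum, k_indenter)` recovers `k_measured`.
#'
#' @param k_measured Measured stiffness, N/mm; must be below `k_indenter`.
#' @param k_indenter Instrument stiffness, N/mm (default 2.67, the
#'   calibrated normal-direction stiffness of the haptic-arm indenter).
#' @return Corrected tissue stiffness, N/mm (always above `k_measured`).
#' @export
correct_for_indenter <- function(k_measured, k_indenter = 2.67) {
  if (any(k_measured <= 0) || any(k_indenter <= 0))
    stop("stiffnesses must be > 0")
  if (any(k_measured >= k_indenter))
    stop("k_measured >= k_indenter: the measurement is saturated by ",
         "instrument compliance and cannot be corrected")
  k_measured * k_indenter / (k_indenter - k_measured)
}

#' Dorsum stiffness map
#'
#' Per-location, per-repetition stiffness estimates over the indentation
#' grid: five points along the 2nd metacarpal (`MC2`), five along the 3rd
#' (`MC3`, both `over_bone`) and five along the inter-metacarpal line
#' (`IM`, `inter_bone`).
#'
#' @param data Data frame with columns `location_id`, `repetition`,
#'   `k_measured` (N/mm) and optionally `grasp_force_n`.
#' @param k_indenter Instrument stiffness used for correction, N/mm.
#' @return A `stiffness_map` data frame with added `k_dorsum` and `region`
#'   columns.
#' @export
stiffness_map <- function(data, k_indenter = 2.67) {
  need <- c("location_id", "repetition", "k_measured")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if (any(data$k_measured <= 0))
    stop("k_measured must be > 0")
  data$k_dorsum <- correct_for_indenter(data$k_measured, k_indenter)
  data$region <- ifelse(grepl("^IM", data$location_id), "inter_bone",
                        "over_bone")
  attr(data, "k_indenter") <- k_indenter
  class(data) <- c("stiffness_map", class(data))
  data
}

#' Summarise a stiffness map by region
#'
#' Unweighted mean and sample standard deviation of the corrected stiffness
#' over all repetitions, overall and within the `over_bone` / `inter_bone`
#' regions, plus per-location means.
#'
#' @param map A [stiffness_map()].
#' @return List with `overall`, `by_region` and `by_location` data frames
#'   (columns `mean_n_mm`, `sd_n_mm`, `n`).
#' @export
summarize_map <- function(map) {
  stopifnot(inherits(map, "stiffness_map"))
  if (!nrow(map)) stop("empty stiffness map")
  smry <- function(x) data.frame(mean_n_mm = mean(x),
                                 sd_n_mm = stats::sd(x), n = length(x))
  by_region <- do.call(rbind, lapply(split(map$k_dorsum, map$region), smry))
  by_region$region <- rownames(by_region)
  rownames(by_region) <- NULL
  by_location <- do.call(rbind,
                         lapply(split(map$k_dorsum, map$location_id), smry))
  by_location$location_id <- rownames(by_location)
  rownames(by_location) <- NULL
  missing_reg <- setdiff(c("over_bone", "inter_bone"), by_region$region)
  if (length(missing_reg))
    warning("no measurements in region(s): ",
            paste(missing_reg, collapse = ", "))
  list(overall = smry(map$k_dorsum), by_region = by_region,
       by_location = by_location)
}

#' Default truth map for the synthetic indentation generator
#'
#' Fifteen locations (MC2_p1..p5, MC3_p1..p5, IM_p1..p5) with per-location
#' true stiffness drawn around region means of 1.1285 N/mm (over bone) and
#' 1.0060 N/mm (between bones), truncated to the plausible dorsum range
#' 0.54-1.59 N/mm.
#'
#' @param over_bone_mean,inter_bone_mean Regional mean stiffnesses, N/mm.
#' @param location_sd Between-location standard deviation, N/mm.
#' @param range_n_mm Truncation bounds, N/mm.
#' @param seed Integer seed for the location draw.
#' @return Data frame `(location_id, region, k_true)`.
#' @export
synthetic_truth_map <- function(over_bone_mean = 1.1285,
                                inter_bone_mean = 1.0060,
                                location_sd = 0.10,
                                range_n_mm = c(0.54, 1.59), seed = 1) {
  loc <- c(paste0("MC2_p", 1:5), paste0("MC3_p", 1:5), paste0("IM_p", 1:5))
  region <- rep(c("over_bone", "over_bone", "inter_bone"), each = 5)
  mu <- ifelse(region == "over_bone", over_bone_mean, inter_bone_mean)
  rng_state <- .save_seed()
  on.exit(.restore_seed(rng_state))
  set.seed(seed)
  k <- stats::rnorm(length(loc), mu, location_sd)
  k <- pmin(pmax(k, range_n_mm[1]), range_n_mm[2])
  data.frame(location_id = loc, region = region, k_true = k)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
  invisible(NULL)
}

#' Generate synthetic force-displacement indentation data
#'
#' Emulates the indentation protocol: for each location and repetition a
#' quasi-static loading ramp of `n_samples` displacement steps over
#' `depth_mm`, with the underlying measured slope equal to
#' `series_elastic(k_true, k_indenter)` (the instrument compliance is part
#' of the physics), independent Gaussian force noise of `noise_sd_n`, and
#' repetition-to-repetition jitter of the true stiffness (hand movement
#' between repeats).  Optionally the true stiffness increases with grasp
#' force.
#'
#' @param truth A truth map from [synthetic_truth_map()] (columns
#'   `location_id`, `k_true`), or `NULL` for the default.
#' @param n_reps Repetitions per location (default 5).
#' @param n_samples Samples per loading ramp (default 200).
#' @param depth_mm Indentation depth, mm (default 2).
#' @param noise_sd_n Force noise standard deviation, N (default 0.02).
#' @param rep_jitter_sd Repetition jitter of the true stiffness, N/mm
#'   (default 0.05).
#' @param grasp_force_n Grasp force level, N (default 0).
#' @param grasp_gain Stiffness increase per N of grasp force, N/mm per N
#'   (default 0.03).
#' @param k_indenter Instrument stiffness, N/mm.
#' @param seed Integer seed; required for reproducibility.
#' @return Data frame `(location_id, repetition, grasp_force_n,
#'   displacement_mm, force_n)` in long format, with the truth map attached
#'   as attribute `truth`.
#' @export
generate_synthetic_indentation <- function(truth = NULL, n_reps = 5,
                                           n_samples = 200, depth_mm = 2,
                                           noise_sd_n = 0.02,
                                           rep_jitter_sd = 0.05,
                                           grasp_force_n = 0,
                                           grasp_gain = 0.03,
                                           k_indenter = 2.67, seed) {
  if (missing(seed)) stop("a seed is required for the synthetic generator")
  if (is.null(truth)) truth <- synthetic_truth_map(seed = seed)
  if (any(truth$k_true <= 0)) stop("truth stiffnesses must be > 0")
  k_eff_truth <- truth$k_true + grasp_gain * grasp_force_n
  if (any(k_eff_truth >= k_indenter))
    stop("infeasible truth: k_true (plus grasp effect) must stay below ",
         "k_indenter = ", k_indenter, " N/mm")
  rng_state <- .save_seed()
  on.exit(.restore_seed(rng_state))
  set.seed(seed)
  d <- seq(0, depth_mm, length.out = n_samples)
  out <- vector("list", nrow(truth) * n_reps)
  i <- 0L
  for (r in seq_len(nrow(truth))) {
    for (rep_i in seq_len(n_reps)) {
      k_rep <- max(0.05, k_eff_truth[r] + stats::rnorm(1, 0, rep_jitter_sd))
      slope <- series_elastic(k_rep, k_indenter)
      f <- slope * d + stats::rnorm(n_samples, 0, noise_sd_n)
      i <- i + 1L
      out[[i]] <- data.frame(location_id = truth$location_id[r],
                             repetition = rep_i,
                             grasp_force_n = grasp_force_n,
                             displacement_mm = d, force_n = f)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- truth
  attr(res, "k_indenter") <- k_indenter
  res
}

#' Run the full indentation pipeline: fit, correct, summarise
#'
#' @param data Long-format indentation data as produced by
#'   [generate_synthetic_indentation()] or read from CSV.
#' @param k_indenter Instrument stiffness, N/mm.
#' @return List: `map` (a [stiffness_map()]), `summary`
#'   (from [summarize_map()]).
#' @export
analyze_indentation <- function(data, k_indenter = 2.67) {
  need <- c("location_id", "repetition", "displacement_mm", "force_n")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  keys <- unique(data[, c("location_id", "repetition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- data$location_id == keys$location_id[i] &
      data$repetition == keys$repetition[i]
    fit <- fit_stiffness(data$displacement_mm[sel], data$force_n[sel])
    data.frame(location_id = keys$location_id[i],
               repetition = keys$repetition[i],
               k_measured = fit$k_measured,
               residual_rms_n = fit$residual_rms_n)
  })
  map <- stiffness_map(do.call(rbind, rows), k_indenter = k_indenter)
  list(map = map, summary = summarize_map(map))
}
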