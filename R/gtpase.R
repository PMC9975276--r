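#' Absorbance trace from a coupled GTPase assay
#'
#' Container for one well of the regenerative NADH-coupled assay: pyruvate
#' kinase / lactate dehydrogenase regenerate GTP from GDP while oxidising
#' NADH 1:1, so the A340 decline rate reports the steady-state GTP hydrolysis
#' velocity at constant GTP.
#'
#' @param time Time, s; strictly increasing, at least 3 samples.
#' @param a340 Absorbance at 340 nm; non-negative.
#' @param protein_conc Total FtsZ concentration in the well, uM.
#' @param gtp_conc GTP concentration, uM.
#' @param label Optional label.
#' @return An object of class `absorbance_trace`.
#' @export
absorbance_trace <- function(time, a340, protein_conc, gtp_conc = NA_real_,
                             label = "") {
  if (length(time) < 3L)
    stop_ftsz("ftszdyn_insufficient_data",
              "an absorbance trace needs at least 3 samples")
  check_strictly_increasing(time)
  if (length(a340) != length(time))
    stop_ftsz("ftszdyn_invalid_argument", "time and a340 lengths differ")
  if (any(a340 < 0))
    stop_ftsz("ftszdyn_invalid_argument", "a340 must be >= 0")
  check_number(protein_conc, "protein_conc", nonneg = TRUE)
  structure(list(time = as.numeric(time), a340 = as.numeric(a340),
                 protein_conc = protein_conc, gtp_conc = gtp_conc,
                 label = label),
            class = "absorbance_trace")
}

#' @export
print.absorbance_trace <- function(x, ...) {
  cat(sprintf(
    "Absorbance trace '%s': %d samples over %g s, %g uM FtsZ, %s uM GTP\n",
    x$label, length(x$time), diff(range(x$time)), x$protein_conc,
    format(x$gtp_conc)))
  invisible(x)
}

#' Hydrolysis velocity from an absorbance trace
#'
#' Fits a least-squares line to A340 over the requested time window and
#' converts its slope to a GTP hydrolysis velocity via Beer-Lambert:
#' `v = max(0, -slope) * 60 / (epsilon * path) * 1e6` uM GTP min^-1
#' (NADH oxidation is 1:1 with GTP regenerated). Rising absorbance clamps to
#' zero velocity: the coupled assay cannot report negative hydrolysis.
#'
#' @param trace An [absorbance_trace()].
#' @param epsilon NADH extinction coefficient at 340 nm, M^-1 cm^-1
#'   (default 6220).
#' @param path Optical path length, cm (default 0.56, a 200 ul well).
#' @param window Time window `c(from, to)` in s; default the whole trace.
#'   Must lie within the trace and contain at least 3 points.
#' @return A one-row data frame with columns `protein_conc` (uM) and
#'   `velocity` (uM GTP min^-1) — a velocity point for [fit_kinetics()].
#' @examples
#' tr <- absorbance_trace(0:10, 0.9 - 0.001 * (0:10), protein_conc = 8)
#' velocity_from_trace(tr)
#' @export
velocity_from_trace <- function(trace, epsilon = 6220, path = 0.56,
                                window = NULL) {
  stopifnot(inherits(trace, "absorbance_trace"))
  check_number(epsilon, "epsilon", positive = TRUE)
  check_number(path, "path", positive = TRUE)
  if (is.null(window)) window <- range(trace$time)
  if (length(window) != 2L || window[1] >= window[2] ||
      window[1] < min(trace$time) || window[2] > max(trace$time))
    stop_ftsz("ftszdyn_invalid_argument",
              "`window` must be an increasing pair within the trace span")
  keep <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(keep) < 3L)
    stop_ftsz("ftszdyn_insufficient_data",
              "velocity window must contain at least 3 points")
  slope <- stats::coef(stats::lm(trace$a340[keep] ~ trace$time[keep]))[[2]]
  v <- max(0, -slope) * 60 / (epsilon * path) * 1e6
  # slopes at the level of floating-point residue on a flat trace are zero
  # velocity, not signal; snap them so that below-Cc wells report exactly 0
  if (v < 1e-9) v <- 0
  data.frame(protein_conc = trace$protein_conc, velocity = v)
}

#' Estimate GTPase activity and critical concentration
#'
#' Ordinary least-squares regression of hydrolysis velocity on FtsZ
#' concentration over the linear range (by default all points with velocity
#' above `min_velocity`, i.e. detectable activity). The slope is the GTPase
#' activity (GTP min^-1 FtsZ^-1); the extrapolated x-intercept is the
#' critical concentration Cc below which no polymerization — and hence no
#' hydrolysis — occurs. The Cc standard error is propagated from the
#' slope/intercept covariance by the delta method.
#'
#' @param points Data frame with columns `protein_conc` (uM) and `velocity`
#'   (uM GTP min^-1), e.g. rows from [velocity_from_trace()].
#' @param min_velocity Points with `velocity > min_velocity` enter the fit
#'   (default 0: points with zero activity are excluded).
#' @param conc_range Optional explicit concentration range `c(lo, hi)`
#'   restricting the points used, for assays where the linear range is chosen
#'   by eye.
#' @return An object of class `kinetic_fit` with elements `activity`,
#'   `activity_sd`, `cc`, `cc_sd`, `n_points`, `r_squared`, `linear_range`.
#' @examples
#' concs <- seq(4, 14, 2)
#' pts <- data.frame(protein_conc = concs, velocity = 0.59 * (concs - 2.12))
#' fit_kinetics(pts)
#' @export
fit_kinetics <- function(points, min_velocity = 0, conc_range = NULL) {
  if (!is.data.frame(points) ||
      !all(c("protein_conc", "velocity") %in% names(points)))
    stop_ftsz("ftszdyn_invalid_argument",
              "`points` needs columns protein_conc and velocity")
  use <- points$velocity > min_velocity
  if (!is.null(conc_range))
    use <- use & points$protein_conc >= conc_range[1] &
      points$protein_conc <= conc_range[2]
  pts <- points[use, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop_ftsz("ftszdyn_insufficient_data",
              "need at least 3 velocity points above min_velocity")
  fit <- stats::lm(velocity ~ protein_conc, data = pts)
  co <- stats::coef(fit)
  b <- co[[1]]; m <- co[[2]]
  if (m <= 0)
    stop_ftsz("ftszdyn_degenerate_fit",
              "nonpositive slope: no concentration-dependent activity")
  # covariance and R^2 computed directly (summary.lm warns on noiseless fits)
  res <- stats::residuals(fit)
  sigma2 <- sum(res^2) / stats::df.residual(fit)
  V <- sigma2 * solve(crossprod(stats::model.matrix(fit)))
  tss <- sum((pts$velocity - mean(pts$velocity))^2)
  # cc = -b/m; delta method over (b, m)
  cc <- -b / m
  cc_var <- V[1, 1] / m^2 + b^2 * V[2, 2] / m^4 - 2 * b * V[1, 2] / m^3
  structure(
    list(activity = m,
         activity_sd = sqrt(V[2, 2]),
         cc = cc,
         cc_sd = sqrt(max(cc_var, 0)),
         n_points = nrow(pts),
         r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
         linear_range = range(pts$protein_conc)),
    class = "kinetic_fit"
  )
}

#' GTPase kinetics of a coassembly mixture
#'
#' Identical regression to [fit_kinetics()], provided as a named entry point
#' to enforce the convention that for mixed-FtsZ reactions `protein_conc`
#' is the TOTAL FtsZ concentration (sum over components), which is how
#' mixture activities and critical concentrations are defined.
#'
#' @inheritParams fit_kinetics
#' @return A `kinetic_fit`; see [fit_kinetics()].
#' @export
mixture_activity <- function(points, min_velocity = 0, conc_range = NULL) {
  fit_kinetics(points, min_velocity = min_velocity, conc_range = conc_range)
}

#' Average replicate kinetic fits
#'
#' Replicate assays are fitted individually and then summarised as the mean
#' activity and Cc across fits with their between-fit standard deviations,
#' the convention used when reporting "average of n assays +/- SD".
#'
#' @param fits List of `kinetic_fit` objects.
#' @return A list with `activity`, `activity_sd`, `cc`, `cc_sd`, `n`.
#' @export
pool_kinetic_fits <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE,
                                           "kinetic_fit")))
  a <- vapply(fits, `[[`, 0, "activity")
  cc <- vapply(fits, `[[`, 0, "cc")
  list(activity = mean(a), activity_sd = stats::sd(a),
       cc = mean(cc), cc_sd = stats::sd(cc), n = length(fits))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("GTPase kinetic fit\n")
  cat(sprintf("  activity: %.4g +/- %.2g GTP min^-1 FtsZ^-1\n",
              x$activity, x$activity_sd))
  cat(sprintf("  critical concentration: %.4g +/- %.2g uM\n", x$cc, x$cc_sd))
  cat(sprintf("  n = %d points over %g-%g uM, R^2 = %.4f\n",
              x$n_points, x$linear_range[1], x$linear_range[2], x$r_squared))
  invisible(x)
}
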