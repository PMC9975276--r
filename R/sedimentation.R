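#' Pellet fraction from sedimentation densitometry
#'
#' Fraction of protein in the pellet after high-speed centrifugation,
#' `pellet / (pellet + supernatant)`, from SDS-PAGE band densities. The
#' fraction is scale-invariant: gel exposure cancels. When a total-lane
#' density is supplied, a QC warning fires if pellet + supernatant deviates
#' from it by more than 25%, flagging loading or quantification problems
#' (the total is never used in the fraction itself).
#'
#' @param density_pellet,density_supernatant Band densities, a.u. (>= 0, not
#'   both zero). Vectors are accepted and recycled as usual.
#' @param density_total Optional total-lane density for the QC check.
#' @return Pellet fraction(s) in \[0, 1\].
#' @examples
#' pellet_fraction(2, 6)  # 0.25
#' @export
pellet_fraction <- function(density_pellet, density_supernatant,
                            density_total = NULL) {
  if (any(density_pellet < 0) || any(density_supernatant < 0))
    stop_ftsz("ftszdyn_invalid_argument", "densities must be >= 0")
  denom <- density_pellet + density_supernatant
  if (any(denom == 0))
    stop_ftsz("ftszdyn_undefined_fraction",
              "pellet and supernatant densities are both zero")
  if (!is.null(density_total) && any(!is.na(density_total))) {
    ok <- is.na(density_total) | density_total <= 0 |
      abs(denom - density_total) / density_total <= 0.25
    if (!all(ok))
      warning(sprintf(
        "pellet + supernatant deviates from total by > 25%% in %d sample(s)",
        sum(!ok)), call. = FALSE)
  }
  density_pellet / denom
}

#' Compare pellet fractions between nucleotide conditions
#'
#' Computes per-replicate pellet fractions and tests the difference between
#' two conditions with a two-sided unpaired t test (pooled-variance Student
#' test by default; set `var_equal = FALSE` for Welch). Groups with zero
#' within-group variance are handled by an epsilon variance guard: identical
#' groups give t = 0, p = 1, and completely separated constant groups give a
#' vanishing p value instead of an error.
#'
#' @param samples Data frame with columns `nucleotide`,
#'   `density_supernatant`, `density_pellet` (and optionally
#'   `density_total`, `label`), e.g. from [make_sedimentation_samples()] or
#'   [read_sedimentation_csv()].
#' @param group_a,group_b Condition labels to compare (default GTP vs GDP).
#' @param var_equal Pooled-variance Student test (`TRUE`, default) or Welch.
#' @return An object of class `sedimentation_result`: `fractions_by_condition`
#'   (named list), per-condition `mean`, `sd` and `n`, `t_statistic`,
#'   `p_value`, `df`, `method`.
#' @examples
#' s <- make_sedimentation_samples(0.4, 0.1, n = 3, noise_sd = 0.02, seed = 1)
#' compare_conditions(s)
#' @export
compare_conditions <- function(samples, group_a = "GTP", group_b = "GDP",
                               var_equal = TRUE) {
  need <- c("nucleotide", "density_supernatant", "density_pellet")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop_ftsz("ftszdyn_invalid_argument",
              paste("`samples` needs columns", paste(need, collapse = ", ")))
  frac <- pellet_fraction(samples$density_pellet,
                          samples$density_supernatant,
                          samples$density_total)
  fa <- frac[samples$nucleotide == group_a]
  fb <- frac[samples$nucleotide == group_b]
  if (length(fa) < 2L || length(fb) < 2L)
    stop_ftsz("ftszdyn_insufficient_data",
              "need at least 2 replicates per condition")

  if (stats::var(fa) == 0 && stats::var(fb) == 0) {
    # degenerate: t.test refuses constant data; epsilon variance guard
    if (mean(fa) == mean(fb)) {
      tt <- list(statistic = c(t = 0), p.value = 1,
                 parameter = c(df = length(fa) + length(fb) - 2))
    } else {
      eps <- max(abs(c(fa, fb)), 1) * 1e-12
      se <- eps * sqrt(1 / length(fa) + 1 / length(fb))
      df <- length(fa) + length(fb) - 2
      tstat <- (mean(fa) - mean(fb)) / se
      tt <- list(statistic = c(t = tstat),
                 p.value = max(2 * stats::pt(-abs(tstat), df),
                               .Machine$double.xmin),
                 parameter = c(df = df))
    }
  } else {
    tt <- stats::t.test(fa, fb, var.equal = var_equal)
  }

  out <- list(
    fractions_by_condition = stats::setNames(list(fa, fb),
                                             c(group_a, group_b)),
    mean = c(mean(fa), mean(fb)),
    sd = c(stats::sd(fa), stats::sd(fb)),
    n = c(length(fa), length(fb)),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    method = if (var_equal) "two-sided unpaired Student t test" else
      "two-sided unpaired Welch t test")
  names(out$mean) <- names(out$sd) <- names(out$n) <- c(group_a, group_b)
  structure(out, class = "sedimentation_result")
}

#' @export
print.sedimentation_result <- function(x, ...) {
  cat("Sedimentation comparison (", x$method, ")\n", sep = "")
  g <- names(x$mean)
  for (i in 1:2)
    cat(sprintf("  %s: pellet fraction %.3f +/- %.3f (n = %d)\n",
                g[i], x$mean[i], x$sd[i], x$n[i]))
  cat(sprintf("  t = %.4g (df = %.4g), p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}
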