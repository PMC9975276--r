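#' Specify an assembly reaction
#'
#' Bundles the composition of an assembly reaction (one FtsZ or a coassembly
#' mixture), its starting GTP, and the kinetic parameters (GTPase activity
#' and critical concentration) applicable to that composition. For mixtures
#' the kinetics should come from [mixture_activity()] on total-concentration
#' points.
#'
#' @param components Named numeric vector of component concentrations, uM
#'   (e.g. `c(SeFtsZ = 8, AtFtsZ1 = 1.6)`).
#' @param gtp_conc Starting GTP concentration, uM.
#' @param kinetics A `kinetic_fit`, or any list with elements `activity`
#'   (GTP min^-1 FtsZ^-1, > 0) and `cc` (uM, >= 0).
#' @param label Optional reaction label, used for consistency checks when
#'   pairing predictions with light-scattering metrics.
#' @return An object of class `reaction_spec`.
#' @examples
#' reaction_spec(c(SeFtsZ = 14), gtp_conc = 50,
#'               kinetics = list(activity = 0.59, cc = 2.12))
#' @export
reaction_spec <- function(components, gtp_conc, kinetics, label = "") {
  if (!is.numeric(components) || length(components) < 1L ||
      any(components < 0))
    stop_ftsz("ftszdyn_invalid_argument",
              "`components` must be non-negative concentrations (uM)")
  check_number(gtp_conc, "gtp_conc", nonneg = TRUE)
  if (!is.list(kinetics) || is.null(kinetics$activity) ||
      is.null(kinetics$cc))
    stop_ftsz("ftszdyn_invalid_argument",
              "`kinetics` needs elements `activity` and `cc`")
  if (kinetics$cc < 0)
    stop_ftsz("ftszdyn_invalid_argument", "`kinetics$cc` must be >= 0")
  structure(list(components = components, gtp_conc = gtp_conc,
                 kinetics = kinetics, label = label),
            class = "reaction_spec")
}

#' Cc-adjusted protein concentration
#'
#' Only protein above the critical concentration polymerizes and hydrolyses
#' GTP, so depletion predictions use the adjusted concentration
#' `max(total - Cc, 0)` uM. The floor at zero keeps concentration series
#' computable; a reaction at or below Cc simply has no active protein.
#'
#' @param spec A [reaction_spec()].
#' @return Adjusted concentration, uM.
#' @examples
#' sp <- reaction_spec(c(SeFtsZ = 14), 50, list(activity = 0.59, cc = 2.12))
#' adjusted_concentration(sp)  # 11.88
#' @export
adjusted_concentration <- function(spec) {
  stopifnot(inherits(spec, "reaction_spec"))
  max(sum(spec$components) - spec$kinetics$cc, 0)
}

#' Predicted GTP depletion time
#'
#' Predicts when the nucleotide pool is exhausted:
#' `time (s) = GTP / (adjusted_conc * activity) * 60`,
#' with the adjusted concentration from [adjusted_concentration()] and
#' activity in GTP min^-1 FtsZ^-1. The reported time is truncated to whole
#' seconds by default (the raw value is retained); set
#' `rounding = "round"` or `"none"` to change the reporting convention.
#'
#' @param spec A [reaction_spec()].
#' @param rounding Reporting convention for `depletion_time`: `"floor"`
#'   (default), `"round"`, or `"none"` (raw seconds).
#' @return An object of class `depletion_prediction` with elements
#'   `total_conc`, `adjusted_conc`, `depletion_time` (s, per `rounding`),
#'   `depletion_time_raw` (s), `defined`.
#' @examples
#' k <- list(activity = 0.59, cc = 2.12)
#' depletion_time(reaction_spec(c(SeFtsZ = 14), 50, k))$depletion_time  # 428
#' depletion_time(reaction_spec(c(SeFtsZ = 4), 50, k))$depletion_time  # 2704
#' @export
depletion_time <- function(spec, rounding = c("floor", "round", "none")) {
  stopifnot(inherits(spec, "reaction_spec"))
  rounding <- match.arg(rounding)
  if (spec$kinetics$activity <= 0)
    stop_ftsz("ftszdyn_invalid_kinetics",
              "GTPase activity must be > 0 to predict depletion")
  adj <- adjusted_concentration(spec)
  if (adj <= 0)
    stop_ftsz("ftszdyn_undefined_prediction",
              "no protein above Cc: no polymerization, no hydrolysis")
  raw <- if (spec$gtp_conc == 0) 0
  else spec$gtp_conc / (adj * spec$kinetics$activity) * 60
  rep_time <- switch(rounding,
                     floor = floor(raw),
                     round = round(raw),
                     none = raw)
  structure(list(total_conc = sum(spec$components),
                 adjusted_conc = adj,
                 depletion_time = rep_time,
                 depletion_time_raw = raw,
                 defined = spec$gtp_conc > 0,
                 label = spec$label),
            class = "depletion_prediction")
}

#' @export
print.depletion_prediction <- function(x, ...) {
  cat("GTP depletion prediction\n")
  cat(sprintf("  total FtsZ: %g uM, adjusted (above Cc): %g uM\n",
              x$total_conc, x$adjusted_conc))
  cat(sprintf("  predicted depletion: %g s%s\n", x$depletion_time,
              if (!x$defined) " (no GTP present)" else ""))
  invisible(x)
}

#' Depletion predictions for a table of reactions
#'
#' Convenience batch wrapper: one prediction per row. Rows at or below the
#' critical concentration get `NA` depletion times rather than an error.
#'
#' @param table Data frame with columns `total_conc`, `gtp_conc`,
#'   `activity`, `cc` (and optionally `label`).
#' @param rounding Passed to [depletion_time()].
#' @return The input with columns `adjusted_conc` and `depletion_time`
#'   appended.
#' @export
depletion_table <- function(table, rounding = "floor") {
  need <- c("total_conc", "gtp_conc", "activity", "cc")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_ftsz("ftszdyn_invalid_argument",
              paste("`table` needs columns", paste(need, collapse = ", ")))
  out <- table
  out$adjusted_conc <- pmax(table$total_conc - table$cc, 0)
  out$depletion_time <- NA_real_
  for (i in seq_len(nrow(table))) {
    if (out$adjusted_conc[i] <= 0) next
    sp <- reaction_spec(c(total = table$total_conc[i]), table$gtp_conc[i],
                        list(activity = table$activity[i], cc = table$cc[i]))
    out$depletion_time[i] <- depletion_time(sp, rounding)$depletion_time
  }
  out
}
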