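# CSV I/O for every trace kind. Metadata travel as leading comment lines of
# the form "# key=value" so each file is self-describing yet remains a plain
# two-to-four-column CSV readable by any tool.

write_with_meta <- function(path, meta, df) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    if (!is.null(meta[[k]]) && !is.na(meta[[k]]))
      writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 15)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) out[[trimws(kv[1])]] <- trimws(kv[2])
  }
  out
}

meta_num <- function(meta, key, default = NA_real_) {
  if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
}

#' Read and write GTPase absorbance traces
#'
#' Columns `time_s`, `a340`; metadata (`protein_conc_uM`, `gtp_conc_uM`,
#' `label`) as leading `# key=value` comment lines.
#'
#' @param trace An [absorbance_trace()].
#' @param path File path.
#' @return `read_gtpase_csv()` returns an `absorbance_trace`;
#'   `write_gtpase_csv()` returns `path` invisibly.
#' @export
write_gtpase_csv <- function(trace, path) {
  stopifnot(inherits(trace, "absorbance_trace"))
  write_with_meta(path, list(protein_conc_uM = trace$protein_conc,
                             gtp_conc_uM = trace$gtp_conc,
                             label = trace$label),
                  data.frame(time_s = trace$time, a340 = trace$a340))
}

#' @rdname write_gtpase_csv
#' @export
read_gtpase_csv <- function(path) {
  meta <- read_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  absorbance_trace(df$time_s, df$a340,
                   protein_conc = meta_num(meta, "protein_conc_uM"),
                   gtp_conc = meta_num(meta, "gtp_conc_uM"),
                   label = meta$label %||% "")
}

#' Read and write light-scattering traces
#'
#' Columns `time_s`, `intensity`; metadata (`nucleotide`, `t_add_s`,
#' `onset_truth_s`, `label`) as leading comment lines.
#'
#' @param trace An [ls_trace()].
#' @param path File path.
#' @return `read_ls_csv()` returns an `ls_trace`; `write_ls_csv()` returns
#'   `path` invisibly.
#' @export
write_ls_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ls_trace"))
  write_with_meta(path, list(nucleotide = trace$nucleotide,
                             t_add_s = trace$meta$t_add,
                             onset_truth_s = trace$meta$onset_truth,
                             label = trace$meta$label),
                  data.frame(time_s = trace$time,
                             intensity = trace$intensity))
}

#' @rdname write_ls_csv
#' @export
read_ls_csv <- function(path) {
  meta <- read_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  m <- list()
  if (!is.null(meta$t_add_s)) m$t_add <- as.numeric(meta$t_add_s)
  if (!is.null(meta$onset_truth_s))
    m$onset_truth <- as.numeric(meta$onset_truth_s)
  if (!is.null(meta$label)) m$label <- meta$label
  ls_trace(df$time_s, df$intensity,
           nucleotide = meta$nucleotide %||% "GTP", meta = m)
}

#' Read and write FRAP traces
#'
#' Columns `time_s`, `bleach`, `reference`, `background`; the prebleach
#' frame count as a leading comment line.
#'
#' @param trace A [frap_trace()].
#' @param path File path.
#' @return `read_frap_csv()` returns a `frap_trace`; `write_frap_csv()`
#'   returns `path` invisibly.
#' @export
write_frap_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  write_with_meta(path, list(n_prebleach = trace$n_prebleach),
                  data.frame(time_s = trace$time, bleach = trace$bleach,
                             reference = trace$reference,
                             background = trace$background))
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  meta <- read_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  frap_trace(df$time_s, df$bleach, df$reference, df$background,
             n_prebleach = as.integer(meta_num(meta, "n_prebleach", 1)))
}

#' Read and write sedimentation densitometry tables
#'
#' Plain CSV with columns `label`, `nucleotide`, `density_total`,
#' `density_supernatant`, `density_pellet`.
#'
#' @param samples Data frame of samples.
#' @param path File path.
#' @return `read_sedimentation_csv()` returns the data frame;
#'   `write_sedimentation_csv()` returns `path` invisibly.
#' @export
write_sedimentation_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sedimentation_csv
#' @export
read_sedimentation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("nucleotide", "density_supernatant", "density_pellet")
  if (!all(need %in% names(df)))
    stop_ftsz("ftszdyn_invalid_argument",
              paste("file needs columns", paste(need, collapse = ", ")))
  df
}
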