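#' Read a beat table from delimited text
#'
#' Reads per-beat (or per-subject) noninvasive measurements from a CSV (or
#' other delimited) file with the canonical header `id, pep_ms, et_ms,
#' sbp_mmhg, dbp_mmhg` and optionally `ef_echo_percent`. Unknown columns
#' are preserved and passed through. Unit conventions are fixed by the
#' column-name suffixes: milliseconds for the intervals, mmHg for the
#' pressures, percent for the echo ejection fraction.
#'
#' Row-level problems (inverted pressures, non-positive or out-of-range
#' intervals) do not abort the read: they are collected, reported as a
#' warning, and attached as the `"problems"` attribute so downstream code
#' can flag the affected rows.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) lets the reader sniff it.
#' @param pep_range,et_range Plausibility ranges (ms) used for warnings
#'   only; widen them to accept unusual cohorts.
#' @return A tibble of beats; attribute `"problems"` holds a tibble of
#'   row-level validation messages (zero rows when clean).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines("id,pep_ms,et_ms,sbp_mmhg,dbp_mmhg\nA,97,303,119,72", path)
#' read_beat_table(path)
#' @export
read_beat_table <- function(path, delim = NULL,
                            pep_range = c(20, 400),
                            et_range = c(100, 600)) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "efcoupling_io_error")
  }
  tab <- tryCatch(
    if (is.null(delim)) {
      readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
    } else {
      readr::read_delim(path, delim = delim, show_col_types = FALSE,
                        progress = FALSE)
    },
    error = function(e) {
      abort(paste0("Could not parse ", path, ": ", conditionMessage(e)),
            class = "efcoupling_schema_error")
    }
  )
  if (nrow(tab) == 0L) {
    abort(paste0("Empty beat table: ", path),
          class = "efcoupling_schema_error")
  }
  required <- c("id", "pep_ms", "et_ms", "sbp_mmhg", "dbp_mmhg")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(
      paste0("Beat table is missing required column(s): ",
             paste(missing, collapse = ", "),
             ". Expected header: id, pep_ms, et_ms, sbp_mmhg, dbp_mmhg",
             " [, ef_echo_percent]."),
      class = "efcoupling_schema_error"
    )
  }
  tab$id <- as.character(tab$id)

  problems <- validate_beat_rows(tab, pep_range, et_range)
  if (nrow(problems)) {
    warn(sprintf("%d row-level validation problem(s); see attr(x, \"problems\").",
                 nrow(problems)))
  }
  attr(tab, "problems") <- problems
  tab
}

validate_beat_rows <- function(tab, pep_range, et_range) {
  msgs <- purrr::pmap(
    list(seq_len(nrow(tab)), tab$pep_ms, tab$et_ms, tab$sbp_mmhg, tab$dbp_mmhg),
    function(row, pep, et, sbp, dbp) {
      m <- character()
      if (!is.finite(pep) || pep <= 0) m <- c(m, "pep_ms must be positive")
      if (!is.finite(et) || et <= 0) m <- c(m, "et_ms must be positive")
      if (!is.finite(sbp) || !is.finite(dbp) || dbp <= 0 || sbp <= dbp) {
        m <- c(m, "need sbp_mmhg > dbp_mmhg > 0")
      }
      if (is.finite(pep) && pep > 0 &&
          (pep < pep_range[1] || pep > pep_range[2])) {
        m <- c(m, sprintf("pep_ms outside plausible range [%g, %g]",
                          pep_range[1], pep_range[2]))
      }
      if (is.finite(et) && et > 0 &&
          (et < et_range[1] || et > et_range[2])) {
        m <- c(m, sprintf("et_ms outside plausible range [%g, %g]",
                          et_range[1], et_range[2]))
      }
      if (length(m)) tibble(row = row, message = m) else NULL
    }
  )
  dplyr::bind_rows(msgs) %||% tibble(row = integer(), message = character())
}

#' Write an ejection-fraction result table
#'
#' Serialises the output of [estimate_ef()] to CSV with percentages at the
#' file boundary (`eff_percent`, `ef_eff_percent`) while the in-memory
#' representation stays in fractions. Numeric columns are rounded to
#' `digits` significant digits.
#'
#' @param results An `ef_estimates` tibble from [estimate_ef()].
#' @param path Output file path.
#' @param digits Significant digits written (default 6).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path, digits = 6) {
  out <- tibble(
    id = results$id,
    pes_mmhg = signif(results$pes_mmhg, digits),
    ees_over_ea = signif(results$ees_over_ea, digits),
    k = signif(results$k, digits),
    pmax_mmhg = signif(results$pmax_mmhg, digits),
    eff_percent = signif(100 * results$eff, digits),
    ef_eff_percent = signif(100 * results$ef_eff, digits),
    converged = results$converged,
    warnings = dplyr::coalesce(results$warnings, ""),
    error = dplyr::coalesce(results$error, "")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Run the estimation pipeline on a beat file
#'
#' Reads a beat table, runs [estimate_ef()] on every row, writes the result
#' table, and — when the input carries an `ef_echo_percent` column — also
#' writes a Bland-Altman agreement report (JSON) comparing the echo
#' reference with the estimated ejection fraction. Failed rows are written
#' flagged, never dropped. Progress and row counts go to standard error;
#' results only to the output files.
#'
#' @param input Path to the beat CSV (see [read_beat_table()]).
#' @param output Path for the result CSV.
#' @param agreement_output Path for the agreement JSON; default replaces
#'   the output extension with `_agreement.json`. Only written when the
#'   input has `ef_echo_percent`.
#' @inheritParams estimate_ef
#' @param loa_multiplier Limits-of-agreement multiplier (default 2).
#' @param quiet Suppress the log lines on standard error.
#' @return Invisibly, a list with `results` (the tibble), `agreement`
#'   (an `agreement_report` or `NULL`) and `summary` (row counts).
#' @export
run_compute <- function(input, output,
                        constants = coupling_constants(),
                        settings = solver_settings(),
                        loa_multiplier = 2,
                        agreement_output = NULL,
                        quiet = FALSE) {
  dir_ok <- dir.exists(dirname(output))
  if (!dir_ok) {
    abort(paste0("Output directory does not exist: ", dirname(output)),
          class = "efcoupling_io_error")
  }
  log_msg <- function(level, ...) {
    if (!quiet) message(sprintf("[%s] %s", level, sprintf(...)))
  }

  beats <- read_beat_table(input)
  log_msg("info", "read %d beats from %s", nrow(beats), input)

  results <- estimate_ef(beats, constants = constants, settings = settings)
  n_fail <- sum(!is.na(results$error))
  n_warn <- sum(nzchar(results$warnings), na.rm = TRUE)
  log_msg("info", "%d converged, %d warned, %d failed",
          sum(results$converged, na.rm = TRUE), n_warn, n_fail)
  if (n_fail > 0) log_msg("error", "%d row(s) failed; see error column", n_fail)

  write_result_table(results, output)

  agreement <- NULL
  if ("ef_echo_percent" %in% names(beats)) {
    ok <- results$converged & !is.na(results$ef_eff) &
      !is.na(beats$ef_echo_percent)
    paired <- tibble(
      ef_echo_percent = beats$ef_echo_percent[ok],
      ef_eff_percent = 100 * results$ef_eff[ok]
    )
    if (nrow(paired) >= 3) {
      agreement <- bland_altman(paired, "ef_echo_percent", "ef_eff_percent",
                                multiplier = loa_multiplier)
      apath <- agreement_output %||%
        paste0(sub("\\.[A-Za-z]+$", "", output), "_agreement.json")
      write_agreement_report(agreement, apath)
      log_msg("info", "agreement report written to %s", apath)
    } else {
      log_msg("warn", "fewer than 3 usable pairs; agreement report skipped")
    }
  }

  invisible(list(
    results = results,
    agreement = agreement,
    summary = list(n = nrow(results),
                   n_converged = sum(results$converged, na.rm = TRUE),
                   n_warned = n_warn, n_failed = n_fail)
  ))
}

#' Serialise an agreement report to JSON
#'
#' @param report An `agreement_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  payload <- as.list(glance(report))
  payload$notes <- report$notes
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Writes the beat table (`beats.csv`, in the [read_beat_table()] schema
#' with `ef_echo_percent`) and the full ground-truth table (`truth.csv`)
#' for a cohort from [sample_cohort()].
#'
#' @param cohort A `subject_truth` tibble.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  beats <- tibble(
    id = cohort$id,
    pep_ms = cohort$pep_ms, et_ms = cohort$et_ms,
    sbp_mmhg = cohort$sbp_mmhg, dbp_mmhg = cohort$dbp_mmhg,
    ef_echo_percent = 100 * cohort$ef_echo_observed
  )
  beats_path <- file.path(dir, "beats.csv")
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(beats, beats_path, progress = FALSE)
  readr::write_csv(as_tibble(cohort), truth_path, progress = FALSE)
  invisible(c(beats = beats_path, truth = truth_path))
}

#' Histogram of estimated ejection fractions
#'
#' @param object An `ef_estimates` tibble from [estimate_ef()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ef_estimates
#' @export
autoplot.ef_estimates <- function(object, ...) {
  ok <- object[object$converged & is.na(object$error), , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = 100 * .data$ef_eff)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "Estimated EF (%)", y = "Beats") +
    ggplot2::theme_minimal()
}
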