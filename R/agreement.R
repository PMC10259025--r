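#' Bland-Altman agreement between a reference and a test method
#'
#' Method-comparison statistics for paired measurements: bias (mean of
#' reference minus test), sample SD of the differences, limits of agreement
#' `bias +/- multiplier * sd`, percentage error
#' `PE = 100 * 2 * sd / mean(reference)` with the conventional <= 30%
#' acceptability rule, and Pearson correlation with its square.
#'
#' The difference is oriented reference minus test, so a test method that
#' reads low yields a positive bias. The limits-of-agreement multiplier
#' defaults to 2; set `multiplier = 1.96` for the exact normal quantile
#' (the two differ by `0.04 * sd_diff`).
#'
#' @param data A data frame holding both series.
#' @param reference,test Columns of `data` (tidy-eval) holding the reference
#'   and test measurements, same unit (percent or fraction — the percentage
#'   error is invariant to a common rescaling). No missing values; at least
#'   3 pairs.
#' @param multiplier Limits-of-agreement multiplier (default 2).
#' @return An object of class `agreement_report`; see [tidy.agreement_report()],
#'   [glance.agreement_report()] and [autoplot.agreement_report()].
#' @examples
#' d <- tibble::tibble(echo = c(60, 65, 70, 68), est = c(55, 58, 61, 66))
#' bland_altman(d, echo, est)
#' @export
bland_altman <- function(data, reference, test, multiplier = 2) {
  ref <- dplyr::pull(data, {{ reference }})
  tst <- dplyr::pull(data, {{ test }})
  if (length(ref) != length(tst)) {
    abort("`reference` and `test` must have the same length.",
          class = "efcoupling_invalid_input")
  }
  if (anyNA(ref) || anyNA(tst)) {
    abort("Missing values in the paired series; drop or impute before pairing.",
          class = "efcoupling_invalid_input")
  }
  n <- length(ref)
  if (n < 3) {
    abort("At least 3 pairs are required.",
          class = "efcoupling_insufficient_data")
  }
  diffs <- ref - tst
  bias <- mean(diffs)
  sd_diff <- sd(diffs)
  mean_ref <- mean(ref)
  if (mean_ref <= 0) {
    abort("Percentage error needs mean(reference) > 0.",
          class = "efcoupling_invalid_input")
  }

  notes <- character()
  if (sd(ref) == 0 || sd(tst) == 0) {
    r <- NA_real_
    notes <- c(notes, "correlation undefined: zero variance in a series")
  } else {
    r <- cor(ref, tst)
  }

  new_agreement_report(
    n = n, bias = bias, sd_diff = sd_diff, multiplier = multiplier,
    mean_reference = mean_ref, r = r, notes = notes,
    data = tibble(reference = ref, test = tst,
                  mean = (ref + tst) / 2, difference = diffs)
  )
}

#' Agreement report from printed summary statistics
#'
#' Reconstructs limits of agreement and percentage error from the three
#' summaries an agreement study typically prints — bias, SD of the
#' differences, and the reference-method mean — when the subject-level
#' pairs themselves are unavailable. Correlation cannot be recovered from
#' summaries and is reported as missing.
#'
#' @param bias Mean difference (reference - test).
#' @param sd_diff SD of the differences (>= 0).
#' @param mean_reference Mean of the reference series (> 0).
#' @inheritParams bland_altman
#' @return A partial `agreement_report` (no subject-level data, `r` = NA).
#' @examples
#' summary_agreement(bias = 8.5, sd_diff = 8.0, mean_reference = 66)
#' @export
summary_agreement <- function(bias, sd_diff, mean_reference, multiplier = 2) {
  if (!is.finite(sd_diff) || sd_diff < 0) {
    abort("`sd_diff` must be non-negative.",
          class = "efcoupling_invalid_input")
  }
  if (!is.finite(mean_reference) || mean_reference <= 0) {
    abort("`mean_reference` must be positive.",
          class = "efcoupling_invalid_input")
  }
  new_agreement_report(
    n = NA_integer_, bias = bias, sd_diff = sd_diff, multiplier = multiplier,
    mean_reference = mean_reference, r = NA_real_,
    notes = "built from summary statistics; correlation unavailable",
    data = NULL
  )
}

new_agreement_report <- function(n, bias, sd_diff, multiplier,
                                 mean_reference, r, notes, data) {
  structure(
    list(
      n = n,
      bias = bias,
      sd_diff = sd_diff,
      loa_low = bias - multiplier * sd_diff,
      loa_high = bias + multiplier * sd_diff,
      multiplier = multiplier,
      pe = 100 * 2 * sd_diff / mean_reference,
      mean_reference = mean_reference,
      r = r,
      r2 = r^2,
      acceptable = (100 * 2 * sd_diff / mean_reference) <= 30,
      notes = notes,
      data = data
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Bland-Altman agreement report",
      if (!is.na(x$n)) sprintf("(n = %d)", x$n) else "(summary-level)", "\n")
  cat(sprintf("  bias (reference - test): %.3f\n", x$bias))
  cat(sprintf("  SD of differences:       %.3f\n", x$sd_diff))
  cat(sprintf("  limits of agreement:     [%.3f, %.3f]  (bias +/- %g SD)\n",
              x$loa_low, x$loa_high, x$multiplier))
  cat(sprintf("  percentage error:        %.1f%%  (%s, 30%% rule)\n",
              x$pe, if (x$acceptable) "acceptable" else "not acceptable"))
  if (!is.na(x$r)) {
    cat(sprintf("  Pearson r = %.3f (R^2 = %.3f)\n", x$r, x$r2))
  }
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return `tidy()`: a two-column tibble of statistic names and values.
#'   `glance()`: the same content as a one-row tibble.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  tibble(
    statistic = c("n", "bias", "sd_diff", "loa_low", "loa_high",
                  "multiplier", "pe", "r", "r2", "acceptable"),
    value = c(x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high,
              x$multiplier, x$pe, x$r, x$r2, as.numeric(x$acceptable))
  )
}

#' @rdname tidy.agreement_report
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    n = x$n, bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    multiplier = x$multiplier, pe = x$pe,
    r = x$r, r2 = x$r2, acceptable = x$acceptable
  )
}

#' Bland-Altman plot
#'
#' Mean-difference plot of the paired data with the bias (solid) and the
#' limits of agreement (dotted) drawn as horizontal lines.
#'
#' @param object An `agreement_report` built from subject-level data.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  if (is.null(object$data)) {
    abort("This report was built from summaries; there are no pairs to plot.",
          class = "efcoupling_invalid_input")
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted") +
    ggplot2::labs(
      x = "Mean of methods", y = "Reference - test",
      title = sprintf("Bias %.2f, LoA [%.2f, %.2f], PE %.1f%%",
                      object$bias, object$loa_low, object$loa_high, object$pe)
    ) +
    ggplot2::theme_minimal()
}
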