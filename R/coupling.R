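#' End-systolic pressure from cuff pressures
#'
#' Estimates left-ventricular end-systolic pressure from systolic and
#' diastolic cuff pressure with the linear regression
#' \eqn{P_{es} = 0.205\,sBP + 0.898\,dBP + 0.4214} (defaults of
#' [coupling_constants()]). Vectorised over `sbp`/`dbp`.
#'
#' @param sbp Systolic blood pressure, mmHg.
#' @param dbp Diastolic blood pressure, mmHg. Must satisfy `sbp > dbp > 0`.
#' @param constants A [coupling_constants()] object.
#'
#' @return End-systolic pressure in mmHg, same length as the inputs.
#' @examples
#' estimate_pes(119, 72) # 89.4724
#' @export
estimate_pes <- function(sbp, dbp, constants = coupling_constants()) {
  check_pressures(sbp, dbp)
  constants$pes_a * sbp + constants$pes_b * dbp + constants$pes_c
}

check_pressures <- function(sbp, dbp) {
  if (any(!is.finite(dbp)) || any(dbp <= 0)) {
    abort("`dbp` must be positive and finite.",
          class = "efcoupling_invalid_input")
  }
  if (any(!is.finite(sbp)) || any(sbp <= 0)) {
    abort("`sbp` must be positive and finite.",
          class = "efcoupling_invalid_input")
  }
  if (any(sbp <= dbp)) {
    abort("`sbp` must exceed `dbp` (inverted or equal cuff pressures).",
          class = "efcoupling_invalid_input")
  }
  invisible(TRUE)
}

check_durations <- function(pep, et) {
  if (any(!is.finite(pep)) || any(pep <= 0)) {
    abort("`pep` must be positive and finite.",
          class = "efcoupling_invalid_input")
  }
  if (any(!is.finite(et)) || any(et <= 0)) {
    abort("`et` must be positive and finite.",
          class = "efcoupling_invalid_input")
  }
  invisible(TRUE)
}

#' Bilinear elastance slope ratio from the coupling ratio
#'
#' The ratio k of the ventricular elastance slope during isovolumic
#' contraction to the slope during ejection, tied empirically to coupling by
#' \eqn{k = 0.53\,(E_{es}/E_a)^{0.51}}. Strictly increasing in `x`.
#'
#' @param x Coupling ratio Ees/Ea (> 0). Vectorised.
#' @inheritParams estimate_pes
#' @return k, dimensionless.
#' @examples
#' k_from_coupling(1) # 0.53
#' @export
k_from_coupling <- function(x, constants = coupling_constants()) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("Coupling ratio `x` must be positive (non-integer power).",
          class = "efcoupling_domain_error")
  }
  constants$c_k * x^constants$p_k
}

#' Hypothetical isovolumic peak pressure
#'
#' The peak pressure the ventricle would develop against a clamped aorta,
#' reconstructed from diastolic arterial pressure and the systolic time
#' intervals: \eqn{P_{max} = P_{ad}\,(1 + k\,ET/PEP)}.
#'
#' @param pad Diastolic arterial pressure, mmHg.
#' @param k Elastance slope ratio (see [k_from_coupling()]).
#' @param et Ejection time. Any time unit, as long as it matches `pep`.
#' @param pep Pre-ejection period, same unit as `et`.
#' @return Pmax in mmHg.
#' @examples
#' pmax_hypothetical(72, 0.6218, 303, 97)
#' @export
pmax_hypothetical <- function(pad, k, et, pep) {
  if (any(pad <= 0) || any(k < 0) || any(et <= 0) || any(pep <= 0)) {
    abort("All of `pad`, `et`, `pep` must be positive and `k` non-negative.",
          class = "efcoupling_invalid_input")
  }
  pad * (1 + k * et / pep)
}

#' Residual of the simultaneous coupling equations
#'
#' The two relations — coupling from pressures and timing,
#' \eqn{E_{es}/E_a = (P_{ad}/P_{es})(1 + k\,ET/PEP) - 1}, and the empirical
#' slope-ratio law \eqn{k = c_k x^{p_k}} — are combined into a single scalar
#' residual \eqn{g(x) = (P_{ad}/P_{es})(1 + c_k x^{p_k} ET/PEP) - 1 - x}
#' whose root is their simultaneous solution. For \eqn{0 < p_k < 1}, g is
#' strictly concave on x > 0, which [solve_coupling()] exploits.
#'
#' @param x Candidate coupling ratio (> 0). Vectorised.
#' @param pad Diastolic arterial pressure, mmHg.
#' @param pes End-systolic pressure, mmHg (see [estimate_pes()]).
#' @param et,pep Ejection time and pre-ejection period, one common unit.
#' @inheritParams estimate_pes
#' @return The residual g(x), dimensionless.
#' @examples
#' coupling_residual(1.3676, pad = 72, pes = 89.4724, et = 303, pep = 97)
#' @export
coupling_residual <- function(x, pad, pes, et, pep,
                              constants = coupling_constants()) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("Coupling ratio `x` must be positive.",
          class = "efcoupling_domain_error")
  }
  if (any(pad <= 0) || any(pes <= 0)) {
    abort("`pad` and `pes` must be positive.",
          class = "efcoupling_invalid_input")
  }
  check_durations(pep, et)
  (pad / pes) * (1 + constants$c_k * x^constants$p_k * et / pep) - 1 - x
}

# derivative of the residual wrt x (used by the Newton step)
coupling_residual_deriv <- function(x, pad, pes, et, pep, constants) {
  (pad / pes) * constants$c_k * constants$p_k * x^(constants$p_k - 1) *
    et / pep - 1
}

#' Ventricular efficiency from the coupling ratio
#'
#' Closed form for the external-work fraction of the pressure-volume area:
#' \eqn{Eff = 1/(1 + 0.5\,E_a/E_{es})}. Strictly increasing in `x`, with
#' range (0, 1).
#'
#' @param x Coupling ratio Ees/Ea (> 0). Vectorised.
#' @return Efficiency as a fraction in (0, 1).
#' @examples
#' efficiency_from_coupling(1) # 2/3
#' @export
efficiency_from_coupling <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("Coupling ratio `x` must be positive.",
          class = "efcoupling_domain_error")
  }
  1 / (1 + 0.5 / x)
}

#' Ejection fraction from ventricular efficiency
#'
#' Under a zero unstressed volume (V0 = 0) the pressure-volume-loop algebra
#' collapses to the exact identity \eqn{EF = Eff/(2 - Eff)}; with V0 > 0 the
#' same expression is an upper approximation (see [ef_shortcut_gap()]).
#' Strictly increasing on \[0, 1\] with `ef_from_efficiency(1) == 1`.
#'
#' @param eff Efficiency as a fraction in \[0, 1\]. Vectorised.
#' @return Ejection fraction as a fraction.
#' @examples
#' ef_from_efficiency(2 / 3) # 0.5
#' @export
ef_from_efficiency <- function(eff) {
  if (any(!is.finite(eff)) || any(eff < 0) || any(eff > 1)) {
    abort("`eff` must lie in [0, 1].", class = "efcoupling_domain_error")
  }
  eff / (2 - eff)
}

#' Solve the coupling equations for one beat
#'
#' Maps one beat's noninvasive measurements (PEP, ET, systolic and diastolic
#' cuff pressure) to the ventricular-arterial coupling ratio by finding the
#' root of [coupling_residual()] with a safeguarded Newton iteration
#' (analytic derivative, bracket maintained at every step, bisection
#' fallback when a Newton step leaves the bracket). Efficiency and ejection
#' fraction are filled in from the closed forms, and the hypothetical
#' isovolumic pressure from [pmax_hypothetical()].
#'
#' The residual is concave, so in the physiological case (`pad < pes`) it
#' has zero or two positive roots; the larger root is returned — it is the
#' attracting fixed point of the natural iteration and the one compatible
#' with observed cohorts (the small root implies implausibly low coupling).
#' When `pad >= pes` there is exactly one positive root; it is returned with
#' a `"pad_ge_pes"` warning flag rather than an error, so cuff artifacts do
#' not abort batch runs.
#'
#' @param pep Pre-ejection period, ms.
#' @param et Ejection time, ms (only the ratio `et/pep` enters the model,
#'   so any one common time unit works).
#' @param sbp,dbp Systolic and diastolic cuff pressure, mmHg.
#' @param id Optional beat/subject label carried into the result.
#' @inheritParams estimate_pes
#' @param settings A [solver_settings()] object.
#'
#' @return An object of class `coupling_estimate`: a list with elements
#'   `ees_over_ea`, `k`, `pes`, `pad`, `pmax`, `eff`, `ef` (fractions, not
#'   percent), `iterations`, `converged`, `residual`, `warnings`, `id`.
#'   Use [tidy()] for a one-row tibble.
#' @seealso [estimate_ef()] for the data-frame pipeline over many beats.
#' @examples
#' est <- solve_coupling(pep = 97, et = 303, sbp = 119, dbp = 72)
#' est$ees_over_ea # about 1.368
#' tidy(est)
#' @export
solve_coupling <- function(pep, et, sbp, dbp, id = NULL,
                           constants = coupling_constants(),
                           settings = solver_settings()) {
  check_pressures(sbp, dbp)
  check_durations(pep, et)
  stopifnot(length(pep) == 1L, length(et) == 1L,
            length(sbp) == 1L, length(dbp) == 1L)

  pes <- estimate_pes(sbp, dbp, constants)
  pad <- dbp
  warnings <- character()
  if (pad >= pes) warnings <- c(warnings, "pad_ge_pes")

  g  <- function(x) coupling_residual(x, pad, pes, et, pep, constants)
  gp <- function(x) coupling_residual_deriv(x, pad, pes, et, pep, constants)

  lo0 <- settings$bracket_low
  hi  <- settings$bracket_high

  # g is concave: increasing up to the stationary point, then decreasing to
  # -Inf. The largest root sits on the descending branch.
  slope <- (pad / pes) * constants$c_k * et / pep
  x_crit <- (slope * constants$p_k)^(1 / (1 - constants$p_k))
  g_max <- g(max(x_crit, lo0))
  if (g_max < 0) {
    abort(
      message = paste0(
        "No positive root: the coupling residual is negative throughout ",
        sprintf("[%g, %g] (g(low) = %.4g, g(high) = %.4g).",
                lo0, hi, g(lo0), g(hi))
      ),
      class = "efcoupling_no_solution",
      g_low = g(lo0), g_high = g(hi), id = id
    )
  }
  lo <- max(x_crit, lo0)
  if (g(hi) > 0) {
    abort(
      message = sprintf(
        "Root exceeds bracket_high = %g (g there is still %.4g > 0); widen the bracket.",
        hi, g(hi)),
      class = "efcoupling_no_solution",
      g_low = g(lo0), g_high = g(hi), id = id
    )
  }

  # safeguarded Newton on [lo, hi]: g(lo) >= 0 > g(hi), g decreasing here
  x <- min(max(settings$initial_guess, lo), hi)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    gx <- g(x)
    d <- gp(x)
    # near a tangent root g' vanishes and |g| <= tol alone leaves x poorly
    # determined; demand a small Newton error estimate or a tight bracket
    x_err <- if (is.finite(d) && d < 0) abs(gx / d) else Inf
    if (abs(gx) <= settings$tolerance &&
        (x_err <= 1e-12 || (hi - lo) <= 1e-11 * max(1, x))) {
      converged <- TRUE
      break
    }
    if (gx > 0) lo <- x else hi <- x
    x_new <- if (is.finite(d) && d < 0) x - gx / d else NA_real_
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi) {
      x_new <- (lo + hi) / 2
    }
    x <- x_new
    if (iter >= settings$max_iterations) break
  }
  if (!converged) {
    abort(
      message = sprintf(
        "Newton iteration did not converge in %d iterations (last x = %.8g, residual = %.4g).",
        settings$max_iterations, x, g(x)),
      class = "efcoupling_no_convergence",
      last_x = x, residual = g(x), id = id
    )
  }

  k <- k_from_coupling(x, constants)
  eff <- efficiency_from_coupling(x)
  structure(
    list(
      ees_over_ea = x,
      k = k,
      pes = pes,
      pad = pad,
      pmax = pmax_hypothetical(pad, k, et, pep),
      eff = eff,
      ef = ef_from_efficiency(eff),
      iterations = iter,
      converged = converged,
      residual = g(x),
      warnings = warnings,
      id = id %||% NA_character_
    ),
    class = "coupling_estimate"
  )
}

#' @export
print.coupling_estimate <- function(x, ...) {
  cat("Coupling estimate", if (!is.na(x$id)) paste0("(", x$id, ")"), "\n")
  cat(sprintf("  Ees/Ea = %.4f  (k = %.4f, Pes = %.2f mmHg, Pmax = %.1f mmHg)\n",
              x$ees_over_ea, x$k, x$pes, x$pmax))
  cat(sprintf("  Eff = %.1f%%, EF = %.1f%%\n", 100 * x$eff, 100 * x$ef))
  cat(sprintf("  %s in %d iterations, |residual| = %.2g\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, abs(x$residual)))
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn solve_coupling one-row tibble of the estimate's fields.
#' @param x A `coupling_estimate`.
#' @param ... Unused.
#' @method tidy coupling_estimate
#' @export
tidy.coupling_estimate <- function(x, ...) {
  tibble(
    id = x$id,
    ees_over_ea = x$ees_over_ea,
    k = x$k,
    pes_mmhg = x$pes,
    pad_mmhg = x$pad,
    pmax_mmhg = x$pmax,
    eff = x$eff,
    ef = x$ef,
    iterations = x$iterations,
    converged = x$converged,
    residual = x$residual,
    warnings = paste(x$warnings, collapse = ";")
  )
}

#' Estimate ejection fraction for a table of beats
#'
#' The full noninvasive pipeline, one row per beat: end-systolic pressure
#' from the cuff pressures, the coupling ratio by [solve_coupling()],
#' then efficiency and ejection fraction in closed form. Rows that fail
#' (invalid input, no root, non-convergence) are flagged in the `error`
#' column and kept in place, never dropped, so the output aligns row-for-row
#' with the input.
#'
#' @param beats A data frame with columns `pep_ms`, `et_ms`, `sbp_mmhg`,
#'   `dbp_mmhg`, and optionally `id` plus any extra columns (preserved).
#' @inheritParams solve_coupling
#' @return A tibble with the input columns plus `pes_mmhg`, `ees_over_ea`,
#'   `k`, `pmax_mmhg`, `eff`, `ef_eff` (fractions), `iterations`,
#'   `converged`, `warnings`, `error`.
#' @examples
#' beats <- tibble::tibble(id = "mean-subject", pep_ms = 97, et_ms = 303,
#'                         sbp_mmhg = 119, dbp_mmhg = 72)
#' estimate_ef(beats)
#' @export
estimate_ef <- function(beats, constants = coupling_constants(),
                        settings = solver_settings()) {
  beats <- as_tibble(beats)
  required <- c("pep_ms", "et_ms", "sbp_mmhg", "dbp_mmhg")
  missing <- setdiff(required, names(beats))
  if (length(missing)) {
    abort(paste0("`beats` is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "efcoupling_schema_error")
  }
  if (!"id" %in% names(beats)) {
    beats$id <- as.character(seq_len(nrow(beats)))
  }

  one <- function(pep, et, sbp, dbp, id) {
    res <- tryCatch(
      tidy(solve_coupling(pep = pep, et = et, sbp = sbp, dbp = dbp, id = id,
                          constants = constants, settings = settings)),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      return(tibble(
        id = as.character(id), ees_over_ea = NA_real_, k = NA_real_,
        pes_mmhg = NA_real_, pad_mmhg = NA_real_, pmax_mmhg = NA_real_,
        eff = NA_real_, ef = NA_real_, iterations = NA_integer_,
        converged = FALSE, residual = NA_real_, warnings = "",
        error = res
      ))
    }
    res$error <- NA_character_
    res
  }

  out <- purrr::pmap_dfr(
    list(beats$pep_ms, beats$et_ms, beats$sbp_mmhg, beats$dbp_mmhg,
         as.character(beats$id)),
    one
  )
  res <- dplyr::bind_cols(
    beats,
    dplyr::select(out, -"id", -"pad_mmhg", ef_eff = "ef")
  )
  class(res) <- c("ef_estimates", class(res))
  attr(res, "constants") <- constants
  res
}

#' @describeIn estimate_ef one-row summary: counts of rows, convergences,
#'   warnings and failures, plus mean Ees/Ea and EF of the converged rows.
#' @param x An `ef_estimates` tibble.
#' @param ... Unused.
#' @method glance ef_estimates
#' @export
glance.ef_estimates <- function(x, ...) {
  ok <- x$converged & is.na(x$error)
  tibble(
    n = nrow(x),
    n_converged = sum(ok),
    n_warned = sum(nzchar(x$warnings), na.rm = TRUE),
    n_failed = sum(!is.na(x$error)),
    mean_ees_over_ea = mean(x$ees_over_ea[ok]),
    mean_ef_eff = mean(x$ef_eff[ok])
  )
}
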