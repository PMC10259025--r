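#' Empirical constants of the coupling model
#'
#' Bundles the regression constants used throughout the estimation chain:
#' the end-systolic pressure formula
#' \eqn{P_{es} = a \cdot sBP + b \cdot dBP + c} (Kappus-type cuff-pressure
#' regression) and the bilinear-elastance slope ratio
#' \eqn{k = c_k (E_{es}/E_a)^{p_k}}. Defaults are the published empirical
#' values; they can be overridden for sensitivity analyses, and every result
#' table records the constants it was computed with.
#'
#' @param c_k Multiplier of the slope-ratio relation (dimensionless, > 0).
#' @param p_k Exponent of the slope-ratio relation; must lie strictly in
#'   (0, 1) — the solver's concavity argument (and hence its root-bracketing
#'   guarantee) depends on it.
#' @param pes_a,pes_b Weights of systolic and diastolic cuff pressure in the
#'   end-systolic pressure estimate (dimensionless).
#' @param pes_c Additive offset of the end-systolic pressure estimate (mmHg).
#'
#' @return An object of class `coupling_constants`: a named list with the
#'   five constants.
#' @examples
#' coupling_constants()
#' coupling_constants(c_k = 0.5) # sensitivity variant
#' @export
coupling_constants <- function(c_k = 0.53, p_k = 0.51,
                               pes_a = 0.205, pes_b = 0.898,
                               pes_c = 0.4214) {
  stopifnot(is.numeric(c_k), length(c_k) == 1L,
            is.numeric(p_k), length(p_k) == 1L,
            is.numeric(pes_a), length(pes_a) == 1L,
            is.numeric(pes_b), length(pes_b) == 1L,
            is.numeric(pes_c), length(pes_c) == 1L)
  if (!is.finite(c_k) || c_k <= 0) {
    abort("`c_k` must be a positive finite number.", class = "efcoupling_invalid_input")
  }
  if (!is.finite(p_k) || p_k <= 0 || p_k >= 1) {
    abort("`p_k` must lie strictly in (0, 1): the residual is concave only then.",
          class = "efcoupling_invalid_input")
  }
  structure(
    list(c_k = c_k, p_k = p_k, pes_a = pes_a, pes_b = pes_b, pes_c = pes_c),
    class = "coupling_constants"
  )
}

#' @export
print.coupling_constants <- function(x, ...) {
  cat("Coupling model constants\n")
  cat(sprintf("  k relation:  k = %.4g * (Ees/Ea)^%.4g\n", x$c_k, x$p_k))
  cat(sprintf("  Pes formula: Pes = %.4g*sBP + %.4g*dBP + %.4g mmHg\n",
              x$pes_a, x$pes_b, x$pes_c))
  invisible(x)
}

#' Settings for the coupling root solver
#'
#' Controls the safeguarded Newton iteration used by [solve_coupling()].
#' The defaults converge in a handful of iterations on physiological input
#' and are safe to leave alone.
#'
#' @param tolerance Convergence bound on the absolute residual.
#' @param max_iterations Iteration cap (>= 1).
#' @param bracket_low,bracket_high Search interval for the coupling ratio;
#'   the solver reports an error if no root lies inside it.
#' @param initial_guess Starting value; must lie inside the bracket.
#'
#' @return An object of class `solver_settings`.
#' @examples
#' solver_settings()
#' solver_settings(tolerance = 1e-12)
#' @export
solver_settings <- function(tolerance = 1e-10, max_iterations = 100L,
                            bracket_low = 1e-3, bracket_high = 50,
                            initial_guess = 1) {
  stopifnot(is.numeric(tolerance), is.numeric(max_iterations),
            is.numeric(bracket_low), is.numeric(bracket_high),
            is.numeric(initial_guess))
  if (tolerance <= 0) {
    abort("`tolerance` must be positive.", class = "efcoupling_invalid_input")
  }
  if (max_iterations < 1) {
    abort("`max_iterations` must be at least 1.", class = "efcoupling_invalid_input")
  }
  if (!(0 < bracket_low && bracket_low < initial_guess &&
        initial_guess < bracket_high)) {
    abort("Require 0 < bracket_low < initial_guess < bracket_high.",
          class = "efcoupling_invalid_input")
  }
  structure(
    list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
         bracket_low = bracket_low, bracket_high = bracket_high,
         initial_guess = initial_guess),
    class = "solver_settings"
  )
}

#' @export
print.solver_settings <- function(x, ...) {
  cat("Coupling solver settings\n")
  cat(sprintf("  bracket [%g, %g], start %g\n",
              x$bracket_low, x$bracket_high, x$initial_guess))
  cat(sprintf("  |residual| tolerance %g, max %d iterations\n",
              x$tolerance, x$max_iterations))
  invisible(x)
}
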