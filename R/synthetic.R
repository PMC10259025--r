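#' Configuration of the synthetic cohort generator
#'
#' Distribution parameters for [sample_cohort()]. The defaults emulate a
#' healthy-adult screening cohort: PEP 97 +/- 14 ms, ET derived, sBP
#' 119 +/- 10 mmHg, dBP 72 +/- 6 mmHg, coupling ratio 1.5 +/- 0.6
#' (truncated above 0.2), EDV 120 +/- 20 mL, V0 = 0, and additive echo
#' noise of 4 percentage points on the observed ejection fraction.
#' All quantities are drawn from truncated normal distributions (rejection
#' sampling) so that pressures, volumes and intervals stay physiological at
#' the stated spreads.
#'
#' @param coupling_mean,coupling_sd Ees/Ea distribution; truncated below at
#'   `coupling_min`.
#' @param coupling_min Lower truncation bound of the coupling draw.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd Cuff pressures, mmHg; pairs are
#'   redrawn until sbp > dbp.
#' @param pep_mean,pep_sd Pre-ejection period, ms; truncated to (20, 400).
#' @param edv_mean,edv_sd End-diastolic volume, mL; truncated below at
#'   `v0 + 10` mL.
#' @param v0 Unstressed (zero-pressure) ventricular volume, mL.
#' @param echo_ef_noise_sd SD of the additive noise on the observed echo
#'   ejection fraction, in percentage points (4 means SD 0.04 on the
#'   fraction scale); observations are truncated to (0, 1).
#' @param timing_noise_sd SD of additive noise on the derived ejection
#'   time, ms (default 0: the timing equations then hold exactly in truth).
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config()
#' cohort_config(v0 = 20)
#' @export
cohort_config <- function(coupling_mean = 1.5, coupling_sd = 0.6,
                          coupling_min = 0.2,
                          sbp_mean = 119, sbp_sd = 10,
                          dbp_mean = 72, dbp_sd = 6,
                          pep_mean = 97, pep_sd = 14,
                          edv_mean = 120, edv_sd = 20,
                          v0 = 0,
                          echo_ef_noise_sd = 4,
                          timing_noise_sd = 0) {
  cfg <- list(
    coupling_mean = coupling_mean, coupling_sd = coupling_sd,
    coupling_min = coupling_min,
    sbp_mean = sbp_mean, sbp_sd = sbp_sd,
    dbp_mean = dbp_mean, dbp_sd = dbp_sd,
    pep_mean = pep_mean, pep_sd = pep_sd,
    edv_mean = edv_mean, edv_sd = edv_sd,
    v0 = v0,
    echo_ef_noise_sd = echo_ef_noise_sd,
    timing_noise_sd = timing_noise_sd
  )
  sds <- c(coupling_sd, sbp_sd, dbp_sd, pep_sd, edv_sd,
           echo_ef_noise_sd, timing_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("All SDs must be finite and non-negative.",
          class = "efcoupling_invalid_input")
  }
  if (v0 < 0) {
    abort("`v0` must be non-negative.", class = "efcoupling_invalid_input")
  }
  if (coupling_min <= 0) {
    abort("`coupling_min` must be positive.",
          class = "efcoupling_invalid_input")
  }
  structure(cfg, class = "cohort_config")
}

# truncated normal by rejection; sd = 0 degenerates to the (clipped) mean
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      abort("Degenerate truncated normal: mean outside the bounds.",
            class = "efcoupling_invalid_input")
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  guard <- 0L
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    guard <- guard + 1L
    if (guard > 1000L) {
      abort("Rejection sampling failed: truncation bounds too far from the mean.",
            class = "efcoupling_generation_error")
    }
  }
  out
}

#' Ejection time consistent with a known coupling ratio
#'
#' Exact inversion of the coupling equations: given a true Ees/Ea, the
#' pre-ejection period and the cuff pressures, returns the beat whose
#' ejection time satisfies the coupling relations exactly,
#' `et = pep * ((x + 1) * pes / pad - 1) / k` with `k` from
#' [k_from_coupling()] and `pes` from [estimate_pes()]. Feeding the result
#' to [solve_coupling()] recovers `x_true` to solver precision, which makes
#' this the ground-truth constructor for synthetic subjects.
#'
#' @param x_true True coupling ratio Ees/Ea (> 0). Vectorised (recycled
#'   against the other arguments).
#' @param pep Pre-ejection period, ms.
#' @param sbp,dbp Cuff pressures, mmHg.
#' @inheritParams estimate_pes
#' @return A tibble with columns `pep_ms`, `et_ms`, `sbp_mmhg`, `dbp_mmhg`.
#' @examples
#' timing_from_truth(1.368, pep = 97, sbp = 119, dbp = 72) # et close to 303
#' @export
timing_from_truth <- function(x_true, pep, sbp, dbp,
                              constants = coupling_constants()) {
  if (any(!is.finite(x_true)) || any(x_true <= 0)) {
    abort("`x_true` must be positive.", class = "efcoupling_domain_error")
  }
  check_pressures(sbp, dbp)
  if (any(pep <= 0)) {
    abort("`pep` must be positive.", class = "efcoupling_invalid_input")
  }
  pes <- estimate_pes(sbp, dbp, constants)
  k <- k_from_coupling(x_true, constants)
  et <- pep * ((x_true + 1) * pes / dbp - 1) / k
  if (any(et <= 0)) {
    abort(
      "Infeasible truth: the implied ejection time is non-positive (coupling too small for these pressures).",
      class = "efcoupling_infeasible_truth"
    )
  }
  if (any(et < 50)) {
    warn("Implied ejection time below 50 ms: physiologically implausible beat.",
         class = "efcoupling_implausible_timing")
  }
  tibble(pep_ms = pep + numeric(length(et)), et_ms = et,
         sbp_mmhg = sbp + numeric(length(et)),
         dbp_mmhg = dbp + numeric(length(et)))
}

#' Simulate a cohort with known ground truth
#'
#' Draws each subject's true coupling ratio, cuff pressures, pre-ejection
#' period and end-diastolic volume from truncated normals, builds an
#' internally consistent pressure-volume loop
#' (`esv = (edv - v0)/(1 + coupling) + v0`, so that
#' `sv/(esv - v0) = coupling` exactly), derives the ejection time by exact
#' inversion via [timing_from_truth()], and adds configurable measurement
#' noise to the observed echo ejection fraction (and optionally to the
#' ejection time). Deterministic given `seed`.
#'
#' @param n Number of subjects (>= 1).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param config A [cohort_config()].
#' @inheritParams estimate_pes
#' @return A tibble of class `subject_truth` with one row per subject:
#'   `id`, `coupling_true`, loop columns (`edv`, `esv`, `v0`, `sv`, `pes`),
#'   beat columns (`pep_ms`, `et_ms`, `sbp_mmhg`, `dbp_mmhg`), `ef_true`
#'   and `ef_echo_observed` (fractions).
#' @examples
#' sample_cohort(5, seed = 1)
#' @export
sample_cohort <- function(n = 44, seed = NULL, config = cohort_config(),
                          constants = coupling_constants()) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  draw <- function() {
    coupling <- rtruncnorm(n, config$coupling_mean, config$coupling_sd,
                           lower = config$coupling_min)
    pep <- rtruncnorm(n, config$pep_mean, config$pep_sd,
                      lower = 20, upper = 400)
    edv <- rtruncnorm(n, config$edv_mean, config$edv_sd,
                      lower = config$v0 + 10)
    # pressures drawn jointly until sbp > dbp
    sbp <- rtruncnorm(n, config$sbp_mean, config$sbp_sd, lower = 0)
    dbp <- rtruncnorm(n, config$dbp_mean, config$dbp_sd, lower = 0)
    bad <- which(sbp <= dbp)
    guard <- 0L
    while (length(bad)) {
      sbp[bad] <- rtruncnorm(length(bad), config$sbp_mean, config$sbp_sd,
                             lower = 0)
      dbp[bad] <- rtruncnorm(length(bad), config$dbp_mean, config$dbp_sd,
                             lower = 0)
      bad <- bad[sbp[bad] <= dbp[bad]]
      guard <- guard + 1L
      if (guard > 1000L) {
        abort("Could not draw sbp > dbp at the configured means/SDs.",
              class = "efcoupling_generation_error")
      }
    }

    pes <- estimate_pes(sbp, dbp, constants)
    k <- k_from_coupling(coupling, constants)
    et <- pep * ((coupling + 1) * pes / dbp - 1) / k
    feasible <- is.finite(et) & et > 0
    if (mean(!feasible) > 0.2) {
      abort(
        "More than 20% of draws imply a non-positive ejection time; adjust the coupling/pressure configuration.",
        class = "efcoupling_generation_error"
      )
    }
    if (config$timing_noise_sd > 0) {
      et[feasible] <- vapply(
        et[feasible],
        function(e) rtruncnorm(1L, e, config$timing_noise_sd, lower = 1),
        numeric(1)
      )
    }

    esv <- (edv - config$v0) / (1 + coupling) + config$v0
    sv <- edv - esv
    ef_true <- sv / edv
    ef_echo <- vapply(
      ef_true,
      function(e) rtruncnorm(1L, e, config$echo_ef_noise_sd / 100,
                             lower = .Machine$double.eps, upper = 1),
      numeric(1)
    )

    tibble(
      id = sprintf("S%04d", seq_len(n)),
      coupling_true = coupling,
      edv = edv, esv = esv, v0 = config$v0, sv = sv, pes = pes,
      pep_ms = pep, et_ms = et, sbp_mmhg = sbp, dbp_mmhg = dbp,
      ef_true = ef_true, ef_echo_observed = ef_echo,
      feasible = feasible
    )
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- dplyr::filter(out, .data$feasible)
  out$feasible <- NULL
  class(out) <- c("subject_truth", class(out))
  out
}
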