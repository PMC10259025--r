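# Independent oracles for the coupling root: plain arithmetic plus bisection,
# sharing no code with the package's Newton solver.

oracle_residual <- function(x, pad, pes, et, pep, c_k = 0.53, p_k = 0.51) {
  (pad / pes) * (1 + c_k * x^p_k * et / pep) - 1 - x
}

# Largest root of the concave residual: bisection on the descending branch,
# i.e. on [x_crit, hi] where x_crit is the stationary point.
oracle_largest_root <- function(pad, pes, et, pep,
                                c_k = 0.53, p_k = 0.51, hi = 50,
                                iters = 200) {
  slope <- (pad / pes) * c_k * et / pep
  x_crit <- (slope * p_k)^(1 / (1 - p_k))
  lo <- x_crit
  if (oracle_residual(lo, pad, pes, et, pep, c_k, p_k) < 0) return(NA_real_)
  if (oracle_residual(hi, pad, pes, et, pep, c_k, p_k) > 0) return(NA_real_)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (oracle_residual(mid, pad, pes, et, pep, c_k, p_k) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random physiologically plausible beats for randomized comparisons.
random_beats <- function(n) {
  tibble::tibble(
    pep_ms = stats::runif(n, 60, 160),
    et_ms = stats::runif(n, 180, 420),
    dbp_mmhg = stats::runif(n, 50, 95),
    sbp_mmhg = NA_real_
  ) |>
    dplyr::mutate(sbp_mmhg = dbp_mmhg + stats::runif(n, 15, 60))
}

# Random valid PV loops.
random_loops <- function(n, v0 = 0) {
  edv <- stats::runif(n, 80, 200)
  esv <- v0 + (edv - v0) * stats::runif(n, 0.2, 0.8)
  tibble::tibble(edv = edv, esv = esv, v0 = v0,
                 pes = stats::runif(n, 60, 130))
}
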