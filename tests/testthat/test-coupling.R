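# Frozen expected values below were computed with independent oracles:
# direct hand arithmetic for the linear formulas, and damped fixed-point
# iteration x <- (pad/pes - 1) + (pad/pes)*0.53*(et/pep)*x^0.51 (run to
# |dx| < 1e-12) for the solved coupling ratio.

test_that("end-systolic pressure formula matches hand arithmetic and rejects bad pressures", {
  expect_equal(estimate_pes(119, 72), 89.4724, tolerance = 1e-12)
  expect_equal(estimate_pes(120, 80), 96.8614, tolerance = 1e-12)
  # vectorised
  expect_equal(estimate_pes(c(119, 120), c(72, 80)), c(89.4724, 96.8614))
  # physiological inputs land strictly between dbp and sbp
  expect_true(estimate_pes(119, 72) > 72 && estimate_pes(119, 72) < 119)

  expect_error(estimate_pes(100, 100), class = "efcoupling_invalid_input")
  expect_error(estimate_pes(80, 90), class = "efcoupling_invalid_input")
  expect_error(estimate_pes(120, -5), class = "efcoupling_invalid_input")
})

test_that("slope-ratio law is increasing with the documented anchor points", {
  expect_identical(k_from_coupling(1), 0.53)
  expect_equal(k_from_coupling(1.3677), 0.53 * exp(0.51 * log(1.3677)),
               tolerance = 1e-12)
  expect_equal(k_from_coupling(1.3677), 0.6218, tolerance = 1e-4)
  xs <- seq(0.1, 10, length.out = 50)
  expect_true(all(diff(k_from_coupling(xs)) > 0))
  expect_error(k_from_coupling(0), class = "efcoupling_domain_error")
  expect_error(k_from_coupling(-1), class = "efcoupling_domain_error")
})

test_that("coupling residual evaluates, vanishes at the oracle root, and is concave", {
  g1 <- coupling_residual(1, pad = 72, pes = 89.4724, et = 303, pep = 97)
  expect_equal(g1, 0.136981, tolerance = 1e-5)

  g_root <- coupling_residual(1.3676255615, pad = 72, pes = 89.4724,
                              et = 303, pep = 97)
  expect_lt(abs(g_root), 1e-3)

  # concavity: second differences negative on a grid
  xs <- seq(0.05, 10, length.out = 200)
  g <- coupling_residual(xs, pad = 72, pes = 89.4724, et = 303, pep = 97)
  expect_true(all(diff(diff(g)) < 0))

  expect_error(coupling_residual(-1, 72, 89, 303, 97),
               class = "efcoupling_domain_error")
})

test_that("hypothetical isovolumic pressure follows the clamped-aorta formula", {
  expect_equal(pmax_hypothetical(72, 0.6218, 303, 97), 211.8, tolerance = 1e-3)
  expect_identical(pmax_hypothetical(88, 0, 300, 100), 88)
  expect_identical(pmax_hypothetical(100, 1, 250, 250), 200)
})

test_that("efficiency and EF closed forms hit their anchors and limits", {
  expect_equal(efficiency_from_coupling(1), 2 / 3, tolerance = 1e-15)
  expect_equal(efficiency_from_coupling(1.3677), 0.7323, tolerance = 1e-4)
  expect_gt(efficiency_from_coupling(1e9), 1 - 1e-9)

  expect_equal(ef_from_efficiency(2 / 3), 0.5, tolerance = 1e-15)
  expect_identical(ef_from_efficiency(1), 1)
  expect_equal(ef_from_efficiency(0.7323), 0.5777, tolerance = 1e-4)

  expect_error(efficiency_from_coupling(0), class = "efcoupling_domain_error")
  expect_error(ef_from_efficiency(1.2), class = "efcoupling_domain_error")
  expect_error(ef_from_efficiency(-0.1), class = "efcoupling_domain_error")
})

test_that("the composed maps collapse to ef = x/(1+x) over the working range", {
  xs <- exp(seq(log(0.1), log(10), length.out = 200))
  ef <- ef_from_efficiency(efficiency_from_coupling(xs))
  expect_equal(ef, xs / (1 + xs), tolerance = 1e-12)
})

test_that("solver reproduces the fixed-point oracle on the cohort-mean beat", {
  est <- solve_coupling(pep = 97, et = 303, sbp = 119, dbp = 72)
  expect_true(est$converged)
  expect_equal(est$ees_over_ea, 1.3676255615, tolerance = 1e-8)
  expect_lt(abs(est$residual), solver_settings()$tolerance)
  # internal consistency of the populated fields
  expect_equal((est$pmax - est$pes) / est$pes, est$ees_over_ea,
               tolerance = 1e-9)
  expect_equal(est$k, k_from_coupling(est$ees_over_ea))
  expect_equal(est$eff, efficiency_from_coupling(est$ees_over_ea))
  expect_equal(est$ef, ef_from_efficiency(est$eff))
  expect_equal(est$ef, 0.5776359, tolerance = 1e-6)
  expect_length(est$warnings, 0)
})

test_that("solver recovers a constructed truth and flags pad >= pes", {
  beat <- timing_from_truth(2.0, pep = 100, sbp = 120, dbp = 75)
  est <- solve_coupling(pep = beat$pep_ms, et = beat$et_ms,
                        sbp = beat$sbp_mmhg, dbp = beat$dbp_mmhg)
  expect_equal(est$ees_over_ea, 2.0, tolerance = 1e-8)

  # pad >= pes: a single root exists and is returned with a warning flag.
  # Construct via custom constants so pes drops below dbp.
  cst <- coupling_constants(pes_a = 0.1, pes_b = 0.5, pes_c = 0)
  est2 <- solve_coupling(pep = 97, et = 303, sbp = 119, dbp = 72,
                         constants = cst)
  expect_true(est2$converged)
  expect_true("pad_ge_pes" %in% est2$warnings)
  expect_gt(est2$ees_over_ea, 0)
})

test_that("a residual that never reaches zero raises a no-solution error", {
  # make (pad/pes)*(1 + c_k*x^p_k*et/pep) - 1 < x for all x > 0:
  # pad/pes = 0.5 via constants, and a tiny et/pep so the concave bump
  # cannot lift g above zero. Verified by grid evaluation.
  cst <- coupling_constants(pes_a = 0.5, pes_b = 1.173611, pes_c = 0)
  # pes = 0.5*119 + 1.173611*72 = 144 -> pad/pes = 0.5
  xs <- exp(seq(log(1e-6), log(50), length.out = 2000))
  g <- 0.5 * (1 + 0.53 * xs^0.51 * 30 / 97) - 1 - xs
  expect_true(all(g < 0))
  expect_error(
    solve_coupling(pep = 97, et = 30, sbp = 119, dbp = 72, constants = cst),
    class = "efcoupling_no_solution"
  )
})

test_that("safeguarded Newton agrees with descending-branch bisection on random beats", {
  withr::local_seed(42)
  beats <- random_beats(300)
  for (i in seq_len(nrow(beats))) {
    b <- beats[i, ]
    pes <- estimate_pes(b$sbp_mmhg, b$dbp_mmhg)
    x_oracle <- oracle_largest_root(b$dbp_mmhg, pes, b$et_ms, b$pep_ms)
    if (is.na(x_oracle)) next
    est <- solve_coupling(pep = b$pep_ms, et = b$et_ms,
                          sbp = b$sbp_mmhg, dbp = b$dbp_mmhg)
    expect_equal(est$ees_over_ea, x_oracle, tolerance = 1e-8)
  }
})

test_that("solved coupling is monotone in et, pep and pad as the physiology dictates", {
  solve_x <- function(pep, et, dbp) {
    solve_coupling(pep = pep, et = et, sbp = dbp + 47, dbp = dbp)$ees_over_ea
  }
  # increasing in et
  xs_et <- vapply(seq(220, 380, by = 20), function(et) solve_x(97, et, 72),
                  numeric(1))
  expect_true(all(diff(xs_et) > 0))
  # decreasing in pep
  xs_pep <- vapply(seq(70, 140, by = 10), function(p) solve_x(p, 303, 72),
                   numeric(1))
  expect_true(all(diff(xs_pep) < 0))
  # increasing in pad (sbp shifted along so pulse pressure is constant)
  xs_pad <- vapply(seq(60, 90, by = 5), function(d) solve_x(97, 303, d),
                   numeric(1))
  expect_true(all(diff(xs_pad) > 0))
})

test_that("estimate_ef composes the chain identically for a table of beats", {
  beats <- tibble::tibble(
    id = c("mean", "other"),
    pep_ms = c(97, 110), et_ms = c(303, 280),
    sbp_mmhg = c(119, 130), dbp_mmhg = c(72, 80),
    site = c("a", "b") # extra column must survive
  )
  res <- estimate_ef(beats)
  expect_s3_class(res, "ef_estimates")
  expect_identical(nrow(res), 2L)
  expect_identical(res$site, beats$site)

  manual <- solve_coupling(pep = 110, et = 280, sbp = 130, dbp = 80)
  expect_equal(res$ees_over_ea[2], manual$ees_over_ea)
  expect_equal(res$ef_eff[2], manual$ef)
  expect_equal(res$ef_eff[1], 0.5776359, tolerance = 1e-6)

  g <- glance(res)
  expect_identical(g$n, 2L)
  expect_identical(g$n_failed, 0L)
})

test_that("failed rows are flagged in place, not dropped", {
  beats <- tibble::tibble(
    id = c("ok", "bad", "ok2"),
    pep_ms = c(97, 0, 100), et_ms = c(303, 300, 300),
    sbp_mmhg = c(119, 120, 125), dbp_mmhg = c(72, 80, 78)
  )
  res <- estimate_ef(beats)
  expect_identical(nrow(res), 3L)
  expect_true(is.na(res$error[1]) && is.na(res$error[3]))
  expect_false(is.na(res$error[2]))
  expect_false(res$converged[2])
  expect_identical(glance(res)$n_failed, 1L)
})
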