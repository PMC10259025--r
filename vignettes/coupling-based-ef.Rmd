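---
title: "Estimating ejection fraction from ventricular-arterial coupling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ejection fraction from ventricular-arterial coupling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efcoupling)
```

## The estimation chain

The package computes left ventricular ejection fraction (EF) from four
noninvasive measurements per beat: pre-ejection period (PEP), ejection time
(ET), and systolic/diastolic cuff pressure (sBP, dBP). The chain has four
steps, each exposed as its own function so intermediate quantities can be
inspected:

1. **End-systolic pressure.** `estimate_pes()` applies the linear
   cuff-pressure regression Pes = 0.205·sBP + 0.898·dBP + 0.4214 mmHg.
   The three coefficients are empirical; they are user-overridable through
   `coupling_constants()` but default to the published values, and for
   physiological inputs the estimate lands strictly between dBP and sBP.

2. **Coupling ratio.** Two relations hold simultaneously: the
   timing/pressure relation Ees/Ea = (Pad/Pes)(1 + k·ET/PEP) − 1, where Pad
   is diastolic arterial pressure and k is the ratio of the bilinearised
   ventricular elastance slopes in the isovolumic-contraction versus
   ejection phases; and the empirical law k = 0.53·(Ees/Ea)^0.51.
   `solve_coupling()` substitutes the second into the first and finds the
   root of the scalar residual
   g(x) = (Pad/Pes)(1 + 0.53·x^0.51·ET/PEP) − 1 − x.

3. **Efficiency.** `efficiency_from_coupling()` applies
   Eff = 1/(1 + 0.5·Ea/Ees), the closed form of external work divided by
   pressure–volume area under a linear end-systolic pressure-volume
   relation and a triangular potential-energy area.

4. **Ejection fraction.** `ef_from_efficiency()` applies
   EF = Eff/(2 − Eff), which is *exact* when the unstressed volume V0 is
   zero and an overestimate otherwise (below).

`estimate_ef()` runs the whole chain over a data frame of beats, one row
each, and never drops a failing row — errors are carried in an `error`
column so batch runs stay aligned with their input.

### Assumptions

The model assumes a linear end-systolic pressure–volume relation through
(V0, 0); a triangular potential-energy area; cuff pressures as valid
surrogates for central pressures (Pad ≡ dBP — the diastolic arterial
pressure in the coupling relations is identified with the cuff diastolic
reading, the only noninvasive option); and V0 = 0 in the final EF step,
which restricts the intended population to structurally normal hearts.
Only the ratio ET/PEP enters the equations, so the time unit cancels; the
I/O layer nevertheless fixes milliseconds (column suffix `_ms`) and warns
when PEP leaves [20, 400] ms or ET leaves [100, 600] ms, with both ranges
overridable in `read_beat_table()`.

## The solver

For exponent p ∈ (0, 1) the residual g is strictly concave on x > 0 with
g → −∞, so it has at most two positive roots. In the physiological case
Pad < Pes we have g(0⁺) < 0, hence zero or two roots; **the larger root is
returned**. This is a genuine design choice — the underlying system itself
does not prefer a root — made because the larger root is the attracting
fixed point of the natural iteration x ← (Pad/Pes − 1) +
(Pad/Pes)·0.53·(ET/PEP)·x^0.51, and because the smaller root (< ≈0.1 for
realistic inputs) would imply implausibly low coupling in healthy subjects.
When Pad ≥ Pes (possible with cuff artifacts) exactly one positive root
exists; it is returned with a `"pad_ge_pes"` warning flag rather than an
error so a single bad cuff reading cannot abort a batch.

The implementation is a safeguarded Newton iteration: the stationary point
x* = ((Pad/Pes)·0.53·0.51·ET/PEP)^(1/0.49) splits the concave curve into
its ascending and descending branches; the largest root is bracketed on
[x*, 50], the bracket is updated every iteration, the Newton step (analytic
derivative) is taken when it stays inside and a bisection step otherwise.
Defaults (all in `solver_settings()`): initial guess 1.0 (clipped into the
bracket), bracket [1e-3, 50], residual tolerance 1e-10, at most 100
iterations. Convergence additionally requires the Newton error estimate
|g/g′| ≤ 1e-12 or a bracket narrower than 1e-11·max(1, x): near a tangent
root (the two roots nearly coinciding) g′ vanishes at the root and a
residual criterion alone would leave x itself determined only to ~1e-5.
With the safeguard the iteration provably converges on this residual class;
typical beats take 4–6 iterations. If g is negative over the whole bracket
a no-solution error reports g at both bracket ends; if the root exceeds the
upper bracket the error says to widen it.

## The pressure-volume-loop oracle

`pv_quantities()` computes Ees = Pes/(ESV − V0), Ea = Pes/SV,
EW = Pes·SV, PVA = EW + 0.5·Pes·(ESV − V0), Eff = EW/PVA and EF = SV/EDV
from volumes and end-systolic pressure. It exists to *check* the shortcut
chain, not to feed it: writing r = SV/(ESV − V0) one gets
Eff = 2r/(2r + 1) and Eff/(2 − Eff) = r/(r + 1) = SV/(EDV − V0), which
equals SV/EDV exactly when V0 = 0. `ef_shortcut_gap()` returns the signed
difference; it is zero to machine precision at V0 = 0 (verified over 10,000
random loops) and positive, growing with V0, otherwise — i.e. the shortcut
*overestimates* EF in hearts with a real unstressed volume. Degenerate
loops (ESV = V0, infinite elastance) are a typed error, as are negative
triangle geometries (ESV < V0). Work and area stay in mmHg·mL; only the
dimensionless ratio Eff is consumed downstream.

## Agreement statistics

`bland_altman()` orients differences as reference − test, so a test method
reading low gives positive bias. The SD of differences uses the n−1 sample
estimator (the standard in agreement studies; nothing here depends on the
alternative). Limits of agreement default to bias ± 2·SD rather than
1.96·SD — the ±2 convention is common in clinical agreement plots and the
two differ by exactly 0.04·SD, with `multiplier = 1.96` available.
Percentage error is 100·2·SD/mean(reference), acceptable at ≤ 30 %; it is
invariant to expressing both series in percent versus fractions, since
numerator and denominator rescale together. With fewer than three pairs the
function refuses; with a zero-variance series the correlation is reported
as `NA` with a note while the rest of the report stands. R² is the squared
Pearson correlation, which for a single predictor coincides with the R² of
a simple linear regression. `summary_agreement()` rebuilds limits and
percentage error from printed bias/SD/mean summaries when subject-level
pairs are unavailable; correlation cannot be recovered from summaries and
is `NA` there by construction.

## The synthetic cohort generator

`sample_cohort()` emulates a healthy-adult screening cohort. Defaults
(`cohort_config()`): coupling ratio 1.5 ± 0.6 truncated above 0.2, sBP
119 ± 10 mmHg, dBP 72 ± 6 mmHg (pairs redrawn until sBP > dBP), PEP
97 ± 14 ms truncated to (20, 400) ms, EDV 120 ± 20 mL truncated above
V0 + 10 mL, V0 = 0 mL, echo noise 4 percentage points of EF, timing noise
0 ms. All draws are truncated normals by rejection sampling, which keeps
every quantity physiological at these spreads without distorting the bulk
of the distribution.

Two structural choices keep the ground truth exact. First, the generator
parameterises each subject by (coupling, EDV, V0) and *derives*
ESV = (EDV − V0)/(1 + coupling) + V0, so the loop identity
SV/(ESV − V0) = coupling holds to machine precision. Second, ET is not
sampled but computed by exact inversion of the coupling relations
(`timing_from_truth()`: ET = PEP·((x + 1)·Pes/Pad − 1)/k), so the beat's
residual vanishes at the true coupling and the solver must recover it to
1e-8 — the end-to-end oracle used throughout the tests. Optional timing
noise is added *after* derivation, leaving the truth well-defined. Echo
noise is additive on the EF scale (truncated to (0, 1)), the simplest model
matching how echo EF dispersion is reported; volume-level noise would be a
future extension. The echo noise SD of 4 percentage points is a plausible
placeholder for within-method echo variability, not an estimate from data.

A consequence worth stating: because ET is the nonlinear inverse image of
the coupling draw, the derived ET distribution is wider (SD ≈ 60 ms) than
the ≈ 18 ms spread a real screening cohort shows, and its mean sits near
313 ms rather than 303 ms — evaluating the inverse at the coupling mean 1.5
does not return the ET mean, the same Jensen-type effect that makes the
chain at cohort-mean inputs yield Ees/Ea ≈ 1.37 rather than the cohort-mean
1.5. The printed characteristics of a real cohort are not jointly
consistent with the coupling equations holding exactly at their means, so a
generator that enforces the equations exactly cannot also match every
marginal moment; this generator prioritises exact ground truth. The realism
test therefore checks 2-standard-error agreement for the *sampled*
quantities and one-cohort-SD agreement for derived ET.

What passing tests on these cohorts do **not** show about real data: no
beat-to-beat variability, arrhythmia, or waveform-level measurement error
is simulated, the echo error model is additive-Gaussian on EF, and cuff
pressure error is absent. In particular, on synthetic V0 = 0 cohorts the
estimator is unbiased against noisy echo by construction, whereas in vivo
the estimator reads *below* echo EF (positive reference-minus-test bias) —
the opposite sign from what a pure V0 > 0 effect would produce, since the
shortcut then overestimates true EF. The package surfaces this sign
structure (see the acceptance tests) rather than tuning it away; the in
vivo bias must involve factors outside this model, e.g. systematic echo
overreading or pressure-surrogate error.

## Problem sizes and numerical checks

The test suite runs the solver-versus-bisection comparison on 1,000
solvable random beats (bisection on the descending branch is the
independent oracle, 200 halvings), round-trips 1,000 log-uniform truths in
[0.3, 5] at 1e-8, checks shortcut exactness on 10,000 random V0 = 0 loops
at 1e-12, and uses seeded cohorts of 1,000–2,000 subjects for the
Bland–Altman recovery properties with 3-sigma Monte-Carlo tolerances. These
sizes make the stochastic assertions sharp while the full suite stays under
half a minute.

## Limitations

- Only the ratio Ees/Ea is identified; absolute Ees or Ea would require
  volumes.
- The linear ESPVR and triangular PVA are idealisations; no curvilinear
  option is provided.
- The EF step assumes V0 = 0 and is population-restricted accordingly;
  `ef_shortcut_gap()` quantifies the violation, it does not correct it.
- The empirical constants (the Pes regression and the k law) are
  cohort-derived; results tables record the constants used so sensitivity
  analyses are reproducible.
- No raw-waveform processing: the package consumes already-derived PEP/ET
  intervals.
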