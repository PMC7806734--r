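---
title: "Models and methods behind vis4m"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vis4m}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vis4m)
```

This vignette documents the statistical models, parameter choices and
numerical conventions used throughout the package, in the spirit of a
methods supplement: what is computed, why it is computed that way, and
where the genuinely open design choices were resolved.

## The assay

The visual-stimuli four-arm maze is an ×-shaped enclosure whose four arms
present controlled stimuli — colored LED floors (blue 452 nm, green
517 nm, red 628 nm, and a phosphor-converted white) or grayscale objects
in dim red light. A mouse explores freely for five minutes (default
`duration_s = 300`), and an experimenter scores the ordered sequence of
arm entries from video. Every statistic in this package derives from that
entry sequence plus the entry/exit timestamps.

## Alternation scoring

An *alternation* is a sliding window of four consecutive entries visiting
four distinct arms. For a collapsed sequence of `N` entries there are
`N − 3` windows, yet the assay's published score divides successful
windows by `N − 2`. We keep `N − 2` as the default because comparability
with reported values matters more than internal elegance — the observed
ceiling of about 96.7% in good performers is exactly `100·(N−3)/(N−2)` at
`N = 30`, confirming this is how the assay is scored in practice. The
`denominator = "windows"` variant (`N − 3`, perfect sequences score 100)
is exposed for users who prefer an unbiased ceiling.

Two related conventions:

* **Re-entry collapsing.** Consecutive same-arm re-entries are collapsed
  (`collapse_reentries()`) before alternation and transition scoring: the
  12 transition types exclude self-pairs, and the chance-level model
  assumes three available arms per step. The raw entry count is kept
  separately (`total_entries` in `summarize_cohort()`) because re-entries
  are legitimate activity.
* **Short sessions.** Sequences with fewer than 4 collapsed entries raise
  an error in `percent_alternation()` and are *flagged*, not dropped and
  not scored 0, by `summarize_cohort()` — imputing 0% would bias group
  means toward impairment.

## The chance level

Under memoryless uniform exploration, each entry is uniform over the three
arms other than the current one (the center forces an arm change). The
probability that a 4-entry window covers all four arms is obtained by
exhaustive enumeration of the `3³ = 27` equally likely continuations of an
arbitrary starting arm; 6 of them complete the remaining three arms, so
the chance level is `2/9 ≈ 22%`. `expected_alternation_percent(N)`
combines this with the `N − 2` denominator by linearity of expectation:
`100·(N−3)·(2/9)/(N−2)`, i.e. the finite-`N` chance level is slightly
*below* 22.2% (21.4% at `N = 30`). Both the asymptotic window probability
and the finite-`N` expectation are exposed, since a reported whole-percent
"22%" is compatible with either reading.

A 4-choice null that allowed self-transitions would give `4!/4⁴ ≈ 9.4%`,
which is inconsistent with the published 22% figure — this is why the
no-repeat null is the right one for this maze.

`null_alternation_test()` compares an observed percentage to the
Monte-Carlo null at the observed `N`, using the add-one empirical
p estimator `p = (1 + #extreme)/(n_sims + 1)` (two-sided by doubling the
chosen tail, capped at 1) so p is never exactly zero.

## Transitions and chord-table quartiles

`transition_profile()` tallies the `N − 1` consecutive ordered pairs over
the 12 ordered types; bidirectional percentages are the sums of the two
opposing ordered percentages. Chord diagrams conventionally display the
most frequent (upper quartile, Q4) or least frequent (Q1) transitions —
3 of the 12 types. Tie handling is not part of the assay's description, so
we impose a deterministic canonical order (alphabetical on origin, then
destination): ranked selections are therefore reproducible even on
all-equal or zero-count profiles. `write_circos_table()` emits the
tab-delimited 4×4 *count* matrix consumed by the Circos tableviewer
(counts, not percentages — the tableviewer normalizes internally), with a
zero diagonal, optionally zeroing everything outside a selected quartile.

## Photometry

The light meter used for the assay reports exposure values (ISO 100),
converted with `lux = 2.5·2^EV` and `cd/m² = 2^(EV−3)`; the formulas imply
a fixed illuminance/luminance ratio of 20 for this meter geometry, which
the package preserves exactly.

Beyond the meter formulas, conversions need the source spectrum:

* **LED spectra** are modeled as Gaussian bands from the published
  peak/FWHM values (`σ = FWHM/2.355`), evaluated on a 1-nm grid over
  300–800 nm and normalized to unit integral. The white LED is a
  blue-diode band (441/19 nm) plus a broad phosphor band (533/104 nm);
  the *relative power* of the two bands is not part of the published
  characterization, so the blue fraction defaults to 0.3 (a typical
  Ce:YAG white LED) and is a constructor argument. Absolute per-opsin
  fluxes for the white arm therefore carry this assumption; ordinal
  comparisons between the four LEDs do not depend on it over any
  reasonable weight range.
* **Illuminance → irradiance** divides by `683 · ∫S(λ)V(λ)dλ` with V the
  CIE 1924 photopic efficiency function, embedded as the standard 5-nm
  table (380–780 nm) and spline-interpolated to the working grid.
  Integration is trapezoidal at 1 nm; the test suite checks the band
  integrals against a 0.1-nm quadrature oracle, and the monochromatic
  special case reproduces the candela definition (683 lux at 555 nm =
  100 µW/cm²) exactly.
* **Photon flux** uses `λ/(hc)` per-wavelength quantization inside the
  same integral, reported as log₁₀ photons/cm²/s.
* **Pigment templates** use the standard A1 visual-pigment nomogram
  (α band plus the short-wavelength β band) parameterized by the peak
  wavelength, normalized to 1 at λmax (the β band can push the raw curve
  a fraction of a percent above 1 near the peak; values are capped at 1
  so the template is a valid weighting function). Mouse pigments: S-opsin
  360 nm, M-opsin 508 nm, rod 498 nm, melanopsin 480 nm.
* **Lens transmission.** No tabulated mouse lens curve ships with the
  package; `mouse_lens_transmission()` is a documented *synthetic*
  logistic model (half-transmission 340 nm, scale 15 nm) that preserves
  the qualitative shape — near-full visible transmission with substantial
  near-UV transmission, which is what lets the 360-nm S-opsin see
  through the lens at all. It can be switched off (`model = "none"`).
  Because of this and the white-LED weights, per-opsin *absolute*
  effective fluxes are approximate; the package's validated claims about
  opsin stimulation are ordinal (blue/white ≫ green/red for S-opsin;
  green/white > blue > red for M-opsin), which is also how the assay's
  stimulus design is described.

Luminance regimes follow the stated boundaries — scotopic below
0.001 cd/m², mesopic on [0.001, 3], photopic above 10 — with the unnamed
overlap (3, 10] labelled `transition`; the mesopic interval is closed at
3 cd/m² so the equal-luminance condition (~3 cd/m²) classifies as mesopic.

## Cohort statistics

Aging cohorts are unbalanced (attrition is severe in old transgenic mice),
so `two_way_anova()` uses **Type-III sums of squares** (sum-to-zero
contrasts, via `car::Anova()` behind the module surface); on balanced
designs this reproduces the classical decomposition exactly, which the
tests verify against `aov()`. The published analyses do not state their
SS type; Type III is what the cited commercial software computes by
default for this design.

`fishers_lsd()` is the unprotected pairwise t on the pooled ANOVA error
term — no multiplicity correction, by definition; protection comes from
gating interpretation on the omnibus F. Group comparisons are run on raw
percentages (no arcsine/logit transform), matching how the assay's results
are reported.

Regressions of alternation on transition predictors follow the assay's
plotting convention (alternation on x, predictor on y); `R²` is invariant
to that choice in simple OLS, and the reported p is the slope t-test.
Composite predictors are *signed sums* of bidirectional percentages
(`composite_transition_score()`), the simplest rule consistent with the
described "positively and negatively paired" combinations; the pair sets
are arguments, not constants.

## The synthetic explorer

The simulator is a stand-in for real tracking data — its purpose is
pipeline testing and qualitative phenotype emulation, not biological
inference. At each step the animal in arm `c` chooses among the other
three arms with weight

```
w(b) = preference(b) × avoidance^[b is remembered as recently visited]
```

Memory covers the last `memory_span = 3` entries *including the current
arm* (the window size defining alternation, minus one). Each remembered
entry is recalled with probability `m`; a recalled visit to arm `a` is
misattributed to arm `b ≠ a` with probability `(1 − d(a,b))/3`, where
`d` is the pairwise discriminability. This concrete confusion kernel is
symmetric within a pair, reduces to perfect recall at `d ≡ 1`, and keeps
the step likelihood exactly computable. Low `d(B,W)` produces the
signature phenotype: standing in the white arm, the animal misattributes
its own current visit to blue and avoids blue (and vice versa), so the
blue↔white bidirectional percentage falls selectively — while entry
counts, which are driven by the renewal time process, are untouched. The
time process (exponential inter-entry intervals at `entry_rate` per
minute; exponential dwells truncated at the next entry and session end)
is drawn *before* the choice sequence, so paired seeds hold activity
exactly constant across choice-parameter manipulations. Dwell times are
exponential because the assay reports no dwell distribution; memoryless
dwells are the minimal assumption.

Presets were calibrated once, by simulation, to the reported cohort
phenotypes and then frozen: the WT preset (m = 0.85, avoidance 0.25, mild
red/dark preference, 6 entries/min) yields cohort mean alternation in the
mid-40s percent, inside the reported wild-type range (37.9–49.3%); the AD
preset (m = 0.55, avoidance 0.35, stronger red preference, 7.5
entries/min, `d(B,W) = 0.35`, `d(G,W) = 0.6`) yields means in the
mid-20s, inside the reported transgenic range (15.5–30.4%), with elevated
total activity and a selective blue↔white transition deficit.

What the generator does **not** emulate: spatial trajectories, speed or
distance (pass-through fields only), center-zone dynamics, within-session
fatigue or habituation, sex effects, and any perceptual mechanism other
than memory confusion. Passing tests therefore demonstrate the pipeline's
correctness on sequences with realistic first-order statistics, not that
the generative model is the true behavioral process.

## Likelihood and parameter recovery

With `memory_span ≤ 3` the step probability is an exact marginalization
over recall/confusion outcomes, implemented as a fold over tag *subsets*
(16 bitmask states) rather than outcome sequences. Because the likelihood
depends on the data only through (memory context, choice) counts — at
most `4·3·3` contexts of length 3 plus shorter start-up contexts — the
counts are aggregated once and each likelihood evaluation is a few
thousand floating-point operations, making bounded optimization
(`optimize`/`L-BFGS-B`) and profile-likelihood 95% intervals
(χ²₁ cutoff, other free parameters re-optimized) cheap. Degenerate
choice states (every candidate annihilated by `avoidance = 0`) fall back
to raw preference weights, identically in the sampler and the likelihood.

Recovery experiments in the test suite run at a well-identified operating
point (m = 0.9, avoidance 0.1): when memory drives choices strongly,
confusion events leave a clear signature and `d(B,W)` is estimated from
200 thirty-entry sessions with a standard error of about 0.03. At weaker
memory settings the same estimator remains consistent but needs more data
— the information about `d` scales with how much avoidance shapes
behavior. Fitting `memory_strength` to memoryless null data correctly
collapses to zero.

## Numerical conventions and test scales

* Percentages are reported on 0–100; probabilities on 0–1.
* All randomness is seeded per call (`withr::with_seed`); no function
  touches the caller's RNG state. Cohorts derive per-session seeds from
  the cohort seed, so a cohort is byte-reproducible.
* Ties in quartile selection break by canonical pair order; `-Inf` log
  fluxes denote unlit arms or zero spectral overlap (the latter with a
  warning).
* Event logs must be strictly ordered and non-overlapping; violations are
  errors naming the file line, not silent repairs.
* Test problem sizes: 1,000 random sequences against the alternation
  oracle; 10⁵ Monte-Carlo null windows; 10⁵-step null-equivalence
  chi-squared; 1,000 simulated null ANOVAs for type-I calibration; 21
  recovery fits at 200 sessions each. These sizes hold the full suite to
  a couple of minutes on a single core while keeping every Monte-Carlo
  bound at three standard errors or better.

## Known limitations

* Per-opsin absolute effective fluxes depend on the synthetic lens curve
  and the assumed white-LED band weights (ordinal statements are robust).
* The `N − 2` denominator slightly deflates alternation relative to the
  window count; cross-study comparisons should check which convention a
  given report uses.
* The ANOVA assumes independent sessions; repeated measures across
  illumination conditions are analyzed separately per condition, as in
  the assay's own reporting, not jointly.
* The simulator's discriminability mechanism is one of several that could
  produce pair-selective transition deficits; recovered `d` values are
  model-relative quantities.
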