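---
title: "Sorting-free deconvolution of subpopulation metabolite profiles: models and methods"
author: "mixdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting-free deconvolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixdeconv)
```

## The problem

Cultures induced into quiescence are mixtures: a G0 subpopulation co-occurs
with cells in G1, S and G2/M, and any bulk metabolome measurement averages
over both. Physically sorting the subpopulations perturbs the metabolome
within minutes (detachment, washing, centrifugation), so `mixdeconv`
implements the alternative: extracts are taken from two end-point cultures
with *different known* subpopulation compositions (an early, 8-h,
proliferation-enriched culture and a late, 96-h, G0-enriched one), mixed at
defined ratios, and measured in bulk by flow-injection time-of-flight mass
spectrometry (FIA-TOFMS). The composition gradient across the mix series
makes the per-cell contribution of each subpopulation identifiable by
regression.

## The mixture model

For each ion, the intensity of a mixed sample is modeled as

$$ I_{mix} = \alpha_P N_P V_P + \alpha_Q N_Q V_Q + \beta, $$

where $N_P$, $N_Q$ are the numbers of non-quiescent and quiescent cells in
the sample, $V_P = V_Q = 1$ by default (forward-scatter data motivate the
equal-volume assumption; the API accepts other values for sensitivity
analyses), $\beta$ is the ion-specific instrument background estimated as
the mean of cell-free blank injections, and $\alpha_P$, $\alpha_Q$ are the
relative per-cell abundances being estimated. With mixing fraction $f$ of
the early extract, a total of $N$ cells per sample, and gated G0 fractions
$g_8$ and $g_{96}$ of the two end-point cultures,

$$ N_Q = N\,(f\,g_8 + (1-f)\,g_{96}), \qquad N_P = N - N_Q . $$

The total $N$ is constant across mixes, so only the split varies; if
$g_8 = g_{96}$ every mix has the same composition and the design is
rank-deficient — `build_mix_design()` refuses it.

Across $K$ conditions (cell line × stimulus) the design matrix is block
diagonal with two columns per condition (`build_design_matrix()`), so the
joint fit over all conditions separates exactly into per-condition
two-parameter problems. Per ion, `fit_alphas()` solves

$$ \min_{\alpha \ge 0} \lVert (I_{mix} - \beta) - X\alpha \rVert^2 $$

with a Lawson–Hanson active-set non-negative least-squares solver
(`nnls_fit()`, KKT tolerance $10^{-10}$). Negative background-subtracted
intensities are kept as data (not floored); non-negativity is a constraint
on the coefficients, which are physical per-cell abundances. On blocks whose
unconstrained optimum is already non-negative the solution coincides with
the closed-form normal-equations solution, a property the test suite checks
to $10^{-10}$ relative on random interior blocks and against an independent
NNLS implementation.

### Bootstrap errors

Coefficient errors come from a residual (fixed-X) bootstrap, 100
repetitions by default: residuals are resampled with replacement *within
each condition block* (the design is fixed by construction, and block-wise
scoping preserves per-condition error structure), added to the fitted
values, and the constrained model is refit; the error is the SD of the
bootstrap draws. On interior solutions with homoscedastic noise the
bootstrap SD tracks the analytic OLS standard error
$\sigma\sqrt{(X^\top X)^{-1}_{jj}}$, with the usual mild downward bias of
raw-residual resampling (factor $\sqrt{(n-p)/n}$, about 4% at $n = 24$).

### Purified profiles

The end-point samples can also be "purified": the modeled contribution of
the minor subpopulation is subtracted, e.g. for the 96-h sample
$I_{G0} = I_{mix} - \alpha_P N_P V_P$, and the remainder is normalized per
focal-population cell. The instrument background is *not* subtracted here —
the purified per-cell value is $\alpha_Q + \beta/N_Q$, which equals
$\alpha_Q$ exactly when $\beta = 0$ — matching the definition of the
purification step as removal of the other population's contribution only.
Negative purified values are floored at zero and flagged. All downstream
statistics use the $\alpha$ coefficients, which are invariant to cell
numbers and pool information across the whole mix series.

## Upstream QC: linearity and biological origin

The model assumes intensities respond linearly to extracted biomass.
`detect_saturation_limit()` operationalizes the saturation limit as the
lowest mean intensity above which the successive-difference slope,
normalized by the initial-region slope (OLS on the first three levels),
stays below a relative cutoff (default 0.1, configurable) for all later
intervals; the concept is descriptive in the source methodology and the
persistence rule here is our concrete choice. Ions already within a factor
2 of their limit in the unspiked extract should be treated as saturated —
the factor is configurable since no published value exists.
`fit_base_model()` then fits the unsaturated points by OLS, and
`cross_matrix_r2()` tests slope transfer to another extract matrix by
refitting only the intercept — its $R^2$ may legitimately be negative when
the fixed slope fits worse than a constant.

`biological_origin_filter()` keeps ions whose intensity scales with the
number of cells extracted in at least one cell line: a stacked per-ion
regression with one slope per cell line and a single shared intercept
pinned by blank (zero-cell) rows. The retention threshold is
family-wise-Bonferroni, $\alpha_{fw}/(n_{ions} \times n_{lines})$ with
$\alpha_{fw} = 0.05$; for 2,099 annotated ions in 6 cell lines this gives
the threshold 3.97e-06 ($\alpha_{fw}$ itself is not printed in the source
methodology; 0.05 reproduces the printed threshold exactly).

## Cytometry gating

`classify_phases()` implements univariate DNA-content gating with an RNA
split for G0: the 2n and 4n peaks are picked from a kernel-smoothed DNA
histogram (bandwidth = Freedman–Diaconis bin width; the two most prominent
modes whose ratio lies in a 1.7–2.3 band; a single mode falls back to
$4n = 2 \times 2n$ with a warning), DNA windows extend $k = 2.5$ robust SDs
(MAD of the mode's ±10% neighbourhood) around each peak, S is strictly
between the windows, and G0 is separated from G1 inside the 2n window by an
RNA threshold. The stated classification rule — G0 has RNA content below the
S and G2/M phases — gives no numeric recipe, so the threshold is
operationalized as the 5th percentile of RNA among events in the S/G2M DNA
region of the *reference* sample (a robust lower envelope of the
proliferating RNA distribution; percentile configurable). Gates derived on
the 8-h sample of a cell line are reused on its 96-h sample, mirroring the
reference-gating scheme. Deriving a threshold requires at least 1% of
reference events in the S/G2M region; a pure-G0 reference fails loudly
rather than thresholding on its own tail. All steps are equivariant under
positive rescaling of either channel.

## Differential statistics

Effect sizes standardize the Q−P difference to the pooled bootstrap SD,
$d = (\alpha_Q - \alpha_P)/\sqrt{(SD_P^2 + SD_Q^2)/2}$; negative $d$ means
lower abundance in quiescent cells. `g0_association()` then asks, per ion,
how consistently $|d|$ exceeds a threshold with one sign across the 18
condition models (6 cell lines × 3 stimuli), scanning thresholds from 3
upward in steps of 1 to the ceiling of the mean absolute effect size (the
fixed grid 3–13 can be supplied). Significance at each threshold is the
upper-tail hypergeometric probability of drawing at least the observed
number of passing entries when sampling the ion's number of conditions from
all same-sign entries pooled over the whole table; the per-ion minimum over
thresholds is reported and Benjamini–Hochberg correction is applied across
ions at the end. Two ambiguities required decisions: the draw count is the
ion's total condition count (18), truncated to the pooled population size —
an alternative reading (draws = the ion's same-sign count) is available via
`draws = "same_sign"`; and a sign tie at a threshold is broken toward the
larger summed $|d|$ with a tie flag. The selection of the best threshold
before BH induces some optimism under the null; that is inherent to the
published procedure and is reproduced rather than corrected (the suite
verifies the realized null discovery fraction at adjusted $p < 0.01$ stays
below 0.02 on 1,000 exchangeable ions).

`stimulus_anova()` (one-way fixed-effects F-test per ion, BH across ions)
and `dynamic_fold_change()` (per-ion steady-state abundance–confluence
regression, $\log_2$(measured/expected) at matching confluence, unpaired
t-test against unperturbed samples, BH) round out the downstream analyses.

## Growth kinetics

`moving_window_rates()` fits OLS lines to $\log_{10}$ confluence in moving
windows: a 24-h window equals 16 consecutive points at the 1.5-h imaging
interval (the window is `round(window/dt)` points, following that
counting), shifted by `round(shift/dt)` points — the nominal 8-h shift
quantizes to 5 points (7.5 h) on a 1.5-h grid, recorded in the output
attributes. The lag time is the intersection of the max-rate window's
tangent with the initial confluence, $lag = (\log_{10} c_{init} - a)/b$;
windows with mean confluence above 0.95 are excluded from max-rate
selection so the tangent is never taken on a saturated stretch, and a
non-positive maximum rate yields a censored lag. Lags are computed
per-replicate (means ± SD are the caller's summary). Expected lags at a
given initial confluence interpolate untreated reference pairs linearly;
out-of-hull queries extend the nearest segment and are flagged.

## Annotation

`annotate_ions()` matches measured m/z against reference monoisotopic
masses computed from elemental formulas (most-abundant-isotope masses;
C, H, N, O, P, S plus common hetero-elements). The default adduct rule is
deprotonation ($[M-H]^-$, expected m/z $= M - 1.007276$) — an assumption,
configurable to $[M+H]^+$ or neutral matching, since polarity is not fixed
by the method description. The 0.003 m/z tolerance is strict (`<`) by
default with inclusivity configurable. α-keto acids detected as
phenylhydrazone derivatives are handled by `derivatize_keto_acids()`
(+C6H8N2−H2O, +90.0582 Da, identifiers prefixed `PHderiv_`); the bundled
reference list contains a few dozen common metabolites and keto acids and
does not claim equivalence to any external database — full Recon3D/HMDB
lists are user-supplied inputs.

## The synthetic-experiment generator

Every stage is exercised against `simulate_mix_experiment()`,
`simulate_spikein_series()`, `simulate_cytometry_events()` and
`simulate_confluence_curve()`, which store their ground truth. Defaults
mirror the study conditions: the eight-point mixing design (100, 85, 70,
55, 40, 25, 10, 0% of the early extract), three replicate mixes, $10^4$
cells per sample, G0 fractions 0.2 (8 h) and 0.6 (96 h) — within the
reported 30–60% end-point range and the roughly 2.25-fold enrichment —
spike series spanning three decades (3–3000 pmol style), and 1.5-h
confluence sampling.

No error model is published for the instrument, so measurement noise is
multiplicative log-normal (mean-preserving, parameterized by a CV of 10%
by default, in the 5–15% range typical of untargeted flow-injection
intensities) plus an optional additive Gaussian floor for the
detection-limit regime; saturation is a hard clip. Cytometry clouds are
log-normal in both channels (DNA CV 4%, typical of good Hoechst staining);
G0 and G1 sit at the 2n DNA peak, G2/M at twice it, and S-phase events are
drawn uniformly over the interior of the 2n–4n gap with a 20% margin per
side, so the default clouds satisfy the separation the gating guarantees
are stated for. The proliferating phases share high RNA locations while G0
sits far below — the feature the G0 gate keys on.

What the simulator does **not** emulate: raw spectra, isotope patterns,
ion suppression beyond a hard clip, doublets or debris in cytometry,
cell-cycle-correlated volume changes, or biological coupling between
subpopulations (the model's own no-interaction assumption). Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to violations of it.

## Numerical choices and degenerate inputs

* NNLS: active-set on the normal equations, KKT tolerance $10^{-10}$
  relative; rank-deficient blocks are flagged unidentifiable, never
  silently zeroed.
* Zero pooled SD makes an effect size undefined (`NA`, excluded
  downstream); `bh_adjust()` excludes `NA`s from the number of tests.
* Exactly constant groups leave the dynamic-profiling t-test undefined
  (`NA`) rather than erroring the whole table.
* Equal G0 fractions at the two end points, missing blanks, a reference
  cytometry sample without proliferating cells, fewer than three
  unsaturated spike points, and zero focal cells during purification are
  all refused with named errors.
* Noise-free generation is bit-identical across calls; all stochastic
  paths are reproducible from a single integer seed.

## Problem sizes

The shipped test suite and the acceptance script run at deliberately
moderate sizes — 200–500 synthetic ions, 100 bootstrap repetitions, $10^4$
cytometry events, 1,000 ions for null calibration — chosen as the smallest
sizes at which the statistical guarantees (median relative error, SE
calibration, discovery-rate control) are stable across seeds. The same
code paths scale to the full-experiment shape (thousands of ions, 18
conditions, 432 mix samples) unchanged.

## Known limitations

* Only the two-subpopulation case is validated end-to-end; the design
  builder is written for it, although the regression scheme generalizes in
  principle.
* The hypergeometric draw-count ambiguity (see above) means association
  p-values under the two readings differ for ions with missing conditions.
* The gating reproduces the stated classification rule, not any manual or
  visual gate placement.
* Confluence is taken as given; no image analysis is performed.
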