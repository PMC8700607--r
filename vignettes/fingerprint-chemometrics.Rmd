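---
title: "Chromatographic fingerprint chemometrics for tea authentication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatographic fingerprint chemometrics for tea authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tea is among the foods most exposed to economically motivated adulteration;
roasted chicory root (*Cichorium intybus*) is a classic undeclared filler.
`chromauth` implements an untargeted authentication workflow: the full
HPLC-UV (280 nm) and HPLC-FLD (280/350 nm) detector traces of hot-water tea
extracts are used whole — absorbance or fluorescence versus retention time
over a 0–25 min run — as chemical descriptors, with no peak identification
or integration. Partial least squares discriminant analysis (PLS-DA)
classifies five tea varieties (black, green, oolong, red/pu-erh, white)
against chicory, and PLS regression quantifies the chicory percentage in
tea/chicory blends.

The raw chromatograms of the original campaign are not publicly deposited,
so the package ships a seeded synthetic chromatogram generator that
reproduces the campaign's statistical structure. All workflows run
end-to-end on generated data, and every stochastic step is controlled by one
integer seed.

## The synthetic campaign

`generate_dataset(run_config(), seed)` emulates a 107-extract study:

* **Class templates.** Each class is a set of Gaussian peaks with per-channel
  amplitudes. The defaults encode the qualitative fingerprint structure of
  the six classes: every tea shares an intense UV peak near 11 min; chicory
  is the UV-richest fingerprint but with intensities about 100-fold below
  any tea; white tea gives the most intense UV profiles; black and green
  teas dominate in FLD intensity; red tea and chicory are the most peak-rich
  in FLD. White tea is split into two sub-templates (`white_a`, `white_b`,
   5 + 5 samples) that both report the label `"white"`, `white_b` carrying two
  low-intensity peaks at chicory retention times — commercial white teas come
  from two distinct productions, one of which crowds the chicory region of
  the score plots. On top of the major named peaks every template carries a
  deterministic background of 10–30 minor peaks (2–10% of the class maxima,
  fixed positions per class): real fingerprints are dense, and without this
  background most retention-time variables would be pure noise, which after
  autoscaling produces a noise-propagation floor in PLS that real data do
  not show.
* **Variability.** Each sample (lot) draws per-peak lognormal amplitude
  factors (CV 5%) and one shared retention shift (s.d. 0.02 min) applied to
  the whole injection — retention drift moves all peaks together. Each
  injection adds a two-cosine low-frequency baseline (random phases,
  amplitude 2% of the class maximum) and white noise (s.d. 0.5% of the class
  maximum).
* **Sequence and drift.** Samples are injected in seeded random order; a
  pooled QC (the unweighted mean of all drift-free sample traces) opens the
  sequence and, after every 10 sample injections, an instrumental blank and
  a QC follow (12 QCs and 11 blanks for 107 samples). Detector sensitivity
  drifts multiplicatively: `s(i) = (1 + slope (i-1)/(N-1)) exp(walk_i)` with
  default slope −0.15 and walk s.d. 0.005 per injection, one walk per
  channel. A `drift_model(factors = ...)` override supports arbitrary drift
  shapes; `qc_block_factors()` builds the block-constant case in which a
  sample and its nearest QC share one factor, isolating the QC correction
  from within-block drift.
* **Grid.** 0–25 min at 0.01 min per point (2501 variables). Tests and
  examples that do not need full resolution use a 0.05 min grid.

What the generator does **not** emulate: peak tailing and co-elution shape
effects, gradient-dependent baseline chemistry, detector saturation, and
compound identities. Passing tests therefore demonstrate the correctness and
internal consistency of the chemometric pipeline under a realistic data
model, not instrument-level fidelity.

## Preprocessing

`preprocess_fingerprints()` applies, in fixed order: Savitzky–Golay
smoothing (window 11 points, order 3), asymmetric least squares baseline
estimation (λ = 1e5, p = 0.01, 10 weight iterations; the estimate minimises
a penalised asymmetric squared loss so peaks sit above the baseline),
segmented integer-lag alignment, and optionally the nearest-QC division.
Autoscaling is deliberately left to the modelling step so prediction rows
can be scaled with calibration statistics only.

Numerical choices that matter:

* **Alignment** maximises the cross-correlation of each of 10 segments with
  the corresponding segment of the mean QC trace, shifting by at most
  `align_max_shift` points (ties prefer the smallest lag). The default bound
  is 5 points (0.05 min): it must cover the injection-to-injection retention
  variation (s.d. 2 points) but stay below the distance between neighbouring
  peaks of *different* compounds, otherwise a segment holding a single
  class-specific peak is pulled onto the nearest feature of the pooled
  reference and distinct compounds are relocated onto each other. Segments
  whose reference trace is effectively flat (s.d. below 1% of the whole
  reference's s.d.) are left unshifted — any lag preference there is pure
  noise.
* **QC division** divides every trace point-wise by the QC nearest in
  injection order (ties toward the preceding QC; a QC always opens the
  sequence), as `(x + ε)/(q + ε)` with `ε = qc_epsilon_frac · max(q)`. Every
  QC row becomes exactly all-ones, and multiplicative drift shared by a
  sample and its QC cancels. The default floor is 5% of the QC maximum:
  after baseline correction a QC trace dips a few percent *below* zero in
  signal-free regions (noise plus asymmetric-least-squares undershoot), so
  any floor below that envelope lets denominators cross zero and turns the
  ratios into heavy-tailed noise.
* **Autoscaling** zeroes columns with s.d. below 1e-12 instead of dividing
  by them.

## The chemometric engine

`pls_fit()` is classical NIPALS PLS2 with X-deflation and Y-deflation,
convergence tolerance 1e-10 and at most 500 iterations per latent variable
(one pass suffices for univariate responses). X is autoscaled internally and
Y mean-centered; coefficients act on the autoscaled space and predictions
fold the scaling back in. Weight vectors are sign-normalised (largest
element positive). Successive score vectors are orthogonal by construction;
rank exhaustion truncates the model at the achieved component count.
`pca_fit()` is a thin wrapper over the singular value decomposition.

Model complexity is chosen by venetian-blind cross-validation
(`cross_validate_pls()`, default 10 blinds; test fold *k* takes samples *k*,
*k + 10*, *k + 20*, …), each fold autoscaled on its training part only.
`select_lv()` returns the smallest count whose error is within 2% of
anything achievable with more components — an operational reading of "the
first important minimum of the CV error". For PLS-DA the cross-validated
quantity is the misassignment rate rather than the response RMSECV, matching
how classification models are reported.

## Classification workflows

`paired_plsda_study()` subsets one tea variety plus chicory, splits 70/30
stratified per class (`ceiling(0.7 n_c)` to calibration, seeded — so the
small classes appear in both sets), fits PLS-DA on a one-hot response and
reports calibration and prediction classification rates. Two-class models
assign by a 0.5 threshold on the chicory response with ties going to the tea
class, so adulterant calls are conservative; multi-class models use argmax.
On the default dataset all five paired models reach 100% on both sets in
both channels.

## Adulteration quantitation

`run_adulteration_study()` blends one tea and one chicory extract (ideal,
drift-free traces) linearly at the design levels — calibration at
0/20/40/60/80/100% chicory, external validation at 15/25/50/75/85%, five
replicates each, fresh baseline and noise per replicate (noise constant
across the block, referenced to the larger extract maximum: detector noise
does not scale with the analyte). A prediction set at 15/50/85% uses
*different* extracts of the same classes; reusing a calibration extract is
an error. Mixtures are preprocessed (no QC division — the standalone design
carries no QCs), the latent-variable count is cross-validated, and the
report row carries LVs, R², RMSEC, RMSECV, external-validation RMSE and
prediction RMSE, all in percentage points of adulterant (pooled over levels).

For white tea the calibration extract comes from one sub-type and the
prediction extract from the other, so prediction errors are an order of
magnitude above the other teas' — the deliberate analogue of the original
campaign's white-tea failure, attributed to low within-class variability.
Predicted percentages are monotone in the true level, and PC1 of a mixture
calibration set orders the scores from pure tea to pure chicory.

## Default problem sizes

The shipped workflows run the full design: 107 samples + 12 QCs + 11 blanks
on 2501 variables per channel, ten paired or adulteration studies per
campaign. Property-style tests that need many repetitions (e.g. the
validation-versus-calibration error ordering over 20 seeds) use the 0.05 min
grid and reduced class counts; those sizes are stated in the tests
themselves.

## Known limitations

* Gaussian peaks only; no tailing, co-elution or saturation.
* Linear mixing of extract traces; real blends add pipetting error and
  matrix effects.
* The alignment is integer-lag and segment-wise; it does not warp within
  segments (no COW/DTW).
* The QC division floor biases ratios toward 1 in signal-free regions; this
  is intentional damping, not an unbiased estimate of the drift there.
* With classes whose peak sets barely overlap, aligning against a pooled
  reference is only well-posed for small admissible shifts (see above).
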