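---
title: "Ordinal entropy-complexity analysis of ischaemic ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal entropy-complexity analysis of ischaemic ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgcomplexity)
```

## The model and its assumptions

The package treats each cardiac beat as a short stationary segment of the
ECG **vector modulus** `M(t) = sqrt(X² + Y² + Z²)`, the Euclidean magnitude
of the orthogonal vectorcardiographic leads. The modulus condenses the
spatio-temporal cardiac vector loop into one non-negative series and is
invariant under rotations of the XYZ frame, which makes it robust to
electrode placement differences between sessions.

Each 512 ms beat window is encoded with the Bandt–Pompe ordinal scheme: the
window is scanned with embedded subvectors of length `D` at delay `τ`
samples, and each subvector is replaced by the permutation describing the
rank order of its values. Amplitudes are discarded; only ordering survives.
The only assumptions this places on the data are (i) finite values and (ii)
that the probability of an order relation between samples a fixed lag apart
does not depend on time within the window — mild compared to spectral or
model-based descriptions, which is the method's main attraction for
nonstationary pathology.

From the pattern distribution `p` of a beat the package computes:

* Shannon entropy `S[p] = −Σ pⱼ ln pⱼ` (natural log throughout) and the
  normalized permutation entropy `H = S / ln L`, `L = D!`;
* the Jensen–Shannon divergence
  `D_JS[p, q] = S[(p+q)/2] − S[p]/2 − S[q]/2`, whose square root is a
  metric;
* disequilibrium `Q = Q₀ D_JS[p, p_e]` against the uniform distribution
  `p_e`, with `Q₀` the inverse of the maximal possible divergence so that
  `Q ∈ [0, 1]`;
* statistical complexity `C = H · Q`, which vanishes both for fully ordered
  and fully random signals and therefore separates processes that identical
  entropies would conflate.

A beat is a point `(H, C)` in the causal plane; a phase of a recording is a
trajectory of window-averaged points; a patient's occlusion is summarized by
the relative endpoint changes `δH` and `δC` and by the JSD of each beat to
the patient's **Mean Control PDF** (the arithmetic mean of all control beat
PDFs, renormalized).

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `D` | 4 | – | 24 symbols are estimable from the ~506 windows of one beat; `D = 5` (120 symbols) would not be |
| `tau` | 2 | samples (2 ms at 1 kHz) | matches the fast time scale of intra-QRS and ST-T slopes |
| `window_ms` | 512 | ms | covers a full cardiac beat at ordinary heart rates |
| `xcorr_threshold` | 0.75 | – | template acceptance gate |
| `rms_limit` | 20 | µV | record exclusion on pre-Q RMS noise |
| `pre_q_ms` | 20 | ms | isoelectric segment used for the noise gate and baseline knots |
| `occlusion_window_s` / `recovery_window_s` | 30 / 15 | s | trajectory averaging windows |
| `line_freq` | 60 | Hz | mains notch (set 50 for European recordings) |
| `alpha` | 0.05 | – | significance level for the normality gate and section tests |

A 512-sample window with `D = 4`, `τ = 2` yields `512 − 3·2 = 506` pattern
windows, about 21 per symbol — enough for a usable per-beat estimate, while
`ordinal_pdf()` warns whenever a caller drops below 5 windows per symbol.

## Design choices where the procedure was genuinely open

**Pattern enumeration.** Patterns are indexed by the position of the
window's rank word in the reverse-lexicographic ordering of permutations:
for `D = 3` the order is (321), (312), (231), (213), (132), (123), so the
fully descending window is type 1 and the fully ascending is type `D!`.
This reproduces the canonical worked example — `{1,2,5,4,3,5}` types 6, 5,
1 — and extends deterministically to `D = 4`.

**Ties.** Ties are broken by temporal order (the earlier sample gets the
lower rank), the standard Bandt–Pompe convention; it makes a constant
segment read as "ascending" rather than crashing or randomizing. No jitter
is injected, keeping the encoding deterministic.

**PDF normalization.** Probabilities are normalized by the actual number of
extracted windows, `K − (D−1)τ`. Printed formulations of the estimator
sometimes carry a `K − (D−1)` denominator; that choice only sums to one for
`τ = 1`, so the package uses the window count for every delay.

**The constant `Q₀`.** `Q₀ = 1 / D_JS[δ, p_e]` is evaluated in closed form
from the divergence between a degenerate distribution and the uniform. That
the degenerate distribution is the global maximizer is verified in the test
suite by numerical maximization over the simplex at `L = 6` (multi-start
BFGS on a softmax parametrization plus corner-biased Dirichlet sampling).

**The Cmin/Cmax envelope.** The bounds are built from the two standard
one-parameter extremal families: for `Cmin`, one component `p ∈ [1/L, 1]`
with the rest equal; for `Cmax`, branches with `m = 0 … L−2` components at
zero, one free component `p ∈ [0, 1/(L−m)]` and the rest equal — branch `m`
joins the uniform over `L−m−1` symbols to the uniform over `L−m` symbols.
Each branch is a smooth curve monotone in `H`, so each is interpolated onto
the `H` grid and the pointwise extremes taken; parameter grids are
quadratically concentrated near `p = 0` where `−p ln p` makes `H` move
fastest. The construction is validated by containment of 10,000 random
distributions and by a dense brute-force scan at `L = 6`.

**Notch filter.** "2nd-order Butterworth at 60 Hz" is read as a band-stop
with ±1 Hz edges, applied forward–backward (`filtfilt`) for zero phase —
a low-pass at 60 Hz would destroy the QRS. The mains frequency is a
configuration parameter.

**Baseline correction.** One spline knot per beat at the midpoint of the
20 ms pre-Q segment, with the local baseline estimated as the median
voltage in that segment: the PR region is isoelectric, so whatever voltage
sits there is wander. A natural cubic spline through the knots is
subtracted per lead. The correction runs after the notch filter and before
the Kors transform; detection runs on the notched lead II, so the knots are
available in time.

**R detection and the Q point.** The built-in detector (band-pass 5–25 Hz,
squared derivative, 120 ms integration, adaptive threshold, 250 ms
refractory) is a deliberately simple stand-in for full ECG delineation,
adequate for clean or synthetic records; externally supplied fiducials in
the sidecar JSON bypass it for exact reproduction on annotated data. The Q
onset is taken as the last sample before R where the band-passed slope
falls below 5 % of the upstroke slope, capped at 80 ms before R.

**Beat acceptance and jitter.** Correlation is computed over the full
512 ms window, maximized over lags within ±50 ms; the maximum-lag
correlation (rather than zero-lag) is compared with the 75 % threshold
because it subsumes the subsequent jitter correction, which is an
integer-sample shift to the best lag (no sub-sample interpolation).
Normalized correlation makes acceptance invariant to amplitude scaling.

**Record-level noise gate.** The RMS is measured on the 40 Hz high-pass
residual of the modulus over the pre-Q segment — an isoelectric stretch
where any high-frequency power is noise — and the whole record is excluded
when the *median* per-beat RMS exceeds 20 µV; per-beat values are retained
for diagnostics. The median makes the record decision robust to a few
locally noisy beats.

**Averaging target.** Window averages are taken over per-beat quantifiers
(H, C, JSD), not over pooled PDFs: the trajectory is the mean state of the
beats in a window, not the state of a pooled pseudo-beat.

**Statistics.** Section comparisons are unpaired (group sizes differ after
QC), gated by the D'Agostino–Pearson omnibus test on both samples; no
multiple-testing correction is applied to the per-section p-values, and
samples below n = 8 (where the kurtosis transformation is undefined) are
routed directly to the Mann–Whitney branch. Recovery sections default to
15 s to mirror the recovery window width; occlusion sections to 30 s.

**δ endpoints.** "Initial" and "final" are the first and last *non-empty*
windows; deltas are not computed when fewer than two windows hold beats.
Incomplete final windows are kept when at least half of their span lies
inside the phase.

## The synthetic generator: what it emulates, what it does not

The generator exists to exercise the pipeline end to end with known ground
truth; it is not a physiological simulation. Each beat is a sum of
Gaussian-shaped P/Q/R/S/T components on an XYZ dipole, projected to the
eight standard leads through a right-inverse of the Kors matrix (so the
Kors transform recovers the dipole exactly), with baseline wander in the
respiratory band, white measurement noise per lead, and 0.6 µV amplitude
quantization. Cohort defaults mirror the emulated study design: 24
patients (9 LAD-like, 15 RCA-like), a 300 s control record, occlusion
durations drawn around 246 s with a 90 s standard deviation, recovery
around 222 s, heart rates around 70 bpm.

The two ischaemia profiles are qualitative:

* **LAD-like** — a broad ST-T "merge" component ramps up linearly over the
  occlusion, deforming the beat towards a monophasic, action-potential-like
  wave. Smooth high-amplitude slopes dominate more of the window, so
  ordinal patterns concentrate on the monotone types: `H` falls, `Q` and
  `C` rise.
* **RCA-like** — quiescent for the first half of the occlusion, then
  broadband micro-fluctuation confined to the ST-T segment ramps up,
  emulating increased repolarization irregularity: pattern diversity grows,
  `H` rises, `C` falls. The fluctuation must be fine-scale: at `τ = 2` ms
  any *smooth* morphological change adds order and lowers entropy, so
  beat-to-beat variability alone cannot raise per-beat `H`.
* **Reperfusion (both)** — the morphology starts from a regularized
  post-deflation state (moderate ST-T merge, no irregularity) and decays
  exponentially to control, so entropy recovers upward and complexity
  downward for both profiles.

The free generator levels were calibrated once, under a fixed seed, so that
the synthetic control region is narrow and sits in the empirically reported
regime (H ≈ 0.83–0.85, C ≈ 0.14–0.16, near the `f^(−2.5)` landmark):
per-lead noise 4 µV RMS, wander 60 µV, `st_max = 1`,
`stt_sigma_max = 12` µV. They live in `cohort_spec()`, not in the
algorithms. What passing tests on this generator shows is that the
*pipeline* recovers the directional signatures (`δH < 0, δC > 0` for
LAD-like occlusion; `δH > 0, δC < 0` for RCA-like; `δH > 0, δC < 0` in
recovery) from raw multi-lead signals; it does not show that real LAD/RCA
occlusions behave this way — the generator was built to emulate those
reported directions, not to predict them. Real ischaemia features the
generator does **not** model include heart-rate drift and arrhythmia,
ectopy, electrode motion artefacts, T-wave alternans, and any coupling
between occlusion site and lead-specific ST vectors.

## Numerical choices and degenerate inputs

* Entropies use the `0 · ln 0 = 0` convention; JSD is clamped at zero
  against rounding; estimated PDFs are renormalized after averaging.
* Constant windows encode as the fully ascending pattern (tie rule), giving
  `H = 0`, `C = 0` rather than an error.
* Flat or empty signals produce an empty beat set with a warning; records
  with no accepted control beats are excluded with a logged reason, as are
  records tripped by the noise gate.
* Beats whose 512 ms window would cross a record edge are dropped and
  counted; jitter-corrected windows that would cross an edge keep their
  original alignment.
* The envelope uses a 1000-point `H` grid by default; containment checks
  allow a 1e-6 interpolation tolerance.
* All randomness (generator, k-noise, landmark Monte-Carlo) flows from the
  single configuration seed; per-patient streams are derived as
  `seed·1000 + patient` so any patient can be regenerated in isolation.

## Problem sizes used by the validation battery

The test suite validates the quantifiers against brute-force oracles
(exhaustive window enumeration for short series, dense extremal-family
scans for the envelope, numerical maximization for `Q₀`), the spectral
calibration of `f^(−k)` noise at `n = 2^16` over 20 seeds, and the full
directional recovery on a 24-patient synthetic cohort at the default
durations — the sizes were chosen to estimate each quantity stably while
keeping a complete run of the suite in the minutes range on a single CPU.

## Known limitations

* The built-in R detector is not a clinical delineator; for real PTCA
  recordings, supply fiducials from a validated delineation algorithm via
  the sidecar annotations.
* The package reads a plain CSV dialect (plus annotation JSON); native
  binary waveform formats must be converted on ingest.
* Per-beat ordinal PDFs at `D = 4` from 506 windows carry estimation noise
  of a few percent per symbol; trajectory conclusions should rest on
  window averages, as implemented, not on single beats.
* The H×C location of a beat depends on the sampling rate through `τ`;
  comparisons across datasets require a common `fs` (or delay rescaling).
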