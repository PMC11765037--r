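# ecgcomplexity

Entropy–complexity plane analysis of multi-lead ECG during acute myocardial
ischaemia.

## What this package does

During balloon occlusion of a coronary artery (PTCA), the ECG deforms in
ways that differ by occlusion site: left anterior descending (LAD) occlusion
tends to raise and merge the ST-T complex into a single action-potential-like
wave, while right coronary artery (RCA) occlusion tends to increase the
beat-to-beat irregularity of repolarization. This package quantifies those
spatio-temporal changes with ordinal information theory, placing each beat of
the ECG **vector modulus** in the **entropy–complexity (H×C) causal plane**
and following its trajectory through the control, occlusion and reperfusion
phases.

The processing chain:

1. **Preprocessing** — 2nd-order Butterworth notch at the mains frequency,
   cubic-spline baseline correction anchored on the isoelectric pre-Q
   segments, Kors transform of the 8 standard leads (I, II, V1–V6) to
   orthogonal X, Y, Z, and the vector modulus
   `M(t) = sqrt(X² + Y² + Z²)`.
2. **Beat processing** — R-wave detection on lead II (or annotation-supplied
   fiducials), 512 ms windows centred on each R wave, a median QRS template,
   normalized cross-correlation acceptance at 75 % with integer-sample jitter
   correction, and a 20 µV RMS noise gate on the 20 ms pre-Q segment.
3. **Ordinal quantifiers** — each beat window is encoded into Bandt–Pompe
   ordinal patterns (embedding dimension `D = 4`, delay `τ = 2`, hence
   `L = 4! = 24` symbols), giving a probability distribution `p` per beat,
   from which

   - normalized permutation entropy `H[p] = S[p] / ln L`,
     `S[p] = −Σ pⱼ ln pⱼ`;
   - disequilibrium `Q[p] = Q₀ · D_JS[p, p_e]`, the normalized
     Jensen–Shannon distance to the uniform distribution `p_e`;
   - statistical complexity `C[p] = H[p] · Q[p]`,

   together with the `Cmin(H)` / `Cmax(H)` envelope of the plane and the
   per-beat Jensen–Shannon divergence `D_JS[p, p_MC]` to the patient's
   **Mean Control PDF** `p_MC` (the average ordinal PDF of all control
   beats).
4. **Trajectory analysis** — quantifiers averaged in 30 s windows during
   occlusion and 15 s windows during recovery; relative endpoint changes
   `δH, δC`; control JSD split into matched sections; per-section
   cross-patient statistics (D'Agostino–Pearson normality gate, then
   Student's t or Mann–Whitney U); the control-region box; and `f^(−k)`
   noise landmarks (`0 ≤ k ≤ 3`) as plane references.
5. **Synthetic cohort generator** — phase-structured 8-lead records at
   1 kHz with ground-truth fiducials, emulating the study design (control
   record plus PTCA record, LAD-like and RCA-like morphology profiles),
   used by the test-suite for end-to-end validation.

## Worked example

The ordinal typing of the series `{1, 2, 5, 4, 3, 5}` with `D = 3`,
`τ = 1` under the enumeration `(321), (312), (231), (213), (132), (123)`:

```r
library(ecgcomplexity)
ordinal_encode(c(1, 2, 5, 4, 3, 5), D = 3, tau = 1)
#> [1] 6 5 1 4
```

The first window `(1,2,5)` is fully ascending (type 6), `(2,5,4)` is type 5,
`(5,4,3)` fully descending (type 1). An `f^(−2.5)` noise series lands where
stable ECG controls live in the plane:

```r
p <- ordinal_pdf(generate_knoise(2.5, 2^14, seed = 1), D = 4, tau = 2)
statistical_complexity(p)
#> HxC point: H = 0.8358, C = 0.1559 (Q = 0.1865)
```

A small synthetic study (4 patients, shortened phases) reproduces the
directional ischaemia signatures:

```r
spec <- cohort_spec(n_patients = 4, arteries = c("LAD","LAD","RCA","RCA"),
                    control_s = 120, occlusion_mean_s = 180,
                    occlusion_sd_s = 30, recovery_mean_s = 90,
                    recovery_sd_s = 20)
st <- run_study(spec, run_config(seed = 42))
summary(st)
#> HxC study summary - synthetic cohort (n=4, seed=42) (4 patients, 0 excluded)
#> Control region: H 0.830-0.840 x C 0.150-0.156 (16 windows)
#>
#> Mean relative endpoint changes by occlusion site:
#>   LAD  occlusion deltaH  -11.4%  deltaC  +31.3%
#>   LAD  recovery  deltaH   +4.1%  deltaC  -10.1%
#>   RCA  occlusion deltaH  +10.1%  deltaC  -42.4%
#>   RCA  recovery  deltaH   +1.2%  deltaC   -3.0%
#>
#> occlusion vs control: 3 of 6 sections significant
#> recovery vs control: 3 of 6 sections significant
#>
#> k-noise landmarks (H, C):
#>   k = 0   H 1.000  C 0.000
#>   k = 1   H 0.993  C 0.009
#>   k = 2   H 0.929  C 0.080
#>   k = 2.5 H 0.826  C 0.162
#>   k = 3   H 0.595  C 0.256
```

Reading the output: LAD-like occlusion moves beats towards **lower entropy
and higher complexity** (the signal becomes more ordered but more
structured), RCA-like occlusion towards **higher entropy and lower
complexity** (more stochastic), and reperfusion raises entropy and lowers
complexity for both — with the control region sitting close to the
`k = 2.5` noise landmark. `plot(st)` draws the trajectories inside the
`Cmin`/`Cmax` envelope. Real recordings enter through `read_ecg_csv()`
(time + one column per lead, µV) with a sidecar annotation JSON carrying
`control`, `inflation`, `deflation`, `end` times and optional
`r_samples`/`q_samples` fiducials; `analyze_patient()` and `run_study()`
consume them identically to synthetic records.

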