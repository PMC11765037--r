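Package: ecgcomplexity
Title: Entropy-Complexity Plane Analysis of Multi-Lead ECG During Acute Ischaemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinal-pattern (Bandt-Pompe) analysis of the electrocardiographic
    vector modulus for studying acute myocardial ischaemia induced by coronary
    balloon occlusion. Provides the full processing chain from raw multi-lead
    ECG to trajectories in the entropy-complexity (HxC) causal plane: notch
    filtering and cubic-spline baseline correction, the Kors transform to
    orthogonal XYZ leads, R-wave detection with median-template beat acceptance
    and an RMS noise gate, per-beat ordinal probability distributions,
    normalized permutation entropy, Jensen-Shannon divergence to a per-patient
    mean control distribution, statistical complexity with its Cmin/Cmax
    envelope, windowed phase trajectories with section statistics, f^(-k)
    noise landmarks for the plane, and a synthetic phase-structured ECG cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
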