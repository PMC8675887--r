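---
title: "Methods: JIP-test derivation, group statistics, and CAP classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: JIP-test derivation, group statistics, and CAP classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ojipcap)
```

This vignette explains the models and procedures implemented in
`ojipcap`, the conventions and tunable parameters behind them, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices a maintainer would want to know about.

## 1. The OJIP transient and the JIP test

A dark-adapted leaf exposed to saturating light shows a polyphasic
fluorescence rise: the origin O (minimal fluorescence F0, all PSII
reaction centers open), inflections J (≈ 2 ms) and I (≈ 30 ms), and the
peak P (maximal fluorescence F_M, all primary quinone acceptors Q_A
reduced). The JIP test reads a small set of cardinal values off this
curve and combines them into yields and energy fluxes.

### Cardinal-point conventions

| setting | default | meaning |
|---|---|---|
| `t0` | 50 µs | origin time for F0 |
| `t300` | 300 µs | time of F300, used for the initial slope |
| `tJ` | 2 ms | J-step time for F_J |
| interpolation | log-time | landmark values by linear interpolation in log10(t) |

F0 is taken at 50 µs, the standard JIP-test origin for
continuous-excitation fluorometers: earlier readings are dominated by
the instrument response, and the convention matches the acquisition
timing of the FluorPen class of devices. Instruments that report F0 at
their first sample can be accommodated by setting `t0`
(`jip_conventions()`), and the choice is echoed in the run manifest.
Landmarks are interpolated against log10(time) because acquisition is
log-spaced — in log-time the curve is locally near-linear, so linear
interpolation there is the least biased simple estimate; plain
linear-time interpolation is available. F_M is the maximum *observed*
point, with no smoothing: smoothing would bias F_M low on noisy curves
and its benefit is not needed at the noise levels of leaf-clip
measurements.

The initial slope of the relative variable fluorescence rise is
estimated as

M0 = 4 · (F300 − F0) / (F_M − F0),

i.e. the rise of V = (F − F0)/(F_M − F0) over the first 0.25 ms
expressed per millisecond — the standard realization of "slope at the
origin of the rise". M0 is reported per ms; PI_ABS depends on M0 only
through V_J/M0, so the unit choice cancels there but matters for
RC0/CS, which is why it is fixed and documented rather than
configurable.

### Parameter formulas

With φ_Po = 1 − F0/F_M, ψ_o = 1 − V_J:

- ABS/CS = F0; TR0/CS = φ_Po·(ABS/CS); ET0/CS = φ_Po·ψ_o·(ABS/CS);
  DI0/CS = (ABS/CS) − (TR0/CS); RC0/CS = φ_Po·(V_J/M0)·(ABS/CS)
- γ_RC/(1 − γ_RC) = RC/ABS = (RC0/CS)/(ABS/CS)
- PI_ABS = [γ_RC/(1 − γ_RC)] · [φ_Po/(1 − φ_Po)] · [ψ_o/(1 − ψ_o)]

The flux identities (DI0 = ABS − TR0, ET0 = ψ_o·TR0, PI_ABS as a triple
product) hold by construction to machine precision and are asserted
over every analyzed sample in the test suite.

Degenerate curves — flat, or peaking at the first sample — are flagged
and routed to a rejects table rather than raising errors, because field
datasets contain dead or detached tissue and one bad leaf must not
abort a batch (`jip_conventions(degenerate = "error")` restores strict
behavior). Two limits produce explicit `NA` markers rather than
numbers: φ_Po = 1 (F0 = 0) makes TR0/DI0 undefined, and V_J = 0 makes
ψ_o/(1 − ψ_o) undefined. The fully quenched limit F0 = F_M is returned
as φ_Po = 0 with zero photochemical fluxes and PI_ABS = 0.

### Area

Area = ∫ (F_M − F(t)) dt from the first acquired point to t(F_M),
trapezoid rule on the acquired grid. On the default 160-point log grid
the quadrature is converged to well under 0.1% (tripling the density
changes the result by < 0.1%), so no higher-order rule is warranted.
Area is the parameter most sensitive to measurement noise: noise in the
observed maximum shifts both the integrand's offset and the upper
limit, so on noisy data its replicate scatter is much larger than that
of the ratio parameters. This is a property of the definition, not of
the estimator.

## 2. The synthetic-data generator

The generator exists so that every downstream stage has ground truth.
It models the rise as a sum of three saturating exponentials,

F(t) = F0 + (F_M − F0) · Σᵢ wᵢ (1 − exp(−kᵢ t)),  Σ wᵢ = 1, k₁ > k₂ > k₃,

the simplest strictly increasing family with controllable J- and I-like
inflections and closed forms for every JIP quantity (cardinal values by
evaluation; Area analytically). Defaults: rates (1500, 80, 4) s⁻¹,
weights (0.45, 0.30, 0.25), F0 = 5000, F_M = 25000 — placing V_J ≈ 0.47
and the phases near the 2 ms / 30 ms / approach-to-P structure of real
transients. Sampling is 160 points log-spaced over 10 µs–1 s,
FluorPen-like. Noise is multiplicative Gaussian (default SD 2%),
matching detector behavior at high signal.

The default factorial experiment mirrors a two-population ×
two-season × day/night design with 10 replicates per cell (80
samples). Cell effects act along three axes — F0 differs by population
(5000 vs 5800; antenna cross-section), F_M/F0 by season (5.0 vs 3.85,
i.e. φ_Po ≈ 0.80 vs 0.74; winter down-regulation), and the fast-phase
weight by day/night (0.45 vs 0.55, shifting V_J by ≈ 0.09) — with 3%
between-replicate jitter on F0 and F_M and 2% weight jitter. These
magnitudes are in the range reported for seasonal and diel contrasts in
seagrass photophysiology and were fixed once as the package's study
conditions; under them CAP re-identifies ≈ 76–77 of 80 samples, the
same order as published field classifications. The generator does *not*
emulate: the K-band and other stress signatures, non-monotone
transients, instrument saturation, correlated (drift-like) noise, or
temperature/light-history dependence of the kinetics. Tests passing on
this generator therefore certify the estimators and the statistical
machinery, not robustness to every pathology of field data.

One identifiability caveat: with the default slowest rate k₃ = 4 s⁻¹
the curve is still ≈ 0.5% below F_M_true at the end of the 1 s window,
so the observed maximum slightly underestimates F_M_true and the
complementary area (which is anchored at F_M) inherits a percent-level
bias. F_M is fully observable only when the window covers ≈ 10/k₃.
Oracle-recovery checks therefore draw their random kinetics with k₃ ∈
[10, 30] s⁻¹ so that truth is identifiable from the window; the
experiment generator keeps k₃ = 4 because a curve still creeping toward
P at 1 s is what real transients look like.

## 3. Group statistics

Each parameter is compared across the bracket contrasts of the
factorial design (day vs night within population × season; summer vs
winter within population × period; population pairs at matched
season × period — 12 contrasts in the 2 × 2 × 2 design) with two-sided
Wilcoxon rank-sum tests: exact null distribution when the pooled n is
≤ 12 and tie-free, otherwise the normal approximation with tie and
continuity corrections. At the default 10 + 10 group sizes the
approximation path is used; its type-I error is verified by simulation
(within [0.035, 0.065] at α = 0.05 over 2000 null replicates). Two
identical samples return p = 1 by convention.

Benjamini–Hochberg adjustment is applied within each parameter's family
of contrasts, matching the per-panel significance displays such data
are published with; a global family is available
(`family = "global"`). Significance codes: \*, \*\*, \*\*\*, \*\*\*\*
at 0.05, 0.01, 0.001, 0.0001 on adjusted p. The contrast family is
data-driven configuration, not hard-coded, because published analyses
rarely enumerate it.

## 4. CAP classification

The multivariate question — can a sample's group be recognized from its
photochemistry alone? — is answered with Canonical Analysis of
Principal Coordinates:

1. z-score the parameter matrix (so fluxes in arbitrary units and
   dimensionless yields weigh equally); Euclidean distances;
2. principal coordinates analysis by Gower double-centering
   G = −½ J (D∘D) J and symmetric eigendecomposition; negative
   eigenvalues (impossible for Euclidean D up to round-off) are
   reported but excluded;
3. retain m orthonormal PCoA axes Q_m and eigenanalyze Q_m′ H Q_m,
   H the hat matrix of the group indicators. Because
   Q_m′ H Q_m = C′C with C the g × m matrix of √n_g-scaled group
   means, the canonical squared correlations and axes come from an SVD
   of the small C rather than an m × m eigendecomposition;
4. leave-one-out allocation: for each holdout the PCoA is *re-fitted*
   on the remaining n − 1 samples, the held-out sample is projected
   onto those axes by Gower's add-a-point formula, and it is assigned
   to the nearest group centroid in canonical space. Re-fitting
   prevents the held-out sample from influencing the axes — the
   leakage-free protocol matters because the axes are low-rank
   summaries of all samples;
5. m = "auto" picks the m in 1..min(rank, n − 2) maximizing LOO
   success, ties to the smallest m (less overfitting); a fixed m is
   accepted and validated against n − 2 and the rank.

Group separation is tested by the trace statistic tr(Q_m′ H Q_m) under
random relabelings, p = (#{permuted ≥ observed} + 1)/(B + 1), default
B = 999. A subtlety dictated the implementation: when m is chosen by
LOO success, the choice depends on the labels, and permuting labels
while keeping the observed m inflates the test (measured 12% rejection
at α = 0.05 on homogeneous data). The permutation therefore repeats the
*whole* procedure — LOO-based selection of m, then the trace at that
m — for every relabeling, restoring exchangeability; calibration
measured on 500 homogeneous replicates gives P(p ≤ 0.05) = 0.046. The
label-independent parts (per-holdout PCoA bases and add-a-point
projections) are computed once and shared across all permutations,
which is what makes the exact test affordable. With a user-fixed m the
selection is label-free and the cheap fixed-m permutation is used.

## 5. Numerical choices and degenerate inputs

- Eigenvalue positivity threshold in PCoA: max(|λ|, 1)·1e−9; axes below
  it are treated as null space.
- Canonical squared correlations are clamped to [0, 1] against
  round-off; permuted traces are compared with a 1e−12 slack on the ≥,
  which can only make p conservative.
- Zero-variance parameter columns are dropped (with a warning) before
  z-scoring; rows with missing parameters are dropped with a report;
  ties in auto-m go to the smaller m; duplicate acquisition timepoints
  keep the first reading with a warning.
- All randomness (noise, jitter, permutations) runs through locally
  seeded RNG (`withr::with_seed`), so library calls never perturb the
  caller's RNG stream and every result is a pure function of inputs
  and seed.

## 6. Problem sizes used by the test suite

The suite exercises the study scale directly: the 80-sample factorial
experiment for the identity and recovery checks and for CAP (999
permutations); 50 random kinetic specs for oracle recovery; 500
replicates for the null calibration of the pairwise-testing pipeline
(8 groups × 10, 3 parameters) and of the CAP permutation p (24-sample,
2-group homogeneous clouds, 99 permutations each — the larger 999-perm
count adds resolution only below p = 0.01, which the calibration of a
5% threshold does not need); enumeration oracles cover all tie-free
rank-sum inputs to pooled n = 8 and 1000 random BH vectors. These sizes
were chosen so each property is measured with binomial error small
compared to its tolerance.

## 7. Known limitations

- The JIP parameter set implemented is the absorption-basis (PI_ABS)
  family; PI_total and the RE-band (I–P phase) parameters are not
  included because the downstream analyses here do not use them.
- CAP is implemented for Euclidean distances (the distance step is a
  single function and is swappable, but nothing else is tested);
  db-RDA/PERMANOVA-style partitioning is out of scope.
- The rank-sum exact path enumerates only tie-free cases; heavily tied
  small samples fall back to the corrected normal approximation.
- The generator's closed-form Area assumes the acquisition window; see
  the identifiability caveat above.
- No attempt is made to reproduce any proprietary instrument's or
  statistics package's exact numerical output; agreement is at the
  level of the published formulas and procedures.
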