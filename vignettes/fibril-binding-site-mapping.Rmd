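---
title: "Methods: mapping a chaperone binding site on amyloid fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a chaperone binding site on amyloid fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilbind)
```

`fibrilbind` combines five quantitative analyses that together localize
where a chaperone-like domain binds on the surface of amyloid-β(1–42)
fibrils. This vignette documents the models behind each stage, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data validation does and does not
demonstrate.

## Two-phase SPR kinetics

A sensorgram concentration series is fitted globally with a two-phase
association / two-phase dissociation model. During the injection
($t < t_0$) the response is a sum of two saturating exponentials with
observed rates $k_{obs,1}$ and $k_{obs,2}$; after the injection stops the
response decays biexponentially from its level $R_0$ at $t_0$, with the
mixing fraction $a \in [0,1]$ weighting the two off-rates. Physically, the
two phases describe a strong, specific binding mode superimposed on a weak,
unspecific surface interaction; the apparent dissociation constants are
$K_D = k_{off}/k_{on}$ per phase, the smaller reported as `kd_strong`.

Three design points deserve comment.

* **Observed-rate pairing.** The model as printed couples the first
  association phase with the *second* off-rate
  ($k_{obs,1} = c\,k_{on1} + k_{off2}$) and vice versa. This "crossed"
  pairing is unusual — the conventional heterogeneous-ligand model pairs
  each phase with its own off-rate — and may well be typographical. Both
  conventions are implemented (`pairing = "crossed"` is the default, being
  the printed form; `"paired"` is one switch away) and the test suite
  exercises both. No claim is made about which was intended.
* **$K_D$ convention.** The equilibrium constant of a phase divides that
  phase's own rates ($k_{off,i}/k_{on,i}$) by default, because an
  equilibrium constant is a property of one binding mode; the crossed
  ratios are also available via `spr_kd(..., pairing = "crossed")`.
* **Label symmetry.** The model is exactly invariant under swapping the
  two phases (including $a \leftrightarrow 1-a$), so a fit may return
  either labelling. Results are canonicalized with
  $k_{off1} \le k_{off2}$, making phase 1 the slowly dissociating one.

Numerically, rates and amplitudes are fitted in log space and $a$ on the
logit scale, so positivity and the $[0,1]$ bound hold by construction.
Optimization is Levenberg–Marquardt over the concatenated, unweighted
residuals of both phases of all retained curves (the protocol excludes the
two lowest concentrations; per-point SD weighting is not implemented
because the assay reports none). Initialization is multistart: one
data-driven start (amplitudes from the maximal response, canonical rate
magnitudes, per-curve $R_0$ from the observed response at $t_0$) plus up to
15 log-uniform draws over the rate bounds, stopping early when additional
starts stop improving the objective by more than 0.1% (patience 3) or when
the residual RMS is already at floating-point floor. Parameter errors are
Jacobian-based (delta method back to the natural scale); these are
covariance-based uncertainties, not replicate spreads.

## Chemical-shift-perturbation mapping

Combined shift changes use
$|\delta_{comb}| = \sqrt{(\delta_{het}/2)^2 + \delta_H^2}$. The factor 2 is
written for ¹³C; it is applied unchanged to ¹⁵N unless overridden, a
deliberate simplification (common alternatives scale ¹⁵N by ~5) kept
configurable through `hetero_scale`.

Peak matching is assignment-driven: each reference peak is compared with
the query peaks carrying the same residue and atom pair. A residue is
`doubled` when the query shows both a peak at the reference position
(within `radius_hetero` × `radius_h` = 0.2 × 0.05 ppm by default, roughly
one line width) and a shifted twin — the signature of two coexisting local
environments, with the shift difference taken from the shifted member.
Reference peaks within each other's radii are `overlapped` and excluded
from all statistics; conflicting query candidates are `ambiguous`; absent
query peaks are `missing`.

The significance rule behind "significant shift changes" is not something
the data dictate uniquely; the default flags residues with
$\delta_{comb} > \text{mean} + 1\,\text{SD}$ over assessable residues
(strict inequality, so an all-equal profile flags nothing), with an
absolute ppm threshold as the alternative. The rule and the numeric
threshold used are always carried in the output. Ambiguously assigned
residues are excluded from the docking restraint set by default since
restraining a docking run on an uncertain assignment is riskier than
omitting it; `include_ambiguous = TRUE` reverses this.

Restraint export replicates the fibril-side residues over three central
chains by default, because the binding epitope repeats along the fibril
axis and docking against edge subunits would expose artificial termini.

## Solvent PRE from inversion-recovery R₁

Relaxation series are fitted with the three-parameter mono-exponential
$I(t) = \text{offset} + \text{amplitude}\cdot e^{-R_1 t}$, which
accommodates inversion recovery (negative amplitude) and
saturation-style data alike. Initialization is analytic (offset from the
longest delay, amplitude from the shortest, rate from a log-linear
regression on the decaying residual) with fallback rate starts spanning
two decades; $R_1$ is fitted in log space. A series whose amplitude is
indistinguishable from zero (|amplitude| ≤ 4× residual SD, with a small
data-scale floor) is flagged `converged = FALSE` — a flat series has no
identifiable rate, and flagging beats throwing for batch use.

Rate uncertainties are parametric Monte-Carlo: 500 synthetic series
(best-fit curve plus Gaussian noise at the user-supplied spectral noise
floor) are refitted and the SD of the refitted rates reported. The solvent
PRE is the doped-minus-undoped rate difference with quadrature errors;
`delta_pre()` differences two PRE profiles (chaperone-present minus
fibril-alone) and flags residues where $|\Delta| > k_\sigma \cdot$ error,
$k_\sigma = 2$ by default — a two-sided two-sigma rule with an expected
false-flag rate of $2\Phi(-2) \approx 4.6\%$ on null residues. Contiguous
flagged residues are reported as segments; decreased segments indicate
burial by the bound chaperone, increased ones newly exposed structure.

The calibration test draws ≥1000 truly null residue pairs with known error
bars and checks the realized false-flag rate against 4.6%. This validates
the flagging rule given correctly estimated errors; the error estimates
themselves are validated separately (the Monte-Carlo SD is compared with
the empirical SD of fits over 200 independently generated noisy series).
Splitting the two keeps each check sharp and the suite fast; a joint
end-to-end calibration at that scale would require millions of refits
without testing anything further.

## Bound fraction from HSQC attenuation

Binding to sonicated fibrils removes a chaperone molecule from the
solution-state spectrum (its tumbling slows beyond detection), so
cross-peak attenuation is linear in the bound population. Per-peak ratios
carry S/N-propagated errors; the summary is an error-weighted mean
(weights $1/\text{err}^2$) rather than a plain mean so that weak peaks do
not dominate, and both the propagated error of the weighted mean and the
SD across peaks are reported — the two candidate readings of a
"± error" on an attenuation figure. A reduced chi-square about the mean
(`uniformity_stat`) checks the uniform-attenuation assumption: values near
1 support a global population effect, large values suggest site-specific
broadening, which this model deliberately ignores (no exchange
contribution is modeled, consistent with the absence of line-width
changes in the underlying experiments). `supernatant_consistency()`
cross-checks the estimate against an independently measured soluble
fraction with a default tolerance of 0.06, spanning the 5–10% range both
measurements must straddle.

## Diameter morphometry

Group summaries use the sample SD. The two-sample test is the unpaired
two-tailed t-test, computable from raw samples or from printed
(mean, SD, n) summaries; both routes agree exactly by construction.
Student (pooled variance) is the default variant — the classical unpaired
test and the default of the analysis software commonly used for such
figures — with Welch available and `variant = "both"` reporting the two.
Zero-variance groups with equal means give $t = 0$, $p = 1$; with unequal
means the p-value is clamped to the smallest representable double and
flagged rather than raising an error.

Cross-section classification uses a single diameter boundary, default
11 nm, the midpoint of the observed class means (13.8 nm for tetrameric
two-filament fibrils, 8.4 nm for dimeric single filaments). A mean exactly
at the boundary is `unclassified` — refusing to classify a tie is safer
than an arbitrary side. The boundary is a package decision, not a measured
quantity, and is configurable.

The p-value printed for the seeded mature-vs-mature comparison in the
source material cannot be reproduced from rounded summary statistics, so
no test asserts it.

## What the synthetic data do and do not show

The generators draw every input kind from the model structure the
corresponding analysis assumes — closed-form two-phase kinetics with
i.i.d. Gaussian sensorgram noise (dissociation tied to the association
value at $t_0$, so noiseless traces are continuous at the injection stop),
mono-exponential recovery with additive noise, shift perturbations
confined to a configured residue subset with optional peak doubling and
intensity attenuation, and zero-truncated normal diameter populations.
Defaults encode the studied system: the 42-residue amyloid-β sequence
(serines at 8 and 26), a nine-step two-fold dilution series from 50 µM, a
strong-phase equilibrium constant of 12.9 nM over a ~10 µM weak phase,
2% relaxation noise, and the reported diameter populations.

Passing the recovery tests therefore shows that each estimator inverts its
own generative model correctly at realistic noise — not that real data
obey those models. Real sensorgrams carry drift, mass-transport limitation
and regeneration artifacts; real spectra carry assignment errors,
non-Gaussian noise and exchange broadening; real micrograph measurements
carry operator bias. None of these are simulated, and the pipeline's
robustness to them is untested by design.

Acquisition noise levels are configuration values, not claims about any
instrument.

## Problem sizes and reproducibility

The validation suite runs at desk scale: 20 seeded replicates of the full
9-concentration duplicate SPR series (~108,000 residual points per
replicate) for parameter recovery; 500 Monte-Carlo simulations against 200
independent replicates for the R₁ error calibration; 1500 null residues
for the PRE flagging calibration; 50 seeds for the bound-fraction
recovery; and a 10⁵-draw permutation oracle for the small-sample t-test
(the 5+5 fixture was chosen so that its exact 252-split permutation
p-value lies within 2×10⁻⁴ of the Student p-value, making the comparison
meaningful despite the discreteness of the permutation distribution).

All stochastic steps are seeded. One user seed fans out to per-stage seeds
through a deterministic hash, so `run_pipeline()` reports are
byte-identical across runs and stage-subset runs reproduce full-run
results.

## Known limitations

* The SPR model excludes mass transport and bivalent analytes; apparent
  constants can overestimate affinity when rebinding is significant.
* CSP matching requires assigned peak lists; no automated assignment or
  3D spectrum processing is provided.
* PREs are reported as rate differences only; no distance conversion or
  spectral-density modeling is attempted.
* The docking restraint table is an export; docking itself, structural
  modeling and image processing are out of scope.
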