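# fibrilbind

Quantitative analyses for localizing where a chaperone-like protein domain
binds on the surface of amyloid-β(1–42) fibrils.

Molecular chaperones such as the Bri2 BRICHOS domain suppress the
fibril-surface-catalyzed generation of new aggregation nuclei (secondary
nucleation), the dominant self-replication route of amyloid-β and a major
source of toxic oligomers. Mapping *where* on the fibril surface such a
chaperone binds requires combining several orthogonal measurements, none of
which is conclusive alone. `fibrilbind` implements that combination as a
tested, reusable pipeline:

- **SPR kinetics** (`spr_fit_global()`): global fitting of a sensorgram
  concentration series with a two-phase association / two-phase dissociation
  model,

  $$R_{asso}(t) = \frac{k_{on1} c B_{max1}}{k_{obs1}}\left(1-e^{-k_{obs1}t}\right)
    + \frac{k_{on2} c B_{max2}}{k_{obs2}}\left(1-e^{-k_{obs2}t}\right),$$
  $$R_{diss}(t) = R_0\left[a\,e^{-k_{off1}(t-t_0)} + (1-a)\,e^{-k_{off2}(t-t_0)}\right],$$

  sharing rates and amplitudes across curves, excluding the lowest
  concentrations per protocol, and reporting a strong (specific) and a weak
  (unspecific) apparent dissociation constant $K_D = k_{off}/k_{on}$.
- **Chemical-shift-perturbation mapping** (`csp_match_peaks()`,
  `csp_select_residues()`): per-residue combined shift changes
  $|\delta_{comb}| = \sqrt{(\delta_C/2)^2 + \delta_H^2}$ between
  fibril-alone and chaperone-present assigned peak lists, with detection of
  peak doubling (coexisting unshifted and shifted environments), overlap,
  ambiguity and missing assignments, and selection of the significantly
  perturbed residues as docking restraints (`csp_export_restraints()`).
- **Solvent PRE** (`fit_r1()`, `r1_mc_error()`, `compute_pre()`,
  `delta_pre()`): per-residue ¹⁵N R₁ from inversion-recovery series
  (mono-exponential fits, Monte-Carlo errors from the spectral noise floor),
  solvent paramagnetic relaxation enhancements as doped-minus-undoped rate
  differences, and condition differences that flag residues buried or
  exposed by chaperone binding.
- **Bound fraction** (`intensity_ratios()`, `bound_fraction()`): the
  population of chaperone bound to fibrils from the uniform attenuation of
  solution-state HSQC cross-peaks, checked against an independently measured
  soluble fraction (`supernatant_consistency()`).
- **Morphometry** (`diameter_summary()`, `ttest_from_summary()`,
  `cross_section_class()`): fibril-diameter statistics, unpaired two-tailed
  t-tests (Student and Welch, from raw samples or printed summaries), and
  classification of dimeric vs tetrameric cross-sections.

A synthetic-data module (`sim_sensorgrams()`, `sim_peak_tables()`,
`sim_inversion_recovery()`, `sim_diameters()`) generates every input kind
with known ground truth, so each stage — and the full pipeline
(`run_pipeline()`) — can be exercised and validated without any external
data. All functions take and return tibbles and compose with the pipe;
fitted objects have `tidy()`/`glance()` methods and `plot_*()`/`autoplot()`
graphics.

## Worked example

Map a binding site from synthetic peak tables in which residues 27, 28,
30–32 and 40–42 sense the bound chaperone, then compare fibril diameter
groups:

```r
library(fibrilbind)

tabs <- sim_peak_tables(perturbed = c(27, 28, 30:32, 40:42),
                        cfg = synth_config(seed = 42))
records <- csp_match_peaks(tabs$reference, tabs$query)
csp_select_residues(records)
#> <active_residue_set> 8 residues: 27, 28, 30, 31, 32, 40, 41, 42
#>   rule: delta_comb > mean + 1*SD (= 0.1304 ppm)

ttest_from_summary(c(13.8, 2.9, 100), c(8.4, 1.5, 100), variant = "both")
#> # A tibble: 2 × 5
#>   variant     t    df        p note
#>   <chr>   <dbl> <dbl>    <dbl> <chr>
#> 1 student  16.5  198  3.64e-39 <NA>
#> 2 welch    16.5  148. 1.70e-35 <NA>

cross_section_class(c(13.8, 8.4))
#> [1] "two-filament (tetramer)" "single-filament (dimer)"
```

The selected residue set is exactly the perturbed ground truth; the
diameter groups (13.8 ± 2.9 nm vs 8.4 ± 1.5 nm, n = 100 each) differ with
p far below 10⁻⁴ under both test variants, and their means fall on opposite
sides of the 11 nm cross-section boundary: thick two-filament fibrils
without the chaperone, thin single-filament fibrils with it.

A one-command synthetic demonstration of all five stages:

```r
report <- run_pipeline(run_config(seed = 1, outdir = "demo_out"))
```

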