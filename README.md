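# dcebbb — blood–brain-barrier leakage mapping from DCE-MRI

Subtle blood–brain-barrier (BBB) disruption is implicated in
neurodegenerative and cerebrovascular disease, but the signal it leaves in
dynamic contrast-enhanced (DCE) MRI is tiny: transfer coefficients of a few
×10⁻³ min⁻¹ and plasma volume fractions around 1–2%. `dcebbb` is an R
package for quantifying that leakage and comparing it between clinical
groups. It is aimed at imaging scientists who have dynamic T1-weighted
series, a variable-flip-angle (VFA) stack, a B1 map and masks per subject,
and want reproducible voxelwise parameter maps plus the full group-level
statistical battery.

## The model

Per voxel, the spoiled-gradient-echo signal
S = M₀ sin(b₁α)(1 − E₁)/(1 − cos(b₁α) E₁), E₁ = e^(−TR/T₁),
links signal to T₁. The VFA stack is fitted for T₁ and M₀ (linearised
DESPOT1 with B1 correction); the dynamic series is inverted for R₁(t), and
concentration follows from C(t) = (R₁(t) − R₁,pre)/r₁. The plasma input
function C_p(t) is the haematocrit-corrected mean concentration over a
venous (sagittal-sinus) region. Assuming unidirectional tracer transport
(Patlak / uptake model),

C_t(t) = v_p · C_p(t) + K^trans · ∫₀ᵗ C_p(τ) dτ,

so voxelwise no-intercept least squares gives the plasma volume fraction
v_p and the BBB transfer coefficient K^trans (min⁻¹). Downstream, the
package provides lesion binarisation and cube-root volumetry, lesion-free
regional means, repeated-measures mixed ANOVA with covariates, Bonferroni
post hocs, clinical mixed-model correlations, and voxelwise Welch t-maps
with cluster-extent thresholding and permutation family-wise-error
correction. A digital phantom and a cohort simulator make every stage
testable without patient data; see the vignette
(`vignettes/bbb-leakage-mapping.Rmd`) for the science and design choices.

## Worked example

Simulate a phantom with the default acquisition (160 dynamics at 7.6 s,
bolus on the 8th dynamic, VFA at 2/5/10°), run the whole per-subject chain,
and extract regional means:

```r
library(dcebbb)

ph   <- generate_phantom(phantom_spec())        # 20 x 20 x 8 voxels
mask <- ph$label_map != 0 & !ph$rois$blood
t1m0 <- fit_vfa_t1(ph$vfa, ph$b1_map, ph$label_map != 0)
conc <- signal_to_concentration(ph$dynamic, t1m0, ph$b1_map)
vif  <- extract_vif(conc, ph$rois$blood)
maps <- subject_qc(fit_volume(conc, vif, mask))
maps$qc$verdict
#> [1] "pass"                       # median vp 0.012, inside (0, 0.1]

regional_means(maps, ph$rois[canonical_regions()])[1:4, ]
#>   region metric  value n_voxels
#> 1     SN ktrans 0.0035      320
#> 2     SN     vp 0.0120      320
#> 3     CA ktrans 0.0030      480
#> 4     CA     vp 0.0150      480
```

The recovered regional values equal the phantom's ground truth (K^trans
3.5×10⁻³ min⁻¹ and v_p 0.012 in the substantia-nigra label, and so on) —
on noiseless data the round trip is exact to better than 1e-6 relative.

Group statistics on a simulated 95-subject cohort (31 CN / 15 CP / 49 PD,
the default design, which encodes mildly elevated disease-group K^trans):

```r
co <- generate_cohort(cohort_design(seed = 1))
rm_anova(co, "ktrans")$table
#>     term df_num df_den      F         p
#> 1  group      2     92   3.96  2.23e-02
#> 2 region      7    658 188.16 1.94e-152
```

Here the group effect (F = 3.96, p = 0.022 with Satterthwaite degrees of
freedom) reflects the designed disease elevation; `posthoc_pairwise()`
localises it to the disease-vs-healthy pair with Bonferroni correction.

A thin command-line front end over the same functions is in
`inst/cli/dcebbb.R` (subcommands `simulate-phantom`, `simulate-cohort`,
`run-subject`, `run-group`; exit codes 0/2/3 for success / validation
error / QC fail).

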