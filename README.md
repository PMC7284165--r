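# hippodwi

Simulation and region-wise analysis of diffusion-weighted MR microscopy of
the epileptic mouse hippocampus.

In mesial temporal lobe epilepsy, hippocampal sclerosis — loss of CA1/CA3
pyramidal cells, dispersion of the dentate granule cell layer (GCL), mossy
fiber sprouting — reorganises the dendritic and axonal scaffolds that give
hippocampal tissue its anisotropic water diffusion. High-resolution HARDI
of fixed sections can resolve these changes as shifts in tensor metrics and
orientation distributions, and they correlate with histologically measured
cell densities. `hippodwi` packages that entire quantitative workflow as
tested, reusable code, together with a parametric digital phantom that
reproduces the statistical structure of such a study (three-group cohorts,
severity-coupled pathology, Rician noise at realistic SNR), so every
estimator and test can be validated against known ground truth.

For researchers in quantitative neuroimaging and image-analysis methods:
the package is useful both to analyse generic single-shell DWI stacks
(NIfTI + FSL `bval`/`bvec`, region label maps) and as a reproducible
simulation bench for region-wise DWI statistics.

## The models at the core

* **Signal**: mono-exponential tensor model, `S_i = S0 exp(-b g_i' D g_i)`,
  single shell (60 directions, b = 1000 s/mm², 6 b0), Rician noise
  `S' = sqrt((S + e1)^2 + e2^2)`, `sigma = S0/SNR`.
* **Tensor estimation**: voxel-wise weighted least squares on log-signals
  with `S^2` weights; metrics `MD = tr(D)/3`,
  `FA = sqrt(3/2) ||lambda - MD|| / ||lambda||`, and the axial in-plane
  principal orientation `theta = atan2(e1y, e1x) mod 180°`.
* **ADC profiles**: per-direction `ADC = -ln(S/S0)/b` expanded in real
  even-order spherical harmonics (order 4); evaluated along the
  dorso-ventral and left–right axes to give `dvD`, `lrD`,
  `dvlr_ratio = dvD/lrD`.
* **Statistics**: V-test on axially doubled angles
  (`V = sum cos(phi_i - phi_0)`, `u = V sqrt(2/n)`, one-sided normal p)
  against the hypothesized region orientations (CA1/DG 90°, CA3 45°,
  hilus/srCA1 0°); one-way ANOVA + Tukey HSD across groups and regions;
  paired ipsilateral/contralateral t-tests; Pearson correlations between
  diffusion parameters and histology proxies (cell density, GCL width).

The phantom couples a cell-density proxy to the tensor field
(`lambda_perp = a_MD - b_MD * density`), so cell loss raises diffusivity
and lowers anisotropy, and draws a per-animal severity scalar so
intra-group diffusion–histology correlations are recoverable. See the
methods vignette (`vignettes/hippodwi-methods.Rmd`) for all parameters and
the reasoning behind their defaults.

## Worked example

```r
library(hippodwi)

# one full in-silico study: 6 control / 9 ipsilateral / 6 contralateral
# slices, 102 x 128 voxels at 40 um, SNR 15
cohort <- run_cohort(run_config(seed = 11))

subset(tidy(cohort), family == "vtest" & roi == "CA1",
       c(group, statistic, p_value, significant))
#>           group statistic p_value significant
#> 1       control     47.47  0.0000        TRUE
#> 2   ipsilateral      1.44  0.0748       FALSE
#> 3 contralateral     44.01  0.0000        TRUE
```

Control CA1 orientations align decisively with the dorso-ventral axis
(u = 47.5), while ipsilateral CA1 — where the phantom removes the pyramidal
dendritic scaffold — is indistinguishable from uniform (p = 0.075).

```r
subset(tidy(cohort), family == "anova_tukey" & test == "tukey" &
         parameter == "FA" & roi == "CA1",
       c(contrast, estimate, p_value))
#>                    contrast estimate  p_value
#> 1     control-contralateral   0.0915 8.66e-04
#> 2 ipsilateral-contralateral  -0.1414 1.67e-06
#> 3       ipsilateral-control  -0.2329 8.71e-10
```

CA1 fractional anisotropy is markedly lower ipsilaterally than in either
comparison group (here ~0.37 vs ~0.60 in controls), the signature of
pyramidal cell degeneration. Diffusion–histology concordance:

```r
subset(tidy(cohort), family == "pearson" & parameter == "FA" &
         histology == "density_CA1", c(subset, estimate, p_value))
#>        subset estimate  p_value
#> 1         all    0.985 4.26e-16
#> 2 ipsilateral    0.881 1.68e-03
```

CA1 FA tracks CA1 cell density even within the ipsilateral group alone
(r = 0.88, n = 9), i.e. the diffusion metric follows pathology severity,
not just group membership. `autoplot(cohort)` draws the group-mean bars
with SD error bars; `autoplot(cohort, "orientations")` the per-region rose
histograms. `fit_external()` applies the same quantification to
user-supplied NIfTI + bval/bvec data.

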