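# isodiel

Dual stable-isotope internal-standard metabolomics for diel studies.

`isodiel` implements the analysis core of an LC-MS workflow for tracking
cyanobacterial metabolite inventories across a sinusoidal light-dark
(diel) cycle. The workflow rests on a fully ¹³C-labeled metabolite extract
spiked in equal amount into every sample: each metabolite — annotated or
not — then has a co-eluting partner peak shifted by nC·Δ(¹³C−¹²C), and the
ratio of the ¹²C (sample) to ¹³C (internal standard, IS) monoisotopic peak
areas is a relative abundance measure in which extraction and matrix
effects cancel. Separate fully ¹³C- and ¹⁵N-labeled cultures credential
features as biological and yield their C/N atom counts from the observed
mass shifts.

## What the package computes

For a feature with unlabeled m/z *m*ᵤ and fully labeled m/z *m*ₗ at charge
*z*, the atom count of the labeled element is

    n = round( z · (mₗ − mᵤ) / Δ ),   Δ₁₃C = 1.0033548 Da, Δ₁₅N = 0.9970349 Da

accepted when the reconstructed shift agrees with the observed one within
a ppm tolerance. A feature is **biological** when the ¹³C culture shows a
co-eluting peak with n ≥ 1; its **isotopic area ratio** is
area(¹²C)/area(¹³C IS). On the metabolite × sample ratio matrix the
package runs the diel statistics cascade:

- one-way ANOVA on log₂ ratios with a conjunctive gate
  (p < 0.05 **and** max/min fold change of condition geometric means > 1.5);
- Student's t test (equal variance) between midday and continuous light
  with the same gates;
- an intra-sample coefficient-of-variation filter (mean per-condition
  CV ≤ 0.3) for the untargeted feature list;
- PCA of auto-scaled log₂ data with per-condition 95% ellipses
  (χ² 2-df scaling of the group covariance);
- peaking-time classification (argmax over the morning/midday/evening/
  midnight means).

A growth module models the half-sine light profile
E(t) = E₀·sin(π·t/P) over the photoperiod P, integrates
d(OD)/dt = μ(t)·OD, and estimates the instantaneous specific growth rate
μ(t) = d ln(OD₇₂₀)/dt from an OD series by centered differences on
smoothed ln(OD).

A first-class synthetic-study generator emulates the full design — mixed
injections with the ¹³C IS, the ¹³C/¹⁵N credentialing cultures, five
conditions (M, MD, E, MN, CL) with replicates, diel abundance classes,
lognormal noise, per-sample matrix effects and background decoys — with a
ground-truth bundle that scores every downstream stage.

## Worked example

```r
library(isodiel)

# credential UDP-xylose from its labeling mass shifts
mz_u <- mz_deprotonated("C14H22N2O16P2")
mz_c <- labeled_mz("C14H22N2O16P2", "13C")
sprintf("UDP-xylose [M-H]- %.5f, fully-13C %.5f", mz_u, mz_c)
#> "UDP-xylose [M-H]- 535.03718, fully-13C 549.08415"
infer_atom_count(mz_u, mz_c, "C")
#> 14

# simulate the full study and run the pipeline
res <- run_pipeline(list(simulate = TRUE, generator = list(seed = 1)),
                    out_dir = "demo_out")
#> [isodiel] annotation: 2460 features in, 1005 annotated
#> [isodiel] credentialing: 97 features, 67 biological, 0 untargeted (0 multimers excluded)
#> [isodiel] pairing: 67 pairs/sample (median), matrix 67 x 15
#> [isodiel] statistics: 57 significant (ANOVA), 20 MD-vs-CL, 67 pass CV gate

head(res$anova[res$anova$significant,
               c("row_id", "p_value", "fold_change", "peak_condition")], 3)
#>      row_id      p_value fold_change peak_condition
#> F001   F001 3.657024e-10    7.048867             MD
#> F002   F002 1.928198e-07    7.715445              M
#> F003   F003 1.192975e-07    9.270735              E
```

The counts mean: all 67 planted metabolites were paired with their IS
partner in each of the 15 samples and credentialed as biological from the
labeled cultures; 57 of them (the rhythmic classes plus the
continuous-light-shifted subset) clear the ANOVA fold-change gate; 20
differ between midday and continuous light; all 67 pass the CV ≤ 0.3
filter at the default 10% area noise. Every feature of biological origin
carried an accepted MS2 annotation here, so the untargeted list is empty;
inputs without spectra leave credentialed features on the untargeted list
instead.

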