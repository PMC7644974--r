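---
title: "Methods: dual-isotope internal-standard quantification and diel statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-isotope internal-standard quantification and diel statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodiel)
```

## The measurement model

The package analyzes LC-MS feature tables from a design in which every
sample is spiked with an equal amount of a fully ¹³C-labeled metabolite
extract. Writing the integrated peak area of a metabolite in sample *s* as

$$A_s^{12C} = q_s \cdot g_s \cdot \varepsilon, \qquad
  A_s^{13C} = q_{IS} \cdot g_s \cdot \varepsilon',$$

where $q_s$ is the quantity in the sample, $q_{IS}$ the (constant) spiked
quantity, $g_s$ a per-injection matrix/extraction factor and
$\varepsilon$ multiplicative peak-integration noise, the isotopic area
ratio $R_s = A_s^{12C} / A_s^{13C} = (q_s / q_{IS})\,
\varepsilon/\varepsilon'$ is free of $g_s$. This is the entire rationale
of the method: anything that scales a whole injection — matrix effects,
losses during extraction, spray efficiency — cancels, and replicate CVs
collapse from the injection-level scale (σ ≈ 0.3 is typical for raw
areas) to the residual integration noise. The package's tests verify both
the exact invariance (scaling one sample's areas leaves its ratios
unchanged) and the CV collapse (< 0.05 under σ = 0.3 injection noise).

Because the IS is a biomass extract, the partner peak exists for every
biological feature, including unannotated m/z features; quantification
does not depend on knowing what the compound is.

### Mass arithmetic

All m/z values are negative-mode deprotonated ions,
$m/z = (M - z\,m_H + z\,m_e)/z$. The electron mass (0.00054858 Da) is a
sub-ppm correction but makes every frozen test value unambiguous. Charge
defaults to 1 ([M−H]⁻); multiply charged species are supported through
the `charge` argument only — the pairing and credentialing searches assume
singly charged features.

Label-induced shifts use Δ(¹³C−¹²C) = 1.0033548 Da and
Δ(¹⁵N−¹⁴N) = 0.9970349 Da. The inverse problem — how many carbons (or
nitrogens) does a feature have, given its unlabeled and fully labeled
m/z — is solved by rounding the shift divided by Δ and accepting the
candidate only when the reconstructed integer shift matches the observed
one within `ppm_tol` of the labeled m/z. Because the shift grows linearly
in n while the measurement error grows with m/z, recovery is exact up to
nC = 60 under ±5 ppm noise at the default 10 ppm tolerance; the property
suite checks this over randomized formulas.

### Natural-abundance isotopologues

`natural_mid()` models the mass isotopologue distribution with a
carbon-only binomial, $P(M{+}i) = \binom{n_C}{i} a^i (1-a)^{n_C-i}$ with
$a = 0.0107$, truncated and renormalized. Heavy isotopes of H, N, O, P, S
are neglected: for the polar metabolites this package targets, carbon
dominates M+1, and the distribution is used qualitatively (it is not part
of the quantification path). Labeled extracts are treated as isotopically
pure by default; `label_purity` in the generator scales the fully labeled
monoisotopic peak by purity^nC so imperfect enrichment can be simulated.

## Pairing, credentialing, and the ratio matrix

Within one mixed injection, `pair_with_internal_standard()` searches, for
each candidate unlabeled feature, all features co-eluting within `rt_tol`
whose m/z is higher by n·Δ¹³C/z for some n in `nc_range`, within
`ppm_tol`. Candidates are ranked by ppm deviation with retention-time
deviation as tie-break, and assignment is one-to-one greedy — a feature
can serve in at most one pair. Defaults: `rt_tol` 0.1 min, `ppm_tol` 10
ppm, `nc_range` 1–60, chosen as typical values for high-resolution TOF
chromatography; no tolerance values are claims about any particular
instrument.

`credential_features()` applies the same shift search between separate
culture injections: a control feature is biological iff the fully ¹³C
culture shows a co-eluting feature shifted by n·Δ¹³C with n ≥ 1. Nitrogen
counts come from the ¹⁵N culture, where n = 0 (an unshifted match) is
admissible so nitrogen-free compounds get nN = 0 rather than "unknown".
Contaminants present in all cultures appear unshifted everywhere and fail
the n ≥ 1 carbon requirement.

The [2M−H]⁻ multimer rule deserves a note. Features matching
2M − m_H + m_e of an annotated compound within `ppm_tol` are flagged, and
the flag removes them from the *untargeted* feature list only; it never
vetoes credentialing or annotated compounds. The reason is chemical:
fructose-1,6-bisphosphate (C6H14O12P2) has exactly twice the formula of
dihydroxyacetone phosphate (C3H7O6P), so the FBP [M−H]⁻ ion is exactly
isobaric with a DHAP dimer adduct. A rule that discarded every dimer-mass
match would silently delete a central CBB-cycle metabolite.

`build_abundance_matrix()` aligns pairs across samples greedily by
(m/z, RT) within the same tolerances, errors on duplicate
metabolite–sample entries, and leaves missing cells as `NA`. Rows with
more than `max_missing_frac` (default 0.5) missing entries are dropped
before statistics; the inferential tests then handle remaining `NA`s
pairwise, and only PCA imputes (row means).

## The statistics cascade

All inferential tests run on log₂ ratios. The displayed transforms in
this workflow are log-scale, and log₂ stabilizes the variance of
multiplicative noise; the per-condition summary is therefore a geometric
mean on the ratio scale. Fold change is max/min of the per-condition
geometric means. The screens use a conjunctive gate — p < `alpha` (0.05)
**and** fold change > `fc_min` (1.5) — and the two filters commute. No
multiple-testing correction is applied by default, matching the raw
p-threshold convention of this analysis style; Benjamini–Hochberg is
available via `adjust = "BH"`. The ANOVA is the classical equal-variance
F test (`oneway.test(var.equal = TRUE)`); Welch correction is not used.
The MD-vs-CL contrast uses Student's two-sample t test, equal variance.

The CV gate computes, per feature and condition, sample SD / mean of the
replicate ratios, and keeps features whose mean per-condition CV is
≤ `cv_max` (0.3). Conditions with zero mean make the CV undefined and
drop the feature with a log entry.

PCA operates on samples: the feature × sample matrix is log₂-transformed,
rows auto-scaled (z-scored; constant rows are flagged and dropped),
transposed, column-centered, and decomposed by SVD. Scores are
$U\,\mathrm{diag}(d)$; explained variance fractions are $d_i^2 / \sum
d^2$. Per-condition 95% regions are ellipses of the bivariate normal
fitted on PC1/PC2, with radius $\sqrt{\chi^2_{0.95,2}}$ — a "95%
confidence area" per group has no single standard definition, so the
package states its convention explicitly. Rank-deficient inputs (e.g. duplicated samples) pad PC2
with zeros for the ellipse fit.

Peaking classification is the argmax of the four diel condition means
(M, MD, E, MN), with ties broken in diel order and flagged.

## Light profile and growth rate

Irradiance is a half-sine: $E(t) = E_0 \sin(\pi (t - t_{dawn})/P)$ during
the photoperiod, zero in the dark, continuous at dawn and dusk. Defaults
are the study conditions: $E_0 = 600$ µmol photons m⁻² s⁻¹, P = 14 h,
24 h cycle.

`simulate_od()` integrates d(OD)/dt = μ(t)·OD with
μ(t) = μ_peak·E(t)/E₀. Because d ln(OD)/dt = μ(t) does not depend on OD,
the classical fourth-order Runge–Kutta step reduces to Simpson quadrature
of μ over each step, which is what the implementation does, in log space
for stability; the integration error against the closed-form half-sine
solution is below 10⁻⁸ at the default dt = 0.05 h. The cumulative
photoperiod ln-growth is analytically μ_peak·2P/π, which ties a measured
ln-growth of 1.43 per cycle to a peak rate of 0.16 h⁻¹.

`instantaneous_mu()` estimates μ = d ln(OD)/dt by centered finite
differences (one-sided at the ends) after optional moving-average
smoothing of ln(OD) over `window` points (default 3; `window = 1`
disables smoothing and makes log-linear series exact). The estimator
recovers a planted μ(t) within 1% of its peak at dt ≤ 0.1 h; the residual
error concentrates at the dawn/dusk kinks where μ′ jumps. The transient
OD dips observed around light transitions in diel cultures are available
as a phenomenological simulation option (`dip_depth`, off by default) —
they are not modeled mechanistically because their cause is an open
question.

## What the generator emulates — and what it does not

`generate_study()` produces mixed injections (unlabeled peak + ¹³C IS
peak per metabolite + background decoys), the three credentialing
injections, the design table, an OD series and ground truth. Defaults
define the study conditions: 67 metabolites (the scale of the annotated
set in this design; the catalog spans sugar phosphates, nucleotides,
sugar nucleotides, amino acids and γ-glutamyl dipeptides, and always
contains the worked exemplars 3PGA and UDP-xylose), 30 background
features, 5 conditions × 3 replicates, 10% lognormal area noise,
lognormal matrix effects with σ = 0.3, 2 ppm m/z jitter, full label
purity. Diel classes are assigned round-robin; a class peaks at its
condition with amplitude 8 (trough 1, neighbors √8), spanning the
qualitative fold-change range of diel metabolomes, with a heavy-tail
option raising a tenth of the rhythmic set to 100-fold. Continuous light
tracks midday for most compounds; a seeded 30% subset departs from its
midday level by 2-fold (alternating direction), emulating the roughly
one-third of compounds that separate the two regimes. Retention times
are a random permutation of an even grid so exact isobars
(G6P/F6P/G1P, γGlu-Leu/γGlu-Ile) stay chromatographically separated well
beyond `rt_tol` — their disambiguation is an RT problem, which the
generator makes solvable by construction.

Deliberately not emulated: profile-mode raw spectra and peak picking
(upstream of this package), chromatographic drift and peak-shape
pathologies, co-eluting isobars (available as a stress option only in
concept — the default never co-elutes them), in-source fragmentation,
adducts beyond [M−H]⁻ and the 2M−H rule, and intermediate isotopologue
peaks (the labeled partner is the fully labeled monoisotopic peak; ratios
never use intermediate isotopologues). Passing tests on this generator
therefore demonstrate the correctness of the arithmetic, pairing logic
and statistics under the stated noise model — not robustness to every
failure mode of real chromatography.

## Problem sizes and determinism

The test suite and the acceptance script run the default study (67
metabolites, 15 samples, ≈ 2 500 features), 1000-row null simulations for
the type-I error checks, and 48 h OD simulations at dt = 0.05 h — sizes
chosen so the full suite completes in well under a minute while keeping
every estimate's Monte-Carlo error far below the thresholds being tested.
All randomness flows from a single integer seed; a fixed seed reproduces
every table byte-for-byte, which the suite asserts by comparing files
from two independent pipeline runs.

## Known limitations

- Charge states above 1 are supported in the arithmetic but not searched
  for in pairing/credentialing.
- The cosine annotator is a minimal stand-in for dedicated spectral
  search tools: greedy one-to-one fragment pairing on √-intensities, no
  retention-indexed libraries, no deconvolution of chimeric spectra.
- Quantification is relative throughout; absolute concentrations require
  external standards and are out of scope.
- The statistics assume lognormal (multiplicative) noise; count-like or
  zero-inflated data would need a different error model.
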