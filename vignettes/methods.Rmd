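---
title: "Methods: post-MI remodeling traits, scar fiber statistics, and founder haplotype QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-MI remodeling traits, scar fiber statistics, and founder haplotype QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmiqtl)
```

`ccmiqtl` analyses variation in myocardial infarction (MI) outcome across
Collaborative Cross (CC) recombinant inbred mouse strains. This vignette is
the package's own account of the models it fits, the parameters that matter,
the numerical choices made where the methodology was genuinely open, and
what the synthetic-data validation does and does not establish.

## Remodeling traits

Each animal contributes a pre-MI and a post-MI echocardiography record. The
two derived hallmarks of LV systolic dysfunction and heart failure (LVSD/HF)
are

* left-ventricular dilation, `LVD = V_after / V_before * 100 - 100`, the
  percent increase in LV diastolic volume, and
* ejection-fraction reduction, `dEF = (EF_before - EF_after) / EF_after *
  100`, the percent EF loss relative to the post-MI value.

Both are ratios, hence invariant to rescaling of the underlying volumes —
a property the tests exercise on randomized inputs. Volumes and EF are taken
as measurements; the echocardiograph's volume reconstruction is not
reimplemented.

Inclusion filters: animals with an infarct of 30% of the LV or less are
excluded (small infarcts do not produce significant EF reduction), and the
per-strain mean infarct size is screened against the ~40% comparability
target with a warning only — the strict rule is the 30% cutoff, the
comparability screen is advisory. Rupture mortality is scored per strain as
the fraction of included animals *not* dying of LV free-wall rupture on days
3–5 post MI; deaths outside the window or from other causes count as
surviving the window. The survival fraction itself is the trait fed to QTL
mapping; no time-to-event model is fitted, since the window is short and the
event binary.

Strains in which the two LVSD/HF hallmarks disagree are excluded from
LVSD/HF analyses. No quantitative criterion for "disagree" is standard, so
the package defines one and reports it: strain-level z-scores of dEF and LVD
of opposite sign with both `|z| > 0.5` (configurable). The gate avoids
flagging strains whose traits are merely near the cohort mean, where signs
are noise.

Strain trait values are means of included animals, with SD reported.

## Scar collagen architecture

Serial 7 µm sections cut parallel to the epicardium give the apparent wall
thickness as `(last tissue section - first tissue section) * 7 µm`; the LV
midwall is the sections at relative depth 40–60% of the tissue span
(inclusive). For each midwall field the paired images — circularly polarized
(collagen bright) and blue-filter brightfield (collagen dark) — are each
min–max rescaled to [0, 1] before subtraction, with negatives clamped to
zero. Rescaling is the package's choice: the two modalities have unrelated
raw intensity scales, and subtracting them unnormalized is meaningless. The
collagen area fraction thresholds the subtracted image by Otsu's method by
default (no method is canonical for this stain pair), with an absolute
fallback threshold for degenerate (constant) images.

Fiber orientations are estimated by a structure tensor per non-overlapping
subwindow (default 16 px): intensity gradients from central differences are
summed into the 2×2 tensor, and the fiber direction is the axial orientation
of the tensor's minor eigenvector — perpendicular to the dominant gradient.
The subwindow weight is the tensor energy (trace); subwindows below
`min_energy` are invalid. Two numerical choices matter here:

* **Gaussian regularization before differentiation** (`blur_sigma = 1.5`
  px). Unsmoothed central differences on thin discrete ridges bias the
  estimated orientation toward the image diagonals by ~10°; with
  regularization, planted orientations are recovered to within ~1.5° at high
  concentration. This is the standard derivative-of-Gaussian practice for
  structure tensors.
* **Angle convention**: axial, degrees in [0, 180), 0° along the image
  x-axis (the circumferential direction in these fields).

Axial circular statistics double the angles, average the unit (or
energy-weighted) vectors, and report the mean resultant length MVL ∈ [0, 1]
(0 random, 1 maximally aligned) and half the resultant's angle as the mean
angle θ_m. Group alignment across a strain's samples takes θ_m from the
resultant of the per-sample mean vectors (unweighted, each sample one
vector), forms `v_i = MVL_i * cos(2 θ_i - 2 θ_m)`, and applies a two-sided
one-sample t-test against zero. Since θ_m maximizes the projection, `mean(v)
>= 0` by construction; the test asks whether samples agree on a common
orientation strongly enough that their projections differ from zero. A group
with identical per-sample vectors has zero variance in `v`; the test is then
degenerate and reported as such rather than given an arbitrary p-value.

## Founder haplotype reconstruction

CC strains are fully inbred, so the hidden state at a SNP is a single
founder of eight — a haploid 8-state HMM, no heterozygous states.
Informative SNPs have all eight founder alleles called and both alleles
present among the founders; others carry no contrast and are dropped before
inference.

* **Emissions**: a call matches the donor founder's allele with probability
  `1 - eps`, mismatches with `eps` (symmetric genotyping error, default
  0.002); missing calls are uninformative (constant across states).
* **Transitions**: between adjacent informative SNPs `d` bp apart the chain
  stays on its founder with probability `exp(-gamma d)` and switches to each
  of the other seven with probability `(1 - exp(-gamma d)) / 7`; default
  `gamma = 1e-7` per bp, i.e. a prior expectation of one switch per 10 Mb.
  The upstream tooling used for such panels does not publish its kernel
  parameters, so these are package defaults, exposed in `hmm_params()`.

Forward–backward is computed with per-locus rescaling (mathematically
identical to log-space accumulation and numerically stable at these state
counts); the test suite verifies the posteriors against brute-force
enumeration over all 8^n paths on small instances to 1e-8. The Viterbi
founder path is also reported, but downstream mapping uses the posterior
probabilities as founder dosages — the expected haplotype contribution —
which propagates uncertainty rather than hardening it.

## Mixed-model genome scan

With strain trait vector `y` and founder-dosage array `D` (loci × strains ×
8), the kinship matrix is `K[a,b] = mean over loci of <D[l,a,], D[l,b,]>`,
rescaled to unit mean diagonal; a leave-one-chromosome-out variant is
available. The null model `y = mu + g + e`, `g ~ N(0, sg2 K)`, is fitted by
maximum likelihood on the eigenbasis of K (one-dimensional profile
optimization over `lambda = sg2/se2`, with the `lambda = 0` boundary checked
explicitly). Variance components are estimated once under the null and the
null covariance is reused at every locus — the standard two-step
approximation that makes permutation scans tractable; each locus fit is then
a weighted least squares of the rotated trait on the rotated dosages.

ML (not REML) likelihoods are used throughout so the locus model nests the
null and `LOD = log10 LR >= 0` holds identically. Dosage columns sum to one
at each locus, so one founder column is dropped during fitting and the
coefficients are re-expressed as eight founder effects centered to mean
zero; a founder absent from the mapping population can be excluded by mask.
Founder effects at a peak get standard errors through the GLS covariance and
two-sided Wald t-tests (df = n − 8); the likelihood-vs-Wald choice for
founder significance is not externally specified, and Wald is used.

Permutation thresholds shuffle the trait across strains — exchangeable under
the null of no genetic effect — and re-estimate the null variance components
for each permutation before re-scanning; the threshold at level `alpha` is
the `ceiling((1 - alpha) n_perm)`-th order statistic of the genome-wide
maximum LOD. Thresholds at 0.05 / 0.10 / 0.63 are reported (significant,
approaching significance, suggestive). A kinship-aware rotation scheme would
be less conservative but couples the permutation to the estimated
covariance; the plain permutation is the simpler, conservative default.

Support intervals walk outward from the peak to the first loci with LOD at
least 2 below the peak and pad each boundary by 10 kb to compensate for
non-uniform SNP spacing, clipping at chromosome ends. Candidate SNPs inside
the interval are kept if their alternate allele is carried by **all**
implicated founders and ranked by: allele private to the implicated founders
first, then missense/splice consequence, then SIFT < 0.05 (deleterious).
Shared alleles are retained at lower rank — a shared variant can still be
causal if its effect is negated by other genomic contributions in the
non-implicated carriers.

## Expression–trait correlation

Expression values arrive log2-scale and are rescaled per transcript to
`2 (x - mean) / sd + 8` — z-scores with mean 8, SD 2 (sample SD, n − 1; the
convention is not fixed upstream, so the package states its choice). On this
scale one unit is a twofold expression difference, and the expression filter
keeps transcripts with mean strictly above 7. Correlation against strain
trait means is Pearson by default (Spearman optional) with the exact t
transform for p-values; per-trait top-500 lists with `|r| >= 0.60` are
intersected across traits. The transform is affine per transcript, so
correlations are invariant to it — a property the tests assert to 1e-12.
The ΔΔCT utility implements `2^-((CT_t,s - CT_r,s) - (CT_t,c - CT_r,c))`.

## The synthetic cohort generator

The generator produces every pipeline input with known ground truth, under
conditions chosen to emulate a CC MI cohort:

* **Genomes**: eight founder haplotypes with Bernoulli(maf) alleles (maf ~
  U(0.1, 0.5) by default), and strain mosaics drawn directly as
  Poisson-breakpoint tilings (default mean 3 breakpoints per chromosome)
  with uniform founder identities. The actual CC funnel breeding is *not*
  simulated generation by generation: the direct mosaic has the right
  qualitative structure to exercise the inference machinery, differing only
  in the segment-length distribution and in realistic founder-proportion
  imbalance, neither of which the HMM or scan depends on. Strains are fully
  homozygous. Genotyping error is a symmetric allele flip (default 0.2%);
  missing calls are a config option handled as uninformative emissions.
* **Traits**: the strain value is baseline + genetic + deviation, with the
  genetic part the planted QTL's founder effect rescaled so that
  `var(genetic) / var(strain values) = h2` exactly in expectation; animal
  records are then constructed by inverting the LVD/dEF formulas, so zero
  animal noise recovers planted strain values exactly. Baselines (EF 65%,
  LV volume 55 µl, trait means 50%/40% with strain SD 20, animal SD 8,
  infarct size 40 ± 4% of LV) reflect typical murine post-MI echo scales;
  no canonical within-strain variance exists, so all are exposed in
  `baseline_echo_params()` rather than hard-coded.
* **Fiber images**: axial von Mises orientations (doubled angles, drawn at
  concentration kappa about 2µ, halved — keeping the MVL–kappa relationship
  analytic), rendered as anti-aliased segments via an accumulating bilinear
  splat; polarized and brightfield channels are complements plus Gaussian
  noise.
* **Expression**: planted correlates are `target_r * z(trait) +
  sqrt(1 - target_r^2) * noise` mapped affinely to a positive log2-intensity
  scale, so the expected sample correlation is `target_r`; remaining
  transcripts are independent.

### What the validation shows, and what it does not

The test suite validates each stage against planted truth at desk scale:
mosaic recovery at ≥ 99% of SNPs, breakpoint localization within 2 SNP
intervals at 1% genotype error, planted-orientation recovery within 3°,
type-I error of the permutation threshold at 0.05 ± 0.03 over 200 null
replicates (50 strains, 2 × 100 loci, 200 permutations), and planted-QTL
capture by the support interval with the correct conferring founder in
≥ 90% of 50 replicates (100 strains, h2 = 0.5). These problem sizes are the
package's validation design: large enough for the binomial error bars to be
meaningful, small enough to run routinely.

Passing them shows the *machinery* is correct and calibrated under the
generative model. It does not certify performance on real data, where
linkage disequilibrium has funnel structure, genotyping error is not
symmetric, histology contains stain variation and registration error the
renderer does not model, and expression arrays have probe and batch effects
outside the generator. The headline biological results of a real cohort
(specific chromosome, LOD, and candidate genes) depend on the real genotypes
and arrays and are not reproducible from synthetic data; what is
reproducible — and reproduced — is every formula, filter, statistic and
decision rule applied along the way.

## Known limitations

* The HMM has no heterozygous states and no X-chromosome special-casing; it
  is for fully inbred autosomal panels.
* The scan supports no covariates beyond the intercept and no epistasis.
* The two-step variance-component approximation slightly deflates LOD near
  very strong peaks relative to exact per-locus ML; the exact fit is
  recoverable by refitting at a single locus but is not used in scans.
* Channel subtraction assumes co-registered image pairs; no registration is
  attempted.
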