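---
title: "Deformation-based morphometry and convergence analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-based morphometry and convergence analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cerebmorph)
```

## The problem

Whole-brain confocal imaging of larval zebrafish, elastically registered
to an annotated reference atlas, yields one displacement field per
subject: the warp that the registration had to apply to match the
subject's brain to the reference. Regions that are smaller in a mutant
than in the reference must be *inflated* during registration, so the
warp itself carries the phenotype. `cerebmorph` analyses cohorts of such
fields to localize regional volume differences between CRISPR-injected
(crispant) and control larvae, to validate them in independent cohorts,
and to test genetic rescue. Two companion modules handle the
non-imaging arms of such a screen: cross-experiment convergence of
differential-expression (DE) gene lists, and fragment-analysis
quantification of guide-RNA cutting efficiency.

Registration itself is out of scope: the pipeline consumes displacement
fields (and DE result tables, and electropherogram peak tables) and is
agnostic to how they were produced.

## Voxel-volume maps

For a displacement field $u(x)$ with the convention $T(x) = x + u(x)$
mapping reference to subject coordinates, the local volume ratio at a
voxel is the Jacobian determinant

$$J(x) = \det\left(I + \nabla u(x)\right),$$

and the log-Jacobian-determinant (LJD) map $\log J(x)$ is zero under
the identity, negative where the subject is locally smaller than the
reference. Gradients are taken by central finite differences in
physical units (one-sided on the boundary planes, which are flagged),
so anisotropic voxel spacing is handled. Voxels with $J$ at or below
`min_jacobian` (default $10^{-3}$) are folds: they are clamped and
counted, and a field with more than 1% folded voxels is rejected as
unusable.

Division volumes are computed by integrating $J$ over the atlas label
of each division — the subject-space volume of the atlas-defined
region, smooth and resolution-independent. The discrete alternative the
field often uses, inverse label propagation (invert $T$ by fixed-point
iteration, pull the annotation onto the subject grid by
nearest-neighbour lookup, count voxels), is provided as
`mode = "pullback"` for cross-checking. Its resolution limit matters:
a boundary displacement below half a voxel cannot change any
nearest-neighbour label, so pull-back counting only resolves
supra-voxel deformations; Jacobian integration has no such floor.

## Voxelwise statistics

Group comparison is a per-voxel two-sided independent-samples t-test,
pooled-variance by default (Welch optional) — the language used for the
study design ("two-way independent sample tests") is read as two-*sided*.
Voxels with zero variance in both groups are flagged and reported at
p = 1. To combine two experiments, an additive two-way ANOVA (main
effects of genotype and batch, no interaction) is fitted per voxel; the
genotype F is the extra-sum-of-squares test of adding genotype to the
batch-only model, i.e. genotype controlled for batch, and symmetrically
for the batch map. All voxels share the design matrix, so both models
are solved once by QR projection and applied to the stacked data — the
results equal `anova(lm(y ~ batch + genotype))` applied voxel by voxel,
which the test suite asserts directly.

Regional tests mirror the study's analysis: a pooled-variance t-test on
per-subject mask volume percentages with a seeded 5000-resample
percentile-bootstrap CI of the mean difference, and a one-way ANOVA
with *unadjusted* pairwise post hoc t-tests for the three-condition
rescue design (the source analysis reports plain "t-test p < 0.01"
post hoc comparisons, so no multiplicity correction is applied by
default).

## From p-map to region mask

The mask pipeline is a fixed chain: threshold the p-map at
`alpha_voxel` (default 0.01; p equal to alpha counts as significant),
optionally restrict to the direction of effect, remove connected
components below `min_cluster` voxels (default 50, 26-connectivity),
then keep only voxels whose mirror position about the grid's
mid-sagittal plane (index $x \mapsto n_x - 1 - x$) has a set voxel
within `sym_tol` voxels (Chebyshev distance, default 2). Each filter is
idempotent, and an optional re-run of the cluster filter after the
symmetry filter is available. The cluster cutoff and symmetry tolerance
are explicit free parameters of this package, not values taken from any
particular study.

By default the end-to-end pipeline masks the *contraction* direction
(crispant mean LJD below control): the biological target is the region
reduced in crispants, and the compensating dilation that any
volume-preserving contraction induces in surrounding tissue would
otherwise enter the mask and dilute validation-cohort volume ratios.
`threshold_pmap()` itself is sign-agnostic; `direction = "both"`
restores the undirected behaviour.

## The synthetic study

The generator exists so that every downstream stage is testable without
imaging data; its defaults are the study conditions used throughout the
test suite.

**Atlas.** A 64 x 80 x 48 voxel grid at 2 um spacing (a full cohort
runs in minutes at this size) with ellipsoidal divisions placed
mirror-symmetrically: a midline pallium, paired optic tecta, paired
lateral cerebellar plate (LCeP) spheres of radius 8 voxels — the
atrophy target — and a midline medulla, all embedded in a brain-envelope
ellipsoid whose unannotated remainder is the division `"Rest"`. The
envelope makes the brain a contiguous volume, so compensation shells
around contracted regions stay inside brain tissue. Three channels
(pan-neuronal, glutamatergic-like, GABAergic-like) carry
division-specific means; subjects add iid Gaussian voxel noise.

**Warps.** Per-subject random warps are Gaussian white-noise vector
fields smoothed with a sigma = 12 um (6-voxel) kernel and rescaled so
the *maximum* displacement magnitude equals `warp_amplitude`
(default 4 um, 2 voxel edges). Amplitude is deliberately defined on the
maximum, not the per-component SD: a smoothed field with 2-voxel
per-component SD would carry displacement-gradient SDs near 0.24 and
routinely fold (negative Jacobians), whereas the max-normalized field
keeps gradients near 0.05 and Jacobians strictly positive, which the
generator verifies (it regenerates on failure and errors after five
attempts).

**Implanted atrophy.** Atrophy with volume scale $s$ (default 0.8; the
magnitude is a testing choice, not an empirical value) is implanted as
a radial map $\rho(r)$ about each twin's centre: uniform scaling
$\rho = s^{1/3} r$ inside the division radius $R_0$, a monotone cubic
Hermite blend returning to the identity with unit slope at
$R_1 = 1.6 R_0$. Inside the core $J = s$ exactly; the shell
$[R_0, R_1]$ dilates by exactly the displaced volume, so total brain
volume changes by well under 1% — a localized deficit without a global
volume change. Discrete gradients blend across the core boundary, so
the realized mean regional Jacobian carries a small upward bias
(about +0.003 at the default radius), far inside the ±0.05 contract.

**Power at the defaults.** With $s = 0.8$ (per-voxel effect
$\ln 0.8 \approx -0.223$), per-voxel LJD noise SD near 0.1, and 14
versus 17 subjects, the voxel t-test has high power: in the test suite
all truth-region voxels reach p ≤ 0.01 and the filtered mask's Dice
overlap with the truth region exceeds 0.5 in at least 18 of 20 seeded
replicates.

Two quantitative properties of the defaults deserve flagging. First,
the discovery mask inevitably includes the one-voxel boundary ring
whose discrete Jacobian blends core and surround: those voxels carry
real partial signal and pass p ≤ 0.01 at these group sizes, so
validation-cohort volume ratios measured in the discovery mask run
about 3% above the implanted scale (0.82-0.84 for s = 0.8), while the
same measurement over the generator-truth region recovers s within
about 2%. Second, the null behaviour of the filter chain is governed
by the warp smoothness: a sigma of 6 voxels makes null t-maps
correlated over roughly 14 voxels FWHM, so effect-free suprathreshold
blobs come in sizes of hundreds of voxels and the 50-voxel cluster
cutoff rarely binds. The symmetry filter removes lateral null blobs,
but a blob straddling the mid-sagittal plane is its own mirror image
and survives any tolerance; across 20 independent effect-free cohorts
the chain returned an empty mask in 13, with every survivor a single
midline-straddling cluster. Localized *lateral* findings are therefore
well protected by the filter chain at these settings; apparent midline
findings require a stricter cluster threshold (set from the observed
null blob sizes) or replication, exactly as the validation-cohort
stage provides.

**What the generator does not emulate.** Real registration error is
not white: it has anatomy-correlated structure, intensity-dependent
failure modes, and boundary artefacts none of which are simulated;
channel noise is Gaussian rather than Poisson-mixed; the atlas has six
divisions, not hundreds. Passing tests therefore demonstrate the
correctness and calibration of the *pipeline*, not the detectability of
any particular effect in real data.

A caveat on calibration checks: LJD maps inherit the warp's spatial
correlation. The per-voxel null p-values remain marginally uniform, but
the *fraction* of brain voxels below a threshold then fluctuates more
than binomially (fewer effective independent tests). The binomial-band
type-I check is therefore run on channel maps, whose voxel noise is
independent by construction; null LJD cohorts are instead required to
produce empty masks through the full filter chain.

## DE convergence

Two experiments' DE tables (gene, baseMean, log2FoldChange, pvalue) are
reduced to a shared universe of genes with baseMean at or above
`min_basemean` (default 100) in *both* experiments — a gene below the
floor in either is excluded. Benjamini-Hochberg adjustment is applied
within the universe per experiment (via `p.adjust`; an independently
coded step-up oracle checks it exactly in the tests), with significance
called strictly below `alpha_fdr` (default 0.1). The convergence
statistic is the upper-tail hypergeometric probability
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, n_A, n_B)$, of the observed
overlap $k$; at the published list sizes (125 and 842 in a universe of
17,629, overlap 31) it reproduces the printed $1.9 \times 10^{-14}$,
which confirms that the expression-filtered universe is the correct
background for that test. The test is applied to the total overlap by
default (a sign-stratified variant is available); directions are
reported as concordant / discordant, with zero fold changes flagged and
left unclassified.

The synthetic DE generator simulates negative-binomial counts for 3
versus 3 replicates per experiment with a configurable number of shared
(sign-consistent by construction) and experiment-specific DE genes. Its
per-gene p-value is a two-sample Student t-test on
$\log_2(\mathrm{count}+1)$ — a deliberate simplification standing in
for a shrinkage-based DE fit, adequate because downstream operations
consume only (p, log2FC, baseMean) triples; library sizes are equal by
construction so baseMean is the plain mean count.

## Fragment QC

A capillary-electrophoresis trace is reduced to peaks (local maxima
with topographic prominence at or above `min_prominence` times the
trace maximum, default 5%; areas by trapezoid integration between
flanking valley minima), and the wildtype fraction is the area share of
the peak nearest the expected product size within
`size_tolerance_bp` (default 2 bp); no peak within tolerance means an
extinguished wildtype product, fraction 0. Detected sizes include the
fluorescent primer tags (18 bp forward + 7 bp reverse), so the expected
size is the declared amplicon size plus a 25 bp offset (configurable).
A subject is included for phenotyping iff at least one guide reduced
the wildtype fraction strictly below `wt_threshold` (default 0.5).

Two geometric preconditions of the area estimator are worth stating.
First, a peak is only quantified if its prominence clears the 5%-of-max
floor; at wildtype fraction 0.9 with two equal indel products, each
indel peak stands at 5.5% of the maximum, an 11% margin, so the
baseline noise must stay near or below 1% of the wildtype peak (ABI
traces comfortably do; the generator's default baseline SD corresponds
to a ~900:1 wildtype-peak SNR). Second, prominence is measured against
the connecting valley: peaks closer than about six peak-widths to a
much larger neighbour lose prominence to valley overlap. The
generator's default indel spectrum (two equal products at -7 and +7 bp,
0.8 bp peak SD) respects both; traces violating them are flagged as
`crowded` rather than silently mis-quantified.

## Reproducibility and sizes

Every generator is a pure function of its spec and seed; cohort subject
i derives its seed as `seed + i`, and all bootstrap resampling is
seeded from the run configuration. Stage invocations write YAML
manifests with the seed, parameters and MD5 hashes of inputs and
outputs; re-running a stage with the same seed reproduces its output
files byte-identically, which the test suite asserts.

Problem sizes used by the test suite: the full 64 x 80 x 48 atlas with
14/17 cohorts for recovery and null properties (20 seeded replicates
each), 64^3 grids for 50 Jacobian-oracle fields, 1000 random p-vectors
and 25 random 3D masks for the filter oracles, and 100 synthetic traces
across wildtype fractions 0.1-0.9. The rescue design uses 16/14/12
subjects — matching the published condition sizes, and giving the
familiar F(2, 39) reference distribution — across 10 seeded replicates.
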