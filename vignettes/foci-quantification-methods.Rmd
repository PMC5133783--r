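---
title: "Methods: 3D foci quantification and companion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D foci quantification and companion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociquant3d)
```

This vignette is the package's own account of its models, parameters and
numerical choices: what each stage assumes, why the defaults are what they
are, and what the synthetic-data validation does and does not demonstrate
about real data.

## Image model and conventions

A stack is a set of non-negative 3D intensity arrays sharing a voxel
geometry, stored as `dim = c(nz, ny, nx)` with 1-based indices. All
physical quantities are in micrometres; voxel sizes are nanometre triples
`c(dz, dy, dx)`. The reference confocal geometry is 47 × 47 nm lateral
sampling with 200 nm z-steps over 42 planes, i.e. a voxel of
4.418 × 10⁻⁴ µm³ — strongly anisotropic, which is why sizes and distances
are always converted through the voxel geometry rather than counted in
pixels of one plane.

## Foci quantification

**Nucleus segmentation.** The DNA counterstain is thresholded globally by
Otsu's method, then closed and hole-filled slice by slice (disc brush,
radius 2 px by default) and labelled in 3D with 26-connectivity.
Components below `min_nucleus_voxels` (default 500) are dropped, as are
nuclei touching the lateral image border: a truncated nucleus would bias
its focus count downward. Finding no nuclei is a warning, not an error, so
batch runs survive empty fields. The procedure assumes nuclei are bright,
compact and separated; touching nuclei are not split (no watershed), which
matches fields plated at sub-confluent density.

**Detection threshold.** No universal intensity threshold works across
cells, so the threshold is computed *within each nucleus*, per channel:
Otsu on the in-nucleus intensities by default, or mean + k·SD (k = 3) via
`threshold_method = "mean_sd"`. Voxels above threshold are grouped into
26-connected components; a component becomes a focus when it has at least
`min_voxels` voxels — an **inclusive** bound (a 50-voxel component passes a
50-voxel minimum), matching the reading of a "minimal size". The reference
thresholds are 50 voxels (0.022 µm³) for γH2AX and 10 voxels for SMC6 on
the reference grid; on other grids the same *physical* volumes should be
re-expressed in voxels (`min_voxels_for_volume()` internally, or by hand as
`round(0.022 / voxel_volume(vs))`). The word "pixels" in such protocols is
interpreted as 3D voxels because 50 × 4.418 × 10⁻⁴ µm³ reproduces the
printed 0.022 µm³ exactly. Both channels are restricted to the nucleus,
for symmetry.

**Overlap rule.** A γH2AX focus is SMC6-positive when its voxel set shares
at least one voxel with any SMC6 focus of the same nucleus, counted at
most once per γH2AX focus. A stricter centroid-containment rule is
available (`rule = "centroid"`); the shared-voxel rule is the default
because object-based colocalization of diffraction-sized blobs is usually
stated as overlap, not containment.

**Cell selection.** Analysis is restricted to cells with at least two
detected SMC6 foci (`selection_min_smc6 = 2`). This automates the visual
pre-selection such experiments apply ("cells with clear second-channel
signal") and makes it reproducible.

**Summaries.** Per condition, the package reports mean ± SEM over cells of
the γH2AX count and of the per-cell SMC6-positive fraction; cells with no
γH2AX foci have an undefined fraction and are excluded from the fraction
average. Whether published "≈50 % positive" figures were computed per cell
then averaged, or pooled over foci, is usually ambiguous; per-cell
averaging is the default (it matches mean ± SEM plots over cells) and
`frac_mode = "pooled"` provides the alternative.

## Deconvolution

Commercial restoration (Huygens CMLE with an SNR setting) is proprietary,
so the package ships classic Richardson–Lucy deconvolution: multiplicative
updates, reflective boundary padding, capped at `max_iter = 40`, with an
optional early stop when the mean relative update falls below 1/SNR² —
the same intent (restoration before thresholding) in a reproducible,
standard form. The PSF is a separable Gaussian truncated at ±3σ and
renormalised; defaults σ_xy = 0.1 µm, σ_z = 0.3 µm are placeholders of the
right order for a high-NA confocal and should be calibrated per microscope.
Deconvolution is **off by default** in `quantify_stack()`: nucleus-local
Otsu thresholds already adapt to blur, and the validation suite checks
detection both with and without it. RL guarantees non-negativity and
approximately conserves flux for interior-supported signal; on noiseless
input the Kullback–Leibler divergence between the observation and the
re-blurred estimate is non-increasing over iterations (verified in the
tests against a brute-force reference implementation of the update).

## Synthetic phantoms: what they emulate, what they do not

`gen_foci_stack()` draws axis-aligned ellipsoidal nuclei on a jittered
grid (simplest shape that still exercises 3D anisotropy), places foci
uniformly inside a 0.75-scaled copy of each ellipsoid (centres strictly
interior), renders them as isotropic-in-µm Gaussian blobs onto the
anisotropic voxel grid, and adds Poisson shot noise plus unit-variance
Gaussian read noise on a photon scale of SNR² photons per intensity unit.
Default channel SNRs are 10 (γH2AX, red), 12 (SMC6, green) and 20 (DNA);
the first two mirror common restoration settings for those fluorophores,
the DNA value reflects a bright counterstain. Each γH2AX focus carries a
co-centred SMC6 focus with probability `coloc_prob` (default 0.5, the
magnitude reported for SMC6 at DSB sites), plus `extra_smc6 = 2` SMC6-only
foci per nucleus. A minimum centre separation (default 0.8 µm) prevents
blob merging, so ground-truth counts are recoverable.

Real data differ in ways the phantom deliberately ignores: nuclei are
neither ellipsoidal nor axis-aligned, foci vary in brightness and size,
background is structured (nucleoli, cytoplasmic signal), the PSF is not
Gaussian, and colocalization in vivo is partial rather than co-centred.
Passing the recovery tests therefore demonstrates that the *measurement
chain* is correct and unbiased under known conditions — not that any
particular biological threshold is optimal for a given microscope.
Published per-condition foci-count distributions are not available
numerically, so the generator's count defaults (~20 per nucleus at the
damage peak) are order-of-magnitude choices, not fits.

## Clonogenic survival

Colony tables carry one row per experiment × dose × plating density.
Plating efficiency comes from the dose-0 control; survival at dose D is
the colony-forming fraction divided by PE, computed per density level
against its density-matched control and averaged with equal weight within
the experiment (how the two densities combine is rarely stated; equal
weighting is the neutral choice). S(0) = 1 by construction and the curve
is invariant under proportional rescaling of counts. Curves aggregate
experiments as mean ± SEM — SEM across *experiments*, not across density
replicates. Genotypes are compared per dose by a paired one-tailed
Student's *t*-test (pairing = experiment), with the one-tailed direction
defaulting to "the second line is more sensitive" and exposed as a flag;
identical curves yield t = 0 and a one-tailed p of 0.5. The
linear–quadratic fit (`fit_lq()`) is an extension beyond raw curves and is
off by default. The simulation model is Binomial(n_plated,
PE·exp(−αD − βD²)), so closed-form expectations are available for
validation.

## Cell-cycle analysis

**Gating.** The 2N peak position µ is the kernel-density mode, scored
jointly with the density at 2µ so a dominant 4N peak is not mistaken for
2N (modes below 5 % of the maximum density are ignored as noise wiggles).
Gates are µ(1 ± k·cv) and 2µ(1 ± k·cv) with k = 2.5; they must not
intersect, which bounds cv < 1/(3k) ≈ 0.13 — comfortably above typical
propidium-iodide CVs of 3–8 %. Raw gate counts are then corrected by
solving the 3 × 3 linear mixing system implied by the model (Gaussian
peaks, uniform S-phase plateau on (µ, 2µ)): the S plateau contributes
k·cv of its mass to the G0/1 gate and 2k·cv to the G2/M gate, and each
peak loses (1 − (2Φ(k) − 1))/2 per tail. Without this correction the
G2/M fraction is overestimated by ≈2·k·cv·f_S, which at cv = 0.04 already
exceeds a 0.02 accuracy requirement. Corrected fractions are clamped to
[0, 1]. This is deliberately *not* a full Dean–Jett–Fox model fit:
peak-anchored gates are transparent, fast, and adequate at the CVs the
package targets.

**Colcemid series.** Under a mitotic block, cycling cells leave G0/1, so
f_G0/1(t) decays towards the non-cycling residual. Gates are anchored on
the t = 0 sample (µ and cv fixed), because at late time points the 2N
peak may be nearly empty and re-estimating µ per sample would let the
gate drift onto the 4N peak. The decay-to-plateau model
f(t) = r + (f₀ − r)·e^(−t/τ) is fitted by bounded Levenberg–Marquardt
(r, f₀ ∈ [0, 1]; τ ∈ [10⁻³, 10⁶] h; started at the series minimum, first
value and a quarter of the time span). The model itself is this package's
formalisation of "a resistant fraction remains" — descriptions of such
experiments typically fit nothing. A constant series is the degenerate
τ → ∞ limit and is returned as plateau = f₀ without invoking the
optimiser.

**Division intervals.** Intervals are lognormal in the generator (mean and
CV specified; cv = 0 degenerates to exact constants). The fold change is
the ratio of sample means and is invariant under a common time-unit
rescaling. The two lines are compared with a two-tailed unpaired Student's
*t*-test on the pooled intervals — the convention chosen to match the
imaging statistics, since time-lapse protocols rarely state one.
`align_generations()` re-indexes lineages so the generation spanning a
shared anchor event (e.g. a medium refresh) gets a common index; gaps are
preserved, never imputed.

## CRISPR verification

Guides are matched exactly (20 nt) on both strands; a hit requires an
NGG PAM immediately 3′ of the protospacer (NAG optionally, as the weaker
alternative PAM). The blunt cut is placed 3 bp 5′ of the PAM — between
protospacer positions 17 and 18 — which is the canonical SpCas9 geometry
and the placement required for a 417-bp amplicon cut to split into
304 + 113 bp. `cut_site` is reported as the length of the 5′ fragment in
forward-strand coordinates, a convention-free quantity; hits are invariant
under reverse-complementing the template, with coordinates transforming as
L − cut. In-silico PCR uses exact primer matching (a verification tool
should not tolerate mismatches), requires a unique facing product, and
recognises a reverse primer supplied already reverse-complemented. The
Surveyor indel estimate corrects for reannealing: only
heteroduplexes are cleaved, so
indel% = 100·(1 − √(1 − f_cut)) with f_cut = (b + c)/(a + b + c); the
estimator is monotone, maps [0, 1] onto [0, 100] %, and inverts exactly.
Off-target work is limited to locating given sequences in given templates;
off-target *scoring* is out of scope. Because the genomic reference around
the edited locus is not bundled, the demonstration amplicon is synthetic —
random sequence carrying the real guide sites and primer pair at positions
that reproduce the published fragment split — and is labelled as such
wherever it appears.

## Statistics

`two_sample_t()` implements the classic pooled-variance Student *t*
(Welch by flag), paired or unpaired, one- or two-tailed; a one-tailed p is
half the two-tailed p when the effect lies in the hypothesised direction.
Zero-variance inputs are handled explicitly (t = 0, p = 1 or 0.5, rather
than NaN). Time points of an imaging experiment are tested independently
without multiplicity correction — mirroring how per-time-point p-values
are usually reported — but `run_foci_experiment()` adds a Holm-corrected
column alongside for honesty, and reports *both* cell-level tests (cells
pooled across experiments) and experiment-level tests (n = experiments,
cells nested), because which level a published "n = 3" refers to is often
ambiguous.

## Problem sizes and numerical tolerances

The validation suite runs phantoms on a coarser 150 × 150 × 300 nm grid
(nuclei of 1.8 × 3 × 3 µm radii, 4 per 20 × 200 × 200 stack), which keeps
a full test run under two minutes while preserving the 2:1 axial
anisotropy the code must handle; minimal focus sizes are re-expressed as
the same physical volumes on that grid (3 and 1 voxels). On this grid the
test phantoms use σ = 0.2 µm blobs with a 1.2 µm minimum separation so
that the nucleus-local Otsu threshold — which admits blob shoulders out to
roughly 0.45 µm — cannot merge adjacent foci; exact ground-truth recovery
is then a fair requirement. Monte-Carlo calibration checks (type-I error
of both *t*-test variants) use 2000 simulations and a three-standard-error
acceptance band. PSF kernels renormalise to unit sum within 10⁻⁹;
the indel round-trip is exact to 10⁻¹²; voxel-radius computations subtract
10⁻⁹ before `ceiling()` to avoid floating-point spill into an extra voxel.

## Known limitations

No watershed separation of touching nuclei; no vendor image formats
(TIFF + JSON sidecar only) and no FCS binary parsing (CSV event lists);
no blind deconvolution or measured-PSF input; no tracking of foci across
time points (each time point is an independent fixed-cell sample); the
phase-fraction correction assumes the univariate Gaussian-peaks +
uniform-S model and will be biased for strongly skewed peaks; Surveyor
band intensities are numeric inputs — gel densitometry is out of scope.
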