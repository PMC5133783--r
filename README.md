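# fociquant3d

Quantification of DNA double-strand-break (DSB) foci in 3D confocal
microscopy, with the companion analyses a DSB-biology study needs:
clonogenic survival, DNA-content cell-cycle analysis, division-interval
statistics and CRISPR edit-verification arithmetic. A seeded synthetic-data
generator produces inputs with known ground truth for every stage, so the
whole pipeline is testable end to end.

## Who this is for

Labs that image DSB markers (e.g. γH2AX) together with a repair factor
(e.g. the SMC5/6 subunit SMC6) in fixed nuclei and need objective,
reproducible per-cell answers to questions such as *how many DSB foci does
each nucleus carry?* and *what fraction of DSB sites is positive for the
second marker?* — plus the standard downstream assays (clonogenic survival
after ionizing radiation or etoposide, colcemid cell-cycle depletion,
time-lapse division intervals, Surveyor-based CRISPR verification) analysed
with matching statistical conventions.

## What it computes

**3D foci quantification.** Image stacks are non-negative intensity grids
with anisotropic voxel geometry (reference acquisition: 47 × 47 nm lateral,
200 nm axial; one voxel = 4.418 × 10⁻⁴ µm³). Nuclei are segmented from the
DNA counterstain (global Otsu threshold, slice-wise closing and hole fill,
3D 26-connected labelling; border-touching nuclei excluded). Within each
nucleus, foci are 26-connected components above a nucleus-local threshold,
kept when they reach a minimal size — 50 voxels (0.022 µm³) for γH2AX, 10
voxels for SMC6 on the reference grid. A γH2AX focus is *SMC6-positive*
when its voxel set shares at least one voxel with an SMC6 focus of the same
nucleus; cells enter analysis when they show at least two SMC6 foci.
Per-condition summaries report mean ± SEM over cells. Optional
Richardson–Lucy deconvolution (capped at 40 iterations) can precede
detection.

**Clonogenic survival.** Plating efficiency PE = colonies/cells plated;
relative survival S(D) = (colony-forming fraction at dose D)/PE, so
S(0) = 1; curves aggregate experiments as mean ± SEM, and genotypes are
compared per dose with a paired one-tailed Student's *t*-test. An optional
linear–quadratic fit of log S(D) = −αD − βD² is included.

**Cell cycle.** DNA histograms are gated around the 2N and 4N peaks
(μ(1 ± k·cv), k = 2.5) with an analytic correction for S-phase spill-in;
colcemid series are fitted with a decay-to-plateau model
f(t) = r + (f₀ − r)·exp(−t/τ) whose plateau r estimates the non-cycling
subpopulation; division intervals give fold change = mean(B)/mean(A) with a
two-tailed unpaired *t*-test.

**CRISPR verification.** Exact protospacer matching on both strands with
NGG (optionally NAG) PAMs, blunt cut 3 bp 5′ of the PAM, Surveyor cleavage
fragment prediction (fragments always sum to the amplicon length), and the
standard indel estimate: f_cut = (b + c)/(a + b + c),
indel% = 100·(1 − √(1 − f_cut)). In-silico PCR with exact primer matching
yields the amplicon.

## Worked example

Generate a noiseless phantom (4 nuclei, 10 γH2AX foci each, half of them
carrying a co-centred SMC6 focus, 2 extra SMC6-only foci) on a coarse
150 × 150 × 300 nm grid and quantify it:

```r
library(fociquant3d)

p <- foci_phantom_params(
  stack_shape = c(20L, 200L, 200L), voxel_size_nm = c(300, 150, 150),
  n_nuclei = 4L, nucleus_radii_um = c(1.8, 3, 3), n_gh2ax = 10L,
  coloc_prob = 0.5, extra_smc6 = 2L, focus_sigma_um = 0.2,
  min_separation_um = 1.2, seed = 41)
ph <- gen_foci_stack(p)
q  <- quantify_stack(ph$stack, min_voxels = c(gh2ax = 3, smc6 = 1))
q$records
#>   nucleus n_gh2ax n_smc6 n_overlap frac_smc6_positive selected
#> 1       1      10      9         7                0.7     TRUE
#> 2       2      10      8         6                0.6     TRUE
#> 3       3      10      8         6                0.6     TRUE
#> 4       4      10      8         6                0.6     TRUE

summarize_condition(q$records, genotype = "WT", timepoint = "30min")
#>   genotype treatment timepoint n_cells mean_gh2ax sem_gh2ax
#> 1       WT      <NA>     30min       4         10         0
#>   mean_frac_smc6_positive sem_frac_smc6_positive
#> 1                   0.625                  0.025
```

Every count matches the generator's ground truth (`ph$truth$counts`): 10
γH2AX foci per nucleus, and the per-nucleus overlap counts are exactly the
co-centred foci that were placed (the minimal focus sizes 3 and 1 voxels
are the 0.022 µm³ and 0.0044 µm³ physical thresholds re-expressed on this
coarser grid). With `coloc_prob = 0.5` the mean SMC6-positive fraction
fluctuates around one half — here 0.625 with 40 foci.

`run_full_demo(master_seed)` chains every stage (imaging, survival, cell
cycle, CRISPR) on synthetic data in about a minute.

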