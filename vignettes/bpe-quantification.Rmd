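---
title: "Quantifying breast density and background parenchymal enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying breast density and background parenchymal enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(bpemri)
```

## The measurement problem

Breast MRI offers two quantitative markers that are candidates for cancer
risk stratification. **MRI breast density (MRBD)** is the percentage of the
whole-breast volume occupied by fibro-glandular tissue (FGT).
**Background parenchymal enhancement (BPE)** is the signal increase of
normal parenchyma after contrast injection, quantified here voxelwise as

$$\mathrm{BPE}(\%) = 100 \times \frac{I_{MTP} - I_{FTP}}{I_{FTP}},$$

where $I_{FTP}$ is the voxel intensity on the first (pre-contrast) frame of
a dynamic contrast-enhanced (DCE) series and $I_{MTP}$ the intensity on the
maximum-enhancement time point — the dynamic frame whose *median* intensity
over the segmented parenchyma is highest. Because normal parenchyma shows
type I (persistent) kinetics, the MTP falls at or near the end of the
series; the search excludes the pre-contrast frame by construction, and
ties resolve to the earliest qualifying frame so the choice is
deterministic.

A measurement pipeline for these markers has to chain several image-level
stages, each with its own failure modes. `bpemri` implements the chain as
composable functions and — because patient data cannot be shipped with a
package — validates every stage against a synthetic DCE breast phantom
whose ground truth is known exactly.

## Pipeline stages

1. **Whole-breast masking** (`region_grow()`, `erode_mask()`,
   `split_laterality()`). Seeded 3D region growing on the
   non-fat-suppressed T2w volume admits voxels whose intensity lies within
   `tolerance` of the running region mean, using 26-connectivity. Admission
   is *best-first*: each wave admits the boundary voxels most similar to
   the running mean, and rejected boundary voxels are reconsidered as the
   mean drifts. A naive wave-order criterion lets the mean dip sharply
   while the front crosses a dark sub-region (a dense FGT lobule), at which
   point the admission band can reach the background; best-first admission
   keeps the mean trajectory monotone-ish and stable. The grown mask is
   then eroded with a ball structuring element (default radius 2 voxels) to
   remove the skin rind and the chest-wall interface, and split at the
   mid-sagittal world plane. Laterality is always derived from the affine
   (world +x = patient right), never from array order, so display
   conventions cannot corrupt left/right labels.

2. **Bias-field correction** (`correct_bias()`). Coil sensitivity imposes
   a smooth multiplicative intensity field that would corrupt intensity
   clustering. The corrector alternates (i) grouping in-mask voxels into
   `n_classes` intensity classes on the current corrected log intensities
   and (ii) fitting a polynomial of total degree `max_order` (default 2) to
   the class-mean-removed log intensities. Removing class means strips
   tissue contrast from the surface fit; class-granularity errors are
   spatially high-frequency and are rejected by the low-order polynomial.
   The field is normalised to mean 1 over the mask, making the correction
   gauge-free: downstream clustering sees the same global scale. This is a
   contract-level implementation of smooth multiplicative field removal,
   not a re-implementation of any specific bias-correction tool; the
   correction hook accepts any externally corrected volume.

3. **FGT segmentation and density** (`fit_fcm()`, `segment_fgt()`,
   `compute_density()`). Fuzzy c-means with $K = 7$ intensity clusters and
   fuzziness $m = 2$ is fitted independently within each breast;
   each voxel is hard-assigned to its maximum-membership cluster (ties to
   the lower index) and FGT is the union of selected clusters — by default
   the three lowest-centroid clusters, since FGT is dark on
   non-fat-suppressed T2w. The selection is overridable (`"lowest:k"`,
   `"highest:k"`, `"gap:high"`, or an explicit index set) to mirror the
   operator fine-tuning such semi-automated tools allow. MRBD is
   $100\,|FGT|/|breast|$ and fibro-glandular volume is the voxel count
   times the voxel volume.

4. **Parenchyma segmentation on DCE and the BPE map**
   (`segment_parenchyma_precontrast()`, `select_mtp()`,
   `compute_bpe_map()`). The whole-breast mask is resampled to the DCE grid
   (nearest neighbour in world coordinates, so masks stay boolean), minus
   any operator-drawn exclusion regions such as fat-suppression failures.
   FCM runs on the *pre-contrast* frame — segmenting before enhancement
   avoids biasing the map towards voxels that enhance. On fat-suppressed
   pre-contrast images parenchyma is bright; the default selection takes
   every cluster above the largest inter-centroid gap, which adapts to how
   many clusters the fat and parenchyma modes each absorb instead of
   hard-coding a count the source method leaves to the operator.
   The BPE map and its distribution summary (median, quartiles, IQR,
   skewness, kurtosis) follow.

5. **Statistics** (`coefficient_of_variation()`, `bland_altman()`,
   `mann_whitney_u()`, `wilcoxon_signed_rank()`, `student_t()`,
   `paired_t()`, `spearman_r()`, `kurtosis_regression()`,
   `cohort_compare()`). Repeatability CVs ($\sigma/\mu \times 100\%$ per
   subject, pooled as the root mean square), Bland–Altman right/left
   agreement with RPC $= 1.96\,SD(\Delta)$, two-sided location tests with
   exact small-sample enumeration, tie-aware Spearman correlation, and the
   ordinary-least-squares model of BPE kurtosis on age, risk group and
   their interaction.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tolerance` (region growing) | 240 | intensity | wide enough to bridge the fat–FGT contrast of the phantom, narrow enough to exclude muscle and air at every modelled density |
| `erode_radius_vox` | 2 | voxels | removes a ≤ 2-voxel skin rind at 2 mm resolution; exposed because the right value tracks voxel size |
| `K` (clusters) | 7 | — | seven intensity clusters resolve sub-tissue texture while keeping clusters populated |
| `m` (fuzziness) | 2 | — | the universal FCM default; exposed |
| FCM convergence | rel. ΔJ < 1e-6, ≤ 300 iter | — | desk-scale data converge far earlier; non-convergence is flagged, not fatal |
| `selection` (T2w) | `lowest:3` | — | FGT is dark on non-FS T2w; the 3-of-7 rule is the documented default, overridable per case |
| `selection` (DCE) | `gap:high` | — | parenchyma is bright on FS pre-contrast frames; the gap rule adapts the cluster count |
| `denominator_floor_frac` | 0.01 | fraction of parenchymal pre-contrast median | the enhancement ratio is undefined near zero; dropped voxels are counted, never silently imputed |
| `bias_amplitude` (phantom) | 0.15 | fraction | a realistic peak deviation for a corrected-era breast coil at 3 T |
| `noise_sigma` (phantom) | 0.02 | fraction of mean tissue signal | high-SNR modern acquisition |
| `enhancement_median_pct` / `enhancement_spread_pct` | 30 / 15 | % | a typical persistent-enhancement level with right-skewed spread |

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds bilateral hemi-ellipsoidal breasts on a
chest-wall slab with a 2-voxel skin rind, on a default 64 × 96 × 32 grid at
2 mm isotropic spacing — small enough that a full analysis runs in seconds,
large enough to preserve 3D morphology. The FGT compartment is a connected,
lobulated central region thresholded from a smoothly modulated ellipsoidal
field at exactly the configured volume fraction, so the ground-truth MRBD
equals the voxel-count ratio by construction.

Within each tissue the phantom adds 6 mm *heterogeneity patches* (three FGT
sub-intensities, four fat sub-intensities). These play two roles: they make
a seven-cluster intensity model meaningful (three clusters genuinely
capture FGT), and — because the patches are high-frequency — intra-tissue
texture stays orthogonal to the low-order polynomial the bias corrector
fits, so texture cannot masquerade as coil bias.

The dynamic series is rendered through the spoiled gradient-echo
steady-state equation (`spgr_signal()`, TR 4.24 ms, flip angle 12°, seven
frames at 59.1 s spacing). Each FGT voxel draws a peak enhancement from a
log-normal distribution parameterised to hit the configured median and IQR
(right-skewed, strictly positive, as parenchymal enhancement is), capped
just inside the sequence's dynamic range $s_0 \sin\alpha$; the voxel's R1
trajectory is obtained by inverting the signal equation at the peak and
interpolating along the kinetic template. Fat is suppressed to a few
percent of parenchymal signal except in configurable fat-suppression
failure patches. A fixed order-2 polynomial bias field (scaled to
`bias_amplitude`) and additive Gaussian noise are applied last.

Gaussian (not Rician) noise is the default deliberately: magnitude bias is
irrelevant to the contracts under test and Gaussian noise keeps the
recovery oracles exact. Deliberately *not* modelled: coil sensitivity
profiles beyond the smooth bias field, cardiac/respiratory motion and
ghosting, parallel-imaging artefacts, partial-volume fat–water mixing, and
contrast-agent pharmacokinetics (enhancement is parameterised directly in
percent because the tissue relaxation rates and relaxivities behind it are
not identifiable from the data the pipeline consumes). Passing
phantom-recovery tests therefore demonstrates that the *computational
chain* is faithful — not that the pipeline is robust to every artefact of
clinical acquisition.

## Numerical choices

- **Quantiles** use linear interpolation between order statistics
  (R type 7) everywhere; the convention is pinned so results are
  bit-reproducible.
- **Skewness and kurtosis** are moment-based: $g_1 = m_3/m_2^{3/2}$ and
  *non-excess* $b_2 = m_4/m_2^2$ (normal → 3). The non-excess convention
  matters when comparing kurtosis magnitudes across software.
- **FCM initialisation** places centroids evenly across the robust
  intensity range (0.5–99.5 percentiles) rather than at evenly spaced
  sample quantiles: quantile placement under-seeds a scarce tissue class
  (at 5% density no initial centroid lands in the FGT mode, and a fixed
  lowest-3 selection then mislabels fat). Range placement seeds every mode
  regardless of its volume fraction and is deterministic; seed-controlled
  jitter is available for sensitivity analysis.
- **Cluster-count degeneracy**: idealised (noise-free) inputs can carry
  fewer distinct intensities than K. `segment_fgt()` reduces K to the
  supportable count and rescales count-based selection rules
  proportionally (e.g. lowest:3-of-7 → lowest:1-of-2), with a message.
- **Exact rank tests** enumerate all $\binom{n_1+n_2}{n_1}$ labelings
  (Mann–Whitney) or all $2^n$ sign patterns (signed rank) up to a combined
  n of 12, handling ties naturally; beyond that, the normal approximation
  with tie and continuity corrections takes over. Two-sided p-values are
  the null probability of a deviation from the centre at least as large as
  observed.
- **Ties** break deterministically everywhere: maximum-membership
  assignment to the lower cluster index, MTP to the earliest frame.
- **Degenerate inputs** are flagged, not patched: zero-variance
  distributions return NA moments with a `degenerate` flag, empty masks
  and all-dropped denominators raise classed errors, erosion that
  annihilates a mask is an explicit error.

## Validation problem sizes

The shipped tests and the acceptance script regenerate everything they
measure. The package's own validation runs use: the default
64 × 96 × 32 phantom for end-to-end recovery at FGT fractions
{0.05, 0.125, 0.20, 0.40} × noise {0, 0.02} and enhancement medians
{10, 15, 20, 30}%; 2000-replicate null simulations (n = 10 + 10) for
type-I error; 2000-replicate coverage simulation for the regression CIs;
and $10^6$ seeded draws for the kurtosis calibration against the analytic
values 3 (normal) and 9/5 (uniform).

## Known limitations

- The bias model is a global low-order polynomial; a field with strong
  local structure (e.g. implant-adjacent flare) needs the external
  correction hook.
- Intensity-only FCM has no spatial regularisation, by design; heavy noise
  produces salt-and-pepper segmentations that erosion does not repair.
- The mid-sagittal split assumes the subject is roughly centred in the
  field of view.
- The group-comparison normality screen (Shapiro–Wilk at 0.05) is a
  heuristic stand-in for the visual histogram inspection an analyst would
  perform; the per-metric test choice is overridable.
- No multiplicity correction is applied by default across the
  group-comparison table; `p.adjust` on the emitted p-value column is the
  caller's one-liner when it is wanted.
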