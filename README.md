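# bpemri

Quantitative breast MRI analysis in R: whole-breast masking, fibro-glandular
tissue (FGT) segmentation, MRI breast density (MRBD), voxelwise background
parenchymal enhancement (BPE) mapping, and the repeatability / agreement /
group-comparison statistics that go with them — validated end-to-end on a
synthetic DCE breast phantom with known ground truth.

## Who this is for

Imaging scientists and biostatisticians working with breast DCE-MRI who
need semi-automated, reproducible density and enhancement measurements —
the quantitative counterparts of the qualitative BI-RADS density and BPE
categories — plus the statistical layer used to assess them (intra-/
inter-user coefficients of variation, Bland–Altman left/right agreement,
two-group comparisons, and a kurtosis-on-age-and-risk regression).

## The measurements

- **MRBD (%)** — the percentage of the whole-breast volume occupied by
  fibro-glandular tissue. Breast masks come from seeded 3D region growing
  on non-fat-suppressed T2w images, eroded to remove skin and chest wall;
  FGT comes from seven-cluster fuzzy c-means intensity clustering (fitted
  per breast after multiplicative bias-field correction), with FGT
  assigned by default to the three lowest-intensity clusters.
- **BPE (%)** — computed voxelwise over the parenchyma segmented on the
  *pre-contrast*, fat-suppressed frame of the dynamic series:

  BPE(%) = 100 × (I_MTP − I_FTP) / I_FTP

  where FTP is the pre-contrast frame and MTP the dynamic frame with the
  highest median parenchymal intensity. The BPE distribution is summarised
  by its median, quartiles, IQR, moment skewness, and non-excess kurtosis
  (normal = 3).
- **Statistics** — CV = (σ/μ)·100% pooled as an RMS across subjects;
  Bland–Altman bias and reproducibility coefficient RPC = 1.96·SD(Δ);
  exact small-sample Mann–Whitney and Wilcoxon signed-rank tests (full
  enumeration up to combined n = 12), Student/paired t, tie-aware Spearman
  correlation, and OLS of BPE kurtosis on age × risk group.

Because clinical scans cannot ship with a package, `bpemri` includes a
first-class phantom generator (`generate_phantom()`): bilateral breasts on
a chest wall with a skin rind, a lobulated FGT compartment hitting an exact
target volume fraction, a spoiled gradient-echo (TR 4.24 ms, FA 12°)
dynamic series with type I persistent kinetics at 59.1 s resolution, a
polynomial bias field, and Gaussian noise — with every generative quantity
returned as ground truth.

## Worked example

```r
library(bpemri)

ph  <- generate_phantom(phantom_config(fgt_fraction = 0.2,
                                       enhancement_median_pct = 30,
                                       rng_seed = 42))
res <- run_subject(ph$t2w, ph$dce, subject_id = "phantom-01")
res[, c("laterality", "fgt_volume_cc", "mrbd_pct", "bpe_median_pct",
        "bpe_iqr_pct", "bpe_skewness", "bpe_kurtosis", "mtp_index")]
#>   laterality fgt_volume_cc mrbd_pct bpe_median_pct bpe_iqr_pct
#> 1       left         25.83       20          30.27       15.37
#> 2      right         25.83       20          30.36       15.87
#>   bpe_skewness bpe_kurtosis mtp_index
#> 1       0.9961        4.696         7
#> 2       1.0844        5.235         7
```

The phantom was generated with a true MRBD of 20.00% and a median
enhancement target of 30%; the pipeline recovers 20.0% density per breast
and BPE medians of 30.3/30.4% with the right-skewed, leptokurtic
distribution the generator draws. `mtp_index = 7` confirms the
maximum-enhancement frame is the last of the seven dynamics, as persistent
kinetics require.

The agreement statistics follow the same grammar:

```r
ba <- bland_altman(data.frame(r = c(1, 2, 3), l = c(2, 2, 2)), r, l)
ba
#> <bland_altman> n = 3, bias 0, RPC +/- 1.96
glance(ba)       # one-row tibble: bias, sd_diff, rpc, limits, n
autoplot(ba)     # the Bland-Altman plot
```

`run_cohort()` drives a manifest of subjects (paths or in-memory volumes)
through the whole chain and emits a tidy results table plus the report:
right-breast group comparison (median and Q1–Q3 per group, test, p),
left/right Bland–Altman agreement, paired tests, and repeatability CVs when
repeated analyses are supplied. A thin command-line wrapper lives at
`inst/scripts/bpemri-cli.R` (`phantom`, `analyse`, `cohort` subcommands).

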