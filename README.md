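# pscdnet

Functional brain-network and imaging-biomarker analysis of **delayed
post-stroke cognitive decline** — the minority of mild-stroke patients
who stay cognitively normal for a year or more and then decline. The
package is aimed at neuroimaging and stroke researchers running nested
case-control analyses of this phenotype: it implements every
quantitative stage downstream of spatial normalization as
seed-deterministic R functions, and ships a synthetic cohort generator
so the whole pipeline is testable without patient data.

## What it computes

- **Functional connectivity**: Pearson correlation matrices from
  region-level BOLD time series, with the Fisher transform
  z = atanh(r) for within/between-network averaging.
- **Graph attributes** at proportional density thresholds
  d ∈ {0.05, 0.10, 0.15, 0.20}: characteristic path length (inverted,
  so lower = worse), global efficiency, Louvain modularity, clustering
  coefficient and transitivity, each normalized against a null
  distribution from degree-preserving random rewiring
  (normalized = raw / null mean; for path length, null CPL / raw CPL).
- **System segregation** of the seven canonical cortical networks
  (VN, SMN, DAN, VAN, LN, FPN, DMN) on the full z matrix:

      SysSeg = (Z̄_w − Z̄_b) / Z̄_w

  with Z̄_w the mean z over within-network pairs and Z̄_b over pairs to
  the other analysis networks.
- **Spring-embedded layouts** (Fruchterman–Reingold) for qualitative
  inspection of network composition.
- **Imaging biomarkers** on a common voxel grid: regional and global
  SUVR against a cerebellar-gray reference (four-composite average),
  WMH volume as % of brain parenchyma, and lesion frequency maps.
- **Clinical statistics**: MMSE-trajectory decliner classification
  (≥ 3 points/year or ≥ 5 points absolute), age/NIHSS control matching,
  t / Wilcoxon / χ² / Fisher group comparisons, Spearman (or Pearson)
  associations, group × WMH interaction regression, and a voxel-wise
  logistic model of group on covariate-adjusted SUVR with uncorrected-p
  thresholding.
- **Synthetic cohorts**: modular block-correlation BOLD, structured
  PET/lesion volumes, and MMSE trajectories coupled to segregation, WMH
  and SUVR — one seed, bit-identical regeneration.

## Worked example

```r
library(pscdnet)

spec <- cohort_spec(n_decliners = 4, n_nondecliners = 4, n_nodes = 60,
                    timepoints = 300, seed = 42)
cohort <- generate_cohort(spec, include_volumes = FALSE)
records <- cohort_records(cohort)
records[, c("id", "group", "mmse_baseline", "mmse_final",
            "wmh_fraction_pct", "generating_segregation")]
#>    id        group mmse_baseline mmse_final wmh_fraction_pct generating_segregation
#> 1 D01     decliner            28         15            1.929                  0.611
#> 2 D02     decliner            27         20            0.391                  0.610
#> 3 D03     decliner            29         22            1.044                  0.647
#> 4 D04     decliner            29         23            0.636                  0.554
#> 5 N01 non_decliner            28         27            0.495                  0.827
#> 6 N02 non_decliner            27         27            0.375                  0.828
#> 7 N03 non_decliner            27         26            0.234                  0.839
#> 8 N04 non_decliner            28         30            0.677                  0.810
```

Decliners (`D*`) carry lower generating segregation and lose MMSE
points; non-decliners stay flat. The pipeline then recovers network
structure from the BOLD signal itself:

```r
fc  <- compute_fc(cohort[[1]]$bold)      # 60 x 60 Pearson matrix
seg <- system_segregation(fisher_z(fc), cohort_partition(cohort))
seg$overall
#>   network    sysseg z_within_mean z_between_mean n_within_pairs n_between_pairs
#> 1 overall 0.5891902     0.2906995      0.1194222            163            1051
```

This decliner's estimated overall segregation (0.589) sits near its
generating ground truth (0.611). Null-normalized graph attributes per
density:

```r
attribute_profile(fc, densities = c(0.10, 0.20), n_null = 20,
                  seed = 1, n_restarts = 5)
#>    density              attribute   raw null_mean null_sd normalized
#> 1      0.1   inv_char_path_length 0.978     0.402 0.00416      2.436
#> 2      0.1      global_efficiency 0.101     0.459 0.00278      0.220
#> 3      0.1             modularity 0.837     0.346 0.01115      2.421
#> ...
```

A normalized modularity of 2.42 means the graph is ~2.4× more modular
than degree-matched rewired nulls; normalized efficiency below 1
reflects the fragmentation of a strongly modular graph at low density.
Finally, the published decliner medians classify as expected:

```r
classify_decliner(mmse_baseline = 29, mmse_final = 23,
                  interval_months = 68.3)
#> [1] "decliner"
```

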