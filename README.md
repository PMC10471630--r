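# basicmodes

Eigen-microstate analysis of spontaneous brain activity in R: extract the
basic activity modes that dominate multivariate (node × time) recordings,
select the leading modes with principled criteria, reconstruct functional
connectivity as a superposition of mode coactivation patterns, quantify how
individual-specific those reconstructions are, and test how modes change
between conditions. The package is aimed at researchers analysing
resting-state fMRI node time courses (or any multivariate biological time
series with spatial structure), and ships a synthetic cohort generator with
planted ground truth so every stage of the pipeline is testable end to end.

## The method

Each time point of a node × time recording is a *microstate* — the
whole-system activity pattern at one instant. Node time courses are
z-scored over time, concatenated across subjects into the ensemble matrix
**A** (N × M), and divided by the root-sum-square of the elements (a
dataset constant *S*), so the total variance is 1. The SVD
**A** = **UΣV**ᵀ yields the basic modes (eigen-microstates)

> **E**ᵢ = **A v**ᵢ = σᵢ **u**ᵢ,  with weight wᵢ = σᵢ² and Σ σᵢ² = 1.

A mode is *leading* when (i) it falls before the scree elbow of the weight
curve (Kneedle), (ii) its weight exceeds the mean weight 1/N, and (iii) it
is significant against a rank-matched permutation null that shuffles node
labels within every time column. Functional connectivity on z-scored data
is FCᵢⱼ = (1/(M−1)) Σₜ AᵢₜAⱼₜ (exactly Pearson correlation), and decomposes
into mode coactivations:

> FCᵢⱼ = (S²/(M−1)) Σₖ Eᵢₖ Eⱼₖ,

so the first k modes give a low-rank FC reconstruction that is exact at
full rank. Individual specificity is measured by two-run identification
accuracy and differential identifiability I_diff = (I_self − I_others) ×
100; condition differences are tested with subject-label-flip permutation
tests (FDR-corrected), after matching modes across conditions with a
Hungarian assignment on pattern correlations; and map-to-map associations
are tested against spatial-autocorrelation-preserving (variogram-matched)
surrogate maps.

## Worked example

```r
library(basicmodes)

basis   <- generate_basis(n_nodes = 100, k_modes = 5, seed = 1)
cohort  <- generate_cohort(basis, cohort_manifest(n_subjects = 10, runs = 2,
                                                  M = 300, seed = 2))
zs       <- lapply(cohort$sessions, function(r) lapply(r, zscore_time_courses))
ensemble <- build_ensemble(unlist(zs, recursive = FALSE))
modeset  <- decompose_ensemble(ensemble)
round(head(modeset$weights, 8), 3)
#> [1] 0.227 0.128 0.073 0.044 0.027 0.008 0.007 0.007

select_leading_modes(modeset, ensemble, n_perm = 500, seed = 3)
#> leading_mode_selection: 5 leading mode(s); elbow at rank 6; 1/N = 0.01
#>  rank      weight passes_elbow passes_threshold     p_value is_leading
#>     1 0.227225343         TRUE             TRUE 0.001996008       TRUE
#>     2 0.128431758         TRUE             TRUE 0.001996008       TRUE
#>     3 0.073169106         TRUE             TRUE 0.001996008       TRUE
#>     4 0.043915885         TRUE             TRUE 0.001996008       TRUE
#>     5 0.026665431         TRUE             TRUE 0.001996008       TRUE
#>     6 0.007569013        FALSE            FALSE 1.000000000      FALSE
```

The five planted modes are recovered: their weights clear the 1/N = 0.01
threshold, the elbow sits at rank 6, and each permutation p-value is at the
resolution floor of 500 permutations (≈ 0.002). FC reconstruction converges
rapidly in the number of modes, and the cohort's planted subject signatures
make individuals identifiable across runs:

```r
fc0 <- compute_fc(ensemble)
sapply(c(1, 3, 5, 10), function(k)
  fc_similarity(reconstruct_fc(modeset, k), fc0))
#> [1] 0.8368 0.9856 0.9992 0.9985

fp <- identifiability_report(lapply(zs, function(r) compute_fc(r[[1]])),
                             lapply(zs, function(r) compute_fc(r[[2]])))
c(accuracy = fp$accuracy, I_diff = round(fp$I_diff, 2))
#> accuracy   I_diff
#>     1.00    11.87
```

Five modes already reconstruct the population FC at r ≈ 0.999, and all 10
subjects are identified from their reconstructed run-2 connectomes
(I_diff ≈ 11.9 similarity percentage points between self and others).

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study on
simulated cohorts and write their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate_cohort.R` | simulate and write the two-run cohort (TSV + manifest) |
| `02_decompose_select.R` | ensemble, decomposition, leading-mode selection, system amplitudes |
| `03_reconstruct_fc.R` | FC reconstruction sweep and full-rank identity check |
| `04_fingerprint.R` | identification accuracy and I_diff vs. number of modes |
| `05_state_comparison.R` | paired two-state amplitude and coactivation tests |
| `06_map_association.R` | surrogate-corrected map associations |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_cohort.R`.

## Scope notes

The package consumes node-level matrices (TSV); conversion from imaging
formats (NIfTI/CIFTI), fMRI preprocessing, and parcellation construction
are upstream of it. The methods vignette
(`vignettes/eigen-microstates.Rmd`) documents the model, the synthetic
generator's assumptions, numerical conventions and known limitations.
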