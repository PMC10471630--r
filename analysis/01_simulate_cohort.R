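#!/usr/bin/env Rscript
# Simulate the study cohorts: a two-run resting cohort with subject
# signatures (for decomposition, FC reconstruction and fingerprinting) and a
# paired two-state cohort with a planted flattening of mode 1 (for the state
# comparison). Sessions are written as TSVs with a JSON manifest.

suppressPackageStartupMessages(library(basicmodes))

out <- "results/cohort"
seed <- 20L

basis <- generate_basis(n_nodes = 100, k_modes = 5, seed = seed)
manifest <- cohort_manifest(n_subjects = 20, runs = 2, M = 300,
                            noise_sd = 0.2, subject_effect = 0.3,
                            state_effect = 0.6, seed = seed + 1L)
cohort <- generate_cohort(basis, manifest)
write_cohort(cohort, out)

message(sprintf("wrote %d subject-run sessions (%d nodes x %d time points) to %s",
                length(cohort$sessions) * manifest$runs,
                nrow(basis$modes), manifest$M, out))
message(sprintf("planted spectrum (variance): %s",
                paste(signif(basis$spectrum^2, 3), collapse = " ")))
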