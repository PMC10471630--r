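#' Cohort design manifest
#'
#' Sampling design for a synthetic cohort: how many subjects, runs and time
#' points, the session noise level, and the scales of the subject-specific
#' basis perturbation and of the state-B flattening of mode 1.
#'
#' Defaults emulate a two-run resting-state fingerprinting design: 20
#' subjects scanned twice with 300 time points per run, i.i.d. sensor noise
#' of standard deviation 0.2 per node, and a subject signature of scale 0.3.
#'
#' @param n_subjects subjects in the cohort.
#' @param runs runs per subject (or per state for two-state designs).
#' @param M time points per run.
#' @param noise_sd standard deviation of i.i.d. additive noise.
#' @param subject_effect scale of the subject-specific basis perturbation.
#' @param state_effect scale (0..1) of the state-B mode-1 flattening.
#' @param seed master seed for the cohort.
#' @return a `cohort_manifest` list.
#' @export
cohort_manifest <- function(n_subjects = 20L, runs = 2L, M = 300L,
                            noise_sd = 0.2, subject_effect = 0.3,
                            state_effect = 0.6, seed = 1L) {
  out <- list(n_subjects = check_count(n_subjects, "n_subjects"),
              runs = check_count(runs, "runs"),
              M = check_count(M, "M"),
              noise_sd = check_scale(noise_sd, "noise_sd"),
              subject_effect = check_scale(subject_effect, "subject_effect"),
              state_effect = check_scale(state_effect, "state_effect"),
              seed = as.integer(seed))
  if (out$state_effect > 1)
    bm_input_error("state_effect must be in [0, 1], got %g", out$state_effect)
  structure(out, class = "cohort_manifest")
}

# Smoothed temporal loadings: white noise passed through a moving-average
# window (circular, ~5 samples), centred, then orthogonalised across the k
# loadings and scaled to unit sample variance (so they are exactly mutually
# orthogonal and zero-mean in-sample). The smoothing stands in for the
# band-pass filtering of BOLD time courses; only the induced low-dimensional
# covariance structure matters downstream.
make_loadings <- function(k, M, window = 5L) {
  l <- vapply(seq_len(k), function(i) {
    x <- stats::filter(stats::rnorm(M), rep(1 / window, window),
                       sides = 2, circular = TRUE)
    as.numeric(x)
  }, numeric(M))
  l <- scale(l, center = TRUE, scale = FALSE)
  l <- qr.Q(qr(l))[, seq_len(k), drop = FALSE] * sqrt(M - 1)
  t(l)  # k x M
}

#' Generate one synthetic session
#'
#' Draws an N x M activity matrix as the planted superposition
#' `sum_k spectrum_k * mode_k * t_k(t) + noise`, where the `t_k` are
#' band-limited, zero-mean, unit-variance temporal loadings, mutually
#' orthogonal in-sample.
#'
#' @param basis a `planted_basis`.
#' @param M number of time points (>= 3; a warning is issued if M <= N).
#' @param noise_sd standard deviation of the i.i.d. additive noise.
#' @param seed integer seed.
#' @return a raw (non-z-scored) `activity_matrix`.
#' @export
generate_session <- function(basis, M, noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(basis, "planted_basis"))
  M <- check_count(M, "M")
  if (M < 3) bm_input_error("M must be >= 3, got %d", M)
  n <- nrow(basis$modes)
  if (M <= n)
    warning(sprintf("M (%d) <= n_nodes (%d); decomposition will be rank-deficient in time",
                    M, n), call. = FALSE)
  noise_sd <- check_scale(noise_sd, "noise_sd")
  k <- ncol(basis$modes)
  vals <- with_seed(seed, {
    tl <- make_loadings(k, M)
    x <- basis$modes %*% (basis$spectrum * tl)
    if (noise_sd > 0) x <- x + matrix(stats::rnorm(n * M, sd = noise_sd), n, M)
    x
  })
  activity_matrix(vals, node_ids = basis$node_ids, zscored = FALSE)
}

# Perturb each mode by `scale` times a random unit tangent direction
# (orthogonal to the mode itself), then re-orthonormalise keeping column
# order and sign alignment with the original basis.
perturb_basis <- function(basis, scale) {
  if (scale == 0) return(basis)
  m <- basis$modes
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    g <- stats::rnorm(n)
    g <- g - m[, j] * sum(g * m[, j])
    g <- g / sqrt(sum(g^2))
    m[, j] <- m[, j] + scale * g
  }
  q <- qr.Q(qr(m))[, seq_len(ncol(m)), drop = FALSE]
  for (j in seq_len(ncol(q))) if (sum(q[, j] * basis$modes[, j]) < 0) q[, j] <- -q[, j]
  dimnames(q) <- dimnames(basis$modes)
  out <- basis
  out$modes <- q
  out
}

#' Generate a multi-subject, multi-run cohort
#'
#' Each subject receives a fixed subject-specific perturbation of the planted
#' basis (scale `manifest$subject_effect`), reused across all of its runs;
#' temporal loadings and noise are redrawn per run. The returned ground truth
#' records every subject basis and seed.
#'
#' @param basis a `planted_basis`.
#' @param manifest a `cohort_manifest`.
#' @return `mode_cohort`: `sessions[[subject]][[run]]` activity matrices,
#'   `subject_bases`, `basis`, `manifest`, and the per-subject/run `seeds`.
#' @export
generate_cohort <- function(basis, manifest) {
  stopifnot(inherits(basis, "planted_basis"), inherits(manifest, "cohort_manifest"))
  ns <- manifest$n_subjects
  seeds <- matrix(derive_seeds(manifest$seed, ns * (manifest$runs + 1L)),
                  ns, manifest$runs + 1L)
  subject_bases <- lapply(seq_len(ns), function(s)
    with_seed(seeds[s, 1L], perturb_basis(basis, manifest$subject_effect)))
  sessions <- lapply(seq_len(ns), function(s)
    lapply(seq_len(manifest$runs), function(r)
      generate_session(subject_bases[[s]], manifest$M, manifest$noise_sd,
                       seed = seeds[s, r + 1L])))
  names(sessions) <- sprintf("sub%03d", seq_len(ns))
  structure(list(sessions = sessions, subject_bases = subject_bases,
                 basis = basis, manifest = manifest, seeds = seeds),
            class = "mode_cohort")
}

# Replace mode 1 by its partial flattening toward its global mean level:
# (1 - effect) * mode1 + effect * mean(mode1), then re-orthonormalise the
# basis with the flattened pattern first. Flattening reduces the spatial
# inhomogeneity of the pattern — its within-system deviations and its
# between-system contrasts shrink alike — so the pattern's natural norm
# L < 1; that lost amplitude is folded into the state-B spectrum (strength
# L * spectrum_1) rather than renormalised away: mode-1 activity genuinely
# weakens in state B. Modes are reordered by the resulting strengths, so
# rank inversions between states can occur, as the mode-matching stage
# expects.
flatten_mode1 <- function(basis, effect) {
  if (effect == 0) return(basis)
  m1 <- basis$modes[, 1]
  new1 <- (1 - effect) * m1 + effect * mean(m1)
  l <- sqrt(sum(new1^2))
  if (l < 1e-8) bm_numerical_error("flattening annihilated mode 1")
  m <- basis$modes
  m[, 1] <- new1 / l
  q <- qr.Q(qr(m))[, seq_len(ncol(m)), drop = FALSE]
  for (j in seq_len(ncol(q))) if (sum(q[, j] * m[, j]) < 0) q[, j] <- -q[, j]
  spec <- basis$spectrum
  spec[1] <- spec[1] * l
  ord <- order(spec, decreasing = TRUE)
  out <- basis
  out$modes <- q[, ord, drop = FALSE]
  out$spectrum <- spec[ord]
  dimnames(out$modes) <- dimnames(basis$modes)
  out$flattened_rank <- match(1L, ord)
  out
}

#' Generate a paired two-state cohort
#'
#' State A uses the planted basis untouched; state B replaces mode 1 by its
#' partial flattening toward its global mean level (spatial contrast shrunk
#' by `manifest$state_effect`, the lost amplitude carried into the state-B
#' spectrum), re-orthonormalised. Each subject's signature perturbation is
#' shared between its two states, so the pairing is real.
#'
#' @param basis a `planted_basis`.
#' @param manifest a `cohort_manifest` (uses `state_effect`, `runs` per state).
#' @return `two_state_cohort`: `stateA[[subject]]` and `stateB[[subject]]`
#'   lists of run sessions, plus the per-state bases and seeds.
#' @export
generate_two_state <- function(basis, manifest) {
  stopifnot(inherits(basis, "planted_basis"), inherits(manifest, "cohort_manifest"))
  if (manifest$state_effect < 0 || manifest$state_effect > 1)
    bm_input_error("state_effect must be in [0, 1]")
  basisB <- flatten_mode1(basis, manifest$state_effect)
  ns <- manifest$n_subjects
  nr <- manifest$runs
  seeds <- matrix(derive_seeds(manifest$seed, ns * (2L * nr + 1L)), ns, 2L * nr + 1L)
  one_state <- function(state_basis, col_off) lapply(seq_len(ns), function(s) {
    sb <- with_seed(seeds[s, 1L], perturb_basis(state_basis, manifest$subject_effect))
    lapply(seq_len(nr), function(r)
      generate_session(sb, manifest$M, manifest$noise_sd,
                       seed = seeds[s, col_off + r]))
  })
  stateA <- one_state(basis, 1L)
  stateB <- one_state(basisB, 1L + nr)
  names(stateA) <- names(stateB) <- sprintf("sub%03d", seq_len(ns))
  structure(list(stateA = stateA, stateB = stateB,
                 basisA = basis, basisB = basisB,
                 manifest = manifest, seeds = seeds),
            class = "two_state_cohort")
}
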