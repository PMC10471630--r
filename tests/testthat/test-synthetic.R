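test_that("planted bases are orthonormal, deterministic and validated", {
  b <- generate_basis(50, 5, smoothness = 10, seed = 1)
  expect_lt(max(abs(crossprod(b$modes) - diag(5))), 1e-10)
  b2 <- generate_basis(50, 5, smoothness = 10, seed = 1)
  expect_identical(b$modes, b2$modes)
  expect_false(identical(b$modes, generate_basis(50, 5, smoothness = 10, seed = 2)$modes))

  expect_error(generate_basis(50, 50), class = "bm_rank_error")
  expect_error(generate_basis(50, 5, partition = rep("a", 50)), class = "bm_input_error")
  expect_error(generate_basis(50, 5, spectrum = c(1, 2, 3, 4, 5)), class = "bm_input_error")
  expect_error(generate_basis(50, 5, partition = rep(c("a", NA), 25)),
               class = "bm_input_error")
})

test_that("variance balancing homogenises the planted signal variance", {
  b <- generate_basis(80, 5, seed = 3)
  rn <- as.vector(b$modes^2 %*% b$spectrum^2)
  expect_lt(stats::sd(rn) / mean(rn), 0.02)
})

test_that("planted patterns are system-dependent", {
  b <- generate_basis(70, 4, seed = 4)
  for (k in 1:4) {
    fit <- stats::aov(b$modes[, k] ~ factor(b$partition))
    expect_lt(summary(fit)[[1]][["Pr(>F)"]][1], 0.01)
  }
})

test_that("sessions have the right shape, determinism and input checks", {
  b <- tiny_basis(40, 3, seed = 2)
  s <- generate_session(b, 120, noise_sd = 0.1, seed = 5)
  expect_equal(dim(s), c(40L, 120L))
  expect_identical(s$values, generate_session(b, 120, noise_sd = 0.1, seed = 5)$values)
  expect_error(generate_session(b, 2), class = "bm_input_error")
  expect_warning(generate_session(b, 30, seed = 1), "rank-deficient")
})

test_that("a single noiseless mode carries all the weight", {
  b <- generate_basis(50, 1, seed = 3)
  s <- generate_session(b, 200, noise_sd = 0, seed = 4)
  ms <- decompose_session(s)
  expect_gte(ms$weights[1], 0.99)
})

test_that("noiseless planted superpositions are recovered exactly", {
  b <- generate_basis(60, 4, seed = 2)
  s <- generate_session(b, 200, noise_sd = 0, seed = 5)
  ms <- decompose_session(s)
  expect_lt(abs(sum(ms$weights[1:4]) - 1), 1e-8)
  r <- abs(diag(stats::cor(b$modes, ms$modes[, 1:4])))
  expect_true(all(1 - r < 1e-6))
})

test_that("planted modes are recovered from noisy sessions", {
  b <- generate_basis(100, 5, seed = 3)
  s <- generate_session(b, 400, noise_sd = 0.2, seed = 7)
  ms <- decompose_session(s)
  mm <- match_modes(b$modes, ms, kA = 5, kB = 5)
  expect_setequal(mm$assignment$rank_b, 1:5)      # distinct modes matched
  expect_true(all(abs(mm$assignment$r) >= 0.95))
})

test_that("mean planted-mode recovery stays high over replicates", {
  rs <- vapply(1:10, function(seed) {
    b <- generate_basis(100, 5, seed = seed)
    s <- generate_session(b, 400, noise_sd = 0.2, seed = seed + 100)
    mm <- match_modes(b$modes, decompose_session(s), kA = 5, kB = 5)
    mean(abs(mm$assignment$r))
  }, numeric(1))
  expect_gte(mean(rs), 0.95)
})

test_that("cohorts share or perturb the planted basis as designed", {
  b <- tiny_basis(40, 3, seed = 6)
  man0 <- cohort_manifest(n_subjects = 4, runs = 2, M = 60, subject_effect = 0, seed = 9)
  co0 <- generate_cohort(b, man0)
  for (sb in co0$subject_bases) expect_identical(sb$modes, b$modes)

  man <- cohort_manifest(n_subjects = 4, runs = 2, M = 60, subject_effect = 0.3, seed = 9)
  co <- generate_cohort(b, man)
  expect_false(identical(co$subject_bases[[1]]$modes, b$modes))
  # subject bases stay orthonormal and are reused across runs
  expect_lt(max(abs(crossprod(co$subject_bases[[2]]$modes) - diag(3))), 1e-10)
  expect_length(co$sessions, 4)
  expect_length(co$sessions[[1]], 2)

  co2 <- generate_cohort(b, man)
  expect_identical(co$sessions[[3]][[2]]$values, co2$sessions[[3]][[2]]$values)
})

test_that("two-state designs flatten mode 1 only in state B", {
  b <- tiny_basis(42, 3, seed = 7)
  man <- cohort_manifest(n_subjects = 3, runs = 1, M = 50, state_effect = 0,
                         subject_effect = 0.2, seed = 4)
  ts0 <- generate_two_state(b, man)
  expect_identical(ts0$basisA$modes, ts0$basisB$modes)
  expect_length(ts0$stateA, 3)
  expect_length(ts0$stateA[[1]], 1)

  man6 <- cohort_manifest(n_subjects = 3, runs = 1, M = 50, state_effect = 0.6,
                          subject_effect = 0.2, seed = 4)
  ts <- generate_two_state(b, man6)
  expect_identical(ts$basisA$modes, b$modes)
  expect_false(identical(ts$basisB$modes, b$modes))
  expect_lt(max(abs(crossprod(ts$basisB$modes) - diag(3))), 1e-8)
  # flattened pattern lost amplitude: state-B spectrum sum is smaller
  expect_lt(sum(ts$basisB$spectrum^2), sum(b$spectrum^2))
  expect_error(cohort_manifest(state_effect = 1.5), class = "bm_input_error")
})
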