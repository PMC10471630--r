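test_that("FC equals Pearson correlation on z-scored sessions", {
  for (seed in 1:3) {
    s <- noise_session(12, 40, seed + 60)
    fc <- compute_fc(s)
    expect_lt(max(abs(fc$values - stats::cor(t(s$values)))), 1e-12)
    expect_lt(max(abs(fc$values - t(fc$values))), 1e-12)
    expect_lt(max(abs(diag(fc$values) - 1)), 1e-8)
  }
  z <- zscore_time_courses(activity_matrix(rbind(c(-1, 0, 1), c(1, 0, -1)) * 1,
                                           zscored = TRUE))
  expect_equal(compute_fc(z)$values[1, 2], -1)
  expect_error(compute_fc(activity_matrix(matrix(rnorm(20), 4))),
               class = "bm_contract_error")
  expect_error(compute_fc(activity_matrix(matrix(c(-1, 1, 1, -1), 2), zscored = FALSE)),
               class = "bm_contract_error")
})

test_that("reconstruction reproduces the hand-computed two-node case", {
  en <- build_ensemble(activity_matrix(rbind(c(-1, 0, 1), c(1, 0, -1)), zscored = TRUE))
  ms <- decompose_ensemble(en)
  expect_equal(reconstruct_fc(ms, 0)$values, matrix(0, 2, 2), ignore_attr = TRUE)
  r1 <- reconstruct_fc(ms, 1)
  expect_equal(r1$values[1, 2], -1)
  expect_equal(r1$values[1, 1], 1)
  expect_equal(mode_coactivation(ms, 1)$values,
               rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  expect_error(reconstruct_fc(ms, 3), class = "bm_index_error")
  expect_error(mode_coactivation(ms, 5), class = "bm_index_error")
})

test_that("full-rank reconstruction is exactly the original FC", {
  sessions <- lapply(1:3, function(i) noise_session(50, 100, i + 10))
  en <- build_ensemble(sessions)
  ms <- decompose_ensemble(en)
  fc0 <- compute_fc(en)
  fcr <- reconstruct_fc(ms, ms$rank)
  expect_lt(max(abs(fcr$values - fc0$values)), 1e-10)
  expect_gt(fc_similarity(fcr, fc0), 1 - 1e-10)
})

test_that("mode coactivations are rank one and sum to the reconstruction", {
  en <- build_ensemble(noise_session(10, 30, 7))
  ms <- decompose_ensemble(en)
  co3 <- mode_coactivation(ms, 3)
  expect_lt(svd(co3$values)$d[2], 1e-10)
  total <- Reduce(`+`, lapply(seq_len(ms$rank), function(k) mode_coactivation(ms, k)$values))
  expect_lt(max(abs(total - reconstruct_fc(ms, ms$rank)$values)), 1e-10)
})

test_that("reconstruction error decreases monotonically in k", {
  en <- build_ensemble(noise_session(15, 50, 8))
  ms <- decompose_ensemble(en)
  fc0 <- compute_fc(en)
  mse <- vapply(0:ms$rank, function(k)
    mean((reconstruct_fc(ms, k)$values - fc0$values)^2), numeric(1))
  expect_true(all(diff(mse) <= 1e-12))
})

test_that("one planted noiseless mode reconstructs FC at k = 1", {
  b <- generate_basis(30, 1, seed = 9)
  s <- generate_session(b, 90, noise_sd = 0, seed = 2)
  en <- build_ensemble(zscore_time_courses(s))
  ms <- decompose_ensemble(en)
  expect_lt(max(abs(reconstruct_fc(ms, 1)$values - compute_fc(en)$values)), 1e-8)
})

test_that("FC similarity uses the strict lower triangle and validates input", {
  fc <- compute_fc(noise_session(8, 30, 12))
  expect_equal(fc_similarity(fc, fc), 1.0)
  neg <- fc; neg$values <- -neg$values
  expect_equal(fc_similarity(fc, neg), -1.0)

  small <- compute_fc(noise_session(2, 30, 13))
  expect_error(fc_similarity(small, small), class = "bm_input_error")

  other <- compute_fc(noise_session(8, 30, 14))
  other$node_ids <- paste0("x", 1:8)
  expect_error(fc_similarity(fc, other), class = "bm_alignment_error")

  flat <- fc; flat$values[] <- 0.5
  expect_error(fc_similarity(fc, flat), class = "bm_undefined_similarity")
})
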