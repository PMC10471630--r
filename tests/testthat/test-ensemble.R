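test_that("z-scoring standardises rows with sample scaling", {
  x <- activity_matrix(rbind(a = c(1, 2, 3), b = c(2, 4, 6)))
  z <- zscore_time_courses(x)
  expect_equal(z$values["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_true(z$zscored)

  z4 <- zscore_time_courses(activity_matrix(matrix(c(2, 4, 6, 8), 1)))
  expect_equal(round(as.vector(z4$values), 4), c(-1.1619, -0.3873, 0.3873, 1.1619))

  expect_error(zscore_time_courses(activity_matrix(rbind(c(1, 2, 3), c(5, 5, 5)))),
               class = "bm_zero_variance_error")
})

test_that("ensembles concatenate, normalise by S and track provenance", {
  s1 <- noise_session(3, 5, 1)
  s2 <- noise_session(3, 5, 2)
  en <- build_ensemble(list(s1, s2))
  expect_equal(dim(en$values), c(3L, 10L))
  expect_equal(en$M, 10L)
  expect_equal(en$segment_index$session, rep(1:2, each = 5))
  expect_lt(abs(sum(en$values^2) - 1), 1e-10)
  raw <- cbind(s1$values, s2$values)
  expect_lt(abs(en$S^2 - sum(raw^2)), 1e-8)

  # the worked two-node example: S is the root-sum-square of all elements
  en2 <- build_ensemble(activity_matrix(rbind(c(-1, 0, 1), c(1, 0, -1)), zscored = TRUE))
  expect_equal(en2$S, 2)
  expect_equal(en2$values, rbind(c(-1, 0, 1), c(1, 0, -1)) / 2, ignore_attr = TRUE)

  s2b <- s2; s2b$node_ids <- rev(s2b$node_ids); rownames(s2b$values) <- s2b$node_ids
  expect_error(build_ensemble(list(s1, s2b)), class = "bm_alignment_error")
  expect_error(build_ensemble(list(s1, activity_matrix(matrix(rnorm(15), 3)))),
               class = "bm_contract_error")
})

test_that("decomposition matches the hand-computed rank-1 examples", {
  en <- build_ensemble(activity_matrix(rbind(c(-1, 0, 1), c(1, 0, -1)), zscored = TRUE))
  ms <- decompose_ensemble(en)
  expect_equal(ms$weights, c(1, 0), tolerance = 1e-12)
  expect_equal(as.vector(ms$modes[, 1]), c(1, -1) / sqrt(2), tolerance = 1e-12)

  en2 <- build_ensemble(activity_matrix(rbind(c(-1, 0, 1), c(-1, 0, 1)), zscored = TRUE))
  ms2 <- decompose_ensemble(en2)
  expect_equal(ms2$weights, c(1, 0), tolerance = 1e-12)
  expect_equal(as.vector(ms2$modes[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("weights sum to one and modes are orthogonal with norm^2 = weight", {
  for (seed in 1:3) {
    en <- build_ensemble(noise_session(8, 25, seed))
    ms <- decompose_ensemble(en)
    expect_lt(abs(sum(ms$weights) - 1), 1e-10)
    g <- crossprod(ms$modes)
    expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
    expect_lt(max(abs(colSums(ms$modes^2) - ms$weights[seq_len(ms$rank)])), 1e-10)
    expect_true(all(diff(ms$weights) <= 1e-12))
  }
})

test_that("decomposition agrees with the dense eigendecomposition of AA^T", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:10, 1); m <- sample((n + 1):30, 1)
    en <- as_ensemble(matrix(rnorm(n * m), n, m))
    ms <- decompose_ensemble(en)
    ev <- eigen(tcrossprod(en$values), symmetric = TRUE)
    expect_lt(max(abs(ms$weights - pmax(ev$values, 0))), 1e-10)
    for (i in seq_len(n)) {
      if (ms$weights[i] < 1e-12) next
      u_svd <- ms$modes[, i] / ms$singular_values[i]
      expect_lt(1 - abs(sum(u_svd * ev$vectors[, i])), 1e-8)
    }
  }
})

test_that("node relabeling permutes mode entries equivariantly", {
  s <- noise_session(7, 30, 4)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  sp <- activity_matrix(s$values[perm, ], node_ids = s$node_ids[perm], zscored = TRUE)
  m1 <- decompose_ensemble(build_ensemble(s))
  m2 <- decompose_ensemble(build_ensemble(sp))
  expect_equal(abs(m1$modes[perm, ]), abs(m2$modes), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("duplicating every time column leaves weights unchanged", {
  s <- noise_session(6, 20, 5)
  en1 <- build_ensemble(s)
  en2 <- as_ensemble(cbind(s$values, s$values), node_ids = s$node_ids)
  w1 <- decompose_ensemble(en1)$weights
  w2 <- decompose_ensemble(en2)$weights
  expect_lt(max(abs(w1 - w2)), 1e-10)
})

test_that("mode time courses are unit-norm right singular vectors", {
  en <- build_ensemble(noise_session(5, 40, 6))
  ms <- decompose_ensemble(en)
  for (i in c(1, ms$rank))
    expect_lt(abs(sqrt(sum(mode_timecourse(ms, i)^2)) - 1), 1e-10)
  expect_error(mode_timecourse(ms, ms$rank + 1), class = "bm_index_error")

  en2 <- build_ensemble(activity_matrix(rbind(c(-1, 0, 1), c(1, 0, -1)), zscored = TRUE))
  ms2 <- decompose_ensemble(en2)
  tc <- mode_timecourse(ms2, 1)
  expect_equal(abs(tc), abs(c(-1, 0, 1) / sqrt(2)), tolerance = 1e-12)
})
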