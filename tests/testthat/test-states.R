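test_that("system amplitudes average node values per system", {
  expect_equal(system_amplitudes(c(1, 3, -2, -4), c("A", "A", "B", "B")),
               c(A = 2, B = -3))
  expect_equal(system_amplitudes(rep(0, 4), c("A", "A", "B", "B")),
               c(A = 0, B = 0))
  expect_error(system_amplitudes(1:4, factor(c("A", "A", "B", "B"),
                                             levels = c("A", "B", "C"))),
               class = "bm_input_error")
  expect_error(system_amplitudes(1:3, c("A", "B")), class = "bm_alignment_error")
})

test_that("mode matching recovers identity, swaps and sign flips", {
  b <- tiny_basis(40, 4, seed = 51)
  id <- match_modes(b$modes, b$modes)
  expect_equal(id$assignment$rank_b, 1:4)
  expect_equal(id$assignment$r, rep(1, 4), tolerance = 1e-12)
  expect_equal(id$assignment$sign, rep(1L, 4))

  swapped <- b$modes[, c(1, 3, 2, 4)]
  sw <- match_modes(b$modes, swapped)
  expect_equal(sw$assignment$rank_b, c(1, 3, 2, 4))

  neg <- match_modes(b$modes, -b$modes)
  expect_equal(neg$assignment$rank_b, 1:4)
  expect_equal(neg$assignment$sign, rep(-1L, 4))
  expect_equal(abs(neg$assignment$r), rep(1, 4), tolerance = 1e-12)
})

test_that("the assignment is optimal and symmetric up to transposition", {
  for (seed in 1:5) {
    set.seed(seed + 70)
    ma <- matrix(rnorm(35 * 5), 35, 5)
    mb <- matrix(rnorm(35 * 5), 35, 5)
    mm <- match_modes(ma, mb)
    bf <- brute_force_assignment(stats::cor(ma, mb))
    expect_equal(mm$assignment$rank_b, bf$assignment)
    expect_equal(sum(abs(mm$assignment$r)), bf$total, tolerance = 1e-12)
    # >= identity assignment
    expect_gte(sum(abs(mm$assignment$r)),
               sum(abs(diag(stats::cor(ma, mb)))) - 1e-12)
    # transposition symmetry: reversing the arguments inverts the assignment
    mm_t <- match_modes(mb, ma)
    expect_equal(mm_t$assignment$rank_b[mm$assignment$rank_b],
                 mm$assignment$rank_a)
  }
})

test_that("group modes from crossproducts equal the SVD pipeline", {
  b <- tiny_basis(30, 3, seed = 61)
  sessions <- lapply(1:3, function(i) generate_session(b, 80, seed = i))
  stats_list <- lapply(sessions, basicmodes:::subject_stats)
  grp <- basicmodes:::group_modes(stats_list, 3)
  en <- build_ensemble(lapply(sessions, zscore_time_courses))
  ms <- decompose_ensemble(en)
  expect_lt(max(abs(grp$modes - ms$modes[, 1:3])), 1e-8)
  expect_lt(max(abs(grp$weights[1:5] - ms$weights[1:5])), 1e-10)
  expect_equal(grp$S, ms$S)
  expect_equal(grp$M, ms$M)
})

test_that("identical states produce no significant differences", {
  b <- tiny_basis(30, 3, seed = 71)
  sess <- lapply(1:5, function(i) list(generate_session(b, 60, seed = i + 700)))
  res <- amplitude_difference_test(sess, sess, mode_rank = 1, n_perm = 60, seed = 2)
  expect_equal(sum(res$per_node$significant), 0L)
  expect_true(all(res$per_node$p == 1))

  part <- b$partition
  resC <- coactivation_difference_test(sess, sess, mode_rank = 1, partition = part,
                                       n_perm = 60, seed = 2)
  expect_equal(sum(resC$per_pair$significant), 0L)
})

test_that("a planted state effect is detected with the expected signature", {
  b <- generate_basis(60, 4, seed = 81)
  man <- cohort_manifest(n_subjects = 12, runs = 1, M = 150, noise_sd = 0.2,
                         subject_effect = 0.2, state_effect = 0.6, seed = 81)
  ts <- generate_two_state(b, man)
  res <- amplitude_difference_test(ts$stateA, ts$stateB, mode_rank = 1,
                                   n_perm = 99, seed = 5)
  tab <- res$per_node
  expect_gt(sum(tab$significant), 0)
  # strongest changes reach the smallest attainable add-one p-value
  expect_equal(min(tab$p), 1 / 100)
  sig <- tab[tab$significant, ]
  ref <- res$reference_mode[match(sig$node, names(res$reference_mode))]
  expect_gt(mean(sign(sig$observed) != sign(ref)), 0.5)
  # changes concentrate where mode-1 amplitude was largest (and so most flattened)
  amp <- abs(res$reference_mode)
  expect_gt(mean(amp[tab$significant]), mean(amp[!tab$significant]))
})

test_that("coactivation differences cover all system pairs and move toward zero", {
  b <- generate_basis(70, 4, seed = 91)   # seven systems by default
  man <- cohort_manifest(n_subjects = 10, runs = 1, M = 150, noise_sd = 0.2,
                         subject_effect = 0.2, state_effect = 0.6, seed = 91)
  ts <- generate_two_state(b, man)
  res <- coactivation_difference_test(ts$stateA, ts$stateB, mode_rank = 1,
                                      partition = b$partition, n_perm = 99, seed = 5)
  expect_equal(nrow(res$per_pair), 28L)   # 21 between + 7 within
  # the most anti-correlated pair of the state-A coactivation moves toward zero
  zsA <- lapply(ts$stateA, function(x) zscore_time_courses(x[[1]]))
  msA <- decompose_ensemble(build_ensemble(zsA))
  coA <- basicmodes:::system_pair_means(mode_coactivation(msA, 1)$values,
                                        factor(b$partition))
  worst <- which.min(coA$value)
  expect_lt(coA$value[worst], 0)
  expect_gt(res$per_pair$observed[worst], 0)
})

test_that("state tests validate pairing", {
  b <- tiny_basis(20, 2, seed = 95)
  sa <- lapply(1:3, function(i) list(generate_session(b, 40, seed = i)))
  expect_error(amplitude_difference_test(sa, sa[1:2]), class = "bm_alignment_error")
})
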