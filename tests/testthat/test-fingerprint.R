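make_fc_lists <- function(n_sub = 6, n_nodes = 20, m = 60, seed = 1) {
  lapply(seq_len(n_sub), function(s) compute_fc(noise_session(n_nodes, m, seed + s)))
}

test_that("similarity tables align subjects and are direction-sensitive", {
  run1 <- make_fc_lists(seed = 100)
  s <- similarity_matrix(run1, run1)
  expect_equal(diag(s), rep(1, 6))
  run2 <- make_fc_lists(seed = 200)
  s12 <- similarity_matrix(run1, run2)
  expect_false(isSymmetric(s12))
  expect_error(similarity_matrix(run1, run2[1:3]), class = "bm_alignment_error")
})

test_that("identification accuracy counts argmax hits, ties incorrect", {
  s <- diag(4) + 0.1
  expect_equal(identification_accuracy(s), 1.0)
  sw <- s[, c(2, 1, 3, 4)]   # two subjects' columns swapped
  expect_equal(identification_accuracy(sw), (4 - 2) / 4)
  tied <- matrix(0.5, 3, 3)
  expect_warning(acc <- identification_accuracy(tied), "tied")
  expect_equal(acc, 0)
})

test_that("differential identifiability follows its definition", {
  s <- matrix(0.6, 5, 5); diag(s) <- 0.9
  di <- differential_identifiability(s)
  expect_equal(di$I_self, 0.9)
  expect_equal(di$I_others, 0.6)
  expect_equal(di$I_diff, 30)
  expect_equal(nrow(di$per_subject), 5)

  flat <- matrix(0.4, 4, 4)
  expect_equal(differential_identifiability(flat)$I_diff, 0)
  expect_error(differential_identifiability(matrix(1, 1, 1)), class = "bm_input_error")
})

test_that("accuracy and I_diff are invariant to a common subject permutation", {
  set.seed(42)
  s <- matrix(runif(49), 7, 7) + diag(7)
  p <- sample(7)
  expect_equal(identification_accuracy(s), identification_accuracy(s[p, p]))
  expect_equal(differential_identifiability(s)$I_diff,
               differential_identifiability(s[p, p])$I_diff)
})

test_that("subject signatures raise intra over inter similarity at every k", {
  b <- generate_basis(60, 4, seed = 31)
  co <- generate_cohort(b, cohort_manifest(n_subjects = 8, runs = 2, M = 150,
                                           noise_sd = 0.2, subject_effect = 0.3,
                                           seed = 31))
  msets <- basicmodes:::cohort_modesets(co, rank = 10)
  tab <- intra_inter_by_k(msets, k_grid = 1:5)
  expect_true(all(tab$mean_intra > tab$mean_inter))
  expect_true(all(diff(tab$accuracy) >= 0) || tab$accuracy[1] == max(tab$accuracy))
  expect_gte(tab$accuracy[5], tab$accuracy[1])
  expect_error(intra_inter_by_k(msets, k_grid = 99), class = "bm_index_error")

  # paired intra-vs-inter test across subjects is significant
  zs <- lapply(co$sessions, function(r) lapply(r, zscore_time_courses))
  s <- similarity_matrix(lapply(zs, function(r) compute_fc(r[[1]])),
                         lapply(zs, function(r) compute_fc(r[[2]])))
  di <- differential_identifiability(s)
  tt <- stats::t.test(di$per_subject$intra_similarity,
                      di$per_subject$mean_inter_similarity, paired = TRUE)
  expect_lt(tt$p.value, 0.05)
})

test_that("subject signatures increase I_diff relative to none", {
  idiff <- vapply(c(0, 0.3), function(se) {
    b <- generate_basis(50, 3, seed = 17)
    co <- generate_cohort(b, cohort_manifest(n_subjects = 8, runs = 2, M = 120,
                                             noise_sd = 0.2, subject_effect = se,
                                             seed = 17))
    zs <- lapply(co$sessions, function(r) lapply(r, zscore_time_courses))
    rep1 <- identifiability_report(lapply(zs, function(r) compute_fc(r[[1]])),
                                   lapply(zs, function(r) compute_fc(r[[2]])))
    rep1$I_diff
  }, numeric(1))
  expect_gt(idiff[2], idiff[1])
  expect_gt(idiff[2], 0)
})
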