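#' Cross-run similarity table
#'
#' Entry (i, j) is the FC similarity between subject i's run-1 matrix and
#' subject j's run-2 matrix. Rows therefore index run-1 queries, columns
#' run-2 candidates; the table is generally asymmetric.
#'
#' @param run1_fcs,run2_fcs equal-length, subject-aligned lists of
#'   `fc_matrix` objects.
#' @return n x n numeric matrix.
#' @export
similarity_matrix <- function(run1_fcs, run2_fcs) {
  n <- length(run1_fcs)
  if (n != length(run2_fcs) || n < 1L)
    bm_alignment_error("run1 and run2 must list the same subjects (%d vs %d)",
                       n, length(run2_fcs))
  nm1 <- names(run1_fcs); nm2 <- names(run2_fcs)
  if (!is.null(nm1) && !is.null(nm2) && !identical(nm1, nm2))
    bm_alignment_error("run1/run2 subject names differ")
  out <- matrix(NA_real_, n, n, dimnames = list(nm1, nm2))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- fc_similarity(run1_fcs[[i]], run2_fcs[[j]])
  out
}

#' Identification accuracy from a similarity table
#'
#' A subject is correctly identified when the most similar run-2 candidate of
#' its run-1 query is itself. Exact ties at the maximum are counted incorrect
#' (they indicate a degenerate configuration) and reported via a warning.
#'
#' @param similarity_table square numeric matrix (rows = queries).
#' @return accuracy in `[0, 1]`.
#' @export
identification_accuracy <- function(similarity_table) {
  s <- as.matrix(similarity_table)
  if (nrow(s) != ncol(s)) bm_input_error("similarity table must be square")
  hits <- vapply(seq_len(nrow(s)), function(i) {
    mx <- max(s[i, ])
    top <- which(s[i, ] == mx)
    length(top) == 1L && top == i
  }, logical(1))
  ties <- vapply(seq_len(nrow(s)), function(i) sum(s[i, ] == max(s[i, ])) > 1L, logical(1))
  if (any(ties))
    warning(sprintf("%d row(s) had tied maxima; counted incorrect", sum(ties)),
            call. = FALSE)
  mean(hits)
}

#' Differential identifiability
#'
#' `I_diff = (I_self - I_others) * 100`, where I_self is the mean
#' intra-subject (diagonal) similarity and I_others the mean inter-subject
#' (off-diagonal) similarity between the two runs.
#'
#' @param similarity_table square numeric matrix.
#' @return list with `I_self`, `I_others`, `I_diff`, and the `per_subject`
#'   table of (intra, mean inter) similarities.
#' @export
differential_identifiability <- function(similarity_table) {
  s <- as.matrix(similarity_table)
  n <- nrow(s)
  if (n != ncol(s)) bm_input_error("similarity table must be square")
  if (n < 2) bm_input_error("need at least 2 subjects, got %d", n)
  intra <- diag(s)
  inter <- vapply(seq_len(n), function(i) mean(s[i, -i]), numeric(1))
  i_self <- mean(intra)
  i_others <- mean(s[row(s) != col(s)])
  list(I_self = i_self, I_others = i_others,
       I_diff = (i_self - i_others) * 100,
       per_subject = data.frame(subject = seq_len(n),
                                intra_similarity = intra,
                                mean_inter_similarity = inter))
}

#' Identifiability report for a two-run cohort
#'
#' Builds the run1-vs-run2 similarity table from per-subject FC matrices and
#' summarises identification accuracy (both query directions and their mean)
#' and differential identifiability.
#'
#' @param run1_fcs,run2_fcs subject-aligned lists of `fc_matrix` objects.
#' @return list with the similarity table, `accuracy` (mean of directions),
#'   `accuracy_run1_to_run2`, `accuracy_run2_to_run1`, `I_self`, `I_others`,
#'   `I_diff`, `per_subject`.
#' @export
identifiability_report <- function(run1_fcs, run2_fcs) {
  s <- similarity_matrix(run1_fcs, run2_fcs)
  a12 <- identification_accuracy(s)
  a21 <- identification_accuracy(t(s))
  di <- differential_identifiability(s)
  c(list(similarity = s, accuracy = mean(c(a12, a21)),
         accuracy_run1_to_run2 = a12, accuracy_run2_to_run1 = a21), di)
}

# Per-subject-run mode sets from a two-run cohort: each subject-run session is
# z-scored and decomposed as its own single-session ensemble.
cohort_modesets <- function(cohort, rank = NULL) {
  stopifnot(inherits(cohort, "mode_cohort"))
  lapply(cohort$sessions, function(runs)
    lapply(runs, function(s)
      decompose_ensemble(build_ensemble(zscore_time_courses(s)), rank = rank)))
}

#' Identifiability as a function of the number of modes
#'
#' Reconstructs every subject-run FC from its first k basic modes, for each k
#' in the grid, and tabulates mean intra-subject similarity, mean
#' inter-subject similarity, identification accuracy and differential
#' identifiability.
#'
#' @param modesets per-subject lists of two per-run `eigenmode_set`s (as
#'   returned by the internal cohort decomposition; any list of lists with
#'   runs 1 and 2 works).
#' @param k_grid integer vector of mode counts (each >= 1).
#' @return data.frame with one row per k: `k`, `mean_intra`, `mean_inter`,
#'   `accuracy`, `I_diff`.
#' @export
intra_inter_by_k <- function(modesets, k_grid) {
  if (!length(modesets)) bm_input_error("empty cohort")
  k_grid <- vapply(k_grid, check_count, integer(1), name = "k")
  rows <- lapply(k_grid, function(k) {
    fcs <- lapply(seq_along(modesets), function(s) {
      ms <- modesets[[s]]
      for (r in 1:2) if (k > ms[[r]]$rank)
        bm_index_error("k = %d exceeds rank %d of subject %d run %d",
                       k, ms[[r]]$rank, s, r)
      lapply(ms[1:2], reconstruct_fc, k = k)
    })
    rep1 <- identifiability_report(lapply(fcs, `[[`, 1), lapply(fcs, `[[`, 2))
    data.frame(k = k, mean_intra = rep1$I_self, mean_inter = rep1$I_others,
               accuracy = rep1$accuracy, I_diff = rep1$I_diff)
  })
  do.call(rbind, rows)
}
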