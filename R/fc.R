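fc_matrix <- function(values, node_ids, kind) {
  dimnames(values) <- list(node_ids, node_ids)
  structure(list(values = values, node_ids = node_ids, kind = kind),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("fc_matrix (%s): %d x %d\n", x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Functional connectivity of a session
#'
#' On z-scored time courses, `FC_ij = (1/(M-1)) sum_t A_it A_jt`, which equals
#' Pearson correlation between the two nodes' time courses exactly. May also
#' be applied to an `ensemble_matrix`, in which case the normalisation by S is
#' undone first (FC of the concatenated time courses).
#'
#' @param session a z-scored `activity_matrix`, or an `ensemble_matrix`.
#' @return an `fc_matrix` of kind `"original"`.
#' @export
compute_fc <- function(session) {
  if (inherits(session, "ensemble_matrix")) {
    a <- session$values * session$S
    ids <- session$node_ids
  } else {
    x <- as_activity(session)
    if (!x$zscored)
      bm_contract_error("compute_fc needs z-scored input; call zscore_time_courses()")
    a <- x$values
    ids <- x$node_ids
  }
  if (ncol(a) < 3) bm_input_error("need at least 3 time points, got %d", ncol(a))
  fc_matrix(tcrossprod(a) / (ncol(a) - 1), ids, "original")
}

#' Reconstruct functional connectivity from the first k basic modes
#'
#' The FC between two nodes decomposes into the joint contribution of their
#' coactivation in each basic mode:
#' `FC_ij = (S^2/(M-1)) sum_{k'=1..k} E_ik' E_jk'`, where the factor S^2
#' corrects for the ensemble normalisation applied before the SVD. At
#' `k = rank` this reproduces the original FC of the ensemble exactly.
#'
#' @param modeset an `eigenmode_set`.
#' @param k number of modes to superpose (0..rank).
#' @return an `fc_matrix` of kind `"reconstructed(k)"`. The diagonal is
#'   reported as computed (a convergence diagnostic), not forced to one.
#' @export
reconstruct_fc <- function(modeset, k) {
  stopifnot(inherits(modeset, "eigenmode_set"))
  k <- check_count(k, "k", min = 0L)
  if (k > modeset$rank)
    bm_index_error("k = %d exceeds retained rank %d", k, modeset$rank)
  n <- length(modeset$node_ids)
  vals <- if (k == 0) matrix(0, n, n) else {
    e <- modeset$modes[, seq_len(k), drop = FALSE]
    modeset$S^2 / (modeset$M - 1) * tcrossprod(e)
  }
  fc_matrix(vals, modeset$node_ids, sprintf("reconstructed(%d)", k))
}

#' Coactivation pattern of a single basic mode
#'
#' The rank-1 matrix `(S^2/(M-1)) E_k E_k^T`: mode k's additive contribution
#' to the functional connectivity.
#'
#' @param modeset an `eigenmode_set`.
#' @param k mode rank (1..rank).
#' @return an `fc_matrix` of kind `"coactivation(k)"`.
#' @export
mode_coactivation <- function(modeset, k) {
  stopifnot(inherits(modeset, "eigenmode_set"))
  k <- check_count(k, "k")
  if (k > modeset$rank)
    bm_index_error("k = %d exceeds retained rank %d", k, modeset$rank)
  e <- modeset$modes[, k]
  fc_matrix(modeset$S^2 / (modeset$M - 1) * tcrossprod(e),
            modeset$node_ids, sprintf("coactivation(%d)", k))
}

#' Similarity between two FC matrices
#'
#' Pearson correlation across the strictly lower-triangular elements
#' (diagonal excluded: original FC diagonals are constant and carry no
#' information).
#'
#' @param a,b `fc_matrix` objects over the same node set.
#' @return correlation scalar in `[-1, 1]`.
#' @export
fc_similarity <- function(a, b) {
  stopifnot(inherits(a, "fc_matrix"), inherits(b, "fc_matrix"))
  if (!identical(a$node_ids, b$node_ids))
    bm_alignment_error("FC matrices cover different node sets")
  n <- length(a$node_ids)
  if (n < 3) bm_input_error("need at least 3 nodes for triangle similarity, got %d", n)
  lt <- lower.tri(a$values)
  x <- a$values[lt]; y <- b$values[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    bm_undefined_similarity("an FC lower triangle has zero variance")
  stats::cor(x, y)
}
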