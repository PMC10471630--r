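#' Standardise node time courses
#'
#' Row-wise z-scoring over time with sample (M-1) scaling, so that the
#' functional-connectivity identity `FC = A A^T / (M-1)` reproduces Pearson
#' correlation exactly.
#'
#' @param matrix an `activity_matrix` (or plain numeric matrix).
#' @return a z-scored `activity_matrix` with node order preserved.
#' @export
zscore_time_courses <- function(matrix) {
  x <- as_activity(matrix)
  if (x$zscored) return(x)
  v <- x$values
  m <- rowMeans(v)
  s <- sqrt(rowSums((v - m)^2) / (ncol(v) - 1))
  if (any(s == 0))
    bm_zero_variance_error("node %s has zero variance over time",
                           x$node_ids[which(s == 0)[1]])
  activity_matrix((v - m) / s, node_ids = x$node_ids, zscored = TRUE)
}

#' Build the normalised ensemble matrix
#'
#' Concatenates z-scored sessions column-wise into the N x M ensemble matrix
#' A, computes the root-sum-square of all its elements (the dataset-dependent
#' constant S), and stores A / S so that the sum of squared elements is one.
#' Each column of A is one microstate: the whole-system activity pattern at a
#' single time point.
#'
#' @param sessions list of z-scored `activity_matrix` objects sharing one
#'   node set and order. A single matrix is promoted to a list of one.
#' @return an `ensemble_matrix`: `values` (A / S), `S`, `M`, `node_ids`, and
#'   `segment_index` mapping each column to its (session, run) of origin.
#' @export
build_ensemble <- function(sessions) {
  if (inherits(sessions, "activity_matrix")) sessions <- list(sessions)
  if (!length(sessions)) bm_input_error("no sessions supplied")
  sessions <- lapply(sessions, as_activity)
  ids <- sessions[[1]]$node_ids
  for (i in seq_along(sessions)) {
    if (!identical(sessions[[i]]$node_ids, ids))
      bm_alignment_error("session %d node ids do not match session 1", i)
    if (!sessions[[i]]$zscored)
      bm_contract_error("session %d is not z-scored; call zscore_time_courses() first", i)
  }
  a <- do.call(cbind, lapply(sessions, function(s) s$values))
  ms <- vapply(sessions, function(s) ncol(s$values), integer(1))
  seg <- data.frame(session = rep(seq_along(sessions), ms),
                    column = seq_len(sum(ms)))
  as_ensemble(a, node_ids = ids, segment_index = seg)
}

#' Normalise an arbitrary matrix into an ensemble
#'
#' Lower-level entry point: divides a node-by-time matrix by the
#' root-sum-square of its elements without enforcing the z-scoring contract.
#' Useful for decomposing raw planted superpositions or externally prepared
#' matrices.
#'
#' @param a N x M numeric matrix.
#' @param node_ids node identifiers (default: row names).
#' @param segment_index optional column provenance table.
#' @return an `ensemble_matrix`.
#' @export
as_ensemble <- function(a, node_ids = rownames(a), segment_index = NULL) {
  a <- as.matrix(a)
  if (anyNA(a) || !all(is.finite(a)))
    bm_numerical_error("ensemble contains non-finite entries")
  if (is.null(node_ids)) node_ids <- default_node_ids(nrow(a))
  s <- sqrt(sum(a^2))
  if (s == 0) bm_input_error("ensemble is identically zero")
  vals <- a / s
  rownames(vals) <- node_ids
  if (is.null(segment_index))
    segment_index <- data.frame(session = 1L, column = seq_len(ncol(a)))
  structure(list(values = vals, S = s, M = ncol(a),
                 node_ids = as.character(node_ids),
                 segment_index = segment_index),
            class = "ensemble_matrix")
}

#' @export
print.ensemble_matrix <- function(x, ...) {
  cat(sprintf("ensemble_matrix: %d nodes x %d microstates, S = %.4g\n",
              nrow(x$values), x$M, x$S))
  invisible(x)
}

#' Decompose an ensemble into eigen-microstates
#'
#' Economy-size SVD of the normalised ensemble A/S = U Sigma V^T. Each basic
#' mode (eigen-microstate) is E_i = sigma_i u_i, the weighted sum of the
#' microstates; its weight w_i = sigma_i^2 is the fraction of total ensemble
#' variance it carries, and the weights sum to one by the normalisation.
#' A deterministic sign convention flips each mode so its largest-magnitude
#' element is positive (ties: lowest node index).
#'
#' @param ensemble an `ensemble_matrix`.
#' @param rank number of modes to retain; default `min(N, M)` (full).
#' @return an `eigenmode_set`: `modes` (N x rank matrix of E_i),
#'   `singular_values`, `weights`, `temporal_coeffs` (M x rank of v_ti),
#'   `S`, `M`, `rank`, `node_ids`.
#' @export
decompose_ensemble <- function(ensemble, rank = NULL) {
  stopifnot(inherits(ensemble, "ensemble_matrix"))
  a <- ensemble$values
  if (anyNA(a) || !all(is.finite(a)))
    bm_numerical_error("ensemble contains non-finite entries")
  full <- min(dim(a))
  if (is.null(rank)) rank <- full
  rank <- check_count(rank, "rank")
  if (rank > full) bm_index_error("rank %d exceeds min(N, M) = %d", rank, full)
  sv <- svd(a, nu = full, nv = full)
  u <- sv$u
  v <- sv$v
  # sign convention: largest-|element| entry of each mode made positive
  for (j in seq_len(full)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  d <- sv$d[seq_len(full)]
  modes <- u[, seq_len(rank), drop = FALSE] *
    rep(d[seq_len(rank)], each = nrow(u))
  dimnames(modes) <- list(ensemble$node_ids, sprintf("mode%d", seq_len(rank)))
  structure(list(modes = modes,
                 singular_values = d,
                 weights = d^2,
                 temporal_coeffs = v[, seq_len(rank), drop = FALSE],
                 S = ensemble$S, M = ensemble$M, rank = rank,
                 node_ids = ensemble$node_ids),
            class = "eigenmode_set")
}

#' @export
print.eigenmode_set <- function(x, ...) {
  cat(sprintf("eigenmode_set: %d nodes, rank %d, top weights: %s\n",
              length(x$node_ids), x$rank,
              paste(signif(utils::head(x$weights, 5), 3), collapse = " ")))
  invisible(x)
}

#' Temporal coefficient series of one mode
#'
#' Returns the length-M series v_ti quantifying the contribution of each
#' microstate (time point) to mode `i`; unit Euclidean norm.
#'
#' @param modeset an `eigenmode_set`.
#' @param i mode rank (1-based, <= retained rank).
#' @return numeric vector of length M.
#' @export
mode_timecourse <- function(modeset, i) {
  stopifnot(inherits(modeset, "eigenmode_set"))
  i <- check_count(i, "i")
  if (i > modeset$rank)
    bm_index_error("mode index %d exceeds retained rank %d", i, modeset$rank)
  modeset$temporal_coeffs[, i]
}
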