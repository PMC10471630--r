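#' Default mode strength spectrum
#'
#' Geometric decay of planted mode strengths (variance ratio 0.55 between
#' successive modes). Chosen so that, against the default session noise, the
#' planted modes dominate the node-level signal (roughly half the ensemble
#' variance for five modes on one hundred nodes), every planted weight clears
#' the 1/N selection threshold, and successive weights are spaced widely
#' enough that sampling noise does not swap or blend neighbouring modes.
#'
#' @param k_modes number of planted modes.
#' @return numeric vector of `k_modes` positive, strictly decreasing strengths.
#' @export
default_mode_spectrum <- function(k_modes) {
  k_modes <- check_count(k_modes, "k_modes")
  sqrt(2 * 0.55^(seq_len(k_modes) - 1))
}

#' Uniform random node coordinates
#'
#' Nodes placed uniformly in a cube; used as stand-in spatial locations for
#' the distance-kernel smoothing and variogram machinery.
#'
#' @param n_nodes number of nodes.
#' @param extent side length of the cube (arbitrary length units).
#' @param seed integer seed.
#' @return `n_nodes` x 3 matrix of coordinates.
#' @export
random_coords <- function(n_nodes, extent = 100, seed = 1L) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  with_seed(seed, matrix(stats::runif(n_nodes * 3, 0, extent), n_nodes, 3,
                         dimnames = list(default_node_ids(n_nodes), c("x", "y", "z"))))
}

#' Block partition of nodes into functional systems
#'
#' Assigns nodes to systems in contiguous, near-equal blocks. Defaults to the
#' seven canonical cortical systems used to aggregate node-level quantities.
#'
#' @param n_nodes number of nodes.
#' @param systems character vector of system names (>= 2).
#' @return character vector of length `n_nodes`, named by node id.
#' @export
block_partition <- function(n_nodes,
                            systems = c("default-mode", "frontoparietal",
                                        "limbic", "ventral-attention",
                                        "dorsal-attention", "somatomotor",
                                        "visual")) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  if (length(systems) < 2L)
    bm_input_error("a partition needs at least 2 systems, got %d", length(systems))
  lab <- systems[ceiling(seq_len(n_nodes) / n_nodes * length(systems))]
  names(lab) <- default_node_ids(n_nodes)
  lab
}

default_node_ids <- function(n) sprintf("n%04d", seq_len(n))

# Squared-exponential kernel on Euclidean coordinates; rows normalised to sum
# one so K %*% x is a weighted spatial average.
smoothing_kernel <- function(coords, length_scale) {
  d2 <- as.matrix(stats::dist(coords))^2
  k <- exp(-d2 / (2 * length_scale^2))
  sweep(k, 1, rowSums(k), "/")
}

# Orthonormalise the columns of x (QR), then flip each column so its
# largest-magnitude entry is positive (ties: lowest row index wins).
orthonormalize <- function(x) {
  q <- qr.Q(qr(x))[, seq_len(ncol(x)), drop = FALSE]
  fix_mode_signs(q)
}

fix_mode_signs <- function(x) {
  for (j in seq_len(ncol(x))) {
    i <- which.max(abs(x[, j]))  # which.max takes the first maximum: lowest index
    if (x[i, j] < 0) x[, j] <- -x[, j]
  }
  x
}

#' Generate a planted orthonormal mode basis
#'
#' Builds `k_modes` orthonormal spatial patterns over the nodes, each a mix of
#' a system-block component (one random level per functional system, shared by
#' its nodes) and a spatially smooth component (white noise averaged through a
#' squared-exponential distance kernel). The mix makes patterns
#' system-dependent yet spatially autocorrelated, mirroring empirical leading
#' basic modes.
#'
#' The patterns are additionally variance-balanced: alternating row rescaling
#' and re-orthonormalisation drive the spectrum-weighted row norms
#' `sum_k spectrum_k^2 m_nk^2` toward a common value, so the planted signal
#' variance is spatially homogeneous. Node-wise standardisation (the
#' pipeline's first step) then rescales all nodes alike instead of warping
#' the planted geometry, which keeps mode recovery well-posed.
#'
#' @param n_nodes number of nodes N.
#' @param k_modes number of planted modes K (< N).
#' @param partition node-to-system labels (length N; >= 2 distinct systems).
#' @param coords N x 3 node coordinates.
#' @param smoothness length scale of the spatial kernel, in coordinate units.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param spectrum K positive non-increasing mode strengths.
#' @param system_weight share (0..1) of the system-block component in the raw
#'   (pre-orthonormalisation) pattern mix.
#' @param balance_iters variance-balancing iterations (0 disables balancing).
#' @return `planted_basis`: list with orthonormal `modes` (N x K),
#'   `spectrum`, `partition`, `coords`, `node_ids`, `seed`.
#' @export
generate_basis <- function(n_nodes, k_modes, partition = block_partition(n_nodes),
                           coords = random_coords(n_nodes, seed = seed + 1L),
                           smoothness = 15, seed = 1L,
                           spectrum = default_mode_spectrum(k_modes),
                           system_weight = 0.6, balance_iters = 100L) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  k_modes <- check_count(k_modes, "k_modes")
  if (k_modes >= n_nodes)
    bm_rank_error("k_modes (%d) must be < n_nodes (%d)", k_modes, n_nodes)
  if (length(partition) != n_nodes)
    bm_input_error("partition labels %d nodes, expected %d", length(partition), n_nodes)
  if (length(unique(partition)) < 2L)
    bm_input_error("partition must contain at least 2 systems")
  if (anyNA(partition)) bm_input_error("partition contains missing system labels")
  coords <- as.matrix(coords)
  if (nrow(coords) != n_nodes || ncol(coords) != 3L)
    bm_input_error("coords must be an %d x 3 matrix", n_nodes)
  if (length(spectrum) != k_modes || any(spectrum <= 0) || is.unsorted(rev(spectrum)))
    bm_input_error("spectrum must be %d positive non-increasing strengths", k_modes)
  system_weight <- check_scale(system_weight, "system_weight")
  if (system_weight > 1) bm_input_error("system_weight must be in [0, 1]")

  node_ids <- if (!is.null(names(partition))) names(partition) else default_node_ids(n_nodes)
  sys <- factor(partition)
  kern <- smoothing_kernel(coords, smoothness)

  raw <- with_seed(seed, {
    vapply(seq_len(k_modes), function(k) {
      sys_vals <- stats::rnorm(nlevels(sys))
      sys_part <- sys_vals[as.integer(sys)]
      smooth_part <- as.vector(kern %*% stats::rnorm(n_nodes))
      system_weight * sys_part / stats::sd(sys_part) +
        (1 - system_weight) * smooth_part / stats::sd(smooth_part)
    }, numeric(n_nodes))
  })
  modes <- balance_rows(orthonormalize(raw), spectrum, balance_iters)
  dimnames(modes) <- list(node_ids, sprintf("mode%d", seq_len(k_modes)))
  names(partition) <- node_ids
  rownames(coords) <- node_ids

  out <- structure(list(modes = modes, spectrum = as.numeric(spectrum),
                        partition = partition, coords = coords,
                        node_ids = node_ids, seed = as.integer(seed)),
                   class = "planted_basis")
  validate_basis(out)
  out
}

# Alternate row rescaling toward constant spectrum-weighted row norms with
# re-orthonormalisation. Converges to (approximately) variance-balanced
# orthonormal patterns; the last step is always an orthonormalisation, so the
# orthonormality invariant holds exactly.
balance_rows <- function(q, spectrum, iters) {
  for (i in seq_len(iters)) {
    r <- sqrt(pmax(as.vector(q^2 %*% spectrum^2), 1e-12))
    q <- orthonormalize(q / r)
  }
  q
}

validate_basis <- function(basis) {
  g <- crossprod(basis$modes)
  if (max(abs(g - diag(ncol(g)))) > 1e-10)
    bm_numerical_error("planted modes are not orthonormal to 1e-10")
  if (any(basis$spectrum <= 0) || is.unsorted(rev(basis$spectrum)))
    bm_input_error("spectrum must be strictly positive and non-increasing")
  if (!identical(names(basis$partition), basis$node_ids) ||
      !identical(rownames(basis$coords), basis$node_ids))
    bm_alignment_error("partition/coords do not cover the basis node ids")
  invisible(basis)
}

#' @export
print.planted_basis <- function(x, ...) {
  cat(sprintf("planted_basis: %d nodes, %d modes, %d systems\n",
              nrow(x$modes), ncol(x$modes), length(unique(x$partition))))
  cat("spectrum:", signif(x$spectrum, 3), "\n")
  invisible(x)
}
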