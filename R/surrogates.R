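# Binned semivariogram of a node-level map over Euclidean node distances.
# Bins are fixed by the coordinate geometry (equal-width over the observed
# pair distances), so all maps on one node set share the binning.
variogram_bins <- function(coords, n_bins = 25L) {
  d <- as.matrix(stats::dist(coords))
  lt <- lower.tri(d)
  pd <- d[lt]
  breaks <- seq(0, max(pd), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(pd, breaks, rightmost.closed = TRUE), 1L), n_bins)
  ij <- which(lt, arr.ind = TRUE)
  list(i = ij[, 1], j = ij[, 2], bin = bin, n_bins = n_bins,
       counts = tabulate(bin, n_bins),
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       pair_dist = pd)
}

binned_variogram <- function(x, bins) {
  sq <- 0.5 * (x[bins$i] - x[bins$j])^2
  sums <- vapply(seq_len(bins$n_bins), function(b) sum(sq[bins$bin == b]), numeric(1))
  ifelse(bins$counts > 0, sums / bins$counts, NA_real_)
}

#' Spatial-autocorrelation-preserving surrogate maps
#'
#' Generates randomised copies of a node-level map that preserve its spatial
#' autocorrelation (binned variogram) while destroying its alignment with any
#' other map. Each surrogate starts from a random permutation of the map
#' values; the permutation is smoothed through squared-exponential distance
#' kernels over a log-spaced grid of length scales, and a weighted mixture of
#' these smoothed versions (plus the raw permutation) is fitted so that the
#' mixture's binned variogram matches the original map's, by count-weighted
#' relative least squares. With `rank_remap = TRUE` the surrogate's values
#' are finally replaced by the original values in rank order, preserving the
#' exact value multiset.
#'
#' @param map numeric node-level map.
#' @param coords node coordinates (N x 3).
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @param n_scales number of candidate smoothing length scales.
#' @param n_bins variogram bins.
#' @param rank_remap preserve the exact value multiset.
#' @return N x `n_surr` matrix of surrogate maps.
#' @export
generate_surrogates <- function(map, coords, n_surr, seed = 1L,
                                n_scales = 8L, n_bins = 25L,
                                rank_remap = FALSE) {
  map <- as.numeric(map)
  n <- length(map)
  coords <- as.matrix(coords)
  if (nrow(coords) != n) bm_alignment_error("map and coords cover different node counts")
  if (stats::sd(map) == 0) bm_undefined_similarity("map is constant")
  n_surr <- check_count(n_surr, "n_surr")
  n_scales <- check_count(n_scales, "n_scales", min = 2L)
  bins <- variogram_bins(coords, n_bins)
  gamma_obs <- binned_variogram(map, bins)
  usable <- bins$counts > 0 & gamma_obs > 0
  wts <- bins$counts[usable]
  go <- gamma_obs[usable]
  scales <- exp(seq(log(as.numeric(stats::quantile(bins$pair_dist, 0.005))),
                    log(as.numeric(stats::quantile(bins$pair_dist, 0.6))),
                    length.out = n_scales))
  kernels <- lapply(scales, function(s) smoothing_kernel(coords, s))
  nk <- n_scales + 1L
  mu <- mean(map)
  sorted_vals <- sort(map)
  ia <- rep(seq_len(nk), each = nk)
  ib <- rep(seq_len(nk), nk)

  one_surrogate <- function() {
    perm <- sample(map)
    s <- cbind(perm, vapply(kernels, function(k) as.vector(k %*% perm), numeric(n)))
    s <- sweep(s, 2, colMeans(s))
    d <- s[bins$i, , drop = FALSE] - s[bins$j, , drop = FALSE]
    # per-bin quadratic forms: gamma_bin(b) = b' Q_bin b, stacked as rows
    p <- d[, ia, drop = FALSE] * d[, ib, drop = FALSE]
    rs <- rowsum(p, bins$bin)
    qfull <- matrix(0, bins$n_bins, nk * nk)
    qfull[as.integer(rownames(rs)), ] <- rs
    qstack <- (0.5 * qfull / pmax(bins$counts, 1L))[usable, , drop = FALSE]
    obj <- function(b) {
      r <- drop(qstack %*% as.vector(tcrossprod(b))) / go - 1
      sum(wts * r^2)
    }
    grd <- function(b) {
      r <- drop(qstack %*% as.vector(tcrossprod(b))) / go - 1
      m <- matrix(crossprod(qstack, 2 * wts * r / go), nk, nk)
      2 * as.vector(m %*% b)
    }
    # start from the best single candidate (affine-rescaled)
    starts <- lapply(seq_len(nk), function(k) {
      gc_k <- qstack[, (k - 1L) * nk + k]
      a2 <- sum(wts * (gc_k / go)) / sum(wts * (gc_k / go)^2)
      b <- numeric(nk); b[k] <- sqrt(max(a2, 1e-12)); b
    })
    b0 <- starts[[which.min(vapply(starts, obj, numeric(1)))]]
    fit <- stats::optim(b0, obj, grd, method = "BFGS",
                        control = list(maxit = 100, reltol = 1e-7))
    best <- drop(s %*% fit$par) + mu
    if (rank_remap) best <- sorted_vals[rank(best, ties.method = "first")]
    best
  }
  out <- with_seed(seed, vapply(seq_len(n_surr), function(k) one_surrogate(),
                                numeric(n)))
  rownames(out) <- names(map)
  out
}

#' Map similarity with a spatial-autocorrelation-corrected permutation test
#'
#' Pearson correlation between a mode map and a target map across nodes, with
#' significance assessed against variogram-matched surrogates of the mode map
#' correlated with the fixed target: two-sided on |r|, add-one estimator.
#'
#' @param mode_map node-level mode pattern.
#' @param target_map node-level reference map (same nodes).
#' @param coords node coordinates.
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @param ... passed to [generate_surrogates()].
#' @return list with `r`, `p`, `n_surr`, and the surrogate null correlations.
#' @export
similarity_with_sa_surrogates <- function(mode_map, target_map, coords,
                                          n_surr = 500L, seed = 1L, ...) {
  mode_map <- as.numeric(mode_map); target_map <- as.numeric(target_map)
  if (length(mode_map) != length(target_map))
    bm_alignment_error("maps cover different node counts")
  if (stats::sd(mode_map) == 0 || stats::sd(target_map) == 0)
    bm_undefined_similarity("constant map supplied")
  r_obs <- stats::cor(mode_map, target_map)
  surr <- generate_surrogates(mode_map, coords, n_surr, seed = seed, ...)
  r_null <- as.vector(stats::cor(surr, target_map))
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + n_surr)
  list(r = r_obs, p = p, n_surr = as.integer(n_surr), null_r = r_null)
}
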