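#' Kneedle elbow detection on a scree curve
#'
#' Locates the elbow of a non-increasing weight curve (convex, decreasing
#' branch of the Kneedle algorithm, evaluated on the raw points). The curve is
#' min-max normalised, flipped to increasing-concave form, and the knee is the
#' first local maximum of the difference curve whose threshold (the maximum
#' minus `sensitivity` times the mean x-spacing) is crossed before the next
#' local maximum.
#'
#' @param weights non-increasing weight sequence.
#' @param n_top number of leading ranks to search (>= 3).
#' @param sensitivity Kneedle sensitivity S; larger is more conservative.
#' @return integer elbow rank, or `NA_integer_` when no elbow exists (flat or
#'   featureless curve). Modes strictly before the elbow pass the scree
#'   criterion.
#' @export
find_elbow <- function(weights, n_top = 30L, sensitivity = 1) {
  if (anyNA(weights)) bm_input_error("weights contain NA")
  n_top <- check_count(n_top, "n_top", min = 3L)
  if (is.unsorted(rev(weights), strictly = FALSE))
    bm_input_error("weights must be non-increasing")
  y <- weights[seq_len(min(n_top, length(weights)))]
  n <- length(y)
  if (n < 3L || max(y) == min(y)) return(NA_integer_)
  x_norm <- (seq_len(n) - 1) / (n - 1)
  y_norm <- (y - min(y)) / (max(y) - min(y))
  y_flip <- 1 - y_norm                       # convex decreasing -> concave increasing
  d <- y_flip - x_norm                       # difference curve
  # local maxima with clipped boundary comparison
  left  <- d >= d[pmax(seq_len(n) - 1L, 1L)]
  right <- d >= d[pmin(seq_len(n) + 1L, n)]
  maxima <- which(left & right & seq_len(n) > 1L & seq_len(n) < n)
  if (!length(maxima)) return(NA_integer_)
  thresh_drop <- sensitivity * mean(diff(x_norm))
  for (k in seq_along(maxima)) {
    j <- maxima[k]
    stop_at <- if (k < length(maxima)) maxima[k + 1L] - 1L else n
    if (j + 1L > stop_at) next
    if (any(d[(j + 1L):stop_at] < d[j] - thresh_drop)) return(as.integer(j))
  }
  NA_integer_
}

# Shuffle the node entries independently within every time column (one
# order() call over column-blocked random keys).
shuffle_columns <- function(a) {
  n <- nrow(a); m <- ncol(a)
  o <- order(rep.int(seq_len(m), rep.int(n, m)), stats::runif(n * m))
  matrix(a[o], n, m)
}

# Ranked weights (squared singular values) of a normalised matrix, via the
# smaller of the two Gram matrices; identical to decompose_ensemble()$weights.
matrix_weights <- function(a) {
  g <- if (nrow(a) <= ncol(a)) tcrossprod(a) else crossprod(a)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)
}

#' Permutation null distribution of mode weights
#'
#' For each permutation instance, the node labels are shuffled independently
#' within every time column of the ensemble — destroying spatial organisation
#' while preserving each microstate's value multiset — and the weight
#' pipeline is recomputed on the shuffled data: node time courses are
#' re-standardised within each concatenated segment, the result is
#' renormalised to unit total variance, and the ranked weight vector is
#' recorded. Recomputing the standardisation under the null keeps the
#' permuted instances exchangeable with the observed ensemble (whose rows
#' are exactly standardised); shuffling the standardised values alone gives
#' a markedly conservative test. `rezscore = FALSE` restores the plain
#' shuffle.
#'
#' @param ensemble an `ensemble_matrix`.
#' @param n_perm number of permutation instances (>= 1).
#' @param seed integer seed.
#' @param rezscore re-apply per-segment row standardisation to each shuffled
#'   instance (default) or shuffle the standardised values only.
#' @return `n_perm` x `min(N, M)` matrix of ranked null weights (one row per
#'   permutation instance; each row sums to one).
#' @export
permutation_null_weights <- function(ensemble, n_perm, seed = 1L,
                                     rezscore = TRUE) {
  stopifnot(inherits(ensemble, "ensemble_matrix"))
  n_perm <- check_count(n_perm, "n_perm")
  a <- ensemble$values
  seg <- split(seq_len(ncol(a)), ensemble$segment_index$session)
  one_null <- function() {
    ap <- shuffle_columns(a)
    if (rezscore) {
      for (cols in seg) {
        block <- ap[, cols, drop = FALSE]
        m <- rowMeans(block)
        s <- sqrt(rowSums((block - m)^2) / (length(cols) - 1))
        s[s == 0] <- 1
        ap[, cols] <- (block - m) / s
      }
      ap <- ap / sqrt(sum(ap^2))
    }
    matrix_weights(ap)
  }
  with_seed(seed, t(vapply(seq_len(n_perm), function(p) one_null(),
                           numeric(min(dim(a))))))
}

#' Permutation p-value for one mode weight
#'
#' Add-one estimator `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so the
#' p-value is never exactly zero; ties count against the observed weight.
#'
#' @param observed_weight observed weight at some rank.
#' @param null_weights null samples of the weight at the same rank.
#' @return p-value in (0, 1].
#' @export
mode_p_value <- function(observed_weight, null_weights) {
  if (!length(null_weights)) bm_input_error("empty null sample")
  (1 + sum(null_weights >= observed_weight)) / (1 + length(null_weights))
}

#' Select the leading basic modes
#'
#' Applies the three leading-mode criteria to a decomposition: (i) the mode
#' lies strictly before the Kneedle scree elbow; (ii) its weight exceeds the
#' mean weight over all N possible modes, 1/N; (iii) its weight is
#' significant against the rank-matched column-shuffle permutation null. The
#' leading modes are the longest prefix of the weight ordering passing all
#' three.
#'
#' @param modeset an `eigenmode_set` from [decompose_ensemble()].
#' @param ensemble the `ensemble_matrix` it was computed from.
#' @param alpha significance level for criterion (iii).
#' @param n_perm permutation instances for the null.
#' @param n_top ranks searched for the elbow (and reported).
#' @param seed integer seed for the permutation null.
#' @param sensitivity Kneedle sensitivity.
#' @return `leading_mode_selection`: per-mode criterion table, `elbow_rank`,
#'   `mean_threshold`, `n_leading`, and a supplementary `prefix_weight_p`
#'   (p-value of the summed leading-prefix weight against the same null; an
#'   interpretation beyond the three per-mode criteria).
#' @export
select_leading_modes <- function(modeset, ensemble, alpha = 0.05,
                                 n_perm = 1000L, n_top = 30L, seed = 1L,
                                 sensitivity = 1) {
  stopifnot(inherits(modeset, "eigenmode_set"), inherits(ensemble, "ensemble_matrix"))
  alpha <- check_scale(alpha, "alpha")
  if (alpha > 1) bm_input_error("alpha must be in (0, 1]")
  w <- modeset$weights
  n_nodes <- length(modeset$node_ids)
  n_top_eff <- min(check_count(n_top, "n_top", 3L), length(w))
  elbow <- find_elbow(w, n_top = n_top_eff, sensitivity = sensitivity)
  nulls <- permutation_null_weights(ensemble, n_perm, seed)
  ranks <- seq_len(n_top_eff)
  pvals <- vapply(ranks, function(r) mode_p_value(w[r], nulls[, r]), numeric(1))
  passes_elbow <- if (is.na(elbow)) rep(FALSE, n_top_eff) else ranks < elbow
  passes_threshold <- w[ranks] > 1 / n_nodes
  passes_all <- passes_elbow & passes_threshold & (pvals < alpha)
  is_leading <- cumprod(passes_all) > 0     # longest all-pass prefix
  n_leading <- sum(is_leading)
  per_mode <- data.frame(rank = ranks, weight = w[ranks],
                         passes_elbow = passes_elbow,
                         passes_threshold = passes_threshold,
                         p_value = pvals, is_leading = is_leading)
  prefix_weight_p <- if (n_leading >= 1) {
    null_prefix <- rowSums(nulls[, seq_len(n_leading), drop = FALSE])
    (1 + sum(null_prefix >= sum(w[seq_len(n_leading)]))) / (1 + nrow(nulls))
  } else NA_real_
  out <- structure(list(per_mode = per_mode, elbow_rank = elbow,
                        mean_threshold = 1 / n_nodes, n_leading = n_leading,
                        prefix_weight_p = prefix_weight_p, alpha = alpha,
                        n_perm = as.integer(n_perm), n_top = n_top_eff,
                        seed = as.integer(seed)),
                   class = "leading_mode_selection")
  stopifnot(identical(which(per_mode$is_leading), seq_len(n_leading)))
  out
}

#' @export
print.leading_mode_selection <- function(x, ...) {
  cat(sprintf("leading_mode_selection: %d leading mode(s); elbow at rank %s; 1/N = %.4g\n",
              x$n_leading, ifelse(is.na(x$elbow_rank), "none", x$elbow_rank),
              x$mean_threshold))
  print(utils::head(x$per_mode, max(x$n_leading + 2L, 6L)), row.names = FALSE)
  invisible(x)
}
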