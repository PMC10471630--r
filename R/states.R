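#' Mean fluctuation amplitude per functional system
#'
#' Averages a node-level mode pattern within each system of the partition.
#'
#' @param mode numeric node-level pattern (named by node id, or aligned with
#'   the partition order).
#' @param partition node-to-system labels (character or factor; a factor with
#'   an empty level is rejected).
#' @return named numeric vector of per-system means, in system order.
#' @export
system_amplitudes <- function(mode, partition) {
  if (is.factor(partition) && any(table(partition) == 0))
    bm_input_error("partition contains an empty system: %s",
                   paste(levels(partition)[table(partition) == 0], collapse = ", "))
  if (length(mode) != length(partition))
    bm_alignment_error("mode covers %d nodes but partition labels %d",
                       length(mode), length(partition))
  if (!is.null(names(mode)) && !is.null(names(partition))) {
    if (!setequal(names(mode), names(partition)))
      bm_alignment_error("mode and partition cover different node ids")
    mode <- mode[names(partition)]
  }
  sys <- factor(partition)
  vapply(split(as.numeric(mode), sys), mean, numeric(1))
}

extract_modes <- function(x) {
  if (inherits(x, "eigenmode_set")) x$modes
  else if (is.matrix(x)) x
  else bm_input_error("expected an eigenmode_set or a node x mode matrix")
}

#' Spatial correspondence between two mode sets
#'
#' Correlates every pair of mode patterns across nodes and finds the optimal
#' one-to-one assignment maximising the summed absolute correlation
#' (Hungarian method), recording the sign of each matched correlation so rank
#' inversions and sign flips between conditions are explicit.
#'
#' @param setA,setB `eigenmode_set`s (or node x mode matrices) over one node set.
#' @param kA,kB numbers of modes compared from each set.
#' @return `mode_correspondence`: signed `correlation` matrix (kA x kB),
#'   `assignment` table (rank_a, rank_b, r, sign), and any unmatched ranks.
#' @export
match_modes <- function(setA, setB, kA = NULL, kB = NULL) {
  ma <- extract_modes(setA); mb <- extract_modes(setB)
  if (nrow(ma) != nrow(mb))
    bm_alignment_error("mode sets cover different node counts (%d vs %d)",
                       nrow(ma), nrow(mb))
  if (!is.null(rownames(ma)) && !is.null(rownames(mb)) &&
      !identical(rownames(ma), rownames(mb)))
    bm_alignment_error("mode sets cover different node ids")
  if (is.null(kA)) kA <- ncol(ma)
  if (is.null(kB)) kB <- ncol(mb)
  kA <- check_count(kA, "kA"); kB <- check_count(kB, "kB")
  if (kA > ncol(ma) || kB > ncol(mb))
    bm_index_error("kA/kB exceed the available mode counts")
  r <- stats::cor(ma[, seq_len(kA), drop = FALSE], mb[, seq_len(kB), drop = FALSE])
  transposed <- kA > kB
  cost <- if (transposed) t(abs(r)) else abs(r)
  sol <- clue::solve_LSAP(cost, maximum = TRUE)
  if (transposed) {
    rank_b <- seq_len(kB); rank_a <- as.integer(sol)
  } else {
    rank_a <- seq_len(kA); rank_b <- as.integer(sol)
  }
  rr <- r[cbind(rank_a, rank_b)]
  assignment <- data.frame(rank_a = rank_a, rank_b = rank_b,
                           r = rr, sign = ifelse(rr >= 0, 1L, -1L))
  assignment <- assignment[order(assignment$rank_a), , drop = FALSE]
  structure(list(correlation = r, assignment = assignment,
                 unmatched_a = setdiff(seq_len(kA), assignment$rank_a),
                 unmatched_b = setdiff(seq_len(kB), assignment$rank_b)),
            class = "mode_correspondence")
}

#' @export
print.mode_correspondence <- function(x, ...) {
  cat("mode_correspondence:\n")
  print(x$assignment, row.names = FALSE)
  invisible(x)
}

# --- group-mode machinery -------------------------------------------------
# Per-subject sufficient statistics: summed session cross-products, summed
# squared elements and time points of the z-scored runs. Group decompositions
# then only need eigen(sum(C)/sum(ss)) — identical to the SVD path, but cheap
# enough to re-run inside permutation loops.

as_run_list <- function(x) {
  if (inherits(x, "activity_matrix") || is.matrix(x)) list(x) else x
}

subject_stats <- function(runs) {
  runs <- lapply(as_run_list(runs), function(r) zscore_time_courses(r))
  ids <- runs[[1]]$node_ids
  c_sum <- 0; ss <- 0; m <- 0L
  for (r in runs) {
    if (!identical(r$node_ids, ids)) bm_alignment_error("runs of one subject disagree on node ids")
    c_sum <- c_sum + tcrossprod(r$values)
    ss <- ss + sum(r$values^2)
    m <- m + ncol(r$values)
  }
  list(C = c_sum, ss = ss, M = m, node_ids = ids)
}

group_modes <- function(stats_list, n_modes) {
  ctot <- Reduce(`+`, lapply(stats_list, `[[`, "C"))
  ss <- sum(vapply(stats_list, `[[`, numeric(1), "ss"))
  m <- sum(vapply(stats_list, `[[`, integer(1), "M"))
  ev <- eigen(ctot / ss, symmetric = TRUE)
  w <- pmax(ev$values, 0)
  u <- fix_mode_signs(ev$vectors[, seq_len(n_modes), drop = FALSE])
  e <- u * rep(sqrt(w[seq_len(n_modes)]), each = nrow(u))
  rownames(e) <- stats_list[[1]]$node_ids
  list(modes = e, weights = w, S = sqrt(ss), M = m)
}

# Sign-aligned pattern of the group mode matched to `reference[, mode_rank]`.
aligned_mode <- function(reference, grp, mode_rank, n_match) {
  corr <- match_modes(reference, grp$modes, kA = n_match, kB = n_match)
  row <- corr$assignment[corr$assignment$rank_a == mode_rank, ]
  row$sign * grp$modes[, row$rank_b]
}

check_paired <- function(stateA, stateB) {
  if (length(stateA) != length(stateB) || !length(stateA))
    bm_alignment_error("states must pair the same subjects (%d vs %d)",
                       length(stateA), length(stateB))
  if (!is.null(names(stateA)) && !is.null(names(stateB)) &&
      !identical(names(stateA), names(stateB)))
    bm_alignment_error("state A and state B subject names differ")
}

# Shared permutation engine for the two state-difference tests. `stat_fun`
# maps a (groupA, groupB) pair of group-mode lists to a numeric statistic
# vector; the null flips each subject's state labels independently.
state_permutation_test <- function(stateA, stateB, mode_rank, n_perm, seed,
                                   fdr_level, n_match, stat_fun) {
  check_paired(stateA, stateB)
  mode_rank <- check_count(mode_rank, "mode_rank")
  n_perm <- check_count(n_perm, "n_perm")
  fdr_level <- check_scale(fdr_level, "fdr_level")
  sa <- lapply(stateA, subject_stats)
  sb <- lapply(stateB, subject_stats)
  ns <- length(sa)
  n_match <- max(n_match, mode_rank)
  reference <- group_modes(sa, n_match)$modes
  observe <- function(la, lb) {
    ga <- group_modes(la, n_match); gb <- group_modes(lb, n_match)
    stat_fun(aligned_mode(reference, ga, mode_rank, n_match), ga,
             aligned_mode(reference, gb, mode_rank, n_match), gb)
  }
  obs <- observe(sa, sb)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      flip <- stats::runif(ns) < 0.5
      la <- mapply(function(f, a, b) if (f) b else a, flip, sa, sb, SIMPLIFY = FALSE)
      lb <- mapply(function(f, a, b) if (f) a else b, flip, sa, sb, SIMPLIFY = FALSE)
      observe(la, lb)
    }, numeric(length(obs)))
  })
  nulls <- matrix(nulls, nrow = length(obs))
  p <- vapply(seq_along(obs), function(i)
    (1 + sum(abs(nulls[i, ]) >= abs(obs[i]))) / (1 + n_perm), numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  list(observed = obs, p = p, q = q, significant = q < fdr_level,
       reference = reference, node_ids = sa[[1]]$node_ids,
       n_perm = as.integer(n_perm), seed = as.integer(seed),
       mode_rank = as.integer(mode_rank), fdr_level = fdr_level)
}

#' Two-state test of regional mode amplitudes
#'
#' Tests, node by node, whether the amplitude of the group basic mode at
#' `mode_rank` differs between two paired states. The observed statistic is
#' the per-node difference (state B minus state A) of the group mode patterns
#' computed from the per-state concatenated ensembles, each matched and
#' sign-aligned to the fixed state-A reference mode. The null flips each
#' subject's state labels independently and recomputes everything;
#' Benjamini-Hochberg FDR is applied across nodes.
#'
#' @param stateA,stateB per-subject (paired, aligned) lists; each element is
#'   an `activity_matrix` or a list of run matrices.
#' @param mode_rank which basic mode to test (default 1).
#' @param n_perm permutation instances.
#' @param seed integer seed.
#' @param fdr_level FDR threshold for the significance flag.
#' @param n_match number of top modes used when re-matching inside the loop.
#' @return `state_difference_report`: per-node table (`node`, `observed`,
#'   `p`, `q`, `significant`) plus the reference mode pattern and metadata.
#' @export
amplitude_difference_test <- function(stateA, stateB, mode_rank = 1L,
                                      n_perm = 500L, seed = 1L,
                                      fdr_level = 0.05, n_match = 5L) {
  res <- state_permutation_test(stateA, stateB, mode_rank, n_perm, seed,
                                fdr_level, n_match,
                                function(ea, ga, eb, gb) eb - ea)
  tab <- data.frame(node = res$node_ids, observed = res$observed, p = res$p,
                    q = res$q, significant = res$significant)
  structure(list(per_node = tab, reference_mode = res$reference[, res$mode_rank],
                 mode_rank = res$mode_rank, n_perm = res$n_perm,
                 seed = res$seed, fdr_level = res$fdr_level),
            class = "state_difference_report")
}

#' @export
print.state_difference_report <- function(x, ...) {
  tab <- if (!is.null(x$per_node)) x$per_node else x$per_pair
  cat(sprintf("state_difference_report (mode %d, %d perms): %d/%d significant at FDR %.2g\n",
              x$mode_rank, x$n_perm, sum(tab$significant), nrow(tab), x$fdr_level))
  invisible(x)
}

# Mean coactivation per unordered system pair; within-system means exclude
# the diagonal (interregional values only).
system_pair_means <- function(mat, sys) {
  sys <- factor(sys)
  ls <- levels(sys)
  ns <- length(ls)
  bs <- rowsum(t(rowsum(mat, sys)), sys)       # block sums, systems x systems
  cnt <- as.numeric(table(sys))
  dsum <- vapply(split(diag(mat), sys), sum, numeric(1))
  denom <- tcrossprod(cnt)
  diag(denom) <- cnt * (cnt - 1)
  vals <- bs
  diag(vals) <- diag(bs) - dsum
  vals <- ifelse(denom > 0, vals / denom, NA_real_)
  idx <- which(upper.tri(vals, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(system_a = ls[idx[, 1]], system_b = ls[idx[, 2]],
             value = vals[idx])
}

#' Two-state test of system-level mode coactivation
#'
#' Tests, for every unordered functional-system pair (including within-system
#' entries), whether the mode's coactivation pattern
#' `(S^2/(M-1)) E E^T` differs between two paired states, using the same
#' subject-label-flip null and mode re-matching as
#' [amplitude_difference_test()]; FDR across the system-pair entries.
#'
#' @inheritParams amplitude_difference_test
#' @param partition node-to-system labels covering the nodes.
#' @return `state_difference_report` with a `per_pair` table
#'   (`system_a`, `system_b`, `observed`, `p`, `q`, `significant`).
#' @export
coactivation_difference_test <- function(stateA, stateB, mode_rank = 1L,
                                         partition, n_perm = 500L, seed = 1L,
                                         fdr_level = 0.05, n_match = 5L) {
  sys <- factor(partition)
  coact <- function(e, grp) {
    m <- grp$S^2 / (grp$M - 1) * tcrossprod(e)
    system_pair_means(m, sys)$value
  }
  first <- subject_stats(stateA[[1]])
  if (length(sys) != length(first$node_ids))
    bm_alignment_error("partition labels %d nodes but sessions have %d",
                       length(sys), length(first$node_ids))
  res <- state_permutation_test(stateA, stateB, mode_rank, n_perm, seed,
                                fdr_level, n_match,
                                function(ea, ga, eb, gb) coact(eb, gb) - coact(ea, ga))
  pairs <- system_pair_means(diag(length(sys)), sys)[, c("system_a", "system_b")]
  tab <- cbind(pairs, data.frame(observed = res$observed, p = res$p,
                                 q = res$q, significant = res$significant))
  structure(list(per_pair = tab, mode_rank = res$mode_rank,
                 n_perm = res$n_perm, seed = res$seed,
                 fdr_level = res$fdr_level),
            class = "state_difference_report")
}
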