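# Small fixtures shared across test files; everything is generated in code.

tiny_basis <- function(n = 50, k = 5, seed = 1) generate_basis(n, k, seed = seed)

# A session decomposed through the standard z-score -> ensemble -> SVD path.
decompose_session <- function(session, rank = NULL) {
  decompose_ensemble(build_ensemble(zscore_time_courses(session)), rank = rank)
}

# z-scored white-noise activity matrix
noise_session <- function(n, m, seed) {
  with_seed_local(seed, zscore_time_courses(activity_matrix(matrix(rnorm(n * m), n, m))))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Exhaustive assignment oracle: maximise sum |r| over all one-to-one
# assignments of rows to columns (small matrices only).
brute_force_assignment <- function(r) {
  n <- nrow(r)
  perms <- matrix(unlist(combinat_perms(seq_len(ncol(r)), n)), ncol = n, byrow = TRUE)
  best <- -Inf; best_p <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    s <- sum(abs(r[cbind(seq_len(n), p)]))
    if (s > best) { best <- s; best_p <- p }
  }
  list(assignment = best_p, total = best)
}

combinat_perms <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i], k - 1))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}
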