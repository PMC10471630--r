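#' @keywords internal
"_PACKAGE"

# Condition constructors. Every user-facing failure is a classed condition so
# callers (and tests) can branch on the class rather than the message text.
bm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "bm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

bm_input_error       <- function(msg, ...) bm_stop("bm_input_error", msg, ...)
bm_rank_error        <- function(msg, ...) bm_stop("bm_rank_error", msg, ...)
bm_parse_error       <- function(msg, ...) bm_stop("bm_parse_error", msg, ...)
bm_alignment_error   <- function(msg, ...) bm_stop("bm_alignment_error", msg, ...)
bm_contract_error    <- function(msg, ...) bm_stop("bm_contract_error", msg, ...)
bm_index_error       <- function(msg, ...) bm_stop("bm_index_error", msg, ...)
bm_config_error      <- function(msg, ...) bm_stop("bm_config_error", msg, ...)
bm_numerical_error   <- function(msg, ...) bm_stop("bm_numerical_error", msg, ...)
bm_zero_variance_error <- function(msg, ...) bm_stop("bm_zero_variance_error", msg, ...)
bm_undefined_similarity <- function(msg, ...) bm_stop("bm_undefined_similarity", msg, ...)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards, so every generator is a pure function of its inputs.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    bm_input_error("seed must be a single finite number, got %s", deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` child seeds from a parent seed, below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    bm_input_error("%s must be a single integer >= %d, got %s", name, min, deparse(x))
  as.integer(x)
}

check_scale <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    bm_input_error("%s must be a single number >= %g, got %s", name, min, deparse(x))
  as.numeric(x)
}
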