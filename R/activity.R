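#' Construct an activity matrix
#'
#' A node-by-time matrix of activity amplitudes for one subject-run, with node
#' identity preserved in the row names.
#'
#' @param values N x M numeric matrix (nodes x time points).
#' @param node_ids ordered node identifiers; defaults to existing row names.
#' @param zscored whether rows are already standardised over time.
#' @param ddof degrees-of-freedom convention used for row scaling (1 = sample).
#' @return an `activity_matrix` object.
#' @export
activity_matrix <- function(values, node_ids = rownames(values),
                            zscored = FALSE, ddof = 1L) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || !all(is.finite(values)))
    bm_input_error("activity values must be finite numerics with no missing entries")
  if (is.null(node_ids)) node_ids <- default_node_ids(nrow(values))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(values))
    bm_input_error("node_ids length (%d) != number of rows (%d)",
                   length(node_ids), nrow(values))
  if (anyDuplicated(node_ids))
    bm_parse_error("duplicate node id: %s", node_ids[duplicated(node_ids)][1])
  rownames(values) <- node_ids
  if (isTRUE(zscored)) {
    m <- rowMeans(values)
    s <- apply(values, 1, stats::sd)
    if (max(abs(m)) >= 1e-8 || max(abs(s - 1)) >= 1e-6)
      bm_contract_error("matrix flagged zscored but rows are not standardised")
  }
  structure(list(values = values, node_ids = node_ids,
                 zscored = isTRUE(zscored), ddof = as.integer(ddof)),
            class = "activity_matrix")
}

#' @export
dim.activity_matrix <- function(x) dim(x$values)

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d nodes x %d time points (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$zscored) "z-scored" else "raw"))
  invisible(x)
}

as_activity <- function(x) {
  if (inherits(x, "activity_matrix")) x
  else activity_matrix(x)
}
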