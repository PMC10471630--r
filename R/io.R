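#' Read a session matrix from TSV
#'
#' Expects a tab-separated file with a header line; the first column holds
#' node ids, the remaining columns numeric time points.
#'
#' @param path file path.
#' @return an `activity_matrix` (raw; z-score downstream).
#' @export
read_session <- function(path) {
  if (!file.exists(path)) bm_parse_error("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) bm_parse_error("%s: need a header and at least one node row", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  if (width < 2L) bm_parse_error("%s: header has no time columns", path)
  for (i in seq_along(cells)) if (length(cells[[i]]) != width)
    bm_parse_error("%s: ragged row at line %d (%d cells, expected %d)",
                   path, i, length(cells[[i]]), width)
  ids <- vapply(cells[-1], `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    bm_parse_error("%s: duplicate node id '%s'", path, ids[duplicated(ids)][1])
  vals <- matrix(NA_real_, length(ids), width - 1L)
  for (i in seq_along(ids)) {
    v <- suppressWarnings(as.numeric(cells[[i + 1L]][-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      bm_parse_error("%s: non-numeric cell at line %d, column %d: '%s'",
                     path, i + 1L, bad + 1L, cells[[i + 1L]][bad + 1L])
    }
    vals[i, ] <- v
  }
  activity_matrix(vals, node_ids = ids)
}

#' Write a session matrix to TSV
#'
#' Values are written with full `%.17g` precision so a write-read round trip
#' is bit-exact.
#'
#' @param session an `activity_matrix`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_session <- function(session, path) {
  x <- as_activity(session)
  header <- paste(c("node", sprintf("t%d", seq_len(ncol(x$values)))), collapse = "\t")
  rows <- vapply(seq_len(nrow(x$values)), function(i)
    paste(c(x$node_ids[i], sprintf("%.17g", x$values[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

write_tsv_matrix <- function(m, path, row_label = "node") {
  header <- paste(c(row_label, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], sprintf("%.10g", m[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One TSV per subject-run plus a JSON manifest recording the design, all
#' seeds, the ground-truth file paths, and a note that the generative
#' distributional choices are synthetic stand-ins, not an empirical model of
#' BOLD data.
#'
#' @param cohort a `mode_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mode_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (s in seq_along(cohort$sessions)) for (r in seq_along(cohort$sessions[[s]])) {
    p <- file.path(dir, sprintf("sub%03d_run%d.tsv", s, r))
    write_session(cohort$sessions[[s]][[r]], p)
    paths[[sprintf("sub%03d_run%d", s, r)]] <- basename(p)
  }
  modes_path <- file.path(dir, "planted_modes.tsv")
  write_tsv_matrix(cohort$basis$modes, modes_path)
  manifest <- list(
    design = unclass(cohort$manifest),
    n_nodes = nrow(cohort$basis$modes),
    k_modes = ncol(cohort$basis$modes),
    spectrum = cohort$basis$spectrum,
    basis_seed = cohort$basis$seed,
    subject_run_seeds = cohort$seeds,
    sessions = paths,
    ground_truth = list(planted_modes = basename(modes_path)),
    note = paste("Synthetic cohort: band-limited loadings, Gaussian noise and",
                 "planted orthonormal modes are stand-in distributional choices,",
                 "not an empirical model of BOLD data."))
  mp <- file.path(dir, "manifest.json")
  write_json_file(manifest, mp)
  invisible(mp)
}

#' Pipeline configuration
#'
#' Bundles the inputs and stage parameters of [run_pipeline()]. Either
#' simulate a cohort (default) or ingest session files laid out as a
#' subject x run matrix of TSV paths.
#'
#' @param out_dir output directory (NULL: keep results in memory only).
#' @param seed master seed; every stochastic stage derives its own seed from it.
#' @param n_nodes,k_modes,smoothness simulated basis geometry.
#' @param n_subjects,runs,M,noise_sd,subject_effect,state_effect cohort design.
#' @param session_paths optional character matrix (subjects x runs) of TSVs to
#'   ingest instead of simulating.
#' @param partition node-to-system labels (required for ingested data when
#'   `compare_states` is on; simulated cohorts carry their own).
#' @param coords node coordinates (for surrogate machinery; optional).
#' @param alpha,n_perm,n_top selection parameters.
#' @param k_grid mode counts for the FC-reconstruction and fingerprint sweeps.
#' @param fdr_level FDR level for state comparison.
#' @param compare_states also run the paired two-state comparison (simulated
#'   designs only unless state session paths are supplied).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L,
                            n_nodes = 100L, k_modes = 5L, smoothness = 15,
                            n_subjects = 20L, runs = 2L, M = 300L,
                            noise_sd = 0.2, subject_effect = 0.3,
                            state_effect = 0.6,
                            session_paths = NULL, partition = NULL,
                            coords = NULL,
                            alpha = 0.05, n_perm = 500L, n_top = 30L,
                            k_grid = c(1:8, 10L), fdr_level = 0.05,
                            compare_states = FALSE) {
  cfg <- as.list(environment())
  if (!is.null(session_paths)) {
    session_paths <- as.matrix(session_paths)
    if (isTRUE(compare_states) && is.null(partition))
      bm_config_error("compare_states requires a node partition for ingested sessions")
    cfg$session_paths <- session_paths
  }
  structure(cfg, class = "pipeline_config")
}

load_or_simulate <- function(cfg, seeds) {
  if (!is.null(cfg$session_paths)) {
    sessions <- apply(cfg$session_paths, 1, function(row) lapply(row, read_session),
                      simplify = FALSE)
    list(sessions = sessions, basis = NULL, cohort = NULL,
         partition = cfg$partition, coords = cfg$coords)
  } else {
    basis <- generate_basis(cfg$n_nodes, cfg$k_modes, smoothness = cfg$smoothness,
                            seed = seeds[1])
    manifest <- cohort_manifest(cfg$n_subjects, cfg$runs, cfg$M, cfg$noise_sd,
                                cfg$subject_effect, cfg$state_effect,
                                seed = seeds[2])
    cohort <- generate_cohort(basis, manifest)
    list(sessions = cohort$sessions, basis = basis, cohort = cohort,
         partition = basis$partition, coords = basis$coords)
  }
}

#' Run the full analysis pipeline
#'
#' Simulate or ingest sessions, z-score, build the group ensemble, decompose,
#' select the leading basic modes, sweep the FC reconstruction over the mode
#' grid, fingerprint the cohort across its two runs, and (optionally) run the
#' paired two-state comparison. Every artifact is written under
#' `config$out_dir` with a JSON provenance sidecar.
#'
#' @param config a `pipeline_config`.
#' @return result bundle (named list of stage outputs), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 6L)
  out <- list(config = config)
  dat <- load_or_simulate(config, seeds)
  msg <- function(fmt, ...) message(sprintf(paste0("[basicmodes] ", fmt), ...))

  zs <- lapply(dat$sessions, function(runs) lapply(runs, zscore_time_courses))
  ensemble <- build_ensemble(unlist(zs, recursive = FALSE))
  modeset <- decompose_ensemble(ensemble)
  msg("ensemble: %d nodes x %d time points, S = %.4g, rank %d",
      nrow(ensemble$values), ensemble$M, ensemble$S, modeset$rank)

  selection <- select_leading_modes(modeset, ensemble, alpha = config$alpha,
                                    n_perm = config$n_perm, n_top = config$n_top,
                                    seed = seeds[3])
  msg("selection: %d leading mode(s), elbow at rank %s",
      selection$n_leading, ifelse(is.na(selection$elbow_rank), "none",
                                  selection$elbow_rank))

  fc_orig <- compute_fc(ensemble)
  k_grid <- config$k_grid[config$k_grid <= modeset$rank]
  fc_sweep <- data.frame(k = k_grid, similarity = vapply(
    k_grid, function(k) fc_similarity(reconstruct_fc(modeset, k), fc_orig),
    numeric(1)))
  msg("FC reconstruction similarity at k = %d: %.4f",
      max(1, selection$n_leading), fc_sweep$similarity[
        match(max(1, selection$n_leading), fc_sweep$k)])

  fp <- NULL
  if (all(vapply(zs, length, integer(1)) >= 2L)) {
    fcs1 <- lapply(zs, function(r) compute_fc(r[[1]]))
    fcs2 <- lapply(zs, function(r) compute_fc(r[[2]]))
    fp <- identifiability_report(fcs1, fcs2)
    msg("fingerprint (original FC): accuracy %.3f, I_diff %.2f",
        fp$accuracy, fp$I_diff)
  }

  states <- NULL
  if (isTRUE(config$compare_states)) {
    if (is.null(dat$partition))
      bm_config_error("compare_states requires a node partition")
    if (is.null(dat$cohort))
      bm_config_error("compare_states currently requires a simulated design")
    ts <- generate_two_state(dat$basis,
                             cohort_manifest(config$n_subjects, 1L, config$M,
                                             config$noise_sd, config$subject_effect,
                                             config$state_effect, seed = seeds[4]))
    nodes <- amplitude_difference_test(ts$stateA, ts$stateB, mode_rank = 1L,
                                       n_perm = config$n_perm, seed = seeds[5],
                                       fdr_level = config$fdr_level)
    pairs <- coactivation_difference_test(ts$stateA, ts$stateB, mode_rank = 1L,
                                          partition = dat$partition,
                                          n_perm = config$n_perm, seed = seeds[6],
                                          fdr_level = config$fdr_level)
    states <- list(cohort = ts, nodes = nodes, pairs = pairs)
    msg("state comparison: %d significant node(s), %d significant system pair(s)",
        sum(nodes$per_node$significant), sum(pairs$per_pair$significant))
  }

  out <- c(out, list(data = dat, ensemble = ensemble, modeset = modeset,
                     selection = selection, fc_original = fc_orig,
                     fc_sweep = fc_sweep, fingerprint = fp, states = states,
                     seeds = seeds))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_tsv_matrix(modeset$modes[, seq_len(min(10L, modeset$rank)), drop = FALSE],
                     file.path(od, "modes.tsv"))
    write_json_file(list(S = modeset$S, M = modeset$M, rank = modeset$rank,
                         weights = modeset$weights), file.path(od, "weights.json"))
    utils::write.table(selection$per_mode, file.path(od, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_file(list(n_leading = selection$n_leading,
                         elbow_rank = selection$elbow_rank,
                         mean_threshold = selection$mean_threshold,
                         prefix_weight_p = selection$prefix_weight_p),
                    file.path(od, "selection.json"))
    utils::write.table(fc_sweep, file.path(od, "fc_similarity_by_k.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fp)) {
      write_tsv_matrix(fp$similarity, file.path(od, "fingerprint_similarity.tsv"),
                       row_label = "subject")
      write_json_file(fp[c("accuracy", "accuracy_run1_to_run2",
                           "accuracy_run2_to_run1", "I_self", "I_others", "I_diff")],
                      file.path(od, "fingerprint.json"))
    }
    if (!is.null(states)) {
      utils::write.table(states$nodes$per_node, file.path(od, "state_nodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(states$pairs$per_pair, file.path(od, "state_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_json_file(list(package_version = as.character(utils::packageVersion("basicmodes")),
                         master_seed = config$seed, stage_seeds = seeds,
                         parameters = config[setdiff(names(config),
                                                     c("session_paths", "partition",
                                                       "coords", "out_dir"))]),
                    file.path(od, "provenance.json"))
  }
  invisible(out)
}
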