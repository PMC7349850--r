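# End-to-end orchestration: simulate -> preprocess -> connectivity ->
# graph metrics -> group statistics -> ROC, with a single validated config
# and a reproducible artifact tree.

summarize_subject <- function(rec, montage, scopes, metrics, parietal,
                              preprocess = TRUE, keep_matrices = FALSE,
                              ...) {
  seg <- if (preprocess) preprocess_recording(rec, montage, ...)
         else segment_recording(rec)
  cms <- list()
  if ("global" %in% scopes) {
    cms$global <- subject_connectivity(seg, scope = "global")
    if ("local" %in% scopes) cms$local <- extract_local(cms$global, parietal)
  } else {
    cms$local <- subject_connectivity(seg, channels = parietal,
                                      scope = "local")
  }
  rows <- lapply(names(cms), function(scope) {
    ns <- summarize_network(cms[[scope]], metrics)
    data.frame(subject_id = rec$subject_id, group = rec$group, scope = scope,
               n_segments = cms[[scope]]$n_segments_used,
               cc = ns$cc_graph, strength = ns$strength_graph,
               bc = ns$bc_graph, stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows),
       matrices = if (keep_matrices) cms)
}


#' Per-subject network summaries for a whole cohort
#'
#' Preprocesses every recording and computes the graph-averaged metrics at
#' the requested scopes.  The local (parietal) scope is extracted from the
#' whole-head matrix when both scopes are requested, and computed directly
#' on the parietal channels when only the local scope is needed (cheaper).
#'
#' @param cohort an `eeg_cohort`.
#' @param montage montage; defaults to the cohort's own.
#' @param scopes subset of `c("global", "local")`.
#' @param metrics metrics to compute, see [summarize_network()].
#' @param parietal parietal electrode labels.
#' @param preprocess preprocess each recording first (default); set to
#'   `FALSE` to correlate the raw generated signal (used for closed-form
#'   oracle checks of the generator).
#' @param return_matrices also return the per-subject connectivity
#'   matrices.
#' @param ... passed to [preprocess_recording()].
#' @return a data frame with columns `subject_id`, `group`, `scope`,
#'   `n_segments`, `cc`, `strength`, `bc` (one row per subject x scope);
#'   with `return_matrices = TRUE`, a list `(summaries, matrices)`.
#' @export
cohort_summaries <- function(cohort, montage = attr(cohort, "montage"),
                             scopes = c("global", "local"),
                             metrics = c("clustering", "strength",
                                         "betweenness"),
                             parietal = parietal_electrodes(),
                             preprocess = TRUE,
                             return_matrices = FALSE, ...) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  per <- lapply(cohort, summarize_subject, montage = montage,
                scopes = scopes, metrics = metrics, parietal = parietal,
                preprocess = preprocess, keep_matrices = return_matrices,
                ...)
  summaries <- do.call(rbind, c(lapply(per, `[[`, "summary"),
                                make.row.names = FALSE))
  if (return_matrices) {
    list(summaries = summaries, matrices = lapply(per, `[[`, "matrices"))
  } else {
    summaries
  }
}

#' Per-subject network summaries for a streamed simulated cohort
#'
#' Like [cohort_summaries()], but generates each subject on the fly from a
#' [simulation_config()] and discards the raw signal once summarised, so
#' full-length cohorts never sit in memory at once.
#'
#' @param config a [simulation_config()].
#' @param scopes,metrics,parietal,... as in [cohort_summaries()].
#' @return the summary data frame.
#' @export
simulate_summaries <- function(config, scopes = c("global", "local"),
                               metrics = c("clustering", "strength",
                                           "betweenness"),
                               parietal = parietal_electrodes(), ...) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  montage <- default_montage(config)
  per <- cohort_map(config, function(rec) {
    summarize_subject(rec, montage, scopes, metrics, parietal, ...)$summary
  }, montage)
  do.call(rbind, c(unname(per), make.row.names = FALSE))
}

pipeline_defaults <- function() {
  list(
    out_dir = "eegconnectome-run",
    seed = 1L,
    scope = "both",
    alpha = 0.05,
    verbosity = 1L,
    write_matrices = FALSE,
    simulation = as.list(unclass(simulation_config())),
    preprocessing = list(low = 0.3, high = 75, order = 5,
                         window_samples = 500, threshold_uV = 100,
                         bad_channel_factor = 10),
    parietal_list = parietal_electrodes(deduplicated = FALSE)
  )
}

#' Validate and normalise a run configuration
#'
#' Accepts a YAML file path or a nested list; collects every problem
#' (unknown keys, Nyquist violations, invalid rates) instead of failing on
#' the first, materialises all defaults explicitly, de-duplicates the
#' parietal list (recording which labels were repeated), and pushes the
#' top-level seed into the simulation block.
#'
#' @param config YAML path or list of overrides; `NULL` gives the full
#'   default configuration.
#' @return list with `config` (normalised `run_config`), `errors`
#'   (character vector) and `warnings`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  defaults <- pipeline_defaults()
  errors <- character()
  warnings <- character()

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  for (blk in c("simulation", "preprocessing")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(bad)) {
        errors <- c(errors, paste0("unknown ", blk, " key(s): ",
                                   paste(bad, collapse = ", ")))
      }
    }
  }
  cfg <- modifyList(defaults, config[intersect(names(config), names(defaults))])
  cfg$seed <- as.integer(cfg$seed)
  cfg$simulation$seed <- cfg$seed
  cfg$simulation$group_sizes <- unlist(cfg$simulation$group_sizes)
  cfg$simulation$parietal_coupling <- unlist(cfg$simulation$parietal_coupling)

  pp <- cfg$preprocessing
  fs <- cfg$simulation$fs
  if (pp$high >= fs / 2) {
    errors <- c(errors, sprintf(
      "band high edge %g Hz violates the Nyquist limit %g Hz", pp$high, fs / 2))
  }
  if (pp$low <= 0 || pp$low >= pp$high) {
    errors <- c(errors, "band edges must satisfy 0 < low < high")
  }
  if (!cfg$scope %in% c("global", "local", "both")) {
    errors <- c(errors, "scope must be one of global/local/both")
  }
  sim <- try(validate_simulation_config(cfg$simulation), silent = TRUE)
  if (inherits(sim, "try-error")) {
    errors <- c(errors, conditionMessage(attr(sim, "condition")))
  } else {
    cfg$simulation <- sim
  }
  dup <- unique(cfg$parietal_list[duplicated(cfg$parietal_list)])
  if (length(dup)) {
    warnings <- c(warnings, paste0(
      "parietal list contains duplicate label(s) ",
      paste(dup, collapse = ", "), "; de-duplicated to ",
      length(unique(cfg$parietal_list)), " electrodes"))
    cfg$parietal_list <- unique(cfg$parietal_list)
  }
  class(cfg) <- "run_config"
  list(config = cfg, errors = errors, warnings = warnings)
}

#' Run the complete analysis pipeline
#'
#' Simulates (or loads) the cohort, preprocesses every subject, builds the
#' whole-head and parietal connectivity matrices, computes the three
#' network metrics, runs the group statistics and the ROC contrast battery,
#' generates the correlated synthetic neuropsychological battery and its
#' metric correlations, and writes every table plus a provenance log under
#' `config$out_dir`.  Deterministic: re-running with the same config yields
#' identical tables.
#'
#' @param config a `run_config`, raw override list, or YAML path (anything
#'   [validate_config()] accepts).
#' @param cohort optionally a pre-built `eeg_cohort` (e.g. from
#'   [read_cohort()]); when `NULL` the cohort is simulated from the config.
#' @return invisibly, a list with `summaries`, `comparisons`, `roc`,
#'   `scores`, `correlations`, `config`, `out_dir`.
#' @export
run_pipeline <- function(config = NULL, cohort = NULL) {
  if (!inherits(config, "run_config")) {
    v <- validate_config(config)
    if (length(v$errors)) {
      stop("invalid configuration:\n  - ",
           paste(v$errors, collapse = "\n  - "), call. = FALSE)
    }
    for (w in v$warnings) warning(w, call. = FALSE)
    config <- v$config
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("eegconnectome %s", packageVersion("eegconnectome")),
                 sprintf("seed: %d", config$seed),
                 sprintf("parietal electrodes used: %d",
                         length(config$parietal_list)))
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0) {
    log_lines <<- c(log_lines, sprintf("stage %-12s %7.2f s", name,
                                       tic() - t0))
  }
  scopes <- switch(config$scope, both = c("global", "local"), config$scope)
  pp <- config$preprocessing
  cohort_dir <- file.path(out_dir, "cohort")
  dir.create(cohort_dir, showWarnings = FALSE)
  mat_dir <- file.path(out_dir, "matrices")
  if (config$write_matrices) dir.create(mat_dir, showWarnings = FALSE)

  manifest_rows <- list()
  # one subject at a time: write the raw signal, preprocess, summarise,
  # optionally write matrices, then drop the signal (full-length 256-channel
  # recordings are far too large to hold as a whole cohort)
  process_one <- function(rec) {
    data.table::fwrite(data.table::as.data.table(t(rec$data)),
                       file.path(cohort_dir, paste0(rec$subject_id, ".tsv")),
                       sep = "\t")
    manifest_rows[[rec$subject_id]] <<- data.frame(
      subject_id = rec$subject_id, group = rec$group,
      file = paste0(rec$subject_id, ".tsv"),
      bad_channels = paste(rec$bad_channels, collapse = ";"),
      stringsAsFactors = FALSE)
    res <- tryCatch(
      summarize_subject(rec, montage, scopes, c("clustering", "strength",
                                                "betweenness"),
                        config$parietal_list,
                        keep_matrices = config$write_matrices,
                        low = pp$low, high = pp$high, order = pp$order,
                        window_samples = pp$window_samples,
                        threshold_uV = pp$threshold_uV,
                        bad_channel_factor = pp$bad_channel_factor),
      error = function(e) {
        stop("pipeline aborted at subject ", rec$subject_id, ": ",
             conditionMessage(e), call. = FALSE)
      })
    if (config$write_matrices) {
      for (scope in names(res$matrices)) {
        write_connectivity(res$matrices[[scope]],
                           file.path(mat_dir, paste0(rec$subject_id, "_",
                                                     scope, ".tsv")))
      }
    }
    res$summary
  }

  t0 <- tic()
  if (is.null(cohort)) {
    montage <- default_montage(config$simulation)
    per <- cohort_map(config$simulation, process_one, montage)
  } else {
    montage <- attr(cohort, "montage")
    per <- lapply(cohort, process_one)
  }
  summaries <- do.call(rbind, c(unname(per), make.row.names = FALSE))
  manifest <- do.call(rbind, c(unname(manifest_rows),
                               make.row.names = FALSE))
  data.table::fwrite(manifest, file.path(cohort_dir, "manifest.tsv"),
                     sep = "\t")
  write_montage(montage, file.path(cohort_dir, "montage.tsv"))
  sim_out <- unclass(config$simulation)
  sim_out$group_sizes <- as.list(sim_out$group_sizes)
  sim_out$parietal_coupling <- as.list(sim_out$parietal_coupling)
  yaml::write_yaml(sim_out, file.path(cohort_dir, "config.yaml"))
  for (id in unique(summaries$subject_id)) {
    n_seg <- summaries$n_segments[summaries$subject_id == id][1]
    log_lines <- c(log_lines, sprintf("retained segments %-8s %d", id, n_seg))
  }
  stage("networks", t0)

  t0 <- tic()
  comparisons <- compare_network_metrics(summaries, alpha = config$alpha)
  stage("stats", t0)

  t0 <- tic()
  roc <- roc_contrasts(summaries)
  stage("roc", t0)

  t0 <- tic()
  local_bc <- summaries[summaries$scope == scopes[length(scopes)], ]
  bc_metric <- setNames(
    if (all(is.na(local_bc$bc))) local_bc$cc else local_bc$bc,
    local_bc$subject_id)
  subject_shell <- lapply(seq_len(nrow(manifest)), function(i) {
    list(subject_id = manifest$subject_id[i], group = manifest$group[i])
  })
  scores <- generate_neuropsych(subject_shell, bc_metric)
  correlations <- metric_score_correlations(
    scores, summaries[summaries$scope == scopes[length(scopes)], ])
  stage("neuropsych", t0)

  fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f), sep = "\t")
  fw(summaries, "summaries.tsv")
  fw(comparison_table(comparisons), "anova.tsv")
  pw <- do.call(rbind, lapply(comparisons, function(cmp) {
    if (is.null(cmp$pairwise)) return(NULL)
    cbind(metric = cmp$metric, scope = cmp$scope, cmp$pairwise)
  }))
  if (!is.null(pw)) fw(pw, "pairwise.tsv")
  fw(roc, "roc.tsv")
  fw(scores, "neuropsych.tsv")
  fw(correlations, "correlations.tsv")
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(summaries = summaries, comparisons = comparisons, roc = roc,
                 scores = scores, correlations = correlations,
                 config = config, out_dir = out_dir))
}
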