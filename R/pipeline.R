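#' Configuration of a full analysis run
#'
#' @param sim optional \code{\link{simulation_config}} for synthetic runs.
#' @param input_dir optional directory holding an envelope dataset
#'   (\code{\link{write_envelope_dataset}} layout) and a
#'   \code{behaviour.csv} press log; ignored when \code{sim} is given.
#' @param preprocess a \code{\link{preprocess_config}}.
#' @param n_states number of HMM states.
#' @param n_restarts number of EM restarts.
#' @param seed global seed; stage seeds are derived by fixed offsets.
#' @param alpha significance level for the statistical batteries.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, input_dir = NULL,
                       preprocess = preprocess_config(), n_states = 8,
                       n_restarts = 10, seed = 1L, alpha = 0.05) {
  if (is.null(sim) && is.null(input_dir))
    .stopf("either sim or input_dir must be supplied")
  structure(list(sim = sim, input_dir = input_dir, preprocess = preprocess,
                 n_states = as.integer(n_states),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 alpha = alpha), class = "run_config")
}

#' Run the full transient-state analysis
#'
#' Orchestrates simulate (or load), standardize + whiten, HMM fit, Viterbi
#' decoding, temporal metrics, partial-correlation maps, per-session
#' transition matrices, behavioural indices and the statistical batteries,
#' writing every table plus the configuration to \code{out_dir}.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory results (model, path,
#'   metrics, maps, transition matrices, indices, stats tables) and the
#'   output paths.
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)

  if (!is.null(config$sim)) {
    cohort <- simulate_cohort(config$sim)
    dataset <- cohort$dataset
    behaviour <- cohort$behaviour
    log_line("stage simulate: %d subjects, %d states, seed %d",
             config$sim$n_subjects, config$sim$n_states, config$sim$seed)
  } else {
    dataset <- read_envelope_dataset(config$input_dir)
    bf <- file.path(config$input_dir, "behaviour.csv")
    if (!file.exists(bf)) .stopf("missing behaviour.csv in %s",
                                 config$input_dir)
    behaviour <- data.table::fread(bf, data.table = FALSE)
    cohort <- NULL
    log_line("stage load: %d recordings from %s",
             length(dataset$recordings), config$input_dir)
  }

  viol <- validate_inputs(dataset_manifest(dataset), behaviour)
  if (length(viol))
    .stopf("input validation failed:\n%s", paste("-", viol, collapse = "\n"))

  obs <- standardize_concatenate(dataset)
  ncomp <- min(config$preprocess$n_components, dataset$n_parcels)
  white <- pca_whiten(obs, ncomp)
  log_line("stage preprocess: %d parcels -> %d components, %d samples",
           dataset$n_parcels, ncomp, ncol(obs$data))
  log_line("  conventions: left-aligned windows, per-recording global-sd")
  log_line("  normalization, PCA sign fixed by largest loading")

  model <- fit_hmm(white, n_states = config$n_states,
                   n_restarts = config$n_restarts, seed = config$seed + 100L)
  log_line("stage fit: K = %d, %d restarts, selected %d, loglik %.2f",
           config$n_states, config$n_restarts, model$selected_restart,
           max(model$restart_scores))

  path <- viterbi_decode(model, white)
  metrics <- metrics_by_segment(path)
  courses <- binarize_states(path)
  maps <- partial_correlation_map(courses, obs$data)
  log_line("stage decode/metrics: dropped course %d in partial correlation",
           model$n_states)

  trans <- lapply(c(pre = "pre", post = "post"), function(ses) {
    seg <- path$segments[path$segments$session == ses, , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    keep <- unlist(Map(seq, seg$first, seg$last))
    sub <- state_path(path$labels[keep], path$n_states,
                      segments = .renumber_segments(seg), fs = path$fs)
    transition_matrix_empirical(sub)
  })

  indices <- behavioural_indices_table(behaviour)
  prepost <- prepost_contrast_battery(metrics, alpha = config$alpha)
  bb <- do.call(rbind, lapply(c("pre", "post"), function(ses)
    brain_behaviour_battery(metrics, indices, session = ses,
                            alpha = config$alpha)))
  log_line("stage stats: Wilcoxon zero-differences discarded, alpha %g",
           config$alpha)

  data.table::fwrite(metrics, file.path(out_dir, "state_metrics.csv"))
  data.table::fwrite(as.data.frame(maps), file.path(out_dir, "state_maps.csv"))
  data.table::fwrite(indices, file.path(out_dir, "behavioural_indices.csv"))
  data.table::fwrite(prepost, file.path(out_dir, "prepost_contrasts.csv"))
  data.table::fwrite(bb, file.path(out_dir, "brain_behaviour.csv"))
  path_tab <- data.frame(sample_index = seq_along(path$labels),
                         state = path$labels)
  data.table::fwrite(path_tab, file.path(out_dir, "state_path.csv"))
  for (ses in names(trans)) if (!is.null(trans[[ses]]))
    data.table::fwrite(as.data.frame(trans[[ses]]),
                       file.path(out_dir, sprintf("transitions_%s.csv", ses)))
  jsonlite::write_json(.serializable_config(config),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(model = model, path = path, metrics = metrics, maps = maps,
                 transitions = trans, indices = indices, prepost = prepost,
                 brain_behaviour = bb, cohort = cohort, out_dir = out_dir))
}

.renumber_segments <- function(seg) {
  n <- seg$last - seg$first + 1L
  last <- cumsum(n)
  data.frame(subject_id = seg$subject_id, session = seg$session,
             first = c(1L, head(last, -1) + 1L), last = last)
}

.serializable_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  if (!is.null(cfg$preprocess)) cfg$preprocess <- unclass(cfg$preprocess)
  cfg
}

#' Validate pipeline inputs
#'
#' Checks the envelope manifest and behavioural press log for schema
#' violations, sampling-rate inconsistencies and subject mismatches.
#' Violations are collected and returned together, not raised one at a
#' time.
#'
#' @param manifest manifest table (subject_id, session, n_samples, fs).
#' @param presses key-press log (subject_id, session, block, press_index,
#'   time_s, key).
#' @return character vector of violations; empty when the inputs are
#'   clean.
#' @export
validate_inputs <- function(manifest, presses) {
  v <- character(0)
  need_m <- c("subject_id", "session", "n_samples", "fs")
  miss <- setdiff(need_m, names(manifest))
  if (length(miss))
    v <- c(v, sprintf("manifest lacks column(s): %s",
                      paste(miss, collapse = ", ")))
  need_p <- c("subject_id", "session", "block", "time_s", "key")
  miss <- setdiff(need_p, names(presses))
  if (length(miss))
    v <- c(v, sprintf("press log lacks column(s): %s",
                      paste(miss, collapse = ", ")))
  if (!length(v)) {
    for (id in unique(manifest$subject_id)) {
      fs_i <- unique(manifest$fs[manifest$subject_id == id])
      if (length(fs_i) > 1)
        v <- c(v, sprintf(
          "subject %s has inconsistent fs across sessions (%s): %s", id,
          paste(manifest$session[manifest$subject_id == id], collapse = ", "),
          paste(fs_i, collapse = " vs ")))
    }
    bad_key <- !presses$key %in% 1:4
    if (any(bad_key))
      v <- c(v, sprintf("press log has %d key(s) outside 1..4",
                        sum(bad_key)))
    only_env <- setdiff(manifest$subject_id, presses$subject_id)
    if (length(only_env))
      v <- c(v, sprintf("subject(s) missing from behaviour: %s",
                        paste(only_env, collapse = ", ")))
    only_beh <- setdiff(presses$subject_id, manifest$subject_id)
    if (length(only_beh))
      v <- c(v, sprintf("subject(s) missing from envelopes: %s",
                        paste(only_beh, collapse = ", ")))
  }
  v
}
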