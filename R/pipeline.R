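#' Pipeline configuration
#'
#' Collects the analysis constants: the 200 ms / 20 ms moving window, the
#' per-window threshold 0.05, the response-period threshold 0.01, the
#' 300 ms response window, and the five-correct-trials-per-cell inclusion
#' rule.
#'
#' @param width,step Moving-window width and step, seconds.
#' @param anchor Window anchoring, `"center"` or `"left"`.
#' @param alpha_timeresolved Per-window significance level.
#' @param alpha_response Response-period significance level.
#' @param response_window Response-epoch width, seconds.
#' @param min_trials_per_cell Inclusion threshold (correct trials per
#'   tactics x cue-position cell per task).
#' @param inclusion_cells Cell definition for the inclusion rule (see
#'   [inclusion_filter()]).
#' @param time_resolved Compute per-neuron time-resolved profiles
#'   (default `TRUE`).
#' @param grid_start,grid_stop Span of the cue-aligned profile grid,
#'   aligned seconds.
#' @param seed Optional integer recorded in the manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(width = 0.2, step = 0.02,
                            anchor = c("center", "left"),
                            alpha_timeresolved = 0.05,
                            alpha_response = 0.01,
                            response_window = 0.3,
                            min_trials_per_cell = 5,
                            inclusion_cells = c("tactics_position",
                                                "tactics_position_color"),
                            time_resolved = TRUE,
                            grid_start = -0.5, grid_stop = 1.5,
                            seed = NULL) {
  anchor <- match.arg(anchor)
  inclusion_cells <- match.arg(inclusion_cells)
  ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!ok(width) || width <= 0) abort("width must be a positive number")
  if (!ok(step) || step <= 0) abort("step must be a positive number")
  if (!ok(alpha_timeresolved) || alpha_timeresolved <= 0 ||
      alpha_timeresolved >= 1) {
    abort("alpha_timeresolved must lie in (0, 1)")
  }
  if (!ok(alpha_response) || alpha_response <= 0 || alpha_response >= 1) {
    abort("alpha_response must lie in (0, 1)")
  }
  if (!ok(response_window) || response_window <= 0) {
    abort("response_window must be a positive number")
  }
  if (!ok(min_trials_per_cell) || min_trials_per_cell < 1) {
    abort("min_trials_per_cell must be >= 1")
  }
  if (!ok(grid_start) || !ok(grid_stop) || grid_start >= grid_stop) {
    abort("grid_start must be below grid_stop")
  }
  structure(
    list(width = width, step = step, anchor = anchor,
         alpha_timeresolved = alpha_timeresolved,
         alpha_response = alpha_response,
         response_window = response_window,
         min_trials_per_cell = min_trials_per_cell,
         inclusion_cells = inclusion_cells,
         time_resolved = time_resolved,
         grid_start = grid_start, grid_stop = grid_stop, seed = seed),
    class = "pipeline_config"
  )
}

write_stage <- function(df, out_dir, name) {
  if (!is.null(out_dir)) {
    readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")),
                     progress = FALSE)
  }
}

#' Run the full cross-task selectivity pipeline
#'
#' Orchestrates inclusion filtering, time-resolved CPD profiles (cue
#' aligned), the response-period ANOVA per task, cross-task
#' classification (with the pooled task-type test), and the population
#' summary. Neurons that fail at any stage are recorded in the manifest
#' and do not abort the run. Outputs are deterministic functions of the
#' session and configuration.
#'
#' @param session A `spike_session`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is written
#'   as a CSV file there (created if needed).
#' @return A list of tibbles: `manifest`, `inclusion`, `profiles` (when
#'   enabled), `response`, `records`, `summary`, `summary_by_area`, and
#'   `failures`.
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_session(session)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  t0 <- Sys.time()
  failures <- tibble(stage = character(), neuron_id = character(),
                     message = character())
  note_failure <- function(stage, neuron_id, e) {
    failures <<- dplyr::bind_rows(
      failures, tibble(stage = stage, neuron_id = neuron_id,
                       message = conditionMessage(e)))
  }

  inclusion <- include_neurons(session,
                               min_trials = config$min_trials_per_cell,
                               cells = config$inclusion_cells)
  keep <- inclusion$neuron_id[inclusion$included]
  if (length(keep) == 0) abort("no neurons pass the inclusion filter")

  profiles <- NULL
  if (isTRUE(config$time_resolved)) {
    grid <- time_grid("CUE_ONSET", start = config$grid_start,
                      stop = config$grid_stop, width = config$width,
                      step = config$step, anchor = config$anchor)
    profiles <- purrr::map_dfr(keep, function(nid) {
      purrr::map_dfr(task_levels, function(tk) {
        tryCatch({
          tr <- dplyr::filter(session$trials, .data$correct,
                              .data$task == tk)
          design <- encode_design(tr)
          wr <- align_and_bin(session, nid, grid,
                              trial_ids = tr$trial_id)
          as_tibble(time_resolved_profile(
            wr, design, alpha = config$alpha_timeresolved))
        }, error = function(e) {
          note_failure("time_resolved", nid, e)
          tibble()
        })
      })
    })
    write_stage(profiles, out_dir, "profiles")
  }

  response <- tryCatch(
    response_period_table(session, neuron_ids = keep,
                          alpha = config$alpha_response,
                          response_window = config$response_window,
                          check_inclusion = FALSE),
    error = function(e) {
      note_failure("response_period", NA_character_, e)
      tibble()
    }
  )
  task_type <- tryCatch(
    task_type_anova(session, neuron_ids = keep,
                    alpha = config$alpha_response,
                    response_window = config$response_window,
                    check_inclusion = FALSE),
    error = function(e) {
      note_failure("task_type", NA_character_, e)
      NULL
    }
  )
  records <- classify_records(
    response, alpha = config$alpha_response,
    task_type_sig = if (is.null(task_type)) NULL else
      dplyr::select(task_type, "neuron_id", "task_type_selective")
  )
  summary <- summarize_population(records)
  summary_by_area <- summarize_population(records, by_area = TRUE)

  write_stage(inclusion, out_dir, "inclusion")
  write_stage(response, out_dir, "response")
  write_stage(records, out_dir, "records")
  write_stage(summary, out_dir, "summary")
  write_stage(summary_by_area, out_dir, "summary_by_area")
  write_stage(failures, out_dir, "failures")

  manifest <- tibble(
    stage = c("inclusion", "time_resolved", "response_period",
              "classification", "summary"),
    n_out = c(sum(inclusion$included),
              if (is.null(profiles)) 0L else
                length(unique(profiles$neuron_id)),
              length(unique(response$neuron_id)),
              length(unique(records$neuron_id)),
              nrow(summary)),
    seed = if (is.null(config$seed)) NA_integer_ else config$seed,
    alpha_timeresolved = config$alpha_timeresolved,
    alpha_response = config$alpha_response,
    width = config$width, step = config$step,
    response_window = config$response_window,
    min_trials_per_cell = config$min_trials_per_cell,
    package_version = as.character(utils::packageVersion("neurocpd")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  write_stage(manifest, out_dir, "manifest")

  list(manifest = manifest, inclusion = inclusion, profiles = profiles,
       response = response, records = records, summary = summary,
       summary_by_area = summary_by_area, failures = failures)
}
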