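#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pf setNames rpois runif rgamma ks.test
#' @importFrom utils head
NULL

# Controlled vocabularies for the two-variant cued-reaching paradigm.
task_levels <- c("TACTICS_PRECUED", "LOCATION_PRECUED")
tactics_levels <- c("PRO", "ANTI")
color_levels <- c("CYAN", "GREEN", "BLUE", "RED")
side_levels <- c("LEFT", "RIGHT")
area_levels <- c("pmPFC", "preSMA", "SMA")

# Colour -> tactics mapping: cyan/green cue pro-reach, blue/red anti-reach.
color_to_tactics <- c(CYAN = "PRO", GREEN = "PRO", BLUE = "ANTI", RED = "ANTI")
# Shade contrast within a tactics level (first colour of each pair = +1).
color_to_shade <- c(CYAN = 1, GREEN = -1, BLUE = 1, RED = -1)

.time_tol <- 1e-9

trials_cols <- c(
  "trial_id", "task", "tactics", "cue_color", "cue_position", "action",
  "correct", "hold_onset", "cue_onset", "go_onset", "hold_release"
)
spikes_cols <- c("neuron_id", "trial_id", "spike_time")
neurons_cols <- c("neuron_id", "area")

#' Assemble a spike-session object
#'
#' A session bundles the three tables describing one recording day: a
#' `trials` table (one row per trial with factor labels and event
#' timestamps, in seconds from trial start), a `spikes` table (one row per
#' spike), and a `neurons` table (one row per unit with its cortical area:
#' pmPFC, preSMA or SMA). Synthetic sessions additionally carry a
#' `ground_truth` table of planted tuning gains.
#'
#' @param trials Tibble with columns `trial_id`, `task`, `tactics`,
#'   `cue_color`, `cue_position`, `action`, `correct`, `hold_onset`,
#'   `cue_onset`, `go_onset`, `hold_release`.
#' @param spikes Tibble with columns `neuron_id`, `trial_id`, `spike_time`.
#' @param neurons Tibble with columns `neuron_id`, `area`. If `NULL`, it is
#'   derived from the distinct neuron ids in `spikes` with area `pmPFC`.
#' @param ground_truth Optional tibble of planted per-neuron gains
#'   (synthetic sessions only).
#' @param validate Check all structural invariants (default `TRUE`).
#' @return An object of class `spike_session`.
#' @seealso [read_session()], [validate_session()], [simulate_session()]
#' @export
spike_session <- function(trials, spikes, neurons = NULL, ground_truth = NULL,
                          validate = TRUE) {
  trials <- as_tibble(trials)
  spikes <- as_tibble(spikes)
  if (is.null(neurons)) {
    neurons <- tibble(neuron_id = unique(spikes$neuron_id), area = "pmPFC")
  }
  neurons <- as_tibble(neurons)
  x <- structure(
    list(trials = trials, spikes = spikes, neurons = neurons,
         ground_truth = ground_truth),
    class = "spike_session"
  )
  if (validate) validate_session(x)
  x
}

#' @export
print.spike_session <- function(x, ...) {
  cat("<spike_session>\n")
  cat(sprintf("  trials : %d (%d correct) across %d task(s)\n",
              nrow(x$trials), sum(x$trials$correct),
              length(unique(x$trials$task))))
  cat(sprintf("  neurons: %d (%s)\n", nrow(x$neurons),
              paste(sprintf("%s: %d", names(table(x$neurons$area)),
                            table(x$neurons$area)), collapse = ", ")))
  cat(sprintf("  spikes : %d rows\n", nrow(x$spikes)))
  if (!is.null(x$ground_truth)) cat("  ground truth: present (synthetic)\n")
  invisible(x)
}

fail_rows <- function(what, rows, table) {
  rows <- head(which(rows), 10)
  abort(sprintf("%s (rows %s of the %s table)", what,
                paste(rows, collapse = ", "), table),
        class = "neurocpd_validation_error")
}

check_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing column(s): %s", table,
                  paste(missing, collapse = ", ")),
          class = "neurocpd_validation_error")
  }
}

#' Validate the structural invariants of a session
#'
#' Checks the trial timeline (hold >= 1 s, delay in 1-1.5 s, response within
#' 1 s on correct trials, strictly increasing events), the label-consistency
#' rules on correct trials (colour determines tactics; action equals cue
#' position under pro-reach and the opposite under anti-reach), spike-time
#' ordering and bounds, and referential integrity between the three tables.
#' Violations raise an error naming the offending row numbers.
#'
#' @param session A `spike_session`.
#' @return The session, invisibly, if all checks pass.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  sp <- session$spikes
  ne <- session$neurons
  check_cols(tr, trials_cols, "trials")
  check_cols(sp, spikes_cols, "spikes")
  check_cols(ne, neurons_cols, "neurons")

  if (anyDuplicated(tr$trial_id)) {
    fail_rows("duplicated trial_id", duplicated(tr$trial_id), "trials")
  }
  bad_enum <- function(x, levels) !(x %in% levels)
  if (any(b <- bad_enum(tr$task, task_levels)))
    fail_rows("unknown task value", b, "trials")
  if (any(b <- bad_enum(tr$tactics, tactics_levels)))
    fail_rows("unknown tactics value", b, "trials")
  if (any(b <- bad_enum(tr$cue_color, color_levels)))
    fail_rows("unknown cue_color value", b, "trials")
  if (any(b <- bad_enum(tr$cue_position, side_levels)))
    fail_rows("unknown cue_position value", b, "trials")
  if (any(b <- bad_enum(tr$action, side_levels)))
    fail_rows("unknown action value", b, "trials")
  if (!is.logical(tr$correct) || anyNA(tr$correct)) {
    abort("trials$correct must be logical with no missing values",
          class = "neurocpd_validation_error")
  }

  if (nrow(tr) > 0) {
    ev <- cbind(tr$hold_onset, tr$cue_onset, tr$go_onset, tr$hold_release)
    if (any(b <- apply(ev, 1, function(r) any(diff(r) <= 0))))
      fail_rows("event timestamps must be strictly increasing", b, "trials")
    if (any(b <- (tr$cue_onset - tr$hold_onset) < 1 - .time_tol))
      fail_rows("hold period shorter than 1 s", b, "trials")
    delay <- tr$go_onset - (tr$cue_onset + 0.5)
    if (any(b <- delay < 1 - .time_tol | delay > 1.5 + .time_tol))
      fail_rows("delay period outside [1, 1.5] s", b, "trials")
    rt <- tr$hold_release - tr$go_onset
    if (any(b <- tr$correct & (rt <= 0 | rt > 1 + .time_tol)))
      fail_rows("correct-trial response time outside (0, 1] s", b, "trials")

    # Label consistency is only enforceable on correct trials.
    ok <- tr$correct
    implied <- unname(color_to_tactics[tr$cue_color])
    if (any(b <- ok & implied != tr$tactics))
      fail_rows("cue colour inconsistent with tactics", b, "trials")
    pro_ok <- tr$tactics == "PRO" & tr$action == tr$cue_position
    anti_ok <- tr$tactics == "ANTI" & tr$action != tr$cue_position
    if (any(b <- ok & !(pro_ok | anti_ok)))
      fail_rows("action inconsistent with tactics and cue position", b,
                "trials")
  }

  if (nrow(sp) > 0) {
    if (any(b <- !(sp$trial_id %in% tr$trial_id)))
      fail_rows("spike references unknown trial_id", b, "spikes")
    if (any(b <- !(sp$neuron_id %in% ne$neuron_id)))
      fail_rows("spike references unknown neuron_id", b, "spikes")
    if (any(b <- sp$spike_time < -.time_tol))
      fail_rows("negative spike time", b, "spikes")
    trial_end <- tr$hold_release[match(sp$trial_id, tr$trial_id)]
    if (any(b <- sp$spike_time > trial_end + .time_tol))
      fail_rows("spike time beyond trial end", b, "spikes")
    ord <- order(sp$neuron_id, sp$trial_id)
    s <- sp[ord, ]
    same <- s$neuron_id[-1] == s$neuron_id[-nrow(s)] &
      s$trial_id[-1] == s$trial_id[-nrow(s)]
    if (nrow(s) > 1 && any(b <- same & diff(s$spike_time) < -.time_tol)) {
      fail_rows("spike times not non-decreasing within a train",
                c(FALSE, b)[order(ord)], "spikes")
    }
  }
  if (any(b <- !(ne$area %in% area_levels)))
    fail_rows("unknown area label", b, "neurons")
  invisible(session)
}

#' Read a session from delimited text files
#'
#' @param trials_path,spikes_path,neurons_path Paths to comma-separated
#'   files with headers `trial_id,task,tactics,cue_color,cue_position,
#'   action,correct,hold_onset,cue_onset,go_onset,hold_release`;
#'   `neuron_id,trial_id,spike_time`; and (optionally) `neuron_id,area`.
#' @return A validated `spike_session`.
#' @export
read_session <- function(trials_path, spikes_path, neurons_path = NULL) {
  trials <- readr::read_csv(
    trials_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      trial_id = readr::col_character(), task = readr::col_character(),
      tactics = readr::col_character(), cue_color = readr::col_character(),
      cue_position = readr::col_character(), action = readr::col_character(),
      correct = readr::col_logical(), .default = readr::col_double()
    )
  )
  spikes <- readr::read_csv(
    spikes_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      neuron_id = readr::col_character(),
      trial_id = readr::col_character(),
      spike_time = readr::col_double()
    )
  )
  neurons <- NULL
  if (!is.null(neurons_path)) {
    neurons <- readr::read_csv(
      neurons_path, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  spike_session(trials, spikes, neurons)
}

fmt_time <- function(x) sprintf("%.9f", x)

#' Write a session to delimited text files
#'
#' Times are written with nine decimal places so that the output is
#' byte-stable and a read/write round trip reproduces the session to within
#' 1e-9 s.
#'
#' @param session A valid `spike_session`.
#' @inheritParams read_session
#' @return The input session, invisibly.
#' @export
write_session <- function(session, trials_path, spikes_path,
                          neurons_path = NULL) {
  validate_session(session)
  tr <- dplyr::mutate(session$trials,
                      dplyr::across(c("hold_onset", "cue_onset", "go_onset",
                                      "hold_release"), fmt_time))
  sp <- dplyr::mutate(session$spikes,
                      spike_time = fmt_time(.data$spike_time))
  readr::write_csv(tr, trials_path, progress = FALSE)
  readr::write_csv(sp, spikes_path, progress = FALSE)
  if (!is.null(neurons_path)) {
    readr::write_csv(session$neurons, neurons_path, progress = FALSE)
  }
  invisible(session)
}

#' Trial counts per inclusion cell for one neuron
#'
#' Counts the neuron's correct trials (trials in which at least one spike of
#' the neuron was recorded) in every cell of the tactics x cue-position
#' design of each task. Used by [inclusion_filter()].
#'
#' @param session A `spike_session`.
#' @param neuron_id A neuron id present in the session.
#' @param cells Which factor combination defines an inclusion cell:
#'   `"tactics_position"` (4 cells per task, the default) or
#'   `"tactics_position_color"` (8 cells per task).
#' @return A tibble with one row per cell and the correct-trial count.
#' @export
inclusion_cells <- function(session, neuron_id,
                            cells = c("tactics_position",
                                      "tactics_position_color")) {
  cells <- match.arg(cells)
  if (!neuron_id %in% session$neurons$neuron_id) {
    abort(sprintf("unknown neuron_id '%s'", neuron_id))
  }
  recorded <- unique(session$spikes$trial_id[
    session$spikes$neuron_id == neuron_id])
  tr <- dplyr::filter(session$trials, .data$correct,
                      .data$trial_id %in% recorded)
  key <- if (cells == "tactics_position") {
    c("task", "tactics", "cue_position")
  } else {
    c("task", "tactics", "cue_position", "cue_color")
  }
  grid <- tidyr::expand_grid(
    task = task_levels, tactics = tactics_levels, cue_position = side_levels
  )
  if (cells == "tactics_position_color") {
    grid <- tidyr::expand_grid(grid, cue_color = color_levels)
    grid <- dplyr::filter(
      grid, color_to_tactics[.data$cue_color] == .data$tactics)
  }
  counts <- dplyr::count(tr, dplyr::across(dplyr::all_of(key)),
                         name = "n_correct")
  dplyr::mutate(dplyr::left_join(grid, counts, by = key),
                n_correct = dplyr::coalesce(.data$n_correct, 0L))
}

#' Neuron inclusion rule
#'
#' A neuron is analysed only if every cell of the tactics x cue-position
#' design of each task holds at least `min_trials` correct trials in which
#' the neuron was recorded (default 5, i.e. 8 cells across the two tasks).
#'
#' @inheritParams inclusion_cells
#' @param min_trials Minimum correct trials required per cell (default 5).
#' @return `TRUE` if the neuron passes, otherwise `FALSE`.
#' @export
inclusion_filter <- function(session, neuron_id, min_trials = 5,
                             cells = c("tactics_position",
                                       "tactics_position_color")) {
  counts <- inclusion_cells(session, neuron_id, cells)
  all(counts$n_correct >= min_trials)
}

#' Apply the inclusion rule to every neuron in a session
#'
#' @inheritParams inclusion_filter
#' @return A tibble `neuron_id, area, included`.
#' @export
include_neurons <- function(session, min_trials = 5,
                            cells = c("tactics_position",
                                      "tactics_position_color")) {
  cells <- match.arg(cells)
  dplyr::mutate(
    session$neurons,
    included = purrr::map_lgl(
      .data$neuron_id,
      ~ inclusion_filter(session, .x, min_trials = min_trials, cells = cells))
  )
}
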