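alignment_events <- c(CUE_ONSET = "cue_onset", GO_ONSET = "go_onset",
                      HOLD_RELEASE = "hold_release")

#' Sliding-window time grid
#'
#' Defines the moving-window analysis grid: windows of `width` seconds
#' (default 0.2) advanced in steps of `step` seconds (default 0.02), with
#' centers `start + k * step` for `k = 0, 1, ...` while the center does not
#' exceed `stop`. Times are relative to the chosen alignment event. With
#' the default `anchor = "center"` each grid time is the window center;
#' with `anchor = "left"` it is the left edge.
#'
#' @param alignment_event One of `"CUE_ONSET"`, `"GO_ONSET"`,
#'   `"HOLD_RELEASE"`.
#' @param start,stop Grid span in aligned seconds (`start < stop`).
#' @param width,step Window width and step, seconds.
#' @param anchor `"center"` or `"left"` window anchoring.
#' @return A `time_grid` object with derived `centers`.
#' @export
time_grid <- function(alignment_event = c("CUE_ONSET", "GO_ONSET",
                                          "HOLD_RELEASE"),
                      start = -0.5, stop = 0.5, width = 0.2, step = 0.02,
                      anchor = c("center", "left")) {
  alignment_event <- match.arg(alignment_event)
  anchor <- match.arg(anchor)
  stopifnot(width > 0, step > 0, start <= stop)
  k <- 0:floor((stop - start) / step + .time_tol)
  structure(
    list(alignment_event = alignment_event, start = start, stop = stop,
         width = width, step = step, anchor = anchor,
         centers = start + k * step),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> aligned to %s: %d windows (width %g s, step %g s) from %g to %g s\n",
              x$alignment_event, length(x$centers), x$width, x$step,
              x$start, x$stop))
  invisible(x)
}

grid_edges <- function(grid) {
  if (grid$anchor == "center") {
    lo <- grid$centers - grid$width / 2
  } else {
    lo <- grid$centers
  }
  list(lo = lo, hi = lo + grid$width)
}

#' Event-aligned sliding-window firing rates
#'
#' Aligns each retained trial's spike train to the grid's alignment event
#' and computes the instantaneous firing rate in every window: spike count
#' in the half-open interval `[lo, hi)` divided by the window width. A
#' window that extends beyond the trial's recorded interval
#' (`[hold_onset, hold_release]` in trial time) yields `NA` for that trial
#' so that
#' no window mixes recorded and unrecorded time.
#'
#' @param session A `spike_session`.
#' @param neuron_id Neuron to analyse.
#' @param grid A [time_grid()].
#' @param correct_only Retain correct trials only (default `TRUE`).
#' @param trial_ids Optional subset of trial ids to retain.
#' @param check_inclusion Require the neuron to pass [inclusion_filter()]
#'   (default `FALSE`; the pipeline applies the filter up front).
#' @return A `windowed_rates` object: the rate matrix (trials x windows),
#'   the retained trials table, and the grid. Use [tidy()] for the long
#'   tabular form.
#' @export
align_and_bin <- function(session, neuron_id, grid,
                          correct_only = TRUE, trial_ids = NULL,
                          check_inclusion = FALSE) {
  stopifnot(inherits(grid, "time_grid"))
  if (!neuron_id %in% session$neurons$neuron_id) {
    abort(sprintf("unknown neuron_id '%s'", neuron_id))
  }
  if (check_inclusion && !inclusion_filter(session, neuron_id)) {
    abort(sprintf("neuron '%s' does not pass the inclusion filter",
                  neuron_id))
  }
  tr <- session$trials
  if (correct_only) tr <- dplyr::filter(tr, .data$correct)
  if (!is.null(trial_ids)) {
    tr <- dplyr::filter(tr, .data$trial_id %in% trial_ids)
  }
  if (nrow(tr) == 0) abort("empty trial set after filtering")

  ev <- tr[[alignment_events[[grid$alignment_event]]]]
  edges <- grid_edges(grid)
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, ]
  sp_by_trial <- split(sp$spike_time, factor(sp$trial_id,
                                             levels = tr$trial_id))
  K <- length(grid$centers)
  rates <- matrix(NA_real_, nrow = nrow(tr), ncol = K,
                  dimnames = list(tr$trial_id, NULL))
  for (i in seq_len(nrow(tr))) {
    s <- sp_by_trial[[i]] - ev[i]
    lo_ok <- edges$lo >= (tr$hold_onset[i] - ev[i]) - .time_tol
    hi_ok <- edges$hi <= (tr$hold_release[i] - ev[i]) + .time_tol
    valid <- lo_ok & hi_ok
    counts <- vapply(seq_len(K), function(k) {
      sum(s >= edges$lo[k] & s < edges$hi[k])
    }, numeric(1))
    rates[i, valid] <- counts[valid] / grid$width
  }
  structure(
    list(neuron_id = neuron_id, grid = grid, rates = rates, trials = tr),
    class = "windowed_rates"
  )
}

#' @export
print.windowed_rates <- function(x, ...) {
  cat(sprintf("<windowed_rates> neuron %s: %d trials x %d windows (%s-aligned)\n",
              x$neuron_id, nrow(x$rates), ncol(x$rates),
              x$grid$alignment_event))
  invisible(x)
}

#' Tidy a windowed-rates object into long format
#'
#' @param x A `windowed_rates` object.
#' @param ... Unused.
#' @return A tibble `neuron_id, trial_id, t_center, rate`.
#' @importFrom generics tidy
#' @export
tidy.windowed_rates <- function(x, ...) {
  tibble(
    neuron_id = x$neuron_id,
    trial_id = rep(rownames(x$rates), times = ncol(x$rates)),
    t_center = rep(x$grid$centers, each = nrow(x$rates)),
    rate = as.vector(x$rates)
  )
}

#' Generics re-exported from other packages
#'
#' See [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()].
#' @name reexports
#' @keywords internal
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @aliases tidy glance autoplot
#' @export tidy glance autoplot
NULL

#' Fixed-epoch firing rates
#'
#' Mean rate over one of the two analysis epochs: `"RESPONSE"` is the
#' 300 ms interval preceding movement onset (hold release),
#' `[hold_release - 0.3, hold_release)`; `"POSTCUE"` is the 500 ms first
#' cue presentation, `[cue_onset, cue_onset + 0.5)`.
#'
#' @inheritParams align_and_bin
#' @param epoch `"RESPONSE"` or `"POSTCUE"`.
#' @param response_window Width of the response epoch in seconds
#'   (default 0.3).
#' @return A tibble `trial_id, rate` over the retained trials.
#' @export
epoch_rate <- function(session, neuron_id, epoch = c("RESPONSE", "POSTCUE"),
                       correct_only = TRUE, trial_ids = NULL,
                       response_window = 0.3) {
  epoch <- match.arg(epoch)
  if (!neuron_id %in% session$neurons$neuron_id) {
    abort(sprintf("unknown neuron_id '%s'", neuron_id))
  }
  tr <- session$trials
  if (correct_only) tr <- dplyr::filter(tr, .data$correct)
  if (!is.null(trial_ids)) {
    tr <- dplyr::filter(tr, .data$trial_id %in% trial_ids)
  }
  if (nrow(tr) == 0) abort("empty trial set after filtering")
  if (epoch == "RESPONSE") {
    lo <- tr$hold_release - response_window
    hi <- tr$hold_release
    width <- response_window
  } else {
    lo <- tr$cue_onset
    hi <- tr$cue_onset + 0.5
    width <- 0.5
  }
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, ]
  sp_by_trial <- split(sp$spike_time, factor(sp$trial_id,
                                             levels = tr$trial_id))
  counts <- vapply(seq_len(nrow(tr)), function(i) {
    s <- sp_by_trial[[i]]
    sum(s >= lo[i] - .time_tol & s < hi[i] - .time_tol)
  }, numeric(1))
  tibble(trial_id = tr$trial_id, rate = counts / width)
}
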