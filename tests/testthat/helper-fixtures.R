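# Hand-built trial rows and tiny sessions used across the test files.

make_trial <- function(trial_id, task = "TACTICS_PRECUED",
                       tactics = "PRO", cue_position = "LEFT",
                       cue_color = NULL, action = NULL, correct = TRUE,
                       delay = 1.2, rt = 0.4) {
  if (is.null(cue_color)) {
    cue_color <- if (tactics == "PRO") "CYAN" else "BLUE"
  }
  if (is.null(action)) {
    action <- if (tactics == "PRO") cue_position else
      setdiff(c("LEFT", "RIGHT"), cue_position)
  }
  tibble::tibble(
    trial_id = trial_id, task = task, tactics = tactics,
    cue_color = cue_color, cue_position = cue_position, action = action,
    correct = correct, hold_onset = 0, cue_onset = 1,
    go_onset = 1.5 + delay, hold_release = 1.5 + delay + rt
  )
}

# A balanced block of the four tactics x position cells for one task,
# one trial per cell (shades alternate with `shade`).
balanced_block <- function(task, rep_id = 1, shade = 1) {
  cells <- tidyr::expand_grid(tactics = c("PRO", "ANTI"),
                              cue_position = c("LEFT", "RIGHT"))
  purrr::pmap_dfr(cells, function(tactics, cue_position) {
    color <- if (tactics == "PRO") {
      if (shade > 0) "CYAN" else "GREEN"
    } else {
      if (shade > 0) "BLUE" else "RED"
    }
    make_trial(
      sprintf("%s_r%d_s%d_%s_%s", substr(task, 1, 1), rep_id,
              (shade + 1) / 2, tactics, cue_position),
      task = task, tactics = tactics, cue_position = cue_position,
      cue_color = color
    )
  })
}

# Balanced trials table: `reps` trials per tactics x position x shade cell
# per task (8 cells per task).
balanced_trials <- function(reps = 1, tasks = c("TACTICS_PRECUED",
                                                "LOCATION_PRECUED")) {
  purrr::map_dfr(tasks, function(tk) {
    purrr::map_dfr(seq_len(reps), function(r) {
      dplyr::bind_rows(balanced_block(tk, r, shade = 1),
                       balanced_block(tk, r, shade = -1))
    })
  })
}

# Spikes placed at fixed phases of each trial for a set of neurons.
phase_spikes <- function(trials, neuron_ids, phases = c(0.5, 2.0)) {
  purrr::map_dfr(neuron_ids, function(nid) {
    purrr::map_dfr(seq_len(nrow(trials)), function(i) {
      tibble::tibble(neuron_id = nid, trial_id = trials$trial_id[i],
                     spike_time = phases[phases < trials$hold_release[i]])
    })
  })
}

tiny_session <- function(reps = 1, neuron_ids = "u1") {
  trials <- balanced_trials(reps)
  spikes <- phase_spikes(trials, neuron_ids)
  spike_session(trials, spikes,
                tibble::tibble(neuron_id = neuron_ids, area = "pmPFC"))
}

# --- Independent least-squares oracle -----------------------------------
# Nested-model F and CPD from explicit normal equations; shares no code
# with the package's QR path.

oracle_sse <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta)^2)
}

oracle_nested <- function(X, y, drop_cols) {
  sse_full <- oracle_sse(X, y)
  Xr <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
  sse_partial <- oracle_sse(Xr, y)
  df_x <- length(drop_cols)
  df_res <- nrow(X) - ncol(X)
  f <- ((sse_partial - sse_full) / df_x) / (sse_full / df_res)
  list(
    sse_full = sse_full, sse_partial = sse_partial, f = f,
    p = stats::pf(f, df_x, df_res, lower.tail = FALSE),
    cpd = (sse_partial - sse_full) / sse_partial
  )
}

# Direct two-sample ECDF scan for the KS statistic.
oracle_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                 numeric(1))))
}

# Classification records with given category counts for one factor.
make_records <- function(factor, n_only_a, n_only_b, n_both,
                         n_none = 0, area = "pmPFC") {
  n <- n_only_a + n_only_b + n_both + n_none
  tibble::tibble(
    neuron_id = sprintf("%s_%04d", substr(factor, 1, 2), seq_len(n)),
    area = area, factor = factor,
    category = rep(c("ONLY_TACTICS_PRECUED", "ONLY_LOCATION_PRECUED",
                     "BOTH", "NONE"),
                   c(n_only_a, n_only_b, n_both, n_none))
  )
}

# Tunings for a neuron with a single planted response-epoch gain.
planted_tuning <- function(neuron_id, factor, task, gain = 20,
                           baseline = 20) {
  tuning_spec(neuron_id, baseline_rate = baseline,
              gains = tibble::tibble(factor = factor, epoch = "response",
                                     task = task, gain = gain))
}
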