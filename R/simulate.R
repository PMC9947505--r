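#' Simulation configuration
#'
#' Captures the behavioural timeline of the two cued-reaching task variants
#' and the composition of the simulated population. Timeline defaults follow
#' the experimental protocol: a 1 s hold period, a 0.5 s first cue, a
#' variable delay drawn uniformly from 1-1.5 s, and a response that must be
#' completed within 1 s of the go signal (simulated reaction times uniform
#' on 0.2-0.6 s). Trial counts are balanced over the tactics x cue-position
#' x colour-shade cells, so `n_trials_per_task` must be divisible by 8.
#'
#' @param n_neurons Named integer vector of neurons per area.
#' @param n_trials_per_task Trials per task variant, divisible by 8.
#' @param delay_range,rt_range Uniform bounds (s) for the delay and the
#'   reaction time (go signal to hold release).
#' @param hold_duration,cue_duration Hold and first-cue durations (s).
#' @param baseline_rate Baseline firing rate (spikes/s) for drawn tunings.
#' @param effect_scale Planted gain as a multiple of `baseline_rate`.
#' @param p_selective Probability that a drawn neuron carries a planted
#'   response-epoch gain on one factor (otherwise it is a null neuron).
#' @param f_task_specific Among selective neurons, the probability that the
#'   gain is planted in exactly one task variant (the task-specific
#'   fraction that downstream classification should recover).
#' @param error_rate Fraction of trials simulated as errors (action flipped,
#'   `correct = FALSE`).
#' @param noise `"poisson"` for inhomogeneous Poisson spiking or `"gamma"`
#'   for a gamma-renewal process with shape `gamma_shape`.
#' @param gamma_shape Shape parameter of the gamma-interval noise model.
#' @param seed Integer seed; every random draw in the simulator derives
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_neurons = c(pmPFC = 30, preSMA = 10, SMA = 10),
                       n_trials_per_task = 160,
                       delay_range = c(1.0, 1.5),
                       rt_range = c(0.2, 0.6),
                       hold_duration = 1.0,
                       cue_duration = 0.5,
                       baseline_rate = 20,
                       effect_scale = 1,
                       p_selective = 0.8,
                       f_task_specific = 0.8,
                       error_rate = 0,
                       noise = c("poisson", "gamma"),
                       gamma_shape = 2,
                       seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(
    length(n_neurons) > 0, all(n_neurons >= 0),
    all(names(n_neurons) %in% area_levels),
    n_trials_per_task > 0, n_trials_per_task %% 8 == 0,
    delay_range[1] >= 1 - .time_tol, delay_range[2] <= 1.5 + .time_tol,
    rt_range[1] > 0, rt_range[2] <= 1,
    hold_duration >= 1 - .time_tol, cue_duration > 0,
    baseline_rate >= 0, effect_scale >= 0,
    p_selective >= 0, p_selective <= 1,
    f_task_specific >= 0, f_task_specific <= 1,
    error_rate >= 0, error_rate < 1,
    gamma_shape > 0
  )
  structure(
    list(n_neurons = n_neurons, n_trials_per_task = n_trials_per_task,
         delay_range = delay_range, rt_range = rt_range,
         hold_duration = hold_duration, cue_duration = cue_duration,
         baseline_rate = baseline_rate, effect_scale = effect_scale,
         p_selective = p_selective, f_task_specific = f_task_specific,
         error_rate = error_rate, noise = noise, gamma_shape = gamma_shape,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_epochs <- c("pre_cue", "post_cue", "delay", "response")
sim_factors <- c("tactics", "cue_position", "action", "task_type")

#' Planted tuning specification for one simulated neuron
#'
#' The neuron's intensity is piecewise constant over the four trial epochs
#' (pre-cue, post-cue, delay, response). Within an epoch it equals the
#' baseline plus, for every row of `gains` matching that epoch and the
#' trial's task, the gain multiplied by the +/-1 contrast of the trial's
#' level on that factor (PRO/RIGHT/RIGHT/TACTICS_PRECUED = +1), clipped at
#' zero. `shade_gain` modulates between the two cue colours within a
#' tactics level, in every epoch.
#'
#' @param neuron_id,area Identifier and area label.
#' @param baseline_rate Baseline intensity, spikes/s.
#' @param gains Tibble `factor, epoch, task, gain` of signed modulations in
#'   spikes/s; `factor` in `r paste(sim_factors, collapse = ", ")`; `task`
#'   may be `"BOTH"` to apply in both variants; `task_type` rows ignore the
#'   `task` column.
#' @param shade_gain Signed colour-shade modulation, spikes/s.
#' @param noise,gamma_shape Spiking noise model (see [sim_config()]).
#' @return A `tuning_spec` list.
#' @export
tuning_spec <- function(neuron_id, area = "pmPFC", baseline_rate = 20,
                        gains = NULL, shade_gain = 0,
                        noise = c("poisson", "gamma"), gamma_shape = 2) {
  noise <- match.arg(noise)
  if (is.null(gains)) {
    gains <- tibble(factor = character(), epoch = character(),
                    task = character(), gain = double())
  }
  gains <- as_tibble(gains)
  stopifnot(
    baseline_rate >= 0, is.finite(baseline_rate),
    all(gains$factor %in% sim_factors),
    all(gains$epoch %in% sim_epochs),
    all(gains$task %in% c(task_levels, "BOTH")),
    all(is.finite(gains$gain)), is.finite(shade_gain),
    area %in% area_levels
  )
  structure(
    list(neuron_id = neuron_id, area = area, baseline_rate = baseline_rate,
         gains = gains, shade_gain = shade_gain, noise = noise,
         gamma_shape = gamma_shape),
    class = "tuning_spec"
  )
}

trial_contrast <- function(trial, factor) {
  switch(factor,
    tactics = if (trial$tactics == "PRO") 1 else -1,
    cue_position = if (trial$cue_position == "RIGHT") 1 else -1,
    action = if (trial$action == "RIGHT") 1 else -1,
    task_type = if (trial$task == "TACTICS_PRECUED") 1 else -1,
    abort(sprintf("unknown factor '%s'", factor))
  )
}

epoch_bounds <- function(trial) {
  c(pre_cue = trial$hold_onset, post_cue = trial$cue_onset,
    delay = trial$cue_onset + 0.5, response = trial$go_onset,
    end = trial$hold_release)
}

epoch_rates_for_trial <- function(tuning, trial) {
  rate <- rep(tuning$baseline_rate, 4)
  names(rate) <- sim_epochs
  g <- tuning$gains
  if (nrow(g) > 0) {
    applies <- g$task == "BOTH" | g$task == trial$task | g$factor == "task_type"
    for (i in which(applies)) {
      rate[g$epoch[i]] <- rate[g$epoch[i]] +
        g$gain[i] * trial_contrast(trial, g$factor[i])
    }
  }
  if (tuning$shade_gain != 0) {
    rate <- rate + tuning$shade_gain * color_to_shade[[trial$cue_color]]
  }
  pmax(rate, 0)
}

#' Instantaneous intensity of a planted tuning
#'
#' @param tuning A [tuning_spec()].
#' @param trial One row of a session's trials table.
#' @param t Times in seconds from trial start, within
#'   `[hold_onset, hold_release]`.
#' @return Intensity in spikes/s at each `t`.
#' @export
intensity <- function(tuning, trial, t) {
  trial <- as.list(trial)
  b <- epoch_bounds(trial)
  if (any(t < b[["pre_cue"]] - .time_tol | t > b[["end"]] + .time_tol)) {
    abort("t outside the trial's recorded interval")
  }
  rate <- epoch_rates_for_trial(tuning, trial)
  idx <- findInterval(pmin(t, b[["end"]] - .time_tol), b[seq_len(4)])
  idx <- pmax(pmin(idx, 4), 1)
  unname(rate[idx])
}

# One trial's spike train from piecewise-constant epoch rates.
draw_spikes_poisson <- function(bounds, rates) {
  dur <- diff(bounds)
  n <- rpois(4, rates * dur)
  if (sum(n) == 0) return(numeric(0))
  sort(unlist(lapply(seq_len(4), function(e) {
    runif(n[e], bounds[e], bounds[e + 1])
  }), use.names = FALSE))
}

# Gamma-renewal spiking via time rescaling: a unit-rate gamma(kappa, kappa)
# renewal process in integrated-intensity time, mapped back through the
# piecewise-linear inverse of the cumulative intensity.
draw_spikes_gamma <- function(bounds, rates, shape) {
  dur <- diff(bounds)
  lam <- cumsum(c(0, rates * dur))
  total <- lam[5]
  if (total <= 0) return(numeric(0))
  n_guess <- max(10, ceiling(total + 4 * sqrt(total / shape)))
  isi <- rgamma(n_guess, shape = shape, rate = shape)
  s <- cumsum(isi)
  while (s[length(s)] < total) {
    isi <- rgamma(n_guess, shape = shape, rate = shape)
    s <- c(s, s[length(s)] + cumsum(isi))
  }
  s <- s[s < total]
  if (length(s) == 0) return(numeric(0))
  idx <- findInterval(s, lam, rightmost.closed = TRUE)
  bounds[idx] + (s - lam[idx]) / rates[idx]
}

draw_tunings <- function(config) {
  areas <- rep(names(config$n_neurons), config$n_neurons)
  n <- length(areas)
  gain <- config$effect_scale * config$baseline_rate
  purrr::map(seq_len(n), function(i) {
    selective <- runif(1) < config$p_selective
    gains <- NULL
    if (selective) {
      fac <- sample(c("tactics", "cue_position", "action"), 1)
      task_specific <- runif(1) < config$f_task_specific
      task <- if (task_specific) sample(task_levels, 1) else "BOTH"
      sign <- sample(c(-1, 1), 1)
      gains <- tibble(factor = fac, epoch = "response", task = task,
                      gain = sign * gain)
    }
    tuning_spec(
      neuron_id = sprintf("n%03d", i), area = areas[i],
      baseline_rate = config$baseline_rate, gains = gains,
      noise = config$noise, gamma_shape = config$gamma_shape
    )
  })
}

simulate_trials <- function(config) {
  per_cell <- config$n_trials_per_task / 8
  design <- tidyr::expand_grid(
    task = task_levels, tactics = tactics_levels,
    cue_position = side_levels, shade = c(1, -1)
  )
  design <- design[rep(seq_len(nrow(design)), each = per_cell), ]
  n <- nrow(design)
  color_pick <- function(tactics, shade) {
    pool <- names(color_to_shade)[color_to_tactics == tactics &
                                    color_to_shade == shade]
    pool[1]
  }
  cue_color <- purrr::map2_chr(design$tactics, design$shade, color_pick)
  action <- ifelse(design$tactics == "PRO", design$cue_position,
                   ifelse(design$cue_position == "LEFT", "RIGHT", "LEFT"))
  correct <- rep(TRUE, n)
  if (config$error_rate > 0) {
    err <- runif(n) < config$error_rate
    action[err] <- ifelse(action[err] == "LEFT", "RIGHT", "LEFT")
    correct[err] <- FALSE
  }
  delay <- runif(n, config$delay_range[1], config$delay_range[2])
  rt <- runif(n, config$rt_range[1], config$rt_range[2])
  hold_onset <- rep(0, n)
  cue_onset <- hold_onset + config$hold_duration
  go_onset <- cue_onset + config$cue_duration + delay
  hold_release <- go_onset + rt
  ord <- sample.int(n)
  tibble(
    trial_id = sprintf("t%04d", seq_len(n)),
    task = design$task[ord], tactics = design$tactics[ord],
    cue_color = cue_color[ord], cue_position = design$cue_position[ord],
    action = action[ord], correct = correct[ord],
    hold_onset = hold_onset, cue_onset = cue_onset,
    go_onset = go_onset[ord], hold_release = hold_release[ord]
  )
}

ground_truth_table <- function(tunings) {
  purrr::map_dfr(tunings, function(tu) {
    g <- tu$gains
    base <- tibble(neuron_id = tu$neuron_id, area = tu$area,
                   baseline_rate = tu$baseline_rate)
    if (nrow(g) == 0) {
      dplyr::bind_cols(base, tibble(factor = NA_character_,
                                    epoch = NA_character_,
                                    task = NA_character_, gain = 0))
    } else {
      dplyr::bind_cols(base[rep(1, nrow(g)), ], g)
    }
  })
}

#' Simulate a two-task recording session with planted selectivity
#'
#' Generates a balanced trial table for both task variants (equal correct
#' trial counts in every tactics x cue-position x colour-shade cell), then
#' draws each neuron's spike trains from its piecewise-constant epoch
#' intensity under Poisson (default) or gamma-renewal noise. The planted
#' tunings are recorded in the returned session's `ground_truth` so that
#' downstream classification can be validated against truth.
#'
#' Reproducibility: the trial structure is drawn from `config$seed` and each
#' neuron's spikes from a substream derived from the seed and the neuron's
#' index, so the same configuration always yields the identical session.
#'
#' @param config A [sim_config()].
#' @param tunings Optional list of [tuning_spec()]s; when omitted, tunings
#'   are drawn from the configuration's population fractions.
#' @return A validated `spike_session` with `ground_truth` populated.
#' @export
simulate_session <- function(config = sim_config(), tunings = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  trials <- simulate_trials(config)
  if (is.null(tunings)) tunings <- draw_tunings(config)
  stopifnot(all(purrr::map_lgl(tunings, inherits, "tuning_spec")))

  n_trials <- nrow(trials)
  bounds_mat <- rbind(trials$hold_onset, trials$cue_onset,
                      trials$cue_onset + 0.5, trials$go_onset,
                      trials$hold_release)
  spikes <- purrr::imap_dfr(tunings, function(tu, i) {
    set.seed((config$seed %% 1000003L) * 1009L + i)
    trains <- lapply(seq_len(n_trials), function(j) {
      trial <- trials[j, ]
      rates <- epoch_rates_for_trial(tu, trial)
      b <- bounds_mat[, j]
      if (tu$noise == "poisson") {
        draw_spikes_poisson(b, rates)
      } else {
        draw_spikes_gamma(b, rates, tu$gamma_shape)
      }
    })
    len <- lengths(trains)
    tibble(neuron_id = tu$neuron_id,
           trial_id = rep(trials$trial_id, len),
           spike_time = unlist(trains, use.names = FALSE))
  })
  neurons <- tibble(
    neuron_id = purrr::map_chr(tunings, "neuron_id"),
    area = purrr::map_chr(tunings, "area")
  )
  spike_session(trials, spikes, neurons,
                ground_truth = ground_truth_table(tunings))
}
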