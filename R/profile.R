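#' Time-resolved selectivity profile
#'
#' Runs the nested-model ANOVA and CPD at every window of a
#' [align_and_bin()] result, for every factor of the design, and masks
#' significance at `alpha` (default 0.05, uncorrected, as is conventional
#' for per-window selectivity traces; `min_consecutive` optionally
#' requires a run of consecutive significant windows, and
#' `adjust = "BH"` applies a Benjamini-Hochberg correction across
#' windows within each factor).
#'
#' Windows where some trials are masked (the window would extend beyond
#' the trial's recorded span) are fitted on the complete trials only;
#' windows with no usable trials or no residual degrees of freedom return
#' `NA`.
#'
#' @param wr A `windowed_rates` object.
#' @param design A [encode_design()] built from the same trials.
#' @param alpha Per-window significance threshold (default 0.05).
#' @param min_consecutive Minimum run length of significant windows for
#'   the mask (default 1).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `selectivity_profile`: a long tibble `neuron_id, task,
#'   factor, t_center, n_trials, cpd, statistic, p_value, sig` with the
#'   grid and thresholds as attributes.
#' @export
time_resolved_profile <- function(wr, design, alpha = 0.05,
                                  min_consecutive = 1,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(wr, "windowed_rates"),
            inherits(design, "design_matrix"))
  idx <- match(design$trial_id, rownames(wr$rates))
  if (anyNA(idx)) abort("design and windowed rates cover different trials")
  Y <- wr$rates[idx, , drop = FALSE]
  task <- unique(wr$trials$task[match(design$trial_id,
                                      wr$trials$trial_id)])
  task <- if (length(task) == 1) task else NA_character_
  K <- ncol(Y)
  factors <- names(design$assign)

  # fit window groups sharing the same complete-trial pattern in one pass
  pattern <- apply(!is.na(Y), 2, paste, collapse = "")
  res <- purrr::map(factors, function(f) {
    list(cpd = rep(NA_real_, K), f = rep(NA_real_, K),
         p = rep(NA_real_, K))
  })
  names(res) <- factors
  n_used <- rep(NA_integer_, K)
  for (pat in unique(pattern)) {
    ks <- which(pattern == pat)
    rows <- which(!is.na(Y[, ks[1]]))
    n_used[ks] <- length(rows)
    if (length(rows) <= ncol(design$matrix)) next
    sub_design <- tryCatch(
      {
        X <- design$matrix[rows, , drop = FALSE]
        q <- qr(X)
        if (q$rank < ncol(X)) NULL else
          list(matrix = X, assign = design$assign, qr = q)
      },
      error = function(e) NULL
    )
    if (is.null(sub_design)) next
    fit <- nested_fit(sub_design, Y[rows, ks, drop = FALSE], factors)
    for (f in factors) {
      res[[f]]$cpd[ks] <- fit$per_factor[[f]]$cpd
      res[[f]]$f[ks] <- fit$per_factor[[f]]$f
      res[[f]]$p[ks] <- fit$per_factor[[f]]$p
    }
  }

  out <- purrr::map_dfr(factors, function(f) {
    p <- res[[f]]$p
    p_adj <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
    sig <- !is.na(p_adj) & p_adj < alpha
    if (min_consecutive > 1) {
      r <- rle(sig)
      r$values[r$values & r$lengths < min_consecutive] <- FALSE
      sig <- inverse.rle(r)
    }
    tibble(
      neuron_id = wr$neuron_id, task = task, factor = f,
      t_center = wr$grid$centers, n_trials = n_used,
      cpd = res[[f]]$cpd, statistic = res[[f]]$f, p_value = p, sig = sig
    )
  })
  structure(out, class = c("selectivity_profile", class(out)),
            grid = wr$grid, alpha = alpha, adjust = adjust)
}

#' @export
tidy.selectivity_profile <- function(x, ...) as_tibble(x)

#' Plot a time-resolved selectivity profile
#'
#' CPD traces over aligned time, one colour per factor, thickened where
#' the factor's effect is significant.
#'
#' @param object A `selectivity_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selectivity_profile
#' @export
autoplot.selectivity_profile <- function(object, ...) {
  grid <- attr(object, "grid")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_center, y = .data$cpd,
                                   colour = .data$factor)) +
    ggplot2::geom_line(ggplot2::aes(linewidth = .data$sig)) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.4,
                                               `TRUE` = 1.4),
                                    guide = "none") +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(
      x = sprintf("time from %s (s)", tolower(grid$alignment_event)),
      y = "coefficient of partial determination", colour = "factor"
    ) +
    ggplot2::theme_minimal()
}

#' Plot trial-averaged windowed rates
#'
#' Mean firing rate over trials with a standard-error ribbon.
#'
#' @param object A `windowed_rates` object.
#' @param group_by Optional trials-table column to split trials by (e.g.
#'   `"tactics"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot windowed_rates
#' @export
autoplot.windowed_rates <- function(object, group_by = NULL, ...) {
  df <- tidy(object)
  df <- dplyr::left_join(df, object$trials, by = "trial_id")
  grp <- if (is.null(group_by)) "neuron_id" else group_by
  summ <- dplyr::summarise(
    dplyr::group_by(df, .data$t_center, .data[[grp]]),
    mean_rate = mean(.data$rate, na.rm = TRUE),
    sem = stats::sd(.data$rate, na.rm = TRUE) /
      sqrt(sum(!is.na(.data$rate))),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$t_center,
                                     y = .data$mean_rate,
                                     colour = .data[[grp]],
                                     fill = .data[[grp]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_rate - .data$sem,
                                      ymax = .data$mean_rate + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = sprintf("time from %s (s)",
                  tolower(object$grid$alignment_event)),
      y = "firing rate (spikes/s)"
    ) +
    ggplot2::theme_minimal()
}
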