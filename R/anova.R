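# Residual sum of squares of Y (vector or matrix of responses) on the
# columns of X, via QR. Returns one SSE per response column.
rss <- function(qr_x, Y) {
  res <- qr.resid(qr_x, Y)
  if (is.matrix(res)) colSums(res^2) else sum(res^2)
}

# Core nested-model comparison shared by all ANOVA entry points.
# Y: n x K response matrix (windows or a single epoch as columns).
# Returns per-factor matrices of sse_partial, F, p, cpd (factors x K).
nested_fit <- function(design, Y, factors = names(design$assign)) {
  X <- design$matrix
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(X))
  p_full <- ncol(X)
  df_res <- nrow(X) - p_full
  if (df_res <= 0) abort("no residual degrees of freedom")
  sse_full <- rss(design$qr, Y)
  out <- purrr::map(factors, function(f) {
    fcols <- design$assign[[f]]
    if (is.null(fcols)) abort(sprintf("factor '%s' not in design", f))
    keep <- setdiff(colnames(X), fcols)
    qr_red <- qr(X[, keep, drop = FALSE])
    if (qr_red$rank < length(keep)) {
      abort(sprintf("reduced design without '%s' is rank-deficient", f),
            class = "neurocpd_rank_error")
    }
    sse_partial <- rss(qr_red, Y)
    df_x <- length(fcols)
    num <- pmax(sse_partial - sse_full, 0)
    degenerate <- sse_full <= .sse_tol * pmax(sse_partial, 1)
    f_stat <- (num / df_x) / (sse_full / df_res)
    p <- pf(f_stat, df_x, df_res, lower.tail = FALSE)
    # zero-residual fits: F undefined; p := 0 if the factor carries any
    # signal, NA if the fit is degenerate in both models
    p[degenerate & sse_partial > 0] <- 0
    p[degenerate & sse_partial <= 0] <- NA_real_
    f_stat[degenerate] <- Inf
    cpd <- ifelse(sse_partial > 0, num / sse_partial, 0)
    list(sse_partial = sse_partial, df = df_x, f = f_stat, p = p,
         cpd = pmin(pmax(cpd, 0), 1), degenerate = degenerate)
  })
  names(out) <- factors
  list(per_factor = out, sse_full = sse_full, df_residual = df_res,
       n = nrow(X))
}

.sse_tol <- 1e-12

#' Nested-model ANOVA for one response vector
#'
#' Fits the full linear encoding model by ordinary least squares and, for
#' each factor, the reduced model with that factor's column(s) omitted.
#' The factor's F statistic is the drop-one (partial) sum-of-squares test
#' `F = ((SSE_partial - SSE_full) / df_X) / (SSE_full / df_residual)` with
#' its p-value from the F distribution; the coefficient of partial
#' determination is `CPD = (SSE_partial - SSE_full) / SSE_partial`, the
#' fraction of response variance uniquely attributable to the factor.
#' Zero-residual (degenerate) fits are flagged rather than silently
#' assigned p-values: `p` is 0 when the factor still carries signal and
#' `NA` otherwise.
#'
#' @param rates Numeric response vector, one value per design row
#'   (firing rates in spikes/s).
#' @param design A [encode_design()] result covering the same trials, in
#'   the same order.
#' @param factors Factors to test (default: all in the design).
#' @param alpha Significance threshold recorded in the `sig` column.
#' @return A `cpd_anova` object; [tidy()] returns the per-factor table
#'   (`factor, df, sse_partial, cpd, statistic, p_value, sig, degenerate`)
#'   and [glance()] the fit-level summary.
#' @export
nested_anova <- function(rates, design, factors = names(design$assign),
                         alpha = 0.05) {
  stopifnot(inherits(design, "design_matrix"))
  fit <- nested_fit(design, matrix(rates, ncol = 1), factors)
  tab <- purrr::map_dfr(factors, function(f) {
    pf_ <- fit$per_factor[[f]]
    tibble(
      factor = f, df = pf_$df, sse_partial = pf_$sse_partial[1],
      cpd = pf_$cpd[1], statistic = pf_$f[1], p_value = pf_$p[1],
      sig = !is.na(pf_$p[1]) & pf_$p[1] < alpha,
      degenerate = pf_$degenerate[1]
    )
  })
  structure(
    list(table = tab, sse_full = fit$sse_full[1],
         df_residual = fit$df_residual, n = fit$n, alpha = alpha),
    class = "cpd_anova"
  )
}

#' @export
print.cpd_anova <- function(x, ...) {
  cat(sprintf("<cpd_anova> n = %d, SSE_full = %.4g, df_residual = %d\n",
              x$n, x$sse_full, x$df_residual))
  print(x$table)
  invisible(x)
}

#' @rdname nested_anova
#' @param x A `cpd_anova` object.
#' @param ... Unused.
#' @export
tidy.cpd_anova <- function(x, ...) x$table

#' @rdname nested_anova
#' @method glance cpd_anova
#' @export
glance.cpd_anova <- function(x, ...) {
  tibble(n = x$n, sse_full = x$sse_full, df_residual = x$df_residual,
         alpha = x$alpha)
}

#' Coefficient of partial determination from nested SSEs
#'
#' `(SSE_partial - SSE_full) / SSE_partial`, the fraction of response
#' variance uniquely ascribable to the omitted factor; defined as 0 when
#' `SSE_partial` is 0 (nothing left to explain).
#'
#' @param result A `cpd_anova` object, or a numeric `sse_partial`.
#' @param factor Factor name (when `result` is a `cpd_anova`).
#' @param sse_full Full-model SSE (when `result` is numeric).
#' @return CPD in `[0, 1]`.
#' @export
compute_cpd <- function(result, factor = NULL, sse_full = NULL) {
  if (inherits(result, "cpd_anova")) {
    stopifnot(!is.null(factor))
    row <- result$table[result$table$factor == factor, ]
    if (nrow(row) == 0) abort(sprintf("factor '%s' not in result", factor))
    sse_partial <- row$sse_partial
    sse_full <- result$sse_full
  } else {
    sse_partial <- result
    stopifnot(is.numeric(sse_partial), !is.null(sse_full))
  }
  if (any(sse_partial < 0) || any(sse_full < 0)) {
    abort("sums of squared errors must be non-negative")
  }
  if (any(sse_partial < sse_full - .sse_tol * pmax(sse_partial, 1))) {
    abort("sse_partial must be >= sse_full (nested models)")
  }
  ifelse(sse_partial > 0,
         pmin(pmax((sse_partial - sse_full) / sse_partial, 0), 1), 0)
}

#' Response-period multifactorial ANOVA for one neuron and task
#'
#' The cross-task classification statistic: rates over the 300 ms interval
#' preceding movement onset (hold release) are modelled with tactics, cue
#' position and action as factors (colour is not included in this epoch
#' model), separately per task variant, and tested at `alpha` (default
#' 0.01).
#'
#' @inheritParams align_and_bin
#' @param task Task variant to analyse.
#' @param alpha Significance threshold (default 0.01).
#' @param response_window Response-epoch width in seconds (default 0.3).
#' @return A `cpd_anova` object.
#' @export
response_period_anova <- function(session, neuron_id,
                                  task = task_levels, alpha = 0.01,
                                  response_window = 0.3,
                                  check_inclusion = TRUE) {
  task <- match.arg(task)
  if (check_inclusion && !inclusion_filter(session, neuron_id)) {
    abort(sprintf("neuron '%s' does not pass the inclusion filter",
                  neuron_id))
  }
  tr <- dplyr::filter(session$trials, .data$correct, .data$task == !!task)
  design <- encode_design(tr, factors = c("tactics", "cue_position",
                                          "action"))
  rates <- epoch_rate(session, neuron_id, epoch = "RESPONSE",
                      trial_ids = tr$trial_id,
                      response_window = response_window)
  rates <- rates$rate[match(design$trial_id, rates$trial_id)]
  nested_anova(rates, design, alpha = alpha)
}

#' Response-period ANOVA table for a whole session
#'
#' Runs [response_period_anova()] for every (included) neuron and both
#' tasks, sharing one design fit per task for speed.
#'
#' @inheritParams response_period_anova
#' @param neuron_ids Neurons to analyse (default: all passing inclusion).
#' @return A tibble `neuron_id, area, task, factor, df, sse_partial, cpd,
#'   statistic, p_value, sig, degenerate`.
#' @export
response_period_table <- function(session, neuron_ids = NULL, alpha = 0.01,
                                  response_window = 0.3,
                                  check_inclusion = TRUE) {
  if (is.null(neuron_ids)) {
    inc <- include_neurons(session)
    neuron_ids <- if (check_inclusion) {
      inc$neuron_id[inc$included]
    } else {
      inc$neuron_id
    }
  }
  if (length(neuron_ids) == 0) {
    abort("no neurons pass the inclusion filter")
  }
  areas <- session$neurons$area[match(neuron_ids,
                                      session$neurons$neuron_id)]
  purrr::map_dfr(task_levels, function(tk) {
    tr <- dplyr::filter(session$trials, .data$correct, .data$task == tk)
    design <- encode_design(tr, factors = c("tactics", "cue_position",
                                            "action"))
    Y <- vapply(neuron_ids, function(nid) {
      r <- epoch_rate(session, nid, epoch = "RESPONSE",
                      trial_ids = tr$trial_id,
                      response_window = response_window)
      r$rate[match(design$trial_id, r$trial_id)]
    }, numeric(nrow(tr)))
    fit <- nested_fit(design, Y)
    purrr::imap_dfr(fit$per_factor, function(pf_, f) {
      tibble(neuron_id = neuron_ids, area = areas, task = tk, factor = f,
             df = pf_$df, sse_partial = pf_$sse_partial, cpd = pf_$cpd,
             statistic = pf_$f, p_value = pf_$p,
             sig = !is.na(pf_$p) & pf_$p < alpha,
             degenerate = pf_$degenerate)
    })
  })
}

#' Compare paired f-values between task periods
#'
#' Compares, across neurons, the selectivity (ANOVA f-value) measured in
#' the response period of one task against the post-cue period of the
#' other, with a two-sample two-tailed Kolmogorov-Smirnov test, and counts
#' how many neurons show reduced selectivity (post-cue f below response f).
#'
#' @param fvals_response,fvals_postcue Per-neuron f-value vectors,
#'   paired by position when of equal length.
#' @return A list with `statistic` (max ECDF gap), `p_value`, the per
#'   neuron `flags` tibble, and `n_reduced`, the number of neurons whose
#'   post-cue f-value is below their response-period f-value (`flags`
#'   and `n_reduced` are `NULL`/`NA` for unpaired samples).
#' @export
crosstask_f_comparison <- function(fvals_response, fvals_postcue) {
  if (length(fvals_response) == 0 || length(fvals_postcue) == 0) {
    abort("empty f-value sample")
  }
  ks <- suppressWarnings(
    ks.test(fvals_response, fvals_postcue, alternative = "two.sided"))
  flags <- NULL
  n_reduced <- NA_integer_
  if (length(fvals_response) == length(fvals_postcue)) {
    flags <- tibble(
      f_response = fvals_response, f_postcue = fvals_postcue,
      reduced = fvals_postcue < fvals_response
    )
    n_reduced <- sum(flags$reduced)
  }
  list(statistic = unname(ks$statistic), p_value = unname(ks$p.value),
       flags = flags, n_reduced = n_reduced,
       n = c(length(fvals_response), length(fvals_postcue)))
}
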