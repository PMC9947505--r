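category_levels <- c("ONLY_TACTICS_PRECUED", "ONLY_LOCATION_PRECUED",
                     "BOTH", "NONE")

category_from_flags <- function(sig_a, sig_b) {
  dplyr::case_when(
    sig_a & !sig_b ~ "ONLY_TACTICS_PRECUED",
    !sig_a & sig_b ~ "ONLY_LOCATION_PRECUED",
    sig_a & sig_b ~ "BOTH",
    TRUE ~ "NONE"
  )
}

# Integer percent, half away from zero.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cross-task category of one neuron for one factor
#'
#' A neuron is selective for a factor in a task if the response-period
#' ANOVA gives `p < alpha` (strictly, default 0.01) for that factor in
#' that task. Crossing the two tasks' flags yields four categories:
#' selective only in the tactics-precued task, only in the
#' location-precued task, in both, or in neither.
#'
#' @param result_tactics_precued,result_location_precued `cpd_anova`
#'   results from [response_period_anova()] for the two task variants.
#' @param factor Factor name (`"tactics"`, `"cue_position"`, `"action"`).
#' @param alpha Significance threshold (default 0.01).
#' @return One of `"ONLY_TACTICS_PRECUED"`, `"ONLY_LOCATION_PRECUED"`,
#'   `"BOTH"`, `"NONE"`.
#' @export
classify_neuron <- function(result_tactics_precued,
                            result_location_precued,
                            factor, alpha = 0.01) {
  p_of <- function(res) {
    stopifnot(inherits(res, "cpd_anova"))
    row <- res$table[res$table$factor == factor, ]
    if (nrow(row) == 0) {
      abort(sprintf("factor '%s' missing from a task result", factor))
    }
    row$p_value
  }
  p_a <- p_of(result_tactics_precued)
  p_b <- p_of(result_location_precued)
  category_from_flags(!is.na(p_a) & p_a < alpha,
                      !is.na(p_b) & p_b < alpha)
}

#' Classify every neuron of a response-period table
#'
#' @param resp A [response_period_table()] result (both tasks present).
#' @param alpha Significance threshold (default 0.01).
#' @param task_type_sig Optional tibble `neuron_id, task_type_selective`
#'   from [task_type_anova()] to carry along.
#' @return A classification-record tibble `neuron_id, area, factor,
#'   category` (one row per neuron x factor), plus `task_type_selective`
#'   when supplied.
#' @export
classify_records <- function(resp, alpha = 0.01, task_type_sig = NULL) {
  wide <- tidyr::pivot_wider(
    dplyr::select(resp, "neuron_id", "area", "task", "factor", "p_value"),
    names_from = "task", values_from = "p_value"
  )
  if (!all(task_levels %in% names(wide))) {
    abort("response-period results must cover both tasks")
  }
  rec <- dplyr::transmute(
    wide,
    neuron_id = .data$neuron_id, area = .data$area, factor = .data$factor,
    category = category_from_flags(
      !is.na(.data$TACTICS_PRECUED) & .data$TACTICS_PRECUED < alpha,
      !is.na(.data$LOCATION_PRECUED) & .data$LOCATION_PRECUED < alpha
    )
  )
  if (!is.null(task_type_sig)) {
    rec <- dplyr::left_join(rec, task_type_sig, by = "neuron_id")
  }
  rec
}

#' Task-type ANOVA over pooled response-period rates
#'
#' Tests whether the response-period rate depends on which task variant is
#' being performed, by pooling correct trials of both tasks and adding the
#' task-type contrast to the factorial design (the pooled design's rank is
#' re-checked by the encoder).
#'
#' @inheritParams response_period_table
#' @param alpha Significance threshold (default 0.01).
#' @return A tibble `neuron_id, task_type_f, task_type_p,
#'   task_type_selective`.
#' @export
task_type_anova <- function(session, neuron_ids = NULL, alpha = 0.01,
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
  tr <- dplyr::filter(session$trials, .data$correct)
  design <- encode_design(tr, factors = c("tactics", "cue_position",
                                          "action", "task_type"))
  Y <- vapply(neuron_ids, function(nid) {
    r <- epoch_rate(session, nid, epoch = "RESPONSE",
                    trial_ids = tr$trial_id,
                    response_window = response_window)
    r$rate[match(design$trial_id, r$trial_id)]
  }, numeric(nrow(tr)))
  fit <- nested_fit(design, as.matrix(Y), factors = "task_type")
  pf_ <- fit$per_factor$task_type
  tibble(neuron_id = neuron_ids, task_type_f = pf_$f,
         task_type_p = pf_$p,
         task_type_selective = !is.na(pf_$p) & pf_$p < alpha)
}

#' Population summary of cross-task selectivity
#'
#' Counts, per factor (optionally per area), how many neurons are
#' selective in only one task, in both, and in total, and derives the
#' task-specific fraction `(n_only_A + n_only_B) / n_selective`.
#' Percentages are reported both exactly and rounded to the nearest
#' integer (half away from zero). With zero selective neurons the
#' fractions are `NA`, not 0. If the records carry a
#' `task_type_selective` flag, the fraction of selective neurons with a
#' task-type effect is added; if `n_recorded` gives the number of recorded
#' neurons (per area or a single total), the prevalence of selective
#' neurons among them is added.
#'
#' @param records A classification-record tibble from
#'   [classify_records()] (columns `neuron_id, area, factor, category`).
#' @param by_area Split the summary by area (default `FALSE`: pool areas).
#' @param n_recorded Optional named vector (by area) or single count of
#'   recorded neurons, for prevalence percentages.
#' @return A tibble with one row per factor (x area), columns
#'   `n_only_tactics_precued, n_only_location_precued, n_both,
#'   n_selective, task_specific_fraction, task_specific_pct,
#'   task_specific_pct_rounded` and, where available,
#'   `task_type_fraction`, `prevalence_pct_rounded`.
#' @export
summarize_population <- function(records, by_area = FALSE,
                                 n_recorded = NULL) {
  if (nrow(records) == 0) abort("no classification records")
  stopifnot(all(records$category %in% category_levels))
  keys <- if (by_area) c("area", "factor") else "factor"
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(keys))),
    n_only_tactics_precued =
      sum(.data$category == "ONLY_TACTICS_PRECUED"),
    n_only_location_precued =
      sum(.data$category == "ONLY_LOCATION_PRECUED"),
    n_both = sum(.data$category == "BOTH"),
    n_none = sum(.data$category == "NONE"),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    n_selective = .data$n_only_tactics_precued +
      .data$n_only_location_precued + .data$n_both,
    task_specific_fraction = ifelse(
      .data$n_selective > 0,
      (.data$n_only_tactics_precued + .data$n_only_location_precued) /
        .data$n_selective, NA_real_),
    task_specific_pct = 100 * .data$task_specific_fraction,
    task_specific_pct_rounded = round_half_up(.data$task_specific_pct)
  )
  if ("task_type_selective" %in% names(records)) {
    tt <- dplyr::summarise(
      dplyr::group_by(
        dplyr::filter(records, .data$category != "NONE"),
        dplyr::across(dplyr::all_of(keys))),
      task_type_fraction = mean(.data$task_type_selective),
      .groups = "drop"
    )
    out <- dplyr::left_join(out, tt, by = keys)
    out <- dplyr::mutate(
      out,
      task_type_pct_rounded = round_half_up(100 * .data$task_type_fraction)
    )
  }
  if (!is.null(n_recorded)) {
    denom <- if (by_area && !is.null(names(n_recorded))) {
      unname(n_recorded[out$area])
    } else {
      sum(n_recorded)
    }
    out <- dplyr::mutate(
      out,
      n_recorded = denom,
      prevalence_pct = 100 * .data$n_selective / .data$n_recorded,
      prevalence_pct_rounded = round_half_up(.data$prevalence_pct)
    )
  }
  out
}

planted_category <- function(ground_truth) {
  g <- dplyr::filter(ground_truth, !is.na(.data$factor),
                     .data$epoch == "response", .data$gain != 0,
                     .data$factor %in% c("tactics", "cue_position",
                                         "action"))
  base <- tidyr::expand_grid(
    neuron_id = unique(ground_truth$neuron_id),
    factor = c("tactics", "cue_position", "action")
  )
  planted <- dplyr::summarise(
    dplyr::group_by(g, .data$neuron_id, .data$factor),
    truth = dplyr::case_when(
      any(.data$task == "BOTH") ||
        (any(.data$task == "TACTICS_PRECUED") &&
           any(.data$task == "LOCATION_PRECUED")) ~ "BOTH",
      any(.data$task == "TACTICS_PRECUED") ~ "ONLY_TACTICS_PRECUED",
      any(.data$task == "LOCATION_PRECUED") ~ "ONLY_LOCATION_PRECUED"
    ),
    .groups = "drop"
  )
  out <- dplyr::left_join(base, planted, by = c("neuron_id", "factor"))
  dplyr::mutate(out, truth = dplyr::coalesce(.data$truth, "NONE"))
}

#' Confusion report of assigned vs planted categories
#'
#' For synthetic sessions only: cross-tabulates, per factor, the category
#' the pipeline assigned against the category implied by the planted
#' response-epoch gains, and derives per-category sensitivity and
#' specificity.
#'
#' @param records Classification records from [classify_records()].
#' @param ground_truth The session's `ground_truth` table.
#' @return A list with `confusion` (tibble `factor, truth, assigned, n`,
#'   all 16 cells per factor) and `by_category` (tibble `factor,
#'   category, sensitivity, specificity, n_true`).
#' @export
recovery_report <- function(records, ground_truth) {
  if (is.null(ground_truth)) abort("session has no ground truth")
  truth <- planted_category(ground_truth)
  joined <- dplyr::inner_join(records, truth,
                              by = c("neuron_id", "factor"))
  if (nrow(joined) == 0) abort("no neurons shared by records and truth")
  grid <- tidyr::expand_grid(
    factor = unique(joined$factor), truth = category_levels,
    assigned = category_levels
  )
  counts <- dplyr::count(joined, .data$factor, .data$truth,
                         assigned = .data$category, name = "n")
  confusion <- dplyr::mutate(
    dplyr::left_join(grid, counts, by = c("factor", "truth", "assigned")),
    n = dplyr::coalesce(.data$n, 0L)
  )
  by_category <- purrr::map_dfr(unique(joined$factor), function(f) {
    sub <- dplyr::filter(joined, .data$factor == f)
    purrr::map_dfr(category_levels, function(cat) {
      is_true <- sub$truth == cat
      is_assigned <- sub$category == cat
      tibble(
        factor = f, category = cat, n_true = sum(is_true),
        sensitivity = ifelse(sum(is_true) > 0,
                             mean(is_assigned[is_true]), NA_real_),
        specificity = ifelse(sum(!is_true) > 0,
                             mean(!is_assigned[!is_true]), NA_real_)
      )
    })
  })
  list(confusion = confusion, by_category = by_category)
}
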