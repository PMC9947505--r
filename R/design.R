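#' Encode trials as a contrast design matrix
#'
#' Builds the regression design for the factorial encoding model. The task
#' structure aliases the naive factor coding in two ways, and the encoder
#' resolves both:
#'
#' * **Action** is fully determined by tactics and cue position on correct
#'   trials (reach toward the cue under pro-reach, away under anti-reach),
#'   so the action contrast `c_A` equals the product `c_T * c_P` — it is
#'   the tactics x position interaction contrast, and is estimable exactly
#'   when all four tactics x position cells are populated.
#' * **Cue colour** has four levels but two of them determine each tactics
#'   level (cyan/green = pro, blue/red = anti). A raw 4-level colour factor
#'   therefore spans the tactics contrast and makes the design
#'   rank-deficient; colour is instead coded as a 2-level *shade* contrast
#'   within the trial's tactics level (`color_coding = "shade"`, the
#'   default). Requesting `color_coding = "levels"` together with tactics
#'   reproduces the aliased design and is rejected.
#'
#' Contrast conventions: `PRO`, `RIGHT`, `RIGHT`, and the first colour of
#' each pair (cyan, blue) are +1; their alternatives are -1.
#'
#' @param trials Tibble of correct trials from a single task variant.
#' @param factors Character vector drawn from `"tactics"`,
#'   `"cue_position"`, `"action"`, `"cue_color"`, `"task_type"`.
#' @param color_coding `"shade"` (default) or `"levels"` (raw 4-level dummy
#'   coding, kept to demonstrate the aliasing).
#' @return A `design_matrix`: the numeric matrix (intercept first), the
#'   factor-to-column map, and the trial ids, with full rank guaranteed.
#' @export
encode_design <- function(trials,
                          factors = c("tactics", "cue_position", "action",
                                      "cue_color"),
                          color_coding = c("shade", "levels")) {
  color_coding <- match.arg(color_coding)
  trials <- as_tibble(trials)
  known <- c("tactics", "cue_position", "action", "cue_color", "task_type")
  if (length(factors) == 0 || !all(factors %in% known)) {
    abort(sprintf("factors must be drawn from: %s",
                  paste(known, collapse = ", ")))
  }
  if (!"task_type" %in% factors &&
      length(unique(trials$task)) > 1) {
    abort("trials span multiple tasks; encode per task or add task_type")
  }
  if (any(!trials$correct)) {
    abort("design encoding expects correct trials only")
  }
  n <- nrow(trials)
  if (n == 0) abort("no trials to encode")

  cols <- list(`(Intercept)` = rep(1, n))
  assign <- list()
  add_col <- function(name, values, factor) {
    cols[[name]] <<- values
    assign[[factor]] <<- c(assign[[factor]], name)
  }
  for (f in factors) {
    switch(f,
      tactics = add_col("tactics",
                        ifelse(trials$tactics == "PRO", 1, -1), f),
      cue_position = add_col("cue_position",
                             ifelse(trials$cue_position == "RIGHT", 1, -1),
                             f),
      action = add_col("action",
                       ifelse(trials$action == "RIGHT", 1, -1), f),
      task_type = add_col("task_type",
                          ifelse(trials$task == "TACTICS_PRECUED", 1, -1),
                          f),
      cue_color = {
        if (color_coding == "shade") {
          add_col("cue_color", unname(color_to_shade[trials$cue_color]), f)
        } else {
          # treatment dummies for the 4 colour levels (reference CYAN)
          for (lv in color_levels[-1]) {
            add_col(paste0("cue_color", lv),
                    as.numeric(trials$cue_color == lv), f)
          }
        }
      }
    )
  }
  X <- do.call(cbind, cols)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(X))]]
    abort(sprintf(
      paste0("rank-deficient design (rank %d < %d columns): column(s) %s ",
             "are linearly dependent given these trials"),
      qr_x$rank, ncol(X), paste(dropped, collapse = ", ")),
      class = "neurocpd_rank_error")
  }
  structure(
    list(matrix = X, assign = assign, factors = factors,
         trial_id = trials$trial_id, qr = qr_x),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d trials x %d columns (full rank)\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  factors:",
      paste(sprintf("%s [%s]", names(x$assign),
                    purrr::map_chr(x$assign, paste, collapse = ",")),
            collapse = "; "), "\n")
  invisible(x)
}
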