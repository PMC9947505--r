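balanced_design <- function(reps = 2, task = "TACTICS_PRECUED",
                            factors = c("tactics", "cue_position",
                                        "action", "cue_color")) {
  tr <- dplyr::filter(balanced_trials(reps), task == !!task)
  encode_design(tr, factors = factors)
}

test_that("nested ANOVA agrees with the brute-force least-squares oracle", {
  set.seed(101)
  for (i in 1:100) {
    reps <- sample(1:8, 1)                 # 8 to 64 trials
    d <- balanced_design(reps)
    n <- nrow(d$matrix)
    y <- rnorm(n, mean = 10, sd = 3)
    res <- nested_anova(y, d)
    for (f in names(d$assign)) {
      o <- oracle_nested(d$matrix, y, d$assign[[f]])
      row <- res$table[res$table$factor == f, ]
      expect_equal(row$statistic, o$f, tolerance = 1e-8)
      expect_equal(row$p_value, o$p, tolerance = 1e-8)
      expect_equal(row$sse_partial, o$sse_partial, tolerance = 1e-8)
      expect_equal(res$sse_full, o$sse_full, tolerance = 1e-8)
      expect_equal(row$cpd, o$cpd, tolerance = 1e-8)
    }
  }
})

test_that("a factor with equal cell means has F = 0 and CPD = 0", {
  d <- balanced_design(2)
  # response depends only on cue position, plus within-cell variation
  # (+0.5 on the first replicate of each cell, -0.5 on the second) that
  # is orthogonal to every design column
  y <- 10 + 4 * d$matrix[, "cue_position"] + rep(c(0.5, -0.5), each = 8)
  res <- nested_anova(y, d)
  tac <- res$table[res$table$factor == "tactics", ]
  expect_equal(tac$statistic, 0, tolerance = 1e-10)
  expect_equal(tac$cpd, 0, tolerance = 1e-10)
  expect_false(tac$sig)
})

test_that("noise-free coding is flagged degenerate, not given fake p", {
  d <- balanced_design(2)
  y <- 3 * d$matrix[, "action"]            # perfect action coder
  res <- nested_anova(y, d)
  act <- res$table[res$table$factor == "action", ]
  expect_true(act$degenerate)
  expect_equal(act$p_value, 0)             # signal present
  expect_equal(act$cpd, 1)
  expect_true(act$sig)
  # a constant response is degenerate with nothing to explain
  res0 <- nested_anova(rep(2, nrow(d$matrix)), d)
  expect_true(all(res0$table$degenerate))
  expect_true(all(is.na(res0$table$p_value)))
  expect_equal(res0$table$cpd, rep(0, 4))
})

test_that("compute_cpd matches its definition and guards its domain", {
  expect_equal(compute_cpd(40, sse_full = 40), 0)
  expect_equal(compute_cpd(10, sse_full = 0), 1)
  expect_equal(compute_cpd(0, sse_full = 0), 0)
  expect_equal(compute_cpd(50, sse_full = 30), 0.4)
  expect_error(compute_cpd(-1, sse_full = 0), "non-negative")
  expect_error(compute_cpd(10, sse_full = 20), "nested")

  # worked 8-trial instance against the oracle
  d <- balanced_design(1)
  set.seed(7)
  y <- rnorm(8, 12, 2)
  res <- nested_anova(y, d)
  o <- oracle_nested(d$matrix, y, "tactics")
  expect_equal(compute_cpd(res, "tactics"), o$cpd, tolerance = 1e-10)
  expect_error(compute_cpd(res, "flavour"), "not in result")
})

test_that("balanced contrasts are orthogonal: dropping colour leaves
           the tactics F unchanged", {
  set.seed(42)
  d_with <- balanced_design(4)
  d_without <- balanced_design(
    4, factors = c("tactics", "cue_position", "action"))
  y <- rnorm(nrow(d_with$matrix), 15, 4)
  f_with <- nested_anova(y, d_with)$table
  f_without <- nested_anova(y, d_without)$table
  # same numerator SS (orthogonality); F differs only through df_residual
  num_with <- f_with$sse_partial[f_with$factor == "tactics"] -
    nested_anova(y, d_with)$sse_full
  num_without <- f_without$sse_partial[f_without$factor == "tactics"] -
    nested_anova(y, d_without)$sse_full
  expect_equal(num_with, num_without, tolerance = 1e-8)
})

test_that("CPD grows monotonically with the planted effect size", {
  d <- balanced_design(4)
  n <- nrow(d$matrix)
  effects <- c(0, 1, 2, 4, 8)
  set.seed(55)
  mean_cpd <- vapply(effects, function(g) {
    mean(vapply(1:200, function(r) {
      y <- 10 + g * d$matrix[, "tactics"] + rnorm(n, 0, 3)
      nested_anova(y, d)$table$cpd[1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cpd) > 0))
  expect_true(all(mean_cpd >= 0 & mean_cpd <= 1))
})

test_that("response-period ANOVA recovers a planted one-task action gain", {
  hits_planted <- 0
  hits_null <- 0
  for (seed in 201:203) {
    cfg <- sim_config(n_neurons = c(pmPFC = 1), n_trials_per_task = 160,
                      seed = seed)
    tu <- planted_tuning("n001", "action", "TACTICS_PRECUED")
    s <- simulate_session(cfg, list(tu))
    ra <- response_period_anova(s, "n001", "TACTICS_PRECUED")
    rb <- response_period_anova(s, "n001", "LOCATION_PRECUED")
    hits_planted <- hits_planted +
      ra$table$sig[ra$table$factor == "action"]
    hits_null <- hits_null + rb$table$sig[rb$table$factor == "action"]
  }
  expect_equal(hits_planted, 3)  # power ~1 at gain = baseline
  expect_lte(hits_null, 1)       # alpha = 0.01 in the unplanted task
})

test_that("a perfect action coder in both tasks is significant in both", {
  cfg <- sim_config(n_neurons = c(pmPFC = 1), n_trials_per_task = 160,
                    seed = 72)
  tu <- planted_tuning("n001", "action", "BOTH")
  s <- simulate_session(cfg, list(tu))
  for (tk in c("TACTICS_PRECUED", "LOCATION_PRECUED")) {
    res <- response_period_anova(s, "n001", tk)
    expect_true(res$table$sig[res$table$factor == "action"])
  }
})

test_that("tidy and glance expose the fit tables", {
  d <- balanced_design(2)
  set.seed(1)
  res <- nested_anova(rnorm(16, 10), d)
  expect_named(tidy(res), c("factor", "df", "sse_partial", "cpd",
                            "statistic", "p_value", "sig", "degenerate"))
  g <- glance(res)
  expect_equal(g$n, 16)
  expect_equal(g$df_residual, 16 - 5)
})

test_that("the KS comparison matches a direct ECDF scan", {
  set.seed(33)
  a <- rchisq(20, df = 3)
  b <- rchisq(20, df = 1)
  cmp <- crosstask_f_comparison(a, b)
  expect_equal(cmp$statistic, oracle_ks_stat(a, b), tolerance = 1e-12)
  expect_equal(cmp$n_reduced, sum(b < a))

  same <- crosstask_f_comparison(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- crosstask_f_comparison(1:10, 100 + 1:10)
  expect_equal(disjoint$statistic, 1)
  expect_lt(disjoint$p_value, 0.001)
  expect_error(crosstask_f_comparison(numeric(0), a), "empty")
})
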