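toy_table <- function(n = 20, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    hospital_id = sprintf("H%02d", 1:n),
    density = runif(n, 0.1, 0.9),
    degree_centralisation = runif(n),
    mean_patient_age = rnorm(n, 68, 8),
    mean_cost_per_patient = rnorm(n, 24000, 5000)
  )
}

test_that("rank correlation is 1 for monotone pairs and matches hand computation", {
  tbl <- tibble::tibble(hospital_id = letters[1:6],
                        x = c(1, 3, 4, 7, 9, 12),
                        y = c(2, 9, 11, 20, 21, 40))
  res <- correlate(tbl, "x", "y")
  expect_equal(res$rho, 1)
  expect_equal(res$method, "rank")

  # hand-computed rank formula: rho = 1 - 6 sum(d^2) / (n(n^2-1))
  tbl$y <- c(5, 3, 9, 1, 8, 7)
  d <- rank(tbl$x) - rank(tbl$y)
  expect_equal(correlate(tbl, "x", "y")$rho,
               1 - 6 * sum(d^2) / (6 * 35))
  # symmetry in the arguments
  expect_equal(correlate(tbl, "x", "y")$rho, correlate(tbl, "y", "x")$rho)
  # rank method is invariant under monotone transforms
  tbl$x2 <- exp(tbl$x)
  expect_equal(correlate(tbl, "x2", "y")$rho, correlate(tbl, "x", "y")$rho)

  tbl$z <- 1
  expect_error(correlate(tbl, "x", "z"), "zero variance")
})

test_that("the permutation null yields approximately uniform p-values", {
  set.seed(207)
  n <- 40
  x <- rnorm(n)
  p <- replicate(300, {
    tbl <- tibble::tibble(hospital_id = as.character(1:n), x = x,
                          y = sample(rnorm(n)))
    correlate(tbl, "x", "y")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("simple regression recovers exact and planted slopes", {
  tbl <- toy_table()
  tbl$y <- 2 * tbl$density + 1
  fit <- suppressWarnings(fit_simple(tbl, "y", "density"))
  expect_equal(fit$terms$beta, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(208)
  slopes <- replicate(50, {
    tbl <- toy_table(n = 85, seed = sample.int(1e6, 1))
    tbl$y <- 100 + 40 * tbl$density + rnorm(85, 0, 10)
    fit_simple(tbl, "y", "density")$terms$beta
  })
  expect_lt(abs(mean(slopes) - 40), 2 * sd(slopes) / sqrt(50))

  tbl$flat <- 3
  expect_error(fit_simple(tbl, "y", "flat"), "singular")
})

test_that("moderation models isolate the index-by-age product term", {
  tbl <- toy_table(30)
  tbl$y <- tbl$density * tbl$mean_patient_age
  fit <- suppressWarnings(
    fit_moderation(tbl, "y", "density", "mean_patient_age"))
  inter <- fit$terms[fit$terms$term == "density:mean_patient_age", ]
  expect_equal(inter$beta, 1, tolerance = 1e-8)
  expect_lt(inter$p_value, 1e-12)
  expect_equal(nrow(fit$terms), 2)  # no age main effect by default
  fit3 <- suppressWarnings(
    fit_moderation(tbl, "y", "density", "mean_patient_age",
                   include_moderator_main = TRUE))
  expect_equal(nrow(fit3$terms), 3)

  # null: product term p-value roughly uniform over seeds
  set.seed(209)
  p <- replicate(200, {
    tbl <- toy_table(n = 40, seed = sample.int(1e6, 1))
    tbl$y <- rnorm(40)
    fit <- fit_moderation(tbl, "y", "density", "mean_patient_age")
    fit$terms$p_value[fit$terms$term == "density:mean_patient_age"]
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("regression residuals are orthogonal to fitted terms", {
  tbl <- toy_table(40, seed = 33)
  tbl$y <- 5 + 3 * tbl$density + rnorm(40)
  fit <- fit_simple(tbl, "y", "density")
  expect_lt(abs(sum(stats::residuals(fit$model) * tbl$density)), 1e-8)
  fitm <- fit_moderation(tbl, "y", "density", "mean_patient_age")
  mm <- stats::model.matrix(fitm$model)
  expect_true(all(abs(crossprod(mm, stats::residuals(fitm$model))) < 1e-6))
})

test_that("extreme groups come from a deterministic sort", {
  tbl <- tibble::tibble(hospital_id = sprintf("H%02d", 1:10),
                        cost = c(4, 9, 1, 7, 3, 10, 2, 8, 5, 6))
  groups <- select_extremes(tbl, "cost", 5)
  expect_setequal(groups$low$cost, 1:5)
  expect_setequal(groups$high$cost, 6:10)
  expect_error(select_extremes(tbl, "cost", 6), "half")

  # all-equal outcomes fall back to id order with a warning
  tbl$cost <- 1
  expect_warning(expect_warning(tied <- select_extremes(tbl, "cost", 3),
                                "ties"), "ties")
  expect_equal(tied$low$hospital_id, c("H01", "H02", "H03"))
  expect_equal(tied$high$hospital_id, c("H08", "H09", "H10"))

  # random tables match a full-sort oracle
  set.seed(210)
  for (rep in 1:5) {
    tbl <- tibble::tibble(hospital_id = sprintf("H%02d", 1:12),
                          v = rnorm(12))
    groups <- select_extremes(tbl, "v", 4)
    expect_equal(groups$low$v, sort(tbl$v)[1:4])
    expect_equal(groups$high$v, sort(tbl$v)[9:12])
  }
})

test_that("the pooled group test reproduces its algebraic equal-n form", {
  set.seed(211)
  low <- rnorm(5); high <- rnorm(5, 1)
  res <- tvalue_group_test(low, high, "two_star")
  expect_equal(res$df, 8)
  expect_equal(res$t_statistic,
               (mean(high) - mean(low)) / sqrt(res$se_low^2 + res$se_high^2))
  same <- tvalue_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_one_tail, 0.5)
  expect_error(tvalue_group_test(c(1, 1), c(1, 1)), "degenerate")
  expect_warning(expect_warning(
    tvalue_group_test(c(1, 2, NA), c(3, 4, Inf)), "non-finite"), "non-finite")
})

test_that("published estimate/stderr/ratio rows are reconciled sensibly", {
  tbl <- tibble::tibble(
    estimate = c(0.04, 0.00, -5.23, -0.11, 1.00),
    stderr = c(0.01, 0.00, 1.29, 0.00, 0.50),
    ratio_printed = c(6.25, 0.24, 0.04, 0.05, 2.00)
  )
  out <- resolve_tvalues(tbl)
  # ratio consistent with rounded inputs: keep the higher-precision ratio
  expect_equal(out$t_value[1], 6.25)
  expect_equal(out$t_source[1], "ratio")
  # 0.00/0.00 is compatible with any ratio
  expect_equal(out$t_value[2], 0.24)
  # corrupted ratio: recompute from estimate and stderr
  expect_equal(out$t_value[3], -5.23 / 1.29)
  expect_equal(out$t_source[3], "recomputed")
  # corrupted ratio and zero stderr: undefined
  expect_true(is.na(out$t_value[4]))
  expect_equal(out$t_source[4], "undefined")
  expect_equal(out$t_value[5], 2.00)
})

test_that("analysis tables join summaries and outcomes one row per hospital", {
  s <- tibble::tibble(hospital_id = c("A", "B", "C"), density = 1:3 / 10)
  o <- tibble::tibble(hospital_id = c("A", "B"), mean_cost_per_patient = 1:2)
  expect_warning(tab <- analysis_table(s, o), "missing")
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c("hospital_id", "density",
                             "mean_cost_per_patient"))
})
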