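test_that("IMR is the pressure-transit-time product with positivity checks", {
  expect_equal(compute_imr(80, 0.5), 40)
  expect_equal(compute_imr(60, 1.0), 60)
  expect_error(compute_imr(100, 0), "positive")
  expect_error(compute_imr(-5, 1), "positive")
  expect_equal(compute_imr(c(80, 60), c(0.5, 1)), c(40, 60))
})

test_that("dichotomisation uses strict clinical thresholds", {
  rec <- manual_records()
  out <- dichotomize(rec)
  expect_identical(out$imr_high, c(TRUE, FALSE, FALSE, TRUE, NA, FALSE))
  expect_identical(out$mvo_high, c(TRUE, FALSE, NA, FALSE, TRUE, TRUE))
  expect_identical(out$severe[1], TRUE)   # both above
  expect_identical(out$severe[4], FALSE)  # IMR high but MVO low
})

test_that("the adequacy filter keeps scores 4-5 with area >= 0.22", {
  rec <- manual_records()
  flt <- filter_successful(rec)
  # one-line oracle
  expect_equal(sum(flt$audit$kept),
               sum(rec$thrombus_score %in% 4:5 & rec$area_fraction >= 0.22))
  expect_identical(flt$audit$kept, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(flt$records$patient_id, c("M1", "M4"))
  # boundary: exactly 0.22 is kept (threshold is a minimum)
  expect_true(flt$audit$kept[4])
  # idempotent and order-independent
  again <- filter_successful(flt$records)
  expect_identical(again$records, flt$records)
  shuf <- filter_successful(rec[c(6, 3, 1, 5, 2, 4), ])
  expect_setequal(shuf$records$patient_id, flt$records$patient_id)
})

test_that("model predictions follow the four family formulas", {
  expect_equal(model_predict("exp", c(100, rep(0, 4)), c(0.25, 0.25, 0.25, 0.25)),
               100)
  expect_equal(model_predict("sat_exp", c(10, 0, 0), c(0.5, 0.5)), 0)
  expect_equal(model_predict("linear", c(1, 2, 3), c(0.5, 0.5)), 3.5)
  expect_equal(model_predict("power", c(2, 1, 1), c(0.5, 0.5)), 0.5)
  expect_warning(y <- model_predict("power", c(2, 1, 1), c(0, 1)), "floored")
  expect_true(is.finite(y))
  expect_error(model_predict("linear", c(1, 2), c(0.5, 0.5)), "length")
})

test_that("noiseless exponential cohorts are recovered exactly", {
  sp <- cohort_spec(60, noise_sd = 0, seed = 2)
  coh <- make_cohort(sp)
  fit <- fit_model(coh, "imr", "exp", n_starts = 5, seed = 1, n_perm = 0)
  expect_equal(fit$r2, 1, tolerance = 1e-6)
  truth <- gauge_fix_coefficients("exp", sp$coefficients)
  expect_lt(max(abs(fit$coefficients - truth) / pmax(abs(truth), 1)), 1e-4)
  expect_true(fit$converged)
})

test_that("a constant target gives R2 = 0 for every family", {
  coh <- make_cohort(cohort_spec(30, model = "linear",
                                 coefficients = c(7, rep(0, 7)),
                                 noise_sd = 0, seed = 3))
  for (m in c("linear", "power", "exp", "sat_exp")) {
    fit <- suppressWarnings(fit_model(coh, "imr", m, n_starts = 3, n_perm = 0))
    expect_equal(fit$r2, 0)
  }
})

test_that("single-fraction exponential fit matches a dense grid search", {
  set.seed(9)
  f1 <- seq(0.05, 0.95, length.out = 10)
  y <- 50 * exp(-2 * f1) + rnorm(10, sd = 1)
  rec <- data.frame(f_1 = f1, imr = y)
  fit <- fit_model(rec, "imr", "exp", n_starts = 5, seed = 1, n_perm = 0)
  grid <- expand.grid(c0 = seq(30, 70, by = 0.25), c1 = seq(0.5, 3.5, by = 0.01))
  sse_grid <- min(vapply(seq_len(nrow(grid)), function(i)
    sum((y - grid$c0[i] * exp(-grid$c1[i] * f1))^2), numeric(1)))
  expect_lte(fit$sse, sse_grid + 1e-6)
  expect_equal(fit$sse, sse_grid, tolerance = 5e-3)  # grid-resolution limit
})

test_that("sample-size and column requirements are enforced", {
  coh <- make_cohort(cohort_spec(20, seed = 1))
  expect_error(fit_model(coh[1:6, ], "imr", "linear"), "at least k \\+ 2 = 9")
  expect_error(fit_model(coh, "mvo", "linear"), "complete records")
  expect_error(fit_model(data.frame(imr = 1:10), "imr", "linear"),
               "no k-fraction columns")
})

test_that("permutation p-values separate signal from noise", {
  ns <- noise_sd_from_range(cohort_spec(100, seed = 4), 0.1)
  coh <- make_cohort(cohort_spec(100, noise_sd = ns, seed = 4))
  fit <- fit_model(coh, "imr", "linear", seed = 1, n_perm = 199)
  expect_lte(fit$p_value, 0.01)   # strong true signal
  expect_lte(fit$p_f, 0.01)
  null <- coh
  null$imr <- withr::with_seed(5, sample(null$imr))
  pf <- replicate(5, NA_real_)
  for (i in 1:5) {
    null$imr <- withr::with_seed(50 + i, sample(coh$imr))
    pf[i] <- fit_model(null, "imr", "linear", seed = i, n_perm = 99)$p_value
  }
  expect_gt(max(pf), 0.1)        # shuffled targets are mostly non-significant
})

test_that("compare_models ranks families and marks notability", {
  ns <- noise_sd_from_range(cohort_spec(200, seed = 6), 0.1)
  coh <- make_cohort(cohort_spec(200, noise_sd = ns, seed = 6))
  tab <- compare_models(coh, "imr", n_starts = 5, seed = 1)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$model, c("linear", "power", "exp", "sat_exp"))
  expect_true(all(diff(tab$r2) <= 0))                # ranked by R2
  r2 <- setNames(tab$r2, tab$model)
  expect_gte(r2[["exp"]], r2[["linear"]] - 1e-9)     # generative family wins
  expect_true(tab$notable[1])
  # notability threshold is strict at 0.2
  tab0 <- compare_models(make_cohort(cohort_spec(30, model = "linear",
                                                 coefficients = c(7, rep(0, 7)),
                                                 noise_sd = 0, seed = 3)),
                         "imr", n_starts = 2, seed = 1)
  expect_false(any(tab0$notable))
})
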