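test_that("KM median of uncensored 1..7 is the sample median", {
  d <- data.frame(time = 1:7, event = 1)
  km <- km_estimate(d)
  expect_equal(km$median_months, 4)
  expect_equal(km$n, 7L)
  expect_equal(km$n_events, 7L)
})

test_that("KM equals the hand-computed product limit on the censored example", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 0, 1, 1, 0, 1))
  km <- km_estimate(d)
  oracle <- km_oracle(d$time, d$event)
  expect_equal(oracle$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0))
  got <- km$curve$surv[match(oracle$time, km$curve$time)]
  expect_equal(got, oracle$surv, tolerance = 1e-12)
  # median = smallest time with S(t) <= 0.5, read from that curve
  expect_equal(km$median_months, 4)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(5)
  d <- data.frame(time = rexp(200) + 0.1, event = 1)
  km <- km_estimate(d)
  emp <- vapply(km$curve$time, function(t) mean(d$time > t), numeric(1))
  expect_equal(km$curve$surv, emp, tolerance = 1e-12)
})

test_that("degenerate KM inputs are handled", {
  expect_error(km_estimate(data.frame(time = numeric(0), event = integer(0))),
               "no records")
  expect_error(km_estimate(data.frame(time = c(0, 1), event = c(1, 1))),
               "positive")
  km <- km_estimate(data.frame(time = c(2, 3, 4), event = 0))
  expect_equal(km$median_months, Inf)
  expect_true(is.na(km$ci_high))
})

test_that("a covariate independent of survival has HR compatible with 1", {
  set.seed(17)
  n <- 10000
  d <- data.frame(time = rexp(n), event = 1,
                  center = sample(1:6, n, TRUE), x = rnorm(n))
  fit <- cox_fit(d, "x")
  expect_lt(fit$ci_low, 1)
  expect_gt(fit$ci_high, 1)
})

test_that("a two-group rate ratio e^0.7 is recovered and matches the grid-search oracle", {
  set.seed(29)
  n <- 20000
  x <- rep(0:1, n / 2)
  d <- data.frame(time = rexp(n, rate = exp(0.7 * x)), event = 1,
                  center = sample(1:6, n, TRUE), x = x)
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$coef - 0.7), 3 * fit$robust_se)

  # independent maximizer of the hand-written partial likelihood on a
  # 200-subject subsample, single centre so stratification is a no-op
  sub <- d[sample(n, 200), ]
  sub$center <- 1L
  sub_fit <- cox_fit(sub, "x", robust = FALSE)
  opt <- optimize(function(b) partial_loglik_oracle(sub$time, sub$event, sub$x, b),
                  interval = c(-3, 3), maximum = TRUE, tol = 1e-9)
  expect_lt(abs(sub_fit$coef - opt$maximum), 1e-4)
})

test_that("Cox estimates are invariant to time rescaling and covariate shifts", {
  d <- simulate_cohort(cohort_config(n = 2000, rng_seed = 13))
  f1 <- cox_fit(d, "bsi")
  d_days <- d; d_days$time <- d$time * 30.4
  f2 <- cox_fit(d_days, "bsi")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
  d_shift <- d; d_shift$bsi <- d$bsi + 100
  f3 <- cox_fit(d_shift, "bsi")
  expect_equal(f1$coef, f3$coef, tolerance = 1e-8)
  expect_equal(f1$robust_se, f3$robust_se, tolerance = 1e-8)
})

test_that("per-subject sandwich SE matches the model SE under correct specification", {
  set.seed(47)
  n <- 4000
  x <- rnorm(n)
  d <- data.frame(time = rexp(n, rate = exp(0.4 * x)), event = 1,
                  center = 1L, x = x)
  rob <- cox_fit(d, "x", robust = TRUE, cluster = "subject")
  mod <- cox_fit(d, "x", robust = FALSE)
  expect_equal(rob$robust_se, mod$robust_se, tolerance = 0.1)
})

test_that("constant covariates and degenerate event structures are refused", {
  d <- simulate_cohort(cohort_config(n = 100, rng_seed = 3))
  d$flat <- 1
  expect_error(cox_fit(d, "flat"), "constant")
  expect_error(cox_fit(d, "nope"), "not present")
  d1 <- d; d1$time <- 1; d1$event <- 1
  expect_error(cox_fit(d1, "bsi"), "distinct event times")
})

test_that("fixed-effects centre adjustment gives results close to stratification", {
  d <- simulate_cohort(cohort_config(n = 5000, rng_seed = 19))
  fs <- cox_fit(d, "bsi", center_adjustment = "stratified")
  ff <- cox_fit(d, "bsi", center_adjustment = "fixed_effects")
  expect_equal(ff$covariate, "bsi")        # centre indicators are not reported
  expect_lt(abs(fs$coef - ff$coef), 3 * fs$robust_se)
})

test_that("stepwise AIC handles the empty candidate list", {
  d <- simulate_cohort(cohort_config(n = 200, rng_seed = 23))
  sel <- stepwise_aic(d, character(0))
  expect_equal(sel$selected, character(0))
  expect_equal(nrow(sel$trajectory), 0L)
  expect_null(sel$final)
})

test_that("stepwise AIC always enters a strong true effect first and rarely noise", {
  # A forward-AIC rule admits an independent noise covariate whenever its
  # chance chi-square improvement exceeds 2 (probability ~0.157), so the
  # guaranteed behaviour is: the strong covariate enters first every time,
  # the noise covariate only in a minority of replicate draws.
  cfg <- cohort_config(n = 5000, rng_seed = 1, mode = "MARGINAL",
                       marginal_covariate = "bsi")
  d <- simulate_cohort(cfg)
  set.seed(101)
  noise_in <- 0L
  for (rep in 1:6) {
    d$noise <- rnorm(nrow(d))
    sel <- stepwise_aic(d, c("noise", "bsi"))
    expect_equal(sel$selected[1], "bsi")
    noise_in <- noise_in + ("noise" %in% sel$selected)
    expect_true(all(diff(c(sel$aic_null, sel$trajectory$aic)) < 0))
  }
  expect_lte(noise_in, 3L)
})

test_that("stepwise AIC is invariant to candidate order without ties", {
  d <- simulate_cohort(cohort_config(n = 5000, rng_seed = 29))
  cands <- c("gleason", "hb", "talp", "psa", "bsi")
  a <- stepwise_aic(d, cands)
  b <- stepwise_aic(d, rev(cands))
  expect_setequal(a$selected, b$selected)
  expect_equal(sort(a$trajectory$aic), sort(b$trajectory$aic), tolerance = 1e-8)
  expect_true(all(diff(c(a$aic_null, a$trajectory$aic)) < 0))
})

test_that("candidates whose fit fails are recorded and skipped", {
  d <- simulate_cohort(cohort_config(n = 2000, rng_seed = 31))
  d$flat <- 0
  sel <- stepwise_aic(d, c("flat", "bsi"))
  expect_true("flat" %in% names(sel$failed))
  expect_true("bsi" %in% sel$selected)
})

test_that("the univariate table stacks one row per covariate", {
  d <- simulate_cohort(cohort_config(n = 2000, rng_seed = 37))
  tab <- cox_univariate_table(d, c("age", "hb", "bsi"))
  expect_equal(tab$covariate, c("age", "hb", "bsi"))
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
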