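test_that("follow-up construction converts days to months at 30.4375", {
  fu <- build_followup(as.Date("2020-01-01"),
                       as.Date("2020-01-01") + 365.25,
                       as.Date("2022-01-01"))
  expect_equal(fu$followup_months, 12.0)
  expect_equal(fu$event, 1L)
  fu2 <- build_followup(as.Date("2020-01-01"), as.Date(NA),
                        as.Date("2020-01-01") + 91.3125)
  expect_equal(fu2$followup_months, 3.0)
  expect_equal(fu2$event, 0L)
  expect_error(build_followup(as.Date("2020-06-01"), as.Date("2020-01-01"),
                              as.Date("2021-01-01")),
               "precedes")
})

test_that("the product-limit estimator matches hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$estimate, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # censoring removes subjects from the risk set
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$estimate, c(2 / 3, 2 / 3, 0))

  # no events: survival stays at 1
  km3 <- km_estimate(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km3$estimate == 1))

  # non-increasing from S(0) = 1 on random data
  set.seed(70)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    km4 <- km_estimate(round(rexp(n, 0.1), 1), rbinom(n, 1, 0.7))
    expect_true(all(diff(c(1, km4$estimate)) <= 1e-12))
  }
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("the log-rank test behaves at the null and under separation", {
  lr0 <- log_rank(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                  rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-10)
  expect_equal(lr0$p_value, 1, tolerance = 1e-10)

  set.seed(71)
  t1 <- rexp(500, 0.01); t2 <- rexp(500, 0.03)
  lr <- log_rank(c(t1, t2), rep(1, 1000), rep(c("lo", "hi"), each = 500))
  expect_lt(lr$p_value, 0.001)
  expect_gte(lr$statistic, 0)
  expect_error(log_rank(1:3, c(1, 1, 1), rep("a", 3)), "two non-empty")
})

test_that("Cox fits recover known hazards and expose Harrell's C", {
  set.seed(72)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.02 * exp(log(2) * x))
  tab <- tibble::tibble(time = t_ev, event = 1L, x = x)
  fit <- cox_fit(tab, "x")
  expect_equal(fit$table$estimate[1], log(2), tolerance = 0.1)
  expect_equal(fit$table$hr[1], exp(fit$table$estimate[1]))
  expect_true(fit$table$hr_low[1] < fit$table$hr[1],
              fit$table$hr[1] < fit$table$hr_high[1])

  # a covariate independent of the hazard: null recovery, CI covers 0
  z <- rnorm(n)
  tab$z <- z
  fit0 <- cox_fit(tab, "z")
  expect_lt(abs(fit0$table$estimate[1]), 0.1)
  expect_true(fit0$table$hr_low[1] < 1 && fit0$table$hr_high[1] > 1)

  # perfectly anti-ordered risk score gives C = 0
  tab2 <- tibble::tibble(time = 1:20, event = 1L, lp = 1:20)
  expect_equal(c_index(tab2$lp, tab2$time, tab2$event), 0)

  expect_error(cox_fit(tibble::tibble(time = 1:3, event = 0L, x = 1:3), "x"),
               "no events")
  expect_error(cox_fit(tibble::tibble(time = 1:3, event = 1L, x = 1), "x"),
               "constant")
})

test_that("c_index equals the brute-force comparable-pairs oracle", {
  expect_equal(c_index(20:1, 1:20, rep(1, 20)), 1.0)
  expect_equal(c_index(rep(2, 20), 1:20, rep(1, 20)), 0.5)
  set.seed(73)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    times <- round(rexp(n, 0.1), sample(0:1, 1))
    events <- rbinom(n, 1, 0.6)
    if (sum(events) == 0) events[1] <- 1L
    lp <- round(rnorm(n), 1)
    expect_equal(c_index(lp, times, events), cindex_brute(lp, times, events))
  }
  # a random predictor sits at chance level
  set.seed(74)
  expect_equal(c_index(rnorm(1000), rexp(1000, 0.1), rep(1, 1000)), 0.5,
               tolerance = 0.05)
  expect_error(c_index(1:3, 1:3, c(0, 0, 0)), "comparable")
})

test_that("c_index agrees with the survival package's concordance", {
  set.seed(75)
  for (i in 1:20) {
    n <- 80
    times <- rexp(n, 0.05)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) events[1] <- 1L
    lp <- rnorm(n)
    ref <- survival::concordance(survival::Surv(times, events) ~ lp,
                                 reverse = TRUE)$concordance
    expect_equal(c_index(lp, times, events), unname(ref))
  }
})

test_that("the paired bootstrap separates signal from noise covariates", {
  set.seed(76)
  n <- 500
  risk <- rnorm(n)
  noise <- rnorm(n)
  t_ev <- rexp(n, 0.02 * exp(1.2 * risk))
  cens <- runif(n, 0, 120)
  tab <- tibble::tibble(time = pmin(t_ev, cens),
                        event = as.integer(t_ev <= cens),
                        risk = risk, noise = noise)

  # adding pure noise: the delta-C interval straddles 0
  h0 <- paired_bootstrap_cindex(tab, "risk", c("risk", "noise"), B = 300,
                                seed = 2)
  expect_lt(h0$ci_low, 0 + 1e-9)
  expect_gt(h0$ci_high, 0 - 1e-9)

  # adding the true driver: positive delta-C, significant
  h1 <- paired_bootstrap_cindex(tab, "noise", c("noise", "risk"), B = 300,
                                seed = 3)
  expect_gt(h1$delta_mean, 0)
  expect_lt(h1$p_value, 0.05)
  expect_gt(h1$c_full, h1$c_base)

  # determinism and the p-value floor
  h2 <- paired_bootstrap_cindex(tab, "noise", c("noise", "risk"), B = 300,
                                seed = 3)
  expect_identical(h1$deltas, h2$deltas)
  expect_identical(h1$p_value, h2$p_value)
  expect_gte(h1$p_value, 2 / 300)

  expect_error(paired_bootstrap_cindex(tab, "risk", "risk"), "strictly")

  # the fixed-fit variant also runs and agrees in sign
  h3 <- paired_bootstrap_cindex(tab, "noise", c("noise", "risk"), B = 100,
                                seed = 4, refit = FALSE)
  expect_gt(h3$delta_mean, 0)
})

test_that("bootstrap p-values are roughly calibrated under the null", {
  # noise covariate added to a real predictor: rejections at alpha = 0.05
  # should stay near the nominal rate (bootstrap p-values run slightly
  # anticonservative; the bound allows for that and for binomial noise)
  set.seed(77)
  rejections <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    n <- 120
    risk <- rnorm(n)
    t_ev <- rexp(n, 0.02 * exp(0.8 * risk))
    cens <- runif(n, 0, 150)
    tab <- tibble::tibble(time = pmin(t_ev, cens),
                          event = as.integer(t_ev <= cens),
                          risk = risk, noise = rnorm(n))
    cmp <- paired_bootstrap_cindex(tab, "risk", c("risk", "noise"), B = 200,
                                   seed = r)
    if (cmp$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 7L)
})

test_that("the survival table derivation excludes unknown stages with a log", {
  clin <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    nhg = 2L,
    age = c(50, 60, 55, 58),
    t_stage = c("1", "X", "2", "3"),
    n_stage = c("0", "0", "X", "1"),
    subtype = "ER+/HER2-",
    followup_months = c(10, 20, 30, NA),
    event = c(1L, 0L, 1L, 0L))
  strata <- tibble::tibble(patient_id = c("A", "B", "C", "D"), score = 0.5,
                           threshold = 0.5,
                           drg_label = factor(c("DRG2-", "DRG2+", "DRG2-", "DRG2+"),
                                              levels = c("DRG2-", "DRG2+")))
  tab <- make_survival_table(clin, strata)
  expect_equal(tab$patient_id, "A")
  exc <- attr(tab, "exclusions")
  expect_setequal(exc, c("B", "C", "D"))
  expect_equal(unname(tab$t2), 0)
  expect_equal(unname(tab$drg), 0)
})
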