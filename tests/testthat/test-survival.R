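records <- function(time, event, reason, device = "CRT-P") {
  data.frame(patient_id = as.character(seq_along(time)), time_years = time,
             event = event, censor_reason = reason, device = device,
             stringsAsFactors = FALSE)
}

test_that("endpoints encode the study censoring rules", {
  recs <- records(c(3, 2, 10), c(TRUE, FALSE, FALSE),
                  c("none", "htx", "admin"))
  ac <- apply_endpoint(recs, endpoint_spec("all_cause_death"))
  expect_equal(ac$event, c(TRUE, FALSE, FALSE))
  comp <- apply_endpoint(recs, endpoint_spec("composite"))
  expect_equal(comp$event, c(TRUE, TRUE, FALSE))
  expect_equal(comp$time, ac$time)
  expect_error(apply_endpoint(records(1, FALSE, "weird")), "weird")
})

test_that("the composite endpoint never has fewer events", {
  co <- generate_cohort(default_cohort_config(2000, seed = 12))
  ac <- apply_endpoint(co$survival, endpoint_spec("all_cause_death"))
  comp <- apply_endpoint(co$survival, endpoint_spec("composite"))
  expect_gte(sum(comp$event), sum(ac$event))
})

test_that("the product-limit estimate matches the hand example", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km_at(km, 1), 2 / 3)
  expect_equal(km_at(km, 2), 1 / 3)
  expect_equal(km_at(km, 3), 1 / 3)
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$ci_lo <= km$surv + 1e-12 & km$surv <= km$ci_hi + 1e-12))
})

test_that("no events means flat survival with zero variance", {
  km <- km_estimate(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_true(all(km$greenwood_var == 0))
})

test_that("KM is consistent for exponential data", {
  set.seed(31)
  lambda <- 0.4
  t <- rexp(5000, lambda)
  km <- km_estimate(t, rep(1, 5000))
  expect_lt(abs(km_at(km, 1 / lambda) - exp(-1)), 0.02)
})

test_that("reverse KM recovers the follow-up distribution", {
  # everyone administratively censored at 8 years
  rk <- reverse_km(rep(8, 40), rep(FALSE, 40))
  expect_equal(rk$median, 8)
  expect_length(rk$undefined, 0)
  # deaths only: the follow-up curve never drops
  rk2 <- reverse_km(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_true("median" %in% rk2$undefined)
  expect_true(is.na(rk2$median))
  # admin censoring at year 12 dominates late follow-up
  set.seed(8)
  t <- pmin(rexp(4000, 0.05), 12)
  rk3 <- reverse_km(t, t < 12)
  expect_equal(rk3$median, 12, tolerance = 1e-8)
})

test_that("identical arms give zero ARR and no significance", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  arr <- arr_table(km, km, 1:3)
  expect_equal(arr$arr, rep(0, 3))
  expect_false(any(arr$significant))
})

test_that("ARR arithmetic and the CI significance rule agree", {
  # S_P(5) = 0.52 vs S_D(5) = 0.57 with tiny variance: 5 pp, significant
  mk <- function(s5) {
    structure(list(time = 5, n_risk = 1e6, n_event = 1, surv = s5,
                   greenwood_var = 1e-8, ci_lo = s5 - 1e-4,
                   ci_hi = s5 + 1e-4, n = 1e6), class = "km_curve")
  }
  arr <- arr_table(mk(0.52), mk(0.57), 5)
  expect_equal(arr$arr, 5, tolerance = 1e-9)
  expect_true(arr$significant)
  # on random curves the flag always matches "0 outside the CI"
  for (seed in 1:10) {
    set.seed(seed)
    a <- km_estimate(rexp(80, 0.3), rbinom(80, 1, 0.7))
    b <- km_estimate(rexp(80, 0.2), rbinom(80, 1, 0.7))
    tab <- arr_table(a, b, 1:5)
    ok <- tab$available
    expect_equal(tab$significant[ok],
                 (tab$ci_lo[ok] > 0 | tab$ci_hi[ok] < 0))
  }
  # horizon beyond support flagged unavailable
  km <- km_estimate(c(1, 2), c(1, 1))
  far <- arr_table(km, km, 50)
  expect_false(far$available)
})

test_that("log-rank is null on identical arms and powerful when separated", {
  t <- c(1, 3, 4, 7, 9)
  e <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(t, e, t, e)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  set.seed(14)
  ta <- rexp(500, 0.3)
  tb <- rexp(500, 0.1)
  lr2 <- logrank_test(ta, rep(1, 500), tb, rep(1, 500))
  expect_lt(lr2$p, 0.001)
})

test_that("Cox estimates are order-invariant and drop constant columns", {
  set.seed(22)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.2 * exp(-0.5 * x))
  e <- rep(1L, n)
  covs <- data.frame(x = x, z = rnorm(n), flat = rep(0, n))
  fit <- cox_fit(t, e, covs)
  expect_equal(fit$dropped, "flat")
  expect_setequal(fit$coefficients$term, c("x", "z"))
  perm <- sample(n)
  fit_p <- cox_fit(t[perm], e[perm], covs[perm, ])
  expect_equal(fit$coefficients$coef, fit_p$coefficients$coef,
               tolerance = 1e-8)
  expect_error(cox_fit(t, e, data.frame(x = c(NA, x[-1]))), "complete")
})

test_that("Cox and the cumulative-hazard ratio agree at large n", {
  set.seed(33)
  n <- 10000
  arm <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.2 * exp(log(0.7) * arm))
  fit <- cox_fit(t, rep(1L, n), data.frame(arm = arm))
  f0 <- survival::survfit(survival::Surv(t[arm == 0], rep(1, n / 2)) ~ 1)
  f1 <- survival::survfit(survival::Surv(t[arm == 1], rep(1, n / 2)) ~ 1)
  haz_at <- function(f, tt) {
    f$cumhaz[max(which(f$time <= tt))]
  }
  tt <- quantile(t, 0.5)
  ratio <- haz_at(f1, tt) / haz_at(f0, tt)
  expect_lt(abs(fit$coefficients$hr - ratio) / ratio, 0.05)
})

test_that("log-rank p and univariable Cox Wald p are of the same order", {
  set.seed(44)
  n <- 800
  arm <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.25 * exp(log(0.75) * arm))
  e <- rep(1L, n)
  lr <- logrank_test(t[arm == 0], e[arm == 0], t[arm == 1], e[arm == 1])
  cx <- cox_fit(t, e, data.frame(arm = arm))
  expect_lt(abs(log10(lr$p) - log10(cx$coefficients$p)), 1)
})

test_that("device_cox supports both published adjustment sets", {
  co <- generate_cohort(default_cohort_config(3000, seed = 17))
  m1 <- device_cox(co$survival, adjustment = "af")
  m2 <- device_cox(co$survival, adjustment = "etiology")
  expect_setequal(m1$multivariable$coefficients$term,
                  c("crtd", "age", "sex", "af", "va"))
  expect_setequal(m2$multivariable$coefficients$term,
                  c("crtd", "age", "sex", "ischemic", "va"))
  expect_equal(m1$univariable$coefficients$coef,
               m2$univariable$coefficients$coef)
})
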