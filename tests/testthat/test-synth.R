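test_that("an empty cohort request yields empty, well-formed containers", {
  cfg <- cohort_config(n_patients = 0, feature_specs = list(
    continuous_feature("x", 0, 1)
  ))
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$features$values), 0)
  expect_equal(ncol(co$features$values), 1)
  expect_equal(nrow(co$survival), 0)
  expect_length(co$latent, 0)
})

test_that("the same config and seed reproduce the cohort exactly", {
  cfg <- default_cohort_config(n_patients = 300, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
})

test_that("invalid config values raise errors naming the field", {
  expect_error(cohort_config(10, baseline_hazard = 0), "baseline_hazard")
  expect_error(cohort_config(10, device_probs = 1.2), "device_probs")
  expect_error(cohort_config(10, admin_censor_years = -1), "admin_censor_years")
  expect_error(cohort_config(10, n_groups = 2, group_weights = c(0.7, 0.7)),
               "group_weights")
  expect_error(
    cohort_config(10, feature_specs = list(binary_feature("bad", 2))),
    "bad"
  )
})

test_that("latent group proportions follow the configured weights", {
  w <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  cfg <- cohort_config(n_patients = 10000, n_groups = 5, group_weights = w,
                       seed = 5,
                       feature_specs = list(continuous_feature("x", 0, 1)))
  co <- generate_cohort(cfg)
  tab <- tabulate(co$latent, 5)
  expect_gt(chisq.test(tab, p = w)$p.value, 0.001)
})

test_that("realized missingness matches the configured MCAR rates", {
  specs <- list(continuous_feature("a", 0, 1), continuous_feature("b", 0, 1),
                binary_feature("c", 0.5))
  cfg <- cohort_config(n_patients = 10000, feature_specs = specs,
                       missing_rates = c(a = 0.1, b = 0.35), seed = 9)
  co <- generate_cohort(cfg)
  frac <- missing_fraction(co$features)
  expect_lt(abs(frac[["a"]] - 0.10), 0.02)
  expect_lt(abs(frac[["b"]] - 0.35), 0.02)
  expect_equal(frac[["c"]], 0)
})

test_that("appended discard features exceed the 40% missingness screen", {
  cfg <- cohort_config(n_patients = 200, extra_discard_features = 3, seed = 2,
                       feature_specs = list(continuous_feature("x", 0, 1)))
  co <- generate_cohort(cfg)
  frac <- missing_fraction(co$features)
  expect_true(all(frac[paste0("discard_", 1:3)] >= 0.40))
})

test_that("uncensored survival matches the exponential closed form", {
  lambda <- 0.25
  cfg <- cohort_config(n_patients = 8000, baseline_hazard = lambda,
                       admin_censor_years = 1e6, seed = 3,
                       feature_specs = list(continuous_feature("x", 0, 1)))
  co <- generate_cohort(cfg)
  expect_true(all(co$survival$event))
  km <- km_estimate(co$survival$time_years, co$survival$event)
  for (t in c(0.5, 1, 2) / lambda) {
    expect_lt(abs(km_at(km, t) - exp(-lambda * t)), 0.02)
  }
})

test_that("event flags and censor reasons are mutually consistent", {
  cfg <- default_cohort_config(n_patients = 2000, seed = 4)
  co <- generate_cohort(cfg)
  s <- co$survival
  expect_true(all(s$censor_reason[s$event] == "none"))
  expect_true(all(s$censor_reason[!s$event] != "none"))
  expect_true(all(s$time_years > 0 & is.finite(s$time_years)))
  expect_true(all(s$censor_reason[s$censor_reason == "crtd_upgrade"] %in%
                    "crtd_upgrade" & s$device[s$censor_reason == "crtd_upgrade"] == "CRT-P"))
})

test_that("cohort CSV round trip preserves values and missingness", {
  cfg <- default_cohort_config(n_patients = 50, seed = 8)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$features$values, co$features$values)
  expect_equal(back$features$missing_mask, co$features$missing_mask)
  expect_equal(back$survival$time_years, co$survival$time_years)
  expect_equal(back$survival$event, co$survival$event)
})

test_that("a YAML config reproduces the in-memory config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_patients = 40, n_groups = 2, group_weights = c(0.4, 0.6),
    feature_specs = list(
      list(name = "x", type = "continuous", mean = c(0, 2), sd = c(1, 1)),
      list(name = "flag", type = "binary", p = c(0.2, 0.8))
    ),
    device_probs = c(0.3, 0.7), baseline_hazard = c(0.1, 0.2),
    device_log_hr = c(0, -0.2), admin_censor_years = 10,
    missing_rates = list(x = 0.1), seed = 21
  ), path)
  cfg <- cohort_config_from_yaml(path)
  ref <- cohort_config(
    n_patients = 40, n_groups = 2, group_weights = c(0.4, 0.6),
    feature_specs = list(continuous_feature("x", c(0, 2), c(1, 1)),
                         binary_feature("flag", c(0.2, 0.8))),
    device_probs = c(0.3, 0.7), baseline_hazard = c(0.1, 0.2),
    device_log_hr = c(0, -0.2), admin_censor_years = 10,
    missing_rates = c(x = 0.1), seed = 21
  )
  expect_identical(generate_cohort(cfg), generate_cohort(ref))
})
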