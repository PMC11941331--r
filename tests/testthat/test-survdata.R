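test_that("AR(1) covariance has the power-decay structure", {
  expect_equal(make_ar1_covariance(1, 0.5), matrix(1, 1, 1))
  expect_equal(make_ar1_covariance(2, 0.5),
               matrix(c(1, 0.5, 0.5, 1), 2, 2))
  s3 <- make_ar1_covariance(3, 0.5)
  expect_equal(s3[1, 3], 0.25)
  expect_true(isSymmetric(s3))
  expect_equal(diag(s3), rep(1, 3))
  expect_true(min(eigen(make_ar1_covariance(40, 0.9))$values) > 0)
  expect_error(make_ar1_covariance(0, 0.5), "positive integer")
  expect_error(make_ar1_covariance(3, 1), "rho")
})

test_that("true coefficient vector lays out strong, weak and null blocks", {
  cfg <- sim_config(n = 50, p = 10, p1 = 3, n_weak = 4, seed = 1)
  tb <- make_true_beta(cfg)
  expect_equal(tb$beta, c(8, 9, 10, 1, 0.8, 0.5, 0.2, 0, 0, 0))
  expect_equal(tb$partition$strong, 1:3)
  expect_equal(tb$partition$weak, 4:7)
  expect_equal(tb$partition$null, 8:10)

  cfg0 <- sim_config(n = 50, p = 5, p1 = 3, n_weak = 0, seed = 1)
  tb0 <- make_true_beta(cfg0)
  expect_equal(tb0$beta, c(8, 9, 10, 0, 0))
  expect_length(tb0$partition$weak, 0)

  cfg6 <- sim_config(n = 50, p = 12, p1 = 3, n_weak = 6, seed = 1)
  expect_equal(make_true_beta(cfg6)$beta[4:9], c(1, 0.8, 0.5, 0.2, 0.2, 0.2))

  expect_error(sim_config(n = 50, p = 5, p1 = 3, n_weak = 4), "exceed")
})

test_that("signal partition enforces disjointness and coverage", {
  expect_error(signal_partition(1:3, 3:4, 5:6, 6), "disjoint")
  expect_error(signal_partition(1:3, 4:5, integer(0), 6), "partition")
  sp <- signal_partition(c(2, 1), 3, 4:6, 6)
  expect_equal(sp$strong, 1:2)
})

test_that("censoring calibration solves the closed-form root for beta = 0", {
  # with beta = 0, T ~ Exp(1) and the censoring probability is (1-e^-c)/c
  for (target in c(0.15, 0.25)) {
    oracle <- uniroot(function(cc) (1 - exp(-cc)) / cc - target,
                      c(1e-6, 100), tol = 1e-12)$root
    got <- calibrate_censoring(rep(0, 3), diag(3), target, seed = 1)
    expect_equal(as.numeric(got), oracle, tolerance = 1e-4)
    expect_lt(abs(as.numeric(got) - oracle), 5e-4) # 3-decimal agreement
  }
})

test_that("calibration is consistent across seeds and errors on bad targets", {
  beta <- c(1, -0.5, 0.25)
  sg <- make_ar1_covariance(3, 0.5)
  c1 <- as.numeric(calibrate_censoring(beta, sg, 0.25, seed = 1))
  c2 <- as.numeric(calibrate_censoring(beta, sg, 0.25, seed = 99))
  expect_lt(abs(log(c1) - log(c2)), 0.15) # probe-sampling noise only
  expect_error(calibrate_censoring(beta, sg, 1.5), "target")
})

test_that("simulated data honour the configured design", {
  cfg <- sim_config(n = 400, p = 8, p1 = 3, n_weak = 3,
                    strong_values = c(0.5, -0.5, 0.25),
                    weak_values = c(0.1, 0.1, 0.1),
                    censor_rate = 0.25, seed = 7)
  sim <- simulate_survival(cfg)
  expect_s3_class(sim$data, "surv_dataset")
  expect_equal(sim$data$n, 400)
  # delta and Y consistent with the stored latent draws
  expect_equal(sim$data$events,
               as.numeric(sim$latent$event_time <= sim$latent$censor_time))
  expect_equal(sim$data$times,
               pmin(sim$latent$event_time, sim$latent$censor_time))
  # seeded determinism
  sim2 <- simulate_survival(cfg, c_censor = sim$c_censor)
  expect_identical(sim$data$covariates, sim2$data$covariates)
  expect_identical(sim$data$times, sim2$data$times)
})

test_that("achieved censoring tracks the target and beta = 0 times have mean 1", {
  cfg <- sim_config(n = 500, p = 4, p1 = 3, n_weak = 0,
                    strong_values = rep(0, 3), censor_rate = 0.15, seed = 3)
  rates <- tt_mean <- numeric(50)
  for (r in 1:50) {
    cfg$seed <- substream_seed(3, paste0("cens-check", r))
    sim <- simulate_survival(cfg)
    rates[r] <- sim$achieved_censoring
    tt_mean[r] <- mean(sim$latent$event_time)
  }
  expect_lt(abs(mean(rates) - 0.15), 0.02)
  expect_lt(abs(mean(tt_mean) - 1), 0.05)
  # higher target gives more censoring on the same stream
  cfg25 <- cfg; cfg25$censor_rate <- 0.25
  sim15 <- simulate_survival(cfg)
  sim25 <- simulate_survival(cfg25)
  expect_gt(sim25$achieved_censoring, sim15$achieved_censoring)
})

test_that("sample covariance of the design converges to Sigma", {
  cfg <- sim_config(n = 5000, p = 6, p1 = 3, n_weak = 0, seed = 11)
  sim <- simulate_survival(cfg, c_censor = 1e12)
  emp <- cov(sim$data$covariates)
  expect_lt(max(abs(emp - make_ar1_covariance(6, 0.5))), 0.05)
})

test_that("dataset validation rejects malformed inputs", {
  expect_error(surv_dataset(c(1, -1), c(1, 0), matrix(0, 2, 1)), "positive")
  expect_error(surv_dataset(c(1, 2), c(1, 2), matrix(0, 2, 1)), "0.*1")
  expect_error(surv_dataset(c(1, 2), c(1, 0), matrix(0, 3, 1)), "common length")
})

test_that("survival CSV round-trip is lossless", {
  d <- make_small_data(n = 30, p = 3)
  path <- tempfile(fileext = ".csv")
  write_survival_csv(d, path)
  d2 <- read_survival_csv(path)
  expect_equal(d2$times, d$times, tolerance = 1e-14)
  expect_equal(d2$events, d$events)
  expect_equal(d2$covariates, d$covariates, tolerance = 1e-14)
  # schema validation names the offending column and line
  bad <- read.csv(path)
  bad$status[3] <- 2
  badpath <- tempfile(fileext = ".csv")
  write.csv(bad, badpath, row.names = FALSE)
  expect_error(read_survival_csv(badpath), "status")
})
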