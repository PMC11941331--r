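test_that("log partial likelihood matches closed forms", {
  d <- make_small_data()
  # beta = 0: l = -sum over events of log |R(t_i)|
  rs <- vapply(which(d$events == 1), function(i) sum(d$times >= d$times[i]),
               numeric(1))
  expect_equal_num(log_partial_likelihood(rep(0, d$p), d), -sum(log(rs)))

  # two subjects, one event: l(b) = b - log(e^b + 1)
  d2 <- make_two_subject_data()
  for (b in c(-2, 0, 0.7, 3)) {
    expect_equal_num(log_partial_likelihood(b, d2), b - log(exp(b) + 1))
  }

  # invariance to covariate location shifts
  b <- c(0.5, -0.2, 0.1, 0, 0.4)
  shifted <- surv_dataset(d$times, d$events,
                          sweep(d$covariates, 2, c(3, -1, 0, 2, 5), "+"))
  expect_equal_num(log_partial_likelihood(b, shifted),
                   log_partial_likelihood(b, d), tol = 1e-9)

  expect_error(log_partial_likelihood(rep(0, 3), d), "length")
  all_cens <- surv_dataset(d$times, rep(0, d$n), d$covariates)
  expect_error(log_partial_likelihood(rep(0, d$p), all_cens), "censored")
})

test_that("score and information match finite differences", {
  d <- make_small_data(n = 60, p = 4, beta = c(0.6, -0.4, 0.2, 0))
  beta <- c(0.3, -0.1, 0.25, -0.5)
  si <- score_and_information(beta, d)
  h <- 1e-6
  fd <- vapply(1:4, function(j) {
    e <- replace(rep(0, 4), j, h)
    (log_partial_likelihood(beta + e, d) -
       log_partial_likelihood(beta - e, d)) / (2 * h)
  }, numeric(1))
  expect_equal(si$score, fd, tolerance = 1e-6, ignore_attr = TRUE)

  h2 <- 1e-4
  num_hess <- matrix(0, 4, 4)
  for (j in 1:4) for (k in 1:4) {
    ej <- replace(rep(0, 4), j, h2)
    ek <- replace(rep(0, 4), k, h2)
    num_hess[j, k] <- (log_partial_likelihood(beta + ej + ek, d) -
                         log_partial_likelihood(beta + ej - ek, d) -
                         log_partial_likelihood(beta - ej + ek, d) +
                         log_partial_likelihood(beta - ej - ek, d)) / (4 * h2^2)
  }
  expect_equal(si$info, -num_hess, tolerance = 1e-4, ignore_attr = TRUE)
  expect_true(isSymmetric(si$info, tol = 1e-10))
  expect_gt(min(eigen(si$info, symmetric = TRUE)$values), -1e-8)
})

test_that("partial likelihood is concave along random segments", {
  d <- make_small_data(n = 50, p = 3, beta = c(0.5, 0, -0.5))
  set.seed(9)
  for (r in 1:20) {
    b1 <- rnorm(3); b2 <- rnorm(3); t <- runif(1)
    lhs <- log_partial_likelihood(t * b1 + (1 - t) * b2, d)
    rhs <- t * log_partial_likelihood(b1, d) +
      (1 - t) * log_partial_likelihood(b2, d)
    expect_gte(lhs, rhs - 1e-10)
  }
})

test_that("the stabilized likelihood survives extreme linear predictors", {
  d <- make_small_data(n = 40, p = 2, beta = c(1, -1))
  big <- c(400, -350)
  ll <- log_partial_likelihood(big, d)
  expect_true(is.finite(ll))
  si <- score_and_information(big, d)
  expect_true(all(is.finite(si$score)))
  expect_true(all(is.finite(si$info)))
})

test_that("Newton MLE agrees with a grid search and recovers parameters", {
  d1 <- make_small_data(n = 150, p = 1, beta = 0.8, seed = 5)
  grid <- seq(-5, 5, by = 0.001)
  ll <- vapply(grid, function(b) log_partial_likelihood(b, d1), numeric(1))
  fit <- fit_mle(d1, 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 0.001)
  # stationarity at the optimum
  expect_lt(abs(score_and_information(fit$beta, d1)$score), 1e-7)

  # parameter recovery at large n: within 3 SEs per coordinate
  beta_true <- c(0.7, -0.4, 0.3)
  dbig <- make_small_data(n = 2000, p = 3, beta = beta_true, seed = 8)
  fitb <- fit_mle(dbig)
  se <- sqrt(diag(solve(score_and_information(fitb$beta, dbig)$info)))
  expect_true(all(abs(fitb$beta - beta_true) <= 3 * se))

  expect_error(fit_mle(d1, integer(0)), "nonempty")
})

test_that("MLE log likelihood at the fit dominates the null model", {
  d <- make_small_data(n = 100, p = 3, beta = c(0.5, 0.2, 0))
  fit <- fit_mle(d)
  expect_gte(fit$loglik, log_partial_likelihood(rep(0, 3), d))
})

test_that("penalized fits satisfy their limiting identities", {
  d <- make_small_data(n = 120, p = 5)
  # huge lambda: exact zero
  f0 <- fit_penalized(d, penalty_spec("lasso", lambda = 50))
  expect_true(all(f0$beta == 0))
  # lambda = 0 matches the unpenalized MLE
  fmle <- fit_mle(d)
  fl0 <- fit_penalized(d, penalty_spec("lasso", lambda = 0))
  expect_equal(fl0$beta, fmle$beta, tolerance = 1e-6)
  expect_error(penalty_spec("lasso", lambda = -1), "nonnegative")
})

test_that("a converged lasso fit satisfies the KKT subgradient conditions", {
  d <- make_small_data(n = 150, p = 6, beta = c(1, -0.8, 0.5, 0, 0, 0),
                       seed = 21)
  lam <- 0.08
  fit <- fit_penalized(d, penalty_spec("lasso", lambda = lam), thresh = 1e-14)
  # glmnet standardizes internally: check KKT on the standardized scale
  # (beta_std = sd * beta, so the score transforms by 1/sd), where the
  # subgradient of the scaled objective (1/n) l is bounded by lam
  sds <- apply(d$covariates, 2, function(v) sqrt(mean((v - mean(v))^2)))
  score <- score_and_information(fit$beta, d)$score / sds / d$n
  nz <- fit$beta != 0
  expect_true(all(abs(score[!nz]) <= lam + 1e-6))
  expect_equal(score[nz], lam * sign(fit$beta[nz]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("weighted ridge obeys its penalty limits", {
  d <- make_small_data(n = 120, p = 5)
  s1 <- c(1, 2)
  # r_n = 0 with p < n matches the full MLE
  f0 <- fit_weighted_ridge(d, s1, 0)
  expect_equal(f0$beta, fit_mle(d)$beta, tolerance = 1e-6)
  # off-set norm nonincreasing along an increasing r_n grid
  norms <- vapply(c(0.1, 1, 10, 100), function(rn) {
    sqrt(sum(fit_weighted_ridge(d, s1, rn)$beta[-s1]^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
  # huge r_n: complement dies, protected set approaches the restricted MLE
  fbig <- fit_weighted_ridge(d, s1, 1e7)
  expect_lt(sqrt(sum(fbig$beta[-s1]^2)), 1e-3)
  expect_equal(fbig$beta[s1], fit_mle(d, s1)$beta, tolerance = 1e-3,
               ignore_attr = TRUE)
  # p >= n without a penalty is refused
  wide <- make_small_data(n = 4, p = 5, beta = rep(0, 5))
  expect_error(fit_weighted_ridge(wide, 1, 0), "unidentifiable")
})

test_that("per-coordinate weights leave zero-weight coordinates unpenalized", {
  d <- make_small_data(n = 120, p = 4, beta = c(0.8, -0.5, 0, 0.3))
  pw <- c(0, 1, 1, 0)
  fit <- fit_penalized(d, penalty_spec("weighted_ridge", lambda = 1e7,
                                       per_coordinate_weights = pw))
  expect_lt(max(abs(fit$beta[pw == 1])), 1e-3)
  expect_equal(fit$beta[pw == 0], fit_mle(d, which(pw == 0))$beta,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("cross-validation is deterministic and stratifies folds by events", {
  d <- make_small_data(n = 100, p = 8, beta = c(1, -0.8, rep(0, 6)), seed = 31)
  cv1 <- cross_validate(d, "lasso", seed = 17)
  cv2 <- cross_validate(d, "lasso", seed = 17)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  foldid <- coxshrink:::stratified_foldid(d$events, 5, 17)
  ev_per_fold <- tapply(d$events, foldid, sum)
  expect_true(all(ev_per_fold >= 1))
  expect_error(coxshrink:::stratified_foldid(rep(0:1, c(95, 5)), 10, 1),
               "fewer events")
  # degenerate single-lambda grid returns that lambda
  cvg <- cross_validate(d, "lasso", lambda = c(0.3, 0.2), nfolds = 5, seed = 1)
  expect_true(cvg$lambda_min %in% c(0.3, 0.2))
})
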