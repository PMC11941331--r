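# small seeded survival datasets used across the suite

make_small_data <- function(n = 120, p = 5, beta = NULL, seed = 42,
                            censor_upper = 3) {
  if (is.null(beta)) beta <- c(0.8, -0.5, 0, 0.3, 0)[seq_len(p)]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  tt <- rexp(n, rate = exp(drop(x %*% beta)))
  cc <- runif(n, 0, censor_upper)
  surv_dataset(pmin(tt, cc), as.numeric(tt <= cc), x)
}

# tiny two-subject dataset with a single covariate: one event at t=1 with a
# risk set of two, giving l(b) = b - log(e^b + 1)
make_two_subject_data <- function() {
  surv_dataset(times = c(1, 2), events = c(1, 0),
               covariates = matrix(c(1, 0), ncol = 1))
}

expect_equal_num <- function(object, expected, tol = 1e-8) {
  expect_equal(unname(object), unname(expected), tolerance = tol)
}
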