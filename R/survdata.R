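#' Right-censored survival dataset
#'
#' Bundles follow-up times `Y = min(T, C)`, event indicators
#' `delta = I(T <= C)` and an `n x p` covariate matrix into a validated
#' container used by every fitting routine in the package.
#'
#' @param times Numeric vector of strictly positive follow-up times.
#' @param events Integer/numeric vector of event indicators, 0 (censored) or
#'   1 (event), same length as `times`.
#' @param covariates Numeric matrix with one row per subject.
#' @param feature_names Optional character vector of column labels; defaults
#'   to `x1..xp`.
#'
#' @return An object of class `surv_dataset`: a list with elements `times`,
#'   `events`, `covariates`, `n`, `p`.
#' @export
surv_dataset <- function(times, events, covariates, feature_names = NULL) {
  times <- as.numeric(times)
  events <- as.numeric(events)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- length(times)
  if (length(events) != n || nrow(covariates) != n) {
    stop("times, events and covariate rows must have a common length n")
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all follow-up times must be finite and strictly positive")
  }
  if (!all(events %in% c(0, 1))) {
    stop("event indicators must be 0 (censored) or 1 (event)")
  }
  if (any(!is.finite(covariates))) {
    stop("covariates must be finite")
  }
  p <- ncol(covariates)
  if (is.null(feature_names)) {
    feature_names <- paste0("x", seq_len(p))
  } else if (length(feature_names) != p) {
    stop("feature_names must have one entry per covariate column")
  }
  colnames(covariates) <- feature_names
  structure(
    list(times = times, events = events, covariates = covariates,
         n = n, p = p),
    class = "surv_dataset"
  )
}

#' @export
print.surv_dataset <- function(x, ...) {
  cat(sprintf("<surv_dataset> n = %d subjects, p = %d covariates, %d events (%.1f%% censored)\n",
              x$n, x$p, sum(x$events), 100 * mean(x$events == 0)))
  invisible(x)
}

#' Partition of covariate indices by signal strength
#'
#' @param strong,weak,null Integer index vectors for the strong (`S1`), weak
#'   (`S2`) and null sets. They must be pairwise disjoint and their union
#'   must be `1..p`.
#' @param p Total number of covariates.
#' @return An object of class `signal_partition`.
#' @export
signal_partition <- function(strong, weak, null, p) {
  strong <- as.integer(strong); weak <- as.integer(weak); null <- as.integer(null)
  all_idx <- c(strong, weak, null)
  if (anyDuplicated(all_idx)) {
    stop("strong, weak and null index sets must be pairwise disjoint")
  }
  if (!setequal(all_idx, seq_len(p))) {
    stop("strong, weak and null sets must partition 1..p")
  }
  structure(list(strong = sort(strong), weak = sort(weak), null = sort(null), p = p),
            class = "signal_partition")
}

#' Simulation configuration for the synthetic survival generator
#'
#' Encodes the simulation design used throughout the package: rows of the
#' design matrix i.i.d. N(0, Sigma) with AR(1) correlation
#' `Sigma[j, j'] = rho^|j - j'|`, a coefficient vector made of a strong
#' block, a weak block and zeros, exponential event times with hazard
#' `lambda0 * exp(x' beta)`, and Uniform(0, c) censoring with `c` calibrated
#' to a target censoring rate.
#'
#' The default weak block follows the pattern `1, 0.8, 0.5, 0.2, ..., 0.2`:
#' blocks longer than four entries are padded with 0.2, shorter blocks
#' truncate that prefix.
#'
#' @param n Sample size.
#' @param p Total number of covariates.
#' @param p1 Number of strong signals (default 3).
#' @param n_weak Number of weak signals (default 7).
#' @param rho AR(1) correlation in (-1, 1) (default 0.5).
#' @param strong_values Strong coefficients (default `c(8, 9, 10)`).
#' @param weak_values Weak coefficients; default is the padded/truncated
#'   `1, 0.8, 0.5, 0.2, ...` pattern of length `n_weak`.
#' @param censor_rate Target censoring proportion in (0, 1) (default 0.15).
#' @param lambda0 Baseline hazard rate (default 1).
#' @param seed Master seed; all random substreams (design, event times,
#'   censoring times, calibration probes, CV folds) are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n, p, p1 = 3, n_weak = 7, rho = 0.5,
                       strong_values = c(8, 9, 10),
                       weak_values = NULL,
                       censor_rate = 0.15, lambda0 = 1, seed = 1L) {
  if (length(strong_values) != p1) {
    stop("strong_values must have length p1")
  }
  if (is.null(weak_values)) {
    weak_values <- weak_value_pattern(n_weak)
  }
  if (length(weak_values) != n_weak) {
    stop("weak_values must have length n_weak")
  }
  if (p1 + n_weak > p) stop("p1 + n_weak must not exceed p")
  if (!(censor_rate > 0 && censor_rate < 1)) stop("censor_rate must lie in (0, 1)")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (lambda0 <= 0) stop("lambda0 must be positive")
  structure(
    list(n = as.integer(n), p = as.integer(p), p1 = as.integer(p1),
         n_weak = as.integer(n_weak), rho = rho,
         strong_values = as.numeric(strong_values),
         weak_values = as.numeric(weak_values),
         censor_rate = censor_rate, lambda0 = lambda0,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# canonical weak-coefficient pattern: 1, 0.8, 0.5 then 0.2 repeated
weak_value_pattern <- function(n_weak) {
  if (n_weak == 0) return(numeric(0))
  prefix <- c(1, 0.8, 0.5, 0.2)
  if (n_weak <= length(prefix)) prefix[seq_len(n_weak)]
  else c(prefix, rep(0.2, n_weak - length(prefix)))
}

#' Deterministic substream seed derived from a master seed
#'
#' One master seed drives independent named substreams (design matrix, event
#' times, censoring, calibration probes, CV folds). The derived seed stays
#' below 2^31.
#'
#' @param seed Master integer seed.
#' @param stream Character label of the substream.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime of the Lehmer generator
  # base-131 polynomial hash of the label (distinguishes permuted digits),
  # folded with the master seed through two Lehmer steps
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% m
  z <- (abs(as.numeric(seed)) %% m)
  z <- (z * 48271) %% m
  z <- (z + h) %% m
  z <- (z * 48271) %% m
  as.integer(z %% 2147483646 + 1)
}

#' AR(1) covariance matrix
#'
#' Builds the `p x p` matrix with entries `rho^|j - j'|` (unit diagonal),
#' positive definite for `|rho| < 1`.
#'
#' @param p Dimension (positive integer).
#' @param rho Correlation parameter in (-1, 1).
#' @return A `p x p` covariance matrix.
#' @export
make_ar1_covariance <- function(p, rho) {
  if (length(p) != 1 || p < 1 || p != round(p)) stop("p must be a positive integer")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  idx <- seq_len(p)
  rho^abs(outer(idx, idx, "-"))
}

#' True coefficient vector and signal partition for a simulation design
#'
#' Lays out the coefficient vector as strong block, weak block, zeros, and
#' returns the matching index partition.
#'
#' @param config A [sim_config()].
#' @return A list with `beta` (length `p`) and `partition`
#'   (a [signal_partition()]).
#' @export
make_true_beta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p; p1 <- config$p1; n_weak <- config$n_weak
  beta <- c(config$strong_values, config$weak_values,
            rep(0, p - p1 - n_weak))
  part <- signal_partition(
    strong = seq_len(p1),
    weak = if (n_weak > 0) p1 + seq_len(n_weak) else integer(0),
    null = if (p > p1 + n_weak) (p1 + n_weak + 1):p else integer(0),
    p = p
  )
  list(beta = beta, partition = part)
}

# conditional censoring probability P(T > C | X) averaged over probe draws:
# for subject hazard lam, C ~ Uniform(0, c):
#   P(T > C) = (1 - exp(-lam c)) / (lam c), computed stably via expm1.
censor_prob_given_rates <- function(lam, c_upper) {
  z <- lam * c_upper
  out <- ifelse(z < 1e-8, 1 - z / 2, -expm1(-z) / z)
  mean(out)
}

#' Calibrate the Uniform(0, c) censoring upper bound
#'
#' Finds `c` such that the censoring proportion under the model
#' `T | X ~ Exponential(lambda0 * exp(x' beta))`, `C ~ Uniform(0, c)` matches
#' a target rate. The expected censoring probability is computed exactly
#' conditional on a Monte Carlo probe sample of covariate rows, which leaves
#' only design-sampling noise; the root is then found by bisection on
#' `log(c)`. With `beta = 0` the criterion is exactly `(1 - e^-c)/c`.
#'
#' @param beta True coefficient vector.
#' @param sigma Covariate covariance matrix (`p x p`).
#' @param target Target censoring rate in (0, 1).
#' @param n_probe Number of probe covariate draws (default 20000).
#' @param seed Seed for the probe stream (independent of the data stream).
#' @param lambda0 Baseline hazard rate.
#' @param tol Bisection tolerance on the censoring probability
#'   (default 1e-10).
#' @param max_iter Maximum bisection iterations.
#' @return The calibrated upper bound `c` (positive scalar), with the
#'   achieved probe censoring probability attached as attribute `achieved`.
#' @export
calibrate_censoring <- function(beta, sigma, target, n_probe = 20000,
                                seed = 1L, lambda0 = 1, tol = 1e-10,
                                max_iter = 200L) {
  if (!(target > 0 && target < 1)) stop("target censoring rate must lie in (0, 1)")
  p <- length(beta)
  if (any(beta != 0)) {
    stopifnot(nrow(sigma) == p, ncol(sigma) == p)
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(substream_seed(seed, "censor-probe"))
    z <- matrix(stats::rnorm(n_probe * p), n_probe, p)
    eta <- drop(z %*% chol(sigma) %*% beta)
  } else {
    eta <- rep(0, min(n_probe, 1L)) # beta = 0: all rates equal lambda0
  }
  lam <- lambda0 * exp(eta - max(eta)) # rescale; absorb scale into c
  scale_back <- exp(max(eta))
  f <- function(cc) censor_prob_given_rates(lam, cc) - target

  lo <- 1e-12; hi <- 1
  expand <- 0L
  while (f(hi) > 0 && expand < 80L) { hi <- hi * 10; expand <- expand + 1L }
  if (f(hi) > 0) stop("censoring target unreachable within bracket")
  if (f(lo) < 0) stop("censoring target unreachable within bracket (target too high)")
  iter <- 0L
  while (iter < max_iter) {
    mid <- sqrt(lo * hi) # bisection on the log scale
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < tol || (hi / lo - 1) < 1e-12) break
    iter <- iter + 1L
  }
  if (iter >= max_iter) stop("censoring calibration did not converge")
  cc <- sqrt(lo * hi)
  out <- cc / scale_back
  attr(out, "achieved") <- censor_prob_given_rates(lam, cc)
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Simulate a right-censored survival dataset
#'
#' Draws covariate rows i.i.d. N(0, Sigma) with AR(1) correlation, event
#' times from an exponential distribution with proportional-hazards rate
#' `lambda0 * exp(x' beta)`, and censoring times Uniform(0, c) with `c`
#' calibrated to the configured censoring rate (or supplied). Fully
#' reproducible given the config seed: the design, event and censoring
#' streams are independent substreams of the master seed.
#'
#' @param config A [sim_config()].
#' @param c_censor Optional pre-calibrated censoring upper bound; when `NULL`
#'   it is calibrated via [calibrate_censoring()].
#' @param max_retries Number of fresh draws attempted if a sample contains
#'   zero events.
#' @return A list with `data` (a [surv_dataset()]), `beta` (true
#'   coefficients), `partition`, `achieved_censoring`, `c_censor`, and
#'   `latent` (the latent event/censoring times, kept for generator checks).
#' @export
simulate_survival <- function(config, c_censor = NULL, max_retries = 20L) {
  stopifnot(inherits(config, "sim_config"))
  truth <- make_true_beta(config)
  sigma <- make_ar1_covariance(config$p, config$rho)
  if (is.null(c_censor)) {
    c_censor <- as.numeric(calibrate_censoring(
      truth$beta, sigma, config$censor_rate, seed = config$seed,
      lambda0 = config$lambda0))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  R <- chol(sigma)
  for (attempt in 0:max_retries) {
    tag <- if (attempt == 0) "" else paste0("-retry", attempt)
    set.seed(substream_seed(config$seed, paste0("design", tag)))
    z <- matrix(stats::rnorm(config$n * config$p), config$n, config$p)
    x <- z %*% R
    eta <- drop(x %*% truth$beta)
    set.seed(substream_seed(config$seed, paste0("event", tag)))
    # T ~ Exp(rate lambda0 e^eta); draw a unit exponential and rescale so the
    # stream is invariant to the rate layout
    tt <- stats::rexp(config$n) / (config$lambda0 * exp(eta))
    set.seed(substream_seed(config$seed, paste0("censor", tag)))
    cens <- stats::runif(config$n, 0, c_censor)
    y <- pmin(tt, cens)
    delta <- as.numeric(tt <= cens)
    if (sum(delta) >= 1) {
      data <- surv_dataset(y, delta, x)
      return(list(data = data, beta = truth$beta, partition = truth$partition,
                  achieved_censoring = mean(delta == 0),
                  c_censor = c_censor,
                  latent = list(event_time = tt, censor_time = cens)))
    }
  }
  stop("simulated sample contained zero events after ", max_retries, " retries")
}

#' Write a survival dataset to CSV
#'
#' Columns `time,status,x1..xp` with a header row; values are written with 15
#' significant digits so that a read/write round trip is lossless at that
#' precision.
#'
#' @param data A [surv_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "surv_dataset"))
  df <- data.frame(time = data$times, status = data$events,
                   data$covariates, check.names = FALSE)
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = 15, format = "g") else v
  }
  out <- as.data.frame(lapply(df, fmt), check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival dataset from CSV
#'
#' Expects the schema written by [write_survival_csv()]: header with columns
#' `time`, `status` and at least one covariate column; `status` must be 0/1.
#'
#' @param path CSV file path.
#' @return A [surv_dataset()].
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time", "status") %in% names(df))) {
    stop("survival CSV must contain 'time' and 'status' columns")
  }
  covs <- setdiff(names(df), c("time", "status"))
  if (length(covs) == 0) stop("survival CSV has no covariate columns")
  bad <- which(!(df$status %in% c(0, 1)))
  if (length(bad) > 0) {
    stop(sprintf("column 'status' must be 0/1; first offending line %d (value %s)",
                 bad[1] + 1L, df$status[bad[1]]))
  }
  surv_dataset(df$time, df$status, as.matrix(df[covs]), feature_names = covs)
}
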