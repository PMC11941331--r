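# ---- asymptotic bias and risk theory --------------------------------------
#
# Numeric evaluation of the limiting (local-alternative) bias and risk of the
# post-selection estimators. Contrasts d1 of the strong block are normalized
# by s1^2 = d1' Sigma_{S1|S2}^{-1} d1, the asymptotic variance of the
# full-model (weighted-ridge) contrast, so ADR(WR) = 1 identically. The
# non-centrality Delta drives everything else through inverse moments of
# non-central chi-square laws.

#' Conditional (Schur-complement) covariance blocks
#'
#' `Sigma_{S1|S2} = Sigma_11 - Sigma_12 Sigma_22^-1 Sigma_21` and its
#' counterpart with the roles of the blocks exchanged.
#'
#' @param sigma_s1s1,sigma_s1s2,sigma_s2s2 Conformable covariance blocks.
#' @return A list with `sigma_s1_given_s2` and `sigma_s2_given_s1`, both
#'   symmetric positive semidefinite.
#' @export
conditional_covariances <- function(sigma_s1s1, sigma_s1s2, sigma_s2s2) {
  s11 <- as.matrix(sigma_s1s1); s22 <- as.matrix(sigma_s2s2)
  s12 <- matrix(sigma_s1s2, nrow = nrow(s11), ncol = nrow(s22))
  inv22 <- tryCatch(solve(s22), error = function(e)
    stop("sigma_s2s2 is singular"))
  inv11 <- tryCatch(solve(s11), error = function(e)
    stop("sigma_s1s1 is singular"))
  c12 <- s11 - s12 %*% inv22 %*% t(s12)
  c21 <- s22 - t(s12) %*% inv11 %*% s12
  list(sigma_s1_given_s2 = (c12 + t(c12)) / 2,
       sigma_s2_given_s1 = (c21 + t(c21)) / 2)
}

#' Non-central chi-square CDF
#'
#' `H_df(x; ncp)`, reducing to the central chi-square CDF at `ncp = 0`.
#'
#' @param x Nonnegative quantile.
#' @param df Positive degrees of freedom.
#' @param ncp Nonnegative non-centrality parameter.
#' @return The CDF value.
#' @export
noncentral_chisq_cdf <- function(x, df, ncp = 0) {
  if (any(x < 0)) stop("x must be nonnegative")
  if (df <= 0) stop("df must be positive")
  if (ncp < 0) stop("ncp must be nonnegative")
  stats::pchisq(x, df = df, ncp = ncp)
}

#' Inverse moments of a (possibly truncated) non-central chi-square
#'
#' Computes `E[(chi^2_df(ncp))^-j * I(chi^2 < upper)]` for `j` in 1, 2 via
#' the exact Poisson-mixture representation: the non-central chi-square is a
#' Poisson(ncp/2) mixture of central chi-squares with `df + 2k` degrees of
#' freedom, and each central truncated inverse moment has the closed form
#' `F_{m-2}(t) / (m - 2)` (order 1) or `F_{m-4}(t) / ((m-2)(m-4))`
#' (order 2). The mixture series is truncated when the Poisson weight falls
#' below 1e-14.
#'
#' @param df Degrees of freedom; must exceed `2 * order` (the moment
#'   diverges otherwise, truncated or not, because the divergence sits at
#'   the origin).
#' @param ncp Nonnegative non-centrality.
#' @param order Moment order `j` (1 or 2): the expectation of
#'   `(chi^2)^-j`.
#' @param upper Upper truncation point (default `Inf` for the full moment).
#' @return The nonnegative moment value.
#' @export
chisq_inverse_moment <- function(df, ncp = 0, order = 1, upper = Inf) {
  if (!(order %in% c(1, 2))) stop("order must be 1 or 2")
  if (ncp < 0) stop("ncp must be nonnegative")
  if (upper < 0) stop("upper truncation must be nonnegative")
  if (df <= 2 * order) {
    stop(sprintf("E[(chi^2_%g)^-%d] diverges: need df > %d (the singularity is at 0)",
                 df, order, 2L * order))
  }
  if (upper == 0) return(0)
  central_term <- function(m) {
    if (order == 1) {
      if (is.infinite(upper)) 1 / (m - 2)
      else stats::pchisq(upper, m - 2) / (m - 2)
    } else {
      if (is.infinite(upper)) 1 / ((m - 2) * (m - 4))
      else stats::pchisq(upper, m - 4) / ((m - 2) * (m - 4))
    }
  }
  half <- ncp / 2
  total <- 0
  k <- 0
  repeat {
    w <- stats::dpois(k, half)
    if (w > 0) total <- total + w * central_term(df + 2 * k)
    # leave only after passing the mode so early tiny weights do not stop us
    if ((w < 1e-14 && k > half) || k > 100000) break
    k <- k + 1
  }
  total
}

#' Inputs for the asymptotic bias/risk evaluators
#'
#' Assembles the covariance blocks, contrast and local-alternative vectors,
#' and derives the quantities of the risk theory: `d2 = Sigma_21
#' Sigma_11^-1 d1`, the normalizers `s1^2 = d1' Sigma_{S1|S2}^-1 d1` and
#' `s2^2 = d2' Sigma_{S2|S1}^-1 d2`, the limit ratio
#' `c = (d1' Sigma_11^-1 d1) / s1^2` (in (0, 1]), and the non-centrality
#' `Delta` ([delta_ncp()]).
#'
#' @param sigma_s1s1,sigma_s1s2,sigma_s2s2 Covariance blocks (in the Cox
#'   model these are blocks of the limiting partial-likelihood information
#'   matrix).
#' @param d1 Contrast vector of length `p1` with `0 < ||d1||^2 <= 1`.
#' @param delta Local-alternative vector of length `p2` (the weak
#'   coefficients scale as `delta / sqrt(n)`).
#' @return An object of class `theory_inputs`.
#' @export
theory_inputs <- function(sigma_s1s1, sigma_s1s2, sigma_s2s2, d1, delta) {
  s11 <- as.matrix(sigma_s1s1); s22 <- as.matrix(sigma_s2s2)
  p1 <- nrow(s11); p2 <- nrow(s22)
  s12 <- matrix(sigma_s1s2, nrow = p1, ncol = p2)
  if (length(d1) != p1) stop("d1 must have length p1")
  if (length(delta) != p2) stop("delta must have length p2")
  nd1 <- sum(d1^2)
  if (!(nd1 > 0 && nd1 <= 1 + 1e-12)) stop("d1 must satisfy 0 < ||d1||^2 <= 1")
  cond <- conditional_covariances(s11, s12, s22)
  inv11 <- solve(s11)
  d2 <- drop(t(s12) %*% inv11 %*% d1)
  s1sq <- drop(t(d1) %*% solve(cond$sigma_s1_given_s2, d1))
  s2sq_den <- drop(t(d2) %*% solve(cond$sigma_s2_given_s1, d2))
  cc <- drop(t(d1) %*% inv11 %*% d1) / s1sq
  structure(
    list(sigma_s1s1 = s11, sigma_s1s2 = s12, sigma_s2s2 = s22,
         sigma_s1_given_s2 = cond$sigma_s1_given_s2,
         sigma_s2_given_s1 = cond$sigma_s2_given_s1,
         d1 = as.numeric(d1), d2 = d2, delta = as.numeric(delta),
         p1 = p1, p2 = p2, s1sq = s1sq, s2sq = s2sq_den, c = cc),
    class = "theory_inputs"
  )
}

#' Non-centrality parameter of the shrinkage risk theory
#'
#' The ratio of quadratic forms
#' `[d1' Sigma_11^-1 Sigma_12 delta delta' Sigma_21 Sigma_11^-1 d1] /
#'  [d1' Sigma_11^-1 Sigma_12 Sigma_{S2|S1}^-1 Sigma_21 Sigma_11^-1 d1]`,
#' which simplifies to `(d2' delta)^2 / s2^2`. Zero iff `d2' delta = 0`;
#' quadratic in the scale of `delta`.
#'
#' @param inputs A [theory_inputs()].
#' @return The nonnegative non-centrality `Delta`.
#' @export
delta_ncp <- function(inputs) {
  stopifnot(inherits(inputs, "theory_inputs"))
  if (inputs$s2sq <= 0) {
    stop("denominator is zero: d1 is orthogonal to the cross-covariance range")
  }
  drop(crossprod(inputs$d2, inputs$delta))^2 / inputs$s2sq
}

#' Asymptotic distributional bias of the post-selection estimators
#'
#' Normalized limiting bias of the contrast `d1' beta1` for the
#' weighted-ridge (0), restricted, shrinkage and positive-shrinkage
#' estimators, driven by `s1^-1 d2' beta2` and inverse moments of the
#' non-central chi-square with `p2` degrees of freedom at non-centrality
#' `Delta`.
#'
#' @param inputs A [theory_inputs()].
#' @param beta2 Weak-signal vector entering the bias terms; defaults to
#'   `inputs$delta` (the local-alternative identification).
#' @return Named numeric vector with elements `wr`, `re`, `se`, `pse`.
#' @export
adb_values <- function(inputs, beta2 = inputs$delta) {
  stopifnot(inherits(inputs, "theory_inputs"))
  p2 <- inputs$p2
  if (p2 <= 2) stop("p2 must exceed 2 for the shrinkage bias (moment divergence)")
  dlt <- delta_ncp(inputs)
  b <- drop(crossprod(inputs$d2, beta2)) / sqrt(inputs$s1sq)
  a <- p2 - 2
  m1 <- chisq_inverse_moment(p2, dlt, order = 1)
  t1 <- chisq_inverse_moment(p2, dlt, order = 1, upper = a)
  h <- noncentral_chisq_cdf(a, p2, dlt)
  c(wr = 0,
    re = b,
    se = a * b * m1,
    pse = b * (a * m1 + t1 - h))
}

#' Asymptotic distributional risk of the post-selection estimators
#'
#' Normalized limiting quadratic risk of the contrast `d1' beta1` under
#' local alternatives `beta2 = delta / sqrt(n)`. The weighted-ridge risk is
#' 1 by the choice of normalizer; the restricted risk is
#' `c + (1 - c) * Delta`; the shrinkage and positive-part risks follow the
#' exact Stein-risk decomposition (conditional-expectation identities for
#' quadratic forms in a normal vector), with all chi-square inverse moments
#' and truncated variants supplied by [chisq_inverse_moment()] and
#' [noncentral_chisq_cdf()]. The decomposition is documented term by term
#' in the methods vignette.
#'
#' @param inputs A [theory_inputs()].
#' @param beta2 Weak-signal vector in the squared-bias terms; defaults to
#'   `inputs$delta`.
#' @return Named numeric vector with elements `wr`, `re`, `se`, `pse`, plus
#'   attribute `delta_ncp`.
#' @export
adr_values <- function(inputs, beta2 = inputs$delta) {
  stopifnot(inherits(inputs, "theory_inputs"))
  p2 <- inputs$p2
  if (p2 <= 4) stop("p2 must exceed 4 (fourth-order inverse moments diverge)")
  cc <- inputs$c
  dlt <- delta_ncp(inputs)
  # squared normalized RE bias: b^2 = (1 - c) * Delta when beta2 = delta
  bsq <- (1 - cc) * drop(crossprod(inputs$d2, beta2))^2 / inputs$s2sq
  a <- p2 - 2
  m1_q2 <- chisq_inverse_moment(p2 + 2, dlt, 1)
  m1_q4 <- chisq_inverse_moment(p2 + 4, dlt, 1)
  m2_q2 <- chisq_inverse_moment(p2 + 2, dlt, 2)
  m2_q4 <- chisq_inverse_moment(p2 + 4, dlt, 2)
  t1_q2 <- chisq_inverse_moment(p2 + 2, dlt, 1, upper = a)
  t1_q4 <- chisq_inverse_moment(p2 + 4, dlt, 1, upper = a)
  t2_q2 <- chisq_inverse_moment(p2 + 2, dlt, 2, upper = a)
  t2_q4 <- chisq_inverse_moment(p2 + 4, dlt, 2, upper = a)
  h_q2 <- noncentral_chisq_cdf(a, p2 + 2, dlt)
  h_q4 <- noncentral_chisq_cdf(a, p2 + 4, dlt)

  adr_wr <- 1
  adr_re <- cc + (1 - cc) * dlt
  # Stein estimator: ADR(SE) = 1 + 2 a b^2 m1_q2
  #   - 2 a (1-c) [m1_q2 + Delta m1_q4] + a^2 (1-c) [m2_q2 + Delta m2_q4]
  adr_se <- 1 + 2 * a * bsq * m1_q2 -
    2 * a * (1 - cc) * (m1_q2 + dlt * m1_q4) +
    a^2 * (1 - cc) * (m2_q2 + dlt * m2_q4)
  # positive-part correction: subtract the region where the shrink factor
  # exceeds 1 (T <= p2 - 2), using the truncated identities
  corr <- 2 * bsq * (h_q2 - a * t1_q2) -
    (1 - cc) * (h_q2 + dlt * h_q4 -
                  2 * a * (t1_q2 + dlt * t1_q4) +
                  a^2 * (t2_q2 + dlt * t2_q4))
  adr_pse <- adr_se + corr
  out <- c(wr = adr_wr, re = adr_re, se = adr_se, pse = adr_pse)
  attr(out, "delta_ncp") <- dlt
  out
}

#' Risk-dominance map over a grid of local-alternative scales
#'
#' Evaluates [adr_values()] along `delta` scaled by a grid of factors and
#' reports, at every grid point, whether the dominance orderings
#' `ADR(PSE) <= ADR(SE) <= ADR(WR)` and `ADR(RE) < ADR(PSE)` hold.
#'
#' @param inputs A [theory_inputs()]; its `delta` defines the direction.
#' @param scale_grid Numeric vector of scale factors applied to `delta`.
#' @return A data.frame with one row per grid point: `scale`,
#'   `delta_norm2`, `delta_ncp`, the four ADR values and logical ordering
#'   flags `ord_pse_se_wr`, `ord_re_below_pse`.
#' @export
dominance_map <- function(inputs, scale_grid = seq(0, 1, length.out = 21)) {
  stopifnot(inherits(inputs, "theory_inputs"))
  rows <- lapply(scale_grid, function(s) {
    ti <- theory_inputs(inputs$sigma_s1s1, inputs$sigma_s1s2,
                        inputs$sigma_s2s2, inputs$d1, inputs$delta * s)
    adr <- adr_values(ti)
    data.frame(scale = s, delta_norm2 = sum((inputs$delta * s)^2),
               delta_ncp = attr(adr, "delta_ncp"),
               adr_wr = adr[["wr"]], adr_re = adr[["re"]],
               adr_se = adr[["se"]], adr_pse = adr[["pse"]],
               ord_pse_se_wr = adr[["pse"]] <= adr[["se"]] + 1e-12 &&
                 adr[["se"]] <= adr[["wr"]] + 1e-12,
               ord_re_below_pse = adr[["re"]] < adr[["pse"]])
  })
  do.call(rbind, rows)
}

#' Monte Carlo normalized risk of a post-selection estimator
#'
#' Simulates the Cox design at sample size `n` with `p1` strong
#' coefficients and `p2` weak coefficients scaled as `delta / sqrt(n)`,
#' fits the requested estimator with the true strong set supplied, and
#' averages the normalized quadratic contrast loss
#' `n * (d1' (beta_hat_S1 - beta_S1))^2 / s1^2` over replicates. The
#' normalizer `s1^2` uses the Schur complement of the limiting
#' partial-likelihood information, estimated from a large reference sample
#' at the true coefficients; under this normalization the weighted-ridge
#' risk converges to 1.
#'
#' @param n Sample size per replicate.
#' @param replicates Number of Monte Carlo replicates.
#' @param strong Strong coefficient values (length `p1`).
#' @param delta Local-alternative vector (length `p2`); the weak
#'   coefficients are `delta / sqrt(n)`.
#' @param d1 Contrast vector (length `p1`, norm at most 1).
#' @param rho AR(1) correlation of the covariates.
#' @param censor_rate Target censoring rate.
#' @param estimator `"wr"` (weighted ridge with the true strong set
#'   unpenalized, rate-formula `r_n`) or `"re"` (restricted MLE on the true
#'   strong set).
#' @param seed Master seed.
#' @param n_ref Reference-sample size for the information estimate.
#' @param c2 Rate-formula constant for the WR penalty.
#' @return A list with `risk` (the Monte Carlo mean), `mc_se` (its standard
#'   error), `theory` (the matching [adr_values()] entry computed from the
#'   estimated information blocks), `n_used`, and `inputs`.
#' @export
mc_normalized_risk <- function(n = 2000, replicates = 500,
                               strong = c(0.8, 0.9, 1.0),
                               delta = rep(0.3, 6),
                               d1 = c(1, 1, 1) / sqrt(3),
                               rho = 0.5, censor_rate = 0.15,
                               estimator = c("wr", "re"), seed = 1L,
                               n_ref = 50000, c2 = 0.01) {
  estimator <- match.arg(estimator)
  p1 <- length(strong); p2 <- length(delta)
  p <- p1 + p2
  beta_true <- c(strong, delta / sqrt(n))
  sigma <- make_ar1_covariance(p, rho)
  cfg0 <- sim_config(n = n, p = p, p1 = p1, n_weak = p2, rho = rho,
                     strong_values = strong, weak_values = delta / sqrt(n),
                     censor_rate = censor_rate, seed = seed)
  cc <- as.numeric(calibrate_censoring(beta_true, sigma, censor_rate,
                                       seed = substream_seed(seed, "cal")))
  # limiting information per observation from one large reference draw
  ref_cfg <- cfg0
  ref_cfg$n <- as.integer(n_ref)
  ref_cfg$seed <- substream_seed(seed, "reference")
  ref <- simulate_survival(ref_cfg, c_censor = cc)
  info <- score_and_information(beta_true, ref$data)$info / n_ref
  s1_idx <- seq_len(p1); s2_idx <- p1 + seq_len(p2)
  inputs <- theory_inputs(info[s1_idx, s1_idx], info[s1_idx, s2_idx],
                          info[s2_idx, s2_idx], d1, delta)
  s1sq <- inputs$s1sq
  a_n <- compute_an(n)
  r_n <- compute_rn(n, p, a_n, c2)
  beta1 <- strong
  losses <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- cfg0
    cfg_r$seed <- substream_seed(seed, paste0("rep", r))
    sim <- simulate_survival(cfg_r, c_censor = cc)
    est <- tryCatch({
      if (estimator == "wr") {
        fit <- fit_weighted_ridge(sim$data, s1_idx, r_n, standardize = FALSE)
        fit$beta[s1_idx]
      } else {
        fit_mle(sim$data, s1_idx)$beta
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(est)) {
      losses[r] <- n * drop(crossprod(d1, est - beta1))^2 / s1sq
    }
  }
  ok <- losses[!is.na(losses)]
  theory <- adr_values(inputs)[[estimator]]
  list(risk = mean(ok), mc_se = stats::sd(ok) / sqrt(length(ok)),
       theory = theory, n_used = length(ok), inputs = inputs)
}
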