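# ---- partial likelihood machinery -----------------------------------------
#
# All quantities follow the Breslow convention: the risk set at an event time
# t is R(t) = {j : Y_j >= t} (closed at the event time), and tied event times
# each use the full risk set. Data are sorted by decreasing follow-up time so
# risk sets are prefixes of the sorted sample; log-sum-exp rescaling keeps
# the risk-set sums finite for arbitrarily large linear predictors.

cox_sorted <- function(data) {
  ord <- order(data$times, decreasing = TRUE)
  y <- data$times[ord]
  # last position of each tie group = end of the risk set for that time
  r <- rle(y)
  ends <- cumsum(r$lengths)
  rs_end <- rep(ends, r$lengths)
  list(ord = ord, y = y, d = data$events[ord],
       x = data$covariates[ord, , drop = FALSE], rs_end = rs_end)
}

# log partial likelihood, score and information in one pass over risk sets.
# what: subset of c("loglik", "score", "info")
cox_pl_core <- function(beta, srt, what = c("loglik", "score", "info")) {
  x <- srt$x; d <- srt$d; rs_end <- srt$rs_end
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  need_score <- any(c("score", "info") %in% what)
  need_info <- "info" %in% what
  ev <- which(d == 1)
  if (length(ev) == 0) stop("data contain no events; partial likelihood undefined")
  re <- rs_end[ev]

  wide <- diff(range(eta)) > 600
  if (!wide) {
    # vectorized path: one global shift keeps every prefix sum in range
    m <- max(eta)
    w <- exp(eta - m)
    S0 <- cumsum(w)
    logS0 <- log(S0) + m
    if (need_score) {
      S1 <- apply(w * x, 2, cumsum)
      xbar_ev <- S1[re, , drop = FALSE] / S0[re]
    }
    if (need_info) {
      v <- numeric(n)
      cnt <- tabulate(re, nbins = n)
      v[cnt > 0] <- cnt[cnt > 0] / S0[cnt > 0]
      dvec <- w * rev(cumsum(rev(v)))
    }
  } else {
    # running-max rescaled recursion for extreme linear predictors
    logS0 <- numeric(n)
    if (need_score) S1bar <- matrix(0, n, p)
    m <- eta[1]; s0 <- 0
    s1 <- if (need_score) numeric(p) else NULL
    for (k in seq_len(n)) {
      ek <- eta[k]
      if (ek > m) {
        adj <- exp(m - ek)
        s0 <- s0 * adj
        if (need_score) s1 <- s1 * adj
        m <- ek
      }
      wk <- exp(ek - m)
      s0 <- s0 + wk
      logS0[k] <- log(s0) + m
      if (need_score) {
        s1 <- s1 + wk * x[k, ]
        S1bar[k, ] <- s1 / s0
      }
    }
    if (need_score) xbar_ev <- S1bar[re, , drop = FALSE]
    if (need_info) {
      # suffix log-sum-exp of event terms -logS0_i, accumulated from the end
      cnt <- tabulate(re, nbins = n)
      lc <- rep(-Inf, n)
      acc <- -Inf
      for (k in n:1) {
        if (cnt[k] > 0) {
          add <- log(cnt[k]) - logS0[k]
          acc <- if (acc == -Inf) add else {
            mm <- max(acc, add); mm + log(exp(acc - mm) + exp(add - mm))
          }
        }
        lc[k] <- acc
      }
      dvec <- ifelse(lc == -Inf, 0, exp(eta + lc))
    }
  }

  out <- list()
  if ("loglik" %in% what) out$loglik <- sum(eta[ev] - logS0[re])
  if (need_score) {
    out$score <- colSums(x[ev, , drop = FALSE]) - colSums(xbar_ev)
  }
  if (need_info) {
    out$info <- crossprod(x * sqrt(dvec)) - crossprod(xbar_ev)
  }
  out
}

check_beta_dim <- function(beta, data) {
  if (length(beta) != data$p) {
    stop(sprintf("beta has length %d but data have p = %d covariates",
                 length(beta), data$p))
  }
  if (sum(data$events) < 1) stop("all observations are censored; at least one event is required")
}

#' Cox log partial likelihood
#'
#' Evaluates `l(beta) = sum_i delta_i [x_i' beta - log sum_{j in R(t_i)}
#' exp(x_j' beta)]` with risk sets `R(t) = {j : Y_j >= t}`, Breslow handling
#' of ties, and log-sum-exp stabilization of the risk-set sums.
#'
#' @param beta Coefficient vector of length `p`.
#' @param data A [surv_dataset()] with at least one event.
#' @return The log partial likelihood (scalar).
#' @export
log_partial_likelihood <- function(beta, data) {
  stopifnot(inherits(data, "surv_dataset"))
  check_beta_dim(beta, data)
  cox_pl_core(beta, cox_sorted(data), what = "loglik")$loglik
}

#' Score vector and information matrix of the Cox partial likelihood
#'
#' @inheritParams log_partial_likelihood
#' @return A list with `score` (gradient of `l` at `beta`) and `info`
#'   (negative Hessian, symmetric positive semidefinite).
#' @export
score_and_information <- function(beta, data) {
  stopifnot(inherits(data, "surv_dataset"))
  check_beta_dim(beta, data)
  out <- cox_pl_core(beta, cox_sorted(data), what = c("score", "info"))
  list(score = out$score, info = out$info)
}

new_cox_fit <- function(beta, loglik, converged, iterations, index_set,
                        extra = list()) {
  structure(c(list(beta = beta, loglik = loglik, converged = converged,
                   iterations = iterations, index_set = index_set), extra),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d coefficients, loglik = %.4f, %s in %d iterations\n",
              length(x$beta), x$loglik,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

# Newton-Raphson core shared by the unpenalized and ridge-penalized fits.
# penalty_diag q >= 0: objective is -l(beta) + sum_j q_j beta_j^2.
cox_newton <- function(data, subset, penalty_diag = NULL, init = NULL,
                       max_iter = 100L, grad_tol = 1e-8, ll_tol = 1e-10,
                       beta_cap = 500) {
  xs <- data$covariates[, subset, drop = FALSE]
  sub_data <- surv_dataset(data$times, data$events, xs)
  srt <- cox_sorted(sub_data)
  k <- length(subset)
  q <- if (is.null(penalty_diag)) rep(0, k) else penalty_diag
  stopifnot(length(q) == k, all(q >= 0))
  beta <- if (is.null(init)) rep(0, k) else init
  obj <- function(b, ll) -ll + sum(q * b^2)
  core <- cox_pl_core(beta, srt)
  f <- obj(beta, core$loglik)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    g <- -core$score + 2 * q * beta # gradient of the penalized objective
    H <- core$info
    diag(H) <- diag(H) + 2 * q
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 * max(diag(H), 1), k), g)
    })
    # step halving on the penalized objective
    alpha <- 1; improved <- FALSE; fc <- f; cand_core <- core; cand <- beta
    for (h in 1:30) {
      cand <- beta - alpha * step
      cand_core <- tryCatch(cox_pl_core(cand, srt), error = function(e) NULL)
      if (!is.null(cand_core)) {
        fc <- obj(cand, cand_core$loglik)
        if (is.finite(fc) && fc <= f + 1e-12) { improved <- TRUE; break }
      }
      alpha <- alpha / 2
    }
    if (!improved) break
    rel_change <- abs(f - fc) / max(1, abs(f))
    beta <- cand; core <- cand_core; f <- fc
    if (max(abs(beta)) > beta_cap) {
      stop("coefficients diverged (monotone likelihood / separation suspected)")
    }
    g_new <- -core$score + 2 * q * beta
    if (sqrt(sum(g_new^2)) < grad_tol || rel_change < ll_tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, loglik = core$loglik, converged = converged,
       iterations = iter)
}

#' Unpenalized Cox MLE on a covariate subset
#'
#' Newton-Raphson maximizer of the log partial likelihood restricted to
#' `subset`, with step halving and a divergence guard against
#' monotone-likelihood separation.
#'
#' @param data A [surv_dataset()].
#' @param subset Integer indices of the covariates to fit (nonempty).
#' @param init Optional starting values.
#' @param max_iter Iteration cap (default 100).
#' @return A `cox_fit` with coefficients on `subset`.
#' @export
fit_mle <- function(data, subset = seq_len(data$p), init = NULL,
                    max_iter = 100L) {
  stopifnot(inherits(data, "surv_dataset"))
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("subset must be nonempty")
  if (sum(data$events) < 1) stop("all observations are censored")
  if (length(subset) >= sum(data$events)) {
    warning("fitting as many coefficients as events or more; estimates will be unstable")
  }
  res <- cox_newton(data, subset, init = init, max_iter = max_iter)
  if (!res$converged) {
    warning("Newton-Raphson did not converge within ", max_iter, " iterations")
  }
  new_cox_fit(stats::setNames(res$beta, colnames(data$covariates)[subset]),
              res$loglik, res$converged, res$iterations, subset)
}

#' Weighted ridge Cox fit: quadratic penalty outside a protected set
#'
#' Minimizes `-l(beta) + r_n * sum_{j not in s1hat} beta_j^2` over all `p`
#' coordinates: coordinates in `s1hat` are unpenalized, all others carry the
#' ridge penalty `r_n`. Covariates are scaled to unit variance internally for
#' penalty fairness; coefficients are returned on the original scale.
#'
#' @param data A [surv_dataset()].
#' @param s1hat Integer indices left unpenalized (the candidate strong set).
#' @param r_n Nonnegative ridge tuning constant.
#' @param standardize Scale columns to unit variance before fitting.
#' @param init Optional starting values (original scale).
#' @param max_iter Iteration cap.
#' @return A `cox_fit` over all `p` coordinates, with `r_n` and `s1hat`
#'   recorded.
#' @export
fit_weighted_ridge <- function(data, s1hat, r_n, standardize = TRUE,
                               init = NULL, max_iter = 100L) {
  stopifnot(inherits(data, "surv_dataset"))
  if (r_n < 0) stop("r_n must be nonnegative")
  s1hat <- as.integer(s1hat)
  p <- data$p
  if (p >= data$n && r_n == 0) {
    stop("p >= n with r_n = 0: the unpenalized full model is unidentifiable")
  }
  q <- rep(r_n, p)
  if (length(s1hat) > 0) q[s1hat] <- 0
  res <- penalized_newton_std(data, q, standardize, init, max_iter)
  if (!res$converged) {
    warning("weighted ridge Newton did not converge within ", max_iter,
            " iterations")
  }
  new_cox_fit(stats::setNames(res$beta, colnames(data$covariates)),
              res$loglik, res$converged, res$iterations, seq_len(p),
              extra = list(r_n = r_n, s1hat = sort(s1hat)))
}

# standardized-scale quadratic-penalty Newton fit, results on original scale
penalized_newton_std <- function(data, penalty_diag, standardize = TRUE,
                                 init = NULL, max_iter = 100L) {
  p <- data$p
  sds <- if (standardize) apply(data$covariates, 2, stats::sd) else rep(1, p)
  sds[sds == 0] <- 1
  sdata <- surv_dataset(data$times, data$events,
                        sweep(data$covariates, 2, sds, "/"))
  init_s <- if (is.null(init)) NULL else init * sds
  res <- cox_newton(sdata, seq_len(p), penalty_diag = penalty_diag,
                    init = init_s, max_iter = max_iter)
  beta <- res$beta / sds
  list(beta = beta, loglik = log_partial_likelihood(beta, data),
       converged = res$converged, iterations = res$iterations)
}

#' Penalty specification for penalized Cox fits
#'
#' @param family One of `"lasso"`, `"enet"`, `"weighted_ridge"`.
#' @param lambda Nonnegative penalty level (for `weighted_ridge` this is the
#'   ridge constant `r_n`).
#' @param alpha Elastic-net mixing in `[0, 1]` (used by `enet`; `lasso`
#'   fixes it at 1).
#' @param per_coordinate_weights Optional nonnegative penalty weights, one
#'   per covariate; 0 leaves a coordinate unpenalized.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("lasso", "enet", "weighted_ridge"),
                         lambda, alpha = 0.5,
                         per_coordinate_weights = NULL) {
  family <- match.arg(family)
  if (lambda < 0) stop("lambda must be nonnegative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!is.null(per_coordinate_weights) && any(per_coordinate_weights < 0)) {
    stop("per-coordinate penalty weights must be nonnegative")
  }
  if (family == "lasso") alpha <- 1
  structure(list(family = family, lambda = lambda, alpha = alpha,
                 per_coordinate_weights = per_coordinate_weights),
            class = "penalty_spec")
}

#' Penalized Cox fit (LASSO / Elastic Net / weighted ridge)
#'
#' LASSO and Elastic Net fits run glmnet's coordinate descent on the partial
#' likelihood; the `weighted_ridge` family uses the package's Newton solver
#' with a per-coordinate quadratic penalty. At `lambda = 0` the objective is
#' the unpenalized partial likelihood and the fit is delegated to
#' [fit_mle()].
#'
#' @param data A [surv_dataset()].
#' @param penalty A [penalty_spec()].
#' @param thresh glmnet convergence threshold.
#' @return A `cox_fit` over all `p` coordinates.
#' @export
fit_penalized <- function(data, penalty, thresh = 1e-12) {
  stopifnot(inherits(data, "surv_dataset"), inherits(penalty, "penalty_spec"))
  if (sum(data$events) < 1) stop("all observations are censored")
  p <- data$p
  pf <- penalty$per_coordinate_weights
  if (is.null(pf)) pf <- rep(1, p)
  if (penalty$family == "weighted_ridge") {
    res <- penalized_newton_std(data, penalty$lambda * pf)
    if (!res$converged) warning("weighted ridge Newton did not converge")
    return(new_cox_fit(stats::setNames(res$beta, colnames(data$covariates)),
                       res$loglik, res$converged, res$iterations, seq_len(p),
                       extra = list(r_n = penalty$lambda)))
  }
  if (penalty$lambda == 0) {
    if (p >= data$n) stop("lambda = 0 with p >= n is unidentifiable")
    return(fit_mle(data, seq_len(p)))
  }
  y <- survival::Surv(data$times, data$events)
  # short warm-start path ending at the requested lambda
  lam_path <- penalty$lambda * c(32, 16, 8, 4, 2, 1)
  g <- glmnet::glmnet(data$covariates, y, family = "cox",
                      alpha = penalty$alpha, lambda = lam_path,
                      penalty.factor = pf, standardize = TRUE,
                      thresh = thresh, maxit = 200000)
  beta <- drop(as.matrix(stats::coef(g, s = penalty$lambda, exact = FALSE)))
  new_cox_fit(stats::setNames(beta, colnames(data$covariates)),
              log_partial_likelihood(beta, data),
              TRUE, as.integer(g$npasses), seq_len(p),
              extra = list(lambda = penalty$lambda, alpha = penalty$alpha,
                           glmnet_fit = g))
}

# event-stratified fold assignment; every fold is guaranteed >= 1 event
stratified_foldid <- function(events, nfolds, seed) {
  n <- length(events)
  if (sum(events == 1) < nfolds) {
    stop("fewer events than folds; reduce nfolds")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(substream_seed(seed, "cv-folds"))
  foldid <- integer(n)
  for (grp in c(1, 0)) {
    idx <- which(events == grp)
    if (length(idx) > 0) {
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  }
  foldid
}

#' Cross-validated penalized Cox fit
#'
#' Cross-validation of the penalized partial likelihood over a lambda grid,
#' scored by the Verweij-van Houwelingen partial-likelihood deviance
#' (glmnet's grouped Cox deviance). Folds are stratified by event status and
#' seeded, so the selected lambda is reproducible.
#'
#' @param data A [surv_dataset()].
#' @param family `"lasso"`, `"enet"` or `"ridge"` (alpha 1, `alpha`, 0).
#' @param lambda Optional lambda grid (glmnet chooses its own when `NULL`).
#' @param nfolds Number of folds (>= 2, default 10).
#' @param seed Seed for the fold assignment.
#' @param alpha Elastic-net mixing used when `family = "enet"`.
#' @param penalty.factor Optional per-coordinate penalty weights.
#' @param nlambda Length of the automatic lambda grid.
#' @param type_measure CV loss: `"deviance"` (Verweij-van Houwelingen
#'   partial-likelihood deviance, default) or `"C"` (cross-validated
#'   concordance).
#' @param thresh glmnet coordinate-descent tolerance; the default 1e-5 is
#'   loose enough for support detection and markedly faster than glmnet's
#'   default on strong-signal data.
#' @param lambda.min.ratio Smallest lambda of the automatic path as a
#'   fraction of lambda_max; the default 0.05 truncates the expensive dense
#'   end of the path, which a sparse tuning rule never selects.
#' @return A list with `lambda_min`, `cv_curve` (data.frame of lambda, CV
#'   loss and its SE), and the underlying `cv.glmnet` object as `fit`.
#' @export
cross_validate <- function(data, family = c("lasso", "enet", "ridge"),
                           lambda = NULL, nfolds = 10, seed = 1L,
                           alpha = 0.5, penalty.factor = NULL,
                           nlambda = 50, type_measure = c("deviance", "C"),
                           thresh = 1e-5, lambda.min.ratio = 0.05) {
  stopifnot(inherits(data, "surv_dataset"))
  family <- match.arg(family)
  type_measure <- match.arg(type_measure)
  if (nfolds < 2) stop("nfolds must be at least 2")
  a <- switch(family, lasso = 1, enet = alpha, ridge = 0)
  foldid <- stratified_foldid(data$events, nfolds, seed)
  y <- survival::Surv(data$times, data$events)
  pf <- if (is.null(penalty.factor)) rep(1, data$p) else penalty.factor
  if (is.null(lambda) && a == 0) {
    # glmnet's automatic path can degenerate for pure ridge (lambda_max is
    # unbounded at alpha = 0); supply a wide fixed geometric grid instead
    lambda <- 10^seq(2, -5, length.out = 70)
  }
  args <- list(x = data$covariates, y = y, family = "cox", alpha = a,
               foldid = foldid, penalty.factor = pf, standardize = TRUE,
               nlambda = nlambda, type.measure = type_measure, thresh = thresh,
               lambda.min.ratio = lambda.min.ratio)
  if (!is.null(lambda)) args$lambda <- lambda
  cv <- do.call(glmnet::cv.glmnet, args)
  list(lambda_min = cv$lambda.min,
       cv_curve = data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd),
       fit = cv)
}
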