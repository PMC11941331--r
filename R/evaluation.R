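# ---- metrics and the Monte Carlo study driver ------------------------------

#' Relative mean squared error of a candidate estimator versus a reference
#'
#' `mean ||reference - beta||^2 / mean ||candidate - beta||^2` across
#' replicates: values above 1 mean the candidate outperforms the reference.
#'
#' @param candidate,reference Matrices of per-replicate estimates (one row
#'   per replicate) on a common coordinate set, or vectors for a single
#'   replicate pair.
#' @param beta_true True coefficient values on that coordinate set.
#' @param trim Optional fraction (per tail) of the most extreme squared
#'   errors trimmed from both averages (default 0, a plain average).
#' @return The RMSE ratio (scalar).
#' @export
relative_mse <- function(candidate, reference, beta_true, trim = 0) {
  cand <- if (is.matrix(candidate)) candidate else matrix(candidate, nrow = 1)
  ref <- if (is.matrix(reference)) reference else matrix(reference, nrow = 1)
  if (!all(dim(cand) == dim(ref))) stop("candidate and reference must have equal dimensions")
  if (ncol(cand) != length(beta_true)) stop("beta_true length must match the estimate columns")
  se_c <- rowSums(sweep(cand, 2, beta_true)^2)
  se_r <- rowSums(sweep(ref, 2, beta_true)^2)
  mse_c <- mean(se_c, trim = trim)
  mse_r <- mean(se_r, trim = trim)
  if (mse_c == 0) stop("candidate mean squared error is zero; RMSE ratio undefined")
  mse_r / mse_c
}

#' False positive rate of a sparse estimate
#'
#' Fraction of the truly zero coefficients that the estimate declares
#' nonzero. Undefined (returns `NA`) when the truth contains no zeros.
#'
#' @param beta_hat Estimated coefficient vector.
#' @param beta_true True coefficient vector of the same length.
#' @return The FPR in `[0, 1]`, or `NA_real_` when no true zeros exist.
#' @export
false_positive_rate <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true)) stop("length mismatch")
  zeros <- which(beta_true == 0)
  if (length(zeros) == 0) return(NA_real_)
  sum(beta_hat[zeros] != 0) / length(zeros)
}

#' Harrell's concordance index for survival risk scores
#'
#' Probability that, among usable (event-anchored) pairs, the subject with
#' the higher risk score fails earlier; ties in score count 1/2.
#'
#' @param risk_scores Numeric risk scores (higher = shorter survival).
#' @param data A [surv_dataset()].
#' @return The concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk_scores, data) {
  stopifnot(inherits(data, "surv_dataset"))
  if (length(risk_scores) != data$n) stop("one score per subject required")
  if (any(!is.finite(risk_scores))) stop("risk scores must be finite")
  fit <- survival::concordance(
    survival::Surv(data$times, data$events) ~ risk_scores, reverse = TRUE)
  cn <- fit$count
  usable <- sum(cn[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no usable pairs (all pairs censored or tied times)")
  as.numeric(fit$concordance)
}

# squared error of an estimator reported on the true strong coordinates;
# coordinates the estimator missed count as 0 estimates
est_on_coords <- function(idx_set, values, coords) {
  v <- rep(0, length(coords))
  hit <- intersect(idx_set, coords)
  if (length(hit) > 0) v[match(hit, coords)] <- values[match(hit, idx_set)]
  v
}

#' Monte Carlo study of the post-selection estimators
#'
#' Runs the full pipeline (simulate, two-step selection, post-selection
#' shrinkage) over a grid of design cells and aggregates, per cell, the
#' relative MSE of the step-1 penalized estimator, the restricted estimator
#' and the positive-shrinkage estimator against the weighted-ridge
#' reference, together with the mean selected strong-set size and the false
#' positive rate of the post-selection support (`S1hat` union `S2hat`).
#'
#' Errors are measured on the true strong coordinates by default
#' (`rmse_coords = "strong"`): every estimator reports 0 for a strong
#' coordinate it misses. `rmse_coords = "full"` measures errors on all `p`
#' coordinates instead. Replicates whose restricted fit fails (divergence or
#' non-convergence) are dropped from the averages and counted in `n_failed`;
#' a cell errors out if more than `max_fail_frac` of its replicates fail.
#'
#' @param grid A data.frame with columns `n`, `p`, `family`, `censor_rate`
#'   (one row per cell).
#' @param replicates Monte Carlo replicates per cell.
#' @param seed Master seed; every replicate derives its own substream.
#' @param c_thresh,kappa,c2,rn_mode,rule,type_measure,alpha,nfolds,tn_form
#'   Pipeline settings, passed through to [run_two_step()] and
#'   [post_selection_estimates()].
#' @param rmse_coords `"strong"` or `"full"`.
#' @param trim Trimming fraction for the RMSE averages (default 0).
#' @param max_fail_frac Maximum tolerated fraction of failed replicates.
#' @param verbose Print one line per completed cell.
#' @return A `simulation_report`: a data.frame with one row per cell and
#'   columns `n`, `p`, `family`, `censor_rate`, `rmse_ple`, `rmse_re`,
#'   `rmse_pse`, `mean_s1_size`, `mean_s2_size`, `fpr`, `applied_frac`,
#'   `n_replicates`, `n_failed`, `seed`.
#' @export
run_study <- function(grid, replicates = 200, seed = 1L,
                      c_thresh = 1, kappa = 0.25, c2 = 0.01,
                      rn_mode = "theory", rule = "lambda.1se",
                      type_measure = "C", alpha = 0.5, nfolds = 10,
                      tn_form = "wald", rmse_coords = c("strong", "full"),
                      trim = 0, max_fail_frac = 0.2, verbose = FALSE) {
  stopifnot(is.data.frame(grid),
            all(c("n", "p", "family", "censor_rate") %in% names(grid)))
  rmse_coords <- match.arg(rmse_coords)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    cell_seed <- substream_seed(seed, sprintf("cell-%d-%d-%s-%g",
                                              cell$n, cell$p, cell$family,
                                              cell$censor_rate))
    cfg <- sim_config(n = cell$n, p = cell$p,
                      censor_rate = cell$censor_rate, seed = cell_seed)
    truth <- make_true_beta(cfg)
    sigma <- make_ar1_covariance(cfg$p, cfg$rho)
    cc <- as.numeric(calibrate_censoring(truth$beta, sigma,
                                         cfg$censor_rate, seed = cell_seed))
    coords <- if (rmse_coords == "strong") truth$partition$strong
              else seq_len(cfg$p)
    beta_ref <- truth$beta[coords]
    nulls <- truth$partition$null
    est_wr <- est_ple <- est_re <- est_pse <- matrix(
      NA_real_, replicates, length(coords))
    s1s <- s2s <- fprs <- applied <- rep(NA_real_, replicates)
    n_failed <- 0L
    for (r in seq_len(replicates)) {
      rep_seed <- substream_seed(cell_seed, paste0("rep", r))
      res <- tryCatch({
        cfg_r <- cfg
        cfg_r$seed <- rep_seed
        sim <- simulate_survival(cfg_r, c_censor = cc)
        sel <- suppressWarnings(run_two_step(
          sim$data, family = cell$family, c_thresh = c_thresh,
          kappa = kappa, c2 = c2, nfolds = nfolds, seed = rep_seed,
          alpha = alpha, rn_mode = rn_mode, rule = rule,
          type_measure = type_measure))
        shr <- suppressWarnings(post_selection_estimates(sim$data, sel,
                                                         tn_form = tn_form))
        if (!shr$converged) stop("restricted fit failed")
        list(sel = sel, shr = shr)
      }, error = function(e) NULL)
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      sel <- res$sel; shr <- res$shr
      est_wr[r, ] <- sel$beta_wr[coords]
      est_ple[r, ] <- sel$beta_ple[coords]
      est_re[r, ] <- est_on_coords(sel$s1hat, shr$beta_re, coords)
      est_pse[r, ] <- est_on_coords(sel$s1hat, shr$beta_pse, coords)
      s1s[r] <- length(sel$s1hat)
      s2s[r] <- length(sel$s2hat)
      support <- union(sel$s1hat, sel$s2hat)
      fprs[r] <- if (length(nulls) > 0)
        length(intersect(support, nulls)) / length(nulls) else NA_real_
      applied[r] <- as.numeric(shr$applied)
    }
    ok <- which(!is.na(s1s))
    if (length(ok) < replicates * (1 - max_fail_frac)) {
      stop(sprintf("cell n=%d p=%d %s: %d of %d replicates failed",
                   cell$n, cell$p, cell$family, n_failed, replicates))
    }
    row <- data.frame(
      n = cell$n, p = cell$p, family = cell$family,
      censor_rate = cell$censor_rate,
      rmse_ple = relative_mse(est_ple[ok, , drop = FALSE],
                              est_wr[ok, , drop = FALSE], beta_ref, trim),
      rmse_re = relative_mse(est_re[ok, , drop = FALSE],
                             est_wr[ok, , drop = FALSE], beta_ref, trim),
      rmse_pse = relative_mse(est_pse[ok, , drop = FALSE],
                              est_wr[ok, , drop = FALSE], beta_ref, trim),
      mean_s1_size = mean(s1s[ok]), mean_s2_size = mean(s2s[ok]),
      fpr = mean(fprs[ok]), applied_frac = mean(applied[ok]),
      n_replicates = length(ok), n_failed = n_failed, seed = cell_seed)
    out[[g]] <- row
    if (verbose) {
      message(sprintf(
        "cell n=%d p=%d %s cens=%.2f: RMSE ple/re/pse = %.2f/%.2f/%.2f, |S1|=%.1f, FPR=%.3f (%d ok, %d failed)",
        cell$n, cell$p, cell$family, cell$censor_rate, row$rmse_ple,
        row$rmse_re, row$rmse_pse, row$mean_s1_size, row$fpr,
        row$n_replicates, n_failed))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("simulation_report", class(res))
  attr(res, "settings") <- list(replicates = replicates, seed = seed,
                                c_thresh = c_thresh, kappa = kappa, c2 = c2,
                                rn_mode = rn_mode, rule = rule,
                                type_measure = type_measure, alpha = alpha,
                                nfolds = nfolds, tn_form = tn_form,
                                rmse_coords = rmse_coords, trim = trim)
  res
}

#' Write a simulation report (and its run manifest) as delimited text
#'
#' @param report A `simulation_report` from [run_study()].
#' @param path Output TSV path; the manifest of fully resolved settings is
#'   written alongside as `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_simulation_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- attr(report, "settings")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
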