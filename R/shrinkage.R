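# ---- post-selection shrinkage estimators ----------------------------------
#
# On the selected strong set S1hat three estimators are compared:
#   RE  - restricted partial-likelihood MLE on S1hat;
#   SE  - Stein-type shrinkage of the weighted-ridge coefficients toward RE
#         by the factor (s2hat - 2) / Tn;
#   PSE - positive-part version capping the factor at 1 so the estimate
#         never crosses to the far side of RE (no sign reversal of the
#         correction).

#' Orthogonal-complement projection of the strong-set design columns
#'
#' Returns `M = I_n - X_S1 (X_S1' X_S1)^+ X_S1'` (Moore-Penrose
#' pseudoinverse, so rank-deficient strong sets are handled), the projector
#' onto the orthogonal complement of the selected strong columns.
#'
#' @param x Design matrix (`n x p`).
#' @param s1hat Strong-set column indices (may be empty).
#' @return An `n x n` symmetric idempotent matrix.
#' @export
projection_complement <- function(x, s1hat) {
  x <- as.matrix(x)
  n <- nrow(x)
  s1hat <- as.integer(s1hat)
  if (length(s1hat) == 0) return(diag(n))
  xs <- x[, s1hat, drop = FALSE]
  sv <- svd(xs)
  pos <- sv$d > max(dim(xs)) * .Machine$double.eps * max(sv$d)
  u <- sv$u[, pos, drop = FALSE]
  diag(n) - tcrossprod(u)
}

#' Weak-signal evidence statistic Tn
#'
#' Quadratic form in the thresholded weak-signal coefficients. The default
#' `"wald"` form is `b' (X_S2' M X_S2) b` (the Wald-type statistic whose
#' limit is the non-central chi-square of the risk theory); `"as_printed"`
#' uses the pseudoinverse of the middle matrix instead,
#' `b' (X_S2' M X_S2)^+ b`.
#'
#' @param beta_wr_s2 Thresholded ridge coefficients on `s2hat`.
#' @param x Design matrix.
#' @param s1hat,s2hat Strong and weak index sets (`s2hat` nonempty).
#' @param form `"wald"` (default) or `"as_printed"`.
#' @return The nonnegative statistic Tn.
#' @export
compute_tn <- function(beta_wr_s2, x, s1hat, s2hat,
                       form = c("wald", "as_printed")) {
  form <- match.arg(form)
  s2hat <- as.integer(s2hat)
  if (length(s2hat) == 0) stop("s2hat is empty; Tn is undefined")
  if (length(beta_wr_s2) != length(s2hat)) {
    stop("beta_wr_s2 must have one entry per index in s2hat")
  }
  x <- as.matrix(x)
  m <- projection_complement(x, s1hat)
  xs2 <- x[, s2hat, drop = FALSE]
  a <- crossprod(xs2, m %*% xs2)
  b <- as.numeric(beta_wr_s2)
  tn <- if (form == "wald") {
    drop(crossprod(b, a %*% b))
  } else {
    sv <- svd(a)
    pos <- sv$d > max(dim(a)) * .Machine$double.eps * max(sv$d, 0)
    apinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    drop(crossprod(b, apinv %*% b))
  }
  max(tn, 0)
}

#' Stein-type shrinkage of the weighted-ridge estimate toward the restricted MLE
#'
#' `beta_se = beta_wr_s1 - ((s2_size - 2) / t_n) * (beta_wr_s1 - beta_re)`.
#'
#' @param beta_wr_s1 Weighted-ridge coefficients on the strong set.
#' @param beta_re Restricted MLE on the strong set.
#' @param s2_size Number of detected weak signals.
#' @param t_n Weak-signal statistic from [compute_tn()].
#' @return The shrinkage estimate (same length as `beta_wr_s1`).
#' @export
shrink_se <- function(beta_wr_s1, beta_re, s2_size, t_n) {
  stopifnot(length(beta_wr_s1) == length(beta_re))
  diff <- beta_wr_s1 - beta_re
  if (t_n == 0) {
    if (all(diff == 0)) return(beta_wr_s1)
    stop("t_n = 0 with beta_wr != beta_re: shrink factor undefined")
  }
  if (t_n < 0) stop("t_n must be nonnegative")
  beta_wr_s1 - ((s2_size - 2) / t_n) * diff
}

#' Positive-part shrinkage estimate
#'
#' Same as [shrink_se()] with the shrink factor `(s2_size - 2) / t_n` capped
#' at 1 (and floored at 0), so the result is a convex combination of the
#' weighted-ridge and restricted estimates and the correction can never
#' overshoot past the restricted MLE.
#'
#' @inheritParams shrink_se
#' @return The positive-part shrinkage estimate.
#' @export
shrink_pse <- function(beta_wr_s1, beta_re, s2_size, t_n) {
  stopifnot(length(beta_wr_s1) == length(beta_re))
  diff <- beta_wr_s1 - beta_re
  if (t_n == 0) {
    if (all(diff == 0)) return(beta_wr_s1)
    stop("t_n = 0 with beta_wr != beta_re: shrink factor undefined")
  }
  if (t_n < 0) stop("t_n must be nonnegative")
  fac <- min(max((s2_size - 2) / t_n, 0), 1)
  beta_wr_s1 - fac * diff
}

#' Post-selection estimators on the selected strong set
#'
#' Computes the restricted MLE on `s1hat` and, when more than two weak
#' signals were detected (`|S2hat| > 2`), the Stein-type and positive-part
#' shrinkage estimators; with two or fewer weak signals the shrinkage step
#' is skipped and both estimators fall back to the restricted MLE.
#'
#' @param data A [surv_dataset()].
#' @param selection A `selection_result` from [run_two_step()].
#' @param tn_form Form of the weak-signal statistic, see [compute_tn()].
#' @return An object of class `shrinkage_result` with fields `beta_re`,
#'   `beta_wr_s1`, `beta_se`, `beta_pse` (all indexed by `s1hat`), `t_n`,
#'   `s2_size`, `applied` (whether shrinkage ran) and `converged`.
#' @export
post_selection_estimates <- function(data, selection,
                                     tn_form = c("wald", "as_printed")) {
  stopifnot(inherits(data, "surv_dataset"),
            inherits(selection, "selection_result"))
  tn_form <- match.arg(tn_form)
  s1 <- selection$s1hat
  s2 <- selection$s2hat
  refit <- tryCatch(
    withCallingHandlers(
      fit_mle(data, s1),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) NULL
  )
  converged <- !is.null(refit) && isTRUE(refit$converged)
  beta_re <- if (is.null(refit)) rep(NA_real_, length(s1)) else refit$beta
  beta_wr_s1 <- selection$beta_wr[s1]
  s2_size <- length(s2)
  if (is.null(refit)) {
    return(structure(
      list(beta_re = beta_re, beta_wr_s1 = beta_wr_s1,
           beta_se = beta_re, beta_pse = beta_re,
           t_n = NA_real_, s2_size = s2_size, applied = FALSE,
           converged = FALSE, s1hat = s1, tn_form = tn_form),
      class = "shrinkage_result"))
  }
  if (s2_size > 2) {
    t_n <- compute_tn(selection$beta_wr[s2], data$covariates, s1, s2,
                      form = tn_form)
    beta_se <- shrink_se(beta_wr_s1, beta_re, s2_size, t_n)
    beta_pse <- shrink_pse(beta_wr_s1, beta_re, s2_size, t_n)
    applied <- TRUE
  } else {
    t_n <- NA_real_
    beta_se <- beta_re
    beta_pse <- beta_re
    applied <- FALSE
  }
  structure(
    list(beta_re = beta_re, beta_wr_s1 = beta_wr_s1, beta_se = beta_se,
         beta_pse = beta_pse, t_n = t_n, s2_size = s2_size,
         applied = applied, converged = converged, s1hat = s1,
         tn_form = tn_form),
    class = "shrinkage_result"
  )
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("<shrinkage_result> |S1hat| = %d, s2 = %d, shrinkage %s\n",
              length(x$s1hat), x$s2_size,
              if (x$applied) sprintf("applied (Tn = %.4g)", x$t_n)
              else "not applied (<= 2 weak signals)"))
  invisible(x)
}

#' Per-estimator coefficient table
#'
#' Lays out the penalized (step-1), restricted and positive-shrinkage
#' coefficients side by side for the union of their supports; coordinates
#' outside a given estimator's index set are shown as dashes when printed.
#'
#' @param selection A `selection_result`.
#' @param shrinkage A `shrinkage_result` from the same data.
#' @return A data.frame with columns `index`, `beta_ple`, `beta_re`,
#'   `beta_pse` (NA marks coordinates outside an estimator's support).
#' @export
coefficient_table <- function(selection, shrinkage) {
  stopifnot(inherits(selection, "selection_result"),
            inherits(shrinkage, "shrinkage_result"))
  idx <- sort(union(which(selection$beta_ple != 0), selection$s1hat))
  ple <- ifelse(selection$beta_ple[idx] != 0, selection$beta_ple[idx], NA_real_)
  re <- pse <- rep(NA_real_, length(idx))
  pos <- match(selection$s1hat, idx)
  re[pos] <- shrinkage$beta_re
  pse[pos] <- shrinkage$beta_pse
  data.frame(index = idx, beta_ple = ple, beta_re = re, beta_pse = pse)
}

#' Write a coefficient table as delimited text
#'
#' @param tab A data.frame from [coefficient_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(tab, path) {
  out <- tab
  for (nm in c("beta_ple", "beta_re", "beta_pse")) {
    out[[nm]] <- ifelse(is.na(tab[[nm]]), "-", sprintf("%.4f", tab[[nm]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
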