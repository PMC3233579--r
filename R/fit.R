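#' Regression design matrix of a trial
#'
#' Builds the analysis design matrix: an intercept, the treatment indicator
#' (1 = treatment arm) and, for every prognostic factor, one dummy
#' indicator per non-reference level (a factor with 5 levels contributes
#' all 4 dummies).  Dummy columns with zero variance in the sample -- a
#' level unobserved in the cohort -- are dropped and flagged.
#'
#' @param profiles integer matrix of level indices (subjects x factors), or
#'   a \code{"trial_record"} (in which case \code{arms} and \code{spec} are
#'   taken from it).
#' @param arms character vector of \code{"T"}/\code{"C"} assignments.
#' @param spec a [factor_spec()].
#' @return A list with \code{X} (the matrix, rows in subject order),
#'   \code{treatment_col} (its column name, \code{"treatment"}),
#'   \code{dropped} (names of removed zero-variance dummies) and
#'   \code{degenerate} (flag, \code{TRUE} if any column was dropped).
#' @export
build_design_matrix <- function(profiles, arms = NULL, spec = NULL) {
  if (inherits(profiles, "trial_record")) {
    arms <- profiles$arms
    spec <- profiles$design$spec
    profiles <- profiles$profiles
  }
  stopifnot(inherits(spec, "factor_spec"), nrow(profiles) == length(arms))
  n <- nrow(profiles)
  cols <- list("(Intercept)" = rep(1, n), treatment = as.numeric(arms == "T"))
  for (k in seq_len(spec$n_factors))
    for (l in 2:spec$levels[k])
      cols[[paste0(spec$names[k], ".l", l)]] <-
        as.numeric(profiles[, k] == l)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  dummy <- setdiff(colnames(X), c("(Intercept)", "treatment"))
  constant <- dummy[vapply(dummy, function(j) {
    v <- X[, j]
    all(v == v[1])
  }, logical(1))]
  if (length(constant)) X <- X[, setdiff(colnames(X), constant), drop = FALSE]
  list(X = X, treatment_col = "treatment", dropped = constant,
       degenerate = length(constant) > 0L)
}

fit_error <- function(msg) {
  stop(errorCondition(msg, class = c("twm_fit_error", "error")))
}

#' Ordinary-least-squares treatment-effect estimate
#'
#' Fits \eqn{y = X\gamma + \epsilon} by pivoted-QR least squares and
#' returns the treatment coefficient with its model-based variance
#' \eqn{\hat\sigma^2 [(X'X)^{-1}]_{zz}}, \eqn{\hat\sigma^2 = RSS/(n-p)},
#' and the two-sided t-test p-value on \eqn{n - p} residual degrees of
#' freedom.  Columns found collinear are dropped from the fit; if the
#' treatment column itself is collinear (e.g. every subject in one arm) or
#' no residual degrees of freedom remain, an error of class
#' \code{"twm_fit_error"} is signalled so the evaluation layer can exclude
#' the replicate with a logged count.
#'
#' @param y numeric response vector.
#' @param X design matrix (same row count), e.g. from
#'   [build_design_matrix()].
#' @param treatment_col name or index of the treatment column.
#' @return An object of class \code{"twm_fit"} with elements
#'   \code{estimate}, \code{variance_estimate}, \code{std_error},
#'   \code{p_value}, \code{t_value}, \code{residual_df}, \code{sigma2},
#'   \code{coefficients}, \code{aliased} and \code{degenerate}.
#' @examples
#' set.seed(7)
#' d <- simulate_trial(trial_design(20, treatment_effect = 1))
#' dm <- build_design_matrix(d)
#' fit_treatment_effect(d$responses, dm$X)
#' @export
fit_treatment_effect <- function(y, X, treatment_col = "treatment") {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("rows of 'X' must match length of 'y'", call. = FALSE)
  if (is.character(treatment_col))
    treatment_col <- match(treatment_col, colnames(X))
  if (is.na(treatment_col))
    stop("treatment column not found in 'X'", call. = FALSE)
  n <- nrow(X)
  qx <- qr(X)
  rank <- qx$rank
  used <- qx$pivot[seq_len(rank)]
  aliased <- colnames(X)[qx$pivot[-seq_len(rank)]]
  if (!(treatment_col %in% used))
    fit_error("treatment effect not estimable: treatment column collinear")
  df <- n - rank
  if (df < 1L) fit_error("no residual degrees of freedom")
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  # a numerically perfect fit (e.g. constant response) has zero residual
  # variance, not rounding dust
  if (rss <= 1e-24 * max(1, sum(y^2))) rss <- 0
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx)[seq_len(rank), seq_len(rank), drop = FALSE])
  j <- match(treatment_col, used)
  var_est <- sigma2 * xtx_inv[j, j]
  est <- unname(coefs[treatment_col])
  se <- sqrt(var_est)
  if (se == 0 && abs(est) <= 1e-8 * max(1, sqrt(mean(y^2)))) est <- 0
  tval <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(
    list(estimate = est, variance_estimate = var_est, std_error = se,
         p_value = pval, t_value = tval, residual_df = df, sigma2 = sigma2,
         coefficients = coefs, aliased = aliased,
         degenerate = length(aliased) > 0L),
    class = "twm_fit")
}

#' @export
print.twm_fit <- function(x, ...) {
  cat(sprintf(
    "Treatment effect: %.4f (SE %.4f), t = %.3f on %d df, p = %.4g\n",
    x$estimate, x$std_error, x$t_value, x$residual_df, x$p_value))
  if (x$degenerate)
    cat("  note: collinear column(s) dropped:",
        paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' Analyze one simulated trial
#'
#' Convenience wrapper: builds the design matrix and fits the treatment
#' effect.  With \code{adjust = FALSE} the model contains the intercept and
#' treatment only (the unadjusted difference-in-means analysis used for
#' allocation schemes that balance nothing).
#'
#' @param record a \code{"trial_record"}.
#' @param adjust include the prognostic-factor dummies? Default
#'   \code{TRUE}.
#' @return A \code{"twm_fit"}; the design-matrix degeneracy flag is OR-ed
#'   into the fit's.
#' @export
analyze_trial <- function(record, adjust = TRUE) {
  stopifnot(inherits(record, "trial_record"))
  if (adjust) {
    dm <- build_design_matrix(record)
    fit <- fit_treatment_effect(record$responses, dm$X, dm$treatment_col)
    fit$degenerate <- fit$degenerate || dm$degenerate
  } else {
    n <- length(record$arms)
    X <- cbind("(Intercept)" = rep(1, n),
               treatment = as.numeric(record$arms == "T"))
    fit <- fit_treatment_effect(record$responses, X)
  }
  fit
}
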