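# Monte-Carlo evaluation engine: replicated trials, Table-style metrics
# (bias, empirical and mean estimated variance, rejection rate) and the two
# allocation predictability indices.

max_seed <- function() .Machine$integer.max - 1L

#' Run a replicated simulation study
#'
#' Simulates independent trials under per-replicate child RNG streams, fits
#' each with [analyze_trial()], and aggregates: bias (mean estimate minus
#' the true effect), the empirical variance of the estimates, the mean of
#' the model-based variance estimates, the rejection rate at the 0.05
#' significance level, the two predictability indices and the mean final
#' imbalances.  Replicates whose treatment effect is not estimable are
#' excluded with a logged count.
#'
#' Cohort draws and allocation randomness use separate child seeds derived
#' from \code{seed}, so two studies run with the same seed but different
#' allocators face identical cohorts (common-cohort pairing).
#'
#' @param design a [trial_design()].
#' @param replicates number of simulated trials; defaults to the design's.
#' @param seed master seed; \code{NULL} continues the ambient RNG stream.
#' @param adjust analyze with prognostic-factor adjustment (default) or the
#'   unadjusted difference in means; see [analyze_trial()].
#' @param tie_mode Predictability-II handling of allocations faced with
#'   equal arm totals: \code{"exclude"} them from the denominator (default)
#'   or \code{"half"}-credit them.
#' @param significance two-sided rejection threshold (default 0.05).
#' @param keep retain the per-replicate estimates, variance estimates and
#'   p-values in the returned object.
#' @return An object of class \code{"twm_study"}; its \code{$metrics} is a
#'   one-row data frame (a [metrics_table()] row).
#' @examples
#' dsn <- trial_design(20, "three_binary", treatment_effect = 1,
#'                     replicates = 200)
#' run_study(dsn, seed = 42)
#' @export
run_study <- function(design, replicates = design$replicates, seed = NULL,
                      adjust = TRUE, tie_mode = c("exclude", "half"),
                      significance = 0.05, keep = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  tie_mode <- match.arg(tie_mode)
  replicates <- as.integer(replicates)
  if (!is.null(seed)) set.seed(seed)
  cohort_seeds <- sample.int(max_seed(), replicates)
  alloc_seeds <- sample.int(max_seed(), replicates)
  est <- numeric(replicates)
  vhat <- numeric(replicates)
  pval <- numeric(replicates)
  ok <- logical(replicates)
  sw_num <- 0; sw_den <- 0
  sm_num <- 0; sm_den <- 0; sm_tie <- 0
  d1_sum <- 0; d2_sum <- 0; d2_n <- 0
  for (r in seq_len(replicates)) {
    set.seed(cohort_seeds[r])
    cohort <- draw_cohort(design)
    set.seed(alloc_seeds[r])
    rec <- simulate_trial(design, cohort)
    fit <- tryCatch(analyze_trial(rec, adjust = adjust),
                    twm_fit_error = function(e) NULL)
    if (!is.null(fit)) {
      ok[r] <- TRUE
      est[r] <- fit$estimate
      vhat[r] <- fit$variance_estimate
      pval[r] <- fit$p_value
    }
    sw_num <- sw_num + sum(rec$switched, na.rm = TRUE)
    sw_den <- sw_den + sum(!is.na(rec$switched))
    sm_num <- sm_num + sum(rec$to_smaller, na.rm = TRUE)
    sm_den <- sm_den + sum(!is.na(rec$to_smaller))
    sm_tie <- sm_tie + sum(is.na(rec$to_smaller))
    d1_sum <- d1_sum + rec$final_d1
    if (!is.na(rec$final_d2)) {
      d2_sum <- d2_sum + rec$final_d2
      d2_n <- d2_n + 1
    }
  }
  excluded <- sum(!ok)
  if (excluded == replicates)
    stop("all replicates excluded: treatment effect never estimable",
         call. = FALSE)
  est <- est[ok]; vhat <- vhat[ok]; pval <- pval[ok]
  m <- length(est)
  rejection <- mean(pval < significance)
  pred2 <- if (tie_mode == "exclude") {
    if (sm_den > 0) sm_num / sm_den else NA_real_
  } else (sm_num + 0.5 * sm_tie) / (sm_den + sm_tie)
  metrics <- data.frame(
    method = design$allocator$method,
    q = if (design$allocator$method == "two_way") design$allocator$q
        else NA_real_,
    n = design$n, scenario = design$scenario,
    effect = design$treatment_effect,
    factor_effect_mean = design$factor_effect_mean,
    adjusted = adjust,
    replicates = replicates, excluded = excluded,
    bias = mean(est) - design$treatment_effect,
    empirical_variance = if (m > 1) stats::var(est) else NA_real_,
    mean_estimated_variance = mean(vhat),
    rejection_rate = rejection,
    rejection_se = sqrt(rejection * (1 - rejection) / m),
    predictability_I = if (sw_den > 0) sw_num / sw_den else NA_real_,
    predictability_II = pred2,
    mean_final_d1 = d1_sum / replicates,
    mean_final_d2 = if (d2_n > 0) d2_sum / d2_n else NA_real_,
    stringsAsFactors = FALSE)
  class(metrics) <- c("metrics_table", "data.frame")
  out <- list(metrics = metrics, design = design, seed = seed,
              replicates = replicates, excluded = excluded,
              tie_mode = tie_mode, adjust = adjust)
  if (keep) {
    out$estimates <- est
    out$variance_estimates <- vhat
    out$p_values <- pval
  }
  structure(out, class = "twm_study")
}

#' @export
print.twm_study <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Monte-Carlo study: %s allocator, n = %d, %s factors, effect %g (%d replicates, %d excluded)\n",
    m$method, m$n, m$scenario, m$effect, m$replicates, m$excluded))
  cat(sprintf("  bias %.4f | var %.4f (mean estimated %.4f) | rejection %.4f (SE %.4f)\n",
              m$bias, m$empirical_variance, m$mean_estimated_variance,
              m$rejection_rate, m$rejection_se))
  cat(sprintf("  predictability I %.4f, II %.4f | mean final D1 %.2f, D2 %.3f\n",
              m$predictability_I, m$predictability_II, m$mean_final_d1,
              m$mean_final_d2))
  invisible(x)
}

#' @export
summary.twm_study <- function(object, ...) object$metrics

#' Allocation predictability indices
#'
#' Recomputes, from the stored assignment sequences alone,
#' Predictability-I -- the probability that the next subject is allocated
#' to the arm different from the previous subject's -- and
#' Predictability-II -- the probability that the next subject is allocated
#' to the arm with fewer subjects so far.  Both are pooled over subjects
#' and replicates as ratios of sums.  Both are 0.5 for schemes a would-be
#' predictor cannot beat.
#'
#' @param records a \code{"trial_record"} or a list of them.
#' @param tie_mode Predictability-II treatment of equal-arm moments:
#'   \code{"exclude"} (default) or \code{"half"} credit.
#' @return Named numeric vector \code{c(predictability_I,
#'   predictability_II)}.
#' @export
predictability_indices <- function(records, tie_mode = c("exclude", "half")) {
  tie_mode <- match.arg(tie_mode)
  if (inherits(records, "trial_record")) records <- list(records)
  sw_num <- 0; sw_den <- 0
  sm_num <- 0; sm_den <- 0; sm_tie <- 0
  for (rec in records) {
    arms <- rec$arms
    n <- length(arms)
    if (n < 2L) next
    sw_num <- sw_num + sum(arms[-1] != arms[-n])
    sw_den <- sw_den + (n - 1L)
    cumT <- cumsum(arms == "T")
    nT_before <- c(0L, cumT[-n])
    nC_before <- (seq_len(n) - 1L) - nT_before
    diffb <- nT_before != nC_before
    smaller <- ifelse(nT_before < nC_before, "T", "C")
    sm_num <- sm_num + sum(arms[diffb] == smaller[diffb])
    sm_den <- sm_den + sum(diffb)
    sm_tie <- sm_tie + sum(!diffb)
  }
  p2 <- if (tie_mode == "exclude") {
    if (sm_den > 0) sm_num / sm_den else NA_real_
  } else (sm_num + 0.5 * sm_tie) / (sm_den + sm_tie)
  c(predictability_I = if (sw_den > 0) sw_num / sw_den else NA_real_,
    predictability_II = p2)
}

#' Sweep the two-way tuning parameter q
#'
#' Runs one study per value of the accrual tuning parameter, sharing the
#' master seed so all rows face common cohorts.  The \code{q = 0} boundary
#' is the pure covariate-adaptive rule A2.
#'
#' @param design a [trial_design()] whose allocator is \code{"two_way"}.
#' @param q_values numeric vector in \eqn{[0, 1]}.
#' @param replicates,seed,adjust,... passed to [run_study()].
#' @return A [metrics_table()] with one row per q.
#' @export
q_sweep <- function(design, q_values, replicates = design$replicates,
                    seed = NULL, adjust = TRUE, ...) {
  stopifnot(inherits(design, "trial_design"),
            design$allocator$method == "two_way")
  if (is.null(seed)) seed <- sample.int(max_seed(), 1)
  rows <- lapply(q_values, function(qv) {
    d <- design
    d$allocator$q <- qv
    run_study(d, replicates = replicates, seed = seed, adjust = adjust,
              ...)$metrics
  })
  tab <- do.call(rbind, rows)
  attr(tab, "seed") <- seed
  attr(tab, "common_cohorts") <- TRUE
  class(tab) <- c("metrics_table", "data.frame")
  tab
}

#' Compare allocation methods under common cohorts
#'
#' Runs one study per allocator with a shared master seed, so every method
#' faces the same subject profiles, prognostic effects and response noise
#' and differences are purely allocation-driven.
#'
#' By default (\code{adjust = "balanced"}) each method is analyzed
#' adjusting for the factors it balances: simple and block randomization
#' with the unadjusted difference in means, the four covariate-balancing
#' methods with the full regression adjustment.  \code{"all"} and
#' \code{"none"} force one analysis for every method.
#'
#' @param design a [trial_design()]; its own allocator is ignored.
#' @param methods character vector of method names and/or a list of
#'   [allocator_config()] objects.
#' @param replicates,seed,... passed to [run_study()].
#' @param adjust \code{"balanced"} (default), \code{"all"} or
#'   \code{"none"}.
#' @return A [metrics_table()] with one row per allocator.
#' @export
method_comparison <- function(design,
                              methods = c("simple", "block", "stratified",
                                          "deterministic_minimization",
                                          "biased_coin_minimization",
                                          "two_way"),
                              replicates = design$replicates, seed = NULL,
                              adjust = c("balanced", "all", "none"), ...) {
  stopifnot(inherits(design, "trial_design"))
  adjust <- match.arg(adjust)
  if (is.null(seed)) seed <- sample.int(max_seed(), 1)
  configs <- lapply(methods, function(m)
    if (inherits(m, "allocator_config")) m else allocator_config(m))
  rows <- lapply(configs, function(cfg) {
    d <- design
    d$allocator <- cfg
    adj <- switch(adjust,
      all = TRUE, none = FALSE,
      balanced = !cfg$method %in% c("simple", "block"))
    run_study(d, replicates = replicates, seed = seed, adjust = adj,
              ...)$metrics
  })
  tab <- do.call(rbind, rows)
  attr(tab, "seed") <- seed
  attr(tab, "common_cohorts") <- TRUE
  class(tab) <- c("metrics_table", "data.frame")
  tab
}

#' Metrics tables
#'
#' Aggregated Monte-Carlo results: one row per study cell (design x
#' allocator or q value) with bias, empirical and mean estimated variance,
#' rejection rate with its binomial standard error, the predictability
#' indices, exclusion counts and the mean final imbalances.  Produced by
#' [run_study()], [q_sweep()] and [method_comparison()]; written to disk by
#' [write_metrics()].
#'
#' @name metrics_table
#' @aliases metrics_table
NULL

#' @export
print.metrics_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @describeIn metrics_table four-panel summary (rejection rate, empirical
#'   variance, and the two predictability indices) against the sweep/
#'   comparison axis: q for a q-sweep table, the method for a comparison.
#' @param x a metrics table.
#' @param ... passed to the panel \code{plot()} calls.
#' @export
plot.metrics_table <- function(x, ...) {
  by_q <- !anyNA(x$q) && length(unique(x$q)) == nrow(x)
  xs <- if (by_q) x$q else seq_len(nrow(x))
  xlab <- if (by_q) "q" else ""
  old <- graphics::par(mfrow = c(2, 2),
                       mar = c(if (by_q) 4 else 7, 4, 2, 1))
  on.exit(graphics::par(old))
  panels <- c(rejection_rate = "Rejection rate",
              empirical_variance = "Empirical variance",
              predictability_I = "Predictability-I",
              predictability_II = "Predictability-II")
  for (j in names(panels)) {
    graphics::plot(xs, x[[j]], type = if (by_q) "b" else "p", pch = 19,
                   xlab = xlab, ylab = panels[[j]], xaxt = if (by_q) "s"
                   else "n", ...)
    if (!by_q)
      graphics::axis(1, at = xs, labels = x$method, las = 2,
                     cex.axis = 0.7)
  }
  invisible(x)
}
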