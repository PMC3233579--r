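#' Design of a simulated two-arm trial
#'
#' Fully determines one simulation scenario: cohort size, prognostic-factor
#' structure, treatment and prognostic effect sizes, allocation scheme and
#' replication count.  Responses are drawn from a normal distribution with
#' unit variance around a linear predictor of treatment plus factor
#' effects.
#'
#' @param n subjects per trial (>= 2); the study designs use 20 and 40.
#' @param factors \code{"three_binary"}, \code{"six_binary"},
#'   \code{"three_polytomous"} (5, 4 and 3 levels) or a custom
#'   [factor_spec()].
#' @param treatment_effect the true treatment effect \eqn{\alpha} added to
#'   treated subjects' mean response (0 for type-I-error studies; 0.5 and
#'   1.0 for power).
#' @param factor_effect_mean average effect \eqn{\bar\beta} of the
#'   prognostic factors; each non-reference level effect is drawn uniformly
#'   on \code{effect_range} (default \eqn{(0, 2\bar\beta)}, whose mean is
#'   \eqn{\bar\beta}).  Reference-level effects are 0 by definition.
#' @param allocator an [allocator_config()].
#' @param replicates default Monte-Carlo replication count for
#'   [run_study()].
#' @param effect_range optional length-2 numeric overriding the effect
#'   interval.
#' @param fixed_prevalences optional list of per-factor level-probability
#'   vectors; when supplied, prevalences are held fixed instead of being
#'   redrawn each replicate.
#' @return An object of class \code{"trial_design"}.
#' @examples
#' trial_design(20, "three_binary", treatment_effect = 1)
#' @export
trial_design <- function(n, factors = "three_binary", treatment_effect = 0,
                         factor_effect_mean = 1,
                         allocator = allocator_config("two_way"),
                         replicates = 10000L, effect_range = NULL,
                         fixed_prevalences = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2", call. = FALSE)
  if (is.character(factors)) {
    scenario <- factors
    spec <- scenario_factors(factors)
  } else {
    stopifnot(inherits(factors, "factor_spec"))
    scenario <- "custom"
    spec <- factors
  }
  stopifnot(inherits(allocator, "allocator_config"))
  if (factor_effect_mean < 0)
    stop("'factor_effect_mean' must be nonnegative", call. = FALSE)
  if (is.null(effect_range))
    effect_range <- c(0, 2 * factor_effect_mean)
  stopifnot(length(effect_range) == 2L, effect_range[1] <= effect_range[2])
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  if (!is.null(fixed_prevalences)) {
    ok <- length(fixed_prevalences) == spec$n_factors &&
      all(mapply(function(p, L) length(p) == L && all(p >= 0) &&
                   abs(sum(p) - 1) < 1e-8, fixed_prevalences, spec$levels))
    if (!ok)
      stop("'fixed_prevalences' must give a probability vector per factor",
           call. = FALSE)
  }
  structure(
    list(n = n, spec = spec, scenario = scenario,
         treatment_effect = treatment_effect,
         factor_effect_mean = factor_effect_mean,
         effect_range = as.numeric(effect_range),
         fixed_prevalences = fixed_prevalences,
         allocator = allocator, replicates = replicates),
    class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Trial design: n = %d, %s factors, treatment effect %g, mean prognostic effect %g\n",
    x$n, x$scenario, x$treatment_effect, x$factor_effect_mean))
  print(x$allocator)
  invisible(x)
}

#' Draw the per-factor level prevalences of one replicate
#'
#' Binary factors receive a non-reference-level probability drawn from
#' Uniform(0.2, 0.8), independently per factor and per replicate;
#' polytomous factors use equal chances for every level.  Fixed prevalences
#' in the design short-circuit the draw.
#'
#' @param design a [trial_design()].
#' @return List of level-probability vectors, one per factor.
#' @export
draw_prevalences <- function(design) {
  if (!is.null(design$fixed_prevalences)) return(design$fixed_prevalences)
  lapply(design$spec$levels, function(L) {
    if (L == 2L) {
      p <- stats::runif(1, 0.2, 0.8)
      c(1 - p, p)
    } else rep(1 / L, L)
  })
}

#' Draw the prognostic-factor effects of one replicate
#'
#' Each non-reference level's effect is an independent draw from the
#' design's uniform effect interval (default \eqn{(0, 2\bar\beta)});
#' reference-level effects are fixed at 0.
#'
#' @param design a [trial_design()].
#' @return List of effect vectors, one per factor, first entry 0.
#' @export
draw_effects <- function(design) {
  lo <- design$effect_range[1]
  hi <- design$effect_range[2]
  lapply(design$spec$levels, function(L)
    c(0, stats::runif(L - 1L, lo, hi)))
}

#' Draw a complete cohort for one replicate
#'
#' Everything in a simulated trial that does not depend on the allocation:
#' prevalences, factor effects, subject profiles and the unit-variance
#' normal response noise.  Sharing a cohort across allocators (as
#' [method_comparison()] does) makes their differences purely
#' allocation-driven.
#'
#' @param design a [trial_design()].
#' @param n number of subjects; defaults to the design's.
#' @return A list with \code{prevalences}, \code{effects}, \code{profiles}
#'   (an \code{n} x K integer matrix of level indices) and \code{eps}.
#' @export
draw_cohort <- function(design, n = design$n) {
  prevalences <- draw_prevalences(design)
  effects <- draw_effects(design)
  K <- design$spec$n_factors
  profiles <- matrix(0L, nrow = n, ncol = K,
                     dimnames = list(NULL, design$spec$names))
  for (k in seq_len(K))
    profiles[, k] <- sample.int(design$spec$levels[k], n, replace = TRUE,
                                prob = prevalences[[k]])
  list(prevalences = prevalences, effects = effects, profiles = profiles,
       eps = stats::rnorm(n))
}

#' Simulate one complete trial
#'
#' Draws (or reuses) a cohort, allocates each subject in sequence with the
#' design's allocator against the running trial state, records the
#' per-subject predictability bookkeeping using the state \emph{before}
#' each allocation, and generates the responses
#' \eqn{y_i \sim N(\alpha\,1[\mathrm{arm}_i = T] + \sum_k \beta_{k,x_{ik}},\, 1)}.
#'
#' @param design a [trial_design()].
#' @param cohort optionally a cohort from [draw_cohort()]; its row count
#'   overrides the design's \code{n} (useful for prefix replays).
#' @return An object of class \code{"trial_record"}: profiles, arms,
#'   responses, prediction flags (\code{switched}: arm differs from the
#'   previous subject's; \code{to_smaller}: allocated to the currently
#'   smaller arm, \code{NA} when the arms were equal), the final arm-size
#'   and distributional imbalances, and the cohort draws.
#' @export
simulate_trial <- function(design, cohort = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (is.null(cohort)) cohort <- draw_cohort(design)
  profiles <- cohort$profiles
  n <- nrow(profiles)
  alloc <- alloc_loop(design$allocator, design$spec, profiles)
  lp <- design$treatment_effect * (alloc$arms == "T")
  for (k in seq_len(design$spec$n_factors))
    lp <- lp + cohort$effects[[k]][profiles[, k]]
  structure(
    list(design = design, profiles = profiles, arms = alloc$arms,
         responses = lp + cohort$eps,
         switched = alloc$switched, to_smaller = alloc$to_smaller,
         final_d1 = alloc$final_d1, final_d2 = alloc$final_d2,
         prevalences = cohort$prevalences, effects = cohort$effects),
    class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "Simulated trial: n = %d (T = %d, C = %d), allocator %s, final D1 = %d, D2 = %.4f\n",
    length(x$arms), sum(x$arms == "T"), sum(x$arms == "C"),
    x$design$allocator$method, x$final_d1, x$final_d2))
  invisible(x)
}

# Sequential allocation engine used by simulate_trial().  Operates on raw
# count matrices for speed; its decisions are definitionally identical to
# the exported per-subject allocators (asserted in the test suite by
# replaying seeds through allocate_sequence()).
alloc_loop <- function(cfg, spec, profiles) {
  n <- nrow(profiles)
  K <- spec$n_factors
  Lmax <- max(spec$levels)
  w <- spec$weights
  cT <- matrix(0, K, Lmax)
  cC <- matrix(0, K, Lmax)
  nT <- 0L
  nC <- 0L
  arms <- character(n)
  switched <- rep(NA, n)
  to_smaller <- rep(NA, n)
  method <- cfg$method
  q <- cfg$q
  bs <- cfg$block_size
  cp <- cfg$coin_probability
  burn <- cfg$burn_in
  use_l1 <- identical(cfg$distance, "L1")
  dist_fun <- if (!use_l1) resolve_distance(cfg$distance)
  if (method == "stratified")
    strata <- new.env(hash = TRUE, parent = emptyenv())
  kseq <- seq_len(K)
  for (i in seq_len(n)) {
    p <- profiles[i, ]
    idx <- cbind(kseq, p)
    if (method == "simple") {
      arm <- if (stats::runif(1) < 0.5) "T" else "C"
    } else if (method == "block") {
      pos <- (i - 1L) %% bs
      used <- if (pos == 0L) 0L else sum(arms[(i - pos):(i - 1L)] == "T")
      arm <- if (stats::runif(1) < (bs / 2 - used) / (bs - pos)) "T" else "C"
    } else if (method == "stratified") {
      key <- paste(p, collapse = ".")
      h <- strata[[key]]
      if (is.null(h)) h <- character(0)
      pos <- length(h) %% bs
      used <- if (pos == 0L) 0L else
        sum(h[(length(h) - pos + 1L):length(h)] == "T")
      arm <- if (stats::runif(1) < (bs / 2 - used) / (bs - pos)) "T" else "C"
      strata[[key]] <- c(h, arm)
    } else if (method == "deterministic_minimization" ||
               method == "biased_coin_minimization") {
      dk <- cT[idx] - cC[idx]
      sT <- sum(abs(dk + 1))
      sC <- sum(abs(dk - 1))
      if (abs(sT - sC) <= TWM_TIE_TOL) {
        arm <- if (stats::runif(1) < 0.5) "T" else "C"
      } else {
        preferred <- if (sT < sC) "T" else "C"
        pick <- if (method == "deterministic_minimization") TRUE
                else stats::runif(1) < cp
        arm <- if (pick) preferred else if (preferred == "T") "C" else "T"
      }
    } else {  # two_way
      if (nT < burn || nC < burn) {
        arm <- if (stats::runif(1) < 0.5) "T" else "C"
      } else if (stats::runif(1) < 1 - (1 - q)^abs(nT - nC)) {
        arm <- if (nT < nC) "T" else if (nC < nT) "C"
               else if (stats::runif(1) < 0.5) "T" else "C"
      } else {
        if (use_l1) {
          aT <- cT
          aT[idx] <- aT[idx] + 1
          d2T <- sum(w * rowSums(abs(aT / (nT + 1) - cC / nC)))
          aC <- cC
          aC[idx] <- aC[idx] + 1
          d2C <- sum(w * rowSums(abs(cT / nT - aC / (nC + 1))))
        } else {
          d2T <- 0
          d2C <- 0
          for (k in kseq) {
            L <- seq_len(spec$levels[k])
            tk <- cT[k, L]
            ck <- cC[k, L]
            tk1 <- tk
            tk1[p[k]] <- tk1[p[k]] + 1
            ck1 <- ck
            ck1[p[k]] <- ck1[p[k]] + 1
            d2T <- d2T + w[k] * dist_fun(tk1 / (nT + 1), ck / nC)
            d2C <- d2C + w[k] * dist_fun(tk / nT, ck1 / (nC + 1))
          }
        }
        arm <- if (d2T < d2C - TWM_TIE_TOL) "T"
               else if (d2C < d2T - TWM_TIE_TOL) "C"
               else if (stats::runif(1) < 0.5) "T" else "C"
      }
    }
    arms[i] <- arm
    if (i > 1L) switched[i] <- arm != arms[i - 1L]
    if (nT != nC) to_smaller[i] <- arm == (if (nT < nC) "T" else "C")
    if (arm == "T") {
      cT[idx] <- cT[idx] + 1
      nT <- nT + 1L
    } else {
      cC[idx] <- cC[idx] + 1
      nC <- nC + 1L
    }
  }
  final_d2 <- if (nT > 0L && nC > 0L) {
    if (use_l1) sum(w * rowSums(abs(cT / nT - cC / nC)))
    else sum(w * vapply(kseq, function(k) {
      L <- seq_len(spec$levels[k])
      dist_fun(cT[k, L] / nT, cC[k, L] / nC)
    }, numeric(1)))
  } else NA_real_
  list(arms = arms, switched = switched, to_smaller = to_smaller,
       final_d1 = abs(nT - nC), final_d2 = final_d2)
}
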