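# Allocation schemes.  Shared contract: given the current trial state, the
# new subject's factor profile and the ambient RNG stream, return "T" or "C".
# All randomness is drawn from R's global RNG, so a caller-side set.seed()
# makes every allocation sequence reproducible.

# Ties in score/imbalance comparisons: differences below this are ties and
# resolved by a fair coin.  Imbalance differences are rationals with small
# denominators, so 1e-12 sits far below their granularity.
TWM_TIE_TOL <- 1e-12

fair_coin <- function() if (stats::runif(1) < 0.5) "T" else "C"

#' Allocator configuration
#'
#' Bundles an allocation method with its tuning parameters.
#'
#' @param method one of \code{"simple"}, \code{"block"}, \code{"stratified"},
#'   \code{"deterministic_minimization"}, \code{"biased_coin_minimization"},
#'   \code{"two_way"}.
#' @param block_size even positive integer, the permuted-block length used by
#'   block and stratified randomization (default 4).
#' @param coin_probability probability, in \eqn{[0.5, 1]}, with which
#'   biased-coin minimization picks the score-minimizing arm (default 0.7;
#'   1 recovers deterministic minimization, 0.5 simple randomization).
#' @param q tuning parameter of the geometric accrual function of two-way
#'   minimization, in \eqn{[0, 1]} (default 0.05).  The boundaries give the
#'   degenerate pure rules: \code{q = 0} always applies the covariate rule
#'   A2, \code{q = 1} applies the size rule A1 whenever the arms differ.
#' @param burn_in minimum number of subjects required in \emph{each} arm
#'   before two-way minimization leaves its initial simple-randomization
#'   phase (default 1, the weakest condition making the arm-wise level
#'   proportions well defined).
#' @param distance distribution distance used by the two-way covariate rule;
#'   see [factor_imbalance()].
#' @return An object of class \code{"allocator_config"}.
#' @export
allocator_config <- function(method = c("two_way", "simple", "block",
                                        "stratified",
                                        "deterministic_minimization",
                                        "biased_coin_minimization"),
                             block_size = 4L, coin_probability = 0.7,
                             q = 0.05, burn_in = 1L, distance = "L1") {
  method <- match.arg(method)
  block_size <- as.integer(block_size)
  if (block_size < 2L || block_size %% 2L != 0L)
    stop("'block_size' must be a positive even integer", call. = FALSE)
  if (!is.numeric(coin_probability) || coin_probability < 0.5 ||
      coin_probability > 1)
    stop("'coin_probability' must lie in [0.5, 1]", call. = FALSE)
  if (!is.numeric(q) || q < 0 || q > 1)
    stop("'q' must lie in [0, 1]", call. = FALSE)
  burn_in <- as.integer(burn_in)
  if (burn_in < 1L) stop("'burn_in' must be >= 1", call. = FALSE)
  resolve_distance(distance)  # fail early on a bad distance
  structure(list(method = method, block_size = block_size,
                 coin_probability = coin_probability, q = q,
                 burn_in = burn_in, distance = distance),
            class = "allocator_config")
}

#' @export
print.allocator_config <- function(x, ...) {
  cat("Allocator:", x$method, "\n")
  extras <- switch(x$method,
    block      = sprintf("block size %d", x$block_size),
    stratified = sprintf("block size %d", x$block_size),
    biased_coin_minimization =
      sprintf("coin probability %g", x$coin_probability),
    two_way = sprintf("q = %g, burn-in %d per arm, %s distance", x$q,
                      x$burn_in,
                      if (is.function(x$distance)) "custom" else x$distance),
    NULL)
  if (!is.null(extras)) cat(" ", extras, "\n")
  invisible(x)
}

#' Geometric accrual probability of the size-balancing rule
#'
#' The probability \eqn{\pi(D_1) = 1 - (1 - q)^{D_1}} with which two-way
#' minimization applies rule A1 (minimize the arm-size imbalance) rather
#' than rule A2 (minimize the covariate-distribution imbalance).  It is 0
#' at \eqn{D_1 = 0}, strictly increasing in \eqn{D_1} for \eqn{q \in (0,1)},
#' and tends to 1 as \eqn{D_1 \to \infty}; \code{q} governs the accrual
#' rate.
#'
#' @param d1 nonnegative integer arm-size imbalance(s).
#' @param q tuning parameter in \eqn{[0, 1]}.
#' @return Probability vector of the same length as \code{d1}.
#' @examples
#' accrual_probability(0:5, q = 0.05)
#' @export
accrual_probability <- function(d1, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1)
    stop("'q' must be a single value in [0, 1]", call. = FALSE)
  if (any(d1 < 0)) stop("'d1' must be nonnegative", call. = FALSE)
  1 - (1 - q)^d1
}

#' Simple randomization
#'
#' A fair coin per subject, independent of the trial state.
#' @return \code{"T"} or \code{"C"}.
#' @export
allocate_simple <- function() fair_coin()

#' Permuted-block randomization
#'
#' Each consecutive block of \code{block_size} subjects receives exactly
#' half of each arm, in uniformly random order.  Implemented as an urn draw
#' over the remaining slots of the current block, which is distributionally
#' identical to drawing the whole block permutation upfront; in particular
#' the final slots of a block are forced.
#'
#' @param previous_arms character vector of the arms already assigned in
#'   this sequence (possibly empty).
#' @param block_size even positive integer.
#' @return \code{"T"} or \code{"C"}.
#' @export
allocate_block <- function(previous_arms, block_size = 4L) {
  block_size <- as.integer(block_size)
  if (block_size < 2L || block_size %% 2L != 0L)
    stop("'block_size' must be a positive even integer", call. = FALSE)
  done <- length(previous_arms)
  in_block <- previous_arms[seq_len(done) > done - done %% block_size]
  rem_T <- block_size / 2 - sum(in_block == "T")
  rem_C <- block_size / 2 - sum(in_block == "C")
  if (stats::runif(1) < rem_T / (rem_T + rem_C)) "T" else "C"
}

# Cross-classification cell of a profile, used as the stratum key.
stratum_key <- function(profile) paste(profile, collapse = ".")

#' Stratified permuted-block randomization
#'
#' Permuted-block randomization run independently within the subject's
#' stratum, the full cross-classification cell of its factor levels.  A
#' truncated final block in a stratum simply stops with the trial.
#'
#' @param strata_history named list mapping stratum keys (see below) to the
#'   character vector of arms previously assigned in that stratum; an
#'   absent key means an empty stratum.
#' @param profile the subject's integer level indices; its stratum key is
#'   the levels pasted with \code{"."}.
#' @param block_size even positive integer.
#' @return \code{"T"} or \code{"C"}.
#' @export
allocate_stratified <- function(strata_history, profile, block_size = 4L) {
  key <- stratum_key(profile)
  prev <- strata_history[[key]]
  if (is.null(prev)) prev <- character(0)
  allocate_block(prev, block_size)
}

#' Pocock-Simon marginal imbalance score
#'
#' The hypothetical sum over factors of the absolute treatment/control
#' count difference at the subject's own levels after placing the subject
#' in the given arm: raw marginal counts, equal factor weights.  This is
#' the criterion both minimization comparators minimize.
#'
#' @param state a [trial_state()].
#' @param profile integer vector of level indices, one per factor.
#' @param arm the hypothetical arm, \code{"T"} or \code{"C"}.
#' @return Nonnegative integer-valued score.
#' @export
marginal_imbalance_score <- function(state, profile, arm) {
  stopifnot(inherits(state, "trial_state"))
  arm <- arm_label(arm)
  profile <- check_profile(profile, state$spec)
  idx <- cbind(seq_len(state$spec$n_factors), profile)
  nT <- state$counts$T[idx]
  nC <- state$counts$C[idx]
  if (arm == "T") nT <- nT + 1L else nC <- nC + 1L
  sum(abs(nT - nC))
}

#' Deterministic Pocock-Simon minimization
#'
#' Assigns the subject to the arm with the strictly smaller marginal
#' imbalance score; a fair coin breaks ties.  Highly balanced but highly
#' predictable.
#'
#' @inheritParams marginal_imbalance_score
#' @return \code{"T"} or \code{"C"}.
#' @export
allocate_det_minimization <- function(state, profile) {
  sT <- marginal_imbalance_score(state, profile, "T")
  sC <- marginal_imbalance_score(state, profile, "C")
  if (sT < sC - TWM_TIE_TOL) "T"
  else if (sC < sT - TWM_TIE_TOL) "C"
  else fair_coin()
}

#' Biased-coin Pocock-Simon minimization
#'
#' As deterministic minimization, but the score-minimizing arm is chosen
#' only with probability \code{coin_probability} (fair coin on score ties).
#'
#' @inheritParams marginal_imbalance_score
#' @param coin_probability probability in \eqn{[0.5, 1]}; 1 recovers the
#'   deterministic rule, 0.5 simple randomization.
#' @return \code{"T"} or \code{"C"}.
#' @export
allocate_biased_coin <- function(state, profile, coin_probability = 0.7) {
  if (!is.numeric(coin_probability) || coin_probability < 0.5 ||
      coin_probability > 1)
    stop("'coin_probability' must lie in [0.5, 1]", call. = FALSE)
  sT <- marginal_imbalance_score(state, profile, "T")
  sC <- marginal_imbalance_score(state, profile, "C")
  if (abs(sT - sC) <= TWM_TIE_TOL) return(fair_coin())
  preferred <- if (sT < sC) "T" else "C"
  if (stats::runif(1) < coin_probability) preferred else other_arm(preferred)
}

# Rule A1: minimize the arm-size imbalance.
two_way_rule_size <- function(state) {
  if (state$n[["T"]] < state$n[["C"]]) "T"
  else if (state$n[["C"]] < state$n[["T"]]) "C"
  else fair_coin()
}

# Rule A2: minimize the prospective overall distributional imbalance.
two_way_rule_distribution <- function(state, profile, distance = "L1") {
  d2T <- prospective_imbalance(state, profile, "T", distance = distance)
  d2C <- prospective_imbalance(state, profile, "C", distance = distance)
  if (d2T < d2C - TWM_TIE_TOL) "T"
  else if (d2C < d2T - TWM_TIE_TOL) "C"
  else fair_coin()
}

#' Two-way minimization
#'
#' The adaptive allocation scheme that is both treatment-adaptive and
#' covariate-adaptive.  While either arm holds fewer than \code{burn_in}
#' subjects, allocation is by fair coin.  Afterwards a Bernoulli draw with
#' probability [accrual_probability()] of the current arm-size imbalance
#' selects rule A1 (allocate to the arm with fewer subjects; fair coin if
#' the arms are equal) or rule A2 (allocate to the arm whose hypothetical
#' overall distributional imbalance is smaller; fair coin on ties).  When
#' the arms are equal in size the accrual probability is zero, so the
#' decision is then purely covariate-adaptive.  Because both rules are
#' comparison-based and the Bernoulli weight is stochastic, every
#' allocation decision is invariant to strictly monotone transformations
#' of either imbalance measure.
#'
#' @inheritParams marginal_imbalance_score
#' @param q,burn_in,distance see [allocator_config()].
#' @return \code{"T"} or \code{"C"}.
#' @examples
#' set.seed(1)
#' spec <- factor_spec(c(2, 2, 2))
#' st <- trial_state(spec)
#' st <- update(st, c(1, 1, 2), allocate_two_way(st, c(1, 1, 2)))
#' st <- update(st, c(2, 1, 1), allocate_two_way(st, c(2, 1, 1)))
#' allocate_two_way(st, c(2, 2, 2))
#' @export
allocate_two_way <- function(state, profile, q = 0.05, burn_in = 1L,
                             distance = "L1") {
  stopifnot(inherits(state, "trial_state"))
  profile <- check_profile(profile, state$spec)
  if (min(state$n) < burn_in) return(fair_coin())
  d1 <- total_imbalance(state)
  if (stats::runif(1) < accrual_probability(d1, q))
    two_way_rule_size(state)
  else
    two_way_rule_distribution(state, profile, distance = distance)
}

#' Sequentially allocate a series of subjects
#'
#' The real-time engine behind the command-line \code{allocate} mode: runs
#' any configured allocator over consecutively recruited subjects,
#' maintaining (and optionally resuming) the trial state.
#'
#' @param profiles an integer matrix (subjects x factors) of level indices,
#'   or a data frame whose columns hold the level labels declared in
#'   \code{spec} (malformed labels are rejected).
#' @param config an [allocator_config()].
#' @param spec a [factor_spec()]; defaults to the spec of \code{state}.
#' @param state a [trial_state()] to resume from, or \code{NULL} to start a
#'   fresh trial.
#' @param strata_history for stratified randomization, the named list of
#'   per-stratum arm histories matching \code{state} (as returned by a
#'   previous call); \code{NULL} rebuilds nothing and starts empty strata.
#' @return A list with \code{arms} (character vector, one per new subject),
#'   the final \code{state}, and \code{strata_history}.
#' @export
allocate_sequence <- function(profiles, config, spec = state$spec,
                              state = NULL, strata_history = NULL) {
  stopifnot(inherits(config, "allocator_config"))
  if (is.null(state)) state <- trial_state(spec)
  stopifnot(inherits(state, "trial_state"))
  prof_mat <- profiles_to_matrix(profiles, state$spec)
  if (is.null(strata_history)) strata_history <- list()
  n_new <- nrow(prof_mat)
  arms <- character(n_new)
  for (i in seq_len(n_new)) {
    p <- prof_mat[i, ]
    arm <- switch(config$method,
      simple  = allocate_simple(),
      block   = allocate_block(state$history, config$block_size),
      stratified = allocate_stratified(strata_history, p,
                                       config$block_size),
      deterministic_minimization = allocate_det_minimization(state, p),
      biased_coin_minimization =
        allocate_biased_coin(state, p, config$coin_probability),
      two_way = allocate_two_way(state, p, q = config$q,
                                 burn_in = config$burn_in,
                                 distance = config$distance))
    arms[i] <- arm
    state <- update(state, p, arm)
    if (config$method == "stratified") {
      key <- stratum_key(p)
      strata_history[[key]] <- c(strata_history[[key]], arm)
    }
  }
  list(arms = arms, state = state, strata_history = strata_history)
}

# Map a covariate table (labels or indices) to an integer profile matrix.
profiles_to_matrix <- function(profiles, spec) {
  if (is.data.frame(profiles)) {
    if (ncol(profiles) != spec$n_factors)
      stop("covariate table must have one column per factor (",
           spec$n_factors, " expected)", call. = FALSE)
    cols <- lapply(seq_len(spec$n_factors), function(k) {
      v <- profiles[[k]]
      if (is.numeric(v)) return(as.integer(v))
      if (is.null(spec$labels))
        stop("factor levels are labels but the factor spec declares none",
             call. = FALSE)
      idx <- match(as.character(v), spec$labels[[k]])
      if (anyNA(idx))
        stop("unknown level(s) for factor '", spec$names[k], "': ",
             paste(unique(v[is.na(idx)]), collapse = ", "), call. = FALSE)
      idx
    })
    prof_mat <- do.call(cbind, cols)
  } else {
    prof_mat <- as.matrix(profiles)
    storage.mode(prof_mat) <- "integer"
  }
  apply(prof_mat, 1L, check_profile, spec = spec)
  prof_mat
}
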