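#' Running allocation state of a two-arm trial
#'
#' Holds the per-arm subject totals, the per-arm, per-factor, per-level
#' counts, and the ordered assignment history.  Every allocator reads (and,
#' through [update()], writes) this object.  Arms are labelled \code{"T"}
#' (treatment) and \code{"C"} (control).
#'
#' @param spec a [factor_spec()].
#' @return An object of class \code{"trial_state"} with zero subjects.
#' @seealso [update.trial_state()], [total_imbalance()],
#'   [overall_imbalance()], [write_trial_state()]
#' @examples
#' st <- trial_state(factor_spec(c(2, 2)))
#' st <- update(st, profile = c(1, 2), arm = "T")
#' total_imbalance(st)
#' @export
trial_state <- function(spec) {
  stopifnot(inherits(spec, "factor_spec"))
  K <- spec$n_factors
  Lmax <- max(spec$levels)
  zero <- matrix(0L, nrow = K, ncol = Lmax,
                 dimnames = list(spec$names, paste0("l", seq_len(Lmax))))
  structure(
    list(spec = spec, n = c(T = 0L, C = 0L),
         counts = list(T = zero, C = zero), history = character(0)),
    class = "trial_state")
}

arm_label <- function(arm) {
  arm <- as.character(arm)
  if (length(arm) != 1L || !arm %in% c("T", "C"))
    stop("'arm' must be \"T\" or \"C\"", call. = FALSE)
  arm
}

other_arm <- function(arm) if (arm == "T") "C" else "T"

check_profile <- function(profile, spec) {
  profile <- as.integer(profile)
  if (length(profile) != spec$n_factors || anyNA(profile))
    stop("profile must give one level index per factor (",
         spec$n_factors, " expected)", call. = FALSE)
  bad <- which(profile < 1L | profile > spec$levels)
  if (length(bad))
    stop("profile level out of range for factor(s) ",
         paste(spec$names[bad], collapse = ", "),
         " (got ", paste(profile[bad], collapse = ", "), ")", call. = FALSE)
  profile
}

#' Add an allocated subject to the trial state
#'
#' Returns a new state with the subject's arm total incremented, the count at
#' the subject's level of every factor incremented in that arm, and the arm
#' appended to the history.  The input state is not modified.
#'
#' @param object a [trial_state()].
#' @param profile integer vector of level indices, one per factor.
#' @param arm \code{"T"} or \code{"C"}.
#' @param ... unused.
#' @return The updated \code{"trial_state"}.
#' @export
update.trial_state <- function(object, profile, arm, ...) {
  arm <- arm_label(arm)
  profile <- check_profile(profile, object$spec)
  idx <- cbind(seq_len(object$spec$n_factors), profile)
  object$n[[arm]] <- object$n[[arm]] + 1L
  object$counts[[arm]][idx] <- object$counts[[arm]][idx] + 1L
  object$history <- c(object$history, arm)
  object
}

#' Imbalance in the total numbers of subjects
#'
#' The absolute difference between the two arm totals, the trial-size
#' imbalance that rule A1 of two-way minimization acts on.
#'
#' @param state a [trial_state()].
#' @return Nonnegative integer.
#' @export
total_imbalance <- function(state) {
  stopifnot(inherits(state, "trial_state"))
  abs(state$n[["T"]] - state$n[["C"]])
}

burnin_error <- function(arm) {
  stop(errorCondition(
    paste0("arm \"", arm, "\" is empty: distributional imbalance is ",
           "undefined until both arms contain a subject (burn-in phase)"),
    class = c("twm_burnin_error", "error")))
}

#' Level distribution of one factor within one arm
#'
#' The level counts of the given factor in the given arm divided by that
#' arm's total; entries sum to 1.
#'
#' @inheritParams total_imbalance
#' @param arm \code{"T"} or \code{"C"}; must contain at least one subject.
#' @param factor integer factor index.
#' @return Numeric vector of proportions, one per level of the factor.
#' @export
factor_distribution <- function(state, arm, factor) {
  stopifnot(inherits(state, "trial_state"))
  arm <- arm_label(arm)
  factor <- as.integer(factor)
  stopifnot(length(factor) == 1L, factor >= 1L,
            factor <= state$spec$n_factors)
  if (state$n[[arm]] == 0L) burnin_error(arm)
  unname(state$counts[[arm]][factor, seq_len(state$spec$levels[factor])] /
    state$n[[arm]])
}

#' Distributional imbalance of one prognostic factor
#'
#' A distance between the two arms' level-proportion distributions of the
#' factor; with the default L1 distance this is
#' \eqn{\sum_l |p_{T,kl} - p_{C,kl}|}, zero iff the two distributions are
#' identical and at most 2.
#'
#' @inheritParams factor_distribution
#' @param distance \code{"L1"} (default), \code{"max"} (largest per-level
#'   discrepancy), or a \code{function(pT, pC)} returning a nonnegative real.
#' @return Nonnegative real.
#' @export
factor_imbalance <- function(state, factor, distance = "L1") {
  dist_fun <- resolve_distance(distance)
  dist_fun(factor_distribution(state, "T", factor),
           factor_distribution(state, "C", factor))
}

#' Overall distributional imbalance across prognostic factors
#'
#' The weighted sum over factors of the per-factor distributional
#' imbalances, using the weights of the state's [factor_spec()].  This is
#' the quantity rule A2 of two-way minimization minimizes prospectively.
#'
#' @inheritParams factor_imbalance
#' @return Nonnegative real; bounded by twice the sum of the weights for the
#'   L1 distance.
#' @export
overall_imbalance <- function(state, distance = "L1") {
  stopifnot(inherits(state, "trial_state"))
  if (state$n[["T"]] == 0L) burnin_error("T")
  if (state$n[["C"]] == 0L) burnin_error("C")
  dist_fun <- resolve_distance(distance)
  spec <- state$spec
  d <- vapply(seq_len(spec$n_factors), function(k) {
    L <- seq_len(spec$levels[k])
    dist_fun(state$counts$T[k, L] / state$n[["T"]],
             state$counts$C[k, L] / state$n[["C"]])
  }, numeric(1))
  sum(spec$weights * d)
}

#' Overall imbalance after a hypothetical allocation
#'
#' The overall distributional imbalance of the state that would result from
#' allocating the given subject to the given arm.  The input state is left
#' untouched; by construction the value equals
#' \code{overall_imbalance(update(state, profile, arm))}.
#'
#' @inheritParams overall_imbalance
#' @param profile integer vector of level indices, one per factor.
#' @param arm the hypothetical arm, \code{"T"} or \code{"C"}.
#' @return Nonnegative real.
#' @export
prospective_imbalance <- function(state, profile, arm, distance = "L1") {
  stopifnot(inherits(state, "trial_state"))
  arm <- arm_label(arm)
  if (state$n[[other_arm(arm)]] == 0L) burnin_error(other_arm(arm))
  overall_imbalance(update(state, profile, arm), distance = distance)
}

#' @export
print.trial_state <- function(x, ...) {
  cat(sprintf("Trial state: %d subject(s) (T = %d, C = %d), D1 = %d\n",
              sum(x$n), x$n[["T"]], x$n[["C"]], total_imbalance(x)))
  if (all(x$n > 0L))
    cat(sprintf("Overall distributional imbalance D2 (L1): %.4f\n",
                overall_imbalance(x)))
  invisible(x)
}

#' Serialize a trial state to JSON
#'
#' Writes (or returns) a plain JSON document with the factor specification,
#' arm totals, count tensors and assignment history, so that a real trial
#' can be resumed between subjects with [read_trial_state()].
#'
#' @param state a [trial_state()].
#' @param path optional file path; if \code{NULL} the JSON string is
#'   returned.
#' @return \code{path} invisibly, or the JSON string.
#' @export
write_trial_state <- function(state, path = NULL) {
  stopifnot(inherits(state, "trial_state"))
  doc <- list(
    format = "twowaymin-trial-state",
    spec = list(levels = state$spec$levels, weights = state$spec$weights,
                names = state$spec$names, labels = state$spec$labels),
    n = as.list(state$n),
    counts = list(T = state$counts$T, C = state$counts$C),
    history = state$history)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Restore a trial state from JSON
#'
#' @param path file path or a JSON string produced by [write_trial_state()].
#' @return A validated \code{"trial_state"}.
#' @export
read_trial_state <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "twowaymin-trial-state"))
    stop("not a twowaymin trial-state document", call. = FALSE)
  labels <- doc$spec$labels
  if (is.null(labels) || length(labels) == 0L) labels <- NULL
  else labels <- lapply(labels, as.character)
  spec <- factor_spec(doc$spec$levels, doc$spec$weights,
                      labels = labels, names = doc$spec$names)
  st <- trial_state(spec)
  st$n <- c(T = as.integer(doc$n$T), C = as.integer(doc$n$C))
  for (a in c("T", "C")) {
    m <- matrix(as.integer(doc$counts[[a]]), nrow = spec$n_factors,
                dimnames = dimnames(st$counts[[a]]))
    st$counts[[a]] <- m
  }
  st$history <- as.character(doc$history)
  validate_trial_state(st)
  st
}

# Internal invariant check: counts consistent with totals and history.
validate_trial_state <- function(state) {
  for (a in c("T", "C")) {
    if (any(state$counts[[a]] < 0L)) stop("negative counts", call. = FALSE)
    sums <- rowSums(state$counts[[a]])
    if (any(sums != state$n[[a]]))
      stop("level counts do not sum to the arm total for arm ", a,
           call. = FALSE)
    if (sum(state$history == a) != state$n[[a]])
      stop("history inconsistent with arm totals for arm ", a, call. = FALSE)
  }
  invisible(state)
}
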