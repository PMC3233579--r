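#' Prognostic-factor structure of a two-arm trial
#'
#' Describes the categorical prognostic factors to be balanced: how many
#' factors, how many levels each has, the nonnegative weight each factor
#' carries in the overall distributional imbalance, and (optionally) the
#' level labels used when allocating from a covariate table.  Level 1 of
#' every factor is the designated reference level.
#'
#' @param levels integer vector, one entry per factor, each >= 2: the number
#'   of levels of that factor.
#' @param weights nonnegative numeric vector of the same length; the weights
#'   of the weighted sum defining the overall distributional imbalance.
#'   Defaults to 1 for every factor; at least one weight must be positive.
#' @param labels optional list of character vectors (one per factor) naming
#'   the levels; the first label of each factor is the reference level.
#' @param names optional character vector of factor names; defaults to
#'   \code{f1, f2, ...}.
#'
#' @return An object of class \code{"factor_spec"}.
#' @examples
#' factor_spec(c(2, 2, 2))                     # three binary factors
#' factor_spec(c(5, 4, 3))                     # three polytomous factors
#' factor_spec(2, labels = list(c("no", "yes")), names = "smoker")
#' @export
factor_spec <- function(levels, weights = rep(1, length(levels)),
                        labels = NULL, names = NULL) {
  levels <- as.integer(levels)
  if (length(levels) < 1L || anyNA(levels) || any(levels < 2L))
    stop("every factor must have at least 2 levels", call. = FALSE)
  if (length(weights) != length(levels))
    stop("'weights' must have one entry per factor", call. = FALSE)
  weights <- as.numeric(weights)
  if (anyNA(weights) || any(weights < 0) || !any(weights > 0))
    stop("'weights' must be nonnegative with at least one positive entry",
         call. = FALSE)
  if (is.null(names)) names <- paste0("f", seq_along(levels))
  if (!is.null(labels)) {
    if (!is.list(labels) || length(labels) != length(levels))
      stop("'labels' must be a list with one character vector per factor",
           call. = FALSE)
    ok <- mapply(function(lab, L) length(lab) == L && !anyDuplicated(lab),
                 labels, levels)
    if (!all(ok))
      stop("each factor's labels must be distinct and match its level count",
           call. = FALSE)
  }
  structure(
    list(n_factors = length(levels), levels = levels, weights = weights,
         names = as.character(names), labels = labels),
    class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat("Prognostic factor specification:", x$n_factors, "factor(s)\n")
  for (k in seq_len(x$n_factors)) {
    lab <- if (!is.null(x$labels)) paste0(" [",
      paste(x$labels[[k]], collapse = ", "), "]") else ""
    cat(sprintf("  %s: %d levels, weight %g%s\n",
                x$names[k], x$levels[k], x$weights[k], lab))
  }
  invisible(x)
}

# Factor structures of the three simulation scenarios.
scenario_factors <- function(scenario) {
  switch(scenario,
    three_binary     = factor_spec(c(2L, 2L, 2L)),
    six_binary       = factor_spec(rep(2L, 6L)),
    three_polytomous = factor_spec(c(5L, 4L, 3L)),
    stop("unknown factor scenario: ", scenario, call. = FALSE))
}

# Resolve a pluggable distribution distance to a function(pT, pC).
resolve_distance <- function(distance) {
  if (is.function(distance)) return(distance)
  switch(match.arg(distance, c("L1", "max")),
    L1  = function(pT, pC) sum(abs(pT - pC)),
    max = function(pT, pC) max(abs(pT - pC)))
}
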