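# Configuration parsing and table writers behind the command-line
# interface.  Results go to files/stdout only; diagnostics to stderr.

run_config_defaults <- function() list(
  method = "two_way", block_size = 4L, coin_probability = 0.7, q = 0.05,
  burn_in = 1L, distance = "L1",
  n = 20L, scenario = "three_binary", factors = NULL,
  treatment_effect = 0, factor_effect_mean = 1,
  replicates = 10000L, seed = NULL,
  significance = 0.05, adjust = "all", tie_mode = "exclude",
  q_values = c(0.01, 0.05, 0.1),
  methods = c("simple", "block", "stratified",
              "deterministic_minimization", "biased_coin_minimization",
              "two_way"))

#' Parse and validate a run configuration
#'
#' Reads a YAML or JSON configuration file (or takes an equivalent named
#' list), rejects unknown keys, validates every parameter through the
#' package constructors, and returns a configuration with every default
#' materialized explicitly (q = 0.05, block size 4, coin probability 0.7,
#' significance 0.05, ...), so that an emitted configuration re-parses to
#' an equivalent one.
#'
#' @param x a file path (\code{.yaml}/\code{.yml}/\code{.json}) or a named
#'   list of settings.
#' @return An object of class \code{"run_config"}: the fully materialized
#'   settings list.
#' @export
parse_run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read YAML configs",
             call. = FALSE)
      yaml::read_yaml(x)
    } else jsonlite::fromJSON(x, simplifyVector = TRUE)
  }
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop("config must be a file path or a list", call. = FALSE)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  # validate through the constructors
  alloc <- as_allocator_config(cfg)
  if (!is.null(cfg$factors) || cfg$scenario == "custom")
    as_factor_spec(cfg)
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  cfg$n <- as.integer(cfg$n)
  cfg$replicates <- as.integer(cfg$replicates)
  if (cfg$significance <= 0 || cfg$significance >= 1)
    stop("'significance' must lie in (0, 1)", call. = FALSE)
  if (!cfg$adjust %in% c("all", "none", "balanced"))
    stop("'adjust' must be \"all\", \"none\" or \"balanced\"", call. = FALSE)
  cfg$tie_mode <- match.arg(cfg$tie_mode, c("exclude", "half"))
  if (any(cfg$q_values < 0 | cfg$q_values > 1))
    stop("'q_values' must lie in [0, 1]", call. = FALSE)
  cfg$method <- alloc$method
  structure(cfg, class = "run_config")
}

as_allocator_config <- function(cfg) {
  allocator_config(cfg$method, block_size = cfg$block_size,
                   coin_probability = cfg$coin_probability, q = cfg$q,
                   burn_in = cfg$burn_in, distance = cfg$distance)
}

as_factor_spec <- function(cfg) {
  if (is.null(cfg$factors)) return(scenario_factors(cfg$scenario))
  f <- cfg$factors
  labels <- f$labels
  if (!is.null(labels)) labels <- lapply(labels, as.character)
  factor_spec(f$levels,
              weights = if (is.null(f$weights)) rep(1, length(f$levels))
                        else f$weights,
              labels = labels, names = f$names)
}

as_trial_design <- function(cfg) {
  trial_design(cfg$n, factors = if (is.null(cfg$factors)) cfg$scenario
                                else as_factor_spec(cfg),
               treatment_effect = cfg$treatment_effect,
               factor_effect_mean = cfg$factor_effect_mean,
               allocator = as_allocator_config(cfg),
               replicates = cfg$replicates)
}

#' Write a run configuration to JSON
#'
#' Emits the fully materialized configuration so a run can be reproduced
#' from its metadata alone; [parse_run_config()] on the result gives back
#' an equivalent configuration.
#'
#' @param cfg a \code{"run_config"}.
#' @param path output path (\code{.json}); \code{NULL} returns the string.
#' @return \code{path} invisibly, or the JSON string.
#' @export
write_run_config <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  cat(write_run_config(x), "\n")
  invisible(x)
}

#' Write a metrics table to CSV
#'
#' Tidy CSV with a fixed column order, floating-point values at 4 decimals
#' (matching the precision of the reported tables; full precision is
#' retained in the in-memory object) and a comment-line metadata header
#' recording the package version, seed and replicate counts.
#'
#' @param table a [metrics_table()] (any data frame works).
#' @param path output file path.
#' @param seed seed to record; defaults to the table's \code{"seed"}
#'   attribute.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(table, path, seed = attr(table, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("twowaymin"))
  writeLines(c(
    paste0("# twowaymin ", version),
    paste0("# seed: ", if (is.null(seed)) "NA" else seed),
    paste0("# replicates: ",
           paste(unique(table$replicates), collapse = ", ")),
    paste0("# common_cohorts: ",
           isTRUE(attr(table, "common_cohorts")))), con)
  out <- as.data.frame(table)
  num <- vapply(out, function(v) is.numeric(v) && !is.integer(v),
                logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), NA, formatC(v, digits = 4, format = "f")))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back a metrics CSV
#'
#' @param path a file written by [write_metrics()].
#' @return A data frame (comment-line metadata skipped).
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
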