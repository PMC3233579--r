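# Shared fixtures and small oracles, all built in code.

# Build a state by replaying explicit (profile, arm) pairs.
replay_state <- function(spec, profiles, arms) {
  st <- trial_state(spec)
  for (i in seq_along(arms))
    st <- update(st, profiles[i, ], arms[i])
  st
}

# A 6-subject single-binary-factor state: T holds levels (3,1), C (2,2)...
# used for hand-derived imbalance values.
state_T31_C22 <- function() {
  spec <- factor_spec(2)
  profiles <- matrix(c(1, 1, 1, 2, 1, 1, 2, 2), ncol = 1)
  arms <- c("T", "T", "T", "T", "C", "C", "C", "C")
  replay_state(spec, profiles, arms)
}

# Random valid profile for a spec.
random_profile <- function(spec) {
  vapply(spec$levels, function(L) sample.int(L, 1L), integer(1))
}

# Random nonempty state with n subjects.
random_state <- function(spec, n) {
  profiles <- t(vapply(seq_len(n), function(i) random_profile(spec),
                       integer(spec$n_factors)))
  arms <- c("T", "C", sample(c("T", "C"), n - 2L, replace = TRUE))
  list(state = replay_state(spec, profiles, arms),
       profiles = profiles, arms = arms)
}

# Independent recount of the Pocock-Simon marginal score from raw
# profile/arm lists (brute-force oracle).
score_oracle <- function(profiles, arms, new_profile, new_arm) {
  profiles <- rbind(profiles, new_profile)
  arms <- c(arms, new_arm)
  sum(vapply(seq_along(new_profile), function(k) {
    l <- new_profile[k]
    abs(sum(profiles[arms == "T", k] == l) -
        sum(profiles[arms == "C", k] == l))
  }, numeric(1)))
}

# Mirror a state's arm labels.
mirror_state <- function(state) {
  state$n <- state$n[c(2, 1)]
  names(state$n) <- c("T", "C")
  state$counts <- list(T = state$counts$C, C = state$counts$T)
  state$history <- ifelse(state$history == "T", "C", "T")
  state
}

# Index of the first subject after which both arms are nonempty.
burnin_length <- function(arms) {
  both <- cumsum(arms == "T") > 0 & cumsum(arms == "C") > 0
  which(both)[1]
}

small_design <- function(n = 20, factors = "three_binary", effect = 0,
                         method = "two_way", replicates = 200, ...) {
  trial_design(n, factors, treatment_effect = effect,
               allocator = allocator_config(method, ...),
               replicates = replicates)
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)
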