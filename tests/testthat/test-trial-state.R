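test_that("arm-size imbalance is the absolute difference of arm totals", {
  spec <- factor_spec(2)
  st <- trial_state(spec)
  expect_identical(total_imbalance(st), 0L)
  for (arm in c("T", "C", "C", "C", "T", "C", "C", "C"))
    st <- update(st, 1, arm)
  # N_T = 2, N_C = 6 -> 4; then balance to 3 vs 5 -> 2
  expect_identical(total_imbalance(st), 4L)
  st <- update(st, 1, "T")
  expect_identical(total_imbalance(st), 3L)
  st2 <- replay_state(factor_spec(2), matrix(1, 14, 1),
                      rep(c("T", "C"), 7))
  expect_identical(total_imbalance(st2), 0L)
})

test_that("factor distributions are proportions that sum to one", {
  st <- state_T31_C22()
  expect_equal(factor_distribution(st, "T", 1), c(0.75, 0.25))
  expect_equal(factor_distribution(st, "C", 1), c(0.5, 0.5))
  spec3 <- factor_spec(3)
  st3 <- replay_state(spec3, matrix(c(1, 2, 2, 3), ncol = 1),
                      rep("T", 4))
  expect_equal(factor_distribution(st3, "T", 1), c(0.25, 0.5, 0.25))
  st4 <- replay_state(factor_spec(2), matrix(1, 4, 1), rep("T", 4))
  expect_equal(factor_distribution(st4, "T", 1), c(1, 0))
  expect_error(factor_distribution(st4, "C", 1),
               class = "twm_burnin_error")
})

test_that("per-factor imbalance is the L1 distance between arm distributions", {
  # identical distributions
  st0 <- replay_state(factor_spec(2), matrix(c(1, 2, 1, 2), ncol = 1),
                      c("T", "T", "C", "C"))
  expect_equal(factor_imbalance(st0, 1), 0)
  # disjoint supports reach the L1 maximum of 2
  st2 <- replay_state(factor_spec(2), matrix(c(1, 2), ncol = 1),
                      c("T", "C"))
  expect_equal(factor_imbalance(st2, 1), 2)
  # hand-derived: |0.75-0.5| + |0.25-0.5| = 0.5
  expect_equal(factor_imbalance(state_T31_C22(), 1), 0.5)
  # the max-over-levels alternative distance
  expect_equal(factor_imbalance(state_T31_C22(), 1, distance = "max"), 0.25)
})

test_that("overall imbalance is the weighted sum of per-factor imbalances", {
  # two factors engineered to D = (0.5, 1.0)
  spec <- factor_spec(c(2, 2))
  profiles <- rbind(c(1, 1), c(1, 1), c(1, 1), c(2, 1),
                    c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  arms <- c(rep("T", 4), rep("C", 4))
  st <- replay_state(spec, profiles, arms)
  expect_equal(factor_imbalance(st, 1), 0.5)
  expect_equal(factor_imbalance(st, 2), 1.0)
  expect_equal(overall_imbalance(st), 1.5)
  spec_w <- factor_spec(c(2, 2), weights = c(2, 0))
  st_w <- replay_state(spec_w, profiles, arms)
  expect_equal(overall_imbalance(st_w), 1.0)
  # zero iff all per-factor imbalances are zero
  st0 <- replay_state(spec, rbind(c(1, 2), c(1, 2)), c("T", "C"))
  expect_equal(overall_imbalance(st0), 0)
})

test_that("prospective imbalance equals update-then-measure and leaves the state untouched", {
  set.seed(401)
  spec <- factor_spec(c(2, 3, 2), weights = c(1, 0.5, 2))
  for (rep in 1:25) {
    rs <- random_state(spec, sample(4:12, 1))
    st <- rs$state
    before <- st
    p <- random_profile(spec)
    for (arm in c("T", "C")) {
      expect_equal(prospective_imbalance(st, p, arm),
                   overall_imbalance(update(st, p, arm)))
      expect_equal(prospective_imbalance(st, p, arm, distance = "max"),
                   overall_imbalance(update(st, p, arm), distance = "max"))
    }
    expect_identical(st, before)
  }
  # symmetric state: both hypothetical arms give the same value
  spec1 <- factor_spec(2)
  sym <- replay_state(spec1, matrix(c(1, 1, 2, 2), ncol = 1),
                      c("T", "C", "T", "C"))
  expect_equal(prospective_imbalance(sym, 1, "T"),
               prospective_imbalance(sym, 1, "C"))
})

test_that("counts are conserved and bounded under random update sequences", {
  set.seed(402)
  spec <- factor_spec(c(2, 5, 3))
  for (rep in 1:10) {
    st <- trial_state(spec)
    arms <- character(0)
    for (i in 1:30) {
      arm <- sample(c("T", "C"), 1)
      st <- update(st, random_profile(spec), arm)
      arms <- c(arms, arm)
    }
    for (a in c("T", "C")) {
      expect_identical(unname(rowSums(st$counts[[a]])),
                       rep(as.numeric(st$n[[a]]), spec$n_factors))
      expect_identical(st$n[[a]], sum(arms == a))
    }
    expect_identical(st$history, arms)
    expect_gte(total_imbalance(st), 0L)
    d2 <- overall_imbalance(st)
    expect_gte(d2, 0)
    expect_lte(d2, 2 * sum(spec$weights))
  }
})

test_that("invalid profiles and arms are rejected with diagnostics", {
  spec <- factor_spec(c(2, 3))
  st <- trial_state(spec)
  expect_error(update(st, c(1, 4), "T"), "out of range")
  expect_error(update(st, c(1, 2, 1), "T"), "one level index per factor")
  expect_error(update(st, c(1, 2), "X"), "arm")
})

test_that("a trial state survives a JSON round trip and validates on read", {
  set.seed(403)
  spec <- factor_spec(c(2, 4), weights = c(1, 3),
                      labels = list(c("no", "yes"), c("a", "b", "c", "d")),
                      names = c("smoker", "stage"))
  rs <- random_state(spec, 9)
  json <- write_trial_state(rs$state)
  back <- read_trial_state(json)
  expect_equal(back, rs$state)
  # file round trip
  path <- tempfile(fileext = ".json")
  write_trial_state(rs$state, path)
  expect_equal(read_trial_state(path), rs$state)
  # corrupted counts are refused
  doc <- jsonlite::fromJSON(json)
  doc$n$T <- doc$n$T + 1L
  expect_error(read_trial_state(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "sum to the arm total|inconsistent")
})
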