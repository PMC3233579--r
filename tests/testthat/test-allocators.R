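test_that("the geometric accrual function has the three required properties", {
  expect_equal(accrual_probability(0, 0.05), 0)
  expect_equal(accrual_probability(0, 0.9), 0)
  expect_equal(accrual_probability(1, 0.05), 0.05)
  expect_equal(accrual_probability(14, 0.05), 0.512325020884, tolerance = 1e-9)
  # strictly increasing, limit 1
  pis <- accrual_probability(0:50, 0.05)
  expect_true(all(diff(pis) > 0))
  expect_equal(accrual_probability(1e4, 0.05), 1, tolerance = 1e-9)
  expect_error(accrual_probability(1, q = 1.5), "q")
  expect_error(allocator_config("two_way", q = -0.1), "'q'")
})

test_that("two-way minimization follows burn-in, rule A1 and rule A2", {
  spec <- factor_spec(c(2, 2, 2))
  # burn-in: an empty arm forces a fair coin
  set.seed(500)
  st <- update(trial_state(spec), c(1, 1, 1), "T")
  draws <- replicate(2000, allocate_two_way(st, c(1, 1, 1)))
  expect_gt(mean(draws == "T"), 0.45)
  expect_lt(mean(draws == "T"), 0.55)
  # rule A1 (forced via q = 1): fewer-subjects arm, deterministically
  rs <- replay_state(spec, matrix(1L, 7, 3),
                     c("T", "C", "C", "C", "C", "C", "C"))
  expect_identical(rs$n[["C"]], 6L)
  expect_true(all(replicate(50, allocate_two_way(rs, c(1, 1, 1), q = 1))
                  == "T"))
  # rule A2 (q = 0, pure covariate-adaptive): smaller prospective D2 wins
  st2 <- replay_state(spec,
                      rbind(c(1, 1, 1), c(2, 2, 2), c(1, 1, 1), c(1, 1, 1)),
                      c("T", "C", "C", "T"))
  p <- c(2, 2, 2)
  d2T <- prospective_imbalance(st2, p, "T")
  d2C <- prospective_imbalance(st2, p, "C")
  expect_true(d2T != d2C)
  want <- if (d2T < d2C) "T" else "C"
  expect_true(all(replicate(50, allocate_two_way(st2, p, q = 0)) == want))
  # equal arm sizes: accrual probability 0, decision purely covariate-adaptive
  expect_equal(accrual_probability(total_imbalance(st2), 0.37), 0)
})

test_that("forcing the size rule keeps the final arm difference at most 1 after burn-in", {
  spec <- factor_spec(c(2, 2))
  design <- trial_design(20, spec, allocator = allocator_config(
    "two_way", q = 1), replicates = 1)
  set.seed(501)
  for (i in 1:100) {
    rec <- simulate_trial(design)
    L <- burnin_length(rec$arms)
    slack <- max(0L, (L - 2L) - (length(rec$arms) - L))
    expect_lte(rec$final_d1, max(1L, slack))
  }
})

test_that("two-way decisions are invariant to monotone transforms of the imbalances", {
  # comparison-based rules: a strictly increasing transform of D2 (exp here,
  # via a custom distance on a single factor) changes no allocation
  spec <- factor_spec(3)
  design1 <- trial_design(24, spec, allocator = allocator_config("two_way"),
                          replicates = 1)
  design2 <- design1
  design2$allocator$distance <- function(pT, pC) exp(sum(abs(pT - pC)))
  for (s in 1:30) {
    set.seed(600 + s)
    cohort <- draw_cohort(design1)
    set.seed(6000 + s)
    arms1 <- simulate_trial(design1, cohort)$arms
    set.seed(6000 + s)
    arms2 <- simulate_trial(design2, cohort)$arms
    expect_identical(arms1, arms2)
  }
  # rule A1 compares arm totals directly, so any increasing transform of
  # D1 (e.g. cubing) preserves every comparison
  d1 <- -10:10
  expect_identical(sign(d1), sign(d1^3))
})

test_that("no allocator has a structural arm preference (label-swap symmetry)", {
  set.seed(502)
  spec <- factor_spec(c(2, 3))
  for (i in 1:20) {
    rs <- random_state(spec, sample(4:10, 1))
    st <- rs$state
    m <- mirror_state(st)
    p <- random_profile(spec)
    expect_equal(marginal_imbalance_score(st, p, "T"),
                 marginal_imbalance_score(m, p, "C"))
    expect_equal(prospective_imbalance(st, p, "T"),
                 prospective_imbalance(m, p, "C"))
    expect_identical(total_imbalance(st), total_imbalance(m))
  }
})

test_that("permuted blocks balance every complete block and force completions", {
  # forced completion: three of four slots used as T,T,C leaves only C
  set.seed(503)
  expect_true(all(replicate(50,
    allocate_block(c("T", "T", "C"), 4)) == "C"))
  # complete blocks hold exactly block_size/2 of each arm; 20 subjects in
  # 5 blocks end perfectly balanced
  design <- trial_design(20, "three_binary",
                         allocator = allocator_config("block"),
                         replicates = 1)
  for (i in 1:25) {
    arms <- simulate_trial(design)$arms
    blocks <- split(arms, rep(1:5, each = 4))
    expect_true(all(vapply(blocks, function(b) sum(b == "T") == 2L,
                           logical(1))))
  }
  expect_error(allocator_config("block", block_size = 3), "even")
  expect_error(allocate_block(character(0), 5), "even")
})

test_that("stratified randomization blocks within strata and degrades with many strata", {
  set.seed(504)
  # same stratum: the block urn forces completion within the stratum
  strata <- list("1.1" = c("T", "T", "C"))
  expect_true(all(replicate(30,
    allocate_stratified(strata, c(1, 1), 4)) == "C"))
  # different strata are independent urns: a fresh stratum is a fair draw
  draws <- replicate(2000, allocate_stratified(strata, c(2, 1), 4))
  expect_gt(mean(draws == "T"), 0.45)
  expect_lt(mean(draws == "T"), 0.55)
  # with 60 strata and n = 20 most strata hold <= 1 subject, so overall
  # balance degrades towards simple randomization while plain blocks stay
  # perfectly balanced
  d_strat <- small_design(20, "three_polytomous", method = "stratified")
  d_block <- small_design(20, "three_polytomous", method = "block")
  d1_strat <- mean(replicate(300, simulate_trial(d_strat)$final_d1))
  d1_block <- mean(replicate(300, simulate_trial(d_block)$final_d1))
  expect_equal(d1_block, 0)
  expect_gt(d1_strat, 1.5)
})

test_that("the marginal imbalance score matches a brute-force recount", {
  set.seed(505)
  spec <- factor_spec(c(2, 3))
  # empty state: the lone subject creates unit imbalance at each factor
  st0 <- trial_state(spec)
  expect_equal(marginal_imbalance_score(st0, c(1, 2), "T"), 2)
  expect_equal(marginal_imbalance_score(trial_state(factor_spec(2)), 1, "C"),
               1)
  for (i in 1:25) {
    rs <- random_state(spec, 5)
    p <- random_profile(spec)
    for (arm in c("T", "C"))
      expect_equal(marginal_imbalance_score(rs$state, p, arm),
                   score_oracle(rs$profiles, rs$arms, p, arm))
  }
})

test_that("deterministic minimization picks the smaller score and alternates on identical profiles", {
  spec <- factor_spec(c(2, 2))
  st <- replay_state(spec, rbind(c(1, 1), c(1, 1), c(1, 1)),
                     c("T", "T", "C"))
  # score(T) = 2*|3-1| = 4, score(C) = 0 -> C surely
  expect_equal(marginal_imbalance_score(st, c(1, 1), "T"), 4)
  expect_equal(marginal_imbalance_score(st, c(1, 1), "C"), 0)
  expect_true(all(replicate(30, allocate_det_minimization(st, c(1, 1)))
                  == "C"))
  # identical profiles from an empty state: after the first coin flip the
  # allocation alternates strictly
  set.seed(506)
  for (i in 1:10) {
    st2 <- trial_state(spec)
    arms <- character(8)
    for (j in 1:8) {
      arms[j] <- allocate_det_minimization(st2, c(2, 1))
      st2 <- update(st2, c(2, 1), arms[j])
    }
    expect_true(all(arms[seq(2, 8, 2)] != arms[seq(1, 7, 2)]))
  }
  # tie -> fair coin
  sym <- replay_state(spec, rbind(c(1, 1), c(1, 1)), c("T", "C"))
  draws <- replicate(2000, allocate_det_minimization(sym, c(1, 1)))
  expect_gt(mean(draws == "T"), 0.45)
  expect_lt(mean(draws == "T"), 0.55)
})

test_that("biased-coin minimization interpolates between deterministic and simple", {
  spec <- factor_spec(c(2, 2))
  set.seed(507)
  # coin probability 1 reduces exactly to the deterministic rule off ties
  for (i in 1:25) {
    rs <- random_state(spec, 7)
    p <- random_profile(spec)
    sT <- marginal_imbalance_score(rs$state, p, "T")
    sC <- marginal_imbalance_score(rs$state, p, "C")
    if (sT != sC) {
      want <- if (sT < sC) "T" else "C"
      expect_identical(allocate_biased_coin(rs$state, p, 1), want)
      expect_identical(allocate_det_minimization(rs$state, p), want)
    }
  }
  # off-tie state: agreement with the score-minimizing arm ~ coin probability
  st <- replay_state(spec, rbind(c(1, 1), c(1, 1), c(1, 1)),
                     c("T", "T", "C"))
  agree7 <- mean(replicate(3000, allocate_biased_coin(st, c(1, 1), 0.7))
                 == "C")
  expect_equal(agree7, 0.7, tolerance = 0.035)
  agree5 <- mean(replicate(3000, allocate_biased_coin(st, c(1, 1), 0.5))
                 == "C")
  expect_equal(agree5, 0.5, tolerance = 0.04)
  expect_error(allocate_biased_coin(st, c(1, 1), 0.3), "coin_probability")
})

test_that("simple randomization is a reproducible fair coin", {
  set.seed(508)
  draws <- replicate(10000, allocate_simple())
  expect_equal(mean(draws == "T"), 0.5, tolerance = 0.02)
  switches <- mean(draws[-1] != draws[-length(draws)])
  expect_equal(switches, 0.5, tolerance = 0.02)
  set.seed(99); a <- replicate(50, allocate_simple())
  set.seed(99); b <- replicate(50, allocate_simple())
  expect_identical(a, b)
})

test_that("the simulator's internal loop matches the exported per-subject allocators", {
  for (method in c("simple", "block", "stratified",
                   "deterministic_minimization",
                   "biased_coin_minimization", "two_way")) {
    design <- small_design(24, "three_polytomous", method = method)
    set.seed(509)
    cohort <- draw_cohort(design)
    set.seed(700)
    rec <- simulate_trial(design, cohort)
    set.seed(700)
    res <- allocate_sequence(cohort$profiles, design$allocator,
                             spec = design$spec)
    expect_identical(rec$arms, res$arms, label = method)
  }
})

test_that("allocation sequences resume from a serialized state", {
  design <- small_design(12, "three_binary", method = "two_way")
  set.seed(510)
  cohort <- draw_cohort(design)
  set.seed(71)
  full <- allocate_sequence(cohort$profiles, design$allocator,
                            spec = design$spec)
  set.seed(71)
  first <- allocate_sequence(cohort$profiles[1:7, , drop = FALSE],
                             design$allocator, spec = design$spec)
  resumed <- read_trial_state(write_trial_state(first$state))
  rest <- allocate_sequence(cohort$profiles[8:12, , drop = FALSE],
                            design$allocator, state = resumed)
  expect_identical(c(first$arms, rest$arms), full$arms)
})
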