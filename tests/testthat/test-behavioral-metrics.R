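cohort_from_policy <- function(policy_agent, n = 1, seed = 1) {
  purrr::map_dfr(seq_len(n), function(p) {
    generate_participant(policy_agent, seed = seed + p, participant = p)
  })
}

test_that("commit probabilities are commitments over offers, cell by cell", {
  # saturated and empty behaviour hit the bounds exactly
  all_in <- generate_participant(
    agent_spec(theta_in = -10, theta_out = 10), # always commits
    seed = 2, participant = 1L
  )
  m <- commit_probability_by_condition(all_in, by = "rank")
  expect_true(all(m$p_commit == 1))
  never <- generate_participant(
    agent_spec(theta_in = 5, theta_out = -5, dv = dv_config("average")),
    seed = 3, participant = 1L
  )
  m0 <- commit_probability_by_condition(never, by = "rank")
  expect_true(all(m0$p_commit == 0))
})

test_that("scripted logs reproduce hand-tallied probabilities", {
  log <- dplyr::bind_rows(
    scripted_trial_log(block = 1L,
                       decisions = c("defer", "defer", "commit",
                                     "defer", "defer", "commit")),
    scripted_trial_log(block = 2L,
                       decisions = c("defer", "defer", "defer",
                                     "defer", "commit", "defer")),
    scripted_trial_log(block = 3L,
                       decisions = rep("defer", 6))
  )
  m <- commit_probability_by_condition(log, by = "rank")
  # bandit 0 (rank 1): offered twice per block (trials 1, 3); one commit
  # (block 1 at t3) over 6 offers
  expect_equal(m$p_commit[m$rank == 1], 1 / 6)
  # bandit 1 (rank 2): offered twice per block; one commit (block 2, t5)
  expect_equal(m$p_commit[m$rank == 2], 1 / 6)
  # bandit 3 (rank 4): one offer per block, one commit -> 1/3
  expect_equal(m$p_commit[m$rank == 4], 1 / 3)
  # tally conservation: offers across cells equal total trials
  expect_equal(sum(m$n_offers), nrow(log))
  # definition fidelity against an independent group-by pass
  check <- stats::aggregate(
    decision ~ rank, data = log,
    FUN = function(d) mean(d == "commit")
  )
  expect_equal(m$p_commit[order(m$rank)],
               check$decision[order(check$rank)])
  # by-trial layout has one cell per trial number
  mt <- commit_probability_by_condition(log, by = "trial")
  expect_setequal(mt$trial, 1:6)
  expect_equal(sum(mt$n_offers), nrow(log))
})

test_that("commitment counts match manual tallies and flag empty blocks", {
  log <- dplyr::bind_rows(
    scripted_trial_log(block = 1L,
                       decisions = c("defer", "defer", "commit",
                                     "defer", "defer", "commit")),
    scripted_trial_log(rule = "rule_out", block = 2L,
                       decisions = c("defer", "defer", "commit",
                                     "defer", "commit", "defer")),
    scripted_trial_log(rule = "rule_out", block = 3L,
                       decisions = rep("defer", 6))
  )
  expect_message(cc <- commitment_counts(log), "without commitments")
  pp <- cc$per_participant
  expect_equal(pp$commits_per_block[pp$rule == "rule_in"], 2)
  expect_equal(pp$first_commit_trial[pp$rule == "rule_in"], 3)
  # rule-out: blocks with 2 and 0 commits; the empty block contributes
  # to the count mean but not to the first-commitment mean
  expect_equal(pp$commits_per_block[pp$rule == "rule_out"], 1)
  expect_equal(pp$first_commit_trial[pp$rule == "rule_out"], 3)
  expect_equal(pp$commit_proportion[pp$rule == "rule_out"], 2 / 12)
  total <- cc$summary[cc$summary$rule == "both", ]
  expect_equal(total$commits_per_block_mean, 3)
})

test_that("an always-commit agent commits four times starting at trial one", {
  log <- cohort_from_policy(agent_spec(theta_in = -10, theta_out = 10))
  cc <- commitment_counts(log)
  expect_true(all(cc$per_participant$commits_per_block == 4))
  expect_true(all(cc$per_participant$first_commit_trial == 1))
})

test_that("threshold cohorts at the fitted criteria show the expected ordering", {
  log <- cohort_from_policy(agent_spec(0.39, 0.12), n = 3, seed = 40)
  cc <- commitment_counts(log)
  pp <- cc$per_participant
  in_counts <- pp$commits_per_block[pp$rule == "rule_in"]
  out_counts <- pp$commits_per_block[pp$rule == "rule_out"]
  expect_true(all(out_counts > in_counts))
  first_in <- pp$first_commit_trial[pp$rule == "rule_in"]
  first_out <- pp$first_commit_trial[pp$rule == "rule_out"]
  expect_true(all(first_out < first_in))
  # context gradient: commitments rise with context length in rule-in
  # and fall in rule-out (the prior reference over/under-estimates the
  # first-trial DV in long/short contexts)
  by_ctx <- log |>
    dplyr::group_by(.data$rule, .data$context, .data$participant,
                    .data$block) |>
    dplyr::summarise(n = sum(.data$decision == "commit"),
                     .groups = "drop") |>
    dplyr::group_by(.data$rule, .data$context) |>
    dplyr::summarise(mean_commits = mean(.data$n), .groups = "drop")
  get <- function(r, ctx) {
    by_ctx$mean_commits[by_ctx$rule == r & by_ctx$context == ctx]
  }
  expect_gt(get("rule_in", "long"), get("rule_in", "short"))
  expect_gt(get("rule_out", "short"), get("rule_out", "long"))
})

test_that("model regressors track the asset pool and accumulate", {
  cfg <- dv_config("average", integration = TRUE)
  # rule-in block, no commitments: pool empty, estimated yield zero
  log_in <- scripted_trial_log(decisions = rep("defer", 6))
  reg <- model_regressors(log_in, cfg)
  expect_equal(reg$est_yield, rep(0, 6))
  expect_equal(reg$est_aggregate_yield, rep(0, 6))
  # single commitment at t3: pool = {bandit 0} afterwards; the estimated
  # yield is vbar_0 - r, recomputed with the current reference
  log1 <- scripted_trial_log(decisions = c("defer", "defer", "commit",
                                           rep("defer", 3)))
  reg1 <- model_regressors(log1, cfg)
  tr <- dv_trace(log1, cfg)
  expected <- c(0, 0, 4.5 - tr$reference[3:6]) # vbar_0 = 4.5 from t3 on
  expect_equal(reg1$est_yield, expected)
  expect_equal(reg1$est_aggregate_yield, cumsum(reg1$est_yield))
  # hand value: pool bandit with vbar 4.2 against r = 3.75 -> 0.45
  single <- tibble::tibble(
    participant = 1L, run = 1L, block = 1L, rule = "rule_in",
    context = "medium", trial = 1L, bandit = 0L, rank = 1L,
    spiral = 4.2, decision = "commit", trial_yield = 0,
    block_end_yield = 0
  )
  expect_equal(model_regressors(single, cfg)$est_yield, 4.2 - 3.75)
  # frozen-reference variant pins each bandit to its entry reference
  # (r at t3 is 3.75: mean of running averages 4.5 and 3.0)
  regf <- model_regressors(log1, cfg, refresh_reference = FALSE)
  expect_equal(regf$est_yield, c(0, 0, rep(4.5 - 3.75, 4)))
})

test_that("rule-out regressors start from a full pool", {
  log_out <- scripted_trial_log(rule = "rule_out",
                                decisions = rep("defer", 6))
  cfg <- dv_config("average", integration = TRUE)
  reg <- model_regressors(log_out, cfg)
  # all four bandits in the pool; unsampled ones carry the prior
  expect_length(reg$est_yield, 6)
  expect_true(all(is.finite(reg$est_yield)))
})
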