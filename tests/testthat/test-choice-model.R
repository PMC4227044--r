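test_that("commit probability is the probit of the linear DV term", {
  p <- probit_params(b_in = 0.5, c_in = 2, b_out = 0.3, c_out = -2)
  expect_equal(commit_probability(-0.25, "rule_in", p), 0.5)
  expect_equal(commit_probability((qnorm(0.95) - 0.5) / 2, "rule_in", p),
               0.95)
  # flat model when the slope is zero
  p0 <- probit_params(0.4, 0, 0.4, 0)
  expect_equal(commit_probability(c(-5, 0, 5), "rule_in", p0),
               rep(pnorm(0.4), 3))
  # monotone increasing for c > 0, decreasing for c < 0
  expect_true(all(diff(commit_probability(seq(-1, 1, 0.1), "rule_in", p)) > 0))
  expect_true(all(diff(commit_probability(seq(-1, 1, 0.1), "rule_out", p)) < 0))
})

test_that("negative log-likelihood sums -log P over both rules", {
  log <- dplyr::bind_rows(
    scripted_trial_log(rule = "rule_in", block = 1L),
    scripted_trial_log(rule = "rule_out", block = 2L)
  )
  cfg <- dv_config("average", integration = TRUE)
  # chance model: n * log(2) regardless of the data
  expect_equal(
    negative_log_likelihood(log, cfg, probit_params(0, 0, 0, 0)),
    nrow(log) * log(2)
  )
  # hand summation from the frozen oracle DV trace
  p <- probit_params(b_in = 0.2, c_in = 1.5, b_out = 0.1, c_out = -1.2)
  dv <- oracle_cur_minus_average
  commit <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  p_in <- pnorm(0.2 + 1.5 * dv)
  p_out <- pnorm(0.1 - 1.2 * dv)
  by_hand <- -sum(log(ifelse(commit, p_in, 1 - p_in))) -
    sum(log(ifelse(commit, p_out, 1 - p_out)))
  expect_equal(negative_log_likelihood(log, cfg, p), by_hand)
  # additivity: concatenating a dataset with itself doubles -LL
  log2 <- dplyr::bind_rows(log, dplyr::mutate(log, block = block + 10L))
  expect_equal(negative_log_likelihood(log2, cfg, p), 2 *
                 negative_log_likelihood(log, cfg, p))
})

test_that("probit fitting recovers known generating parameters", {
  truth <- c(b_in = -7, c_in = 2, b_out = 8, c_out = -2)
  dat <- probit_dataset(10000, truth["b_in"], truth["c_in"],
                        truth["b_out"], truth["c_out"], seed = 31)
  fit <- fit_probit(dat, dv_config("none", integration = FALSE))
  est_in <- fit$params[fit$params$rule == "rule_in", ]
  est_out <- fit$params[fit$params$rule == "rule_out", ]
  expect_lt(abs(est_in$b - truth["b_in"]) / abs(truth["b_in"]), 0.05)
  expect_lt(abs(est_in$c - truth["c_in"]) / abs(truth["c_in"]), 0.05)
  expect_lt(abs(est_out$b - truth["b_out"]) / abs(truth["b_out"]), 0.05)
  expect_lt(abs(est_out$c - truth["c_out"]) / abs(truth["c_out"]), 0.05)
  # rule-out slope carries the expected negative sign
  expect_lt(est_out$c, 0)
  # BIC invariant holds on the stored fields
  expect_equal(fit$bic, fit$n_params * log(fit$n_obs) +
                 2 * fit$neg_log_likelihood)
  expect_equal(fit$n_params, 4L)
})

test_that("decisions independent of the DV yield a near-zero fitted slope", {
  set.seed(77)
  dat <- probit_dataset(4000, 0, 0, 0, 0, seed = 77)
  fit <- fit_probit(dat, dv_config("none", integration = FALSE))
  # |c| should be within ~3 SE of zero; with n = 2000 per rule SE ~ 0.03
  expect_lt(max(abs(fit$params$c)), 0.12)
})

test_that("the probit criterion -b/c recovers a noisy threshold agent's theta", {
  coh <- generate_cohort(
    n = 1, theta_in_mean = 0.4, theta_in_sd = 0, theta_out_mean = 0.1,
    theta_out_sd = 0, slope = 3, seed = 55
  )
  fit <- fit_probit(coh$trials, dv_config("average", integration = TRUE))
  theta_in <- fit$params$theta[fit$params$rule == "rule_in"]
  theta_out <- fit$params$theta[fit$params$rule == "rule_out"]
  expect_lt(abs(theta_in - 0.4), 0.15)
  expect_lt(abs(theta_out - 0.1), 0.15)
  expect_lt(fit$params$c[fit$params$rule == "rule_out"], 0)
})

test_that("complete separation is flagged, not fatal", {
  coh <- generate_cohort(n = 1, theta_in_sd = 0, theta_out_sd = 0,
                         slope = Inf, seed = 9)
  fit <- fit_probit(coh$trials, dv_config("average", integration = TRUE))
  expect_true(fit$boundary)
  expect_true(is.finite(fit$neg_log_likelihood))
})

test_that("criterion model recovers deterministic-agent thresholds on its grid", {
  coh <- generate_cohort(
    n = 1, theta_in_mean = 0.4, theta_in_sd = 0,
    theta_out_mean = 0.1, theta_out_sd = 0, slope = Inf, seed = 13
  )
  fit <- fit_criterion_model(coh$trials)
  expect_lt(abs(fit$theta_in - 0.4), 0.06)
  expect_lt(abs(fit$theta_out - 0.1), 0.06)
  # the fitted thresholds reproduce every observed decision
  dat <- add_decision_variable(coh$trials, fit$dv_config)
  pred <- ifelse(dat$rule == "rule_in", dat$dv >= fit$theta_in,
                 dat$dv <= fit$theta_out)
  expect_equal(mean(pred == (dat$decision == "commit")), 1)
  # condition table is well-formed
  expect_true(all(fit$condition_table$p_predicted >= 0 &
                    fit$condition_table$p_predicted <= 1))
  expect_equal(nrow(fit$condition_table), 24L)
  expect_equal(fit$bic, fit$n_params * log(fit$n_obs) +
                 2 * fit$neg_log_likelihood)
})

test_that("a criterion above every achievable DV predicts zero rule-in commits", {
  coh <- generate_cohort(n = 1, theta_in_mean = 5, theta_in_sd = 0,
                         theta_out_mean = 0.1, theta_out_sd = 0,
                         slope = Inf, seed = 21, truncate = c(-1, 5))
  dat <- add_decision_variable(coh$trials,
                               dv_config("average", integration = TRUE))
  din <- dat[dat$rule == "rule_in", ]
  expect_true(all(din$decision == "defer"))
  # replaying the threshold rule at the generating criterion predicts
  # zero commits in every rule-in condition
  pred <- tapply(din$dv >= 5, interaction(din$context, din$rank), mean)
  expect_true(all(pred == 0))
  # and the fitted plateau is pushed to the top of the search grid
  fit <- fit_criterion_model(coh$trials)
  expect_equal(fit$theta_in_range[2], 1.5)
  in_cells <- fit$condition_table[fit$condition_table$rule == "rule_in", ]
  expect_true(all(in_cells$p_observed == 0))
})

test_that("predicted commitment responds monotonically to criterion shifts", {
  coh <- generate_cohort(n = 1, slope = 3, seed = 42)
  dat <- add_decision_variable(coh$trials,
                               dv_config("average", integration = TRUE))
  din <- dat[dat$rule == "rule_in", ]
  n_commit <- vapply(seq(-1, 1.5, 0.25),
                     function(th) sum(din$dv >= th), numeric(1))
  expect_true(all(diff(n_commit) <= 0))
})

test_that("identical duplicate participants give a degenerate paired contrast", {
  one <- generate_participant(agent_spec(slope = 3), seed = 5,
                              participant = 1L)
  two <- dplyr::mutate(one, participant = 2L)
  expect_warning(
    cmp <- compare_dvs(dplyr::bind_rows(one, two)),
    "zero-variance"
  )
  expect_true(is.na(cmp$contrast$statistic) || cmp$contrast$statistic == 0)
  expect_true(cmp$contrast$degenerate)
  # a DV compared against itself differs by exactly zero for everyone
  per <- cmp$per_participant
  self_diff <- per$nll[per$anchor == "average" & per$integration] -
    per$nll[per$anchor == "average" & per$integration]
  expect_equal(self_diff, rep(0, 2))
})

test_that("BIC ranking penalizes parameters and validates inputs", {
  fake <- function(nll, k, n) {
    structure(list(neg_log_likelihood = nll, n_params = k, n_obs = n,
                   bic = k * log(n) + 2 * nll, model = "m"),
              class = "criterion_fit")
  }
  tab <- bic_compare(base = fake(100, 2, 500), leaky = fake(100, 3, 500))
  expect_equal(tab$model[1], "base") # equal -LL, fewer params wins
  expect_true(all(diff(tab$bic) >= 0))
  expect_error(bic_compare(a = fake(100, 2, 500), b = fake(100, 2, 400)),
               "n_obs")
})
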