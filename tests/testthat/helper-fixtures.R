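# Shared fixtures: a scripted 6-trial offer/spiral sequence whose
# decision-variable traces were hand-computed (running means and
# references worked out on paper, independently of dv_trace), plus small
# builders for scripted blocks and trial logs.

scripted_events <- function() {
  tibble::tibble(
    trial = 1:6,
    bandit = c(0L, 1L, 0L, 2L, 1L, 3L),
    spiral = c(4.0, 3.0, 5.0, 3.5, 4.0, 2.5)
  )
}

# hand-computed DV traces for the scripted sequence
oracle_cur_minus_average <- c(0.25, -0.5, 0.75, -1 / 6, -1 / 3, -1.0)
oracle_cur_minus_next <- c(0.25, -1.0, 1.5, -1.0, -1.0, -2.0)
oracle_previous_raw <- c(0.25, -1.0, 2.0, -1.5, 0.5, -1.5)
oracle_integrated <- c(4.0, 3.0, 4.5, 3.5, 3.5, 2.5) # running means

# a block config with a fixed, known rank -> bandit-id mapping:
# bandit id i carries rank i + 1 (bandit 0 shortest ... bandit 3 longest)
fixed_block <- function(rule, context = "medium") {
  cfg <- make_block(rule, context, seed = 1)
  means <- context_means(context)
  cfg$bandits <- tibble::tibble(
    bandit = 0:3,
    mean = means,
    sd = c(0.5, 1.0, 0.5, 1.0),
    payoff = payoff_for_rank(1:4),
    rank = 1:4
  )
  cfg
}

# scripted single-block trial log (the schema of generate_participant)
scripted_trial_log <- function(rule = "rule_in", context = "medium",
                               participant = 1L, block = 1L,
                               decisions = NULL) {
  ev <- scripted_events()
  if (is.null(decisions)) {
    decisions <- c("defer", "defer", "commit", "defer", "defer", "commit")
  }
  tibble::tibble(
    participant = participant,
    run = 1L,
    block = block,
    rule = rule,
    context = context,
    trial = ev$trial,
    bandit = ev$bandit,
    rank = ev$bandit + 1L, # fixed_block mapping
    spiral = ev$spiral,
    decision = decisions,
    trial_yield = 0,
    block_end_yield = 0
  )
}

always_commit <- function(dv, rule) "commit"
always_defer <- function(dv, rule) "defer"

# direct synthetic choice data where the DV is trivially the spiral
# (anchor none, integration off), so probit recovery is tested without
# the task simulator in the loop
probit_dataset <- function(n_trials, b_in, c_in, b_out, c_out, seed) {
  set.seed(seed)
  per_rule <- n_trials / 2
  make_rule <- function(rule, b, c) {
    n_blocks <- ceiling(per_rule / 10)
    offset <- if (rule == "rule_out") n_blocks else 0L
    tibble::tibble(
      participant = 1L,
      block = offset + rep(seq_len(n_blocks), each = 10)[seq_len(per_rule)],
      rule = rule,
      trial = rep(1:10, times = n_blocks)[seq_len(per_rule)],
      bandit = 0L,
      spiral = rnorm(per_rule, 3.75, 1),
      decision = NA_character_
    ) |>
      dplyr::mutate(
        decision = ifelse(runif(per_rule) < pnorm(b + c * spiral),
                          "commit", "defer")
      )
  }
  dplyr::bind_rows(
    make_rule("rule_in", b_in, c_in),
    make_rule("rule_out", b_out, c_out)
  )
}

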