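#' Decision-variable configuration
#'
#' The candidate decision variables cross two features: *integration*
#' (average the spiral lengths seen so far at a bandit, vs. take only the
#' current spiral) and *anchoring* (subtract a block-level reference from
#' the bandit's value estimate). The reference can be the raw spiral of
#' the previous trial (`"previous"`), the best competitor's running
#' average (`"max_next"`), or the mean running average over all bandits
#' presented so far (`"average"`). The anchor `"average"` with integration
#' is the current-minus-average DV; `"max_next"` with integration is
#' current-minus-next.
#'
#' @param anchor One of `"none"`, `"previous"`, `"max_next"`, `"average"`.
#' @param integration Logical; average over a bandit's sample history?
#' @param v_prior Reference used on the first trial of a block (and
#'   whenever the chosen anchor is not yet defined). Defaults to 3.75, the
#'   grand-mean spiral length of the design.
#' @param leak Optional leak rate lambda in (0, 1]; when supplied, value
#'   integration is an exponential moving average
#'   `v <- (1 - lambda) * v + lambda * s` instead of an equal-weight mean.
#' @param free_prior Logical; when `TRUE` (used with `leak`), the moving
#'   average initializes at `v_prior` with the first sample entering
#'   through the leak update, so `v_prior` acts as a fittable pseudo-prior.
#' @return A `dv_config` object.
#' @export
#' @examples
#' dv_config("average", integration = TRUE) # current-minus-average
dv_config <- function(anchor = c("average", "none", "previous", "max_next"),
                      integration = TRUE, v_prior = 3.75,
                      leak = NULL, free_prior = FALSE) {
  anchor <- match.arg(anchor)
  if (!is.null(leak)) {
    stopifnot(is.numeric(leak), length(leak) == 1L, leak > 0, leak <= 1)
  }
  structure(
    list(
      anchor = anchor,
      integration = isTRUE(integration),
      v_prior = v_prior,
      leak = leak,
      free_prior = isTRUE(free_prior)
    ),
    class = "dv_config"
  )
}

#' @export
print.dv_config <- function(x, ...) {
  cat("<dv_config> anchor =", x$anchor,
      "| integration =", x$integration,
      "| v_prior =", x$v_prior,
      if (!is.null(x$leak)) paste("| leak =", x$leak) else "",
      if (x$free_prior) "| free prior" else "", "\n")
  invisible(x)
}

#' The eight candidate decision variables
#'
#' @return Tibble with one row per anchor x integration combination and a
#'   list-column of ready-made [dv_config()] objects.
#' @export
dv_config_grid <- function() {
  grid <- tidyr::expand_grid(
    anchor = c("none", "previous", "max_next", "average"),
    integration = c(FALSE, TRUE)
  )
  grid$config <- purrr::map2(
    grid$anchor, grid$integration,
    function(a, i) dv_config(anchor = a, integration = i)
  )
  grid
}

# Observation history for one block: per-bandit sample counts and running
# value estimates, the previous trial's raw spiral, and the trial counter.
new_dv_history <- function(config) {
  structure(
    list(
      n = integer(4),
      vbar = rep(NA_real_, 4),
      prev_spiral = NA_real_,
      current_spiral = NA_real_,
      trial = 0L
    ),
    class = "dv_history"
  )
}

# Fold the current trial's sample into the history (before the DV for
# that trial is computed: the current spiral counts toward v-bar at t).
dv_observe <- function(hist, bandit, spiral, config) {
  i <- bandit + 1L
  if (hist$n[i] == 0L) {
    hist$vbar[i] <- if (!is.null(config$leak) && config$free_prior) {
      (1 - config$leak) * config$v_prior + config$leak * spiral
    } else {
      spiral
    }
  } else if (!is.null(config$leak)) {
    hist$vbar[i] <- (1 - config$leak) * hist$vbar[i] + config$leak * spiral
  } else {
    hist$vbar[i] <- hist$vbar[i] + (spiral - hist$vbar[i]) / (hist$n[i] + 1)
  }
  hist$n[i] <- hist$n[i] + 1L
  hist$trial <- hist$trial + 1L
  hist$current_spiral <- spiral
  hist
}

# After the trial's DV is computed, the trial's spiral becomes the
# "previous" raw sample for the next trial.
dv_advance <- function(hist, spiral) {
  hist$prev_spiral <- spiral
  hist
}

#' Running value estimate of a sample sequence
#'
#' Equal-weight mean of the samples, or an exponential moving average
#' when a leak rate is given (initialized at the first sample, or at
#' `v_prior` under `free_prior`).
#'
#' @param samples Numeric vector of spiral lengths, oldest first.
#' @param leak Optional leak rate lambda in (0, 1].
#' @param v_prior,free_prior See [dv_config()].
#' @return The value estimate after the last sample.
#' @export
#' @examples
#' running_average(c(3, 4)) # 3.5
#' running_average(c(3, 4), leak = 1) # 4: full leak keeps only the last
running_average <- function(samples, leak = NULL, v_prior = 3.75,
                            free_prior = FALSE) {
  if (length(samples) == 0L) {
    stop("`samples` must contain at least one observation", call. = FALSE)
  }
  if (is.null(leak)) {
    return(mean(samples))
  }
  stopifnot(leak > 0, leak <= 1)
  v <- if (free_prior) {
    (1 - leak) * v_prior + leak * samples[1L]
  } else {
    samples[1L]
  }
  for (s in samples[-1L]) {
    v <- (1 - leak) * v + leak * s
  }
  v
}

#' Block reference value for an anchored decision variable
#'
#' @param hist A `dv_history` (internal state built by the simulator or
#'   by [dv_trace()]), already updated with the current trial's sample.
#' @param anchor `"previous"`, `"max_next"` or `"average"`.
#' @param current Offered bandit id (0-3).
#' @param config The [dv_config()] supplying `v_prior`.
#' @return The reference r(t). On the first trial of a block — or whenever
#'   the requested anchor does not yet exist (e.g. no competitor has been
#'   presented for `"max_next"`) — the reference falls back to `v_prior`.
#' @export
reference_value <- function(hist, anchor, current, config) {
  anchor <- match.arg(anchor, c("previous", "max_next", "average"))
  if (hist$trial <= 1L) {
    return(config$v_prior)
  }
  if (anchor == "previous") {
    if (is.na(hist$prev_spiral)) config$v_prior else hist$prev_spiral
  } else if (anchor == "max_next") {
    others <- which(hist$n > 0L & seq_len(4L) != current + 1L)
    if (length(others) == 0L) config$v_prior else max(hist$vbar[others])
  } else {
    presented <- hist$n > 0L
    mean(hist$vbar[presented])
  }
}

#' Decision variable for the offered bandit
#'
#' The absolute term is the current spiral (integration off) or the
#' bandit's running average including the current spiral (integration
#' on); anchored configurations subtract the reference value.
#'
#' @inheritParams reference_value
#' @param config A [dv_config()].
#' @return List with `value`, `absolute` and `reference` (`NA` for
#'   unanchored configurations).
#' @export
compute_dv <- function(hist, config, current) {
  i <- current + 1L
  if (hist$n[i] == 0L) {
    stop("bandit ", current, " has no samples yet", call. = FALSE)
  }
  absolute <- if (config$integration) hist$vbar[i] else hist$current_spiral
  if (config$anchor == "none") {
    list(value = absolute, absolute = absolute, reference = NA_real_)
  } else {
    r <- reference_value(hist, config$anchor, current, config)
    list(value = absolute - r, absolute = absolute, reference = r)
  }
}

#' Decision-variable trace along a logged block
#'
#' Replays a block's offer/spiral sequence and computes the decision
#' variable at every trial strictly from the information available then
#' (no lookahead). Works on a `block_log` or on any tibble with ordered
#' `trial`, `bandit` and `spiral` columns describing a single block.
#'
#' @param events Tibble of one block's trials, ordered by `trial`.
#' @param config A [dv_config()].
#' @return Tibble with `trial`, `bandit`, `spiral`, `dv`, `absolute`,
#'   `reference` and `vbar` (the offered bandit's running average).
#' @export
#' @examples
#' cfg <- make_block("rule_in", "medium", seed = 1)
#' log <- run_block(threshold_policy(0.39, 0.12), cfg,
#'                  dv_config("average"), seed = 2)
#' dv_trace(log, dv_config("max_next"))
dv_trace <- function(events, config) {
  if (is.unsorted(events$trial, strictly = TRUE)) {
    stop("`events` must be ordered by strictly increasing `trial`",
         call. = FALSE)
  }
  hist <- new_dv_history(config)
  n <- nrow(events)
  dv <- absolute <- reference <- vbar <- numeric(n)
  for (j in seq_len(n)) {
    hist <- dv_observe(hist, events$bandit[j], events$spiral[j], config)
    v <- compute_dv(hist, config, events$bandit[j])
    hist <- dv_advance(hist, events$spiral[j])
    dv[j] <- v$value
    absolute[j] <- v$absolute
    reference[j] <- v$reference
    vbar[j] <- hist$vbar[events$bandit[j] + 1L]
  }
  tibble::tibble(
    trial = events$trial,
    bandit = events$bandit,
    spiral = events$spiral,
    dv = dv,
    absolute = absolute,
    reference = reference,
    vbar = vbar
  )
}

#' Add a decision-variable column to a trial log
#'
#' Computes [dv_trace()] block-by-block over a full trial log (one or
#' many participants) and appends `dv` and `reference` columns.
#'
#' @param trials Trial-log tibble with `participant`, `block`, `trial`,
#'   `bandit`, `spiral` columns (participant optional for single logs).
#' @param config A [dv_config()].
#' @return `trials` with `dv` and `reference` columns added (replaced if
#'   already present).
#' @export
add_decision_variable <- function(trials, config) {
  trials$dv <- NULL
  trials$reference <- NULL
  keys <- intersect(c("participant", "block"), names(trials))
  if (length(keys) == 0L) {
    tr <- dv_trace(trials, config)
    trials$dv <- tr$dv
    trials$reference <- tr$reference
    return(trials)
  }
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      tr <- dv_trace(df, config)
      df$dv <- tr$dv
      df$reference <- tr$reference
      df
    }) |>
    dplyr::ungroup()
}
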