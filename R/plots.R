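#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a criterion sweep
#'
#' Expected block-end yield as a function of the commitment criterion,
#' with a Monte-Carlo standard-error ribbon and the reward-maximizing
#' criterion marked.
#'
#' @param object A `policy_sweep` from [reward_maximizing_criterion()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot policy_sweep
#' @export
autoplot.policy_sweep <- function(object, ...) {
  theta_star <- attr(object, "theta_star")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta,
                                       y = .data$mean_yield)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_yield - .data$se,
                   ymax = .data$mean_yield + .data$se),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = theta_star, linetype = "dashed") +
    ggplot2::labs(
      x = "commitment criterion (DV units)",
      y = "expected block-end yield (£)",
      title = sprintf("%s: reward-maximizing criterion %.2f",
                      object$rule[1L], theta_star)
    ) +
    ggplot2::theme_minimal()
}

#' Plot commitment-probability profiles
#'
#' Commitment probability by payoff rank (or trial number), per context
#' and rule — the standard behavioural summary of the task.
#'
#' @param metrics Output of [commit_probability_by_condition()].
#' @return A ggplot.
#' @export
plot_commit_profiles <- function(metrics) {
  xvar <- if ("rank" %in% names(metrics)) "rank" else "trial"
  ggplot2::ggplot(metrics, ggplot2::aes(
    x = .data[[xvar]], y = .data$p_commit, colour = .data$context
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~rule) +
    ggplot2::labs(x = xvar, y = "P(commit)") +
    ggplot2::theme_minimal()
}
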