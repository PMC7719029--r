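#' Plot a fitted race model
#'
#' `type = "ssrt"` overlays the participant-level SSRT posterior densities
#' (one line per participant); `type = "trace"` shows trace plots of the
#' group-level location parameters for convergence review.
#'
#' @param object An `ssm_fit`.
#' @param type Plot type.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssm_fit <- function(object, type = c("ssrt", "trace"), ...) {
  type <- match.arg(type)
  if (type == "ssrt") {
    d <- ssrt_posterior(object)
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$ssrt,
                                      group = .data$participant_id)) +
        ggplot2::geom_density(colour = "grey40", linewidth = 0.3) +
        ggplot2::labs(x = "SSRT (s)", y = "posterior density",
                      title = object$group %||% NULL) +
        ggplot2::theme_minimal())
  }
  d <- tidy(object, level = "group") |>
    dplyr::filter(grepl("_loc$", .data$parameter))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  group = .data$chain)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = "value") +
    ggplot2::theme_minimal()
}

#' Staircase trajectory of a session
#'
#' Plots the stop-signal delay over stop trials together with the running
#' cumulative stop accuracy, which the one-up-one-down rule drives towards
#' 50%.
#'
#' @param session A session tibble from [run_session()].
#' @return A ggplot object.
#' @export
plot_staircase <- function(session) {
  st <- session |>
    analysable_trials() |>
    dplyr::filter(.data$trial_type == "stop") |>
    dplyr::mutate(stop_trial = dplyr::row_number(),
                  cum_acc = cumsum(.data$response == "none") /
                    .data$stop_trial)
  long <- tidyr::pivot_longer(st[, c("stop_trial", "ssd", "cum_acc")],
                              -"stop_trial")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stop_trial,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(ssd = "SSD (s)",
                            cum_acc = "cumulative stop accuracy"))) +
    ggplot2::geom_hline(data = data.frame(name = "cum_acc", y = 0.5),
                        ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed") +
    ggplot2::labs(x = "stop trial") +
    ggplot2::theme_minimal()
}
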