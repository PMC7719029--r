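# Observed summaries used by the posterior predictive check: go RT deciles,
# stop accuracy (overall and by SSD band), go error and omission rates.
session_summaries <- function(trials, ssd_breaks = NULL) {
  trials <- analysable_trials(trials)
  go <- trials[trials$trial_type %in% c("go_left", "go_right"), ]
  stop_tr <- trials[trials$trial_type == "stop", ]
  go_resp <- go[!is.na(go$rt), ]
  dec <- quantile(go_resp$rt, probs = seq(0.1, 0.9, 0.1), names = FALSE,
                  na.rm = TRUE)
  out <- tibble::tibble(
    stat = c(paste0("go_rt_q", seq(10, 90, 10)),
             "stop_accuracy", "go_omission_rate", "go_error_rate",
             "mean_ssd"),
    value = c(dec,
              mean(stop_tr$response == "none"),
              mean(is.na(go$rt)),
              mean(go_resp$response != go_resp$stimulus),
              mean(stop_tr$ssd)))
  if (!is.null(ssd_breaks)) {
    band <- cut(stop_tr$ssd, breaks = ssd_breaks, include.lowest = TRUE)
    acc <- tapply(stop_tr$response == "none", band, mean)
    out <- dplyr::bind_rows(out, tibble::tibble(
      stat = paste0("stop_accuracy_ssd_band", seq_along(acc)),
      value = as.numeric(acc)))
  }
  out
}

#' Posterior predictive check of a fitted race model
#'
#' Draws random retained posterior samples, simulates a complete session
#' per participant for each with the task engine (fresh trial sequence and
#' staircase), and compares observed and simulated summaries: go RT
#' deciles, overall stop accuracy and stop accuracy within SSD bands, go
#' error and omission rates.
#'
#' @param fit An `ssm_fit`.
#' @param task A [task_config()] describing the sessions to simulate.
#' @param n_draws Number of posterior draws (> 0).
#' @param seed Integer seed.
#' @return An object of class `ssm_ppc`: a list with `observed` (per
#'   participant) and `simulated` (per draw and participant) summary
#'   tibbles. `tidy()` reduces it to one row per participant and statistic
#'   with the predictive 95% interval and a coverage flag.
#' @export
posterior_predictive <- function(fit, task = task_config(), n_draws = 50,
                                 seed = 1) {
  stopifnot(inherits(fit, "ssm_fit"))
  if (n_draws < 1) rlang::abort("n_draws must be at least 1")
  nc <- dim(fit$draws$phi)[1]
  nk <- dim(fit$draws$phi)[2]
  obs_ssd <- fit$sessions$ssd[fit$sessions$trial_type == "stop"]
  ssd_breaks <- unique(quantile(obs_ssd, c(0, 0.25, 0.5, 0.75, 1),
                                na.rm = TRUE))
  if (length(ssd_breaks) < 3) ssd_breaks <- NULL
  observed <- fit$sessions |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ session_summaries(.x, ssd_breaks)) |>
    dplyr::ungroup()

  withr::with_seed(seed, {
    picks <- tibble::tibble(chain = sample.int(nc, n_draws, replace = TRUE),
                            iteration = sample.int(nk, n_draws, replace = TRUE))
    sim <- purrr::map_dfr(seq_len(n_draws), function(d) {
      seq_seed <- sample.int(.Machine$integer.max, 1)
      purrr::map_dfr(seq_along(fit$participants), function(i) {
        theta <- fit$draws$phi[picks$chain[d], picks$iteration[d], i, ]
        theta <- matrix(theta, 1, 11)
        pars <- setNames(drop(to_natural(theta)), race_param_names())
        sequence <- build_trial_sequence(task, seed = seq_seed + i)
        ses <- run_session(pars, sequence, task,
                           seed = sample.int(.Machine$integer.max, 1))
        s <- session_summaries(ses, ssd_breaks)
        s$participant_id <- fit$participants[i]
        s$draw <- d
        s
      })
    })
    structure(list(observed = observed, simulated = sim,
                   n_draws = n_draws), class = "ssm_ppc")
  })
}

#' @rdname posterior_predictive
#' @param x An `ssm_ppc` object.
#' @param ... Unused.
#' @export
tidy.ssm_ppc <- function(x, ...) {
  pred <- x$simulated |>
    dplyr::group_by(.data$participant_id, .data$stat) |>
    dplyr::summarise(pred_lo = quantile(.data$value, 0.025, na.rm = TRUE),
                     pred_hi = quantile(.data$value, 0.975, na.rm = TRUE),
                     pred_mean = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  x$observed |>
    dplyr::rename(observed = "value") |>
    dplyr::filter(is.finite(.data$observed)) |>
    dplyr::inner_join(pred, by = c("participant_id", "stat")) |>
    dplyr::mutate(inside = .data$observed >= .data$pred_lo &
                    .data$observed <= .data$pred_hi)
}

#' @rdname tidy_ssm_fit
#' @export
glance.ssm_fit <- function(x, ...) {
  tibble::tibble(
    group = x$group %||% NA_character_,
    n_participants = length(x$participants),
    n_chains = dim(x$draws$phi)[1],
    n_retained = dim(x$draws$phi)[2],
    max_rhat = max(x$rhat$rhat),
    converged = x$converged,
    burnin_blocks = x$burnin_blocks_used,
    n_floor = x$n_floor)
}

#' Tidy draws from a fitted race model
#'
#' Returns the retained posterior draws in long format: one row per chain,
#' iteration, parameter and (for participant-level rows) participant.
#' Participant-level failure probabilities are reported on the probability
#' scale; group-level rows describe the sampling scale (probit for `p_tf`,
#' `p_gf`), with `_loc` and `_scale` suffixes on the parameter names.
#'
#' @param x An `ssm_fit`.
#' @param level `"participant"`, `"group"` or both.
#' @param ... Unused.
#' @return Tibble with columns `chain`, `iteration`, `level`,
#'   `participant_id`, `parameter`, `value`.
#' @name tidy_ssm_fit
#' @export
tidy.ssm_fit <- function(x, level = c("participant", "group"), ...) {
  level <- match.arg(level, several.ok = TRUE)
  nc <- dim(x$draws$phi)[1]
  nk <- dim(x$draws$phi)[2]
  nm <- race_param_names()
  out <- list()
  if ("participant" %in% level) {
    out$part <- purrr::map_dfr(seq_along(x$participants), function(i) {
      purrr::map_dfr(seq_along(nm), function(j) {
        v <- as.vector(x$draws$phi[, , i, j])
        if (j %in% PROBIT_IDX) v <- pnorm(v)
        tibble::tibble(chain = rep(seq_len(nc), nk),
                       iteration = rep(seq_len(nk), each = nc),
                       level = "participant",
                       participant_id = x$participants[i],
                       parameter = nm[j], value = v)
      })
    })
  }
  if ("group" %in% level) {
    out$grp <- purrr::map_dfr(seq_along(nm), function(j) {
      dplyr::bind_rows(
        tibble::tibble(chain = rep(seq_len(nc), nk),
                       iteration = rep(seq_len(nk), each = nc),
                       level = "group", participant_id = NA_character_,
                       parameter = paste0(nm[j], "_loc"),
                       value = as.vector(x$draws$loc[, , j])),
        tibble::tibble(chain = rep(seq_len(nc), nk),
                       iteration = rep(seq_len(nk), each = nc),
                       level = "group", participant_id = NA_character_,
                       parameter = paste0(nm[j], "_scale"),
                       value = as.vector(x$draws$scale[, , j])))
    })
  }
  dplyr::bind_rows(out)
}

#' @export
print.ssm_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Hierarchical race model fit%s: %d participants, %d chains x %d draws\n",
    if (!is.na(g$group)) paste0(" (", g$group, ")") else "",
    g$n_participants, g$n_chains, g$n_retained))
  cat(sprintf("  max R-hat %.3f (%s), %d floored likelihoods\n",
              g$max_rhat, if (g$converged) "converged" else "NOT converged",
              g$n_floor))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
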