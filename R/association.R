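#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (the Pearson correlation of
#' the rank vectors). Errors on constant input, for which the coefficient
#' is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (length(x) < 3) rlang::abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::abort("Spearman correlation undefined for constant input")
  }
  cor(x, y, method = "spearman")
}

#' Highest density interval of a sample
#'
#' The shortest interval containing at least `mass` of the sample: over the
#' sorted draws, the minimal-width window of `ceiling(mass * n)`
#' observations (ties broken toward the earlier window).
#'
#' @param samples Numeric vector (>= 20 draws recommended).
#' @param mass Probability mass, strictly between 0 and 1.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) rlang::abort("empty sample")
  if (mass <= 0 || mass >= 1) rlang::abort("mass must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  w <- min(max(ceiling(mass * n), 1L), n)
  if (w == n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - w + 1L)
  widths <- x[starts + w - 1L] - x[starts]
  i <- which.min(widths) # which.min takes the first minimum: earlier window
  c(lower = x[i], upper = x[i + w - 1L])
}

#' ROPE decision rule for a credible interval
#'
#' Compares a highest density interval with a region of practical
#' equivalence (ROPE): the null is rejected when the two intervals do not
#' overlap, the effect is declared practically null when the HDI lies
#' entirely inside the ROPE, and the verdict is undecided otherwise.
#'
#' @param interval Numeric length-2 `(lower, upper)` HDI.
#' @param rope Numeric length-2 region of practical equivalence; the
#'   default `(-0.1, 0.1)` corresponds to a small Spearman effect size.
#' @return One of `"reject_null"`, `"within_rope"`, `"undecided"`.
#' @export
rope_decision <- function(interval, rope = c(-0.1, 0.1)) {
  if (length(interval) != 2 || any(!is.finite(interval)) ||
      interval[1] > interval[2]) {
    rlang::abort("interval must be finite (lower, upper) with lower <= upper")
  }
  if (length(rope) != 2 || rope[1] > rope[2]) {
    rlang::abort("malformed ROPE")
  }
  if (interval[2] < rope[1] || interval[1] > rope[2]) return("reject_null")
  if (interval[1] >= rope[1] && interval[2] <= rope[2]) return("within_rope")
  "undecided"
}

#' Posterior distribution of a brain-behaviour Spearman correlation
#'
#' For each retained posterior draw of the participant-level SSRT (or any
#' other draw-indexed behavioural measure), computes the Spearman
#' correlation across participants with a fixed per-participant covariate
#' (typically a corrected metabolite concentration). The resulting
#' distribution of correlation values is summarised by its 95% highest
#' density interval and the ROPE decision rule.
#'
#' @param draws Tibble of aligned posterior draws with columns `chain`,
#'   `iteration`, `participant_id` and a value column (default `ssrt`),
#'   e.g. from [ssrt_posterior()].
#' @param values Tibble with `participant_id` and a per-participant value
#'   column (default `residual`), e.g. one (region, metabolite) slice of
#'   [correct_concentrations()] output. Participant sets must match
#'   exactly.
#' @param draw_col,value_col Names of the value columns in `draws` and
#'   `values`.
#' @param rope Region of practical equivalence for the correlation.
#' @param mass HDI probability mass.
#' @return An object of class `cor_posterior` with fields `r_samples`,
#'   `hdi`, `rope`, `verdict`, `r_mean`, `r_point` (the correlation of the
#'   posterior-mean measure), `n_draws`, `n_participants`.
#' @export
posterior_correlation <- function(draws, values, draw_col = "ssrt",
                                  value_col = "residual",
                                  rope = c(-0.1, 0.1), mass = 0.95) {
  p_draws <- sort(unique(draws$participant_id))
  p_vals <- sort(unique(values$participant_id))
  if (!identical(p_draws, p_vals)) {
    rlang::abort(paste0(
      "participant mismatch; only in draws: ",
      toString(setdiff(p_draws, p_vals)), "; only in values: ",
      toString(setdiff(p_vals, p_draws))))
  }
  if (anyDuplicated(values$participant_id)) {
    rlang::abort("values must have one row per participant")
  }
  wide <- draws |>
    dplyr::select("chain", "iteration", "participant_id",
                  value = dplyr::all_of(draw_col)) |>
    tidyr::pivot_wider(names_from = "participant_id",
                       values_from = "value")
  mat <- as.matrix(wide[, p_draws, drop = FALSE])
  if (nrow(mat) < 100) rlang::abort("need at least 100 aligned draws")
  v <- values[[value_col]][match(p_draws, values$participant_id)]
  rv <- rank(v)
  r_samples <- apply(mat, 1, function(row) cor(rank(row), rv)) # Spearman
  h <- hdi(r_samples, mass)
  structure(list(r_samples = r_samples, hdi = h, rope = rope, mass = mass,
                 verdict = rope_decision(h, rope),
                 r_mean = mean(r_samples),
                 r_point = spearman_r(colMeans(mat), v),
                 n_draws = nrow(mat), n_participants = length(p_draws)),
            class = "cor_posterior")
}

#' @export
tidy.cor_posterior <- function(x, ...) {
  tibble::tibble(r_mean = x$r_mean, r_point = x$r_point,
                 hdi_low = x$hdi[["lower"]], hdi_high = x$hdi[["upper"]],
                 rope_low = x$rope[1], rope_high = x$rope[2],
                 verdict = x$verdict, n_draws = x$n_draws,
                 n_participants = x$n_participants)
}

#' @export
glance.cor_posterior <- function(x, ...) tidy(x)

#' @export
print.cor_posterior <- function(x, ...) {
  cat(sprintf(
    "Posterior Spearman correlation: mean R = %.3f, %d%% HDI (%.3f, %.3f)\n",
    x$r_mean, round(100 * x$mass), x$hdi[["lower"]], x$hdi[["upper"]]))
  cat(sprintf("ROPE (%.2f, %.2f): %s  [%d draws, %d participants]\n",
              x$rope[1], x$rope[2], x$verdict, x$n_draws, x$n_participants))
  invisible(x)
}

#' Plot a posterior correlation distribution
#'
#' Histogram of the Spearman correlation draws with the HDI bounds (red)
#' and the ROPE (black band), in the style commonly used for Bayesian
#' estimation reports.
#'
#' @param object A `cor_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cor_posterior <- function(object, ...) {
  df <- tibble::tibble(r = object$r_samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::annotate("rect", xmin = object$rope[1], xmax = object$rope[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.25, fill = "black") +
    ggplot2::geom_vline(xintercept = unname(object$hdi), colour = "red") +
    ggplot2::labs(x = "Spearman R", y = "draws",
                  subtitle = sprintf("%d%% HDI (%.2f, %.2f): %s",
                                     round(100 * object$mass),
                                     object$hdi[["lower"]],
                                     object$hdi[["upper"]],
                                     object$verdict)) +
    ggplot2::theme_minimal()
}
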