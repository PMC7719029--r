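#' Canonical race-model parameter names
#'
#' The race model has 11 free parameters per participant: ex-Gaussian
#' mu/sigma/tau for the matching go runner, the mismatching go runner and
#' the stop runner (seconds), plus the trigger-failure and go-failure
#' probabilities `p_tf` and `p_gf`.
#'
#' @return Character vector of length 11 in canonical order.
#' @export
race_param_names <- function() {
  c("mu_go_match", "sigma_go_match", "tau_go_match",
    "mu_go_mismatch", "sigma_go_mismatch", "tau_go_mismatch",
    "mu_stop", "sigma_stop", "tau_stop",
    "p_tf", "p_gf")
}

#' Construct one participant's race-model parameters
#'
#' @param go_match,go_mismatch,stop Numeric length-3 vectors `c(mu, sigma,
#'   tau)` in seconds for the three runners; all components must be > 0.
#' @param p_tf,p_gf Trigger-failure and go-failure probabilities in
#'   `[0, 1]`.
#' @return A named numeric vector of length 11 with class `race_params`,
#'   ordered as [race_param_names()].
#' @examples
#' p <- race_params(go_match = c(0.5, 0.05, 0.1),
#'                  go_mismatch = c(0.6, 0.05, 0.1),
#'                  stop = c(0.2, 0.03, 0.05),
#'                  p_tf = 0.05, p_gf = 0.02)
#' ssrt_from_params(p)
#' @export
race_params <- function(go_match, go_mismatch, stop, p_tf = 0, p_gf = 0) {
  for (v in list(go_match, go_mismatch, stop)) {
    if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0)) {
      rlang::abort("each runner needs c(mu, sigma, tau), all finite and > 0")
    }
  }
  if (p_tf < 0 || p_tf > 1 || p_gf < 0 || p_gf > 1) {
    rlang::abort("p_tf and p_gf must lie in [0, 1]")
  }
  out <- c(go_match, go_mismatch, stop, p_tf, p_gf)
  names(out) <- race_param_names()
  class(out) <- c("race_params", "numeric")
  out
}

# Coerce a named vector, list, or one-row data frame to the canonical
# 11-vector. Used at every user-facing boundary.
as_race_params <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) rlang::abort("expected exactly one row of parameters")
    x <- unlist(x[race_param_names()])
  }
  if (is.list(x)) x <- unlist(x)
  nm <- race_param_names()
  if (!all(nm %in% names(x))) {
    rlang::abort(paste0("missing parameters: ",
                        paste(setdiff(nm, names(x)), collapse = ", ")))
  }
  p <- as.numeric(x[nm])
  names(p) <- nm
  if (any(!is.finite(p))) rlang::abort("non-finite parameter value")
  if (any(p[1:9] <= 0)) rlang::abort("mu, sigma, tau must all be > 0")
  if (p["p_tf"] < 0 || p["p_tf"] > 1 || p["p_gf"] < 0 || p["p_gf"] > 1) {
    rlang::abort("p_tf and p_gf must lie in [0, 1]")
  }
  p
}

#' Stop-signal reaction time implied by race parameters
#'
#' SSRT is defined as the sum of the stop runner's ex-Gaussian `mu` and
#' `tau` (the mean finishing time of the stop process). It does not depend
#' on the go runners or the failure probabilities.
#'
#' @param params Race parameters: a [race_params()] vector, a named list,
#'   or a data frame with the 11 parameter columns (one SSRT per row).
#' @return Numeric vector of SSRT values in seconds.
#' @export
ssrt_from_params <- function(params) {
  if (is.data.frame(params)) {
    return(params$mu_stop + params$tau_stop)
  }
  p <- as_race_params(params)
  unname(p["mu_stop"] + p["tau_stop"])
}
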