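# truncated-normal draws by inverse-CDF
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# deterministic per-stage seed derivation from a master seed
derive_seed <- function(seed, stage, i = 0L) {
  ((as.double(seed) * 7919 + stage * 104729 + i * 131) %% 2147483587) + 1
}

#' Specification of a synthetic two-group cohort
#'
#' Describes the ground truth of a simulated patient/control study:
#' group-level means and SDs of the 11 race-model parameters (failure
#' probabilities on the probit scale), and the metabolite model used by
#' [generate_metabolites()]. Defaults emulate a frontotemporal-dementia /
#' progressive-supranuclear-palsy cohort versus age- and sex-matched
#' controls: 33 patients and 20 controls; a slower and more variable stop
#' process plus more frequent attentional failures in patients (group SSRT
#' about 0.40 s versus 0.25 s); a GABA deficit confined to the right
#' inferior frontal gyrus; negative coupling between frontal metabolite
#' levels and the true SSRT within patients (none in the occipital control
#' region); CRLB noise centred on published spectral-quality values; and
#' lower grey-matter fractions in patients.
#'
#' @param n_controls,n_patients Group sizes.
#' @param race_params Tibble with columns `parameter`, `control_mean`,
#'   `control_sd`, `patient_mean`, `patient_sd` (sampling scale).
#' @param metabolites Tibble of metabolite model settings per (region,
#'   metabolite): baseline, covariate coefficients, group deficit,
#'   SSRT coupling (concentration units per SD of true patient SSRT),
#'   residual noise SD, and CRLB distribution per group.
#' @param age_mean,age_sd Age distribution (years), shared by both groups.
#' @param tissue Tibble of tissue-fraction distributions per group.
#' @param seed Master seed for all generation stages.
#' @return A list with class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 20L, n_patients = 33L,
                        race_params = default_race_param_spec(),
                        metabolites = default_metabolite_spec(),
                        age_mean = 66, age_sd = 7,
                        tissue = default_tissue_spec(),
                        seed = 1L) {
  stopifnot(n_controls >= 0, n_patients >= 0)
  if (any(race_params$control_sd <= 0) || any(race_params$patient_sd <= 0)) {
    rlang::abort("race parameter SDs must be positive")
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 race_params = race_params, metabolites = metabolites,
                 age_mean = age_mean, age_sd = age_sd, tissue = tissue,
                 seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_race_param_spec <- function() {
  tibble::tibble(
    parameter = race_param_names(),
    control_mean = c(0.55, 0.08, 0.15, 0.70, 0.10, 0.20,
                     0.20, 0.03, 0.05, qnorm(0.03), qnorm(0.02)),
    control_sd = c(0.06, 0.02, 0.04, 0.08, 0.02, 0.05,
                   0.03, 0.01, 0.015, 0.30, 0.30),
    patient_mean = c(0.65, 0.10, 0.25, 0.80, 0.12, 0.28,
                     0.27, 0.05, 0.13, qnorm(0.10), qnorm(0.05)),
    patient_sd = c(0.09, 0.03, 0.07, 0.10, 0.03, 0.08,
                   0.05, 0.02, 0.05, 0.35, 0.35))
}

#' @rdname cohort_spec
#' @export
default_metabolite_spec <- function() {
  tibble::tibble(
    region = rep(c("right_IFG", "right_occipital"), each = 2),
    metabolite = rep(c("GABA", "glutamate"), 2),
    baseline = c(1.0, 5.5, 1.0, 5.5),
    beta_age = c(-0.008, -0.020, -0.008, -0.020),
    beta_sex = c(0.05, 0.10, 0.05, 0.10),
    beta_gm = c(1.2, 4.0, 1.2, 4.0),
    beta_wm = c(0.3, 2.0, 0.3, 2.0),
    deficit = c(0.38, 0.00, 0.00, 0.00),
    coupling = c(-0.10, -0.46, 0.00, 0.00),
    noise_sd = c(0.20, 0.80, 0.20, 0.80),
    crlb_control_mean = c(9.4, 2.1, 19.2, 2.3),
    crlb_control_sd = c(1.1, 0.3, 8.0, 0.7),
    crlb_patient_mean = c(12.3, 2.4, 19.4, 2.4),
    crlb_patient_sd = c(4.4, 0.5, 9.3, 1.1))
}

#' @rdname cohort_spec
#' @export
default_tissue_spec <- function() {
  tibble::tibble(
    group = c("control", "patient"),
    f_gm_mean = c(0.45, 0.38), f_gm_sd = c(0.04, 0.05),
    f_wm_mean = c(0.35, 0.33), f_wm_sd = c(0.04, 0.04))
}

#' Draw the participants of a synthetic cohort
#'
#' Participant-level race parameters are drawn from group truncated-normal
#' distributions on the sampling scale; failure probabilities are drawn on
#' the probit scale and reported as probabilities. Ages and sexes are
#' matched across groups by construction (drawn from the same
#' distributions).
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `participant_id`, `group`, `age`, `sex`, the 11
#'   race-parameter columns (natural scale) and `true_ssrt`.
#' @export
generate_participants <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  priors <- race_priors()
  withr::with_seed(derive_seed(spec$seed, 1L), {
    gen_group <- function(n, group, prefix) {
      if (n == 0) return(NULL)
      mcol <- paste0(group, "_mean")
      scol <- paste0(group, "_sd")
      draws <- vapply(seq_len(11), function(j) {
        rtnorm(n, spec$race_params[[mcol]][j], spec$race_params[[scol]][j],
               priors$lower[j], priors$upper[j])
      }, numeric(n))
      draws <- matrix(draws, nrow = n)
      colnames(draws) <- race_param_names()
      out <- tibble::as_tibble(draws)
      out$p_tf <- pnorm(out$p_tf)
      out$p_gf <- pnorm(out$p_gf)
      out$participant_id <- sprintf("%s%02d", prefix, seq_len(n))
      out$group <- group
      out$age <- round(rtnorm(n, spec$age_mean, spec$age_sd, 45, 85), 1)
      out$sex <- sample(rep(c("F", "M"), length.out = n))
      out$true_ssrt <- out$mu_stop + out$tau_stop
      out
    }
    dplyr::bind_rows(gen_group(spec$n_controls, "control", "C"),
                     gen_group(spec$n_patients, "patient", "P")) |>
      dplyr::select("participant_id", "group", "age", "sex",
                    dplyr::all_of(race_param_names()), "true_ssrt")
  })
}

#' Simulate task sessions for a cohort
#'
#' Runs one full session per participant through the task engine (including
#' the practice block, which downstream analyses exclude).
#'
#' @param participants Output of [generate_participants()].
#' @param task A [task_config()].
#' @param seed Integer seed (defaults to a stage seed derived from nothing
#'   but the participants' order, so pass one for full control).
#' @return Tibble of trial records for all participants, with
#'   `participant_id`.
#' @export
generate_sessions <- function(participants, task = task_config(), seed = 2L) {
  purrr::map_dfr(seq_len(nrow(participants)), function(i) {
    pars <- as_race_params(participants[i, race_param_names()])
    sq <- build_trial_sequence(task, seed = derive_seed(seed, 2L, i),
                               include_practice = TRUE)
    ses <- run_session(pars, sq, task, seed = derive_seed(seed, 3L, i))
    ses$participant_id <- participants$participant_id[i]
    dplyr::relocate(ses, "participant_id")
  })
}

#' Generate a synthetic metabolite table
#'
#' Concentrations follow `baseline + beta_age (age - 65) + beta_sex I(male)
#' + beta_gm f_gm + beta_wm f_wm - deficit I(patient) + coupling z(SSRT) +
#' noise`, where `z(SSRT)` is the true SSRT standardised within the patient
#' group (controls get no coupling, emulating the absence of a
#' brain-behaviour association in health), `deficit` is non-zero only for
#' frontal GABA by default, and the noise SD is scaled by each record's
#' drawn CRLB relative to its cell mean. Patients have lower grey-matter
#' fractions and higher CRLB, as in the published spectral-quality table.
#'
#' @param participants Output of [generate_participants()].
#' @param spec A [cohort_spec()].
#' @return Tibble of metabolite records (see [correct_concentrations()]).
#' @export
generate_metabolites <- function(participants, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(derive_seed(spec$seed, 4L), {
    n <- nrow(participants)
    tis <- spec$tissue[match(participants$group, spec$tissue$group), ]
    f_gm <- pmin(pmax(rnorm(n, tis$f_gm_mean, tis$f_gm_sd), 0.15), 0.7)
    f_wm <- pmin(pmax(rnorm(n, tis$f_wm_mean, tis$f_wm_sd), 0.1), 0.6)
    over <- f_gm + f_wm > 0.95
    f_wm[over] <- 0.95 - f_gm[over]
    f_csf <- pmax(1 - f_gm - f_wm, 0)
    is_pat <- participants$group == "patient"
    z <- rep(0, n)
    if (sum(is_pat) > 1) {
      z[is_pat] <- as.numeric(scale(participants$true_ssrt[is_pat]))
    }
    purrr::map_dfr(seq_len(nrow(spec$metabolites)), function(k) {
      m <- spec$metabolites[k, ]
      crlb <- ifelse(is_pat,
                     rtnorm(n, m$crlb_patient_mean, m$crlb_patient_sd, 1, 90),
                     rtnorm(n, m$crlb_control_mean, m$crlb_control_sd, 1, 90))
      cell_mean_crlb <- (m$crlb_control_mean + m$crlb_patient_mean) / 2
      conc <- m$baseline +
        m$beta_age * (participants$age - 65) +
        m$beta_sex * (participants$sex == "M") +
        m$beta_gm * f_gm + m$beta_wm * f_wm -
        m$deficit * is_pat +
        m$coupling * z +
        rnorm(n, 0, m$noise_sd * crlb / cell_mean_crlb)
      tibble::tibble(participant_id = participants$participant_id,
                     group = participants$group,
                     region = m$region, metabolite = m$metabolite,
                     concentration = conc, crlb = crlb,
                     f_gm = f_gm, f_wm = f_wm, f_csf = f_csf,
                     age = participants$age, sex = participants$sex)
    })
  })
}

#' Apply the study exclusion rules
#'
#' Participants with fewer than `min_stop_trials` analysable stop trials
#' are excluded from the behavioural (SSRT) analyses but retained for the
#' metabolite group comparison; every exclusion is logged with its reason.
#'
#' @param sessions Trial records with `participant_id`.
#' @param metabolites Optional metabolite table (returned unchanged, for
#'   symmetry with the study's handling).
#' @param min_stop_trials Exclusion threshold (default 50).
#' @return List with `behavioural` (filtered sessions), `metabolites`, and
#'   `exclusions` (tibble `participant_id`, `n_stop_trials`, `reason`).
#' @export
apply_exclusions <- function(sessions, metabolites = NULL,
                             min_stop_trials = 50L) {
  counts <- sessions |>
    analysable_trials() |>
    dplyr::filter(.data$trial_type == "stop") |>
    dplyr::count(.data$participant_id, name = "n_stop_trials")
  all_ids <- unique(sessions$participant_id)
  counts <- dplyr::left_join(tibble::tibble(participant_id = all_ids),
                             counts, by = "participant_id") |>
    dplyr::mutate(n_stop_trials = dplyr::coalesce(.data$n_stop_trials, 0L))
  excl <- dplyr::filter(counts, .data$n_stop_trials < min_stop_trials) |>
    dplyr::mutate(reason = sprintf("fewer than %d stop trials",
                                   min_stop_trials))
  list(behavioural = dplyr::filter(sessions,
                                   !.data$participant_id %in% excl$participant_id),
       metabolites = metabolites,
       exclusions = excl)
}
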