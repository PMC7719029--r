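SESSION_COLS <- c("participant_id", "block", "trial", "trial_type",
                  "stimulus", "is_init_go", "is_practice", "ssd_s",
                  "response", "rt_s")

#' Read and write the session table dialect
#'
#' Sessions are exchanged as TSV with columns `participant_id`, `block`,
#' `trial`, `trial_type`, `stimulus`, `is_init_go`, `is_practice`, `ssd_s`,
#' `response`, `rt_s`; times are in seconds with missing values written as
#' empty fields. `read_session_tsv()` validates types and enumerations and
#' reports offending line numbers; an `ms` unit flag converts millisecond
#' inputs.
#'
#' @param sessions Trial records as produced by [generate_sessions()] /
#'   [run_session()] (internal column names `ssd`, `rt`).
#' @param path File path.
#' @param time_unit Unit of `ssd_s`/`rt_s` values in the file: `"s"` or
#'   `"ms"` (converted to seconds on read).
#' @return `read_session_tsv()` a validated tibble with internal column
#'   names; `write_session_tsv()` the path, invisibly.
#' @export
write_session_tsv <- function(sessions, path) {
  out <- sessions
  if (!"is_practice" %in% names(out)) out$is_practice <- FALSE
  out <- dplyr::rename(out, ssd_s = "ssd", rt_s = "rt")
  out <- dplyr::mutate(out,
                       ssd_s = signif(.data$ssd_s, 6),
                       rt_s = signif(.data$rt_s, 6),
                       response = ifelse(is.na(.data$response) |
                                           .data$response == "none",
                                         NA_character_, .data$response))
  readr::write_tsv(out[, SESSION_COLS], path, na = "")
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path, time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  hdr <- names(readr::read_tsv(path, n_max = 0, na = "",
                               col_types = readr::cols(
                                 .default = readr::col_character())))
  miss <- setdiff(SESSION_COLS, hdr)
  if (length(miss)) {
    rlang::abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    block = readr::col_integer(), trial = readr::col_integer(),
    trial_type = readr::col_character(), stimulus = readr::col_character(),
    is_init_go = readr::col_logical(), is_practice = readr::col_logical(),
    ssd_s = readr::col_double(), response = readr::col_character(),
    rt_s = readr::col_double()), na = "")
  bad_type <- which(!raw$trial_type %in%
                      c("go_left", "go_right", "stop", "no_go"))
  if (length(bad_type)) {
    rlang::abort(paste0("invalid trial_type at line(s): ",
                        toString(head(bad_type + 1L, 10))))
  }
  bad_resp <- which(!is.na(raw$response) &
                      !raw$response %in% c("left", "right"))
  if (length(bad_resp)) {
    rlang::abort(paste0("invalid response at line(s): ",
                        toString(head(bad_resp + 1L, 10))))
  }
  scale <- if (time_unit == "ms") 1e-3 else 1
  out <- dplyr::mutate(raw,
                       ssd = .data$ssd_s * scale, rt = .data$rt_s * scale,
                       response = ifelse(is.na(.data$response), "none",
                                         .data$response))
  dplyr::select(out, -"ssd_s", -"rt_s")
}

#' Read and write the metabolite table dialect
#'
#' One row per participant x region x metabolite with the columns required
#' by [correct_concentrations()].
#'
#' @param records Metabolite records.
#' @param path File path.
#' @return `read_metabolite_tsv()` a validated tibble;
#'   `write_metabolite_tsv()` the path, invisibly.
#' @export
write_metabolite_tsv <- function(records, path) {
  check_metabolite_records(records)
  readr::write_tsv(records, path, na = "")
  invisible(path)
}

#' @rdname write_metabolite_tsv
#' @export
read_metabolite_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(), region = readr::col_character(),
    metabolite = readr::col_character(),
    concentration = readr::col_double(), crlb = readr::col_double(),
    f_gm = readr::col_double(), f_wm = readr::col_double(),
    f_csf = readr::col_double(), age = readr::col_double(),
    sex = readr::col_character()), na = "")
  check_metabolite_records(raw)
  raw
}

#' Execution presets for [run_study()]
#'
#' * `paper`: the full design -- 20 controls + 33 patients, five blocks of
#'   120 trials, 33 chains thinned by 10 with 500 retained draws. This is
#'   the configuration the method is described with; it takes hours of CPU.
#' * `demo`: the full cohort and task, but a lighter sampler (13 chains,
#'   thinning 2, 300 retained draws) sized so the complete pipeline runs in
#'   minutes while leaving the scientific pattern intact.
#' * `ci`: a scaled-down smoke-test preset (8 + 8 participants, 300-trial
#'   sessions, 13 chains, 150 retained draws).
#'
#' @param preset Preset name.
#' @param seed Master seed.
#' @return List with `cohort` ([cohort_spec()]), `task` ([task_config()])
#'   and `sampler` ([sampler_config()]).
#' @export
study_preset <- function(preset = c("demo", "ci", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  small_task <- task_config(blocks = 2L, trials_per_block = 150L,
                            n_go = 225L, n_nogo = 25L, n_stop = 50L,
                            practice_trials = 10L)
  switch(preset,
    paper = list(cohort = cohort_spec(seed = seed),
                 task = task_config(),
                 sampler = sampler_config(seed = derive_seed(seed, 9L))),
    demo = list(cohort = cohort_spec(seed = seed),
                task = task_config(),
                sampler = sampler_config(n_chains = 13L, thin = 2L,
                                         burnin_block_iters = 150L,
                                         max_burnin_blocks = 8L,
                                         final_iterations = 300L,
                                         seed = derive_seed(seed, 9L))),
    ci = list(cohort = cohort_spec(n_controls = 8L, n_patients = 8L,
                                   seed = seed),
              task = small_task,
              sampler = sampler_config(n_chains = 13L, thin = 2L,
                                       burnin_block_iters = 100L,
                                       max_burnin_blocks = 6L,
                                       final_iterations = 150L,
                                       seed = derive_seed(seed, 9L))))
}

#' Run the full synthetic study pipeline
#'
#' Generates a cohort, simulates sessions, applies the exclusion rules,
#' fits the hierarchical race model (patients always; controls optionally,
#' for the group SSRT comparison), corrects metabolite concentrations,
#' runs the region-by-diagnosis ANOVAs, and computes the posterior
#' Spearman associations between every (region, metabolite) residual and
#' the patients' SSRT draws, plus a trigger-failure specificity screen.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param preset See [study_preset()].
#' @param fit_controls Also fit the control group (needed for the group
#'   SSRT HDI comparison)?
#' @param rope,mass ROPE bounds and HDI mass for the association stage.
#' @param min_stop_trials Behavioural exclusion threshold.
#' @param outdir Optional directory; when given, session/metabolite/
#'   posterior tables (TSV), the association report and a manifest (JSON)
#'   are written there.
#' @return A `study_report` list: `participants`, `exclusions`, `fits`,
#'   `group_ssrt` (group-level SSRT HDIs and overlap flag, when both
#'   groups are fitted), `anova` (per metabolite), `associations`
#'   (tidy verdict table) and `manifest`.
#' @export
run_study <- function(seed = 1L, preset = "demo", fit_controls = TRUE,
                      rope = c(-0.1, 0.1), mass = 0.95,
                      min_stop_trials = 50L, outdir = NULL) {
  cfg <- study_preset(preset, seed)
  participants <- generate_participants(cfg$cohort)
  sessions <- generate_sessions(participants, cfg$task,
                                seed = derive_seed(seed, 5L))
  metabolites <- generate_metabolites(participants, cfg$cohort)
  excl <- apply_exclusions(sessions, metabolites, min_stop_trials)
  behavioural <- dplyr::left_join(
    excl$behavioural,
    participants[, c("participant_id", "group")], by = "participant_id")

  fits <- list()
  pat_sessions <- dplyr::filter(behavioural, .data$group == "patient")
  fits$patient <- fit_race_model(pat_sessions,
                                 config = cfg$sampler, group = "patient")
  if (fit_controls && any(behavioural$group == "control")) {
    ctl_cfg <- cfg$sampler
    ctl_cfg$seed <- derive_seed(seed, 10L)
    fits$control <- fit_race_model(
      dplyr::filter(behavioural, .data$group == "control"),
      config = ctl_cfg, group = "control")
  }

  group_ssrt <- NULL
  if (length(fits) == 2) {
    j_mu <- match("mu_stop", race_param_names())
    j_tau <- match("tau_stop", race_param_names())
    group_ssrt <- purrr::map_dfr(names(fits), function(g) {
      d <- fits[[g]]$draws
      s <- as.vector(d$loc[, , j_mu] + d$loc[, , j_tau])
      h <- hdi(s, mass)
      tibble::tibble(group = g, mean_ssrt = mean(s),
                     hdi_low = h[["lower"]], hdi_high = h[["upper"]])
    })
    group_ssrt <- dplyr::mutate(
      group_ssrt,
      overlaps = max(group_ssrt$hdi_low) <= min(group_ssrt$hdi_high))
  }

  corrected <- correct_concentrations(metabolites)
  anovas <- lapply(unique(corrected$metabolite), function(m)
    group_region_anova(corrected, m))
  names(anovas) <- unique(corrected$metabolite)

  ssrt_draws <- ssrt_posterior(fits$patient)
  ptf_draws <- tidy(fits$patient, level = "participant") |>
    dplyr::filter(.data$parameter == "p_tf") |>
    dplyr::select("chain", "iteration", "participant_id", p_tf = "value")
  assoc_ids <- intersect(unique(ssrt_draws$participant_id),
                         unique(corrected$participant_id))
  cells <- dplyr::distinct(corrected, .data$region, .data$metabolite)
  associations <- purrr::map_dfr(seq_len(nrow(cells)), function(k) {
    vals <- corrected |>
      dplyr::filter(.data$region == cells$region[k],
                    .data$metabolite == cells$metabolite[k],
                    .data$group == "patient",
                    .data$participant_id %in% assoc_ids)
    dr <- dplyr::filter(ssrt_draws,
                        .data$participant_id %in% vals$participant_id)
    purrr::map_dfr(c("ssrt", "p_tf"), function(measure) {
      d <- if (measure == "ssrt") dr else
        dplyr::filter(ptf_draws, .data$participant_id %in% vals$participant_id)
      cp <- posterior_correlation(d, vals, draw_col = measure,
                                  rope = rope, mass = mass)
      dplyr::mutate(tidy(cp), region = cells$region[k],
                    metabolite = cells$metabolite[k], measure = measure,
                    .before = 1)
    })
  })

  manifest <- list(
    seed = seed, preset = preset,
    package_version = as.character(utils::packageVersion("stopsig")),
    task = unclass(cfg$task), sampler = unclass(cfg$sampler),
    cohort = list(n_controls = cfg$cohort$n_controls,
                  n_patients = cfg$cohort$n_patients,
                  seed = cfg$cohort$seed),
    rope = rope, hdi_mass = mass, min_stop_trials = min_stop_trials,
    exclusions = nrow(excl$exclusions),
    rhat_max = vapply(fits, function(f) max(f$rhat$rhat), numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    n_floor = vapply(fits, function(f) f$n_floor, numeric(1)))

  report <- structure(list(participants = participants,
                           sessions = sessions,
                           metabolites = metabolites,
                           exclusions = excl$exclusions,
                           fits = fits, group_ssrt = group_ssrt,
                           corrected = corrected, anova = anovas,
                           associations = associations,
                           manifest = manifest),
                      class = "study_report")
  if (!is.null(outdir)) write_study_report(report, outdir)
  report
}

write_study_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_session_tsv(report$sessions, file.path(outdir, "sessions.tsv"))
  write_metabolite_tsv(report$metabolites,
                       file.path(outdir, "metabolites.tsv"))
  for (g in names(report$fits)) {
    readr::write_tsv(tidy(report$fits[[g]]),
                     file.path(outdir, paste0("posterior_", g, ".tsv")))
    jsonlite::write_json(
      list(rhat = report$fits[[g]]$rhat,
           converged = report$fits[[g]]$converged,
           config = unclass(report$fits[[g]]$config)),
      file.path(outdir, paste0("posterior_", g, "_meta.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  readr::write_tsv(report$associations,
                   file.path(outdir, "associations.tsv"))
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic stop-signal / MRS study\n")
  cat(sprintf("  %d participants, %d excluded from behavioural analyses\n",
              nrow(x$participants), nrow(x$exclusions)))
  if (!is.null(x$group_ssrt)) {
    cat("\nGroup-level SSRT (s):\n")
    print(as.data.frame(x$group_ssrt), row.names = FALSE)
  }
  for (m in names(x$anova)) {
    cat(sprintf("\n%s simple main effects of group:\n", m))
    print(as.data.frame(x$anova[[m]]$simple_effects), row.names = FALSE)
  }
  cat("\nPosterior Spearman associations (patients, SSRT):\n")
  print(as.data.frame(
    dplyr::select(
      dplyr::filter(x$associations, .data$measure == "ssrt"),
      "region", "metabolite", "r_mean", "hdi_low", "hdi_high", "verdict")),
    row.names = FALSE)
  invisible(x)
}
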