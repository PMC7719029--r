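#' Stop-signal task configuration
#'
#' Defaults follow the study design: five blocks of 120 trials with 450 go,
#' 51 no-go and 99 stop trials in total, the first 20 trials of each block
#' being go trials used only to initialise the staircase. The staircase
#' targets 50% cumulative stop accuracy with a one-up-one-down rule.
#'
#' @param blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param n_go,n_nogo,n_stop Total trial counts over the session; must sum
#'   to `blocks * trials_per_block`.
#' @param init_go_per_block Leading go trials per block used to set the
#'   starting SSD; excluded from likelihood analysis.
#' @param ssd_step_s Staircase step (s): the SSD moves up by one step after
#'   a successful stop and down by one step after a failed stop.
#' @param ssd_min_s,ssd_max_s Staircase bounds (s).
#' @param init_ssd_offset_s Offset subtracted from the mean initialisation
#'   go RT to give the starting SSD of each block (s).
#' @param default_ssd_s Fallback starting SSD when no initialisation RTs
#'   were observed (s).
#' @param practice_trials Number of practice go trials (block 0), generated
#'   on request and excluded from all analyses.
#' @return A list of settings with class `task_config`.
#' @export
task_config <- function(blocks = 5L, trials_per_block = 120L,
                        n_go = 450L, n_nogo = 51L, n_stop = 99L,
                        init_go_per_block = 20L,
                        ssd_step_s = 0.05, ssd_min_s = 0, ssd_max_s = 1.5,
                        init_ssd_offset_s = 0.25, default_ssd_s = 0.25,
                        practice_trials = 20L) {
  cfg <- list(blocks = as.integer(blocks),
              trials_per_block = as.integer(trials_per_block),
              n_go = as.integer(n_go), n_nogo = as.integer(n_nogo),
              n_stop = as.integer(n_stop),
              init_go_per_block = as.integer(init_go_per_block),
              ssd_step_s = ssd_step_s, ssd_min_s = ssd_min_s,
              ssd_max_s = ssd_max_s,
              init_ssd_offset_s = init_ssd_offset_s,
              default_ssd_s = default_ssd_s,
              practice_trials = as.integer(practice_trials))
  if (cfg$n_go + cfg$n_nogo + cfg$n_stop != cfg$blocks * cfg$trials_per_block) {
    rlang::abort("trial composition must sum to blocks * trials_per_block")
  }
  if (cfg$n_go < cfg$blocks * cfg$init_go_per_block) {
    rlang::abort("not enough go trials to reserve the initialisation trials")
  }
  if (cfg$ssd_min_s > cfg$ssd_max_s || cfg$ssd_step_s <= 0) {
    rlang::abort("invalid staircase settings")
  }
  structure(cfg, class = "task_config")
}

# Split `total` into `k` near-equal integer parts, order shuffled.
split_counts <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  counts <- rep(c(base + 1L, base), c(extra, k - extra))
  counts[sample.int(k)]
}

# Left/right labels balanced within +/- 1, in random order.
balanced_sides <- function(n) {
  sides <- rep(c("left", "right"), length.out = n)
  sample(sides)
}

#' Build a randomised trial sequence
#'
#' Generates the ordered list of trial specifications for one session:
#' trial counts follow the configuration exactly, the leading
#' `init_go_per_block` trials of every block are go trials flagged
#' `is_init_go`, the remaining trials are shuffled within block, and
#' left/right go stimuli are balanced within one trial. Every trial carries
#' a `stimulus` side (for stop and no-go trials this is the side of the
#' arrow that is later signalled), balanced within trial type.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; required, since downstream analyses must be
#'   reproducible.
#' @param include_practice Prepend the practice block (block 0, flagged
#'   `is_practice`)?
#' @return A tibble with columns `block`, `trial`, `trial_type`,
#'   `stimulus`, `is_init_go`, `is_practice`.
#' @export
build_trial_sequence <- function(config = task_config(), seed,
                                 include_practice = FALSE) {
  if (missing(seed) || is.null(seed)) {
    rlang::abort("a seed is required to build a trial sequence")
  }
  withr::with_seed(seed, {
    n_init <- config$blocks * config$init_go_per_block
    n_free_go <- config$n_go - n_init
    go_sides <- balanced_sides(config$n_go)
    # per-block allocation of the non-init trials: stop and no-go counts are
    # spread near-evenly, go trials fill the remaining slots
    nogo_per_block <- split_counts(config$n_nogo, config$blocks)
    stop_per_block <- split_counts(config$n_stop, config$blocks)
    slots <- config$trials_per_block - config$init_go_per_block
    go_per_block <- slots - nogo_per_block - stop_per_block
    if (any(go_per_block < 0)) {
      rlang::abort("per-block composition infeasible after reserving init trials")
    }
    nogo_sides <- balanced_sides(config$n_nogo)
    stop_sides <- balanced_sides(config$n_stop)
    gi <- ni <- si <- 0L
    blocks <- vector("list", config$blocks)
    for (b in seq_len(config$blocks)) {
      init <- tibble::tibble(
        trial_type = paste0("go_", go_sides[gi + seq_len(config$init_go_per_block)]),
        is_init_go = TRUE)
      gi <- gi + config$init_go_per_block
      rest_types <- c(rep("go", go_per_block[b]),
                      rep("no_go", nogo_per_block[b]),
                      rep("stop", stop_per_block[b]))
      rest_types <- sample(rest_types)
      rest <- tibble::tibble(trial_type = rest_types, is_init_go = FALSE)
      n_g <- sum(rest_types == "go")
      rest$trial_type[rest$trial_type == "go"] <-
        paste0("go_", go_sides[gi + seq_len(n_g)])
      gi <- gi + n_g
      blocks[[b]] <- dplyr::bind_rows(init, rest)
      blocks[[b]]$block <- b
    }
    out <- dplyr::bind_rows(blocks)
    out$stimulus <- NA_character_
    is_go <- out$trial_type %in% c("go_left", "go_right")
    out$stimulus[is_go] <- sub("^go_", "", out$trial_type[is_go])
    out$stimulus[out$trial_type == "no_go"] <- nogo_sides
    out$stimulus[out$trial_type == "stop"] <- stop_sides
    out$is_practice <- FALSE
    if (include_practice && config$practice_trials > 0) {
      practice <- tibble::tibble(
        trial_type = paste0("go_", balanced_sides(config$practice_trials)),
        is_init_go = FALSE, block = 0L)
      practice$stimulus <- sub("^go_", "", practice$trial_type)
      practice$is_practice <- TRUE
      out <- dplyr::bind_rows(practice, out)
    }
    out <- dplyr::group_by(out, .data$block)
    out <- dplyr::mutate(out, trial = dplyr::row_number())
    out <- dplyr::ungroup(out)
    dplyr::select(out, "block", "trial", "trial_type", "stimulus",
                  "is_init_go", "is_practice")
  })
}

#' Starting SSD from the initialisation go trials
#'
#' The starting SSD of each block is the mean RT of the block's leading go
#' trials minus a fixed offset, clipped to the staircase bounds; omitted
#' trials contribute nothing. If every initialisation trial was omitted the
#' configured default SSD is used with a warning.
#'
#' @param init_go_rts Numeric vector of observed initialisation go RTs
#'   (seconds); `NA`s (omissions) are dropped.
#' @param config A [task_config()].
#' @return Starting SSD in seconds.
#' @export
init_ssd <- function(init_go_rts, config = task_config()) {
  rts <- init_go_rts[!is.na(init_go_rts)]
  if (length(rts) == 0) {
    rlang::warn("no initialisation go RTs observed; using default SSD")
    return(min(max(config$default_ssd_s, config$ssd_min_s), config$ssd_max_s))
  }
  ssd <- mean(rts) - config$init_ssd_offset_s
  min(max(ssd, config$ssd_min_s), config$ssd_max_s)
}

#' Staircase state for SSD tracking
#'
#' `staircase_new()` creates the tracker; `staircase_update()` applies the
#' one-up-one-down rule that targets 50% cumulative stop accuracy: the SSD
#' increases by one step after a successful stop (making stopping harder)
#' and decreases by one step after a failed stop, clipped to the bounds.
#'
#' @param ssd Current stop-signal delay (s).
#' @param config A [task_config()].
#' @param state A `staircase_state` list.
#' @param stop_succeeded Logical: was the response successfully withheld?
#' @return A `staircase_state` list with fields `current_ssd`, `step`,
#'   `bounds`, `n_stop_success`, `n_stop_total`.
#' @export
staircase_new <- function(ssd, config = task_config()) {
  structure(list(current_ssd = min(max(ssd, config$ssd_min_s), config$ssd_max_s),
                 step = config$ssd_step_s,
                 bounds = c(config$ssd_min_s, config$ssd_max_s),
                 n_stop_success = 0L, n_stop_total = 0L),
            class = "staircase_state")
}

#' @rdname staircase_new
#' @export
staircase_update <- function(state, stop_succeeded) {
  delta <- if (isTRUE(stop_succeeded)) state$step else -state$step
  state$current_ssd <- min(max(state$current_ssd + delta, state$bounds[1]),
                           state$bounds[2])
  state$n_stop_total <- state$n_stop_total + 1L
  state$n_stop_success <- state$n_stop_success + as.integer(isTRUE(stop_succeeded))
  state
}

#' Simulate a full task session for one participant
#'
#' Runs the trial sequence against a race-model participant: go and no-go
#' trials are simulated directly; stop trials take their SSD from the
#' staircase, which restarts in each block from the block's initialisation
#' go trials and then follows the one-up-one-down rule. No-go trials carry
#' SSD 0 and do not move the staircase.
#'
#' @param params Race parameters of the simulated participant.
#' @param sequence Trial specifications from [build_trial_sequence()].
#' @param config A [task_config()].
#' @param seed Integer seed (required).
#' @return A tibble of trial records: the sequence columns plus `ssd`,
#'   `response`, `rt`.
#' @export
run_session <- function(params, sequence, config = task_config(), seed) {
  if (missing(seed) || is.null(seed)) {
    rlang::abort("a seed is required to run a session")
  }
  p <- as_race_params(params)
  withr::with_seed(seed, {
    n <- nrow(sequence)
    ssd <- rep(NA_real_, n)
    response <- character(n)
    rt <- rep(NA_real_, n)
    stair <- NULL
    init_rts <- numeric(0)
    cur_block <- -1L
    for (i in seq_len(n)) {
      tt <- sequence$trial_type[i]
      if (sequence$block[i] != cur_block) {
        cur_block <- sequence$block[i]
        stair <- NULL
        init_rts <- numeric(0)
      }
      trial_ssd <- NA_real_
      if (tt %in% c("stop", "no_go")) {
        if (tt == "no_go") {
          trial_ssd <- 0
        } else {
          if (is.null(stair)) stair <- staircase_new(init_ssd(init_rts, config), config)
          trial_ssd <- stair$current_ssd
        }
      }
      rec <- simulate_trials(tt, ssd = ifelse(is.na(trial_ssd), 0, trial_ssd),
                             params = p, stimulus = sequence$stimulus[i])
      ssd[i] <- trial_ssd
      response[i] <- rec$response
      rt[i] <- rec$rt
      if (isTRUE(sequence$is_init_go[i])) {
        init_rts <- c(init_rts, rec$rt)
      }
      if (tt == "stop") {
        stair <- staircase_update(stair, rec$response == "none")
      }
    }
    out <- sequence
    out$ssd <- ssd
    out$response <- response
    out$rt <- rt
    tibble::as_tibble(out)
  })
}
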