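#' Build a factorial trial schedule
#'
#' Generates per-subject trial tables for the approach-avoidance task. Each
#' run contains one repetition of all money (5) x shock (5) x action context
#' (2) combinations with long anticipation-to-movement intervals (AMI,
#' 6-7 s; 50 trials), plus 12 short-AMI filler trials (0.5-5.5 s) whose
#' condition cells are drawn uniformly without replacement from the
#' factorial. Trial order is shuffled within run; onsets accumulate the
#' inter-trial interval, AMI, movement window and outcome screen.
#'
#' @param config a [task_config()].
#' @param n_subjects number of subjects.
#' @param seed integer seed (mandatory; schedules are reproducible).
#' @return a tibble with columns `subject, run, trial, money, shocks,
#'   action_context, ami, onset, is_long`.
#' @export
#' @examples
#' sched <- build_schedule(task_config(), n_subjects = 1, seed = 1)
#' nrow(sched)          # 186
#' sum(sched$is_long)   # 150
build_schedule <- function(config = task_config(), n_subjects, seed) {
  validate_task_config(config)
  if (missing(seed)) stop("seed must be provided", call. = FALSE)
  set.seed(seed)
  if (n_subjects == 0L) return(empty_schedule())
  cells <- expand.grid(money = config$money_levels,
                       shocks = config$shock_levels,
                       action_context = config$action_contexts,
                       stringsAsFactors = FALSE)
  out <- vector("list", n_subjects * config$n_runs)
  k <- 0L
  for (subj in seq_len(n_subjects)) {
    for (run in seq_len(config$n_runs)) {
      n_long <- nrow(cells)
      long <- cells
      long$ami <- stats::runif(n_long, config$long_ami_range[1],
                               config$long_ami_range[2])
      long$is_long <- TRUE
      short <- cells[sample.int(n_long, config$n_short_per_run), ]
      short$ami <- stats::runif(config$n_short_per_run,
                                config$short_ami_range[1],
                                config$short_ami_range[2])
      short$is_long <- FALSE
      run_tab <- rbind(long, short)
      run_tab <- run_tab[sample.int(nrow(run_tab)), ]
      iti <- stats::runif(nrow(run_tab), config$iti_range[1],
                          config$iti_range[2])
      dur <- run_tab$ami + config$movement_window + config$outcome_screen
      run_tab$onset <- cumsum(iti) + c(0, cumsum(dur)[-nrow(run_tab)])
      run_tab$subject <- subj
      run_tab$run <- run
      run_tab$trial <- seq_len(nrow(run_tab))
      k <- k + 1L
      out[[k]] <- run_tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tibble::as_tibble(res[, c("subject", "run", "trial", "money", "shocks",
                            "action_context", "ami", "onset", "is_long")])
}

empty_schedule <- function() {
  tibble::tibble(subject = integer(0), run = integer(0), trial = integer(0),
                 money = integer(0), shocks = integer(0),
                 action_context = character(0), ami = numeric(0),
                 onset = numeric(0), is_long = logical(0))
}

#' Simulate anticipatory cardiac states and beat-by-beat traces
#'
#' Draws a latent trial-wise heart-rate deceleration
#' \eqn{\delta_{it} \sim N(\bar\delta + u_i, \sigma_{trial})} for every
#' trial (independent of money, shocks and action context), and, for
#' long-AMI trials, generates beat times from an inhomogeneous rate:
#' subject baseline BPM before the anticipation onset, ramping linearly to
#' baseline + \eqn{\delta_{it}} over the first `ramp_seconds` of the
#' anticipation window and flat thereafter, with optional beat-level noise.
#' The latent \eqn{\delta_{it}} is returned so recovery of the bradycardia
#' index through the preprocessing pipeline can be checked against truth.
#'
#' @param trials a schedule from [build_schedule()].
#' @param params a [cardiac_params()].
#' @param seed integer seed.
#' @return `trials` with added columns `baseline_bpm`, `delta_true`, and a
#'   list-column `beats` of beat times in seconds relative to run start
#'   (NULL for short-AMI trials). Traces span onset - 2.5 s to 1.5 s past
#'   the end of the anticipation window (at least onset + 8.5 s), covering
#'   both the baseline and the 5-7 s response window.
#' @export
simulate_cardiac <- function(trials, params = cardiac_params(), seed) {
  stopifnot(inherits(params, "pat_cardiac_params"))
  if (missing(seed)) stop("seed must be provided", call. = FALSE)
  set.seed(seed)
  subjects <- unique(trials$subject)
  base_i <- stats::setNames(
    stats::rnorm(length(subjects), params$baseline_bpm_mean,
                 params$baseline_bpm_sd), subjects)
  if (any(base_i <= 0))
    stop("generator produced nonpositive baseline BPM; ",
         "check baseline_bpm_mean/sd", call. = FALSE)
  off_i <- stats::setNames(
    stats::rnorm(length(subjects), 0, params$delta_subject_sd), subjects)
  b <- base_i[as.character(trials$subject)]
  delta <- stats::rnorm(nrow(trials),
                        params$delta_mean + off_i[as.character(trials$subject)],
                        params$delta_trial_sd)
  beats <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (!trials$is_long[i]) next
    beats[[i]] <- simulate_beats(onset = trials$onset[i],
                                 span = c(-2.5, max(trials$ami[i], 7) + 1.5),
                                 baseline = b[i], delta = delta[i],
                                 ramp = params$ramp_seconds,
                                 noise_sd = params$beat_noise_sd)
  }
  out <- trials
  out$baseline_bpm <- unname(b)
  out$delta_true <- delta
  out$beats <- beats
  out
}

# Beat times for one trial. Each inter-beat interval satisfies
# ibi = 60 / BPM(interval midpoint) (fixed-point iteration), so that the
# 60/IBI series recovered downstream tracks the instantaneous rate with
# minimal lag through the ramp.
simulate_beats <- function(onset, span, baseline, delta, ramp, noise_sd) {
  rate <- function(t) {
    rel <- t - onset
    baseline + if (rel <= 0) 0 else delta * min(rel / ramp, 1)
  }
  t <- onset + span[1]
  stop_t <- onset + span[2]
  beats <- numeric(0)
  repeat {
    eps <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
    ibi <- 60 / max(rate(t) + eps, 20)
    for (k in 1:3)
      ibi <- 60 / max(rate(t + ibi / 2) + eps, 20)
    beats <- c(beats, t)
    t <- t + ibi
    if (t > stop_t) break
  }
  beats
}

#' Simulate approach/avoid choices from a decision-value agent
#'
#' Computes trial-wise decision values under the agent's model (base or one
#' of the freezing variants), maps them to approach probabilities through
#' the logistic function, and draws Bernoulli choices. Money and shock
#' levels are standardized against their balanced design distribution
#' (mean 3, SD \eqn{\sqrt 2}); the money-shock difference against SD 2; the
#' bradycardia input is standardized against its pooled mean and SD. When
#' `random_effect_scale > 0`, each subject's coefficient vector is perturbed
#' by independent zero-mean normals with SD proportional to the group value.
#'
#' @param trials trial table with `subject, money, shocks, action_context`.
#' @param dhr numeric vector, one bradycardia value per trial (any scale;
#'   standardized internally).
#' @param agent an [agent_params()].
#' @param seed integer seed.
#' @return character vector, `"approach"` or `"avoid"` per trial.
#' @export
simulate_choices <- function(trials, dhr, agent = agent_params(), seed) {
  if (missing(seed)) stop("seed must be provided", call. = FALSE)
  if (length(dhr) != nrow(trials) || anyNA(dhr))
    stop("dhr must be complete, one value per trial", call. = FALSE)
  set.seed(seed)
  z <- standardized_features(trials, dhr)
  params <- agent$choice_params
  kind <- param_kind(params)
  X <- choice_design(z, kind)
  subjects <- unique(trials$subject)
  eta <- numeric(nrow(trials))
  for (subj in subjects) {
    idx <- trials$subject == subj
    coefs <- as.numeric(params)
    if (agent$random_effect_scale > 0)
      coefs <- coefs + stats::rnorm(length(coefs), 0,
                                    agent$random_effect_scale * abs(coefs))
    eta[idx] <- X[idx, , drop = FALSE] %*% coefs
  }
  p <- p_approach(eta)
  ifelse(stats::runif(nrow(trials)) < p, "approach", "avoid")
}

# Generator-side standardization of raw trial features. Levels use the
# balanced-design population moments so that e.g. money 5 maps to +1.414;
# dhr uses its pooled empirical mean and (population) SD.
standardized_features <- function(trials, dhr) {
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  dhr_sd <- sd_pop(dhr)
  if (dhr_sd == 0) dhr_sd <- 1
  tibble::tibble(
    z_money = (trials$money - 3) / sqrt(2),
    z_shocks = (trials$shocks - 3) / sqrt(2),
    z_dms = (trials$money - trials$shocks) / 2,
    z_dhr = (dhr - mean(dhr)) / dhr_sd,
    ac_code = ifelse(trials$action_context == "active", -1, 1))
}

#' Simulate response times for active-response trials
#'
#' An active (button-press) response occurs when approaching in the active
#' context or avoiding in the passive context; only those trials carry a
#' response time, drawn from a shifted log-normal whose location is linear
#' in standardized money, shocks, the sum-coded choice (+1 approach /
#' -1 avoid), the bradycardia index and their interactions.
#'
#' @param trials trial table.
#' @param choices character vector from [simulate_choices()].
#' @param dhr bradycardia values, one per trial.
#' @param agent an [agent_params()].
#' @param seed integer seed.
#' @return numeric vector of RTs in seconds; NA on passive-response trials.
#' @export
simulate_rts <- function(trials, choices, dhr, agent = agent_params(), seed) {
  if (missing(seed)) stop("seed must be provided", call. = FALSE)
  rp <- agent$rt
  if (rp$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  set.seed(seed)
  z <- standardized_features(trials, dhr)
  ch <- ifelse(choices == "approach", 1, -1)
  active <- is_active_response(trials$action_context, choices)
  mu <- rp$intercept + rp$b_choice * ch +
    rp$b_money_choice * z$z_money * ch +
    rp$b_shocks_choice * z$z_shocks * ch +
    rp$b_dhr * z$z_dhr
  rt <- rp$shift + exp(stats::rnorm(nrow(trials), mu, rp$sigma))
  rt[!active] <- NA_real_
  rt
}

#' @rdname simulate_rts
#' @export
is_active_response <- function(action_context, choices) {
  (action_context == "active" & choices == "approach") |
    (action_context == "passive" & choices == "avoid")
}

#' Sample probabilistic trial outcomes
#'
#' Draws the money / shocks / nothing outcome per trial from the
#' contingency triple matching the choice: 40/40/20 on approach and
#' 10/10/80 on avoid under the default configuration.
#'
#' @param choices character vector of `"approach"` / `"avoid"`.
#' @param config a [task_config()].
#' @param seed integer seed.
#' @return character vector of outcomes.
#' @export
sample_outcomes <- function(choices, config = task_config(), seed) {
  validate_task_config(config)
  if (missing(seed)) stop("seed must be provided", call. = FALSE)
  set.seed(seed)
  labels <- c("money", "shocks", "nothing")
  u <- stats::runif(length(choices))
  out <- character(length(choices))
  for (arm in c("approach", "avoid")) {
    p <- if (arm == "approach") config$p_outcome_approach else config$p_outcome_avoid
    idx <- choices == arm
    out[idx] <- labels[findInterval(u[idx], cumsum(p), left.open = TRUE) + 1L]
  }
  out
}

#' Shock intensity calibration staircase
#'
#' Reproduces the shock work-up: five shocks, starting at intensity level 2,
#' each rated 1-5; ratings of 3 or lower raise the level by one, a rating of
#' 5 lowers it by one, a rating of 4 keeps it, clipped to levels 1-10. The
#' returned `final_level` is the level at which the fifth shock was
#' delivered.
#'
#' @param ratings integer vector of exactly 5 ratings in 1-5.
#' @return list with `final_level` and `trajectory` (the 5 delivery levels).
#' @export
#' @examples
#' shock_workup(c(3, 3, 4, 4, 4))$final_level  # 4
shock_workup <- function(ratings) {
  if (length(ratings) != 5L || !all(ratings %in% 1:5))
    stop("ratings must be exactly 5 integers in 1-5", call. = FALSE)
  level <- 2L
  traj <- integer(5)
  for (i in 1:5) {
    traj[i] <- level
    step <- if (ratings[i] <= 3) 1L else if (ratings[i] == 5) -1L else 0L
    level <- min(max(level + step, 1L), 10L)
  }
  list(final_level = traj[5], trajectory = traj)
}

#' Simulate a complete task dataset
#'
#' Orchestrates schedule construction, cardiac-state generation, choice,
#' response-time and outcome simulation into one trial table plus the
#' beat-time traces. All randomness derives from named substreams of the
#' single root seed, so identical calls produce identical tables.
#'
#' @param config a [task_config()].
#' @param agent an [agent_params()].
#' @param n_subjects number of subjects (0 gives an empty table).
#' @param seed integer root seed.
#' @return list with `trials` (schedule columns plus `choice, rt, outcome,
#'   dhr_true, baseline_bpm`) and `traces` (tibble with the `beats`
#'   list-column).
#' @export
simulate_dataset <- function(config = task_config(), agent = agent_params(),
                             n_subjects, seed) {
  validate_task_config(config)
  if (missing(seed)) stop("seed must be provided", call. = FALSE)
  trials <- build_schedule(config, n_subjects, seed = seed)
  if (nrow(trials) == 0L) {
    empty <- trials
    empty$choice <- character(0); empty$rt <- numeric(0)
    empty$outcome <- character(0); empty$dhr_true <- numeric(0)
    empty$baseline_bpm <- numeric(0)
    return(list(trials = empty, traces = empty_schedule()))
  }
  card <- simulate_cardiac(trials, agent$cardiac, seed = seed + 1L)
  choices <- simulate_choices(trials, card$delta_true, agent, seed = seed + 2L)
  rts <- simulate_rts(trials, choices, card$delta_true, agent, seed = seed + 3L)
  outcomes <- sample_outcomes(choices, config, seed = seed + 4L)
  trials$choice <- choices
  trials$rt <- rts
  trials$outcome <- outcomes
  trials$dhr_true <- card$delta_true
  trials$baseline_bpm <- card$baseline_bpm
  traces <- card[card$is_long,
                 c("subject", "run", "trial", "onset", "ami", "beats")]
  list(trials = trials, traces = traces)
}

#' Simulate standardized factorial trials for recovery experiments
#'
#' Fast path for parameter-recovery studies: builds balanced factorial
#' money/shock/action-context trials (no timing, no cardiac traces) with an
#' exogenous standardized bradycardia input drawn from N(0, 1), plus the
#' pooled standardized predictor columns used by the model fitters.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject; a multiple of 50 fills whole
#'   factorial repetitions, otherwise the remainder is sampled without
#'   replacement.
#' @param seed integer seed.
#' @return tibble with raw levels, `dhr`, and `z_money, z_shocks, z_dms,
#'   z_dhr, ac_code` columns.
#' @export
simulate_standardized_trials <- function(n_subjects, n_trials, seed) {
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  if (missing(seed)) stop("seed must be provided", call. = FALSE)
  set.seed(seed)
  cells <- expand.grid(money = 1:5, shocks = 1:5,
                       action_context = c("active", "passive"),
                       stringsAsFactors = FALSE)
  per_subject <- function(subj) {
    reps <- n_trials %/% nrow(cells)
    rem <- n_trials %% nrow(cells)
    idx <- c(rep(seq_len(nrow(cells)), reps),
             if (rem > 0) sample.int(nrow(cells), rem))
    tab <- cells[sample(idx), ]
    tab$subject <- subj
    tab
  }
  trials <- do.call(rbind, lapply(seq_len(n_subjects), per_subject))
  rownames(trials) <- NULL
  trials <- tibble::as_tibble(trials)
  trials$dhr <- stats::rnorm(nrow(trials))
  cbind_features(trials, trials$dhr)
}

cbind_features <- function(trials, dhr) {
  z <- standardized_features(trials, dhr)
  trials$z_money <- z$z_money
  trials$z_shocks <- z$z_shocks
  trials$z_dms <- z$z_dms
  trials$z_dhr <- z$z_dhr
  trials$ac_code <- z$ac_code
  trials
}
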