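#' Task configuration for the approach-avoidance task simulator
#'
#' Encodes the structural constants of the task: factorial money/shock levels,
#' the two action contexts, trial timing, and the outcome contingencies tied
#' to the approach/avoid choice (40/40/20 money/shocks/nothing on approach;
#' 10/10/80 on avoid).
#'
#' @param n_runs number of runs per subject (each run holds one full
#'   5 x 5 x 2 factorial of long-anticipation trials plus 12 short trials).
#' @param long_ami_range seconds; range of the long anticipation-to-movement
#'   interval (AMI). Only long-AMI trials enter cardiac analyses because the
#'   heart-rate response develops slowly.
#' @param short_ami_range seconds; range of the short AMI filler trials.
#' @param n_short_per_run number of short-AMI trials per run.
#' @param iti_range seconds; inter-trial interval range.
#' @param movement_window seconds; duration of the target-movement window.
#' @param outcome_screen seconds; duration of the outcome screen.
#' @param p_outcome_approach probability triple (money, shocks, nothing)
#'   applied when the agent approaches.
#' @param p_outcome_avoid probability triple applied when the agent avoids.
#' @param tr seconds; repetition time of the imaging grid.
#'
#' @return an object of class `pat_task_config` (a named list).
#' @export
task_config <- function(n_runs = 3L,
                        long_ami_range = c(6.0, 7.0),
                        short_ami_range = c(0.5, 5.5),
                        n_short_per_run = 12L,
                        iti_range = c(9, 11),
                        movement_window = 0.7,
                        outcome_screen = 1.5,
                        p_outcome_approach = c(money = 0.40, shocks = 0.40, nothing = 0.20),
                        p_outcome_avoid = c(money = 0.10, shocks = 0.10, nothing = 0.80),
                        tr = 1.5) {
  cfg <- list(
    money_levels = 1:5,
    shock_levels = 1:5,
    action_contexts = c("active", "passive"),
    n_runs = as.integer(n_runs),
    long_ami_range = long_ami_range,
    short_ami_range = short_ami_range,
    n_short_per_run = as.integer(n_short_per_run),
    iti_range = iti_range,
    movement_window = movement_window,
    outcome_screen = outcome_screen,
    p_outcome_approach = p_outcome_approach,
    p_outcome_avoid = p_outcome_avoid,
    tr = tr
  )
  class(cfg) <- "pat_task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "pat_task_config"))
  if (length(cfg$money_levels) != 5L || length(cfg$shock_levels) != 5L)
    stop("money/shock level sets must each have 5 members", call. = FALSE)
  for (p in list(cfg$p_outcome_approach, cfg$p_outcome_avoid)) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("outcome probability triples must be nonnegative and sum to 1",
           call. = FALSE)
  }
  if (cfg$n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  if (cfg$long_ami_range[1] < cfg$short_ami_range[2])
    stop("long and short AMI ranges must be disjoint", call. = FALSE)
  invisible(cfg)
}

#' Cardiac generator parameters
#'
#' Parameters of the anticipatory heart-rate deceleration generator. The
#' trial-wise deceleration \eqn{\delta_{it}} is drawn as
#' `Normal(delta_mean + subject offset, delta_trial_sd)` with subject offsets
#' `Normal(0, delta_subject_sd)`, independent of money, shocks and action
#' context. Beat times follow an inhomogeneous rate: subject baseline BPM
#' before trial onset, ramping linearly to baseline + \eqn{\delta_{it}} over
#' the first `ramp_seconds` of the anticipation window, then flat.
#'
#' @param baseline_bpm_mean,baseline_bpm_sd between-subject distribution of
#'   resting heart rate (BPM).
#' @param delta_mean group-mean anticipatory deceleration in BPM (negative =
#'   slowing); default -1.77.
#' @param delta_subject_sd between-subject SD of the deceleration (BPM).
#' @param delta_trial_sd within-subject, between-trial SD (BPM).
#' @param beat_noise_sd SD of beat-level BPM noise added to the instantaneous
#'   rate (BPM); 0 gives deterministic beat times.
#' @param ramp_seconds seconds after anticipation onset at which the ramp
#'   reaches its plateau.
#'
#' @return a named list of class `pat_cardiac_params`.
#' @export
cardiac_params <- function(baseline_bpm_mean = 70,
                           baseline_bpm_sd = 7,
                           delta_mean = -1.77,
                           delta_subject_sd = 1.0,
                           delta_trial_sd = 2.0,
                           beat_noise_sd = 0,
                           ramp_seconds = 5) {
  if (baseline_bpm_mean <= 0) stop("baseline BPM must be positive", call. = FALSE)
  if (delta_subject_sd < 0 || delta_trial_sd < 0 || beat_noise_sd < 0)
    stop("SDs must be nonnegative", call. = FALSE)
  structure(list(baseline_bpm_mean = baseline_bpm_mean,
                 baseline_bpm_sd = baseline_bpm_sd,
                 delta_mean = delta_mean,
                 delta_subject_sd = delta_subject_sd,
                 delta_trial_sd = delta_trial_sd,
                 beat_noise_sd = beat_noise_sd,
                 ramp_seconds = ramp_seconds),
            class = "pat_cardiac_params")
}

#' Response-time generator parameters
#'
#' Shifted log-normal response times for trials with an active (button-press)
#' response: `RT = shift + exp(Normal(mu, sigma))` with `mu` linear in the
#' standardized money and shock levels, a sum-coded choice term
#' (approach = +1, avoid = -1), the bradycardia index, and their
#' interactions. Default slope values follow the reported group-level
#' effects: faster responses for avoid choices (choice +0.04 on the approach
#' side), a positive money-by-choice and negative shocks-by-choice
#' modulation, and slower responses on trials with weaker bradycardia
#' (dhr +0.03).
#'
#' @param intercept location intercept on the log-seconds scale.
#' @param b_choice,b_money_choice,b_shocks_choice,b_dhr location slopes.
#' @param shift onset shift in seconds (>= 0).
#' @param sigma log-scale SD (> 0).
#' @return a named list of class `pat_rt_params`.
#' @export
rt_params <- function(intercept = log(0.25),
                      b_choice = 0.04,
                      b_money_choice = 0.04,
                      b_shocks_choice = -0.04,
                      b_dhr = 0.03,
                      shift = 0.2,
                      sigma = 0.25) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (shift < 0) stop("shift must be >= 0", call. = FALSE)
  structure(list(intercept = intercept, b_choice = b_choice,
                 b_money_choice = b_money_choice,
                 b_shocks_choice = b_shocks_choice,
                 b_dhr = b_dhr, shift = shift, sigma = sigma),
            class = "pat_rt_params")
}

#' Choice-agent parameters for the simulator
#'
#' Bundles a decision-value parameter set (see [param_set()] /
#' [pat_group_params()]), the cardiac generator, the RT generator, and the
#' scale of per-subject random deviations of the choice coefficients
#' (SD = `random_effect_scale * |group coefficient|`; 0 disables random
#' effects, as used for parameter recovery).
#'
#' @param choice_params a `pat_params` object (defaults to the group-level
#'   base-model estimates).
#' @param cardiac a `pat_cardiac_params` object.
#' @param rt a `pat_rt_params` object.
#' @param random_effect_scale nonnegative scalar.
#' @return a named list of class `pat_agent`.
#' @export
agent_params <- function(choice_params = pat_group_params("base"),
                         cardiac = cardiac_params(),
                         rt = rt_params(),
                         random_effect_scale = 0.5) {
  stopifnot(inherits(choice_params, "pat_params"))
  if (random_effect_scale < 0)
    stop("random_effect_scale must be >= 0", call. = FALSE)
  structure(list(choice_params = choice_params,
                 cardiac = cardiac, rt = rt,
                 random_effect_scale = random_effect_scale),
            class = "pat_agent")
}
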