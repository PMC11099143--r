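# Shared fixtures and independent oracles.

# Standardized feature table built directly from z values.
make_ztrials <- function(z_money = 0, z_shocks = 0, z_dms = 0, z_dhr = 0,
                         ac_code = 1, subject = 1L) {
  tibble::tibble(z_money = z_money, z_shocks = z_shocks, z_dms = z_dms,
                 z_dhr = z_dhr, ac_code = ac_code, subject = subject)
}

# Independent per-trial summation oracle for the Bernoulli log-likelihood.
loglik_oracle <- function(data, params) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    row <- data[i, , drop = FALSE]
    dv <- decision_value(row, params)
    p <- 1 / (1 + exp(-dv))
    y <- as.numeric(row$choice == "approach")
    total <- total + y * log(p) + (1 - y) * log(1 - p)
  }
  total
}

# Brute-force minimal-window scan for the highest density interval:
# examine every pair of order statistics whose enclosed fraction reaches
# the mass.
hdi_oracle <- function(samples, mass) {
  s <- sort(samples)
  n <- length(s)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if ((j - i + 1) / n >= mass && (s[j] - s[i]) < diff(best)) {
        best <- c(s[i], s[j])
      }
    }
  }
  best
}

# Beat times with piecewise-constant BPM: `segments` is a data.frame with
# bpm and until (end time); beats start at `from`.
beats_from_bpm <- function(segments, from) {
  t <- from
  beats <- t
  end <- max(segments$until)
  repeat {
    seg <- which(segments$until > t)[1]
    if (is.na(seg)) break
    t <- t + 60 / segments$bpm[seg]
    if (t > end) break
    beats <- c(beats, t)
  }
  beats
}

# Generating conditions for direct bradycardia-index draws (no traces).
make_dhr_data <- function(n_subjects, n_trials, delta = -1.77,
                          subject_sd = 1, trial_sd = 2, seed = 1) {
  trials <- simulate_standardized_trials(n_subjects, n_trials, seed = seed)
  set.seed(seed + 1L)
  offsets <- rnorm(n_subjects, 0, subject_sd)
  trials$dhr <- delta + offsets[trials$subject] +
    rnorm(nrow(trials), 0, trial_sd)
  trials
}
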