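#' Trial-wise decision values from group-level parameters
#'
#' Computes the decision-value vector for a set of trials using a
#' group-level (not subject-level) parameter row, as used to build
#' model-based parametric regressors.
#'
#' @param trials standardized trial table.
#' @param params a `pat_params` row (e.g. [pat_group_params()]).
#' @param kind optional; must match `param_kind(params)` when given.
#' @return numeric decision-value vector.
#' @export
trial_dvs_from_params <- function(trials, params, kind = NULL) {
  if (!is.null(kind) && !identical(kind, param_kind(params)))
    stop("requested kind does not match the parameter set", call. = FALSE)
  decision_value(trials, params)
}

#' Difference-score regressor between base and freezing-model DVs
#'
#' `DVdiff = DV_base - DV_freezing`; positive values mean the freezing
#' model predicts relatively more avoidance on that trial, negative values
#' relatively more approach.
#'
#' @param dv_base,dv_mod equal-length decision-value vectors in the same
#'   trial order.
#' @return numeric vector of difference scores.
#' @export
dv_diff <- function(dv_base, dv_mod) {
  if (length(dv_base) != length(dv_mod))
    stop("decision-value vectors differ in length", call. = FALSE)
  dv_base - dv_mod
}

#' Split a difference-score regressor by sign
#'
#' Partitions the nonzero entries of a DVdiff vector into a
#' positive-subset (freezing model predicts more avoidance) and a
#' negative-subset (more approach) modulator; exactly-zero trials are
#' assigned to neither.
#'
#' @param dvdiff difference scores.
#' @param trials optional table subset alongside the scores.
#' @return list with elements `positive` and `negative`, each a list of
#'   `index`, `values`, and (when `trials` given) `trials`.
#' @export
split_by_sign <- function(dvdiff, trials = NULL) {
  pick <- function(sel) {
    out <- list(index = which(sel), values = dvdiff[sel])
    if (!is.null(trials)) out$trials <- trials[sel, , drop = FALSE]
    out
  }
  list(positive = pick(dvdiff > 0), negative = pick(dvdiff < 0))
}

#' Per-subject correlation diagnostics between two trial-wise regressors
#'
#' Computes the rank (Spearman, default) correlation between two regressor
#' vectors within each subject, then summarizes the mean and SD across
#' subjects. Subjects with a constant vector (undefined correlation) are
#' excluded with a warning.
#'
#' @param reg_a,reg_b numeric vectors over trials.
#' @param subjects subject id per trial.
#' @param method correlation method passed to [stats::cor()].
#' @return list with `mean`, `sd`, `per_subject` (named vector),
#'   `n_excluded`.
#' @export
regressor_correlations <- function(reg_a, reg_b, subjects,
                                   method = "spearman") {
  stopifnot(length(reg_a) == length(reg_b),
            length(subjects) == length(reg_a))
  ids <- unique(subjects)
  r <- vapply(ids, function(s) {
    a <- reg_a[subjects == s]; b <- reg_b[subjects == s]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = method)
  }, 0)
  names(r) <- ids
  if (anyNA(r))
    warning(sum(is.na(r)), " subject(s) with constant regressor excluded")
  r_ok <- r[!is.na(r)]
  list(mean = mean(r_ok), sd = stats::sd(r_ok), per_subject = r,
       n_excluded = sum(is.na(r)))
}

#' Canonical double-gamma hemodynamic response function
#'
#' Standard two-gamma HRF: a response gamma (delay 6 s, dispersion 1 s)
#' minus an undershoot gamma (delay 16 s, dispersion 1 s) scaled by 1/6,
#' normalized to unit peak. The implemented peak (0.1 s grid) is at 5.0 s.
#'
#' @param t time in seconds (vector); values < 0 return 0.
#' @param peak_delay,peak_disp,under_delay,under_disp,ratio shape
#'   constants of the two gamma densities.
#' @return HRF amplitude at `t`.
#' @export
canonical_hrf <- function(t, peak_delay = 6, peak_disp = 1,
                          under_delay = 16, under_disp = 1, ratio = 1 / 6) {
  raw <- function(x) {
    v <- stats::dgamma(x, shape = peak_delay / peak_disp,
                       scale = peak_disp) -
      ratio * stats::dgamma(x, shape = under_delay / under_disp,
                            scale = under_disp)
    v[x < 0] <- 0
    v
  }
  peak <- max(raw(seq(0, 32, by = 0.01)))
  raw(t) / peak
}

#' Build an HRF-convolved design matrix
#'
#' Constructs, at microtime resolution, an unmodulated boxcar regressor
#' over the event durations plus one column per parametric modulator. Each
#' modulator is demeaned across its events before convolution (the
#' orthogonalization with respect to the unmodulated regressor); modulators
#' are NOT serially orthogonalized against each other, so shared variance
#' is left to the error term. Columns are convolved with the canonical HRF,
#' sampled on the TR grid, and augmented with an intercept and a
#' discrete-cosine drift set implementing the high-pass cutoff.
#'
#' @param events data.frame with `onset` and `duration` (seconds).
#' @param modulators named list of numeric vectors (one value per event),
#'   or NULL for an unmodulated design. All-empty or constant-zero
#'   modulators are dropped with a warning.
#' @param tr repetition time in seconds.
#' @param microtime microtime bin in seconds.
#' @param highpass high-pass cutoff in Hz (drift set); NULL disables.
#' @param run_duration total run length in seconds (default: last event
#'   offset + 30 s).
#' @return a `pat_design`: list with `matrix` (TR grid x columns), `time`,
#'   `roles` (column metadata), `tr`.
#' @export
build_design_matrix <- function(events, modulators = NULL, tr = 1.5,
                                microtime = 0.1, highpass = 1 / 128,
                                run_duration = NULL) {
  if (anyDuplicated(events$onset))
    stop("overlapping duplicate events", call. = FALSE)
  if (is.null(run_duration))
    run_duration <- max(events$onset + events$duration) + 30
  grid <- seq(0, run_duration, by = microtime)
  hrf <- canonical_hrf(seq(0, 32, by = microtime))
  boxcar <- function(height) {
    x <- numeric(length(grid))
    for (i in seq_len(nrow(events))) {
      sel <- grid >= events$onset[i] &
        grid < events$onset[i] + events$duration[i]
      x[sel] <- x[sel] + height[i]
    }
    x
  }
  conv_ds <- function(x) {
    y <- stats::convolve(x, rev(hrf), type = "open")[seq_along(grid)] *
      microtime
    tr_time <- seq(0, run_duration, by = tr)
    stats::approx(grid, y, xout = tr_time, rule = 2)$y
  }
  cols <- list(anticipation = conv_ds(boxcar(rep(1, nrow(events)))))
  roles <- c("unmodulated")
  pre_conv_sums <- c(anticipation = NA_real_)
  if (!is.null(modulators)) {
    for (nm in names(modulators)) {
      v <- modulators[[nm]]
      if (!length(v) || all(v == v[1] & v[1] == 0)) {
        warning("modulator '", nm, "' is empty; dropped")
        next
      }
      vd <- v - mean(v)
      if (all(abs(vd) < 1e-14)) {
        warning("modulator '", nm, "' is constant; dropped after demeaning")
        next
      }
      bx <- boxcar(vd)
      pre_conv_sums[nm] <- sum(vd)
      cols[[nm]] <- conv_ds(bx)
      roles <- c(roles, "modulator")
    }
  }
  tr_time <- seq(0, run_duration, by = tr)
  X <- do.call(cbind, cols)
  X <- cbind(intercept = 1, X)
  roles <- c("constant", roles)
  if (!is.null(highpass)) {
    K <- floor(2 * run_duration * highpass)
    if (K >= 1) {
      drift <- sapply(seq_len(K), function(k)
        cos(pi * k * (tr_time + tr / 2) / run_duration))
      colnames(drift) <- paste0("drift", seq_len(K))
      X <- cbind(X, drift)
      roles <- c(roles, rep("drift", K))
    }
  }
  structure(list(matrix = X, time = tr_time, roles = roles, tr = tr,
                 pre_conv_sums = pre_conv_sums),
            class = "pat_design")
}

#' Simulate BOLD from a design and recover the betas by OLS
#'
#' Generates `y = X beta + Normal(0, noise_sd)` on the design's TR grid and
#' refits by ordinary least squares (no autoregressive prewhitening),
#' reporting estimates and standard errors. A rank-deficient design is an
#' error naming the collinear columns.
#'
#' @param design a `pat_design` or a plain numeric matrix.
#' @param true_betas numeric vector, one per design column.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return list with `estimates`, `se`, `true_betas`, `sigma`.
#' @export
simulate_bold_and_recover <- function(design, true_betas, noise_sd, seed) {
  X <- if (inherits(design, "pat_design")) design$matrix else design
  if (length(true_betas) != ncol(X))
    stop("need one beta per design column", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  y <- drop(X %*% true_betas) + stats::rnorm(nrow(X), 0, noise_sd)
  est <- qr.coef(qx, y)
  res <- y - drop(X %*% est)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / max(df, 1)
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(diag(XtXinv) * sigma2)
  list(estimates = est, se = stats::setNames(se, colnames(X)),
       true_betas = true_betas, sigma = sqrt(sigma2))
}
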