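#' Trial-wise decision values
#'
#' Linear predictor of the probability of approaching: the base model
#' combines an intercept with standardized money, shocks, action context
#' and bradycardia plus the money:shocks, money:ac and shocks:ac
#' interactions; the freezing variants add exactly one bradycardia
#' interaction (shocks for aversive value, the money-shock difference for
#' value comparison, action context for action invigoration).
#'
#' @param data table with `z_money, z_shocks, z_dms, z_dhr, ac_code`.
#' @param params a `pat_params` object whose kind selects the added term.
#' @return numeric vector of decision values (unbounded).
#' @export
decision_value <- function(data, params) {
  stopifnot(inherits(params, "pat_params"))
  X <- choice_design(data, param_kind(params))
  drop(X %*% as.numeric(params))
}

#' Logistic choice rule
#'
#' Maps a decision value to the probability of approaching:
#' \eqn{p = 1 / (1 + e^{-DV})}.
#'
#' @param dv numeric vector of decision values.
#' @return probabilities in [0, 1].
#' @export
p_approach <- function(dv) 1 / (1 + exp(-dv))

#' Bernoulli log-likelihood of a decision-value model
#'
#' @param data standardized analysis-set table with a `choice` column
#'   (`"approach"`/`"avoid"` or 1/0).
#' @param params a `pat_params` object.
#' @param clamp probability floor/ceiling guarding the logs.
#' @return scalar log-likelihood.
#' @export
choice_loglik <- function(data, params, clamp = 1e-12) {
  if (nrow(data) == 0L) stop("empty data", call. = FALSE)
  y <- choice_to_binary(data$choice)
  p <- p_approach(decision_value(data, params))
  p <- pmin(pmax(p, clamp), 1 - clamp)
  sum(y * log(p) + (1 - y) * log1p(-p))
}

choice_to_binary <- function(choice) {
  if (is.character(choice) || is.factor(choice))
    as.numeric(as.character(choice) == "approach")
  else as.numeric(choice)
}

# Iteratively reweighted least squares for the Bernoulli/logit likelihood.
fit_logistic_irls <- function(X, y, max_iter = 100L, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    new_beta <- tryCatch(
      solve(crossprod(X, X * w), crossprod(X, w * z)),
      error = function(e) stop("rank-deficient design in logistic fit",
                               call. = FALSE))
    delta <- max(abs(new_beta - beta))
    beta <- drop(new_beta)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  separated <- any(abs(eta) > 25) || max(abs(beta)) > 25
  if (separated) beta <- pmin(pmax(beta, -25), 25)
  list(coefficients = stats::setNames(beta, colnames(X)),
       converged = converged, separated = separated)
}

#' Fit a decision-value choice model
#'
#' Pooled maximum likelihood (the default) maximizes the Bernoulli
#' likelihood over all trials of all subjects via iteratively reweighted
#' least squares, with uncertainty from a nonparametric bootstrap over
#' subjects. The hierarchical method fits the same fixed effects with
#' per-subject random intercepts and uncorrelated random slopes
#' (via `lme4::glmer`), drawing approximate posterior samples from the
#' asymptotic normal of the fixed effects. Quasi/complete separation is
#' flagged (with clamped estimates), never silent.
#'
#' @param data standardized analysis-set table with `subject` and `choice`.
#' @param kind model kind: `"base"`, `"av"`, `"vc"`, `"ai"`, `"full"`.
#' @param method `"pooled_ml"` or `"hierarchical"`.
#' @param n_boot bootstrap resamples for `pooled_ml` (0 skips interval
#'   estimation); number of normal draws for `hierarchical`.
#' @param seed optional seed for the resampling.
#' @return a `pat_fit` object: estimates, samples, 90/95% HDIs,
#'   significance labels, log-likelihood, AIC, convergence flags.
#' @export
fit_choice_model <- function(data, kind = "base",
                             method = c("pooled_ml", "hierarchical"),
                             n_boot = 500L, seed = NULL) {
  method <- match.arg(method)
  if (nrow(data) == 0L) stop("empty data", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- choice_to_binary(data$choice)
  X <- choice_design(data, kind)
  if (method == "pooled_ml") {
    fit <- fit_logistic_irls(X, y)
    if (fit$separated)
      warning("possible complete separation; estimates clamped")
    est <- fit$coefficients
    samples <- NULL
    if (n_boot > 0) {
      subjects <- unique(data$subject)
      samples <- matrix(NA_real_, n_boot, ncol(X),
                        dimnames = list(NULL, colnames(X)))
      for (b in seq_len(n_boot)) {
        take <- sample(subjects, length(subjects), replace = TRUE)
        idx <- unlist(lapply(take, function(s) which(data$subject == s)),
                      use.names = FALSE)
        bf <- fit_logistic_irls(X[idx, , drop = FALSE], y[idx])
        samples[b, ] <- bf$coefficients
      }
    }
    params <- param_set(est, kind)
    ll <- choice_loglik(data, params)
    res <- new_pat_fit(estimates = est, kind = kind, method = method,
                       samples = samples, loglik = ll,
                       n_obs = nrow(data),
                       converged = fit$converged,
                       separated = fit$separated,
                       fingerprint = data_fingerprint(data))
  } else {
    df <- as.data.frame(data)
    df$.y <- y
    rhs <- "z_money * z_shocks + ac_code + z_money:ac_code + z_shocks:ac_code + z_dhr"
    extra <- switch(kind, base = NULL, av = "z_shocks:z_dhr",
                    vc = "z_dms:z_dhr", ai = "ac_code:z_dhr",
                    full = paste("z_money:z_dhr", "z_shocks:z_dhr",
                                 "ac_code:z_dhr", "z_money:z_shocks:z_dhr",
                                 "z_money:ac_code:z_dhr",
                                 "z_shocks:ac_code:z_dhr", sep = " + "))
    if (!is.null(extra)) rhs <- paste(rhs, extra, sep = " + ")
    form <- stats::as.formula(paste(
      ".y ~", rhs,
      "+ (1 + z_money + z_shocks + ac_code + z_dhr || subject)"))
    gfit <- lme4::glmer(form, data = df, family = stats::binomial())
    fe <- lme4::fixef(gfit)
    est <- stats::setNames(as.numeric(fe)[match_terms(names(fe), kind)],
                           model_terms(kind))
    V <- as.matrix(stats::vcov(gfit))[match_terms(names(fe), kind),
                                      match_terms(names(fe), kind)]
    ndraw <- max(n_boot, 1000L)
    L <- chol(V)
    samples <- matrix(stats::rnorm(ndraw * length(est)), ndraw) %*% L
    samples <- sweep(samples, 2, est, "+")
    colnames(samples) <- model_terms(kind)
    conv <- length(gfit@optinfo$conv$lme4$messages) == 0
    res <- new_pat_fit(estimates = est, kind = kind, method = method,
                       samples = samples,
                       loglik = as.numeric(stats::logLik(gfit)),
                       n_obs = nrow(data), converged = conv,
                       separated = FALSE,
                       fingerprint = data_fingerprint(data))
  }
  finalize_fit(res)
}

# glmer reorders/renames interaction terms; map back to the package's
# canonical term order.
match_terms <- function(fitted_names, kind) {
  canon <- model_terms(kind)
  lookup <- gsub("ac", "ac_code", canon, fixed = TRUE)
  lookup[1] <- "(Intercept)"
  norm <- function(x) vapply(strsplit(x, ":"), function(p)
    paste(sort(p), collapse = ":"), "")
  match(norm(lookup), norm(fitted_names))
}

data_fingerprint <- function(data) {
  cols <- intersect(c("z_money", "z_shocks", "z_dms", "z_dhr", "ac_code"),
                    names(data))
  y <- if ("choice" %in% names(data)) sum(choice_to_binary(data$choice)) else NA
  paste(nrow(data), y,
        paste(sprintf("%.6f", vapply(data[cols], sum, 0)), collapse = ","))
}

new_pat_fit <- function(estimates, kind, method, samples, loglik, n_obs,
                        converged, separated, fingerprint,
                        extra = list()) {
  structure(c(list(estimates = estimates, kind = kind, method = method,
                   samples = samples, loglik = loglik,
                   n_params = length(estimates), n_obs = n_obs,
                   aic = 2 * length(estimates) - 2 * loglik,
                   converged = converged, separated = separated,
                   fingerprint = fingerprint,
                   hdi90 = NULL, hdi95 = NULL, labels = NULL),
              extra),
            class = "pat_fit")
}

finalize_fit <- function(fit) {
  if (!is.null(fit$samples) && nrow(fit$samples) >= 100) {
    fit$hdi90 <- apply(fit$samples, 2, hdi, mass = 0.90)
    fit$hdi95 <- apply(fit$samples, 2, hdi, mass = 0.95)
    fit$labels <- label_significance(fit)
  }
  fit
}

#' @export
print.pat_fit <- function(x, ...) {
  cat(sprintf("Decision-model fit [%s, %s]: %d obs, loglik %.2f, AIC %.2f\n",
              x$kind, x$method, x$n_obs, x$loglik, x$aic))
  tab <- data.frame(estimate = round(x$estimates, 4))
  if (!is.null(x$hdi95)) {
    tab$hdi95_lo <- round(x$hdi95[1, ], 4)
    tab$hdi95_hi <- round(x$hdi95[2, ], 4)
    tab$label <- x$labels
  }
  print(tab)
  if (x$separated) cat("warning: separation detected\n")
  invisible(x)
}

#' Fit the shifted log-normal response-time model
#'
#' Maximum likelihood for `RT = shift + exp(Normal(mu, sigma))` with `mu`
#' linear in the full money x shocks x choice x bradycardia interaction
#' set. Only trials with an active (button-press) response are used. With a
#' known shift the location coefficients are the least-squares solution on
#' `log(RT - shift)`; an unknown shift is profiled over a grid on
#' `[0, min RT)`, rejecting any candidate that leaves a nonpositive
#' shifted RT.
#'
#' @param data table with `rt`, `choice`, and standardized predictors;
#'   rows with NA `rt` are dropped (passive responses).
#' @param shift known shift in seconds, or NULL to profile.
#' @param n_grid grid size for profiling the shift.
#' @param n_boot bootstrap resamples over subjects (0 to skip).
#' @param seed optional seed.
#' @return a `pat_fit` with location coefficients plus `sigma` and `shift`.
#' @export
fit_rt_model <- function(data, shift = NULL, n_grid = 50L, n_boot = 0L,
                         seed = NULL) {
  data <- data[!is.na(data$rt), , drop = FALSE]
  if (nrow(data) == 0L) stop("no active-response trials", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data$choice_code <- ifelse(choice_to_binary(data$choice) == 1, 1, -1)
  X <- stats::model.matrix(~ z_money * z_shocks * choice_code * z_dhr,
                           data = data)
  rt <- data$rt
  fit_at_shift <- function(sh) {
    if (any(rt <= sh)) return(NULL)
    ylog <- log(rt - sh)
    ls <- stats::lm.fit(X, ylog)
    sigma <- sqrt(mean(ls$residuals^2))
    ll <- sum(stats::dnorm(ylog, ylog - ls$residuals, sigma, log = TRUE)) -
      sum(ylog)
    list(coef = ls$coefficients, sigma = sigma, loglik = ll, shift = sh)
  }
  if (is.null(shift)) {
    grid <- seq(0, min(rt) * (1 - 1e-6), length.out = n_grid)
    fits <- lapply(grid, fit_at_shift)
    fits <- fits[!vapply(fits, is.null, TRUE)]
    if (!length(fits)) stop("no admissible shift", call. = FALSE)
    best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  } else {
    best <- fit_at_shift(shift)
    if (is.null(best))
      stop("shift leaves nonpositive RTs; rejected", call. = FALSE)
  }
  samples <- NULL
  if (n_boot > 0) {
    subjects <- unique(data$subject)
    samples <- matrix(NA_real_, n_boot, ncol(X),
                      dimnames = list(NULL, colnames(X)))
    for (b in seq_len(n_boot)) {
      take <- sample(subjects, length(subjects), replace = TRUE)
      idx <- unlist(lapply(take, function(s) which(data$subject == s)),
                    use.names = FALSE)
      ylog <- log(rt[idx] - best$shift)
      samples[b, ] <- stats::lm.fit(X[idx, , drop = FALSE],
                                    ylog)$coefficients
    }
  }
  res <- new_pat_fit(estimates = best$coef, kind = "rt", method = "ml",
                     samples = samples, loglik = best$loglik,
                     n_obs = nrow(data), converged = TRUE,
                     separated = FALSE,
                     fingerprint = paste(nrow(data), sprintf("%.6f", sum(rt))),
                     extra = list(sigma = best$sigma, shift = best$shift))
  finalize_fit(res)
}

#' Fit the Gaussian heart-rate condition model
#'
#' Linear model of the trial-wise bradycardia index on the full
#' money x shocks x action-context interaction set. With sum-coded,
#' balanced predictors the intercept estimates the grand anticipatory
#' heart-rate change (negative = deceleration). Uncertainty via
#' nonparametric bootstrap over subjects.
#'
#' @param data standardized table with a `dhr` column in BPM.
#' @param n_boot bootstrap resamples (0 to skip).
#' @param seed optional seed.
#' @return a `pat_fit`.
#' @export
fit_hr_model <- function(data, n_boot = 500L, seed = NULL) {
  if (nrow(data) == 0L) stop("empty data", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- stats::model.matrix(~ z_money * z_shocks * ac_code, data = data)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design", call. = FALSE)
  ls <- stats::lm.fit(X, data$dhr)
  sigma <- sqrt(mean(ls$residuals^2))
  ll <- sum(stats::dnorm(data$dhr, data$dhr - ls$residuals, sigma,
                         log = TRUE))
  samples <- NULL
  if (n_boot > 0) {
    subjects <- unique(data$subject)
    samples <- matrix(NA_real_, n_boot, ncol(X),
                      dimnames = list(NULL, colnames(X)))
    for (b in seq_len(n_boot)) {
      take <- sample(subjects, length(subjects), replace = TRUE)
      idx <- unlist(lapply(take, function(s) which(data$subject == s)),
                    use.names = FALSE)
      samples[b, ] <- stats::lm.fit(X[idx, , drop = FALSE],
                                    data$dhr[idx])$coefficients
    }
  }
  res <- new_pat_fit(estimates = ls$coefficients, kind = "hr", method = "ml",
                     samples = samples, loglik = ll, n_obs = nrow(data),
                     converged = TRUE, separated = FALSE,
                     fingerprint = data_fingerprint(data),
                     extra = list(sigma = sigma))
  finalize_fit(res)
}

#' Highest density interval of a sample
#'
#' The narrowest contiguous interval containing the requested probability
#' mass of the empirical distribution.
#'
#' @param samples numeric vector (at least 100 values).
#' @param mass interval mass, e.g. 0.90 or 0.95.
#' @return numeric length-2 vector (lower, upper).
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 100L) stop("need at least 100 samples for an HDI", call. = FALSE)
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)
  c(s[i], s[i + m - 1L])
}

#' Significance labels from 90% and 95% HDIs
#'
#' An effect is "significant" when its 95% HDI excludes 0, "marginal" when
#' only the 90% HDI excludes 0, and "not significant" otherwise.
#'
#' @param fit a `pat_fit` with `hdi90` and `hdi95` computed, or a list with
#'   those two elements (2 x k matrices).
#' @return character vector of labels per coefficient.
#' @export
label_significance <- function(fit) {
  h90 <- fit$hdi90; h95 <- fit$hdi95
  if (is.null(h90) || is.null(h95))
    stop("both HDIs must be computed first", call. = FALSE)
  excl <- function(h) h[1, ] > 0 | h[2, ] < 0
  ifelse(excl(h95), "significant",
         ifelse(excl(h90), "marginal", "not significant"))
}

#' Compare fitted decision-value models
#'
#' Ranks fits of the base and freezing models on identical data by
#' information criterion (AIC for pooled maximum likelihood), with ties
#' broken by parameter count (fewer parameters rank first).
#'
#' @param fits named list of `pat_fit` objects fitted to the same data.
#' @return tibble with model, loglik, n_params, aic, delta_aic, rank.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "pat_fit")))
  fps <- vapply(fits, `[[`, "", "fingerprint")
  if (length(unique(fps)) != 1L)
    stop("fits were not computed on identical data", call. = FALSE)
  tab <- tibble::tibble(
    model = if (!is.null(names(fits))) names(fits) else
      vapply(fits, `[[`, "", "kind"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_params = vapply(fits, `[[`, 0L, "n_params"),
    aic = vapply(fits, `[[`, 0, "aic"))
  ord <- order(tab$aic, tab$n_params)
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  tab[ord, ]
}

#' Parameter-recovery harness
#'
#' Simulates choice data from a generating parameter set (balanced
#' factorial trials, exogenous standardized bradycardia, no random
#' effects), refits the matching model by pooled maximum likelihood, and
#' aggregates per-coefficient bias, RMSE and 90%-interval coverage across
#' replicates. Non-convergent replicates are recorded, not fatal.
#'
#' @param params generating `pat_params`.
#' @param n_subjects,n_trials size of each simulated dataset.
#' @param n_replicates number of simulate-fit replicates.
#' @param seed integer root seed.
#' @param n_boot bootstrap resamples per replicate (needed for coverage;
#'   0 reports bias/RMSE only).
#' @return list with `summary` (tibble: coefficient, generating, mean
#'   estimate, bias, rmse, coverage90) and `estimates` (replicate matrix).
#' @export
recover_parameters <- function(params, n_subjects, n_trials,
                               n_replicates = 20L, seed = 1L,
                               n_boot = 100L) {
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  kind <- param_kind(params)
  truth <- as.numeric(params)
  est <- matrix(NA_real_, n_replicates, length(truth),
                dimnames = list(NULL, names(params)))
  covered <- matrix(NA, n_replicates, length(truth))
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    s <- seed + 131L * r
    trials <- simulate_standardized_trials(n_subjects, n_trials, seed = s)
    agent <- agent_params(choice_params = params,
                          random_effect_scale = 0)
    trials$choice <- simulate_choices(trials, trials$dhr, agent,
                                      seed = s + 7L)
    fit <- fit_choice_model(trials, kind, n_boot = n_boot, seed = s + 11L)
    if (!fit$converged) { n_failed <- n_failed + 1L; next }
    est[r, ] <- fit$estimates
    if (!is.null(fit$hdi90))
      covered[r, ] <- fit$hdi90[1, ] <= truth & truth <= fit$hdi90[2, ]
  }
  ok <- stats::complete.cases(est)
  summary <- tibble::tibble(
    coefficient = names(params),
    generating = truth,
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - truth,
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            matrix(truth, sum(ok), length(truth),
                                   byrow = TRUE))^2)),
    coverage90 = if (n_boot > 0) colMeans(covered[ok, , drop = FALSE])
      else NA_real_)
  list(summary = summary, estimates = est, n_failed = n_failed)
}
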