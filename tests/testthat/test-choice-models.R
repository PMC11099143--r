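table1_dv_example <- function() {
  # money 5 (z = +1.414), shock 1 (z = -1.414), passive, neutral dhr
  make_ztrials(z_money = sqrt(2), z_shocks = -sqrt(2), z_dms = sqrt(2),
               ac_code = 1)
}

test_that("decision values evaluate the linear model term by term", {
  at_zero <- make_ztrials(ac_code = 1)
  at_zero$ac_code <- 0  # hypothetical mean-context evaluation
  expect_error(choice_design(at_zero, "base"), "ac_code")
  # with all standardized features at 0 and passive/active cancelling,
  # the intercept carries through: average the two contexts
  dv_pass <- decision_value(make_ztrials(ac_code = 1), pat_group_params("base"))
  dv_act <- decision_value(make_ztrials(ac_code = -1), pat_group_params("base"))
  expect_equal((dv_pass + dv_act) / 2, 0.73)
  # worked example: high reward, low threat, passive, neutral bradycardia
  dv <- decision_value(table1_dv_example(), pat_group_params("base"))
  expect_equal(dv, 3.1903, tolerance = 1e-4)
  expect_equal(p_approach(dv), 0.9605, tolerance = 1e-4)
})

test_that("freezing models with a zero added coefficient reduce to the base model", {
  base <- pat_group_params("base")
  set.seed(1)
  trials <- make_ztrials(z_money = rnorm(50), z_shocks = rnorm(50),
                         z_dms = rnorm(50), z_dhr = rnorm(50),
                         ac_code = sample(c(-1, 1), 50, TRUE))
  for (kind in c("av", "vc", "ai")) {
    vals <- c(as.numeric(base), 0)
    mod <- param_set(setNames(vals, model_terms(kind)), kind)
    expect_equal(decision_value(trials, mod), decision_value(trials, base))
  }
})

test_that("the logistic choice rule has the right limits and symmetry", {
  expect_equal(p_approach(0), 0.5)
  expect_equal(p_approach(Inf), 1)
  expect_equal(p_approach(-Inf), 0)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(p_approach(x), 1 - p_approach(-x))
  expect_true(all(diff(p_approach(x)) > 0))
})

test_that("the choice log-likelihood matches a per-trial summation oracle", {
  zero <- param_set(setNames(rep(0, 8), model_terms("base")), "base")
  one <- make_ztrials(); one$choice <- "approach"
  expect_equal(choice_loglik(one, zero), log(0.5))
  set.seed(2)
  trials <- make_ztrials(z_money = rnorm(100), z_shocks = rnorm(100),
                         z_dms = rnorm(100), z_dhr = rnorm(100),
                         ac_code = sample(c(-1, 1), 100, TRUE))
  trials$choice <- sample(c("approach", "avoid"), 100, TRUE)
  params <- pat_group_params("av")
  trials$z_dms <- (trials$z_money - trials$z_shocks) / 2
  expect_equal(choice_loglik(trials, params),
               loglik_oracle(trials, params), tolerance = 1e-10)
  expect_error(choice_loglik(trials[0, ], params), "empty")
})

test_that("pooled maximum likelihood agrees with an independent logistic fitter", {
  trials <- simulate_standardized_trials(10, 150, seed = 3)
  agent <- agent_params(random_effect_scale = 0)
  trials$choice <- simulate_choices(trials, trials$dhr, agent, seed = 4)
  fit <- fit_choice_model(trials, "base", n_boot = 0)
  X <- as.data.frame(model.matrix(
    ~ z_money * z_shocks + ac_code + z_money:ac_code + z_shocks:ac_code +
      z_dhr, data = trials))
  X$y <- as.numeric(trials$choice == "approach")
  ref <- glm(y ~ . - 1, data = X, family = binomial())
  expect_equal(sort(unname(fit$estimates)), sort(unname(coef(ref))),
               tolerance = 1e-6)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
})

test_that("complete separation is flagged rather than silently returned", {
  trials <- simulate_standardized_trials(2, 100, seed = 5)
  trials$choice <- "approach"
  expect_warning(fit <- fit_choice_model(trials, "base", n_boot = 0),
                 "separation")
  expect_true(fit$separated)
})

test_that("pooled estimates converge to the generating values as trials grow", {
  gen <- pat_group_params("base")
  agent <- agent_params(choice_params = gen, random_effect_scale = 0)
  err <- vapply(c(1000, 10000, 45000), function(n) {
    trials <- simulate_standardized_trials(max(1, n / 150), 150, seed = n)
    trials$choice <- simulate_choices(trials, trials$dhr, agent,
                                      seed = n + 1)
    fit <- fit_choice_model(trials, "base", n_boot = 0)
    sqrt(mean((fit$estimates - as.numeric(gen))^2))
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("hierarchical fitting reproduces pooled point estimates on pooled-data generators", {
  trials <- simulate_standardized_trials(15, 100, seed = 6)
  agent <- agent_params(random_effect_scale = 0)
  trials$choice <- simulate_choices(trials, trials$dhr, agent, seed = 7)
  pooled <- fit_choice_model(trials, "base", n_boot = 200, seed = 8)
  # random-effect variances sit at the boundary on pooled-generator data,
  # so the mixed-model optimizer may grumble; that is the expected regime
  hier <- suppressWarnings(suppressMessages(
    fit_choice_model(trials, "base", method = "hierarchical", n_boot = 500)))
  boot_sd <- apply(pooled$samples, 2, sd)
  expect_true(all(abs(hier$estimates - pooled$estimates) < 3 * boot_sd))
})

test_that("the HDI is the narrowest window and matches a brute-force scan", {
  set.seed(9)
  u <- runif(10000)
  expect_equal(diff(hdi(u, 0.95)), 0.95, tolerance = 0.01)
  z <- rnorm(10000)
  expect_equal(hdi(z, 0.95), c(-1.96, 1.96), tolerance = 0.05)
  const <- rep(1.3, 200)
  expect_equal(hdi(const, 0.9), c(1.3, 1.3))
  expect_error(hdi(rnorm(50), 0.9), "100 samples")
  for (mass in c(0.90, 0.95)) {
    s <- rexp(400)  # skewed: HDI differs from equal-tail interval
    expect_equal(hdi(s, mass), hdi_oracle(s, mass))
  }
})

test_that("significance labels follow the two-interval rule", {
  fake <- list(hdi95 = cbind(a = c(0.3, 1.4), b = c(-0.1, 0.5),
                             c = c(-0.2, 0.35)),
               hdi90 = cbind(a = c(0.35, 1.3), b = c(0.01, 0.4),
                             c = c(-0.15, 0.3)))
  expect_equal(unname(label_significance(fake)),
               c("significant", "marginal", "not significant"))
  expect_error(label_significance(list(hdi95 = fake$hdi95)), "HDIs")
})

test_that("model comparison ranks by information criterion with parsimony tie-breaks", {
  gen <- pat_group_params("av")
  gen["z_shocks:z_dhr"] <- 0.4  # exaggerate the interaction for a clear win
  agent <- agent_params(choice_params = gen, random_effect_scale = 0)
  trials <- simulate_standardized_trials(60, 150, seed = 10)
  trials$choice <- simulate_choices(trials, trials$dhr, agent, seed = 11)
  fits <- lapply(c(base = "base", av = "av", vc = "vc", ai = "ai"),
                 function(k) fit_choice_model(trials, k, n_boot = 0))
  cmp <- compare_models(fits)
  expect_equal(cmp$model[1], "av")
  # base-generated data: the base model stays within 2 criterion units
  agent0 <- agent_params(random_effect_scale = 0)
  trials0 <- simulate_standardized_trials(60, 150, seed = 12)
  trials0$choice <- simulate_choices(trials0, trials0$dhr, agent0, seed = 13)
  fits0 <- lapply(c(base = "base", av = "av", vc = "vc", ai = "ai"),
                  function(k) fit_choice_model(trials0, k, n_boot = 0))
  cmp0 <- compare_models(fits0)
  expect_lt(cmp0$delta_aic[cmp0$model == "base"], 2)
  # mismatched data are refused
  other <- fit_choice_model(trials0[1:500, ], "base", n_boot = 0)
  expect_error(compare_models(list(fits$base, other)), "identical data")
})

test_that("parameter recovery reports small bias and calibrated intervals", {
  res <- recover_parameters(pat_group_params("base"), n_subjects = 40,
                            n_trials = 150, n_replicates = 8, seed = 14,
                            n_boot = 120)
  expect_true(all(abs(res$summary$bias[res$summary$coefficient %in%
                                         c("z_money", "z_shocks")]) < 0.05))
  # a zero-coefficient generator: ~90% of 90% intervals should cover 0
  zero <- param_set(setNames(rep(0, 8), model_terms("base")), "base")
  res0 <- recover_parameters(zero, n_subjects = 40, n_trials = 150,
                             n_replicates = 10, seed = 15, n_boot = 120)
  expect_gt(mean(res0$summary$coverage90), 0.7)
  expect_error(recover_parameters(zero, 10, 0, 2, 1), "positive")
})
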