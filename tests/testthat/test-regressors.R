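test_that("trial-wise decision values from group parameters follow the rows", {
  at_zero <- make_ztrials(ac_code = 1)[rep(1, 5), ]
  at_zero$ac_code <- rep(c(1, -1), length.out = 5)
  dv <- trial_dvs_from_params(at_zero, pat_group_params("base"))
  expect_equal(dv, 0.73 + 0.07 * at_zero$ac_code)
  expect_error(trial_dvs_from_params(at_zero, pat_group_params("av"),
                                     kind = "vc"), "match")
  expect_equal(trial_dvs_from_params(at_zero, pat_group_params("base")),
               trial_dvs_from_params(at_zero, pat_group_params("base")))
})

test_that("difference scores subtract freezing-model from base DVs", {
  expect_equal(dv_diff(c(1, 2), c(1, 2)), c(0, 0))
  expect_error(dv_diff(1:3, 1:2), "length")
  # hand-traced example: shock z = +1.414, dhr = -1, other features 0;
  # base vs aversive-value rows differ in the shock slope (-1.10 vs
  # -1.11), the bradycardia slope (0.05 vs 0.04) and the added
  # shocks-by-bradycardia term (0.07):
  # 0.01*sqrt(2) + 0.01*(-1)*(-1)... term-by-term: 0.08*sqrt(2) - 0.01
  dvb <- drop(cbind(1, sqrt(2), -1) %*% c(0.73, -1.10, 0.05))
  dva <- drop(cbind(1, sqrt(2), -1, -sqrt(2)) %*% c(0.73, -1.11, 0.04, 0.07))
  expect_equal(dv_diff(dvb, dva), 0.08 * sqrt(2) - 0.01, tolerance = 1e-10)
})

test_that("sign-splitting partitions the nonzero difference scores", {
  s <- split_by_sign(c(1, -2, 0))
  expect_equal(s$positive$index, 1L)
  expect_equal(s$negative$index, 2L)
  expect_equal(length(s$positive$index) + length(s$negative$index), 2)
  set.seed(1)
  d <- rnorm(200) * rbinom(200, 1, 0.8)
  sp <- split_by_sign(d)
  expect_equal(length(sp$positive$index) + length(sp$negative$index),
               sum(d != 0))
  expect_length(intersect(sp$positive$index, sp$negative$index), 0)
})

test_that("regressor correlations summarize per-subject rank agreement", {
  set.seed(2)
  subj <- rep(1:5, each = 40)
  a <- rnorm(200)
  same <- regressor_correlations(a, a, subj)
  expect_equal(same$mean, 1)
  expect_equal(same$sd, 0)
  neg <- regressor_correlations(a, -a, subj)
  expect_equal(neg$mean, -1)
  b <- a; b[subj == 3] <- 0  # constant within one subject
  expect_warning(res <- regressor_correlations(a, b, subj), "constant")
  expect_equal(res$n_excluded, 1)
})

test_that("base and freezing DVs are nearly collinear while difference scores are not", {
  trials <- simulate_standardized_trials(20, 150, seed = 3)
  dvb <- trial_dvs_from_params(trials, pat_group_params("base"))
  for (kind in c("av", "vc", "ai")) {
    dvk <- trial_dvs_from_params(trials, pat_group_params(kind))
    full <- regressor_correlations(dvb, dvk, trials$subject)
    expect_gt(abs(full$mean), 0.99)
    diffd <- regressor_correlations(dvb, dv_diff(dvb, dvk), trials$subject)
    expect_lt(abs(diffd$mean), 0.15)
  }
})

test_that("the canonical HRF has the standard double-gamma shape", {
  expect_equal(canonical_hrf(0), 0)
  expect_equal(canonical_hrf(-1), 0)
  grid <- seq(0, 32, by = 0.1)
  h <- canonical_hrf(grid)
  expect_equal(max(h), 1, tolerance = 1e-6)       # unit peak
  peak_t <- grid[which.max(h)]
  expect_true(peak_t >= 4.8 && peak_t <= 5.2)     # implemented peak: 5.0 s
  expect_lt(abs(canonical_hrf(30)), 0.01)         # tail within 1% of zero
  expect_lt(min(h), 0)                            # undershoot present
})

test_that("modulators are demeaned before convolution and the design is linear", {
  events <- data.frame(onset = c(10, 30, 50, 70), duration = rep(6, 4))
  mods <- list(dv = c(2, 4, 6, 8))
  des <- build_design_matrix(events, mods, run_duration = 120)
  expect_lt(abs(des$pre_conv_sums["dv"]), 1e-10)
  # adding a constant to a modulator leaves its column unchanged
  des2 <- build_design_matrix(events, list(dv = c(2, 4, 6, 8) + 17),
                              run_duration = 120)
  expect_equal(des$matrix[, "dv"], des2$matrix[, "dv"], tolerance = 1e-10)
  # superposition: column of (a + b) equals column of a plus column of b
  a <- c(1, -1, 2, -2); b <- c(0.5, 3, -1, 1)
  da <- build_design_matrix(events, list(m = a), run_duration = 120)
  db <- build_design_matrix(events, list(m = b), run_duration = 120)
  dab <- build_design_matrix(events, list(m = a + b), run_duration = 120)
  expect_equal(dab$matrix[, "m"],
               da$matrix[, "m"] + db$matrix[, "m"], tolerance = 1e-8)
})

test_that("a single brief event reproduces the sampled HRF up to scale", {
  events <- data.frame(onset = 10, duration = 0.1)
  des <- build_design_matrix(events, NULL, tr = 1.5, microtime = 0.1,
                             highpass = NULL, run_duration = 60)
  col <- des$matrix[, "anticipation"]
  ref <- canonical_hrf(des$time - 10)
  expect_gt(cor(col[des$time > 10], ref[des$time > 10]), 0.999)
})

test_that("degenerate design inputs are rejected or dropped with warnings", {
  events <- data.frame(onset = c(10, 10), duration = c(6, 6))
  expect_error(build_design_matrix(events, NULL), "duplicate")
  ok <- data.frame(onset = c(10, 30), duration = c(6, 6))
  expect_warning(build_design_matrix(ok, list(flat = c(3, 3)),
                                     run_duration = 60), "constant")
  expect_warning(build_design_matrix(ok, list(none = numeric(0)),
                                     run_duration = 60), "empty")
})

test_that("sign-split columns span the unsplit difference column", {
  set.seed(4)
  onsets <- seq(10, 190, by = 20)
  events <- data.frame(onset = onsets, duration = rep(6, length(onsets)))
  v <- rnorm(length(onsets))
  sp <- split_by_sign(v)
  full <- build_design_matrix(events, list(m = v), highpass = NULL,
                              run_duration = 230)
  pos <- build_design_matrix(events[sp$positive$index, ],
                             list(m = sp$positive$values), highpass = NULL,
                             run_duration = 230)
  neg <- build_design_matrix(events[sp$negative$index, ],
                             list(m = sp$negative$values), highpass = NULL,
                             run_duration = 230)
  basis <- cbind(pos$matrix[, c("anticipation", "m")],
                 neg$matrix[, c("anticipation", "m")],
                 full$matrix[, "anticipation"], 1)
  resid <- lm.fit(basis, full$matrix[, "m"])$residuals
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("synthetic BOLD recovery is exact without noise and errors on collinearity", {
  events <- data.frame(onset = seq(10, 150, by = 20), duration = rep(6, 8))
  set.seed(5)
  mods <- list(dv_base = rnorm(8), dvdiff_av = rnorm(8))
  des <- build_design_matrix(events, mods, run_duration = 200)
  betas <- seq_len(ncol(des$matrix)) / 10
  rec <- simulate_bold_and_recover(des, betas, noise_sd = 0, seed = 6)
  expect_equal(unname(rec$estimates), betas, tolerance = 1e-8)
  dup <- cbind(des$matrix, dup_col = des$matrix[, "dv_base"])
  expect_error(simulate_bold_and_recover(dup, c(betas, 1), 0, 1),
               "collinear")
})

test_that("a true effect on the difference regressor is detected across seeds", {
  events <- data.frame(onset = seq(10, 290, by = 20), duration = rep(6, 15))
  set.seed(7)
  mods <- list(dv_base = rnorm(15), dvdiff_av = rnorm(15))
  des <- build_design_matrix(events, mods, run_duration = 340)
  betas <- numeric(ncol(des$matrix))
  betas[colnames(des$matrix) == "dvdiff_av"] <- 1
  signs <- vapply(1:100, function(s)
    sign(simulate_bold_and_recover(des, betas, noise_sd = 0.5,
                                   seed = s)$estimates["dvdiff_av"]), 0)
  expect_gte(mean(signs == 1), 0.95)
})
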