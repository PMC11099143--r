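#' Run configuration for an end-to-end pipeline run
#'
#' @param seed mandatory integer root seed; every stage draws from named
#'   substreams of it.
#' @param out_dir output directory (created if missing).
#' @param n_subjects simulated sample size.
#' @param config a [task_config()].
#' @param agent an [agent_params()].
#' @param fit_method `"pooled_ml"` or `"hierarchical"`.
#' @param n_boot bootstrap resamples for the fits.
#' @param n_replicates replicates for the recovery stage (0 skips it).
#' @return a `pat_run_config` list.
#' @export
run_config <- function(seed, out_dir = tempfile("patsim-run-"),
                       n_subjects = 8L, config = task_config(),
                       agent = agent_params(random_effect_scale = 0),
                       fit_method = "pooled_ml", n_boot = 200L,
                       n_replicates = 0L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_subjects = as.integer(n_subjects), config = config,
                 agent = agent, fit_method = fit_method,
                 n_boot = as.integer(n_boot),
                 n_replicates = as.integer(n_replicates)),
            class = "pat_run_config")
}

#' Run the full simulate-preprocess-fit-compare-design pipeline
#'
#' Stages: simulate a dataset, derive the bradycardia index from the beat
#' traces, apply exclusions and standardize predictors, fit the four
#' decision-value models plus the heart-rate and response-time models,
#' compare the choice models, build per-subject difference-score regressors
#' with correlation diagnostics, and assemble a toy design matrix for the
#' first subject's first run. All artifacts are written under
#' `config$out_dir` with a checksum manifest; identical config and seed
#' give identical bundles.
#'
#' @param config a [run_config()].
#' @return the artifact bundle (list), invisibly also written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pat_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("stage %-12s ok (%.2f s)", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  sim <- stage("simulate", simulate_dataset(config$config, config$agent,
                                            config$n_subjects,
                                            seed = config$seed))
  say("simulate: %d trials, %d subjects", nrow(sim$trials),
      config$n_subjects)

  pre <- stage("preprocess", {
    tab <- compute_dhr_table(sim$trials, sim$traces)
    ex <- apply_exclusions(tab)
    std <- standardize_predictors(ex$trials)
    list(analysis = std, report = ex$report)
  })
  say("preprocess: %d trials retained", nrow(pre$analysis))

  fits <- stage("fit", {
    kinds <- c(base = "base", av = "av", vc = "vc", ai = "ai")
    lapply(kinds, function(k)
      fit_choice_model(pre$analysis, k, method = config$fit_method,
                       n_boot = config$n_boot, seed = config$seed + 20L))
  })
  hr_fit <- stage("fit_hr", fit_hr_model(pre$analysis,
                                         n_boot = config$n_boot,
                                         seed = config$seed + 21L))
  rt_fit <- stage("fit_rt", fit_rt_model(pre$analysis,
                                         shift = config$agent$rt$shift,
                                         seed = config$seed + 22L))
  comparison <- stage("compare", compare_models(fits))

  regs <- stage("build_design", {
    dv_base <- trial_dvs_from_params(pre$analysis, pat_group_params("base"))
    diffs <- lapply(c(av = "av", vc = "vc", ai = "ai"), function(k)
      dv_diff(dv_base, trial_dvs_from_params(pre$analysis,
                                             pat_group_params(k))))
    cors <- lapply(diffs, function(d)
      regressor_correlations(dv_base, d, pre$analysis$subject))
    first <- pre$analysis[pre$analysis$subject ==
                            min(pre$analysis$subject) &
                            pre$analysis$run ==
                            min(pre$analysis$run), , drop = FALSE]
    events <- data.frame(onset = first$onset, duration = first$ami)
    fb <- trial_dvs_from_params(first, pat_group_params("base"))
    mods <- c(list(dv_base = fb),
              lapply(c(av = "av", vc = "vc", ai = "ai"), function(k)
                dv_diff(fb, trial_dvs_from_params(first,
                                                  pat_group_params(k)))))
    names(mods) <- c("dv_base", "dvdiff_av", "dvdiff_vc", "dvdiff_ai")
    design <- build_design_matrix(events, mods, tr = config$config$tr)
    list(dv_base = dv_base, diffs = diffs, correlations = cors,
         design = design)
  })

  recovery <- NULL
  if (config$n_replicates > 0)
    recovery <- stage("recover",
                      recover_parameters(config$agent$choice_params,
                                         n_subjects = config$n_subjects,
                                         n_trials = 150,
                                         n_replicates = config$n_replicates,
                                         seed = config$seed + 30L,
                                         n_boot = 0))

  bundle <- list(config = config, trials = sim$trials,
                 analysis = pre$analysis, exclusions = pre$report,
                 fits = fits, hr_fit = hr_fit, rt_fit = rt_fit,
                 comparison = comparison, regressors = regs,
                 recovery = recovery, log = log_lines)
  write_bundle(bundle)
  bundle
}

write_bundle <- function(bundle) {
  out <- bundle$config$out_dir
  utils::write.csv(strip_list_cols(bundle$trials),
                   file.path(out, "trials.csv"), row.names = FALSE)
  utils::write.csv(strip_list_cols(bundle$analysis),
                   file.path(out, "analysis_set.csv"), row.names = FALSE)
  utils::write.table(bundle$exclusions, file.path(out, "exclusions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(bundle$fits, fit_to_json),
                       file.path(out, "fits.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(bundle$comparison, file.path(out, "comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  des <- bundle$regressors$design
  utils::write.table(cbind(time = des$time, des$matrix),
                     file.path(out, "design_matrix.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(write_report(bundle), file.path(out, "report.md"))
  writeLines(bundle$log, file.path(out, "pipeline.log"))
  writeLines(jsonlite::toJSON(config_echo(bundle$config), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA),
             file.path(out, "config_echo.json"))
  # the log carries wall-clock timings; everything else must be replayable
  files <- setdiff(list.files(out), c("checksums.txt", "pipeline.log"))
  sums <- tools::md5sum(file.path(out, files))
  writeLines(paste(unname(sums), files), file.path(out, "checksums.txt"))
  invisible(out)
}

strip_list_cols <- function(df) {
  df[, !vapply(df, is.list, TRUE), drop = FALSE]
}

config_echo <- function(config) {
  list(seed = config$seed, n_subjects = config$n_subjects,
       fit_method = config$fit_method, n_boot = config$n_boot,
       n_replicates = config$n_replicates,
       task = unclass(config$config),
       agent = list(choice_kind = param_kind(config$agent$choice_params),
                    choice_params = as.list(config$agent$choice_params),
                    cardiac = unclass(config$agent$cardiac),
                    rt = unclass(config$agent$rt),
                    random_effect_scale = config$agent$random_effect_scale))
}

fit_to_json <- function(fit) {
  out <- list(kind = fit$kind, method = fit$method,
              estimates = as.list(fit$estimates), loglik = fit$loglik,
              aic = fit$aic, n_obs = fit$n_obs, converged = fit$converged,
              separated = fit$separated)
  if (!is.null(fit$hdi95)) {
    out$hdi95 <- apply(fit$hdi95, 2, as.list)
    out$hdi90 <- apply(fit$hdi90, 2, as.list)
    out$labels <- as.list(stats::setNames(fit$labels,
                                          names(fit$estimates)))
  }
  out
}

#' Write beat times as plain text
#'
#' One beat timestamp (seconds) per line, with `# trial subject run trial`
#' marker lines preceding each trial's beats.
#'
#' @param traces tibble with `subject, run, trial, beats`.
#' @param path output file path.
#' @export
write_beat_times <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(traces))) {
    writeLines(sprintf("# trial %d %d %d", traces$subject[i],
                       traces$run[i], traces$trial[i]), con)
    writeLines(sprintf("%.6f", traces$beats[[i]]), con)
  }
  invisible(path)
}

#' Read beat times written by [write_beat_times()]
#'
#' @param path file path.
#' @return tibble with `subject, run, trial, beats` (list-column).
#' @export
read_beat_times <- function(path) {
  lines <- readLines(path)
  marker <- grepl("^# trial ", lines)
  idx <- which(marker)
  meta <- do.call(rbind, lapply(strsplit(lines[idx], " "), function(p)
    as.integer(p[3:5])))
  ends <- c(idx[-1] - 1L, length(lines))
  beats <- lapply(seq_along(idx), function(i)
    as.numeric(lines[seq(idx[i] + 1L, ends[i])]))
  tibble::tibble(subject = meta[, 1], run = meta[, 2], trial = meta[, 3],
                 beats = beats)
}

#' Human-readable run report
#'
#' Markdown summary of a pipeline bundle: exclusion counts, fitted vs.
#' generating coefficients, significance labels, model comparison, and
#' regressor-correlation diagnostics. Incomplete bundles yield a partial
#' report with warnings rather than an error.
#'
#' @param bundle result of [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
write_report <- function(bundle) {
  lines <- c("# Pipeline run report", "",
             sprintf("- seed: %d", bundle$config$seed),
             sprintf("- subjects: %d", bundle$config$n_subjects),
             sprintf("- trials simulated: %d", nrow(bundle$trials)),
             sprintf("- analysis set: %d trials", nrow(bundle$analysis)),
             "", "## Exclusions", "")
  lines <- c(lines, sprintf("- %s: %d", bundle$exclusions$rule,
                            bundle$exclusions$n_excluded))
  lines <- c(lines, "", "## Choice-model estimates", "")
  if (length(bundle$fits)) {
    gen <- bundle$config$agent$choice_params
    for (nm in names(bundle$fits)) {
      f <- bundle$fits[[nm]]
      lines <- c(lines, sprintf("### %s", nm), "",
                 "| coefficient | estimate | generating | label |",
                 "|---|---|---|---|")
      for (j in seq_along(f$estimates)) {
        g <- if (nm == param_kind(gen) &&
                 names(f$estimates)[j] %in% names(gen))
          sprintf("%.3f", gen[[names(f$estimates)[j]]]) else "-"
        lab <- if (!is.null(f$labels)) f$labels[j] else "-"
        lines <- c(lines, sprintf("| %s | %.3f | %s | %s |",
                                  names(f$estimates)[j], f$estimates[j],
                                  g, lab))
      }
      lines <- c(lines, "")
    }
    lines <- c(lines, "## Model comparison", "",
               "| model | loglik | k | AIC | dAIC | rank |",
               "|---|---|---|---|---|---|")
    cm <- bundle$comparison
    for (i in seq_len(nrow(cm)))
      lines <- c(lines, sprintf("| %s | %.2f | %d | %.2f | %.2f | %d |",
                                cm$model[i], cm$loglik[i], cm$n_params[i],
                                cm$aic[i], cm$delta_aic[i], cm$rank[i]))
  } else {
    lines <- c(lines, "WARNING: model fitting not run")
  }
  lines <- c(lines, "", "## Regressor diagnostics", "")
  if (!is.null(bundle$regressors)) {
    for (nm in names(bundle$regressors$correlations)) {
      cc <- bundle$regressors$correlations[[nm]]
      lines <- c(lines,
                 sprintf("- base DV vs DVdiff_%s: mean r = %.3f, sd = %.3f",
                         nm, cc$mean, cc$sd))
    }
  } else lines <- c(lines, "WARNING: regressor stage not run")
  if (!is.null(bundle$recovery)) {
    lines <- c(lines, "", "## Parameter recovery",
               "(generating values from the group-level parameter table)",
               "")
    rs <- bundle$recovery$summary
    for (i in seq_len(nrow(rs)))
      lines <- c(lines, sprintf("- %s: generating %.3f, bias %+.4f",
                                rs$coefficient[i], rs$generating[i],
                                rs$bias[i]))
  }
  lines
}
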