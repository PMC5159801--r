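# End-to-end pipeline: simulate -> fit -> infer, with on-disk artifacts and
# replicate-level reproduction summaries.

mode_defaults <- function(experiment_mode) {
  switch(experiment_mode,
    # Main experiment: predicted-pair recalibration (23/45 ms), slight
    # opposite separation of the unpredicted cells (38/29 ms pattern).
    "action" = list(n_subjects = 15, baseline_bias_ms = 34,
                    adaptation_effect_ms = 22, unpredicted_effect_ms = -9),
    # Visual-cue control: null regime at the higher overall sound-after bias.
    "visual-cue" = list(n_subjects = 16, baseline_bias_ms = 57.5,
                        adaptation_effect_ms = 0, unpredicted_effect_ms = 0),
    # Tactile-cue control: null regime.
    "tactile-cue" = list(n_subjects = 15, baseline_bias_ms = 63.5,
                         adaptation_effect_ms = 0, unpredicted_effect_ms = 0)
  )
}

#' Pipeline run configuration
#'
#' Resolves everything one pipeline run needs. The experiment mode selects
#' the generative regime of the corresponding experiment: `"action"` (actions
#' predict the audio-visual pair; 22 ms adaptation effect for predicted
#' pairs), `"visual-cue"` and `"tactile-cue"` (cue-contingent controls; null
#' effect). All population fields can be overridden.
#'
#' @param experiment_mode `"action"`, `"visual-cue"` or `"tactile-cue"`.
#' @param n_subjects Cohort size; defaults to the mode's analysed sample
#'   size (15, 16, 15).
#' @param design A [design_config()].
#' @param population_overrides Named list of [population_spec()] fields that
#'   override the mode defaults (e.g. `list(adaptation_effect_ms = 0)`).
#' @param exclusion An [exclusion_rule()].
#' @param seed Master seed; every stage seed is spawned from it.
#' @param out_dir Output directory for artifacts, or `NULL` to skip writing.
#' @return A `run_config` object.
#' @export
run_config <- function(experiment_mode = "action",
                       n_subjects = NULL,
                       design = design_config(),
                       population_overrides = list(),
                       exclusion = exclusion_rule(),
                       seed = 1,
                       out_dir = NULL) {
  experiment_mode <- match.arg(experiment_mode, c("action", "visual-cue", "tactile-cue"))
  stopifnot(inherits(design, "design_config"), inherits(exclusion, "exclusion_rule"))
  assert_count(seed, "seed")
  defs <- mode_defaults(experiment_mode)
  n_subjects <- n_subjects %||% defs$n_subjects
  assert_count(n_subjects, "n_subjects", lower = 1)
  pop_args <- modifyList(
    list(n_subjects = n_subjects,
         baseline_bias_ms = defs$baseline_bias_ms,
         adaptation_effect_ms = defs$adaptation_effect_ms,
         unpredicted_effect_ms = defs$unpredicted_effect_ms),
    as.list(population_overrides)
  )
  pop_args$n_subjects <- n_subjects
  population <- do.call(population_spec, pop_args)
  structure(
    list(experiment_mode = experiment_mode, n_subjects = as.integer(n_subjects),
         design = design, population = population, exclusion = exclusion,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", x$experiment_mode, "mode,", x$n_subjects, "subjects, seed",
      x$seed, "\n")
  cat(sprintf("  population: beta = %g ms, delta = %g ms, u = %g ms, between-SD = %g ms\n",
              x$population$baseline_bias_ms, x$population$adaptation_effect_ms,
              x$population$unpredicted_effect_ms, x$population$between_subject_sd_ms))
  if (!is.null(x$out_dir)) cat("  out_dir:", x$out_dir, "\n")
  invisible(x)
}

config_echo <- function(config) {
  list(
    experiment_mode = config$experiment_mode,
    n_subjects = config$n_subjects,
    seed = config$seed,
    design = unclass(config$design),
    population = unclass(config$population),
    exclusion = unclass(config$exclusion)
  )
}

#' Run the full simulate-fit-infer pipeline
#'
#' Simulates a cohort under the configured generative regime, fits the
#' psychometric function per subject and condition, applies the exclusion
#' rule, and runs the inferential layer on the retained subjects' PSS
#' values: the 2 x 2 within-subject ANOVA, the paired t-tests of adaptation
#' order within predicted and within unpredicted pairs, per-condition
#' one-sample bias tests of PSS against 0, and the achieved power of the
#' interaction test. With fewer than 3 retained subjects inference is
#' skipped with an explicit notice.
#'
#' When `config$out_dir` is set, writes `trials.csv`, `fits.csv`,
#' `report.json` and `run.log` there (atomically, via temp-then-rename);
#' re-running the same configuration reproduces every artifact byte for byte
#' except the log's timestamps.
#'
#' @param config A [run_config()].
#' @return The statistical report (list, class `stat_report`), invisibly
#'   carrying the trials and fits as attributes `trials` and `fits`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(msg) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                      " INFO ", msg))
  }
  note(paste0("run start: mode=", config$experiment_mode,
              " n=", config$n_subjects, " seed=", config$seed))
  note(paste0("resolved config: ",
              jsonlite::toJSON(config_echo(config), auto_unbox = TRUE)))

  sim <- simulate_cohort(config$design, config$population, config$seed,
                         config$experiment_mode)
  note(sprintf("simulated %d trials for %d subjects", nrow(sim$trials),
               config$n_subjects))

  fits <- fit_all(sim$trials, seed = spawn_seed(config$seed, 2L))
  excl <- apply_exclusion(fits, config$exclusion)
  kept <- excl$kept
  n_kept <- length(unique(kept$subject_id))
  note(sprintf("fitted %d curves; %d subject(s) excluded", nrow(fits),
               nrow(excl$excluded)))

  cond_means <- kept |>
    dplyr::group_by(.data$condition, .data$adaptation_order, .data$outcome_predicted) |>
    dplyr::summarise(mean_pss_ms = mean(.data$alpha_ms),
                     sd_pss_ms = sd(.data$alpha_ms),
                     mean_sigma_ms = mean(.data$sigma_ms),
                     mean_r_squared = mean(.data$r_squared),
                     .groups = "drop")

  report <- list(
    experiment_mode = config$experiment_mode,
    seed = config$seed,
    n_subjects_simulated = config$n_subjects,
    n_subjects_analyzed = n_kept,
    exclusions = excl$excluded,
    condition_means = cond_means,
    inference_performed = n_kept >= 3,
    notices = character(0),
    config = config_echo(config)
  )

  if (n_kept < 3) {
    msg <- sprintf("inference skipped: only %d subject(s) retained (need >= 3)",
                   n_kept)
    report$notices <- msg
    note(msg)
  } else {
    est <- kept |>
      dplyr::select("subject_id", "adaptation_order", "outcome_predicted",
                    pss_ms = "alpha_ms")
    anova <- rm_anova_2x2(est)
    wide <- est |>
      dplyr::mutate(cond = condition_label(.data$adaptation_order,
                                           .data$outcome_predicted)) |>
      dplyr::select("subject_id", "cond", "pss_ms") |>
      tidyr::pivot_wider(names_from = "cond", values_from = "pss_ms")
    t_pred <- paired_t(wide[["sound-second/predicted"]],
                       wide[["sound-first/predicted"]])
    t_unpred <- paired_t(wide[["sound-second/unpredicted"]],
                         wide[["sound-first/unpredicted"]])
    bias <- dplyr::bind_rows(lapply(
      setdiff(names(wide), "subject_id"),
      function(cond) {
        dplyr::mutate(one_sample_t(wide[[cond]], 0), condition = cond,
                      .before = 1)
      }
    ))
    eta2_int <- anova$partial_eta_sq[anova$effect == "interaction"]
    report$anova <- anova
    report$t_tests <- dplyr::bind_rows(
      dplyr::mutate(t_pred, contrast = "sound-second - sound-first (predicted)",
                    .before = 1),
      dplyr::mutate(t_unpred, contrast = "sound-second - sound-first (unpredicted)",
                    .before = 1)
    )
    report$bias_tests <- bias
    report$adaptation_effect_ms <- t_pred$mean_diff
    report$achieved_power <- if (eta2_int > 0 && eta2_int < 1) {
      achieved_power(eta2_int, n_kept, 0.05)
    } else {
      NA_real_
    }
    note(sprintf("interaction F(1,%d) = %.3f, p %s, partial eta^2 = %.3f",
                 anova$df2[3], anova$F[3], format_p(anova$p[3]),
                 anova$partial_eta_sq[3]))
  }
  class(report) <- "stat_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials_csv(sim$trials, file.path(config$out_dir, "trials.csv"))
    write_fits_csv(fits, file.path(config$out_dir, "fits.csv"))
    write_atomically(function(p) {
      jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "columns")
    }, file.path(config$out_dir, "report.json"))
    note(paste0("artifacts written to ", config$out_dir))
    write_atomically(function(p) writeLines(log_lines, p),
                     file.path(config$out_dir, "run.log"))
  }

  attr(report, "trials") <- sim$trials
  attr(report, "fits") <- fits
  report
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report>", x$experiment_mode, "mode;",
      x$n_subjects_analyzed, "of", x$n_subjects_simulated, "subjects analysed\n")
  cm <- x$condition_means
  for (i in seq_len(nrow(cm))) {
    cat(sprintf("  %-26s mean PSS = %6.1f ms (SD %5.1f), mean r^2 = %.2f\n",
                cm$condition[i], cm$mean_pss_ms[i], cm$sd_pss_ms[i],
                cm$mean_r_squared[i]))
  }
  if (isTRUE(x$inference_performed)) {
    a <- x$anova
    for (i in seq_len(nrow(a))) {
      cat(sprintf("  %-18s F(1,%d) = %6.3f, p %s, partial eta^2 = %.3f\n",
                  a$effect[i], a$df2[i], a$F[i], format_p(a$p[i]),
                  a$partial_eta_sq[i]))
    }
    cat(sprintf("  adaptation effect (predicted pairs): %.1f ms; achieved power %.3f\n",
                x$adaptation_effect_ms, x$achieved_power))
  } else {
    cat(" ", paste(x$notices, collapse = "\n  "), "\n")
  }
  invisible(x)
}

#' Replicate-level reproduction of an experiment's qualitative result
#'
#' Runs the full pipeline `replicates` times under the generative regime of
#' the chosen experiment (1 = action-contingent effect; 2, 3 = cue-contingent
#' null controls) and summarises the mean recovered condition PSS values, the
#' mean adaptation effect (sound-second minus sound-first fitted PSS,
#' predicted pairs), and rejection rates of the interaction and follow-up
#' paired tests at alpha = .05.
#'
#' @param experiment_id 1, 2 or 3.
#' @param replicates Number of independent simulated cohorts (>= 1).
#' @param seed Master seed; replicate seeds are spawned from it.
#' @param n_subjects Optional cohort-size override.
#' @param ... Further overrides forwarded to [run_config()]
#'   (`population_overrides`, `design`, ...).
#' @return List with `summary` (one-row tibble) and `replicates` (one row
#'   per replicate).
#' @export
reproduce_experiment <- function(experiment_id = 1, replicates = 20, seed = 1,
                                 n_subjects = NULL, ...) {
  stopifnot(experiment_id %in% 1:3)
  assert_count(replicates, "replicates", lower = 1)
  mode <- c("action", "visual-cue", "tactile-cue")[experiment_id]
  rows <- lapply(seq_len(replicates), function(r) {
    cfg <- run_config(experiment_mode = mode, n_subjects = n_subjects,
                      seed = spawn_seed(seed, 3000L + r), ...)
    rep_ <- run_pipeline(cfg)
    cm <- rep_$condition_means
    pss <- setNames(cm$mean_pss_ms, cm$condition)
    if (!isTRUE(rep_$inference_performed)) {
      return(tibble::tibble(replicate = r, !!!as.list(pss),
                            adaptation_effect_ms = NA_real_,
                            p_interaction = NA_real_, p_predicted = NA_real_,
                            p_unpredicted = NA_real_))
    }
    tibble::tibble(
      replicate = r, !!!as.list(pss),
      adaptation_effect_ms = rep_$adaptation_effect_ms,
      p_interaction = rep_$anova$p[rep_$anova$effect == "interaction"],
      p_predicted = rep_$t_tests$p_two_tailed[1],
      p_unpredicted = rep_$t_tests$p_two_tailed[2]
    )
  })
  reps <- dplyr::bind_rows(rows)
  pss_cols <- setdiff(names(reps),
                      c("replicate", "adaptation_effect_ms", "p_interaction",
                        "p_predicted", "p_unpredicted"))
  summary <- dplyr::bind_cols(
    tibble::tibble(experiment_id = experiment_id, mode = mode,
                   replicates = replicates),
    dplyr::summarise(reps, dplyr::across(dplyr::all_of(pss_cols), mean)),
    dplyr::summarise(
      reps,
      mean_adaptation_effect_ms = mean(.data$adaptation_effect_ms, na.rm = TRUE),
      reject_interaction = mean(.data$p_interaction < 0.05, na.rm = TRUE),
      reject_predicted = mean(.data$p_predicted < 0.05, na.rm = TRUE),
      reject_unpredicted = mean(.data$p_unpredicted < 0.05, na.rm = TRUE)
    )
  )
  list(summary = summary, replicates = reps)
}

#' Parameter-recovery study for a single condition
#'
#' Simulates independent observers answering the standard per-condition SOA
#' schedule (each SOA presented its repetition count of times), with true PSS
#' drawn around `alpha_true_ms`, and refits each observer with the weighted
#' Gaussian. Used to quantify recovery bias of the fitted PSS under binomial
#' response noise.
#'
#' @param alpha_true_ms Generative condition-mean PSS, ms.
#' @param n_observers Number of simulated observers.
#' @param sigma_ms,scale Generative temporal sensitivity and peak rate.
#' @param between_subject_sd_ms SD of true PSS across observers, ms.
#' @param config A [design_config()] supplying the SOA grid and counts.
#' @param seed Integer seed.
#' @return Tibble with one row per observer: `alpha_true_ms` (that observer's
#'   draw), fitted `alpha_ms`, `sigma_ms`, `scale`, `r_squared`.
#' @export
recover_pss <- function(alpha_true_ms, n_observers = 200, sigma_ms = 120,
                        scale = 0.85, between_subject_sd_ms = 15,
                        config = design_config(), seed = 1) {
  stopifnot(inherits(config, "design_config"))
  assert_count(n_observers, "n_observers", lower = 1)
  grid <- config$soa_grid_ms
  counts <- config$per_condition_soa_counts
  withr::with_seed(seed, {
    alpha_i <- rnorm(n_observers, alpha_true_ms, between_subject_sd_ms)
    sims <- lapply(seq_len(n_observers), function(i) {
      p <- simultaneity_prob(list(alpha_ms = alpha_i[i], sigma_ms = sigma_ms,
                                  scale = scale, lapse = 0), grid)
      rbinom(length(grid), counts, p)
    })
  })
  dplyr::bind_rows(lapply(seq_len(n_observers), function(i) {
    tab <- tibble::tibble(soa_ms = grid, n_presented = counts,
                          n_simultaneous = sims[[i]], weight = counts)
    fit <- fit_gaussian(tab, seed = spawn_seed(seed, 500L + i))
    tibble::tibble(observer = i, alpha_true_ms = alpha_i[i],
                   alpha_ms = fit$alpha_ms, sigma_ms = fit$sigma_ms,
                   scale = fit$scale, r_squared = fit$r_squared)
  }))
}
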