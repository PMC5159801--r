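# Generative observer: scaled-Gaussian simultaneity-judgment model and
# cohort simulation.

#' Generative observer parameters
#'
#' Parameters of the scaled-Gaussian simultaneity-response curve
#' \eqn{p(soa) = lapse + s \cdot \exp(-(soa - \alpha)^2 / (2\sigma^2))}:
#' `alpha_ms` is the point of subjective simultaneity (PSS; positive = the
#' sound must come after the flash), `sigma_ms` the temporal sensitivity
#' (Gaussian SD), `scale` the peak "simultaneous" response rate, and `lapse`
#' an optional floor rate (default 0, i.e. the pure 3-parameter model).
#'
#' @param alpha_ms PSS in ms.
#' @param sigma_ms Gaussian SD in ms; must be positive.
#' @param scale Peak response rate in (0, 1].
#' @param lapse Floor response rate in [0, 0.1]; `lapse + scale` must not
#'   exceed 1.
#' @return An `observer_params` object.
#' @export
observer_params <- function(alpha_ms, sigma_ms, scale = 0.85, lapse = 0) {
  assert_scalar_number(alpha_ms, "alpha_ms")
  assert_scalar_number(sigma_ms, "sigma_ms")
  if (sigma_ms <= 0) abort("`sigma_ms` must be positive.", class = "avrecal_domain_error")
  assert_scalar_number(scale, "scale")
  if (scale <= 0 || scale > 1) {
    abort("`scale` must lie in (0, 1].", class = "avrecal_domain_error")
  }
  assert_scalar_number(lapse, "lapse", 0, 0.1)
  if (lapse + scale > 1) {
    abort("`lapse + scale` must not exceed 1.", class = "avrecal_domain_error")
  }
  structure(list(alpha_ms = alpha_ms, sigma_ms = sigma_ms, scale = scale,
                 lapse = lapse),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> alpha = %g ms, sigma = %g ms, scale = %g, lapse = %g\n",
              x$alpha_ms, x$sigma_ms, x$scale, x$lapse))
  invisible(x)
}

#' Probability of a "simultaneous" response
#'
#' Evaluates the scaled-Gaussian psychometric function at one or more SOAs.
#' The curve peaks at `alpha_ms` (the PSS) with height `lapse + scale` and is
#' symmetric about the peak.
#'
#' @param params An [observer_params()] (or any list with fields `alpha_ms`,
#'   `sigma_ms`, `scale`, `lapse`).
#' @param soa_ms Numeric vector of SOAs in ms (negative = audio first).
#' @return Numeric vector of probabilities in `[lapse, lapse + scale]`.
#' @examples
#' simultaneity_prob(observer_params(23, 150, 0.9), 23) # peak: 0.9
#' @export
simultaneity_prob <- function(params, soa_ms) {
  sigma <- params$sigma_ms
  if (!is.numeric(sigma) || sigma <= 0) {
    abort("`sigma_ms` must be positive.", class = "avrecal_domain_error")
  }
  lapse <- params$lapse %||% 0
  lapse + params$scale * exp(-(soa_ms - params$alpha_ms)^2 / (2 * sigma^2))
}

#' Population specification for cohort simulation
#'
#' Defines the generative distribution of per-subject, per-condition observer
#' parameters. Condition-mean PSS values are built exactly from a baseline
#' bias `beta` (`baseline_bias_ms`, the positive sound-after bias), an
#' adaptation effect `delta` (`adaptation_effect_ms`, the sound-second minus
#' sound-first PSS separation for predicted pairs) and an analogous effect for
#' unpredicted pairs:
#' predicted/sound-first = beta - delta/2, predicted/sound-second =
#' beta + delta/2, and likewise with `unpredicted_effect_ms` for the
#' unpredicted cells. Per-cell PSS values then add independent zero-mean
#' Gaussian noise (`between_subject_sd_ms`); `sigma` and `scale` are drawn
#' from Gaussians truncated (clamped) to their valid ranges.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param baseline_bias_ms Mean PSS across conditions, ms.
#' @param adaptation_effect_ms Predicted-pair PSS separation, ms.
#' @param unpredicted_effect_ms Unpredicted-pair separation, ms (0 = null).
#' @param between_subject_sd_ms SD of per-cell PSS noise, ms.
#' @param sigma_mean_ms,sigma_sd_ms Temporal-sensitivity distribution, ms.
#' @param scale_mean,scale_sd Peak-rate distribution.
#' @param lapse Lapse rate given to every observer.
#' @param seed Integer seed for all draws.
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_subjects = 15,
                            baseline_bias_ms = 34,
                            adaptation_effect_ms = 22,
                            unpredicted_effect_ms = 0,
                            between_subject_sd_ms = 15,
                            sigma_mean_ms = 120,
                            sigma_sd_ms = 20,
                            scale_mean = 0.85,
                            scale_sd = 0.05,
                            lapse = 0,
                            seed = 1) {
  assert_count(n_subjects, "n_subjects", lower = 1)
  assert_scalar_number(baseline_bias_ms, "baseline_bias_ms")
  assert_scalar_number(adaptation_effect_ms, "adaptation_effect_ms")
  assert_scalar_number(unpredicted_effect_ms, "unpredicted_effect_ms")
  assert_scalar_number(between_subject_sd_ms, "between_subject_sd_ms", lower = 0)
  assert_scalar_number(sigma_mean_ms, "sigma_mean_ms", lower = 0.001)
  assert_scalar_number(sigma_sd_ms, "sigma_sd_ms", lower = 0)
  assert_scalar_number(scale_mean, "scale_mean", 0.001, 1)
  assert_scalar_number(scale_sd, "scale_sd", lower = 0)
  assert_scalar_number(lapse, "lapse", 0, 0.1)
  assert_count(seed, "seed")
  structure(
    list(n_subjects = as.integer(n_subjects),
         baseline_bias_ms = baseline_bias_ms,
         adaptation_effect_ms = adaptation_effect_ms,
         unpredicted_effect_ms = unpredicted_effect_ms,
         between_subject_sd_ms = between_subject_sd_ms,
         sigma_mean_ms = sigma_mean_ms, sigma_sd_ms = sigma_sd_ms,
         scale_mean = scale_mean, scale_sd = scale_sd,
         lapse = lapse, seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Condition-mean PSS values implied by a population spec
#'
#' @param spec A [population_spec()].
#' @return Tibble with one row per condition and its generative mean PSS.
#' @examples
#' condition_means(population_spec(baseline_bias_ms = 34, adaptation_effect_ms = 22))
#' @export
condition_means <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  tibble::tibble(
    adaptation_order = rep(adaptation_orders(), 2L),
    outcome_predicted = rep(c(TRUE, FALSE), each = 2L),
    mean_alpha_ms = c(
      spec$baseline_bias_ms - spec$adaptation_effect_ms / 2,
      spec$baseline_bias_ms + spec$adaptation_effect_ms / 2,
      spec$baseline_bias_ms - spec$unpredicted_effect_ms / 2,
      spec$baseline_bias_ms + spec$unpredicted_effect_ms / 2
    )
  )
}

#' Draw a cohort of generative observers
#'
#' Draws per-subject, per-condition observer parameters around the condition
#' means of `spec` (see [condition_means()]). PSS noise is independent across
#' the four cells of a subject; `sigma` and `scale` are drawn once per
#' subject (a subject's temporal sensitivity is a stable trait) and clamped
#' into their valid ranges. Fully deterministic given `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return Tibble with columns `subject_id`, `adaptation_order`,
#'   `outcome_predicted`, `alpha_ms`, `sigma_ms`, `scale`, `lapse`.
#' @export
make_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  means <- condition_means(spec)
  n <- spec$n_subjects
  ids <- sprintf("s%03d", seq_len(n))

  withr::with_seed(spec$seed, {
    sigma <- pmin(pmax(rnorm(n, spec$sigma_mean_ms, spec$sigma_sd_ms), 10), 1000)
    scl <- pmin(pmax(rnorm(n, spec$scale_mean, spec$scale_sd), 0.05), 1 - spec$lapse)
    noise <- matrix(rnorm(n * 4L, 0, spec$between_subject_sd_ms), nrow = n)
  })

  tidyr::crossing(subject_id = ids, means) |>
    dplyr::arrange(.data$subject_id) |>
    dplyr::mutate(
      alpha_ms = .data$mean_alpha_ms + as.vector(t(noise)),
      sigma_ms = rep(sigma, each = 4L),
      scale = rep(scl, each = 4L),
      lapse = spec$lapse
    ) |>
    dplyr::select(-"mean_alpha_ms")
}

params_for_trials <- function(params, trials) {
  if (inherits(params, "observer_params")) {
    tibble::tibble(
      alpha_ms = params$alpha_ms, sigma_ms = params$sigma_ms,
      scale = params$scale, lapse = params$lapse,
      .rows = nrow(trials)
    )
  } else {
    stopifnot(is.data.frame(params),
              all(c("adaptation_order", "outcome_predicted", "alpha_ms",
                    "sigma_ms", "scale") %in% names(params)))
    if (!"lapse" %in% names(params)) params$lapse <- 0
    key <- condition_label(trials$adaptation_order, trials$outcome_predicted)
    pkey <- condition_label(params$adaptation_order, params$outcome_predicted)
    idx <- match(key, pkey)
    if (anyNA(idx[trials$phase == "test"])) {
      abort("`params` is missing parameters for some test-trial conditions.",
            class = "avrecal_data_error")
    }
    params[idx, c("alpha_ms", "sigma_ms", "scale", "lapse")]
  }
}

#' Simulate simultaneity-judgment responses
#'
#' Fills the `response` column of a schedule: each non-catch test trial draws
#' a Bernoulli "simultaneous" response with probability
#' [simultaneity_prob()] at the trial's SOA; catch trials (both phases) are
#' answered correctly (`"catch-response"`) with probability 0.95 and
#' otherwise left `"none"`; non-catch learning trials carry no response.
#'
#' @param params Either a single [observer_params()] applied to all trials,
#'   or a per-condition tibble as produced by [make_population()] (rows for
#'   one subject).
#' @param schedule Trial tibble from [build_test_schedule()] /
#'   [build_learning_schedule()].
#' @param seed Integer seed; identical seeds give identical responses.
#' @return The schedule with `response` filled in.
#' @export
simulate_responses <- function(params, schedule, seed) {
  stopifnot(is.data.frame(schedule))
  if (nrow(schedule) == 0L) return(schedule)
  p <- params_for_trials(params, schedule)
  prob <- p$lapse + p$scale *
    exp(-(schedule$soa_ms - p$alpha_ms)^2 / (2 * p$sigma_ms^2))
  live <- schedule$phase == "test" & !schedule$is_catch
  withr::with_seed(seed, {
    u <- runif(nrow(schedule))
    u_catch <- runif(nrow(schedule))
  })
  resp <- rep("none", nrow(schedule))
  resp[live] <- ifelse(u[live] < prob[live], "simultaneous", "not-simultaneous")
  resp[schedule$is_catch] <- ifelse(u_catch[schedule$is_catch] < 0.95,
                                    "catch-response", "none")
  schedule$response <- resp
  schedule
}

#' Aggregate trials into per-condition response tables
#'
#' Computes, separately for each subject, condition and SOA, the number of
#' presentations and of "simultaneous" responses. Catch trials and trials
#' without a simultaneity judgment are excluded. The per-SOA presentation
#' count doubles as the fitting weight (each squared error is weighted by how
#' often its SOA was repeated).
#'
#' @param trials Trial tibble with responses filled.
#' @return Tibble with columns `subject_id`, `adaptation_order`,
#'   `outcome_predicted`, `soa_ms`, `n_presented`, `n_simultaneous`,
#'   `weight`.
#' @export
aggregate_responses <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) {
    return(tibble::tibble(subject_id = character(), adaptation_order = character(),
                          outcome_predicted = logical(), soa_ms = numeric(),
                          n_presented = integer(), n_simultaneous = integer(),
                          weight = integer()))
  }
  bad <- setdiff(unique(trials$adaptation_order),
                 c(adaptation_orders(), NA_character_))
  if (length(bad)) {
    abort(paste0("Unknown adaptation_order label(s): ", paste(bad, collapse = ", ")),
          class = "avrecal_data_error")
  }
  trials |>
    dplyr::filter(.data$phase == "test", !.data$is_catch,
                  .data$response %in% c("simultaneous", "not-simultaneous")) |>
    dplyr::group_by(.data$subject_id, .data$adaptation_order,
                    .data$outcome_predicted, .data$soa_ms) |>
    dplyr::summarise(
      n_presented = dplyr::n(),
      n_simultaneous = sum(.data$response == "simultaneous"),
      .groups = "drop"
    ) |>
    dplyr::mutate(weight = .data$n_presented) |>
    dplyr::arrange(.data$subject_id, .data$adaptation_order,
                   dplyr::desc(.data$outcome_predicted), .data$soa_ms)
}

#' Simulate a full cohort end to end
#'
#' For each subject: assigns a counterbalancing cell, builds the learning and
#' test schedules, and simulates responses from that subject's generative
#' parameters. All randomness derives from `seed` through a deterministic
#' per-subject seed-spawning rule, so any subject's data can be regenerated
#' independently.
#'
#' @param config A [design_config()].
#' @param spec A [population_spec()].
#' @param seed Master integer seed.
#' @param experiment_mode Passed to [assign_counterbalancing()].
#' @return List with `trials` (all subjects' trial rows) and `population`
#'   (the generative parameters from [make_population()]).
#' @export
simulate_cohort <- function(config, spec, seed, experiment_mode = "action") {
  stopifnot(inherits(config, "design_config"), inherits(spec, "population_spec"))
  spec$seed <- spawn_seed(seed, 1L)
  pop <- make_population(spec)
  ids <- unique(pop$subject_id)
  trials <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    mapping <- assign_counterbalancing(i - 1L, experiment_mode)
    lrn <- build_learning_schedule(config, mapping, spawn_seed(seed, 100L + i), ids[i])
    tst <- build_test_schedule(config, mapping, spawn_seed(seed, 10000L + i), ids[i])
    sub <- dplyr::bind_rows(lrn, tst)
    simulate_responses(pop[pop$subject_id == ids[i], ], sub,
                       spawn_seed(seed, 20000L + i))
  }))
  list(trials = trials, population = pop)
}
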