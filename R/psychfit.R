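# Repetition-weighted least-squares fitting of the scaled-Gaussian
# psychometric function; per-cohort fitting and subject exclusion.

#' Repetition-weighted sum of squared errors
#'
#' Loss minimised by the psychometric fit:
#' \eqn{\sum_i w_i (\hat{p}_i - p(soa_i; \alpha, \sigma, s))^2}, where
#' \eqn{\hat{p}_i} is the observed proportion of "simultaneous" responses at
#' SOA i and the weight \eqn{w_i} is the number of times that SOA was
#' presented, so sparsely sampled extreme SOAs influence the fit less.
#' Rows with zero presentations are excluded.
#'
#' @param params An [observer_params()] (or list with `alpha_ms`, `sigma_ms`,
#'   `scale`, optional `lapse`).
#' @param table A response table (one subject x condition) as produced by
#'   [aggregate_responses()].
#' @return Nonnegative number.
#' @examples
#' tab <- tibble::tibble(soa_ms = c(-233, 0, 233), n_presented = c(8, 20, 8),
#'                       n_simultaneous = c(1, 18, 2), weight = c(8, 20, 8))
#' weighted_sse(observer_params(0, 100, 0.9), tab)
#' @export
weighted_sse <- function(params, table) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  tab <- table[table$n_presented > 0, ]
  prop <- tab$n_simultaneous / tab$n_presented
  pred <- simultaneity_prob(params, tab$soa_ms)
  sum(tab$n_presented * (prop - pred)^2)
}

default_fit_bounds <- function() {
  list(lower = c(alpha_ms = -300, sigma_ms = 10, scale = 1e-6),
       upper = c(alpha_ms = 300, sigma_ms = 1000, scale = 1.2))
}

#' Fit the scaled-Gaussian psychometric function
#'
#' Minimises the repetition-weighted SSE over the three free parameters
#' (mean `alpha_ms` = PSS, SD `sigma_ms` = temporal sensitivity, amplitude
#' `scale`) with bounded quasi-Newton optimisation (`optim`, L-BFGS-B) and
#' multiple starts: one data-driven start (peak location, half the SOA range,
#' peak height) plus seeded random restarts within the bounds. The solution
#' with the lowest weighted SSE wins; ties go to the smaller `sigma_ms`.
#' Goodness of fit is the weighted coefficient of determination
#' r-squared = 1 - SSE_w / SST_w, with SST_w taken about the weighted mean
#' proportion.
#'
#' @param table Response table for one subject x condition
#'   ([aggregate_responses()] output); needs >= 5 distinct SOAs with nonzero
#'   presentations.
#' @param n_restarts Number of random restarts beyond the data-driven start.
#' @param seed Seed for the restart draws (fits are deterministic given data
#'   and seed).
#' @param lower,upper Named bound vectors over `(alpha_ms, sigma_ms, scale)`.
#'   The default amplitude cap of 1.2 slightly exceeds 1 so pure least
#'   squares can absorb noise at the peak.
#' @return One-row tibble: `alpha_ms`, `sigma_ms`, `scale`, `sse_weighted`,
#'   `r_squared`, `converged`, `n_restarts_used`.
#' @examples
#' p <- observer_params(40, 120, 0.8)
#' cfg <- design_config()
#' tab <- tibble::tibble(
#'   soa_ms = cfg$soa_grid_ms, n_presented = cfg$per_condition_soa_counts,
#'   n_simultaneous = round(cfg$per_condition_soa_counts *
#'                          simultaneity_prob(p, cfg$soa_grid_ms) * 100) / 100,
#'   weight = cfg$per_condition_soa_counts)
#' fit_gaussian(tab)
#' @export
fit_gaussian <- function(table, n_restarts = 10, seed = 1,
                         lower = default_fit_bounds()$lower,
                         upper = default_fit_bounds()$upper) {
  stopifnot(is.data.frame(table))
  tab <- table[table$n_presented > 0, , drop = FALSE]
  if (length(unique(tab$soa_ms)) < 5) {
    abort("Need at least 5 distinct SOAs with nonzero presentations.",
          class = "avrecal_data_error")
  }
  soa <- tab$soa_ms
  w <- tab$n_presented
  prop <- tab$n_simultaneous / tab$n_presented

  wmean <- sum(w * prop) / sum(w)
  sst <- sum(w * (prop - wmean)^2)
  if (sst == 0) {
    abort(
      sprintf(paste0("Degenerate fit: all observed proportions equal %.3f; ",
                     "the psychometric function is unidentifiable."), wmean),
      class = "avrecal_degenerate_fit"
    )
  }

  obj <- function(th) {
    sum(w * (prop - th[3] * exp(-(soa - th[1])^2 / (2 * th[2]^2)))^2)
  }

  start0 <- c(
    alpha_ms = soa[which.max(prop)],
    sigma_ms = diff(range(soa)) / 2,
    scale = max(prop)
  )
  start0 <- pmin(pmax(start0, lower), upper)
  starts <- withr::with_seed(seed, {
    rand <- replicate(n_restarts, lower + runif(3) * (upper - lower))
    cbind(start0, rand)
  })

  best <- NULL
  n_used <- 0L
  for (j in seq_len(ncol(starts))) {
    n_used <- n_used + 1L
    res <- tryCatch(
      optim(starts[, j], obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) ||
        res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && res$par[2] < best$par[2])) {
      best <- res
    }
  }
  if (is.null(best)) {
    abort("Optimisation failed from every start.", class = "avrecal_fit_error")
  }

  tibble::tibble(
    alpha_ms = unname(best$par[1]),
    sigma_ms = unname(best$par[2]),
    scale = unname(best$par[3]),
    sse_weighted = best$value,
    r_squared = 1 - best$value / sst,
    converged = best$convergence == 0,
    n_restarts_used = n_used
  )
}

#' Fit every subject x condition of a dataset
#'
#' Aggregates a trial table (or accepts a pre-aggregated response table) and
#' fits the psychometric function per subject and condition. Subjects missing
#' one of the four conditions are flagged `incomplete` (their available cells
#' are still fitted) with a warning.
#'
#' @param dataset Trial tibble with responses, or a table already in
#'   [aggregate_responses()] format.
#' @param n_restarts,seed Passed to [fit_gaussian()].
#' @return Tibble keyed by `subject_id` and `condition`
#'   (`"<order>/<predictedness>"`), with the fit columns of [fit_gaussian()]
#'   plus `adaptation_order`, `outcome_predicted` and `incomplete`.
#' @export
fit_all <- function(dataset, n_restarts = 10, seed = 1) {
  stopifnot(is.data.frame(dataset))
  agg <- if ("n_presented" %in% names(dataset)) dataset else aggregate_responses(dataset)
  if (nrow(agg) == 0L) {
    abort("No analysable test trials in `dataset`.", class = "avrecal_data_error")
  }
  fits <- agg |>
    dplyr::group_by(.data$subject_id, .data$adaptation_order, .data$outcome_predicted) |>
    dplyr::group_modify(function(tab, key) {
      fit_gaussian(tab, n_restarts = n_restarts,
                   seed = spawn_seed(seed, sum(utf8ToInt(paste0(key$subject_id,
                                                                key$adaptation_order,
                                                                key$outcome_predicted)))))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(condition = condition_label(.data$adaptation_order,
                                              .data$outcome_predicted),
                  .after = "subject_id")
  n_cond <- table(fits$subject_id)
  incomplete <- names(n_cond)[n_cond < 4L]
  if (length(incomplete)) {
    warn(paste0("Subject(s) with missing conditions (marked incomplete): ",
                paste(incomplete, collapse = ", ")))
  }
  fits$incomplete <- fits$subject_id %in% incomplete
  fits
}

#' Subject exclusion rule
#'
#' Thresholds for discarding subjects with unusable psychometric functions:
#' poor temporal sensitivity (very wide curves), flat curves (tiny
#' amplitude), or poor goodness of fit. A subject is excluded when any of its
#' condition fits violates any threshold. The defaults are a pragmatic
#' reconstruction of "poor temporal sensitivity" screening and are fully
#' configurable.
#'
#' @param max_sigma_ms Largest acceptable fitted SD, ms.
#' @param min_scale Smallest acceptable fitted amplitude.
#' @param min_r_squared Smallest acceptable weighted r-squared.
#' @return An `exclusion_rule` object.
#' @export
exclusion_rule <- function(max_sigma_ms = 400, min_scale = 0.2,
                           min_r_squared = 0.1) {
  assert_scalar_number(max_sigma_ms, "max_sigma_ms", lower = 1e-9)
  assert_scalar_number(min_scale, "min_scale", lower = 1e-9)
  assert_scalar_number(min_r_squared, "min_r_squared", lower = 1e-9)
  structure(list(max_sigma_ms = max_sigma_ms, min_scale = min_scale,
                 min_r_squared = min_r_squared),
            class = "exclusion_rule")
}

#' Apply a subject exclusion rule to a fits table
#'
#' @param fits Output of [fit_all()].
#' @param rule An [exclusion_rule()].
#' @return List with `kept` (fits of retained subjects) and `excluded`
#'   (tibble of `subject_id` and semicolon-separated `reasons`). Applying the
#'   rule to `kept` again is a no-op.
#' @export
apply_exclusion <- function(fits, rule = exclusion_rule()) {
  stopifnot(is.data.frame(fits), inherits(rule, "exclusion_rule"))
  per_fit_reasons <- function(f) {
    r <- character(0)
    if (any(f$sigma_ms > rule$max_sigma_ms)) {
      r <- c(r, sprintf("sigma_ms > %g", rule$max_sigma_ms))
    }
    if (any(f$scale < rule$min_scale)) r <- c(r, sprintf("scale < %g", rule$min_scale))
    if (any(f$r_squared < rule$min_r_squared)) {
      r <- c(r, sprintf("r_squared < %g", rule$min_r_squared))
    }
    if (isTRUE(any(f$incomplete))) r <- c(r, "incomplete conditions")
    r
  }
  excluded <- fits |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(f, key) {
      r <- per_fit_reasons(f)
      if (length(r)) {
        tibble::tibble(subject_id = key$subject_id,
                       reasons = paste(r, collapse = "; "))
      } else {
        NULL
      }
    }) |>
    dplyr::bind_rows()
  if (nrow(excluded) == 0L) {
    excluded <- tibble::tibble(subject_id = character(), reasons = character())
  }
  list(kept = fits[!fits$subject_id %in% excluded$subject_id, ],
       excluded = excluded)
}
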