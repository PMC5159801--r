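# Cohort-level inference: 2x2 within-subject ANOVA, t-tests, effect sizes
# and achieved power.

#' Partial eta squared from an F statistic
#'
#' \eqn{\eta^2_p = F \cdot df_1 / (F \cdot df_1 + df_2)}, the within-subjects
#' effect-size convention \eqn{SS_{effect} / (SS_{effect} + SS_{error})}.
#'
#' @param f F statistic (nonnegative).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Number in [0, 1).
#' @examples
#' partial_eta_sq(8.697, 1, 14) # 0.383
#' @export
partial_eta_sq <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 >= 1), all(df2 >= 1))
  f * df1 / (f * df1 + df2)
}

#' Cohen's d for paired / one-sample contrasts
#'
#' The standardized-difference convention \eqn{d_z = t / \sqrt{n}}.
#'
#' @param t t statistic.
#' @param n Number of (pairs of) observations.
#' @return d_z.
#' @examples
#' cohens_dz(5.197, 16) # 1.299
#' @export
cohens_dz <- function(t, n) {
  stopifnot(all(n >= 1))
  t / sqrt(n)
}

check_estimates <- function(est, value_col = "pss_ms") {
  stopifnot(is.data.frame(est),
            all(c("subject_id", "adaptation_order", "outcome_predicted",
                  value_col) %in% names(est)))
  counts <- est |>
    dplyr::count(.data$subject_id)
  bad <- counts$subject_id[counts$n != 4L]
  dup <- est |>
    dplyr::count(.data$subject_id, .data$adaptation_order, .data$outcome_predicted) |>
    dplyr::filter(.data$n > 1L)
  if (length(bad) || nrow(dup)) {
    abort(paste0("Incomplete or duplicated 2x2 cells for subject(s): ",
                 paste(unique(c(bad, dup$subject_id)), collapse = ", ")),
          class = "avrecal_data_error")
  }
  invisible(est)
}

# Wide per-subject cell matrix: columns y11 (first/pred), y12 (first/unpred),
# y21 (second/pred), y22 (second/unpred).
cells_wide <- function(est, value_col = "pss_ms") {
  check_estimates(est, value_col)
  wide <- est |>
    dplyr::mutate(cell = paste0(
      ifelse(.data$adaptation_order == "sound-first", "y1", "y2"),
      ifelse(.data$outcome_predicted, "1", "2"))) |>
    dplyr::select("subject_id", "cell", value = dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value") |>
    dplyr::arrange(.data$subject_id)
  as.matrix(wide[, c("y11", "y12", "y21", "y22")])
}

#' 2 x 2 fully within-subject ANOVA
#'
#' Repeated-measures ANOVA on one value per subject and condition, with
#' adaptation order and outcome predictedness as within factors. Sums of
#' squares are computed directly from the cell decomposition (each 1-df
#' effect tested against its own effect-by-subject interaction), so no model
#' fitting is involved and the classical identity F = t^2 against the
#' per-subject contrast holds exactly (see [interaction_equals_t()]).
#' Sphericity is not an issue at 1 numerator df.
#'
#' @param est Tibble with columns `subject_id`, `adaptation_order`,
#'   `outcome_predicted` and the response in `value_col`; complete 2 x 2 per
#'   subject, n >= 3 subjects.
#' @param value_col Name of the response column (default `"pss_ms"`).
#' @return Tibble with one row per effect (`adaptation_order`,
#'   `outcome_predicted`, `interaction`): `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`.
#' @export
rm_anova_2x2 <- function(est, value_col = "pss_ms") {
  y <- cells_wide(est, value_col)
  n <- nrow(y)
  if (n < 3) abort("Need at least 3 complete subjects.", class = "avrecal_data_error")

  grand <- mean(y)
  subj <- rowMeans(y)
  a <- cbind(rowMeans(y[, c("y11", "y12")]), rowMeans(y[, c("y21", "y22")])) # order
  b <- cbind(rowMeans(y[, c("y11", "y21")]), rowMeans(y[, c("y12", "y22")])) # outcome
  a_m <- colMeans(a)
  b_m <- colMeans(b)
  ab_m <- matrix(colMeans(y), 2, 2, byrow = TRUE) # rows: order, cols: outcome

  ss_a <- 2 * n * sum((a_m - grand)^2)
  ss_b <- 2 * n * sum((b_m - grand)^2)
  ss_ab <- n * sum((ab_m - outer(rowMeans(ab_m), colMeans(ab_m), `+`) + grand)^2)
  ss_as <- 2 * sum((a - outer(subj, a_m - grand, `+`))^2)
  ss_bs <- 2 * sum((b - outer(subj, b_m - grand, `+`))^2)
  # Interaction-by-subject residual from the full cell decomposition.
  cell_idx <- cbind(order = c(1, 1, 2, 2), outcome = c(1, 2, 1, 2))
  resid <- y
  for (k in 1:4) {
    i <- cell_idx[k, 1]; j <- cell_idx[k, 2]
    resid[, k] <- y[, k] - ab_m[i, j] - (a[, i] - a_m[i]) - (b[, j] - b_m[j]) +
      (subj - grand)
  }
  ss_abs <- sum(resid^2)

  df2 <- n - 1
  f <- c(ss_a / (ss_as / df2), ss_b / (ss_bs / df2), ss_ab / (ss_abs / df2))
  tibble::tibble(
    effect = c("adaptation_order", "outcome_predicted", "interaction"),
    F = f,
    df1 = 1L,
    df2 = df2,
    p = pf(f, 1, df2, lower.tail = FALSE),
    partial_eta_sq = partial_eta_sq(f, 1, df2)
  )
}

t_result <- function(tt, n, mean_diff, d_av = NA_real_) {
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_two_tailed = tt$p.value,
    mean_diff = mean_diff,
    d_z = cohens_dz(unname(tt$statistic), n),
    d_av = d_av,
    n = n
  )
}

#' Paired two-tailed t-test with effect sizes
#'
#' Classical paired t-test, reporting both d_z (`t / sqrt(n)`) and d_av (mean
#' difference over the average of the two condition SDs).
#'
#' @param x,y Per-subject paired values (equal length >= 3).
#' @return One-row tibble: `t`, `df`, `p_two_tailed`, `mean_diff`, `d_z`,
#'   `d_av`, `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3) abort("Need at least 3 pairs.", class = "avrecal_data_error")
  d <- x - y
  if (sd(d) == 0) {
    abort("Zero variance of paired differences; t is undefined.",
          class = "avrecal_degenerate_error")
  }
  t_result(t.test(x, y, paired = TRUE), n, mean(d),
           d_av = mean(d) / ((sd(x) + sd(y)) / 2))
}

#' One-sample two-tailed t-test with effect sizes
#'
#' @param x Per-subject values (length >= 3).
#' @param mu Null value (default 0, e.g. testing a PSS bias against true
#'   simultaneity).
#' @return As [paired_t()]; for one sample, `d_av` equals `d_z`.
#' @export
one_sample_t <- function(x, mu = 0) {
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n < 3) abort("Need at least 3 observations.", class = "avrecal_data_error")
  if (sd(x) == 0) {
    if (all(x == mu)) {
      return(tibble::tibble(t = 0, df = n - 1, p_two_tailed = 1, mean_diff = 0,
                            d_z = 0, d_av = 0, n = n))
    }
    abort("Zero variance; t is undefined.", class = "avrecal_degenerate_error")
  }
  mean_diff <- mean(x) - mu
  out <- t_result(t.test(x, mu = mu), n, mean_diff)
  out$d_av <- out$d_z
  out
}

#' Check the F = t^2 identity for the 2 x 2 interaction
#'
#' In a fully within 2 x 2 design the interaction F equals the squared
#' one-sample t on the per-subject double difference
#' `(y11 - y12) - (y21 - y22)`. This diagnostic recomputes both routes and
#' returns whether they agree to within `tol` (relative to the magnitude of
#' F), which guards the hand-rolled sums-of-squares implementation.
#'
#' @param est As in [rm_anova_2x2()].
#' @param value_col Response column name.
#' @param tol Absolute/relative tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
interaction_equals_t <- function(est, value_col = "pss_ms", tol = 1e-9) {
  y <- cells_wide(est, value_col)
  f_int <- rm_anova_2x2(est, value_col)$F[3]
  dd <- (y[, "y11"] - y[, "y12"]) - (y[, "y21"] - y[, "y22"])
  t2 <- unname(t.test(dd, mu = 0)$statistic)^2
  abs(f_int - t2) <= tol * max(1, abs(f_int))
}

#' Achieved power of the 1-df within-subjects F test
#'
#' Converts a partial eta squared into Cohen's
#' \eqn{f = \sqrt{\eta^2_p / (1 - \eta^2_p)}}, forms the noncentrality
#' \eqn{\lambda = f^2 n}, and evaluates
#' \eqn{P(F_{1, n-1; \lambda} > F_{crit}(\alpha))} with the noncentral F
#' distribution. No correlation or nonsphericity adjustment is applied.
#'
#' @param eta2_partial Effect size in (0, 1).
#' @param n Number of subjects (>= 2).
#' @param alpha Significance level.
#' @return Power in (0, 1).
#' @examples
#' achieved_power(0.383, n = 16) # >= 0.8
#' @export
achieved_power <- function(eta2_partial, n, alpha = 0.05) {
  if (!is.numeric(eta2_partial) || length(eta2_partial) != 1L ||
      eta2_partial <= 0 || eta2_partial >= 1) {
    abort("`eta2_partial` must lie strictly between 0 and 1.",
          class = "avrecal_domain_error")
  }
  assert_count(n, "n", lower = 2)
  assert_scalar_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  f2 <- eta2_partial / (1 - eta2_partial)
  lambda <- f2 * n
  fcrit <- qf(1 - alpha, 1, n - 1)
  pf(fcrit, 1, n - 1, ncp = lambda, lower.tail = FALSE)
}
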