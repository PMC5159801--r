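test_that("partial eta squared and d_z reproduce their closed forms", {
  expect_equal(partial_eta_sq(8.697, 1, 14), 0.383, tolerance = 5e-4)
  expect_equal(partial_eta_sq(2.449, 1, 14), 0.149, tolerance = 5e-3)
  expect_equal(cohens_dz(5.197, 16), 1.299, tolerance = 5e-4)
  expect_equal(cohens_dz(6.284, 15), 1.623, tolerance = 5e-4)
  expect_equal(cohens_dz(2.132, 15), 0.551, tolerance = 1e-3)
})

test_that("the 2x2 within ANOVA agrees with aov's error-stratified fit", {
  for (seed in c(1, 2, 3)) {
    est <- random_estimates(12, seed)
    mine <- rm_anova_2x2(est)
    d <- dplyr::mutate(est, o = factor(adaptation_order),
                       b = factor(outcome_predicted), s = factor(subject_id))
    fit <- summary(stats::aov(pss_ms ~ o * b + Error(s / (o * b)), data = d))
    ref_f <- c(fit[["Error: s:o"]][[1]]["o", "F value"],
               fit[["Error: s:b"]][[1]]["b", "F value"],
               fit[["Error: s:o:b"]][[1]]["o:b", "F value"])
    expect_equal(mine$F, unname(ref_f), tolerance = 1e-10)
    ref_p <- c(fit[["Error: s:o"]][[1]]["o", "Pr(>F)"],
               fit[["Error: s:b"]][[1]]["b", "Pr(>F)"],
               fit[["Error: s:o:b"]][[1]]["o:b", "Pr(>F)"])
    expect_equal(mine$p, unname(ref_p), tolerance = 1e-10)
    expect_true(all(mine$df1 == 1) && all(mine$df2 == 11))
    expect_true(all(mine$partial_eta_sq >= 0 & mine$partial_eta_sq < 1))
  }
})

test_that("parallel condition effects produce a null interaction", {
  est <- random_estimates(10, 4)
  # force the per-subject interaction contrasts (a2-a1) - (b2-b1) to be
  # exactly mean-centred: the interaction sum of squares is then identically
  # zero while its subject-level error term stays positive
  wide <- tidyr::pivot_wider(
    dplyr::mutate(est, cell = paste0(adaptation_order, outcome_predicted)),
    id_cols = "subject_id", names_from = "cell", values_from = "pss_ms")
  e <- seq(-9, 9, by = 2) # centred per-subject deviations
  wide$`sound-secondFALSE` <- wide$`sound-firstFALSE` +
    (wide$`sound-secondTRUE` - wide$`sound-firstTRUE`) + e
  est2 <- tidyr::pivot_longer(wide, -subject_id, values_to = "pss_ms") |>
    dplyr::mutate(adaptation_order = sub("(TRUE|FALSE)$", "", name),
                  outcome_predicted = grepl("TRUE$", name)) |>
    dplyr::select(subject_id, adaptation_order, outcome_predicted, pss_ms)
  a <- rm_anova_2x2(est2)
  expect_lt(a$F[a$effect == "interaction"], 1e-10)
})

test_that("incomplete designs are rejected with the offending subjects named", {
  est <- random_estimates(5, 1)
  expect_error(rm_anova_2x2(est[-1, ]), "s001", class = "avrecal_data_error")
  expect_error(rm_anova_2x2(random_estimates(2, 1)), class = "avrecal_data_error")
})

test_that("paired t matches the direct formula and handles degenerate input", {
  withr::with_seed(10, {
    x <- rnorm(10, 40, 20)
    y <- rnorm(10, 30, 20)
  })
  res <- paired_t(x, y)
  d <- x - y
  t_direct <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(res$t, t_direct, tolerance = 1e-12)
  expect_equal(res$df, 9)
  expect_equal(res$p_two_tailed, 2 * pt(abs(t_direct), 9, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$d_z, t_direct / sqrt(10), tolerance = 1e-12)
  expect_equal(res$d_av, mean(d) / ((sd(x) + sd(y)) / 2), tolerance = 1e-12)
  expect_equal(sign(res$t), sign(res$mean_diff))

  expect_error(paired_t(x, x), class = "avrecal_degenerate_error")
  same <- one_sample_t(rep(5, 8), mu = 5)
  expect_equal(same$t, 0)
  expect_equal(same$p_two_tailed, 1)
})

test_that("one-sample t matches the direct formula", {
  withr::with_seed(12, x <- rnorm(15, 50, 40))
  res <- one_sample_t(x, mu = 0)
  t_direct <- mean(x) / (sd(x) / sqrt(15))
  expect_equal(res$t, t_direct, tolerance = 1e-12)
  expect_equal(res$d_z, t_direct / sqrt(15), tolerance = 1e-12)
  expect_equal(res$d_av, res$d_z)
})

test_that("interaction F equals squared one-sample t on the double difference", {
  for (seed in 1:25) {
    expect_true(interaction_equals_t(random_estimates(sample(3:30, 1), seed)))
  }
  # explicit two-route check on one cohort, and sensitivity to perturbation
  est <- random_estimates(8, 99)
  f_int <- rm_anova_2x2(est)$F[3]
  wide <- tidyr::pivot_wider(
    dplyr::mutate(est, cell = paste0(adaptation_order, outcome_predicted)),
    id_cols = "subject_id", names_from = "cell", values_from = "pss_ms")
  dd <- (wide$`sound-firstTRUE` - wide$`sound-firstFALSE`) -
    (wide$`sound-secondTRUE` - wide$`sound-secondFALSE`)
  t2 <- (mean(dd) / (sd(dd) / sqrt(length(dd))))^2
  expect_lt(abs(f_int - t2), 1e-9 * max(1, f_int))
  expect_gt(abs(f_int * 1.001 - t2), 1e-9 * max(1, f_int))
})

test_that("achieved power follows the noncentral-F route and is monotone", {
  pw <- achieved_power(0.383, 16, 0.05)
  expect_gte(pw, 0.8)
  # independent evaluation of the same quantity
  f2 <- 0.383 / (1 - 0.383)
  expect_equal(pw, pf(qf(0.95, 1, 15), 1, 15, ncp = f2 * 16, lower.tail = FALSE),
               tolerance = 1e-12)
  # strictly increasing in n, limit 1
  ns <- c(4, 8, 16, 32, 64, 200)
  powers <- vapply(ns, function(n) achieved_power(0.383, n), numeric(1))
  expect_true(all(diff(powers) > 0))
  expect_gt(achieved_power(0.383, 5000), 0.999999)

  expect_error(achieved_power(0, 16), class = "avrecal_domain_error")
  expect_error(achieved_power(1.2, 16), class = "avrecal_domain_error")
  expect_error(achieved_power(0.3, 1), class = "avrecal_config_error")
})

test_that("effect and null generative regimes separate in rejection rates", {
  # Effect regime: 22 ms predicted-pair separation, n = 15 per cohort.
  reps <- 25
  p_pred <- p_unpred <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- population_spec(n_subjects = 15, baseline_bias_ms = 34,
                            adaptation_effect_ms = 22, unpredicted_effect_ms = 0,
                            seed = 7000 + r)
    pop <- make_population(spec)
    fits <- dplyr::bind_rows(lapply(seq_len(nrow(pop)), function(i) {
      tab <- binom_table(pop$alpha_ms[i], pop$sigma_ms[i], pop$scale[i],
                         seed = 90000 + 100 * r + i)
      cbind(pop[i, c("subject_id", "adaptation_order", "outcome_predicted")],
            fit_gaussian(tab, seed = i))
    }))
    wide <- tidyr::pivot_wider(
      dplyr::mutate(fits, cell = paste0(adaptation_order, outcome_predicted)),
      id_cols = "subject_id", names_from = "cell", values_from = "alpha_ms")
    p_pred[r] <- paired_t(wide$`sound-secondTRUE`, wide$`sound-firstTRUE`)$p_two_tailed
    p_unpred[r] <- paired_t(wide$`sound-secondFALSE`, wide$`sound-firstFALSE`)$p_two_tailed
  }
  expect_gte(mean(p_pred < 0.05), 0.70)
  expect_lte(mean(p_unpred < 0.05), 0.15)
})
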