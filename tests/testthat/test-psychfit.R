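test_that("weighted SSE matches hand-computed values", {
  perfect <- model_table(10, 120, 0.8)
  expect_equal(weighted_sse(observer_params(10, 120, 0.8), perfect), 0)

  toy <- tibble::tibble(soa_ms = c(-233, 0, 233), n_presented = c(8, 20, 8),
                        n_simultaneous = c(8, 20, 8) * c(0.1, 0.9, 0.2),
                        weight = c(8, 20, 8))
  expect_equal(weighted_sse(observer_params(0, 100, 0.9), toy), 0.1707,
               tolerance = 5e-4)

  doubled <- dplyr::mutate(toy, n_presented = n_presented * 2,
                           n_simultaneous = n_simultaneous * 2,
                           weight = weight * 2)
  expect_equal(weighted_sse(observer_params(0, 100, 0.9), doubled),
               2 * weighted_sse(observer_params(0, 100, 0.9), toy))

  # zero-presentation rows are dropped from the sum
  padded <- dplyr::bind_rows(toy, tibble::tibble(soa_ms = 500, n_presented = 0,
                                                 n_simultaneous = 0, weight = 0))
  expect_equal(weighted_sse(observer_params(0, 100, 0.9), padded),
               weighted_sse(observer_params(0, 100, 0.9), toy))
})

test_that("noise-free curves are recovered to numerical precision", {
  tab <- model_table(40, 120, 0.8)
  fit <- fit_gaussian(tab)
  expect_equal(fit$alpha_ms, 40, tolerance = 0.1 / 40)
  expect_lt(abs(fit$sigma_ms - 120), 0.1)
  expect_lt(abs(fit$scale - 0.8), 0.001)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("fitted PSS is shift-equivariant and scale-invariant", {
  for (seed in c(2, 5)) {
    tab <- binom_table(15, 130, 0.85, seed = seed)
    base <- fit_gaussian(tab)$alpha_ms
    for (delta in c(-40, 25)) {
      shifted <- dplyr::mutate(tab, soa_ms = soa_ms + delta)
      expect_equal(fit_gaussian(shifted)$alpha_ms, base + delta,
                   tolerance = 1e-4 * max(1, abs(base)))
    }
    scaled <- dplyr::mutate(tab, n_simultaneous = n_simultaneous * 0.6)
    expect_equal(fit_gaussian(scaled)$alpha_ms, base,
                 tolerance = 1e-3 * max(1, abs(base)))
  }
})

test_that("repetition weighting pulls the fit away from noisy extreme SOAs", {
  # corrupt the sparsely-sampled leftmost SOA of an otherwise clean curve
  tab <- model_table(20, 110, 0.8)
  tab$n_simultaneous[1] <- tab$n_presented[1] * 0.85
  weighted <- fit_gaussian(tab)
  flat <- dplyr::mutate(tab, prop = n_simultaneous / n_presented,
                        n_presented = 1, n_simultaneous = prop, weight = 1)
  unweighted <- fit_gaussian(flat[, c("soa_ms", "n_presented", "n_simultaneous", "weight")])
  expect_gt(abs(weighted$alpha_ms - unweighted$alpha_ms), 0.5)
  sse_w <- weighted_sse(as.list(weighted[, c("alpha_ms", "sigma_ms", "scale")]), tab)
  sse_u <- weighted_sse(as.list(unweighted[, c("alpha_ms", "sigma_ms", "scale")]), tab)
  expect_lt(sse_w, sse_u)
})

test_that("the optimizer is at least as good as a dense grid search", {
  withr::with_seed(11, {
    pars <- data.frame(alpha = runif(5, -80, 80), sigma = runif(5, 40, 300),
                       s = runif(5, 0.3, 0.95))
  })
  for (i in seq_len(nrow(pars))) {
    tab <- binom_table(pars$alpha[i], pars$sigma[i], pars$s[i], seed = 100 + i)
    fit <- fit_gaussian(tab)
    expect_lte(fit$sse_weighted, grid_min_sse(tab) + 1e-6)
  }
})

test_that("degenerate and underdetermined tables are rejected with diagnostics", {
  flat <- tibble::tibble(soa_ms = default_grid(), n_presented = default_counts(),
                         n_simultaneous = default_counts() * 0.5,
                         weight = default_counts())
  expect_error(fit_gaussian(flat), class = "avrecal_degenerate_fit")
  expect_error(fit_gaussian(flat), "0.500")

  few <- model_table(0, 100, 0.8)[5:8, ]
  expect_error(fit_gaussian(few), class = "avrecal_data_error")
})

test_that("binomial sampling leaves the mean recovered PSS unbiased", {
  rec <- recover_pss(23, n_observers = 500, between_subject_sd_ms = 0, seed = 61)
  expect_equal(mean(rec$alpha_ms), 23, tolerance = 2 / 23)
})

test_that("cohort fitting yields one labelled fit per subject and condition", {
  cfg <- design_config()
  spec <- population_spec(n_subjects = 15, seed = 2)
  sim <- simulate_cohort(cfg, spec, seed = 41)
  fits <- fit_all(sim$trials, seed = 1)
  expect_equal(nrow(fits), 60)
  expect_setequal(unique(fits$condition),
                  c("sound-first/predicted", "sound-first/unpredicted",
                    "sound-second/predicted", "sound-second/unpredicted"))
  expect_true(all(table(fits$subject_id) == 4))
  expect_true(all(fits$sigma_ms > 0))
  expect_true(all(fits$r_squared <= 1))
  # realistic binomial cohorts land in the expected goodness-of-fit band
  expect_gt(mean(fits$r_squared), 0.6)
  expect_lt(mean(fits$r_squared), 0.95)

  # fitting is deterministic given data and restart seed
  expect_identical(fits, fit_all(sim$trials, seed = 1))

  # a subject missing a condition is flagged incomplete
  drop <- with(sim$trials, subject_id == "s001" & phase == "test" &
                 adaptation_order == "sound-first" & outcome_predicted %in% TRUE)
  expect_warning(pf2 <- fit_all(sim$trials[!drop, ], seed = 1), "incomplete")
  expect_true(all(pf2$incomplete[pf2$subject_id == "s001"]))
  expect_false(any(pf2$incomplete[pf2$subject_id != "s001"]))
})

test_that("subject exclusion flags rule violations and is idempotent", {
  cfg <- design_config()
  sim <- simulate_cohort(cfg, population_spec(n_subjects = 6, seed = 3), seed = 55)
  fits <- fit_all(sim$trials, seed = 1)

  clean <- apply_exclusion(fits, exclusion_rule())
  expect_equal(nrow(clean$excluded), 0)
  expect_identical(clean$kept, fits)

  # inject one subject with hopeless temporal sensitivity
  bad <- fits
  bad$sigma_ms[bad$subject_id == "s003"][1] <- 1000
  res <- apply_exclusion(bad, exclusion_rule(max_sigma_ms = 400))
  expect_equal(res$excluded$subject_id, "s003")
  expect_match(res$excluded$reasons, "sigma_ms")
  expect_false("s003" %in% res$kept$subject_id)

  # idempotence: excluding the kept set again changes nothing
  again <- apply_exclusion(res$kept, exclusion_rule(max_sigma_ms = 400))
  expect_identical(again$kept, res$kept)
  expect_equal(nrow(again$excluded), 0)
})
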