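# Fixtures and independent oracles shared across tests. Everything is
# generated in code; no data files.

default_grid <- function() c(-233, -166, -133, -100, -66, -33, 0, 33, 66, 100, 133, 166, 233)
default_counts <- function() c(8, 10, 12, 14, 16, 18, 20, 18, 16, 14, 12, 10, 8)

# Scaled-Gaussian evaluated independently of the package (oracle formula).
oracle_prob <- function(alpha, sigma, s, soa) s * exp(-(soa - alpha)^2 / (2 * sigma^2))

# Noise-free response table whose proportions lie exactly on the curve.
model_table <- function(alpha, sigma, s, grid = default_grid(),
                        counts = default_counts()) {
  p <- oracle_prob(alpha, sigma, s, grid)
  tibble::tibble(soa_ms = grid, n_presented = counts,
                 n_simultaneous = counts * p, weight = counts)
}

# Binomial-noise response table.
binom_table <- function(alpha, sigma, s, seed, grid = default_grid(),
                        counts = default_counts()) {
  p <- oracle_prob(alpha, sigma, s, grid)
  withr::with_seed(seed, {
    tibble::tibble(soa_ms = grid, n_presented = counts,
                   n_simultaneous = rbinom(length(grid), counts, p),
                   weight = counts)
  })
}

# Brute-force minimum weighted SSE over a dense parameter grid, written from
# the loss definition (independent of the package's optimizer). For each
# (alpha, sigma) the SSE is a quadratic in s, evaluated on the full s grid via
# its precomputed coefficients.
grid_min_sse <- function(tab,
                         alpha_grid = seq(-100, 100, by = 1),
                         sigma_grid = seq(20, 400, by = 2),
                         s_grid = seq(0.1, 1, by = 0.01)) {
  tab <- tab[tab$n_presented > 0, ]
  prop <- tab$n_simultaneous / tab$n_presented
  w <- tab$n_presented
  soa <- tab$soa_ms
  par <- expand.grid(alpha = alpha_grid, sigma = sigma_grid)
  g <- exp(-(outer(par$alpha, soa, `-`))^2 / (2 * par$sigma^2))
  a_const <- sum(w * prop^2)
  b <- as.vector(g %*% (w * prop))
  c_ <- as.vector((g * g) %*% w)
  best <- Inf
  for (s in s_grid) best <- min(best, min(a_const - 2 * s * b + s * s * c_))
  best
}

# Random complete 2x2 within-subject estimate table.
random_estimates <- function(n_subjects, seed) {
  withr::with_seed(seed, {
    tidyr::crossing(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                    adaptation_order = c("sound-first", "sound-second"),
                    outcome_predicted = c(TRUE, FALSE)) |>
      dplyr::mutate(pss_ms = rnorm(n_subjects * 4, 30, 25))
  })
}
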