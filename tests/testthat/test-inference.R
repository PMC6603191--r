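truth_theta <- c(alpha0 = 0.363, alpha_b = 0.388, beta_b = 0.031,
                 delta = 0.617)
fixed_mf <- list(beta0 = 0.011, a_plus_c = 0.034, sd = 0.1)

# zero-noise dataset over three regions, generated from the modulated-field
# parameter set
three_region_data <- function(doses = seq(0, 10, by = 0.5)) {
  te <- ago_lit$modulated
  rbind(
    generate_dose_response(te, ago$nte, half_field, doses = doses,
                           noise_sd = 0),
    generate_dose_response(te, ago$nte, unif_field, doses = doses,
                           noise_sd = 0))
}

test_that("coefficient of determination matches hand-computed values", {
  expect_equal(r_squared(c(0.5, 0.1), c(0.5, 0.1)), 1)
  expect_equal(r_squared(c(0.5, 0.1), c(0.4, 0.1)), 0.875)
  obs <- c(0.6, 0.3, 0.1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_error(r_squared(c(0.2, 0.2), c(0.1, 0.3)), "zero variance")
  # -ln S scale option
  expect_equal(r_squared(c(0.5, 0.1), c(0.5, 0.1), scale = "neglog"), 1)
})

test_that("reduced chi-squared matches hand-computed values", {
  expect_equal(chi_squared(c(0.5, 0.1), c(0.5, 0.1), c(0.05, 0.02)), 0)
  expect_equal(chi_squared(c(0.5, 0.1), c(0.4, 0.1), c(0.05, 0.02)), 2.0)
  x2 <- chi_squared(c(0.5, 0.1), c(0.45, 0.12), c(0.05, 0.02))
  expect_equal(chi_squared(c(0.5, 0.1), c(0.45, 0.12), 3 * c(0.05, 0.02)),
               x2 / 9, tolerance = 1e-12)
  expect_warning(
    x2b <- chi_squared(c(0.5, 0.1), c(0.4, 0.1), c(0.05, 0)), "excluded")
  expect_equal(x2b, 4)
  expect_error(chi_squared(0.5, 0.4, 0), "all standard deviations")
})

test_that("log-likelihood is additive, order-invariant and peaks at truth", {
  data <- three_region_data(doses = c(0, 1, 2, 4, 8))
  ll <- log_likelihood(truth_theta, fixed_mf, data, half_field)
  # zero residuals: pure normalization term
  expect_equal(ll, sum(dnorm(0, 0, 0.1, log = TRUE)) * nrow(data))
  # permutation invariance
  perm <- data[sample(nrow(data)), ]
  expect_equal(log_likelihood(truth_theta, fixed_mf, perm, half_field), ll)
  # duplicated record contributes exactly twice
  one <- data[7, , drop = FALSE]
  expect_equal(log_likelihood(truth_theta, fixed_mf, rbind(one, one),
                              half_field),
               2 * log_likelihood(truth_theta, fixed_mf, one, half_field))
  # any single-parameter perturbation lowers the likelihood
  for (p in names(truth_theta)) {
    th <- truth_theta; th[p] <- th[p] * 1.2 + 0.01
    expect_lt(log_likelihood(th, fixed_mf, data, half_field), ll)
  }
  bad <- data; bad$surviving_fraction[1] <- 0
  expect_error(log_likelihood(truth_theta, fixed_mf, bad, half_field),
               "surviving fractions")
})

test_that("chains are exactly reproducible given a seed", {
  data <- three_region_data(doses = c(0, 2, 4, 8))
  p1 <- run_mcmc(data, fixed_mf, half_field, n_draws = 600, n_burn = 200,
                 seed = 7)
  p2 <- run_mcmc(data, fixed_mf, half_field, n_draws = 600, n_burn = 200,
                 seed = 7)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_mcmc(data, fixed_mf, half_field, n_draws = 600, n_burn = 200,
                 seed = 8)
  expect_false(identical(p1$draws, p3$draws))
  expect_true(all(p1$acceptance_rate > 0 & p1$acceptance_rate < 1))
  expect_true(all(p1$draws >= 0))
})

test_that("prior-only chain reproduces the truncated-normal prior mean", {
  pr <- prior_spec(mean = c(alpha0 = 0.4, alpha_b = 0.3, beta_b = 0.05,
                            delta = 0.6),
                   sd = c(alpha0 = 0.2, alpha_b = 0.3, beta_b = 0.05,
                          delta = 0.9))
  empty <- data.frame(region = character(), dose_Gy = numeric(),
                      surviving_fraction = numeric(), sd = numeric())
  post <- run_mcmc(empty, fixed_mf, half_field, priors = pr,
                   n_draws = 24000, n_burn = 4000, seed = 3)
  # closed-form mean of a normal truncated at 0 (independent oracle)
  tn_mean <- function(m, s) {
    z <- -m / s
    m + s * dnorm(z) / (1 - pnorm(z))
  }
  for (p in colnames(post$draws)) {
    mc_se <- sd(post$draws[, p]) / sqrt(200)  # generous ESS guess
    expect_equal(mean(post$draws[, p]), tn_mean(pr$mean[[p]], pr$sd[[p]]),
                 tolerance = max(5 * mc_se, 0.02 * pr$mean[[p]] + 1e-4))
  }
})

test_that("posterior concentrates on dense low-noise synthetic data", {
  te <- ago_lit$modulated
  # essentially noise-free measurements: tiny likelihood sd on -ln S
  fixed <- list(beta0 = 0.011, a_plus_c = 0.034, sd = 0.0025)
  data <- three_region_data(doses = seq(0, 10, by = 0.25))
  post <- run_mcmc(data, fixed, half_field, n_draws = 6000, n_burn = 2000,
                   seed = 5)
  m <- colMeans(post$draws); s <- apply(post$draws, 2, sd)
  for (p in names(truth_theta)) {
    expect_lt(s[[p]], 0.05 * truth_theta[[p]])
    expect_lt(abs(m[[p]] - truth_theta[[p]]), 3 * s[[p]] + 0.01 * truth_theta[[p]])
  }
})

test_that("posterior summary reports parameters, GoF and a coherent band", {
  data <- three_region_data(doses = c(0, 1, 2, 4, 6, 8, 10))
  post <- run_mcmc(data, fixed_mf, half_field, n_draws = 2000, n_burn = 500,
                   seed = 11)
  smry <- posterior_summary(post, data, fixed_mf, half_field,
                            dose_grid = seq(0, 10, by = 1))
  expect_setequal(smry$params$parameter, names(truth_theta))
  expect_true(all(smry$band$lower <= smry$band$mean + 1e-12))
  expect_true(all(smry$band$mean <= smry$band$upper + 1e-12))
  expect_gt(smry$r_squared, 0.99)  # zero-noise data, converged chain
  # degenerate chain: band collapses onto the mean curve
  deg <- post
  deg$draws <- matrix(rep(truth_theta, each = 200), 200, 4,
                      dimnames = list(NULL, names(truth_theta)))
  smry_deg <- posterior_summary(deg, data, fixed_mf, half_field,
                                dose_grid = c(0, 2, 4))
  expect_equal(smry_deg$band$lower, smry_deg$band$upper, tolerance = 1e-12)
  expect_error(posterior_summary(
    structure(list(draws = post$draws[1:50, ]), class = "imk_posterior"),
    data, fixed_mf, half_field), "at least 100")
})

test_that("predictive band widens with the data uncertainty", {
  data <- three_region_data(doses = c(0, 1, 2, 4, 6, 8, 10))
  width <- function(sd_val) {
    fixed <- list(beta0 = 0.011, a_plus_c = 0.034, sd = sd_val)
    post <- run_mcmc(data, fixed, half_field, n_draws = 2000, n_burn = 500,
                     seed = 13)
    smry <- posterior_summary(post, data, fixed, half_field,
                              dose_grid = c(2, 4, 6))
    mean(smry$band$upper - smry$band$lower)
  }
  expect_gt(width(0.2), width(0.05))
})

test_that("the 95.4% band covers the generating curve on noisy data", {
  te <- ago_lit$modulated
  dose_grid <- c(0, 1, 2, 4, 6, 8, 10)
  hits <- 0; total <- 0
  for (seed in 1:10) {
    data <- rbind(
      generate_dose_response(te, ago$nte, half_field, doses = dose_grid,
                             noise_sd = 0.1, seed = seed),
      generate_dose_response(te, ago$nte, unif_field, doses = dose_grid,
                             noise_sd = 0.1, seed = seed + 1000))
    post <- run_mcmc(data, fixed_mf, half_field, n_draws = 2500, n_burn = 800,
                     seed = seed)
    smry <- posterior_summary(post, data, fixed_mf, half_field,
                              dose_grid = dose_grid)
    for (rg in unique(smry$band$region)) {
      b <- smry$band[smry$band$region == rg, ]
      s_true <- predict_survival(truth_theta, fixed_mf, half_field,
                                 b$dose_Gy, rg)
      hits <- hits + sum(s_true >= b$lower - 1e-12 &
                           s_true <= b$upper + 1e-12)
      total <- total + nrow(b)
    }
  }
  expect_gte(hits / total, 0.85)
})

test_that("chi-squared on correctly-modelled noisy data is near one", {
  te <- ago_lit$modulated
  x2s <- vapply(1:10, function(seed) {
    data <- rbind(
      generate_dose_response(te, ago$nte, half_field,
                             doses = seq(0.5, 10, by = 0.5),
                             noise_sd = 0.1, seed = seed),
      generate_dose_response(te, ago$nte, unif_field,
                             doses = seq(0.5, 10, by = 0.5),
                             noise_sd = 0.1, seed = seed + 500))
    cal <- predict_survival(truth_theta, fixed_mf, half_field, data$dose_Gy,
                            as.character(data$region))
    chi_squared(data$surviving_fraction, cal,
                data$surviving_fraction * data$sd)
  }, numeric(1))
  expect_gte(median(x2s), 0.5)
  expect_lte(median(x2s), 1.7)
})
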