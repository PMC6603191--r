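test_that("noiseless dose-response records equal the model predictions", {
  ds <- generate_dose_response(ago$uniform, ago$nte, unif_field, noise_sd = 0)
  expect_setequal(unique(ds$region), "uniform")
  th <- c(alpha0 = ago$uniform$alpha0, alpha_b = ago$nte$alpha_b,
          beta_b = ago$nte$beta_b, delta = ago$nte$delta)
  expect_equal(ds$surviving_fraction,
               predict_survival(th, list(beta0 = ago$uniform$beta0),
                                unif_field, ds$dose_Gy, ds$region),
               tolerance = 1e-12)
  # 4 Gy acute uniform: targeted effects dominate, S_T ~ 0.043 times the
  # bystander factor
  s4 <- ds$surviving_fraction[ds$dose_Gy == 4]
  expect_equal(s4, 0.0433541 * exp(-w_nte(ago$nte, unif_field, 4, "uniform")),
               tolerance = 1e-4)
  expect_equal(s4, 0.043, tolerance = 0.1)
})

test_that("generation is reproducible by seed with stable means", {
  d1 <- generate_dose_response(ago$modulated, ago$nte, half_field,
                               noise_sd = 0.1, seed = 42)
  d2 <- generate_dose_response(ago$modulated, ago$nte, half_field,
                               noise_sd = 0.1, seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_dose_response(ago$modulated, ago$nte, half_field,
                               noise_sd = 0.1, seed = 43)
  expect_false(identical(d1$surviving_fraction, d3$surviving_fraction))
  expect_error(generate_dose_response(ago$modulated, ago$nte, half_field,
                                      noise_sd = 0.1), "seed")
  # all survival in (0, 1]; zero-dose controls exactly 1
  expect_true(all(d1$surviving_fraction > 0 & d1$surviving_fraction <= 1))
  expect_true(all(d1$surviving_fraction[d1$dose_Gy == 0] == 1))
})

test_that("noise on -ln S has the configured standard deviation", {
  w_at_4 <- vapply(1:400, function(seed) {
    ds <- generate_dose_response(ago$uniform, ago$nte, unif_field,
                                 doses = 4, noise_sd = 0.1, seed = seed)
    -log(ds$surviving_fraction)
  }, numeric(1))
  expect_equal(sd(w_at_4), 0.1, tolerance = 0.1)
})

test_that("recovery-curve generator matches its closed form and round-trips", {
  # no repair: flat noiseless curve
  flat <- generate_recovery_curve(te_params(0.363, 0.011, 0), ago$nte,
                                  half_field, region = "in_field",
                                  method = "closed_form")
  expect_equal(diff(range(flat$surviving_fraction)), 0, tolerance = 1e-12)
  # with repair: monotone rise to a plateau (increments vanish at large tau)
  crv <- generate_recovery_curve(ago$uniform, ago$nte, unif_field,
                                 method = "closed_form")
  expect_true(all(diff(crv$surviving_fraction) >= 0))
  expect_gt(crv$surviving_fraction[5] / crv$surviving_fraction[1], 1.5)
  # discretized and closed-form routes agree
  taus <- c(0, 0.5, 4, 24)
  a <- generate_recovery_curve(ago$uniform, ago$nte, unif_field, taus = taus,
                               method = "discretized")
  b <- generate_recovery_curve(ago$uniform, ago$nte, unif_field, taus = taus,
                               method = "closed_form")
  expect_equal(a$surviving_fraction, b$surviving_fraction, tolerance = 1e-5)
  # module round trip: estimators recover the generating values
  est <- estimate_a_plus_c(
    generate_recovery_curve(ago$uniform, ago$nte, unif_field,
                            taus = c(0, 1e-4, 0.25, 1, 4, 24, 48),
                            method = "closed_form"), step = 1e-4)
  expect_equal(est$a_plus_c, 1.684, tolerance = 0.01)
  expect_equal(est$beta0, 0.081, tolerance = 1e-6)
})

test_that("dose-rate regimen datasets expose repair-dependent protraction", {
  # no repair: identical survival across regimens
  ds0 <- generate_doserate_regimens(ago$modulated, ago$nte, half_field,
                                    noise_sd = 0)
  s_if <- ds0$surviving_fraction[ds0$region == "in_field"]
  expect_equal(diff(range(s_if)), 0, tolerance = 1e-9)
  # active repair: survival rises as the average dose rate falls
  ds1 <- generate_doserate_regimens(ago$uniform, ago$nte, unif_field,
                                    noise_sd = 0)
  expect_true(all(diff(ds1$surviving_fraction) > 0))
  expect_true(all(ds1$dose_Gy == 4))
  # out-of-field survival is fractionation-independent
  s_of <- ds0$surviving_fraction[ds0$region == "out_of_field"]
  expect_equal(diff(range(s_of)), 0, tolerance = 1e-12)
})
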