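# Double-Hill elastance curves and the elastance-pressure coupling.

# direct transcription of the double-Hill curve, kept independent of the
# package's vectorized implementation
hill_oracle <- function(t, T, e_max, e_min, m1, m2, tau1f, tau2f) {
  n <- (e_max - e_min) / 2
  tau1 <- tau1f * T
  tau2 <- tau2f * T
  x1 <- (t / tau1)^m1
  x2 <- (t / tau2)^m2
  n * (x1 / (1 + x1)) * (1 / (1 + x2)) + e_min
}

test_that("normalized LV elastance matches the closed-form curve", {
  lv <- lv_elastance_params()

  # at onset the ascending Hill term vanishes, leaving exactly E_min
  expect_identical(normalized_elastance(0, 1, lv), 0.06)

  # at t = tau1 the ascending term is exactly 1/2; the descending term is
  # 1/(1 + (tau1/tau2)^m2), within 1e-6 of 1 for the steep LV relaxation
  at_tau1 <- normalized_elastance(0.269, 1, lv)
  h2 <- 1 / (1 + (0.269 / 0.452)^27.4)
  expect_equal(at_tau1, 1.02 * 0.5 * h2 + 0.06, tolerance = 1e-12)
  expect_equal(at_tau1, 0.57, tolerance = 1e-3)

  # just before the cycle ends the curve has relaxed back to E_min
  expect_equal(normalized_elastance(1 - 1e-9, 1, lv), 0.06, tolerance = 1e-4)

  # random times agree with the direct transcription
  set.seed(42)
  ts <- runif(50, 0, 2)
  expect_equal(normalized_elastance(ts, 0.857, lv),
               hill_oracle(ts %% 0.857, 0.857, 2.1, 0.06, 1.32, 27.4,
                           0.269, 0.452),
               tolerance = 1e-12)
})

test_that("elastance curve is periodic and bounded below by E_min", {
  lv <- lv_elastance_params()
  la <- la_elastance_params()
  tg <- seq(0, 0.999, length.out = 600)
  for (p in list(lv, la)) {
    e <- normalized_elastance(tg, 1, p)
    expect_true(all(e >= p$e_min - 1e-15))
    expect_equal(min(e), p$e_min, tolerance = 1e-9)
    expect_lt(max(abs(normalized_elastance(tg + 1, 1, p) - e)), 1e-12)
  }
})

test_that("LA curve is the LV-shaped curve shifted by 0.85 T", {
  la <- la_elastance_params()
  unshifted <- elastance_params(e_max = la$e_max, e_min = la$e_min,
                                m1 = la$m1, m2 = la$m2,
                                tau1_frac = la$tau1_frac,
                                tau2_frac = la$tau2_frac, onset_frac = 0)
  T <- 0.857
  tg <- seq(0, T, length.out = 400)
  expect_equal(normalized_elastance(tg, T, la),
               normalized_elastance(tg - 0.85 * T, T, unshifted),
               tolerance = 1e-12)
})

test_that("scaling strategies behave as documented", {
  T <- 1
  lv_cfg <- chamber_config(lv_elastance_params(), label = "LV")
  tg <- seq(0, T, length.out = 2000)

  # literal: identical to the normalized curve read as mmHg/mL
  expect_equal(chamber_elastance(tg, T, lv_cfg, "literal-eq3"),
               normalized_elastance(tg, T, lv_cfg$params))

  # emax-scaled: composition with E_max; at onset 2.1 * 0.06 = 0.126
  expect_equal(chamber_elastance(0, T, lv_cfg, "emax-scaled"), 0.126)

  # peak-rescaled attains e_max and e_min exactly
  e <- chamber_elastance(tg, T, lv_cfg, "peak-rescaled")
  expect_equal(max(e), 2.1, tolerance = 1e-6)
  expect_equal(min(e), 0.06, tolerance = 1e-9)

  # LA minimum falls at the onset instant for every strategy
  la_cfg <- chamber_config(la_elastance_params(), label = "LA")
  for (s in c("literal-eq3", "emax-scaled", "peak-rescaled")) {
    curve <- chamber_elastance(tg, T, la_cfg, s)
    expect_equal(chamber_elastance(0.85 * T, T, la_cfg, s), min(curve),
                 tolerance = 1e-6)
  }

  # degenerate flat chamber: e_max = e_min collapses to a constant
  flat <- chamber_config(elastance_params(e_max = 0.06, e_min = 0.06,
                                          m1 = 1.32, m2 = 27.4,
                                          tau1_frac = 0.269,
                                          tau2_frac = 0.452), label = "LV")
  expect_equal(chamber_elastance(tg, T, flat, "peak-rescaled"),
               rep(0.06, length(tg)))

  expect_error(chamber_elastance(0, T, lv_cfg, "no-such-strategy"))
})

test_that("parameter validation rejects non-physical values", {
  expect_error(elastance_params(0.05, 0.06, 1, 1, 0.2, 0.4), "e_max")
  expect_error(elastance_params(2, 0.06, -1, 1, 0.2, 0.4), "m1")
  expect_error(elastance_params(2, 0.06, 1, 1, 0.5, 0.4), "tau1")
  expect_error(normalized_elastance(0, -1, lv_elastance_params()), "positive")
})

test_that("chamber pressure is the elastance relation and linear in volume", {
  expect_identical(chamber_pressure(50, 1.5, 50), 0)
  expect_identical(chamber_pressure(60, 1.0, 10), 50)
  expect_equal(chamber_pressure(110, 1.43, 10), 143)
  # linearity in (v - v0)
  v0 <- 12
  for (x in c(5, 20, 80)) {
    expect_equal(chamber_pressure(v0 + 2 * x, 1.7, v0) -
                   chamber_pressure(v0, 1.7, v0),
                 2 * (chamber_pressure(v0 + x, 1.7, v0) -
                        chamber_pressure(v0, 1.7, v0)))
  }
  expect_error(chamber_pressure(50, -1), "non-negative")
})
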