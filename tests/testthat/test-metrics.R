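# PV-loop stroke work, transvalvular gradients, RMS error and the
# counterfactual workload breakdown.

test_that("PV-loop area matches closed-form rectangle and ellipse oracles", {
  # rectangle traversed as a loop: area (110-10) * (120-50) = 7000
  p <- c(10, 110, 110, 10, 10)
  v <- c(50, 50, 120, 120, 50)
  w <- pv_workload(p, v)
  expect_equal(unname(w["mmHg_mL"]), 7000)
  expect_equal(unname(w["J"]), 7000 * 1.33322e-4)

  # orientation invariance
  w_rev <- pv_workload(rev(p), rev(v))
  expect_equal(w, w_rev)

  # dense ellipse loop: shoelace area within 0.1% of pi a b
  th <- seq(0, 2 * pi, length.out = 2001)
  a <- 45; b <- 35
  pe <- 80 + b * sin(th)
  ve <- 110 + a * cos(th)
  expect_equal(unname(pv_workload(pe, ve)["mmHg_mL"]), pi * a * b,
               tolerance = 1e-3)

  # open loops are rejected
  expect_error(pv_workload(c(10, 110, 110, 60), c(50, 50, 120, 120)),
               "not closed")
})

test_that("transvalvular gradients match a constructed half-sine oracle", {
  r <- healthy_steady_result()
  fake <- r
  n <- nrow(fake$waveforms)
  # constant gradient during a synthetic ejection window
  open <- seq_len(n) <= n / 3
  fake$waveforms$q_av <- ifelse(open, 200, 0)
  fake$waveforms$p_lv <- ifelse(open, fake$waveforms$p_cao + 12,
                                fake$waveforms$p_cao - 30)
  g <- transvalvular_gradients(fake)
  expect_equal(unname(g["mean"]), 12)
  expect_equal(unname(g["max"]), 12)

  # half-sine gradient of amplitude G: mean 2G/pi, max G
  G <- 40
  idx <- which(open)
  fake$waveforms$p_lv[idx] <- fake$waveforms$p_cao[idx] +
    G * sin(pi * (seq_along(idx) - 1) / (length(idx) - 1))
  g2 <- transvalvular_gradients(fake)
  expect_equal(unname(g2["max"]), G, tolerance = 1e-6)
  expect_equal(unname(g2["mean"]), 2 * G / pi, tolerance = 1e-2)

  # a valve that never opens is an error
  fake$waveforms$q_av <- 0
  expect_error(transvalvular_gradients(fake), "ejection")
})

test_that("opening the aortic orifice lowers the mean gradient", {
  state <- NULL
  grads <- vapply(c(0.58, 1.75), function(eoa) {
    m <- lpm_model(make_patient(eoa_av = eoa, sv = 50, sbp = 130, dbp = 70))
    r <- simulate_lpm(m, init = state)
    state <<- r$state
    transvalvular_gradients(r)["mean"]
  }, numeric(1))
  expect_gt(grads[1], grads[2])
  expect_gt(grads[1], 15)  # severe stenosis carries a large gradient
  expect_lt(grads[2], 15)
})

test_that("rms error behaves as an L2 distance on a common grid", {
  x <- seq(0, 1, length.out = 500)
  expect_identical(rms_error(x, x), 0)
  expect_equal(rms_error(x + 5, x), 5)
  A <- 17
  s <- A * sin(2 * pi * seq(0, 1 - 1e-9, length.out = 4000))
  expect_equal(rms_error(s, rep(0, 4000)), A / sqrt(2), tolerance = 1e-3)
  expect_error(rms_error(1:5, 1:6), "length")

  # resampling puts an irregular tracing on a uniform grid
  t_irr <- sort(runif(80, 0, 1))
  rs <- resample_waveform(t_irr, sin(t_irr), n = 64)
  expect_identical(nrow(rs), 64L)
  expect_equal(rs$value, sin(rs$time), tolerance = 1e-2)
})

test_that("workload rises with regurgitant orifice at fixed forward targets", {
  ws <- vapply(c(0.1, 0.25), function(reoa) {
    rep <- calibrate_full(make_patient(eoa_av = 1.5, eoa_mr = reoa,
                                       sbp = 120, dbp = 70, sv = 55))
    unname(lv_workload(rep$result)["mmHg_mL"])
  }, numeric(1))
  expect_gt(ws[2], ws[1])
})

test_that("a disease-free patient has an empty, near-zero breakdown", {
  bd <- workload_breakdown(make_patient())
  expect_identical(nrow(bd$table), 0L)

  # forcing the constituents anyway: correcting an already-normal valve
  # changes nothing, so the contributions are ~0
  bd2 <- workload_breakdown(make_patient(), constituents = c("AS", "MS"))
  expect_true(all(abs(bd2$table$percent) < 1))
  expect_error(workload_breakdown(make_patient(), constituents = "XX"),
               "unknown")
})

test_that("severe-AS-with-MR breakdown ranks MR above AS", {
  rep <- calibrate_full(make_severe_combined_patient())
  bd <- workload_breakdown(rep)
  tab <- bd$table
  expect_setequal(tab$constituent, c("AS", "AR", "MR"))
  expect_true(all(is.na(tab$error)))
  mr <- tab$percent[tab$constituent == "MR"]
  as_ <- tab$percent[tab$constituent == "AS"]
  ar <- tab$percent[tab$constituent == "AR"]
  expect_gt(mr, as_)     # mitral regurgitation dominates this disease mix
  expect_gt(as_, ar)
  expect_gt(mr, 20)
  expect_lt(abs(ar), 12) # mild AR contributes little

  # correcting a leak never makes the counterfactual workload exceed the
  # diseased one at fixed targets
  expect_true(all(tab$workload_mmHg_mL[tab$constituent %in% c("AR", "MR")]
                  <= bd$baseline_workload * 1.05))

  # convention flag: increase = reduction mapped through the ratio
  bd_inc <- workload_breakdown(rep, convention = "increase")
  w_cf <- bd_inc$table$workload_mmHg_mL[bd_inc$table$constituent == "MR"]
  red <- 100 * (bd$baseline_workload - w_cf) / bd$baseline_workload
  inc <- 100 * (bd$baseline_workload - w_cf) / w_cf
  expect_equal(bd$table$percent[tab$constituent == "MR"], red,
               tolerance = 0.2)
  expect_equal(bd_inc$table$percent[bd_inc$table$constituent == "MR"], inc,
               tolerance = 0.5)
})

test_that("hemodynamic metrics are internally consistent for stenosis", {
  rep <- calibrate_full(make_patient(eoa_av = 0.6, sv = 50, sbp = 125,
                                     dbp = 70))
  m <- hemodynamic_metrics(rep$result)
  expect_gte(m$max_av_gradient, m$mean_av_gradient)
  expect_gt(m$mean_av_gradient, 0)
  expect_gt(m$peak_p_lv, m$peak_p_ao)  # stenosis: LV exceeds aorta
  expect_gt(m$ef, 0)
  expect_lte(m$ef, 1)
  expect_equal(m$forward_sv, 50, tolerance = 0.1)
  expect_equal(m$lv_workload_J, m$lv_workload_mmHg_mL * 1.33322e-4)
})
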