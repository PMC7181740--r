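# The assembled network: pulmonary source, ODE right-hand side, steady-state
# integration and its invariants.

test_that("pulmonary inflow is a rectified sine with the analytic mean", {
  q <- 400; t_ee <- 0.3; T <- 0.857
  expect_equal(pulmonary_inflow(t_ee / 2, q, t_ee, T), q)
  expect_identical(pulmonary_inflow((t_ee + T) / 2, q, t_ee, T), 0)
  expect_equal(pulmonary_inflow(T + t_ee / 2, q, t_ee, T), q)  # periodic
  # cycle mean equals q * 2 t_ee / (pi T)
  tg <- seq(0, T, length.out = 200001)[-1]
  expect_equal(mean(pulmonary_inflow(tg, q, t_ee, T)),
               q * 2 * t_ee / (pi * T), tolerance = 1e-4)
  expect_error(pulmonary_inflow(0.1, q, 1.2, T), "t_ee")
})

test_that("the equilibrium state is a fixed point of the network", {
  # flat chambers at E_min, volumes placed so both chamber pressures equal
  # the venous sink pressure, all capacitors at the sink pressure, no source
  flat <- elastance_params(e_max = 0.06, e_min = 0.06, m1 = 1.32, m2 = 27.4,
                           tau1_frac = 0.269, tau2_frac = 0.452)
  p <- make_patient()
  model <- lpm_model(p, lv = chamber_config(flat, label = "LV"),
                     la = chamber_config(flat, label = "LA"))
  model$q_mpv <- 0
  p_cv0 <- model$params$p_cv0
  y <- initial_state(v_lv = p_cv0 / 0.06, v_la = p_cv0 / 0.06)
  y[c("p_cao", "p_csac", "p_cpa", "p_cpvc")] <- p_cv0
  f <- assemble_odes(model)
  expect_lt(max(abs(f(0.4, y))), 1e-10)
})

test_that("without a source, flows decay toward zero", {
  model <- lpm_model(make_patient())
  model$q_mpv <- 0
  r <- suppressWarnings(
    simulate_lpm(model, max_cycles = 80, allow_unsteady = TRUE))
  first <- r$summary$sv_av[1]
  last <- utils::tail(r$summary$sv_av, 1)
  expect_lt(last, 2)
  expect_true(first > last || first < 1e-6)
})

test_that("healthy defaults reach a periodic steady state with closed cycles", {
  r <- healthy_steady_result()
  expect_true(r$steady)
  expect_equal(forward_sv_of(r), 70, tolerance = 1)  # q_mpv not yet calibrated

  wf <- r$waveforms
  n <- nrow(wf)

  # chamber volume conservation over the steady cycle (< 0.5% of EDV)
  expect_lt(abs(wf$v_lv[n] - wf$v_lv[1]), 0.005 * max(wf$v_lv))
  expect_lt(abs(wf$v_la[n] - wf$v_la[1]), 0.005 * max(wf$v_la))

  # valve flows are non-negative at every output sample
  expect_true(all(wf$q_av >= 0))
  expect_true(all(wf$q_mv >= 0))

  # regurgitant branches are absent: identically zero flow
  expect_true(all(wf$q_ar == 0))
  expect_true(all(wf$q_mr == 0))

  # node continuity: cycle-mean aortic-valve net inflow equals the
  # cycle-mean total systemic outflow (upper + lower branches) within 1%
  T <- wf$time_s[n]
  q_in <- r$forward_sv / T   # q_ar is absent here
  expect_equal(r$mean_q_systemic, q_in, tolerance = 0.01)
  params <- circulation_params()
  q_lower <- mean((wf$p_j - wf$p_csac) / (params$r_pda + params$r_sa))
  expect_equal(r$mean_q_ub + q_lower, q_in, tolerance = 0.015)
})

test_that("steady state is idempotent: restarting from it converges at once", {
  r <- healthy_steady_result()
  model <- lpm_model(make_patient())
  r2 <- simulate_lpm(model, init = r$state, max_cycles = 30)
  expect_true(r2$steady)
  expect_lte(r2$cycles_run, 7)
  expect_equal(r2$forward_sv, r$forward_sv, tolerance = 1e-3)
})

test_that("degenerate compliance raises an error rather than returning NaN", {
  model <- lpm_model(make_patient())
  model$params$c_ao <- 1e-9
  expect_error(simulate_lpm(model, max_cycles = 30),
               "degenerate|steady")
})

test_that("peak LV pressure and workload fall as the aortic orifice opens", {
  eoas <- c(0.5, 1.0, 1.5, 2.0)
  peaks <- numeric(length(eoas))
  areas <- numeric(length(eoas))
  state <- NULL
  for (i in seq_along(eoas)) {
    model <- lpm_model(make_patient(eoa_av = eoas[i], sv = 54, sbp = 115,
                                    dbp = 40))
    r <- simulate_lpm(model, init = state)
    state <- r$state
    peaks[i] <- r$peak_p_lv
    areas[i] <- lv_workload(r)["mmHg_mL"]
  }
  expect_true(all(diff(peaks) < 0))
  expect_true(all(diff(areas) < 0))
})

test_that("forward stroke volume increases with the source amplitude", {
  model <- lpm_model(make_patient())
  svs <- numeric(3)
  state <- NULL
  for (i in seq_along(svs)) {
    model$q_mpv <- c(250, 400, 550)[i]
    r <- simulate_lpm(model, init = state)
    state <- r$state
    svs[i] <- forward_sv_of(r)
  }
  expect_true(all(diff(svs) > 0))
})

test_that("antiparallel valve branches never conduct simultaneously", {
  model <- lpm_model(make_severe_combined_patient())
  r <- simulate_lpm(model)
  wf <- r$waveforms
  expect_true(all(wf$q_av >= 0))
  expect_true(all(wf$q_ar >= 0))
  expect_true(all(wf$q_mv >= 0))
  expect_true(all(wf$q_mr >= 0))
  # forward and regurgitant flow of one valve conduct materially only in
  # the brief switching transitions (inductive flow decaying through zero)
  aortic_both <- wf$q_av > 0.05 * max(wf$q_av) & wf$q_ar > 0.05 * max(wf$q_ar)
  mitral_both <- wf$q_mv > 0.05 * max(wf$q_mv) & wf$q_mr > 0.05 * max(wf$q_mr)
  expect_lt(mean(aortic_both), 0.05)
  expect_lt(mean(mitral_both), 0.05)
  # regurgitant volumes are substantial for this disease mix
  expect_gt(r$regurgitant_sv_mr, 10)
  expect_gt(r$regurgitant_sv_ar, 1)
})

test_that("forward_sv_of refuses non-steady results", {
  model <- lpm_model(make_patient())
  r <- suppressWarnings(
    simulate_lpm(model, max_cycles = 3, allow_unsteady = TRUE))
  expect_false(r$steady)
  expect_error(forward_sv_of(r), "steady")
})
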