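# Two-step patient-specific parameter estimation.

test_that("total systemic resistance is the pressure/flow quotient", {
  expect_equal(total_systemic_resistance(100, 83.33), 1.20, tolerance = 1e-3)
  expect_identical(total_systemic_resistance(0, 50), 0)
  expect_equal(total_systemic_resistance(mean_arterial_pressure(120, 80),
                                         83.33),
               93.3333 / 83.33, tolerance = 1e-4)
  expect_error(total_systemic_resistance(100, 0), "positive")
  expect_error(mean_arterial_pressure(80, 90), "sbp > dbp")
})

test_that("flow calibration recovers the stroke volume of a known source", {
  model <- lpm_model(make_patient())
  model$q_mpv <- 430
  truth <- simulate_lpm(model)
  target <- forward_sv_of(truth)

  model2 <- lpm_model(make_patient())
  model2$q_mpv <- 300  # start away from the truth
  cal <- calibrate_qmpv(model2, target_sv = target)
  r <- simulate_lpm(cal, init = attr(cal, "cal_state"))
  expect_equal(forward_sv_of(r), target, tolerance = 0.1)
  expect_equal(cal$q_mpv, 430, tolerance = 0.02 * 430)

  expect_error(calibrate_qmpv(model2, target_sv = 0), "positive")
})

test_that("calibrated source amplitude increases with the target", {
  model <- lpm_model(make_patient())
  q1 <- calibrate_qmpv(model, target_sv = 55)$q_mpv
  q2 <- calibrate_qmpv(model, target_sv = 75)$q_mpv
  expect_gt(q2, q1)
})

test_that("pressure calibration reproduces known aortic extrema", {
  # generate targets from a known parameter set, then recover the
  # observables (parameter uniqueness is not asserted)
  model <- lpm_model(make_patient())
  model$params$r_sa <- 1.3
  model$params$c_ao <- 1.1
  model$params$c_sac <- 3.0
  truth <- simulate_lpm(model)

  model2 <- lpm_model(make_patient())  # Table-1 initial values
  cal <- calibrate_systemic(model2, sbp = truth$sbp_ao, dbp = truth$dbp_ao)
  r <- simulate_lpm(cal, init = attr(cal, "cal_state"))
  expect_equal(r$sbp_ao, truth$sbp_ao, tolerance = 0.5)
  expect_equal(r$dbp_ao, truth$dbp_ao, tolerance = 0.5)

  expect_error(calibrate_systemic(model2, sbp = 100, dbp = 100), "sbp > dbp")
})

test_that("widening pulse pressure at fixed MAP lowers total compliance", {
  map <- 93.33
  compliances <- vapply(c(40, 60), function(pp) {
    sbp <- map + 2 * pp / 3
    dbp <- map - pp / 3
    rep <- calibrate_full(make_patient(sbp = sbp, dbp = dbp))
    rep$c_ao + rep$c_sac
  }, numeric(1))
  expect_lt(compliances[2], compliances[1])
})

test_that("full calibration meets all three targets and logs step order", {
  rep <- calibrate_full(make_patient())
  expect_true(rep$converged)
  expect_lt(abs(rep$residuals["sv_ml"]), 0.1)
  expect_lt(abs(rep$residuals["sbp_mmhg"]), 0.5)
  expect_lt(abs(rep$residuals["dbp_mmhg"]), 0.5)

  # the flow step precedes the pressure step in every outer iteration
  steps <- rep$log[rep$log %in% c("flow", "pressure")]
  expect_identical(steps[1], "flow")
  flows <- which(rep$log == "flow")
  pressures <- which(rep$log == "pressure")
  expect_length(flows, length(pressures))
  expect_true(all(flows < pressures))
})

test_that("calibration never touches the fixed Table-1 constants", {
  before <- circulation_params()
  rep <- calibrate_full(make_patient(eoa_av = 1.0, eoa_mr = 0.1,
                                     sbp = 135, dbp = 75, sv = 55))
  after <- rep$model$params
  fixed <- c("r_ao", "r_sv", "r_pda", "l_pv", "l_pc", "r_pv", "r_pvc",
             "r_pc", "r_pa", "c_pvc", "c_pa", "p_cv0", "rho")
  for (nm in fixed) expect_identical(after[[nm]], before[[nm]])
  # and r_ub is untouched by the two-step patient calibration
  expect_identical(after$r_ub, before$r_ub)
})

test_that("a competent valve and an absent branch give the same calibration", {
  p_absent <- make_patient(eoa_av = 1.2, sbp = 130, dbp = 75, sv = 60)
  rep1 <- calibrate_full(p_absent)
  # the same record built through the grade mapping with grade "none"
  p_grade <- make_patient(eoa_av = 1.2, sbp = 130, dbp = 75, sv = 60,
                          eoa_ar = grade_to_regurgitant_eoa("none"),
                          eoa_mr = grade_to_regurgitant_eoa("none"))
  rep2 <- calibrate_full(p_grade)
  expect_equal(rep1$q_mpv, rep2$q_mpv)
  expect_equal(rep1$r_sa, rep2$r_sa)
  expect_equal(lv_workload(rep1$result), lv_workload(rep2$result))
})

test_that("recalibrating an already calibrated model converges immediately", {
  rep <- calibrate_full(make_patient())
  rep2 <- calibrate_full(rep$model)
  expect_true(rep2$converged)
  expect_identical(rep2$iterations, 1L)
})

test_that("measured EDV is honored by adjusting the LV unloaded volume", {
  rep <- calibrate_full(make_patient(edv = 150, esv = 80))
  expect_true(rep$converged)
  expect_equal(rep$result$edv, 150, tolerance = 0.5)
  expect_gt(rep$v0_lv, 0)
})

test_that("upper-body calibration reaches the 15% healthy flow split", {
  ub <- calibrate_upper_body()
  expect_true(ub$converged)
  expect_lt(abs(ub$fraction - 0.15), 1e-3)

  # halving the calibrated resistance strictly increases the fraction;
  # a very large resistance starves the branch
  model <- ub$report$model
  state <- ub$report$result$state
  model$params$r_ub <- ub$r_ub / 2
  half <- upper_body_fraction(simulate_lpm(model, init = state))
  expect_gt(half, ub$fraction)
  model$params$r_ub <- 1e5
  starved <- upper_body_fraction(simulate_lpm(model, init = state))
  expect_lt(starved, 0.01)
})
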