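# Patient-specific parameter estimation: a flow step that fits the
# pulmonary inflow amplitude to the measured forward LVOT stroke volume,
# followed by a pressure step that fits the systemic resistance and the two
# compliances to the brachial cuff pressures; the two steps alternate until
# both target sets hold simultaneously.

#' Total systemic resistance from mean pressure and cardiac output
#'
#' The quotient of mean (brachial) arterial pressure and cardiac output,
#' treating peripheral venous pressure as negligible. Used to initialize the
#' systemic artery resistance as `R_total - (r_ao + r_sv + r_pda)`.
#'
#' @param mean_pressure mean arterial pressure (mmHg); see [mean_arterial_pressure()].
#' @param cardiac_output cardiac output (mL/s).
#' @return Resistance (mmHg s/mL).
#' @export
total_systemic_resistance <- function(mean_pressure, cardiac_output) {
  if (any(cardiac_output <= 0)) {
    stop("cardiac output must be positive", call. = FALSE)
  }
  mean_pressure / cardiac_output
}

#' Mean arterial pressure from cuff pressures
#'
#' The standard cuff estimate `MAP = DBP + (SBP - DBP)/3`.
#'
#' @param sbp,dbp systolic and diastolic brachial pressures (mmHg).
#' @return MAP (mmHg).
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(sbp <= dbp)) stop("require sbp > dbp", call. = FALSE)
  dbp + (sbp - dbp) / 3
}

# simulate with a warm-start cache; env carries `state`
sim_cached <- function(model, cache, ...) {
  res <- simulate_lpm(model, init = cache$state, ...)
  cache$state <- res$state
  res
}

#' Calibrate the pulmonary inflow amplitude to the forward stroke volume
#'
#' Scalar solve for `q_mpv` such that the simulated forward LVOT stroke
#' volume matches `target_sv` within `tol`. Secant iteration from the
#' lossless-cycle estimate, falling back to bisection on the physiological
#' bracket when needed.
#'
#' @param model an [lpm_model()].
#' @param target_sv measured forward LVOT stroke volume (mL), `> 0`.
#' @param tol tolerance (mL).
#' @param bracket search interval for `q_mpv` (mL/s).
#' @param cache optional environment carrying a warm-start `state`.
#' @return The model with calibrated `q_mpv` (invisibly carries the last
#'   result in `attr(, "result")`).
#' @export
calibrate_qmpv <- function(model, target_sv = model$patient$forward_lvot_sv,
                           tol = model$config$sv_tol,
                           bracket = c(50, 800), cache = NULL) {
  stopifnot(inherits(model, "lpm_model"))
  if (!is.numeric(target_sv) || target_sv <= 0) {
    stop("target forward stroke volume must be positive", call. = FALSE)
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  f <- function(q) {
    m <- model
    m$q_mpv <- q
    forward_sv_of(sim_cached(m, cache)) - target_sv
  }
  q0 <- min(max(model$q_mpv, bracket[1]), bracket[2])
  f0 <- f(q0)
  if (abs(f0) <= tol) {
    model$q_mpv <- q0
  } else {
    q1 <- min(max(q0 * (1 - 0.15 * sign(f0)), bracket[1]), bracket[2])
    f1 <- f(q1)
    it <- 0
    while (abs(f1) > tol && it < 40) {
      if (f1 == f0) break
      q2 <- q1 - f1 * (q1 - q0) / (f1 - f0)
      if (!is.finite(q2) || q2 < bracket[1] || q2 > bracket[2]) {
        # fall back to bisection on the bracket
        lo <- bracket[1]; hi <- bracket[2]
        flo <- f(lo)
        if (flo > 0) {
          stop("calibration bracket exhausted: even q_mpv = ", lo,
               " mL/s overshoots the target stroke volume", call. = FALSE)
        }
        fhi <- f(hi)
        if (fhi < 0) {
          stop("calibration bracket exhausted: q_mpv = ", hi,
               " mL/s cannot reach the target stroke volume", call. = FALSE)
        }
        root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                               tol = 1e-3)
        q1 <- root$root; f1 <- f(q1)
        break
      }
      q0 <- q1; f0 <- f1
      q1 <- q2; f1 <- f(q1)
      it <- it + 1
    }
    if (abs(f1) > tol) {
      stop(sprintf(paste0("flow calibration did not reach tolerance: ",
                          "|SV error| = %.3f mL after %d iterations"),
                   abs(f1), it), call. = FALSE)
    }
    model$q_mpv <- q1
  }
  attr(model, "cal_state") <- cache$state
  model
}

#' Calibrate systemic resistance and compliances to cuff pressures
#'
#' Bound-constrained Levenberg-Marquardt least squares on the residuals
#' `(max P_ao - sbp, min P_ao - dbp)` over `(r_sa, c_ao, c_sac)`. The two
#' residuals do not uniquely pin down three parameters: the aortic and
#' systemic compliances trade off against each other, so the observable
#' match, not parameter uniqueness, is the contract.
#'
#' @param model an [lpm_model()].
#' @param sbp,dbp target systolic/diastolic aortic pressures (mmHg).
#' @param tol tolerance on both residuals (mmHg).
#' @param lower,upper parameter bounds for `(r_sa, c_ao, c_sac)`.
#' @param cache optional warm-start environment.
#' @return The model with calibrated `params`.
#' @export
calibrate_systemic <- function(model, sbp = model$patient$sbp,
                               dbp = model$patient$dbp,
                               tol = model$config$bp_tol,
                               lower = c(0.05, 0.02, 0.05),
                               upper = c(10, 10, 40), cache = NULL) {
  stopifnot(inherits(model, "lpm_model"))
  if (!is.numeric(sbp) || !is.numeric(dbp) || sbp <= dbp) {
    stop("require sbp > dbp", call. = FALSE)
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  start <- pmin(pmax(c(model$params$r_sa, model$params$c_ao,
                       model$params$c_sac), lower), upper)
  # two pressure residuals cannot pin down three parameters: the two
  # compliances trade off along a flat manifold. A weak log-scale pull
  # toward the starting compliances selects one solution without
  # perturbing the (much larger) pressure residuals.
  reg_w <- 0.05
  resid <- function(par) {
    m <- model
    m$params$r_sa <- par[1]
    m$params$c_ao <- par[2]
    m$params$c_sac <- par[3]
    r <- sim_cached(m, cache)
    c(r$sbp_ao - sbp, r$dbp_ao - dbp,
      reg_w * log(par[2] / start[2]), reg_w * log(par[3] / start[3]))
  }
  par <- start
  niter <- 0
  for (attempt in 1:4) {
    fit <- minpack.lm::nls.lm(
      par = par, lower = lower, upper = upper, fn = resid,
      control = minpack.lm::nls.lm.control(
        maxiter = 40, ftol = 1e-10, ptol = 1e-10, epsfcn = 1e-4))
    par <- fit$par
    niter <- niter + fit$niter
    res <- fit$fvec[1:2]
    if (all(abs(res) <= tol)) break  # a restart resets the trust region
  }
  if (any(abs(res) > tol)) {
    stop(sprintf(paste0("pressure calibration did not converge: residuals ",
                        "SBP %+.2f, DBP %+.2f mmHg (tolerance %.2f) after %d ",
                        "iterations"), res[1], res[2], tol, niter),
         call. = FALSE)
  }
  model$params$r_sa <- fit$par[1]
  model$params$c_ao <- fit$par[2]
  model$params$c_sac <- fit$par[3]
  attr(model, "cal_state") <- cache$state
  model
}

# secant adjustment of the LV unloaded volume so simulated EDV matches the
# measured one (tolerance 0.5 mL)
adjust_v0_lv <- function(model, target_edv, cache, tol = 0.5, max_iter = 12) {
  g <- function(v0) {
    m <- model
    m$lv$v0 <- v0
    sim_cached(m, cache)$edv - target_edv
  }
  v0_0 <- model$lv$v0
  g0 <- g(v0_0)
  if (abs(g0) <= tol) return(model)
  v0_1 <- v0_0 - g0  # EDV shifts roughly one-for-one with v0
  g1 <- g(v0_1)
  it <- 0
  while (abs(g1) > tol && it < max_iter && g1 != g0) {
    v2 <- v0_1 - g1 * (v0_1 - v0_0) / (g1 - g0)
    v0_0 <- v0_1; g0 <- g1
    v0_1 <- v2; g1 <- g(v0_1)
    it <- it + 1
  }
  model$lv$v0 <- v0_1
  model
}

#' Full two-step patient-specific calibration
#'
#' Alternates the flow step ([calibrate_qmpv()]) and the pressure step
#' ([calibrate_systemic()]) until the simulated forward stroke volume and
#' aortic pressure extrema simultaneously match the patient's measurements.
#' When the patient record carries a measured EDV, the LV unloaded volume is
#' additionally adjusted so the simulated end-diastolic volume matches.
#'
#' @param patient a [patient_inputs()] record, or an already-assembled
#'   [lpm_model()] (whose current parameters are then the starting point).
#' @param params,config network constants and run configuration (ignored
#'   when `patient` is already a model).
#' @param max_outer maximum outer alternations.
#' @return An object of class `calibration_report`: the optimized `q_mpv`,
#'   `r_sa`, `c_ao`, `c_sac` (and `r_ub` in force), residuals, the number of
#'   outer `iterations`, `converged`, the step `log`, the calibrated
#'   `model` and its final simulation `result`.
#' @export
calibrate_full <- function(patient, params = circulation_params(),
                           config = run_config(),
                           max_outer = config$max_outer) {
  if (inherits(patient, "lpm_model")) {
    model <- patient
  } else {
    model <- lpm_model(patient, params = params, config = config)
    # initialize R_SA from the measured mean pressure and cardiac output
    map <- mean_arterial_pressure(model$patient$sbp, model$patient$dbp)
    co <- model$patient$forward_lvot_sv / model$patient$T
    r_tot <- total_systemic_resistance(map, co)
    r_sa0 <- r_tot - (model$params$r_ao + model$params$r_sv +
                        model$params$r_pda)
    model$params$r_sa <- min(max(r_sa0, 0.05), 10)
  }
  cfg <- model$config
  tgt <- model$patient
  cache <- new.env(parent = emptyenv())
  # physiologically informed start state shortens the first transient
  ela_min <- elastance_affine(model$la, cfg$strategy)$b  # diastolic LA elastance
  y0 <- initial_state(v_lv = if (!is.null(tgt$edv)) tgt$edv else 130,
                      v_la = min(8 / max(ela_min, 1e-6), 1500))
  y0["p_cao"] <- mean_arterial_pressure(tgt$sbp, tgt$dbp)
  y0["p_csac"] <- y0["p_cao"] * 0.95
  y0["p_cpa"] <- 14
  y0["p_cpvc"] <- 8
  cache$state <- y0

  log <- character()
  converged <- FALSE
  iterations <- 0
  res <- NULL
  for (i in seq_len(max_outer)) {
    iterations <- i
    model <- calibrate_qmpv(model, cache = cache)
    log <- c(log, "flow")
    model <- calibrate_systemic(model, cache = cache)
    log <- c(log, "pressure")
    if (!is.null(tgt$edv)) {
      model <- adjust_v0_lv(model, tgt$edv, cache)
      log <- c(log, "v0")
    }
    res <- sim_cached(model, cache)
    ok_sv <- abs(res$forward_sv - tgt$forward_lvot_sv) <= cfg$sv_tol
    ok_sbp <- abs(res$sbp_ao - tgt$sbp) <= cfg$bp_tol
    ok_dbp <- abs(res$dbp_ao - tgt$dbp) <= cfg$bp_tol
    if (ok_sv && ok_sbp && ok_dbp) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    q_mpv = model$q_mpv,
    r_sa = model$params$r_sa,
    c_ao = model$params$c_ao,
    c_sac = model$params$c_sac,
    r_ub = model$params$r_ub,
    v0_lv = model$lv$v0,
    residuals = c(sv_ml = res$forward_sv - tgt$forward_lvot_sv,
                  sbp_mmhg = res$sbp_ao - tgt$sbp,
                  dbp_mmhg = res$dbp_ao - tgt$dbp),
    iterations = iterations,
    converged = converged,
    log = log,
    model = model,
    result = res
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration report\n")
  cat(sprintf("  converged: %s after %d outer iteration(s)\n",
              x$converged, x$iterations))
  cat(sprintf("  q_mpv %.1f mL/s, r_sa %.3f mmHg.s/mL, c_ao %.3f, c_sac %.3f mL/mmHg\n",
              x$q_mpv, x$r_sa, x$c_ao, x$c_sac))
  cat(sprintf("  residuals: SV %+.3f mL, SBP %+.2f mmHg, DBP %+.2f mmHg\n",
              x$residuals[1], x$residuals[2], x$residuals[3]))
  invisible(x)
}

#' Healthy baseline patient
#'
#' The documented healthy reference configuration on which the upper-body
#' resistance is calibrated: normal valve areas, no regurgitation,
#' 120/80 mmHg cuff pressures, 70 mL forward stroke volume, 70 bpm.
#'
#' @param config a [run_config()] supplying the normal valve areas.
#' @return A [patient_inputs()] record.
#' @export
healthy_baseline <- function(config = run_config()) {
  T <- 60 / 70
  patient_inputs(
    forward_lvot_sv = 70, T = T, t_ej = 0.3 * T,
    eoa_av = config$normal_av_eoa, eoa_mv = config$normal_mv_eoa,
    a_ao = circular_area(3.0), a_lvot = circular_area(2.0),
    sbp = 120, dbp = 80
  )
}

#' Calibrate the upper-body resistance on the healthy baseline
#'
#' Solves for `r_ub` such that the upper-body branch carries 15% of the
#' cycle-mean systemic flow in the healthy baseline configuration. Because
#' changing `r_ub` shifts the aortic pressures, the solve is interleaved
#' with full recalibration until the fraction holds within `tol` (absolute)
#' in the recalibrated model.
#'
#' @param patient the healthy baseline [patient_inputs()] (default
#'   [healthy_baseline()]).
#' @param params,config network constants and run configuration.
#' @param target target flow fraction.
#' @param tol absolute tolerance on the fraction.
#' @param max_outer maximum interleaved recalibrations.
#' @return A list: `r_ub`, achieved `fraction`, the final
#'   `calibration_report`, and `converged`.
#' @export
calibrate_upper_body <- function(patient = healthy_baseline(config),
                                 params = circulation_params(),
                                 config = run_config(),
                                 target = 0.15, tol = 1e-3,
                                 max_outer = 6) {
  rep <- calibrate_full(patient, params = params, config = config)
  fraction <- upper_body_fraction(rep$result)
  converged <- FALSE
  for (i in seq_len(max_outer)) {
    if (abs(fraction - target) <= tol) {
      converged <- TRUE
      break
    }
    model <- rep$model
    cache <- new.env(parent = emptyenv())
    cache$state <- rep$result$state
    g <- function(log_rub) {
      m <- model
      m$params$r_ub <- exp(log_rub)
      upper_body_fraction(sim_cached(m, cache)) - target
    }
    root <- stats::uniroot(g, log(c(0.2, 200)), tol = 1e-4)
    model$params$r_ub <- exp(root$root)
    rep <- calibrate_full(model)
    fraction <- upper_body_fraction(rep$result)
  }
  if (!converged && abs(fraction - target) <= tol) converged <- TRUE
  if (!converged) {
    stop(sprintf(paste0("upper-body calibration did not reach the target ",
                        "flow fraction: %.4f vs %.4f"), fraction, target),
         call. = FALSE)
  }
  list(r_ub = rep$model$params$r_ub, fraction = fraction,
       report = rep, converged = converged)
}
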