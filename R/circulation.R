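# The electrical-analog circulation network and its integration to
# periodic steady state.
#
# Topology: a prescribed pulmonary-valve flow source feeds the pulmonary
# arterial capacitor C_PA; flow passes through R_PA + R_PC with inductor
# L_PC to the pulmonary venous capacitor C_PVC, then through R_PVC + R_PV
# with inductor L_PV into the left atrium. LA and LV are elastance chambers
# joined by the mitral forward branch (MR branch antiparallel); the LV
# ejects through the aortic forward branch (AR branch antiparallel) into the
# aortic capacitor C_ao. From C_ao, R_ao leads to a junction from which the
# upper-body resistance R_ub drains to the central venous pressure P_CV0,
# and R_pda + R_SA lead through the systemic capacitor C_SAC and R_SV to
# P_CV0. The junction pressure is solved algebraically from continuity at
# every derivative evaluation. The right heart is not modelled; the
# prescribed source replaces it.

#' Circulation network constants
#'
#' All resistances (mmHg s/mL), compliances (mL/mmHg), inertances
#' (mmHg s^2/mL) and the venous sink pressure of the systemic and pulmonary
#' networks. `r_sa`, `c_ao` and `c_sac` are initial values refined by
#' patient calibration; `r_ub` is calibrated once on a healthy baseline so
#' the upper-body branch carries 15% of systemic flow; all others are fixed
#' constants.
#'
#' @param r_ao,r_sv,r_pda fixed aortic, systemic-vein and proximal
#'   descending-aorta resistances.
#' @param r_sa systemic artery resistance (initial value, calibrated).
#' @param r_ub upper-body resistance (calibrated on the healthy baseline).
#' @param c_ao,c_sac aortic and systemic compliances (initial values,
#'   calibrated).
#' @param l_pv,l_pc pulmonary vein / capillary inertances.
#' @param r_pv,r_pvc,r_pc,r_pa pulmonary resistances.
#' @param c_pvc,c_pa pulmonary compliances.
#' @param p_cv0 central venous pressure (mmHg).
#' @param rho blood density (g/cm^3).
#' @return An object of class `circulation_params`.
#' @export
circulation_params <- function(r_ao = 0.05, r_sv = 0.05, r_pda = 0.05,
                               r_sa = 0.8, r_ub = 7, c_ao = 0.5, c_sac = 2,
                               l_pv = 0.0005, l_pc = 0.0003,
                               r_pv = 0.002, r_pvc = 0.001,
                               r_pc = 0.21, r_pa = 0.01,
                               c_pvc = 40, c_pa = 4,
                               p_cv0 = 4, rho = 1.05) {
  vals <- list(r_ao = r_ao, r_sv = r_sv, r_pda = r_pda, r_sa = r_sa,
               r_ub = r_ub, c_ao = c_ao, c_sac = c_sac, l_pv = l_pv,
               l_pc = l_pc, r_pv = r_pv, r_pvc = r_pvc, r_pc = r_pc,
               r_pa = r_pa, c_pvc = c_pvc, c_pa = c_pa, p_cv0 = p_cv0,
               rho = rho)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && v > 0, TRUE)]
  bad <- setdiff(bad, "p_cv0")  # sink pressure may in principle be zero
  if (length(bad) > 0) {
    stop("circulation parameters must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(vals, class = "circulation_params")
}

# names of the Table-1 constants that calibration must never touch
fixed_circulation_constants <- function() {
  c("r_ao", "r_sv", "r_pda", "l_pv", "l_pc", "r_pv", "r_pvc", "r_pc",
    "r_pa", "c_pvc", "c_pa", "p_cv0", "rho")
}

#' Simulation run configuration
#'
#' @param dt integration step (s); the cycle is integrated with a classical
#'   fourth-order Runge-Kutta scheme at this resolution.
#' @param n_out number of uniform samples of the final steady cycle in the
#'   returned waveforms.
#' @param max_cycles maximum number of cardiac cycles before the run is
#'   declared non-convergent.
#' @param steady_tol relative beat-to-beat change in forward stroke volume
#'   and in the aortic pressure extrema below which the run is periodic.
#' @param strategy elastance scaling strategy, see [chamber_elastance()].
#' @param normal_av_eoa,normal_mv_eoa "normal condition" valve areas (cm^2)
#'   used when a disease constituent is counterfactually corrected.
#' @param accelerate apply periodic steady-state extrapolation of the slow
#'   filling transient (recommended).
#' @param sv_tol,bp_tol calibration tolerances on forward stroke volume (mL)
#'   and aortic pressure extrema (mmHg).
#' @param max_outer maximum outer alternations of the two calibration steps.
#' @return An object of class `run_config`.
#' @export
run_config <- function(dt = 1e-4, n_out = 1000, max_cycles = 500,
                       steady_tol = 1e-5,
                       strategy = c("peak-rescaled", "emax-scaled",
                                    "literal-eq3"),
                       normal_av_eoa = 3.0, normal_mv_eoa = 4.0,
                       accelerate = TRUE, sv_tol = 0.1, bp_tol = 0.5,
                       max_outer = 20) {
  strategy <- match.arg(strategy)
  stopifnot(dt > 0, n_out >= 16, max_cycles >= 3, steady_tol > 0,
            normal_av_eoa > 0, normal_mv_eoa > 0, sv_tol > 0, bp_tol > 0,
            max_outer >= 1)
  structure(list(dt = dt, n_out = n_out, max_cycles = max_cycles,
                 steady_tol = steady_tol, strategy = strategy,
                 normal_av_eoa = normal_av_eoa,
                 normal_mv_eoa = normal_mv_eoa,
                 accelerate = accelerate, sv_tol = sv_tol, bp_tol = bp_tol,
                 max_outer = max_outer),
            class = "run_config")
}

#' Prescribed pulmonary-valve inflow
#'
#' A rectified sine of amplitude `q_mpv` and duration `t_ee`, zero for the
#' remainder of the cycle, periodic in `T`. Its cycle mean is
#' `q_mpv * 2 t_ee / (pi T)`.
#'
#' @param t time (s), vectorized.
#' @param q_mpv amplitude (mL/s).
#' @param t_ee ejection duration (s), `0 < t_ee <= T`.
#' @param T cycle period (s).
#' @return Flow (mL/s).
#' @export
pulmonary_inflow <- function(t, q_mpv, t_ee, T) {
  if (t_ee <= 0 || t_ee > T) stop("require 0 < t_ee <= T", call. = FALSE)
  tp <- t %% T
  ifelse(tp <= t_ee, q_mpv * sin(pi * tp / t_ee), 0)
}

#' Assemble a patient-specific lumped-parameter model
#'
#' Binds validated patient inputs, circulation constants, chamber
#' configurations and valve branches into a simulable model object. The
#' regurgitant branches are included only when the patient record carries a
#' regurgitant EOA.
#'
#' @param patient a [patient_inputs()] record.
#' @param params [circulation_params()].
#' @param config [run_config()].
#' @param q_mpv pulmonary inflow amplitude (mL/s); refined by calibration.
#' @param lv,la chamber configurations; defaults use the standard adult
#'   elastance parameters with zero unloaded volume.
#' @return An object of class `lpm_model`.
#' @export
lpm_model <- function(patient, params = circulation_params(),
                      config = run_config(), q_mpv = NULL,
                      lv = chamber_config(lv_elastance_params(), label = "LV"),
                      la = chamber_config(la_elastance_params(), label = "LA")) {
  stopifnot(inherits(patient, "patient_inputs"),
            inherits(params, "circulation_params"),
            inherits(config, "run_config"))
  if (is.null(q_mpv)) {
    # lossless-cycle estimate: source mean equals forward SV per beat
    q_mpv <- patient$forward_lvot_sv * pi / (2 * patient$t_ej)
  }
  valves <- list(
    av = valve_spec(patient$eoa_av, "aortic", ref_area = patient$a_ao,
                    rho = params$rho),
    ar = if (!is.null(patient$eoa_ar)) {
      valve_spec(patient$eoa_ar, "aortic", ref_area = patient$a_lvot,
                 rho = params$rho)
    },
    mv = valve_spec(patient$eoa_mv, "mitral", rho = params$rho),
    mr = if (!is.null(patient$eoa_mr)) {
      valve_spec(patient$eoa_mr, "mitral", rho = params$rho)
    }
  )
  structure(list(patient = patient, params = params, config = config,
                 q_mpv = q_mpv, lv = lv, la = la, valves = valves),
            class = "lpm_model")
}

#' @export
print.lpm_model <- function(x, ...) {
  cat("Lumped-parameter left-heart model\n")
  cat(sprintf("  q_mpv %.1f mL/s, r_sa %.3f, c_ao %.3f, c_sac %.3f, r_ub %.2f\n",
              x$q_mpv, x$params$r_sa, x$params$c_ao, x$params$c_sac,
              x$params$r_ub))
  cat(sprintf("  elastance strategy: %s\n", x$config$strategy))
  print(x$patient)
  invisible(x)
}

# flatten a model into the parameter list consumed by the C++ core
model_pars <- function(model) {
  chamber_entry <- function(cfg) {
    aff <- elastance_affine(cfg, model$config$strategy)
    p <- cfg$params
    T <- model$patient$T
    list(a = aff$a, b = aff$b, m1 = p$m1, m2 = p$m2,
         tau1 = p$tau1_frac * T, tau2 = p$tau2_frac * T,
         onset = p$onset_frac * T, v0 = cfg$v0)
  }
  valve_entry <- function(v) {
    if (is.null(v)) list(present = FALSE) else
      list(present = TRUE, l = v$l, k = v$k)
  }
  list(lv = chamber_entry(model$lv), la = chamber_entry(model$la),
       av = valve_entry(model$valves$av), ar = valve_entry(model$valves$ar),
       mv = valve_entry(model$valves$mv), mr = valve_entry(model$valves$mr),
       circ = model$params[setdiff(names(model$params), "rho")],
       q_mpv = model$q_mpv, t_ee = model$patient$t_ej, T = model$patient$T)
}

state_names <- function() {
  c("v_lv", "v_la", "q_av", "q_ar", "q_mv", "q_mr", "p_cao", "p_csac",
    "p_cpa", "p_cpvc", "q_lpc", "q_lpv")
}

#' Default initial state
#'
#' Flows and capacitor pressures start at zero (discharged network);
#' chamber volumes start at physiological defaults since they cannot be
#' zero. Steady-state cycling absorbs the transient.
#'
#' @param v_lv,v_la initial chamber volumes (mL).
#' @return Named numeric state vector.
#' @export
initial_state <- function(v_lv = 120, v_la = 50) {
  y <- stats::setNames(numeric(12), state_names())
  y["v_lv"] <- v_lv
  y["v_la"] <- v_la
  y
}

#' State-derivative function of the assembled network
#'
#' Returns `d(state)/dt` as a function `f(t, y)`, the ODE right-hand side of
#' the full network (chamber volume balances, valve inductor equations with
#' diode gating, capacitor node balances, and the algebraically solved
#' systemic junction). Useful for inspection and verification; the
#' integrator itself runs in compiled code.
#'
#' @param model an [lpm_model()].
#' @return `function(t, y)` returning the named derivative vector.
#' @export
assemble_odes <- function(model) {
  stopifnot(inherits(model, "lpm_model"))
  pars <- model_pars(model)
  function(t, y) {
    stopifnot(length(y) == 12)
    lpm_derivs_cpp(pars, t, as.numeric(y))
  }
}

#' Integrate the model to periodic steady state
#'
#' Runs the network cycle by cycle (classical RK4 at step `dt`) until the
#' forward stroke volume and the aortic pressure extrema each change by less
#' than `steady_tol` (relative) between consecutive cycles, then returns the
#' final steady cycle resampled to `n_out` uniform points. A slow
#' left-atrial filling transient dominates convergence; an Aitken-type
#' extrapolation of the cycle-to-cycle state map (enabled by default)
#' shortens it substantially.
#'
#' @param model an [lpm_model()].
#' @param init optional initial state (see [initial_state()]); a previous
#'   result's `$state` warm-starts the run.
#' @param max_cycles,steady_tol override the model's run configuration.
#' @param allow_unsteady return (with a warning) instead of erroring when no
#'   steady state is reached; the result is flagged `steady = FALSE`.
#' @return An object of class `lpm_result`: `waveforms` (data frame of the
#'   final cycle: time, chamber/node pressures, branch flows, volumes),
#'   per-cycle `summary`, scalar cycle metrics (`forward_sv`, `edv`, `esv`,
#'   `peak_p_lv`, `peak_p_ao`, `sbp_ao`, `dbp_ao`), `cycles_run`, `steady`,
#'   the final `state`, and run metadata (`dt`, elastance strategy).
#' @export
simulate_lpm <- function(model, init = NULL, max_cycles = NULL,
                         steady_tol = NULL, allow_unsteady = FALSE) {
  stopifnot(inherits(model, "lpm_model"))
  cfg <- model$config
  if (is.null(init)) init <- initial_state()
  if (is.null(max_cycles)) max_cycles <- cfg$max_cycles
  if (is.null(steady_tol)) steady_tol <- cfg$steady_tol
  raw <- lpm_simulate_cpp(model_pars(model), as.numeric(init), cfg$dt,
                          as.integer(max_cycles), steady_tol,
                          cfg$accelerate)
  if (!raw$steady && !allow_unsteady) {
    last <- raw$summary[nrow(raw$summary), ]
    stop(sprintf(paste0(
      "no periodic steady state within %d cycles (last cycle: forward SV ",
      "%.2f mL, aortic pressure %.1f/%.1f mmHg); increase max_cycles or ",
      "inspect the configuration"), raw$cycles, last["sv_av"],
      last["pao_max"], last["pao_min"]), call. = FALSE)
  }
  if (!raw$steady) {
    warning("returning non-steady result (", raw$cycles, " cycles)",
            call. = FALSE)
  }
  dense <- raw$dense
  tt <- dense[, "time_s"]
  t_out <- seq(0, model$patient$T, length.out = cfg$n_out + 1)
  wf <- as.data.frame(lapply(colnames(dense)[-1], function(cn) {
    stats::approx(tt, dense[, cn], xout = t_out)$y
  }))
  names(wf) <- colnames(dense)[-1]
  wf <- cbind(time_s = t_out, wf)

  # final-cycle scalar metrics from the dense (solver-grid) recording
  n <- nrow(dense) - 1
  dt <- raw$dt
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2) * dt
  last_summary <- raw$summary[nrow(raw$summary), ]
  structure(list(
    waveforms = wf,
    summary = as.data.frame(raw$summary),
    forward_sv = unname(last_summary["sv_av"]),
    regurgitant_sv_ar = unname(last_summary["sv_ar"]),
    regurgitant_sv_mr = unname(last_summary["sv_mr"]),
    edv = unname(last_summary["vlv_max"]),
    esv = unname(last_summary["vlv_min"]),
    peak_p_lv = max(dense[, "p_lv"]),
    peak_p_ao = max(dense[, "p_cao"]),
    sbp_ao = unname(last_summary["pao_max"]),
    dbp_ao = unname(last_summary["pao_min"]),
    mean_q_ub = trap((dense[, "p_j"] - model$params$p_cv0) /
                       model$params$r_ub) / model$patient$T,
    mean_q_systemic = trap((dense[, "p_cao"] - dense[, "p_j"]) /
                             model$params$r_ao) / model$patient$T,
    cycles_run = raw$cycles,
    steady = raw$steady,
    state = stats::setNames(raw$state, state_names()),
    meta = list(dt = raw$dt, strategy = cfg$strategy,
                steady_tol = steady_tol, max_cycles = max_cycles)
  ), class = "lpm_result")
}

#' @export
print.lpm_result <- function(x, ...) {
  cat("Lumped-parameter simulation result\n")
  cat(sprintf("  steady: %s after %d cycles (dt %.2g s, strategy %s)\n",
              x$steady, x$cycles_run, x$meta$dt, x$meta$strategy))
  cat(sprintf("  forward SV %.1f mL, aorta %.1f/%.1f mmHg, peak LV %.1f mmHg\n",
              x$forward_sv, x$sbp_ao, x$dbp_ao, x$peak_p_lv))
  cat(sprintf("  LV EDV %.1f mL, ESV %.1f mL\n", x$edv, x$esv))
  invisible(x)
}

#' Forward stroke volume of a steady cycle
#'
#' The integral of the forward aortic-valve flow over one steady cycle;
#' regurgitant flow is excluded.
#'
#' @param result an [simulate_lpm()] result with `steady = TRUE`.
#' @return Volume (mL).
#' @export
forward_sv_of <- function(result) {
  stopifnot(inherits(result, "lpm_result"))
  if (!isTRUE(result$steady)) {
    stop("forward stroke volume requires a steady result", call. = FALSE)
  }
  result$forward_sv
}

#' Upper-body flow fraction of a steady cycle
#'
#' Cycle-mean flow through the upper-body branch divided by the cycle-mean
#' total systemic flow (the flow leaving the aortic capacitor).
#'
#' @param result an [simulate_lpm()] result.
#' @return Dimensionless fraction.
#' @export
upper_body_fraction <- function(result) {
  stopifnot(inherits(result, "lpm_result"))
  result$mean_q_ub / result$mean_q_systemic
}
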