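# Global and local hemodynamic metrics: pressure-volume loop stroke work,
# transvalvular gradients, RMS error against reference tracings, and the
# counterfactual one-at-a-time workload breakdown.

MMHG_ML_PER_J <- 1 / 1.33322e-4

#' Pressure-volume loop stroke work
#'
#' Signed shoelace area of the closed LV pressure-volume loop over one
#' steady cycle, reported as a magnitude in mmHg mL and joules
#' (1 mmHg mL = 1.33322e-4 J). The loop must close: first and last samples
#' must coincide within `tol` (relative to the loop's extent).
#'
#' @param p pressure series (mmHg) over one cycle.
#' @param v volume series (mL), same length.
#' @param tol relative closure tolerance.
#' @return Named numeric vector `c(mmHg_mL = , J = )`.
#' @export
pv_workload <- function(p, v, tol = 0.05) {
  if (length(p) != length(v)) {
    stop("pressure and volume series must have equal length", call. = FALSE)
  }
  n <- length(p)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  p_ext <- max(diff(range(p)), 1e-9)
  v_ext <- max(diff(range(v)), 1e-9)
  if (abs(p[1] - p[n]) > tol * p_ext || abs(v[1] - v[n]) > tol * v_ext) {
    stop("pressure-volume loop is not closed: first and last samples differ ",
         "beyond tolerance", call. = FALSE)
  }
  pc <- c(p, p[1])
  vc <- c(v, v[1])
  area <- abs(sum((pc[-1] + pc[-length(pc)]) / 2 * diff(vc)))
  c(mmHg_mL = area, J = area / MMHG_ML_PER_J)
}

#' LV workload of a simulation result
#'
#' Convenience wrapper: [pv_workload()] on the LV pressure and volume
#' waveforms of one steady cycle.
#'
#' @param result an [simulate_lpm()] result.
#' @return Named numeric vector `c(mmHg_mL = , J = )`.
#' @export
lv_workload <- function(result) {
  stopifnot(inherits(result, "lpm_result"))
  wf <- result$waveforms
  n <- nrow(wf)
  # drop the duplicated cycle-end sample; pv_workload closes the loop itself
  pv_workload(wf$p_lv[-n], wf$v_lv[-n])
}

#' Transvalvular aortic gradients of a steady cycle
#'
#' The instantaneous net gradient `P_LV - P_ao` during forward ejection
#' (aortic valve conducting): `mean` is its time average over the ejection
#' interval, `max` its peak.
#'
#' @param result an [simulate_lpm()] result.
#' @return Named numeric vector `c(mean = , max = )` in mmHg.
#' @export
transvalvular_gradients <- function(result) {
  stopifnot(inherits(result, "lpm_result"))
  wf <- result$waveforms
  open <- wf$q_av > 1e-9
  if (!any(open)) {
    stop("no ejection interval: the aortic valve never conducts",
         call. = FALSE)
  }
  g <- pmax(wf$p_lv[open] - wf$p_cao[open], 0)
  c(mean = mean(g), max = max(g))
}

#' Root-mean-square error between two waveforms
#'
#' Both series must already be sampled on a common uniform grid over one
#' cycle (see [resample_waveform()]).
#'
#' @param sim,ref numeric series of equal length.
#' @return RMS difference, in the series' units.
#' @export
rms_error <- function(sim, ref) {
  if (length(sim) != length(ref)) {
    stop("series lengths differ; resample to a common grid first",
         call. = FALSE)
  }
  sqrt(mean((sim - ref)^2))
}

#' Resample a time series onto a uniform grid
#'
#' Linear interpolation of `(time, value)` onto `n` uniform points spanning
#' the series' time range; used to put simulated and reference (e.g.
#' catheter) tracings on a common grid before [rms_error()].
#'
#' @param time,value the series.
#' @param n number of output samples.
#' @return A data frame with columns `time` and `value`.
#' @export
resample_waveform <- function(time, value, n = 1000) {
  stopifnot(length(time) == length(value), n >= 2)
  t_out <- seq(min(time), max(time), length.out = n)
  data.frame(time = t_out,
             value = stats::approx(time, value, xout = t_out)$y)
}

#' Hemodynamic metrics of a steady cycle
#'
#' @param result an [simulate_lpm()] result.
#' @return An object of class `hemodynamic_metrics`: LV workload (mmHg mL
#'   and J), peak LV and aortic pressures, mean and maximum aortic valve
#'   gradients, forward stroke volume, EDV, ESV and ejection fraction.
#' @export
hemodynamic_metrics <- function(result) {
  stopifnot(inherits(result, "lpm_result"))
  w <- lv_workload(result)
  g <- transvalvular_gradients(result)
  structure(list(
    lv_workload_mmHg_mL = unname(w["mmHg_mL"]),
    lv_workload_J = unname(w["J"]),
    peak_p_lv = result$peak_p_lv,
    peak_p_ao = result$peak_p_ao,
    mean_av_gradient = unname(g["mean"]),
    max_av_gradient = unname(g["max"]),
    forward_sv = result$forward_sv,
    edv = result$edv,
    esv = result$esv,
    ef = (result$edv - result$esv) / result$edv
  ), class = "hemodynamic_metrics")
}

#' @export
print.hemodynamic_metrics <- function(x, ...) {
  cat("Hemodynamic metrics (one steady cycle)\n")
  cat(sprintf("  LV workload      : %.0f mmHg.mL (%.3f J)\n",
              x$lv_workload_mmHg_mL, x$lv_workload_J))
  cat(sprintf("  peak pressures   : LV %.1f, aorta %.1f mmHg\n",
              x$peak_p_lv, x$peak_p_ao))
  cat(sprintf("  AV gradient      : mean %.1f, max %.1f mmHg\n",
              x$mean_av_gradient, x$max_av_gradient))
  cat(sprintf("  forward SV       : %.1f mL; EDV %.1f, ESV %.1f mL (EF %.0f%%)\n",
              x$forward_sv, x$edv, x$esv, 100 * x$ef))
  invisible(x)
}

# which disease constituents does a patient record carry?
detect_constituents <- function(patient, config) {
  cons <- character()
  if (patient$eoa_av < config$normal_av_eoa) cons <- c(cons, "AS")
  if (!is.null(patient$eoa_ar)) cons <- c(cons, "AR")
  if (patient$eoa_mv < config$normal_mv_eoa) cons <- c(cons, "MS")
  if (!is.null(patient$eoa_mr)) cons <- c(cons, "MR")
  cons
}

# counterfactual record with one constituent replaced by its normal condition
correct_constituent <- function(patient, constituent, config) {
  p <- unclass(patient)
  switch(constituent,
    AS = { p$eoa_av <- min(config$normal_av_eoa, 0.95 * p$a_ao) },
    AR = { p$eoa_ar <- NULL },
    MS = { p$eoa_mv <- config$normal_mv_eoa },
    MR = { p$eoa_mr <- NULL },
    stop("unknown disease constituent: ", constituent, call. = FALSE)
  )
  do.call(patient_inputs, p[!vapply(p, is.null, TRUE)])
}

#' Counterfactual workload breakdown of disease constituents
#'
#' Replaces each valvular disease constituent by its normal condition
#' one-at-a-time (stenotic valve to the configured normal orifice area,
#' regurgitant branch removed), recalibrates the counterfactual model to the
#' same measured targets (forward stroke volume and cuff pressures:
#' predicted-intervention semantics), simulates it, and reports each
#' constituent's contribution to the LV workload.
#'
#' Conventions: `"reduction"` (default) reports the percent decrease of the
#' workload achieved by correcting the constituent,
#' `100 (W_dis - W_cf) / W_dis` — the predicted percent decrease in LV
#' workload following that intervention; `"increase"` reports the percent
#' excess of the diseased workload over the corrected one,
#' `100 (W_dis - W_cf) / W_cf`.
#'
#' @param patient a [patient_inputs()] record, or an already calibrated
#'   `calibration_report` for the diseased state.
#' @param constituents subset of `c("AS", "AR", "MS", "MR")`; by default all
#'   constituents present in the record.
#' @param params,config network constants and run configuration.
#' @param convention contribution convention, see Details.
#' @return An object of class `breakdown_result`: `baseline_workload`
#'   (mmHg mL), a data frame `table` with one row per constituent
#'   (`constituent`, `workload_mmHg_mL`, `percent`, `error`), and the
#'   convention used. Counterfactual calibration failures are reported per
#'   constituent without aborting the others.
#' @export
workload_breakdown <- function(patient, constituents = NULL,
                               params = circulation_params(),
                               config = run_config(),
                               convention = c("reduction", "increase")) {
  convention <- match.arg(convention)
  if (inherits(patient, "calibration_report")) {
    base_rep <- patient
    patient <- base_rep$model$patient
    config <- base_rep$model$config
  } else {
    stopifnot(inherits(patient, "patient_inputs"))
    base_rep <- calibrate_full(patient, params = params, config = config)
  }
  if (is.null(constituents)) {
    constituents <- detect_constituents(patient, config)
  } else {
    bad <- setdiff(constituents, c("AS", "AR", "MS", "MR"))
    if (length(bad) > 0) {
      stop("unknown constituents: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  w_dis <- unname(lv_workload(base_rep$result)["mmHg_mL"])
  rows <- lapply(constituents, function(con) {
    cf <- tryCatch({
      cf_patient <- correct_constituent(patient, con, config)
      rep <- calibrate_full(cf_patient, params = params, config = config)
      w_cf <- unname(lv_workload(rep$result)["mmHg_mL"])
      pct <- if (convention == "increase") {
        100 * (w_dis - w_cf) / w_cf
      } else {
        100 * (w_dis - w_cf) / w_dis
      }
      data.frame(constituent = con, workload_mmHg_mL = w_cf, percent = pct,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(constituent = con, workload_mmHg_mL = NA_real_,
                 percent = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    cf
  })
  empty <- data.frame(constituent = character(), workload_mmHg_mL = numeric(),
                      percent = numeric(), error = character(),
                      stringsAsFactors = FALSE)
  structure(list(
    baseline_workload = w_dis,
    table = do.call(rbind, c(list(empty), rows)),
    convention = convention,
    baseline_report = base_rep
  ), class = "breakdown_result")
}

#' @export
print.breakdown_result <- function(x, ...) {
  cat("LV workload breakdown (counterfactual one-at-a-time correction)\n")
  cat(sprintf("  diseased workload: %.0f mmHg.mL; convention: %s\n",
              x$baseline_workload, x$convention))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    if (is.na(r$percent)) {
      cat(sprintf("  %-3s: calibration failed (%s)\n", r$constituent, r$error))
    } else {
      cat(sprintf("  %-3s: corrected workload %.0f mmHg.mL, contribution %+.1f%%\n",
                  r$constituent, r$workload_mmHg_mL, r$percent))
    }
  }
  invisible(x)
}
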