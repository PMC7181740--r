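# Derivation of model inputs from raw Doppler-echocardiography measurements.

#' Forward LVOT stroke volume from Doppler measurements
#'
#' `SV = A_LVOT * VTI_LVOT = pi d^2/4 * VTI`: the volume crossing the left
#' ventricular outflow tract per beat, the model's sole flow input.
#'
#' @param d_lvot LVOT diameter (cm).
#' @param vti_lvot LVOT velocity-time integral (cm).
#' @return Stroke volume (mL).
#' @export
forward_lvot_sv <- function(d_lvot, vti_lvot) {
  if (any(d_lvot <= 0) || any(vti_lvot < 0)) {
    stop("d_lvot must be positive and vti_lvot non-negative", call. = FALSE)
  }
  circular_area(d_lvot) * vti_lvot
}

#' Cross-sectional area of a circular vessel
#' @param d diameter (cm).
#' @return Area `pi d^2 / 4` (cm^2).
#' @export
circular_area <- function(d) {
  if (any(d <= 0)) stop("diameter must be positive", call. = FALSE)
  pi * d^2 / 4
}

#' Aortic valve EOA by the continuity equation
#'
#' `EOA = forward LVOT stroke volume / VTI_AO`.
#'
#' @param forward_sv forward LVOT stroke volume (mL).
#' @param vti_ao velocity-time integral in the ascending aorta (cm).
#' @return Effective orifice area (cm^2).
#' @export
eoa_by_continuity <- function(forward_sv, vti_ao) {
  if (any(vti_ao <= 0)) stop("vti_ao must be positive", call. = FALSE)
  forward_sv / vti_ao
}

#' Elliptical mitral valve area
#'
#' The mitral orifice is approximated as an ellipse with diameters measured
#' in the apical two- and four-chamber views: `A = pi d1 d2 / 4`.
#'
#' @param d1,d2 orthogonal mitral diameters (cm).
#' @return Valve area (cm^2).
#' @export
mitral_area <- function(d1, d2) {
  if (any(d1 <= 0) || any(d2 <= 0)) {
    stop("mitral diameters must be positive", call. = FALSE)
  }
  pi * d1 * d2 / 4
}

#' Biplane ellipsoid left-ventricular volume
#'
#' `V = A1 * A2 / mean(L1, L2)` from areas and long-axis lengths measured in
#' the apical four- and two-chamber views. Implemented exactly in this form;
#' set `conventional = TRUE` for the textbook biplane ellipsoid formula
#' `V = (8 / (3 pi)) A1 A2 / mean(L1, L2)`.
#'
#' @param a1,a2 LV areas (cm^2) in the two apical views.
#' @param l1,l2 LV long-axis lengths (cm) in the two apical views.
#' @param conventional apply the `8/(3 pi)` geometric factor (default off).
#' @return Volume (mL).
#' @export
biplane_volume <- function(a1, a2, l1, l2, conventional = FALSE) {
  if (any(l1 <= 0) || any(l2 <= 0)) {
    stop("lengths must be positive", call. = FALSE)
  }
  if (any(a1 < 0) || any(a2 < 0)) stop("areas must be non-negative", call. = FALSE)
  v <- a1 * a2 / ((l1 + l2) / 2)
  if (conventional) v <- v * 8 / (3 * pi)
  v
}

#' Ejection fraction
#' @param edv end-diastolic volume (mL).
#' @param esv end-systolic volume (mL), `edv > esv >= 0`.
#' @return `(edv - esv) / edv`, in (0, 1].
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(esv < 0) || any(edv <= esv)) {
    stop("require edv > esv >= 0", call. = FALSE)
  }
  (edv - esv) / edv
}

#' Assemble validated patient inputs
#'
#' The complete set of patient-specific calibration inputs for the
#' lumped-parameter model. Either build directly (precomputed dialect) or
#' derive from raw Doppler measurements with [build_patient_inputs()].
#'
#' @param forward_lvot_sv forward LVOT stroke volume (mL).
#' @param T cardiac cycle period (s).
#' @param t_ej systolic ejection time (s), `< T`.
#' @param eoa_av aortic valve effective orifice area (cm^2), `< a_ao`.
#' @param eoa_mv mitral valve effective orifice area (cm^2).
#' @param a_ao ascending aorta cross-sectional area (cm^2).
#' @param a_lvot LVOT cross-sectional area (cm^2).
#' @param eoa_ar,eoa_mr regurgitant EOAs (cm^2) or `NULL` when the valve is
#'   competent (the regurgitant branch is then omitted from the network).
#' @param sbp,dbp brachial systolic/diastolic cuff pressures (mmHg).
#' @param edv,esv optional measured end-diastolic/systolic volumes (mL).
#' @return An object of class `patient_inputs`.
#' @export
patient_inputs <- function(forward_lvot_sv, T, t_ej, eoa_av, eoa_mv,
                           a_ao, a_lvot, eoa_ar = NULL, eoa_mr = NULL,
                           sbp, dbp, edv = NULL, esv = NULL) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(forward_lvot_sv) && forward_lvot_sv > 0,
      "forward_lvot_sv must be positive (mL)")
  chk(is.numeric(T) && T > 0, "cycle period T must be positive (s)")
  chk(is.numeric(t_ej) && t_ej > 0 && t_ej < T,
      "ejection time t_ej must lie in (0, T) (s)")
  chk(is.numeric(eoa_av) && eoa_av > 0, "eoa_av must be positive (cm^2)")
  chk(is.numeric(eoa_mv) && eoa_mv > 0, "eoa_mv must be positive (cm^2)")
  chk(is.numeric(a_ao) && a_ao > 0, "a_ao must be positive (cm^2)")
  chk(is.numeric(a_lvot) && a_lvot > 0, "a_lvot must be positive (cm^2)")
  chk(is.numeric(sbp) && is.numeric(dbp) && sbp > dbp && dbp > 0,
      "require sbp > dbp > 0 (mmHg)")
  if (is.numeric(eoa_av) && is.numeric(a_ao) && eoa_av >= a_ao) {
    problems <- c(problems, paste0(
      "eoa_av (", eoa_av, " cm^2) must be smaller than the aortic area a_ao (",
      a_ao, " cm^2): the energy loss coefficient is undefined otherwise"))
  }
  if (!is.null(eoa_ar)) {
    chk(is.numeric(eoa_ar) && eoa_ar > 0, "eoa_ar must be positive (cm^2)")
    if (is.numeric(eoa_ar) && is.numeric(a_lvot) && eoa_ar >= a_lvot) {
      problems <- c(problems,
                    "eoa_ar must be smaller than the LVOT area a_lvot")
    }
  }
  if (!is.null(eoa_mr)) {
    chk(is.numeric(eoa_mr) && eoa_mr > 0, "eoa_mr must be positive (cm^2)")
  }
  if (!is.null(edv) || !is.null(esv)) {
    chk(is.numeric(edv) && is.numeric(esv) && edv > esv && esv >= 0,
        "when supplied, volumes must satisfy edv > esv >= 0 (mL)")
  }
  if (length(problems) > 0) {
    stop("invalid patient inputs:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(
    list(forward_lvot_sv = forward_lvot_sv, T = T, t_ej = t_ej,
         eoa_av = eoa_av, eoa_mv = eoa_mv, a_ao = a_ao, a_lvot = a_lvot,
         eoa_ar = eoa_ar, eoa_mr = eoa_mr, sbp = sbp, dbp = dbp,
         edv = edv, esv = esv),
    class = "patient_inputs"
  )
}

#' @export
print.patient_inputs <- function(x, ...) {
  cat("Patient inputs (lumped-parameter model)\n")
  cat(sprintf("  forward LVOT SV : %.1f mL\n", x$forward_lvot_sv))
  cat(sprintf("  cycle period    : %.3f s (HR %.1f bpm), ejection %.3f s\n",
              x$T, 60 / x$T, x$t_ej))
  cat(sprintf("  aortic valve    : EOA %.2f cm^2 (aorta %.2f, LVOT %.2f cm^2)\n",
              x$eoa_av, x$a_ao, x$a_lvot))
  cat(sprintf("  mitral valve    : EOA %.2f cm^2\n", x$eoa_mv))
  cat(sprintf("  regurgitation   : AR %s, MR %s (REOA cm^2)\n",
              if (is.null(x$eoa_ar)) "none" else sprintf("%.2f", x$eoa_ar),
              if (is.null(x$eoa_mr)) "none" else sprintf("%.2f", x$eoa_mr)))
  cat(sprintf("  cuff pressures  : %g/%g mmHg\n", x$sbp, x$dbp))
  if (!is.null(x$edv)) {
    cat(sprintf("  volumes         : EDV %.0f, ESV %.0f mL (EF %.0f%%)\n",
                x$edv, x$esv, 100 * ejection_fraction(x$edv, x$esv)))
  }
  invisible(x)
}

#' Doppler measurement record
#'
#' Raw echocardiographic measurements from which all model inputs are
#' derived; see [build_patient_inputs()] for the derivation chain.
#'
#' @param d_lvot,vti_lvot LVOT diameter and velocity-time integral (cm).
#' @param d_ao,vti_ao ascending aorta diameter and VTI (cm).
#' @param d1_mv,d2_mv mitral diameters in the apical 2- and 4-chamber views (cm).
#' @param hr heart rate (bpm), in (20, 250).
#' @param t_ej systolic ejection time (s).
#' @param ar_grade,mr_grade qualitative regurgitation grades, see
#'   [grade_to_regurgitant_eoa()].
#' @param sbp,dbp brachial cuff pressures (mmHg).
#' @param a1,a2,l1,l2 optional biplane LV areas (cm^2) and lengths (cm) at
#'   one cardiac phase pair, used to derive EDV/ESV.
#' @param edv,esv optional volumes (mL), overriding the biplane derivation.
#' @return An object of class `doppler_measurements`.
#' @export
doppler_measurements <- function(d_lvot, vti_lvot, d_ao, vti_ao,
                                 d1_mv, d2_mv, hr, t_ej,
                                 ar_grade = "none", mr_grade = "none",
                                 sbp, dbp,
                                 a1 = NULL, a2 = NULL, l1 = NULL, l2 = NULL,
                                 edv = NULL, esv = NULL) {
  if (!is.numeric(hr) || hr <= 20 || hr >= 250) {
    stop("heart rate must lie in (20, 250) bpm", call. = FALSE)
  }
  for (v in list(d_lvot, vti_lvot, d_ao, vti_ao, d1_mv, d2_mv, t_ej, sbp, dbp)) {
    if (!is.numeric(v) || v <= 0) {
      stop("all lengths, VTIs, times and pressures must be positive",
           call. = FALSE)
    }
  }
  structure(
    list(d_lvot = d_lvot, vti_lvot = vti_lvot, d_ao = d_ao, vti_ao = vti_ao,
         d1_mv = d1_mv, d2_mv = d2_mv, hr = hr, t_ej = t_ej,
         ar_grade = ar_grade, mr_grade = mr_grade, sbp = sbp, dbp = dbp,
         a1 = a1, a2 = a2, l1 = l1, l2 = l2, edv = edv, esv = esv),
    class = "doppler_measurements"
  )
}

#' Derive model inputs from raw Doppler measurements
#'
#' Applies the full derivation chain: forward LVOT stroke volume from the
#' LVOT diameter and VTI; aortic and LVOT areas from their diameters; aortic
#' EOA by the continuity equation; elliptical mitral area from the two
#' apical-view diameters; regurgitant EOAs from the qualitative grades;
#' cycle period from heart rate (`T = 60/HR`); optional biplane-ellipsoid
#' EDV/ESV. Invariant violations are collected and reported together.
#'
#' @param m a [doppler_measurements()] record.
#' @return A validated [patient_inputs()] object.
#' @export
build_patient_inputs <- function(m) {
  stopifnot(inherits(m, "doppler_measurements"))
  sv <- forward_lvot_sv(m$d_lvot, m$vti_lvot)
  patient_inputs(
    forward_lvot_sv = sv,
    T = 60 / m$hr,
    t_ej = m$t_ej,
    eoa_av = eoa_by_continuity(sv, m$vti_ao),
    eoa_mv = mitral_area(m$d1_mv, m$d2_mv),
    a_ao = circular_area(m$d_ao),
    a_lvot = circular_area(m$d_lvot),
    eoa_ar = grade_to_regurgitant_eoa(m$ar_grade),
    eoa_mr = grade_to_regurgitant_eoa(m$mr_grade),
    sbp = m$sbp, dbp = m$dbp,
    edv = m$edv, esv = m$esv
  )
}
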