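#' Double-Hill elastance parameters for a heart chamber
#'
#' Container for the parameters of the normalized double-Hill time-varying
#' elastance curve that drives chamber contraction. The ascending Hill term
#' models cooperative myocyte recruitment during contraction, the descending
#' term models relaxation. Times are expressed as fractions of the cardiac
#' cycle period `T`, so one parameter set serves any heart rate.
#'
#' @param e_max maximum elastance (mmHg/mL), slope of the end-systolic
#'   pressure-volume relation.
#' @param e_min minimum (diastolic) elastance (mmHg/mL).
#' @param m1,m2 dimensionless ascending / descending Hill gradients.
#' @param tau1_frac,tau2_frac ascending / descending time translations as
#'   fractions of the cycle period.
#' @param onset_frac contraction onset as a fraction of the cycle period
#'   (0 for the LV; 0.85 for the LA, i.e. atrial contraction begins 0.15 T
#'   before the ventricular onset of the next beat).
#' @return An object of class `elastance_params`. The normalization constant
#'   `n_norm = (e_max - e_min)/2` is derived, not user-set.
#' @seealso [lv_elastance_params()], [la_elastance_params()],
#'   [normalized_elastance()]
#' @export
elastance_params <- function(e_max, e_min, m1, m2, tau1_frac, tau2_frac,
                             onset_frac = 0) {
  stopifnot(is.numeric(e_max), is.numeric(e_min))
  if (!(e_max >= e_min && e_min > 0)) {
    stop("require e_max >= e_min > 0", call. = FALSE)
  }
  if (m1 <= 0 || m2 <= 0) stop("Hill gradients m1, m2 must be positive", call. = FALSE)
  if (!(tau1_frac > 0 && tau1_frac < tau2_frac && tau2_frac < 1)) {
    stop("require 0 < tau1_frac < tau2_frac < 1", call. = FALSE)
  }
  if (onset_frac < 0 || onset_frac >= 1) {
    stop("onset_frac must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(e_max = e_max, e_min = e_min, m1 = m1, m2 = m2,
         tau1_frac = tau1_frac, tau2_frac = tau2_frac,
         onset_frac = onset_frac, n_norm = (e_max - e_min) / 2),
    class = "elastance_params"
  )
}

#' Standard adult left-ventricular elastance parameters
#' @return `elastance_params` for the LV (E_max 2.1, E_min 0.06 mmHg/mL,
#'   m1 1.32, m2 27.4, tau1 0.269 T, tau2 0.452 T, onset 0).
#' @export
lv_elastance_params <- function() {
  elastance_params(e_max = 2.1, e_min = 0.06, m1 = 1.32, m2 = 27.4,
                   tau1_frac = 0.269, tau2_frac = 0.452, onset_frac = 0)
}

#' Standard adult left-atrial elastance parameters
#' @return `elastance_params` for the LA (E_max 0.17, E_min 0.06 mmHg/mL,
#'   m1 1.32, m2 13.1, tau1 0.110 T, tau2 0.18 T, onset 0.85 T).
#' @export
la_elastance_params <- function() {
  elastance_params(e_max = 0.17, e_min = 0.06, m1 = 1.32, m2 = 13.1,
                   tau1_frac = 0.110, tau2_frac = 0.18, onset_frac = 0.85)
}

#' Chamber configuration: elastance parameters plus unloaded volume
#'
#' @param params an [elastance_params()] object.
#' @param v0 unloaded volume (mL), the volume at which the chamber generates
#'   zero pressure. Defaults to 0; for the LV it may be adjusted during
#'   calibration so the simulated end-diastolic volume matches a measured one.
#' @param label chamber identifier, `"LV"` or `"LA"`.
#' @return An object of class `chamber_config`.
#' @export
chamber_config <- function(params, v0 = 0, label = c("LV", "LA")) {
  label <- match.arg(label)
  stopifnot(inherits(params, "elastance_params"), is.finite(v0))
  structure(list(params = params, v0 = v0, label = label),
            class = "chamber_config")
}

# raw product of the ascending and descending Hill terms at cycle time tp
hill_product <- function(tp, m1, m2, tau1, tau2) {
  x1 <- (tp / tau1)^m1
  x2 <- (tp / tau2)^m2
  h <- (x1 / (1 + x1)) * (1 / (1 + x2))
  h[tp <= 0] <- 0
  h
}

#' Normalized double-Hill elastance
#'
#' Evaluates the dimensionless elastance curve
#' \deqn{E_N(t') = N \frac{(t'/\tau_1)^{m_1}}{1 + (t'/\tau_1)^{m_1}}
#'   \frac{1}{1 + (t'/\tau_2)^{m_2}} + E_{min}}
#' with \eqn{t' = (t - \mathrm{onset} \cdot T) \bmod T},
#' \eqn{\tau_i = \mathrm{tau_i\_frac} \cdot T} and
#' \eqn{N = (E_{max} - E_{min})/2}. Periodic in `T`; the onset shift lets the
#' atrial curve wrap across the cycle boundary.
#'
#' @param t time (s), vectorized.
#' @param T cycle period (s).
#' @param params an [elastance_params()] object.
#' @return Dimensionless elastance values, `>= e_min`.
#' @export
normalized_elastance <- function(t, T, params) {
  stopifnot(inherits(params, "elastance_params"))
  if (!is.numeric(T) || T <= 0) stop("cycle period T must be positive", call. = FALSE)
  tau1 <- params$tau1_frac * T
  tau2 <- params$tau2_frac * T
  if (tau1 <= 0 || tau2 <= 0) stop("tau values must be positive", call. = FALSE)
  tp <- (t - params$onset_frac * T) %% T
  params$n_norm * hill_product(tp, params$m1, params$m2, tau1, tau2) +
    params$e_min
}

# peak of the raw Hill product over one cycle (dense grid)
peak_hill_product <- function(params, n = 4096) {
  tp <- seq(0, 1, length.out = n)
  max(hill_product(tp, params$m1, params$m2, params$tau1_frac,
                   params$tau2_frac))
}

#' Dimensional chamber elastance
#'
#' Converts the normalized double-Hill curve into mmHg/mL under one of three
#' scaling strategies:
#' \describe{
#'   \item{`"literal-eq3"`}{reads the normalized curve directly as mmHg/mL
#'     (its constants already carry elastance units).}
#'   \item{`"emax-scaled"`}{multiplies the normalized curve by `e_max`, the
#'     literal composition of the normalized-elastance definition with the
#'     double-Hill curve.}
#'   \item{`"peak-rescaled"` (default)}{affinely rescales the raw Hill
#'     product so the curve attains exactly `e_max` at its peak and `e_min`
#'     at its trough. This honors the definition of a normalized elastance
#'     curve (unit peak) and yields physiological atrial volumes, so it is
#'     the default.}
#' }
#' The strategy in force is recorded in simulation run metadata.
#'
#' @param t time (s), vectorized.
#' @param T cycle period (s).
#' @param cfg a [chamber_config()].
#' @param strategy scaling strategy, see Details.
#' @return Elastance in mmHg/mL.
#' @export
chamber_elastance <- function(t, T, cfg,
                              strategy = c("peak-rescaled", "emax-scaled",
                                           "literal-eq3")) {
  stopifnot(inherits(cfg, "chamber_config"))
  if (is.character(strategy)) {
    strategy <- match.arg(strategy)
  } else {
    stop("unknown elastance scaling strategy", call. = FALSE)
  }
  p <- cfg$params
  en <- normalized_elastance(t, T, p)
  switch(strategy,
    "literal-eq3" = en,
    "emax-scaled" = p$e_max * en,
    "peak-rescaled" = {
      pk <- peak_hill_product(p)
      tp <- (t - p$onset_frac * T) %% T
      raw <- hill_product(tp, p$m1, p$m2, p$tau1_frac * T, p$tau2_frac * T)
      (p$e_max - p$e_min) * raw / pk + p$e_min
    }
  )
}

# affine representation E(t) = a * h1h2(t') + b used by the C++ core
elastance_affine <- function(cfg, strategy) {
  p <- cfg$params
  switch(strategy,
    "literal-eq3" = list(a = p$n_norm, b = p$e_min),
    "emax-scaled" = list(a = p$e_max * p$n_norm, b = p$e_max * p$e_min),
    "peak-rescaled" = list(a = (p$e_max - p$e_min) / peak_hill_product(p),
                           b = p$e_min),
    stop("unknown elastance scaling strategy", call. = FALSE)
  )
}

#' Chamber pressure from the elastance relation
#'
#' \eqn{P = E \, (V - V_0)}: instantaneous pressure generated by a chamber of
#' elastance `e` at volume `v` above its unloaded volume `v0`. Volumes below
#' `v0` yield negative pressures.
#'
#' @param v chamber volume (mL).
#' @param e elastance (mmHg/mL), `>= 0`.
#' @param v0 unloaded volume (mL).
#' @return Pressure in mmHg.
#' @export
chamber_pressure <- function(v, e, v0 = 0) {
  if (any(e < 0)) stop("elastance must be non-negative", call. = FALSE)
  e * (v - v0)
}
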