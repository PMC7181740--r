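# Net-pressure-gradient valve models.
#
# Each valve branch is an inertance in series with a flow-dependent
# (Bernoulli) resistance: PG_net = L dQ/dt + k Q|Q|, computed in dyn/cm^2
# and converted to mmHg. Aortic branches use the energy-loss coefficient
# (EOA corrected for downstream pressure recovery); mitral branches use the
# EOA directly, pressure recovery being negligible in the large LV/LA.

DYN_PER_MMHG <- 1333.22

#' Energy loss coefficient of a valve orifice
#'
#' Corrects an effective orifice area for pressure recovery in the receiving
#' vessel of cross-section `ref_area`:
#' `elco = eoa * ref_area / (ref_area - eoa)`. Always greater than `eoa`;
#' diverges as the orifice approaches the vessel area (no recovery margin)
#' and tends to `eoa` for an orifice discharging into a very large chamber.
#'
#' @param eoa effective orifice area (cm^2).
#' @param ref_area receiving cross-sectional area (cm^2): ascending aorta for
#'   the forward aortic valve, LVOT for the aortic regurgitant jet.
#' @return Energy loss coefficient (cm^2).
#' @export
energy_loss_coefficient <- function(eoa, ref_area) {
  if (any(eoa <= 0)) stop("eoa must be positive", call. = FALSE)
  if (any(eoa >= ref_area)) {
    stop("eoa must be smaller than the receiving area (coefficient undefined)",
         call. = FALSE)
  }
  eoa * ref_area / (ref_area - eoa)
}

#' Instantaneous net pressure gradient across the aortic valve
#'
#' `dp = (2 pi rho / sqrt(elco)) dQ/dt + (rho / (2 elco^2)) Q|Q|`, evaluated
#' in dyn/cm^2 and returned in mmHg. The signed convective term `Q|Q|` keeps
#' the formulation direction-consistent for transient reverse flow.
#'
#' @param q transvalvular flow (mL/s).
#' @param dqdt flow acceleration (mL/s^2).
#' @param elco energy loss coefficient (cm^2), see
#'   [energy_loss_coefficient()].
#' @param rho blood density (g/cm^3).
#' @return Net pressure gradient (mmHg).
#' @export
aortic_net_gradient <- function(q, dqdt, elco, rho = 1.05) {
  if (any(elco <= 0)) stop("elco must be positive", call. = FALSE)
  ((2 * pi * rho / sqrt(elco)) * dqdt +
     (rho / (2 * elco^2)) * q * abs(q)) / DYN_PER_MMHG
}

#' Instantaneous net pressure gradient across the mitral valve
#'
#' `dp = (m_mv / eoa) dQ/dt + (rho / (2 eoa^2)) Q|Q|` in dyn/cm^2, returned
#' in mmHg. Pressure recovery is ignored (large receiving chamber). The same
#' formulation serves the regurgitant branch with the regurgitant EOA.
#'
#' @param q transvalvular flow (mL/s).
#' @param dqdt flow acceleration (mL/s^2).
#' @param eoa effective orifice area (cm^2).
#' @param m_mv mitral inertance constant (g/cm^2), default 0.53.
#' @param rho blood density (g/cm^3).
#' @return Net pressure gradient (mmHg).
#' @export
mitral_net_gradient <- function(q, dqdt, eoa, m_mv = 0.53, rho = 1.05) {
  if (any(eoa <= 0)) stop("eoa must be positive", call. = FALSE)
  if (m_mv <= 0) stop("m_mv must be positive", call. = FALSE)
  ((m_mv / eoa) * dqdt + (rho / (2 * eoa^2)) * q * abs(q)) / DYN_PER_MMHG
}

#' Map a qualitative regurgitation grade to a representative regurgitant EOA
#'
#' Colour-Doppler regurgitation severity is graded qualitatively; each grade
#' maps to a representative regurgitant effective orifice area on the
#' clinical cm^2 scale. `"none"` maps to `NULL`: the regurgitant branch is
#' omitted from the network entirely.
#'
#' @param grade one of `"none"`, `"mild"`, `"mild-moderate"`,
#'   `"moderate-severe"`, `"severe"`.
#' @return Regurgitant EOA in cm^2, or `NULL` for `"none"`.
#' @export
grade_to_regurgitant_eoa <- function(grade) {
  grades <- c("none" = NA, "mild" = 0.05, "mild-moderate" = 0.10,
              "moderate-severe" = 0.25, "severe" = 0.35)
  if (!is.character(grade) || length(grade) != 1 || !grade %in% names(grades)) {
    stop("unknown regurgitation grade: ",
         paste(deparse(grade), collapse = ""),
         " (expected one of ", paste(names(grades), collapse = ", "), ")",
         call. = FALSE)
  }
  val <- grades[[grade]]
  if (is.na(val)) NULL else val
}

#' Valve branch specification
#'
#' Bundles the geometry of one valve branch and precomputes the inertance
#' `L` and convective coefficient `k` (both in mmHg-based units) used by the
#' circulation network: aortic branches take
#' `L = 2 pi rho / sqrt(elco)`, mitral branches `L = m_mv / eoa`; both take
#' `k = rho / (2 area^2)` with `area` the energy-loss coefficient (aortic)
#' or the EOA itself (mitral).
#'
#' @param eoa effective orifice area (cm^2).
#' @param kind `"aortic"` or `"mitral"`.
#' @param ref_area receiving area (cm^2), required for aortic branches.
#' @param m_mv mitral inertance constant (g/cm^2).
#' @param rho blood density (g/cm^3).
#' @return An object of class `valve_spec` with elements `l` (mmHg s^2/mL)
#'   and `k` (mmHg s^2/mL^2).
#' @export
valve_spec <- function(eoa, kind = c("aortic", "mitral"), ref_area = NULL,
                       m_mv = 0.53, rho = 1.05) {
  kind <- match.arg(kind)
  if (!is.numeric(eoa) || eoa <= 0) stop("eoa must be positive", call. = FALSE)
  if (kind == "aortic") {
    if (is.null(ref_area)) {
      stop("aortic branches need a receiving reference area", call. = FALSE)
    }
    elco <- energy_loss_coefficient(eoa, ref_area)
    l <- 2 * pi * rho / sqrt(elco) / DYN_PER_MMHG
    k <- rho / (2 * elco^2) / DYN_PER_MMHG
    area_eff <- elco
  } else {
    l <- m_mv / eoa / DYN_PER_MMHG
    k <- rho / (2 * eoa^2) / DYN_PER_MMHG
    area_eff <- eoa
  }
  structure(list(eoa = eoa, kind = kind, ref_area = ref_area,
                 m_mv = m_mv, rho = rho, area_eff = area_eff,
                 l = l, k = k),
            class = "valve_spec")
}

#' Diode state update for a valve branch
#'
#' A closed branch opens (with zero initial flow) when its driving pressure
#' turns positive; an open branch closes, clamping its flow to zero, once the
#' flow has decayed to zero under a non-positive driving pressure. Flow is
#' never negative in the branch direction.
#'
#' @param state a list with elements `q` (flow, mL/s) and `open` (logical).
#' @param driving_dp driving pressure difference across the branch (mmHg).
#' @return The updated state list.
#' @export
update_branch_state <- function(state, driving_dp) {
  stopifnot(is.list(state), is.numeric(state$q), is.logical(state$open))
  q <- max(state$q, 0)
  open <- state$open
  if (!open && driving_dp > 0) {
    open <- TRUE
    q <- 0
  } else if (open && q <= 0 && driving_dp <= 0) {
    open <- FALSE
    q <- 0
  }
  list(q = q, open = open)
}
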