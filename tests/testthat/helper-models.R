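# Shared fixtures: patient records are built in code, no files needed.

# a patient record from the usual clinical scalars, with the geometric
# defaults (aorta 3.0 cm, LVOT 2.0 cm) used throughout the tests
make_patient <- function(eoa_av = 3.0, eoa_mv = 4.0, eoa_ar = NULL,
                         eoa_mr = NULL, sbp = 120, dbp = 80, sv = 70,
                         hr = 70, t_ej_frac = 0.3, edv = NULL, esv = NULL) {
  T <- 60 / hr
  patient_inputs(
    forward_lvot_sv = sv, T = T, t_ej = t_ej_frac * T,
    eoa_av = eoa_av, eoa_mv = eoa_mv,
    a_ao = circular_area(3.0), a_lvot = circular_area(2.0),
    eoa_ar = eoa_ar, eoa_mr = eoa_mr,
    sbp = sbp, dbp = dbp, edv = edv, esv = esv
  )
}

# Patient #1-like pre-intervention state: severe AS, mild AR, moderate-to-
# severe MR, wide pulse pressure
make_severe_combined_patient <- function() {
  make_patient(eoa_av = 0.5, eoa_ar = 0.05, eoa_mr = 0.25,
               sbp = 115, dbp = 40, sv = 54, hr = 70.7)
}

# one healthy steady simulation, shared across tests (computed lazily once)
healthy_steady_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_lpm(lpm_model(make_patient()))
    }
    cache
  }
})
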