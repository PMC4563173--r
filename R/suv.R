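#' SUV calibration parameters
#'
#' Bundles the quantities needed to convert a PET activity-concentration
#' volume (Bq/ml) into body-weight standardized uptake values.
#'
#' @param injected_activity_mbq Injected activity in MBq (decay-uncorrected,
#'   at injection time).
#' @param injection_to_scan_min Minutes between injection and scan start.
#' @param patient_weight_kg Patient weight in kg.
#' @param isotope_half_life_min Isotope half-life in minutes; defaults to
#'   fluorine-18 (109.77 min), the isotope of both FDG and FLT.
#' @return An object of class `suv_calibration`.
#' @export
suv_calibration <- function(injected_activity_mbq,
                            injection_to_scan_min,
                            patient_weight_kg,
                            isotope_half_life_min = 109.77) {
  vals <- c(injected_activity = injected_activity_mbq,
            interval = injection_to_scan_min,
            weight = patient_weight_kg,
            half_life = isotope_half_life_min)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    stop(sprintf("suv_calibration: %s must be strictly positive",
                 paste(bad, collapse = ", ")))
  structure(list(injected_activity_mbq = injected_activity_mbq,
                 injection_to_scan_min = injection_to_scan_min,
                 patient_weight_kg = patient_weight_kg,
                 isotope_half_life_min = isotope_half_life_min),
            class = "suv_calibration")
}

#' Convert PET activity concentration to SUV
#'
#' Body-weight SUV: `SUV = C / (D / W)` with `C` the activity concentration
#' in Bq/ml, `D` the injected activity in Bq and `W` the patient weight in
#' grams, taking tissue density as 1 g/ml so the result is dimensionless.
#' With `decay_correct = TRUE` (the default) the injected activity is
#' decayed from injection time to scan start, `D_scan = D * 2^(-t/T_half)`,
#' the convention under which a uniform tracer distribution has SUV 1 at any
#' time point; SUV values then increase by `2^(t/T_half)` relative to the
#' uncorrected quotient.
#'
#' @param pet `voxel_grid` of activity concentration in Bq/ml.
#' @param cal A [suv_calibration()].
#' @param decay_correct Logical; decay-correct the injected dose to scan
#'   start (default `TRUE`).
#' @return A PET-role `voxel_grid` of dimensionless SUV values.
#' @export
compute_suv <- function(pet, cal, decay_correct = TRUE) {
  stopifnot(inherits(pet, "voxel_grid"), inherits(cal, "suv_calibration"))
  if (any(pet$data < 0, na.rm = TRUE))
    stop("compute_suv: PET activity concentrations must be non-negative (Bq/ml)")
  dose_bq <- cal$injected_activity_mbq * 1e6
  if (decay_correct)
    dose_bq <- dose_bq * 2^(-cal$injection_to_scan_min / cal$isotope_half_life_min)
  weight_g <- cal$patient_weight_kg * 1000
  suv <- pet$data / (dose_bq / weight_g)
  voxel_grid(suv, pet$spacing, pet$origin, role = "PET")
}
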