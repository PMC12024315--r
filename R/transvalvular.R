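#' Blood rheology and density parameters
#'
#' Shear-thinning (Carreau-Yasuda) blood model. Defaults are the parameter
#' set standard in valve CFD work: density 1050 kg/m3, zero-shear viscosity
#' 0.16 Pa.s, infinite-shear viscosity 0.0035 Pa.s, power constant
#' n = 0.2128, transition parameter a = 0.64, relaxation time lambda = 8.2 s.
#'
#' @param density blood density (kg/m3).
#' @param mu0 zero-shear viscosity (Pa.s).
#' @param mu_inf infinite-shear viscosity (Pa.s).
#' @param n power-law constant (dimensionless).
#' @param a transition parameter (dimensionless).
#' @param lambda relaxation time (s).
#' @return A list of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1050, mu0 = 0.16, mu_inf = 0.0035,
                             n = 0.2128, a = 0.64, lambda = 8.2) {
  if (!(mu0 > mu_inf && mu_inf > 0)) {
    stop("fluid_properties: require mu0 > mu_inf > 0", call. = FALSE)
  }
  if (lambda <= 0) stop("fluid_properties: lambda must be > 0",
                        call. = FALSE)
  if (density <= 0) stop("fluid_properties: density must be > 0",
                         call. = FALSE)
  structure(list(density = density, mu0 = mu0, mu_inf = mu_inf,
                 n = n, a = a, lambda = lambda),
            class = "fluid_properties")
}

#' Carreau-Yasuda apparent viscosity
#'
#' `mu(g) = mu_inf + (mu0 - mu_inf) * (1 + (lambda * g)^a)^((n - 1) / a)`,
#' monotone non-increasing in the shear rate `g`, with limits `mu0` at zero
#' shear and `mu_inf` at infinite shear.
#'
#' @param shear_rate shear rate (1/s), vectorized; must be non-negative.
#' @param props a [fluid_properties()] object.
#' @return Apparent viscosity (Pa.s).
#' @export
carreau_yasuda_viscosity <- function(shear_rate, props = fluid_properties()) {
  if (any(shear_rate < 0)) {
    stop("carreau_yasuda_viscosity: shear rate must be >= 0", call. = FALSE)
  }
  props$mu_inf + (props$mu0 - props$mu_inf) *
    (1 + (props$lambda * shear_rate)^props$a)^((props$n - 1) / props$a)
}

#' Simplified-Bernoulli pressure gradient from peak velocity
#'
#' The clinical relation `DP = 4 * v^2` (mmHg from m/s); the constant 4
#' absorbs the 1/2 * rho factor and the Pa-to-mmHg conversion.
#'
#' @param v peak transvalvular velocity (m/s), vectorized, non-negative.
#' @return Peak gradient (mmHg).
#' @export
dp_from_vmax <- function(v) {
  if (any(v < 0)) stop("dp_from_vmax: velocity must be >= 0", call. = FALSE)
  4 * v^2
}

#' Peak velocity implied by a simplified-Bernoulli gradient
#'
#' @param dp peak gradient (mmHg), vectorized, non-negative.
#' @return Peak velocity (m/s); inverse of [dp_from_vmax()].
#' @export
vmax_from_dp <- function(dp) {
  if (any(dp < 0)) stop("vmax_from_dp: gradient must be >= 0", call. = FALSE)
  sqrt(dp / 4)
}

#' Peak velocity from flow rate and effective orifice area
#'
#' Continuity through the effective orifice: `v = (q / eoa) / 100`, with `q`
#' in ml/s and `eoa` in cm2 giving cm/s, converted to m/s.
#'
#' @param q_peak peak systolic flow rate (ml/s), non-negative.
#' @param eoa effective orifice area (cm2), positive.
#' @return Peak velocity (m/s).
#' @export
vmax_from_flow <- function(q_peak, eoa) {
  if (any(eoa <= 0)) stop("vmax_from_flow: eoa must be > 0", call. = FALSE)
  if (any(q_peak < 0)) stop("vmax_from_flow: flow must be >= 0",
                            call. = FALSE)
  (q_peak / eoa) / 100
}

#' Effective orifice area calibrated from flow and gradient
#'
#' Closed-form inversion of the continuity + simplified-Bernoulli chain:
#' `eoa = q / (100 * sqrt(dp / 4))`. Useful for backing EOA out of observed
#' (flow, gradient) pairs instead of relying on manufacturer charts.
#'
#' @param q_peak peak systolic flow rate (ml/s), positive.
#' @param dp peak gradient (mmHg), positive.
#' @return EOA (cm2) such that `dp_from_vmax(vmax_from_flow(q_peak, eoa))`
#'   reproduces `dp`.
#' @export
calibrate_eoa <- function(q_peak, dp) {
  if (any(dp <= 0)) {
    stop("calibrate_eoa: gradient must be > 0 (zero gradient implies an ",
         "infinite orifice)", call. = FALSE)
  }
  if (any(q_peak <= 0)) stop("calibrate_eoa: flow must be > 0",
                             call. = FALSE)
  q_peak / (100 * vmax_from_dp(dp))
}

#' Scale a resting flow rate to a physical-stress state
#'
#' Physical activity (or patient growth) is modelled as a uniform relative
#' increase in peak systolic flow rate; the default factor 1.25 is the 25%
#' increase measured in exercise studies of aortic stenosis patients. Under
#' a fixed orifice the implied gradient ratio is `factor^2` (1.5625 for the
#' default).
#'
#' @param q_rest resting peak systolic flow rate (ml/s), non-negative.
#' @param factor multiplicative increase (> 0), default 1.25.
#' @return Stress-state flow rate (ml/s).
#' @export
apply_stress <- function(q_rest, factor = 1.25) {
  if (any(q_rest < 0)) stop("apply_stress: flow must be >= 0", call. = FALSE)
  if (factor <= 0) stop("apply_stress: factor must be > 0", call. = FALSE)
  q_rest * factor
}

#' Murray's-law outflow split for the aortic arch branches
#'
#' The arch flow (inlet minus descending aorta) is distributed with the
#' brachiocephalic trunk (BCT) carrying half of it — equal to the combined
#' flow of the left common carotid (LCC) and left subclavian (LSA) — and the
#' LCC/LSA sharing the other half in proportion to their diameters raised to
#' the Murray exponent (3 for the classic law).
#'
#' @param q_inlet inlet flow (ml/s).
#' @param q_descending descending-aorta flow (ml/s), `<= q_inlet`.
#' @param d_lcc,d_lsa branch diameters (mm), positive.
#' @param exponent Murray exponent (default 3).
#' @return A list of class `outflow_split` with `q_inlet`, `q_descending`
#'   and `flows`, a named vector over `BCT`, `LCC`, `LSA` (ml/s) summing to
#'   the arch flow.
#' @export
murray_split <- function(q_inlet, q_descending, d_lcc, d_lsa, exponent = 3) {
  if (q_descending < 0 || q_descending > q_inlet) {
    stop("murray_split: require 0 <= q_descending <= q_inlet",
         call. = FALSE)
  }
  if (d_lcc <= 0 || d_lsa <= 0) {
    stop("murray_split: branch diameters must be > 0", call. = FALSE)
  }
  q_arch <- q_inlet - q_descending
  bct <- q_arch / 2
  w <- c(d_lcc, d_lsa)^exponent
  lcc_lsa <- (q_arch / 2) * w / sum(w)
  structure(list(q_inlet = q_inlet, q_descending = q_descending,
                 flows = c(BCT = bct, LCC = lcc_lsa[1], LSA = lcc_lsa[2])),
            class = "outflow_split")
}

#' Predict per-size, per-state transvalvular outcomes for a cohort
#'
#' Applies the reduced-order chain (continuity through the EOA, simplified
#' Bernoulli, stress scaling) to each patient of a characteristics table,
#' for the three candidate sizes (one smaller, reference, one larger) at
#' rest and under stress.
#'
#' @param cohort data frame with at least `patient_id`,
#'   `reference_valve_size` (mm) and `peak_systolic_flow` (ml/s), e.g.
#'   `load_fixture("table1")`.
#' @param eoa_by_size named numeric, valve label size (mm) to EOA (cm2);
#'   must cover one size below and above each reference.
#' @param stress_factor flow increase under stress (default 1.25).
#' @return Data frame with one row per (patient, size class, state):
#'   `patient_id, valve_size_mm, size_class, state, q_mls, eoa_cm2,
#'   vmax_mps, dp_mmhg`.
#' @export
predict_cohort <- function(cohort, eoa_by_size, stress_factor = 1.25) {
  need <- c("patient_id", "reference_valve_size", "peak_systolic_flow")
  if (!all(need %in% names(cohort))) {
    stop("predict_cohort: cohort must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  sizes_avail <- as.numeric(names(eoa_by_size))
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    sizes <- neighbour_sizes(cohort$reference_valve_size[i], sizes_avail)
    cells <- expand.grid(size_class = names(sizes),
                         state = c("rest", "stress"),
                         stringsAsFactors = FALSE)
    size_mm <- sizes[cells$size_class]
    eoa <- eoa_by_size[as.character(size_mm)]
    q <- ifelse(cells$state == "stress",
                apply_stress(cohort$peak_systolic_flow[i], stress_factor),
                cohort$peak_systolic_flow[i])
    vm <- vmax_from_flow(q, eoa)
    data.frame(patient_id = cohort$patient_id[i],
               valve_size_mm = as.numeric(size_mm),
               size_class = cells$size_class, state = cells$state,
               q_mls = q, eoa_cm2 = as.numeric(eoa), vmax_mps = vm,
               dp_mmhg = dp_from_vmax(vm), row.names = NULL)
  })
  do.call(rbind, rows)
}
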