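#' Aortic stenosis severity from peak jet velocity
#'
#' Standard echo grading by peak velocity: below 2.5 m/s not stenotic,
#' 2.5 to <3.0 m/s mild, 3.0 to 4.0 m/s moderate, above 4 m/s severe.
#' Boundary values fall in the lower grade at 2.5 (mild) and 4.0 (moderate);
#' "severe" requires strictly more than 4 m/s.
#'
#' @param vmax peak velocity (m/s), vectorized, non-negative.
#' @param thresholds named numeric with `mild`, `moderate`, `severe` lower
#'   bounds (m/s); the defaults are the conventional 2.5 / 3.0 / 4.0.
#' @return Ordered factor with levels `none < mild < moderate < severe`.
#' @export
stenosis_grade <- function(vmax,
                           thresholds = c(mild = 2.5, moderate = 3.0,
                                          severe = 4.0)) {
  if (any(vmax < 0)) stop("stenosis_grade: velocity must be >= 0",
                          call. = FALSE)
  g <- ifelse(vmax > thresholds[["severe"]], "severe",
       ifelse(vmax >= thresholds[["moderate"]], "moderate",
       ifelse(vmax >= thresholds[["mild"]], "mild", "none")))
  factor(g, levels = c("none", "mild", "moderate", "severe"), ordered = TRUE)
}

#' Patient-prosthesis mismatch class from indexed orifice area
#'
#' PPM is graded on the EOA indexed to body surface area: iEOA above
#' 0.85 cm2/m2 is no mismatch, 0.65-0.85 moderate, below 0.65 severe.
#'
#' @param eoa effective orifice area (cm2), positive.
#' @param bsa body surface area (m2), positive.
#' @return Ordered factor with levels `none < moderate < severe`
#'   (vectorized).
#' @export
ppm_class <- function(eoa, bsa) {
  if (any(eoa <= 0) || any(bsa <= 0)) {
    stop("ppm_class: eoa and bsa must be > 0", call. = FALSE)
  }
  ieoa <- eoa / bsa
  g <- ifelse(ieoa < 0.65, "severe",
       ifelse(ieoa <= 0.85, "moderate", "none"))
  factor(g, levels = c("none", "moderate", "severe"), ordered = TRUE)
}

#' A healthy-reference percentile range for one metric
#'
#' @param metric metric name.
#' @param median healthy median.
#' @param p3,p97 3rd and 97th percentile values, `p3 <= median <= p97`.
#' @param direction which tail is pathological: `"high"` (NFD, flow angle,
#'   gradient, velocity) or `"low"` (WPD).
#' @return A list of class `reference_range`.
#' @export
reference_range <- function(metric, median, p3, p97,
                            direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (!(p3 <= median && median <= p97)) {
    stop("reference_range: require p3 <= median <= p97", call. = FALSE)
  }
  structure(list(metric = metric, median = median, p3 = p3, p97 = p97,
                 direction = direction),
            class = "reference_range")
}

#' Default healthy reference ranges
#'
#' Medians are the published healthy-cohort values (gradient 6 mmHg,
#' peak velocity 1.2 m/s, flow angle 8 degrees, NFD 0.03, WPD 0.75). The
#' 3rd/97th percentile bounds are NOT published for the flow-profile
#' metrics; the values shipped here are synthetic placeholders spanning a
#' plausible healthy band around each median, and should be replaced with
#' cohort-derived percentiles for clinical use.
#'
#' @return Named list of [reference_range()] objects over `dp_mmhg`,
#'   `vmax_mps`, `angle_deg`, `nfd`, `wpd`.
#' @export
healthy_reference_ranges <- function() {
  list(
    dp_mmhg   = reference_range("dp_mmhg",   6,    2.5,  11.5, "high"),
    vmax_mps  = reference_range("vmax_mps",  1.2,  0.8,  1.7,  "high"),
    angle_deg = reference_range("angle_deg", 8,    2,    16,   "high"),
    nfd       = reference_range("nfd",       0.03, 0.005, 0.09, "high"),
    wpd       = reference_range("wpd",       0.75, 0.55, 0.92, "low")
  )
}

#' Flag a value against a healthy percentile range
#'
#' @param value numeric, vectorized.
#' @param range a [reference_range()].
#' @return Factor over `normal`, `above_p97`, `below_p3`.
#' @export
percentile_flag <- function(value, range) {
  if (!inherits(range, "reference_range")) {
    stop("percentile_flag: 'range' must be a reference_range",
         call. = FALSE)
  }
  g <- ifelse(value > range$p97, "above_p97",
       ifelse(value < range$p3, "below_p3", "normal"))
  factor(g, levels = c("normal", "above_p97", "below_p3"))
}

#' Grade a cohort results table
#'
#' Appends clinical classification columns to a long results table: peak
#' velocity (backed out of the gradient where absent), stenosis grade,
#' percentile flags for every metric with a reference range, and — when
#' `bsa` and `eoa_cm2` are available — the PPM class.
#'
#' @param results data frame with at least `dp_mmhg` (and optionally
#'   `vmax_mps`, `nfd`, `wpd`, `angle_deg`, `eoa_cm2`).
#' @param ranges named list of [reference_range()]s, default
#'   [healthy_reference_ranges()].
#' @param bsa optional named numeric of body surface area (m2) keyed by
#'   `patient_id`, enabling PPM grading.
#' @return `results` with added columns `vmax_mps` (if absent),
#'   `stenosis`, `flag_<metric>` and optionally `ppm`.
#' @export
grade_cohort <- function(results, ranges = healthy_reference_ranges(),
                         bsa = NULL) {
  if (!"vmax_mps" %in% names(results)) {
    results$vmax_mps <- vmax_from_dp(results$dp_mmhg)
  }
  results$stenosis <- stenosis_grade(results$vmax_mps)
  for (metric in names(ranges)) {
    if (metric %in% names(results)) {
      results[[paste0("flag_", metric)]] <-
        percentile_flag(results[[metric]], ranges[[metric]])
    }
  }
  if (!is.null(bsa) && "eoa_cm2" %in% names(results)) {
    results$ppm <- ppm_class(results$eoa_cm2,
                             as.numeric(bsa[as.character(results$patient_id)]))
  }
  results
}
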