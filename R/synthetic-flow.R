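#' Parameters for a synthetic eccentric-jet velocity plane
#'
#' Describes an idealized peak-systolic jet on a circular cross-section, the
#' kind of eccentric flow seen in the ascending aorta downstream of a
#' prosthetic valve. The jet is a top-hat ("plug") or parabolic patch of
#' through-plane velocity whose centre can be displaced off the lumen axis
#' (eccentricity), tilted away from the plane normal, and overlaid with a
#' solid-body swirl, retrograde flow outside the jet, and Gaussian noise.
#'
#' The plug profile is the default because the flow-displacement metric has
#' an exact closed form for it (the velocity-weighted centroid of a symmetric
#' patch is its centre), which makes the generator directly verifiable.
#'
#' @param lumen_radius lumen radius (mm).
#' @param grid_spacing lattice spacing (mm); must be `< lumen_radius / 4`.
#' @param jet_center_offset length-2 numeric, in-plane displacement of the
#'   jet centre from the lumen centre (mm).
#' @param jet_radius jet radius (mm); the jet disk must lie fully inside the
#'   lumen.
#' @param peak_velocity peak through-plane jet velocity (m/s).
#' @param tilt_deg deviation of the jet axis from the plane normal
#'   (degrees, in `[0, 90)`). The through-plane component keeps the jet
#'   profile; tilting adds a uniform in-plane component `vz * tan(tilt)`
#'   so every jet vector deviates from the normal by exactly `tilt_deg`.
#' @param swirl_strength tangential in-plane speed at the lumen wall (m/s);
#'   applied as solid-body rotation about the jet centre.
#' @param retrograde_fraction uniform retrograde through-plane flow outside
#'   the jet, as a fraction of `peak_velocity` (in `[0, 1)`).
#' @param noise_sd standard deviation of Gaussian noise added to each
#'   velocity component inside the lumen (m/s).
#' @param profile `"plug"` (default) or `"parabolic"`.
#' @param seed integer seed; the plane is bit-reproducible given the seed.
#'
#' @return A list of class `jet_params`.
#' @export
jet_params <- function(lumen_radius = 15, grid_spacing = 0.5,
                       jet_center_offset = c(0, 0), jet_radius = 7.5,
                       peak_velocity = 1.5, tilt_deg = 0,
                       swirl_strength = 0, retrograde_fraction = 0,
                       noise_sd = 0, profile = c("plug", "parabolic"),
                       seed = 1L) {
  profile <- match.arg(profile)
  p <- list(lumen_radius = lumen_radius, grid_spacing = grid_spacing,
            jet_center_offset = as.numeric(jet_center_offset),
            jet_radius = jet_radius, peak_velocity = peak_velocity,
            tilt_deg = tilt_deg, swirl_strength = swirl_strength,
            retrograde_fraction = retrograde_fraction, noise_sd = noise_sd,
            profile = profile, seed = as.integer(seed))
  fail <- function(...) stop("jet_params: ", ..., call. = FALSE)
  if (p$lumen_radius <= 0) fail("lumen_radius must be > 0")
  if (p$grid_spacing <= 0) fail("grid_spacing must be > 0")
  if (length(p$jet_center_offset) != 2L) {
    fail("jet_center_offset must be a 2-vector (mm)")
  }
  if (p$jet_radius <= 0 || p$jet_radius > p$lumen_radius) {
    fail("jet_radius must satisfy 0 < jet_radius <= lumen_radius")
  }
  if (sqrt(sum(p$jet_center_offset^2)) + p$jet_radius >
      p$lumen_radius + 1e-12) {
    fail("|jet_center_offset| + jet_radius must not exceed lumen_radius ",
         "(jet fully inside the lumen)")
  }
  if (p$peak_velocity < 0) fail("peak_velocity must be >= 0")
  if (p$tilt_deg < 0 || p$tilt_deg >= 90) fail("tilt_deg must be in [0, 90)")
  if (p$retrograde_fraction < 0 || p$retrograde_fraction >= 1) {
    fail("retrograde_fraction must be in [0, 1)")
  }
  if (p$noise_sd < 0) fail("noise_sd must be >= 0")
  class(p) <- "jet_params"
  p
}

# run expr with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic velocity plane with an eccentric jet
#'
#' @param params a [jet_params()] object.
#' @return A [velocity_plane()] whose lumen mask is the disk of radius
#'   `lumen_radius`; velocities outside the mask are zero.
#' @export
make_jet_plane <- function(params) {
  if (!inherits(params, "jet_params")) params <- do.call(jet_params, params)
  if (params$grid_spacing >= params$lumen_radius / 4) {
    stop("make_jet_plane: grid_spacing must be < lumen_radius / 4",
         call. = FALSE)
  }
  R <- params$lumen_radius
  h <- params$grid_spacing
  ax <- seq(-R, R, by = h)
  g <- expand.grid(x = ax, y = ax)
  x <- g$x; y <- g$y
  mask <- x^2 + y^2 <= R^2

  cx <- params$jet_center_offset[1]
  cy <- params$jet_center_offset[2]
  r_jet <- sqrt((x - cx)^2 + (y - cy)^2)
  in_jet <- mask & r_jet <= params$jet_radius

  vz <- numeric(length(x))
  if (params$profile == "plug") {
    vz[in_jet] <- params$peak_velocity
  } else {
    vz[in_jet] <- params$peak_velocity *
      (1 - (r_jet[in_jet] / params$jet_radius)^2)
  }
  if (params$retrograde_fraction > 0) {
    vz[mask & !in_jet] <- -params$retrograde_fraction * params$peak_velocity
  }

  vx <- numeric(length(x))
  vy <- numeric(length(x))

  # tilt: uniform deflection of the jet axis; direction of displacement if
  # the jet is eccentric, +x otherwise
  if (params$tilt_deg > 0) {
    u <- params$jet_center_offset
    if (sum(u^2) == 0) u <- c(1, 0) else u <- u / sqrt(sum(u^2))
    t_amp <- tan(params$tilt_deg * pi / 180)
    vx[in_jet] <- vz[in_jet] * t_amp * u[1]
    vy[in_jet] <- vz[in_jet] * t_amp * u[2]
  }

  # solid-body swirl about the jet centre, tangential speed reaching
  # swirl_strength at radius lumen_radius
  if (params$swirl_strength > 0) {
    omega <- params$swirl_strength / R
    vx[mask] <- vx[mask] - omega * (y[mask] - cy)
    vy[mask] <- vy[mask] + omega * (x[mask] - cx)
  }

  if (params$noise_sd > 0) {
    n_in <- sum(mask)
    noise <- with_seed(params$seed,
                       matrix(stats::rnorm(3 * n_in, sd = params$noise_sd),
                              ncol = 3))
    vx[mask] <- vx[mask] + noise[, 1]
    vy[mask] <- vy[mask] + noise[, 2]
    vz[mask] <- vz[mask] + noise[, 3]
  }

  velocity_plane(x, y, vx, vy, vz, mask, spacing = h, lumen_radius = R)
}

#' Parameters for a synthetic virtual-replacement cohort
#'
#' Describes the stated world of a virtual aortic valve replacement study:
#' each patient receives three candidate prosthesis sizes (one smaller than
#' the reference, the reference, one larger) and is simulated at rest and
#' under physical stress, i.e. a 3 x 2 design with six outcome cells per
#' patient. Stress raises the peak systolic flow rate by `stress_factor`
#' (default 1.25, a 25% increase). Transvalvular velocity follows
#' continuity through the effective orifice area (EOA) and the pressure
#' gradient follows the simplified Bernoulli relation, so with
#' `stress_nonlinearity = 0` the stress/rest gradient ratio is exactly
#' `stress_factor^2`. Flow-profile metrics (NFD, WPD, flow angle) are drawn
#' per patient and held approximately constant across sizes and states,
#' emulating the empirical finding that profile shape is a property of the
#' patient's aorta rather than of valve size or activity level.
#'
#' @param n_patients number of patients (default 10).
#' @param eoa_by_size named numeric, valve label size (mm) to EOA (cm2).
#'   The default map is synthetic (monotone in label size, roughly
#'   calibrated so a 400 ml/s flow through a 25 mm valve gives a low-teens
#'   gradient); it is not a manufacturer chart.
#' @param reference_sizes label sizes (mm) eligible as a patient's reference
#'   valve; each must have a neighbour one size smaller and larger in
#'   `eoa_by_size`.
#' @param flow_range length-2 numeric, uniform range of peak systolic flow
#'   at rest (ml/s). Default 235-539 ml/s, the span observed in surgical
#'   aortic stenosis cohorts.
#' @param stress_factor multiplicative flow increase under stress (> 1).
#' @param stress_nonlinearity multiplicative perturbation applied to the
#'   stress-state gradient, `dp_stress = stress_factor^2 * dp_rest *
#'   (1 + stress_nonlinearity)`; default 0 gives the pure Bernoulli ratio.
#' @param nfd_distribution list with `location` and `scale` of the
#'   patient-level normalized flow displacement (Gaussian, clamped to
#'   `[0, 0.5]`).
#' @param seed integer seed.
#'
#' @return A list of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_patients = 10,
                              eoa_by_size = c("21" = 1.7, "23" = 2.0,
                                              "25" = 2.3, "27" = 2.6),
                              reference_sizes = c(23, 25),
                              flow_range = c(235, 539),
                              stress_factor = 1.25,
                              stress_nonlinearity = 0,
                              nfd_distribution = list(location = 0.12,
                                                      scale = 0.04),
                              seed = 1L) {
  p <- list(n_patients = as.integer(n_patients), eoa_by_size = eoa_by_size,
            reference_sizes = as.numeric(reference_sizes),
            flow_range = as.numeric(flow_range),
            stress_factor = stress_factor,
            stress_nonlinearity = stress_nonlinearity,
            nfd_distribution = nfd_distribution, seed = as.integer(seed))
  fail <- function(msg) stop("cohort_gen_params: ", msg, call. = FALSE)
  if (p$n_patients < 1) fail("n_patients must be >= 1")
  if (is.null(names(p$eoa_by_size)) || any(p$eoa_by_size <= 0)) {
    fail("eoa_by_size must be a named vector of positive EOA (cm2)")
  }
  if (length(p$flow_range) != 2L || any(p$flow_range <= 0) ||
      p$flow_range[1] > p$flow_range[2]) {
    fail("flow_range must be a positive, ordered interval (ml/s)")
  }
  if (p$stress_factor <= 1) fail("stress_factor must be > 1")
  class(p) <- "cohort_gen_params"
  p
}

# size one step smaller / larger than a reference label within a sorted map
neighbour_sizes <- function(reference, sizes_available) {
  s <- sort(sizes_available)
  i <- match(reference, s)
  if (is.na(i)) {
    stop("configuration error: reference size ", reference,
         " not present in eoa_by_size", call. = FALSE)
  }
  if (i == 1L || i == length(s)) {
    stop("configuration error: eoa_by_size lacks a size ",
         if (i == 1L) "smaller" else "larger",
         " than reference ", reference, " mm", call. = FALSE)
  }
  c(smaller = s[i - 1L], reference = s[i], larger = s[i + 1L])
}

#' Generate a synthetic virtual-replacement cohort
#'
#' @param params a [cohort_gen_params()] object.
#' @return A data frame with one row per (patient, size class, state) cell
#'   and columns `patient_id, valve_size_mm, size_class, state, q_mls,
#'   eoa_cm2, vmax_mps, dp_mmhg, nfd, wpd, angle_deg`. Deterministic under
#'   `params$seed`.
#' @export
make_cohort <- function(params = cohort_gen_params()) {
  if (!inherits(params, "cohort_gen_params")) {
    params <- do.call(cohort_gen_params, params)
  }
  sizes_avail <- as.numeric(names(params$eoa_by_size))
  with_seed(params$seed, {
    n <- params$n_patients
    q_rest <- stats::runif(n, params$flow_range[1], params$flow_range[2])
    ref <- sample(params$reference_sizes, n, replace = TRUE)
    # patient-level flow profile, nearly constant across cells
    nfd_pat <- pmin(pmax(stats::rnorm(n, params$nfd_distribution$location,
                                      params$nfd_distribution$scale), 0), 0.5)
    wpd_pat <- pmin(pmax(stats::rnorm(n, 0.44, 0.06), 0.05), 0.95)
    ang_pat <- pmin(pmax(stats::rnorm(n, 28, 6), 1), 80)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      sizes <- neighbour_sizes(ref[i], sizes_avail)
      cells <- expand.grid(size_class = names(sizes),
                           state = c("rest", "stress"),
                           stringsAsFactors = FALSE)
      size_mm <- sizes[cells$size_class]
      eoa <- params$eoa_by_size[as.character(size_mm)]
      q <- ifelse(cells$state == "stress",
                  apply_stress(q_rest[i], params$stress_factor), q_rest[i])
      vm <- vmax_from_flow(q, eoa)
      dp <- dp_from_vmax(vm)
      dp <- ifelse(cells$state == "stress",
                   dp * (1 + params$stress_nonlinearity), dp)
      # small cell-level wobble so profiles are approximately, not exactly,
      # constant (an NFD jitter of 0.005 ~ the printed rounding step)
      jit <- function(sd) stats::rnorm(nrow(cells), 0, sd)
      rows[[i]] <- data.frame(
        patient_id = i,
        valve_size_mm = as.numeric(size_mm),
        size_class = cells$size_class,
        state = cells$state,
        q_mls = q,
        eoa_cm2 = as.numeric(eoa),
        vmax_mps = vm,
        dp_mmhg = dp,
        nfd = pmin(pmax(nfd_pat[i] + jit(0.005), 0), 0.5),
        wpd = pmin(pmax(wpd_pat[i] + jit(0.01), 0), 1),
        angle_deg = pmin(pmax(ang_pat[i] + jit(0.5), 0), 90),
        row.names = NULL
      )
    }
    do.call(rbind, rows)
  })
}

#' Write / read a cohort results table
#'
#' Comma-separated, UTF-8, header row, `.` decimal separator; doubles are
#' written at full precision so a round trip is exact. Lines starting with
#' `#` are metadata comments and are skipped on read.
#'
#' @param cohort data frame as produced by [make_cohort()] or
#'   [load_fixture()].
#' @param path CSV path.
#' @param header_lines optional character vector written as `#` comments.
#' @return `path` (write) or the data frame (read).
#' @export
write_cohort <- function(cohort, path, header_lines = character()) {
  write_csv_full(cohort, path, header_lines = header_lines)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
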