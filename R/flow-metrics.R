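#' Lumen geometry of a velocity plane
#'
#' The lumen centre is the unweighted area centroid of the masked points;
#' the diameter is the equivalent-circle diameter `2 * sqrt(A / pi)` with
#' `A = n_lumen * spacing^2`, so non-circular lumens are reduced to a circle
#' of equal area.
#'
#' @param plane a [velocity_plane()].
#' @return A list with `centroid` (length-2, mm) and `diameter` (mm).
#' @export
lumen_geometry <- function(plane) {
  assert_plane(plane, min_lumen_points = 1L)
  m <- plane$mask
  centroid <- c(mean(plane$x[m]), mean(plane$y[m]))
  area <- sum(m) * plane$spacing^2
  list(centroid = centroid, diameter = 2 * sqrt(area / pi))
}

#' Normalized flow displacement (NFD)
#'
#' Distance between the lumen centre and the centre of forward flow,
#' normalized to the lumen diameter. The forward-flow centre is the centroid
#' of lumen points with positive through-plane velocity, by default weighted
#' by that velocity. A perfectly centred jet gives 0; values grow as the jet
#' hugs the vessel wall, with 0.5 the geometric ceiling (flow centre on the
#' wall of the equivalent circle).
#'
#' @param plane a [velocity_plane()].
#' @param weighted weight the forward-flow centroid by through-plane
#'   velocity (default `TRUE`); `FALSE` uses the unweighted centroid of the
#'   forward-flow region.
#' @return NFD, dimensionless.
#' @export
nfd <- function(plane, weighted = TRUE) {
  assert_plane(plane)
  geom <- lumen_geometry(plane)
  fwd <- plane$mask & plane$vz > 0
  if (!any(fwd)) {
    stop("nfd undefined: no forward flow on the plane (fully retrograde?)",
         call. = FALSE)
  }
  w <- if (weighted) plane$vz[fwd] else rep(1, sum(fwd))
  centre <- c(sum(w * plane$x[fwd]), sum(w * plane$y[fwd])) / sum(w)
  sqrt(sum((centre - geom$centroid)^2)) / geom$diameter
}

#' Degree of wall parallelism (WPD)
#'
#' Mean, over lumen points with nonzero velocity, of the ratio of the
#' through-plane speed to the sum of through-plane and in-plane speeds:
#' `|vz| / (|vz| + |v_inplane|)`. Flow perfectly parallel to the centreline
#' gives 1; purely in-plane flow gives 0.
#'
#' @param plane a [velocity_plane()].
#' @param include_retrograde include points with negative through-plane
#'   velocity in the average (default `TRUE`: every measured vector counts).
#' @return WPD in `[0, 1]`.
#' @export
wpd <- function(plane, include_retrograde = TRUE) {
  assert_plane(plane)
  vin <- sqrt(plane$vx^2 + plane$vy^2)
  vth <- abs(plane$vz)
  keep <- plane$mask & (vin + vth) > 0
  if (!include_retrograde) keep <- keep & plane$vz >= 0
  if (!any(keep)) {
    stop("wpd undefined: all velocities are zero", call. = FALSE)
  }
  mean(vth[keep] / (vth[keep] + vin[keep]))
}

#' Flow angle
#'
#' Mean angular deviation of the velocity vectors from the plane normal,
#' in degrees: `acos(vz / |v|)` averaged over lumen points with nonzero
#' velocity. Axial flow gives 0; retrograde vectors contribute angles above
#' 90 degrees rather than being folded back.
#'
#' @param plane a [velocity_plane()].
#' @param include_retrograde include points with negative through-plane
#'   velocity (default `TRUE`).
#' @return Mean angle in degrees, in `[0, 180]`.
#' @export
flow_angle <- function(plane, include_retrograde = TRUE) {
  assert_plane(plane)
  speed <- sqrt(plane$vx^2 + plane$vy^2 + plane$vz^2)
  keep <- plane$mask & speed > 0
  if (!include_retrograde) keep <- keep & plane$vz >= 0
  if (!any(keep)) {
    stop("flow angle undefined: all velocities are zero", call. = FALSE)
  }
  ratio <- pmin(pmax(plane$vz[keep] / speed[keep], -1), 1)
  mean(acos(ratio)) * 180 / pi
}

#' Peak velocity magnitude on the plane
#'
#' @param plane a [velocity_plane()].
#' @return Maximum velocity magnitude over lumen points (m/s).
#' @export
vmax_plane <- function(plane) {
  assert_plane(plane, min_lumen_points = 1L)
  m <- plane$mask
  max(sqrt(plane$vx[m]^2 + plane$vy[m]^2 + plane$vz[m]^2))
}

#' All flow-profile metrics of a plane
#'
#' @param plane a [velocity_plane()].
#' @param weighted,include_retrograde passed to [nfd()], [wpd()] and
#'   [flow_angle()].
#' @return A one-row data frame with columns `nfd, wpd, angle_deg,
#'   vmax_mps`.
#' @export
flow_metrics <- function(plane, weighted = TRUE, include_retrograde = TRUE) {
  data.frame(
    nfd = nfd(plane, weighted = weighted),
    wpd = wpd(plane, include_retrograde = include_retrograde),
    angle_deg = flow_angle(plane, include_retrograde = include_retrograde),
    vmax_mps = vmax_plane(plane)
  )
}
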