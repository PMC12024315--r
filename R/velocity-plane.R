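#' Construct a velocity plane
#'
#' A velocity plane is a regular square lattice of 3-component velocity
#' samples on an analysis cross-section, together with a boolean lumen mask.
#' In-plane coordinates are in millimetres with the plane normal along +z;
#' velocities are in metres per second, `vz` being the through-plane
#' component. Points outside the lumen mask must carry zero velocity.
#'
#' @param x,y numeric vectors of in-plane sample coordinates (mm).
#' @param vx,vy numeric vectors, in-plane velocity components (m/s).
#' @param vz numeric vector, through-plane velocity component (m/s).
#' @param mask logical vector, `TRUE` for points inside the lumen.
#' @param spacing positive scalar, lattice spacing (mm).
#' @param lumen_radius optional nominal lumen radius (mm), carried as
#'   metadata by the synthetic generator.
#'
#' @return An object of class `velocity_plane`.
#' @export
velocity_plane <- function(x, y, vx, vy, vz, mask, spacing,
                           lumen_radius = NA_real_) {
  n <- length(x)
  if (any(lengths(list(y, vx, vy, vz, mask)) != n)) {
    stop("velocity_plane: all point vectors must have equal length",
         call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("velocity_plane: 'spacing' must be a positive scalar (mm)",
         call. = FALSE)
  }
  mask <- as.logical(mask)
  if (!any(mask)) {
    stop("velocity_plane: lumen mask is empty", call. = FALSE)
  }
  if (any(abs(vx[!mask]) > 0 | abs(vy[!mask]) > 0 | abs(vz[!mask]) > 0)) {
    stop("velocity_plane: nonzero velocity outside the lumen mask",
         call. = FALSE)
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         vx = as.numeric(vx), vy = as.numeric(vy), vz = as.numeric(vz),
         mask = mask, spacing = as.numeric(spacing),
         lumen_radius = as.numeric(lumen_radius)),
    class = "velocity_plane"
  )
}

#' @export
print.velocity_plane <- function(x, ...) {
  cat("<velocity_plane>\n")
  cat(sprintf("  points: %d (%d in lumen), spacing %.3g mm\n",
              length(x$x), sum(x$mask), x$spacing))
  vm <- sqrt(x$vx^2 + x$vy^2 + x$vz^2)[x$mask]
  cat(sprintf("  |v| in lumen: max %.3g m/s, mean %.3g m/s\n",
              max(vm), mean(vm)))
  invisible(x)
}

# internal: stop unless the plane satisfies the analysis preconditions
assert_plane <- function(plane, min_lumen_points = 16L) {
  if (!inherits(plane, "velocity_plane")) {
    stop("expected a 'velocity_plane' object", call. = FALSE)
  }
  if (sum(plane$mask) < min_lumen_points) {
    stop(sprintf("velocity plane has %d lumen points; at least %d required",
                 sum(plane$mask), min_lumen_points), call. = FALSE)
  }
  invisible(plane)
}

sidecar_path <- function(path) {
  if (grepl("\\.csv$", path)) sub("\\.csv$", ".json", path)
  else paste0(path, ".json")
}

#' Write a velocity plane to CSV with a JSON sidecar
#'
#' The CSV carries one row per lattice point with columns
#' `x_mm,y_mm,vx_mps,vy_mps,vz_mps,in_lumen`; the sidecar (same path with a
#' `.json` extension) records `spacing_mm` and `lumen_radius_mm`. Values are
#' written at full double precision so that a read-back is exact.
#'
#' @param plane a [velocity_plane()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plane <- function(plane, path) {
  assert_plane(plane, min_lumen_points = 1L)
  df <- data.frame(
    x_mm = plane$x, y_mm = plane$y,
    vx_mps = plane$vx, vy_mps = plane$vy, vz_mps = plane$vz,
    in_lumen = as.integer(plane$mask)
  )
  write_csv_full(df, path)
  jsonlite::write_json(
    list(spacing_mm = plane$spacing, lumen_radius_mm = plane$lumen_radius),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Read a velocity plane written by [write_plane()]
#'
#' @param path CSV path; the JSON sidecar is looked up next to it.
#' @return A [velocity_plane()].
#' @export
read_plane <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("x_mm", "y_mm", "vx_mps", "vy_mps", "vz_mps", "in_lumen")
  if (!all(need %in% names(df))) {
    stop("plane CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing JSON sidecar for plane file: ", side, call. = FALSE)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  velocity_plane(df$x_mm, df$y_mm, df$vx_mps, df$vy_mps, df$vz_mps,
                 df$in_lumen != 0, spacing = meta$spacing_mm,
                 lumen_radius = if (is.null(meta$lumen_radius_mm))
                   NA_real_ else meta$lumen_radius_mm)
}

# internal: CSV writer preserving full double precision (17 significant
# digits survive a write/read round trip exactly)
write_csv_full <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
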