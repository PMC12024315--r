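# Brute-force oracles, written as plain point loops independent of the
# vectorized implementations they check.

oracle_nfd <- function(plane, weighted = TRUE) {
  cx <- 0; cy <- 0; n <- 0
  for (i in seq_along(plane$x)) {
    if (plane$mask[i]) {
      cx <- cx + plane$x[i]; cy <- cy + plane$y[i]; n <- n + 1
    }
  }
  cx <- cx / n; cy <- cy / n
  diam <- 2 * sqrt(n * plane$spacing^2 / pi)
  fx <- 0; fy <- 0; wsum <- 0
  for (i in seq_along(plane$x)) {
    if (plane$mask[i] && plane$vz[i] > 0) {
      w <- if (weighted) plane$vz[i] else 1
      fx <- fx + w * plane$x[i]; fy <- fy + w * plane$y[i]; wsum <- wsum + w
    }
  }
  sqrt((fx / wsum - cx)^2 + (fy / wsum - cy)^2) / diam
}

oracle_wpd <- function(plane) {
  acc <- 0; n <- 0
  for (i in seq_along(plane$x)) {
    if (plane$mask[i]) {
      vin <- sqrt(plane$vx[i]^2 + plane$vy[i]^2)
      vth <- abs(plane$vz[i])
      if (vin + vth > 0) {
        acc <- acc + vth / (vth + vin); n <- n + 1
      }
    }
  }
  acc / n
}

oracle_angle <- function(plane) {
  acc <- 0; n <- 0
  for (i in seq_along(plane$x)) {
    if (plane$mask[i]) {
      sp <- sqrt(plane$vx[i]^2 + plane$vy[i]^2 + plane$vz[i]^2)
      if (sp > 0) {
        acc <- acc + acos(max(-1, min(1, plane$vz[i] / sp))); n <- n + 1
      }
    }
  }
  acc / n * 180 / pi
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wsr_p <- function(x, y) {
  d <- (y - x)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  W_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  lower <- mean(W_all <= W_obs + 1e-9)
  upper <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# U (sample2-higher pairs + half ties) by double loop
oracle_u <- function(s1, s2) {
  u <- 0
  for (a in s1) for (b in s2) {
    u <- u + (b > a) + 0.5 * (b == a)
  }
  u
}

# exact two-sided Mann-Whitney p by enumerating group assignments
oracle_mwu_p <- function(s1, s2) {
  pooled <- c(s1, s2)
  n1 <- length(s1)
  idx <- utils::combn(length(pooled), n1)
  U_obs <- oracle_u(s1, s2)
  U_all <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  lower <- mean(U_all <= U_obs + 1e-9)
  upper <- mean(U_all >= U_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# random noisy plane used by several metric tests
random_plane <- function(seed, noise_sd = 0.4) {
  make_jet_plane(jet_params(lumen_radius = 12, grid_spacing = 1.5,
                            jet_center_offset = c(3, -2), jet_radius = 5,
                            peak_velocity = 1.4, tilt_deg = 15,
                            swirl_strength = 0.3, noise_sd = noise_sd,
                            seed = seed))
}
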