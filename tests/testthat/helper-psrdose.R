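# Shared fixtures, generated in code.

# small phantom sized for a 10x10 field, coarse voxels for speed
small_phantom <- function() {
  dose_grid(c(26, 26, 30), c(1, 1, 0.5), c(-13, -13, 100), ssd = 100)
}

# small commissioning study reused across commissioning tests
small_study <- function(noise_sigma = 0, rng_seed = 3, n_particles = 2e4,
                        fields = list(c(10, 10), c(4, 4))) {
  synthetic_study(n_rings = 4, n_energy_bins = 3, fields = fields,
                  noise_sigma = noise_sigma, n_particles = n_particles,
                  rng_seed = rng_seed, phantom = small_phantom(),
                  profile_depths = c(5, 10))
}

# beam model whose three rings carry prescribed primary-photon intensities
# (scatter and electron intensity suppressed to a negligible share)
three_ring_model <- function(intensities = c(0.2, 0.3, 0.5)) {
  m <- build_toy_beam_model(3, 1, toy_beam_spec(
    electron_fraction = 1e-9, scatter_fraction = 1e-9))
  prim <- m$subsources$pclass == 0L
  m$subsources$relative_intensity[prim] <-
    intensities * sum(m$subsources$relative_intensity[prim])
  m
}

# vectorized trilinear interpolation at many points (voxel-center
# coordinates), NA outside the interpolation domain
trilinear_many <- function(grid, pts) {
  dims <- grid$dims
  fc <- sweep(sweep(pts, 2, grid$origin), 2, grid$voxel_size, "/") - 0.5
  ok <- fc[, 1] >= 0 & fc[, 2] >= 0 & fc[, 3] >= 0 &
    fc[, 1] <= dims[1] - 1 & fc[, 2] <= dims[2] - 1 & fc[, 3] <= dims[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  f <- fc[ok, , drop = FALSE]
  i0 <- pmin(floor(f), matrix(rep(dims - 2, each = nrow(f)), nrow(f)))
  fr <- f - i0
  v <- grid$values
  at <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  }
  c00 <- at(0, 0, 0) * (1 - fr[, 1]) + at(1, 0, 0) * fr[, 1]
  c10 <- at(0, 1, 0) * (1 - fr[, 1]) + at(1, 1, 0) * fr[, 1]
  c01 <- at(0, 0, 1) * (1 - fr[, 1]) + at(1, 0, 1) * fr[, 1]
  c11 <- at(0, 1, 1) * (1 - fr[, 1]) + at(1, 1, 1) * fr[, 1]
  c0 <- c00 * (1 - fr[, 2]) + c10 * fr[, 2]
  c1 <- c01 * (1 - fr[, 2]) + c11 * fr[, 2]
  out[ok] <- c0 * (1 - fr[, 3]) + c1 * fr[, 3]
  out
}

# reference R implementation of the gamma index by exhaustive search over
# a refined neighborhood (oracle for the C++ path)
gamma_oracle <- function(d_eval, d_ref, dose_percent, dist_mm,
                         low_frac = 0.1, refine = 10, search_factor = 3) {
  normalizer <- max(d_ref$values)
  dd <- dose_percent / 100 * normalizer
  dta_cm <- dist_mm / 10
  sp <- d_ref$voxel_size
  dims <- d_ref$dims
  radius <- search_factor * dta_cm
  offs <- expand.grid(
    ox = seq(-radius, radius, by = sp[1] / refine),
    oy = seq(-radius, radius, by = sp[2] / refine),
    oz = seq(-radius, radius, by = sp[3] / refine))
  offs <- as.matrix(offs[offs$ox^2 + offs$oy^2 + offs$oz^2 <= radius^2, ])
  r2 <- rowSums(offs^2)
  g <- array(NA_real_, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      dref <- d_ref$values[i, j, k]
      if (dref <= low_frac * normalizer) next
      ctr <- d_ref$origin + (c(i, j, k) - 0.5) * sp
      de <- trilinear_many(d_eval, sweep(offs, 2, ctr, "+"))
      g2 <- min(r2 / dta_cm^2 + (de - dref)^2 / dd^2, na.rm = TRUE)
      g[i, j, k] <- sqrt(g2)
    }
  g
}
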