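#' Particle classes of the PSR beam model
#'
#' The phase space of a clinical photon beam is partitioned by interaction
#' history into exactly three classes: primary photons (direct from the
#' target), scattered photons (head scatter), and contaminant electrons.
#'
#' @return Character vector of the three class names, in canonical order.
#'   The integer codes used throughout the package are `0`, `1`, `2` in
#'   this order.
#' @export
particle_classes <- function() {
  c("primary_photon", "scattered_photon", "electron")
}

#' Toy parameterization of a PSR beam model
#'
#' The analytical functional forms fitted from vendor phase-space files are
#' not reproduced here; instead the spectrum/intensity/angular-width
#' schedules below give a documented stand-in that preserves the structure
#' every downstream algorithm needs: a per-sub-source relative intensity
#' and a local angular spread about the focal ray.
#'
#' Per ring, the energy spectrum is a gamma-shaped histogram over the
#' energy bins, with a mean energy that softens linearly off axis. Ring
#' intensities are proportional to annulus area times an exponential radial
#' decay (slower for primaries than for head scatter). Angular width is
#' constant for primaries and contaminant electrons and grows linearly with
#' ring radius for scattered photons.
#'
#' @param r_max Outer radius (cm) of the outermost ring on the phase-space
#'   plane.
#' @param e_min,e_max Energy range (MeV) spanned by the energy bins.
#' @param electron_fraction Fraction of the total particle intensity
#'   carried by contaminant electrons (about 1% in a clinical photon beam).
#' @param scatter_fraction Fraction of the *photon* intensity carried by
#'   scattered photons.
#' @param primary_mean_e,scatter_mean_e,electron_mean_e On-axis mean energy
#'   (MeV) per class.
#' @param spectrum_shape Shape parameter of the gamma-shaped spectrum.
#' @param primary_radial_decay,scatter_radial_decay Radial e-folding length
#'   (cm) of the ring intensity beyond the area factor.
#' @param offaxis_softening Fractional drop of the mean energy from axis to
#'   `r_max`.
#' @param primary_width Angular width (rad) of primary sub-sources.
#' @param scatter_width0,scatter_width_slope Angular width (rad) of
#'   scattered sub-sources at the axis and its increase towards `r_max`.
#' @param electron_width Angular width (rad) of electron sub-sources.
#' @param plane_z Phase-space plane location (cm from the target, just
#'   above the secondary collimator).
#' @param source_z Virtual focal point location (cm); rays emanate from
#'   `(0, 0, source_z)`.
#' @param sad Source-axis distance (cm).
#' @return A list of parameters, class `"toy_beam_spec"`.
#' @export
toy_beam_spec <- function(r_max = 6, e_min = 0.25, e_max = 6,
                          electron_fraction = 0.01, scatter_fraction = 0.15,
                          primary_mean_e = 2.0, scatter_mean_e = 1.0,
                          electron_mean_e = 0.8, spectrum_shape = 3,
                          primary_radial_decay = 8, scatter_radial_decay = 4,
                          offaxis_softening = 0.3,
                          primary_width = 0.01,
                          scatter_width0 = 0.04, scatter_width_slope = 0.06,
                          electron_width = 0.12,
                          plane_z = 26, source_z = 0, sad = 100) {
  spec <- as.list(environment())
  num <- vapply(spec, is.numeric, logical(1))
  if (!all(num)) stop("toy_beam_spec parameters must be numeric")
  nonneg <- c("r_max", "e_min", "e_max", "electron_fraction",
              "scatter_fraction", "primary_mean_e", "scatter_mean_e",
              "electron_mean_e", "spectrum_shape", "primary_radial_decay",
              "scatter_radial_decay", "offaxis_softening", "primary_width",
              "scatter_width0", "scatter_width_slope", "electron_width")
  bad <- nonneg[vapply(nonneg, function(p) spec[[p]] < 0, logical(1))]
  if (length(bad)) {
    stop("negative toy_beam_spec parameter(s): ", paste(bad, collapse = ", "))
  }
  if (spec$e_min >= spec$e_max) stop("e_min must be < e_max")
  if (spec$electron_fraction >= 1) stop("electron_fraction must be < 1")
  structure(spec, class = "toy_beam_spec")
}

#' Build a toy PSR beam model
#'
#' Partitions the phase-space plane into `n_rings` equal-width concentric
#' rings and `n_energy_bins` equal-width energy bins, for each of the three
#' particle classes, yielding `n_rings * n_energy_bins * 3` PSR
#' sub-sources. Sub-sources are stored in canonical order (class-major,
#' then energy bin, then ring); this order is the column order of the
#' sub-source dose matrix A. Relative intensities are normalized to sum to
#' one, with the electron class pinned to exactly
#' `spec$electron_fraction` of the total.
#'
#' @param n_rings,n_energy_bins Number of rings / energy bins (>= 1).
#' @param spec A [toy_beam_spec()].
#' @return A `beam_model` object: header fields (`n_rings`,
#'   `n_energy_bins`, `plane_z`, `source_z`, `sad`) plus a `subsources`
#'   data frame with one row per sub-source (`ring`, `ebin`, `pclass`
#'   integer code 0/1/2, `r_inner`, `r_outer`, `e_low`, `e_high`,
#'   `relative_intensity`, `angular_width`).
#' @examples
#' m <- build_toy_beam_model(40, 20)
#' nrow(m$subsources)  # 2400
#' @export
build_toy_beam_model <- function(n_rings, n_energy_bins,
                                 spec = toy_beam_spec()) {
  if (!is.numeric(n_rings) || length(n_rings) != 1L || n_rings < 1 ||
      n_rings != round(n_rings)) {
    stop("n_rings must be a positive integer")
  }
  if (!is.numeric(n_energy_bins) || length(n_energy_bins) != 1L ||
      n_energy_bins < 1 || n_energy_bins != round(n_energy_bins)) {
    stop("n_energy_bins must be a positive integer")
  }
  if (!inherits(spec, "toy_beam_spec")) spec <- do.call(toy_beam_spec, spec)
  n_rings <- as.integer(n_rings)
  n_energy_bins <- as.integer(n_energy_bins)

  r_edges <- seq(0, spec$r_max, length.out = n_rings + 1L)
  e_edges <- seq(spec$e_min, spec$e_max, length.out = n_energy_bins + 1L)
  r_mid <- (r_edges[-1] + r_edges[-(n_rings + 1L)]) / 2
  e_mid <- (e_edges[-1] + e_edges[-(n_energy_bins + 1L)]) / 2
  area <- r_edges[-1]^2 - r_edges[-(n_rings + 1L)]^2

  mean_e_class <- c(spec$primary_mean_e, spec$scatter_mean_e,
                    spec$electron_mean_e)
  decay_class <- c(spec$primary_radial_decay, spec$scatter_radial_decay,
                   spec$scatter_radial_decay)

  rows <- vector("list", 3L)
  for (cls in 0:2) {
    radial <- area * exp(-r_mid / decay_class[cls + 1L])
    # off-axis spectral softening, floored away from zero
    ebar <- pmax(mean_e_class[cls + 1L] *
                   (1 - spec$offaxis_softening * r_mid / spec$r_max),
                 0.4 * mean_e_class[cls + 1L])
    spectra <- vapply(ebar, function(eb) {
      w <- dgamma(e_mid, shape = spec$spectrum_shape,
                  rate = spec$spectrum_shape / eb)
      if (sum(w) <= 0) w <- rep(1, n_energy_bins)
      w / sum(w)
    }, numeric(n_energy_bins))
    spectra <- matrix(spectra, nrow = n_energy_bins)  # n_energy_bins x n_rings
    # canonical within-class order: energy-major, then ring
    df <- expand.grid(ring = seq_len(n_rings) - 1L,
                      ebin = seq_len(n_energy_bins) - 1L)
    df <- df[order(df$ebin, df$ring), , drop = FALSE]
    inten <- radial[df$ring + 1L] *
      spectra[cbind(df$ebin + 1L, df$ring + 1L)]
    width <- switch(as.character(cls),
      "0" = rep(spec$primary_width, nrow(df)),
      "1" = spec$scatter_width0 +
        spec$scatter_width_slope * r_mid[df$ring + 1L] / spec$r_max,
      "2" = rep(spec$electron_width, nrow(df)))
    rows[[cls + 1L]] <- data.frame(
      ring = df$ring, ebin = df$ebin, pclass = cls,
      r_inner = r_edges[df$ring + 1L], r_outer = r_edges[df$ring + 2L],
      e_low = e_edges[df$ebin + 1L], e_high = e_edges[df$ebin + 2L],
      relative_intensity = inten / sum(inten),
      angular_width = width)
  }
  ef <- spec$electron_fraction
  sf <- spec$scatter_fraction
  rows[[1]]$relative_intensity <- rows[[1]]$relative_intensity *
    (1 - ef) * (1 - sf)
  rows[[2]]$relative_intensity <- rows[[2]]$relative_intensity *
    (1 - ef) * sf
  rows[[3]]$relative_intensity <- rows[[3]]$relative_intensity * ef
  subsources <- do.call(rbind, rows)
  rownames(subsources) <- NULL

  structure(list(n_rings = n_rings, n_energy_bins = n_energy_bins,
                 plane_z = spec$plane_z, source_z = spec$source_z,
                 sad = spec$sad, subsources = subsources, spec = spec),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(
    "PSR beam model: %d rings x %d energy bins x 3 classes = %d sub-sources\n",
    x$n_rings, x$n_energy_bins, nrow(x$subsources)))
  cat(sprintf("phase-space plane z = %g cm, focal point z = %g cm, SAD = %g cm\n",
              x$plane_z, x$source_z, x$sad))
  cat(sprintf("electron intensity fraction = %.4f\n",
              sum(x$subsources$relative_intensity[x$subsources$pclass == 2L])))
  invisible(x)
}

#' Group electron PSRs into per-energy-bin effective PSRs
#'
#' Contaminant electrons are ~1% of the beam, so individual electron PSR
#' dose tallies are statistically noisy. Electron sub-sources sharing an
#' energy bin are therefore grouped into a single "effective PSR" that is
#' commissioned with one common correction factor.
#'
#' @param model A `beam_model`.
#' @return Named list, one element per energy bin (names `"0"`, `"1"`,
#'   ...), each the integer vector of 1-based sub-source row indices of the
#'   electron PSRs in that bin. Every electron sub-source appears in
#'   exactly one group.
#' @export
group_electron_effective_psrs <- function(model) {
  stopifnot(inherits(model, "beam_model"))
  el <- which(model$subsources$pclass == 2L)
  groups <- split(el, model$subsources$ebin[el])
  groups[order(as.integer(names(groups)))]
}

# --- jaw helpers -----------------------------------------------------------

#' Rectangular jaw opening at isocenter
#'
#' @param x,y Either a half-width pair `c(lo, hi)` in cm at the isocenter
#'   plane, or a single full width (symmetric about the axis).
#' @return List with `x` and `y` ranges, class `"jaw"`.
#' @export
jaw_rectangle <- function(x, y = x) {
  fix <- function(v) {
    if (length(v) == 1L) v <- c(-v / 2, v / 2)
    if (length(v) != 2L || v[1] >= v[2]) stop("invalid jaw range")
    as.numeric(v)
  }
  structure(list(x = fix(x), y = fix(y)), class = "jaw")
}

as_jaw <- function(j) {
  if (inherits(j, "jaw")) return(j)
  if (is.numeric(j) && length(j) %in% 1:2) {
    return(jaw_rectangle(j[1], j[length(j)]))
  }
  if (is.list(j) && all(c("x", "y") %in% names(j))) {
    return(jaw_rectangle(j$x, j$y))
  }
  stop("cannot interpret jaw specification")
}

# distance range from the beam axis to a rectangle (used for ring overlap)
rect_radial_range <- function(xr, yr) {
  cx <- max(xr[1], min(0, xr[2]))
  cy <- max(yr[1], min(0, yr[2]))
  rmin <- sqrt(cx^2 + cy^2)
  corners <- expand.grid(x = xr, y = yr)
  rmax <- sqrt(max(corners$x^2 + corners$y^2))
  c(rmin, rmax)
}

# --- source sampling -------------------------------------------------------

#' Sample source particles from a PSR beam model
#'
#' Sub-sources are drawn proportionally to their relative intensity, but
#' only from sub-sources whose ring overlaps the jaw opening projected onto
#' the phase-space plane and expanded by `margin` ("within or nearby the
#' jaw open area"). To keep tallies unbiased per full-model history, every
#' particle carries the acceptance correction weight
#' `(restricted intensity mass) / (total intensity)`: drawing all `n`
#' particles from the restricted sub-sources over-represents them by the
#' inverse of that mass fraction, so each sampled particle stands for
#' `mass/total` of a full history. The sampling weight proper is one.
#'
#' Positions are area-uniform within the ring annulus; the direction is the
#' focal ray from `(0, 0, source_z)` through the position, tilted by a
#' polar angle drawn from a Rayleigh distribution with scale equal to the
#' sub-source angular width (equivalent to independent Gaussian tilts in
#' the two transverse directions); energy is uniform within the sub-source
#' energy bin.
#'
#' @param model A `beam_model`.
#' @param n Number of particles (>= 1).
#' @param jaw Jaw opening at isocenter ([jaw_rectangle()] or width(s)).
#' @param margin Expansion (cm, at the phase-space plane) of the projected
#'   jaw rectangle defining "nearby".
#' @param rng_seed Integer seed; identical seeds give identical particles.
#' @return A data frame of class `"source_particles"` with columns `x, y,
#'   z` (cm, on the phase-space plane), `ux, uy, uz` (unit direction),
#'   `energy` (MeV), `weight`, `pclass`, `subsource` (1-based model row),
#'   `cp` (control point, `NA` until assigned), `fm_x, fm_y` (FM-plane
#'   intersection, `NA` until computed).
#' @export
sample_source_particles <- function(model, n, jaw, margin = 0.5,
                                    rng_seed = NULL) {
  stopifnot(inherits(model, "beam_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  jaw <- as_jaw(jaw)
  ss <- model$subsources

  f <- (model$plane_z - model$source_z) / (model$sad - model$source_z)
  xr <- f * jaw$x + c(-margin, margin)
  yr <- f * jaw$y + c(-margin, margin)
  rr <- rect_radial_range(xr, yr)
  accept <- ss$r_inner < rr[2] & ss$r_outer > rr[1]
  if (!any(accept)) {
    stop("empty field: jaw projection overlaps no ring of the beam model")
  }
  mass <- sum(ss$relative_intensity[accept])
  total <- sum(ss$relative_intensity)
  acc_weight <- mass / total

  with_seed(rng_seed, {
    idx_pool <- which(accept)
    idx <- idx_pool[sample.int(length(idx_pool), n, replace = TRUE,
                               prob = ss$relative_intensity[idx_pool])]
    r2 <- runif(n, ss$r_inner[idx]^2, ss$r_outer[idx]^2)
    r <- sqrt(r2)
    phi <- runif(n, 0, 2 * pi)
    x <- r * cos(phi)
    y <- r * sin(phi)
    z <- rep(model$plane_z, n)

    # focal ray
    dzp <- model$plane_z - model$source_z
    nrm <- sqrt(x^2 + y^2 + dzp^2)
    ux <- x / nrm; uy <- y / nrm; uz <- dzp / nrm

    # Rayleigh polar tilt about the focal ray
    w <- ss$angular_width[idx]
    theta <- w * sqrt(-2 * log(runif(n)))
    psi <- runif(n, 0, 2 * pi)
    hn <- sqrt(ux^2 + uy^2)
    e1x <- ifelse(hn < 1e-12, 1, uy / pmax(hn, 1e-300))
    e1y <- ifelse(hn < 1e-12, 0, -ux / pmax(hn, 1e-300))
    e1z <- 0
    e2x <- uy * e1z - uz * e1y
    e2y <- uz * e1x - ux * e1z
    e2z <- ux * e1y - uy * e1x
    ct <- cos(theta); st <- sin(theta)
    cp_ <- cos(psi); sp_ <- sin(psi)
    vx <- ct * ux + st * (cp_ * e1x + sp_ * e2x)
    vy <- ct * uy + st * (cp_ * e1y + sp_ * e2y)
    vz <- ct * uz + st * (cp_ * e1z + sp_ * e2z)
    nv <- sqrt(vx^2 + vy^2 + vz^2)

    energy <- runif(n, ss$e_low[idx], ss$e_high[idx])

    structure(data.frame(
      x = x, y = y, z = z,
      ux = vx / nv, uy = vy / nv, uz = vz / nv,
      energy = energy, weight = rep(acc_weight, n),
      pclass = ss$pclass[idx], subsource = idx,
      cp = NA_integer_, fm_x = NA_real_, fm_y = NA_real_),
      class = c("source_particles", "data.frame"),
      acceptance_weight = acc_weight)
  })
}

#' Collimate particles by the jaw opening
#'
#' Drops particles whose straight ray misses the jaw opening, evaluated at
#' the collimator plane `at_z` (jaw edges given at isocenter are projected
#' back by `at_z / sad`). Used for static open-field calculations; VMAT
#' plan calculations collimate through the fluence map instead.
#'
#' @param particles `source_particles`.
#' @param jaw Jaw opening at isocenter.
#' @param model The `beam_model` the particles came from (for geometry).
#' @param at_z Plane (cm from target) at which the jaw cut is applied.
#' @return The retained subset of `particles`.
#' @export
collimate_jaw <- function(particles, jaw, model, at_z = 50) {
  jaw <- as_jaw(jaw)
  f <- (at_z - model$source_z) / (model$sad - model$source_z)
  t <- (at_z - particles$z) / particles$uz
  px <- particles$x + particles$ux * t
  py <- particles$y + particles$uy * t
  keep <- px >= f * jaw$x[1] & px < f * jaw$x[2] &
    py >= f * jaw$y[1] & py < f * jaw$y[2]
  particles[keep, , drop = FALSE]
}

# --- model serialization ---------------------------------------------------

#' Read/write a beam model as documented JSON
#'
#' The file holds a header (`n_rings`, `n_energy_bins`, `plane_z`,
#' `source_z`, `sad`) and the flat sub-source records in canonical order.
#' The round trip is exact (numbers are written at full precision).
#'
#' @param model A `beam_model`.
#' @param path File path (`.json`).
#' @return `write_beam_model` returns `path` invisibly; `read_beam_model`
#'   returns the `beam_model`.
#' @export
write_beam_model <- function(model, path) {
  stopifnot(inherits(model, "beam_model"))
  obj <- list(
    format = "psrdose-beam-model-v1",
    n_rings = model$n_rings, n_energy_bins = model$n_energy_bins,
    plane_z = model$plane_z, source_z = model$source_z, sad = model$sad,
    subsources = model$subsources)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_beam_model
#' @export
read_beam_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "psrdose-beam-model-v1")) {
    stop("not a psrdose beam model file: ", path)
  }
  ss <- as.data.frame(obj$subsources)
  ss$ring <- as.integer(ss$ring)
  ss$ebin <- as.integer(ss$ebin)
  ss$pclass <- as.integer(ss$pclass)
  structure(list(n_rings = as.integer(obj$n_rings),
                 n_energy_bins = as.integer(obj$n_energy_bins),
                 plane_z = as.numeric(obj$plane_z),
                 source_z = as.numeric(obj$source_z),
                 sad = as.numeric(obj$sad), subsources = ss, spec = NULL),
            class = "beam_model")
}
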