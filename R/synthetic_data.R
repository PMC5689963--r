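#' Default water phantoms
#'
#' `"test"`: 30 x 30 x 30 voxels at 5 mm, beam entrance surface at
#' SSD 100 cm (vertical-beam commissioning layout). `"full"`: 200 x 200 x
#' 160 at 2.5 mm, lateral extent 50 cm, covering a 40 x 40 cm^2 field.
#' `"plan"`: 30 x 30 x 30 at 5 mm centered on the isocenter, the layout
#' used for rotational (VMAT) dose calculations. `"commissioning"`:
#' 50 x 50 cm^2 lateral extent at 1 cm lateral / 5 mm depth resolution,
#' 30 cm deep, sized for the 40x40 / 10x10 / 2x2 commissioning field trio.
#'
#' @param profile One of `"test"`, `"full"`, `"plan"`,
#'   `"commissioning"`.
#' @param sad Source-axis distance (cm); the isocenter sits at
#'   `(0, 0, sad)`.
#' @return A `dose_grid` of zeros.
#' @export
make_default_phantom <- function(profile = c("test", "full", "plan",
                                             "commissioning"),
                                 sad = 100) {
  profile <- match.arg(profile)
  switch(profile,
    test = dose_grid(c(30, 30, 30), 0.5, c(-7.5, -7.5, 100), ssd = 100),
    full = dose_grid(c(200, 200, 160), 0.25, c(-25, -25, 100), ssd = 100),
    plan = dose_grid(c(30, 30, 30), 0.5, c(-7.5, -7.5, sad - 7.5),
                     ssd = sad - 7.5),
    commissioning = dose_grid(c(50, 50, 60), c(1, 1, 0.5),
                              c(-25, -25, 100), ssd = 100))
}

#' Ground-truth correction factors for a synthetic study
#'
#' Deterministic, strictly positive factors: photon factors vary smoothly
#' around one across the sub-sources (emulating a real linac whose
#' spectrum and lateral particle distribution differ from the reference
#' model); electron factors are constant within each energy bin, as the
#' effective-PSR grouping assumes.
#'
#' @param model A `beam_model`.
#' @return Numeric vector, one factor per sub-source (canonical order).
#' @export
make_true_factors <- function(model) {
  ss <- model$subsources
  x <- numeric(nrow(ss))
  ph <- ss$pclass < 2L
  i <- seq_len(sum(ph))
  x[ph] <- 1 + 0.25 * sin(2 * pi * i / max(i)) +
    0.1 * cos(6 * pi * i / max(i))
  ebin_factors <- 0.8 + 0.5 * abs(sin(1 + seq_len(model$n_energy_bins)))
  x[!ph] <- ebin_factors[ss$ebin[!ph] + 1L]
  x
}

#' Generate synthetic water-phantom measurements
#'
#' Builds the measurement vector `b = A x_true + eps` with i.i.d.
#' Gaussian noise of standard deviation `noise_sigma` percent of the
#' field's dmax dose (homoscedastic in absolute dose within a field), and
#' reshapes it into per-field depth-dose and profile curves. A single
#' global factor rescales all fields so the 10x10 (or first) field's dmax
#' dose reads 100, emulating relative water-tank normalization while
#' preserving inter-field ratios. The ground truth is attached as
#' attributes.
#'
#' @param A `subsource_dose_matrix` (with `row_meta`).
#' @param x_true Non-negative ground-truth factors, one per column.
#' @param noise_sigma Noise SD, percent of the per-field dmax dose.
#' @param rng_seed Integer seed.
#' @return A `measurement_set` with attributes `x_true` and
#'   `normalization_factor`.
#' @export
make_synthetic_measurements <- function(A, x_true, noise_sigma = 0.2,
                                        rng_seed = 1) {
  stopifnot(inherits(A, "subsource_dose_matrix"))
  if (length(x_true) != ncol(A$values)) {
    stop("x_true length does not match the number of sub-sources")
  }
  if (any(x_true < 0)) stop("x_true must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  rm_ <- A$row_meta
  b0 <- as.vector(A$values %*% x_true)

  fields <- unique(rm_$field)
  dmax_dose <- vapply(fields, function(f) {
    i <- rm_$field == f & rm_$curve_type == "depth"
    find_dmax(rm_$position_cm[i], b0[i])$dose
  }, numeric(1))
  names(dmax_dose) <- fields

  b <- with_seed(rng_seed, {
    sdv <- noise_sigma / 100 * dmax_dose[rm_$field]
    b0 + rnorm(length(b0), 0, sdv)
  })
  ref_field <- if ("10x10" %in% fields) "10x10" else fields[1]
  nf <- 100 / dmax_dose[[ref_field]]
  b <- pmax(b * nf, 0)

  key <- paste(rm_$field, rm_$curve_type,
               ifelse(rm_$curve_type == "depth", "", rm_$depth_cm))
  curves <- lapply(unique(key), function(k) {
    i <- which(key == k)
    i <- i[order(rm_$position_cm[i])]
    r1 <- rm_[i[1], ]
    list(field = r1$field, curve_type = r1$curve_type,
         depth_cm = if (r1$curve_type == "depth") NA_real_ else r1$depth_cm,
         positions = rm_$position_cm[i], doses = b[i])
  })
  ms <- measurement_set(curves,
                        normalization = sprintf("dmax(%s) = 100", ref_field),
                        detector = "synthetic")
  attr(ms, "x_true") <- x_true
  attr(ms, "normalization_factor") <- nf
  ms
}

#' Generate a toy VMAT arc
#'
#' Control points with gantry angles evenly spaced over
#' `360 (K - 1) / K` degrees and MU weights normalized to one. Aperture
#' schedules: `"sweeping_slit"` -- a narrow slit traversing the field
#' left to right across the arc, producing the sparse per-pixel fluence
#' typical of VMAT; `"oscillating"` -- per-leaf-pair sinusoidal aperture
#' centers; `"open"` -- fully open to the jaw.
#'
#' @param K Number of control points (>= 1).
#' @param aperture_schedule One of `"sweeping_slit"`, `"oscillating"`,
#'   `"open"`.
#' @param mu_schedule `"uniform"` or `"peaked"` (Gaussian over the arc).
#' @param field_size Square jaw opening (cm at isocenter).
#' @param slit_width Slit width (cm) of the sweeping schedule.
#' @param n_leaf_pairs Leaf pairs spanning the field in y.
#' @param rng_seed Kept for interface symmetry; the schedules are
#'   deterministic.
#' @return A `vmat_arc`.
#' @export
make_toy_vmat_arc <- function(K,
                              aperture_schedule = c("sweeping_slit",
                                                    "oscillating", "open"),
                              mu_schedule = c("uniform", "peaked"),
                              field_size = 10, slit_width = 2,
                              n_leaf_pairs = 10, rng_seed = 1) {
  aperture_schedule <- match.arg(aperture_schedule)
  mu_schedule <- match.arg(mu_schedule)
  if (!is.numeric(K) || K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  W <- field_size
  jaw <- jaw_rectangle(W, W)
  angles <- if (K == 1) 0 else 360 * (seq_len(K) - 1) / K
  mu <- switch(mu_schedule,
    uniform = rep(1, K),
    peaked = exp(-0.5 * ((seq_len(K) - (K + 1) / 2) / (K / 6))^2))
  mu <- mu / sum(mu)
  y_edges <- seq(-W / 2, W / 2, length.out = n_leaf_pairs + 1)

  cps <- lapply(seq_len(K), function(k) {
    frac <- if (K == 1) 0.5 else (k - 1) / (K - 1)
    leaves <- switch(aperture_schedule,
      open = data.frame(y_low = y_edges[-(n_leaf_pairs + 1)],
                        y_high = y_edges[-1],
                        left = -W / 2, right = W / 2),
      sweeping_slit = {
        left <- -W / 2 + (W - slit_width) * frac
        data.frame(y_low = y_edges[-(n_leaf_pairs + 1)],
                   y_high = y_edges[-1],
                   left = left, right = left + slit_width)
      },
      oscillating = {
        i <- seq_len(n_leaf_pairs)
        ctr <- (W / 2 - slit_width) *
          sin(2 * pi * (frac + i / n_leaf_pairs))
        data.frame(y_low = y_edges[-(n_leaf_pairs + 1)],
                   y_high = y_edges[-1],
                   left = pmax(ctr - slit_width, -W / 2),
                   right = pmin(ctr + slit_width, W / 2))
      })
    control_point(k - 1L, angles[k], mu[k], leaves, jaw)
  })
  vmat_arc(cps, arc_id = sprintf("toy-%s-K%d", aperture_schedule, K))
}

#' End-to-end synthetic commissioning study
#'
#' Generates everything the commissioning pipeline needs with a known
#' ground truth: a toy beam model, the sub-source dose matrix A over the
#' commissioning field trio (40x40, 10x10, 2x2 cm^2), ground-truth
#' factors and synthetic measurements `b = A x_true + eps`.
#'
#' @param n_rings,n_energy_bins Beam-model partition (default 8 x 6 for
#'   fast runs; the clinical-scale partition is 40 x 20).
#' @param fields Field list (cm).
#' @param noise_sigma Measurement noise, percent of per-field dmax dose.
#' @param n_particles Histories per field for matrix A.
#' @param rng_seed Integer seed driving model sampling and noise.
#' @param phantom A `dose_grid` (default the commissioning phantom).
#' @param profile_depths Profile depths (cm).
#' @return List with `model`, `A`, `x_true`, `measurements`, `phantom`.
#' @export
synthetic_study <- function(n_rings = 8, n_energy_bins = 6,
                            fields = list(c(40, 40), c(10, 10), c(2, 2)),
                            noise_sigma = 0.2, n_particles = 1.5e5,
                            rng_seed = 1, phantom = NULL,
                            profile_depths = c(5, 10, 20)) {
  phantom <- phantom %||% make_default_phantom("commissioning")
  model <- build_toy_beam_model(n_rings, n_energy_bins)
  A <- build_subsource_matrix(model, fields, phantom,
                              profile_depths = profile_depths,
                              n_particles = n_particles,
                              rng_seed = rng_seed)
  x_true <- make_true_factors(model)
  ms <- make_synthetic_measurements(A, x_true, noise_sigma = noise_sigma,
                                    rng_seed = rng_seed + 1000L)
  list(model = model, A = A, x_true = x_true, measurements = ms,
       phantom = phantom)
}
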