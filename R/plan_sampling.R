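#' VMAT control point
#'
#' One discrete state of an arc: gantry angle, monitor-unit (MU) weight,
#' MLC aperture and jaw. Leaf travel is along x; each leaf pair covers a
#' y strip and opens the x interval `[left, right]` (all cm at
#' isocenter).
#'
#' @param index 0-based control-point index within the arc.
#' @param gantry_angle Gantry angle (degrees); rotation is about the y
#'   axis through the isocenter, IEC 61217 sense.
#' @param mu_weight MU fraction delivered at this control point (>= 0).
#' @param leaves Data frame with `y_low`, `y_high`, `left`, `right` (cm at
#'   isocenter), `left <= right` per pair.
#' @param jaw Jaw opening ([jaw_rectangle()] or widths).
#' @return List, class `"control_point"`.
#' @export
control_point <- function(index, gantry_angle, mu_weight, leaves, jaw) {
  if (!is.finite(gantry_angle)) stop("gantry angle must be finite")
  if (mu_weight < 0) stop("mu_weight must be >= 0")
  leaves <- as.data.frame(leaves)
  stopifnot(all(c("y_low", "y_high", "left", "right") %in% names(leaves)))
  if (any(leaves$left > leaves$right)) {
    stop("each leaf pair needs left <= right")
  }
  structure(list(index = as.integer(index), gantry_angle = gantry_angle,
                 mu_weight = mu_weight, leaves = leaves, jaw = as_jaw(jaw)),
            class = "control_point")
}

#' A VMAT arc: an ordered list of control points
#'
#' @param control_points List of [control_point()]s with positive total MU.
#' @param arc_id Arc label.
#' @return List, class `"vmat_arc"`.
#' @export
vmat_arc <- function(control_points, arc_id = "arc1") {
  if (!length(control_points)) stop("an arc needs at least one control point")
  mu <- vapply(control_points, `[[`, numeric(1), "mu_weight")
  if (sum(mu) <= 0) stop("total MU weight of an arc must be positive")
  structure(list(control_points = control_points, arc_id = arc_id),
            class = "vmat_arc")
}

#' @export
print.vmat_arc <- function(x, ...) {
  mu <- vapply(x$control_points, `[[`, numeric(1), "mu_weight")
  cat(sprintf("VMAT arc '%s': %d control points, total MU weight %g\n",
              x$arc_id, length(x$control_points), sum(mu)))
  invisible(x)
}

# vectorized aperture test at isocenter coordinates for one control point
in_aperture <- function(x_iso, y_iso, cp) {
  lv <- cp$leaves
  pair <- findInterval(y_iso, c(lv$y_low[1], lv$y_high), left.open = FALSE)
  ok <- pair >= 1L & pair <= nrow(lv) & y_iso >= lv$y_low[1]
  pair[!ok] <- 1L
  inside <- ok & x_iso >= lv$left[pair] & x_iso <= lv$right[pair]
  inside
}

# --- fluence maps ----------------------------------------------------------

#' Build the fluence-map stack of an arc
#'
#' The fluence map (FM) lives on a plane at the MLC upper surface
#' (`fm_z`, default 50 cm from the target). For control point k and a
#' pixel whose center projects to `(x, y)` at isocenter scale,
#' `FM(x, y, k) = mu_k` inside the aperture, `mu_k * T` inside the jaw
#' but under a closed leaf (T = MLC transmission), and 0 outside the jaw.
#' The pixel grid spans exactly the jaw projection, so its edges align
#' with the jaw edges.
#'
#' @param arc A `vmat_arc`.
#' @param transmission MLC transmission fraction T in (0, 1).
#' @param pixel_size Pixel size (cm) on the FM plane.
#' @param fm_z FM plane location (cm from target).
#' @param sad Source-axis distance (cm).
#' @return A `fluence_map_stack`: pixel grid metadata, `values` array
#'   `(nx, ny, K)`, and the per-pixel total `sum_k` used as the biased
#'   particle weight.
#' @export
build_fluence_maps <- function(arc, transmission = 0.015,
                               pixel_size = 0.25, fm_z = 50, sad = 100) {
  stopifnot(inherits(arc, "vmat_arc"))
  if (transmission <= 0 || transmission >= 1) {
    stop("transmission must be in (0, 1)")
  }
  K <- length(arc$control_points)
  f <- fm_z / sad
  jaw <- arc$control_points[[1]]$jaw
  ox <- f * jaw$x[1]; oy <- f * jaw$y[1]
  nx <- max(1L, round(f * diff(jaw$x) / pixel_size))
  ny <- max(1L, round(f * diff(jaw$y) / pixel_size))
  px <- f * diff(jaw$x) / nx   # snap the pixel size to the jaw extent
  py <- f * diff(jaw$y) / ny
  xc <- (ox + (seq_len(nx) - 0.5) * px) / f   # pixel centers at iso scale
  yc <- (oy + (seq_len(ny) - 0.5) * py) / f
  gx <- rep(xc, times = ny)
  gy <- rep(yc, each = nx)
  values <- array(0, dim = c(nx, ny, K))
  for (k in seq_len(K)) {
    cp <- arc$control_points[[k]]
    open <- in_aperture(gx, gy, cp)
    values[, , k] <- cp$mu_weight * ifelse(open, 1, transmission)
  }
  structure(list(origin = c(ox, oy), pixel_size = c(px, py),
                 nx = nx, ny = ny, K = K, values = values,
                 sum_k = apply(values, c(1, 2), sum),
                 fm_z = fm_z, sad = sad, transmission = transmission,
                 arc_id = arc$arc_id),
            class = "fluence_map_stack")
}

#' Cumulative probability distribution over control points at a pixel
#'
#' `CPDF_m = sum_{k <= m} FM(x, y, k) / sum_k FM(x, y, k)`; non-
#' decreasing with final entry exactly one.
#'
#' @param fm A `fluence_map_stack`.
#' @param ix,iy 1-based pixel indices.
#' @return Numeric vector of length K.
#' @export
compute_cpdf <- function(fm, ix, iy) {
  stopifnot(inherits(fm, "fluence_map_stack"))
  v <- fm$values[ix, iy, ]
  tot <- sum(v)
  if (tot <= 0) stop("zero-mass pixel: no fluence at (", ix, ", ", iy, ")")
  cp <- cumsum(v) / tot
  cp[length(cp)] <- 1
  cp
}

#' Pre-compute the numerical inverse-CPDF look-up table
#'
#' For each pixel, bin centers `gamma_b = (b - 0.5) / n_prob_bins` are
#' mapped to the control point k satisfying
#' `CPDF_{k-1} <= gamma < CPDF_k` (with `CPDF_{-1} = 0`), so a draw
#' through the table reproduces the categorical distribution
#' `FM(., k) / sum FM` up to the bin resolution; entries within half a
#' bin of a CPDF jump may differ from an exact sequential search by one
#' control point. Zero-mass pixels are flagged with `NA`.
#'
#' @param fm A `fluence_map_stack`.
#' @param n_prob_bins Number of probability bins (default `16 * K`).
#' @return An `inverse_cpdf_table`: integer array `(nx, ny, n_prob_bins)`
#'   of 1-based control-point indices.
#' @export
build_inverse_lookup <- function(fm, n_prob_bins = NULL) {
  stopifnot(inherits(fm, "fluence_map_stack"))
  n_prob_bins <- as.integer(n_prob_bins %||% (16L * fm$K))
  if (n_prob_bins < 1L) stop("n_prob_bins must be >= 1")
  centers <- (seq_len(n_prob_bins) - 0.5) / n_prob_bins
  tab <- array(NA_integer_, dim = c(fm$nx, fm$ny, n_prob_bins))
  for (iy in seq_len(fm$ny)) {
    for (ix in seq_len(fm$nx)) {
      tot <- fm$sum_k[ix, iy]
      if (tot <= 0) next
      cp <- cumsum(fm$values[ix, iy, ]) / tot
      # k : CPDF_{k-1} <= gamma < CPDF_k  (1-based k)
      k <- findInterval(centers, cp, left.open = FALSE) + 1L
      tab[ix, iy, ] <- pmin(k, fm$K)
    }
  }
  structure(list(table = tab, n_prob_bins = n_prob_bins, K = fm$K),
            class = "inverse_cpdf_table")
}

# FM-plane intersection of particle rays; returns pixel indices (NA when
# outside the grid) plus the intersection scaled to isocenter coordinates
fm_pixel_of <- function(particles, fm) {
  t <- (fm$fm_z - particles$z) / particles$uz
  px <- particles$x + particles$ux * t
  py <- particles$y + particles$uy * t
  ix <- floor((px - fm$origin[1]) / fm$pixel_size[1]) + 1L
  iy <- floor((py - fm$origin[2]) / fm$pixel_size[2]) + 1L
  bad <- ix < 1L | ix > fm$nx | iy < 1L | iy > fm$ny
  ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  f <- fm$fm_z / fm$sad
  list(ix = ix, iy = iy, x = px / f, y = py / f)
}

#' Assign control points by FM-based biased sampling
#'
#' Each particle's FM-plane pixel is found; one uniform deviate is mapped
#' through the pre-computed inverse-CPDF table to a control-point index,
#' and the particle weight is multiplied by `sum_k FM(x, y, k)`, the
#' pixel's total fluence. Particles outside the FM grid (beyond the jaw)
#' or at zero-mass pixels are given zero weight and flagged in the
#' `discarded` attribute; they are not "less useful" particles.
#'
#' @param particles `source_particles`.
#' @param fm A `fluence_map_stack`.
#' @param table An `inverse_cpdf_table` for `fm`.
#' @param rng_seed Integer seed.
#' @return The particles with `cp` (1-based control point), `fm_x, fm_y`
#'   and updated weights; attribute `n_discarded` counts out-of-grid /
#'   zero-mass particles.
#' @export
assign_control_points_biased <- function(particles, fm, table,
                                         rng_seed = NULL) {
  stopifnot(inherits(fm, "fluence_map_stack"),
            inherits(table, "inverse_cpdf_table"))
  n <- nrow(particles)
  hit <- fm_pixel_of(particles, fm)
  with_seed(rng_seed, {
    gam <- runif(n)
    bin <- pmin(floor(gam * table$n_prob_bins) + 1L, table$n_prob_bins)
    ok <- !is.na(hit$ix)
    k <- rep(NA_integer_, n)
    k[ok] <- table$table[cbind(hit$ix[ok], hit$iy[ok], bin[ok])]
    w <- numeric(n)
    w[ok] <- fm$sum_k[cbind(hit$ix[ok], hit$iy[ok])]
    ok <- ok & !is.na(k) & w > 0
    particles$cp <- ifelse(ok, k, NA_integer_)
    particles$fm_x <- hit$x
    particles$fm_y <- hit$y
    particles$weight <- particles$weight * ifelse(ok, w, 0)
    attr(particles, "n_discarded") <- sum(!ok)
    particles
  })
}

#' Assign control points by conventional FM weighting
#'
#' The baseline estimator: the control point is drawn uniformly over the
#' K control points and the particle weight is multiplied by
#' `K * FM(x, y, k)`, so both methods are unbiased for the same per-
#' (pixel, control point) fluence and differ only in variance.
#'
#' @inheritParams assign_control_points_biased
#' @return As [assign_control_points_biased()].
#' @export
assign_control_points_weighting <- function(particles, fm, rng_seed = NULL) {
  stopifnot(inherits(fm, "fluence_map_stack"))
  n <- nrow(particles)
  hit <- fm_pixel_of(particles, fm)
  with_seed(rng_seed, {
    k <- sample.int(fm$K, n, replace = TRUE)
    ok <- !is.na(hit$ix)
    w <- numeric(n)
    w[ok] <- fm$K * fm$values[cbind(hit$ix[ok], hit$iy[ok], k[ok])]
    ok <- ok & w > 0
    particles$cp <- ifelse(ok, k, NA_integer_)
    particles$fm_x <- hit$x
    particles$fm_y <- hit$y
    particles$weight <- particles$weight * ifelse(ok, w, 0)
    attr(particles, "n_discarded") <- sum(is.na(hit$ix))
    particles
  })
}

#' Rotate particles to the beam geometry of a control point
#'
#' Positions and directions are rotated about the y axis through the
#' isocenter by the gantry angle (IEC 61217 sense): at 0 degrees the beam
#' points along +z; at 180 degrees the x and z components are negated and
#' y is preserved. Direction norms are preserved.
#'
#' @param particles `source_particles`.
#' @param cp A [control_point()] (or a bare gantry angle in degrees).
#' @param isocenter Isocenter position (cm), default `(0, 0, 100)`.
#' @return The rotated particles.
#' @export
rotate_to_beam <- function(particles, cp, isocenter = c(0, 0, 100)) {
  ang <- if (inherits(cp, "control_point")) cp$gantry_angle else cp
  if (!is.finite(ang)) stop("gantry angle must be finite")
  if (ang == 0) return(particles)
  th <- ang * pi / 180
  ct <- cos(th); st <- sin(th)
  x <- particles$x - isocenter[1]
  z <- particles$z - isocenter[3]
  particles$x <- ct * x + st * z + isocenter[1]
  particles$z <- -st * x + ct * z + isocenter[3]
  ux <- particles$ux; uz <- particles$uz
  particles$ux <- ct * ux + st * uz
  particles$uz <- -st * ux + ct * uz
  particles
}

#' Count "less useful" source particles
#'
#' A particle is "less useful" when its FM-plane position lies inside the
#' jaw opening but under a closed MLC leaf at its assigned control point:
#' it only contributes through leaf transmission. Discarded particles
#' (outside the jaw) are excluded from both numerator and denominator.
#'
#' @param particles Particles with assigned control points (`cp` set).
#' @param arc The `vmat_arc` the control points refer to.
#' @return List with `count`, `total`, `fraction` and `percent`.
#' @export
count_less_useful <- function(particles, arc) {
  stopifnot(inherits(arc, "vmat_arc"))
  assigned <- !is.na(particles$cp)
  if (!any(assigned)) {
    stop("particles have no assigned control points")
  }
  p <- particles[assigned, , drop = FALSE]
  count <- 0L
  for (k in sort(unique(p$cp))) {
    i <- p$cp == k
    open <- in_aperture(p$fm_x[i], p$fm_y[i], arc$control_points[[k]])
    count <- count + sum(!open)
  }
  total <- nrow(p)
  list(count = count, total = total, fraction = count / total,
       percent = 100 * count / total)
}

# --- plan dose calculation -------------------------------------------------

#' Calculate the dose of a VMAT arc
#'
#' Samples source particles from the beam model (restricted to the arc's
#' jaw), assigns each a control point by the chosen method, multiplies in
#' the FM weight, rotates to the control point's gantry angle and
#' transports into the phantom. Runs either a fixed number of particles
#' (split into `n_batches` statistical batches) or successive chunks
#' until the target average uncertainty (percent of the maximum dose) is
#' met.
#'
#' @param arc A `vmat_arc`.
#' @param model A `beam_model`.
#' @param phantom A `dose_grid`.
#' @param method `"biased"` (inverse-CPDF sampling) or `"weighting"`
#'   (uniform control point, FM weight).
#' @param n_particles Fixed particle budget (mutually exclusive with
#'   `target_uncertainty`).
#' @param target_uncertainty Target average statistical uncertainty
#'   (percent of the maximum dose, voxels above 50% of it).
#' @param chunk_size Particles per chunk when iterating to a target.
#' @param min_chunks Minimum number of chunks before the uncertainty
#'   estimate is trusted (the SEM of B batch means has a relative error
#'   of about `1/sqrt(2(B-1))`, so stopping on very few chunks is
#'   unreliable).
#' @param max_particles Particle cap; an unreachable target raises a
#'   budget error.
#' @param rng_seed Integer seed (chunk i uses `rng_seed + i - 1`).
#' @param n_batches Statistical batches for the fixed-budget mode.
#' @param transmission,pixel_size,fm_z FM construction parameters (see
#'   [build_fluence_maps()]).
#' @param margin Jaw-restriction sampling margin (cm at the phase-space
#'   plane).
#' @param isocenter Isocenter (cm).
#' @param config A [transport_config()].
#' @param fm,table Optional pre-built FM stack and inverse table.
#' @return List with `dose` (a `dose_grid`, per history), `uncertainty`
#'   (percent), `n_particles` sampled, `less_useful` (list from
#'   [count_less_useful()]), `n_discarded`, and `batch_doses`.
#' @export
calculate_plan_dose <- function(arc, model, phantom,
                                method = c("biased", "weighting"),
                                n_particles = NULL,
                                target_uncertainty = NULL,
                                chunk_size = 50000, min_chunks = 10,
                                max_particles = 4e6,
                                rng_seed = 1, n_batches = 10,
                                transmission = 0.015, pixel_size = 0.25,
                                fm_z = 50, margin = 0.5,
                                isocenter = NULL,
                                config = transport_config(),
                                fm = NULL, table = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(arc, "vmat_arc"), inherits(model, "beam_model"),
            inherits(phantom, "dose_grid"))
  if (is.null(n_particles) && is.null(target_uncertainty)) {
    stop("give either n_particles or target_uncertainty")
  }
  isocenter <- isocenter %||% c(0, 0, model$sad)
  fm <- fm %||% build_fluence_maps(arc, transmission = transmission,
                                   pixel_size = pixel_size, fm_z = fm_z,
                                   sad = model$sad)
  if (method == "biased" && is.null(table)) {
    table <- build_inverse_lookup(fm)
  }
  jaw <- arc$control_points[[1]]$jaw

  run_chunk <- function(n, seed, nb) {
    p <- sample_source_particles(model, n, jaw, margin = margin,
                                 rng_seed = seed)
    p <- if (method == "biased") {
      assign_control_points_biased(p, fm, table, rng_seed = seed + 10007L)
    } else {
      assign_control_points_weighting(p, fm, rng_seed = seed + 10007L)
    }
    n_disc <- attr(p, "n_discarded")
    lu <- count_less_useful(p, arc)
    keep <- !is.na(p$cp)
    p <- p[keep, , drop = FALSE]
    for (k in sort(unique(p$cp))) {
      i <- p$cp == k
      p[i, ] <- rotate_to_beam(p[i, , drop = FALSE],
                               arc$control_points[[k]], isocenter)
    }
    res <- transport_and_tally(p, phantom, lut = NULL, n_batches = nb,
                               n_histories = n, config = config)
    list(res = res, lu = lu, n_disc = n_disc)
  }

  if (!is.null(n_particles)) {
    ch <- run_chunk(as.integer(n_particles), as.integer(rng_seed), n_batches)
    unc <- if (n_batches >= 2) {
      estimate_average_uncertainty(ch$res$batch_doses,
                                   max(ch$res$dose$values))
    } else NA_real_
    return(list(dose = ch$res$dose, uncertainty = unc,
                n_particles = as.integer(n_particles),
                less_useful = ch$lu, n_discarded = ch$n_disc,
                batch_doses = ch$res$batch_doses))
  }

  chunks <- list()
  lu_count <- 0L; lu_total <- 0L; n_disc <- 0L
  n_sampled <- 0L
  i <- 0L
  repeat {
    i <- i + 1L
    ch <- run_chunk(as.integer(chunk_size), as.integer(rng_seed) + i - 1L, 1L)
    chunks[[i]] <- ch$res$dose$values
    lu_count <- lu_count + ch$lu$count
    lu_total <- lu_total + ch$lu$total
    n_disc <- n_disc + ch$n_disc
    n_sampled <- n_sampled + as.integer(chunk_size)
    if (i >= max(2L, min_chunks)) {
      m <- Reduce(`+`, chunks) / i
      unc <- estimate_average_uncertainty(chunks, max(m))
      if (!is.na(unc) && unc <= target_uncertainty) break
    }
    if (n_sampled >= max_particles) {
      stop("budget error: target uncertainty not reached within ",
           max_particles, " particles")
    }
  }
  m <- Reduce(`+`, chunks) / length(chunks)
  list(dose = dose_grid(phantom$dims, phantom$voxel_size, phantom$origin,
                        ssd = phantom$ssd, values = m),
       uncertainty = unc, n_particles = n_sampled,
       less_useful = list(count = lu_count, total = lu_total,
                          fraction = lu_count / lu_total,
                          percent = 100 * lu_count / lu_total),
       n_discarded = n_disc, batch_doses = chunks)
}

#' Static open-field dose
#'
#' Convenience wrapper for commissioning-style open fields: samples,
#' collimates with the jaw and transports with [transport_and_tally()].
#'
#' @param model A `beam_model`.
#' @param jaw Jaw opening at isocenter.
#' @param phantom A `dose_grid`.
#' @param n_particles Histories.
#' @param rng_seed Seed.
#' @param n_batches Statistical batches.
#' @param margin Sampling margin (cm).
#' @param config A [transport_config()].
#' @return List with `dose`, `batch_doses`, `edep`.
#' @export
calculate_field_dose <- function(model, jaw, phantom, n_particles,
                                 rng_seed = 1, n_batches = 10, margin = 0.5,
                                 config = transport_config()) {
  p <- sample_source_particles(model, n_particles, jaw, margin = margin,
                               rng_seed = rng_seed)
  p <- collimate_jaw(p, jaw, model)
  transport_and_tally(p, phantom, lut = NULL, n_batches = n_batches,
                      n_histories = n_particles, config = config)
}

# --- plan JSON I/O ---------------------------------------------------------

#' Read/write a treatment plan as documented JSON
#'
#' Schema: `{"format": "psrdose-plan-v1", "arcs": [{"arc_id": ...,
#' "control_points": [{"index": ..., "gantry_angle_deg": ...,
#' "mu_weight": ..., "jaw": {"x": [lo, hi], "y": [lo, hi]},
#' "leaves": [{"y_low": ..., "y_high": ..., "left": ..., "right": ...},
#' ...]}]}]}`. A stand-in for DICOM-RT Plan content at the fidelity the
#' dose engine needs.
#'
#' @param arcs A `vmat_arc` or list of them.
#' @param path File path (`.json`).
#' @return `write_plan` returns `path` invisibly; `read_plan` returns a
#'   list of `vmat_arc`s.
#' @export
write_plan <- function(arcs, path) {
  if (inherits(arcs, "vmat_arc")) arcs <- list(arcs)
  obj <- list(format = "psrdose-plan-v1", arcs = lapply(arcs, function(a) {
    list(arc_id = a$arc_id, control_points = lapply(a$control_points,
      function(cp) list(index = cp$index,
                        gantry_angle_deg = cp$gantry_angle,
                        mu_weight = cp$mu_weight,
                        jaw = list(x = cp$jaw$x, y = cp$jaw$y),
                        leaves = cp$leaves)))
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "psrdose-plan-v1")) {
    stop("not a psrdose plan file: ", path)
  }
  lapply(obj$arcs, function(a) {
    vmat_arc(lapply(a$control_points, function(cp) {
      lv <- cp$leaves
      leaves <- data.frame(y_low = unlist(lv$y_low),
                           y_high = unlist(lv$y_high),
                           left = unlist(lv$left),
                           right = unlist(lv$right))
      control_point(cp$index, cp$gantry_angle_deg, cp$mu_weight, leaves,
                    jaw_rectangle(unlist(cp$jaw$x), unlist(cp$jaw$y)))
    }), arc_id = a$arc_id)
  })
}
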