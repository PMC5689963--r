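#' Configuration of the simplified kernel transport
#'
#' The transport stand-in deposits each particle's energy
#' deterministically along its ray: photons with a build-up-then-
#' exponential depth kernel `k(d) = amp * (exp(-mu d) - exp(-beta d))`
#' (giving a realistic dmax around 1.4-1.5 cm for a ~2 MeV mean-energy
#' beam), electrons with a linear ramp-down within a finite range; both are
#' spread laterally with a Gaussian whose width grows with depth and is
#' larger for scattered photons. All statistical noise therefore comes
#' from the source sampling, and transport of a fixed particle list is
#' bit-reproducible.
#'
#' @param mu_a,mu_b Photon attenuation `mu(E) = mu_a * E^mu_b` (1/cm).
#' @param beta_a,beta_b Build-up coefficient `beta(E) = beta_a * E^beta_b`
#'   (1/cm); `beta > mu` over the beam's energy range.
#' @param deposit_fraction Fraction of the particle energy deposited over
#'   the full kernel (the rest escapes), keeping the total deposited
#'   energy below the incident energy.
#' @param e_range_a,e_range_b Electron range `R(E) = e_range_a * E +
#'   e_range_b` (cm). The defaults confine contaminant-electron dose to
#'   the build-up region of the photon kernel, consistent with the
#'   commissioning model's assumption that voxels after build-up are
#'   beyond the electron penetration depth.
#' @param sigma0,sigma_slope Lateral Gaussian width `sigma(d) = sigma0 +
#'   sigma_slope * d` (cm), per particle class (primary photon, scattered
#'   photon, electron).
#' @param stencil_half Half-width of the lateral deposition stencil
#'   (voxels).
#' @return List of parameters, class `"transport_config"`.
#' @export
transport_config <- function(mu_a = 0.065, mu_b = -0.18,
                             beta_a = 3.2, beta_b = -0.35,
                             deposit_fraction = 0.85,
                             e_range_a = 0.2, e_range_b = 0.05,
                             sigma0 = c(0.10, 0.30, 0.25),
                             sigma_slope = c(0.025, 0.06, 0.10),
                             stencil_half = 2L) {
  structure(list(mu_a = mu_a, mu_b = mu_b, beta_a = beta_a, beta_b = beta_b,
                 deposit_fraction = deposit_fraction,
                 e_range_a = e_range_a, e_range_b = e_range_b,
                 sigma0 = rep_len(sigma0, 3L),
                 sigma_slope = rep_len(sigma_slope, 3L),
                 stencil_half = as.integer(stencil_half)),
            class = "transport_config")
}

# per-particle kernel parameters (vectorized over the particle frame)
kernel_params <- function(particles, config) {
  e <- particles$energy
  cls <- particles$pclass
  photon <- cls < 2L
  kp1 <- kp2 <- kamp <- numeric(length(e))
  mu <- config$mu_a * e^config$mu_b
  beta <- config$beta_a * e^config$beta_b
  kp1[photon] <- mu[photon]
  kp2[photon] <- beta[photon]
  kamp[photon] <- config$deposit_fraction * e[photon] /
    (1 / mu[photon] - 1 / beta[photon])
  rng <- config$e_range_a * e + config$e_range_b
  kp1[!photon] <- rng[!photon]
  kamp[!photon] <- 2 * config$deposit_fraction * e[!photon] / rng[!photon]
  list(ktype = as.integer(cls == 2L), kp1 = kp1, kp2 = kp2, kamp = kamp,
       sig0 = config$sigma0[cls + 1L],
       sigs = config$sigma_slope[cls + 1L])
}

# --- commissioning voxel selection -----------------------------------------

#' Commissioning measurement geometry for one field
#'
#' @param field_size `(wx, wy)` field size (cm) at isocenter (scalar for a
#'   square field).
#' @param ssd Source-to-surface distance (cm).
#' @param profile_depths Depths (cm) of the inline/cross-line profiles.
#' @return List, class `"commissioning_geometry"`.
#' @export
commissioning_geometry <- function(field_size, ssd = 100,
                                   profile_depths = c(5, 10, 20)) {
  field_size <- rep_len(as.numeric(field_size), 2L)
  if (any(field_size <= 0)) stop("field sizes must be positive")
  structure(list(field_size = field_size, ssd = ssd,
                 profile_depths = as.numeric(profile_depths)),
            class = "commissioning_geometry")
}

field_label <- function(field_size) {
  sprintf("%gx%g", field_size[1], field_size[2])
}

#' Select commissioning voxels and build the row-index look-up table
#'
#' Commissioning uses only the central-axis depth-dose column plus the
#' inline (x) and cross-line (y) voxel rows at the requested depths, not
#' the full 3D volume. The returned look-up table (LUT) has one integer
#' per voxel: a 0-based row index into matrix A, or -1 for voxels not used
#' in commissioning. Row order is deterministic: the depth curve first
#' (increasing depth), then for each profile depth in order the inline row
#' (increasing x) and the cross-line row (increasing y); voxels already
#' assigned (the central-axis intersections) are not duplicated.
#'
#' @param grid A `dose_grid` (values ignored; geometry only).
#' @param geom A [commissioning_geometry()].
#' @return List with `lut` (integer array, grid-shaped) and `row_meta`
#'   (data frame: `row` 1-based, `field`, `curve_type` one of
#'   `depth`/`inline`/`crossline`, `depth_cm`, `position_cm`, and voxel
#'   indices `ix, iy, iz` 1-based).
#' @export
select_commissioning_voxels <- function(grid, geom) {
  stopifnot(inherits(grid, "dose_grid"),
            inherits(geom, "commissioning_geometry"))
  dims <- grid$dims
  depth_extent <- dims[3] * grid$voxel_size[3]
  if (any(geom$profile_depths <= 0 | geom$profile_depths >= depth_extent)) {
    stop("requested profile depth outside the phantom")
  }
  xc <- voxel_centers(grid, 1)
  yc <- voxel_centers(grid, 2)
  zc <- voxel_centers(grid, 3)
  ix0 <- which.min(abs(xc))   # voxel column containing the beam axis
  iy0 <- which.min(abs(yc))

  lut <- array(-1L, dim = dims)
  meta <- list()
  nxt <- 0L
  push <- function(ix, iy, iz, type, depth, pos) {
    if (lut[ix, iy, iz] >= 0L) return(invisible(NULL))
    lut[ix, iy, iz] <<- nxt
    nxt <<- nxt + 1L
    meta[[length(meta) + 1L]] <<- data.frame(
      row = nxt, curve_type = type, depth_cm = depth, position_cm = pos,
      ix = ix, iy = iy, iz = iz)
    invisible(NULL)
  }
  depths_vox <- zc - grid$origin[3]
  for (iz in seq_len(dims[3])) {
    push(ix0, iy0, iz, "depth", depths_vox[iz], depths_vox[iz])
  }
  for (d in geom$profile_depths) {
    iz <- min(max(floor(d / grid$voxel_size[3]) + 1L, 1L), dims[3])
    for (ix in seq_len(dims[1])) {
      push(ix, iy0, iz, "inline", depths_vox[iz], xc[ix])
    }
    for (iy in seq_len(dims[2])) {
      push(ix0, iy, iz, "crossline", depths_vox[iz], yc[iy])
    }
  }
  row_meta <- do.call(rbind, meta)
  row_meta$field <- field_label(geom$field_size)
  list(lut = lut, row_meta = row_meta)
}

# --- transport -------------------------------------------------------------

#' Transport particles and tally dose (and, concurrently, matrix A)
#'
#' Ray-traces every particle into the phantom and deposits dose with the
#' deterministic depth kernels of [transport_config()]. When a row-index
#' LUT is supplied, every deposition into a selected voxel is also
#' accumulated -- in the same pass -- into the entry of the sub-source dose
#' matrix A whose column is the sub-source index carried by the particle
#' and whose row is given by the LUT. Batch statistics (contiguous equal
#' splits of the particle stream) provide per-voxel and per-entry standard
#' errors.
#'
#' Doses are per sampled history: totals are divided by `n_histories` and
#' by the voxel volume.
#'
#' @param particles A `source_particles` frame.
#' @param grid A `dose_grid` defining the phantom (values ignored).
#' @param lut Optional LUT from [select_commissioning_voxels()] (the full
#'   list or just its `lut` array), with `row_meta` passed along.
#' @param n_batches Number of statistical batches (>= 1).
#' @param n_histories Number of source histories the particle list
#'   represents (defaults to `nrow(particles)`; pass the pre-collimation
#'   count when particles have been filtered).
#' @param config A [transport_config()].
#' @param model The `beam_model` (needed for column metadata when
#'   tallying).
#' @return List with `dose` (a `dose_grid`), `batch_doses` (list of
#'   `n_batches` arrays), `edep` (total deposited energy, MeV-weighted),
#'   and -- when a LUT is given -- `A`, a `subsource_dose_matrix`.
#' @export
transport_and_tally <- function(particles, grid, lut = NULL, n_batches = 10,
                                n_histories = NULL,
                                config = transport_config(), model = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  n <- nrow(particles)
  n_batches <- max(1L, as.integer(n_batches))
  n_histories <- n_histories %||% n
  row_meta <- NULL
  lut_arr <- integer(0)
  n_rows <- 0L
  n_sub <- if (!is.null(model)) nrow(model$subsources) else
    if (n > 0) max(particles$subsource) else 0L
  if (!is.null(lut)) {
    if (is.list(lut) && !is.null(lut$lut)) {
      row_meta <- lut$row_meta
      lut_arr <- as.integer(lut$lut)
      n_rows <- sum(lut$lut >= 0L)
    } else {
      lut_arr <- as.integer(lut)
      n_rows <- sum(lut_arr >= 0L)
    }
    if (n > 0 && anyNA(particles$subsource)) {
      stop("particles carry no sub-source index; cannot tally matrix A")
    }
  }

  if (n == 0L) {
    res <- list(dose = array(0, grid$dims), batch_dose = NULL,
                A = matrix(0, n_rows, max(n_sub, 0L)), edep = 0)
    out <- list(
      dose = dose_grid(grid$dims, grid$voxel_size, grid$origin,
                       ssd = grid$ssd),
      batch_doses = rep(list(array(0, grid$dims)), n_batches),
      edep = 0)
    if (!is.null(lut)) {
      out$A <- subsource_dose_matrix(res$A, res$A * 0, row_meta,
                                     if (!is.null(model)) model$subsources)
    }
    return(out)
  }

  kp <- kernel_params(particles, config)
  batch <- as.integer(floor((seq_len(n) - 1L) * n_batches / n))
  res <- cpp_transport_tally(
    particles$x, particles$y, particles$z,
    particles$ux, particles$uy, particles$uz,
    particles$weight, kp$ktype, kp$kp1, kp$kp2, kp$kamp, kp$sig0, kp$sigs,
    as.integer(particles$subsource) - 1L, batch, n_batches,
    grid$origin, grid$voxel_size, grid$dims,
    min(grid$voxel_size), config$stencil_half, min(grid$voxel_size[1:2]),
    lut_arr, n_rows, n_sub)

  voxvol <- prod(grid$voxel_size)
  norm <- 1 / (n_histories * voxvol)
  dose <- dose_grid(grid$dims, grid$voxel_size, grid$origin, ssd = grid$ssd,
                    values = res$dose * norm)
  nb <- n_histories / n_batches
  batch_doses <- lapply(seq_len(n_batches), function(b) {
    array(res$batch_dose[((b - 1) * prod(grid$dims) + 1):(b * prod(grid$dims))] /
            (nb * voxvol), dim = grid$dims)
  })
  out <- list(dose = dose, batch_doses = batch_doses, edep = res$edep)

  if (!is.null(lut) && n_rows > 0) {
    A <- matrix(res$A, n_rows, n_sub) * norm
    Ab <- array(res$A_batch, dim = c(n_rows, n_sub, n_batches)) / (nb * voxvol)
    if (n_batches > 1) {
      m <- apply(Ab, c(1, 2), mean)
      se <- sqrt(apply(Ab, c(1, 2), stats::var) / n_batches)
    } else {
      se <- A * 0
    }
    out$A <- subsource_dose_matrix(A, se, row_meta,
                                   if (!is.null(model)) model$subsources)
  }
  out
}

# --- sub-source dose matrix ------------------------------------------------

#' Sub-source dose matrix (matrix A)
#'
#' Commissioning-voxel-by-sub-source dose tally: entry (i, j) is the dose
#' per history that sub-source j deposits in commissioning voxel i.
#'
#' @param values,stderr Numeric matrices (rows = commissioning voxels,
#'   columns = sub-sources in canonical beam-model order).
#' @param row_meta Data frame describing the rows (field, curve type,
#'   depth, lateral position, voxel indices).
#' @param col_meta Sub-source descriptor data frame (the beam model's
#'   `subsources`).
#' @return A `subsource_dose_matrix`.
#' @export
subsource_dose_matrix <- function(values, stderr = NULL, row_meta = NULL,
                                  col_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(stderr)) stderr <- values * 0
  stopifnot(all(dim(stderr) == dim(values)))
  if (!is.null(row_meta)) stopifnot(nrow(row_meta) == nrow(values))
  if (!is.null(col_meta)) stopifnot(nrow(col_meta) == ncol(values))
  structure(list(values = values, stderr = as.matrix(stderr),
                 row_meta = row_meta, col_meta = col_meta),
            class = "subsource_dose_matrix")
}

#' @export
print.subsource_dose_matrix <- function(x, ...) {
  cat(sprintf("sub-source dose matrix A: %d commissioning voxels x %d sub-sources\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$row_meta)) {
    cat("fields:", paste(unique(x$row_meta$field), collapse = ", "), "\n")
  }
  invisible(x)
}

rbind_subsource_matrices <- function(mats) {
  subsource_dose_matrix(
    do.call(rbind, lapply(mats, `[[`, "values")),
    do.call(rbind, lapply(mats, `[[`, "stderr")),
    {
      rm_ <- do.call(rbind, lapply(mats, `[[`, "row_meta"))
      rm_$row <- seq_len(nrow(rm_))
      rm_
    },
    mats[[1]]$col_meta)
}

#' Build the commissioning sub-source dose matrix for a set of open fields
#'
#' For every field, samples jaw-restricted source particles, collimates
#' them, transports them through the water phantom and tallies matrix A
#' concurrently; the per-field row blocks are stacked in field order.
#'
#' @param model A `beam_model`.
#' @param fields List of field sizes (cm at isocenter), e.g.
#'   `list(c(40, 40), c(10, 10), c(2, 2))`.
#' @param grid Water-phantom `dose_grid`.
#' @param profile_depths Profile depths (cm) per field.
#' @param n_particles Histories sampled per field.
#' @param rng_seed Base seed; field `i` uses `rng_seed + i - 1`.
#' @param n_batches Statistical batches for the per-entry standard error.
#' @param margin Jaw-restriction margin (cm at the phase-space plane).
#' @param config A [transport_config()].
#' @return A `subsource_dose_matrix` covering all fields.
#' @export
build_subsource_matrix <- function(model, fields, grid,
                                   profile_depths = c(5, 10, 20),
                                   n_particles = 1e5, rng_seed = 1,
                                   n_batches = 10, margin = 0.5,
                                   config = transport_config()) {
  stopifnot(inherits(model, "beam_model"))
  mats <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    fs <- rep_len(as.numeric(fields[[i]]), 2L)
    geom <- commissioning_geometry(fs, ssd = grid$ssd,
                                   profile_depths = profile_depths)
    sel <- select_commissioning_voxels(grid, geom)
    p <- sample_source_particles(model, n_particles, jaw_rectangle(fs[1], fs[2]),
                                 margin = margin, rng_seed = rng_seed + i - 1)
    p <- collimate_jaw(p, jaw_rectangle(fs[1], fs[2]), model)
    res <- transport_and_tally(p, grid, lut = sel, n_batches = n_batches,
                               n_histories = n_particles, config = config,
                               model = model)
    mats[[i]] <- res$A
  }
  rbind_subsource_matrices(mats)
}

# --- plain-text serialization of matrix A ----------------------------------

#' Read/write a sub-source dose matrix as a plain-text bundle
#'
#' Writes a directory containing `meta.json` (shape, column descriptors),
#' `values.csv`, `stderr.csv` and `row_meta.csv`.
#'
#' @param A A `subsource_dose_matrix`.
#' @param path Directory path.
#' @return `write_subsource_matrix` returns `path` invisibly;
#'   `read_subsource_matrix` returns the matrix object.
#' @export
write_subsource_matrix <- function(A, path) {
  stopifnot(inherits(A, "subsource_dose_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(format = "psrdose-subsource-matrix-v1",
                            n_rows = nrow(A$values), n_cols = ncol(A$values)),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  write.csv(A$values, file.path(path, "values.csv"), row.names = FALSE)
  write.csv(A$stderr, file.path(path, "stderr.csv"), row.names = FALSE)
  if (!is.null(A$row_meta)) {
    write.csv(A$row_meta, file.path(path, "row_meta.csv"), row.names = FALSE)
  }
  if (!is.null(A$col_meta)) {
    write.csv(A$col_meta, file.path(path, "col_meta.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_subsource_matrix
#' @export
read_subsource_matrix <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "psrdose-subsource-matrix-v1")) {
    stop("not a psrdose sub-source matrix bundle: ", path)
  }
  values <- as.matrix(read.csv(file.path(path, "values.csv")))
  stderr <- as.matrix(read.csv(file.path(path, "stderr.csv")))
  dimnames(values) <- dimnames(stderr) <- NULL
  row_meta <- if (file.exists(file.path(path, "row_meta.csv"))) {
    read.csv(file.path(path, "row_meta.csv"))
  }
  col_meta <- if (file.exists(file.path(path, "col_meta.csv"))) {
    read.csv(file.path(path, "col_meta.csv"))
  }
  subsource_dose_matrix(values, stderr, row_meta, col_meta)
}
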