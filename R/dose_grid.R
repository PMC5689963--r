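#' 3D voxelized dose grid
#'
#' Voxels are axis-aligned with half-open extents; the stored value is the
#' dose at the voxel center. Indexing is 0-based in the geometry formulas
#' (voxel `i` spans `origin + [i, i+1) * voxel_size`). Coordinates follow
#' the package convention: right-handed, z along the beam axis from the
#' target (z = 0) toward the isocenter (z = SAD), all lengths in cm.
#'
#' @param dims Integer vector `(nx, ny, nz)`.
#' @param voxel_size Numeric `(dx, dy, dz)` in cm (scalar recycled).
#' @param origin Corner of the grid (cm), i.e. the lower boundary of voxel
#'   `(0, 0, 0)`.
#' @param ssd Source-to-surface distance (cm); by convention the beam
#'   entrance surface for a vertical beam is the low-z face, so
#'   `ssd = origin[3]` when the source sits at z = 0. Metadata only.
#' @param values Optional array of voxel doses (defaults to zero).
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(dims, voxel_size, origin, ssd = NA_real_,
                      values = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  origin <- rep_len(as.numeric(origin), 3L)
  if (is.null(values)) {
    values <- array(0, dim = dims)
  } else {
    values <- array(as.numeric(values), dim = dims)
  }
  structure(list(origin = origin, voxel_size = voxel_size, dims = dims,
                 values = values, ssd = as.numeric(ssd)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose grid %d x %d x %d, voxel %g x %g x %g cm, origin (%g, %g, %g)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("ssd = %g cm, max dose = %g, total = %g\n",
              x$ssd, max(x$values), sum(x$values)))
  invisible(x)
}

voxel_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 0.5) * grid$voxel_size[axis]
}

#' Interpolate dose at a depth/lateral position
#'
#' Trilinear interpolation of the dose grid between voxel centers. Depth
#' is measured from the beam entrance surface (the low-z grid face);
#' `lateral` is the `(x, y)` offset from the beam axis.
#'
#' @param grid A `dose_grid`.
#' @param depth Depth below the entrance surface (cm).
#' @param lateral `(x, y)` position (cm).
#' @return Interpolated dose value.
#' @export
dose_at <- function(grid, depth, lateral = c(0, 0)) {
  stopifnot(inherits(grid, "dose_grid"))
  p <- c(lateral[1], lateral[2], grid$origin[3] + depth)
  dose_at_point(grid, p)
}

dose_at_point <- function(grid, p) {
  # continuous voxel-center coordinates
  fc <- (p - grid$origin) / grid$voxel_size - 0.5
  if (any(fc < 0) || any(fc > grid$dims - 1)) {
    stop("query point outside the dose grid interpolation domain")
  }
  i0 <- pmin(pmax(floor(fc), 0), grid$dims - 2)
  fr <- fc - i0
  v <- grid$values
  i <- i0 + 1L  # 1-based
  c000 <- v[i[1], i[2], i[3]];     c100 <- v[i[1] + 1, i[2], i[3]]
  c010 <- v[i[1], i[2] + 1, i[3]]; c110 <- v[i[1] + 1, i[2] + 1, i[3]]
  c001 <- v[i[1], i[2], i[3] + 1]; c101 <- v[i[1] + 1, i[2], i[3] + 1]
  c011 <- v[i[1], i[2] + 1, i[3] + 1]; c111 <- v[i[1] + 1, i[2] + 1, i[3] + 1]
  c00 <- c000 * (1 - fr[1]) + c100 * fr[1]
  c10 <- c010 * (1 - fr[1]) + c110 * fr[1]
  c01 <- c001 * (1 - fr[1]) + c101 * fr[1]
  c11 <- c011 * (1 - fr[1]) + c111 * fr[1]
  c0 <- c00 * (1 - fr[2]) + c10 * fr[2]
  c1 <- c01 * (1 - fr[2]) + c11 * fr[2]
  c0 * (1 - fr[3]) + c1 * fr[3]
}

#' Central-axis depth-dose curve of a grid
#'
#' Samples the dose along the beam axis (x = y = 0) at every voxel-center
#' depth by trilinear interpolation.
#'
#' @param grid A `dose_grid`.
#' @return Data frame with `depth_cm` and `dose`.
#' @export
central_axis_curve <- function(grid) {
  zc <- voxel_centers(grid, 3) - grid$origin[3]
  dose <- vapply(zc, function(d) dose_at(grid, d, c(0, 0)), numeric(1))
  data.frame(depth_cm = zc, dose = dose)
}

# --- MetaImage I/O ---------------------------------------------------------

#' Write/read a dose grid in MetaImage format
#'
#' Standard `.mhd` text header plus a little-endian raw data file
#' (`ElementType` `MET_FLOAT` by default, `MET_DOUBLE` for a lossless
#' round trip). The `Offset` tag stores the grid origin (corner), and
#' `ElementSpacing` the voxel size, both in cm.
#'
#' @param grid A `dose_grid`.
#' @param path Path of the `.mhd` header; the raw file is written next to
#'   it with extension `.raw`.
#' @param element_type `"MET_FLOAT"` (32-bit) or `"MET_DOUBLE"` (64-bit).
#' @return `write_mhd` returns `path` invisibly; `read_mhd` returns a
#'   `dose_grid` (with `ssd = NA`, which MetaImage does not carry).
#' @export
write_mhd <- function(grid, path, element_type = c("MET_FLOAT", "MET_DOUBLE")) {
  stopifnot(inherits(grid, "dose_grid"))
  element_type <- match.arg(element_type)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  if (identical(raw_name, basename(path))) raw_name <- paste0(basename(path), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(grid$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(grid$voxel_size, digits = 17), collapse = " ")),
    paste("DimSize =", paste(grid$dims, collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(grid$values), con,
           size = if (element_type == "MET_FLOAT") 4L else 8L,
           endian = "little")
  invisible(path)
}

#' @rdname write_mhd
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), character(1))
  get <- function(k) vals[match(k, keys)]
  if (!identical(get("ObjectType"), "Image") || !identical(get("NDims"), "3")) {
    stop("unsupported MetaImage header: ", path)
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  etype <- get("ElementType")
  size <- switch(etype, MET_FLOAT = 4L, MET_DOUBLE = 8L,
                 stop("unsupported ElementType: ", etype))
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(dims), size = size, endian = "little")
  dose_grid(dims, spacing, origin, values = v)
}

# --- batch statistics ------------------------------------------------------

#' Average statistical uncertainty from batch doses
#'
#' The per-voxel standard error of the batch mean, relative to a reference
#' (prescription-like) dose, averaged over voxels whose mean dose exceeds
#' `threshold_frac` of the reference.
#'
#' @param batch_doses List (length >= 2) of `dose_grid`s or arrays of
#'   identical shape, one per independent batch.
#' @param reference_dose Positive reference dose (e.g. the prescription or
#'   maximum dose).
#' @param threshold_frac Fraction of `reference_dose` a voxel's mean dose
#'   must exceed to enter the average (default 0.5; use 0 to average over
#'   all non-empty voxels).
#' @return Average relative uncertainty, in percent.
#' @export
estimate_average_uncertainty <- function(batch_doses, reference_dose,
                                         threshold_frac = 0.5) {
  if (length(batch_doses) < 2L) {
    stop("at least 2 batches are required for an uncertainty estimate")
  }
  if (!is.numeric(reference_dose) || reference_dose <= 0) {
    stop("reference_dose must be positive")
  }
  arrs <- lapply(batch_doses, function(b) {
    if (inherits(b, "dose_grid")) b$values else b
  })
  B <- length(arrs)
  m <- Reduce(`+`, arrs) / B
  s2 <- Reduce(`+`, lapply(arrs, function(a) (a - m)^2)) / (B - 1)
  sem <- sqrt(s2 / B)
  sel <- m > threshold_frac * reference_dose
  if (!any(sel)) return(NA_real_)
  100 * mean(sem[sel]) / reference_dose
}
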