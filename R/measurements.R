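#' Measured-style water-phantom dose data
#'
#' A measurement set holds, per field size, a central-axis depth-dose
#' curve and inline/cross-line lateral profiles at listed depths, in
#' relative dose units (the absolute calibration of water-tank data is
#' arbitrary; commissioning recovers a single global scale).
#'
#' @param curves List of curves; each a list with `field` (label, e.g.
#'   `"10x10"`), `curve_type` (`"depth"`, `"inline"` or `"crossline"`),
#'   `depth_cm` (`NA` for depth curves), `positions` (cm, strictly
#'   increasing; depth for depth curves, lateral offset for profiles) and
#'   `doses` (>= 0).
#' @param normalization Free-text tag describing the dose normalization.
#' @param detector Detector label (metadata only).
#' @return A `measurement_set`.
#' @export
measurement_set <- function(curves, normalization = "relative",
                            detector = "synthetic") {
  for (cv in curves) {
    stopifnot(length(cv$positions) == length(cv$doses))
    if (any(cv$doses < 0)) stop("measured doses must be non-negative")
    if (any(diff(cv$positions) <= 0)) {
      stop("curve positions must be strictly increasing")
    }
  }
  structure(list(curves = curves, normalization = normalization,
                 detector = detector),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("measurement set: %d curves (%s, detector %s)\n",
              length(x$curves), x$normalization, x$detector))
  for (cv in x$curves) {
    cat(sprintf("  %s %s%s: %d points\n", cv$field, cv$curve_type,
                if (is.na(cv$depth_cm)) "" else sprintf(" @ %g cm", cv$depth_cm),
                length(cv$positions)))
  }
  invisible(x)
}

find_curve <- function(ms, field, curve_type, depth_cm = NA) {
  for (cv in ms$curves) {
    if (cv$field == field && cv$curve_type == curve_type &&
        (is.na(depth_cm) || isTRUE(abs(cv$depth_cm - depth_cm) < 1e-6))) {
      return(cv)
    }
  }
  NULL
}

#' Align a measurement set with the rows of matrix A
#'
#' Builds the measurement vector b ordered like the rows of the
#' sub-source dose matrix: for every row, the curve with the matching
#' field / curve type / depth is found and its dose is linearly
#' interpolated at the row's position (exact when the measurement
#' positions coincide with the commissioning voxel centers, as for
#' synthetic data).
#'
#' @param ms A `measurement_set`.
#' @param row_meta Row metadata of a `subsource_dose_matrix`.
#' @return Numeric vector, one dose per row.
#' @export
align_measurements <- function(ms, row_meta) {
  stopifnot(inherits(ms, "measurement_set"))
  b <- numeric(nrow(row_meta))
  key <- paste(row_meta$field, row_meta$curve_type,
               ifelse(row_meta$curve_type == "depth", "", row_meta$depth_cm))
  for (k in unique(key)) {
    i <- which(key == k)
    r1 <- row_meta[i[1], ]
    cv <- find_curve(ms, r1$field, r1$curve_type,
                     if (r1$curve_type == "depth") NA else r1$depth_cm)
    if (is.null(cv)) {
      stop("no measured curve for rows: ", k)
    }
    b[i] <- approx(cv$positions, cv$doses, xout = row_meta$position_cm[i],
                   rule = 2)$y
  }
  b
}

# --- CSV serialization -----------------------------------------------------

curve_file_name <- function(cv) {
  if (cv$curve_type == "depth") {
    sprintf("field_%s_depth.csv", cv$field)
  } else {
    sprintf("field_%s_%s_d%g.csv", cv$field, cv$curve_type, cv$depth_cm)
  }
}

#' Read/write a measurement set as per-curve CSV files
#'
#' One file per curve. Metadata (`field_size_cm`, `curve_type`,
#' `depth_cm` or axis, `normalization`, `detector`) is stored in `#`
#' comment lines above the `position_cm, dose_rel` columns.
#'
#' @param ms A `measurement_set`.
#' @param path Directory to hold the CSV files.
#' @return `write_measurement_set` returns `path` invisibly;
#'   `read_measurement_set` returns the `measurement_set`.
#' @export
write_measurement_set <- function(ms, path) {
  stopifnot(inherits(ms, "measurement_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (cv in ms$curves) {
    f <- file.path(path, curve_file_name(cv))
    hdr <- c(sprintf("# field_size_cm: %s", cv$field),
             sprintf("# curve_type: %s", cv$curve_type),
             sprintf("# depth_cm: %s",
                     if (is.na(cv$depth_cm)) "axis" else cv$depth_cm),
             sprintf("# normalization: %s", ms$normalization),
             sprintf("# detector: %s", ms$detector))
    writeLines(hdr, f)
    suppressWarnings(write.table(
      data.frame(position_cm = cv$positions, dose_rel = cv$doses),
      f, append = TRUE, sep = ",", row.names = FALSE, quote = FALSE))
  }
  invisible(path)
}

#' @rdname write_measurement_set
#' @export
read_measurement_set <- function(path) {
  files <- sort(list.files(path, pattern = "^field_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no measurement curves found in ", path)
  normalization <- "relative"; detector <- "unknown"
  curves <- lapply(files, function(f) {
    hdr <- grep("^#", readLines(f, n = 10), value = TRUE)
    gv <- function(key) {
      x <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
      if (!length(x)) return(NA_character_)
      trimws(sub(paste0("^# ", key, ":"), "", x[1]))
    }
    normalization <<- gv("normalization") %||% normalization
    detector <<- gv("detector") %||% detector
    d <- read.csv(f, comment.char = "#")
    depth <- gv("depth_cm")
    list(field = gv("field_size_cm"), curve_type = gv("curve_type"),
         depth_cm = if (identical(depth, "axis")) NA_real_
                    else as.numeric(depth),
         positions = d$position_cm, doses = d$dose_rel)
  })
  measurement_set(curves, normalization, detector)
}
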