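#' Commissioning configuration
#'
#' @param penumbra_low,penumbra_high Fractions of the same-depth
#'   central-axis dose delimiting the penumbra: profile points with dose
#'   strictly inside `(low, high) * cax` are penumbra, dilated by
#'   `penumbra_dilate` measurement points on each side (TG-53-style 20-80%
#'   convention).
#' @param penumbra_dilate Dilation width (points).
#' @param electron_depth_split Fixed depth (cm) separating build-up from
#'   post-build-up rows; `NULL` (default) uses the per-field dmax of the
#'   measured depth curve.
#' @param tol Relative objective-change stopping tolerance of the
#'   projected-gradient solver.
#' @param max_iterations Iteration cap of the solver.
#' @param weight_by_variance Weight rows by inverse tally variance
#'   (off by default; the standard errors of A are recorded but unused).
#' @return List, class `"commissioning_config"`.
#' @export
commissioning_config <- function(penumbra_low = 0.2, penumbra_high = 0.8,
                                 penumbra_dilate = 1L,
                                 electron_depth_split = NULL,
                                 tol = 1e-10, max_iterations = 50000L,
                                 weight_by_variance = FALSE) {
  stopifnot(tol > 0, max_iterations >= 1,
            penumbra_low < penumbra_high)
  structure(list(penumbra_low = penumbra_low, penumbra_high = penumbra_high,
                 penumbra_dilate = as.integer(penumbra_dilate),
                 electron_depth_split = electron_depth_split,
                 tol = tol, max_iterations = as.integer(max_iterations),
                 weight_by_variance = weight_by_variance),
            class = "commissioning_config")
}

#' Label commissioning rows by dosimetric region
#'
#' Depth-curve rows are split at the per-field dmax (from the measured
#' depth curve) into `build_up` and `after_build_up`. Profile rows are
#' split by the 20-80% rule: points with dose strictly between
#' `penumbra_low` and `penumbra_high` of the same-depth central-axis dose
#' are `penumbra` (dilated by one measurement point each side); points at
#' or above the high fraction are `inner_beam`, at or below the low
#' fraction `outer_beam`.
#'
#' @param ms A `measurement_set`.
#' @param row_meta Row metadata of the sub-source dose matrix.
#' @param config A [commissioning_config()].
#' @return Character vector of region labels, one per row.
#' @export
label_regions <- function(ms, row_meta, config = commissioning_config()) {
  labels <- character(nrow(row_meta))
  for (field in unique(row_meta$field)) {
    dc <- find_curve(ms, field, "depth")
    if (is.null(dc)) stop("no depth curve measured for field ", field)
    split_depth <- config$electron_depth_split %||%
      find_dmax(dc$positions, dc$doses)$depth
    dr <- which(row_meta$field == field & row_meta$curve_type == "depth")
    labels[dr] <- ifelse(row_meta$depth_cm[dr] < split_depth,
                         "build_up", "after_build_up")
    pr <- which(row_meta$field == field & row_meta$curve_type != "depth")
    for (k in unique(paste(row_meta$curve_type[pr], row_meta$depth_cm[pr]))) {
      i <- pr[paste(row_meta$curve_type[pr], row_meta$depth_cm[pr]) == k]
      i <- i[order(row_meta$position_cm[i])]
      cv <- find_curve(ms, field, row_meta$curve_type[i[1]],
                       row_meta$depth_cm[i[1]])
      if (is.null(cv)) {
        stop("no measured ", row_meta$curve_type[i[1]], " profile at depth ",
             row_meta$depth_cm[i[1]], " for field ", field)
      }
      cax <- approx(dc$positions, dc$doses,
                    xout = row_meta$depth_cm[i[1]], rule = 2)$y
      dose <- approx(cv$positions, cv$doses,
                     xout = row_meta$position_cm[i], rule = 2)$y
      pen <- dose > config$penumbra_low * cax &
        dose < config$penumbra_high * cax
      if (config$penumbra_dilate > 0 && any(pen)) {
        for (d_ in seq_len(config$penumbra_dilate)) {
          pen <- pen | c(FALSE, pen[-length(pen)]) | c(pen[-1], FALSE)
        }
      }
      lab <- ifelse(pen, "penumbra",
                    ifelse(dose >= config$penumbra_high * cax,
                           "inner_beam", "outer_beam"))
      labels[i] <- lab
    }
  }
  labels
}

#' Extract the commissioning submatrices A1p, A2p, A2e
#'
#' `A1p`: photon columns restricted to non-build-up, non-penumbra rows
#' (voxels beyond the electron penetration depth). `A2p`: photon columns
#' on build-up rows. `A2e`: electron columns on build-up rows, summed
#' within energy-bin groups (one column per effective PSR). Penumbra rows
#' are excluded from all submatrices.
#'
#' @param A A `subsource_dose_matrix`.
#' @param labels Region labels from [label_regions()].
#' @param model The `beam_model` defining the column layout.
#' @return List with the three submatrices, the row index vectors
#'   `rows1` (photon stage) and `rows2` (build-up), `photon_cols`, and
#'   `electron_groups` (list of column indices per energy bin).
#' @export
extract_submatrices <- function(A, labels, model) {
  stopifnot(inherits(A, "subsource_dose_matrix"),
            length(labels) == nrow(A$values))
  photon_cols <- which(model$subsources$pclass < 2L)
  groups <- group_electron_effective_psrs(model)
  rows1 <- which(labels %in% c("after_build_up", "inner_beam", "outer_beam"))
  rows2 <- which(labels == "build_up")
  A2e <- if (length(rows2)) {
    vapply(groups, function(cols) {
      rowSums(A$values[rows2, cols, drop = FALSE])
    }, numeric(length(rows2)))
  } else {
    matrix(0, 0, length(groups))
  }
  if (length(rows2) == 1L) A2e <- matrix(A2e, nrow = 1L)
  list(A1p = A$values[rows1, photon_cols, drop = FALSE],
       A2p = A$values[rows2, photon_cols, drop = FALSE],
       A2e = A2e,
       rows1 = rows1, rows2 = rows2,
       photon_cols = photon_cols, electron_groups = groups)
}

#' Non-negative least squares by projected gradient descent
#'
#' Minimizes `||M x - target||^2` subject to `x >= 0` with projected
#' gradient descent using Barzilai-Borwein steps and a halving line
#' search that keeps the objective non-increasing. Stops when the
#' relative objective change drops below `tol`, the projected gradient
#' vanishes, or `max_iterations` is reached (the latter sets a warning
#' flag in the diagnostics and returns the best iterate).
#'
#' @param M Matrix (rows = data, columns = unknowns), finite entries.
#' @param target Data vector.
#' @param x0 Non-negative starting point (default all ones).
#' @param tol Relative objective-change tolerance.
#' @param max_iterations Iteration cap.
#' @return List with `x`, `objective`, `iterations`, `converged`.
#' @export
solve_nnls_pgd <- function(M, target, x0 = NULL, tol = 1e-10,
                           max_iterations = 50000L) {
  M <- as.matrix(M)
  if (!all(is.finite(M)) || !all(is.finite(target))) {
    stop("non-finite entries in the NNLS system")
  }
  stopifnot(nrow(M) == length(target))
  x <- pmax(x0 %||% rep(1, ncol(M)), 0)
  if (length(x) != ncol(M)) stop("x0 length does not match ncol(M)")

  # column equilibration: a positive diagonal rescale preserves the
  # non-negativity constraint and conditions the gradient steps (column
  # norms of a sub-source dose matrix span orders of magnitude). The
  # rescale is floored at 1e-3 of the largest column so numerically dead
  # columns are not amplified into unidentifiable directions: their
  # gradients stay negligible and they remain at the starting point.
  cn <- sqrt(colSums(M^2))
  cn <- pmax(cn, 1e-3 * max(cn, 0), .Machine$double.xmin)
  M <- sweep(M, 2, cn, "/")
  x <- x * cn

  # work on the normal equations: f(x) = x'Gx - 2 x'h + c
  G <- crossprod(M)
  h <- as.vector(crossprod(M, target))
  cc <- sum(target^2)
  fobj <- function(x) max(sum(x * (G %*% x)) - 2 * sum(x * h) + cc, 0)

  # Lipschitz estimate for the initial step (a few power iterations)
  v <- rep(1 / sqrt(ncol(M)), ncol(M))
  nv <- 1
  for (i in 1:15) {
    v <- as.vector(G %*% v)
    nv <- sqrt(sum(v^2))
    if (nv == 0) break
    v <- v / nv
  }
  L <- max(nv, .Machine$double.eps)
  alpha0 <- 1 / (2 * L)

  f <- fobj(x)
  g <- 2 * as.vector(G %*% x - h)
  f_scale <- max(f, cc, .Machine$double.eps)
  dx <- dg <- NULL
  it <- 0L
  converged <- FALSE
  patience <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    alpha <- alpha0
    if (!is.null(dx)) {
      sy <- sum(dx * dg)
      if (is.finite(sy) && sy > 0) alpha <- sum(dx * dx) / sy
      if (!is.finite(alpha) || alpha <= 0) alpha <- alpha0
    }
    fn <- Inf
    for (hh in 1:40) {
      xn <- pmax(x - alpha * g, 0)
      fn <- fobj(xn)
      if (fn <= f) break
      alpha <- alpha / 2
    }
    if (fn > f) { converged <- TRUE; break }  # no descent direction left
    gn <- 2 * as.vector(G %*% xn - h)
    dx <- xn - x
    dg <- gn - g
    progress <- f - fn
    x <- xn; f <- fn; g <- gn
    if (f < 1e-20 * f_scale) { converged <- TRUE; break }
    # stall detection: require repeated negligible progress, since
    # Barzilai-Borwein steps alternate short and long strides
    patience <- if (progress < tol * max(f, 1e-14 * f_scale))
      patience + 1L else 0L
    pg <- ifelse(x == 0 & g > 0, 0, g)
    if (patience >= 10L || max(abs(pg)) < 1e-14 * sqrt(f_scale)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("NNLS projected gradient reached the iteration cap")
  }
  # report the objective in the original (non-normal-equation) form
  f_exact <- sum((M %*% x - target)^2)
  list(x = as.vector(x) / cn, objective = f_exact, iterations = it,
       converged = converged)
}

#' Run the two-stage beam-model commissioning
#'
#' Stage 1 (photons): solves `min_{x >= 0} ||A1p x - b1||^2` on the
#' non-build-up, non-penumbra rows, after pre-scaling the measurements by
#' the closed-form global scalar `s = argmin_s ||s A1p 1 - b1||` so
#' factors near one mean "no change". Stage 2 (electrons): with the
#' photon dose `A2p x_p` fixed, solves
#' `min_{x >= 0} ||A2e x + A2p x_p - b2||^2` on the build-up rows for one
#' factor per electron effective PSR. Because the stage-1 rows lie beyond
#' the electron penetration depth, stage 2 leaves every stage-1 residual
#' unchanged.
#'
#' @param A `subsource_dose_matrix` covering the commissioning fields.
#' @param ms `measurement_set` of the linac to be commissioned.
#' @param model The reference `beam_model`.
#' @param config A [commissioning_config()].
#' @param fields Optional character vector of field labels (as in
#'   `A$row_meta$field`) restricting which rows are used.
#' @return List with `factors` (a `correction_factors` object: `x_photon`,
#'   `x_electron` or `NULL`, `global_scale`, solver diagnostics) and
#'   `model`, the commissioned beam model. If no build-up rows are
#'   available the electron stage signals a
#'   `psrdose_electron_stage_error` warning and `x_electron` is `NULL`.
#' @export
run_commissioning <- function(A, ms, model,
                              config = commissioning_config(),
                              fields = NULL) {
  stopifnot(inherits(A, "subsource_dose_matrix"),
            inherits(ms, "measurement_set"),
            inherits(model, "beam_model"))
  rm_ <- A$row_meta
  keep <- if (is.null(fields)) seq_len(nrow(rm_)) else
    which(rm_$field %in% fields)
  if (!length(keep)) stop("no commissioning rows for the requested fields")
  Ak <- subsource_dose_matrix(A$values[keep, , drop = FALSE],
                              A$stderr[keep, , drop = FALSE],
                              rm_[keep, , drop = FALSE], A$col_meta)
  b <- align_measurements(ms, Ak$row_meta)
  labels <- label_regions(ms, Ak$row_meta, config)
  sub <- extract_submatrices(Ak, labels, model)
  if (!length(sub$rows1)) stop("no post-build-up rows; cannot commission")

  b1 <- b[sub$rows1]
  c1 <- as.vector(sub$A1p %*% rep(1, ncol(sub$A1p)))
  s <- sum(c1 * b1) / sum(c1^2)
  if (!is.finite(s) || s <= 0) {
    stop("normalization error: measurement scale incompatible with matrix A")
  }

  st1 <- solve_nnls_pgd(sub$A1p, b1 / s, tol = config$tol,
                        max_iterations = config$max_iterations)
  xp <- st1$x

  xe <- NULL
  st2 <- NULL
  if (!length(sub$rows2)) {
    warning(structure(
      class = c("psrdose_electron_stage_error", "warning", "condition"),
      list(message = paste("no build-up rows: electron stage skipped,",
                           "photon factors returned"),
           call = sys.call())))
  } else {
    b2 <- b[sub$rows2] / s
    target2 <- b2 - as.vector(sub$A2p %*% xp)
    st2 <- solve_nnls_pgd(sub$A2e, target2, tol = config$tol,
                          max_iterations = config$max_iterations)
    xe <- st2$x
  }

  factors <- structure(list(
    x_photon = xp, x_electron = xe, global_scale = s,
    photon_cols = sub$photon_cols, electron_groups = sub$electron_groups,
    diagnostics = list(
      stage1 = st1[c("objective", "iterations", "converged")],
      stage2 = if (!is.null(st2))
        st2[c("objective", "iterations", "converged")])),
    class = "correction_factors")
  list(factors = factors,
       model = apply_correction_factors(model, factors))
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("correction factors: %d photon PSRs (range %.3g..%.3g)",
              length(x$x_photon), min(x$x_photon), max(x$x_photon)))
  if (!is.null(x$x_electron)) {
    cat(sprintf("; %d electron effective PSRs (range %.3g..%.3g)",
                length(x$x_electron), min(x$x_electron), max(x$x_electron)))
  }
  cat(sprintf("\nglobal scale s = %.6g\n", x$global_scale))
  invisible(x)
}

#' Apply correction factors to a beam model
#'
#' Each photon sub-source intensity is multiplied by its factor; each
#' electron sub-source by the factor of its energy-bin effective PSR (or
#' one when the electron stage was skipped). By dose linearity, the
#' commissioned model's dose at the commissioning voxels equals `A x`.
#'
#' @param model A `beam_model`.
#' @param factors A `correction_factors` object.
#' @return The commissioned `beam_model`.
#' @export
apply_correction_factors <- function(model, factors) {
  stopifnot(inherits(model, "beam_model"),
            inherits(factors, "correction_factors"))
  ss <- model$subsources
  if (length(factors$x_photon) != length(factors$photon_cols) ||
      max(factors$photon_cols) > nrow(ss)) {
    stop("correction factor dimensions do not match the model")
  }
  ss$relative_intensity[factors$photon_cols] <-
    ss$relative_intensity[factors$photon_cols] * factors$x_photon
  if (!is.null(factors$x_electron)) {
    if (length(factors$x_electron) != length(factors$electron_groups)) {
      stop("electron factor dimensions do not match the model")
    }
    for (gi in seq_along(factors$electron_groups)) {
      cols <- factors$electron_groups[[gi]]
      ss$relative_intensity[cols] <-
        ss$relative_intensity[cols] * factors$x_electron[gi]
    }
  }
  model$subsources <- ss
  model
}

#' Predict commissioned doses at the commissioning voxels
#'
#' The dose of the commissioned model at the rows of A, in measurement
#' units: `s * A x` with the full per-column factor vector (photon
#' factors; electron group factors expanded to their member columns).
#'
#' @param A `subsource_dose_matrix`.
#' @param factors `correction_factors`.
#' @return Numeric vector, one dose per row of A.
#' @export
predict_commissioned_rows <- function(A, factors) {
  x <- rep(1, ncol(A$values))
  x[factors$photon_cols] <- factors$x_photon
  if (!is.null(factors$x_electron)) {
    for (gi in seq_along(factors$electron_groups)) {
      x[factors$electron_groups[[gi]]] <- factors$x_electron[gi]
    }
  }
  factors$global_scale * as.vector(A$values %*% x)
}

#' Read/write correction factors as JSON
#'
#' @param factors A `correction_factors` object.
#' @param path File path (`.json`).
#' @return `write_correction_factors` returns `path` invisibly;
#'   `read_correction_factors` returns the object.
#' @export
write_correction_factors <- function(factors, path) {
  obj <- list(format = "psrdose-correction-factors-v1",
              x_photon = factors$x_photon,
              x_electron = factors$x_electron,
              global_scale = factors$global_scale,
              photon_cols = factors$photon_cols,
              electron_groups = unname(lapply(factors$electron_groups,
                                              as.integer)),
              diagnostics = factors$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_correction_factors
#' @export
read_correction_factors <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "psrdose-correction-factors-v1")) {
    stop("not a psrdose correction-factor file: ", path)
  }
  structure(list(x_photon = obj$x_photon,
                 x_electron = obj$x_electron,
                 global_scale = obj$global_scale,
                 photon_cols = as.integer(obj$photon_cols),
                 electron_groups = lapply(obj$electron_groups, as.integer),
                 diagnostics = obj$diagnostics),
            class = "correction_factors")
}
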