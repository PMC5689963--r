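#' RMS and maximum dose differences
#'
#' Differences between calculated and measured doses, expressed in percent
#' of the measured dose at dmax:
#' `rms = 100 / D_max * sqrt(mean((Dc - Dm)^2))` and
#' `max = 100 / D_max * max(|Dc - Dm|)`.
#'
#' @param d_calc,d_meas Calculated and measured dose vectors (same length).
#' @param d_max_meas Positive normalizer: the measured dose at dmax.
#' @return Percent difference.
#' @export
rms_percent <- function(d_calc, d_meas, d_max_meas) {
  check_cmp(d_calc, d_meas, d_max_meas)
  100 / d_max_meas * sqrt(mean((d_calc - d_meas)^2))
}

#' @rdname rms_percent
#' @export
max_percent <- function(d_calc, d_meas, d_max_meas) {
  check_cmp(d_calc, d_meas, d_max_meas)
  100 / d_max_meas * max(abs(d_calc - d_meas))
}

check_cmp <- function(d_calc, d_meas, d_max_meas) {
  if (length(d_calc) != length(d_meas) || length(d_calc) < 1) {
    stop("dose vectors must be non-empty and of equal length")
  }
  if (!is.numeric(d_max_meas) || length(d_max_meas) != 1 || d_max_meas <= 0) {
    stop("d_max_meas must be a positive scalar")
  }
  invisible(NULL)
}

#' Locate dmax on a depth-dose curve
#'
#' The depth of maximum dose, refined below the sampling grid by a
#' parabolic fit through the three samples around the discrete maximum.
#' A curve that is still rising at its last sample has no identifiable
#' dmax and raises an error.
#'
#' @param depths,doses Sampled depth-dose curve (depths strictly
#'   increasing).
#' @return List with `depth` (cm) and `dose` (parabola apex value).
#' @export
find_dmax <- function(depths, doses) {
  stopifnot(length(depths) == length(doses), length(depths) >= 2)
  i <- which.max(doses)
  if (i == length(doses)) {
    stop("no identifiable dmax: depth-dose curve is still rising at its end")
  }
  if (i == 1) return(list(depth = depths[1], dose = doses[1]))
  x <- depths[(i - 1):(i + 1)]
  y <- doses[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (!is.finite(co[3]) || co[3] >= 0) {
    return(list(depth = depths[i], dose = doses[i]))
  }
  xm <- -co[2] / (2 * co[3])
  xm <- min(max(xm, x[1]), x[3])
  list(depth = unname(xm), dose = unname(co[1] + co[2] * xm + co[3] * xm^2))
}

#' Distance-to-agreement between two dose curves
#'
#' For each selected point `x` of the measured curve, the DTA is the
#' smallest distance `|x - y|` such that the linearly interpolated
#' calculated curve attains the measured value: `Dc(y) = Dm(x)`. Points
#' where the calculated curve never crosses the measured value within its
#' support are capped at `cap` and flagged.
#'
#' @param pos_calc,dose_calc Calculated curve (positions sorted
#'   increasing, >= 2 points).
#' @param pos_meas,dose_meas Measured curve.
#' @param mask Logical (or index) selection of measured points to
#'   evaluate; must select at least one point.
#' @param cap DTA value (cm) assigned to no-crossing points.
#' @return List with `dta` (per evaluated point, cm), `capped` (logical),
#'   `average` and `maximum`.
#' @export
dta <- function(pos_calc, dose_calc, pos_meas, dose_meas,
                mask = NULL, cap = 1.0) {
  stopifnot(length(pos_calc) == length(dose_calc), length(pos_calc) >= 2,
            length(pos_meas) == length(dose_meas))
  if (is.null(mask)) mask <- rep(TRUE, length(pos_meas))
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0) stop("empty DTA evaluation mask")
  out <- vapply(idx, function(i) {
    v <- dose_meas[i]
    dy <- dose_calc - v
    best <- Inf
    # exact hits at nodes
    hit <- which(dy == 0)
    if (length(hit)) best <- min(abs(pos_calc[hit] - pos_meas[i]))
    cross <- which(dy[-length(dy)] * dy[-1] < 0)
    for (s in cross) {
      t <- dy[s] / (dy[s] - dy[s + 1])
      y <- pos_calc[s] + t * (pos_calc[s + 1] - pos_calc[s])
      best <- min(best, abs(y - pos_meas[i]))
    }
    best
  }, numeric(1))
  capped <- !is.finite(out) | out > cap
  out[capped] <- cap
  list(dta = out, capped = capped, average = mean(out), maximum = max(out))
}

#' Output factor of a field relative to a reference field
#'
#' Central-axis dose of the field at its own dmax divided by the
#' reference-field (conventionally 10 x 10 cm^2) central-axis dose at its
#' dmax, both at the same SSD.
#'
#' @param dose_field,dose_ref `dose_grid`s of the field and the reference
#'   field.
#' @return Dimensionless output factor.
#' @export
output_factor <- function(dose_field, dose_ref) {
  cf <- central_axis_curve(dose_field)
  cr <- central_axis_curve(dose_ref)
  mf <- find_dmax(cf$depth_cm, cf$dose)
  mr <- find_dmax(cr$depth_cm, cr$dose)
  if (mr$dose <= 0) stop("reference field has zero central-axis dose")
  mf$dose / mr$dose
}

#' Gamma-index acceptance criteria
#'
#' @param dose_percent Dose-difference criterion, percent of the
#'   normalizer (global normalization).
#' @param dist_mm Distance-to-agreement criterion (mm).
#' @param low_dose_threshold Fraction of the normalizer below which
#'   reference voxels are excluded from the passing-rate statistic.
#' @param normalizer Dose normalizer; `NULL` means the reference grid's
#'   maximum.
#' @return List, class `"gamma_criteria"`.
#' @export
gamma_criteria <- function(dose_percent = 2, dist_mm = 2,
                           low_dose_threshold = 0.1, normalizer = NULL) {
  stopifnot(dose_percent > 0, dist_mm > 0, low_dose_threshold >= 0)
  structure(list(dose_percent = dose_percent, dist_mm = dist_mm,
                 low_dose_threshold = low_dose_threshold,
                 normalizer = normalizer),
            class = "gamma_criteria")
}

#' 3D gamma index between two co-registered dose grids
#'
#' For every reference voxel above the low-dose threshold,
#' `gamma = min over r' of sqrt(|r' - r|^2 / dta^2 +
#' (D_eval(r') - D_ref(r))^2 / dd^2)`, with the evaluated dose trilinearly
#' interpolated on a sub-voxel search grid (`refine` points per voxel per
#' axis) within `search_factor * dta` of the voxel. Note gamma is not
#' symmetric: swapping evaluated and reference grids changes the result.
#'
#' @param d_eval,d_ref Evaluated and reference `dose_grid`s on identical
#'   geometry.
#' @param crit A [gamma_criteria()].
#' @param refine Sub-voxel refinement factor of the search grid.
#' @param search_factor Search radius in units of the distance criterion.
#' @return List with `gamma` (a `dose_grid` of gamma values, `NA` below
#'   threshold), `pass_rate` (percent of evaluated voxels with
#'   `gamma <= 1`), and `n_evaluated`.
#' @export
gamma_index_3d <- function(d_eval, d_ref, crit = gamma_criteria(),
                           refine = 10, search_factor = 3) {
  stopifnot(inherits(d_eval, "dose_grid"), inherits(d_ref, "dose_grid"))
  if (!all(d_eval$dims == d_ref$dims) ||
      max(abs(d_eval$voxel_size - d_ref$voxel_size)) > 1e-9 ||
      max(abs(d_eval$origin - d_ref$origin)) > 1e-9) {
    stop("gamma requires co-registered grids (resample upstream)")
  }
  normalizer <- crit$normalizer %||% max(d_ref$values)
  if (normalizer <= 0) stop("reference grid has no dose")
  dd <- crit$dose_percent / 100 * normalizer
  dta_cm <- crit$dist_mm / 10
  res <- cpp_gamma3d(as.vector(d_eval$values), as.vector(d_ref$values),
                     d_ref$dims, d_ref$voxel_size, dd, dta_cm,
                     crit$low_dose_threshold * normalizer,
                     as.integer(refine), search_factor)
  list(gamma = dose_grid(d_ref$dims, d_ref$voxel_size, d_ref$origin,
                         ssd = d_ref$ssd, values = res$gamma),
       pass_rate = 100 * res$n_pass / max(res$n_evaluated, 1),
       n_evaluated = res$n_evaluated)
}

#' Particle-count reduction factor between two sampling methods
#'
#' Ratio of the source particles a baseline method needs to those the
#' improved method needs to reach the same statistical uncertainty.
#'
#' @param n_baseline,n_method Particle counts.
#' @return The reduction factor (`> 1` means the method is more
#'   efficient).
#' @export
reduction_factor <- function(n_baseline, n_method) {
  stopifnot(n_baseline > 0, n_method > 0)
  n_baseline / n_method
}
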