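# hand-built measurement set + row metadata for labeling tests
flat_profile_fixture <- function(edge = "linear") {
  depths <- seq(0.25, 14.75, by = 0.5)
  pdd <- exp(-0.05 * depths) - exp(-2 * depths)  # peak near 1.5 cm
  xs <- seq(-6, 6, by = 0.5)
  cax5 <- stats::approx(depths, pdd, xout = 5)$y
  prof <- if (edge == "linear") {
    # flat inside, linear ramp through the 20-80% band at the field edge
    pmax(pmin((4.5 - abs(xs)) / 1.5, 1), 0) * cax5
  } else {
    ifelse(abs(xs) < 4, 1, 0) * cax5  # infinitely sharp edge
  }
  ms <- measurement_set(list(
    list(field = "10x10", curve_type = "depth", depth_cm = NA_real_,
         positions = depths, doses = pdd),
    list(field = "10x10", curve_type = "inline", depth_cm = 5,
         positions = xs, doses = prof)))
  row_meta <- rbind(
    data.frame(row = seq_along(depths), curve_type = "depth",
               depth_cm = depths, position_cm = depths,
               ix = 13, iy = 13, iz = seq_along(depths), field = "10x10"),
    data.frame(row = length(depths) + seq_along(xs),
               curve_type = "inline", depth_cm = 5, position_cm = xs,
               ix = seq_along(xs), iy = 13, iz = 10, field = "10x10"))
  list(ms = ms, row_meta = row_meta, depths = depths, xs = xs, prof = prof,
       cax5 = cax5)
}

test_that("region labeling splits build-up, penumbra and beam regions", {
  fx <- flat_profile_fixture("linear")
  lab <- label_regions(fx$ms, fx$row_meta)
  dmax <- find_dmax(fx$depths, stats::approx(fx$depths, fx$ms$curves[[1]]$doses,
                                             xout = fx$depths)$y)$depth
  depth_lab <- lab[seq_along(fx$depths)]
  expect_true(all(depth_lab[fx$depths < dmax] == "build_up"))
  expect_true(all(depth_lab[fx$depths >= dmax] == "after_build_up"))

  prof_lab <- lab[-seq_along(fx$depths)]
  frac <- fx$prof / fx$cax5
  core <- frac > 0.2 & frac < 0.8        # the strict 20-80% band
  expect_true(all(prof_lab[core] == "penumbra"))
  # dilation: direct neighbors of the band are penumbra too
  dil <- core | c(FALSE, core[-length(core)]) | c(core[-1], FALSE)
  expect_true(all(prof_lab[dil] == "penumbra"))
  expect_true(all(prof_lab[!dil & frac >= 0.8] == "inner_beam"))
  expect_true(all(prof_lab[!dil & frac <= 0.2] == "outer_beam"))

  # an infinitely sharp edge has no point inside the 20-80% band
  fx2 <- flat_profile_fixture("step")
  lab2 <- label_regions(fx2$ms, fx2$row_meta)
  expect_false(any(lab2 == "penumbra"))

  # a monotonically rising depth curve has no identifiable dmax
  bad <- fx$ms
  bad$curves[[1]]$doses <- seq_along(fx$depths)
  expect_error(label_regions(bad, fx$row_meta), "no identifiable dmax")
})

test_that("submatrix extraction follows columns, groups and row regions", {
  st <- small_study()
  b <- align_measurements(st$measurements, st$A$row_meta)
  lab <- label_regions(st$measurements, st$A$row_meta)
  sub <- extract_submatrices(st$A, lab, st$model)

  n_re <- st$model$n_rings * st$model$n_energy_bins
  expect_equal(ncol(sub$A1p), 2 * n_re)             # two photon classes
  expect_lte(ncol(sub$A2e), st$model$n_energy_bins)
  expect_equal(length(sub$rows1) + length(sub$rows2) + sum(lab == "penumbra"),
               nrow(st$A$values))
  expect_false(any(lab[sub$rows1] == "penumbra"))

  # each effective-PSR column is the brute-force sum of its members
  groups <- group_electron_effective_psrs(st$model)
  for (gi in seq_along(groups)) {
    brute <- rowSums(st$A$values[sub$rows2, groups[[gi]], drop = FALSE])
    expect_equal(unname(sub$A2e[, gi]), unname(brute))
  }

  # a 40 x 20 partition gives 1600 photon columns
  m40 <- build_toy_beam_model(40, 20)
  expect_equal(sum(m40$subsources$pclass < 2), 1600)
})

test_that("projected-gradient NNLS: recovery, zero target, active-set oracle", {
  set.seed(13)
  # well-conditioned noiseless system: exact recovery
  M <- matrix(runif(40, 0.5, 1.5), 10, 4)
  M[1:4, ] <- M[1:4, ] + 2 * diag(4)
  x_true <- c(0.5, 1.2, 0.8, 2.0)
  r <- solve_nnls_pgd(M, as.vector(M %*% x_true))
  expect_lt(max(abs(r$x - x_true) / x_true), 1e-4)
  expect_true(all(r$x >= 0))

  # zero target gives the zero solution
  r0 <- solve_nnls_pgd(M, rep(0, 10))
  expect_equal(r0$x, rep(0, 4), tolerance = 1e-10)

  # the returned objective never exceeds the starting objective
  x0 <- rep(2, 4)
  b2 <- rnorm(10)
  r2 <- solve_nnls_pgd(M, b2, x0 = x0)
  expect_lte(r2$objective, sum((M %*% x0 - b2)^2))
  expect_true(all(r2$x >= 0))

  expect_error(solve_nnls_pgd(matrix(c(1, NA, 1, 1), 2, 2), c(1, 1)),
               "non-finite")

  # independent active-set oracle (Lawson-Hanson) on small instances
  skip_if_not_installed("pracma")
  for (seed in 1:8) {
    set.seed(seed)
    M6 <- matrix(abs(rnorm(18)), 6, 3)
    b6 <- as.vector(M6 %*% abs(rnorm(3))) - 2 * M6[, 2]  # push one
    ours <- solve_nnls_pgd(M6, b6)                       # factor to zero
    oracle <- pracma::lsqnonneg(M6, b6)
    f_oracle <- sum((M6 %*% oracle$x - b6)^2)
    expect_lt(abs(ours$objective - f_oracle), 1e-8 * (1 + f_oracle))
  }
})

test_that("identity commissioning returns unit factors and the same model", {
  st <- small_study(noise_sigma = 0)
  # measurement equals the reference model (x_true = 1)
  ms1 <- make_synthetic_measurements(st$A, rep(1, ncol(st$A$values)),
                                     noise_sigma = 0, rng_seed = 1)
  cm <- run_commissioning(st$A, ms1, st$model)
  expect_lt(max(abs(cm$factors$x_photon - 1)), 1e-3)
  pred <- predict_commissioned_rows(st$A, cm$factors)
  b <- align_measurements(ms1, st$A$row_meta)
  expect_lt(sqrt(sum((pred - b)^2) / sum(b^2)), 1e-6)
})

test_that("two-stage separation and degenerate inputs behave as specified", {
  st <- small_study(noise_sigma = 0)
  cm <- run_commissioning(st$A, st$measurements, st$model)
  # the electron stage must not change any stage-1 (photon) residual:
  # recompute stage-1 residuals with and without the electron factors
  lab <- label_regions(st$measurements, st$A$row_meta)
  sub <- extract_submatrices(st$A, lab, st$model)
  b <- align_measurements(st$measurements, st$A$row_meta)
  pred_full <- predict_commissioned_rows(st$A, cm$factors)
  cf_photon_only <- cm$factors
  cf_photon_only$x_electron <- NULL
  pred_ph <- predict_commissioned_rows(st$A, cf_photon_only)
  # electron columns deposit nothing beyond the build-up region, so the
  # predictions agree exactly on stage-1 rows
  expect_equal(pred_full[sub$rows1], pred_ph[sub$rows1], tolerance = 1e-9)

  # post-build-up-only measurements: electron stage signals, photon
  # factors still returned
  deep <- st$A$row_meta$curve_type == "depth" & st$A$row_meta$depth_cm > 3
  prof <- st$A$row_meta$curve_type != "depth"
  keep <- which(deep | prof)
  rm_deep <- st$A$row_meta[keep, ]
  rm_deep$row <- seq_len(nrow(rm_deep))
  A_deep <- subsource_dose_matrix(st$A$values[keep, ], st$A$stderr[keep, ],
                                  rm_deep, st$A$col_meta)
  expect_warning(
    cm2 <- run_commissioning(A_deep, st$measurements, st$model,
                             config = commissioning_config(
                               electron_depth_split = 0.01)),
    class = "psrdose_electron_stage_error")
  expect_null(cm2$factors$x_electron)
  expect_length(cm2$factors$x_photon, sum(st$model$subsources$pclass < 2))
})

test_that("multi-field commissioning does not worsen the combined objective", {
  st <- small_study(noise_sigma = 0.2)
  cm_all <- run_commissioning(st$A, st$measurements, st$model)
  cm_one <- run_commissioning(st$A, st$measurements, st$model,
                              fields = "10x10")
  b <- align_measurements(st$measurements, st$A$row_meta)
  lab <- label_regions(st$measurements, st$A$row_meta)
  fit_rows <- which(lab != "penumbra")
  obj <- function(cm) {
    sum((predict_commissioned_rows(st$A, cm$factors)[fit_rows] -
           b[fit_rows])^2)
  }
  expect_lte(obj(cm_all), obj(cm_one) * (1 + 1e-8))
})

test_that("applying correction factors rescales intensities linearly", {
  st <- small_study(noise_sigma = 0)
  m <- st$model
  nph <- sum(m$subsources$pclass < 2)
  groups <- group_electron_effective_psrs(m)
  unit <- structure(list(
    x_photon = rep(1, nph), x_electron = rep(1, length(groups)),
    global_scale = 1, photon_cols = which(m$subsources$pclass < 2),
    electron_groups = groups, diagnostics = NULL),
    class = "correction_factors")
  expect_identical(apply_correction_factors(m, unit)$subsources,
                   m$subsources)

  # zeroing one sub-source removes exactly its column from the dose
  cf0 <- unit
  cf0$x_photon[5] <- 0
  pred <- predict_commissioned_rows(st$A, cf0)
  full <- predict_commissioned_rows(st$A, unit)
  expect_equal(full - pred, st$A$values[, unit$photon_cols[5]],
               tolerance = 1e-10)

  # dimension mismatch is an error
  bad <- unit
  bad$x_photon <- bad$x_photon[-1]
  expect_error(apply_correction_factors(m, bad), "dimensions")
})
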