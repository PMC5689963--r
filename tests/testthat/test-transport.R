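test_that("commissioning-voxel selection builds a consistent LUT", {
  g <- dose_grid(c(30, 30, 30), 0.5, c(-7.5, -7.5, 100), ssd = 100)
  geom <- commissioning_geometry(c(10, 10), profile_depths = c(5, 8, 12))
  sel <- select_commissioning_voxels(g, geom)
  # nz depth rows plus 3 * (nx + ny) profile voxels minus the 2 central
  # intersections per profile depth
  expect_equal(nrow(sel$row_meta), 30 + 3 * (30 + 30) - 3 * 2)
  expect_equal(sum(sel$lut >= 0L), nrow(sel$row_meta))
  # LUT round trip: the voxel of row r maps back to r (0-based in lut)
  rm_ <- sel$row_meta
  expect_equal(sel$lut[cbind(rm_$ix, rm_$iy, rm_$iz)], rm_$row - 1L)
  # a voxel off every curve is excluded
  expect_identical(sel$lut[2, 2, 2], -1L)
  # unique, contiguous row indices
  expect_setequal(sel$lut[sel$lut >= 0L], 0:(nrow(rm_) - 1L))

  sel0 <- select_commissioning_voxels(
    g, commissioning_geometry(c(10, 10), profile_depths = numeric(0)))
  expect_equal(nrow(sel0$row_meta), 30)
  expect_true(all(sel0$row_meta$curve_type == "depth"))

  expect_error(
    select_commissioning_voxels(
      g, commissioning_geometry(c(10, 10), profile_depths = 99)),
    "outside the phantom")
})

test_that("tally: single-column streams, empty streams, determinism", {
  m <- build_toy_beam_model(3, 2)
  ph <- small_phantom()
  sel <- select_commissioning_voxels(
    ph, commissioning_geometry(c(10, 10), profile_depths = c(5, 10)))
  p <- sample_source_particles(m, 3000, jaw_rectangle(10), rng_seed = 9)

  j <- p$subsource[1]
  pj <- p[p$subsource == j, , drop = FALSE]
  rj <- transport_and_tally(pj, ph, lut = sel, n_histories = 3000, model = m)
  other <- setdiff(seq_len(nrow(m$subsources)), j)
  expect_true(all(rj$A$values[, other] == 0))
  expect_gt(sum(rj$A$values[, j]), 0)

  r0 <- transport_and_tally(p[0, ], ph, lut = sel, n_histories = 10,
                            model = m)
  expect_true(all(r0$dose$values == 0))
  expect_true(all(r0$A$values == 0))

  # same particle list twice: bit-identical dose (transport is
  # deterministic; all randomness lives in the sampling)
  r1 <- transport_and_tally(p, ph, lut = sel, n_histories = 3000, model = m)
  r2 <- transport_and_tally(p, ph, lut = sel, n_histories = 3000, model = m)
  expect_identical(r1$dose$values, r2$dose$values)
  expect_identical(r1$A$values, r2$A$values)

  # energy boundedness and non-negativity
  expect_true(all(r1$dose$values >= 0))
  expect_lte(r1$edep, sum(p$energy * p$weight))

  # tally requires sub-source indices
  pna <- p
  pna$subsource <- NA_integer_
  expect_error(transport_and_tally(pna, ph, lut = sel, model = m),
               "no sub-source index")
})

test_that("concurrent matrix A equals per-sub-source partitioned passes bit-exactly", {
  m <- build_toy_beam_model(3, 2)
  ph <- small_phantom()
  sel <- select_commissioning_voxels(
    ph, commissioning_geometry(c(10, 10), profile_depths = c(5, 10)))
  p <- sample_source_particles(m, 5000, jaw_rectangle(10), rng_seed = 21)
  conc <- transport_and_tally(p, ph, lut = sel, n_histories = 5000,
                              model = m)$A$values
  part <- 0 * conc
  for (j in sort(unique(p$subsource))) {
    pj <- p[p$subsource == j, , drop = FALSE]  # stream order preserved
    part <- part + transport_and_tally(pj, ph, lut = sel,
                                       n_histories = 5000,
                                       model = m)$A$values
  }
  expect_identical(conc, part)
})

test_that("tally linearity: commissioning-row doses equal A times history shares", {
  # with the identical particle stream, the dose at commissioning voxels
  # assembled from matrix A columns reproduces the direct tally exactly
  m <- build_toy_beam_model(3, 2)
  ph <- small_phantom()
  sel <- select_commissioning_voxels(
    ph, commissioning_geometry(c(10, 10), profile_depths = c(5, 10)))
  p <- sample_source_particles(m, 4000, jaw_rectangle(10), rng_seed = 33)
  r <- transport_and_tally(p, ph, lut = sel, n_histories = 4000, model = m)
  rm_ <- r$A$row_meta
  direct <- r$dose$values[cbind(rm_$ix, rm_$iy, rm_$iz)]
  expect_equal(rowSums(r$A$values), direct, tolerance = 1e-12)
})

test_that("dose_at performs trilinear interpolation with range checks", {
  g <- dose_grid(c(4, 4, 4), 1, c(-2, -2, 0))
  g$values[] <- seq_len(64)
  # voxel-center query returns the stored value
  expect_equal(dose_at(g, 2.5, c(-1.5, -1.5)), g$values[1, 1, 3])
  # midpoint along z: arithmetic mean of the two voxel values
  expect_equal(dose_at(g, 2, c(-1.5, -1.5)),
               (g$values[1, 1, 2] + g$values[1, 1, 3]) / 2)
  expect_error(dose_at(g, 10, c(0, 0)), "outside")
  expect_error(dose_at(g, 2, c(5, 0)), "outside")
})

test_that("average uncertainty estimator matches closed forms", {
  dims <- c(5, 5, 5)
  mk <- function(v) array(v, dims)
  expect_equal(estimate_average_uncertainty(list(mk(10), mk(10)), 10), 0)
  # two batches v, v + delta: SEM = delta / 2
  expect_equal(
    estimate_average_uncertainty(list(mk(10), mk(10 + 0.4)), 20,
                                 threshold_frac = 0.2),
    100 * 0.4 / 2 / 20)
  expect_error(estimate_average_uncertainty(list(mk(1)), 1), "at least 2")
  expect_error(estimate_average_uncertainty(list(mk(1), mk(1)), 0),
               "positive")

  # 10 batches of unit-variance noise: SEM ~ 1/sqrt(10)
  set.seed(4)
  batches <- replicate(10, array(rnorm(1000), c(10, 10, 10)),
                       simplify = FALSE)
  u <- estimate_average_uncertainty(batches, 100, threshold_frac = -Inf)
  expect_equal(u, 100 * (1 / sqrt(10)) / 100, tolerance = 0.2)
})

test_that("MetaImage files round-trip dose grids", {
  g <- make_default_phantom("test")
  set.seed(8)
  g$values[] <- runif(length(g$values))
  f <- withr::local_tempfile(fileext = ".mhd")
  write_mhd(g, f, element_type = "MET_DOUBLE")
  g2 <- read_mhd(f)
  expect_identical(as.vector(g$values), as.vector(g2$values))
  expect_equal(g2$dims, g$dims)
  expect_equal(g2$voxel_size, g$voxel_size)
  expect_equal(g2$origin, g$origin)
  # 32-bit storage: lossy once, then idempotent
  write_mhd(g, f, element_type = "MET_FLOAT")
  g3 <- read_mhd(f)
  write_mhd(g3, f, element_type = "MET_FLOAT")
  expect_identical(g3$values, read_mhd(f)$values)
  expect_equal(g3$values, g$values, tolerance = 1e-6)
})
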