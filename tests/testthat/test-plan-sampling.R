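test_that("fluence maps encode MU, aperture and transmission", {
  T_ <- 0.015
  arc_open <- make_toy_vmat_arc(4, "open", mu_schedule = "peaked")
  fm <- build_fluence_maps(arc_open, transmission = T_)
  mu <- vapply(arc_open$control_points, `[[`, numeric(1), "mu_weight")
  for (k in 1:4) {
    expect_equal(as.vector(fm$values[, , k]),
                 rep(mu[k], fm$nx * fm$ny))
  }

  # fully closed aperture (zero-width leaves): transmission everywhere
  arc_closed <- make_toy_vmat_arc(2, "open")
  for (k in 1:2) {
    arc_closed$control_points[[k]]$leaves$left <- 99
    arc_closed$control_points[[k]]$leaves$right <- 99
  }
  fm_c <- build_fluence_maps(arc_closed, transmission = T_)
  mu_c <- vapply(arc_closed$control_points, `[[`, numeric(1), "mu_weight")
  for (k in 1:2) {
    expect_equal(as.vector(fm_c$values[, , k]),
                 rep(mu_c[k] * T_, fm_c$nx * fm_c$ny))
  }

  # a single open leaf pair on one control point only: pixels above
  # transmission level exactly match a brute-force point-in-aperture test
  arc1 <- make_toy_vmat_arc(3, "open")
  for (k in 1:3) {
    arc1$control_points[[k]]$leaves$left <- 99
    arc1$control_points[[k]]$leaves$right <- 99
  }
  arc1$control_points[[2]]$leaves$left[4] <- -2
  arc1$control_points[[2]]$leaves$right[4] <- 1
  fm1 <- build_fluence_maps(arc1, transmission = T_)
  cp2 <- arc1$control_points[[2]]
  f <- fm1$fm_z / fm1$sad
  xc <- (fm1$origin[1] + (seq_len(fm1$nx) - 0.5) * fm1$pixel_size[1]) / f
  yc <- (fm1$origin[2] + (seq_len(fm1$ny) - 0.5) * fm1$pixel_size[2]) / f
  lv <- cp2$leaves[4, ]
  brute <- outer(xc, yc, function(x, y)
    x >= lv$left & x <= lv$right & y >= lv$y_low & y < lv$y_high)
  above_T <- fm1$values[, , 2] > cp2$mu_weight * T_ + 1e-15
  expect_equal(above_T, brute, ignore_attr = TRUE)
  expect_true(all(fm1$values[, , c(1, 3)] <=
                    max(vapply(arc1$control_points, `[[`, numeric(1),
                               "mu_weight")) * T_ + 1e-15))

  expect_error(build_fluence_maps(make_toy_vmat_arc(2), transmission = 0),
               "transmission")
})

test_that("CPDF normalization and the forced small cases", {
  arc <- make_toy_vmat_arc(2, "open")
  arc$control_points[[1]]$mu_weight <- 0.25
  arc$control_points[[2]]$mu_weight <- 0.75
  fm <- build_fluence_maps(arc)
  expect_equal(compute_cpdf(fm, 3, 3), c(0.25, 1))

  # K = 1
  fm1 <- build_fluence_maps(make_toy_vmat_arc(1, "open"))
  expect_equal(compute_cpdf(fm1, 1, 1), 1)

  # uniform FM over K = 178: CPDF_m = (m + 1) / 178 (0-based m)
  fm178 <- build_fluence_maps(make_toy_vmat_arc(178, "open"))
  expect_equal(compute_cpdf(fm178, 5, 5), (1:178) / 178, tolerance = 1e-12)

  # monotone, last entry exactly one, at every pixel of a sparse arc
  fms <- build_fluence_maps(make_toy_vmat_arc(12, "sweeping_slit"))
  for (ix in c(1, 7, 20)) {
    cp <- compute_cpdf(fms, ix, 10)
    expect_true(all(diff(cp) >= 0))
    expect_identical(cp[length(cp)], 1)
  }

  fm0 <- fm
  fm0$values[1, 1, ] <- 0
  fm0$sum_k[1, 1] <- 0
  expect_error(compute_cpdf(fm0, 1, 1), "zero-mass")
})

test_that("inverse look-up table reproduces the sequential CPDF search", {
  # uniform over K = 4 with 8 bins: equal quartiles
  fm4 <- build_fluence_maps(make_toy_vmat_arc(4, "open"))
  tab <- build_inverse_lookup(fm4, 8)
  expect_equal(tab$table[2, 2, ], rep(1:4, each = 2))

  # single control point: every entry is that control point
  fm1 <- build_fluence_maps(make_toy_vmat_arc(1, "open"))
  t1 <- build_inverse_lookup(fm1, 16)
  expect_true(all(t1$table == 1L))

  expect_error(build_inverse_lookup(fm4, 0), "n_prob_bins")

  # oracle: sequential linear scan of the CPDF. A draw routed through the
  # table can differ from the exact search only when the draw falls
  # within half a probability bin of a CPDF jump, so the disagreement
  # rate scales like K / (4 n_bins) and vanishes as the table refines.
  fm <- build_fluence_maps(make_toy_vmat_arc(17, "sweeping_slit"))
  seq_search <- function(cp, g) findInterval(g, cp, left.open = FALSE) + 1L
  set.seed(99)
  gam <- runif(1e4)
  rates <- c()
  for (nbins in c(16L * 17L, 64L * 17L, 1024L * 17L)) {
    tb <- build_inverse_lookup(fm, nbins)
    mism <- 0
    for (px in list(c(4, 9), c(11, 15))) {
      cp <- compute_cpdf(fm, px[1], px[2])
      exact <- pmin(seq_search(cp, gam), fm$K)
      bin <- pmin(floor(gam * nbins) + 1L, nbins)
      viatab <- tb$table[px[1], px[2], bin]
      mism <- mism + mean(viatab != exact)
      # any disagreement sits within half a bin of a CPDF jump
      bad <- which(viatab != exact)
      if (length(bad)) {
        expect_true(all(vapply(gam[bad], function(g)
          min(abs(g - cp)) <= 0.5 / nbins + 1e-12, logical(1))))
      }
    }
    rates <- c(rates, mism / 2)
  }
  expect_lt(rates[1], 0.05)
  expect_lt(rates[2], rates[1])       # refining the table helps
  expect_lt(rates[3], 0.002)          # and drives disagreement to ~0
})

test_that("biased assignment draws the per-pixel categorical distribution", {
  m <- build_toy_beam_model(4, 3)
  # two control points with FM proportions (0.2, 0.8) everywhere
  arc <- make_toy_vmat_arc(2, "open")
  arc$control_points[[1]]$mu_weight <- 0.2
  arc$control_points[[2]]$mu_weight <- 0.8
  fm <- build_fluence_maps(arc)
  # a table resolution whose bin edges align with the 0.2 CPDF jump, so
  # the quantized draw probabilities are exact
  tab <- build_inverse_lookup(fm, 4000)
  p <- sample_source_particles(m, 1e5, jaw_rectangle(10), margin = 0,
                               rng_seed = 2)
  pb <- assign_control_points_biased(p, fm, tab, rng_seed = 3)
  ok <- !is.na(pb$cp)
  counts <- tabulate(pb$cp[ok], 2)
  expect_gt(stats::chisq.test(counts, p = c(0.2, 0.8))$p.value, 0.01)
  # biased weights are the pixel fluence total, constant per pixel
  expect_equal(unique(round(pb$weight[ok] / p$weight[ok], 12)), 1)

  # a pixel whose fluence sits on a single control point always gets it
  arc1 <- make_toy_vmat_arc(2, "open")
  arc1$control_points[[1]]$mu_weight <- 1e-30
  arc1$control_points[[2]]$mu_weight <- 1
  fm1 <- build_fluence_maps(arc1)
  tb1 <- build_inverse_lookup(fm1)
  p1 <- assign_control_points_biased(p, fm1, tb1, rng_seed = 5)
  expect_true(all(p1$cp[!is.na(p1$cp)] == 2L))
})

test_that("both estimators are unbiased for the same (pixel, k) fluence", {
  m <- build_toy_beam_model(4, 3)
  arc <- make_toy_vmat_arc(6, "sweeping_slit", field_size = 6,
                           slit_width = 2)
  fm <- build_fluence_maps(arc)
  # fine table so quantization is negligible against the Monte Carlo SE
  tab <- build_inverse_lookup(fm, 2048L * fm$K)
  p <- sample_source_particles(m, 2e5, jaw_rectangle(6), margin = 0,
                               rng_seed = 8)
  hit <- psrdose:::fm_pixel_of(p, fm)
  px <- c(9, 7)
  at_px <- which(!is.na(hit$ix) & hit$ix == px[1] & hit$iy == px[2])
  expect_gt(length(at_px), 300)

  for (method in c("biased", "weighting")) {
    pa <- if (method == "biased") {
      assign_control_points_biased(p, fm, tab, rng_seed = 31)
    } else {
      assign_control_points_weighting(p, fm, rng_seed = 31)
    }
    sub <- pa[at_px, ]
    base_w <- p$weight[at_px]
    for (k in c(1L, 3L)) {
      # E[weight * 1{cp = k}] per particle at this pixel = FM(pixel, k)
      wk <- ifelse(!is.na(sub$cp) & sub$cp == k, sub$weight / base_w, 0)
      se <- stats::sd(wk) / sqrt(length(wk))
      quant <- fm$sum_k[px[1], px[2]] / tab$n_prob_bins
      expect_lt(abs(mean(wk) - fm$values[px[1], px[2], k]),
                3 * se + quant + 1e-12)
    }
    # per-pixel weight variance: zero for the biased method, positive
    # for FM weighting on a non-uniform pixel
    wv <- stats::var(sub$weight[!is.na(sub$cp)] /
                       base_w[!is.na(sub$cp)])
    if (method == "biased") expect_lt(wv, 1e-20) else expect_gt(wv, 0)
  }
})

test_that("FM weighting with K = 1 coincides with biased sampling", {
  m <- build_toy_beam_model(3, 2)
  arc <- make_toy_vmat_arc(1, "open")
  fm <- build_fluence_maps(arc)
  tab <- build_inverse_lookup(fm)
  p <- sample_source_particles(m, 5000, jaw_rectangle(10), rng_seed = 4)
  pb <- assign_control_points_biased(p, fm, tab, rng_seed = 6)
  pw <- assign_control_points_weighting(p, fm, rng_seed = 6)
  expect_identical(pb$cp, pw$cp)
  expect_equal(pb$weight, pw$weight, tolerance = 1e-12)
})

test_that("gantry rotation follows the IEC convention", {
  m <- build_toy_beam_model(3, 2)
  p <- sample_source_particles(m, 100, jaw_rectangle(10), rng_seed = 12)
  iso <- c(0, 0, 100)
  expect_identical(rotate_to_beam(p, 0, iso), p)

  p180 <- rotate_to_beam(p, 180, iso)
  expect_equal(p180$x, -p$x, tolerance = 1e-12)
  expect_equal(p180$y, p$y)
  expect_equal(p180$z - 100, -(p$z - 100), tolerance = 1e-9)
  expect_equal(p180$ux, -p$ux, tolerance = 1e-12)
  expect_equal(p180$uz, -p$uz, tolerance = 1e-12)

  back <- rotate_to_beam(rotate_to_beam(p, 73.2, iso), -73.2, iso)
  expect_equal(back$x, p$x, tolerance = 1e-12)
  expect_equal(back$z, p$z, tolerance = 1e-12)
  expect_equal(back$ux, p$ux, tolerance = 1e-12)
  nrm <- sqrt(p180$ux^2 + p180$uy^2 + p180$uz^2)
  expect_equal(nrm, rep(1, 100), tolerance = 1e-12)
})

test_that("less-useful accounting matches the aperture geometry", {
  # uniform in-jaw fluence: rings spanning the jaw with area-weighted
  # intensity, so positions are uniform over the jaw rectangle
  m <- build_toy_beam_model(6, 2, toy_beam_spec(
    r_max = 8, primary_radial_decay = 1e6, scatter_radial_decay = 1e6,
    electron_fraction = 1e-9, scatter_fraction = 1e-9))

  arc_open <- make_toy_vmat_arc(3, "open")
  fm_o <- build_fluence_maps(arc_open)
  tab_o <- build_inverse_lookup(fm_o)
  p <- sample_source_particles(m, 4e4, jaw_rectangle(10), margin = 0,
                               rng_seed = 14)
  po <- assign_control_points_biased(p, fm_o, tab_o, rng_seed = 15)
  expect_equal(count_less_useful(po, arc_open)$fraction, 0)

  # single control point whose aperture covers half the jaw area
  arc_h <- make_toy_vmat_arc(1, "open")
  arc_h$control_points[[1]]$leaves$left <- -5
  arc_h$control_points[[1]]$leaves$right <- 0
  fm_h <- build_fluence_maps(arc_h)
  tab_h <- build_inverse_lookup(fm_h)
  ph_ <- assign_control_points_biased(p, fm_h, tab_h, rng_seed = 16)
  lu <- count_less_useful(ph_, arc_h)
  p_hat <- lu$fraction
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / lu$total))

  # sparse slit arc: biased sampling yields fewer less-useful particles
  # than FM weighting on the same particle stream
  arc_s <- make_toy_vmat_arc(12, "sweeping_slit")
  fm_s <- build_fluence_maps(arc_s)
  tab_s <- build_inverse_lookup(fm_s)
  lb <- count_less_useful(
    assign_control_points_biased(p, fm_s, tab_s, rng_seed = 17), arc_s)
  lw <- count_less_useful(
    assign_control_points_weighting(p, fm_s, rng_seed = 18), arc_s)
  expect_lt(lb$fraction, lw$fraction)
  tt <- stats::prop.test(c(lb$count, lw$count), c(lb$total, lw$total),
                         alternative = "less")
  expect_lt(tt$p.value, 0.01)

  expect_error(count_less_useful(p, arc_s), "no assigned control points")
})

test_that("a single open control point reproduces the static field bit-exactly", {
  m <- build_toy_beam_model(4, 3)
  ph <- make_default_phantom("test")
  arc0 <- make_toy_vmat_arc(1, "open", field_size = 10)
  pd <- calculate_plan_dose(arc0, m, ph, "biased", n_particles = 15000,
                            rng_seed = 19)
  sf <- calculate_field_dose(m, jaw_rectangle(10), ph, 15000, rng_seed = 19)
  expect_identical(pd$dose$values, sf$dose$values)
  expect_equal(pd$less_useful$fraction, 0)
})

test_that("plan JSON serialization round-trips", {
  arcs <- list(make_toy_vmat_arc(5, "oscillating"),
               make_toy_vmat_arc(3, "sweeping_slit", mu_schedule = "peaked"))
  f <- withr::local_tempfile(fileext = ".json")
  write_plan(arcs, f)
  arcs2 <- read_plan(f)
  expect_length(arcs2, 2)
  for (i in 1:2) {
    expect_equal(arcs2[[i]]$control_points, arcs[[i]]$control_points)
    expect_equal(arcs2[[i]]$arc_id, arcs[[i]]$arc_id)
  }
})
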