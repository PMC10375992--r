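# Transcranial channel detection, suture mapping, co-localization, TBI metrics.

test_that("skull-half projections separate upper and lower vessels", {
  nz <- 64; nx <- 8; ny <- 2
  b <- structure(list(z_air_skin = matrix(5, nx, ny),
                      z_skin_skull = matrix(20, nx, ny),
                      z_skull_brain = matrix(40, nx, ny),
                      z_midline = matrix(30, nx, ny),
                      validity = array(TRUE, c(nx, ny, 3))),
                 class = "BoundarySet")
  v <- array(0, c(nz, nx, ny))
  v[22, 2, 1] <- 1                             # upper half only
  octa <- new_derived_volume(v, "decorrelation")
  h <- skull_half_projections(octa, b)
  expect_gt(h$upper$pixels[2, 1], 0)
  expect_equal(h$lower$pixels[2, 1], 0)
  # empty angiogram -> zero projections
  h0 <- skull_half_projections(new_derived_volume(v * 0, "decorrelation"), b)
  expect_true(all(h0$upper$pixels == 0) && all(h0$lower$pixels == 0))
  # degenerate skull thinner than 2 voxels -> no-data
  b$z_skull_brain[1, 1] <- 21; b$z_midline[1, 1] <- 20.5
  hd <- skull_half_projections(octa, b)
  expect_true(is.nan(hd$upper$pixels[1, 1]))
})

test_that("detect_channels intersects, filters small areas, is symmetric", {
  up <- new_enface(matrix(0, 20, 20), "octa_mean", "upper_skull")
  lo <- new_enface(matrix(0, 20, 20), "octa_mean", "lower_skull")
  up$pixels[3:5, 3:5] <- 1                     # disjoint patterns
  lo$pixels[10:12, 10:12] <- 1
  expect_equal(nrow(detect_channels(up, lo, 0.5)$components), 0)
  # overlapping blob, plus a single-pixel coincidence that must be filtered
  lo$pixels[3:5, 3:5] <- 1
  up$pixels[18, 18] <- 1; lo$pixels[18, 18] <- 1
  calls <- detect_channels(up, lo, 0.5, min_area = 4)
  expect_equal(nrow(calls$components), 1)
  expect_equal(calls$components$area, 9)
  expect_false(calls$channel_mask[18, 18])
  # symmetry in (upper, lower)
  c2 <- detect_channels(lo, up, 0.5, min_area = 4)
  expect_identical(calls$channel_mask, c2$channel_mask)
  # containment: mask subset of both binarized inputs
  expect_true(all(!calls$channel_mask | (up$pixels >= 0.5)))
  expect_true(all(!calls$channel_mask | (lo$pixels >= 0.5)))
})

test_that("noise-free 3-channel phantom is called exactly", {
  sc <- build_scene(std_config(n_repeats = 2L), seed = 13)
  rs <- render_series(sc, snr_db = Inf, seed = 13)
  int <- suppressWarnings(compute_intensity(rs$tomo))
  dop <- compute_dopu(rs$tomo, intensity_weighted = TRUE)
  seg <- segment_volume(int, dop)
  D <- ssada_decorrelation(split_spectrum(rs$tomo, 4, 0.5), int)
  h <- skull_half_projections(D, seg$boundaries)
  thr <- calibrate_flow_threshold(h$upper, h$lower, probs = 0.99)
  calls <- detect_channels(h$upper, h$lower, thr, 4)
  m <- match_channels(calls, rs$truth$channel_truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("suture map: degenerate cases and phantom recovery", {
  # uniformly high-retardation skull -> empty mask
  rp <- new_enface(matrix(60, 10, 10), "mean_retardation", "skull", "deg")
  ip <- new_enface(matrix(20, 10, 10), "mean_intensity", "skull", "dB")
  expect_false(any(build_suture_map(rp, ip)$suture_mask))
  # all-suture skull (dn = 0 everywhere): mask covers the skull pixels
  cfg <- bare_config(dn = c(skin = 0, skull = 0), n_repeats = 1L)
  cfg$sutures$width_vox <- 1e6                 # whole plate is suture-like
  sc <- build_scene(cfg, seed = 2)
  rs <- render_series(sc, snr_db = 25, seed = 2)
  int <- compute_intensity(rs$tomo)
  dop <- compute_dopu(rs$tomo, intensity_weighted = TRUE)
  # dn = 0 skull is not depolarizing: segment from truth boundaries instead
  b <- structure(list(z_air_skin = rs$truth$boundaries$z_air_skin,
                      z_skin_skull = rs$truth$boundaries$z_skin_skull,
                      z_skull_brain = rs$truth$boundaries$z_skull_brain,
                      z_midline = (rs$truth$boundaries$z_skin_skull +
                                     rs$truth$boundaries$z_skull_brain) / 2,
                      validity = array(TRUE, c(48, 16, 3))),
                 class = "BoundarySet")
  ret <- compute_retardation(rs$tomo)
  sm <- build_suture_map(layer_projection(ret, "skull", b),
                         layer_projection(int, "skull", b),
                         int_threshold = -Inf)
  inner <- sm$suture_mask[2:47, 2:15]          # opening trims the frame edge
  expect_gt(mean(inner), 0.98)
  # standard phantom at SNR 25: mask overlaps the true sutures
  ph <- std_phantom()
  sm2 <- build_suture_map(
    layer_projection(ph$retardation, "skull", ph$seg$boundaries),
    layer_projection(ph$intensity, "skull", ph$seg$boundaries))
  expect_gte(jaccard(sm2$suture_mask, ph$truth$suture_mask), 0.7)
})

test_that("co-localization flags suture channels and control channels", {
  ph <- std_phantom_n4()
  seg <- segment_volume(ph$intensity,
                        compute_dopu(ph$tomo, intensity_weighted = TRUE))
  h <- skull_half_projections(ph$decorr, seg$boundaries)
  thr <- calibrate_flow_threshold(h$upper, h$lower, probs = 0.99)
  calls <- detect_channels(h$upper, h$lower, thr, 4)
  ret <- compute_retardation(ph$tomo)
  sm <- build_suture_map(layer_projection(ret, "skull", seg$boundaries),
                         layer_projection(ph$intensity, "skull", seg$boundaries))
  cc <- colocalize(calls, sm, 2)
  expect_equal(cc$suture_fraction, 1.0)
  # empty call set -> no-data fraction
  empty <- detect_channels(new_enface(matrix(0, 96, 32), "octa_mean"),
                           new_enface(matrix(0, 96, 32), "octa_mean"), 0.5)
  expect_true(is.na(colocalize(empty, sm)$suture_fraction))
  # control phantom: the channel planted outside sutures is flagged FALSE
  cfgo <- std_config(n_repeats = 2L)
  cfgo$vessels$n_trans <- 1L
  cfgo$vessels$n_trans_outside <- 1L
  sco <- build_scene(cfgo, seed = 17)
  rso <- render_series(sco, snr_db = 25, seed = 17)
  into <- compute_intensity(rso$tomo)
  sego <- segment_volume(into, compute_dopu(rso$tomo, intensity_weighted = TRUE))
  Do <- ssada_decorrelation(split_spectrum(rso$tomo, 4, 0.5), into)
  ho <- skull_half_projections(Do, sego$boundaries)
  co <- detect_channels(ho$upper, ho$lower,
                        calibrate_flow_threshold(ho$upper, ho$lower), 4)
  reto <- compute_retardation(rso$tomo)
  smo <- build_suture_map(layer_projection(reto, "skull", sego$boundaries),
                          layer_projection(into, "skull", sego$boundaries))
  cco <- colocalize(co, smo, 2)
  truth_out <- rso$truth$channel_truth[!rso$truth$channel_truth$inside_suture, ]
  d2 <- (cco$components$cx - truth_out$x)^2 + (cco$components$cy - truth_out$y)^2
  hit <- which.min(d2)
  expect_lte(sqrt(d2[hit]), 3)
  expect_false(cco$components$inside_suture[hit])
})

test_that("tbi_metrics handles degenerate angiograms and bad ROIs", {
  roi <- list(x0 = 2, x1 = 11, y0 = 2, y1 = 11)
  zero <- list(list(timepoint = 0.5, image = matrix(0, 12, 12)))
  m0 <- tbi_metrics(zero, roi, 0.1)
  expect_equal(m0$vessel_density, 0)
  expect_equal(m0$avascular_area, 100)
  full <- list(list(timepoint = 1, image = matrix(1, 12, 12)))
  m1 <- tbi_metrics(full, roi, 0.1)
  expect_equal(m1$vessel_density, 1)
  expect_equal(m1$avascular_area, 0)
  expect_error(tbi_metrics(full, list(x0 = 0, x1 = 30, y0 = 1, y1 = 5), 0.1),
               "ROI")
  expect_error(tbi_metrics(list(list(timepoint = 2, image = matrix(0, 4, 4)),
                                list(timepoint = 1, image = matrix(0, 4, 4))),
                           list(x0 = 1, x1 = 2, y0 = 1, y1 = 2), 0.1),
               "sorted")
})

test_that("vessel density tracks the planted fraction monotonically", {
  cfg <- bare_config(undulation_amp = 2.5, n_repeats = 2L)
  roi <- list(x0 = 12, x1 = 37, y0 = 4, y1 = 13)
  for (s in 1:2) {
    base <- build_scene(cfg, seed = 40 + s)
    rs0 <- render_series(base, snr_db = 25, seed = 40 + s)
    int0 <- compute_intensity(rs0$tomo)
    b0 <- segment_volume(int0, compute_dopu(rs0$tomo, intensity_weighted = TRUE))$boundaries
    D0 <- ssada_decorrelation(split_spectrum(rs0$tomo, 4, 0.5), int0)
    thr <- calibrate_flow_threshold(layer_projection(D0, "intracranial", b0),
                                    probs = 0.999)
    dens <- c()
    for (f in c(0.08, 0.2)) {
      sc <- plant_roi_vessels(base, roi, f, seed = 40 + s)
      rs <- render_series(sc, snr_db = 25, seed = 40 + s)
      int <- compute_intensity(rs$tomo)
      b <- segment_volume(int, compute_dopu(rs$tomo, intensity_weighted = TRUE))$boundaries
      D <- ssada_decorrelation(split_spectrum(rs$tomo, 4, 0.5), int)
      m <- tbi_metrics(list(list(timepoint = 1,
                                 image = layer_projection(D, "intracranial", b))),
                       roi, thr)
      dens <- c(dens, m$vessel_density)
      expect_lt(abs(m$vessel_density - sc$tbi$fraction_planted), 0.03)
    }
    expect_true(all(diff(dens) > 0))
  }
})
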