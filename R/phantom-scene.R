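#' Scene configuration for the cranial phantom
#'
#' Describes a three-layer cranium (skin / skull / brain under air) on a
#' regular voxel grid: smooth boundary surfaces, per-layer optical properties,
#' pigment spots in the skin plus a pigmented sheet at the skull base,
#' a birefringent skull interrupted by non-birefringent high-backscatter
#' suture gaps, and planted vessels (skin, brain, and transcranial vessels
#' routed through the sutures).
#'
#' Defaults emulate an adult-zebrafish cranial acquisition: 3.4 um axial and
#' 8 um transverse voxel pitch, ~100 um skin and ~200 um skull on the default
#' 256 x 192 x 96 (z,x,y) grid, and cumulative single-pass retardation
#' reaching 30 deg at the skin-skull boundary and 60 deg at the skull base
#' (the skull's retardation span is centred on 45 deg so that the
#' phase-scrambled skull plate stays clearly depolarizing, DOPU <= ~0.55).
#'
#' @param grid integer c(nz, nx, ny) voxel counts (z = depth, fastest axis)
#' @param pitch_um voxel pitch in micrometres, c(z, x, y)
#' @param offsets depth (voxel) of the flat part of the Air-Skin, Skin-Skull
#'   and Skull-Brain surfaces; default scales with nz
#' @param undulation_amp peak amplitude (voxels) of the band-limited random
#'   surface undulation; 0 gives exactly flat surfaces
#' @param undulation_waves number of sinusoidal harmonics in the undulation
#' @param lambda0_um centre wavelength (um)
#' @param target_retardation_deg named c(skin=, skull=): cumulative single-pass
#'   retardation (deg) at the skin-skull boundary and at the skull base; the
#'   per-layer birefringence dn is derived from these and the mean layer
#'   thickness unless `dn` is given explicitly
#' @param dn optional named c(skin=, skull=) birefringence values overriding
#'   the targets
#' @param backscatter named relative backscatter power per tissue class
#' @param attenuation_per_um named attenuation coefficient per layer (1/um)
#' @param pigment list: n_spots, spot_radius_um (range), sheet_voxels
#' @param sutures list: width_vox, lateral_frac (x positions of the paired
#'   lateral sutures as fractions of nx)
#' @param vessels list: n_skin, n_brain, n_trans, n_trans_outside (control
#'   channels planted away from sutures), radius_um
#' @param n_repeats default number of repeated B-scans per slow-axis position
#' @param line_rate_hz spectrometer line rate (metadata only)
#' @return a list of class "mfoct_scene_config"
#' @export
scene_config <- function(grid = c(nz = 256L, nx = 192L, ny = 96L),
                         pitch_um = c(z = 3.4, x = 8, y = 8),
                         offsets = NULL,
                         undulation_amp = 2.5,
                         undulation_waves = 2L,
                         lambda0_um = 0.84,
                         target_retardation_deg = c(skin = 30, skull = 60),
                         dn = NULL,
                         backscatter = c(skin = 1, skull = 2, suture = 4,
                                         pigment = 8, brain = 0.5, vessel = 1.2),
                         attenuation_per_um = c(skin = 0.002, skull = 0.003,
                                                brain = 0.002),
                         pigment = list(n_spots = 6L, spot_radius_um = c(25, 45),
                                        sheet_voxels = 3L),
                         sutures = list(width_vox = 3L,
                                        lateral_frac = c(0.22, 0.78)),
                         vessels = list(n_skin = 4L, n_brain = 5L, n_trans = 3L,
                                        n_trans_outside = 0L, radius_um = 12),
                         n_repeats = 4L,
                         line_rate_hz = 25000) {
  grid <- as.integer(grid)
  names(grid) <- c("nz", "nx", "ny")
  if (is.null(offsets)) offsets <- round(grid[["nz"]] * c(0.16, 0.27, 0.51))
  cfg <- list(grid = grid, pitch_um = pitch_um, offsets = offsets,
              undulation_amp = undulation_amp,
              undulation_waves = as.integer(undulation_waves),
              lambda0_um = lambda0_um,
              target_retardation_deg = target_retardation_deg, dn = dn,
              backscatter = backscatter,
              attenuation_per_um = attenuation_per_um,
              pigment = pigment, sutures = sutures, vessels = vessels,
              n_repeats = as.integer(n_repeats), line_rate_hz = line_rate_hz)
  class(cfg) <- "mfoct_scene_config"
  cfg
}

# band-limited random surface undulation, peak-normalized to `amp` voxels
random_undulation <- function(nx, ny, amp, waves) {
  if (amp <= 0 || waves < 1) return(matrix(0, nx, ny))
  u <- matrix(0, nx, ny)
  xs <- seq_len(nx) / nx; ys <- seq_len(ny) / ny
  for (k in seq_len(waves)) {
    fx <- sample(1:2, 1); fy <- sample(1:2, 1)
    ph <- runif(2, 0, 2 * pi)
    u <- u + outer(sin(2 * pi * fx * xs + ph[1]),
                   cos(2 * pi * fy * ys + ph[2])) / k
  }
  mx <- max(abs(u))
  if (mx > 0) u <- u * (amp / mx)
  u
}

# expand an (nx, ny) map along z into an (nz, nx, ny) array
expand_z <- function(m, nz) {
  array(rep(as.vector(m), each = nz), dim = c(nz, nrow(m), ncol(m)))
}

# rasterize a z-aligned cylindrical tube into a voxel mask
rasterize_vertical_tube <- function(dim3, pitch_um, x0, y0, z1, z2, r_um) {
  nz <- dim3[1]; nx <- dim3[2]; ny <- dim3[3]
  dx <- (seq_len(nx) - x0) * pitch_um[["x"]]
  dy <- (seq_len(ny) - y0) * pitch_um[["y"]]
  disc <- outer(dx^2, dy^2, "+") <= r_um^2
  m <- array(FALSE, dim3)
  zr <- max(1L, floor(z1)):min(nz, ceiling(z2))
  m[zr, , ] <- aperm(array(disc, c(nx, ny, length(zr))), c(3L, 1L, 2L))
  m
}

# rasterize an x-aligned tube (constant depth z0, lateral position y0)
rasterize_horizontal_tube <- function(dim3, pitch_um, z0, y0, x1, x2, r_um) {
  nz <- dim3[1]; nx <- dim3[2]; ny <- dim3[3]
  dz <- (seq_len(nz) - z0) * pitch_um[["z"]]
  dy <- (seq_len(ny) - y0) * pitch_um[["y"]]
  disc <- outer(dz^2, dy^2, "+") <= r_um^2  # (nz, ny)
  m <- array(FALSE, dim3)
  xr <- max(1L, round(x1)):min(nx, round(x2))
  for (x in xr) m[, x, ] <- m[, x, ] | disc
  m
}

#' Build a cranial phantom scene
#'
#' Deterministically realizes a [scene_config()]: boundary surfaces (constant
#' offsets plus band-limited random undulation), suture and pigment masks, and
#' planted vasculature. Transcranial vessels are routed through suture columns
#' only (control channels, if requested, are planted away from any suture).
#'
#' @param config a [scene_config()]
#' @param seed integer seed; the same (config, seed) pair always yields an
#'   identical scene
#' @return a list of class "PhantomScene"
#' @export
build_scene <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mfoct_scene_config"))
  nz <- config$grid[["nz"]]; nx <- config$grid[["nx"]]; ny <- config$grid[["ny"]]
  off <- config$offsets
  if (any(config$grid <= 0)) stop("invalid geometry: non-positive grid")
  if (is.unsorted(off) || off[1] < 4 || off[3] > nz - 6)
    stop("invalid geometry: layer offsets do not fit within nz")
  # each randomized scene component draws from its own substream, so e.g.
  # disabling pigment yields a matched scene with identical surfaces/vessels
  set.seed(stage_seed(seed, "phantom.surfaces"))
  pitch <- config$pitch_um

  # layers conform to the head curvature: one shared base undulation plus a
  # smaller independent component per surface (thickness varies mildly)
  u_base <- random_undulation(nx, ny, config$undulation_amp,
                              config$undulation_waves)
  u_ind <- 0.3 * config$undulation_amp
  z_as <- off[1] + u_base + random_undulation(nx, ny, u_ind,
                                              config$undulation_waves)
  z_ss <- off[2] + u_base + random_undulation(nx, ny, u_ind,
                                              config$undulation_waves)
  z_sb <- off[3] + u_base + random_undulation(nx, ny, u_ind,
                                              config$undulation_waves)
  # enforce ordering and keep surfaces inside the grid
  z_as <- clamp(z_as, 3, nz - 8)
  z_ss <- pmax(z_ss, z_as + 2); z_sb <- pmax(z_sb, z_ss + 2)
  z_sb <- pmin(z_sb, nz - 4)

  # birefringence from cumulative-retardation targets: delta = (360/lambda0) * dn * 2 * d
  th_skin_um <- mean(z_ss - z_as) * pitch[["z"]]
  th_skull_um <- mean(z_sb - z_ss) * pitch[["z"]]
  tr <- config$target_retardation_deg
  dn <- config$dn %||% c(
    skin = unname(tr[["skin"]] * config$lambda0_um / (720 * th_skin_um)),
    skull = unname((tr[["skull"]] - tr[["skin"]]) * config$lambda0_um /
                     (720 * th_skull_um)))

  # suture map: central cross + paired lateral (longitudinal) sutures
  suture <- matrix(FALSE, nx, ny)
  if (config$sutures$width_vox >= 1) {          # width 0: suture-free skull
    hw <- floor(config$sutures$width_vox / 2)
    cx <- round(nx / 2); cy <- round(ny / 2)
    suture[abs(seq_len(nx) - cx) <= hw, ] <- TRUE
    suture[, abs(seq_len(ny) - cy) <= hw] <- TRUE
    for (fr in config$sutures$lateral_frac) {
      lx <- round(nx * fr)
      suture[abs(seq_len(nx) - lx) <= hw, ] <- TRUE
    }
  }

  b_as <- round_half_up(z_as); b_ss <- round_half_up(z_ss)
  b_sb <- round_half_up(z_sb)

  # pigment: spots inside the skin + sheet at the skull base (plate columns only)
  pig <- array(FALSE, c(nz, nx, ny))
  set.seed(stage_seed(seed, "phantom.pigment"))
  n_spots <- config$pigment$n_spots
  spot_centers <- NULL
  if (n_spots > 0) {
    rr <- config$pigment$spot_radius_um
    for (s in seq_len(n_spots)) {
      r_um <- runif(1, rr[1], rr[2])
      rx <- r_um / pitch[["x"]]; ry <- r_um / pitch[["y"]]
      # clamp so the spot fits in the grid (very small lateral grids)
      rx <- min(rx, (nx - 3) / 2); ry <- min(ry, (ny - 3) / 2)
      x0 <- runif(1, 2 + rx, nx - 1 - rx); y0 <- runif(1, 2 + ry, ny - 1 - ry)
      zc <- (z_as[round(x0), round(y0)] + z_ss[round(x0), round(y0)]) / 2
      az <- 0.45 * (z_ss[round(x0), round(y0)] - z_as[round(x0), round(y0)])
      dx2 <- ((seq_len(nx) - x0) / rx)^2; dy2 <- ((seq_len(ny) - y0) / ry)^2
      dz2 <- ((seq_len(nz) - zc) / max(az, 1))^2
      blob <- outer(dz2, outer(dx2, dy2, "+"), "+") <= 1
      pig <- pig | blob
      spot_centers <- rbind(spot_centers, c(x0, y0))
    }
    # confine spots to the skin band
    zi <- expand_z(matrix(1, nx, ny), nz) * seq_len(nz)
    in_skin <- zi >= expand_z(b_as, nz) & zi < expand_z(b_ss, nz)
    pig <- pig & in_skin
  }
  sheet <- config$pigment$sheet_voxels
  if (sheet > 0) {
    zi <- array(rep(seq_len(nz), nx * ny), c(nz, nx, ny))
    sheet_band <- zi >= expand_z(b_sb - sheet, nz) & zi < expand_z(b_sb, nz)
    plate <- expand_z(!suture, nz)
    pig <- pig | (sheet_band & plate)
  }

  # vessels
  set.seed(stage_seed(seed, "phantom.vessels"))
  vs <- config$vessels
  r_um <- vs$radius_um
  v_skin <- array(FALSE, c(nz, nx, ny)); v_brain <- v_skin; v_trans <- v_skin
  vessel_set <- list()
  add_vessel <- function(tag, geom) {
    vessel_set[[length(vessel_set) + 1L]] <<- c(list(id = length(vessel_set) + 1L,
                                                     tag = tag), geom)
  }
  for (i in seq_len(vs$n_skin %||% 0L)) {
    y0 <- runif(1, 3, ny - 2)
    z0 <- mean((z_as + z_ss) / 2)
    v_skin <- v_skin | rasterize_horizontal_tube(c(nz, nx, ny), pitch, z0, y0,
                                                 1, nx, r_um)
    add_vessel("skin", list(z0 = z0, y0 = y0, radius_um = r_um))
  }
  for (i in seq_len(vs$n_brain %||% 0L)) {
    y0 <- runif(1, 3, ny - 2)
    z0 <- runif(1, max(b_sb) + 4, nz - 5)
    v_brain <- v_brain | rasterize_horizontal_tube(c(nz, nx, ny), pitch, z0, y0,
                                                   1, nx, r_um)
    add_vessel("brain", list(z0 = z0, y0 = y0, radius_um = r_um))
  }

  # transcranial channels: anchors sampled on the suture map (or, for control
  # channels, at least 3 px away from any suture), mutually separated
  rx <- r_um / pitch[["x"]]
  margin <- ceiling(rx) + 2
  sample_anchors <- function(eligible, n, existing) {
    anchors <- existing
    idx <- which(eligible, arr.ind = TRUE)
    idx <- idx[idx[, 1] > margin & idx[, 1] < nx - margin &
               idx[, 2] > margin & idx[, 2] < ny - margin, , drop = FALSE]
    got <- NULL
    while (n > 0 && nrow(idx) > 0) {
      k <- sample.int(nrow(idx), 1)
      a <- idx[k, ]
      ok <- TRUE
      if (!is.null(anchors))
        ok <- all(sqrt((anchors[, 1] - a[1])^2 + (anchors[, 2] - a[2])^2) >= 10)
      if (ok) {
        anchors <- rbind(anchors, a)
        got <- rbind(got, a)
        n <- n - 1
      }
      idx <- idx[-k, , drop = FALSE]
    }
    list(got = got, all = anchors)
  }
  anchors <- NULL; channel_truth <- NULL
  if ((vs$n_trans %||% 0L) > 0) {
    res <- sample_anchors(suture, vs$n_trans, NULL)
    anchors <- res$all
    for (i in seq_len(nrow(res$got))) {
      a <- res$got[i, ]
      z1 <- z_ss[a[1], a[2]] - 4; z2 <- z_sb[a[1], a[2]] + 12
      v_trans <- v_trans | rasterize_vertical_tube(c(nz, nx, ny), pitch,
                                                   a[1], a[2], z1, z2, r_um)
      add_vessel("transcranial", list(x0 = a[1], y0 = a[2], z1 = z1, z2 = z2,
                                      radius_um = r_um))
      channel_truth <- rbind(channel_truth,
                             data.frame(x = a[1], y = a[2], inside_suture = TRUE))
    }
  }
  if ((vs$n_trans_outside %||% 0L) > 0) {
    far <- !dilate_square(suture, 3L)
    res <- sample_anchors(far, vs$n_trans_outside, anchors)
    for (i in seq_len(nrow(res$got))) {
      a <- res$got[i, ]
      z1 <- z_ss[a[1], a[2]] - 4; z2 <- z_sb[a[1], a[2]] + 12
      v_trans <- v_trans | rasterize_vertical_tube(c(nz, nx, ny), pitch,
                                                   a[1], a[2], z1, z2, r_um)
      add_vessel("transcranial", list(x0 = a[1], y0 = a[2], z1 = z1, z2 = z2,
                                      radius_um = r_um))
      channel_truth <- rbind(channel_truth,
                             data.frame(x = a[1], y = a[2], inside_suture = FALSE))
    }
  }
  # vessels never carry pigment
  pig <- pig & !(v_skin | v_brain | v_trans)

  scene <- list(
    grid = config$grid, pitch_um = pitch, lambda0_um = config$lambda0_um,
    boundaries = list(z_air_skin = z_as, z_skin_skull = z_ss,
                      z_skull_brain = z_sb),
    dn = dn, backscatter = config$backscatter,
    attenuation_per_um = config$attenuation_per_um,
    pigment_mask = pig, suture_mask = suture,
    vessel_masks = list(skin = v_skin, brain = v_brain, transcranial = v_trans),
    vessel_set = vessel_set,
    channel_truth = channel_truth %||%
      data.frame(x = integer(), y = integer(), inside_suture = logical()),
    config = config, seed = seed)
  class(scene) <- "PhantomScene"
  scene
}

#' @export
print.PhantomScene <- function(x, ...) {
  cat(sprintf("PhantomScene %d x %d x %d (z,x,y), %d vessel(s), %d channel(s)\n",
              x$grid[["nz"]], x$grid[["nx"]], x$grid[["ny"]],
              length(x$vessel_set), nrow(x$channel_truth)))
  invisible(x)
}

#' Plant ROI-confined brain vessels at a target en-face coverage
#'
#' Used to emulate revascularization time courses after a penetrating brain
#' injury: random small-disc footprints are accumulated inside the ROI until
#' their union covers (at least) `fraction` of it, then extruded over a fixed
#' axial band in the brain so every footprint pixel has an identical axial
#' vessel extent. The exactly-planted coverage is recorded in `scene$tbi`.
#'
#' @param scene a PhantomScene
#' @param roi list/vector with x0, x1, y0, y1 (inclusive en-face bounds)
#' @param fraction target footprint coverage of the ROI in [0, 1]
#' @param seed integer seed
#' @param disc_radius_px footprint disc radius (pixels)
#' @param axial_extent axial extrusion length in voxels (inside the brain)
#' @return the scene with vessels added and `tbi = list(roi, fraction_planted,
#'   footprint)` attached
#' @export
plant_roi_vessels <- function(scene, roi, fraction, seed = 1L,
                              disc_radius_px = 2L, axial_extent = 10L) {
  stopifnot(inherits(scene, "PhantomScene"), fraction >= 0, fraction <= 1)
  roi <- as.list(roi)
  nz <- scene$grid[["nz"]]; nx <- scene$grid[["nx"]]; ny <- scene$grid[["ny"]]
  stopifnot(roi$x0 >= 1, roi$y0 >= 1, roi$x1 <= nx, roi$y1 <= ny)
  set.seed(stage_seed(seed, "tbi"))
  foot <- matrix(FALSE, nx, ny)
  area <- (roi$x1 - roi$x0 + 1) * (roi$y1 - roi$y0 + 1)
  r <- disc_radius_px
  guard <- 0
  while (sum(foot) / area < fraction && guard < 10000) {
    x0 <- round(runif(1, roi$x0, roi$x1)); y0 <- round(runif(1, roi$y0, roi$y1))
    xs <- max(roi$x0, x0 - r):min(roi$x1, x0 + r)
    ys <- max(roi$y0, y0 - r):min(roi$y1, y0 + r)
    disc <- outer((xs - x0)^2, (ys - y0)^2, "+") <= r^2
    foot[xs, ys] <- foot[xs, ys] | disc
    guard <- guard + 1
  }
  z1 <- min(round_half_up(scene$boundaries$z_skull_brain)) + 4L
  z2 <- min(nz, z1 + axial_extent - 1L)
  add <- array(FALSE, c(nz, nx, ny))
  add[z1:z2, , ] <- aperm(array(foot, c(nx, ny, z2 - z1 + 1L)), c(3L, 1L, 2L))
  scene$vessel_masks$brain <- scene$vessel_masks$brain | add
  scene$pigment_mask <- scene$pigment_mask & !add
  scene$tbi <- list(roi = roi, fraction_planted = sum(foot) / area,
                    footprint = foot, z_band = c(z1, z2))
  scene
}
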