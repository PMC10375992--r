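#' Dual-channel complex tomogram series
#'
#' Container for a polarization-resolved OCT acquisition: complex amplitudes
#' of the horizontal (H) and vertical (V) detection channels on a regular
#' (z, x, y) grid with N repeated B-scans per slow-axis (y) position.
#'
#' @param H,V complex arrays of dim (nz, nx, ny, N)
#' @param pitch_um voxel pitch c(z, x, y) in micrometres
#' @param lambda0_um centre wavelength (um)
#' @param line_rate_hz spectrometer line rate
#' @return object of class "PolTomogramSeries"
#' @export
new_pol_tomogram <- function(H, V, pitch_um = c(z = 3.4, x = 8, y = 8),
                             lambda0_um = 0.84, line_rate_hz = 25000) {
  stopifnot(length(dim(H)) == 4, identical(dim(H), dim(V)))
  if (any(!is.finite(H)) || any(!is.finite(V)))
    stop("tomogram contains non-finite values")
  structure(list(H = H, V = V, n_repeats = dim(H)[4],
                 acquisition = list(pitch_um = pitch_um,
                                    lambda0_um = lambda0_um,
                                    line_rate_hz = line_rate_hz)),
            class = "PolTomogramSeries")
}

#' @export
print.PolTomogramSeries <- function(x, ...) {
  d <- dim(x$H)
  cat(sprintf("PolTomogramSeries %d x %d x %d (z,x,y), %d repeat(s), 2 channels\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Render a polarization-resolved tomogram series from a phantom scene
#'
#' Forward model, per voxel:
#' \itemize{
#'   \item fully developed speckle: one complex circular-Gaussian draw with
#'     mean power = backscatter x exp(-2 x attenuation x path);
#'   \item cumulative single-pass retardation delta(z) = (360/lambda0) x dn x 2 x d(z)
#'     through birefringent voxels splits the field over (H, V) as
#'     (|H|, |V|) = |g| (cos delta, sin delta) so that atan(|V|/|H|) recovers delta;
#'   \item skull voxels (outside sutures) scramble the relative H/V phase
#'     uniformly per voxel -- a depolarization mechanism that drives kernel-
#'     averaged DOPU down to |cos 2 delta| while leaving the amplitude-ratio
#'     retardation estimate unbiased;
#'   \item pigment voxels draw an independent polarization state uniform on the
#'     Poincare sphere per voxel (strong depolarization: low DOPU);
#'   \item static voxels reuse one speckle realization across all N repeats;
#'     vessel voxels redraw speckle independently per repeat (full flow
#'     decorrelation); additive complex detector noise per channel/repeat sets
#'     the stated SNR relative to the skin surface backscatter.
#' }
#'
#' @param scene a [build_scene()] result
#' @param snr_db signal-to-noise ratio in dB relative to the skin backscatter
#'   power; `Inf` renders noise-free
#' @param n_repeats number of repeats N (default from the scene config)
#' @param seed integer seed
#' @return list with elements `tomo` ([new_pol_tomogram()]) and `truth`
#'   (class "PhantomGroundTruth": true boundary maps, pigment/suture/vessel
#'   masks, per-voxel layer labels, channel table, seed)
#' @export
render_series <- function(scene, snr_db = 25, n_repeats = NULL, seed = 1L) {
  stopifnot(inherits(scene, "PhantomScene"))
  if (is.na(snr_db) || is.nan(snr_db) || snr_db == -Inf)
    stop("invalid SNR: noise scale must be positive (use Inf for noise-free)")
  N <- as.integer(n_repeats %||% scene$config$n_repeats)
  stopifnot(N >= 1)
  nz <- scene$grid[["nz"]]; nx <- scene$grid[["nx"]]; ny <- scene$grid[["ny"]]
  nvox <- nz * nx * ny
  pitch_z <- scene$pitch_um[["z"]]
  set.seed(stage_seed(seed, "render"))

  b_as <- expand_z(round_half_up(scene$boundaries$z_air_skin), nz)
  b_ss <- expand_z(round_half_up(scene$boundaries$z_skin_skull), nz)
  b_sb <- expand_z(round_half_up(scene$boundaries$z_skull_brain), nz)
  zi <- array(rep(seq_len(nz), nx * ny), c(nz, nx, ny))
  lab <- (zi >= b_as) + (zi >= b_ss) + (zi >= b_sb)  # 0 air,1 skin,2 skull,3 brain
  suture_col <- expand_z(scene$suture_mask, nz)
  pig <- scene$pigment_mask
  flow <- scene$vessel_masks$skin | scene$vessel_masks$brain |
    scene$vessel_masks$transcranial

  bs <- scene$backscatter
  P <- c(0, bs[["skin"]], bs[["skull"]], bs[["brain"]])[lab + 1L]
  P[lab == 2L & suture_col] <- bs[["suture"]]
  P[flow & lab > 0L] <- bs[["vessel"]]
  P[pig] <- bs[["pigment"]]
  dim(P) <- c(nz, nx, ny)

  att <- scene$attenuation_per_um
  alpha <- c(0, att[["skin"]], att[["skull"]], att[["brain"]])[lab + 1L]
  dim(alpha) <- c(nz, nx, ny)
  cum_a <- apply(alpha, c(2, 3), cumsum)           # (nz, nx, ny)
  P <- P * exp(-2 * (cum_a - alpha / 2) * pitch_z)

  # cumulative retardation (deg), midpoint of each voxel
  kdeg <- 360 / scene$lambda0_um * 2 * pitch_z
  rate <- c(0, kdeg * scene$dn[["skin"]], kdeg * scene$dn[["skull"]], 0)[lab + 1L]
  rate[lab == 2L & suture_col] <- 0                 # sutures: dn = 0
  dim(rate) <- c(nz, nx, ny)
  delta <- apply(rate, c(2, 3), cumsum) - rate / 2

  q <- cos(2 * delta * pi / 180)
  psi <- array(pi / 2, c(nz, nx, ny))
  scramble <- lab == 2L & !suture_col & !pig        # depolarizing skull plate
  psi[scramble] <- runif(sum(scramble), 0, 2 * pi)
  npig <- sum(pig)
  if (npig > 0) {
    q[pig] <- runif(npig, -1, 1)
    psi[pig] <- runif(npig, 0, 2 * pi)
  }
  aH <- sqrt((1 + q) / 2)
  aVc <- sqrt((1 - q) / 2) * exp(1i * psi)
  rm(q, psi, rate, alpha, cum_a, zi, b_as, b_ss, b_sb, suture_col)

  amp <- sqrt(P / 2)
  g_static <- amp * (rnorm(nvox) + 1i * rnorm(nvox))
  dim(g_static) <- c(nz, nx, ny)
  noise_sd <- if (is.infinite(snr_db)) 0 else
    sqrt(bs[["skin"]] * 10^(-snr_db / 10) / 2)

  H <- array(0i, c(nz, nx, ny, N)); V <- H
  nf <- sum(flow)
  for (n in seq_len(N)) {
    g <- g_static
    if (nf > 0) g[flow] <- amp[flow] * (rnorm(nf) + 1i * rnorm(nf))
    h <- g * aH; v <- g * aVc
    if (noise_sd > 0) {
      h <- h + noise_sd * (rnorm(nvox) + 1i * rnorm(nvox))
      v <- v + noise_sd * (rnorm(nvox) + 1i * rnorm(nvox))
    }
    H[, , , n] <- h; V[, , , n] <- v
  }

  tomo <- new_pol_tomogram(H, V, pitch_um = scene$pitch_um,
                           lambda0_um = scene$lambda0_um,
                           line_rate_hz = scene$config$line_rate_hz)
  truth <- structure(list(
    boundaries = scene$boundaries, layer_labels = lab,
    pigment_mask = pig, suture_mask = scene$suture_mask,
    vessel_masks = scene$vessel_masks, flow_mask = flow,
    channel_truth = scene$channel_truth, rng_seed = seed),
    class = "PhantomGroundTruth")
  list(tomo = tomo, truth = truth)
}

#' Closed-form cumulative retardation of the phantom forward model
#'
#' Independent oracle for retardation tests: delta(z) = (360/lambda0) * dn * 2 * d,
#' where d is the physical path (um) inside the birefringent layer down to the
#' axial position z (voxel centres, midpoint rule, matching the renderer).
#'
#' @param scene a PhantomScene
#' @param z axial voxel index (may be fractional)
#' @param x,y lateral voxel indices
#' @return retardation in degrees at (z, x, y)
#' @export
expected_retardation <- function(scene, z, x, y) {
  zas <- scene$boundaries$z_air_skin[x, y]
  zss <- scene$boundaries$z_skin_skull[x, y]
  b_as <- round_half_up(zas); b_ss <- round_half_up(zss)
  pitch_z <- scene$pitch_um[["z"]]
  kdeg <- 360 / scene$lambda0_um * 2 * pitch_z
  # voxels counted at their centres (renderer integrates rate/2 at the voxel)
  d_skin <- clamp(z - b_as + 0.5, 0, b_ss - b_as)
  d_skull <- max(0, z - b_ss + 0.5)
  kdeg * (scene$dn[["skin"]] * d_skin + scene$dn[["skull"]] * d_skull)
}
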