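# Shared fixtures: small phantom configurations and cached renders.
# Everything is generated in code at test time; the cache lives for one
# test_dir() run so expensive renders are shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# standard reduced-grid scene (full feature set); the spec-era default grid
# (256 x 192 x 96) is scaled down to keep the suite inside its CPU budget --
# thresholds are in voxel/fraction units and are unchanged.
std_config <- function(n_repeats = 2L, ...) {
  scene_config(grid = c(96, 96, 32), offsets = c(16, 30, 56),
               vessels = list(n_skin = 2L, n_brain = 3L, n_trans = 3L,
                              n_trans_outside = 0L, radius_um = 12),
               n_repeats = n_repeats, ...)
}

# a bare scene: no pigment, no vessels, flat or undulating
bare_config <- function(undulation_amp = 0, n_repeats = 1L, ...) {
  scene_config(grid = c(96, 48, 16), offsets = c(16, 30, 56),
               undulation_amp = undulation_amp,
               pigment = list(n_spots = 0L, spot_radius_um = c(25, 45),
                              sheet_voxels = 0L),
               vessels = list(n_skin = 0L, n_brain = 0L, n_trans = 0L,
                              n_trans_outside = 0L, radius_um = 12),
               n_repeats = n_repeats, ...)
}

std_phantom <- function() {
  cached("std_phantom", function() {
    sc <- build_scene(std_config(), seed = 7)
    rs <- render_series(sc, snr_db = 25, seed = 7)
    int <- compute_intensity(rs$tomo)
    dop <- compute_dopu(rs$tomo, intensity_weighted = TRUE)
    c(rs, list(scene = sc, intensity = int, dopu = dop,
               retardation = compute_retardation(rs$tomo),
               seg = segment_volume(int, dop)))
  })
}

std_phantom_n4 <- function() {
  cached("std_phantom_n4", function() {
    sc <- build_scene(std_config(n_repeats = 4L), seed = 7)
    rs <- render_series(sc, snr_db = 25, seed = 7)
    int <- compute_intensity(rs$tomo)
    c(rs, list(scene = sc, intensity = int,
               decorr = ssada_decorrelation(
                 split_spectrum(rs$tomo, M = 4, overlap = 0.5), int)))
  })
}

noisefree_phantom <- function() {
  cached("noisefree_phantom", function() {
    sc <- build_scene(std_config(n_repeats = 1L), seed = 2)
    rs <- render_series(sc, snr_db = Inf, seed = 2)
    int <- suppressWarnings(compute_intensity(rs$tomo))
    dop <- compute_dopu(rs$tomo, intensity_weighted = TRUE)
    c(rs, list(scene = sc, intensity = int, dopu = dop,
               retardation = compute_retardation(rs$tomo)))
  })
}

# build a PolTomogramSeries from an explicit per-voxel polarization state:
# H = g * sqrt((1+q)/2), V = g * sqrt((1-q)/2) * exp(i psi)
state_tomo <- function(q, u, v, amplitude = 1, n_repeats = 1L) {
  stopifnot(length(dim(q)) == 3)
  psi <- atan2(v, u)
  aH <- sqrt((1 + q) / 2)
  aV <- sqrt((1 - q) / 2) * exp(1i * psi)
  d <- dim(q)
  H <- array(rep(amplitude * aH, n_repeats), c(d, n_repeats))
  V <- array(rep(amplitude * aV, n_repeats), c(d, n_repeats))
  new_pol_tomogram(H, V)
}

# expand an (nx, ny) en-face map along z into an (nz, nx, ny) array
expand_cols <- function(m, nz) {
  array(rep(as.vector(m), each = nz), c(nz, nrow(m), ncol(m)))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
rmse <- function(a, b) sqrt(mean((a - b)^2, na.rm = TRUE))

seg_accuracy <- function(seg, truth) {
  est <- array(0L, dim(truth$layer_labels))
  est[seg$layers$skin] <- 1L
  est[seg$layers$skull] <- 2L
  est[seg$layers$brain] <- 3L
  mean(est == truth$layer_labels)
}

match_channels <- function(calls, truth, tol_px = 3) {
  if (nrow(truth) == 0) return(list(recall = NA_real_, precision = NA_real_))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    if (nrow(calls$components) > 0) {
      dmin <- min(sqrt((calls$components$cx - truth$x[i])^2 +
                       (calls$components$cy - truth$y[i])^2))
      if (dmin <= tol_px) tp <- tp + 1
    }
  }
  list(recall = tp / nrow(truth),
       precision = if (nrow(calls$components) > 0)
         tp / nrow(calls$components) else 0)
}
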