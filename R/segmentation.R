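#' Segmentation parameters
#'
#' Thresholds and smoothing settings for the DOPU-intensity organ
#' segmentation. The method sets three thresholds (an intensity threshold for
#' the Air-Skin boundary, a lower intensity threshold supporting the
#' Skull-Brain boundary, and a DOPU threshold selecting depolarizing
#' skull/pigment tissue); published values do not exist, so defaults are
#' auto-derived per volume: intensity thresholds sit 8 dB (Air-Skin) and 4 dB
#' (Skull-Brain) above the air noise floor, the DOPU threshold is 0.75.
#'
#' @param thr_int_air_skin dB threshold for the intensity mask (NULL = noise
#'   floor + 8)
#' @param thr_int_skull_brain lower dB cutoff applied inside the
#'   DOPU-intensity mask (NULL = noise floor + 4)
#' @param thr_dopu DOPU threshold in (0, 1); voxels at or below it count as
#'   depolarizing
#' @param opening_width lateral length (voxels) of the line structuring
#'   element used to remove pigment-spot blobs (default 15 ~ 120 um)
#' @param spline_smoothing smoothing parameter (spar of
#'   [stats::smooth.spline()]); 0 disables smoothing
#' @param min_component_area connected components smaller than this (voxels,
#'   per B-scan) are discarded before edge picking
#' @param min_column_count columns of the cleaned mask with fewer true voxels
#'   than this are flagged invalid (suppresses residual speckle/smear columns)
#' @param thickness_tol columns whose skull thickness (z_sb - z_ss) deviates
#'   from the volume median by more than this many voxels are invalidated
#'   (catches pigment blobs merged into the skull band); Inf disables
#' @return a list of class "SegmentationParams"
#' @export
segmentation_params <- function(thr_int_air_skin = NULL,
                                thr_int_skull_brain = NULL,
                                thr_dopu = 0.75,
                                opening_width = 15L,
                                spline_smoothing = 0.6,
                                min_component_area = 20L,
                                min_column_count = 5L,
                                thickness_tol = 8) {
  stopifnot(thr_dopu > 0, thr_dopu < 1, opening_width >= 1,
            spline_smoothing >= 0, min_column_count >= 0, thickness_tol > 0)
  structure(list(thr_int_air_skin = thr_int_air_skin,
                 thr_int_skull_brain = thr_int_skull_brain,
                 thr_dopu = thr_dopu,
                 opening_width = as.integer(opening_width),
                 spline_smoothing = spline_smoothing,
                 min_component_area = as.integer(min_component_area),
                 min_column_count = as.integer(min_column_count),
                 thickness_tol = thickness_tol),
            class = "SegmentationParams")
}

# noise floor (dB) from the top air rows of an intensity_dB volume
noise_floor_db <- function(intensity, ref_rows = NULL) {
  ref_rows <- ref_rows %||% seq_len(min(6L, dim(intensity$values)[1]))
  median(intensity$values[ref_rows, , ])
}

#' Threshold masks from intensity and DOPU volumes
#'
#' The intensity mask selects tissue (intensity >= threshold); the DOPU mask
#' selects depolarizing scattering tissue (DOPU <= threshold) gated by the
#' lower intensity cutoff so that fully-noise air voxels (which also
#' depolarize) are excluded.
#'
#' @param intensity DerivedVolume, kind "intensity_dB"
#' @param dopu DerivedVolume, kind "dopu"
#' @param p a [segmentation_params()]
#' @return list with logical arrays `intensity_mask` and `dopu_mask` plus the
#'   resolved thresholds
#' @export
make_masks <- function(intensity, dopu, p = segmentation_params()) {
  stopifnot(inherits(intensity, "DerivedVolume"), intensity$kind == "intensity_dB",
            inherits(dopu, "DerivedVolume"), dopu$kind == "dopu")
  if (!identical(dim(intensity$values), dim(dopu$values)))
    stop("intensity and DOPU volumes are not co-registered (grid mismatch)")
  floor_db <- noise_floor_db(intensity)
  thr_hi <- p$thr_int_air_skin %||% (floor_db + 8)
  thr_lo <- p$thr_int_skull_brain %||% (floor_db + 4)
  intensity_mask <- intensity$values >= thr_hi
  dopu_mask <- dopu$values <= p$thr_dopu & intensity$values >= thr_lo
  list(intensity_mask = intensity_mask, dopu_mask = dopu_mask,
       thr_int_air_skin = thr_hi, thr_int_skull_brain = thr_lo,
       thr_dopu = p$thr_dopu)
}

#' Combine intensity and DOPU masks
#'
#' Elementwise product (logical AND) of two boolean masks on the same grid.
#'
#' @param intensity_mask,dopu_mask logical arrays of identical dimension
#' @return logical array
#' @export
combine_masks <- function(intensity_mask, dopu_mask) {
  if (!identical(dim(intensity_mask), dim(dopu_mask)))
    stop("masks are on different grids")
  intensity_mask & dopu_mask
}

#' Morphological opening of the DOPU-intensity mask
#'
#' Opening with a lateral 1 x `opening_width` line element, applied per
#' B-scan: laterally narrow pigment-spot blobs are removed while the
#' full-width skull plate band is preserved. This is the step that protects
#' the Skin-Skull boundary from skin pigmentation.
#'
#' @param mask logical array (nz, nx, ny) or matrix (nz, nx)
#' @param p a [segmentation_params()]
#' @return cleaned mask, same shape
#' @export
open_mask <- function(mask, p = segmentation_params()) {
  w <- p$opening_width
  if (is.matrix(mask)) return(open_line_rows(mask, w))
  out <- mask
  for (y in seq_len(dim(mask)[3])) out[, , y] <- open_line_rows(mask[, , y], w)
  out
}

#' Extract raw layer boundaries from the masks
#'
#' Per A-scan column: the Air-Skin boundary is the first true row of the
#' intensity mask; the Skin-Skull boundary is the first true row of the
#' cleaned DOPU-intensity mask; the Skull-Brain boundary is one past its last
#' true row (all bands are half-open \code{[upper, lower)}). Columns without
#' any true row are flagged invalid. Connected components smaller than
#' `min_component_area` are discarded per B-scan before edge picking.
#'
#' @param intensity_mask logical array (nz, nx, ny)
#' @param cleaned_mask opened DOPU-intensity mask, same grid
#' @param p a [segmentation_params()]
#' @return a "BoundarySet": matrices (nx, ny) `z_air_skin`, `z_skin_skull`,
#'   `z_skull_brain` (NA where invalid) and logical `validity` (nx, ny, 3)
#' @export
extract_boundaries <- function(intensity_mask, cleaned_mask,
                               p = segmentation_params()) {
  if (!identical(dim(intensity_mask), dim(cleaned_mask)))
    stop("masks are on different grids")
  d <- dim(intensity_mask)
  nz <- d[1]; nx <- d[2]; ny <- d[3]
  first_true <- function(m) {
    # m: (nz, nx) -> first true row per column, NA if none
    hit <- max.col(t(m * seq(nz, 1)), ties.method = "first")
    hit[colSums(m) == 0] <- NA_integer_
    hit
  }
  last_true <- function(m) {
    hit <- max.col(t(m * seq_len(nz)), ties.method = "last")
    hit[colSums(m) == 0] <- NA_integer_
    hit
  }
  z_as <- z_ss <- z_sb <- matrix(NA_real_, nx, ny)
  for (y in seq_len(ny)) {
    im <- intensity_mask[, , y]
    cm <- cleaned_mask[, , y]
    if (p$min_component_area > 1 && any(cm))
      cm <- filter_small_components(cm, p$min_component_area)
    z_as[, y] <- first_true(im)
    ss <- first_true(cm)
    sb <- last_true(cm) + 1  # half-open: first row below the skull
    few <- colSums(cm) < (p$min_column_count %||% 0L)
    ss[few] <- NA; sb[few] <- NA
    z_ss[, y] <- ss
    z_sb[, y] <- sb
  }
  # skull-thickness consistency: pigment blobs merged into the skull band make
  # the apparent skull abruptly thicker or thinner; such columns are invalid
  tol <- p$thickness_tol %||% Inf
  if (is.finite(tol)) {
    th <- z_sb - z_ss
    med_th <- median(th, na.rm = TRUE)
    if (is.finite(med_th)) {
      bad <- !is.na(th) & abs(th - med_th) > tol
      z_ss[bad] <- NA; z_sb[bad] <- NA
    }
  }
  validity <- array(FALSE, c(nx, ny, 3))
  validity[, , 1] <- !is.na(z_as)
  validity[, , 2] <- !is.na(z_ss)
  validity[, , 3] <- !is.na(z_sb)
  if (!any(validity)) warning("empty masks: all boundary columns invalid")
  structure(list(z_air_skin = z_as, z_skin_skull = z_ss, z_skull_brain = z_sb,
                 validity = validity),
            class = "BoundarySet")
}

#' Smooth boundary surfaces with per-B-scan splines
#'
#' Each boundary is fitted per B-scan with a cubic smoothing spline over the
#' valid columns (one robust re-fit drops columns whose residual exceeds
#' 3 x MAD, which suppresses single-column speckle spikes), then evaluated at
#' every column so invalid columns are interpolated. A width-3 cross-B-scan
#' running median stabilizes the surfaces along the slow axis, and the
#' ordering invariant z_as <= z_ss <= z_sb is re-imposed by clipping (clipped
#' columns are flagged invalid). B-scans with fewer than 4 valid columns are
#' left invalid.
#'
#' @param raw a BoundarySet from [extract_boundaries()]
#' @param p a [segmentation_params()]
#' @return a smoothed BoundarySet with `z_midline` = (z_ss + z_sb) / 2
#' @export
smooth_boundaries <- function(raw, p = segmentation_params()) {
  stopifnot(inherits(raw, "BoundarySet"))
  nx <- nrow(raw$z_air_skin); ny <- ncol(raw$z_air_skin)
  fit_one <- function(z) {
    out <- matrix(NA_real_, nx, ny)
    for (y in seq_len(ny)) {
      zy <- z[, y]
      ok <- which(!is.na(zy))
      if (length(ok) < 4) next
      out[, y] <- fit_spline_robust(ok, zy[ok], nx, p$spline_smoothing)
    }
    out
  }
  # B-scans with NO data at all (e.g. the whole scan lies in a suture, so no
  # depolarizing skull exists) are filled by interpolation along the slow
  # axis; B-scans with only 1-3 valid columns hold ambiguous data and are
  # left invalid instead.
  fill_y <- function(m, raw_z) {
    bad <- which(colSums(!is.na(raw_z)) == 0)
    good <- which(colSums(is.finite(m)) > 0)
    if (length(bad) == 0 || length(good) < 2) return(m)
    for (x in seq_len(nx))
      m[x, bad] <- approx(good, m[x, good], xout = bad, rule = 2)$y
    m
  }
  z_as <- fill_y(fit_one(raw$z_air_skin), raw$z_air_skin)
  z_ss <- fill_y(fit_one(raw$z_skin_skull), raw$z_skin_skull)
  z_sb <- fill_y(fit_one(raw$z_skull_brain), raw$z_skull_brain)
  # cross-B-scan median filter (width 3) for en-face stability
  med3 <- function(m) {
    if (ny < 3) return(m)
    t(apply(m, 1, function(r) if (all(is.finite(r))) runmed(r, 3) else r))
  }
  z_as <- med3(z_as); z_ss <- med3(z_ss); z_sb <- med3(z_sb)
  validity <- array(FALSE, c(nx, ny, 3))
  validity[, , 1] <- is.finite(z_as)
  validity[, , 2] <- is.finite(z_ss)
  validity[, , 3] <- is.finite(z_sb)
  # ordering invariant, re-imposed by clipping to the neighbouring boundary
  both12 <- validity[, , 1] & validity[, , 2]
  clip12 <- both12 & (z_ss < z_as)
  z_ss[clip12] <- z_as[clip12]
  both23 <- validity[, , 2] & validity[, , 3]
  clip23 <- both23 & (z_sb < z_ss)
  z_sb[clip23] <- z_ss[clip23]
  mid <- (z_ss + z_sb) / 2
  structure(list(z_air_skin = z_as, z_skin_skull = z_ss, z_skull_brain = z_sb,
                 z_midline = mid, validity = validity,
                 clipped = clip12 | clip23),
            class = "BoundarySet")
}

# cubic smoothing spline with one robust reiteration; spar = 0 interpolates
fit_spline_robust <- function(x, z, nx, spar) {
  fit_once <- function(x, z) {
    if (length(unique(z)) == 1) return(function(at) rep(z[1], length(at)))
    sp <- if (spar > 0)
      smooth.spline(x, z, spar = spar, cv = FALSE, keep.data = FALSE)
    else smooth.spline(x, z, lambda = 1e-10, keep.data = FALSE)
    function(at) predict(sp, at)$y
  }
  f <- fit_once(x, z)
  res <- z - f(x)
  s <- mad(res)
  if (is.finite(s) && s > 0) {
    keep <- abs(res) <= 3 * s
    if (sum(keep) >= 4 && any(!keep)) f <- fit_once(x[keep], z[keep])
  } else if (s == 0) {
    # majority of columns sit exactly on the fit; drop gross outliers
    keep <- abs(res) <= 1
    if (sum(keep) >= 4 && any(!keep)) f <- fit_once(x[keep], z[keep])
  }
  f(seq_len(nx))
}

#' Voxel masks of the three layers
#'
#' Half-open depth bands per column: skin = \code{[z_as, z_ss)}, skull =
#' \code{[z_ss, z_sb)}, brain = \code{[z_sb, nz]}. Fractional boundaries are
#' rounded half-up. Columns with any invalid boundary are excluded from all
#' three masks.
#'
#' @param b a BoundarySet
#' @param nz number of axial voxels
#' @return list of logical arrays (nz, nx, ny): `skin`, `skull`, `brain`
#' @export
layer_masks <- function(b, nz) {
  stopifnot(inherits(b, "BoundarySet"))
  nx <- nrow(b$z_air_skin); ny <- ncol(b$z_air_skin)
  ok <- b$validity[, , 1] & b$validity[, , 2] & b$validity[, , 3]
  as_i <- expand_z(round_half_up(b$z_air_skin), nz)
  ss_i <- expand_z(round_half_up(b$z_skin_skull), nz)
  sb_i <- expand_z(round_half_up(b$z_skull_brain), nz)
  okz <- expand_z(ok, nz); okz[is.na(okz)] <- FALSE
  zi <- array(rep(seq_len(nz), nx * ny), c(nz, nx, ny))
  list(skin = okz & zi >= as_i & zi < ss_i,
       skull = okz & zi >= ss_i & zi < sb_i,
       brain = okz & zi >= sb_i)
}

#' Run the full organ segmentation on derived volumes
#'
#' Convenience wrapper: threshold masks, DOPU-intensity combination,
#' morphological opening, boundary extraction, spline smoothing, layer masks.
#'
#' @param intensity DerivedVolume "intensity_dB"
#' @param dopu DerivedVolume "dopu"
#' @param p a [segmentation_params()]
#' @return list: `masks` (from [make_masks()], plus `combined`, `cleaned`),
#'   `raw` and `boundaries` (BoundarySets), `layers` (layer masks)
#' @export
segment_volume <- function(intensity, dopu, p = segmentation_params()) {
  m <- make_masks(intensity, dopu, p)
  combined <- combine_masks(m$intensity_mask, m$dopu_mask)
  cleaned <- open_mask(combined, p)
  raw <- extract_boundaries(m$intensity_mask, cleaned, p)
  b <- smooth_boundaries(raw, p)
  layers <- layer_masks(b, dim(intensity$values)[1])
  list(masks = c(m, list(combined = combined, cleaned = cleaned)),
       raw = raw, boundaries = b, layers = layers)
}
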