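#' En-face image container
#'
#' @param pixels (nx, ny) matrix (scalar kinds) or (nx, ny, 3) array (RGB)
#' @param kind one of "mean_intensity", "mean_retardation", "retardation_gray",
#'   "octa_mean", "octa_depth_rgb", "merged_rgb", "fused_bscan"
#' @param layer_tag depth band the image was formed over
#' @param units units of scalar pixels ("dB", "deg", "" for unitless)
#' @return object of class "EnFaceImage"; no-data pixels are NaN
#' @export
new_enface <- function(pixels, kind, layer_tag = NA_character_, units = "") {
  structure(list(pixels = pixels, kind = kind, layer_tag = layer_tag,
                 units = units), class = "EnFaceImage")
}

#' @export
print.EnFaceImage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("EnFaceImage <%s> %d x %d%s, band=%s\n", x$kind, d[1], d[2],
              if (length(d) == 3) " RGB" else "", x$layer_tag))
  invisible(x)
}

# resolve a named depth band to per-column half-open [upper, lower) bounds
band_bounds <- function(b, band, nz) {
  stopifnot(inherits(b, "BoundarySet"))
  mid <- b$z_midline %||% ((b$z_skin_skull + b$z_skull_brain) / 2)
  bounds <- switch(band,
    skin = list(b$z_air_skin, b$z_skin_skull),
    skull = list(b$z_skin_skull, b$z_skull_brain),
    brain = list(b$z_skull_brain, b$z_skull_brain * 0 + nz + 1),
    extracranial = list(b$z_air_skin, mid),
    intracranial = list(mid, b$z_skull_brain * 0 + nz + 1),
    upper_skull = list(b$z_skin_skull, mid),
    lower_skull = list(mid, b$z_skull_brain),
    stop("unknown layer band: ", band))
  u <- round_half_up(bounds[[1]]); l <- round_half_up(bounds[[2]])
  u <- pmax(u, 1L); l <- pmin(l, nz + 1L)
  list(upper = u, lower = l)
}

#' Mean projection of a volume over a boundary-defined depth band
#'
#' Per (x, y) column: the mean of voxels in the half-open band
#' \code{[upper, lower)}. Columns where the band is empty or a boundary is
#' invalid yield NaN (no-data).
#'
#' @param volume a DerivedVolume
#' @param band one of "skin", "skull", "brain", "extracranial",
#'   "intracranial", "upper_skull", "lower_skull"
#' @param b a BoundarySet
#' @param stat only "mean" is provided
#' @return an [new_enface()] image, kind "mean_intensity", "mean_retardation"
#'   or "octa_mean" according to the volume kind
#' @export
layer_projection <- function(volume, band, b, stat = "mean") {
  stopifnot(inherits(volume, "DerivedVolume"), stat == "mean")
  v <- volume$values
  nz <- dim(v)[1]; nx <- dim(v)[2]; ny <- dim(v)[3]
  bb <- band_bounds(b, band, nz)
  out <- matrix(NaN, nx, ny)
  for (y in seq_len(ny)) {
    cs <- rbind(0, apply(v[, , y, drop = TRUE], 2, cumsum))
    u <- bb$upper[, y]; l <- bb$lower[, y]
    ok <- is.finite(u) & is.finite(l) & l > u
    if (!any(ok)) next
    ui <- u[ok]; li <- l[ok]
    idx <- which(ok)
    out[idx, y] <- (cs[cbind(li, idx)] - cs[cbind(ui, idx)]) / (li - ui)
  }
  if (!any(is.finite(out))) warning("band '", band, "' produced no valid pixels")
  kind <- switch(volume$kind, intensity_dB = , intensity_linear = "mean_intensity",
                 retardation_deg = "mean_retardation", dopu = "mean_dopu",
                 decorrelation = "octa_mean")
  units <- switch(volume$kind, intensity_dB = "dB", retardation_deg = "deg", "")
  new_enface(out, kind, band, units)
}

#' DOPU-intensity fused B-scans
#'
#' Fused rendering in which hue encodes DOPU and brightness encodes intensity:
#' hue ramps from green (low DOPU, depolarizing) to red (DOPU = 1), the value
#' channel is the percentile-windowed dB intensity, saturation is 1. Strongly
#' reflecting depolarizing pigment therefore renders bright green.
#'
#' @param intensity DerivedVolume "intensity_dB"
#' @param dopu DerivedVolume "dopu"
#' @param window brightness display window as dB percentiles (low, high)
#' @return 4-D numeric array (nz, nx, ny, 3) of RGB in [0, 1]
#' @export
fuse_dopu_intensity <- function(intensity, dopu, window = c(0.01, 0.99)) {
  stopifnot(inherits(intensity, "DerivedVolume"), inherits(dopu, "DerivedVolume"))
  if (!identical(dim(intensity$values), dim(dopu$values)))
    stop("volumes are not co-registered")
  db <- intensity$values
  w <- quantile(db, window, names = FALSE)
  val <- clamp((db - w[1]) / max(w[2] - w[1], .Machine$double.eps), 0, 1)
  hue_deg <- 120 * (1 - clamp(dopu$values, 0, 1))   # 0 = red, 120 = green
  d <- dim(db)
  rgb3 <- grDevices::hsv(h = as.vector(hue_deg) / 360, s = 1, v = as.vector(val))
  cr <- grDevices::col2rgb(rgb3) / 255
  out <- array(0, c(d, 3))
  out[, , , 1] <- cr[1, ]; out[, , , 2] <- cr[2, ]; out[, , , 3] <- cr[3, ]
  out
}

#' Retardation grayscale image
#'
#' Linear rescale of a mean-retardation projection from [0, 90] deg to [0, 1]
#' gray: bright = high retardation (pigment spots), dark = low retardation
#' (cranial sutures).
#'
#' @param proj an EnFaceImage of kind "mean_retardation"
#' @return an EnFaceImage of kind "retardation_gray"
#' @export
retardation_grayscale <- function(proj) {
  stopifnot(inherits(proj, "EnFaceImage"), proj$kind == "mean_retardation")
  new_enface(clamp(proj$pixels / 90, 0, 1), "retardation_gray",
             proj$layer_tag, "")
}

#' Split an angiogram into extra- and intracranial projections
#'
#' The cranial midline (mid-depth of the skull) divides the volume: the
#' extracranial band \code{[z_air_skin, z_midline)} above it and the
#' intracranial band \code{[z_midline, nz]} below it, each averaged to an
#' en-face OCTA projection.
#'
#' @param octa DerivedVolume "decorrelation"
#' @param b a BoundarySet with a valid midline
#' @return list(extra =, intra =) of EnFaceImages
#' @export
split_extra_intra <- function(octa, b) {
  stopifnot(inherits(octa, "DerivedVolume"), octa$kind == "decorrelation")
  list(extra = layer_projection(octa, "extracranial", b),
       intra = layer_projection(octa, "intracranial", b))
}

#' Merge extra- and intracranial angiograms into a red/green image
#'
#' R = extracranial projection normalized to its maximum, G = intracranial
#' likewise, B = 0; vessels present in both compartments render yellow.
#'
#' @param extra,intra EnFaceImages on the same grid
#' @return an EnFaceImage of kind "merged_rgb"
#' @export
merge_red_green <- function(extra, intra) {
  stopifnot(inherits(extra, "EnFaceImage"), inherits(intra, "EnFaceImage"))
  if (!identical(dim(extra$pixels), dim(intra$pixels)))
    stop("projections are on different grids")
  norm01 <- function(m) {
    mx <- max(m[is.finite(m)], 0)
    m <- if (mx > 0) m / mx else m * 0
    m[!is.finite(m)] <- 0
    clamp(m, 0, 1)
  }
  d <- dim(extra$pixels)
  out <- array(0, c(d, 3))
  out[, , 1] <- norm01(extra$pixels)
  out[, , 2] <- norm01(intra$pixels)
  new_enface(out, "merged_rgb", "extracranial+intracranial")
}

#' Depth-color encoded en-face angiogram
#'
#' Per column: hue encodes the decorrelation-weighted mean relative depth
#' within the band (blue = shallow, red = deep), brightness encodes the
#' maximum decorrelation in the band normalized over the image. Columns with
#' no flow are black.
#'
#' @param octa DerivedVolume "decorrelation"
#' @param band layer band name (see [layer_projection()])
#' @param b a BoundarySet
#' @return an EnFaceImage of kind "octa_depth_rgb"
#' @export
depth_encode <- function(octa, band, b) {
  stopifnot(inherits(octa, "DerivedVolume"), octa$kind == "decorrelation")
  v <- octa$values
  nz <- dim(v)[1]; nx <- dim(v)[2]; ny <- dim(v)[3]
  bb <- band_bounds(b, band, nz)
  t_rel <- matrix(NaN, nx, ny); bright <- matrix(0, nx, ny)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      u <- bb$upper[x, y]; l <- bb$lower[x, y]
      if (!is.finite(u) || !is.finite(l) || l <= u) next
      col <- v[u:(l - 1), x, y]
      s <- sum(col)
      if (s > 0) {
        zrel <- (seq_along(col) - 1) / max(length(col) - 1, 1)
        t_rel[x, y] <- sum(col * zrel) / s
        bright[x, y] <- max(col)
      }
    }
  }
  mx <- max(bright, 0)
  if (mx > 0) bright <- bright / mx
  hue_deg <- 240 * (1 - t_rel)                   # blue shallow -> red deep
  out <- array(0, c(nx, ny, 3))
  okv <- is.finite(hue_deg) & bright > 0
  if (any(okv)) {
    cr <- grDevices::col2rgb(grDevices::hsv(h = hue_deg[okv] / 360, s = 1,
                                            v = bright[okv])) / 255
    r <- out[, , 1]; g <- out[, , 2]; bl <- out[, , 3]
    r[okv] <- cr[1, ]; g[okv] <- cr[2, ]; bl[okv] <- cr[3, ]
    out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- bl
  }
  new_enface(out, "octa_depth_rgb", band)
}
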