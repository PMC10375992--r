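#' Upper- and lower-skull angiogram projections
#'
#' The skull is split at the cranial midline: the upper band runs from the
#' Skin-Skull boundary to the midline, the lower band from the midline to the
#' Skull-Brain boundary; each is averaged to an en-face OCTA projection.
#' Vessels present in both at the same (x, y) are candidate transcranial
#' channels. Columns whose skull is thinner than 2 voxels are no-data.
#'
#' @param octa DerivedVolume "decorrelation"
#' @param b a BoundarySet
#' @return list(upper =, lower =) of EnFaceImages
#' @export
skull_half_projections <- function(octa, b) {
  stopifnot(inherits(octa, "DerivedVolume"), octa$kind == "decorrelation")
  upper <- layer_projection(octa, "upper_skull", b)
  lower <- layer_projection(octa, "lower_skull", b)
  thin <- (b$z_skull_brain - b$z_skin_skull) < 2
  thin[!is.finite(thin)] <- TRUE
  upper$pixels[thin] <- NaN
  lower$pixels[thin] <- NaN
  list(upper = upper, lower = lower)
}

#' Detect transcranial channels from the skull-half projections
#'
#' Channel mask = (upper >= threshold) AND (lower >= threshold); connected
#' components smaller than `min_area` pixels are discarded; the remainder are
#' labelled with centroids.
#'
#' @param upper,lower EnFaceImages from [skull_half_projections()]
#' @param bin_threshold binarization threshold on the mean decorrelation;
#'   typically calibrated as the 99th percentile of a vessel-free
#'   (static-tissue) projection, see [calibrate_flow_threshold()]
#' @param min_area minimum component area in pixels
#' @return list of class "ChannelCallSet": `channel_mask` (nx, ny),
#'   `components` data.frame(label, cx, cy, area, inside_suture),
#'   `params` thresholds used
#' @export
detect_channels <- function(upper, lower, bin_threshold, min_area = 4L) {
  stopifnot(inherits(upper, "EnFaceImage"), inherits(lower, "EnFaceImage"))
  if (!identical(dim(upper$pixels), dim(lower$pixels)))
    stop("projections are on different grids")
  up <- upper$pixels; lo <- lower$pixels
  up[!is.finite(up)] <- -Inf; lo[!is.finite(lo)] <- -Inf
  mask <- up >= bin_threshold & lo >= bin_threshold
  lab <- label_components(mask, 8L)
  comp <- NULL
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < min_area) {
        mask[idx] <- FALSE
        next
      }
      comp <- rbind(comp, data.frame(label = k, cx = mean(idx[, 1]),
                                     cy = mean(idx[, 2]), area = nrow(idx),
                                     inside_suture = NA))
    }
  }
  comp <- comp %||% data.frame(label = integer(), cx = numeric(),
                               cy = numeric(), area = integer(),
                               inside_suture = logical())
  if (nrow(comp) > 0) comp$label <- seq_len(nrow(comp))
  structure(list(channel_mask = mask, components = comp,
                 params = list(bin_threshold = bin_threshold,
                               min_area = min_area)),
            class = "ChannelCallSet")
}

#' Calibrate the flow binarization threshold on static tissue
#'
#' Returns the given percentile (default 99th) of the finite pixels of one or
#' more vessel-free projections; used as `bin_threshold` for
#' [detect_channels()] and as `flow_threshold` for [tbi_metrics()]. With real
#' data one would supply a user-selected background region instead.
#'
#' @param ... EnFaceImages (or numeric matrices) of static-tissue angiogram
#'   projections
#' @param probs percentile in (0, 1)
#' @return numeric threshold
#' @export
calibrate_flow_threshold <- function(..., probs = 0.99) {
  px <- unlist(lapply(list(...), function(p) {
    v <- if (inherits(p, "EnFaceImage")) p$pixels else p
    v[is.finite(v)]
  }))
  quantile(px, probs, names = FALSE)
}

#' Suture map from skull projections
#'
#' Cranial sutures show high backscatter and minimal birefringence, so the
#' suture mask is (mean retardation <= ret_threshold) AND (mean intensity >=
#' int_threshold), cleaned by a width-3 opening and small-component removal.
#'
#' @param skull_retardation_proj EnFaceImage "mean_retardation" over the skull
#' @param skull_intensity_proj EnFaceImage "mean_intensity" over the skull
#' @param ret_threshold degrees; default 35
#' @param int_threshold dB; default the 25th percentile of the finite
#'   intensity pixels (a loose gate: it only needs to reject dim/no-data
#'   pixels -- a transcranial vessel darkens the suture right at its
#'   crossing, so a tight gate would erase the channels of interest)
#' @param min_area small-component removal threshold (px)
#' @return list of class "SutureMap": `suture_mask` (nx, ny) and `params`
#' @export
build_suture_map <- function(skull_retardation_proj, skull_intensity_proj,
                             ret_threshold = 35, int_threshold = NULL,
                             min_area = 8L) {
  rp <- skull_retardation_proj$pixels; ip <- skull_intensity_proj$pixels
  if (!identical(dim(rp), dim(ip)))
    stop("projections are on different grids")
  int_threshold <- int_threshold %||% quantile(ip[is.finite(ip)], 0.25,
                                               names = FALSE)
  mask <- is.finite(rp) & is.finite(ip) & rp <= ret_threshold &
    ip >= int_threshold
  # opening with a 3x3 square element (suture lines are thin but contiguous)
  er <- boxfilt2(mask * 1, 3L, 3L) >= 1 - 1e-9
  mask_open <- dilate_square(er, 1L)
  mask_open <- filter_small_components(mask_open, min_area)
  structure(list(suture_mask = mask_open,
                 params = list(ret_threshold = ret_threshold,
                               int_threshold = int_threshold,
                               min_area = min_area)),
            class = "SutureMap")
}

#' Co-localize channel calls with the suture map
#'
#' A component is inside a suture when its centroid falls on the suture mask
#' dilated by `dilation_px` (the mask is thin; the margin makes the centroid
#' test robust). The summary is the fraction of components inside; NA when
#' there are no components.
#'
#' @param calls a ChannelCallSet
#' @param sutures a SutureMap (or logical matrix)
#' @param dilation_px dilation margin in pixels
#' @return the ChannelCallSet with `inside_suture` filled and a
#'   `suture_fraction` element added
#' @export
colocalize <- function(calls, sutures, dilation_px = 2L) {
  stopifnot(inherits(calls, "ChannelCallSet"))
  sm <- if (inherits(sutures, "SutureMap")) sutures$suture_mask else sutures
  if (!identical(dim(calls$channel_mask), dim(sm)))
    stop("call set and suture map are on different grids")
  smd <- dilate_square(sm, as.integer(dilation_px))
  comp <- calls$components
  if (nrow(comp) > 0) {
    comp$inside_suture <- smd[cbind(round_half_up(comp$cx),
                                    round_half_up(comp$cy))]
    calls$suture_fraction <- mean(comp$inside_suture)
  } else {
    calls$suture_fraction <- NA_real_
  }
  calls$components <- comp
  calls$params$dilation_px <- dilation_px
  calls
}

#' Vessel metrics for TBI revascularization monitoring
#'
#' For each timepoint the en-face angiogram is binarized at `flow_threshold`
#' inside the ROI: `vessel_density` is the fraction of ROI pixels at or above
#' threshold; `avascular_area` is the area (px) of the largest connected
#' below-threshold component inside the ROI (the wound core).
#'
#' @param octa_series list of entries `list(timepoint = hours, image =
#'   EnFaceImage or matrix)`, sorted by timepoint
#' @param roi list or vector with x0, x1, y0, y1 (inclusive pixel bounds)
#' @param flow_threshold binarization threshold (see
#'   [calibrate_flow_threshold()])
#' @return data.frame: timepoint, vessel_density, avascular_area, roi_area
#' @export
tbi_metrics <- function(octa_series, roi, flow_threshold) {
  roi <- as.list(roi)
  tp <- vapply(octa_series, function(e) e$timepoint, numeric(1))
  if (is.unsorted(tp)) stop("series must be sorted by timepoint")
  out <- NULL
  for (e in octa_series) {
    px <- if (inherits(e$image, "EnFaceImage")) e$image$pixels else e$image
    if (roi$x0 < 1 || roi$y0 < 1 || roi$x1 > nrow(px) || roi$y1 > ncol(px) ||
        roi$x0 > roi$x1 || roi$y0 > roi$y1)
      stop("ROI outside grid")
    sub <- px[roi$x0:roi$x1, roi$y0:roi$y1, drop = FALSE]
    sub[!is.finite(sub)] <- 0
    bin <- sub >= flow_threshold
    density <- mean(bin)
    lab <- label_components(!bin, 8L)
    avas <- if (max(lab) > 0) max(tabulate(lab[lab > 0])) else 0L
    out <- rbind(out, data.frame(timepoint = e$timepoint,
                                 vessel_density = density,
                                 avascular_area = avas,
                                 roi_area = length(bin)))
  }
  out
}
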