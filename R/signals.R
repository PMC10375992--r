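#' Derived scalar volume
#'
#' A real-valued per-voxel map sharing the tomogram grid: linear or dB
#' intensity, accumulative retardation (deg), DOPU, or SSADA decorrelation.
#'
#' @param values numeric array (nz, nx, ny)
#' @param kind one of "intensity_dB", "intensity_linear", "retardation_deg",
#'   "dopu", "decorrelation"
#' @param pitch_um voxel pitch c(z, x, y)
#' @param validity optional logical array flagging voxels where the value is
#'   well defined
#' @return object of class "DerivedVolume"
#' @export
new_derived_volume <- function(values, kind, pitch_um = c(z = 3.4, x = 8, y = 8),
                               validity = NULL) {
  kind <- match.arg(kind, c("intensity_dB", "intensity_linear",
                            "retardation_deg", "dopu", "decorrelation"))
  stopifnot(length(dim(values)) == 3)
  structure(list(values = values, kind = kind, pitch_um = pitch_um,
                 validity = validity), class = "DerivedVolume")
}

#' @export
print.DerivedVolume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("DerivedVolume <%s> %d x %d x %d (z,x,y)\n", x$kind,
              d[1], d[2], d[3]))
  invisible(x)
}

#' OCT intensity from a dual-channel tomogram
#'
#' Per voxel I = |H|^2 + |V|^2. In dB the reference level is the median
#' noise-floor power estimated from the top air rows, so the air background
#' sits near 0 dB and tissue near its SNR.
#'
#' @param tomo a PolTomogramSeries
#' @param repeat_policy "mean" (average I over repeats) or "first"
#' @param scale "dB" or "linear"
#' @param ref_rows axial rows used for the noise-floor estimate (dB scale);
#'   defaults to the top 6 rows
#' @param floor_db value assigned to zero-power voxels on the dB scale
#' @return a [new_derived_volume()] of kind "intensity_dB" or "intensity_linear"
#' @export
compute_intensity <- function(tomo, repeat_policy = c("mean", "first"),
                              scale = c("dB", "linear"), ref_rows = NULL,
                              floor_db = -120) {
  stopifnot(inherits(tomo, "PolTomogramSeries"))
  repeat_policy <- match.arg(repeat_policy)
  scale <- match.arg(scale)
  I4 <- Mod(tomo$H)^2 + Mod(tomo$V)^2
  I <- if (repeat_policy == "first") I4[, , , 1, drop = TRUE] else
    rowMeans(I4, dims = 3)
  dim(I) <- dim(tomo$H)[1:3]
  if (scale == "linear")
    return(new_derived_volume(I, "intensity_linear",
                              tomo$acquisition$pitch_um))
  ref_rows <- ref_rows %||% seq_len(min(6L, dim(I)[1]))
  i_ref <- median(I[ref_rows, , ])
  if (!is.finite(i_ref) || i_ref <= 0) {
    if (max(I) <= 0) {
      warning("all-zero volume: dB undefined, returning floor value")
      return(new_derived_volume(array(floor_db, dim(I)), "intensity_dB",
                                tomo$acquisition$pitch_um))
    }
    warning("noise floor is zero (noise-free data); using max(I) * 1e-7 as dB reference")
    i_ref <- max(I) * 1e-7
  }
  db <- 10 * log10(I / i_ref)
  db[!is.finite(db)] <- floor_db
  db <- pmax(db, floor_db)
  new_derived_volume(db, "intensity_dB", tomo$acquisition$pitch_um)
}

#' Accumulative retardation from a dual-channel tomogram
#'
#' Circular-input PS-OCT estimator delta = atan(|V| / |H|) in degrees,
#' range [0, 90]; computed per repeat and averaged. Voxels with |H| = |V| = 0
#' in every repeat are set to 0 and flagged invalid.
#'
#' @param tomo a PolTomogramSeries
#' @return a [new_derived_volume()] of kind "retardation_deg" with a validity mask
#' @export
compute_retardation <- function(tomo) {
  stopifnot(inherits(tomo, "PolTomogramSeries"))
  aH <- Mod(tomo$H); aV <- Mod(tomo$V)
  delta <- atan2(aV, aH) * 180 / pi
  zero <- aH == 0 & aV == 0
  delta[zero] <- 0
  d <- rowMeans(delta, dims = 3)
  dim(d) <- dim(tomo$H)[1:3]
  valid <- rowSums(zero, dims = 3) < dim(tomo$H)[4]
  dim(valid) <- dim(tomo$H)[1:3]
  new_derived_volume(d, "retardation_deg", tomo$acquisition$pitch_um,
                     validity = valid)
}

#' Degree of polarization uniformity (DOPU)
#'
#' Stokes-averaging DOPU computed per B-scan: per voxel the Stokes vector
#' (I, Q, U, V) is formed from the repeat-averaged channel products, the
#' (Q, U, V) part is normalized by I, and DOPU is the Euclidean norm of the
#' (kz x kx) windowed mean of the normalized vectors, clipped to [0, 1].
#'
#' @param tomo a PolTomogramSeries
#' @param kernel odd c(kz, kx) window in voxels (default 5 x 5, about three
#'   speckle diameters)
#' @param intensity_weighted if TRUE, average I-weighted Stokes components and
#'   normalize by the windowed I instead of normalizing per voxel first
#' @return a [new_derived_volume()] of kind "dopu"
#' @export
compute_dopu <- function(tomo, kernel = c(5L, 5L), intensity_weighted = FALSE) {
  stopifnot(inherits(tomo, "PolTomogramSeries"))
  kz <- as.integer(kernel[1]); kx <- as.integer(kernel[2])
  if (kz %% 2 != 1 || kx %% 2 != 1 || kz < 1 || kx < 1)
    stop("DOPU kernel must be odd-sized and >= 1 in each axis")
  d <- dim(tomo$H)
  if (kz > d[1] || kx > d[2]) stop("DOPU kernel larger than B-scan")
  HV <- tomo$H * Conj(tomo$V)
  I <- rowMeans(Mod(tomo$H)^2 + Mod(tomo$V)^2, dims = 3)
  Q <- rowMeans(Mod(tomo$H)^2 - Mod(tomo$V)^2, dims = 3)
  U <- rowMeans(2 * Re(HV), dims = 3)
  Vs <- rowMeans(-2 * Im(HV), dims = 3)
  dim(I) <- dim(Q) <- dim(U) <- dim(Vs) <- d[1:3]
  out <- array(0, d[1:3])
  for (y in seq_len(d[3])) {
    if (intensity_weighted) {
      iw <- boxfilt2(matrix(I[, , y], d[1], d[2]), kz, kx)
      mq <- boxfilt2(matrix(Q[, , y], d[1], d[2]), kz, kx) / iw
      mu <- boxfilt2(matrix(U[, , y], d[1], d[2]), kz, kx) / iw
      mv <- boxfilt2(matrix(Vs[, , y], d[1], d[2]), kz, kx) / iw
      mq[iw <= 0] <- 0; mu[iw <= 0] <- 0; mv[iw <= 0] <- 0
    } else {
      Iy <- matrix(I[, , y], d[1], d[2])
      nz0 <- Iy > 0
      q <- ifelse(nz0, matrix(Q[, , y], d[1], d[2]) / Iy, 0)
      u <- ifelse(nz0, matrix(U[, , y], d[1], d[2]) / Iy, 0)
      v <- ifelse(nz0, matrix(Vs[, , y], d[1], d[2]) / Iy, 0)
      mq <- boxfilt2(q, kz, kx); mu <- boxfilt2(u, kz, kx)
      mv <- boxfilt2(v, kz, kx)
    }
    out[, , y] <- sqrt(mq^2 + mu^2 + mv^2)
  }
  out <- clamp(out, 0, 1)
  new_derived_volume(out, "dopu", tomo$acquisition$pitch_um)
}
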