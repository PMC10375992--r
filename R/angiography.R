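#' Split an A-scan series into spectral sub-band amplitude volumes
#'
#' Each A-scan's complex depth profile is inverse-transformed to a synthetic
#' spectrum, multiplied by M Gaussian windows with equally spaced centres, and
#' transformed back; the band amplitude is the modulus, with the two
#' polarization channels combined as sqrt(|H|^2 + |V|^2). With M = 1 a flat
#' full-width window is used, so the output equals the unsplit amplitudes.
#'
#' Window layout: centres at (m - 1/2) nz / M along the spectral axis, FWHM =
#' (nz / M) (1 + overlap). The phantom emits complex tomograms directly; this
#' synthetic-spectrum route stands in for spectrometer data.
#'
#' @param tomo a PolTomogramSeries with N >= 1 repeats
#' @param M number of spectral bands (>= 1); must not exceed nz / 4
#' @param overlap fractional overlap between adjacent Gaussian windows
#' @return a list of class "SplitSpectrumSet": `amplitudes` array of dim
#'   (nz, nx, ny, N, M), `band_centers`, `band_fwhm`, `M`, `n_repeats`
#' @export
split_spectrum <- function(tomo, M = 4L, overlap = 0.5) {
  stopifnot(inherits(tomo, "PolTomogramSeries"))
  M <- as.integer(M)
  d <- dim(tomo$H)
  nz <- d[1]
  if (M < 1) stop("M must be >= 1")
  if (M > nz / 4) stop("M exceeds spectral samples / 4: bands degenerate")
  N <- d[4]
  if (M == 1L) {
    windows <- matrix(1, nz, 1)
    centers <- nz / 2; fwhm <- nz
  } else {
    centers <- (seq_len(M) - 0.5) * nz / M
    fwhm <- (nz / M) * (1 + overlap)
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    k <- seq_len(nz)
    windows <- sapply(centers, function(c0) exp(-(k - c0)^2 / (2 * sigma^2)))
  }
  amps <- array(0, c(d[1:3], N, M))
  ncol_mat <- d[2] * d[3]
  for (n in seq_len(N)) {
    for (ch in c("H", "V")) {
      prof <- tomo[[ch]][, , , n]
      dim(prof) <- c(nz, ncol_mat)
      spec <- mvfft(prof)                       # depth profile -> synthetic spectrum
      for (m in seq_len(M)) {
        band <- Mod(mvfft(spec * windows[, m], inverse = TRUE) / nz)^2
        dim(band) <- d[1:3]
        amps[, , , n, m] <- amps[, , , n, m] + band
      }
    }
  }
  amps <- sqrt(amps)                            # channel-combined amplitude
  structure(list(amplitudes = amps, band_centers = centers, band_fwhm = fwhm,
                 M = M, n_repeats = N,
                 pitch_um = tomo$acquisition$pitch_um),
            class = "SplitSpectrumSet")
}

#' SSADA decorrelation volume
#'
#' Split-spectrum amplitude-decorrelation:
#' D = 1 - (1 / (M (N-1))) sum_m sum_n A_mn A_m,n+1 / ((A_mn^2 + A_m,n+1^2) / 2),
#' clipped to [0, 1]. Voxels whose intensity is below `floor_db` are masked to
#' 0: pure noise decorrelates fully and must not masquerade as flow.
#' A pair of exactly-zero amplitudes is treated as perfectly correlated
#' (term = 1) and left to the intensity floor.
#'
#' @param bands a [split_spectrum()] result with N >= 2 repeats
#' @param intensity optional DerivedVolume of kind "intensity_dB" used for the
#'   noise floor mask
#' @param floor_db dB threshold; default median of the top-6-row air region
#'   of `intensity` + 6 dB. Ignored when `intensity` is NULL.
#' @return a [new_derived_volume()] of kind "decorrelation"
#' @export
ssada_decorrelation <- function(bands, intensity = NULL, floor_db = NULL) {
  stopifnot(inherits(bands, "SplitSpectrumSet"))
  N <- bands$n_repeats; M <- bands$M
  if (N < 2) stop("SSADA requires N >= 2 repeats")
  A <- bands$amplitudes
  d3 <- dim(A)[1:3]
  corr <- array(0, d3)
  for (m in seq_len(M)) {
    for (n in seq_len(N - 1)) {
      a1 <- A[, , , n, m]; a2 <- A[, , , n + 1, m]
      den <- (a1^2 + a2^2) / 2
      term <- ifelse(den > 0, a1 * a2 / den, 1)
      corr <- corr + term
    }
  }
  D <- clamp(1 - corr / (M * (N - 1)), 0, 1)
  if (!is.null(intensity)) {
    stopifnot(inherits(intensity, "DerivedVolume"),
              intensity$kind == "intensity_dB")
    if (is.null(floor_db)) {
      ref_rows <- seq_len(min(6L, d3[1]))
      floor_db <- median(intensity$values[ref_rows, , ]) + 6
    }
    D[intensity$values < floor_db] <- 0
  }
  new_derived_volume(D, "decorrelation", bands$pitch_um)
}
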