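# Portable, dependency-free file formats.
#
# Volumes (complex tomograms and derived scalar volumes) are stored as a JSON
# sidecar (<prefix>.json: shapes, metadata, config hash) plus a raw
# little-endian float64 payload (<prefix>.bin). Two payload dialects exist for
# complex data: "ri" (all real planes then all imaginary planes per channel)
# and "ir" (imaginary first); the sidecar's plane_order tag disambiguates, and
# readers must produce identical series from either. En-face images are
# written as plain-text PGM (P2, scalar) / PPM (P3, RGB) plus a float CSV.

mfoct_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
err_format <- function(msg) mfoct_error(msg, "mfoct_format_error")
err_config <- function(msg) mfoct_error(msg, "mfoct_config_error")

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a dual-channel tomogram series
#'
#' @param tomo a PolTomogramSeries
#' @param prefix file prefix; writes `<prefix>.json` and `<prefix>.bin`
#' @param plane_order "ri" (real planes first) or "ir" (imaginary first);
#'   recorded in the sidecar
#' @param config_hash optional provenance hash stored in the sidecar
#' @return prefix, invisibly
#' @export
write_tomogram <- function(tomo, prefix, plane_order = c("ri", "ir"),
                           config_hash = NULL) {
  stopifnot(inherits(tomo, "PolTomogramSeries"))
  plane_order <- match.arg(plane_order)
  if (any(!is.finite(tomo$H)) || any(!is.finite(tomo$V)))
    err_format("payload: non-finite values in tomogram")
  meta <- list(format = "mfoct-tomogram", version = 1L,
               dim = dim(tomo$H), channels = c("H", "V"),
               plane_order = plane_order,
               acquisition = tomo$acquisition,
               config_hash = config_hash)
  write_json_sidecar(meta, paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (ch in c("H", "V")) {
    planes <- if (plane_order == "ri")
      list(Re(tomo[[ch]]), Im(tomo[[ch]]))
    else list(Im(tomo[[ch]]), Re(tomo[[ch]]))
    for (p in planes)
      writeBin(as.vector(p), con, size = 8, endian = "little")
  }
  invisible(prefix)
}

#' Read a dual-channel tomogram series
#'
#' Validates the sidecar (channels, shape, payload size) and the payload
#' (finiteness); errors name the offending field.
#'
#' @param prefix file prefix as used by [write_tomogram()]
#' @return a PolTomogramSeries
#' @export
read_tomogram <- function(prefix) {
  jp <- paste0(prefix, ".json"); bp <- paste0(prefix, ".bin")
  if (!file.exists(jp)) err_format(paste0("missing sidecar: ", jp))
  if (!file.exists(bp)) err_format(paste0("missing payload: ", bp))
  meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  if (!identical(meta$format, "mfoct-tomogram"))
    err_format("field 'format': not an mfoct-tomogram")
  for (ch in c("H", "V"))
    if (!ch %in% meta$channels)
      err_format(paste0("field 'channels': missing channel ", ch))
  d <- as.integer(meta$dim)
  if (length(d) != 4 || any(d <= 0)) err_format("field 'dim': need 4 positive sizes")
  n <- prod(d)
  expect_bytes <- n * 8 * 4
  if (file.info(bp)$size != expect_bytes)
    err_format(sprintf("field 'dim': payload has %d bytes, dim implies %d",
                       file.info(bp)$size, expect_bytes))
  con <- file(bp, "rb")
  on.exit(close(con))
  ord <- meta$plane_order %||% "ri"
  read_ch <- function() {
    p1 <- readBin(con, "double", n, size = 8, endian = "little")
    p2 <- readBin(con, "double", n, size = 8, endian = "little")
    if (ord == "ri") complex(real = p1, imaginary = p2)
    else complex(real = p2, imaginary = p1)
  }
  H <- array(read_ch(), d); V <- array(read_ch(), d)
  if (any(!is.finite(H)) || any(!is.finite(V)))
    err_format("payload: NaN/Inf values in tomogram")
  acq <- meta$acquisition
  new_pol_tomogram(H, V,
                   pitch_um = unlist(acq$pitch_um),
                   lambda0_um = acq$lambda0_um %||% 0.84,
                   line_rate_hz = acq$line_rate_hz %||% 25000)
}

#' Write / read a derived scalar volume
#'
#' Raw float64 payload plus a JSON sidecar carrying kind, units and pitch.
#'
#' @param vol a DerivedVolume
#' @param prefix file prefix
#' @param config_hash optional provenance hash
#' @return prefix, invisibly
#' @export
write_derived_volume <- function(vol, prefix, config_hash = NULL) {
  stopifnot(inherits(vol, "DerivedVolume"))
  meta <- list(format = "mfoct-volume", version = 1L, dim = dim(vol$values),
               kind = vol$kind,
               units = switch(vol$kind, intensity_dB = "dB",
                              retardation_deg = "deg", ""),
               pitch_um = vol$pitch_um, config_hash = config_hash)
  write_json_sidecar(meta, paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(vol$values), con, size = 8, endian = "little")
  invisible(prefix)
}

#' @rdname write_derived_volume
#' @export
read_derived_volume <- function(prefix) {
  jp <- paste0(prefix, ".json"); bp <- paste0(prefix, ".bin")
  if (!file.exists(jp)) err_format(paste0("missing sidecar: ", jp))
  meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  if (!identical(meta$format, "mfoct-volume"))
    err_format("field 'format': not an mfoct-volume")
  d <- as.integer(meta$dim)
  con <- file(bp, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", prod(d), size = 8, endian = "little")
  new_derived_volume(array(v, d), meta$kind, unlist(meta$pitch_um))
}

#' Write a boundary set as CSV
#'
#' One row per (x, y) column: the three boundaries, the midline and validity
#' flags. A `# config_hash=` comment line carries provenance.
#'
#' @param b a BoundarySet
#' @param path CSV path
#' @param config_hash optional provenance hash
#' @export
write_boundaries <- function(b, path, config_hash = NULL) {
  stopifnot(inherits(b, "BoundarySet"))
  nx <- nrow(b$z_air_skin); ny <- ncol(b$z_air_skin)
  df <- data.frame(x = rep(seq_len(nx), ny), y = rep(seq_len(ny), each = nx),
                   z_air_skin = as.vector(b$z_air_skin),
                   z_skin_skull = as.vector(b$z_skin_skull),
                   z_skull_brain = as.vector(b$z_skull_brain),
                   z_midline = as.vector(b$z_midline %||%
                                           ((b$z_skin_skull + b$z_skull_brain) / 2)),
                   valid_air_skin = as.vector(b$validity[, , 1]),
                   valid_skin_skull = as.vector(b$validity[, , 2]),
                   valid_skull_brain = as.vector(b$validity[, , 3]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash=", config_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  df <- read.csv(path, comment.char = "#")
  nx <- max(df$x); ny <- max(df$y)
  m <- function(col) matrix(df[[col]], nx, ny)
  validity <- array(FALSE, c(nx, ny, 3))
  validity[, , 1] <- m("valid_air_skin")
  validity[, , 2] <- m("valid_skin_skull")
  validity[, , 3] <- m("valid_skull_brain")
  structure(list(z_air_skin = m("z_air_skin"), z_skin_skull = m("z_skin_skull"),
                 z_skull_brain = m("z_skull_brain"), z_midline = m("z_midline"),
                 validity = validity), class = "BoundarySet")
}

#' Export an en-face image
#'
#' Scalar images are written as float CSV plus a P2 (text) PGM preview;
#' RGB images as a P3 (text) PPM. No-data pixels export as 0 in the previews
#' and NaN in the CSV.
#'
#' @param img an EnFaceImage
#' @param prefix file prefix
#' @param config_hash optional provenance hash
#' @export
write_enface <- function(img, prefix, config_hash = NULL) {
  stopifnot(inherits(img, "EnFaceImage"))
  px <- img$pixels
  if (length(dim(px)) == 3) {
    v <- round(clamp(px, 0, 1) * 255)
    v[!is.finite(v)] <- 0
    con <- file(paste0(prefix, ".ppm"), "w")
    on.exit(close(con))
    writeLines(c("P3",
                 paste0("# mfoct ", img$kind, " band=", img$layer_tag,
                        if (!is.null(config_hash)) paste0(" config_hash=", config_hash)),
                 paste(nrow(px), ncol(px)), "255"), con)
    # PPM raster is row-major top-to-bottom; emit y as rows, x as columns
    for (y in seq_len(ncol(px))) {
      trip <- rbind(v[, y, 1], v[, y, 2], v[, y, 3])
      writeLines(paste(as.vector(trip), collapse = " "), con)
    }
  } else {
    utils::write.table(px, paste0(prefix, ".csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    fin <- px[is.finite(px)]
    lo <- if (length(fin)) min(fin) else 0
    hi <- if (length(fin)) max(fin) else 1
    sc <- if (hi > lo) (px - lo) / (hi - lo) else px * 0
    v <- round(clamp(sc, 0, 1) * 255)
    v[!is.finite(v)] <- 0
    con <- file(paste0(prefix, ".pgm"), "w")
    on.exit(close(con))
    writeLines(c("P2",
                 paste0("# mfoct ", img$kind, " band=", img$layer_tag,
                        " units=", img$units,
                        if (!is.null(config_hash)) paste0(" config_hash=", config_hash)),
                 paste(nrow(px), ncol(px)), "255"), con)
    for (y in seq_len(ncol(px)))
      writeLines(paste(v[, y], collapse = " "), con)
  }
  invisible(prefix)
}

#' Write channel calls and vessel metrics
#'
#' @param calls a ChannelCallSet
#' @param prefix file prefix; writes `<prefix>.csv` (components) and
#'   `<prefix>.json` (params + summary)
#' @param config_hash optional provenance hash
#' @export
write_channel_calls <- function(calls, prefix, config_hash = NULL) {
  stopifnot(inherits(calls, "ChannelCallSet"))
  con <- file(paste0(prefix, ".csv"), "w")
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash=", config_hash), con)
  write.csv(calls$components, con, row.names = FALSE)
  close(con)
  write_json_sidecar(list(params = calls$params,
                          n_components = nrow(calls$components),
                          suture_fraction = calls$suture_fraction %||% NA,
                          config_hash = config_hash),
                     paste0(prefix, ".json"))
  invisible(prefix)
}

#' @param metrics data.frame from [tbi_metrics()]
#' @param path CSV path
#' @rdname write_channel_calls
#' @export
write_metrics <- function(metrics, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash=", config_hash), con)
  write.csv(metrics, con, row.names = FALSE)
  invisible(path)
}
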