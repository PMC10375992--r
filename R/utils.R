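#' @useDynLib mfoct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats smooth.spline predict runmed median quantile mad rnorm runif mvfft fft approx
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each pipeline
#' stage draws from its own substream so that stage-level reruns reproduce the
#' full-pipeline result. The substream seed is a 31-bit FNV-1a style hash of the
#' stage name folded into the master seed.
#'
#' @param seed master integer seed
#' @param stage stage name, e.g. "phantom", "render", "angio"
#' @return an integer seed in [0, 2^31 - 1]
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 2166136261 %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- bitwXor(h, code)
    # multiply by FNV prime modulo 2^31-1, in double precision-safe steps
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + abs(seed)) %% 2147483647)
}

# 31-bit FNV-1a hash of a character string (used for config provenance hashes)
fnv1a_hash <- function(x) {
  h <- 2166136261 %% 2147483647
  for (code in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- bitwXor(h, code)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round-half-up to integer (boundary -> voxel index convention)
round_half_up <- function(x) floor(x + 0.5)

#' 2-D box filter with shrinking windows at the borders
#'
#' Mean filter over an odd-sized (kr x kc) window, computed with summed-area
#' tables; windows are cropped (not padded) at the image borders so border
#' values remain unbiased means.
#'
#' @param m numeric matrix
#' @param kr,kc odd window sizes along rows / columns
#' @return matrix of local means, same shape as `m`
#' @keywords internal
boxfilt2 <- function(m, kr, kc) {
  stopifnot(kr %% 2 == 1, kc %% 2 == 1, kr >= 1, kc >= 1)
  if (is.null(dim(m))) m <- matrix(m, length(m), 1L)
  nr <- nrow(m); nc <- ncol(m)
  if (kr > nr || kc > nc) stop("box filter kernel larger than image")
  hr <- (kr - 1L) / 2L; hc <- (kc - 1L) / 2L
  # summed-area table with a zero border
  sat <- matrix(0, nr + 1L, nc + 1L)
  cs <- m
  if (nr > 1L) cs <- apply(cs, 2L, cumsum)
  if (nc > 1L) cs <- t(apply(cs, 1L, cumsum))
  sat[-1L, -1L] <- cs
  r1 <- pmax(seq_len(nr) - hr, 1L); r2 <- pmin(seq_len(nr) + hr, nr)
  c1 <- pmax(seq_len(nc) - hc, 1L); c2 <- pmin(seq_len(nc) + hc, nc)
  S <- sat[r2 + 1L, c2 + 1L, drop = FALSE] - sat[r1, c2 + 1L, drop = FALSE] -
       sat[r2 + 1L, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  S / cnt
}

# binary dilation with a (2r+1) square element, via box filter
dilate_square <- function(mask, r) {
  if (r <= 0) return(mask)
  boxfilt2(mask * 1, 2L * r + 1L, 2L * r + 1L) > 0
}

# morphological opening of a binary matrix with a horizontal 1 x w line element,
# applied along rows (dim 2 = lateral). Erosion then dilation by running sums.
open_line_rows <- function(mask, w) {
  stopifnot(w >= 1)
  if (w == 1) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  if (w > nc) return(matrix(FALSE, nr, nc))
  run <- function(m, k, full) {
    # centered running sum of length k along columns; partial windows at border
    cs <- cbind(0, t(apply(m, 1L, cumsum)))
    if (nr == 1L) cs <- matrix(c(0, cumsum(m)), 1L)
    h1 <- floor((k - 1) / 2); h2 <- k - 1 - h1
    c1 <- pmax(seq_len(nc) - h1, 1L); c2 <- pmin(seq_len(nc) + h2, nc)
    s <- cs[, c2 + 1L, drop = FALSE] - cs[, c1, drop = FALSE]
    if (full) s >= (c2 - c1 + 1L)[col(s)] & (c2 - c1 + 1L)[col(s)] == k else s > 0
  }
  er <- run(mask * 1, w, full = TRUE)
  run(er * 1, w, full = FALSE)
}

#' Label connected components of a binary matrix
#'
#' @param mask logical matrix
#' @param connectivity 4 or 8
#' @return integer matrix of labels (0 = background), labels are 1..n
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  label_components_cpp(mask, as.integer(connectivity))
}

# drop connected components smaller than min_area from a binary matrix
filter_small_components <- function(mask, min_area, connectivity = 8L) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}
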