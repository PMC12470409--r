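# Low-level image operations on H x W x 3 double arrays with values in [0, 1].
# Everything here is a pure deterministic function of its arguments; the
# augmentation and fixtures modules are built on top of these primitives.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

check_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop_invalid(sprintf("%s must be an H x W x 3 array (got %s)",
                         what, paste(dim(img), collapse = "x")))
  }
  if (!is.double(img)) storage.mode(img) <- "double"
  img
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luma weights (0.299, 0.587, 0.114).
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @return H x W matrix in \[0, 1\].
#' @keywords internal
rgb_to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# RGB (in [0,1]) -> HSV with h, s, v all in [0,1]. Vectorized over pixels.
rgb_to_hsv_arr <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  s <- ifelse(v > 0, d / v, 0)
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  rmax <- nz & (v == r)
  gmax <- nz & !rmax & (v == g)
  bmax <- nz & !rmax & !gmax
  h[rmax] <- ((g[rmax] - b[rmax]) / d[rmax]) / 6
  h[gmax] <- (2 + (b[gmax] - r[gmax]) / d[gmax]) / 6
  h[bmax] <- (4 + (r[bmax] - g[bmax]) / d[bmax]) / 6
  h <- h %% 1
  list(h = h, s = s, v = v)
}

hsv_to_rgb_arr <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  sel <- i == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- i == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- i == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- i == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- i == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- i >= 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  out <- array(0, c(nrow(h), ncol(h), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Shift the hue of an image
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param degrees rotation on the color wheel (360 = full turn).
#' @return image array of the same shape.
#' @keywords internal
shift_hue <- function(img, degrees) {
  if (degrees == 0) return(img)
  hsv <- rgb_to_hsv_arr(img)
  clip01(hsv_to_rgb_arr(hsv$h + degrees / 360, hsv$s, hsv$v))
}

# Mirror-reflect an index vector into [1, n] (reflection includes the edge
# sample, i.e. indices ..., 2, 1, 1, 2, ... at the low border).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx < 0, idx + period, idx)
  as.integer(ifelse(idx < n, idx, period - 1L - idx)) + 1L
}

#' Bilinear image resize
#'
#' Maps output pixel centers to input coordinates (half-pixel convention)
#' and interpolates bilinearly; used to restore model input size after
#' center cropping and to build the toy adapter's pooled features.
#'
#' @param img H x W x 3 array (or H x W matrix).
#' @param out_h,out_w output size in pixels.
#' @return resized array/matrix.
#' @keywords internal
resize_bilinear <- function(img, out_h, out_w) {
  ismat <- is.matrix(img)
  if (ismat) img <- array(img, c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  sy <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  sx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  sy <- pmin(pmax(sy, 1), h)
  sx <- pmin(pmax(sx, 1), w)
  y0 <- pmin(floor(sy), h - 1); y0[h == 1] <- 1
  x0 <- pmin(floor(sx), w - 1); x0[w == 1] <- 1
  if (h == 1) y0 <- rep(1, out_h)
  if (w == 1) x0 <- rep(1, out_w)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  wy <- sy - y0; wx <- sx - x0
  out <- array(0, c(out_h, out_w, nc))
  for (c in seq_len(nc)) {
    m <- img[, , c]
    a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
    d <- m[y1, x0, drop = FALSE]; e <- m[y1, x1, drop = FALSE]
    top <- a * (1 - rep(wx, each = out_h)) + b * rep(wx, each = out_h)
    bot <- d * (1 - rep(wx, each = out_h)) + e * rep(wx, each = out_h)
    out[, , c] <- top * (1 - wy) + bot * wy
  }
  if (ismat) out[, , 1] else out
}

gaussian_kernel_1d <- function(sigma, size = NULL) {
  if (is.null(size)) size <- 2L * max(1L, ceiling(3 * sigma)) + 1L
  if (size %% 2 == 0) stop_invalid("Gaussian kernel size must be odd")
  r <- (size - 1L) / 2L
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_1d_reflect <- function(m, kernel, along) {
  r <- (length(kernel) - 1L) / 2L
  n <- if (along == 1) nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - 1L - r
    idx <- reflect_index(seq_len(n) + off, n)
    out <- out + kernel[j] * (if (along == 1) m[idx, , drop = FALSE]
                              else m[, idx, drop = FALSE])
  }
  out
}

#' Gaussian blur with reflect padding
#'
#' Separable convolution; `size` defaults to the usual 2*ceil(3*sigma)+1.
#'
#' @param img H x W x 3 array.
#' @param sigma standard deviation in pixels; 0 returns the input unchanged.
#' @param size odd kernel size, or NULL for the default.
#' @keywords internal
gaussian_blur <- function(img, sigma, size = NULL) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma, size)
  for (c in 1:3) {
    img[, , c] <- convolve_1d_reflect(
      convolve_1d_reflect(img[, , c], k, along = 1), k, along = 2)
  }
  img
}

#' Rotate an image about its center
#'
#' Inverse-mapped bilinear rotation; out-of-bounds samples are
#' mirror-reflected so no black corners are introduced (black corners would
#' be trivially flagged as out-of-distribution downstream). Output size
#' equals input size.
#'
#' @param img H x W x 3 array.
#' @param degrees counter-clockwise rotation angle.
#' @keywords internal
rotate_image <- function(img, degrees) {
  if (degrees %% 360 == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  th <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: rotate output coords by -theta to find source coords
  sy <- cos(th) * yy + sin(th) * xx + cy
  sx <- -sin(th) * yy + cos(th) * xx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  iy0 <- reflect_index(as.integer(y0), h)
  iy1 <- reflect_index(as.integer(y0) + 1L, h)
  ix0 <- reflect_index(as.integer(x0), w)
  ix1 <- reflect_index(as.integer(x0) + 1L, w)
  out <- img
  for (c in 1:3) {
    m <- img[, , c]
    v <- m[cbind(c(iy0), c(ix0))] * (1 - c(wy)) * (1 - c(wx)) +
         m[cbind(c(iy0), c(ix1))] * (1 - c(wy)) * c(wx) +
         m[cbind(c(iy1), c(ix0))] * c(wy) * (1 - c(wx)) +
         m[cbind(c(iy1), c(ix1))] * c(wy) * c(wx)
    out[, , c] <- matrix(v, h, w)
  }
  out
}

#' Center crop by a pixel margin
#'
#' Removes `margin` pixels from every side.
#' @keywords internal
center_crop <- function(img, margin) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (2 * margin >= min(h, w)) {
    stop_invalid(sprintf("crop margin %d too large for %dx%d image",
                         margin, h, w))
  }
  img[(margin + 1):(h - margin), (margin + 1):(w - margin), , drop = FALSE]
}

flip_horizontal <- function(img) img[, dim(img)[2]:1, , drop = FALSE]
flip_vertical <- function(img) img[dim(img)[1]:1, , , drop = FALSE]

# Photometric adjustments following the common torchvision semantics:
# brightness scales intensities, contrast blends with the mean gray level,
# saturation blends with the per-pixel gray image, hue rotates the wheel.
adjust_brightness <- function(img, factor) clip01(img * factor)

adjust_contrast <- function(img, factor) {
  m <- mean(rgb_to_gray(img))
  clip01(factor * img + (1 - factor) * m)
}

adjust_saturation <- function(img, factor) {
  g <- rgb_to_gray(img)
  out <- img
  for (c in 1:3) out[, , c] <- factor * img[, , c] + (1 - factor) * g
  clip01(out)
}

color_jitter <- function(img, brightness = 1, contrast = 1, saturation = 1,
                         hue = 0) {
  img <- adjust_brightness(img, brightness)
  img <- adjust_contrast(img, contrast)
  img <- adjust_saturation(img, saturation)
  shift_hue(img, hue * 360)
}
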