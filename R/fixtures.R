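# Synthetic leukocyte-like image fixtures.
#
# Five visually distinct (non-biological) class recipes stand in for the
# five white-blood-cell sub-types so the whole inference pipeline can be
# exercised without external datasets. Acquisition-domain shift (staining,
# lighting, optics, sensor noise) is emulated by a deterministic corruption
# chain applied after rendering: tint -> hue shift -> brightness -> blur ->
# additive noise, clipping to [0,1] after each multiplicative step.

#' Names of the five synthetic cell classes
#'
#' Lexicographically sorted, matching the class-per-subdirectory reader:
#' index 0 = basophil, ..., index 4 = neutrophil.
#' @return character vector of length 5.
#' @export
wbc_class_names <- function() {
  c("basophil", "eosinophil", "lymphocyte", "monocyte", "neutrophil")
}

#' Describe an acquisition domain
#'
#' A domain bundles the corruption parameters that emulate differences in
#' staining, lighting and equipment between laboratories.
#'
#' @param name domain identifier.
#' @param hue_shift hue rotation in degrees on the color wheel.
#' @param brightness_gain multiplicative intensity factor (> 0).
#' @param blur_sigma Gaussian blur standard deviation in pixels (>= 0).
#' @param background_tint length-3 RGB multiplier in \[0, 1\].
#' @param noise_sd additive Gaussian noise standard deviation in intensity
#'   units (>= 0).
#' @return an object of class `domain_spec`.
#' @export
domain_spec <- function(name, hue_shift = 0, brightness_gain = 1,
                        blur_sigma = 0, background_tint = c(1, 1, 1),
                        noise_sd = 0) {
  if (brightness_gain <= 0) stop_invalid("brightness_gain must be > 0")
  if (blur_sigma < 0) stop_invalid("blur_sigma must be >= 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (length(background_tint) != 3 || any(background_tint < 0) ||
      any(background_tint > 1)) {
    stop_invalid("background_tint must be an RGB triple in [0, 1]")
  }
  structure(list(name = as.character(name), hue_shift = hue_shift,
                 brightness_gain = brightness_gain, blur_sigma = blur_sigma,
                 background_tint = as.double(background_tint),
                 noise_sd = noise_sd),
            class = "domain_spec")
}

#' The identity acquisition domain (no corruption)
#' @return a `domain_spec` that leaves rendered images untouched.
#' @export
identity_domain <- function() domain_spec("identity")

#' Built-in benchmark domains
#'
#' Four synthetic "laboratories" with increasing acquisition shift relative
#' to `lab_a`: hue (stain) rotation up to 25 degrees, brightness 0.85-1.30,
#' blur up to 1.8 px, mild channel tints and sensor noise up to 0.05 —
#' magnitudes a microscopist would recognise as plausible inter-lab
#' variation, fixed once and not tuned.
#'
#' @return named list of four `domain_spec` objects.
#' @export
builtin_domains <- function() {
  list(
    lab_a = domain_spec("lab_a", hue_shift = 0, brightness_gain = 1,
                        blur_sigma = 0, background_tint = c(1, 1, 1),
                        noise_sd = 0.01),
    lab_b = domain_spec("lab_b", hue_shift = 12, brightness_gain = 1.15,
                        blur_sigma = 0.8,
                        background_tint = c(1.00, 0.92, 0.98),
                        noise_sd = 0.02),
    lab_c = domain_spec("lab_c", hue_shift = -18, brightness_gain = 0.85,
                        blur_sigma = 1.2,
                        background_tint = c(0.95, 1.00, 0.90),
                        noise_sd = 0.03),
    lab_d = domain_spec("lab_d", hue_shift = 25, brightness_gain = 1.30,
                        blur_sigma = 1.8,
                        background_tint = c(0.90, 0.97, 1.00),
                        noise_sd = 0.05)
  )
}

# --- rendering ------------------------------------------------------------

# Soft-edged ellipse alpha mask on the unit square grid.
ellipse_alpha <- function(yy, xx, cy, cx, a, b, theta = 0, edge = 0.03) {
  dy <- yy - cy; dx <- xx - cx
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  d <- sqrt(u^2 + v^2) - 1
  clip01(0.5 - d / (2 * edge))
}

blend <- function(img, alpha, color) {
  for (c in 1:3) img[, , c] <- img[, , c] * (1 - alpha) + color[c] * alpha
  img
}

# Scatter n soft dots (granules) of radius r inside the disc of radius rad
# around (cy, cx); consumes RNG draws.
add_granules <- function(img, yy, xx, cy, cx, rad, n, r, color, strength) {
  if (n == 0) return(img)
  ang <- stats::runif(n, 0, 2 * pi)
  rr <- rad * sqrt(stats::runif(n))
  gy <- cy + rr * sin(ang); gx <- cx + rr * cos(ang)
  for (i in seq_len(n)) {
    d2 <- (yy - gy[i])^2 + (xx - gx[i])^2
    img <- blend(img, strength * exp(-d2 / (2 * r^2)), color)
  }
  img
}

# Render one clean (identity-domain) cell image for class index 0..4.
# Non-biological recipes chosen only to make the five classes separable:
#   basophil    - round nucleus filling the cell, dense dark granules
#   eosinophil  - bi-lobed nucleus, coarse reddish granules
#   lymphocyte  - small cell, large round dark nucleus, thin rim
#   monocyte    - large cell, pale kidney-shaped (indented) nucleus
#   neutrophil  - 3-4 small nuclear lobes, fine pale granules
render_cell <- function(class_idx, size) {
  yy <- matrix(seq_len(size), size, size) / size
  xx <- matrix(seq_len(size), size, size, byrow = TRUE) / size
  img <- array(0, c(size, size, 3))
  # plasma background with two faint red-cell ghosts for texture
  bg <- c(0.93, 0.91, 0.96)
  for (c in 1:3) img[, , c] <- bg[c]
  for (i in 1:2) {
    a <- ellipse_alpha(yy, xx, stats::runif(1, 0.1, 0.9),
                       stats::runif(1, 0.1, 0.9),
                       0.10, 0.10, edge = 0.05)
    img <- blend(img, 0.35 * a, c(0.97, 0.82, 0.80))
  }
  cy <- stats::runif(1, 0.46, 0.54); cx <- stats::runif(1, 0.46, 0.54)
  rot <- stats::runif(1, 0, 2 * pi)
  jit <- stats::runif(1, 0.9, 1.1)
  if (class_idx == 0L) {            # basophil-like
    rad <- 0.30 * jit
    img <- blend(img, ellipse_alpha(yy, xx, cy, cx, rad, 0.95 * rad, rot),
                 c(0.70, 0.60, 0.80))
    img <- blend(img,
                 ellipse_alpha(yy, xx, cy, cx, 0.80 * rad, 0.75 * rad, rot),
                 c(0.38, 0.22, 0.52))
    img <- add_granules(img, yy, xx, cy, cx, 0.85 * rad, 60, 0.013,
                        c(0.25, 0.10, 0.40), 0.8)
  } else if (class_idx == 1L) {     # eosinophil-like
    rad <- 0.30 * jit
    img <- blend(img, ellipse_alpha(yy, xx, cy, cx, rad, 0.95 * rad, rot),
                 c(0.82, 0.72, 0.76))
    off <- 0.40 * rad
    for (s in c(-1, 1)) {
      img <- blend(img, ellipse_alpha(yy, xx, cy + s * off * sin(rot),
                                      cx + s * off * cos(rot),
                                      0.42 * rad, 0.34 * rad, rot),
                   c(0.45, 0.25, 0.55))
    }
    img <- add_granules(img, yy, xx, cy, cx, 0.88 * rad, 45, 0.016,
                        c(0.86, 0.45, 0.33), 0.75)
  } else if (class_idx == 2L) {     # lymphocyte-like
    rad <- 0.22 * jit
    img <- blend(img, ellipse_alpha(yy, xx, cy, cx, rad, rad, rot),
                 c(0.62, 0.68, 0.85))
    img <- blend(img,
                 ellipse_alpha(yy, xx, cy, cx, 0.85 * rad, 0.82 * rad, rot),
                 c(0.30, 0.16, 0.46))
  } else if (class_idx == 3L) {     # monocyte-like
    rad <- 0.35 * jit
    img <- blend(img, ellipse_alpha(yy, xx, cy, cx, rad, 0.92 * rad, rot),
                 c(0.76, 0.76, 0.87))
    nuc <- ellipse_alpha(yy, xx, cy, cx, 0.72 * rad, 0.62 * rad, rot)
    dent <- ellipse_alpha(yy, xx, cy + 0.45 * rad * sin(rot),
                          cx + 0.45 * rad * cos(rot),
                          0.45 * rad, 0.40 * rad, rot)
    img <- blend(img, clip01(nuc - dent), c(0.56, 0.42, 0.66))
  } else {                          # neutrophil-like
    rad <- 0.30 * jit
    img <- blend(img, ellipse_alpha(yy, xx, cy, cx, rad, 0.95 * rad, rot),
                 c(0.80, 0.74, 0.82))
    n_lobes <- sample(3:4, 1)
    ang0 <- stats::runif(1, 0, 2 * pi)
    for (l in seq_len(n_lobes)) {
      a <- ang0 + 2 * pi * l / n_lobes + stats::runif(1, -0.3, 0.3)
      img <- blend(img, ellipse_alpha(yy, xx, cy + 0.42 * rad * sin(a),
                                      cx + 0.42 * rad * cos(a),
                                      0.30 * rad, 0.24 * rad, a),
                   c(0.40, 0.22, 0.52))
    }
    img <- add_granules(img, yy, xx, cy, cx, 0.88 * rad, 80, 0.009,
                        c(0.80, 0.62, 0.70), 0.35)
  }
  # per-image acquisition jitter: slide-to-slide staining intensity and
  # color vary even within one laboratory, so every render gets a small
  # photometric perturbation (the counterpart of the geometric jitter in
  # position/size/rotation above)
  img <- shift_hue(clip01(img), stats::runif(1, -4, 4))
  clip01(img * stats::runif(1, 0.95, 1.05))
}

# Apply the acquisition-domain corruption chain. `clip = FALSE` exposes the
# unclipped linear render for verification of the multiplicative steps.
apply_domain <- function(img, domain, clip = TRUE, noise_seed = NULL) {
  cl <- if (clip) clip01 else identity
  tint <- domain$background_tint
  if (any(tint != 1)) {
    for (c in 1:3) img[, , c] <- img[, , c] * tint[c]
    img <- cl(img)
  }
  if (domain$hue_shift != 0) img <- shift_hue(img, domain$hue_shift)
  if (domain$brightness_gain != 1) {
    img <- cl(img * domain$brightness_gain)
  }
  if (domain$blur_sigma > 0) img <- gaussian_blur(img, domain$blur_sigma)
  if (domain$noise_sd > 0) {
    noise <- if (is.null(noise_seed)) {
      stats::rnorm(length(img), 0, domain$noise_sd)
    } else {
      with_seed(noise_seed, stats::rnorm(length(img), 0, domain$noise_sd))
    }
    img <- cl(img + array(noise, dim(img)))
  }
  img
}

#' Generate a synthetic labelled cell-image dataset
#'
#' Renders `n_per_class` images for each of the five classes and applies the
#' domain's corruption chain. The generator is a pure function of its
#' arguments: the same `(n_per_class, domain, image_size, seed)` produce
#' bit-identical images. Each image gets its own seed derived from `seed`,
#' so the clean render of image i does not depend on how much randomness
#' other images (or the noise step) consumed.
#'
#' @param n_per_class images per class (>= 1).
#' @param domain a [domain_spec()]; default no corruption.
#' @param image_size square image side in pixels (>= 32).
#' @param seed integer seed.
#' @return object of class `synthetic_dataset`: list with `images` (list of
#'   H x W x 3 arrays in \[0,1\]), `labels` (integer 0..4), `class_names`,
#'   `domain`, `seed`.
#' @export
generate_dataset <- function(n_per_class, domain = identity_domain(),
                             image_size = 64, seed = 1) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop_invalid("n_per_class must be >= 1")
  }
  if (!is.numeric(image_size) || image_size < 32) {
    stop_invalid("image_size must be >= 32")
  }
  if (!inherits(domain, "domain_spec")) {
    stop_invalid("domain must be a domain_spec")
  }
  n_per_class <- as.integer(n_per_class)
  image_size <- as.integer(image_size)
  images <- vector("list", 5L * n_per_class)
  labels <- integer(5L * n_per_class)
  idx <- 0L
  for (cls in 0:4) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      clean <- with_seed(derive_seed(seed, 2L * (cls * 100000L + i)),
                         render_cell(cls, image_size))
      images[[idx]] <- apply_domain(
        clean, domain,
        noise_seed = derive_seed(seed, 2L * (cls * 100000L + i) + 1L))
      labels[idx] <- cls
    }
  }
  structure(list(images = images, labels = labels,
                 class_names = wbc_class_names(), domain = domain,
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d images, %d classes, domain '%s', seed %d\n",
              length(x$images), length(unique(x$labels)), x$domain$name,
              x$seed))
  invisible(x)
}

# --- toy classifier adapter -----------------------------------------------

# Otsu's threshold on a grayscale matrix (256 bins).
otsu_threshold <- function(g) {
  h <- tabulate(pmin(pmax(floor(g * 256) + 1, 1), 256), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  which.max(sigma_b) / 256
}

toy_low_features <- function(img) {
  as.vector(resize_bilinear(rgb_to_gray(img), 8, 8))
}

toy_mid_features <- function(img) {
  n <- length(img[, , 1])
  unlist(lapply(1:3, function(c) {
    tabulate(pmin(pmax(floor(img[, , c] * 16) + 1, 1), 16), nbins = 16) / n
  }), use.names = FALSE)
}

toy_high_features <- function(img) {
  g <- rgb_to_gray(img)
  t <- otsu_threshold(g)
  fg <- g < t
  if (sum(fg) < 10) fg <- g < stats::quantile(g, 0.3, names = FALSE)
  n <- sum(fg)
  h <- nrow(g)
  ys <- (row(g)[fg]) / h; xs <- (col(g)[fg]) / h
  cyy <- mean(ys); cxx <- mean(xs)
  cov <- stats::cov(cbind(ys, xs))
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  elong <- if (ev[1] > 1e-12) max(ev[2], 0) / ev[1] else 1
  # boundary pixels: foreground with at least one 4-neighbour background
  fgp <- rbind(FALSE, fg, FALSE); fgp <- cbind(FALSE, fgp, FALSE)
  nb <- fgp[1:h, 2:(h + 1)] & fgp[3:(h + 2), 2:(h + 1)] &
        fgp[2:(h + 1), 1:h] & fgp[2:(h + 1), 3:(h + 2)]
  boundary <- sum(fg & !nb) / n
  c(area = n / length(g),
    fg_mean = mean(g[fg]),
    fg_sd = if (n > 1) stats::sd(g[fg]) else 0,
    fg_r = mean(img[, , 1][fg]),
    fg_g = mean(img[, , 2][fg]),
    fg_b = mean(img[, , 3][fg]),
    bg_mean = if (n < length(g)) mean(g[!fg]) else 0,
    radial_sd = sqrt(mean((ys - cyy)^2 + (xs - cxx)^2)),
    boundary = boundary,
    elongation = elong)
}

toy_features <- function(img) {
  list(low = toy_low_features(img), mid = toy_mid_features(img),
       high = toy_high_features(img))
}

#' Fit the deterministic toy classifier adapter
#'
#' A nearest-centroid classifier over hand-crafted features standing in for
#' a deep network. Its three tagged feature layers are: `"low"` — an 8x8
#' downsampled grayscale flatten (64 values), `"mid"` — a 16-bin histogram
#' per color channel (48 values), `"high"` — 10 shape/intensity moments of
#' the Otsu-thresholded foreground. Class probabilities are a softmax over
#' negative Euclidean distances (in internally standardized feature space)
#' to the per-class centroids. Fitting and inference are fully
#' deterministic.
#'
#' @param train a `synthetic_dataset` (or any list with `images`, `labels`,
#'   `class_names`) containing all five classes.
#' @return an object of class `classifier_adapter` with fields `n_classes`,
#'   `layer_tags`, `input_size`, and closures `features(image)` and
#'   `probabilities(image)`.
#' @export
make_toy_adapter <- function(train) {
  if (length(train$images) == 0) stop_data("training set is empty")
  n_classes <- length(train$class_names)
  present <- sort(unique(train$labels))
  if (!identical(as.integer(present), 0:(n_classes - 1))) {
    stop_data(sprintf("toy adapter fit requires all %d classes; got labels {%s}",
                      n_classes, paste(present, collapse = ",")))
  }
  input_size <- dim(train$images[[1]])[1]
  feats <- t(vapply(train$images,
                    function(im) unlist(toy_features(im), use.names = FALSE),
                    numeric(122)))
  mu <- colMeans(feats)
  sdv <- pmax(apply(feats, 2, stats::sd), 1e-8)
  z <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  # balance the three layers in the centroid distance (each layer's squared
  # distance divided by its dimension), so the 64 low-level dims do not
  # drown the 10 shape moments
  ldim <- rep(c(64, 48, 10), times = c(64, 48, 10))
  zb <- sweep(z, 2, sqrt(ldim), "/")
  centroids <- t(vapply(0:(n_classes - 1), function(cls) {
    colMeans(zb[train$labels == cls, , drop = FALSE])
  }, numeric(ncol(zb))))
  # temperature from the typical margin between the two closest centroids,
  # so softmax probabilities are informative rather than near-uniform
  dall <- t(apply(zb, 1, function(zq) {
    sort(sqrt(colSums((t(centroids) - zq)^2)))[1:2]
  }))
  temp <- max(stats::median(dall[, 2] - dall[, 1]), 1e-6)

  prep <- function(image) {
    image <- check_image(image)
    if (dim(image)[1] != input_size || dim(image)[2] != input_size) {
      image <- resize_bilinear(image, input_size, input_size)
    }
    image
  }
  structure(list(
    name = "toy",
    n_classes = n_classes,
    layer_tags = c("low", "mid", "high"),
    input_size = input_size,
    features = function(image) toy_features(prep(image)),
    probabilities = function(image) {
      f <- unlist(toy_features(prep(image)), use.names = FALSE)
      zq <- (f - mu) / sdv / sqrt(ldim)
      d <- sqrt(colSums((t(centroids) - zq)^2))
      e <- exp(-(d - min(d)) / temp)
      e / sum(e)
    }
  ), class = "classifier_adapter")
}

#' @export
print.classifier_adapter <- function(x, ...) {
  cat(sprintf("classifier_adapter '%s': %d classes, input %dpx, layers %s\n",
              x$name, x$n_classes, x$input_size,
              paste(x$layer_tags, collapse = "/")))
  invisible(x)
}
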