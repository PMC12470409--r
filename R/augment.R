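# Deterministic test-time augmentation.
#
# The augmentation set A is an ordered, named list of pure image transforms.
# Test-time inference applies every transform to the input image and fuses
# the model's predictions over the original plus the |A| augmented copies;
# order matters because downstream fusion weights are index-aligned.

AUG_KINDS <- c("center_crop", "hflip", "vflip", "rotate", "gaussian_blur",
               "color_jitter")

#' Create a single augmentation transform
#'
#' @param kind one of `"center_crop"`, `"hflip"`, `"vflip"`, `"rotate"`,
#'   `"gaussian_blur"`, `"color_jitter"`.
#' @param name unique identifier; defaults to kind plus its strength.
#' @param ... strength parameters per kind: `margin` (pixels, center_crop),
#'   `degrees` (rotate), `sigma` and `size` (gaussian_blur), `brightness`,
#'   `contrast`, `saturation`, `hue` (color_jitter; hue as a fraction of
#'   the color wheel).
#' @return object of class `augmentation_transform`.
#' @export
augmentation <- function(kind, name = NULL, ...) {
  if (!kind %in% AUG_KINDS) {
    stop_invalid(sprintf("unknown augmentation kind '%s'", kind))
  }
  params <- list(...)
  if (is.null(name)) {
    suffix <- switch(kind,
      center_crop = params$margin, rotate = params$degrees,
      gaussian_blur = params$sigma, "")
    name <- if (identical(suffix, "")) kind else paste0(kind, "_", suffix)
  }
  structure(list(name = name, kind = kind, params = params),
            class = "augmentation_transform")
}

#' Apply one augmentation transform to an image
#'
#' Pure and deterministic; output always has the input (model) size:
#' crops are resized back bilinearly, rotations preserve size with
#' reflect fill.
#'
#' @param transform an `augmentation_transform`.
#' @param img H x W x 3 array in \[0, 1\].
#' @return transformed image of identical shape.
#' @export
apply_augmentation <- function(transform, img) {
  img <- check_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  p <- transform$params
  switch(transform$kind,
    center_crop = resize_bilinear(center_crop(img, p$margin), h, w),
    hflip = flip_horizontal(img),
    vflip = flip_vertical(img),
    rotate = rotate_image(img, p$degrees),
    gaussian_blur = gaussian_blur(img, p$sigma,
                                  size = if (is.null(p$size)) NULL else p$size),
    color_jitter = color_jitter(img,
      brightness = if (is.null(p$brightness)) 1 else p$brightness,
      contrast = if (is.null(p$contrast)) 1 else p$contrast,
      saturation = if (is.null(p$saturation)) 1 else p$saturation,
      hue = if (is.null(p$hue)) 0 else p$hue)
  )
}

#' Build an augmentation set from a list of transforms
#'
#' @param transforms list of `augmentation_transform` objects (possibly
#'   empty); names must be unique.
#' @return object of class `augmentation_set`.
#' @export
augmentation_set <- function(transforms = list()) {
  nm <- vapply(transforms, function(t) t$name, character(1))
  if (anyDuplicated(nm)) stop_invalid("augmentation names must be unique")
  structure(list(transforms = transforms), class = "augmentation_set")
}

#' @export
length.augmentation_set <- function(x) length(x$transforms)

#' @export
print.augmentation_set <- function(x, ...) {
  cat(sprintf("augmentation_set with %d transforms\n", length(x)))
  for (t in x$transforms) cat(" -", t$name, "\n")
  invisible(x)
}

#' Build the default 14-transform augmentation set
#'
#' Exactly, and in this order: 7 center crops with pixel margins 5, 8, 10,
#' 13, 15, 18, 20 (seven integers evenly spaced over \[5, 20\], resized back
#' to the input size), horizontal flip, vertical flip, rotations by +5, +10
#' and +20 degrees (reflect fill), one Gaussian blur (sigma 1.0, 5x5
#' kernel), and one deterministic color jitter (brightness x1.1, contrast
#' x0.9, saturation x1.1, hue +0.02 of the wheel).
#'
#' @param input_size model input side in pixels; must exceed twice the
#'   largest crop margin.
#' @return an `augmentation_set` of 14 transforms.
#' @export
build_default_augmentations <- function(input_size = 64) {
  margins <- c(5L, 8L, 10L, 13L, 15L, 18L, 20L)
  if (input_size <= 2 * max(margins)) {
    stop_invalid(sprintf(
      "input_size %d too small: need > %d for the largest crop margin",
      input_size, 2 * max(margins)))
  }
  tr <- c(
    lapply(margins, function(m) augmentation("center_crop", margin = m)),
    list(
      augmentation("hflip"),
      augmentation("vflip"),
      augmentation("rotate", degrees = 5),
      augmentation("rotate", degrees = 10),
      augmentation("rotate", degrees = 20),
      augmentation("gaussian_blur", sigma = 1.0, size = 5L),
      augmentation("color_jitter", brightness = 1.1, contrast = 0.9,
                   saturation = 1.1, hue = 0.02)
    )
  )
  augmentation_set(tr)
}

#' Apply test-time augmentation to an image
#'
#' Returns the original image followed by every augmented copy, in the
#' set's order: element 1 is the input itself (M_0), element i+1 is the
#' i-th transform applied to the input.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param augset an `augmentation_set`.
#' @return list of `length(augset) + 1` images.
#' @export
apply_tta <- function(image, augset) {
  image <- check_image(image)
  if (!inherits(augset, "augmentation_set")) {
    stop_invalid("augset must be an augmentation_set")
  }
  c(list(image),
    lapply(augset$transforms, function(t) apply_augmentation(t, image)))
}

#' Expand a labelled dataset with its augmented copies
#'
#' Appends every transform of every image to the dataset (originals first,
#' then all copies of image 1, image 2, ...), replicating labels. Used on
#' the training side so that the fitted classifier and the training
#' feature distribution have seen the same augmentation set that test-time
#' augmentation will apply — the premise that makes augmented test copies
#' in-distribution in the first place.
#'
#' @param dataset list with `images` and `labels` (and optionally other
#'   fields, which are preserved).
#' @param augset an `augmentation_set`.
#' @return the dataset with `(|A|+1) * n` images.
#' @export
augment_dataset <- function(dataset, augset) {
  if (length(augset) == 0) return(dataset)
  extra_imgs <- list()
  extra_labs <- integer()
  for (i in seq_along(dataset$images)) {
    tta <- apply_tta(dataset$images[[i]], augset)
    extra_imgs <- c(extra_imgs, tta[-1])
    extra_labs <- c(extra_labs, rep(dataset$labels[i], length(augset)))
  }
  dataset$images <- c(dataset$images, extra_imgs)
  dataset$labels <- c(dataset$labels, extra_labs)
  dataset
}

# --- config serialization -------------------------------------------------
# The augmentation set travels with the fitted filter model so inference
# always reuses the training-time A; a plain-list config keeps it JSON-safe.

#' Serialize an augmentation set to a plain-list config
#' @param augset an `augmentation_set`.
#' @return unclassed list (one entry per transform: name, kind, params).
#' @export
augset_to_config <- function(augset) {
  lapply(augset$transforms, function(t) {
    c(list(name = t$name, kind = t$kind), t$params)
  })
}

#' Rebuild an augmentation set from its config
#' @param config list as produced by [augset_to_config()].
#' @return an `augmentation_set`.
#' @export
config_to_augset <- function(config) {
  augmentation_set(lapply(config, function(e) {
    do.call(augmentation,
            c(list(kind = e$kind, name = e$name),
              e[setdiff(names(e), c("kind", "name"))]))
  }))
}
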