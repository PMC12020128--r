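# Synthetic pest scenes: seeded multi-object images with boxes and pixel
# masks. These stand in for field imagery so the whole pipeline (augmentation,
# dual-branch training, test-time adaptation, evaluation) can be exercised
# end-to-end without any external dataset.

#' Specification of a synthetic scene distribution
#'
#' Defines the study conditions under which scenes are drawn: image geometry,
#' number of pest classes, per-image object count and size ranges, background
#' texture, and the base seed. The same spec and seed always reproduce the
#' same scenes byte for byte.
#'
#' @param image_height,image_width image size in pixels
#' @param num_classes number of pest classes K (>= 2); class determines both
#'   the colour and the shape family of an object
#' @param objects_per_image integer range `c(lo, hi)`, `lo >= 0`
#' @param object_scale object diameter as a fraction of the shorter image
#'   side, range `c(lo, hi)` with `hi < 1`
#' @param background_texture one of `"flat"`, `"gradient"`, `"speckle"`
#' @param seed integer base seed
#' @return an object of class `scene_spec`
#' @export
scene_spec <- function(image_height = 64L, image_width = 64L,
                       num_classes = 3L,
                       objects_per_image = c(1L, 3L),
                       object_scale = c(0.15, 0.35),
                       background_texture = c("speckle", "flat", "gradient"),
                       seed = 1L) {
  background_texture <- match.arg(background_texture)
  stopifnot(image_height >= 8, image_width >= 8, num_classes >= 2,
            length(objects_per_image) == 2L,
            objects_per_image[1] >= 0,
            objects_per_image[1] <= objects_per_image[2],
            length(object_scale) == 2L, object_scale[1] > 0,
            object_scale[1] <= object_scale[2])
  if (object_scale[2] >= 1) {
    stop("object_scale upper bound must be < 1: objects may not exceed the image")
  }
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    num_classes = as.integer(num_classes),
    objects_per_image = as.integer(objects_per_image),
    object_scale = as.numeric(object_scale),
    background_texture = background_texture,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Construct a labeled scene record
#'
#' The universal sample record: an RGB image in `[0,1]`, half-open 0-based
#' pixel boxes, integer class ids in `[0, K)`, and an integer mask where 0 is
#' background and `c + 1` marks pixels of an object of class `c`.
#'
#' @param image H x W x 3 array, values in `[0,1]`
#' @param boxes n x 4 matrix, columns `xmin, ymin, xmax, ymax` (pixels,
#'   half-open, 0-based)
#' @param class_ids integer vector, length n
#' @param mask H x W integer matrix
#' @return an object of class `labeled_scene`
#' @export
labeled_scene <- function(image, boxes, class_ids, mask) {
  boxes <- matrix(as.numeric(boxes), ncol = 4L,
                  dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
  sc <- structure(list(image = image, boxes = boxes,
                       class_ids = as.integer(class_ids), mask = mask),
                  class = "labeled_scene")
  validate_scene(sc)
  sc
}

validate_scene <- function(scene) {
  stopifnot(inherits(scene, "labeled_scene"))
  d <- dim(scene$image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be H x W x 3")
  if (min(scene$image) < 0 || max(scene$image) > 1) {
    stop("image values must lie in [0, 1]")
  }
  H <- d[1]; W <- d[2]
  b <- scene$boxes
  if (nrow(b) != length(scene$class_ids)) {
    stop("boxes and class_ids lengths differ")
  }
  if (nrow(b) > 0) {
    ok <- b[, 1] >= 0 & b[, 1] < b[, 3] & b[, 3] <= W &
      b[, 2] >= 0 & b[, 2] < b[, 4] & b[, 4] <= H
    if (!all(ok)) stop("invalid box: need 0 <= min < max <= image extent")
  }
  if (!all(dim(scene$mask) == c(H, W))) stop("mask must be H x W")
  invisible(scene)
}

scene_dims <- function(scene) dim(scene$image)[1:2]

# fixed per-class palette: distinct hues, backgrounds stay grey/green-ish
class_palette <- function(K) {
  t(sapply(seq_len(K) - 1L, function(c) {
    grDevices::col2rgb(grDevices::hsv((c / K + 0.02) %% 1, 0.85, 0.9)) / 255
  }))
}

# membership of pixel centers in a shape; family cycles with class id
shape_member <- function(family, xc, yc, r, px, py, theta) {
  dx <- px - xc; dy <- py - yc
  rx <- cos(theta) * dx + sin(theta) * dy
  ry <- -sin(theta) * dx + cos(theta) * dy
  switch(family + 1L,
    (rx / r)^2 + (ry / (0.6 * r))^2 <= 1,                    # ellipse
    abs(rx) / r + abs(ry) / (0.8 * r) <= 1,                  # diamond
    abs(rx) <= r * 0.85 & abs(ry) <= r * 0.55                # bar
  )
}

draw_background <- function(spec) {
  H <- spec$image_height; W <- spec$image_width
  base <- switch(spec$background_texture,
    flat = array(rep(c(0.45, 0.52, 0.4), each = H * W), c(H, W, 3)),
    gradient = {
      gx <- matrix(rep(seq(0.3, 0.62, length.out = W), each = H), H, W)
      array(c(gx, gx * 0.95 + 0.05, gx * 0.85), c(H, W, 3))
    },
    speckle = {
      base <- array(rep(c(0.45, 0.52, 0.4), each = H * W), c(H, W, 3))
      base + array(stats::runif(H * W * 3, -0.06, 0.06), c(H, W, 3))
    })
  pmin(pmax(base, 0), 1)
}

#' Generate one synthetic scene
#'
#' Draws a background, places non-overlapping filled shapes (ellipse, diamond
#' or bar depending on class), and records tight boxes and a pixel mask that
#' are mutually consistent. Deterministic in `(spec, index)`.
#'
#' @param spec a [scene_spec()]
#' @param index scene index within the dataset (>= 0)
#' @return a [labeled_scene()]
#' @export
generate_scene <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_height; W <- spec$image_width
  pal <- class_palette(spec$num_classes)
  with_seed(derive_seed(spec$seed, "scene", index), {
    img <- draw_background(spec)
    mask <- matrix(0L, H, W)
    n_obj <- if (spec$objects_per_image[1] == spec$objects_per_image[2]) {
      spec$objects_per_image[1]
    } else {
      sample(spec$objects_per_image[1]:spec$objects_per_image[2], 1L)
    }
    boxes <- matrix(numeric(0), 0L, 4L)
    class_ids <- integer(0)
    # pixel centers
    py <- matrix(rep(seq_len(H) - 0.5, W), H, W)
    px <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
    placed <- matrix(numeric(0), 0L, 3L)  # xc, yc, r
    for (o in seq_len(n_obj)) {
      r <- stats::runif(1, spec$object_scale[1], spec$object_scale[2]) *
        min(H, W) / 2
      r <- max(r, 2)
      ok <- FALSE
      while (!ok && r >= 2) {
        for (try in 1:200) {
          xc <- stats::runif(1, r + 1, W - r - 1)
          yc <- stats::runif(1, r + 1, H - r - 1)
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - xc)^2 + (placed[, 2] - yc)^2) >
                  placed[, 3] + r + 2)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) r <- r * 0.8  # crowded image: shrink and retry
      }
      if (!ok) next
      cls <- sample.int(spec$num_classes, 1L) - 1L
      theta <- stats::runif(1, 0, pi)
      mem <- shape_member(cls %% 3L, xc, yc, r, px, py, theta)
      if (!any(mem)) next
      col <- pal[cls + 1L, ]
      shade <- 0.85 + 0.3 * ((py - yc) / (2 * r))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mem] <- pmin(pmax(col[ch] * shade[mem], 0), 1)
        img[, , ch] <- plane
      }
      mask[mem] <- cls + 2L - 1L  # cls + 1
      rows <- which(rowSums(mem) > 0)
      cols <- which(colSums(mem) > 0)
      boxes <- rbind(boxes, c(min(cols) - 1L, min(rows) - 1L,
                              max(cols), max(rows)))
      class_ids <- c(class_ids, cls)
      placed <- rbind(placed, c(xc, yc, r))
    }
    # quantize to the 8-bit grid so PNG round-trips are exact
    img <- round(img * 255) / 255
    labeled_scene(img, boxes, class_ids, mask)
  })
}

#' Generate a list of scenes
#'
#' @param spec a [scene_spec()]
#' @param n number of scenes (>= 1)
#' @return list of [labeled_scene()]
#' @export
generate_scenes <- function(spec, n) {
  stopifnot(n >= 1)
  lapply(seq_len(n) - 1L, function(i) generate_scene(spec, i))
}
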