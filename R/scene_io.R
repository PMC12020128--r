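# Disk formats: PNG images, single-channel PNG masks (pixel value = class
# index), YOLO-format label text (class cx cy w h, normalized, 6 decimals)
# and a COCO-style JSON (images / annotations / categories). Boxes are stored
# normalized only at the file boundary; in memory they are 0-based half-open
# pixel boxes.

#' Write YOLO-format labels
#'
#' One line per box: `class cx cy w h`, all normalized to `[0,1]`, 6 decimals.
#' @param boxes n x 4 pixel box matrix (`xmin, ymin, xmax, ymax`)
#' @param class_ids integer vector
#' @param width,height image size in pixels
#' @param path output file
#' @export
write_yolo_labels <- function(boxes, class_ids, width, height, path) {
  lines <- character(0)
  if (nrow(boxes) > 0) {
    cx <- (boxes[, 1] + boxes[, 3]) / 2 / width
    cy <- (boxes[, 2] + boxes[, 4]) / 2 / height
    w <- (boxes[, 3] - boxes[, 1]) / width
    h <- (boxes[, 4] - boxes[, 2]) / height
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", class_ids, cx, cy, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format labels back to pixel boxes
#'
#' @param path label file
#' @param width,height image size in pixels
#' @return list with `boxes` (pixel matrix) and `class_ids`
#' @export
read_yolo_labels <- function(path, width, height) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(list(boxes = matrix(numeric(0), 0L, 4L), class_ids = integer(0)))
  }
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  cx <- m[, 2] * width; cy <- m[, 3] * height
  w <- m[, 4] * width; h <- m[, 5] * height
  list(boxes = cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2),
       class_ids = as.integer(m[, 1]))
}

write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
}

coco_from_scenes <- function(scenes, file_names, num_classes) {
  ann <- list(); aid <- 0L
  images <- lapply(seq_along(scenes), function(i) {
    d <- dim(scenes[[i]]$image)
    list(id = i, file_name = file_names[i], width = d[2], height = d[1])
  })
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    for (j in seq_len(nrow(sc$boxes))) {
      aid <- aid + 1L
      b <- sc$boxes[j, ]
      ann[[aid]] <- list(
        id = aid, image_id = i, category_id = sc$class_ids[j] + 1L,
        bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
        area = (b[3] - b[1]) * (b[4] - b[2]), iscrowd = 0L)
    }
  }
  list(images = images, annotations = ann,
       categories = lapply(seq_len(num_classes), function(c) {
         list(id = c, name = paste0("pest_", c - 1L))
       }))
}

#' Generate a dataset on disk
#'
#' Writes `images/scene_####.png`, `labels/scene_####.txt` (YOLO),
#' `masks/scene_####.png`, and `annotations.json` (COCO-style), plus a
#' `manifest.json` with counts. The written files round-trip through
#' [read_scene_dataset()].
#'
#' @param spec a [scene_spec()]
#' @param n number of scenes (>= 1)
#' @param dir output directory (created if missing)
#' @return (invisibly) the list of generated [labeled_scene()]s
#' @export
generate_dataset <- function(spec, n, dir) {
  stopifnot(n >= 1)
  scenes <- generate_scenes(spec, n)
  for (sub in c("images", "labels", "masks")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  stem <- sprintf("scene_%04d", seq_len(n) - 1L)
  for (i in seq_len(n)) {
    sc <- scenes[[i]]
    png::writePNG(sc$image, file.path(dir, "images", paste0(stem[i], ".png")))
    write_yolo_labels(sc$boxes, sc$class_ids,
                      spec$image_width, spec$image_height,
                      file.path(dir, "labels", paste0(stem[i], ".txt")))
    write_mask_png(sc$mask, file.path(dir, "masks", paste0(stem[i], ".png")))
  }
  coco <- coco_from_scenes(scenes, paste0(stem, ".png"), spec$num_classes)
  jsonlite::write_json(coco, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(n_images = n, num_classes = spec$num_classes,
         image_height = spec$image_height, image_width = spec$image_width),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(scenes)
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param dir dataset directory
#' @return list of [labeled_scene()]
#' @export
read_scene_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  lapply(imgs, function(f) {
    stem <- sub("\\.png$", "", f)
    image <- png::readPNG(file.path(dir, "images", f))
    H <- dim(image)[1]; W <- dim(image)[2]
    lab <- read_yolo_labels(file.path(dir, "labels", paste0(stem, ".txt")), W, H)
    mask <- read_mask_png(file.path(dir, "masks", paste0(stem, ".png")))
    if (nrow(lab$boxes) > 0) {
      # guard against 6-decimal rounding nudging a box edge past the border
      lab$boxes[, c(1, 3)] <- pmin(pmax(lab$boxes[, c(1, 3)], 0), W)
      lab$boxes[, c(2, 4)] <- pmin(pmax(lab$boxes[, c(2, 4)], 0), H)
    }
    labeled_scene(image, lab$boxes, lab$class_ids, mask)
  })
}
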