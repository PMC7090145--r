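#' Colour classification rule for leaf-area segmentation
#'
#' A pixel is "leaf" when its green channel is bright enough and
#' dominates both red and blue; a pixel is "reference black" when every
#' channel is at most \code{black_max}. All thresholds act on 8-bit
#' (0-255) channels.
#'
#' @param min_green Minimum green channel value (default 60).
#' @param margin_r Minimum G - R dominance (default 20).
#' @param margin_b Minimum G - B dominance (default 20).
#' @param black_max Maximum per-channel intensity of reference pixels
#'   (default 60).
#' @return A \code{color_rule} list.
#' @export
color_rule <- function(min_green = 60, margin_r = 20, margin_b = 20,
                       black_max = 60) {
  stopifnot(min_green >= 0, min_green <= 255, margin_r >= 0, margin_b >= 0,
            black_max >= 0, black_max <= 255)
  structure(list(min_green = min_green, margin_r = margin_r,
                 margin_b = margin_b, black_max = black_max),
            class = "color_rule")
}

# Accepts a leaf_scene, an HxWx3 array (0-255 integers or 0-1 doubles),
# and rejects anything without 3 colour channels.
.as_rgb255 <- function(image) {
  if (inherits(image, "leaf_scene")) image <- image$image
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("expected an RGB image (H x W x 3 array); got ",
         paste(dim(image), collapse = "x"), call. = FALSE)
  }
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) <= 1) image <- image * 255
  image
}

#' Read a plant image from disk
#'
#' Supports PNG and TIFF (8-bit RGB). Returns the image as an
#' H x W x 3 array scaled to 0-255.
#' @param path Image file path.
#' @return Numeric H x W x 3 array.
#' @export
read_plant_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG and TIFF are supported)",
         call. = FALSE))
  .as_rgb255(img)
}

#' Segment green (leaf) pixels
#'
#' @param image RGB image (array or [render_leaf_scene()] scene).
#' @param rule A [color_rule()].
#' @return Logical H x W mask, TRUE where the pixel is classified leaf.
#' @export
segment_green <- function(image, rule = color_rule()) {
  img <- .as_rgb255(image)
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  G >= rule$min_green & (G - R) >= rule$margin_r & (G - B) >= rule$margin_b
}

#' Locate the 1 cm^2 black reference square
#'
#' Thresholds dark pixels, labels 4-connected components, and returns
#' the largest one. A square-ness guard rejects components whose
#' bounding-box fill ratio is below \code{min_fill} (shadows, wires);
#' this can be overridden with \code{force = TRUE}.
#'
#' @param image RGB image.
#' @param rule A [color_rule()].
#' @param min_fill Minimum bounding-box fill ratio (default 0.85).
#' @param force Accept the largest component even if it fails the guard.
#' @return List with \code{mask} (logical H x W) and \code{px_per_cm2}
#'   (its pixel count — the image-specific scale).
#' @export
find_reference_square <- function(image, rule = color_rule(),
                                  min_fill = 0.85, force = FALSE) {
  img <- .as_rgb255(image)
  black <- img[, , 1] <= rule$black_max & img[, , 2] <= rule$black_max &
    img[, , 3] <= rule$black_max
  if (!any(black)) stop("calibration failed: no black pixels found", call. = FALSE)
  lab <- EBImage::bwlabel(black)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  mask <- lab == best
  idx <- which(mask, arr.ind = TRUE)
  bbox <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  fill <- sizes[best] / bbox
  if (fill < min_fill && !force) {
    stop(sprintf(paste0("calibration failed: largest black component has ",
                        "bounding-box fill ratio %.2f < %.2f (not square-like); ",
                        "use force = TRUE to accept it"), fill, min_fill),
         call. = FALSE)
  }
  if (fill < min_fill) {
    warning(sprintf("accepting non-square reference component (fill %.2f)", fill))
  }
  list(mask = mask, px_per_cm2 = sizes[best])
}

#' Measure leaf area from an image
#'
#' The scale-free area measurement at the core of the image pipeline:
#' leaf area in cm^2 is the count of green pixels divided by the pixel
#' count of the in-frame 1 cm^2 black reference square. Because both
#' counts scale identically with resolution, the ratio is invariant to
#' uniform image rescaling (to within rasterisation error).
#'
#' @param image RGB image (array, scene, or file path).
#' @param rule A [color_rule()].
#' @param ... Passed to [find_reference_square()].
#' @return List: \code{area_cm2}, \code{green_px}, \code{ref_px}.
#' @export
measure_leaf_area <- function(image, rule = color_rule(), ...) {
  if (is.character(image)) image <- read_plant_image(image)
  green <- segment_green(image, rule)
  ref <- find_reference_square(image, rule, ...)
  green_px <- sum(green & !ref$mask)
  list(area_cm2 = green_px / ref$px_per_cm2,
       green_px = green_px, ref_px = ref$px_per_cm2)
}

# Filename convention: <plant>_<group>_day<NN>.<ext>, e.g. p03_salt_day07.png
.parse_scene_filename <- function(path) {
  b <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(b, regexec("^([A-Za-z0-9]+)_([A-Za-z0-9]+)_day(\\d+)$", b))[[1]]
  if (length(m) != 4) return(NULL)
  list(plant = m[2], group = m[3], day = as.integer(m[4]))
}

#' Measure leaf area for a batch of images
#'
#' Applies [measure_leaf_area()] to each file. Filenames must follow
#' \code{<plant>_<group>_day<NN>.<ext>}. Failures (unparseable names,
#' unreadable files, calibration errors) are recorded as error rows with
#' \code{status} holding the message — never silently dropped.
#'
#' @param paths Character vector of image paths (may be empty).
#' @param rule A [color_rule()].
#' @return Data frame with columns \code{plant}, \code{group},
#'   \code{day}, \code{area_cm2}, \code{green_px}, \code{ref_px},
#'   \code{status} ("ok" or the error message).
#' @export
batch_measure <- function(paths, rule = color_rule()) {
  empty <- data.frame(plant = character(), group = character(),
                      day = integer(), area_cm2 = numeric(),
                      green_px = integer(), ref_px = integer(),
                      status = character())
  if (length(paths) == 0) return(empty)
  rows <- lapply(paths, function(p) {
    meta <- .parse_scene_filename(p)
    if (is.null(meta)) {
      return(data.frame(plant = NA_character_, group = NA_character_,
                        day = NA_integer_, area_cm2 = NA_real_,
                        green_px = NA_integer_, ref_px = NA_integer_,
                        status = paste0("unparseable filename: ", basename(p))))
    }
    res <- tryCatch(measure_leaf_area(p, rule), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(plant = meta$plant, group = meta$group, day = meta$day,
                 area_cm2 = NA_real_, green_px = NA_integer_,
                 ref_px = NA_integer_, status = conditionMessage(res))
    } else {
      data.frame(plant = meta$plant, group = meta$group, day = meta$day,
                 area_cm2 = res$area_cm2, green_px = res$green_px,
                 ref_px = res$ref_px, status = "ok")
    }
  })
  do.call(rbind, rows)
}
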