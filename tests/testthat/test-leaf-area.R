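# assemble a plain RGB test image from scratch
blank_image <- function(h, w, rgb = c(255, 255, 255)) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

test_that("green segmentation is the documented channel predicate", {
  img <- blank_image(60, 80)
  expect_equal(sum(segment_green(img)), 0)         # all white
  img[10:39, 20:59, 1] <- 0; img[10:39, 20:59, 2] <- 180; img[10:39, 20:59, 3] <- 0
  mask <- segment_green(img)
  expect_equal(sum(mask), 30 * 40)
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] %in% 10:39))
  # non-RGB input is a format error
  expect_error(segment_green(matrix(0, 5, 5)), "RGB")
})

test_that("reference detection takes the largest square-like black component", {
  img <- blank_image(120, 120)
  img[30:79, 30:79, ] <- 0                          # 50x50 square
  ref <- find_reference_square(img)
  expect_equal(ref$px_per_cm2, 2500)
  # scattered 1-px black noise does not win
  set.seed(1)
  pts <- cbind(sample(1:120, 20), sample(c(1:25, 85:120), 20))
  for (i in 1:20) img[pts[i, 1], pts[i, 2], ] <- 0
  expect_equal(find_reference_square(img)$px_per_cm2, 2500)
  # a thin diagonal line fails the square-ness guard
  line <- blank_image(100, 100)
  for (i in 1:80) line[10 + i + 0:1, 10 + i, ] <- 0   # 2-px thick, 4-connected
  expect_error(find_reference_square(line), "fill ratio")
  expect_warning(res <- find_reference_square(line, force = TRUE), "non-square")
  expect_equal(res$px_per_cm2, 160)
  # no black pixels at all
  expect_error(find_reference_square(blank_image(10, 10)), "no black")
})

test_that("measured area is the green/reference pixel ratio", {
  img <- blank_image(150, 200)
  img[10:59, 10:59, ] <- 0                          # 2500-px reference
  img[80:129, 100:149, 1] <- 0                      # 2500-px green block
  img[80:129, 100:149, 2] <- 180
  img[80:129, 100:149, 3] <- 0
  expect_equal(measure_leaf_area(img)$area_cm2, 1.0)
  # zero green pixels -> 0 cm^2
  img2 <- blank_image(100, 100); img2[10:59, 10:59, ] <- 0
  expect_equal(measure_leaf_area(img2)$area_cm2, 0)
})

test_that("rendered scenes are measured within 1% of ground truth", {
  for (areas in list(c(2.5, 0.7), 1.0, c(0.5, 1.5, 3.0))) {
    sc <- render_leaf_scene(areas, px_per_cm = 40, seed = 17)
    m <- measure_leaf_area(sc)
    expect_lt(abs(m$area_cm2 - sc$truth$total_area_cm2) /
                sc$truth$total_area_cm2, 0.01)
    # segmentation agrees with the renderer's own mask
    expect_lt(abs(sum(segment_green(sc)) - sc$truth$green_px) /
                max(sc$truth$green_px, 1), 0.01)
  }
})

test_that("area measurement is invariant to doubling the resolution", {
  lo <- measure_leaf_area(render_leaf_scene(c(2.5, 0.7), 40, seed = 5))$area_cm2
  hi <- measure_leaf_area(render_leaf_scene(c(2.5, 0.7), 80, seed = 5))$area_cm2
  expect_lt(abs(hi - lo) / lo, 0.01)
})

test_that("adding green pixels never decreases the measured area", {
  sc <- render_leaf_scene(1.0, 40, seed = 8)
  base <- measure_leaf_area(sc)$area_cm2
  img <- sc$image
  bg <- which(!sc$green_mask & !sc$reference_mask, arr.ind = TRUE)
  for (k in c(5, 50, 500)) {
    img2 <- img
    sel <- bg[seq_len(k), , drop = FALSE]
    img2[cbind(sel, 1)] <- 0; img2[cbind(sel, 2)] <- 180; img2[cbind(sel, 3)] <- 0
    expect_gte(measure_leaf_area(img2)$area_cm2, base)
  }
})

test_that("batch measurement maps files, isolating failures per file", {
  expect_equal(nrow(batch_measure(character(0))), 0)
  dir <- withr::local_tempdir()
  areas <- list(p1 = 1.0, p2 = 2.0, p3 = 0.5)
  paths <- character(0)
  for (i in seq_along(areas)) {
    sc <- render_leaf_scene(areas[[i]], 40, seed = i)
    p <- file.path(dir, sprintf("p%d_control_day%02d.png", i, i))
    write_leaf_scene(sc, p)
    paths <- c(paths, p)
  }
  tab <- batch_measure(paths)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$status == "ok"))
  for (i in 1:3) {
    single <- measure_leaf_area(paths[i])$area_cm2
    expect_equal(tab$area_cm2[i], single)
    expect_equal(tab$day[i], i)
  }
  # one corrupt file: error recorded, others unaffected
  bad <- file.path(dir, "p9_salt_day01.png")
  writeLines("not a png", bad)
  unnamed <- file.path(dir, "oddname.png")
  file.copy(paths[1], unnamed)
  tab2 <- batch_measure(c(paths[1:2], bad, unnamed))
  expect_equal(sum(tab2$status == "ok"), 2)
  expect_equal(sum(tab2$status != "ok"), 2)
  expect_match(tab2$status[4], "unparseable")
})

test_that("PNG round-trip preserves the measured area", {
  sc <- render_leaf_scene(c(1.3, 0.6), 40, seed = 12)
  p <- withr::local_tempfile(fileext = ".png")
  write_leaf_scene(sc, p)
  expect_equal(measure_leaf_area(p)$area_cm2, measure_leaf_area(sc)$area_cm2)
})
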