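# Localization I/O, ROI geometry and rendering.

test_that("localization CSV round-trips and honours the dialect", {
  set.seed(11)
  locs <- localization_table("n7", "gH2AX",
                             x = runif(25, 0, 5000), y = runif(25, 0, 5000),
                             frame = sample.int(2000, 25))
  f <- withr::local_tempfile(fileext = ".csv")
  write_localizations(locs, f)
  back <- read_localizations(f, channel = "gH2AX", nucleus_id = "n7")
  expect_equal(nrow(back), nrow(locs))
  expect_equal(back$x, locs$x, tolerance = 1e-9)
  expect_equal(back$y, locs$y, tolerance = 1e-9)
  expect_identical(back$channel, locs$channel)
  expect_identical(back$frame, locs$frame)

  # pixel-unit dialect scales coordinates by the camera pixel size
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x [nm],y [nm]", "1,2", "3,4", "5,6"), f2)
  px <- read_localizations(
    f2, loc_dialect(unit = "pixel", pixel_size = 160)
  )
  expect_equal(px$x, c(1, 3, 5) * 160)
  expect_equal(px$y, c(2, 4, 6) * 160)
  nm <- read_localizations(f2)
  expect_equal(nm$x, c(1, 3, 5))
})

test_that("missing mapped columns and non-finite rows are handled", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x [nm],frame", "1,1"), f)
  expect_error(read_localizations(f), "'y \\[nm\\]'")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x [nm],y [nm]", "1,2", "NA,3", "4,5"), f2)
  expect_message(got <- read_localizations(f2), "dropped 1")
  expect_equal(nrow(got), 2L)
  expect_identical(attr(got, "n_dropped"), 1L)
})

test_that("ROI areas match their closed forms and degenerate ROIs error", {
  m <- roi_mask(matrix(TRUE, 100, 100), pixel_size = 20)
  expect_equal(roi_area(m), 4.0e6)
  p <- roi_polygon(rbind(c(0, 0), c(2000, 0), c(2000, 2000), c(0, 2000)))
  expect_equal(roi_area(p), 4.0e6)
  expect_error(roi_mask(matrix(FALSE, 10, 10), 20), "empty ROI")
  # bow-tie polygon self-intersects
  expect_error(
    roi_polygon(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
    "self-intersecting"
  )
})

test_that("raster and polygon ROIs survive a file round trip", {
  mask <- matrix(FALSE, 40, 40)
  mask[10:30, 5:35] <- TRUE
  roi <- roi_mask(mask, pixel_size = 20, nucleus_id = "m1")
  f <- withr::local_tempfile(fileext = ".tif")
  write_roi_mask(roi, f)
  back <- load_roi(f, pixel_size = 20)
  expect_equal(back$mask, roi$mask)
  expect_equal(roi_area(back), roi_area(roi))

  poly <- roi_polygon(rbind(c(0, 0), c(3000, 100), c(2500, 2800), c(100, 2000)))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_roi_polygon(poly, f2)
  back2 <- load_roi(f2)
  expect_equal(roi_area(back2), roi_area(poly))
})

test_that("rendering conserves in-ROI counts and respects pixel binning", {
  roi <- roi_rect(0, 0, 1000, 1000, "r")
  # five localizations inside one 20-nm pixel
  locs <- localization_table("r", "A", x = rep(105, 5) + c(0, 1, 2, 3, 4),
                             y = rep(210, 5))
  img <- render_localizations(locs, roi, pixel_size = 20)
  expect_equal(sum(img$grid), 5L)
  expect_equal(img$grid[11, 6], 5L) # floor(210/20)+1, floor(105/20)+1
  expect_equal(sum(img$grid == 0), length(img$grid) - 1L)

  empty <- localization_table(character(0), character(0), numeric(0), numeric(0))
  img0 <- render_localizations(empty, roi)
  expect_true(all(img0$grid == 0))
})

test_that("render conservation holds across random tables (mask oracle)", {
  set.seed(42)
  mask <- matrix(runif(30 * 30) > 0.3, 30, 30)
  mask[1, 1] <- TRUE
  roi <- roi_mask(mask, pixel_size = 50, nucleus_id = "m")
  for (i in 1:100) {
    n <- sample(0:300, 1)
    locs <- localization_table("m", "A",
                               x = runif(n, -100, 1600), y = runif(n, -100, 1600))
    # oracle: direct mask lookup per point
    ix <- floor(locs$x / 50) + 1
    iy <- floor(locs$y / 50) + 1
    ok <- which(ix >= 1 & ix <= 30 & iy >= 1 & iy <= 30)
    inside <- if (length(ok)) sum(mask[cbind(iy[ok], ix[ok])]) else 0L
    img <- suppressMessages(render_localizations(locs, roi, pixel_size = 20))
    expect_equal(sum(img$grid), inside)
  }
})

test_that("out-of-ROI filtering is deterministic and counted", {
  set.seed(5)
  roi <- roi_rect(0, 0, 500, 500, "r")
  locs <- localization_table("r", "A", runif(200, -100, 700), runif(200, -100, 700))
  a <- suppressMessages(filter_in_roi(locs, roi))
  b <- suppressMessages(filter_in_roi(locs, roi))
  expect_identical(a$x, b$x)
  expect_identical(attr(a, "n_dropped"), attr(b, "n_dropped"))
  expect_equal(nrow(a) + attr(a, "n_dropped"), 200L)
})

test_that("rendered 16-bit TIFF stores exact counts", {
  roi <- roi_rect(0, 0, 200, 200, "r")
  locs <- localization_table("r", "A", runif(50, 0, 200), runif(50, 0, 200))
  img <- render_localizations(locs, roi, pixel_size = 20)
  f <- withr::local_tempfile(fileext = ".tif")
  write_rendered_tiff(img, f)
  back <- round(tiff::readTIFF(f) * 65535)
  expect_equal(sum(back), 50)
})

test_that("convex-hull fallback ROI warns and contains its points", {
  set.seed(3)
  locs <- localization_table("n", "A", runif(100, 0, 1000), runif(100, 0, 1000))
  expect_warning(roi <- convex_hull_roi(locs), "non-canonical")
  expect_true(all(roi_contains(roi, locs$x, locs$y)))
})
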