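test_that("image stacks round-trip through TIFF with spacing and shape intact", {
  set.seed(42)
  vox <- array(sample(0:5000, 2 * 4 * 8 * 8, replace = TRUE),
               dim = c(2, 4, 8, 8))
  stk <- image_stack(vox, c(200, 80, 80),
                     list(channel_meta("RAD-51", 647),
                          channel_meta("MSH-5", 555)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stk, path)
  back <- read_stack(path, channels = stk$channels, spacing = c(200, 80, 80))
  expect_identical(dim(back$voxels), c(2L, 4L, 8L, 8L))
  expect_equal(back$voxels, vox, ignore_attr = TRUE)
  expect_equal(unname(back$spacing), c(200, 80, 80))
  expect_identical(channel_names(back), c("RAD-51", "MSH-5"))
})

test_that("a plane count not divisible by the declared channels is rejected", {
  vox <- array(1, dim = c(3, 1, 4, 4))
  stk <- image_stack(vox, c(200, 80, 80),
                     lapply(c("a", "b", "c"), channel_meta, emission_nm = 555))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stk, path)  # 3 planes on disk
  expect_error(read_stack(path, channels = c("a", "b"), spacing = c(200, 80, 80)),
               "channel/plane mismatch")
})

test_that("stack constructor enforces its invariants", {
  ok <- array(0, dim = c(1, 2, 3, 3))
  metas <- list(channel_meta("x", 555))
  expect_error(image_stack(ok, c(0, 80, 80), metas), "positive")
  expect_error(image_stack(ok, c(200, 80, 80), c(metas, metas)),
               "channel count")
  bad <- ok; bad[1, 1, 1, 1] <- -5
  expect_error(image_stack(bad, c(200, 80, 80), metas), "non-negative")
  expect_error(channel_meta("x", -1), "positive")
})

test_that("voxel-center physical coordinates invert exactly", {
  spacing <- c(125, 40, 40)
  vox <- matrix(c(0, 0, 0, 3, 7, 11, 2, 5, 9), ncol = 3, byrow = TRUE)
  nm <- vox_to_nm(vox, spacing)
  expect_equal(nm[1, ], c(62.5, 20, 20))  # voxel 0 sits at half a spacing
  expect_equal(nm_to_vox(nm, spacing), vox)
})

test_that("max projection equals the per-pixel maximum over z", {
  set.seed(7)
  vox <- array(runif(4 * 8 * 8, 0, 100), dim = c(1, 4, 8, 8))
  stk <- image_stack(vox, c(200, 80, 80), list(channel_meta("a", 555)))
  proj <- max_project(stk, "a")
  manual <- matrix(0, 8, 8)
  for (y in 1:8) for (x in 1:8) manual[y, x] <- max(vox[1, , y, x])
  expect_equal(proj, manual)
  # single-z stack projects to the identical plane
  one <- image_stack(array(vox[1, 1, , ], dim = c(1, 1, 8, 8)),
                     c(200, 80, 80), list(channel_meta("a", 555)))
  expect_equal(max_project(one, "a"), matrix(vox[1, 1, , ], 8, 8))
  expect_error(max_project(stk, "nope"), "unknown channel")
})

test_that("JSON ROIs round-trip and expose centroids", {
  rois <- list(nucleus_roi("r1", cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))),
               nucleus_roi("r2", cbind(c(20, 30, 25), c(0, 0, 9))))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_length(back, 2L)
  expect_identical(roi_ids(back), c("r1", "r2"))
  expect_equal(unname(back[[1]]$centroid_xy), c(5, 5))
  expect_equal(back[[2]]$xy, rois[[2]]$xy, ignore_attr = TRUE)
  # stability across re-reads
  again <- read_rois(path)
  expect_identical(roi_ids(again), roi_ids(back))
})

test_that("ImageJ .roi polygons are imported; non-polygon types are refused", {
  path <- withr::local_tempfile(fileext = ".roi")
  write_imagej_roi_fixture(path, xs = c(3, 13, 13, 3), ys = c(2, 2, 12, 12))
  rois <- read_rois(path)
  expect_length(rois, 1L)
  expect_equal(unname(rois[[1]]$centroid_xy), c(8, 7))
  bad <- withr::local_tempfile(fileext = ".roi")
  write_imagej_roi_fixture(bad, xs = c(0, 10, 10, 0), ys = c(0, 0, 8, 8),
                           type = 5L)  # line ROI
  expect_error(read_rois(bad), "unsupported ROI type")
})

test_that("degenerate and empty ROI inputs error", {
  expect_error(nucleus_roi("bad", cbind(c(0, 1), c(0, 1))), "3 vertices")
  expect_error(nucleus_roi("flat", cbind(c(0, 1, 2), c(0, 0, 0))),
               "degenerate")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(rois = list()), path)
  expect_error(read_rois(path), "empty")
})

test_that("detection tables round-trip losslessly through TSV", {
  df <- data.frame(
    focus_id = sprintf("f%02d", 1:5), species = "RAD-51",
    z_vox = c(0, 3, 7, 2, 9), y_vox = c(1, 4, 2, 8, 3),
    x_vox = c(5, 0, 6, 1, 2),
    z_nm = c(100, 700, 1500, 500, 1900) + 1 / 3,
    y_nm = sqrt(2) * (1:5), x_nm = pi * (1:5),
    peak_height = c(1000.25, 812.5, 1/ 7, 2000, 55.125),
    nucleus_id = c("n1", NA, "n2", "n1", NA),
    rel_position_pct = c(12.5, NA, 80 + 1 / 3, 12.5, NA),
    stringsAsFactors = FALSE)
  tab <- detection_table(df)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_detection_table(tab, path)
  back <- read_detection_table(path)
  expect_identical(as.data.frame(back), as.data.frame(tab))

  empty <- detection_table()
  write_detection_table(empty, path)
  back_empty <- read_detection_table(path)
  expect_identical(nrow(back_empty), 0L)
  expect_identical(names(back_empty), names(empty))
})

test_that("duplicate focus ids are rejected on construction and on read", {
  df <- data.frame(focus_id = c("a", "a"), species = "s",
                   z_vox = 0:1, y_vox = 0:1, x_vox = 0:1,
                   z_nm = c(100, 300), y_nm = c(40, 120), x_nm = c(40, 120),
                   peak_height = c(1, 2), stringsAsFactors = FALSE)
  expect_error(detection_table(df), "duplicate")
  good <- df; good$focus_id <- c("a", "b")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_detection_table(detection_table(good), path)
  lines <- readLines(path)
  lines[3] <- sub("^b\t", "a\t", lines[3])
  writeLines(lines, path)
  expect_error(read_detection_table(path), "duplicate")
})

test_that("OME physical sizes are parsed, nm and um units alike", {
  ome <- paste0(
    '<?xml version="1.0"?><OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels PhysicalSizeX="0.08" PhysicalSizeY="0.08"',
    ' PhysicalSizeZ="0.2" SizeX="8" SizeY="8"/></Image></OME>')
  sp <- gonadfoci:::parse_ome_spacing(ome)
  expect_equal(unname(sp), c(200, 80, 80))
  ome_nm <- sub('PhysicalSizeZ="0.2"',
                'PhysicalSizeZ="125" PhysicalSizeZUnit="nm"', ome)
  expect_equal(unname(gonadfoci:::parse_ome_spacing(ome_nm))[1], 125)
  expect_null(gonadfoci:::parse_ome_spacing("plain text description"))
})
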