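test_that("write/read round trip preserves volumes and metadata bit-exactly", {
  p <- skin_scene_params(n_depths = 6L, pixel_count_xy = 64L,
                         dej_depth_index = 3L, dej_window_len = 2L,
                         cell_count = 12L, seed = 5L)
  g <- generate_stack(p)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(g$stack, f)
  st2 <- read_stack(f)
  expect_identical(st2$shg, g$stack$shg)
  expect_identical(st2$thg, g$stack$thg)
  expect_identical(st2$meta, g$stack$meta)
  expect_identical(st2$dej_window, g$stack$dej_window)

  # paper-geometry metadata survives a round trip
  meta <- acquisition_meta(512L, 295, 1.8, 14L)
  tiny <- hgm_stack(array(10, c(8, 8, 2)), array(20, c(8, 8, 2)), meta)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(tiny, f2)
  m2 <- read_stack(f2)$meta
  expect_identical(m2$pixel_count_xy, 512L)
  expect_equal(m2$field_of_view_um, 295)
  expect_equal(m2$z_step_um, 1.8)
  expect_identical(m2$bit_depth, 14L)
})

test_that("channel order declaration controls volume assignment", {
  g <- generate_stack(small_params(3L))
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(g$stack, f1, channel_order = "shg_first")
  write_stack(g$stack, f2, channel_order = "thg_first")
  s1 <- read_stack(f1)
  s2 <- read_stack(f2)
  expect_identical(s1$shg, s2$shg)
  expect_identical(s1$thg, s2$thg)
  # swapping only the declaration swaps the volumes exactly
  meta_path <- paste0(f1, ".meta")
  txt <- readLines(meta_path)
  txt <- sub("channel_order=shg_first", "channel_order=thg_first", txt)
  raw <- thgratio:::read_tiff_pages(f1)
  f3 <- withr::local_tempfile(fileext = ".tif")
  thgratio:::write_tiff_pages(f3, raw$pages)   # no description
  writeLines(txt, paste0(f3, ".meta"))
  s3 <- read_stack(f3)
  expect_identical(s3$shg, s1$thg)
  expect_identical(s3$thg, s1$shg)
})

test_that("constant-THG file reads back with the constant mean", {
  st <- flat_stack(shg_val = 0, thg_val = 150)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, f)
  expect_equal(mean(read_stack(f)$thg), 150)
})

test_that("reader rejects malformed or inconsistent files", {
  expect_error(read_stack(file.path(tempdir(), "absent.tif")), "not found")
  # odd page count
  f <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(1L, 8, 8), matrix(2L, 8, 8), matrix(3L, 8, 8))
  thgratio:::write_tiff_pages(f, pages,
    description = "pixel_count_xy=8\nfield_of_view_um=4.6\nz_step_um=1.8\nbit_depth=14\nchannel_order=shg_first")
  expect_error(read_stack(f), "odd page count")
  # value above 2^14 - 1 under a 14-bit declaration
  f2 <- withr::local_tempfile(fileext = ".tif")
  thgratio:::write_tiff_pages(f2, list(matrix(20000L, 8, 8), matrix(0L, 8, 8)),
    description = "pixel_count_xy=8\nfield_of_view_um=4.6\nz_step_um=1.8\nbit_depth=14\nchannel_order=shg_first")
  expect_error(read_stack(f2), "bit_depth")
  # no description and no sidecar
  f3 <- withr::local_tempfile(fileext = ".tif")
  thgratio:::write_tiff_pages(f3, list(matrix(1L, 8, 8), matrix(2L, 8, 8)))
  expect_error(read_stack(f3), "no metadata")
})

test_that("distinct seeds produce files with different checksums", {
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(generate_stack(small_params(1L))$stack, f1, sidecar = FALSE)
  write_stack(generate_stack(small_params(2L))$stack, f2, sidecar = FALSE)
  sums <- tools::md5sum(c(f1, f2))
  expect_false(sums[[1]] == sums[[2]])
})

test_that("empty volumes are rejected at construction", {
  meta <- acquisition_meta(8L, 5, 1.8, 14L)
  expect_error(hgm_stack(array(0, c(8, 8, 0)), array(0, c(8, 8, 0)), meta),
               "empty")
  expect_error(hgm_stack(array(0, c(8, 8, 2)), array(0, c(8, 4, 2)), meta),
               "identical dimensions")
  expect_error(hgm_stack(array(20000, c(8, 8, 2)), array(0, c(8, 8, 2)), meta),
               "bit depth")
})

test_that("written TIFFs are readable by an independent reader (tifffile)", {
  f <- file.path(tempdir(), "oracle.tif")
  st <- flat_stack(shg_val = 321, thg_val = 1234, n = 16L, nd = 3L)
  write_stack(st, f)
  script <- paste0("import tifffile,sys; a=tifffile.imread(sys.argv[1]); ",
                   "print(a.shape[0], a.dtype, int(a[0].max()), int(a[1].max()))")
  out <- tryCatch(system2("python", c("-c", shQuote(script), shQuote(f)),
                          stdout = TRUE, stderr = TRUE),
                  warning = function(w) NULL, error = function(e) NULL)
  expect_false(is.null(out))
  expect_equal(out[length(out)], "6 uint16 321 1234")
})

test_that("pseudocolor rendering maps channels to green and magenta", {
  meta <- acquisition_meta(8L, 5, 1.8, 14L)
  shg_only <- hgm_stack(array(100, c(8, 8, 1)), array(0, c(8, 8, 1)), meta)
  img <- render_pseudocolor(shg_only, 1)
  expect_true(all(img[, , 2] == 1) && all(img[, , c(1, 3)] == 0))
  thg_only <- hgm_stack(array(0, c(8, 8, 1)), array(100, c(8, 8, 1)), meta)
  img2 <- render_pseudocolor(thg_only, 1)
  expect_true(all(img2[, , c(1, 3)] == 1) && all(img2[, , 2] == 0))
  dark <- hgm_stack(array(0, c(8, 8, 1)), array(0, c(8, 8, 1)), meta)
  expect_true(all(render_pseudocolor(dark, 1) == 0))
  expect_error(render_pseudocolor(dark, 2), "out of range")
})
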