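test_that("select_roi returns the bounding box of a solid suprathreshold block", {
  fr <- matrix(150, 512, 512)
  fr[101:400, 121:380] <- 2000
  roi <- select_roi(fr, threshold = 1600)
  expect_identical(unlist(roi[c("row_start", "row_end", "col_start", "col_end")],
                          use.names = FALSE), c(101L, 400L, 121L, 380L))
  expect_error(select_roi(matrix(150, 64, 64), threshold = 1600), "no ROI")
  expect_error(select_roi(fr, threshold = 0), "threshold")
})

test_that("select_roi excludes the vignetted border on a generated DEJ frame", {
  g <- generate_stack(small_params(1L))
  fr <- thg_frame(g$stack, g$truth$dej_frames[1])
  roi <- select_roi(fr)
  # every pixel outside the ROI is below threshold after cleanup
  cleaned <- thgratio:::majority3(fr > 1600)
  outside <- !thgratio:::rasterize_region(roi, dim(fr))
  lab <- thgratio:::label_components(cleaned)
  big <- which.max(tabulate(lab[lab > 0]))
  expect_equal(sum(outside & lab == big), 0)
  # idempotence: ROI of the crop never exceeds the crop
  crop <- fr[roi$row_start:roi$row_end, roi$col_start:roi$col_end]
  roi2 <- select_roi(crop)
  expect_lte(roi_area(roi2), roi_area(roi))
})

test_that("snr_at_threshold is the plain ratio and degree-0 homogeneous", {
  expect_equal(snr_at_threshold(1600, 150), 1600 / 150)
  expect_gte(snr_at_threshold(1600, 150), 10)
  expect_equal(snr_at_threshold(42, 42), 1)
  expect_equal(snr_at_threshold(1500, 150), 10)
  for (k in c(0.1, 2, 17)) {
    expect_equal(snr_at_threshold(k * 1600, k * 150),
                 snr_at_threshold(1600, 150))
  }
  expect_error(snr_at_threshold(1600, 0), "positive")
})

test_that("focus score detects blur, is zero on flat frames, gain-invariant", {
  expect_equal(focus_score(matrix(7, 32, 32)), 0)
  g <- generate_stack(small_params(2L))
  fr <- thg_frame(g$stack, g$truth$dej_frames[1])
  blurred <- thgratio:::gaussian_blur(fr, 8)
  expect_gt(focus_score(fr), focus_score(blurred))
  expect_equal(focus_score(2 * fr), focus_score(fr))
})

test_that("melanin piece detector fires on melanin caps only", {
  gm <- generate_stack(small_preset("melanin_containing", 3L))
  z <- gm$truth$dej_frames[1]
  expect_true(detect_melanin_pieces(thg_frame(gm$stack, z),
                                    gm$truth$cytoplasm_mask[, , z]))
  gp <- generate_stack(small_preset("paper_cohort", 3L))
  zp <- gp$truth$dej_frames[1]
  expect_false(detect_melanin_pieces(thg_frame(gp$stack, zp),
                                     gp$truth$cytoplasm_mask[, , zp]))
  # uniform cytoplasm: nothing exceeds twice the median
  fr <- matrix(1000, 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[20:40, 20:40] <- TRUE
  expect_false(detect_melanin_pieces(fr, mask))
  expect_error(detect_melanin_pieces(fr, matrix(FALSE, 64, 64)), "empty")
})

test_that("preview admits clean stacks and flags blurred/melanin ones", {
  suppressWarnings({
    pv_ok <- preview_stack(generate_stack(small_preset("paper_cohort", 4L))$stack,
                           noise_depth_index = 12L)
    pv_blur <- preview_stack(generate_stack(small_preset("blurred", 4L))$stack,
                             noise_depth_index = 12L)
    pv_mel <- preview_stack(generate_stack(small_preset("melanin_containing", 4L))$stack,
                            noise_depth_index = 12L)
  })
  expect_true(pv_ok$admitted)
  expect_true(pv_blur$blurred)
  expect_false(pv_blur$admitted)
  expect_false(pv_mel$admitted)
  expect_true(pv_mel$melanin_pieces || pv_mel$ratio_over_1p6)
  # invariant: admitted == !(any flag)
  for (pv in list(pv_ok, pv_blur, pv_mel)) {
    expect_identical(pv$admitted,
                     !(pv$blurred || pv$melanin_pieces || pv$ratio_over_1p6))
  }
})

test_that("screening boundaries are strict for coverage and inclusive for cells", {
  mk_stack <- function(n_supra) {
    shg <- matrix(150, 16, 16)
    if (n_supra > 0) shg[seq_len(n_supra)] <- 2000
    meta <- acquisition_meta(16L, 9.2, 1.8, 14L)
    hgm_stack(array(shg, c(16, 16, 1)), array(150, c(16, 16, 1)), meta)
  }
  roi <- rect_roi(1, 16, 1, 16)
  # coverage exactly 0.25 fails (strict), 12 cells, clear orientation
  sq <- screen_subimage(mk_stack(64), 1, roi, cell_count = 12,
                        orientation_coherence = 0.5)
  expect_equal(sq$shg_coverage_frac, 0.25)
  expect_false(sq$qualified)
  # coverage just above 0.25 with exactly 10 cells passes
  sq2 <- screen_subimage(mk_stack(67), 1, roi, cell_count = 10,
                         orientation_coherence = 0.5)
  expect_gt(sq2$shg_coverage_frac, 0.25)
  expect_true(sq2$qualified)
  # 9 cells fail even at high coverage
  sq3 <- screen_subimage(mk_stack(230), 1, roi, cell_count = 9,
                         orientation_coherence = 0.5)
  expect_false(sq3$qualified)
  # unclear orientation fails
  sq4 <- screen_subimage(mk_stack(67), 1, roi, cell_count = 12,
                         orientation_coherence = 0.1)
  expect_false(sq4$qualified)
})

test_that("screen coverage equals a brute-force pixel-count oracle on 16x16 frames", {
  meta <- acquisition_meta(16L, 9.2, 1.8, 14L)
  roi <- rect_roi(3, 14, 2, 15)
  set.seed(11)
  for (rep in 1:5) {
    shg <- matrix(sample(0:4000, 256, replace = TRUE), 16, 16)
    st <- hgm_stack(array(shg, c(16, 16, 1)), array(150, c(16, 16, 1)), meta)
    # oracle: direct double loop
    n_in <- 0L; n_hit <- 0L
    for (r in roi$row_start:roi$row_end) {
      for (cc in roi$col_start:roi$col_end) {
        n_in <- n_in + 1L
        if (shg[r, cc] > 1600) n_hit <- n_hit + 1L
      }
    }
    sq <- screen_subimage(st, 1, roi, 12, 0.5)
    expect_equal(sq$shg_coverage_frac, n_hit / n_in)
  }
})

test_that("qualify_stack needs three qualified subimages and is monotone", {
  mk <- function(q) structure(list(qualified = q), class = "subimage_qc")
  expect_true(qualify_stack(lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE), mk)))
  expect_false(qualify_stack(lapply(c(TRUE, TRUE, rep(FALSE, 8)), mk)))
  expect_false(qualify_stack(list()))
  set.seed(21)
  for (i in 1:20) {
    recs <- lapply(runif(sample(0:8, 1)) > 0.5, mk)
    before <- qualify_stack(recs)
    after <- qualify_stack(c(recs, list(mk(TRUE))))
    expect_true(!before || after)  # adding a qualified record never flips TRUE -> FALSE
  }
})
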