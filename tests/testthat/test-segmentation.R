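test_that("collagen segmentation: blank frames give empty masks, output stays suprathreshold", {
  roi <- rect_roi(5, 60, 5, 60)
  expect_equal(sum(segment_collagen(matrix(150, 64, 64), roi)), 0)
  g <- generate_stack(small_params(1L))
  z <- g$truth$dej_frames[1]
  sfr <- shg_frame(g$stack, z)
  roi2 <- select_roi(thg_frame(g$stack, z))
  mask <- segment_collagen(sfr, roi2)
  expect_gt(sum(mask), 0)
  expect_true(all(sfr[mask] > 1600))       # hard invariant
  expect_error(segment_collagen(sfr, rect_roi(1, 500, 1, 500)), "outside")
})

test_that("a single synthetic fiber is recovered with Dice >= 0.7", {
  g <- generate_stack(small_params(9L, fiber_count = 1L))
  z <- g$truth$dej_frames[1]
  truth <- g$truth$collagen_mask[, , z]
  expect_gt(sum(truth), 50)
  roi <- select_roi(thg_frame(g$stack, z))
  mask <- segment_collagen(shg_frame(g$stack, z), roi)
  expect_gte(dice_coef(mask, truth), 0.7)
})

test_that("exclusions subtract exactly and never add pixels", {
  mask <- matrix(FALSE, 64, 64)
  mask[10:40, 10:40] <- TRUE
  # empty list is the identity
  expect_identical(as.vector(apply_exclusions(mask, list())), as.vector(mask))
  # whole-frame exclusion empties the mask
  whole <- rect_roi(1, 64, 1, 64)
  expect_equal(sum(apply_exclusions(mask, list(whole))), 0)
  # a capillary-wall rectangle: area decreases exactly by the overlap
  capillary <- rect_roi(30, 50, 35, 55)
  out <- apply_exclusions(mask, list(capillary))
  overlap <- sum(mask & thgratio:::rasterize_region(capillary, dim(mask)))
  expect_gt(overlap, 0)
  expect_equal(sum(out), sum(mask) - overlap)
  expect_equal(attr(out, "excluded_frac"), overlap / sum(mask))
  # monotonicity over random region lists
  set.seed(31)
  for (i in 1:10) {
    rois <- lapply(1:3, function(j) {
      r0 <- sample(1:50, 1); c0 <- sample(1:50, 1)
      rect_roi(r0, r0 + sample(3:12, 1), c0, c0 + sample(3:12, 1))
    })
    out_i <- apply_exclusions(mask, rois)
    expect_true(all(!out_i | mask))
  }
  expect_error(apply_exclusions(mask, list(rect_roi(60, 70, 1, 5))), "outside")
})

test_that("manual cytoplasm selection takes unions without double counting", {
  # vertices on pixel edges (half-integer): 20 x 10 = 200 px each
  poly1 <- cbind(c(9.5, 9.5, 29.5, 29.5), c(9.5, 19.5, 19.5, 9.5))
  poly2 <- cbind(c(39.5, 39.5, 59.5, 59.5), c(29.5, 39.5, 39.5, 29.5))
  m <- manual_select_cytoplasm(list(poly1, poly2), c(64, 64))
  expect_equal(sum(m), 400)
  expect_identical(attr(m, "provenance"), "manual")
  # overlapping polygons: union, not sum
  poly3 <- cbind(c(9.5, 9.5, 29.5, 29.5), c(14.5, 24.5, 24.5, 14.5))
  m2 <- manual_select_cytoplasm(list(poly1, poly3), c(64, 64))
  expect_lt(sum(m2), 400)
  expect_equal(sum(m2), sum(thgratio:::rasterize_region(poly1, c(64, 64)) |
                              thgratio:::rasterize_region(poly3, c(64, 64))))
  expect_error(manual_select_cytoplasm(list(), c(64, 64)), "at least one")
})

test_that("one bright cell with a dark nucleus yields exactly one labeled cell", {
  sc <- single_cell_frame()
  roi <- rect_roi(1, nrow(sc$frame), 1, ncol(sc$frame))
  masks <- segment_cells(sc$frame, roi)
  expect_equal(count_cells(masks), 1)
  expect_gt(sum(masks$nucleus), 0)
  # nucleus strictly inside the cell
  expect_true(all(masks$cell_labels[masks$nucleus] == 1))
  expect_gte(dice_coef(masks$cytoplasm, sc$cytoplasm), 0.8)
  # blank frame: zero cells, not an error
  expect_equal(count_cells(segment_cells(matrix(150, 96, 96), roi)), 0)
})

test_that("DEJ mosaic segmentation recovers cells and cytoplasm against truth", {
  g <- generate_stack(skin_preset("paper_cohort", 5))
  z <- g$truth$dej_frames[1]
  fr <- thg_frame(g$stack, z)
  roi <- select_roi(fr)
  masks <- segment_cells(fr, roi)
  collagen <- segment_collagen(shg_frame(g$stack, z), roi)
  masks$cytoplasm <- masks$cytoplasm & !collagen
  # count within +/-30% of the truth cells interior to the ROI
  in_roi <- thgratio:::rasterize_region(roi, dim(fr))
  labs <- g$truth$cell_labels
  border_labs <- unique(labs[thgratio:::dilate3(!in_roi)])
  interior <- setdiff(unique(labs[in_roi]), c(0L, border_labs))
  n_truth <- length(interior)
  expect_gt(n_truth, 0)
  n_seg <- count_cells(masks)
  expect_lt(abs(n_seg / n_truth - 1), 0.3)
  expect_gte(dice_coef(masks$cytoplasm, g$truth$cytoplasm_mask[, , z]), 0.6)
  # determinism
  masks2 <- segment_cells(fr, roi)
  expect_identical(masks$cell_labels, masks2$cell_labels)
})

test_that("excluding whole cells reduces the count by exactly that many", {
  g <- generate_stack(small_params(5L))
  z <- g$truth$dej_frames[1]
  fr <- thg_frame(g$stack, z)
  masks <- segment_cells(fr, select_roi(fr))
  n0 <- count_cells(masks)
  expect_gte(n0, 4)
  victims <- sort(unique(masks$cell_labels[masks$cell_labels > 0]))[1:3]
  excl <- matrix(masks$cell_labels %in% victims, nrow(fr), ncol(fr))
  masks$cytoplasm <- apply_exclusions(masks$cytoplasm, list(excl))
  expect_equal(count_cells(masks), n0 - 3)
})

test_that("cytoplasm-mask mean THG recovers the configured expectation within 3%", {
  # acquisition-scale cohort preset: the vignette falloff ring is then a
  # small fraction of the ROI, as in the imaging geometry being emulated
  means <- vapply(1:10, function(s) {
    g <- generate_stack(skin_preset("paper_cohort", s))
    z <- g$truth$dej_frames[1]
    fr <- thg_frame(g$stack, z)
    roi <- select_roi(fr)
    masks <- segment_cells(fr, roi)
    cyto <- masks$cytoplasm & !segment_collagen(shg_frame(g$stack, z), roi)
    mean(fr[cyto])
  }, numeric(1))
  expect_lt(abs(mean(means) / 1809 - 1), 0.03)
})

test_that("orientation coherence separates oriented fibers from isotropy", {
  # single straight fiber: near-perfect orientation
  fr <- matrix(150, 96, 96)
  fr[46:50, ] <- 3000
  mask <- fr > 1600
  expect_gt(orientation_coherence(fr, mask), 0.8)
  # isotropic noise: low mean coherence over 10 seeds
  set.seed(41)
  coh <- vapply(1:10, function(i) {
    nf <- matrix(rnorm(96 * 96, 1000, 200), 96, 96)
    orientation_coherence(nf, matrix(TRUE, 96, 96))
  }, numeric(1))
  expect_lt(mean(coh), 0.2)
  # 90-degree rotation leaves coherence unchanged
  g <- generate_stack(small_params(3L))
  z <- g$truth$dej_frames[1]
  sfr <- shg_frame(g$stack, z)
  m <- sfr > 1600
  rot <- function(m) t(m)[, nrow(m):1]
  expect_equal(orientation_coherence(rot(sfr), rot(m)),
               orientation_coherence(sfr, m), tolerance = 1e-6)
  expect_error(orientation_coherence(sfr, matrix(FALSE, 128, 128)), "small")
})
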