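# Previewing, ROI-selecting and screening phases: decide which stacks and
# which subimages enter the ratio computation.

#' Rectangular region of interest
#'
#' 1-based inclusive pixel bounds of the analysis window on a frame.
#'
#' @param row_start,row_end,col_start,col_end inclusive 1-based bounds.
#' @return an object of class `rect_roi`.
#' @export
rect_roi <- function(row_start, row_end, col_start, col_end) {
  stopifnot(row_start >= 1, col_start >= 1,
            row_end >= row_start, col_end >= col_start)
  structure(list(row_start = as.integer(row_start), row_end = as.integer(row_end),
                 col_start = as.integer(col_start), col_end = as.integer(col_end)),
            class = "rect_roi")
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("ROI rows %d..%d x cols %d..%d (%d px)\n", x$row_start,
              x$row_end, x$col_start, x$col_end, roi_area(x)))
  invisible(x)
}

#' @rdname rect_roi
#' @param roi a `rect_roi`.
#' @export
roi_area <- function(roi) {
  (roi$row_end - roi$row_start + 1L) * (roi$col_end - roi$col_start + 1L)
}

# Crop a matrix to an ROI, with bounds checking.
crop_roi <- function(frame, roi) {
  if (roi$row_end > nrow(frame) || roi$col_end > ncol(frame))
    stop("ROI outside frame")
  frame[roi$row_start:roi$row_end, roi$col_start:roi$col_end, drop = FALSE]
}

# Paste a cropped matrix back into frame coordinates (zero/FALSE elsewhere).
uncrop_roi <- function(crop, roi, dm) {
  out <- if (is.logical(crop)) matrix(FALSE, dm[1], dm[2]) else matrix(0, dm[1], dm[2])
  out[roi$row_start:roi$row_end, roi$col_start:roi$col_end] <- crop
  out
}

#' Select the rectangular ROI by intensity thresholding
#'
#' Vignetting makes frames dim toward the scan border, where photomultiplier
#' noise dominates. Only pixels with sufficient SNR are analysed: the ROI is
#' the axis-aligned bounding rectangle of the largest 8-connected component
#' of suprathreshold pixels, after a 3x3 majority vote that removes isolated
#' hot pixels and bridges 1-pixel dark membrane lines. With
#' `method = "otsu"` the threshold is first computed from the frame
#' histogram instead of the fixed default.
#'
#' @param frame 2-D intensity image (THG at the basal-layer depth).
#' @param threshold grayscale threshold (default 1600, which gives SNR
#'   ~10.7 over a noise floor of ~150).
#' @param method `"fixed"` or `"otsu"`.
#' @return a [rect_roi()].
#' @export
select_roi <- function(frame, threshold = 1600, method = c("fixed", "otsu")) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame), length(frame) > 0)
  if (method == "otsu") {
    threshold <- otsu_threshold(frame)
  } else {
    if (threshold <= 0 || threshold > 16383)
      stop("fixed threshold must lie in (0, 16383]")
  }
  supra <- frame > threshold
  if (!any(supra))
    stop("no ROI: no pixel above threshold ", format(threshold))
  cleaned <- majority3(supra)
  if (!any(cleaned)) cleaned <- supra   # degenerate tiny inputs
  lab <- label_components(cleaned, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- which.max(sizes)
  px <- which(lab == biggest, arr.ind = TRUE)
  rect_roi(min(px[, 1]), max(px[, 1]), min(px[, 2]), max(px[, 2]))
}

#' Signal-to-noise ratio implied by a threshold
#'
#' The ratio of an intensity threshold to the dark-region noise mean; an SNR
#' of at least 10 is desired when choosing analysis thresholds.
#'
#' @param threshold grayscale threshold.
#' @param noise_mean mean grayscale of uniformly dark regions.
#' @return dimensionless SNR.
#' @export
snr_at_threshold <- function(threshold, noise_mean) {
  if (noise_mean <= 0) stop("noise_mean must be positive")
  threshold / noise_mean
}

#' Focus score of a frame
#'
#' Variance of the discrete Laplacian normalised by the squared frame mean;
#' higher is sharper, a constant frame scores 0, and the score is invariant
#' under a global intensity gain. Used to operationalise the "too blurred to
#' recognise basal-cell outlines" preview exclusion.
#'
#' @param frame 2-D intensity image, at least 8x8.
#' @return dimensionless sharpness score.
#' @export
focus_score <- function(frame) {
  stopifnot(is.matrix(frame), nrow(frame) >= 8, ncol(frame) >= 8)
  m <- mean(frame)
  if (m == 0 || stats::sd(frame) == 0) return(0)
  nr <- nrow(frame); nc <- ncol(frame)
  inner <- frame[2:(nr - 1), 2:(nc - 1)]
  lap <- frame[1:(nr - 2), 2:(nc - 1)] + frame[3:nr, 2:(nc - 1)] +
    frame[2:(nr - 1), 1:(nc - 2)] + frame[2:(nr - 1), 3:nc] - 4 * inner
  stats::var(as.vector(lap)) / m^2
}

#' Detect THG-bright melanin pieces among basal cells
#'
#' Melanin accumulations appear as small very bright THG blobs inside or
#' adjacent to basal-cell cytoplasm. The detector flags the frame when any
#' connected blob of at least `min_blob_px` pixels, inside or adjacent to
#' the cytoplasm mask, exceeds `factor` times the cytoplasm median
#' intensity.
#'
#' @param frame 2-D THG intensity image.
#' @param cytoplasm_mask logical mask of cytoplasm pixels (nonempty).
#' @param min_blob_px minimum blob size in pixels.
#' @param factor brightness multiple of the cytoplasm median.
#' @return logical flag.
#' @export
detect_melanin_pieces <- function(frame, cytoplasm_mask, min_blob_px = 20L,
                                  factor = 2) {
  stopifnot(is.matrix(frame), identical(dim(frame), dim(cytoplasm_mask)))
  if (!any(cytoplasm_mask)) stop("empty cytoplasm mask")
  med <- stats::median(frame[cytoplasm_mask])
  bright <- frame > factor * med
  # "inside or adjacent": within ~3 px of cytoplasm, so a compact melanin cap
  # excluded from the mask itself is still fully covered
  near_cyto <- dilate3(dilate3(dilate3(cytoplasm_mask)))
  cand <- bright & near_cyto
  if (!any(cand)) return(FALSE)
  lab <- label_components(cand, connectivity = 8L)
  any(tabulate(lab[lab > 0L]) >= min_blob_px)
}

#' Preview a stack at the dermal-epidermal junction
#'
#' First-phase coarse filter, applied before any segmentation: a stack is
#' not analysed when (1) its DEJ frames are too blurred to make out cell
#' outlines, (2) THG-bright melanin pieces are visible among basal cells, or
#' (3) a provisional cytoplasm/collagen brightness ratio exceeds the
#' phototype-I value of 1.6, either of which suggests melanin. The
#' provisional ratio uses threshold-derived proxy masks (THG-bright,
#' SHG-dark pixels as cytoplasm; SHG-bright pixels as collagen) without any
#' manual exclusion.
#'
#' @param stack an [hgm_stack()].
#' @param dej_frames depth indices spanning the DEJ (defaults to the stack's
#'   recorded window).
#' @param focus_floor admission floor for [focus_score()].
#' @param roi_threshold grayscale threshold for the proxy masks.
#' @param melanin_ratio_cutoff provisional-ratio exclusion cutoff.
#' @param noise_depth_index deep frame used for the provisional noise value.
#' @return an object of class `preview_decision` with flags `blurred`,
#'   `melanin_pieces`, `ratio_over_1p6`, `admitted`, the mean `focus_score`,
#'   the provisional ratio and free-text `notes`.
#' @export
preview_stack <- function(stack, dej_frames = stack$dej_window,
                          focus_floor = 0.055, roi_threshold = 1600,
                          melanin_ratio_cutoff = 1.6,
                          noise_depth_index = 80L) {
  stopifnot(inherits(stack, "hgm_stack"))
  if (n_depths(stack) == 0L) stop("empty stack")
  if (is.null(dej_frames) || length(dej_frames) == 0L)
    stop("dej_frames must be supplied (or recorded in the stack)")
  notes <- character()
  fs <- vapply(dej_frames, function(z) focus_score(thg_frame(stack, z)),
               numeric(1))
  blurred <- mean(fs) < focus_floor
  melanin <- FALSE
  ratio_over <- FALSE
  prov_ratio <- NA_real_
  if (!blurred) {
    roi <- tryCatch(select_roi(thg_frame(stack, dej_frames[1]),
                               threshold = roi_threshold),
                    error = function(e) NULL)
    if (is.null(roi)) {
      notes <- c(notes, "no suprathreshold ROI at the DEJ")
    } else {
      noise <- tryCatch(estimate_noise(stack, roi, noise_depth_index),
                        error = function(e) NA_real_)
      ratios <- c()
      for (z in dej_frames) {
        tfr <- thg_frame(stack, z)
        sfr <- shg_frame(stack, z)
        in_roi <- rasterize_region(roi, dim(tfr))
        cyto_proxy <- in_roi & tfr > roi_threshold & sfr <= roi_threshold
        col_proxy <- in_roi & sfr > roi_threshold
        if (any(cyto_proxy)) {
          if (detect_melanin_pieces(tfr, cyto_proxy)) melanin <- TRUE
        }
        if (any(cyto_proxy) && any(col_proxy) && is.finite(noise)) {
          num <- mean(tfr[cyto_proxy]) - noise
          den <- mean(tfr[col_proxy]) - noise
          if (den > 0) ratios <- c(ratios, num / den)
        }
      }
      if (length(ratios)) {
        prov_ratio <- mean(ratios)
        ratio_over <- prov_ratio > melanin_ratio_cutoff
      } else notes <- c(notes, "provisional ratio not computable")
    }
  } else {
    notes <- c(notes, sprintf("focus %.4g below floor %.4g", mean(fs), focus_floor))
  }
  structure(list(blurred = blurred, melanin_pieces = melanin,
                 ratio_over_1p6 = ratio_over,
                 admitted = !(blurred || melanin || ratio_over),
                 focus_score = mean(fs), provisional_ratio = prov_ratio,
                 notes = paste(notes, collapse = "; ")),
            class = "preview_decision")
}

#' @export
print.preview_decision <- function(x, ...) {
  cat(sprintf("preview: %s (blurred=%s, melanin=%s, ratio>1.6=%s, focus=%.3g)\n",
              if (x$admitted) "admitted" else "excluded", x$blurred,
              x$melanin_pieces, x$ratio_over_1p6, x$focus_score))
  if (nzchar(x$notes)) cat(" notes:", x$notes, "\n")
  invisible(x)
}

#' Screen one subimage for qualification
#'
#' A DEJ subimage qualifies for the ratio computation when (1) SHG
#' intensities above `shg_threshold` occupy strictly more than
#' `coverage_min` of the ROI area, (2) the collagen fibers are clear enough
#' to see their orientation (structure-tensor coherence at or above
#' `coherence_floor`), and (3) at least `min_cells` distinguishable basal
#' cells were segmented in the ROI.
#'
#' @param stack an [hgm_stack()].
#' @param depth_index 1-based depth index.
#' @param roi a [rect_roi()].
#' @param cell_count number of segmented basal cells (from [count_cells()]).
#' @param orientation_coherence fiber orientation coherence in `[0, 1]`
#'   (from [orientation_coherence()]).
#' @param shg_threshold grayscale threshold for collagen coverage.
#' @param coverage_min strict lower bound on the covered ROI fraction.
#' @param coherence_floor minimum coherence counted as a clear orientation.
#' @param min_cells minimum basal-cell count (inclusive).
#' @return an object of class `subimage_qc` (also a one-row list usable as a
#'   data.frame row) with fields `depth_index`, `shg_coverage_frac`,
#'   `orientation_clear`, `cell_count`, `qualified`.
#' @export
screen_subimage <- function(stack, depth_index, roi, cell_count,
                            orientation_coherence, shg_threshold = 1600,
                            coverage_min = 0.25, coherence_floor = 0.3,
                            min_cells = 10L) {
  .check_depth(stack, depth_index)
  sfr <- shg_frame(stack, depth_index)
  crop <- crop_roi(sfr, roi)
  coverage <- mean(crop > shg_threshold)
  orientation_clear <- is.finite(orientation_coherence) &&
    orientation_coherence >= coherence_floor
  qualified <- (coverage > coverage_min) && orientation_clear &&
    (cell_count >= min_cells)
  structure(list(depth_index = as.integer(depth_index),
                 shg_coverage_frac = coverage,
                 orientation_clear = orientation_clear,
                 cell_count = as.integer(cell_count),
                 qualified = qualified),
            class = "subimage_qc")
}

#' Does a stack have enough qualified subimages?
#'
#' A stack is counted into the final results only if it has at least three
#' qualified subimages.
#'
#' @param qc_records list of `subimage_qc` records (possibly empty), or a
#'   data.frame with a logical `qualified` column.
#' @param min_qualified required number of qualified subimages.
#' @return logical.
#' @export
qualify_stack <- function(qc_records, min_qualified = 3L) {
  q <- if (is.data.frame(qc_records)) qc_records$qualified
  else vapply(qc_records, function(r) isTRUE(r$qualified), logical(1))
  sum(q) >= min_qualified
}
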