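# Processing-phase segmentation: collagen fibers from SHG, basal-cell
# cytoplasm and nuclei from THG, with declarative exclusion regions standing
# in for the interactive edits of the original protocol.

#' Segment collagen fibers from an SHG frame
#'
#' Within the ROI, keeps pixels that are both suprathreshold
#' (`SHG > threshold`) and ridge-like (single-scale Frangi-style tubular
#' response above its Otsu cut over the suprathreshold set), then closes
#' 1-pixel gaps, re-intersects with the suprathreshold set (the output never
#' contains sub-threshold pixels) and removes components smaller than
#' `min_size` pixels. Empty outside the ROI.
#'
#' @param shg_frame 2-D SHG intensity image.
#' @param roi a [rect_roi()].
#' @param threshold grayscale threshold (default 1600).
#' @param min_size minimum fiber component size in pixels (default 30 at
#'   the 295/512 um/px scale).
#' @param ridge_sigma scale (pixels) of the ridge filter.
#' @return logical fiber mask, full frame size.
#' @export
segment_collagen <- function(shg_frame, roi, threshold = 1600, min_size = 30L,
                             ridge_sigma = 2) {
  crop <- crop_roi(shg_frame, roi)
  supra <- crop > threshold
  if (!any(supra))
    return(matrix(FALSE, nrow(shg_frame), ncol(shg_frame)))
  resp <- ridge_response(crop, sigma = ridge_sigma)
  # Otsu over the whole ROI response separates background from fiber ridges.
  # The response peaks on fiber cores and rolls off at tube edges, so the
  # cores are dilated back over the suprathreshold set to recover the full
  # tube width without admitting non-ridge bright blobs.
  cut <- if (length(unique(as.numeric(resp))) > 1L) otsu_threshold(resp) else -Inf
  core <- supra & resp > cut
  mask <- dilate3(dilate3(core)) & supra
  mask <- close3(mask) & supra
  lab <- label_components(mask, connectivity = 8L)
  if (max(lab) > 0L) {
    keep <- which(tabulate(lab[lab > 0L]) >= min_size)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
  }
  uncrop_roi(mask, roi, dim(shg_frame))
}

#' Remove exclusion regions from a mask
#'
#' Declarative replacement for the protocol's manual removal of regions
#' covering signals not induced by collagen fibers (basal cells,
#' fibroblasts, red blood cells, capillary walls, lipid). Never adds pixels.
#'
#' @param mask logical image.
#' @param exclusions list of region specifications: [rect_roi()] objects,
#'   `n x 2` polygon vertex matrices of (row, col), logical masks, or
#'   `list(rows=, cols=)` index pairs.
#' @return the mask minus the union of the exclusion regions, with the
#'   excluded-area fraction attached as attribute `excluded_frac`.
#' @export
apply_exclusions <- function(mask, exclusions = list()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (length(exclusions) == 0L) {
    attr(mask, "excluded_frac") <- 0
    return(mask)
  }
  excl <- matrix(FALSE, nrow(mask), ncol(mask))
  for (rg in exclusions) excl <- excl | rasterize_region(rg, dim(mask))
  out <- mask & !excl
  attr(out, "excluded_frac") <-
    if (any(mask)) sum(mask & excl) / sum(mask) else 0
  out
}

#' Segment basal-cell cytoplasm and nuclei from a THG frame
#'
#' Within the ROI: light Gaussian smoothing, Otsu foreground extraction,
#' hole filling (nuclei are dark holes in the bright cytoplasm), then
#' distance-transform watershed to split touching cells, with seeds taken
#' from smoothed distance maxima at a minimum separation of half the
#' expected cell diameter. Inside each cell the nucleus is the interior
#' dark basin: pixels below the cell's own Otsu cut (per-cell relative
#' thresholding — vignetting makes a global dark cut unusable), in
#' components of at least `min_nucleus_px` pixels that do not touch the
#' cell boundary. Cytoplasm is the cell minus its nuclei. Components
#' touching the ROI border or smaller than `min_cell_px` are dropped.
#' Deterministic given the frame.
#'
#' @param thg_frame 2-D THG intensity image.
#' @param roi a [rect_roi()].
#' @param cell_diameter_px expected cell diameter in pixels.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels.
#' @param min_cell_px minimum cell area.
#' @param min_nucleus_px minimum nucleus area.
#' @return an object of class `segmentation_masks`: logical `cytoplasm`,
#'   `nucleus`, `excluded` images, integer `cell_labels` (0 = background),
#'   and an empty `collagen` slot to be filled by [segment_collagen()].
#' @export
segment_cells <- function(thg_frame, roi, cell_diameter_px = 21,
                          smooth_sigma = 1, min_cell_px = 100L,
                          min_nucleus_px = 15L) {
  dm <- dim(thg_frame)
  crop <- crop_roi(thg_frame, roi)
  sm <- gaussian_blur(crop, smooth_sigma)
  empty <- function() {
    structure(list(collagen = matrix(FALSE, dm[1], dm[2]),
                   cytoplasm = matrix(FALSE, dm[1], dm[2]),
                   nucleus = matrix(FALSE, dm[1], dm[2]),
                   excluded = matrix(FALSE, dm[1], dm[2]),
                   cell_labels = matrix(0L, dm[1], dm[2])),
              class = "segmentation_masks")
  }
  if (diff(range(sm)) < 1e-6 * max(1, mean(sm))) return(empty())
  cut <- otsu_threshold(sm)
  fg <- sm > cut
  if (!any(fg)) return(empty())
  fg0 <- fg
  fg <- fill_compact_holes(fg)   # nuclei are compact dark basins; membranes thin lines
  basins <- fg & !fg0
  dt <- distance_transform(fg)
  seeds <- peak_seeds(gaussian_blur(dt, 1), fg, min_sep = cell_diameter_px / 2,
                      min_value = 2)
  if (max(seeds) == 0L) return(empty())
  lab <- watershed_seeded(-dt, seeds, fg)
  # Drop border-touching and undersized cells. Border contact is judged on
  # each cell's thick core (distance > 2.5 px from background): bright
  # fiber corridors that connect cells and happen to reach the ROI border
  # are thin and must not disqualify an interior cell.
  nr <- nrow(lab); nc <- ncol(lab)
  thick <- dt > 2.5
  labc <- lab
  labc[!thick] <- 0L
  border_labs <- setdiff(unique(c(labc[1:2, ], labc[(nr - 1):nr, ],
                                  labc[, 1:2], labc[, (nc - 1):nc])), 0L)
  sizes <- tabulate(lab[lab > 0L])
  drop <- union(border_labs, which(sizes < min_cell_px))
  lab[lab %in% drop] <- 0L
  # relabel sequentially
  keep <- sort(setdiff(unique(as.vector(lab)), 0L))
  relab <- matrix(0L, nr, nc)
  nucleus <- matrix(FALSE, nr, nc)
  nxt <- 0L
  for (l in keep) {
    nxt <- nxt + 1L
    cellpx <- lab == l
    relab[cellpx] <- nxt
    cand <- basins & cellpx
    if (!any(cand)) next
    vals <- crop[cellpx]
    if (length(unique(vals)) < 2L) next
    ccut <- otsu_threshold(vals)     # per-cell relative cut: robust to vignetting
    dlab <- label_components(cand, connectivity = 4L)
    if (max(dlab) == 0L) next
    for (d in seq_len(max(dlab))) {
      comp <- dlab == d
      if (sum(comp) >= min_nucleus_px &&
          stats::median(crop[comp]) < ccut)
        nucleus <- nucleus | comp
    }
  }
  # cytoplasm = cell minus nucleus, restricted to originally-bright pixels
  # (filled basins too small to count as nuclei are still not cytoplasm)
  cytoplasm <- relab > 0L & fg0 & !nucleus
  structure(list(collagen = matrix(FALSE, dm[1], dm[2]),
                 cytoplasm = uncrop_roi(cytoplasm, roi, dm),
                 nucleus = uncrop_roi(nucleus, roi, dm),
                 excluded = matrix(FALSE, dm[1], dm[2]),
                 cell_labels = uncrop_roi(relab, roi, dm)),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf("segmentation: %d cells, %d px cytoplasm, %d px nucleus, %d px collagen\n",
              count_cells(x), sum(x$cytoplasm), sum(x$nucleus), sum(x$collagen)))
  invisible(x)
}

#' Build a cytoplasm mask from manually selected regions
#'
#' When fewer than 10 cells survive automatic segmentation and cleanup, the
#' protocol falls back to pure manual selection of cytoplasm. Regions are
#' given declaratively (polygons, rectangles, masks) so the "manual" step is
#' reproducible; the result is flagged with attribute `provenance =
#' "manual"`.
#'
#' @param regions nonempty list of region specifications (see
#'   [apply_exclusions()] for accepted forms).
#' @param dm frame dimension `c(rows, cols)`.
#' @return logical cytoplasm mask (union of the regions, no double
#'   counting).
#' @export
manual_select_cytoplasm <- function(regions, dm) {
  if (length(regions) == 0L) stop("manual selection requires at least one region")
  out <- matrix(FALSE, dm[1], dm[2])
  for (rg in regions) out <- out | rasterize_region(rg, dm)
  attr(out, "provenance") <- "manual"
  out
}

#' Count distinguishable segmented cells
#'
#' @param masks a `segmentation_masks` object.
#' @return number of distinct positive labels with nonempty cytoplasm.
#' @export
count_cells <- function(masks) {
  stopifnot(inherits(masks, "segmentation_masks"))
  labs <- masks$cell_labels[masks$cytoplasm & masks$cell_labels > 0L]
  length(unique(labs))
}

#' Structure-tensor orientation coherence
#'
#' Measures whether fibers are "clear enough to see their orientation":
#' eigenvalue spread `(l1 - l2) / (l1 + l2)` of the mask-averaged outer
#' product of smoothed image gradients. 1 = a single dominant orientation,
#' 0 = isotropic. Invariant under frame rotation by 90 degrees.
#'
#' @param shg_frame 2-D SHG intensity image.
#' @param mask logical mask of at least `min_px` pixels over which the
#'   tensor is averaged.
#' @param grad_sigma Gaussian smoothing sigma before differentiation.
#' @param min_px minimum mask size.
#' @return coherence in `[0, 1]`.
#' @export
orientation_coherence <- function(shg_frame, mask, grad_sigma = 1.5,
                                  min_px = 50L) {
  stopifnot(identical(dim(shg_frame), dim(mask)))
  if (sum(mask) < min_px)
    stop("mask too small for orientation estimation (needs >= ", min_px, " px)")
  s <- gaussian_blur(shg_frame, grad_sigma)
  nr <- nrow(s); nc <- ncol(s)
  gr <- matrix(0, nr, nc)
  gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (s[3:nr, ] - s[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (s[, 3:nc] - s[, 1:(nc - 2)]) / 2
  jrr <- mean(gr[mask]^2)
  jcc <- mean(gc[mask]^2)
  jrc <- mean((gr * gc)[mask])
  tr <- jrr + jcc
  if (tr == 0) return(0)
  sqrt((jrr - jcc)^2 + 4 * jrc^2) / tr
}
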