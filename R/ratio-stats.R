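# Processing- and inspecting-phase statistics: noise estimation, the
# noise-corrected brightness ratio, stack averaging and cohort aggregation.

#' Estimate the photomultiplier noise floor of a stack
#'
#' Mean THG intensity over all pixels *outside* the rectangular ROI at the
#' designated deep subimage (default the 80th frame, ~144 um below the
#' surface at a 1.8 um z-step, where vignetted off-ROI regions are uniformly
#' dark). For shorter stacks the deepest frame is used and the fallback is
#' reported via a warning.
#'
#' @param stack an [hgm_stack()].
#' @param roi the stack's [rect_roi()].
#' @param noise_depth_index 1-based depth index of the noise frame.
#' @return mean grayscale noise estimate.
#' @export
estimate_noise <- function(stack, roi, noise_depth_index = 80L) {
  stopifnot(inherits(stack, "hgm_stack"))
  nd <- n_depths(stack)
  if (nd < 1L) stop("stack has no frames")
  z <- min(noise_depth_index, nd)
  if (z < noise_depth_index)
    warning(sprintf("stack has %d frames; noise taken from deepest frame %d instead of %d",
                    nd, z, noise_depth_index))
  fr <- thg_frame(stack, z)
  outside <- !rasterize_region(roi, dim(fr))
  if (!any(outside)) stop("ROI covers the whole frame: no outside pixels for noise")
  mean(fr[outside])
}

#' Noise-corrected cytoplasm-to-collagen brightness ratio of one subimage
#'
#' The intrinsic basal-cell-cytoplasm to collagen-fiber THG-brightness ratio
#' of a subimage is
#' \deqn{(THG_{cytoplasm} - noise) / (THG_{collagen} - noise)}
#' where the two numerator/denominator terms are mean THG grayscale over the
#' respective segmentation masks and `noise` is the stack's dark-region
#' estimate. The correction makes the ratio invariant under any common gain
#' and offset of the three quantities.
#'
#' @param thg_frame 2-D THG intensity image.
#' @param cytoplasm_mask,collagen_mask nonempty logical masks.
#' @param noise grayscale noise estimate from [estimate_noise()].
#' @param depth_index depth index recorded in the result.
#' @return an object of class `ratio_result` with fields `depth_index`,
#'   `thg_cytoplasm`, `thg_collagen`, `noise`, `ratio`.
#' @export
subimage_ratio <- function(thg_frame, cytoplasm_mask, collagen_mask, noise,
                           depth_index = NA_integer_) {
  stopifnot(identical(dim(thg_frame), dim(cytoplasm_mask)),
            identical(dim(thg_frame), dim(collagen_mask)))
  if (!any(cytoplasm_mask)) stop("empty cytoplasm mask")
  if (!any(collagen_mask)) stop("empty collagen mask")
  mc <- mean(thg_frame[cytoplasm_mask])
  mf <- mean(thg_frame[collagen_mask])
  if (mf <= noise)
    stop(sprintf("collagen mean (%.1f) not above noise (%.1f): bad noise frame or failed segmentation",
                 mf, noise))
  structure(list(depth_index = as.integer(depth_index),
                 thg_cytoplasm = mc, thg_collagen = mf, noise = noise,
                 ratio = (mc - noise) / (mf - noise)),
            class = "ratio_result")
}

#' Average the qualified subimage ratios of one stack
#'
#' The final ratio of a stack is the unweighted mean over its qualified
#' subimages; at least three qualified subimages are required.
#'
#' @param results list of `ratio_result` objects (one per screened
#'   subimage, matching `qc` by position).
#' @param qc list of `subimage_qc` records from [screen_subimage()].
#' @param min_qualified required number of qualified subimages.
#' @return the stack mean ratio.
#' @export
stack_ratio <- function(results, qc, min_qualified = 3L) {
  stopifnot(length(results) == length(qc))
  q <- vapply(qc, function(r) isTRUE(r$qualified), logical(1))
  if (sum(q) < min_qualified)
    stop("only ", sum(q), " qualified subimages; ", min_qualified, " required")
  mean(vapply(results[q], function(r) r$ratio, numeric(1)))
}

#' Inspecting-phase inclusion rule
#'
#' Stacks whose mean ratio is strictly higher than the phototype-I value of
#' 1.6 are considered melanin-containing and excluded from the intrinsic
#' (melanin-free) cohort.
#'
#' @param stack_mean_ratio finite stack mean ratio.
#' @param cutoff exclusion cutoff (strict).
#' @return `TRUE` if the stack is included.
#' @export
inspect_stack <- function(stack_mean_ratio, cutoff = 1.6) {
  stopifnot(is.finite(stack_mean_ratio))
  stack_mean_ratio <= cutoff
}

#' Aggregate per-stack ratios into a cohort summary
#'
#' @param per_stack data.frame with columns `stack_id`, `ratio` (NA for
#'   excluded stacks) and `reason` (`"included"` or one of `blurred`,
#'   `melanin_pieces`, `ratio_over_1p6`, `no_roi`,
#'   `insufficient_qualified_subimages`).
#' @return an object of class `cohort_summary`: included stack ratios, the
#'   cohort mean, the standard error of the mean (sample sd / sqrt(n),
#'   `NA` when n = 1) and the exclusion table.
#' @export
cohort_summary <- function(per_stack) {
  stopifnot(is.data.frame(per_stack),
            all(c("stack_id", "ratio", "reason") %in% names(per_stack)))
  ok <- per_stack$reason == "included"
  if (!any(ok)) stop("zero included stacks: ",
                     paste(unique(per_stack$reason), collapse = ", "))
  ratios <- per_stack$ratio[ok]
  n <- length(ratios)
  structure(list(stack_ratios = stats::setNames(ratios, per_stack$stack_id[ok]),
                 included_n = n,
                 excluded = per_stack[!ok, c("stack_id", "reason")],
                 mean = mean(ratios),
                 sem = if (n >= 2L) stats::sd(ratios) / sqrt(n) else NA_real_),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d stacks included, ratio %.3f +/- %.3f (mean +/- SEM)\n",
              x$included_n, x$mean, x$sem))
  if (nrow(x$excluded))
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  excluded %s: %s\n", x$excluded$stack_id[i],
                  x$excluded$reason[i]))
  invisible(x)
}
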