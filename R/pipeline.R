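# End-to-end orchestration of the five phases, run configuration and the
# seven-point Physician Global Assessment (PGA) lookup.

#' Run configuration
#'
#' Gathers every numeric constant used by the five phases in one place,
#' together with the inputs and output location. Inputs may be TIFF file
#' paths, `skin_scene_params`/preset specifications (generated on the fly),
#' or in-memory [hgm_stack()] objects.
#'
#' @param inputs named list of inputs. Each element is one of: a character
#'   TIFF path, an [hgm_stack()], a [skin_scene_params()] object, or a
#'   `list(preset = <name>, seed = <int>)` specification. Names become
#'   stack ids (unnamed inputs are numbered `stack_1`, ...).
#' @param dej_depth_window integer vector of DEJ depth indices to analyse;
#'   `NULL` uses each stack's own recorded window.
#' @param roi_threshold grayscale threshold for ROI selection (THG) and
#'   collagen coverage/segmentation (SHG).
#' @param roi_method `"fixed"` or `"otsu"`.
#' @param shg_coverage_min strict minimum covered ROI fraction.
#' @param min_cells minimum distinguishable basal cells (inclusive).
#' @param min_qualified_subimages subimages needed for a stack ratio.
#' @param melanin_ratio_cutoff strict exclusion cutoff on the ratio.
#' @param noise_depth_index depth of the noise frame.
#' @param coherence_floor minimum orientation coherence.
#' @param focus_floor minimum focus score admitted at preview.
#' @param cell_diameter_px expected basal-cell diameter in pixels.
#' @param manual_exclusions named list (by stack id) of lists of region
#'   specifications removed from both measurement masks.
#' @param manual_cytoplasm named list (by stack id) of per-depth lists of
#'   regions used as cytoplasm when automatic segmentation yields too few
#'   cells.
#' @param out_dir optional directory for plain-text reports.
#' @param seed seed applied before any stochastic input generation.
#' @return an object of class `run_config`.
#' @export
run_config <- function(inputs,
                       dej_depth_window = NULL,
                       roi_threshold = 1600,
                       roi_method = c("fixed", "otsu"),
                       shg_coverage_min = 0.25,
                       min_cells = 10L,
                       min_qualified_subimages = 3L,
                       melanin_ratio_cutoff = 1.6,
                       noise_depth_index = 80L,
                       coherence_floor = 0.3,
                       focus_floor = 0.055,
                       cell_diameter_px = 21,
                       manual_exclusions = list(),
                       manual_cytoplasm = list(),
                       out_dir = NULL,
                       seed = 1L) {
  roi_method <- match.arg(roi_method)
  if (length(inputs) == 0L) stop("no input stacks")
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    names(inputs) <- sprintf("stack_%d", seq_along(inputs))
  thr <- c(roi_threshold, shg_coverage_min, min_cells, min_qualified_subimages,
           melanin_ratio_cutoff, noise_depth_index, coherence_floor, focus_floor)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  structure(list(inputs = inputs, dej_depth_window = dej_depth_window,
                 roi_threshold = roi_threshold, roi_method = roi_method,
                 shg_coverage_min = shg_coverage_min,
                 min_cells = as.integer(min_cells),
                 min_qualified_subimages = as.integer(min_qualified_subimages),
                 melanin_ratio_cutoff = melanin_ratio_cutoff,
                 noise_depth_index = as.integer(noise_depth_index),
                 coherence_floor = coherence_floor,
                 focus_floor = focus_floor,
                 cell_diameter_px = cell_diameter_px,
                 manual_exclusions = manual_exclusions,
                 manual_cytoplasm = manual_cytoplasm,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.load_input <- function(input) {
  if (inherits(input, "hgm_stack")) return(input)
  if (is.character(input)) return(read_stack(input))
  if (inherits(input, "skin_scene_params")) return(generate_stack(input)$stack)
  if (is.list(input) && !is.null(input$preset)) {
    seed <- if (is.null(input$seed)) 1L else input$seed
    return(generate_stack(skin_preset(input$preset, seed = seed))$stack)
  }
  stop("unrecognised input specification")
}

# Analyse one loaded stack; returns list(row, qc_rows, log_lines).
.process_stack <- function(stack, id, cfg, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  row <- function(reason, ratio = NA_real_, noise = NA_real_, nq = 0L)
    data.frame(stack_id = id, n_qualified = nq, noise = noise, ratio = ratio,
               included = reason == "included", reason = reason,
               stringsAsFactors = FALSE)
  dej <- if (!is.null(cfg$dej_depth_window)) cfg$dej_depth_window
  else stack$dej_window
  if (is.null(dej))
    stop("stack ", id, ": no DEJ depth window in config or stack metadata")
  ## Phase 1: previewing
  pv <- preview_stack(stack, dej, focus_floor = cfg$focus_floor,
                      roi_threshold = cfg$roi_threshold,
                      melanin_ratio_cutoff = cfg$melanin_ratio_cutoff,
                      noise_depth_index = cfg$noise_depth_index)
  if (!pv$admitted) {
    reason <- if (pv$blurred) "blurred"
    else if (pv$melanin_pieces) "melanin_pieces" else "ratio_over_1p6"
    say("%s: excluded at preview (%s)", id, reason)
    return(list(row = row(reason), qc = NULL))
  }
  ## Phase 2: ROI selection on the shallowest DEJ frame
  roi <- tryCatch(select_roi(thg_frame(stack, dej[1]),
                             threshold = cfg$roi_threshold,
                             method = cfg$roi_method),
                  error = function(e) NULL)
  if (is.null(roi)) {
    say("%s: excluded, no ROI", id)
    return(list(row = row("no_roi"), qc = NULL))
  }
  noise <- estimate_noise(stack, roi, cfg$noise_depth_index)
  ## Phases 3-4 per DEJ subimage: segmentation, screening, ratio
  excl <- cfg$manual_exclusions[[id]]
  if (is.null(excl)) excl <- list()
  qc <- list(); results <- list(); qc_rows <- NULL
  for (z in dej) {
    sfr <- shg_frame(stack, z)
    tfr <- thg_frame(stack, z)
    collagen <- segment_collagen(sfr, roi, threshold = cfg$roi_threshold)
    collagen <- apply_exclusions(collagen, excl)
    masks <- segment_cells(tfr, roi, cell_diameter_px = cfg$cell_diameter_px)
    cyto <- apply_exclusions(masks$cytoplasm, excl)
    cyto <- cyto & !collagen       # fiber regions are never cytoplasm
    masks$cytoplasm <- cyto
    ncells <- count_cells(masks)
    provenance <- "auto"
    manual <- cfg$manual_cytoplasm[[id]]
    if (ncells < cfg$min_cells && !is.null(manual) &&
        !is.null(manual[[as.character(z)]])) {
      cyto <- manual_select_cytoplasm(manual[[as.character(z)]], dim(tfr))
      cyto <- cyto & !collagen
      ncells <- cfg$min_cells      # operator-asserted distinguishable cells
      provenance <- "manual"
    }
    coher <- tryCatch(orientation_coherence(sfr, collagen),
                      error = function(e) NA_real_)
    sq <- screen_subimage(stack, z, roi, ncells, coher,
                          shg_threshold = cfg$roi_threshold,
                          coverage_min = cfg$shg_coverage_min,
                          coherence_floor = cfg$coherence_floor,
                          min_cells = cfg$min_cells)
    rr <- if (sq$qualified && any(cyto) && any(collagen)) {
      tryCatch(subimage_ratio(tfr, cyto, collagen, noise, depth_index = z),
               error = function(e) NULL)
    } else NULL
    if (is.null(rr)) {
      if (sq$qualified) sq$qualified <- FALSE  # unmeasurable => not qualified
      rr <- structure(list(depth_index = z, thg_cytoplasm = NA_real_,
                           thg_collagen = NA_real_, noise = noise,
                           ratio = NA_real_), class = "ratio_result")
    }
    qc[[length(qc) + 1L]] <- sq
    results[[length(results) + 1L]] <- rr
    qc_rows <- rbind(qc_rows, data.frame(
      stack_id = id, depth_index = z, coverage = sq$shg_coverage_frac,
      coherence = coher, cell_count = sq$cell_count,
      qualified = sq$qualified, ratio = rr$ratio, provenance = provenance,
      stringsAsFactors = FALSE))
  }
  nq <- sum(vapply(qc, `[[`, logical(1), "qualified"))
  if (!qualify_stack(qc, cfg$min_qualified_subimages)) {
    say("%s: excluded, %d qualified subimages", id, nq)
    return(list(row = row("insufficient_qualified_subimages", noise = noise,
                          nq = nq), qc = qc_rows))
  }
  sr <- stack_ratio(results, qc, cfg$min_qualified_subimages)
  ## Phase 5: inspecting
  if (!inspect_stack(sr, cfg$melanin_ratio_cutoff)) {
    say("%s: excluded at inspection, ratio %.3f", id, sr)
    return(list(row = row("ratio_over_1p6", noise = noise, nq = nq),
                qc = qc_rows))
  }
  say("%s: included, ratio %.3f (noise %.1f, %d subimages)", id, sr, noise, nq)
  list(row = row("included", ratio = sr, noise = noise, nq = nq), qc = qc_rows)
}

#' Run the five-phase pipeline over a batch of stacks
#'
#' For each stack: previewing, ROI selection, per-depth segmentation and
#' screening, noise-corrected ratios with the stack mean, and the
#' inspecting-phase exclusion; then cohort aggregation. Every stack appears
#' exactly once in the report, included or excluded with a reason. With
#' `out_dir` set, per-depth QC and per-stack tables are written as
#' tab-separated text.
#'
#' @param config a [run_config()].
#' @param verbose emit per-stack progress via [message()].
#' @return a list of class `pipeline_result`: `summary` (a
#'   [cohort_summary()]), `stacks` (per-stack data.frame) and `qc`
#'   (per-depth data.frame).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  rows <- NULL; qcs <- NULL
  for (i in seq_along(config$inputs)) {
    id <- names(config$inputs)[i]
    stack <- .load_input(config$inputs[[i]])
    res <- .process_stack(stack, id, config, verbose)
    rows <- rbind(rows, res$row)
    qcs <- rbind(qcs, res$qc)
    rm(stack)
  }
  summary <- cohort_summary(rows)
  out <- structure(list(summary = summary, stacks = rows, qc = qcs),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rows, file.path(config$out_dir, "stacks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(qcs))
      utils::write.table(qcs, file.path(config$out_dir, "subimage_qc.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(sprintf("included_n\t%d", summary$included_n),
                 sprintf("mean_ratio\t%.6f", summary$mean),
                 sprintf("sem\t%.6f", summary$sem)),
               file.path(config$out_dir, "cohort_summary.tsv"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

.pga_table <- data.frame(
  score = c(-2L, -1L, 0L, 1L, 2L, 3L, 4L),
  descriptor = c(
    "Disease progression as patches",
    "Active border extension",
    "No change",
    "Round follicular repigmentation",
    "Perifollicular repigmentation with confluence <10% of the lesion",
    "Repigmentation between 10% and 90% of the lesion",
    "Repigmentation with confluence >90% of the lesion"),
  stringsAsFactors = FALSE)

#' The seven-point Physician Global Assessment table
#'
#' Clinical repigmentation scores (-2 to 4) used to rate vitiligo treatment
#' response.
#'
#' @return data.frame with columns `score` and `descriptor`.
#' @export
pga_table <- function() .pga_table

.norm_desc <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Look up a PGA score by descriptor
#'
#' Matching is case-insensitive and whitespace-normalised; no fuzzy
#' matching. A descriptor that omits the trailing "of the lesion"
#' qualifier is also accepted.
#'
#' @param descriptor canonical descriptor text.
#' @return integer score in `[-2, 4]`.
#' @export
pga_score <- function(descriptor) {
  d <- .norm_desc(descriptor)
  canon <- .norm_desc(.pga_table$descriptor)
  hit <- match(d, canon)
  if (is.na(hit))
    hit <- match(d, sub(" of the lesion$", "", canon))
  if (is.na(hit)) stop("unrecognised PGA descriptor: ", descriptor)
  .pga_table$score[hit]
}
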