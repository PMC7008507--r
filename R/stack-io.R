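# Two-channel harmonic-generation-microscopy (HGM) stack container and
# serialization.  A stack holds co-registered SHG and THG intensity volumes
# acquired frame-by-frame from the skin surface downward.

#' Acquisition metadata for an HGM stack
#'
#' @param pixel_count_xy pixels per frame side (frames are square).
#' @param field_of_view_um physical side length of a frame in micrometres.
#' @param z_step_um depth spacing between consecutive frames in micrometres.
#' @param bit_depth bits per sample of the digitiser; intensities must lie in
#'   `[0, 2^bit_depth - 1]`. Photomultiplier signals are typically mapped to
#'   14-bit grayscale held in 16-bit containers.
#' @return an object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(pixel_count_xy = 512L, field_of_view_um = 295,
                             z_step_um = 1.8, bit_depth = 14L) {
  stopifnot(pixel_count_xy > 0, field_of_view_um > 0, z_step_um > 0,
            bit_depth > 0, bit_depth <= 16)
  structure(list(pixel_count_xy = as.integer(pixel_count_xy),
                 field_of_view_um = as.numeric(field_of_view_um),
                 z_step_um = as.numeric(z_step_um),
                 bit_depth = as.integer(bit_depth)),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("HGM acquisition: %d x %d px, %.1f x %.1f um, z-step %.2f um, %d-bit\n",
              x$pixel_count_xy, x$pixel_count_xy, x$field_of_view_um,
              x$field_of_view_um, x$z_step_um, x$bit_depth))
  invisible(x)
}

#' Two-channel HGM image stack
#'
#' Bundles the co-registered SHG and THG volumes of one acquisition. Volumes
#' are 3-D arrays indexed `[row, col, depth]`; depth index 1 is the shallowest
#' frame (skin surface) and depth increases toward the dermis.
#'
#' @param shg,thg numeric 3-D arrays of identical dimension holding grayscale
#'   intensities in `[0, 2^bit_depth - 1]`.
#' @param meta an [acquisition_meta()].
#' @param depth0_um depth of the first frame below the skin surface (um).
#' @param dej_window optional integer vector of depth indices spanning the
#'   dermal-epidermal junction, where basal cells and collagen coexist.
#' @return an object of class `hgm_stack`.
#' @export
hgm_stack <- function(shg, thg, meta, depth0_um = 0, dej_window = NULL) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (!is.array(shg) || length(dim(shg)) != 3L)
    stop("shg must be a 3-D array [row, col, depth]")
  if (!identical(dim(shg), dim(thg)))
    stop("shg and thg must have identical dimensions")
  if (any(dim(shg) == 0L)) stop("empty volume")
  vmax <- 2^meta$bit_depth - 1
  rng <- range(shg, thg)
  if (rng[1] < 0 || rng[2] > vmax)
    stop(sprintf("intensity %g outside [0, %d] for declared bit depth %d",
                 if (rng[1] < 0) rng[1] else rng[2], vmax, meta$bit_depth))
  if (!is.null(dej_window)) {
    dej_window <- as.integer(dej_window)
    if (min(dej_window) < 1L || max(dej_window) > dim(shg)[3])
      stop("dej_window outside stack depth range")
  }
  structure(list(shg = shg, thg = thg, meta = meta,
                 depth0_um = as.numeric(depth0_um), dej_window = dej_window),
            class = "hgm_stack")
}

#' @export
print.hgm_stack <- function(x, ...) {
  d <- dim(x$shg)
  cat(sprintf("hgm_stack: %d frames of %d x %d px (SHG + THG)\n", d[3], d[1], d[2]))
  print(x$meta)
  if (!is.null(x$dej_window))
    cat("DEJ window: depths", min(x$dej_window), "-", max(x$dej_window), "\n")
  invisible(x)
}

#' Number of depth frames in a stack
#' @param stack an [hgm_stack()].
#' @export
n_depths <- function(stack) dim(stack$shg)[3]

#' Extract one channel frame
#'
#' @param stack an [hgm_stack()].
#' @param depth_index 1-based depth index.
#' @return numeric intensity matrix.
#' @export
shg_frame <- function(stack, depth_index) {
  .check_depth(stack, depth_index)
  stack$shg[, , depth_index]
}

#' @rdname shg_frame
#' @export
thg_frame <- function(stack, depth_index) {
  .check_depth(stack, depth_index)
  stack$thg[, , depth_index]
}

.check_depth <- function(stack, depth_index) {
  if (depth_index < 1L || depth_index > n_depths(stack))
    stop("depth index ", depth_index, " out of range 1..", n_depths(stack))
}

.meta_to_text <- function(stack, channel_order = "shg_first") {
  lines <- c(
    paste0("pixel_count_xy=", stack$meta$pixel_count_xy),
    paste0("field_of_view_um=", format(stack$meta$field_of_view_um, digits = 10)),
    paste0("z_step_um=", format(stack$meta$z_step_um, digits = 10)),
    paste0("bit_depth=", stack$meta$bit_depth),
    paste0("channel_order=", channel_order),
    paste0("depth0_um=", format(stack$depth0_um, digits = 10)))
  if (!is.null(stack$dej_window))
    lines <- c(lines, paste0("dej_window=", min(stack$dej_window), ":",
                             max(stack$dej_window)))
  paste(lines, collapse = "\n")
}

.parse_meta_text <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  as.list(stats::setNames(vals, keys))
}

#' Write an HGM stack to a multi-page TIFF
#'
#' Pages are depth-major with channels interleaved: page `2k-1` is the first
#' channel and page `2k` the second channel of depth `k` (channel order per
#' `channel_order`, default SHG first). Acquisition metadata is stored as a
#' key=value text block in the first page's ImageDescription; a plain-text
#' sidecar `<path>.meta` with the same content is written alongside as a
#' fallback for TIFF tools that strip descriptions.
#'
#' @param stack an [hgm_stack()].
#' @param path output file path.
#' @param channel_order `"shg_first"` or `"thg_first"`.
#' @param sidecar write the sidecar metadata file (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, channel_order = c("shg_first", "thg_first"),
                        sidecar = TRUE) {
  stopifnot(inherits(stack, "hgm_stack"))
  channel_order <- match.arg(channel_order)
  nd <- n_depths(stack)
  if (nd == 0L) stop("cannot write an empty stack")
  first <- if (channel_order == "shg_first") stack$shg else stack$thg
  second <- if (channel_order == "shg_first") stack$thg else stack$shg
  pages <- vector("list", 2L * nd)
  for (k in seq_len(nd)) {
    pages[[2L * k - 1L]] <- first[, , k]
    pages[[2L * k]] <- second[, , k]
  }
  meta_txt <- .meta_to_text(stack, channel_order)
  write_tiff_pages(path, pages, description = meta_txt)
  if (sidecar) writeLines(meta_txt, paste0(path, ".meta"))
  invisible(path)
}

#' Read an HGM stack from a multi-page TIFF
#'
#' Expects the layout produced by [write_stack()]: depth-major pages with the
#' two channels interleaved. Metadata is taken from the TIFF ImageDescription,
#' or from the sidecar file if the description is absent.
#'
#' @param path TIFF file path.
#' @param sidecar optional explicit sidecar path (default `<path>.meta`).
#' @return an [hgm_stack()].
#' @export
read_stack <- function(path, sidecar = NULL) {
  tf <- read_tiff_pages(path)
  np <- length(tf$pages)
  if (np %% 2L != 0L)
    stop("odd page count (", np, ") for a two-channel interleaved layout")
  meta_txt <- tf$description
  if (is.na(meta_txt)) {
    sc <- if (is.null(sidecar)) paste0(path, ".meta") else sidecar
    if (!file.exists(sc))
      stop("no metadata: TIFF has no ImageDescription and no sidecar at ", sc)
    meta_txt <- paste(readLines(sc), collapse = "\n")
  }
  kv <- .parse_meta_text(meta_txt)
  need <- c("pixel_count_xy", "field_of_view_um", "z_step_um", "bit_depth",
            "channel_order")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("metadata missing keys: ", paste(miss, collapse = ", "))
  meta <- acquisition_meta(as.integer(kv$pixel_count_xy),
                           as.numeric(kv$field_of_view_um),
                           as.numeric(kv$z_step_um),
                           as.integer(kv$bit_depth))
  nd <- np %/% 2L
  d1 <- dim(tf$pages[[1]])
  vol1 <- array(0, c(d1[1], d1[2], nd))
  vol2 <- array(0, c(d1[1], d1[2], nd))
  for (k in seq_len(nd)) {
    vol1[, , k] <- tf$pages[[2L * k - 1L]]
    vol2[, , k] <- tf$pages[[2L * k]]
  }
  vmax <- 2^meta$bit_depth - 1
  if (max(vol1, vol2) > vmax)
    stop(sprintf("intensity %d exceeds 2^%d - 1 = %d: wrong bit_depth declaration?",
                 max(vol1, vol2), meta$bit_depth, vmax))
  if (kv$channel_order == "shg_first") {
    shg <- vol1; thg <- vol2
  } else if (kv$channel_order == "thg_first") {
    shg <- vol2; thg <- vol1
  } else stop("unknown channel_order: ", kv$channel_order)
  dej <- NULL
  if (!is.null(kv$dej_window)) {
    bounds <- as.integer(strsplit(kv$dej_window, ":", fixed = TRUE)[[1]])
    dej <- seq(bounds[1], bounds[2])
  }
  depth0 <- if (!is.null(kv$depth0_um)) as.numeric(kv$depth0_um) else 0
  hgm_stack(shg, thg, meta, depth0_um = depth0, dej_window = dej)
}

#' Render a pseudocolor overlay of one depth
#'
#' THG is mapped to magenta and SHG to green, each channel normalised to its
#' own frame maximum — the conventional display for two-channel harmonic
#' generation images. Intended for reports and documentation only; all
#' quantification uses raw grayscale.
#'
#' @param stack an [hgm_stack()].
#' @param depth_index 1-based depth index.
#' @return numeric array `[row, col, 3]` with RGB values in `[0, 1]`.
#' @export
render_pseudocolor <- function(stack, depth_index) {
  .check_depth(stack, depth_index)
  s <- shg_frame(stack, depth_index)
  t <- thg_frame(stack, depth_index)
  sn <- if (max(s) > 0) s / max(s) else s
  tn <- if (max(t) > 0) t / max(t) else t
  out <- array(0, c(dim(s), 3L))
  out[, , 1] <- tn           # magenta = red + blue
  out[, , 2] <- sn           # green
  out[, , 3] <- tn
  out
}
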