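# Synthetic two-channel skin stack generator with voxel-level ground truth.
# Emulates the statistical structure the ratio pipeline assumes: a
# dermal-epidermal-junction (DEJ) cell mosaic with THG-bright cytoplasm and
# THG-dark nuclei, oriented collagen fibers bright in SHG with a weaker
# co-registered THG signal, edge vignetting, a ~150-grayscale noise floor,
# optional melanin-bright caps, and depth attenuation below the DEJ.

#' Parameters of a synthetic skin scene
#'
#' Class means are *total* expected grayscale values (noise floor included),
#' so the configured `cytoplasm_mean` etc. are directly comparable to masked
#' means measured on the generated stack. Rendered signal amplitude for a
#' class is therefore `mean - noise_floor_mean`.
#'
#' @param n_depths number of depth frames.
#' @param pixel_count_xy pixels per frame side (default 256 for desk-scale
#'   runs; the acquisition-scale 512 is available).
#' @param dej_depth_index first depth index (1-based) of the DEJ window.
#' @param dej_window_len number of consecutive DEJ frames where basal cells
#'   and collagen coexist.
#' @param cell_count number of basal cells (Voronoi seeds) per DEJ frame.
#' @param cell_diameter_um mean basal-cell diameter in micrometres.
#' @param cytoplasm_mean expected THG grayscale of melanin-lacking cytoplasm.
#' @param nucleus_mean expected THG grayscale of nuclei (dark).
#' @param collagen_shg_mean expected SHG grayscale on collagen fibers.
#' @param collagen_thg_mean expected THG grayscale on collagen fibers.
#' @param fiber_count collagen fibers per dermal frame.
#' @param fiber_width_um fiber tube width in micrometres.
#' @param fiber_orientation_kappa concentration of fiber directions (von
#'   Mises kappa; high = clearly oriented).
#' @param noise_floor_mean dark-region THG mean grayscale (photomultiplier
#'   noise floor, default 150).
#' @param noise_sd additive noise standard deviation.
#' @param vignette_radius_frac fraction of the frame half-width at which the
#'   cosine edge dimming begins.
#' @param melanin_fraction fraction of basal cells given THG-bright melanin
#'   caps (0 for vitiligo lesions).
#' @param melanin_mean expected THG grayscale of melanin caps.
#' @param attenuation_len_um 1/e depth-attenuation length below the DEJ.
#' @param blur_sigma_px optional global blur (pixels) emulating subject
#'   motion; 0 disables.
#' @param z_step_um depth spacing in micrometres.
#' @param um_per_px lateral sampling (default the 295/512 um/px of the
#'   acquisition geometry).
#' @param seed random seed; identical parameters and seed reproduce the
#'   stack voxel-for-voxel.
#' @return an object of class `skin_scene_params`.
#' @export
skin_scene_params <- function(n_depths = 96L,
                              pixel_count_xy = 256L,
                              dej_depth_index = 40L,
                              dej_window_len = 5L,
                              cell_count = 120L,
                              cell_diameter_um = 12,
                              cytoplasm_mean = 1809,
                              nucleus_mean = 450,
                              collagen_shg_mean = 3000,
                              collagen_thg_mean = 1650,
                              fiber_count = 40L,
                              fiber_width_um = 2.3,
                              fiber_orientation_kappa = 8,
                              noise_floor_mean = 150,
                              noise_sd = 50,
                              vignette_radius_frac = 0.75,
                              melanin_fraction = 0,
                              melanin_mean = 6000,
                              attenuation_len_um = 15,
                              blur_sigma_px = 0,
                              z_step_um = 1.8,
                              um_per_px = 295 / 512,
                              seed = 1L) {
  p <- list(n_depths = as.integer(n_depths),
            pixel_count_xy = as.integer(pixel_count_xy),
            dej_depth_index = as.integer(dej_depth_index),
            dej_window_len = as.integer(dej_window_len),
            cell_count = as.integer(cell_count),
            cell_diameter_um = cell_diameter_um,
            cytoplasm_mean = cytoplasm_mean,
            nucleus_mean = nucleus_mean,
            collagen_shg_mean = collagen_shg_mean,
            collagen_thg_mean = collagen_thg_mean,
            fiber_count = as.integer(fiber_count),
            fiber_width_um = fiber_width_um,
            fiber_orientation_kappa = fiber_orientation_kappa,
            noise_floor_mean = noise_floor_mean,
            noise_sd = noise_sd,
            vignette_radius_frac = vignette_radius_frac,
            melanin_fraction = melanin_fraction,
            melanin_mean = melanin_mean,
            attenuation_len_um = attenuation_len_um,
            blur_sigma_px = blur_sigma_px,
            z_step_um = z_step_um,
            um_per_px = um_per_px,
            seed = as.integer(seed))
  class(p) <- "skin_scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  means <- c(p$cytoplasm_mean, p$nucleus_mean, p$collagen_shg_mean,
             p$collagen_thg_mean, p$melanin_mean, p$noise_floor_mean)
  if (any(means < 0) || any(means > 16383))
    stop("intensity means must lie in [0, 16383]")
  if (p$cytoplasm_mean <= p$noise_floor_mean)
    stop("cytoplasm_mean must exceed noise_floor_mean")
  if (p$melanin_fraction < 0 || p$melanin_fraction > 1)
    stop("melanin_fraction must lie in [0, 1]")
  if (p$dej_depth_index < 1L || p$dej_depth_index >= p$n_depths)
    stop("inconsistent geometry: dej_depth_index must lie inside the stack")
  if (p$dej_depth_index + p$dej_window_len - 1L > p$n_depths)
    stop("inconsistent geometry: DEJ window extends past the last frame")
  if (p$n_depths < 1L || p$pixel_count_xy < 16L)
    stop("degenerate stack geometry")
  invisible(p)
}

#' Named scene presets
#'
#' Ready-made parameter sets for the generator, one per scenario the QC
#' phases must recognise:
#' * `paper_cohort` — melanin-free (vitiligo) skin calibrated so the true
#'   noise-corrected ratio is (1809-150)/(1650-150) = 1.106.
#' * `melanin_containing` — pigmented skin: bright melanin caps on most
#'   basal cells and cytoplasm brightened so the true ratio exceeds 1.6.
#' * `blurred` — subject motion: global blur strong enough to defeat the
#'   focus metric.
#' * `sparse_collagen` — too few fibers for the 25% SHG-coverage screen.
#' * `few_cells` — fewer than 10 basal cells per frame.
#'
#' @param name preset name.
#' @param seed random seed stored in the returned parameters.
#' @return a [skin_scene_params()] object.
#' @export
skin_preset <- function(name = c("paper_cohort", "melanin_containing",
                                 "blurred", "sparse_collagen", "few_cells"),
                        seed = 1L) {
  name <- match.arg(name)
  switch(name,
         paper_cohort = skin_scene_params(seed = seed),
         melanin_containing = skin_scene_params(melanin_fraction = 0.6,
                                                cytoplasm_mean = 2700,
                                                seed = seed),
         blurred = skin_scene_params(blur_sigma_px = 8, seed = seed),
         sparse_collagen = skin_scene_params(fiber_count = 7L, seed = seed),
         few_cells = skin_scene_params(cell_count = 6L, seed = seed))
}

# Vignette gain field: flat (=1) inside vignette_radius_frac of the frame
# half-width (sup-norm radius, so the flat core is square and matches the
# rectangular ROI the pipeline derives), cosine falloff to 0 at the border.
.vignette_field <- function(n, r0) {
  ctr <- (n + 1) / 2
  half <- (n - 1) / 2
  d <- abs(seq_len(n) - ctr) / half
  rfrac <- outer(d, d, pmax)
  v <- matrix(1, n, n)
  out <- rfrac > r0
  v[out] <- cos(pi / 2 * pmin(1, (rfrac[out] - r0) / (1 - r0)))
  v
}

# Voronoi cell mosaic: labels, membrane lines, nuclei, melanin caps.
.make_mosaic <- function(p) {
  n <- p$pixel_count_xy
  k <- p$cell_count
  sr <- stats::runif(k, 1, n)
  sc <- stats::runif(k, 1, n)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  best <- matrix(Inf, n, n)
  lab <- matrix(0L, n, n)
  for (i in seq_len(k)) {
    d2 <- (rows - sr[i])^2 + (cols - sc[i])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- i
  }
  # membrane = any pixel with a 4-neighbour in a different cell (2 px wide:
  # THG shows cell outlines as distinct dark lines)
  membrane <- matrix(FALSE, n, n)
  membrane[-1, ] <- membrane[-1, ] | (lab[-1, ] != lab[-n, ])
  membrane[-n, ] <- membrane[-n, ] | (lab[-n, ] != lab[-1, ])
  membrane[, -1] <- membrane[, -1] | (lab[, -1] != lab[, -n])
  membrane[, -n] <- membrane[, -n] | (lab[, -n] != lab[, -1])
  d_px <- p$cell_diameter_um / p$um_per_px
  nucleus <- matrix(FALSE, n, n)
  frac <- stats::runif(k, 0.4, 0.6)
  ecc <- stats::runif(k, 0.6, 1)
  ang <- stats::runif(k, 0, pi)
  for (i in seq_len(k)) {
    a <- frac[i] * d_px / 2
    b <- a * ecc[i]
    dr <- rows - sr[i]; dc <- cols - sc[i]
    u <- dr * cos(ang[i]) + dc * sin(ang[i])
    w <- -dr * sin(ang[i]) + dc * cos(ang[i])
    nucleus <- nucleus | ((u / a)^2 + (w / b)^2 <= 1 & lab == i)
  }
  nucleus <- nucleus & !membrane
  # melanin caps sit over/beside the nucleus (supranuclear caps); they may
  # overwrite nucleus pixels, so the nucleus truth is reduced accordingly
  melanin <- matrix(FALSE, n, n)
  n_mel <- round(p$melanin_fraction * k)
  if (n_mel > 0) {
    mel_cells <- sample(k, n_mel)
    cap_r <- max(3.2, 0.15 * d_px)
    theta <- stats::runif(n_mel, 0, 2 * pi)
    for (j in seq_along(mel_cells)) {
      i <- mel_cells[j]
      off <- 0.25 * d_px
      cr <- sr[i] + off * cos(theta[j])
      cc <- sc[i] + off * sin(theta[j])
      cap <- (rows - cr)^2 + (cols - cc)^2 <= cap_r^2
      melanin <- melanin | (cap & lab == i & !membrane)
    }
    nucleus <- nucleus & !melanin
  }
  list(labels = lab, membrane = membrane, nucleus = nucleus, melanin = melanin,
       seed_rows = sr, seed_cols = sc)
}

# Collagen fibers: smooth random-walk tubes with near-von-Mises orientations
# (wrapped-normal sd 1/sqrt(kappa), adequate for kappa >= 2).
.make_fibers <- function(p) {
  n <- p$pixel_count_xy
  center <- matrix(FALSE, n, n)
  mu <- stats::runif(1, 0, pi)
  step <- 1.5
  max_steps <- ceiling(3 * n / step)
  for (i in seq_len(p$fiber_count)) {
    th0 <- mu + stats::rnorm(1, 0, 1 / sqrt(p$fiber_orientation_kappa))
    r <- stats::runif(1, 1, n); c <- stats::runif(1, 1, n)
    for (dir in c(1, -1)) {
      th <- if (dir == 1) th0 else th0 + pi
      rr <- r; cc <- c
      for (s in seq_len(max_steps)) {
        th <- th + stats::rnorm(1, 0, 0.04)
        rr <- rr + step * sin(th)
        cc <- cc + step * cos(th)
        ri <- round(rr); ci <- round(cc)
        if (ri < 1 || ri > n || ci < 1 || ci > n) break
        center[ri, ci] <- TRUE
      }
    }
  }
  if (!any(center)) return(matrix(FALSE, n, n))
  dist_to_line <- distance_transform(!center)
  width_px <- p$fiber_width_um / p$um_per_px
  dist_to_line <= width_px / 2
}

#' Generate a synthetic HGM stack with ground truth
#'
#' Builds one cell mosaic (reused across epidermal and DEJ frames: basal and
#' suprabasal keratinocytes are vertically coherent) and one fiber set
#' (collagen bundles extend through the imaged dermis), then assembles
#' per-depth frames: epidermis = mosaic only, DEJ window = mosaic with
#' fibers overlaid (fiber precedence, keeping truth masks disjoint), dermis
#' = fibers only with exponential depth attenuation. Vignetting multiplies
#' signal but not noise; independent Gaussian noise with the configured
#' floor mean is added everywhere and values are clipped to `[0, 16383]`.
#'
#' Truth masks label class pixels rendered at nominal calibrated intensity
#' (vignette gain 1 and no depth attenuation), so masked empirical means are
#' directly comparable to the configured class means; `background_mask`
#' marks zero-signal (pure noise-floor) voxels.
#'
#' @param params a [skin_scene_params()] (or [skin_preset()]) object.
#' @return a list with components `stack` (an [hgm_stack()]) and `truth`
#'   (class `synthetic_truth`: masks, per-frame DEJ cell labels, configured
#'   class means and the true noise-corrected ratio).
#' @export
generate_stack <- function(params) {
  stopifnot(inherits(params, "skin_scene_params"))
  validate_scene_params(params)
  p <- params
  set.seed(p$seed)
  n <- p$pixel_count_xy
  nd <- p$n_depths
  dej <- seq(p$dej_depth_index, p$dej_depth_index + p$dej_window_len - 1L)
  mos <- .make_mosaic(p)
  fib <- .make_fibers(p)
  v <- .vignette_field(n, p$vignette_radius_frac)
  core <- v >= 1 - 1e-9

  floor_m <- p$noise_floor_mean
  cyt_sig <- p$cytoplasm_mean - floor_m
  nuc_sig <- p$nucleus_mean - floor_m
  mem_sig <- nuc_sig                    # membranes rendered nucleus-dark
  mel_sig <- p$melanin_mean - floor_m
  f_shg_sig <- p$collagen_shg_mean - floor_m
  f_thg_sig <- p$collagen_thg_mean - floor_m

  cyto_px <- mos$labels > 0L & !mos$membrane & !mos$nucleus & !mos$melanin
  mosaic_thg <- matrix(0, n, n)
  mosaic_thg[cyto_px] <- cyt_sig
  mosaic_thg[mos$nucleus] <- nuc_sig
  mosaic_thg[mos$membrane] <- mem_sig
  mosaic_thg[mos$melanin] <- mel_sig

  dej_thg <- mosaic_thg
  dej_thg[fib] <- f_thg_sig
  fib_shg <- matrix(0, n, n)
  fib_shg[fib] <- f_shg_sig
  fib_thg <- matrix(0, n, n)
  fib_thg[fib] <- f_thg_sig
  epi_shg <- matrix(0, n, n)

  if (p$blur_sigma_px > 0) {
    mosaic_thg <- gaussian_blur(mosaic_thg, p$blur_sigma_px)
    dej_thg <- gaussian_blur(dej_thg, p$blur_sigma_px)
    fib_shg <- gaussian_blur(fib_shg, p$blur_sigma_px)
    fib_thg <- gaussian_blur(fib_thg, p$blur_sigma_px)
  }

  shg <- array(0, c(n, n, nd))
  thg <- array(0, c(n, n, nd))
  bg <- array(FALSE, c(n, n, nd))
  dej_end <- max(dej)
  for (z in seq_len(nd)) {
    if (z < min(dej)) {
      sig_t <- mosaic_thg; sig_s <- epi_shg
    } else if (z <= dej_end) {
      sig_t <- dej_thg; sig_s <- fib_shg
    } else {
      a <- exp(-(z - dej_end) * p$z_step_um / p$attenuation_len_um)
      sig_t <- fib_thg * a
      sig_s <- fib_shg * a
    }
    bg[, , z] <- sig_t == 0 & sig_s == 0
    thg[, , z] <- sig_t * v
    shg[, , z] <- sig_s * v
  }
  npx <- n * n * nd
  thg <- thg + stats::rnorm(npx, floor_m, p$noise_sd)
  shg <- shg + stats::rnorm(npx, floor_m, p$noise_sd)
  thg <- array(pmin(pmax(round(thg), 0), 16383), c(n, n, nd))
  shg <- array(pmin(pmax(round(shg), 0), 16383), c(n, n, nd))

  meta <- acquisition_meta(pixel_count_xy = n,
                           field_of_view_um = n * p$um_per_px,
                           z_step_um = p$z_step_um, bit_depth = 14L)
  stack <- hgm_stack(shg, thg, meta, dej_window = dej)

  cyto_v <- array(FALSE, c(n, n, nd))
  nuc_v <- array(FALSE, c(n, n, nd))
  col_v <- array(FALSE, c(n, n, nd))
  mel_v <- array(FALSE, c(n, n, nd))
  for (z in seq_len(dej_end)) {
    in_dej <- z >= min(dej)
    cy <- cyto_px & core
    nu <- mos$nucleus & core
    me <- mos$melanin & core
    if (in_dej) {
      cy <- cy & !fib; nu <- nu & !fib; me <- me & !fib
      col_v[, , z] <- fib & core
    }
    cyto_v[, , z] <- cy
    nuc_v[, , z] <- nu
    mel_v[, , z] <- me
  }
  truth <- structure(list(
    cytoplasm_mask = cyto_v,
    nucleus_mask = nuc_v,
    collagen_mask = col_v,
    melanin_mask = mel_v,
    background_mask = bg,
    cell_labels = mos$labels,
    dej_frames = dej,
    true_cytoplasm_mean = p$cytoplasm_mean,
    true_collagen_thg_mean = p$collagen_thg_mean,
    true_noise_mean = floor_m,
    true_ratio = (p$cytoplasm_mean - floor_m) /
      (p$collagen_thg_mean - floor_m),
    params = p), class = "synthetic_truth")
  list(stack = stack, truth = truth)
}

#' Write truth masks as a labeled multi-page TIFF
#'
#' One page per depth; pixel codes: 0 background/unlabeled, 1 cytoplasm,
#' 2 nucleus, 3 collagen, 4 melanin.
#'
#' @param truth a `synthetic_truth` object from [generate_stack()].
#' @param path output TIFF path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  nd <- dim(truth$cytoplasm_mask)[3]
  pages <- vector("list", nd)
  for (z in seq_len(nd)) {
    m <- matrix(0L, nrow(truth$cell_labels), ncol(truth$cell_labels))
    m[truth$cytoplasm_mask[, , z]] <- 1L
    m[truth$nucleus_mask[, , z]] <- 2L
    m[truth$collagen_mask[, , z]] <- 3L
    m[truth$melanin_mask[, , z]] <- 4L
    pages[[z]] <- m
  }
  write_tiff_pages(path, pages, description = "thgratio truth labels")
  invisible(path)
}
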