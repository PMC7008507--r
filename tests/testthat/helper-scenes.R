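# Shared fixtures: all synthetic scenes are generated in code at test time.

# Desk-scale generator parameters: same intensity world as the full presets,
# smaller geometry for unit-test speed.
small_params <- function(seed = 1L, ...) {
  args <- list(n_depths = 12L, pixel_count_xy = 128L, dej_depth_index = 6L,
               dej_window_len = 3L, cell_count = 60L, fiber_count = 16L,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(skin_scene_params, args)
}

# Small-geometry analogue of a named preset.
small_preset <- function(name, seed = 1L) {
  switch(name,
         paper_cohort = small_params(seed),
         melanin_containing = small_params(seed, melanin_fraction = 0.6,
                                           cytoplasm_mean = 2700),
         blurred = small_params(seed, blur_sigma_px = 8),
         sparse_collagen = small_params(seed, fiber_count = 2L),
         few_cells = small_params(seed, cell_count = 6L),
         stop("unknown small preset"))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# One bright disc cell with a dark elliptical nucleus on a noise-floor
# background; returns frame plus truth masks.
single_cell_frame <- function(n = 96L, cell_r = 28, nuc_a = 12, nuc_b = 8,
                              cyto = 1809, nuc = 450, floor_m = 150,
                              sd = 30, seed = 7L) {
  set.seed(seed)
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  cell <- (rows - ctr)^2 + (cols - ctr)^2 <= cell_r^2
  nucl <- ((rows - ctr) / nuc_a)^2 + ((cols - ctr) / nuc_b)^2 <= 1
  sig <- matrix(0, n, n)
  sig[cell] <- cyto - floor_m
  sig[nucl] <- nuc - floor_m
  frame <- pmin(pmax(round(sig + rnorm(n * n, floor_m, sd)), 0), 16383)
  list(frame = matrix(frame, n, n), cell = cell, nucleus = nucl,
       cytoplasm = cell & !nucl)
}

# Constant-intensity stack helper.
flat_stack <- function(shg_val = 0, thg_val = 150, n = 64L, nd = 10L,
                       bit_depth = 14L) {
  meta <- acquisition_meta(pixel_count_xy = n, field_of_view_um = n * 295 / 512,
                          z_step_um = 1.8, bit_depth = bit_depth)
  hgm_stack(array(shg_val, c(n, n, nd)), array(thg_val, c(n, n, nd)), meta)
}
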