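# Low-level image operations shared by the QC and segmentation phases.
# All operate on plain numeric/logical matrices (row, col); nothing here is
# specific to harmonic-generation imaging.

#' @useDynLib thgratio, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Banded convolution matrix for a 1-D Gaussian, rows renormalised at the
# edges (replicate-like boundary, preserves flat fields exactly).
.gauss_band <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (j in seq_along(x)) {
    idx <- seq_len(n) + x[j]
    ok <- idx >= 1L & idx <= n
    K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + k[j]
  }
  K / rowSums(K)
}

# Separable Gaussian blur of a matrix; sigma = 0 is the identity.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  Kr <- .gauss_band(nrow(x), sigma)
  Kc <- .gauss_band(ncol(x), sigma)
  Kr %*% x %*% t(Kc)
}

# Sum over the 3x3 neighbourhood (pixels outside the frame count as `pad`).
.sum3 <- function(x, pad = 0) {
  nr <- nrow(x); nc <- ncol(x)
  p <- matrix(pad, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- x
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out + p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  }
  out
}

# 3x3 majority filter on a logical matrix (5-of-9 vote).
majority3 <- function(mask) {
  .sum3(mask * 1) >= 5
}

dilate3 <- function(mask) .sum3(mask * 1) > 0
erode3 <- function(mask) .sum3(mask * 1, pad = 1) == 9

# Binary closing that bridges 1-pixel gaps.
close3 <- function(mask) erode3(dilate3(mask))

# Fill compact dark basins: background components whose interior distance
# to the foreground reaches at least `min_thick` px (nucleus-like blobs),
# leaving thin line-shaped background (cell membranes) untouched.
fill_compact_holes <- function(mask, min_thick = 2.5) {
  bg <- label_components(!mask, connectivity = 4L)
  if (max(bg) == 0L) return(mask)
  d <- distance_transform(!mask)
  maxd <- vapply(split(d[bg > 0L], bg[bg > 0L]), max, numeric(1))
  fillable <- as.integer(names(maxd))[maxd >= min_thick]
  # outer background (touching the frame border) is never a hole
  border <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)])), 0L)
  fillable <- setdiff(fillable, border)
  mask | matrix(bg %in% fillable, nrow(mask), ncol(mask))
}

# Fill interior holes: background components not touching the frame border.
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  border <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)])), 0L)
  hole <- bg > 0L & !matrix(bg %in% border, nrow(bg), ncol(bg))
  mask | hole
}

#' Otsu's threshold
#'
#' Histogram-based two-class threshold maximising between-class variance.
#'
#' @param values numeric vector (or matrix) of intensities.
#' @param nbins number of histogram bins.
#' @return the threshold intensity; pixels strictly above it form the
#'   foreground class.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsu_threshold: no finite values")
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot <- w[nbins]; mu_t <- mu[nbins]
  w0 <- w[-nbins]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - tot * mu[-nbins][valid])^2 /
    (w0[valid] * w1[valid])
  br[-c(1L, nbins + 1L)][which.max(sigma_b)]
}

# Wrappers over the compiled kernels ------------------------------------

label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  .cpp_label_components(mask, as.integer(connectivity))
}

# Approximate Euclidean distance of each TRUE pixel to the nearest FALSE one.
distance_transform <- function(mask) {
  stopifnot(is.matrix(mask))
  .cpp_chamfer_dist(mask)
}

watershed_seeded <- function(elevation, seeds, mask) {
  stopifnot(all(dim(elevation) == dim(seeds)), all(dim(seeds) == dim(mask)))
  .cpp_watershed(elevation, seeds, mask)
}

# Local maxima of `x` (within mask) kept greedily with a minimum pairwise
# separation, strongest first; returns a seed label matrix.
peak_seeds <- function(x, mask, min_sep, min_value = 1) {
  nr <- nrow(x); nc <- ncol(x)
  p <- matrix(-Inf, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- x
  nbmax <- matrix(-Inf, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1 && dc == 1) next
    nbmax <- pmax(nbmax, p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)])
  }
  cand <- which(mask & x >= nbmax & x >= min_value, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(0L, nr, nc))
  ord <- order(-x[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(NA_real_, 0, 2)
  for (i in seq_len(nrow(cand))) {
    pt <- cand[i, ]
    if (nrow(keep) == 0L ||
        min((keep[, 1] - pt[1])^2 + (keep[, 2] - pt[2])^2) >= min_sep^2) {
      keep <- rbind(keep, pt)
    }
  }
  seeds <- matrix(0L, nr, nc)
  seeds[keep] <- seq_len(nrow(keep))
  seeds
}

# Single-scale Frangi-style ridge response: bright tubular structures give a
# high score.  Hessian from finite differences of the sigma-smoothed image.
ridge_response <- function(frame, sigma = 2) {
  s <- gaussian_blur(frame, sigma)
  nr <- nrow(s); nc <- ncol(s)
  shift <- function(m, dr, dc) {
    # replicate edges: avoids spurious Hessian extremes at the crop border
    ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  dxx <- shift(s, 0, 1) - 2 * s + shift(s, 0, -1)
  dyy <- shift(s, 1, 0) - 2 * s + shift(s, -1, 0)
  dxy <- (shift(s, 1, 1) - shift(s, 1, -1) - shift(s, -1, 1) +
            shift(s, -1, -1)) / 4
  tmp <- sqrt((dxx - dyy)^2 + 4 * dxy^2)
  l1 <- (dxx + dyy + tmp) / 2   # larger algebraic eigenvalue
  l2 <- (dxx + dyy - tmp) / 2   # more negative across a bright ridge
  # order by magnitude: lam_small = min |.|, lam_big = max |.|
  swap <- abs(l1) > abs(l2)
  lam_small <- ifelse(swap, l2, l1)
  lam_big <- ifelse(swap, l1, l2)
  resp <- matrix(0, nr, nc)
  on <- lam_big < 0                      # bright ridge
  rb2 <- (lam_small[on] / lam_big[on])^2
  s2 <- lam_small[on]^2 + lam_big[on]^2
  c2 <- max(s2) / 4
  if (c2 <= 0) c2 <- 1
  resp[on] <- exp(-rb2 / (2 * 0.25)) * (1 - exp(-s2 / (2 * c2)))
  resp
}

# Rasterise a region spec into a logical matrix of dimension `dm`.
# Accepted forms: a rect_roi, a list(rows=, cols=) index pair, a logical
# matrix, or an n x 2 polygon matrix of (row, col) vertices (even-odd fill).
rasterize_region <- function(region, dm) {
  nr <- dm[1]; nc <- dm[2]
  out <- matrix(FALSE, nr, nc)
  if (inherits(region, "rect_roi")) {
    if (region$row_end > nr || region$col_end > nc)
      stop("region outside frame")
    out[region$row_start:region$row_end,
        region$col_start:region$col_end] <- TRUE
    return(out)
  }
  if (is.matrix(region) && is.logical(region)) {
    if (!all(dim(region) == dm)) stop("mask region has wrong dimensions")
    return(region)
  }
  if (is.list(region) && !is.null(region$rows)) {
    if (max(region$rows) > nr || max(region$cols) > nc ||
        min(region$rows) < 1 || min(region$cols) < 1)
      stop("region outside frame")
    out[cbind(region$rows, region$cols)] <- TRUE
    return(out)
  }
  if (is.matrix(region) && ncol(region) == 2L) {
    if (any(region[, 1] < 0.5) || any(region[, 1] > nr + 0.5) ||
        any(region[, 2] < 0.5) || any(region[, 2] > nc + 0.5))
      stop("region outside frame")
    ry <- region[, 1]; cx <- region[, 2]
    n <- length(ry)
    jj <- c(n, seq_len(n - 1L))
    for (r in seq_len(nr)) {
      # horizontal scanline through row centre r
      cross <- (ry > r) != (ry[jj] > r)
      if (!any(cross)) next
      xs <- cx[cross] + (r - ry[cross]) *
        (cx[jj][cross] - cx[cross]) / (ry[jj][cross] - ry[cross])
      xs <- sort(xs)
      for (i in seq(1, length(xs) - 1, by = 2)) {
        c0 <- ceiling(xs[i]); c1 <- floor(xs[i + 1])
        if (c1 >= c0) out[r, max(1, c0):min(nc, c1)] <- TRUE
      }
    }
    return(out)
  }
  stop("unrecognised region specification")
}
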