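# Minimal baseline-TIFF codec: multi-page, single-sample, 16-bit unsigned,
# uncompressed, little-endian.  Written from scratch because no TIFF package
# is available in this package's dependency footprint; the format subset is
# the TIFF 6.0 baseline required for grayscale microscopy stacks and is
# readable by standard tools (ImageJ, tifffile).

.TIFF_SHORT <- 3L
.TIFF_LONG <- 4L
.TIFF_ASCII <- 2L

.u16raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

.u32raw <- function(v) {
  v <- as.numeric(v)
  b0 <- v %% 256; v <- v %/% 256
  b1 <- v %% 256; v <- v %/% 256
  b2 <- v %% 256; b3 <- v %/% 256
  as.raw(rbind(b0, b1, b2, b3))
}

.ifd_entry <- function(tag, type, count, value_raw4) {
  c(.u16raw(tag), .u16raw(type), .u32raw(count), value_raw4)
}

# pages: list of integer/numeric matrices (row, col), values in [0, 65535].
# description: single string stored in the first page's ImageDescription.
write_tiff_pages <- function(path, pages, description = NULL) {
  stopifnot(length(pages) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.u16raw(42L), con)
  # precompute layout: header(8) | page strips | description | IFD chain
  strip_sizes <- vapply(pages, function(p) 2L * length(p), integer(1))
  strip_offsets <- 8 + cumsum(c(0, strip_sizes[-length(strip_sizes)]))
  desc <- NULL
  desc_off <- 0
  pos <- 8 + sum(strip_sizes)
  if (!is.null(description)) {
    desc <- c(charToRaw(description), as.raw(0L))
    if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))
    desc_off <- pos
    pos <- pos + length(desc)
  }
  n_entries <- function(i) if (i == 1L && !is.null(desc)) 10L else 9L
  ifd_sizes <- vapply(seq_along(pages), function(i) 2L + 12L * n_entries(i) + 4L,
                      integer(1))
  ifd_offsets <- pos + cumsum(c(0, ifd_sizes[-length(ifd_sizes)]))
  writeBin(.u32raw(ifd_offsets[1]), con)
  for (p in pages) {
    writeBin(.u16raw(as.vector(t(p))), con)  # TIFF is row-major
  }
  if (!is.null(desc)) writeBin(desc, con)
  short_val <- function(v) c(.u16raw(v), as.raw(c(0L, 0L)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    w <- ncol(p); h <- nrow(p)
    entries <- list(
      .ifd_entry(256L, .TIFF_LONG, 1L, .u32raw(w)),
      .ifd_entry(257L, .TIFF_LONG, 1L, .u32raw(h)),
      .ifd_entry(258L, .TIFF_SHORT, 1L, short_val(16L)),
      .ifd_entry(259L, .TIFF_SHORT, 1L, short_val(1L)),
      .ifd_entry(262L, .TIFF_SHORT, 1L, short_val(1L))
    )
    if (i == 1L && !is.null(desc)) {
      entries <- c(entries, list(
        .ifd_entry(270L, .TIFF_ASCII, length(desc), .u32raw(desc_off))))
    }
    entries <- c(entries, list(
      .ifd_entry(273L, .TIFF_LONG, 1L, .u32raw(strip_offsets[i])),
      .ifd_entry(277L, .TIFF_SHORT, 1L, short_val(1L)),
      .ifd_entry(278L, .TIFF_LONG, 1L, .u32raw(h)),
      .ifd_entry(279L, .TIFF_LONG, 1L, .u32raw(strip_sizes[i]))
    ))
    writeBin(.u16raw(length(entries)), con)
    for (e in entries) writeBin(e, con)
    nxt <- if (i < length(pages)) ifd_offsets[i + 1] else 0
    writeBin(.u32raw(nxt), con)
  }
  invisible(path)
}

.rd_u16 <- function(r, off, endian) {
  a <- as.integer(r[off + 1L]); b <- as.integer(r[off + 2L])
  if (endian == "little") a + 256L * b else 256L * a + b
}

.rd_u32 <- function(r, off, endian) {
  b <- as.numeric(as.integer(r[off + 1:4]))
  if (endian == "little") sum(b * c(1, 256, 65536, 16777216))
  else sum(rev(b) * c(1, 256, 65536, 16777216))
}

# Returns list(pages = list of integer matrices, description = chr | NA)
read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  r <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(r[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (.rd_u16(r, 2L, endian) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- .rd_u32(r, 4L, endian)
  pages <- list()
  description <- NA_character_
  type_size <- c(1L, 1L, 2L, 4L, 8L)
  while (ifd_off != 0) {
    n <- .rd_u16(r, ifd_off, endian)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd_off + 2L + 12L * (k - 1L)
      tag <- .rd_u16(r, e, endian)
      type <- .rd_u16(r, e + 2L, endian)
      count <- .rd_u32(r, e + 4L, endian)
      sz <- if (type <= 5L) type_size[type] else 1L
      nbytes <- sz * count
      voff <- if (nbytes <= 4) e + 8L else .rd_u32(r, e + 8L, endian)
      vals <- if (type == .TIFF_SHORT) {
        vapply(seq_len(count), function(j) .rd_u16(r, voff + 2L * (j - 1L), endian),
               integer(1))
      } else if (type == .TIFF_LONG) {
        vapply(seq_len(count), function(j) .rd_u32(r, voff + 4L * (j - 1L), endian),
               numeric(1))
      } else if (type == .TIFF_ASCII) {
        raw_s <- r[voff + seq_len(count)]
        raw_s <- raw_s[raw_s != as.raw(0L)]
        rawToChar(raw_s)
      } else NULL
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- g(256L); h <- g(257L)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    if (g(259L, 1L) != 1L) stop("unsupported TIFF compression")
    if (any(g(258L, 16L) != 16L)) stop("unsupported bits per sample (need 16)")
    if (g(277L, 1L) != 1L) stop("unsupported samples per pixel (need 1)")
    offs <- g(273L); cnts <- g(279L)
    if (is.null(offs) || is.null(cnts)) stop("TIFF page missing strip layout")
    buf <- raw(0)
    for (j in seq_along(offs)) buf <- c(buf, r[offs[j] + seq_len(cnts[j])])
    ints <- as.integer(buf[c(TRUE, FALSE)]) + 256L * as.integer(buf[c(FALSE, TRUE)])
    if (endian == "big")
      ints <- 256L * as.integer(buf[c(TRUE, FALSE)]) + as.integer(buf[c(FALSE, TRUE)])
    pages[[length(pages) + 1L]] <- matrix(ints, nrow = h, ncol = w, byrow = TRUE)
    if (is.na(description) && !is.null(g(270L))) description <- g(270L)
    ifd_off <- .rd_u32(r, ifd_off + 2L + 12L * n, endian)
  }
  list(pages = pages, description = description)
}
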