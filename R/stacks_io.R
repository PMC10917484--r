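#' 3D image stacks with a declared numeric precision
#'
#' An `image_stack` holds a 3D grid of real-valued intensities indexed as
#' (rows, cols, frames) together with a declared IEEE-754 precision.  Frame 1
#' corresponds to TIFF page 1 (Fiji's 1-based frame numbering).  R stores all
#' numerics as doubles; a stack declared `binary32` holds doubles whose values
#' are exactly binary32-representable, and the constructor enforces this by
#' rounding.
#'
#' @param data numeric 3D array (a matrix is promoted to a single-frame
#'   stack); all values must be finite.
#' @param precision `"binary32"` (default) or `"binary64"`.
#' @return An object of class `image_stack`: a list with elements `data`
#'   (3D array) and `precision`.
#' @examples
#' s <- image_stack(array(runif(24), c(2, 3, 4)))
#' dim(s)
#' @export
image_stack <- function(data, precision = c("binary32", "binary64")) {
  precision <- match.arg(precision)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L) {
    hd_stop("hd_error_bad_stack", "stack data must be a 3D array (rows, cols, frames)")
  }
  if (!is.numeric(data)) {
    hd_stop("hd_error_bad_stack", "stack data must be numeric")
  }
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    hd_stop("hd_error_bad_stack", "stack data must be finite (no NaN/Inf)")
  }
  if (any(dim(data) < 1L)) {
    hd_stop("hd_error_bad_stack", "every stack dimension must have length >= 1")
  }
  data <- precision_cast(precision)(data)
  structure(list(data = data, precision = precision), class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d (%s), range [%.6g, %.6g]\n",
              d[1], d[2], d[3], x$precision, min(x$data), max(x$data)))
  invisible(x)
}

#' Convert a stack to another declared precision
#'
#' Rounds every element to its nearest value at the target precision
#' (round-to-nearest-even) and updates the declared precision.  The input is
#' unchanged.  Converting to the precision the stack already has is the
#' identity; the operation is idempotent.
#'
#' @param stack an [image_stack].
#' @param precision `"binary32"` or `"binary64"`.
#' @return A new [image_stack] at the requested precision.
#' @examples
#' s64 <- image_stack(array(0.3, c(1, 1, 1)), "binary64")
#' s32 <- as_precision(s64, "binary32")
#' s32$data[1, 1, 1] == 0.300000011920928955078125
#' @export
as_precision <- function(stack, precision = c("binary32", "binary64")) {
  precision <- match.arg(precision)
  stopifnot(inherits(stack, "image_stack"))
  image_stack(precision_cast(precision)(stack$data), precision)
}

# ---------------------------------------------------------------------------
# Container formats.
#
# binary32 stacks are stored as uncompressed multi-page grayscale TIFF with
# IEEE float samples (SampleFormat = 3, 32 bits), one page per frame, readable
# by libtiff/Fiji.  The installed TIFF bindings read such files bit-exactly
# but cannot write float samples, so the writer below emits the (simple)
# baseline-TIFF byte layout itself; the round trip through the independent
# libtiff reader is part of the test suite.
#
# binary64 stacks use the package's raw container (extension .rawstack):
#   bytes 0..7   magic "HDRAWSTK"
#   int32        format version (1)
#   int32        bits per sample (32 or 64)
#   int32 x 3    rows, cols, frames
#   payload      little-endian IEEE floats, column-major within each frame,
#                frames in order
# ---------------------------------------------------------------------------

RAWSTACK_MAGIC <- charToRaw("HDRAWSTK")

tiff_ext <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

# A structurally valid TIFF header whose first-IFD offset is 0 declares a
# file with no image pages; libtiff rejects it with a generic open error, so
# the distinction is made here.
tiff_with_zero_pages <- function(path) {
  if (file.size(path) < 8) return(FALSE)
  hdr <- readBin(path, "raw", n = 8L)
  le <- identical(hdr[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00)))
  be <- identical(hdr[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a)))
  if (!le && !be) return(FALSE)
  off <- sum(as.integer(hdr[5:8]) * if (le) 256^(0:3) else 256^(3:0))
  off == 0
}
rawstack_ext <- function(path) grepl("\\.rawstack$", path, ignore.case = TRUE)

# Write a multi-page float32 grayscale baseline TIFF (little-endian, one
# strip per page).  `pages` is a list of numeric matrices.
write_float32_tiff <- function(pages, path) {
  n_pages <- length(pages)
  h <- nrow(pages[[1]])
  w <- ncol(pages[[1]])
  data_bytes <- as.numeric(w) * h * 4
  ifd_bytes <- 2 + 10 * 12 + 4
  total <- 8 + n_pages * (data_bytes + ifd_bytes)
  if (total > 2^31 - 1) {
    hd_stop("hd_error_unwritable", "stack too large for a classic TIFF container")
  }
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e) hd_stop("hd_error_unwritable",
                    sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con), add = TRUE)

  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry_long <- function(tag, value) { w16(tag); w16(4L); w32(1L); w32(value) }
  entry_short <- function(tag, value) { w16(tag); w16(3L); w32(1L); w16(value); w16(0L) }

  writeBin(charToRaw("II"), con)  # little-endian byte order mark
  w16(42L)
  first_ifd <- 8 + data_bytes
  w32(first_ifd)
  for (p in seq_len(n_pages)) {
    m <- pages[[p]]
    writeBin(as.double(as.vector(t(m))), con, size = 4L, endian = "little")
    w16(10L)  # entry count; tags must be ascending
    entry_long(256L, w)            # ImageWidth
    entry_long(257L, h)            # ImageLength
    entry_short(258L, 32L)         # BitsPerSample
    entry_short(259L, 1L)          # Compression: none
    entry_short(262L, 1L)          # Photometric: BlackIsZero
    data_off <- 8 + (p - 1) * (data_bytes + ifd_bytes)
    entry_long(273L, data_off)     # StripOffsets
    entry_short(277L, 1L)          # SamplesPerPixel
    entry_long(278L, h)            # RowsPerStrip
    entry_long(279L, data_bytes)   # StripByteCounts
    entry_short(339L, 3L)          # SampleFormat: IEEE float
    next_ifd <- if (p < n_pages) 8 + p * (data_bytes + ifd_bytes) + data_bytes else 0
    w32(next_ifd)
  }
  invisible(path)
}

write_rawstack <- function(stack, path, precision) {
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e) hd_stop("hd_error_unwritable",
                    sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con), add = TRUE)
  writeBin(RAWSTACK_MAGIC, con)
  writeBin(1L, con, size = 4L, endian = "little")
  bits <- if (precision == "binary32") 32L else 64L
  writeBin(bits, con, size = 4L, endian = "little")
  writeBin(as.integer(dim(stack$data)), con, size = 4L, endian = "little")
  writeBin(as.double(stack$data), con,
           size = if (precision == "binary32") 4L else 8L, endian = "little")
  invisible(path)
}

read_rawstack <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, RAWSTACK_MAGIC)) {
    hd_stop("hd_error_bad_format", sprintf("'%s' is not a rawstack container", path))
  }
  version <- readBin(con, "integer", size = 4L, endian = "little")
  if (!identical(version, 1L)) {
    hd_stop("hd_error_bad_format", sprintf("unsupported rawstack version %d", version))
  }
  bits <- readBin(con, "integer", size = 4L, endian = "little")
  dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  n <- prod(dims)
  vals <- readBin(con, "double", n = n, size = bits %/% 8L, endian = "little")
  if (length(vals) != n) {
    hd_stop("hd_error_bad_format", sprintf("rawstack payload truncated in '%s'", path))
  }
  dim(vals) <- dims
  image_stack(vals, if (bits == 32L) "binary32" else "binary64")
}

#' Read a 3D image stack from disk
#'
#' Reads a single- or multi-page grayscale TIFF (float32 pages bit-exactly;
#' 8/16-bit integer pages are promoted to float, keeping their raw integer
#' values), or the package's `.rawstack` container (which also carries
#' binary64 payloads).  Frames are ordered as stored pages.
#'
#' @param path path to a `.tif`/`.tiff` or `.rawstack` file.
#' @param precision target precision for the returned stack, or `NULL`
#'   (default) to keep the stored precision (TIFF pages are binary32 native;
#'   integer pages are promoted to binary32).
#' @return An [image_stack] of shape (rows, cols, frames).
#' @export
read_stack <- function(path, precision = NULL) {
  if (!file.exists(path)) {
    hd_stop("hd_error_missing_file", sprintf("no such file: '%s'", path))
  }
  stack <- if (rawstack_ext(path)) {
    read_rawstack(path)
  } else {
    pages <- tryCatch(
      tiff::readTIFF(path, all = TRUE, as.is = TRUE),
      error = function(e) {
        if (grepl("floating point", conditionMessage(e), fixed = TRUE)) {
          tiff::readTIFF(path, all = TRUE)
        } else if (tiff_with_zero_pages(path)) {
          hd_stop("hd_error_empty_stack",
                  sprintf("'%s' contains zero image pages", path))
        } else {
          hd_stop("hd_error_bad_format",
                  sprintf("cannot read '%s' as TIFF: %s", path, conditionMessage(e)))
        }
      })
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L) {
      hd_stop("hd_error_empty_stack", sprintf("'%s' contains zero image pages", path))
    }
    for (p in pages) {
      if (length(dim(p)) == 3L && dim(p)[3] > 1L) {
        hd_stop("hd_error_not_grayscale",
                sprintf("'%s' has %d channels per pixel; only grayscale stacks are supported",
                        path, dim(p)[3]))
      }
    }
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) dim(p) <- dim(p)[1:2]
      p
    })
    d1 <- dim(pages[[1]])
    if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1)))) {
      hd_stop("hd_error_bad_format", sprintf("pages of '%s' have inconsistent dimensions", path))
    }
    a <- array(0, c(d1, length(pages)))
    for (k in seq_along(pages)) a[, , k] <- pages[[k]]
    image_stack(a, "binary32")
  }
  if (!is.null(precision) && precision != stack$precision) {
    stack <- as_precision(stack, precision)
  }
  stack
}

#' Write a 3D image stack to disk
#'
#' binary32 stacks are written as uncompressed multi-page grayscale float32
#' TIFF (readable by Fiji and libtiff); binary64 stacks use the documented
#' `.rawstack` container, since classic TIFF readers do not support 64-bit
#' float samples.  Writing is bit-faithful at the declared precision:
#' `read_stack(write_stack(...))` reproduces the values exactly.
#'
#' @param stack an [image_stack].
#' @param path destination; `.tif`/`.tiff` for binary32, `.rawstack` for
#'   either precision.
#' @param precision storage precision; defaults to the stack's declared
#'   precision.
#' @param allow_narrowing set `TRUE` to permit writing a binary64 stack at
#'   binary32 (a lossy narrowing); otherwise this raises an error.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, precision = stack$precision,
                        allow_narrowing = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  precision <- check_precision(precision)
  if (stack$precision == "binary64" && precision == "binary32" && !allow_narrowing) {
    hd_stop("hd_error_precision_narrowing",
            "writing a binary64 stack at binary32 narrows precision; pass allow_narrowing = TRUE")
  }
  if (tiff_ext(path)) {
    if (precision == "binary64") {
      hd_stop("hd_error_unsupported_precision",
              "binary64 stacks cannot be stored as TIFF; use the .rawstack container")
    }
    data <- round_binary32(stack$data)
    pages <- lapply(seq_len(dim(data)[3]), function(k) data[, , k])
    write_float32_tiff(pages, path)
  } else if (rawstack_ext(path)) {
    write_rawstack(stack, path, precision)
  } else {
    hd_stop("hd_error_bad_format",
            sprintf("unsupported output format for '%s'; use .tif/.tiff or .rawstack", path))
  }
  invisible(path)
}
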