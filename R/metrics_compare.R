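#' Image-quality comparison between two stacks
#'
#' Computes, for each frame k with N pixels of reference r and test t:
#' `MSE = sum((r - t)^2) / N`, `RMSE = sqrt(MSE)`,
#' `MAE = sum(|r - t|) / N`, `SNR = 10*log10(sum(r^2) / sum((r - t)^2))` dB,
#' and `PSNR = 10*log10(max(r)^2 / MSE)` dB, with the peak taken from the
#' reference frame (inputs are float stacks, so no fixed bit-depth peak
#' applies).  The stack-level report aggregates each metric as mean +/- SD
#' over frames.  Identical frames yield RMSE = MAE = 0 and an infinite
#' SNR/PSNR sentinel; an all-zero reference frame has undefined SNR,
#' reported as `NA` for that frame.  RMSE and MAE are symmetric in
#' (ref, test); SNR and PSNR are not, since they normalize by the
#' reference.
#'
#' @param ref,test [image_stack]s or 3D arrays of identical shape.
#' @return An object of class `quality_report`: list with `per_frame` (data
#'   frame of frame, snr, psnr, rmse, mae), `summary` (mean and sd per
#'   metric), and `formulas` (the exact definitions used, so deviations from
#'   other tools are auditable).
#' @examples
#' a <- array(c(1, 1), c(1, 2, 1)); b <- array(c(1, 0), c(1, 2, 1))
#' quality(a, b)$per_frame$rmse  # sqrt(0.5)
#' @export
quality <- function(ref, test) {
  r <- if (inherits(ref, "image_stack")) ref$data else ref
  t <- if (inherits(test, "image_stack")) test$data else test
  if (!identical(dim(r), dim(t))) {
    hd_stop("hd_error_shape_mismatch",
            sprintf("shape mismatch: reference %s vs test %s",
                    paste(dim(r), collapse = "x"), paste(dim(t), collapse = "x")))
  }
  n_frames <- dim(r)[3]
  per <- data.frame(frame = seq_len(n_frames), snr = NA_real_,
                    psnr = NA_real_, rmse = NA_real_, mae = NA_real_)
  for (k in seq_len(n_frames)) {
    rk <- r[, , k]
    tk <- t[, , k]
    n <- length(rk)
    err2 <- sum((rk - tk)^2)
    mse <- err2 / n
    per$rmse[k] <- sqrt(mse)
    per$mae[k] <- sum(abs(rk - tk)) / n
    sig2 <- sum(rk^2)
    per$snr[k] <- if (err2 == 0) Inf else if (sig2 == 0) NA_real_ else 10 * log10(sig2 / err2)
    peak <- max(rk)
    per$psnr[k] <- if (mse == 0) Inf else if (peak == 0) NA_real_ else 10 * log10(peak^2 / mse)
  }
  summ <- data.frame(
    metric = c("snr", "psnr", "rmse", "mae"),
    mean = vapply(per[c("snr", "psnr", "rmse", "mae")], mean, numeric(1)),
    sd = vapply(per[c("snr", "psnr", "rmse", "mae")], stats::sd, numeric(1)),
    row.names = NULL)
  structure(list(
    per_frame = per,
    summary = summ,
    aggregation = "per-frame metrics, then mean +/- SD over frames",
    formulas = c(
      snr = "10*log10(sum(ref^2) / sum((ref-test)^2)) dB per frame",
      psnr = "10*log10(max(ref)^2 / MSE) dB per frame, peak from the reference frame",
      rmse = "sqrt(sum((ref-test)^2) / N) per frame",
      mae = "sum(|ref-test|) / N per frame")),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report> ", x$aggregation, "\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %s +/- %s\n", s$metric[i],
                format(s$mean[i], digits = 6), format(s$sd[i], digits = 3)))
  }
  invisible(x)
}

# Replace non-finite metric values by string sentinels for serialization.
inf_sentinel <- function(x) {
  ifelse(is.na(x), "undefined", ifelse(is.infinite(x), "+Inf", x))
}

#' Serialize a quality report to JSON
#'
#' Infinite SNR/PSNR values (identical inputs) are written as the string
#' sentinel `"+Inf"` and undefined values as `"undefined"`, never as JSON
#' non-finite numbers.
#'
#' @param report a `quality_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_quality_json <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  obj <- list(
    aggregation = report$aggregation,
    formulas = as.list(report$formulas),
    summary = lapply(seq_len(nrow(report$summary)), function(i) {
      list(metric = report$summary$metric[i],
           mean = inf_sentinel(report$summary$mean[i]),
           sd = inf_sentinel(report$summary$sd[i]))
    }),
    per_frame = lapply(seq_len(nrow(report$per_frame)), function(i) {
      p <- report$per_frame[i, ]
      list(frame = p$frame, snr = inf_sentinel(p$snr), psnr = inf_sentinel(p$psnr),
           rmse = p$rmse, mae = p$mae)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Byte-level comparison of two stored stacks
#'
#' Compares two files (or raw vectors) byte by byte.  Equal-length inputs
#' yield the exact set of differing byte offsets (0-based) plus a histogram
#' of offsets modulo 4: two binary32 payloads that differ only in low-order
#' mantissa bits differ in at most one byte per 4-byte word, which this
#' word-phase histogram exposes.  Length mismatch is reported as a
#' structural difference, not an error.  `n_differing_bytes == 0` holds
#' exactly when the payloads are byte-identical.
#'
#' @param a,b file paths or raw vectors.
#' @return An object of class `byte_diff_report`: `total_bytes`,
#'   `n_differing_bytes`, `differing_offsets` (0-based),
#'   `word_phase_histogram` (offsets mod 4), `structural_difference`.
#' @export
byte_compare <- function(a, b) {
  as_raw <- function(x) {
    if (is.raw(x)) return(x)
    if (!file.exists(x)) hd_stop("hd_error_missing_file", sprintf("no such file: '%s'", x))
    readBin(x, "raw", n = file.size(x))
  }
  ra <- as_raw(a)
  rb <- as_raw(b)
  if (length(ra) != length(rb)) {
    return(structure(list(structural_difference = TRUE,
                          total_bytes = c(a = length(ra), b = length(rb)),
                          n_differing_bytes = NA_integer_,
                          differing_offsets = integer(0),
                          word_phase_histogram = NULL),
                     class = "byte_diff_report"))
  }
  idx <- which(ra != rb)
  offsets <- idx - 1L
  structure(list(structural_difference = FALSE,
                 total_bytes = length(ra),
                 n_differing_bytes = length(offsets),
                 differing_offsets = offsets,
                 word_phase_histogram = table(factor(offsets %% 4L, levels = 0:3))),
            class = "byte_diff_report")
}

#' @export
print.byte_diff_report <- function(x, ...) {
  if (x$structural_difference) {
    cat(sprintf("<byte_diff_report> structural difference: %d vs %d bytes\n",
                x$total_bytes[["a"]], x$total_bytes[["b"]]))
  } else {
    cat(sprintf("<byte_diff_report> %d of %d bytes differ\n",
                x$n_differing_bytes, x$total_bytes))
    if (x$n_differing_bytes > 0) {
      cat("  offsets mod 4: ",
          paste(sprintf("%s:%d", names(x$word_phase_histogram), x$word_phase_histogram),
                collapse = " "), "\n")
    }
  }
  invisible(x)
}

#' Intensity profile along one row of one frame
#'
#' Returns the intensities along a full row of the given frame (both
#' 1-based, frame 1 = TIFF page 1).  The row defaults to the center row
#' `ceiling(n_rows / 2)`, covering the length of the image through its
#' approximate center.
#'
#' @param stack an [image_stack] or 3D array.
#' @param frame 1-based frame index.
#' @param row 1-based row index, default center row.
#' @return An object of class `line_profile`: `frame`, `row`, `positions`
#'   (1..n_cols), `values`.
#' @export
line_profile <- function(stack, frame, row = NULL) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  d <- dim(a)
  frame <- as.integer(frame)
  if (is.na(frame) || frame < 1L || frame > d[3]) {
    hd_stop("hd_error_out_of_range",
            sprintf("frame %s out of range 1..%d", frame, d[3]))
  }
  if (is.null(row)) row <- ceiling(d[1] / 2)
  row <- as.integer(row)
  if (is.na(row) || row < 1L || row > d[1]) {
    hd_stop("hd_error_out_of_range", sprintf("row %s out of range 1..%d", row, d[1]))
  }
  structure(list(frame = frame, row = row, positions = seq_len(d[2]),
                 values = a[row, , frame]),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> frame %d, row %d, %d positions, range [%.6g, %.6g]\n",
              x$frame, x$row, length(x$positions), min(x$values), max(x$values)))
  invisible(x)
}

#' Export a line profile as CSV
#'
#' Writes `position,value` rows suitable for external plotting.
#'
#' @param profile a `line_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "line_profile"))
  # %.17g guarantees the printed doubles parse back to the identical values
  utils::write.csv(data.frame(position = profile$positions,
                              value = sprintf("%.17g", profile$values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- exact decimal expansion of IEEE-754 values ----------------------------
# Every finite binary float is a dyadic rational m * 2^e; its decimal
# expansion is finite and computed exactly here with small-digit bignum
# arithmetic (no big-integer dependency is available, and the digit counts
# involved -- at most ~1080 for binary64 subnormals -- make schoolbook
# multiplication ample).

# digits: little-endian base-10 integer vector
big_mul_small <- function(digits, k) {
  v <- digits * k
  carry <- 0
  i <- 1L
  while (i <= length(v) || carry > 0) {
    if (i > length(v)) v[i] <- 0
    t <- v[i] + carry
    v[i] <- t %% 10
    carry <- t %/% 10
    i <- i + 1L
  }
  v
}

big_from_count <- function(m) {
  # m: nonnegative double holding an exact integer <= 2^53
  s <- sprintf("%.0f", m)
  rev(as.integer(strsplit(s, "")[[1]]))
}

big_to_string <- function(digits) {
  s <- paste(rev(digits), collapse = "")
  sub("^0+(?=.)", "", s, perl = TRUE)
}

# Decompose the stored IEEE value into (sign, m, e) with value = sign*m*2^e,
# m a nonnegative integer.
ieee_decompose <- function(x, precision) {
  size <- if (precision == "binary32") 4L else 8L
  n_mant <- if (precision == "binary32") 23L else 52L
  n_exp <- if (precision == "binary32") 8L else 11L
  bias <- if (precision == "binary32") 127L else 1023L
  r <- writeBin(as.double(x), raw(), size = size, endian = "little")
  bits <- as.integer(rawToBits(r))  # bit i-1 of the word at index i
  mant <- sum(bits[seq_len(n_mant)] * 2^(seq_len(n_mant) - 1))
  expo <- sum(bits[n_mant + seq_len(n_exp)] * 2^(seq_len(n_exp) - 1))
  sign <- if (bits[n_mant + n_exp + 1L] == 1L) -1 else 1
  if (expo == 2^n_exp - 1) {
    hd_stop("hd_error_unparseable", "value is not finite at the requested precision")
  }
  if (expo == 0) {
    list(sign = sign, m = mant, e = 1L - bias - n_mant)   # subnormal (or zero)
  } else {
    list(sign = sign, m = 2^n_mant + mant, e = expo - bias - n_mant)
  }
}

#' Exact decimal expansion of the nearest IEEE-754 value
#'
#' Parses `decimal_text`, rounds it to the nearest binary32 or binary64
#' value (round-to-nearest-even), and returns the full, untruncated decimal
#' expansion of that stored value.  For example the nearest binary32 to
#' `"0.3"` is exactly `0.300000011920928955078125`.  Parsing the returned
#' string back at the same precision recovers the identical stored value.
#'
#' @param decimal_text character scalar holding a finite decimal number.
#' @param precision `"binary32"` or `"binary64"`.
#' @return Character scalar: the exact decimal expansion.
#' @examples
#' float_repr("0.3", "binary32")
#' float_repr("0.5", "binary64")
#' @export
float_repr <- function(decimal_text, precision = c("binary32", "binary64")) {
  precision <- match.arg(precision)
  if (!is.character(decimal_text) || length(decimal_text) != 1L) {
    hd_stop("hd_error_unparseable", "decimal_text must be a single character string")
  }
  x <- suppressWarnings(as.numeric(decimal_text))
  if (is.na(x) || !is.finite(x)) {
    hd_stop("hd_error_unparseable",
            sprintf("'%s' does not parse as a finite decimal number", decimal_text))
  }
  if (precision == "binary32") {
    x <- readBin(writeBin(x, raw(), size = 4L), "double", size = 4L)
  }
  parts <- ieee_decompose(x, precision)
  if (parts$m == 0) return("0")
  digits <- big_from_count(parts$m)
  sign_str <- if (parts$sign < 0) "-" else ""
  if (parts$e >= 0) {
    for (i in seq_len(parts$e)) digits <- big_mul_small(digits, 2L)
    return(paste0(sign_str, big_to_string(digits)))
  }
  k <- -parts$e
  for (i in seq_len(k)) digits <- big_mul_small(digits, 5L)  # m*5^k = m*2^e * 10^k
  s <- big_to_string(digits)
  if (nchar(s) <= k) s <- paste0(strrep("0", k - nchar(s) + 1L), s)
  int_part <- substr(s, 1L, nchar(s) - k)
  frac_part <- substr(s, nchar(s) - k + 1L, nchar(s))
  frac_part <- sub("0+$", "", frac_part)
  if (frac_part == "") return(paste0(sign_str, int_part))
  paste0(sign_str, int_part, ".", frac_part)
}
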