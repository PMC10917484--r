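#' Default per-direction Hessian weights
#'
#' The Hessian penalty weights the six second-derivative components so the
#' off-diagonal terms, which each occur twice in the symmetric Hessian, count
#' double, and the axial (z) terms are scaled by the axial-continuity weight
#' `sigma`: one factor of `sigma` per z-derivative.  This gives
#' `w = (xx = 1, xy = 2, xz = 2*sigma, yy = 1, yz = 2*sigma, zz = sigma^2)`.
#' All weights can be overridden individually.
#'
#' @param sigma axial weight, >= 0.  `sigma = 0` disables the z-coupled
#'   terms (pure frame-by-frame 2D regularization).
#' @return Named numeric vector over the six directions.
#' @export
default_hessian_weights <- function(sigma = 1) {
  if (!(is.numeric(sigma) && length(sigma) == 1L && is.finite(sigma) && sigma >= 0)) {
    hd_stop("hd_error_bad_param", "sigma must be a single finite number >= 0")
  }
  c(xx = 1, xy = 2, xz = 2 * sigma, yy = 1, yz = 2 * sigma, zz = sigma^2)
}

check_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) != 6L ||
      !identical(sort(names(weights)), sort(DIRECTION_LABELS))) {
    hd_stop("hd_error_bad_param",
            "weights must be a numeric vector named xx, xy, xz, yy, yz, zz")
  }
  if (!all(is.finite(weights)) || any(weights < 0)) {
    hd_stop("hd_error_bad_param", "weights must be finite and >= 0")
  }
  weights[DIRECTION_LABELS]
}

#' Fourier-domain spectrum of the composite Hessian operator
#'
#' Builds the non-negative real grid `values[k] = sum_d w_d^2 *
#' prod_{axes a of d} (2 - 2*cos(2*pi*k_a/n_a))` over the periodic frequency
#' lattice of the given shape: the squared modulus of the DFT of each
#' (circulant) second-difference stencil, weighted and summed over the six
#' directions.  This is the denominator of the FFT-based image update and
#' depends only on the stack shape, `sigma` and the weights, so it is built
#' once per shape and can be persisted (see [load_or_build]).
#'
#' The spectrum is exactly zero at DC (`values[1,1,1] == 0`: second
#' differences annihilate constants), symmetric under frequency negation,
#' and deterministic (identical inputs give bit-identical values).
#'
#' @param shape integer vector (n1, n2, n3), all >= 1.
#' @param sigma axial weight; only consulted through the default `weights`.
#' @param weights per-direction weights; default [default_hessian_weights].
#' @return An object of class `operator_spectrum`: list with `shape`,
#'   `sigma`, `weights`, `values` (n1 x n2 x n3 array).
#' @examples
#' sp <- build_spectrum(c(2, 1, 1), sigma = 1,
#'                      weights = c(xx = 1, xy = 1, xz = 1, yy = 1, yz = 1, zz = 1))
#' sp$values[2, 1, 1]  # (2 - 2*cos(pi))^2 = 16, xx is the only active term
#' @export
build_spectrum <- function(shape, sigma = 1,
                           weights = default_hessian_weights(sigma)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    hd_stop("hd_error_bad_shape", "shape must be three positive integers")
  }
  weights <- check_weights(weights)
  # |DFT of the 1D second/first-difference stencil|^2 factor per axis:
  # 2 - 2*cos(2*pi*k/n), exactly 0 at k = 0.
  omega <- lapply(shape, function(n) 2 - 2 * cos(2 * pi * (0:(n - 1L)) / n))
  values <- array(0, shape)
  dirs <- hessian_directions()
  for (d in DIRECTION_LABELS) {  # fixed summation order for determinism
    ax <- dirs[[d]]
    fac <- lapply(1:3, function(a) {
      m <- sum(ax == a)
      if (m == 0L) rep(1, shape[a]) else omega[[a]]^m
    })
    values <- values + weights[[d]]^2 *
      outer(outer(fac[[1]], fac[[2]]), fac[[3]])
  }
  structure(list(shape = shape, sigma = as.double(sigma),
                 weights = weights, values = values),
            class = "operator_spectrum")
}

#' @export
print.operator_spectrum <- function(x, ...) {
  cat(sprintf("<operator_spectrum> shape %s, sigma %g, max %g\n",
              paste(x$shape, collapse = " x "), x$sigma, max(x$values)))
  invisible(x)
}

#' Shape-keyed cache identifier
#'
#' Returns the `"n1-n2-n3"` string used as the cache filename stem for a
#' stack shape, e.g. `"128-256-180"`.  Injective over shapes.
#'
#' @param shape integer vector (n1, n2, n3).
#' @return Character scalar.
#' @export
cache_key <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    hd_stop("hd_error_bad_shape", "shape must be three positive integers")
  }
  paste(shape, collapse = "-")
}

spectrum_cache_path <- function(cache_dir, shape) {
  file.path(cache_dir, paste0(cache_key(shape), ".rds"))
}

valid_spectrum_record <- function(obj, shape) {
  is.list(obj) &&
    identical(obj$format_version, 1L) &&
    inherits(obj$spectrum, "operator_spectrum") &&
    identical(obj$spectrum$shape, as.integer(shape)) &&
    is.numeric(obj$spectrum$sigma) &&
    is.numeric(obj$spectrum$weights) && length(obj$spectrum$weights) == 6L &&
    is.array(obj$spectrum$values) &&
    identical(dim(obj$spectrum$values), as.integer(shape)) &&
    all(is.finite(obj$spectrum$values))
}

#' Load a persisted operator spectrum, or build and persist it
#'
#' On a cache miss the spectrum is built, written under
#' `cache_dir/<n1-n2-n3>.rds` (a self-describing record carrying shape,
#' sigma, weights and a format version) and returned.  On a hit the stored
#' spectrum is returned, bit-identical to a fresh build.  A cache file whose
#' stored `sigma`/`weights` differ from the request is stale and is rebuilt;
#' a corrupt or unreadable file is rebuilt and overwritten with a warning.
#'
#' @inheritParams build_spectrum
#' @param cache_dir writable directory (created if absent).
#' @return An `operator_spectrum`.
#' @export
load_or_build <- function(shape, sigma = 1,
                          weights = default_hessian_weights(sigma),
                          cache_dir = tempdir()) {
  weights <- check_weights(weights)
  if (!dir.exists(cache_dir)) {
    ok <- dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) hd_stop("hd_error_unwritable",
                     sprintf("cannot create cache directory '%s'", cache_dir))
  }
  path <- spectrum_cache_path(cache_dir, shape)
  if (file.exists(path)) {
    obj <- tryCatch(readRDS(path), error = function(e) NULL)
    if (!is.null(obj) && valid_spectrum_record(obj, shape)) {
      sp <- obj$spectrum
      if (identical(sp$sigma, as.double(sigma)) &&
          identical(unname(sp$weights), unname(weights))) {
        hd_log("DEBUG", "spectrum cache hit: ", path)
        return(sp)
      }
      hd_log("DEBUG", "spectrum cache stale (sigma/weights changed): ", path)
    } else {
      hd_warn("hd_warning_corrupt_cache",
              sprintf("corrupt spectrum cache '%s'; rebuilding", path))
    }
  } else {
    hd_log("DEBUG", "spectrum cache miss: ", path)
  }
  sp <- build_spectrum(shape, sigma, weights)
  saveRDS(list(format_version = 1L, spectrum = sp), path)
  sp
}
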