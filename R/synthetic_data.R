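#' Phantom specification
#'
#' Describes a synthetic 3D fluorescence stack: smooth bright curvilinear
#' filaments on a dark background, blurred by a Gaussian point-spread
#' function and corrupted by Gaussian read noise and (optionally) Poisson
#' shot noise.  The default shape matches the 128 x 256 x 180 stacks the
#' denoiser targets; tests scale it down.
#'
#' @param shape stack shape (rows, cols, frames); default
#'   `c(128, 256, 180)`.
#' @param n_filaments number of random 3D polyline filaments.
#' @param filament_intensity peak intensity of the filament structure
#'   (arbitrary camera units; defaults give a unit-scale stack).
#' @param background constant background level, >= 0.
#' @param psf_sigma Gaussian blur width in voxels.
#' @param gaussian_noise_sd standard deviation of additive Gaussian noise.
#' @param poisson if `TRUE`, the signal term is replaced by
#'   `Poisson(photon_scale * clean) / photon_scale` before Gaussian noise is
#'   added.
#' @param photon_scale photons per intensity unit for the Poisson model,
#'   > 0.
#' @param seed integer seed; the phantom is fully determined by it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 256L, 180L), n_filaments = 12L,
                         filament_intensity = 1, background = 0.05,
                         psf_sigma = 1.5, gaussian_noise_sd = 0.1,
                         poisson = FALSE, photon_scale = 500, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    hd_stop("hd_error_bad_shape", "shape must be three positive integers")
  }
  stopifnot(n_filaments >= 0, filament_intensity >= 0, background >= 0,
            psf_sigma >= 0, gaussian_noise_sd >= 0, photon_scale > 0)
  structure(list(shape = shape, n_filaments = as.integer(n_filaments),
                 filament_intensity = as.double(filament_intensity),
                 background = as.double(background),
                 psf_sigma = as.double(psf_sigma),
                 gaussian_noise_sd = as.double(gaussian_noise_sd),
                 poisson = isTRUE(poisson),
                 photon_scale = as.double(photon_scale),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Periodic separable Gaussian blur via FFT; kernel normalized to unit sum so
# the stack mean is preserved.
gaussian_blur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  kern1 <- function(n) {
    i <- 0:(n - 1L)
    dist <- pmin(i, n - i)  # circular distance to index 0
    k <- exp(-dist^2 / (2 * sigma^2))
    k / sum(k)
  }
  k3 <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  out <- Re(stats::fft(stats::fft(x) * stats::fft(k3), inverse = TRUE)) / length(x)
  pmax(out, 0)  # clip FFT round-off undershoot; the blur of a nonneg field is nonneg
}

#' Generate a clean/noisy phantom pair
#'
#' Draws `n_filaments` random 3D polylines (random start, smoothly wandering
#' direction), rasterizes them into the grid, blurs with the Gaussian PSF,
#' rescales so the structure peaks at `filament_intensity`, and adds the
#' background to give the clean stack.  The noisy stack applies the declared
#' noise model.  The global RNG state is saved and restored, so generation
#' has no side effects; the same seed always yields byte-identical output.
#'
#' @param spec a [phantom_spec].
#' @return List with elements `clean` and `noisy`, both binary64
#'   [image_stack]s of shape `spec$shape`.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(16, 16, 8), seed = 7))
#' range(ph$clean$data)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    d <- spec$shape
    acc <- array(0, d)
    if (spec$n_filaments > 0L && spec$filament_intensity > 0) {
      n_steps <- max(4L, ceiling(1.5 * max(d)))
      for (fil in seq_len(spec$n_filaments)) {
        pos <- stats::runif(3) * (d - 1) + 1
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        for (s in seq_len(n_steps)) {
          ix <- round(pos)
          if (all(ix >= 1) && all(ix <= d)) {
            acc[ix[1], ix[2], ix[3]] <- acc[ix[1], ix[2], ix[3]] + 1
          }
          # wander smoothly: small random kick, renormalized
          dir <- dir + 0.25 * stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          pos <- pos + 0.5 * dir
        }
      }
      acc <- gaussian_blur3(acc, spec$psf_sigma)
      m <- max(acc)
      if (m > 0) acc <- acc * (spec$filament_intensity / m)
    }
    clean <- spec$background + acc
    signal <- if (spec$poisson) {
      stats::rpois(length(clean), spec$photon_scale * clean) / spec$photon_scale
    } else {
      clean
    }
    noisy <- signal + stats::rnorm(length(clean), 0, spec$gaussian_noise_sd)
    dim(noisy) <- d
    list(clean = image_stack(clean, "binary64"),
         noisy = image_stack(noisy, "binary64"))
  })
}
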