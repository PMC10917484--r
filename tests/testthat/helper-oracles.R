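# Independent oracles used across the suite.  These deliberately avoid the
# package's operator implementations: differences are computed with explicit
# element-by-element loops, adjoints through materialized operator matrices,
# and spectra through DFTs of explicit periodic stencils.

DIRS <- c("xx", "xy", "xz", "yy", "yz", "zz")
DIR_AXES <- list(xx = c(1, 1), xy = c(1, 2), xz = c(1, 3),
                 yy = c(2, 2), yz = c(2, 3), zz = c(3, 3))

# forward difference with zero-filled last slice, triple loop
loop_forward_diff <- function(a, dim) {
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    nxt <- idx
    nxt[dim] <- nxt[dim] + 1L
    if (nxt[dim] <= d[dim]) {
      out[i, j, k] <- a[nxt[1], nxt[2], nxt[3]] - a[i, j, k]
    }
  }
  out
}

# backward difference with zero-filled first slice, triple loop
loop_back_diff <- function(a, dim) {
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    prv <- idx
    prv[dim] <- prv[dim] - 1L
    if (prv[dim] >= 1L) {
      out[i, j, k] <- a[i, j, k] - a[prv[1], prv[2], prv[3]]
    }
  }
  out
}

loop_second_diff <- function(a, d) {
  ax <- DIR_AXES[[d]]
  if (ax[1] == ax[2]) {
    loop_back_diff(loop_forward_diff(a, ax[1]), ax[1])
  } else {
    loop_forward_diff(loop_forward_diff(a, ax[1]), ax[2])
  }
}

# Materialize a linear operator on grids of the given shape as an explicit
# matrix, by applying it to every basis vector.
materialize <- function(op, shape) {
  n <- prod(shape)
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- array(0, shape)
    e[j] <- 1
    m[, j] <- as.vector(op(e))
  }
  m
}

# Loop transcriptions of the first-difference adjoints (the explicit
# boundary formulas of F^T and B^T, applied element by element).
loop_adj_forward <- function(a, dim) {
  d <- dim(a)
  n <- d[dim]
  out <- array(0, d)
  if (n < 2) return(out)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    p <- idx[dim]
    at <- function(q) { idx2 <- idx; idx2[dim] <- q; a[idx2[1], idx2[2], idx2[3]] }
    out[i, j, k] <- if (p == 1) -at(1) else if (p == n) at(n - 1) else at(p - 1) - at(p)
  }
  out
}

loop_adj_back <- function(a, dim) {
  d <- dim(a)
  n <- d[dim]
  out <- array(0, d)
  if (n < 2) return(out)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    p <- idx[dim]
    at <- function(q) { idx2 <- idx; idx2[dim] <- q; a[idx2[1], idx2[2], idx2[3]] }
    out[i, j, k] <- if (p == 1) -at(2) else if (p == n) at(n) else at(p) - at(p + 1)
  }
  out
}

loop_adjoint_second_diff <- function(a, d) {
  ax <- DIR_AXES[[d]]
  if (ax[1] == ax[2]) {
    loop_adj_forward(loop_adj_back(a, ax[1]), ax[1])
  } else {
    loop_adj_forward(loop_adj_forward(a, ax[2]), ax[1])
  }
}

# Straight-line transcription of one split-Bregman iteration: loop-based
# second differences and adjoints, scalar-loop shrinkage, and the FFT image
# update written out.  Binary64 throughout.
oracle_iterate_once <- function(u, f, state, spec_values, mu, lambda, weights) {
  shape <- dim(u)
  csum <- NULL
  newstate <- state
  for (d in DIRS) {
    s <- loop_second_diff(u, d) + state$b[[d]]
    t_d <- weights[[d]] / lambda
    dp <- array(0, shape)
    for (i in seq_along(s)) dp[i] <- sign(s[i]) * max(abs(s[i]) - t_d, 0)
    bp <- s - dp
    r <- dp - bp
    cd <- weights[[d]] * loop_adjoint_second_diff(r, d)
    newstate$d[[d]] <- dp
    newstate$b[[d]] <- bp
    csum <- if (is.null(csum)) cd else csum + cd
  }
  rhs <- mu * f + lambda * csum
  unew <- Re(stats::fft(stats::fft(rhs) / (mu + lambda * spec_values),
                        inverse = TRUE)) / length(rhs)
  list(u = unew, state = newstate)
}

# Spectrum oracle: squared modulus of the DFT of explicit periodic stencils.
stencil_1d <- function(n, order) {
  k <- rep(0, n)
  if (order == 1) {        # forward difference a[i+1] - a[i], circulant
    k[1] <- -1
    if (n >= 2) k[2] <- k[2] + 1 else k[1] <- k[1] + 1
  } else {                 # second difference, circulant [1, -2, 1]
    k[1] <- -2
    if (n >= 2) {
      k[2] <- k[2] + 1
      k[n] <- k[n] + 1
    } else {
      k[1] <- k[1] + 2
    }
  }
  k
}

stencil_spectrum <- function(shape, weights) {
  values <- array(0, shape)
  for (d in DIRS) {
    ax <- DIR_AXES[[d]]
    k1 <- if (1 %in% ax) stencil_1d(shape[1], sum(ax == 1)) else c(1, rep(0, shape[1] - 1))
    k2 <- if (2 %in% ax) stencil_1d(shape[2], sum(ax == 2)) else c(1, rep(0, shape[2] - 1))
    k3 <- if (3 %in% ax) stencil_1d(shape[3], sum(ax == 3)) else c(1, rep(0, shape[3] - 1))
    kern <- outer(outer(k1, k2), k3)
    values <- values + weights[[d]]^2 * Mod(stats::fft(kern))^2
  }
  values
}

# independent binary32 rounding (C float cast via a 4-byte buffer)
f32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L), "double", size = 4L,
               n = length(x))
  dim(y) <- d
  y
}

rmse_of <- function(a, b) {
  x <- if (inherits(a, "image_stack")) a$data else a
  y <- if (inherits(b, "image_stack")) b$data else b
  sqrt(mean((x - y)^2))
}

small_phantom <- function(shape = c(16, 16, 8), seed = 1, noise_sd = 0.1, ...) {
  make_phantom(phantom_spec(shape = shape, seed = seed,
                            gaussian_noise_sd = noise_sd, n_filaments = 4, ...))
}
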