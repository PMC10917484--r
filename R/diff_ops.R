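#' The six Hessian directions
#'
#' The 3D Hessian has six independent second-derivative components: xx, xy,
#' xz, yy, yz, zz.  Each maps to the ordered pair of axes its second
#' difference acts on (x = rows = axis 1, y = cols = axis 2, z = frames =
#' axis 3); diagonal members repeat one axis.
#'
#' @return Named list of length 6; each element is an integer pair of axes.
#' @examples
#' hessian_directions()$xy
#' @export
hessian_directions <- function() {
  list(xx = c(1L, 1L), xy = c(1L, 2L), xz = c(1L, 3L),
       yy = c(2L, 2L), yz = c(2L, 3L), zz = c(3L, 3L))
}

DIRECTION_LABELS <- c("xx", "xy", "xz", "yy", "yz", "zz")

check_direction <- function(d) {
  if (!is.character(d) || length(d) != 1L || !(d %in% DIRECTION_LABELS)) {
    hd_stop("hd_error_bad_direction",
            sprintf("direction must be one of %s", paste(DIRECTION_LABELS, collapse = ", ")))
  }
  d
}

check_axis <- function(dim) {
  if (!(length(dim) == 1L && dim %in% 1:3)) {
    hd_stop("hd_error_bad_axis", "axis must be 1, 2 or 3")
  }
  as.integer(dim)
}

#' Call-count instrumentation
#'
#' A mutable counter record tracking how often the difference operators and
#' the shrinkage step execute.  Instrumentation is opt-in: operators only
#' touch counters when one is passed, so the disabled path has zero overhead.
#' In the reference denoiser each of the six directional tasks applies four
#' first-difference operators per iteration (two forward-type, two
#' backward-type), i.e. 24 difference calls and 6 shrinkage executions per
#' iteration.
#'
#' @return An object of class `call_counters` (an environment) with fields
#'   `forward_calls`, `backward_calls`, `shrink_executions`,
#'   `iterations_completed`, all starting at 0.
#' @examples
#' ctr <- call_counters()
#' forward_diff(array(1, c(2, 2, 2)), 1, counters = ctr)
#' as.list(ctr)$forward_calls
#' @export
call_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$forward_calls <- 0L
  e$backward_calls <- 0L
  e$shrink_executions <- 0L
  e$iterations_completed <- 0L
  class(e) <- "call_counters"
  e
}

counter_bump <- function(counters, field, by = 1L) {
  if (!is.null(counters)) {
    counters[[field]] <- counters[[field]] + as.integer(by)
  }
  invisible(counters)
}

counter_merge <- function(counters, delta) {
  if (!is.null(counters)) {
    for (f in c("forward_calls", "backward_calls", "shrink_executions")) {
      counters[[f]] <- counters[[f]] + delta[[f]]
    }
  }
  invisible(counters)
}

#' @export
as.list.call_counters <- function(x, ...) {
  list(forward_calls = x$forward_calls,
       backward_calls = x$backward_calls,
       shrink_executions = x$shrink_executions,
       iterations_completed = x$iterations_completed)
}

#' @export
print.call_counters <- function(x, ...) {
  cat(sprintf(paste0("<call_counters> forward: %d, backward: %d, ",
                     "shrink: %d, iterations: %d\n"),
              x$forward_calls, x$backward_calls,
              x$shrink_executions, x$iterations_completed))
  invisible(x)
}

#' Size-reducing adjacent difference
#'
#' The raw adjacent-element difference `a[i+1] - a[i]` along one axis, before
#' any zero-fill: the output loses one slice along `dim` (a 128 x 256 x 180
#' input differenced along axis 1 yields 127 x 256 x 180).  Both public
#' difference operators are built on this quantity and restore the input
#' shape by writing zeros into the lost boundary slice.
#'
#' @param a numeric 3D array.
#' @param dim axis (1, 2 or 3).
#' @param impl `"vectorized"` (single preallocated slab subtraction) or
#'   `"naive"` (copies the two shifted operands into temporaries slice by
#'   slice before subtracting, mirroring a straightforward hand-written
#'   implementation).  Both produce bit-identical values.
#' @return Array with `dim(a)[dim] - 1` slices along `dim` (zero slices if
#'   the axis has length 1).
#' @export
first_diff_reduced <- function(a, dim, impl = c("vectorized", "naive")) {
  impl <- match.arg(impl)
  dim <- check_axis(dim)
  d <- dim(a)
  n <- d[dim]
  dd <- d
  dd[dim] <- max(n - 1L, 0L)
  if (n < 2L) return(array(0, dd))
  if (impl == "vectorized") {
    return(slab(a, dim, 2:n) - slab(a, dim, 1:(n - 1L)))
  }
  # naive: materialize both shifted operands with per-slice copies
  a1 <- array(0, dd)
  a2 <- array(0, dd)
  for (i in seq_len(n - 1L)) {
    slab(a1, dim, i) <- slab(a, dim, i + 1L)
    slab(a2, dim, i) <- slab(a, dim, i)
  }
  a1 - a2
}

#' First-order finite differences with zero-fill
#'
#' `forward_diff` computes `out[i] = a[i+1] - a[i]` along `dim` for positions
#' `1..n-1` and writes zeros into the last slice; `back_diff` computes
#' `out[i] = a[i] - a[i-1]` for positions `2..n` and zeros the first slice.
#' Output shape always equals input shape.  A length-1 axis yields an
#' all-zero result.
#'
#' @param a finite numeric 3D array.
#' @param dim axis (1, 2 or 3).
#' @param impl `"vectorized"` or `"naive"`; bit-identical results (see
#'   [first_diff_reduced]).
#' @param counters optional [call_counters]; when supplied, `forward_diff`
#'   increments `forward_calls` and `back_diff` increments `backward_calls`.
#' @return Array of the same shape as `a`.
#' @examples
#' a <- array(seq_len(8), c(2, 2, 2))
#' forward_diff(a, 1)
#' @export
forward_diff <- function(a, dim, impl = c("vectorized", "naive"), counters = NULL) {
  impl <- match.arg(impl)
  dim <- check_axis(dim)
  counter_bump(counters, "forward_calls")
  n <- dim(a)[dim]
  out <- array(0, dim(a))
  if (n >= 2L) {
    red <- first_diff_reduced(a, dim, impl)
    if (impl == "naive") {
      for (i in seq_len(n - 1L)) slab(out, dim, i) <- slab(red, dim, i)
    } else {
      slab(out, dim, 1:(n - 1L)) <- red
    }
  }
  out
}

#' @rdname forward_diff
#' @export
back_diff <- function(a, dim, impl = c("vectorized", "naive"), counters = NULL) {
  impl <- match.arg(impl)
  dim <- check_axis(dim)
  counter_bump(counters, "backward_calls")
  n <- dim(a)[dim]
  out <- array(0, dim(a))
  if (n >= 2L) {
    red <- first_diff_reduced(a, dim, impl)
    if (impl == "naive") {
      for (i in seq_len(n - 1L)) slab(out, dim, i + 1L) <- slab(red, dim, i)
    } else {
      slab(out, dim, 2:n) <- red
    }
  }
  out
}

# Exact adjoints of the zero-filled first differences (derived from the
# explicit operator matrices; validated against a transpose oracle in the
# tests).  With F = forward_diff, B = back_diff along an axis of length n:
#   (F^T y)[1] = -y[1];  (F^T y)[j] = y[j-1] - y[j], j in 2..n-1;  (F^T y)[n] = y[n-1]
#   (B^T y)[1] = -y[2];  (B^T y)[j] = y[j] - y[j+1], j in 2..n-1;  (B^T y)[n] = y[n]
# F^T is backward-type and B^T forward-type, so together with one forward and
# one backward call per direction they preserve the two-of-each call pattern.
adj_forward_diff <- function(a, dim, counters = NULL) {
  dim <- check_axis(dim)
  counter_bump(counters, "backward_calls")
  n <- dim(a)[dim]
  out <- array(0, dim(a))
  if (n >= 2L) {
    slab(out, dim, 1L) <- -slab(a, dim, 1L)
    if (n >= 3L) {
      slab(out, dim, 2:(n - 1L)) <- slab(a, dim, 1:(n - 2L)) - slab(a, dim, 2:(n - 1L))
    }
    slab(out, dim, n) <- slab(a, dim, n - 1L)
  }
  out
}

adj_back_diff <- function(a, dim, counters = NULL) {
  dim <- check_axis(dim)
  counter_bump(counters, "forward_calls")
  n <- dim(a)[dim]
  out <- array(0, dim(a))
  if (n >= 2L) {
    slab(out, dim, 1L) <- -slab(a, dim, 2L)
    if (n >= 3L) {
      slab(out, dim, 2:(n - 1L)) <- slab(a, dim, 2:(n - 1L)) - slab(a, dim, 3:n)
    }
    slab(out, dim, n) <- slab(a, dim, n)
  }
  out
}

#' Second-order finite differences and their adjoints
#'
#' `second_diff` applies the discrete second derivative for one Hessian
#' direction: diagonal directions (xx, yy, zz) compose
#' `back_diff(forward_diff(a, ax), ax)`; cross directions (xy, xz, yz)
#' compose two forward differences, `forward_diff(forward_diff(a, ax1), ax2)`.
#' `adjoint_second_diff` applies the exact linear adjoint (matrix transpose)
#' of the same operator under the zero-fill convention, so that
#' `<second_diff(x, d), y> == <x, adjoint_second_diff(y, d)>` for all x, y.
#'
#' @param a finite numeric 3D array.
#' @param d direction label: one of `"xx"`, `"xy"`, `"xz"`, `"yy"`, `"yz"`,
#'   `"zz"`.
#' @param impl passed to the constituent first differences.
#' @param counters optional [call_counters]; each call applies four
#'   first-difference operators in total across the forward and adjoint pair
#'   (two forward-type, two backward-type).
#' @return Array of the same shape as `a`.
#' @examples
#' a <- array(0, c(5, 1, 1)); a[, 1, 1] <- (0:4)^2
#' second_diff(a, "xx")[2:4, 1, 1]  # constant 2 in the interior
#' @export
second_diff <- function(a, d, impl = c("vectorized", "naive"), counters = NULL) {
  impl <- match.arg(impl)
  d <- check_direction(d)
  ax <- hessian_directions()[[d]]
  if (ax[1] == ax[2]) {
    back_diff(forward_diff(a, ax[1], impl, counters), ax[1], impl, counters)
  } else {
    forward_diff(forward_diff(a, ax[1], impl, counters), ax[2], impl, counters)
  }
}

#' @rdname second_diff
#' @export
adjoint_second_diff <- function(a, d, impl = c("vectorized", "naive"),
                                counters = NULL) {
  d <- check_direction(d)
  ax <- hessian_directions()[[d]]
  if (ax[1] == ax[2]) {
    # (B o F)^T = F^T o B^T
    adj_forward_diff(adj_back_diff(a, ax[1], counters), ax[1], counters)
  } else {
    # (F_b o F_a)^T = F_a^T o F_b^T
    adj_forward_diff(adj_forward_diff(a, ax[2], counters), ax[1], counters)
  }
}
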