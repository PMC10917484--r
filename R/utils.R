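# Internal helpers shared across modules.

# Extract a slab of a 3D array along `dim` at indices `idx`, keeping
# dimensions.  `idx = TRUE` selects everything along an axis.
slab <- function(a, dim, idx) {
  i <- list(TRUE, TRUE, TRUE)
  i[[dim]] <- idx
  a[i[[1]], i[[2]], i[[3]], drop = FALSE]
}

`slab<-` <- function(a, dim, idx, value) {
  i <- list(TRUE, TRUE, TRUE)
  i[[dim]] <- idx
  a[i[[1]], i[[2]], i[[3]]] <- value
  a
}

# Round every element of x to its nearest IEEE-754 binary32 value, returning
# doubles that hold exactly binary32-representable values.  The round trip
# through a 4-byte buffer uses the C float cast (round-to-nearest-even).
round_binary32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L),
               what = "double", size = 4L, n = length(x))
  dim(y) <- d
  y
}

PRECISIONS <- c("binary32", "binary64")

check_precision <- function(precision) {
  match.arg(precision, PRECISIONS)
}

# Identity for binary64, binary32 rounding otherwise.  Used to enforce the
# uniform-precision policy: every array-valued intermediate in a binary32 run
# is stored at binary32.
precision_cast <- function(precision) {
  if (precision == "binary32") round_binary32 else identity
}

# Condition constructors: every user-facing failure mode has a distinct class
# under the "hd_error" umbrella so callers (and the CLI) can dispatch on it.
hd_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "hd_error")))
}

hd_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "hd_warning")))
}

# Minimal leveled logger writing to stderr; level set via
# options(hessdenoise.log_level = "DEBUG"|"INFO"|"WARN").
hd_log <- function(level = c("INFO", "DEBUG", "WARN"), ...) {
  level <- match.arg(level)
  threshold <- getOption("hessdenoise.log_level", "INFO")
  ranks <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

# Evaluate `expr` with the global RNG seeded to `seed`, restoring any
# pre-existing RNG state afterwards, so callers never observe a global
# side effect.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Largest absolute elementwise discrepancy between a and b, relative to the
# largest magnitude in b.  This is the package's definition of "max relative
# error" for whole-stack comparisons (documented in the vignette; it avoids
# division by near-zero background voxels).
max_rel_err <- function(a, b) {
  denom <- max(abs(b))
  if (denom == 0) {
    return(if (max(abs(a)) == 0) 0 else Inf)
  }
  max(abs(a - b)) / denom
}
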