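#' @keywords internal
#' @importFrom randomForest randomForest
#' @importFrom e1071 svm
#' @importFrom class knn
#' @importFrom jsonlite fromJSON
#' @importFrom png readPNG
#' @importFrom stats rnorm runif predict
"_PACKAGE"

# Condition helpers: every domain error carries a subclass so callers can
# distinguish e.g. a missing face from an I/O failure.
fs_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fs_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

fs_warning <- function(class, msg) {
  warning(structure(
    class = c(class, "fs_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package functions are deterministic without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a root seed and one or more integer keys.
# Linear congruential folding keeps every derived seed in [0, 2^31 - 2].
derive_seed <- function(root, ...) {
  keys <- c(...)
  s <- as.double(root) %% 2147483647
  for (k in keys) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Vectorized bilinear sampling of an image matrix at continuous 0-based
# (x, y) positions; samples outside the image contribute 0.
bilinear_sample <- function(image, x, y) {
  h <- nrow(image)
  w <- ncol(image)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  px <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xi))
    v[ok] <- image[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  (1 - fx) * (1 - fy) * px(x0, y0) +
    fx * (1 - fy) * px(x0 + 1, y0) +
    (1 - fx) * fy * px(x0, y0 + 1) +
    fx * fy * px(x0 + 1, y0 + 1)
}
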