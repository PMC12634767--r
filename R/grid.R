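#' Normalized time grid
#'
#' Construct the common grid of `K` time points on the normalized cycle
#' interval \[0, 1\].  The default grid is equally spaced and includes both
#' endpoints, so normalized-time landmarks (0, 0.5, 1) are addressable
#' exactly.  A custom strictly increasing sequence spanning \[0, 1\] may be
#' supplied instead.
#'
#' @param K integer, number of grid points (>= 2).
#' @param points optional numeric vector of explicit grid points; overrides
#'   `K`.  Must start at 0, end at 1 and be strictly increasing.
#' @return numeric vector of class `"time_grid"`.
#' @examples
#' time_grid(5)
#' @export
time_grid <- function(K = 100L, points = NULL) {
  if (is.null(points)) {
    K <- as.integer(K)
    if (is.na(K) || K < 2L)
      stop("a time grid needs at least 2 points, got K = ", K)
    points <- seq(0, 1, length.out = K)
  } else {
    points <- as.numeric(points)
    if (length(points) < 2L)
      stop("a time grid needs at least 2 points")
    if (any(diff(points) <= 0))
      stop("grid points must be strictly increasing")
    if (abs(points[1L]) > 1e-12 || abs(points[length(points)] - 1) > 1e-12)
      stop("grid must span [0, 1]: first point ", points[1L],
           ", last point ", points[length(points)])
  }
  structure(points, class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("Normalized time grid: K =", length(x),
      "points on [", x[1L], ",", x[length(x)], "]\n")
  invisible(x)
}

is_time_grid <- function(x) inherits(x, "time_grid")

as_time_grid <- function(x) {
  if (is_time_grid(x)) x else time_grid(points = x)
}

same_grid <- function(a, b, tol = 1e-12) {
  length(a) == length(b) && max(abs(as.numeric(a) - as.numeric(b))) <= tol
}
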