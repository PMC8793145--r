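# Internal numerical helpers shared across modules.

#' @importFrom rlang .data abort warn %||%
#' @import tibble
NULL

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Edge lengths of a closed polygon given an n x 2 coordinate matrix.
closed_edge_lengths <- function(xy) {
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  sqrt(rowSums((nxt - xy)^2))
}

poly_perimeter <- function(xy) sum(closed_edge_lengths(xy))

# Shoelace signed area; positive = counterclockwise in right-handed coords.
poly_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Arc-length-weighted centroid of the closed polygonal curve (not the area
# centroid): each edge contributes its midpoint weighted by its length.
curve_centroid <- function(xy) {
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  len <- sqrt(rowSums((nxt - xy)^2))
  mid <- (xy + nxt) / 2
  colSums(mid * len) / sum(len)
}

# Gaussian KDE evaluated on an arbitrary grid; chunked to bound memory.
# reflect = TRUE folds mass at zero (boundary correction for non-negative
# data), keeping the integral over [0, Inf) equal to 1.
gauss_kde <- function(x, grid, bw, reflect = FALSE) {
  stopifnot(bw > 0, length(x) > 0)
  dens <- numeric(length(grid))
  chunk <- max(1L, floor(5e6 / length(grid)))
  for (i in seq(1L, length(x), by = chunk)) {
    xi <- x[i:min(i + chunk - 1L, length(x))]
    d <- outer(grid, xi, "-")
    dens <- dens + rowSums(stats::dnorm(d, sd = bw))
    if (reflect) {
      dens <- dens + rowSums(stats::dnorm(outer(grid, -xi, "-"), sd = bw))
    }
  }
  dens / length(x)
}

# Silverman's rule-of-thumb bandwidth (stats::bw.nrd0), guarded for
# near-constant samples.
silverman_bw <- function(x) {
  if (stats::sd(x) == 0) {
    abort("cannot choose a kernel bandwidth: sample has zero variance")
  }
  stats::bw.nrd0(x)
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

# Stable seed derivation: k child seeds < 2^31 from one parent seed.
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, k))
}
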