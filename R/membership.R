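# Piecewise-linear membership primitives: triangles and trapezoids on a
# bounded universe. These are the only shapes the risk model uses.

#' Canonical five-term linguistic labels
#'
#' Ordered labels of the five-term partitions used throughout the package:
#' `fm` (very small), `m` (small), `Md` (medium), `M` (high), `FM` (very
#' high).
#'
#' @format Character vector of length 5.
#' @export
term_labels <- c("fm", "m", "Md", "M", "FM")

#' Membership functions
#'
#' Construct a triangular or trapezoidal membership function from its knots.
#' A triangle is given by left foot `a`, peak `b` and right foot `c`; a
#' trapezoid by left foot `a`, left shoulder `b`, right shoulder `c` and
#' right foot `d`. Knots must be non-decreasing; a zero-width ramp (two
#' coincident knots) degenerates to a step, with the peak/plateau value 1
#' attained at the coincident knot itself, so end-of-universe shoulder terms
#' reach full membership exactly at the bound.
#'
#' @param a,b,c,d Knot coordinates, non-decreasing.
#' @return An object of class `"mf"` with fields `shape` and `knots`.
#' @examples
#' membership(mf_triangle(0, 1, 2), c(0.25, 1, 1.75))
#' @export
mf_triangle <- function(a, b, c) new_mf("triangle", c(a, b, c))

#' @rdname mf_triangle
#' @export
mf_trapezoid <- function(a, b, c, d) new_mf("trapezoid", c(a, b, c, d))

#' @rdname mf_triangle
#' @param shape `"triangle"` or `"trapezoid"`.
#' @param knots Numeric vector of 3 (triangle) or 4 (trapezoid) knots.
#' @export
new_mf <- function(shape, knots) {
  shape <- match.arg(shape, c("triangle", "trapezoid"))
  n_expected <- if (shape == "triangle") 3L else 4L
  if (!is.numeric(knots) || length(knots) != n_expected ||
      any(!is.finite(knots))) {
    stop(sprintf("a %s membership function needs %d finite knots, got %d",
                 shape, n_expected, length(knots)), call. = FALSE)
  }
  knots <- as.numeric(knots)
  if (is.unsorted(knots)) {
    stop("membership knots must be non-decreasing", call. = FALSE)
  }
  structure(list(shape = shape, knots = knots), class = "mf")
}

#' Evaluate a membership function
#'
#' Piecewise-linear membership degree: exactly 0 outside the support,
#' exactly 1 on the peak/plateau (closed interval), linear on the ramps.
#'
#' @param mf An `"mf"` object.
#' @param x Numeric vector of crisp values.
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
membership <- function(mf, x) {
  if (!inherits(mf, "mf")) stop("'mf' must be a membership function", call. = FALSE)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  k <- mf$knots
  if (mf$shape == "triangle") {
    a <- k[1L]; pl <- k[2L]; pr <- k[2L]; d <- k[3L]
  } else {
    a <- k[1L]; pl <- k[2L]; pr <- k[3L]; d <- k[4L]
  }
  up   <- if (pl > a) (x - a) / (pl - a) else as.numeric(x >= pl)
  down <- if (d > pr) (d - x) / (d - pr) else as.numeric(x <= pr)
  out <- pmin(up, down, 1)
  out[out < 0] <- 0
  out[!is.finite(x)] <- NA_real_
  out
}

#' @rdname membership
#' @return `mf_support()`: the closed interval outside which membership is 0.
#' @export
mf_support <- function(mf) {
  k <- mf$knots
  c(k[1L], k[length(k)])
}

# Representative abscissa of the full-membership region (peak, or plateau
# midpoint). Used to check that term peaks increase along a partition.
mf_peak <- function(mf) {
  k <- mf$knots
  if (mf$shape == "triangle") k[2L] else (k[2L] + k[3L]) / 2
}

#' @export
print.mf <- function(x, ...) {
  cat(sprintf("<%s membership function> knots: %s\n",
              x$shape, paste(format(x$knots), collapse = ", ")))
  invisible(x)
}
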