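# Linguistic variables: a bounded universe carrying an ordered five-term
# partition (fm, m, Md, M, FM), plus fuzzification of crisp values.

#' Linguistic variable
#'
#' A named, bounded universe together with an ordered five-term partition.
#' Terms must be named `fm, m, Md, M, FM` (very small ... very high), their
#' peaks must strictly increase, and the partition must cover the universe
#' (every point has positive membership in at least one term).
#'
#' @param name Variable identifier.
#' @param lower,upper Universe bounds (`lower < upper`).
#' @param units Unit label carried as metadata (no conversion is performed).
#' @param terms Named list of five `"mf"` objects, names `term_labels`.
#' @return An object of class `"lingvar"`.
#' @seealso [standard_partition()] for the default evenly spaced layout.
#' @export
linguistic_variable <- function(name, lower, upper, units = "", terms) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(lower) || !is.numeric(upper) || !is.finite(lower) ||
      !is.finite(upper) || lower >= upper) {
    stop("universe must satisfy lower < upper with finite bounds", call. = FALSE)
  }
  if (!is.list(terms) || length(terms) != 5L ||
      !identical(names(terms), term_labels)) {
    stop("'terms' must be a named list of 5 membership functions in order ",
         paste(term_labels, collapse = ", "), call. = FALSE)
  }
  if (!all(vapply(terms, inherits, logical(1), what = "mf"))) {
    stop("every term must be an 'mf' object", call. = FALSE)
  }
  peaks <- vapply(terms, mf_peak, numeric(1))
  if (any(diff(peaks) <= 0)) {
    stop("term peaks must strictly increase in the order fm < m < Md < M < FM",
         call. = FALSE)
  }
  v <- structure(
    list(name = name, lower = as.numeric(lower), upper = as.numeric(upper),
         units = units, terms = terms),
    class = "lingvar"
  )
  # coverage: max membership over terms positive on a dense grid
  grid <- seq(v$lower, v$upper, length.out = 501L)
  mx <- do.call(pmax, lapply(terms, membership, x = grid))
  if (any(mx <= 0)) {
    stop(sprintf("partition of '%s' does not cover its universe", name),
         call. = FALSE)
  }
  v
}

#' Evenly spaced five-term partition
#'
#' Builds the default term layout on `[a, b]`: breakpoints
#' `c_i = a + i (b - a) / 4`, shoulder trapezoids at the ends and
#' half-overlapping triangles inside. `fm = trapezoid(a, a, a + s, c1)`,
#' `m = triangle(a, c1, c2)`, `Md = triangle(c1, c2, c3)`,
#' `M = triangle(c2, c3, b)`, `FM = trapezoid(c3, b - s, b, b)` with
#' `s = shoulder_fraction * (b - a)`. Memberships sum to one on the interior
#' `[c1, c3]` (partition of unity).
#'
#' @param name Variable identifier.
#' @param lower,upper Universe bounds.
#' @param units Unit label.
#' @param shoulder_fraction Plateau width of the end trapezoids as a
#'   fraction of the universe width, in `[0, 0.25)`. The default `1/8` puts
#'   each shoulder halfway between the bound and the nearest interior peak.
#' @return A `"lingvar"`.
#' @examples
#' v <- standard_partition("RISK", 1, 10)
#' v$terms$Md$knots  # 3.25 5.50 7.75
#' @export
standard_partition <- function(name, lower, upper, units = "",
                               shoulder_fraction = 1 / 8) {
  partition_from_peaks(name, lower, upper, units = units,
                       shoulder_fraction = shoulder_fraction)
}

#' Five-term partition with displaced interior peaks
#'
#' Generalization of [standard_partition()] used by the calibration stage:
#' the three interior peaks `p1 < p2 < p3` may sit anywhere strictly inside
#' the universe, and triangle feet remain tied to the neighbouring peaks
#' (or universe bounds), preserving the half-overlap structure.
#'
#' @inheritParams standard_partition
#' @param peaks Numeric vector of 3 interior peak positions, strictly
#'   increasing, inside `(lower, upper)`. `NULL` gives the evenly spaced
#'   defaults.
#' @return A `"lingvar"`.
#' @export
partition_from_peaks <- function(name, lower, upper, units = "",
                                 shoulder_fraction = 1 / 8, peaks = NULL) {
  if (!is.numeric(shoulder_fraction) || length(shoulder_fraction) != 1L ||
      shoulder_fraction < 0 || shoulder_fraction >= 0.25) {
    stop("'shoulder_fraction' must lie in [0, 0.25)", call. = FALSE)
  }
  width <- upper - lower
  if (is.null(peaks)) peaks <- lower + (1:3) * width / 4
  if (length(peaks) != 3L || any(diff(peaks) <= 0) ||
      peaks[1L] <= lower || peaks[3L] >= upper) {
    stop("'peaks' must be 3 strictly increasing values inside the universe",
         call. = FALSE)
  }
  s <- shoulder_fraction * width
  if (lower + s > peaks[1L] || upper - s < peaks[3L]) {
    stop("shoulder plateau overruns the nearest interior peak", call. = FALSE)
  }
  terms <- list(
    fm = mf_trapezoid(lower, lower, lower + s, peaks[1L]),
    m  = mf_triangle(lower, peaks[1L], peaks[2L]),
    Md = mf_triangle(peaks[1L], peaks[2L], peaks[3L]),
    M  = mf_triangle(peaks[2L], peaks[3L], upper),
    FM = mf_trapezoid(peaks[3L], upper - s, upper, upper)
  )
  linguistic_variable(name, lower, upper, units, terms)
}

# Clamp crisp values to the universe. Values outside the variation field are
# pulled to the nearest bound (the field was defined from the observed
# min/max of a small cohort, so new patients may legitimately fall outside);
# strict = TRUE turns clamping into an error instead.
clamp_to_universe <- function(var, x, strict = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("input for '%s' must be finite numeric", var$name),
         call. = FALSE)
  }
  out_of_range <- x < var$lower | x > var$upper
  if (any(out_of_range)) {
    if (strict) {
      stop(sprintf("%d value(s) of '%s' outside [%g, %g] (strict mode)",
                   sum(out_of_range), var$name, var$lower, var$upper),
           call. = FALSE)
    }
    warning(sprintf("%d value(s) of '%s' clamped to [%g, %g]",
                    sum(out_of_range), var$name, var$lower, var$upper),
            call. = FALSE)
    x <- pmin(pmax(x, var$lower), var$upper)
  }
  x
}

#' Fuzzify a crisp value
#'
#' Maps a crisp value to its membership degree in each of the variable's
#' five terms. Values outside the universe are clamped to the bounds with a
#' warning (or rejected when `strict = TRUE`).
#'
#' @param var A `"lingvar"`.
#' @param x A single finite numeric value.
#' @param strict Reject (rather than clamp) out-of-universe values.
#' @return Named numeric vector of 5 degrees in `[0, 1]`, at least one
#'   positive.
#' @export
fuzzify <- function(var, x, strict = FALSE) {
  if (length(x) != 1L) stop("'x' must be a single value", call. = FALSE)
  x <- clamp_to_universe(var, x, strict = strict)
  vapply(var$terms, membership, numeric(1), x = x)
}

# Vectorized fuzzification: n x 5 matrix of degrees, columns in term order.
fuzzify_matrix <- function(var, x) {
  vapply(var$terms, membership, numeric(length(x)), x = x) |>
    matrix(nrow = length(x), ncol = 5L,
           dimnames = list(NULL, term_labels))
}

#' @export
print.lingvar <- function(x, ...) {
  cat(sprintf("<linguistic variable> %s on [%g, %g] %s\n",
              x$name, x$lower, x$upper, x$units))
  for (lab in names(x$terms)) {
    mf <- x$terms[[lab]]
    cat(sprintf("  %-3s %-9s (%s)\n", lab, mf$shape,
                paste(format(mf$knots, trim = TRUE), collapse = ", ")))
  }
  invisible(x)
}
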