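# Mamdani engine: MIN rule firing, MIN-clip implication, MAX aggregation,
# sampled-grid defuzzification, and a complete per-inference trace.

output_grid <- function(fis) {
  seq(fis$output$lower, fis$output$upper,
      length.out = fis$options$resolution)
}

# 5 x G matrix: each output term sampled on the output grid.
output_term_samples <- function(fis, grid = output_grid(fis)) {
  m <- t(fuzzify_matrix(fis$output, grid))
  rownames(m) <- term_labels
  m
}

#' Rule firing strengths
#'
#' AND-composition of the antecedent: the firing strength of each rule is
#' the MIN over the membership degrees of its antecedent terms.
#'
#' @param fis A `"fis"`.
#' @param degrees Named list, one entry per input variable, each a named
#'   degree vector as returned by [fuzzify()].
#' @return Numeric vector of strengths in `[0, 1]`, one per rule.
#' @export
firing_strengths <- function(fis, degrees) {
  miss <- setdiff(names(fis$inputs), names(degrees))
  if (length(miss)) {
    stop("missing fuzzified degrees for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  per_var <- lapply(names(fis$inputs), function(v) {
    d <- degrees[[v]][fis$rules[[v]]]
    if (anyNA(d)) stop(sprintf("unknown term label for '%s'", v), call. = FALSE)
    unname(d)
  })
  do.call(pmin, per_var)
}

#' Aggregate clipped consequents
#'
#' MIN-clip each rule's consequent set at its firing strength, then combine
#' by pointwise MAX over the output grid.
#'
#' @param fis A `"fis"`.
#' @param strengths Firing strengths, one per rule.
#' @return List with `x` (grid) and `mu` (aggregated membership in
#'   `[0, 1]`).
#' @export
aggregate_curve <- function(fis, strengths) {
  if (length(strengths) != nrow(fis$rules)) {
    stop("need exactly one firing strength per rule", call. = FALSE)
  }
  grid <- output_grid(fis)
  samples <- output_term_samples(fis, grid)
  # Rules sharing a consequent term collapse under MAX, so clip each of the
  # five output terms once at the max strength among its rules.
  term_strength <- vapply(term_labels, function(lab) {
    s <- strengths[fis$rules$consequent == lab]
    if (length(s)) max(s) else 0
  }, numeric(1))
  mu <- rep(0, length(grid))
  for (t in seq_along(term_labels)) {
    if (term_strength[t] > 0) {
      mu <- pmax(mu, pmin(term_strength[t], samples[t, ]))
    }
  }
  list(x = grid, mu = mu)
}

#' Defuzzify a sampled membership curve
#'
#' `defuzz_centroid()` is the discrete center of mass
#' `sum(x * mu) / sum(mu)` over the sampling grid. `defuzz_bisector()`
#' returns the grid point splitting the mass in half; `defuzz_mom()` the
#' mean of the grid points attaining the maximum membership.
#'
#' @param x Grid abscissae.
#' @param mu Membership values in `[0, 1]`.
#' @return Crisp value within the support of the curve.
#' @export
defuzz_centroid <- function(x, mu) {
  total <- sum(mu)
  if (!is.finite(total) || total <= 0) {
    stop("cannot defuzzify a zero-mass curve: no rule fired", call. = FALSE)
  }
  sum(x * mu) / total
}

#' @rdname defuzz_centroid
#' @export
defuzz_bisector <- function(x, mu) {
  total <- sum(mu)
  if (!is.finite(total) || total <= 0) {
    stop("cannot defuzzify a zero-mass curve: no rule fired", call. = FALSE)
  }
  x[which(cumsum(mu) >= total / 2)[1L]]
}

#' @rdname defuzz_centroid
#' @export
defuzz_mom <- function(x, mu) {
  mx <- max(mu)
  if (!is.finite(mx) || mx <= 0) {
    stop("cannot defuzzify a zero-mass curve: no rule fired", call. = FALSE)
  }
  mean(x[mu >= mx - 1e-12])
}

defuzz <- function(x, mu, method) {
  switch(method,
         centroid = defuzz_centroid(x, mu),
         bisector = defuzz_bisector(x, mu),
         mom = defuzz_mom(x, mu),
         stop("unknown defuzzification method: ", method, call. = FALSE))
}

#' Run one inference
#'
#' Fuzzifies the crisp inputs, fires all rules by MIN, aggregates the
#' clipped consequents by MAX and defuzzifies, recording every intermediate
#' in an `"inference_trace"`.
#'
#' @param fis A `"fis"`.
#' @param inputs Named numeric vector or list, one finite value per input
#'   variable.
#' @param strict Reject (rather than clamp) out-of-universe inputs.
#' @return An `"inference_trace"` with fields `inputs` (as given),
#'   `clamped` (values actually used), `degrees`, `firing`, `curve`
#'   (data frame `x`, `mu`), `crisp` and `defuzz`.
#' @export
infer <- function(fis, inputs, strict = FALSE) {
  stopifnot(inherits(fis, "fis"))
  inputs <- unlist(inputs)
  miss <- setdiff(names(fis$inputs), names(inputs))
  if (length(miss)) {
    stop("missing input(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  strict <- strict || !fis$options$clamp
  clamped <- vapply(names(fis$inputs), function(v) {
    clamp_to_universe(fis$inputs[[v]], inputs[[v]], strict = strict)
  }, numeric(1))
  degrees <- lapply(names(fis$inputs), function(v) {
    vapply(fis$inputs[[v]]$terms, membership, numeric(1), x = clamped[[v]])
  })
  names(degrees) <- names(fis$inputs)
  firing <- firing_strengths(fis, degrees)
  curve <- aggregate_curve(fis, firing)
  crisp <- defuzz(curve$x, curve$mu, fis$options$defuzz)
  structure(
    list(inputs = inputs[names(fis$inputs)], clamped = clamped,
         degrees = degrees, firing = firing,
         curve = data.frame(x = curve$x, mu = curve$mu),
         crisp = crisp, defuzz = fis$options$defuzz,
         resolution = fis$options$resolution),
    class = "inference_trace"
  )
}

#' Batch inference
#'
#' Crisp outputs for many input tuples at once, sharing the sampled output
#' terms across the batch. Identical numerics to [infer()], evaluated in
#' chunks to bound memory.
#'
#' @param fis A `"fis"`.
#' @param newdata Data frame (or named list) with one numeric column per
#'   input variable.
#' @param chunk_size Rows evaluated per chunk.
#' @return Numeric vector of crisp outputs, one per row.
#' @export
infer_batch <- function(fis, newdata, chunk_size = 2000L) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(names(fis$inputs), names(newdata))
  if (length(miss)) {
    stop("missing input column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(newdata)
  if (n == 0L) return(numeric(0))
  grid <- output_grid(fis)
  samples <- output_term_samples(fis, grid)
  g <- length(grid)
  vars <- names(fis$inputs)
  strict <- !fis$options$clamp
  clamped <- lapply(vars, function(v) {
    clamp_to_universe(fis$inputs[[v]], newdata[[v]], strict = strict)
  })
  names(clamped) <- vars
  consequent_idx <- match(fis$rules$consequent, term_labels)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    m <- length(idx)
    deg <- lapply(vars, function(v) fuzzify_matrix(fis$inputs[[v]], clamped[[v]][idx]))
    names(deg) <- vars
    # m x nrules firing strengths
    strengths <- do.call(pmin, lapply(vars, function(v) {
      deg[[v]][, fis$rules[[v]], drop = FALSE]
    }))
    # collapse to per-output-term strengths (m x 5)
    term_strength <- vapply(seq_along(term_labels), function(t) {
      cols <- which(consequent_idx == t)
      if (!length(cols)) return(rep(0, m))
      do.call(pmax, as.data.frame(strengths[, cols, drop = FALSE]))
    }, numeric(m))
    term_strength <- matrix(term_strength, nrow = m)
    curve <- matrix(0, m, g)
    for (t in seq_along(term_labels)) {
      st <- term_strength[, t]
      if (any(st > 0)) {
        curve <- pmax(curve, pmin(matrix(st, m, g),
                                  matrix(samples[t, ], m, g, byrow = TRUE)))
      }
    }
    mass <- rowSums(curve)
    if (any(mass <= 0)) {
      stop("cannot defuzzify a zero-mass curve: no rule fired", call. = FALSE)
    }
    out[idx] <- switch(
      fis$options$defuzz,
      centroid = as.vector(curve %*% grid) / mass,
      vapply(seq_len(m), function(i) defuzz(grid, curve[i, ], fis$options$defuzz),
             numeric(1))
    )
  }
  out
}

#' @export
print.inference_trace <- function(x, ...) {
  cat("<inference trace>\n")
  for (v in names(x$inputs)) {
    note <- if (!isTRUE(all.equal(x$inputs[[v]], x$clamped[[v]]))) " (clamped)" else ""
    cat(sprintf("  %s = %g%s: ", v, x$clamped[[v]], note))
    d <- x$degrees[[v]]
    cat(paste(sprintf("%s=%.3f", names(d)[d > 0], d[d > 0]), collapse = ", "), "\n")
  }
  active <- which(x$firing > 0)
  cat(sprintf("  %d of %d rules fired; strongest rule #%d (strength %.3f)\n",
              length(active), length(x$firing), which.max(x$firing),
              max(x$firing)))
  cat(sprintf("  crisp output (%s, %d grid points): %.4f\n",
              x$defuzz, x$resolution, x$crisp))
  invisible(x)
}
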