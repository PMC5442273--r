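# Membership-knot calibration. The published figures show the term layouts
# only graphically, so the knot geometry is recovered by least squares
# against the printed rows of the diagonal sweep.
#
# Parameterization (12 free numbers): per variable a shoulder fraction and
# three dimensionless interior-peak offsets, each offset expressed in units
# of the quarter width h = (upper - lower) / 4 and bounded to (-0.45, 0.45)
# so the peak ordering can never invert. Triangle feet stay tied to the
# neighbouring peaks (half-overlap preserved), which keeps the fit
# identifiable from a dozen points.

cal_vars <- c("MDA", "DONORS_PROTONS", "RISK")
offset_bound <- 0.45
sf_max <- 0.25 - 1e-4

#' Default knot parameterization
#'
#' The parameter vector of the evenly spaced default layout: shoulder
#' fraction 1/8 and zero peak offsets for each of the three variables.
#' Layout: `c(sf, o1, o2, o3)` per variable in the order MDA,
#' DONORS_PROTONS, RISK; offsets are in units of the variable's quarter
#' width.
#'
#' @return Named numeric vector of length 12.
#' @export
default_knot_par <- function() {
  stats::setNames(
    rep(c(1 / 8, 0, 0, 0), times = 3L),
    as.vector(t(outer(cal_vars, c("sf", "o1", "o2", "o3"), paste, sep = ".")))
  )
}

# Project an arbitrary parameter vector into the feasible region: offsets
# into [-offset_bound, offset_bound], shoulder fractions into [0, sf_max]
# and further capped so the shoulder plateau cannot overrun the nearest
# interior peak.
project_knot_par <- function(par) {
  par <- stats::setNames(as.numeric(par), names(default_knot_par()))
  for (i in seq_along(cal_vars)) {
    j <- (i - 1L) * 4L
    o <- pmin(pmax(par[j + 2:4], -offset_bound), offset_bound)
    par[j + 2:4] <- o
    cap <- min(sf_max, (1 + o[1L]) / 4 - 1e-4, (1 - o[3L]) / 4 - 1e-4)
    par[j + 1L] <- min(max(par[j + 1L], 0), cap)
  }
  par
}

# Build an oral-cancer system from a (feasible) parameter vector.
fis_from_knot_par <- function(par, resolution = 1001L) {
  uni <- list(MDA = mda_universe, DONORS_PROTONS = donors_universe,
              RISK = risk_universe)
  sf <- numeric(0)
  peaks <- list()
  for (i in seq_along(cal_vars)) {
    v <- cal_vars[i]
    j <- (i - 1L) * 4L
    h <- (uni[[v]][2L] - uni[[v]][1L]) / 4
    sf[v] <- par[j + 1L]
    peaks[[v]] <- uni[[v]][1L] + (1:3) * h + par[j + 2:4] * h
  }
  oral_fis(shoulder_fraction = sf, peaks = peaks, resolution = resolution)
}

#' Calibrate membership knots against printed sweep rows
#'
#' Fits the 12-parameter knot geometry (see [default_knot_par()]) by
#' minimizing the sum of squared risk residuals on the fit rows, with a
#' derivative-free Nelder-Mead search started deterministically at the
#' evenly spaced default layout. Rows named in `holdout` are excluded from
#' the fit and reported as holdout absolute errors. The fitted SSE can
#' never exceed the default layout's SSE (the start point is evaluated).
#'
#' @param rows Data frame with columns `index`, `MDA`, `DONORS_PROTONS`,
#'   `RISK` (e.g. [table2_printed()] or a [diagonal_sweep()]).
#' @param holdout Integer indices (values of `rows$index`) held out of the
#'   fit; may be empty.
#' @param resolution Output grid size used during fitting and in the
#'   returned system.
#' @param budget Total objective-evaluation budget for the simplex search.
#' @return An object of class `"calibration_result"`: `par` (fitted,
#'   feasible), `fis` (calibrated system), `sse`, `initial_sse`,
#'   `fit_residuals` (predicted - printed on the fit rows),
#'   `holdout_errors` (absolute, named by row index), `fit_rows`,
#'   `holdout_rows`, `evaluations`.
#' @export
calibrate <- function(rows, holdout = c(3L, 46L, 99L), resolution = 1001L,
                      budget = 2000L) {
  rows <- as.data.frame(rows)
  stopifnot(all(c("index", "MDA", "DONORS_PROTONS", "RISK") %in% names(rows)))
  in_holdout <- rows$index %in% holdout
  fit <- rows[!in_holdout, , drop = FALSE]
  held <- rows[in_holdout, , drop = FALSE]
  if (nrow(fit) == 0L) {
    stop("no rows left to fit after removing the holdout set", call. = FALSE)
  }
  evals <- 0L
  objective <- function(par) {
    evals <<- evals + 1L
    f <- fis_from_knot_par(project_knot_par(par), resolution = resolution)
    sum((infer_batch(f, fit) - fit$RISK)^2)
  }
  par <- default_knot_par()
  initial_sse <- objective(par)
  best <- list(par = par, value = initial_sse)
  # restarted simplex: each restart rebuilds the simplex around the current
  # best point, which recovers progress when Nelder-Mead collapses early
  rounds <- 3L
  per_round <- max(100L, budget %/% rounds)
  for (r in seq_len(rounds)) {
    opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = per_round, reltol = 1e-12))
    if (opt$value < best$value) best <- list(par = opt$par, value = opt$value)
    if (best$value < 1e-12) break
  }
  par_fit <- project_knot_par(best$par)
  fis_fit <- fis_from_knot_par(par_fit, resolution = resolution)
  pred_fit <- infer_batch(fis_fit, fit)
  pred_held <- if (nrow(held)) infer_batch(fis_fit, held) else numeric(0)
  res <- structure(
    list(
      par = par_fit,
      fis = fis_fit,
      sse = sum((pred_fit - fit$RISK)^2),
      initial_sse = initial_sse,
      fit_residuals = stats::setNames(pred_fit - fit$RISK, fit$index),
      holdout_errors = stats::setNames(abs(pred_held - held$RISK), held$index),
      fit_rows = transform(fit, predicted = pred_fit),
      holdout_rows = if (nrow(held)) transform(held, predicted = pred_held) else held,
      evaluations = evals
    ),
    class = "calibration_result"
  )
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration result>\n")
  cat(sprintf("  fit rows: %d, SSE %.6g (default layout: %.6g), %d evaluations\n",
              nrow(x$fit_rows), x$sse, x$initial_sse, x$evaluations))
  if (length(x$holdout_errors)) {
    cat(sprintf("  holdout |error| (rows %s): %s\n",
                paste(names(x$holdout_errors), collapse = ", "),
                paste(sprintf("%.4f", x$holdout_errors), collapse = ", ")))
  }
  invisible(x)
}

#' Synthetic knot-recovery harness
#'
#' End-to-end self test of the calibration stage: draw a ground-truth
#' system with seeded random knot perturbations (shoulder fractions uniform
#' on `[0.05, 0.20]`, peak offsets uniform within 15 % of the quarter
#' width), generate its 101-row diagonal sweep, calibrate a fresh default
#' system against the 12 rows matching the published fit pattern (printed
#' indices minus the holdout rows 3, 46, 99), and report how well the
#' held-out risks and the knot parameters are recovered.
#'
#' @param seed Integer RNG seed; the whole harness is deterministic given
#'   it.
#' @param resolution Output grid size.
#' @param budget Objective-evaluation budget passed to [calibrate()].
#' @return List with `seed`, `true_par`, `fitted_par`, `par_error`
#'   (max absolute difference), `holdout_errors`,
#'   `max_holdout_error`, `sse` and the underlying `calibration` result.
#' @export
synthetic_recovery_test <- function(seed = 0L, resolution = 1001L,
                                    budget = 2000L) {
  true_par <- with_local_seed(seed, {
    par <- default_knot_par()
    for (i in seq_along(cal_vars)) {
      j <- (i - 1L) * 4L
      par[j + 1L] <- stats::runif(1L, 0.05, 0.20)
      par[j + 2:4] <- stats::runif(3L, -0.15, 0.15)
    }
    project_knot_par(par)
  })
  truth <- fis_from_knot_par(true_par, resolution = resolution)
  sweep <- diagonal_sweep(truth)
  printed_idx <- c(1:5, 44:48, 97:101)
  holdout <- c(3L, 46L, 99L)
  cal <- calibrate(sweep[sweep$index %in% printed_idx, ],
                   holdout = holdout, resolution = resolution,
                   budget = budget)
  list(
    seed = seed,
    true_par = true_par,
    fitted_par = cal$par,
    par_error = max(abs(cal$par - true_par)),
    holdout_errors = cal$holdout_errors,
    max_holdout_error = if (length(cal$holdout_errors)) max(cal$holdout_errors) else 0,
    sse = cal$sse,
    calibration = cal
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
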