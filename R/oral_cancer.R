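# The concrete decision-support system: serum MDA and proton-donor capacity
# in, 1-10 malignization risk out, through the published 25-rule base.

# Variation fields observed on the study cohort. The proton-donor upper
# bound is taken as 58.25 so the final point of the published diagonal sweep
# lies inside the universe (the methods text rounds it to 58.2; the 0.05
# discrepancy is documented, not silently dropped).
mda_universe    <- c(1.1, 6.7)     # nmol/ml
donors_universe <- c(38.5, 58.25)  # inhibition %
risk_universe   <- c(1, 10)        # dimensionless risk scale

#' The 25-rule oral-cancer rule matrix
#'
#' Complete 5 x 5 rule matrix: rows are MDA terms, columns proton-donor
#' terms (both fm ... FM), cells the consequent RISK term. The matrix is
#' monotone: the risk term is non-decreasing along MDA for every donors
#' column and non-increasing along donors for every MDA row, encoding
#' "IF MDA is increased AND proton donors are decreased THEN the risk is
#' elevated".
#'
#' @return 5 x 5 character matrix with dimnames `MDA`, `DONORS_PROTONS`.
#' @export
oral_rule_matrix <- function() {
  matrix(
    c("Md", "Md", "m",  "fm", "fm",
      "Md", "Md", "m",  "m",  "fm",
      "M",  "Md", "Md", "m",  "m",
      "M",  "M",  "Md", "Md", "m",
      "FM", "FM", "M",  "Md", "Md"),
    nrow = 5L, byrow = TRUE,
    dimnames = list(MDA = term_labels, DONORS_PROTONS = term_labels)
  )
}

# Expand a 5 x 5 matrix into the rule data frame, MDA term outermost so rule
# indices follow the published numbering (rules 1-5 are MDA = fm, etc.).
rules_from_matrix <- function(mat) {
  data.frame(
    MDA = rep(term_labels, each = 5L),
    DONORS_PROTONS = rep(term_labels, times = 5L),
    consequent = as.vector(t(mat)),
    stringsAsFactors = FALSE
  )
}

# Rule-matrix sanity: complete coverage and bidirectional monotonicity of
# the consequent term index.
check_rule_matrix <- function(mat) {
  stopifnot(identical(dim(mat), c(5L, 5L)), all(mat %in% term_labels))
  idx <- matrix(match(mat, term_labels), 5L, 5L)
  if (any(apply(idx, 2L, diff) < 0)) {
    stop("rule matrix not monotone non-decreasing in MDA", call. = FALSE)
  }
  if (any(apply(idx, 1L, diff) > 0)) {
    stop("rule matrix not monotone non-increasing in DONORS_PROTONS",
         call. = FALSE)
  }
  invisible(mat)
}

#' Build the oral-cancer risk system
#'
#' Assembles the two-input Mamdani system: MDA on `[1.1, 6.7]` nmol/ml,
#' proton-donor capacity on `[38.5, 58.25]` inhibition %, risk on
#' `[1, 10]`, each carrying a five-term partition, plus the complete
#' 25-rule base of [oral_rule_matrix()].
#'
#' The default membership layout is the evenly spaced [standard_partition()]
#' on every variable; the published figures do not print knot coordinates,
#' so [calibrate()] can refine this layout against the published
#' input/output table. `peaks` overrides the interior peak positions per
#' variable (as used by the calibration stage).
#'
#' @param shoulder_fraction Scalar or named numeric (names `MDA`,
#'   `DONORS_PROTONS`, `RISK`): plateau fraction of the end trapezoids.
#' @param peaks Optional named list of 3-vectors of interior peaks per
#'   variable.
#' @param resolution Output sampling grid size.
#' @param defuzz Defuzzifier (default centroid).
#' @param clamp Clamp out-of-universe inputs.
#' @return A `"fis"` ready for [risk_score()], [diagonal_sweep()] and
#'   friends.
#' @examples
#' sys <- oral_fis()
#' risk_score(sys, mda = 6.588, donors = 38.895)$risk
#' @export
oral_fis <- function(shoulder_fraction = 1 / 8, peaks = NULL,
                     resolution = 1001L,
                     defuzz = c("centroid", "bisector", "mom"),
                     clamp = TRUE) {
  vars <- c("MDA", "DONORS_PROTONS", "RISK")
  sf <- if (length(shoulder_fraction) == 1L) {
    stats::setNames(rep(shoulder_fraction, 3L), vars)
  } else shoulder_fraction
  stopifnot(all(vars %in% names(sf)))
  uni <- list(MDA = mda_universe, DONORS_PROTONS = donors_universe,
              RISK = risk_universe)
  units <- c(MDA = "nmol/ml", DONORS_PROTONS = "inhibition%", RISK = "risk 1-10")
  lv <- lapply(vars, function(v) {
    partition_from_peaks(v, uni[[v]][1L], uni[[v]][2L], units = units[[v]],
                         shoulder_fraction = sf[[v]], peaks = peaks[[v]])
  })
  names(lv) <- vars
  rules <- rules_from_matrix(check_rule_matrix(oral_rule_matrix()))
  fis_definition(inputs = lv[c("MDA", "DONORS_PROTONS")],
                 output = lv$RISK, rules = rules,
                 options = fis_options(defuzz = match.arg(defuzz),
                                       resolution = resolution,
                                       clamp = clamp))
}

#' Score a single patient
#'
#' @param fis The oral-cancer system (see [oral_fis()], or a calibrated one
#'   from [calibrate()]).
#' @param mda Serum malondialdehyde, nmol/ml.
#' @param donors Serum proton-donor capacity, inhibition %.
#' @param strict Reject (rather than clamp) out-of-universe values.
#' @return List with `risk` (crisp value in `[1, 10]`) and `trace` (the
#'   full `"inference_trace"`).
#' @export
risk_score <- function(fis, mda, donors, strict = FALSE) {
  trace <- infer(fis, c(MDA = mda, DONORS_PROTONS = donors), strict = strict)
  list(risk = trace$crisp, trace = trace)
}

#' Inputs of the published diagonal sweep
#'
#' The published result table walks both universes simultaneously over 101
#' equally spaced points: `mda = 6.7 - 0.056 (i - 1)` and
#' `donors = 38.5 + 0.1975 (i - 1)` for `i = 1..101`, i.e. from (highest
#' MDA, lowest donors) down to (lowest MDA, highest donors).
#'
#' @param indices Integer row indices in `1..101`.
#' @return Data frame with `index`, `MDA`, `DONORS_PROTONS`.
#' @export
sweep_inputs <- function(indices = 1:101) {
  stopifnot(all(indices %in% 1:101))
  # snap float rounding back onto the universe bounds (row 101 lands a few
  # ulp below the MDA lower bound otherwise)
  data.frame(
    index = as.integer(indices),
    MDA = pmin(pmax(6.7 - 0.056 * (indices - 1), mda_universe[1L]),
               mda_universe[2L]),
    DONORS_PROTONS = pmin(pmax(38.5 + 0.1975 * (indices - 1),
                               donors_universe[1L]), donors_universe[2L])
  )
}

#' Reproduce the diagonal risk sweep
#'
#' Evaluates the system along the 101 input pairs of [sweep_inputs()].
#'
#' @param fis The oral-cancer system.
#' @return Data frame `index`, `MDA`, `DONORS_PROTONS`, `RISK`.
#' @export
diagonal_sweep <- function(fis) {
  rows <- sweep_inputs()
  rows$RISK <- infer_batch(fis, rows)
  rows
}

#' Risk response surface
#'
#' Evaluates the crisp risk on the Cartesian grid of `n_mda` x `n_donors`
#' equally spaced points over both input universes; the maximum sits at the
#' (high MDA, low donors) corner and the minimum at the opposite one.
#'
#' @param fis The oral-cancer system.
#' @param n_mda,n_donors Grid sizes (each at least 2).
#' @return Numeric matrix of risks, rows indexed by MDA value, columns by
#'   donors value (coordinates in the dimnames).
#' @export
response_surface <- function(fis, n_mda = 50L, n_donors = 50L) {
  stopifnot(n_mda >= 2L, n_donors >= 2L)
  mda <- seq(fis$inputs$MDA$lower, fis$inputs$MDA$upper, length.out = n_mda)
  donors <- seq(fis$inputs$DONORS_PROTONS$lower,
                fis$inputs$DONORS_PROTONS$upper, length.out = n_donors)
  grid <- expand.grid(MDA = mda, DONORS_PROTONS = donors)
  risk <- infer_batch(fis, grid)
  matrix(risk, nrow = n_mda, ncol = n_donors,
         dimnames = list(MDA = format(mda, trim = TRUE),
                         DONORS_PROTONS = format(donors, trim = TRUE)))
}

#' @rdname response_surface
#' @param surface A matrix from `response_surface()`.
#' @param path Output file; tab-separated with row/column coordinate
#'   headers.
#' @export
write_surface_tsv <- function(surface, path) {
  utils::write.table(surface, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' The 15 published sweep rows
#'
#' The published result table prints rows 1-5, 44-48 and 97-101 of the
#' 101-row diagonal sweep (inputs and crisp risk to four decimals). These
#' rows, bundled as a plain-text fixture, are the calibration evidence for
#' the membership-knot geometry.
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return Data frame `index`, `MDA`, `DONORS_PROTONS`, `RISK`.
#' @export
table2_printed <- function(path = system.file("extdata", "table2_printed.csv",
                                              package = "fisrisk")) {
  df <- utils::read.csv(path)
  names(df) <- c("index", "MDA", "DONORS_PROTONS", "RISK")
  df
}
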