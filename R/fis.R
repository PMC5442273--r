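# FIS definition: input/output linguistic variables, rule base, engine
# options, and a JSON configuration format with a lossless round trip.

#' Engine options
#'
#' Options of the Mamdani engine. The composition follows the MIN-MAX
#' method: rule firing by MIN over antecedent degrees, implication by
#' MIN-clipping the consequent set, aggregation by pointwise MAX.
#' Product/sum variants are deliberately not offered.
#'
#' @param defuzz Defuzzifier: `"centroid"` (default; center of mass of the
#'   aggregated set), `"bisector"` or `"mom"` (mean of maximum) for
#'   sensitivity checks.
#' @param resolution Number of uniform grid points (both endpoints
#'   included) on which the output universe is sampled; at least 101.
#' @param clamp Clamp out-of-universe inputs to the bounds (warning) rather
#'   than reject them.
#' @return A list of validated options.
#' @export
fis_options <- function(defuzz = c("centroid", "bisector", "mom"),
                        resolution = 1001L, clamp = TRUE) {
  defuzz <- match.arg(defuzz)
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 101L) {
    stop("'resolution' must be an integer >= 101", call. = FALSE)
  }
  list(and_method = "min", implication = "min", aggregation = "max",
       defuzz = defuzz, resolution = resolution, clamp = isTRUE(clamp))
}

#' Assemble a fuzzy inference system
#'
#' @param inputs Named list of input `"lingvar"` objects (names must equal
#'   each variable's own `name`).
#' @param output A single output `"lingvar"`.
#' @param rules Data frame with one column per input variable (antecedent
#'   term labels) plus a `consequent` column (output term labels). Rows are
#'   the rules; the AND connective is implicit. No two rows may share an
#'   identical antecedent.
#' @param options See [fis_options()].
#' @return An object of class `"fis"`.
#' @export
fis_definition <- function(inputs, output, rules, options = fis_options()) {
  if (!is.list(inputs) || length(inputs) < 1L ||
      !all(vapply(inputs, inherits, logical(1), what = "lingvar"))) {
    stop("'inputs' must be a list of linguistic variables", call. = FALSE)
  }
  names(inputs) <- vapply(inputs, `[[`, character(1), "name")
  if (!inherits(output, "lingvar")) {
    stop("'output' must be a linguistic variable", call. = FALSE)
  }
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  needed <- c(names(inputs), "consequent")
  if (!all(needed %in% names(rules))) {
    stop("'rules' must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  rules <- rules[, needed, drop = FALSE]
  for (v in names(inputs)) {
    bad <- setdiff(unique(rules[[v]]), term_labels)
    if (length(bad)) {
      stop(sprintf("unknown term label(s) for '%s': %s", v,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (any(!rules$consequent %in% term_labels)) {
    stop("unknown consequent term label", call. = FALSE)
  }
  key <- do.call(paste, c(rules[names(inputs)], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate rule antecedents are not allowed", call. = FALSE)
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 options = options),
            class = "fis")
}

#' @export
print.fis <- function(x, ...) {
  cat(sprintf("<fuzzy inference system> %d input(s), %d rules, %s defuzz, resolution %d\n",
              length(x$inputs), nrow(x$rules), x$options$defuzz,
              x$options$resolution))
  for (v in x$inputs) {
    cat(sprintf("  input  %s on [%g, %g] %s\n", v$name, v$lower, v$upper, v$units))
  }
  cat(sprintf("  output %s on [%g, %g] %s\n", x$output$name, x$output$lower,
              x$output$upper, x$output$units))
  invisible(x)
}

lingvar_to_doc <- function(v, role) {
  list(
    name = v$name, role = role, universe = c(v$lower, v$upper),
    units = v$units,
    terms = lapply(names(v$terms), function(lab) {
      mf <- v$terms[[lab]]
      list(label = lab, shape = mf$shape, knots = mf$knots)
    })
  )
}

doc_to_lingvar <- function(d) {
  terms <- stats::setNames(
    lapply(d$terms, function(t) new_mf(t$shape, unlist(t$knots))),
    vapply(d$terms, `[[`, character(1), "label")
  )
  linguistic_variable(d$name, d$universe[[1L]], d$universe[[2L]],
                      units = d$units, terms = terms[term_labels])
}

#' Read and write a FIS definition config
#'
#' Serializes the complete system (variables, term knots, rules, engine
#' options) to a JSON document at full double precision, so that
#' write / read / write reproduces the file byte for byte.
#'
#' @param fis A `"fis"` object.
#' @param path File path.
#' @return `fis_read()` returns the reconstructed (and re-validated)
#'   `"fis"`; `fis_write()` returns `path` invisibly.
#' @export
fis_write <- function(fis, path) {
  stopifnot(inherits(fis, "fis"))
  doc <- list(
    variables = c(
      lapply(fis$inputs, lingvar_to_doc, role = "input"),
      list(lingvar_to_doc(fis$output, role = "output"))
    ),
    rules = lapply(seq_len(nrow(fis$rules)), function(i) {
      ant <- as.list(fis$rules[i, names(fis$inputs), drop = FALSE])
      list(`if` = ant, then = fis$rules$consequent[[i]])
    }),
    options = fis$options
  )
  names(doc$variables) <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname fis_write
#' @export
fis_read <- function(path) {
  doc <- jsonlite::read_json(path)
  roles <- vapply(doc$variables, `[[`, character(1), "role")
  inputs <- lapply(doc$variables[roles == "input"], doc_to_lingvar)
  output <- doc_to_lingvar(doc$variables[roles == "output"][[1L]])
  rules <- do.call(rbind, lapply(doc$rules, function(r) {
    as.data.frame(c(r$`if`, list(consequent = r$then)),
                  stringsAsFactors = FALSE)
  }))
  opts <- doc$options
  fis_definition(
    inputs, output, rules,
    options = fis_options(defuzz = opts$defuzz,
                          resolution = opts$resolution,
                          clamp = opts$clamp)
  )
}
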