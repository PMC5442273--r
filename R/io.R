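# Patient-table IO and seeded fixture generation.

#' Read a patient table
#'
#' Reads a comma-separated table with header columns `id`, `mda`,
#' `donors_protons` (case-insensitive, any order). Rows with non-numeric
#' biomarker values are collected and reported together with their file
#' line numbers; nothing is silently dropped.
#'
#' @param path CSV path.
#' @return Data frame with columns `id`, `MDA`, `DONORS_PROTONS`.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  nm <- tolower(names(df))
  needed <- c("id", "mda", "donors_protons")
  miss <- setdiff(needed, nm)
  if (length(miss)) {
    stop(sprintf("patient table '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  names(df) <- nm
  mda <- suppressWarnings(as.numeric(df$mda))
  donors <- suppressWarnings(as.numeric(df$donors_protons))
  bad <- which(!is.finite(mda) | !is.finite(donors))
  if (length(bad)) {
    stop(sprintf("non-numeric biomarker value(s) at line(s) %s of '%s'",
                 paste(bad + 1L, collapse = ", "), path), call. = FALSE)
  }
  data.frame(id = df$id, MDA = mda, DONORS_PROTONS = donors,
             stringsAsFactors = FALSE)
}

#' Score a batch of patients
#'
#' One output row per input row, in order, with the crisp risk and the
#' rule of maximal firing strength (ties broken by rule index).
#'
#' @param fis The risk system.
#' @param records Data frame from [read_patients()] or
#'   [generate_fixture()].
#' @return Data frame `id`, `MDA`, `DONORS_PROTONS`, `RISK`, `top_rule`.
#' @export
score_batch <- function(fis, records) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(id = character(0), MDA = numeric(0),
                      DONORS_PROTONS = numeric(0), RISK = numeric(0),
                      top_rule = character(0), stringsAsFactors = FALSE))
  }
  risk <- infer_batch(fis, records)
  top <- vapply(seq_len(n), function(i) {
    tr <- infer(fis, c(MDA = records$MDA[i],
                       DONORS_PROTONS = records$DONORS_PROTONS[i]))
    rule_label(fis, which.max(tr$firing))
  }, character(1))
  data.frame(id = if ("id" %in% names(records)) records$id else as.character(seq_len(n)),
             MDA = records$MDA, DONORS_PROTONS = records$DONORS_PROTONS,
             RISK = risk, top_rule = top, stringsAsFactors = FALSE)
}

# Human-readable rendering of rule i, e.g.
# "MDA=FM & DONORS_PROTONS=fm -> RISK=FM".
rule_label <- function(fis, i) {
  ant <- vapply(names(fis$inputs), function(v) {
    sprintf("%s=%s", v, fis$rules[[v]][i])
  }, character(1))
  sprintf("%s -> %s=%s", paste(ant, collapse = " & "),
          fis$output$name, fis$rules$consequent[i])
}

#' Write a scored table
#'
#' CSV output with risks formatted to four decimal places, matching the
#' typesetting of the published sweep table.
#'
#' @param scored Data frame from [score_batch()].
#' @param path Output path.
#' @export
write_scored <- function(scored, path) {
  out <- scored
  out$RISK <- sprintf("%.4f", out$RISK)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic patient table
#'
#' Seeded stand-in for a patient cohort: biomarker pairs drawn uniformly
#' over the two input universes (MDA on `[1.1, 6.7]` nmol/ml, proton
#' donors on `[38.5, 58.25]` inhibition %). Deterministic given the seed;
#' the caller's RNG stream is left untouched.
#'
#' @param seed Integer seed.
#' @param n Number of patients (default 16, the size of the study cohort).
#' @return Data frame `id`, `MDA`, `DONORS_PROTONS`.
#' @export
generate_fixture <- function(seed, n = 16L) {
  stopifnot(n >= 1L)
  with_local_seed(seed, {
    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      MDA = stats::runif(n, mda_universe[1L], mda_universe[2L]),
      DONORS_PROTONS = stats::runif(n, donors_universe[1L], donors_universe[2L]),
      stringsAsFactors = FALSE
    )
  })
}
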