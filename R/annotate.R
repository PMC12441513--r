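# Diagnostic-ion / neutral-loss rule engine: encodes class-characteristic
# fragment ions, neutral-loss series and serial losses, scores MS2 spectra
# against them and assigns compound classes; also validates candidate
# annotations coming out of the molecular network.

#' The packaged fragmentation rulebase
#'
#' Class-characteristic diagnostic ions (e.g. the retro-Diels-Alder flavonoid
#' ion near m/z 169.066, iridoid ions 179.0565/89.0249, indole-alkaloid
#' ring-C-cleavage ions 160.076/170.097/144.081), neutral losses (glucuronide
#' 176.0321 Da, glucosyl 162.0528 Da, H2O, CO, CH2O, CH3, O, CO2) and serial
#' losses (the sesquiterpene CH2 ladder, consecutive CH3 losses of
#' anthraquinones, CH2O series of oligosaccharides). Diagnostic ions carry
#' weight 2, losses weight 1; tolerances default to 0.01 Da. Users can edit
#' the CSV and reload with [read_rulebase()].
#'
#' @return Rulebase data frame (see [read_rulebase()]).
#' @export
default_rulebase <- function() {
  read_rulebase(system.file("extdata", "rulebase.csv", package = "herbnet",
                            mustWork = TRUE))
}

#' Enumerate neutral losses in a spectrum
#'
#' All pairwise mass differences among the precursor and fragment peaks with
#' `from > to` and loss > 1 Da, sorted by loss.
#'
#' @param spectrum A `Spectrum`.
#' @param min_loss Smallest loss reported (Da).
#' @return Data frame with columns `from_mz`, `to_mz`, `loss`.
#' @export
detect_neutral_losses <- function(spectrum, min_loss = 1) {
  mzs <- c(spectrum$precursor_mz, spectrum$mz)
  if (length(mzs) < 2) {
    return(data.frame(from_mz = numeric(0), to_mz = numeric(0),
                      loss = numeric(0)))
  }
  pairs <- expand.grid(from_mz = mzs, to_mz = mzs)
  pairs$loss <- pairs$from_mz - pairs$to_mz
  pairs <- pairs[pairs$loss > min_loss, , drop = FALSE]
  pairs <- unique(pairs)
  pairs[order(pairs$loss), c("from_mz", "to_mz", "loss")]
}

#' Longest serial-loss chain
#'
#' Length of the longest chain of peaks (starting from the precursor or any
#' peak) in which each member lies `delta` (within `tol`) below the previous
#' one, e.g. the consecutive CH2 (14.0157 Da) losses of sesquiterpenes.
#'
#' @param spectrum A `Spectrum`.
#' @param delta Loss per step, Da.
#' @param tol Matching tolerance, Da.
#' @return Integer chain length (1 when no step is found).
#' @export
detect_serial_losses <- function(spectrum, delta, tol = 0.01) {
  mzs <- sort(unique(c(spectrum$precursor_mz, spectrum$mz)), decreasing = TRUE)
  n <- length(mzs)
  if (n == 0) return(0L)
  # longest path in the DAG of delta-steps; mzs descending so a step goes i->j, j>i
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    steps <- which(abs(mzs[i] - mzs - delta) <= tol)
    for (j in steps) best[j] <- max(best[j], best[i] + 1L)
  }
  max(best)
}

match_any_peak <- function(peaks, target, tol) {
  length(peaks) > 0 && any(abs(peaks - target) <= tol)
}

# Evaluate one rule against a spectrum; returns matched value or NA.
evaluate_rule <- function(spectrum, rule, losses) {
  if (rule$kind == "diagnostic_ion") {
    hit <- which(abs(spectrum$mz - rule$value) <= rule$tolerance)
    if (length(hit)) return(spectrum$mz[hit[[1]]])
    return(NA_real_)
  }
  if (rule$kind == "neutral_loss") {
    hit <- which(abs(losses$loss - rule$value) <= rule$tolerance)
    if (length(hit)) return(losses$loss[hit[[1]]])
    return(NA_real_)
  }
  # serial_loss
  len <- detect_serial_losses(spectrum, rule$value, rule$tolerance)
  if (len - 1L >= rule$series_count) return(as.numeric(len - 1L))
  NA_real_
}

#' Classify an MS2 spectrum by diagnostic ions and neutral losses
#'
#' Scores every class in the rulebase (restricted to the spectrum's polarity):
#' each satisfied rule contributes its weight. The top class is returned when
#' its score reaches `min_score` and beats the runner-up by at least `margin`;
#' otherwise the result is `"unclassified"` with both scores reported.
#'
#' @param spectrum A `Spectrum`.
#' @param rulebase Rulebase data frame (default [default_rulebase()]).
#' @param min_score Minimum winning score (default 2, i.e. one diagnostic ion
#'   or two neutral losses).
#' @param margin Required lead over the runner-up score (default 1).
#' @return List with `compound_class`, `score`, `runner_up`,
#'   `runner_up_score`, and `matched_rules` (data frame `rule_id`, `observed`).
#' @export
classify_spectrum <- function(spectrum, rulebase = default_rulebase(),
                              min_score = 2, margin = 1) {
  rb <- rulebase[rulebase$polarity == spectrum$polarity, , drop = FALSE]
  unclassified <- list(compound_class = "unclassified", score = 0,
                       runner_up = NA_character_, runner_up_score = 0,
                       matched_rules = data.frame(rule_id = character(0),
                                                  observed = numeric(0)))
  if (nrow(rb) == 0 || length(spectrum$mz) == 0) return(unclassified)
  losses <- detect_neutral_losses(spectrum)
  rb$observed <- vapply(seq_len(nrow(rb)), function(i) {
    evaluate_rule(spectrum, rb[i, ], losses)
  }, numeric(1))
  rb$satisfied <- !is.na(rb$observed)
  scores <- tapply(rb$weight * rb$satisfied, rb$class, sum)
  scores <- sort(unlist(scores), decreasing = TRUE)
  top <- names(scores)[[1]]
  runner_score <- if (length(scores) > 1) scores[[2]] else 0
  runner <- if (length(scores) > 1) names(scores)[[2]] else NA_character_
  if (scores[[1]] < min_score || scores[[1]] - runner_score < margin) {
    out <- unclassified
    out$score <- unname(scores[[1]])
    out$runner_up <- if (scores[[1]] >= min_score) top else runner
    out$runner_up_score <- unname(runner_score)
    return(out)
  }
  hit <- rb[rb$satisfied & rb$class == top, , drop = FALSE]
  list(compound_class = top, score = unname(scores[[1]]),
       runner_up = runner, runner_up_score = unname(runner_score),
       matched_rules = data.frame(rule_id = hit$rule_id,
                                  observed = hit$observed))
}

#' Validate a proposed class annotation against MS2 evidence
#'
#' Accepts the proposal when the rule engine agrees, or when it returns
#' unclassified but the proposed class ties for the top score (compatible
#' evidence). Rejects otherwise, recording the conflicting class — this is
#' the pruning step that removes spectral-library false positives.
#'
#' @param spectrum The feature's MS2 `Spectrum` (or `NULL` for no evidence).
#' @param proposed_class Class label to check.
#' @param rulebase Rulebase data frame.
#' @param ... Passed to [classify_spectrum()].
#' @return List with `accept` (logical), `reason`, and the classification.
#' @export
validate_annotation <- function(spectrum, proposed_class,
                                rulebase = default_rulebase(), ...) {
  if (is.null(spectrum)) {
    return(list(accept = FALSE, reason = "no evidence", classification = NULL))
  }
  cls <- classify_spectrum(spectrum, rulebase, ...)
  if (identical(cls$compound_class, proposed_class)) {
    return(list(accept = TRUE, reason = "rule engine agrees",
                classification = cls))
  }
  if (cls$compound_class == "unclassified" &&
      (is.na(cls$runner_up) || identical(cls$runner_up, proposed_class) ||
       cls$score == 0)) {
    return(list(accept = TRUE, reason = "no conflicting evidence",
                classification = cls))
  }
  list(accept = FALSE,
       reason = paste0("spectrum supports '",
                       if (cls$compound_class == "unclassified") cls$runner_up
                       else cls$compound_class,
                       "' (score ", cls$score, ")"),
       classification = cls)
}
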