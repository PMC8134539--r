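#' Partition subjects by an ADOS total cutoff
#'
#' @param ados_total numeric totals (no missing values).
#' @param cutoff integer cutoff.
#' @param rule `">="` (default: severe iff `total >= cutoff`) or `">"`.
#' @return factor with levels `severe`, `mild`.
#' @export
thresholdPartition <- function(ados_total, cutoff, rule = c(">=", ">")) {
  rule <- match.arg(rule)
  if (anyNA(ados_total)) stop("totals must be present")
  sev <- if (rule == ">=") ados_total >= cutoff else ados_total > cutoff
  factor(ifelse(sev, "severe", "mild"), levels = c("severe", "mild"))
}

#' Agreement metrics between two severe/mild labelings
#'
#' Percentage of agreement (PoA), sensitivity (reference-severe called
#' severe) and specificity (reference-mild called mild) of `test`
#' against `reference`.  An empty reference class leaves the
#' corresponding rate `NA` (undefined), never 0.
#'
#' @param reference,test factors/vectors with values `severe`/`mild`,
#'   same length.
#' @return list with `poa`, `sensitivity`, `specificity` and the 2x2
#'   `counts` table.
#' @export
confusionMetrics <- function(reference, test) {
  reference <- as.character(reference); test <- as.character(test)
  if (length(reference) != length(test)) stop("length mismatch")
  ok <- c("severe", "mild")
  if (!all(reference %in% ok) || !all(test %in% ok))
    stop("labels must be severe/mild")
  counts <- table(factor(reference, ok), factor(test, ok),
                  dnn = c("reference", "test"))
  nsev <- sum(counts["severe", ]); nmld <- sum(counts["mild", ])
  list(
    poa = (counts["severe", "severe"] + counts["mild", "mild"]) /
      length(reference),
    sensitivity = if (nsev) counts["severe", "severe"] / nsev else NA_real_,
    specificity = if (nmld) counts["mild", "mild"] / nmld else NA_real_,
    counts = counts
  )
}

#' Sweep ADOS cutoffs against an FC-based partition
#'
#' For each integer cutoff, partitions subjects at the cutoff
#' ([thresholdPartition()]) and computes agreement metrics in both
#' orientations: with the cutoff partition as the reference and with
#' the FC-based partition as the reference (PoA is identical under
#' either).
#'
#' @param fc_labels severe/mild labels from the FC-based partition.
#' @param ados_total per-subject ADOS totals.
#' @param cutoff_range integer cutoffs to sweep (default 9:17).
#' @param rule cutoff convention, see [thresholdPartition()].
#' @return data.frame with one row per cutoff: `cutoff`, `poa`,
#'   `sens_cutoff_ref`, `spec_cutoff_ref`, `sens_fc_ref`,
#'   `spec_fc_ref`, `n_severe_cutoff`, `n_severe_fc`.
#' @export
cutoffSweep <- function(fc_labels, ados_total, cutoff_range = 9:17,
                        rule = ">=") {
  rows <- lapply(cutoff_range, function(ct) {
    cutlab <- thresholdPartition(ados_total, ct, rule)
    a <- confusionMetrics(cutlab, fc_labels)   # cutoff as reference
    b <- confusionMetrics(fc_labels, cutlab)   # FC partition as reference
    data.frame(cutoff = ct, poa = a$poa,
               sens_cutoff_ref = a$sensitivity,
               spec_cutoff_ref = a$specificity,
               sens_fc_ref = b$sensitivity, spec_fc_ref = b$specificity,
               n_severe_cutoff = sum(cutlab == "severe"),
               n_severe_fc = sum(fc_labels == "severe"))
  })
  if (!length(rows))
    return(data.frame(cutoff = integer(0), poa = numeric(0),
                      sens_cutoff_ref = numeric(0),
                      spec_cutoff_ref = numeric(0),
                      sens_fc_ref = numeric(0), spec_fc_ref = numeric(0),
                      n_severe_cutoff = integer(0),
                      n_severe_fc = integer(0)))
  do.call(rbind, rows)
}
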