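#' Published per-ablation accuracy table
#'
#' The per-ablation true positive rate (%), false discovery rate (%) and
#' agreement-disagreement ratio reported for ten porcine microwave
#' ablations across CECT and the five perfusion maps, as digitized from
#' the underlying accuracy study. One HBV cell (ablation 2) is garbled in
#' the printed source; its rates are stored as NA. These printed values serve as
#' worked-example inputs for the pooling and rate-identity checks.
#'
#' @return data.frame with columns ablation, modality, tpr_pct, fdr_pct,
#'   adr.
#' @export
studyAccuracyTable <- function() {
  p <- system.file("extdata", "study_accuracy_table.csv",
                   package = "necromap", mustWork = TRUE)
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Published pooled cutoffs per modality
#'
#' The single upper thresholds used to compute all-ablation accuracies:
#' 200 HU (CECT), 74/75/100 ml/min (AF/PF/TF), 29 ml (HBV), 38 s (MTT).
#'
#' @return named numeric vector of cutoffs in each modality's units.
#' @export
studyCutoffs <- function() .STUDY_CUTOFFS
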