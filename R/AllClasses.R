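#' @import methods
#' @importFrom stats median ks.test kruskal.test cor.test pnorm qnorm
#'   p.adjust rlnorm rgamma rexp runif rbinom setNames complete.cases
#'   quantile
#' @importFrom utils read.delim write.table head
NULL

#' SyntheticCohort: a simulated immunoradiotherapy cohort
#'
#' Container for one simulated cohort: patient roster with true response
#' groups, longitudinal absolute blood counts, per-timepoint bulk expression
#' matrices mixed from a known signature, the ground-truth cell-type
#' fractions behind those mixtures, progression/survival records, and
#' IHC-style cell densities. Produced by [simulateCohort()]; every
#' downstream module of the package can be exercised on it without any
#' patient-level data.
#'
#' @slot patients data.frame with columns patient_id, true_group
#'   (Progressive/Stable/Elite), has_tumor_data, enrollment_day.
#' @slot blood data.frame of draws: patient_id, day, neutrophils,
#'   lymphocytes, monocytes (absolute counts, 1e9/L).
#' @slot expression named list of genes x samples matrices, one per biopsy
#'   timepoint (baseline, C1, C3).
#' @slot trueFractions matrix, samples x cell types; rows sum to 1.
#' @slot survival data.frame: patient_id, endpoint, time_days, event.
#' @slot ihc data.frame: sample_id, patient_id, CD68, CD3, CD20 (cells/mm2).
#' @slot config list, the validated configuration the cohort was drawn from.
#' @export
setClass("SyntheticCohort",
  representation(
    patients = "data.frame",
    blood = "data.frame",
    expression = "list",
    trueFractions = "matrix",
    survival = "data.frame",
    ihc = "data.frame",
    config = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- object@patients$patient_id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated patient_id in patients")
  check_ref <- function(tab, what) {
    if (nrow(tab) && !all(tab$patient_id %in% ids))
      sprintf("%s references unknown patient_id", what) else character()
  }
  msg <- c(msg, check_ref(object@blood, "blood"),
           check_ref(object@survival, "survival"))
  if (nrow(object@blood)) {
    cnt <- as.matrix(object@blood[, c("neutrophils", "lymphocytes", "monocytes")])
    if (any(cnt < 0)) msg <- c(msg, "negative blood counts")
  }
  if (nrow(object@trueFractions)) {
    rs <- rowSums(object@trueFractions)
    if (any(abs(rs - 1) > 1e-8))
      msg <- c(msg, "trueFractions rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' DeconvResult: cell-type scores for a set of bulk samples
#'
#' Holds the output of reference-based deconvolution: one nonnegative score
#' per (sample, cell type), the method tag, and per-sample annotation
#' (timepoint, response group) used by the group-comparison and
#' heatmap-normalization steps.
#'
#' @slot scores matrix, samples x cell types, nonnegative.
#' @slot method character tag, e.g. "nnls" or "wnnls".
#' @slot sampleInfo data.frame keyed by sample_id with optional columns
#'   timepoint and response_group; zero rows when no annotation is attached.
#' @export
setClass("DeconvResult",
  representation(
    scores = "matrix",
    method = "character",
    sampleInfo = "data.frame"
  ),
  prototype(method = "nnls", sampleInfo = data.frame())
)

setValidity("DeconvResult", function(object) {
  msg <- character()
  if (any(object@scores < -1e-12)) msg <- c(msg, "negative scores")
  if (is.null(colnames(object@scores))) msg <- c(msg, "scores need cell-type column names")
  if (nrow(object@sampleInfo) &&
      nrow(object@sampleInfo) != nrow(object@scores))
    msg <- c(msg, "sampleInfo rows must match score rows")
  if (length(msg)) msg else TRUE
})

#' ThresholdSelection: a ROC-derived biomarker cutoff with provenance
#'
#' The result of training-set threshold selection: the full ROC curve, its
#' trapezoidal AUC, the selected cutoff, the positive likelihood ratio
#' (sensitivity / (1 - specificity)) attained there, the selection flavor,
#' and the training/validation sample sizes.
#'
#' @slot threshold numeric cutoff; scores >= threshold are called "high".
#' @slot lrPlus positive likelihood ratio at the cutoff (Inf when FPR = 0).
#' @slot auc area under the ROC curve, in [0, 1].
#' @slot trainingN,validationN integer sample sizes.
#' @slot roc data.frame with columns threshold, tpr, fpr.
#' @slot flavor "lrplus" or "youden".
#' @export
setClass("ThresholdSelection",
  representation(
    threshold = "numeric",
    lrPlus = "numeric",
    auc = "numeric",
    trainingN = "integer",
    validationN = "integer",
    roc = "data.frame",
    flavor = "character"
  ),
  prototype(validationN = NA_integer_, flavor = "lrplus")
)

setValidity("ThresholdSelection", function(object) {
  msg <- character()
  if (length(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@patients$true_group)
  cat("SyntheticCohort:", nrow(object@patients), "patients (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  cat("  blood draws:", nrow(object@blood),
      "| expression timepoints:", length(object@expression),
      "| survival records:", nrow(object@survival), "\n")
  cat("  seed:", object@config$seed, "\n")
  invisible(object)
})

setMethod("show", "DeconvResult", function(object) {
  cat("DeconvResult (", object@method, "): ",
      nrow(object@scores), " samples x ", ncol(object@scores),
      " cell types\n", sep = "")
  invisible(object)
})

setMethod("show", "ThresholdSelection", function(object) {
  cat(sprintf(
    "ThresholdSelection [%s]: threshold = %.4g (LR+ = %.3g), AUC = %.3f\n",
    object@flavor, object@threshold, object@lrPlus, object@auc))
  cat(sprintf("  training n = %d, validation n = %s\n", object@trainingN,
              ifelse(is.na(object@validationN), "-", object@validationN)))
  invisible(object)
})
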