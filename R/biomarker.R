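## MonoLR biomarker derivation: availability-based train/validation split,
## ROC construction, trapezoidal AUC, maximum-LR+ threshold selection, and
## blood-tumor rank correlation.

#' Split patients into training and validation sets by data availability
#'
#' Training patients have clinical, blood and tumor data; validation
#' patients have clinical and blood data but no tumor samples. Patients
#' lacking baseline blood belong to neither set and are returned with the
#' reason.
#'
#' @param patients data.frame with patient_id and has_tumor_data.
#' @param hasBaselineBlood logical vector (or named vector keyed by
#'   patient_id); defaults to all TRUE.
#' @return list with `training`, `validation` (character id vectors) and
#'   `excluded` data.frame (patient_id, reason).
#' @export
splitByAvailability <- function(patients, hasBaselineBlood = NULL) {
  ids <- patients$patient_id
  if (is.null(hasBaselineBlood)) hasBaselineBlood <- rep(TRUE, length(ids))
  if (!is.null(names(hasBaselineBlood)))
    hasBaselineBlood <- hasBaselineBlood[ids] %in% TRUE
  excluded <- data.frame(patient_id = ids[!hasBaselineBlood],
                         reason = rep("no baseline blood",
                                      sum(!hasBaselineBlood)),
                         stringsAsFactors = FALSE)
  ok <- hasBaselineBlood
  list(training = ids[ok & patients$has_tumor_data],
       validation = ids[ok & !patients$has_tumor_data],
       excluded = excluded)
}

#' ROC curve for a score predicting the Progressive class
#'
#' Candidate thresholds are the distinct observed score values plus the
#' two infinite endpoints; a sample is called positive (predicted
#' Progressive) when its score is at or above the threshold. TPR and FPR
#' are computed per threshold; as the threshold decreases both are
#' nondecreasing and the curve runs from (0, 0) to (1, 1).
#'
#' @param scores numeric scores (higher = more Progressive-like).
#' @param labels logical or character vector; `positive` names the
#'   Progressive class for character labels.
#' @param positive positive-class label (default "Progressive").
#' @return data.frame with columns threshold (decreasing), tpr, fpr.
#' @export
rocPoints <- function(scores, labels, positive = "Progressive") {
  if (!is.logical(labels)) labels <- labels == positive
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("both classes must be present to build a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Trapezoidal area under a ROC curve
#'
#' Integrates TPR over FPR by the trapezoid rule. On tie-free data this
#' equals the Mann-Whitney concordance probability (the chance a random
#' positive outscores a random negative).
#'
#' @param curve a data.frame from [rocPoints()].
#' @return AUC in \[0, 1\].
#' @export
aucTrapezoid <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]; y <- curve$tpr[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Select a biomarker threshold by maximum positive likelihood ratio
#'
#' Scans the ROC candidate cut points and picks the one maximizing
#' LR+ = TPR / FPR among points with FPR > 0. Any point with FPR = 0 and
#' TPR > 0 has infinite LR+ and dominates; among those the one with the
#' highest TPR is chosen. Remaining ties are broken by higher Youden J
#' (TPR - FPR), then by the smaller threshold. `flavor = "youden"`
#' maximizes Youden J instead (ties by smaller threshold). Because the
#' candidates are the observed score values, the selection is invariant
#' under any strictly increasing transform of the scores.
#'
#' @param curve a data.frame from [rocPoints()].
#' @param flavor "lrplus" (default) or "youden".
#' @param trainingN,validationN sample sizes recorded in the result.
#' @return a [ThresholdSelection-class].
#' @export
selectThresholdLrPlus <- function(curve, flavor = c("lrplus", "youden"),
                                  trainingN = NA_integer_,
                                  validationN = NA_integer_) {
  flavor <- match.arg(flavor)
  cand <- curve[is.finite(curve$threshold) | curve$threshold == Inf, ,
                drop = FALSE]
  cand <- cand[cand$tpr > 0 | cand$fpr > 0, , drop = FALSE]  # drop (0,0)
  if (!nrow(cand) || all(cand$tpr == 0))
    stop("degenerate ROC curve: no cut point with TPR > 0")
  auc <- aucTrapezoid(curve)
  if (flavor == "youden") {
    j <- cand$tpr - cand$fpr
    best <- which(j == max(j))
    best <- best[order(cand$threshold[best])][1]
  } else {
    zeroFpr <- cand$fpr == 0 & cand$tpr > 0
    if (any(zeroFpr)) {
      best <- which(zeroFpr)
      best <- best[order(-cand$tpr[best], cand$threshold[best])][1]
    } else {
      lr <- cand$tpr / cand$fpr
      best <- which(lr == max(lr))
      j <- cand$tpr - cand$fpr
      best <- best[order(-j[best], cand$threshold[best])][1]
    }
  }
  lrBest <- if (cand$fpr[best] > 0) cand$tpr[best] / cand$fpr[best] else Inf
  new("ThresholdSelection",
      threshold = cand$threshold[best], lrPlus = lrBest, auc = auc,
      trainingN = as.integer(trainingN), validationN = as.integer(validationN),
      roc = curve, flavor = flavor)
}

#' Dichotomize scores at a selected threshold
#'
#' Labels a score "high" when it is at or above the threshold (a score
#' exactly at the threshold is "high"). Missing scores are excluded and
#' reported. Relabeling the output is idempotent.
#'
#' @param scores named numeric vector (names = patient ids).
#' @param selection a [ThresholdSelection-class] or a numeric threshold.
#' @return list with `labels` (named character, "high"/"low") and
#'   `excluded` (ids of patients without a score).
#' @export
applyThreshold <- function(scores, selection) {
  t <- if (is(selection, "ThresholdSelection")) selectedThreshold(selection)
       else as.numeric(selection)
  miss <- names(scores)[is.na(scores)]
  ok <- scores[!is.na(scores)]
  list(labels = setNames(ifelse(ok >= t, "high", "low"), names(ok)),
       excluded = miss)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Rank correlation with average ranks for ties; the package's measure of
#' blood-tumor biomarker agreement. A constant vector leaves the
#' correlation undefined and is reported as such.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearmanCorr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                note = "undefined: constant input"))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
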