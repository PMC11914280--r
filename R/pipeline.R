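## Table IO and the end-to-end analysis pipeline:
## simulate -> blood kinetics -> deconvolution -> MDCLR -> biomarker
## threshold -> dichotomized survival, with a manifest for reproducibility.

#' Read / write tab-separated tables with schema checks
#'
#' All package IO is tab-separated with explicit headers. `readTsv`
#' verifies that the expected columns are present and that numeric columns
#' parse, reporting the offending column or row; `writeTsv` writes without
#' quoting or row names so that read(write(x)) round-trips exactly.
#'
#' @param path file path.
#' @param columns required column names (others are allowed and kept).
#' @param numericColumns columns that must parse as numbers.
#' @return data.frame (readTsv); invisibly `path` (writeTsv).
#' @export
readTsv <- function(path, columns = NULL, numericColumns = NULL) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!is.null(columns)) {
    miss <- setdiff(columns, names(x))
    if (length(miss))
      stop(sprintf("%s: missing expected column(s): %s", basename(path),
                   paste(miss, collapse = ", ")))
  }
  for (cc in intersect(numericColumns %||% character(), names(x))) {
    v <- x[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("%s: malformed numeric cell in column %s, row %d",
                     basename(path), cc, bad[1]))
      x[[cc]] <- num
    }
  }
  x
}

#' @rdname readTsv
#' @param x data.frame to write.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a blood-draw table
#'
#' TSV with columns patient_id, day, neutrophils, lymphocytes, monocytes.
#'
#' @param path file path.
#' @return data.frame of draws.
#' @export
readBloodTsv <- function(path) {
  readTsv(path,
          columns = c("patient_id", "day", "neutrophils", "lymphocytes",
                      "monocytes"),
          numericColumns = c("day", "neutrophils", "lymphocytes",
                             "monocytes"))
}

#' Read a survival-record table
#'
#' TSV with columns patient_id, endpoint, time_days, event.
#'
#' @param path file path.
#' @return data.frame of records.
#' @export
readSurvivalTsv <- function(path) {
  readTsv(path, columns = c("patient_id", "endpoint", "time_days", "event"),
          numericColumns = c("time_days", "event"))
}

#' Read an expression (genes x samples) TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
readExpressionTsv <- function(path) {
  x <- readTsv(path, columns = "gene")
  m <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- x$gene
  m
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration, in order: simulate the cohort; window blood
#' draws into period summaries; deconvolve each biopsy timepoint against
#' the built-in signature; compute per-sample MDCLR (full formula) and the
#' subgroup-normalized heatmap table with KS group tests; split patients
#' into training (blood + tumor) and validation (blood only) sets; build
#' the ROC on training baseline MonoLR against the Progressive label,
#' select the maximum-LR+ threshold and apply it to both sets; estimate
#' dichotomized KM curves with logrank and O/E hazard ratios per set and
#' endpoint; compute the one-year landmark rate; and write every table
#' plus a manifest (config, seed, file hashes) to `outDir`. Re-running
#' with the same config yields byte-identical outputs.
#'
#' @param config a [cohortConfig()].
#' @param outDir output directory, or NULL to skip writing.
#' @param landmarkDays landmark time for the PFS rate (default 365).
#' @param flavor threshold-selection flavor, "lrplus" or "youden".
#' @return invisibly, a list with all intermediate results.
#' @export
runPipeline <- function(config = cohortConfig(), outDir = NULL,
                        landmarkDays = 365, flavor = "lrplus") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("simulate", simulateCohort(config))
  pts <- patients(cohort)

  summaries <- stage("blood", summarizePatientPeriods(bloodDraws(cohort)))
  base <- summaries[summaries$period == "baseline", ]
  baseMonolr <- setNames(base$monolr, base$patient_id)

  ## deconvolution per timepoint with annotation
  sig <- defaultSignature()
  exprs <- expressionMatrices(cohort)
  deconv <- stage("deconv", {
    res <- lapply(names(exprs), function(tp) {
      m <- exprs[[tp]]
      pids <- sub(sprintf("_%s$", tp), "", colnames(m))
      si <- data.frame(
        sample_id = colnames(m), timepoint = tp,
        response_group = ifelse(
          pts$true_group[match(pids, pts$patient_id)] == "Progressive",
          "Progressive", "StableElite"),
        stringsAsFactors = FALSE)
      deconvolveLS(m, sig, sumToOne = TRUE, sampleInfo = si)
    })
    names(res) <- names(exprs)
    res
  })
  combined <- if (length(deconv)) {
    new("DeconvResult",
        scores = do.call(rbind, lapply(deconv, cellScores)),
        method = "nnls",
        sampleInfo = do.call(rbind, lapply(deconv, sampleInfo)))
  } else NULL

  mdclr <- stage("scores", if (!is.null(combined)) {
    si <- sampleInfo(combined)
    data.frame(si, mdclr = mdclrFull(combined), stringsAsFactors = FALSE)
  } else NULL)
  heat <- if (!is.null(combined)) heatmapNormalize(combined) else NULL
  ctTests <- if (!is.null(combined)) celltypeGroupTests(combined) else NULL

  ## biomarker: training/validation split, ROC, threshold
  hasBase <- setNames(pts$patient_id %in% base$patient_id, pts$patient_id)
  split <- splitByAvailability(pts, hasBase)
  labels <- setNames(pts$true_group == "Progressive", pts$patient_id)
  tr <- split$training
  ## with no tumor data there is no training set: the validation-only path
  ## runs the blood and survival stages and skips threshold derivation
  biomarker <- if (length(tr) >= 2 && length(unique(labels[tr])) == 2) {
    stage("biomarker", {
      curve <- rocPoints(baseMonolr[tr], labels[tr])
      selectThresholdLrPlus(curve, flavor = flavor,
                            trainingN = length(tr),
                            validationN = length(split$validation))
    })
  } else NULL

  ## dichotomized survival per set and endpoint
  surv <- survivalRecords(cohort)
  groupsOf <- function(ids) applyThreshold(baseMonolr[ids], biomarker)$labels
  survOut <- stage("survival", {
    out <- list()
    if (is.null(biomarker)) sets <- character() else
      sets <- c("training", "validation")
    for (set in sets) {
      ids <- split[[set]]
      if (length(ids) < 4) next
      lab <- groupsOf(ids)
      for (ep in unique(surv$endpoint)) {
        d <- surv[surv$endpoint == ep & surv$patient_id %in% ids, ]
        d$grp <- lab[d$patient_id]
        lo <- d[d$grp == "low", ]; hi <- d[d$grp == "high", ]
        if (nrow(lo) < 2 || nrow(hi) < 2) next
        lr <- logrankTest(lo, hi)
        out[[paste(set, ep, sep = ".")]] <- list(
          set = set, endpoint = ep,
          km_low = kmCurve(lo), km_high = kmCurve(hi),
          logrank = lr, hr = hazardRatioOE(lr, numerator = 1))
      }
    }
    out
  })
  kmAll <- kmCurve(surv[surv$endpoint == "PFS", ])
  landmark <- landmarkRate(kmAll, landmarkDays)

  result <- list(cohort = cohort, summaries = summaries,
                 deconvolution = deconv, mdclr = mdclr, heatmap = heat,
                 celltypeTests = ctTests, split = split,
                 threshold = biomarker, survival = survOut,
                 kmOverall = kmAll, landmark = landmark)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCohort(cohort, file.path(outDir, "cohort"))
    writeTsv(summaries, file.path(outDir, "period_summaries.tsv"))
    if (!is.null(mdclr)) writeTsv(mdclr, file.path(outDir, "mdclr.tsv"))
    if (!is.null(heat))
      writeTsv(data.frame(cell_type = rownames(heat), heat,
                          check.names = FALSE),
               file.path(outDir, "heatmap_normalized.tsv"))
    if (!is.null(ctTests))
      writeTsv(ctTests, file.path(outDir, "celltype_tests.tsv"))
    if (!is.null(biomarker)) {
      writeTsv(rocCurve(biomarker), file.path(outDir, "roc.tsv"))
      jsonlite::write_json(
        list(threshold = selectedThreshold(biomarker),
             lr_plus = if (is.finite(biomarker@lrPlus)) biomarker@lrPlus else "Inf",
             auc = aucOf(biomarker), flavor = flavor,
             training_n = biomarker@trainingN,
             validation_n = biomarker@validationN),
        file.path(outDir, "threshold_selection.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    kmTab <- do.call(rbind, lapply(names(survOut), function(nm) {
      x <- survOut[[nm]]
      rbind(data.frame(set = x$set, endpoint = x$endpoint, group = "low",
                       x$km_low$curve),
            data.frame(set = x$set, endpoint = x$endpoint, group = "high",
                       x$km_high$curve))
    }))
    if (is.null(kmTab))
      kmTab <- data.frame(set = character(), endpoint = character(),
                          group = character(), time = numeric(),
                          n_risk = integer(), n_event = integer(),
                          n_censor = integer(), survival = numeric(),
                          var = numeric())
    writeTsv(kmTab, file.path(outDir, "km_curves.tsv"))
    hrTab <- do.call(rbind, lapply(survOut, function(x)
      data.frame(set = x$set, endpoint = x$endpoint, hr = x$hr$hr,
                 hr_lower = x$hr$lower, hr_upper = x$hr$upper,
                 logrank_chisq = x$logrank$chisq,
                 logrank_p = x$logrank$p_value)))
    if (is.null(hrTab))
      hrTab <- data.frame(set = character(), endpoint = character(),
                          hr = numeric(), hr_lower = numeric(),
                          hr_upper = numeric(), logrank_chisq = numeric(),
                          logrank_p = numeric())
    writeTsv(hrTab, file.path(outDir, "hazard_ratios.tsv"))
    writeTsv(data.frame(landmark_days = landmarkDays,
                        rate = landmark$rate, lower = landmark$lower,
                        upper = landmark$upper, successes = landmark$successes,
                        n = landmark$n),
             file.path(outDir, "landmark.tsv"))
    files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                          "manifest.json"))
    hashes <- tools::md5sum(file.path(outDir, files))
    jsonlite::write_json(
      list(seed = config$seed, landmark_days = landmarkDays,
           flavor = flavor,
           files = as.list(setNames(unname(hashes), files))),
      file.path(outDir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
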