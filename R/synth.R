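## Synthetic-cohort generator: blood kinetics, response groups, expression
## mixtures with known fractions, and survival outcomes, all from one seed.

.GROUPS <- c("Progressive", "Stable", "Elite")
.TIMEPOINTS <- c("baseline", "C1", "C3")

.MYELOID_TYPES <- c("Monocytes", "Macrophages_M0", "Macrophages_M1",
                    "Macrophages_M2", "Dendritic_myeloid")
.LYMPHOID_TYPES <- c("T_CD4", "T_CD8", "B_cells", "NK")

## run `expr` under a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Built-in synthetic marker signature
#'
#' A deterministic genes x cell-types reference with five myeloid
#' (monocytes, M0/M1/M2 macrophages, myeloid dendritic cells) and four
#' lymphoid (CD4 T, CD8 T, B, NK) populations. Each cell type carries
#' `nMarkers` high-expression marker genes (around 100 units) over a low
#' basal level elsewhere, the structure reference-based deconvolution
#' relies on. The matrix is synthetic: it is a stand-in with the right
#' shape, not a published reference profile.
#'
#' @param nMarkers markers per cell type (default 12).
#' @return nonnegative matrix, genes x 9 cell types, unique rownames.
#' @export
defaultSignature <- function(nMarkers = 12) {
  types <- c(.MYELOID_TYPES, .LYMPHOID_TYPES)
  .withSeed(761042, {
    genes <- unlist(lapply(types, function(ct)
      sprintf("%s_mk%02d", ct, seq_len(nMarkers))))
    sig <- matrix(runif(length(genes) * length(types), 0, 4),
                  nrow = length(genes), ncol = length(types),
                  dimnames = list(genes, types))
    for (j in seq_along(types)) {
      idx <- (j - 1L) * nMarkers + seq_len(nMarkers)
      sig[idx, j] <- runif(nMarkers, 60, 140)
    }
    sig
  })
}

#' Configuration for the synthetic cohort generator
#'
#' Validated configuration object. Defaults encode the translational-cohort
#' structure the generator emulates: 56 patients of whom 37 carry tumor
#' data, a roughly 27:7:3 Progressive:Stable:Elite split, baseline blood
#' medians of 0.78 vs 1.10 (lymphocytes), 0.67 vs 0.58 (monocytes) and 5.7
#' vs 3.5 (neutrophils) x 1e9/L for Progressive vs Stable+Elite, per-period
#' multipliers driving the Progressive lymphopenia and MonoLR rise over
#' cycles, and an exponential survival model whose log-hazard is linear in
#' baseline MonoLR.
#'
#' @param nPatients number of patients (>= 0).
#' @param propProgressive fraction of patients in the Progressive group.
#' @param eliteFraction fraction of non-progressive patients labelled Elite.
#' @param propTumorData fraction of patients with tumor biopsies.
#' @param groupBloodMedians 2 x 3 matrix (rows Progressive, StableElite;
#'   columns lymphocytes, monocytes, neutrophils), baseline medians, 1e9/L.
#' @param lymphMultipliers,monoMultipliers 2 x 4 matrices of per-period
#'   (baseline, cycle1, cycle2, cycle3) median multipliers by group.
#' @param monolrHazardCoef log-hazard slope per unit baseline MonoLR.
#' @param medianPfsDays target median time-to-progression (days) for a
#'   patient at the reference MonoLR of 0.73; sets the hazard intercept.
#' @param censorRate expected fraction of censored records, in \[0, 1\].
#' @param drawsPerPeriod blood draws per patient per period (>= 1).
#' @param noiseDispersion log-normal sdlog of blood counts (> 0).
#' @param exprDepth,exprDispersion depth scaling and multiplicative noise
#'   of the expression mixtures.
#' @param withExpression generate expression/fractions/IHC for
#'   tumor-bearing patients (TRUE); FALSE keeps the tumor-availability
#'   flags but skips the matrices, for blood-only experiments.
#' @param seed integer root seed; fixed seed implies identical cohorts.
#' @return named list of validated settings (class "cohortConfig").
#' @export
cohortConfig <- function(nPatients = 56,
                         propProgressive = 27 / 37,
                         eliteFraction = 0.3,
                         propTumorData = 37 / 56,
                         groupBloodMedians = NULL,
                         lymphMultipliers = NULL,
                         monoMultipliers = NULL,
                         monolrHazardCoef = 1.2,
                         medianPfsDays = 75,
                         censorRate = 0.15,
                         drawsPerPeriod = 2,
                         noiseDispersion = 0.35,
                         exprDepth = 1,
                         exprDispersion = 0.2,
                         withExpression = TRUE,
                         seed = 1) {
  if (is.null(groupBloodMedians)) {
    groupBloodMedians <- matrix(
      c(0.78, 0.67, 5.7,
        1.10, 0.58, 3.5), nrow = 2, byrow = TRUE,
      dimnames = list(c("Progressive", "StableElite"),
                      c("lymphocytes", "monocytes", "neutrophils")))
  }
  if (is.null(lymphMultipliers)) {
    ## cycle-3 targets: lymphocytes 0.56 (Progressive) and 0.85 (Stable+Elite)
    lymphMultipliers <- matrix(
      c(1, 0.90, 0.80, 0.56 / 0.78,
        1, 0.95, 0.90, 0.85 / 1.10), nrow = 2, byrow = TRUE,
      dimnames = list(c("Progressive", "StableElite"), .PERIODS$period))
  }
  if (is.null(monoMultipliers)) {
    ## cycle-3 MonoLR targets: 1.3 (Progressive) and 0.59 (Stable+Elite)
    monoMultipliers <- matrix(
      c(1, 1.02, 1.05, 1.3 * 0.56 / 0.67,
        1, 1.00, 1.00, 0.59 * 0.85 / 0.58), nrow = 2, byrow = TRUE,
      dimnames = list(c("Progressive", "StableElite"), .PERIODS$period))
  }
  cfg <- list(nPatients = nPatients, propProgressive = propProgressive,
              eliteFraction = eliteFraction, propTumorData = propTumorData,
              groupBloodMedians = groupBloodMedians,
              lymphMultipliers = lymphMultipliers,
              monoMultipliers = monoMultipliers,
              monolrHazardCoef = monolrHazardCoef,
              medianPfsDays = medianPfsDays,
              censorRate = censorRate, drawsPerPeriod = drawsPerPeriod,
              noiseDispersion = noiseDispersion,
              exprDepth = exprDepth, exprDispersion = exprDispersion,
              withExpression = withExpression, seed = seed)
  .validateConfig(cfg)
  class(cfg) <- c("cohortConfig", "list")
  cfg
}

.validateConfig <- function(cfg) {
  stopField <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid config field `%s`: %s", field, why))
  stopField(length(cfg$nPatients) == 1 && cfg$nPatients >= 0 &&
              cfg$nPatients == round(cfg$nPatients),
            "nPatients", "must be a nonnegative integer")
  for (f in c("propProgressive", "eliteFraction", "propTumorData",
              "censorRate"))
    stopField(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0, 1]")
  stopField(all(cfg$groupBloodMedians > 0), "groupBloodMedians",
            "all counts must be strictly positive")
  stopField(cfg$drawsPerPeriod >= 1, "drawsPerPeriod", "must be >= 1")
  stopField(cfg$noiseDispersion > 0, "noiseDispersion", "must be positive")
  stopField(cfg$medianPfsDays > 0, "medianPfsDays", "must be positive")
  stopField(length(cfg$seed) == 1 && is.finite(cfg$seed),
            "seed", "must be a finite scalar")
  invisible(TRUE)
}

#' Simulate expression matrices as noisy signature mixtures
#'
#' Mixes the columns of a signature with per-sample cell-type fractions:
#' the expected expression of sample s is `depth * signature %*%
#' fractions[s, ]`, perturbed by multiplicative log-normal noise with sdlog
#' `dispersion` (mean-one, so the expectation is preserved). With
#' `dispersion = 0` the noiseless product is returned exactly, which is
#' what makes the deconvolution round-trip testable to machine precision.
#'
#' @param signature nonnegative genes x cell-types matrix.
#' @param fractions samples x cell-types matrix; rows sum to 1.
#' @param depth positive depth scaling.
#' @param dispersion nonnegative noise sdlog.
#' @param seed integer seed.
#' @return genes x samples matrix.
#' @export
simulateExpression <- function(signature, fractions, depth = 1,
                               dispersion = 0.2, seed = 1) {
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != ncol(signature))
    stop(sprintf("fractions have %d cell types but signature has %d",
                 ncol(fractions), ncol(signature)))
  if (any(abs(rowSums(fractions) - 1) > 1e-8))
    stop("fractions rows must sum to 1")
  if (any(signature < 0)) stop("signature must be nonnegative")
  mu <- depth * (signature %*% t(fractions))
  if (dispersion > 0) {
    noise <- .withSeed(seed, matrix(
      rlnorm(length(mu), meanlog = -dispersion^2 / 2, sdlog = dispersion),
      nrow = nrow(mu)))
    mu <- mu * noise
  }
  dimnames(mu) <- list(rownames(signature),
                       rownames(fractions) %||% paste0("S", seq_len(nrow(fractions))))
  mu
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate progression and survival outcomes
#'
#' Event times are exponential with rate `exp(intercept + coef * MonoLR)`,
#' so the log hazard is linear in baseline MonoLR; the intercept is chosen
#' so a patient at the reference MonoLR of 0.73 has the configured median
#' time-to-progression. Censoring is an independent exponential clock
#' calibrated so the expected censored fraction equals `censorRate`.
#' Elite patients have their event time resampled until it is at least 365
#' days (and any censoring deferred past day 365), matching the label's
#' definition of at least a year on treatment. Overall survival is derived
#' as progression time plus an independent exponential post-progression
#' time.
#'
#' @param patients data.frame with patient_id and true_group.
#' @param baselineMonolr named numeric vector, one value per patient.
#' @param coef log-hazard slope per unit MonoLR.
#' @param censorRate expected censored fraction in \[0, 1).
#' @param seed integer seed.
#' @param medianPfsDays median progression time at MonoLR 0.73.
#' @return data.frame: patient_id, endpoint ("PFS"/"OS"), time_days, event.
#' @export
simulateOutcomes <- function(patients, baselineMonolr, coef = 1.2,
                             censorRate = 0.15, seed = 1,
                             medianPfsDays = 75) {
  miss <- setdiff(patients$patient_id, names(baselineMonolr))
  if (length(miss))
    stop("missing baseline MonoLR for patient(s): ",
         paste(head(miss, 3), collapse = ", "))
  intercept <- log(log(2) / medianPfsDays) - coef * 0.73
  .withSeed(seed, {
    rows <- lapply(seq_len(nrow(patients)), function(i) {
      pid <- patients$patient_id[i]
      grp <- patients$true_group[i]
      lam <- exp(intercept + coef * baselineMonolr[[pid]])
      tEvent <- rexp(1, lam)
      if (identical(grp, "Elite")) {
        while (tEvent < 365) tEvent <- rexp(1, lam)
      }
      event <- 1L
      tObs <- tEvent
      if (censorRate > 0 && censorRate < 1) {
        lamC <- lam * censorRate / (1 - censorRate)
        tCens <- rexp(1, lamC)
        if (identical(grp, "Elite")) tCens <- 365 + tCens
        if (tCens < tEvent) { tObs <- tCens; event <- 0L }
      } else if (censorRate >= 1) {
        tObs <- runif(1, 0, tEvent); event <- 0L
      }
      tOs <- tEvent + rexp(1, 1 / 120)   # post-progression survival
      rbind(
        data.frame(patient_id = pid, endpoint = "PFS",
                   time_days = max(tObs, 0.5), event = event,
                   stringsAsFactors = FALSE),
        data.frame(patient_id = pid, endpoint = "OS",
                   time_days = max(if (event) tOs else tObs, 0.5),
                   event = event, stringsAsFactors = FALSE))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Draws the full bundle from one configuration: patient roster with true
#' response groups and tumor-data availability, log-normal blood draws per
#' protocol period with group- and period-specific target medians,
#' Dirichlet ground-truth cell-type fractions (myeloid-skewed in
#' Progressive patients, further skewed after SBRT at C3), expression
#' matrices mixed from [defaultSignature()], exponential survival with
#' log-hazard linear in baseline MonoLR, and IHC-style CD68/CD3/CD20
#' densities proportional to the true fractions. The same config and seed
#' reproduce the identical bundle.
#'
#' @param config a [cohortConfig()] object.
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "cohortConfig")) .validateConfig(config)
  n <- as.integer(config$nPatients)
  emptyBundle <- function() new("SyntheticCohort",
    patients = data.frame(patient_id = character(), true_group = character(),
                          has_tumor_data = logical(), enrollment_day = integer(),
                          stringsAsFactors = FALSE),
    blood = data.frame(patient_id = character(), day = integer(),
                       neutrophils = numeric(), lymphocytes = numeric(),
                       monocytes = numeric(), stringsAsFactors = FALSE),
    expression = list(),
    trueFractions = matrix(numeric(), 0, 0),
    survival = data.frame(patient_id = character(), endpoint = character(),
                          time_days = numeric(), event = integer(),
                          stringsAsFactors = FALSE),
    ihc = data.frame(sample_id = character(), patient_id = character(),
                     CD68 = numeric(), CD3 = numeric(), CD20 = numeric(),
                     stringsAsFactors = FALSE),
    config = unclass(config))
  if (n == 0L) return(emptyBundle())

  sig <- defaultSignature()
  types <- colnames(sig)

  .withSeed(config$seed, {
    nProg <- round(n * config$propProgressive)
    nElite <- round((n - nProg) * config$eliteFraction)
    nStable <- n - nProg - nElite
    groups <- sample(rep(.GROUPS, times = c(nProg, nStable, nElite)))
    ids <- sprintf("P%03d", seq_len(n))
    nTumor <- round(n * config$propTumorData)
    hasTumor <- rep(FALSE, n)
    hasTumor[sample(n, nTumor)] <- TRUE
    pts <- data.frame(patient_id = ids, true_group = groups,
                      has_tumor_data = hasTumor, enrollment_day = 0L,
                      stringsAsFactors = FALSE)

    ## ---- blood draws ----
    gm <- config$groupBloodMedians
    gRow <- ifelse(groups == "Progressive", "Progressive", "StableElite")
    blood <- do.call(rbind, lapply(seq_len(n), function(i) {
      g <- gRow[i]
      do.call(rbind, lapply(seq_len(nrow(.PERIODS)), function(p) {
        days <- sample(seq(.PERIODS$from[p], .PERIODS$to[p]),
                       config$drawsPerPeriod, replace = TRUE)
        lMed <- gm[g, "lymphocytes"] * config$lymphMultipliers[g, p]
        mMed <- gm[g, "monocytes"] * config$monoMultipliers[g, p]
        nMed <- gm[g, "neutrophils"]
        data.frame(patient_id = ids[i], day = as.integer(days),
                   neutrophils = rlnorm(length(days), log(nMed),
                                        config$noiseDispersion),
                   lymphocytes = rlnorm(length(days), log(lMed),
                                        config$noiseDispersion),
                   monocytes = rlnorm(length(days), log(mMed),
                                      config$noiseDispersion),
                   stringsAsFactors = FALSE)
      }))
    }))

    ## ---- ground-truth fractions + expression per biopsy timepoint ----
    tumorIds <- if (!isFALSE(config$withExpression)) ids[hasTumor]
                else character()
    fracList <- list(); exprList <- list(); ihcRows <- list()
    if (length(tumorIds)) {
      myl <- types %in% .MYELOID_TYPES
      for (tp in .TIMEPOINTS) {
        fr <- t(vapply(tumorIds, function(pid) {
          g <- gRow[match(pid, ids)]
          alpha <- rep(1, length(types))
          alpha[myl] <- if (g == "Progressive") 2.5 else 0.8
          if (tp == "C3" && g == "Progressive") alpha[myl] <- alpha[myl] * 1.5
          x <- rgamma(length(types), shape = alpha, rate = 1)
          x / sum(x)
        }, numeric(length(types))))
        colnames(fr) <- types
        rownames(fr) <- paste(tumorIds, tp, sep = "_")
        fracList[[tp]] <- fr
      }
    }
    fractions <- if (length(fracList)) do.call(rbind, fracList) else
      matrix(numeric(), 0, 0)
    if (length(tumorIds)) {
      for (k in seq_along(.TIMEPOINTS)) {
        tp <- .TIMEPOINTS[k]
        exprList[[tp]] <- simulateExpression(
          sig, fracList[[tp]], depth = config$exprDepth,
          dispersion = config$exprDispersion,
          seed = (config$seed + 1000L * k) %% .Machine$integer.max)
      }
      ## IHC densities proportional to fractions at baseline
      frB <- fracList[["baseline"]]
      ihcRows <- data.frame(
        sample_id = rownames(frB),
        patient_id = tumorIds,
        CD68 = pmax(0, 40 * rowSums(frB[, .MYELOID_TYPES, drop = FALSE]) *
                      rlnorm(nrow(frB), 0, 0.3)),
        CD3 = pmax(0, 120 * rowSums(frB[, c("T_CD4", "T_CD8"), drop = FALSE]) *
                     rlnorm(nrow(frB), 0, 0.3)),
        CD20 = pmax(0, 60 * frB[, "B_cells"] * rlnorm(nrow(frB), 0, 0.3)),
        stringsAsFactors = FALSE)
      rownames(ihcRows) <- NULL
    } else {
      ihcRows <- data.frame(sample_id = character(), patient_id = character(),
                            CD68 = numeric(), CD3 = numeric(),
                            CD20 = numeric(), stringsAsFactors = FALSE)
    }

    ## ---- survival from baseline MonoLR ----
    summ <- summarizePatientPeriods(blood)
    base <- summ[summ$period == "baseline", ]
    monolr <- setNames(base$monolr, base$patient_id)
    ## fall back to the group-typical value if a patient had no usable draw
    missing <- setdiff(ids, names(monolr))
    if (length(missing)) {
      fallback <- ifelse(gRow[match(missing, ids)] == "Progressive", 0.86, 0.53)
      monolr <- c(monolr, setNames(fallback, missing))
    }
    surv <- simulateOutcomes(pts, monolr, coef = config$monolrHazardCoef,
                             censorRate = config$censorRate,
                             seed = (config$seed + 77L) %% .Machine$integer.max,
                             medianPfsDays = config$medianPfsDays)

    new("SyntheticCohort", patients = pts, blood = blood,
        expression = exprList, trueFractions = fractions,
        survival = surv, ihc = ihcRows, config = unclass(config))
  })
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits patients.tsv, blood.tsv, survival.tsv, ihc.tsv, fractions.tsv and
#' one expression_<timepoint>.tsv per biopsy timepoint, plus manifest.json
#' recording the configuration (including the seed), so any stage can be
#' re-run from its persisted inputs.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) writeTsv(x, file.path(dir, f))
  wt(patients(cohort), "patients.tsv")
  wt(bloodDraws(cohort), "blood.tsv")
  wt(survivalRecords(cohort), "survival.tsv")
  wt(ihcDensities(cohort), "ihc.tsv")
  fr <- trueFractions(cohort)
  if (nrow(fr))
    wt(data.frame(sample_id = rownames(fr), fr, check.names = FALSE),
       "fractions.tsv")
  for (tp in names(expressionMatrices(cohort))) {
    m <- expressionMatrices(cohort)[[tp]]
    wt(data.frame(gene = rownames(m), m, check.names = FALSE),
       sprintf("expression_%s.tsv", tp))
  }
  cfg <- cohortConfigOf(cohort)
  cfg$groupBloodMedians <- as.data.frame(cfg$groupBloodMedians)
  cfg$lymphMultipliers <- as.data.frame(cfg$lymphMultipliers)
  cfg$monoMultipliers <- as.data.frame(cfg$monoMultipliers)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(cfg, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
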