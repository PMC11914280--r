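## Blood-count kinetics: protocol-period windowing, per-patient per-cycle
## medians, and the MonoLR / NLR ratios.

.PERIODS <- data.frame(
  period = c("baseline", "cycle1", "cycle2", "cycle3"),
  from = c(-7L, 1L, 22L, 43L),
  to = c(0L, 21L, 42L, 63L),
  stringsAsFactors = FALSE
)

#' Assign a blood-draw day to a treatment period
#'
#' Days are integer offsets from Cycle 1 Day 1. The protocol windows are
#' closed integer intervals: baseline \[-7, 0\], cycle1 \[1, 21\],
#' cycle2 \[22, 42\], cycle3 \[43, 63\]; days outside return `NA`.
#'
#' @param day integer vector of day offsets.
#' @return character vector of period labels, `NA` outside all windows.
#' @examples
#' assignPeriod(c(-7, 0, 1, 21, 22, 64))
#' @export
assignPeriod <- function(day) {
  if (!is.numeric(day) || any(!is.finite(day)) || any(day != round(day)))
    stop("`day` must be integer-valued")
  out <- rep(NA_character_, length(day))
  for (i in seq_len(nrow(.PERIODS)))
    out[day >= .PERIODS$from[i] & day <= .PERIODS$to[i]] <- .PERIODS$period[i]
  out
}

#' Monocyte/lymphocyte ratio (MonoLR)
#'
#' Absolute monocyte count divided by absolute lymphocyte count, both in
#' 1e9/L. The ratio is dimensionless and scale-invariant; a healthy
#' reference value is about 0.25. A zero lymphocyte count is rejected as a
#' data artifact rather than returned as infinity.
#'
#' @param monocytes,lymphocytes nonnegative absolute counts (1e9/L);
#'   vectorized.
#' @return monocytes / lymphocytes.
#' @examples
#' monoLymphRatio(0.5, 1.0)
#' @export
monoLymphRatio <- function(monocytes, lymphocytes) {
  .checkRatio(monocytes, lymphocytes, "monocytes")
  monocytes / lymphocytes
}

#' Neutrophil/lymphocyte ratio (NLR)
#'
#' As [monoLymphRatio()] with neutrophils in the numerator.
#'
#' @param neutrophils,lymphocytes nonnegative absolute counts (1e9/L).
#' @return neutrophils / lymphocytes.
#' @export
neutLymphRatio <- function(neutrophils, lymphocytes) {
  .checkRatio(neutrophils, lymphocytes, "neutrophils")
  neutrophils / lymphocytes
}

.checkRatio <- function(num, den, what) {
  if (any(num < 0) || any(den < 0))
    stop(sprintf("%s and lymphocytes must be nonnegative", what))
  if (any(den == 0))
    stop("lymphocyte count of 0: ratio undefined (data artifact?)")
  invisible(TRUE)
}

#' Per-patient, per-period median blood counts with MonoLR and NLR
#'
#' Windows draws into the protocol periods via [assignPeriod()] and takes,
#' per (patient, period) with at least one in-window draw, the median of
#' each absolute count. MonoLR and NLR are computed on the period medians
#' (median monocytes / median lymphocytes, etc.), matching the convention
#' of summarizing counts first and forming the ratio second. Draws outside
#' all windows contribute nothing; no row is emitted for empty windows.
#'
#' @param draws data.frame with columns patient_id, day, neutrophils,
#'   lymphocytes, monocytes.
#' @return data.frame: patient_id, period, n_draws, median_neutrophils,
#'   median_lymphocytes, median_monocytes, monolr, nlr. Ratios are `NA`
#'   when the median lymphocyte count is 0.
#' @export
summarizePatientPeriods <- function(draws) {
  need <- c("patient_id", "day", "neutrophils", "lymphocytes", "monocytes")
  miss <- setdiff(need, names(draws))
  if (length(miss)) stop("draws missing columns: ", paste(miss, collapse = ", "))
  bad <- draws$neutrophils < 0 | draws$lymphocytes < 0 | draws$monocytes < 0
  if (any(bad))
    stop(sprintf("negative count for patient %s at day %d",
                 draws$patient_id[which(bad)[1]], draws$day[which(bad)[1]]))
  draws$period <- assignPeriod(draws$day)
  draws <- draws[!is.na(draws$period), , drop = FALSE]
  if (!nrow(draws)) {
    return(data.frame(patient_id = character(), period = character(),
                      n_draws = integer(), median_neutrophils = numeric(),
                      median_lymphocytes = numeric(),
                      median_monocytes = numeric(),
                      monolr = numeric(), nlr = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(draws$patient_id, draws$period, drop = TRUE)
  pieces <- lapply(split(draws, key), function(d) {
    ml <- median(d$lymphocytes)
    mm <- median(d$monocytes)
    mn <- median(d$neutrophils)
    data.frame(patient_id = d$patient_id[1], period = d$period[1],
               n_draws = nrow(d),
               median_neutrophils = mn, median_lymphocytes = ml,
               median_monocytes = mm,
               monolr = if (ml > 0) mm / ml else NA_real_,
               nlr = if (ml > 0) mn / ml else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$patient_id,
                   match(out$period, .PERIODS$period)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test, the package's default nonparametric
#' two-group comparison. Returns the maximum ECDF gap D and the asymptotic
#' two-sided p-value.
#'
#' @param valuesA,valuesB nonempty numeric vectors.
#' @return list with `statistic` (D), `p_value`.
#' @export
groupCompareKS <- function(valuesA, valuesB) {
  if (!length(valuesA) || !length(valuesB))
    stop("both samples must be nonempty")
  kt <- suppressWarnings(ks.test(valuesA, valuesB, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
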