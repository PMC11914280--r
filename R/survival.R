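## Survival and trial-design statistics: response classification,
## Kaplan-Meier with Greenwood variance, median and landmark rates with
## Wilson intervals, logrank / O-E hazard ratios, exact binomial tails,
## the Fleming single-stage design, and the linear-quadratic BED.

#' Classify treatment response
#'
#' Three-level response label: "Progressive" when progression is confirmed
#' within the first 12 weeks (progression day <= 84, boundary inclusive
#' toward the worse category); "Elite" when the patient stays on treatment
#' for at least one year (>= 365 days) with disease control (best response
#' SD or PR); "Stable" otherwise, when disease is controlled for at least
#' 12 weeks.
#'
#' @param progressionDay day of confirmed progression, or NA if none.
#' @param treatmentDurationDays days on treatment (>= 0).
#' @param bestResponse one of "PD", "SD", "PR", "CR".
#' @return "Progressive", "Stable" or "Elite".
#' @export
classifyResponse <- function(progressionDay, treatmentDurationDays,
                             bestResponse = "SD") {
  if (!is.na(progressionDay) && progressionDay < 0)
    stop("progression before day 0 is inconsistent")
  if (treatmentDurationDays < 0) stop("negative treatment duration")
  if (!is.na(progressionDay) && progressionDay <= 84) return("Progressive")
  if (treatmentDurationDays >= 365 && bestResponse %in% c("SD", "PR", "CR"))
    return("Elite")
  "Stable"
}

#' Kaplan-Meier survival curve with Greenwood variance
#'
#' Product-limit estimate of S(t) from right-censored records; censored
#' times shrink the risk set without introducing steps. The Greenwood
#' variance S(t)^2 * sum(d / (n (n - d))) is reported at every event time.
#'
#' @param records data.frame with columns time_days (> 0) and event (0/1).
#' @return list of class "kmCurve": data.frame `curve` (time, n_risk,
#'   n_event, n_censor, survival, var) over distinct event times, plus
#'   `n` and the fitted [survival::survfit] object in `fit`.
#' @export
kmCurve <- function(records) {
  if (!nrow(records)) stop("need at least one record")
  if (any(records$time_days <= 0)) stop("nonpositive survival time")
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ 1,
    data = records, conf.type = "log-log")
  s <- summary(fit, censored = FALSE)
  d <- s$n.event; nr <- s$n.risk
  gw <- s$surv^2 * cumsum(ifelse(nr > d, d / (nr * (nr - d)), 0))
  curve <- data.frame(time = s$time, n_risk = nr, n_event = d,
                      n_censor = s$n.censor, survival = s$surv, var = gw)
  structure(list(curve = curve, n = nrow(records), fit = fit),
            class = "kmCurve")
}

#' Evaluate a KM curve at a time point
#'
#' Step-function value of S(t): 1 before the first event, the last
#' estimate at or before `t` otherwise.
#'
#' @param km a [kmCurve()] result.
#' @param t time (same units as the records).
#' @return S(t).
#' @export
kmSurvivalAt <- function(km, t) {
  cv <- km$curve
  idx <- which(cv$time <= t)
  if (!length(idx)) 1 else cv$survival[max(idx)]
}

#' Median survival with 95\% confidence interval
#'
#' Smallest time with S(t) <= 0.5; the interval comes from the log-log
#' transformed (Brookmeyer-Crowley-style) survival bounds. When S stays
#' above 0.5 throughout follow-up the median is not reached (`NA`).
#'
#' @param km a [kmCurve()] result.
#' @return list with `median`, `lower`, `upper` (NA = not reached).
#' @export
medianSurvival <- function(km) {
  cv <- km$curve
  hit <- which(cv$survival <= 0.5)
  med <- if (length(hit)) cv$time[min(hit)] else NA_real_
  q <- quantile(km$fit, probs = 0.5)
  list(median = med, lower = unname(q$lower), upper = unname(q$upper))
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n counts with 0 <= successes <= n, n > 0.
#' @param level confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper` (proportions).
#' @export
wilsonInterval <- function(successes, n, level = 0.95) {
  if (n <= 0 || successes < 0 || successes > n)
    stop("need 0 <= successes <= n with n > 0")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(estimate = p, lower = max(0, centre - hw), upper = min(1, centre + hw))
}

#' Landmark survival rate with Wilson interval
#'
#' S(t) at a landmark time with a Wilson score interval computed from the
#' effective success count (S(t) x n, which equals the crude
#' progression-free count when no censoring precedes the landmark). The
#' crude mode takes the observed counts directly. A landmark beyond the
#' last follow-up time is flagged as extrapolation.
#'
#' @param km a [kmCurve()] result.
#' @param tLandmark landmark time (> 0), e.g. 365 for one year.
#' @param level confidence level.
#' @return list with `rate`, `lower`, `upper`, `successes`, `n`,
#'   `extrapolated`.
#' @export
landmarkRate <- function(km, tLandmark, level = 0.95) {
  if (tLandmark <= 0) stop("landmark must be positive")
  s <- kmSurvivalAt(km, tLandmark)
  extrap <- tLandmark > max(km$fit$time)
  eff <- round(s * km$n)
  wi <- wilsonInterval(eff, km$n, level)
  list(rate = s, lower = wi$lower, upper = wi$upper,
       successes = eff, n = km$n, extrapolated = extrap)
}

#' Two-group logrank test with observed/expected table
#'
#' Standard two-group logrank: per event time a 2 x 2 hypergeometric
#' contribution to observed-minus-expected, summed into a 1-df chi-square
#' statistic. Observed and expected event counts per group are returned
#' for downstream hazard-ratio estimation.
#'
#' @param groupA,groupB data.frames with time_days and event columns.
#' @return list with `chisq`, `p_value`, `observed` (length 2),
#'   `expected` (length 2), group order (A, B).
#' @export
logrankTest <- function(groupA, groupB) {
  if (!nrow(groupA) || !nrow(groupB)) stop("both groups must be nonempty")
  dat <- rbind(
    data.frame(time_days = groupA$time_days, event = groupA$event, g = "A"),
    data.frame(time_days = groupB$time_days, event = groupB$event, g = "B"))
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ g, data = dat)
  p <- 1 - stats::pchisq(sd$chisq, df = 1)
  list(chisq = unname(sd$chisq), p_value = p,
       observed = as.numeric(sd$obs), expected = as.numeric(sd$exp))
}

#' Hazard ratio from logrank observed/expected counts
#'
#' Pike estimator HR = (O1/E1) / (O2/E2) with a log-scale interval using
#' SE(log HR) = sqrt(1/E1 + 1/E2). The orientation (which group is the
#' numerator) is explicit and echoed in the output; swapping it inverts
#' the ratio exactly.
#'
#' @param lr a [logrankTest()] result.
#' @param numerator 1 or 2: which group goes on top (default 1 = group A).
#' @param level confidence level.
#' @return list with `hr`, `lower`, `upper`, `numerator`.
#' @export
hazardRatioOE <- function(lr, numerator = 1, level = 0.95) {
  o <- lr$observed; e <- lr$expected
  if (any(e == 0)) stop("zero expected events: HR undefined")
  i <- numerator; j <- 3 - numerator
  hr <- (o[i] / e[i]) / (o[j] / e[j])
  se <- sqrt(1 / e[1] + 1 / e[2])
  z <- qnorm(1 - (1 - level) / 2)
  list(hr = hr, lower = exp(log(hr) - z * se), upper = exp(log(hr) + z * se),
       numerator = numerator)
}

#' Exact binomial upper-tail probability
#'
#' P(X >= r) for X ~ Binomial(n, p), by direct summation of log-space
#' terms (numerically stable at large n, no underflow).
#'
#' @param n trials, r threshold (0 <= r <= n), p success probability.
#' @return probability.
#' @export
binomialTail <- function(n, r, p) {
  if (r < 0 || r > n || p < 0 || p > 1 || n < 0) stop("invalid arguments")
  if (r == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  k <- r:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

#' Fleming single-stage phase II design
#'
#' Finds the smallest evaluable sample size n, with its success threshold
#' r, such that the exact binomial one-sided type-I error
#' P(X >= r | p0) <= alpha and the power P(X >= r | p1) >= power. For each
#' n, r is the smallest count meeting the alpha constraint; achieved
#' operating characteristics are reported alongside the design, since
#' printed designs in the literature sometimes rest on approximations
#' whose nominal alpha an exact calculation does not reproduce.
#'
#' @param p0 null (uninteresting) response rate.
#' @param p1 alternative rate, p0 < p1.
#' @param alpha one-sided type-I level.
#' @param power required power at p1.
#' @param nMax search cap (default 500).
#' @return list with `n`, `r`, `achieved_alpha`, `achieved_power`, and the
#'   inputs.
#' @export
flemingSingleStage <- function(p0, p1, alpha, power, nMax = 500) {
  if (!(p0 > 0 && p1 < 1 && p0 < p1)) stop("need 0 < p0 < p1 < 1")
  if (alpha <= 0 || alpha > 1 || power <= 0 || power > 1)
    stop("alpha and power must lie in (0, 1]")
  for (n in 1:nMax) {
    ## smallest r with P(X >= r | p0) <= alpha
    tails0 <- vapply(0:n, function(r) binomialTail(n, r, p0), numeric(1))
    rOk <- which(tails0 <= alpha)
    if (!length(rOk)) next
    r <- rOk[1] - 1L  # back to r scale (which() is 1-based over 0:n)
    pw <- binomialTail(n, r, p1)
    if (pw >= power) {
      return(list(n = n, r = as.integer(r),
                  achieved_alpha = binomialTail(n, r, p0),
                  achieved_power = pw,
                  p0 = p0, p1 = p1, alpha = alpha, power = power))
    }
  }
  stop(sprintf("no feasible design with n <= %d", nMax))
}

#' Biologically effective dose (linear-quadratic model)
#'
#' BED = n * d * (1 + d / (alpha/beta)) for n fractions of d Gy each; a
#' 45 Gy in 3 x 15 Gy regimen at alpha/beta = 10 gives 112.5 Gy, above
#' the 100 Gy ablative-dose benchmark.
#'
#' @param nFractions number of fractions (> 0).
#' @param dosePerFraction dose per fraction, Gy (> 0).
#' @param alphaBeta tissue alpha/beta ratio, Gy (> 0).
#' @return BED in Gy.
#' @export
bedLQ <- function(nFractions, dosePerFraction, alphaBeta = 10) {
  if (nFractions <= 0 || dosePerFraction < 0) stop("invalid regimen")
  if (alphaBeta <= 0) stop("alpha/beta must be positive")
  nFractions * dosePerFraction * (1 + dosePerFraction / alphaBeta)
}
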