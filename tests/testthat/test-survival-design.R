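test_that("response classification uses the 84-day and 365-day boundaries", {
  expect_equal(classifyResponse(70, 70, "PD"), "Progressive")
  expect_equal(classifyResponse(84, 84, "PD"), "Progressive")  # boundary
  expect_equal(classifyResponse(85, 200, "SD"), "Stable")
  expect_equal(classifyResponse(NA, 400, "SD"), "Elite")
  expect_equal(classifyResponse(NA, 400, "PR"), "Elite")
  expect_equal(classifyResponse(NA, 200, "SD"), "Stable")
  expect_error(classifyResponse(-1, 10), "inconsistent")
})

test_that("KM estimate matches closed forms on toy and exponential data", {
  four <- data.frame(time_days = 1:4, event = 1L)
  km <- kmCurve(four)
  expect_equal(km$curve$survival, c(0.75, 0.50, 0.25, 0))
  expect_equal(medianSurvival(km)$median, 2)
  # Greenwood variance at the first event: S^2 * d/(n(n-d)) = .75^2/12
  expect_equal(km$curve$var[1], 0.75^2 * (1 / (4 * 3)))
  # all censored: S stays at 1, median not reached
  cens <- data.frame(time_days = 1:4, event = 0L)
  kmC <- kmCurve(cens)
  expect_true(all(kmC$curve$survival == 1) || nrow(kmC$curve) == 0)
  expect_equal(kmSurvivalAt(kmC, 10), 1)
  expect_true(is.na(medianSurvival(kmC)$median))
  expect_error(kmCurve(data.frame(time_days = 0, event = 1)), "nonpositive")
  # no censoring: KM equals the empirical survival function
  set.seed(8)
  t <- rexp(200, 0.02)
  kmE <- kmCurve(data.frame(time_days = t, event = 1L))
  for (q in c(10, 50, 100))
    expect_equal(kmSurvivalAt(kmE, q), mean(t > q))
})

test_that("landmark rate reproduces the one-year arithmetic with Wilson CI", {
  # 5 of 60 progression-free at one year, no earlier censoring
  rec <- data.frame(time_days = c(rep(200, 55), rep(400, 5)),
                    event = c(rep(1L, 55), rep(0L, 5)))
  km <- kmCurve(rec)
  lr <- landmarkRate(km, 365)
  expect_equal(round(100 * lr$rate, 1), 8.3)
  expect_equal(round(100 * lr$lower, 1), 3.6)
  expect_equal(round(100 * lr$upper, 1), 18.1)
  expect_equal(lr$successes, 5)
  expect_false(lr$extrapolated)
  expect_error(landmarkRate(km, -1), "positive")
})

test_that("Wilson interval endpoints behave at the boundaries", {
  wi <- wilsonInterval(5, 60)
  expect_equal(round(100 * wi$lower, 1), 3.6)
  expect_equal(round(100 * wi$upper, 1), 18.1)
  expect_equal(wilsonInterval(0, 10)$lower, 0)
  expect_equal(wilsonInterval(10, 10)$upper, 1)
  expect_error(wilsonInterval(5, 0), "n > 0")
})

test_that("logrank equals the per-event-time hypergeometric tabulation", {
  a <- data.frame(time_days = c(2, 4, 6), event = 1L)
  b <- data.frame(time_days = c(1, 3, 5), event = c(1L, 0L, 1L))
  out <- logrankTest(a, b)
  # brute-force O-E and variance over distinct event times
  all <- rbind(cbind(a, g = 0), cbind(b, g = 1))
  ev <- sort(unique(all$time_days[all$event == 1]))
  oe <- 0; v <- 0
  for (t in ev) {
    atRisk <- all$time_days >= t
    n <- sum(atRisk); n1 <- sum(atRisk & all$g == 0)
    d <- sum(all$time_days == t & all$event == 1)
    d1 <- sum(all$time_days == t & all$event == 1 & all$g == 0)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(out$chisq, oe^2 / v)
  expect_equal(out$observed[1], sum(a$event))
  # identical groups: statistic 0, p 1
  same <- data.frame(time_days = c(1, 2, 3), event = 1L)
  ident <- logrankTest(same, same)
  expect_equal(ident$chisq, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1, tolerance = 1e-8)
  expect_error(logrankTest(same, same[0, ]), "nonempty")
})

test_that("hazard ratio inverts under group swap and is 1 for identical groups", {
  set.seed(14)
  a <- data.frame(time_days = rexp(80, 0.02), event = 1L)
  b <- data.frame(time_days = rexp(80, 0.04), event = 1L)
  lr <- logrankTest(a, b)
  h1 <- hazardRatioOE(lr, numerator = 1)
  h2 <- hazardRatioOE(lr, numerator = 2)
  expect_equal(h1$hr, 1 / h2$hr)
  expect_equal(h1$lower, 1 / h2$upper)
  same <- data.frame(time_days = c(1, 2, 3, 4), event = 1L)
  lrS <- logrankTest(same, same)
  expect_equal(hazardRatioOE(lrS)$hr, 1)
})

test_that("exact binomial tail is stable, monotone, and correct", {
  expect_equal(binomialTail(10, 0, 0.3), 1)
  expect_equal(binomialTail(10, 3, 0), 0)
  expect_equal(binomialTail(10, 10, 1), 1)
  # against the complementary CDF (independent implementation in stats)
  for (n in c(5, 54, 200))
    for (r in c(1, floor(n / 3)))
      expect_equal(binomialTail(n, r, 0.32),
                   pbinom(r - 1, n, 0.32, lower.tail = FALSE))
  # monotone nondecreasing in p, nonincreasing in r
  ps <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(ps, function(p)
    binomialTail(30, 10, p), numeric(1))) >= 0))
  rs <- 0:30
  expect_true(all(diff(vapply(rs, function(r)
    binomialTail(30, r, 0.4), numeric(1))) <= 0))
  # no underflow at large n
  expect_gt(binomialTail(5000, 100, 0.05), 0)
  expect_error(binomialTail(10, 11, 0.5), "invalid")
})

test_that("Fleming design satisfies its constraints and matches brute force", {
  des <- flemingSingleStage(0.05, 0.50, 0.05, 0.90)
  # re-evaluate the two exact-binomial constraints
  expect_lte(des$achieved_alpha, 0.05)
  expect_gte(des$achieved_power, 0.90)
  # brute-force oracle: smallest feasible n over an exhaustive (n, r) grid
  feasible <- function(n) {
    for (r in 0:n) {
      if (binomialTail(n, r, 0.05) <= 0.05 &&
          binomialTail(n, r, 0.50) >= 0.90) return(r)
    }
    NA
  }
  nStar <- NA
  for (n in 1:100) if (!is.na(feasible(n))) { nStar <- n; break }
  expect_equal(des$n, nStar)
  expect_equal(des$r, feasible(nStar))
  # degenerate corner
  deg <- flemingSingleStage(0.05, 0.5, alpha = 1, power = 1e-9)
  expect_equal(deg$n, 1)
  expect_equal(deg$r, 0L)
  expect_error(flemingSingleStage(0.5, 0.4, 0.05, 0.9), "p0 < p1")
})

test_that("linear-quadratic BED matches the ablative-regimen arithmetic", {
  expect_equal(bedLQ(3, 15, 10), 112.5)
  expect_gt(bedLQ(3, 15, 10), 100)
  # d -> 0 limit: BED approaches total dose
  expect_equal(bedLQ(45, 1e-9, 10), 45 * 1e-9 * (1 + 1e-10), tolerance = 1e-6)
  # halving alpha/beta increases BED
  expect_gt(bedLQ(3, 15, 5), bedLQ(3, 15, 10))
  expect_error(bedLQ(3, 15, 0), "positive")
})

test_that("median survival CI comes from log-log bounds and covers truth", {
  set.seed(9)
  rec <- data.frame(time_days = rexp(500, log(2) / 100), event = 1L)
  ms <- medianSurvival(kmCurve(rec))
  expect_true(ms$lower < ms$median && ms$median < ms$upper)
  expect_lt(abs(ms$median - 100) / 100, 0.15)
})
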