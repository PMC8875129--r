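test_that("exactly linear standards are fit to machine precision", {
  # low-range gastrodin curve: y = 0.2159 x + 0.0002
  grid <- c(0.1, 0.25, 0.5, 1, 2.5, 5)
  std <- generate_standards(nominal_concs = grid, slope = 0.2159,
                            intercept = 0.0002)
  cv <- fit_calibration(std)
  expect_equal(cv$segments$slope, 0.2159, tolerance = 1e-10)
  expect_equal(cv$segments$intercept, 0.0002, tolerance = 1e-10)
  expect_gte(cv$segments$r, 0.9999)
  expect_equal(cv$lloq, 0.1)
  # fit-then-evaluate reproduces the inputs
  bc <- back_calculate(cv, std$signal)
  expect_equal(bc$conc, grid, tolerance = 1e-9)
})

test_that("segmented fits keep the boundary standard in both segments", {
  std <- generate_standards(slope = 1.8823, intercept = 0.07998)
  cv <- fit_calibration(std, split_at = 2.5)
  expect_equal(nrow(cv$segments), 2L)
  expect_equal(cv$segments$n, c(7L, 8L))  # 2.5 counted in both
  expect_equal(cv$lloq, 0.025)
})

test_that("fit refuses degenerate standards and warns on poor linearity", {
  expect_error(
    fit_calibration(data.frame(nominal_conc = c(1, 2), signal = c(1, 2))),
    "at least 3")
  expect_error(
    fit_calibration(data.frame(nominal_conc = rep(2, 4), signal = 1:4)),
    "variance")
  set.seed(1)
  noisy <- data.frame(nominal_conc = 1:6, signal = 1:6 + rnorm(6, sd = 2))
  expect_warning(fit_calibration(noisy), "r <")
})

test_that("slope estimates are within 3 standard errors of truth under gaussian noise", {
  grid <- c(0.025, 0.05, 0.1, 0.25, 0.5, 1, 2.5)
  truth_slope <- 1.8823
  sigma <- 0.05
  # exact sampling standard error of an OLS slope under iid N(0, sigma)
  se_true <- sigma / sqrt(sum((grid - mean(grid))^2))
  set.seed(20260925)
  hits <- 0L
  for (i in 1:1000) {
    std <- data.frame(nominal_conc = grid,
                      signal = truth_slope * grid + 0.07998 +
                        rnorm(length(grid), sd = sigma))
    cv <- suppressWarnings(fit_calibration(std))
    if (abs(cv$segments$slope - truth_slope) <= 3 * se_true) hits <- hits + 1L
  }
  expect_gte(hits, 990L)
})

test_that("back-calculation inverts the calibration lines", {
  std <- generate_standards(slope = 1.8823, intercept = 0.07998)
  cv <- fit_calibration(std, split_at = 2.5)
  # inverse of the low-range puerarin line at signal 1.96228
  bc <- back_calculate(cv, 1.96228)
  expect_equal(bc$conc, 1.000, tolerance = 1e-6)
  expect_equal(bc$flag, "ok")
  # signal equal to the intercept maps to zero, below the LLOQ
  bc0 <- back_calculate(cv, 0.07998)
  expect_equal(bc0$conc, 0, tolerance = 1e-12)
  expect_equal(bc0$flag, "below_lloq")
  # a signal mapping below zero concentration is non-quantifiable
  bneg <- back_calculate(cv, -0.5)
  expect_true(is.na(bneg$conc))
  expect_equal(bneg$flag, "non_quantifiable")
})

test_that("concentration -> signal -> concentration round-trips inside each segment", {
  # truth lines continuous at the 2.5 boundary, so the shared standard is
  # consistent with both segments
  segs <- data.frame(lo = c(0.025, 2.5), hi = c(2.5, 100),
                     slope = c(1.8823, 1.8758),
                     intercept = c(0.07998, 0.07998 + (1.8823 - 1.8758) * 2.5))
  std <- generate_standards(segments = segs)
  cv <- fit_calibration(std, split_at = 2.5)
  set.seed(42)
  for (conc in c(runif(25, 0.025, 2.5), runif(25, 2.5, 100))) {
    seg <- if (conc <= 2.5) 1 else 2
    signal <- segs$slope[seg] * conc + segs$intercept[seg]
    expect_equal(back_calculate(cv, signal)$conc, conc,
                 tolerance = 1e-9)
  }
})

test_that("every finite signal is assigned to exactly one segment or flagged", {
  std <- generate_standards(slope = 1.8823, intercept = 0.07998)
  cv <- fit_calibration(std, split_at = 2.5)
  set.seed(3)
  sig <- c(runif(200, -1, 250), cv$segments$intercept)
  bc <- suppressWarnings(back_calculate(cv, sig))
  expect_equal(nrow(bc), length(sig))
  expect_true(all(bc$flag %in% c("ok", "below_lloq", "non_quantifiable")))
  expect_true(all(is.na(bc$conc) == (bc$flag == "non_quantifiable")))
  expect_true(all(bc$conc[bc$flag == "ok"] >= cv$lloq))
})

test_that("qc_stats computes precision and recovery as defined", {
  # perfect measurements
  perfect <- qc_stats(data.frame(nominal = 5, measured = rep(5, 6)))
  expect_equal(perfect$recovery, 100)
  expect_equal(perfect$intra_day_rsd, 0)
  # constant positive bias: recovery only (matches a reported low-level
  # puerarin recovery of 104.44%)
  biased <- qc_stats(data.frame(nominal = 0.1,
                                measured = rep(0.1 * 1.0444, 6)))
  expect_equal(biased$recovery, 104.44, tolerance = 1e-9)
  expect_equal(biased$intra_day_rsd, 0, tolerance = 1e-6)
  # hand computation: {9, 10, 11} vs nominal 10 -> mean 10, sd 1
  hand <- qc_stats(data.frame(nominal = 10, measured = c(9, 10, 11)))
  expect_equal(hand$recovery, 100)
  expect_equal(hand$intra_day_rsd, 10, tolerance = 1e-12)
  expect_true(is.na(hand$inter_day_rsd))  # single day
})

test_that("qc_stats handles days and is scale invariant", {
  qc <- data.frame(nominal = 5,
                   measured = c(4.8, 5.2, 4.9, 5.3, 5.0, 5.2),
                   day = rep(1:3, each = 2))
  r1 <- qc_stats(qc)
  # inter-day RSD from the daily means, by hand
  dm <- tapply(qc$measured, qc$day, mean)
  expect_equal(r1$inter_day_rsd, 100 * sd(dm) / mean(dm), tolerance = 1e-12)
  # scaling measurements and nominal together changes nothing
  qc2 <- transform(qc, nominal = nominal * 7.3, measured = measured * 7.3)
  r2 <- qc_stats(qc2)
  expect_equal(r2$recovery, r1$recovery, tolerance = 1e-12)
  expect_equal(r2$intra_day_rsd, r1$intra_day_rsd, tolerance = 1e-12)
  expect_equal(r2$inter_day_rsd, r1$inter_day_rsd, tolerance = 1e-12)
  # a single replicate has no defined RSD
  single <- qc_stats(data.frame(nominal = 5, measured = 5.1))
  expect_true(is.na(single$intra_day_rsd))
})
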