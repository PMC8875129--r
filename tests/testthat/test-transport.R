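test_that("TEER is resistance difference times area, negatives flagged not censored", {
  expect_equal(teer(500, 120, 1.12), 425.6)
  expect_equal(teer(300, 300), 0)
  expect_error(teer(Inf, 0, 1.12), "finite")
  res <- data.frame(well_id = c("a", "b", "c"),
                    r1_ohm = c(500, 300, 100), r0_ohm = c(120, 100, 150),
                    area_cm2 = 1.12)
  at <- assess_teer(res, threshold = 300)
  expect_equal(at$teer_ohm_cm2, c(425.6, 224.0, -56.0))
  expect_equal(at$integrity_ok, c(TRUE, FALSE, FALSE))
})

test_that("cumulative amounts apply the sampling-dilution correction", {
  # single sample reduces to Cn * VR
  expect_equal(cumulative_amounts(2, vr = 1.5, vs = 0.2), 3.0)
  # hand mass balance: mass in receiver plus mass removed in prior samples
  expect_equal(cumulative_amounts(c(1, 2), vr = 1.5, vs = 0.2),
               c(1.5, 2 * 1.5 + 0.2 * 1))
  # without withdrawal the correction vanishes
  concs <- c(0.3, 0.9, 1.7, 2.2)
  expect_equal(cumulative_amounts(concs, vr = 1.5, vs = 0), concs * 1.5)
  # a gap poisons itself and everything after it
  dq <- cumulative_amounts(c(1, NA, 3), vr = 1.5, vs = 0.2)
  expect_equal(is.na(dq), c(FALSE, TRUE, TRUE))
  expect_error(cumulative_amounts(c(1, 2), vr = 1, vs = 1), "smaller")
})

test_that("corrected amounts equal event-by-event bookkeeping on random sequences", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    concs <- runif(n, 0, 20)
    vr <- runif(1, 0.5, 2)
    vs <- runif(1, 0.05, vr / 3)
    expect_equal(cumulative_amounts(concs, vr, vs),
                 bookkeeping_dq(concs, vr, vs), tolerance = 1e-13)
  }
})

test_that("corrected amounts recover the simulator's true transported mass", {
  sch <- default_schedule()
  for (dir in DIRECTIONS) {
    w <- simulate_well(efflux_params(), sch, dir, c0 = 100)
    dq <- cumulative_amounts(w$concs, vr = w$vr, vs = w$vs)
    expect_lt(max(abs(dq - w$truth$cum_mass_true) / w$truth$cum_mass_true),
              1e-9)
  }
})

test_that("transport rate is the least-squares slope against time in seconds", {
  # 1 ug per 60-minute step = 1/3600 ug/s
  fit <- transport_rate(c(1, 2, 3), times = c(60, 120, 180))
  expect_equal(fit$rate, 1 / 3600, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(transport_rate(rep(2.5, 4), times = c(30, 60, 90, 120))$rate,
               0, tolerance = 1e-15)
  # fit window restricts the regression
  dq <- c(1, 2, 3, 3.2, 3.3)
  tt <- c(30, 60, 90, 120, 150)
  early <- transport_rate(dq, tt, window = c(0, 90))
  expect_equal(early$n, 3L)
  expect_equal(early$rate, 1 / 1800, tolerance = 1e-12)
  expect_lt(transport_rate(dq, tt)$rate, early$rate)
  expect_error(transport_rate(1, 30), "2 points")
})

test_that("papp normalises rate by area and donor concentration", {
  expect_equal(papp(0.001, area = 1.12, c0 = 100), 0.001 / 112,
               tolerance = 1e-12)
  expect_equal(papp(0, 1.12, 100), 0)
  # homogeneity: doubling c0 at fixed rate halves Papp
  expect_equal(papp(0.001, 1.12, 200), papp(0.001, 1.12, 100) / 2)
})

test_that("efflux ratio matches the reported group ratios and is scale invariant", {
  expect_equal(round(efflux_ratio(1.766, 1.225), 3), 1.442)
  expect_equal(round(efflux_ratio(2.866, 2.407), 3), 1.191)
  expect_equal(efflux_ratio(3.2, 3.2), 1)
  k <- 1e-6  # same ratio whether Papp is in cm/s or 1e-6 cm/s
  expect_equal(efflux_ratio(2.866 * k, 2.407 * k),
               efflux_ratio(2.866, 2.407), tolerance = 1e-12)
  expect_error(efflux_ratio(1, 0), "positive")
  expect_true(is.na(efflux_ratio(NA_real_, 2.4)))
})

test_that("the 1.5 rule classifies by strict inequality", {
  expect_equal(classify_mechanism(1.442), "passive-consistent")
  expect_equal(classify_mechanism(3.531), "active-transport-likely")
  expect_equal(classify_mechanism(1.5), "passive-consistent")
  expect_equal(classify_mechanism(NA_real_), "undetermined")
  expect_error(classify_mechanism(-2), "positive")
})

test_that("noiseless passive sink simulations recover the permeability through the full pipeline", {
  sch <- default_schedule()
  w <- simulate_well(passive_params(p = 1e-6), sch, "AP_to_BL", c0 = 100)
  # sink regime: receiver stays well below 10% of donor
  expect_lt(max(w$truth$conc_true), 0.1 * 100)
  expect_lt(abs(well_papp(w) - 1e-6) / 1e-6, 0.02)
  # restricting to the early window shrinks the depletion bias further
  expect_lt(abs(well_papp(w, window = c(0, 90)) - 1e-6) / 1e-6, 0.011)
})

test_that("group summaries aggregate wells and classify the ratio of means", {
  wr <- data.frame(
    well_id = c("a", "b"), condition = "X", compound = "drug",
    direction = c("AP_to_BL", "BL_to_AP"),
    papp_cm_per_s = c(2.0e-6, 3.0e-6))
  sg <- summarize_groups(wr)
  expect_equal(sg$papp_ab_mean, 2.0e-6)
  expect_equal(sg$papp_ba_mean, 3.0e-6)
  expect_equal(sg$er, 1.5)
  expect_equal(sg$classification, "passive-consistent")  # strict > 1.5
  # identical wells have zero spread
  wr2 <- data.frame(well_id = letters[1:4], condition = "Y",
                    compound = "drug",
                    direction = rep(DIRECTIONS, each = 2),
                    papp_cm_per_s = rep(2e-6, 4))
  sg2 <- summarize_groups(wr2)
  expect_equal(sg2$papp_ab_sd, 0)
  expect_equal(sg2$er_well_sd, 0)
  # a missing secretory arm yields an undefined, never imputed, ER
  wr3 <- data.frame(well_id = "a", condition = "Z", compound = "drug",
                    direction = "AP_to_BL", papp_cm_per_s = 2e-6)
  sg3 <- summarize_groups(wr3)
  expect_true(is.na(sg3$er))
  expect_equal(sg3$classification, "undetermined")
  # no absorptive wells at all: summary undefined
  wr4 <- transform(wr3, direction = "BL_to_AP")
  expect_error(summarize_groups(wr4), "AP_to_BL")
})

test_that("passive simulations with measurement noise stay near unit efflux ratio", {
  p <- passive_params(noise_cv = 0.05)
  hits <- 0L
  for (s in 1:50) {
    sg <- condition_summary(p, c0 = 50, n_wells = 6, seed = 3000 + s)
    if (sg$er >= 0.85 && sg$er <= 1.15) hits <- hits + 1L
  }
  expect_gte(hits, 48L)  # >= 95% of runs
})
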