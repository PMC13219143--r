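params <- exposure_parameters()
soil_cell <- mc_cell("soil", 557.2, baf = 47.80, treatment = "HNB")
veg_cell <- mc_cell("vegetable", 8.48, crop = "lettuce", treatment = "HNB")

test_that("degenerate ranges reproduce the deterministic chain bitwise", {
  det_soil <- thq(adi_soil(557.2, 47.80, params), params)
  ranges <- list(
    parameter_range("concentration", 557.2, 557.2),
    parameter_range("BAF", 47.80, 47.80),
    parameter_range("EF", 365, 365),
    parameter_range("IR", 50, 50),
    parameter_range("BW", 70, 70)
  )
  r <- run_monte_carlo(soil_cell, ranges, iterations = 500, seed = 1)
  expect_identical(r$draws$thq, rep(det_soil, 500))

  det_veg <- thq(adi_veg(8.48, "lettuce", params), params)
  rv <- run_monte_carlo(veg_cell, list(), iterations = 200, seed = 1)
  expect_identical(rv$draws$thq, rep(det_veg, 200))
})

test_that("single uniform parameter: empirical mean matches the midpoint value", {
  # THQ is linear in IR, so E[THQ] equals THQ at IR = (a+b)/2 exactly
  r <- run_monte_carlo(soil_cell, list(parameter_range("IR", 10, 100)),
                       iterations = 10000, seed = 5)
  mid <- thq(adi_soil(557.2, 47.80,
                      exposure_parameters(IR_soil = 55)), params)
  se <- sd(r$draws$thq) / sqrt(r$iterations)
  expect_lt(abs(mean(r$draws$thq) - mid), 3 * se)
})

test_that("identical seed reproduces identical draw vectors", {
  ranges <- c(list(parameter_range("concentration", 400, 700)),
              default_adult_ranges("soil"))
  a <- run_monte_carlo(soil_cell, ranges, iterations = 300, seed = 7)
  b <- run_monte_carlo(soil_cell, ranges, iterations = 300, seed = 7)
  expect_identical(a$draws, b$draws)
  c2 <- run_monte_carlo(soil_cell, ranges, iterations = 300, seed = 8)
  expect_false(identical(a$draws$thq, c2$draws$thq))
})

test_that("log-THQ equals the sum of log-parameter draws plus a constant", {
  # multiplicative chain: log THQ = log conc + log IR - log BW + const
  ranges <- list(parameter_range("concentration", 100, 1000),
                 parameter_range("IR", 10, 100),
                 parameter_range("BW", 50, 95))
  r <- run_monte_carlo(soil_cell, ranges, iterations = 50, seed = 2)
  const <- log(47.80 / 100 * params$RBA * 1e-6 / params$RfD)
  expect_equal(log(r$draws$thq),
               log(r$draws$concentration) + log(r$draws$IR) -
                 log(r$draws$BW) + const)
})

test_that("exceedance probability is the strict tail fraction, monotone in
           the threshold", {
  r <- run_monte_carlo(soil_cell, list(parameter_range("IR", 10, 100)),
                       iterations = 2000, seed = 3)
  expect_equal(exceedance_probability(r, max(r$draws$thq) + 1), 0)
  expect_equal(exceedance_probability(r, -1), 1)
  thresholds <- seq(0, 0.2, by = 0.01)
  probs <- vapply(thresholds, function(t) exceedance_probability(r, t),
                  numeric(1))
  expect_true(all(diff(probs) <= 0))
  # closed-form uniform tail: THQ uniform on [lo, hi], threshold at midpoint
  lo <- min(r$draws$thq); hi <- max(r$draws$thq)
  midpoint <- (lo + hi) / 2
  p <- exceedance_probability(r, midpoint)
  se <- sqrt(0.25 / r$iterations)
  expect_lt(abs(p - 0.5), 3 * se + (hi - lo) / r$iterations)
})

test_that("histogram counts sum to draws and probabilities to one", {
  r <- run_monte_carlo(soil_cell, list(parameter_range("IR", 10, 100)),
                       iterations = 10000, seed = 4)
  h1 <- mc_histogram(r, bins = 1)
  expect_equal(h1$probability, 1)
  h <- mc_histogram(r, bins = 10)
  expect_equal(sum(h$count), 10000)
  expect_equal(sum(h$probability), 1)
  # uniform THQ in IR: each of 10 equal bins holds ~1/10 within 3 SE
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(h$probability - 0.1) < 3 * se + 2 / 10000))
  # degenerate draws land in one bin
  r0 <- run_monte_carlo(soil_cell, list(), iterations = 100, seed = 1)
  h0 <- mc_histogram(r0, bins = 5)
  expect_equal(sum(h0$count > 0), 1)
  expect_equal(sum(h0$count), 100)
})

test_that("swing sensitivity: degenerate parameter contributes exactly zero,
           wide ranges dominate narrow ones", {
  ranges <- list(parameter_range("concentration", 100, 1000),  # x10 span
                 parameter_range("BW", 60, 78),                # x1.3 span
                 parameter_range("EF", 200, 200))              # degenerate
  r <- run_monte_carlo(soil_cell, ranges, iterations = 2000, seed = 6)
  sw <- sensitivity_analysis(r, "swing")
  expect_identical(sw$score[sw$parameter == "EF"], 0)
  expect_equal(sw$parameter[1], "concentration")
  conc_rank <- sw$rank[sw$parameter == "concentration"]
  bw_rank <- sw$rank[sw$parameter == "BW"]
  expect_lt(conc_rank, bw_rank)
  rc <- sensitivity_analysis(r, "rank_correlation")
  expect_lt(rc$rank[rc$parameter == "concentration"],
            rc$rank[rc$parameter == "BW"])
})

test_that("rank correlation magnitude is ~1 for a single varied parameter", {
  r <- run_monte_carlo(soil_cell, list(parameter_range("IR", 10, 100)),
                       iterations = 500, seed = 9)
  rc <- sensitivity_analysis(r, "rank_correlation")
  expect_equal(abs(rc$score[rc$parameter == "IR"]), 1)
  # body weight correlates negatively: sign retained in the score
  r2 <- run_monte_carlo(soil_cell, list(parameter_range("BW", 50, 95)),
                        iterations = 500, seed = 9)
  rc2 <- sensitivity_analysis(r2, "rank_correlation")
  expect_equal(rc2$score[rc2$parameter == "BW"], -1)
})

test_that("standard error of the mean shrinks as 1/sqrt(n)", {
  ranges <- list(parameter_range("concentration", 100, 1000))
  sems <- vapply(c(500L, 8000L), function(n) {
    reps <- vapply(1:30, function(i) {
      mean(run_monte_carlo(soil_cell, ranges, iterations = n,
                           seed = 100 + i)$draws$thq)
    }, numeric(1))
    sd(reps)
  }, numeric(1))
  ratio <- sems[1] / sems[2]
  expect_gt(ratio, sqrt(8000 / 500) * 0.5)
  expect_lt(ratio, sqrt(8000 / 500) * 2)
})

test_that("domain-violating ranges are rejected before sampling", {
  expect_error(parameter_range("BAF", 0, 120), "domain")
  expect_error(parameter_range("BW", -5, 50), "domain")
  expect_error(parameter_range("IR", 40, 10), "min <= max")
  expect_error(run_monte_carlo(veg_cell,
                               list(parameter_range("BAF", 10, 50))),
               "vegetable")
})

test_that("grid simulation covers 16 soil and 12 vegetable combinations", {
  d <- generate_dataset(synthetic_spec(seed = 10))
  g <- run_monte_carlo_grid(d, iterations = 100, seed = 10)
  expect_equal(sum(g$pathway == "soil"), 16)
  expect_equal(sum(g$pathway == "vegetable"), 12)
  expect_true(all(g$iterations == 100))
  expect_true(all(g$p_exceed_1 >= 0 & g$p_exceed_1 <= 1))
  g2 <- run_monte_carlo_grid(d, iterations = 100, seed = 10)
  expect_identical(as.data.frame(g), as.data.frame(g2))
})
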