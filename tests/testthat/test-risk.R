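params <- exposure_parameters()

test_that("soil intake equation reproduces the condition-mean value", {
  expect_equal(adi_soil(0, 50, params), 0)
  # condition means: 557.2 mg/kg at 47.80 % gastric BAF
  expect_equal(adi_soil(557.2, 47.80, params), 1.522e-4, tolerance = 5e-3)
  # unit-cancellation sanity: BAF 100%, RBA 1, chosen so ADI = 1 mg/kg/day
  p1 <- exposure_parameters(RBA = 1)
  expect_equal(adi_soil(1.4e6, 100, p1), 1.0)
  expect_error(exposure_parameters(BW = 0), "BW")
})

test_that("vegetable intake equation reproduces printed table cells", {
  expect_equal(adi_veg(0, "lettuce", params), 0)
  expect_equal(adi_veg(8.48, "lettuce", params), 1.87e-3, tolerance = 5e-3)
  expect_equal(adi_veg(13.10, "lettuce", params), 2.89e-3, tolerance = 5e-3)
  expect_error(adi_veg(1, "potato", params), "potato")
})

test_that("hazard quotient and cancer risk chain from the intake", {
  expect_equal(thq(params$RfD, params), 1.0)
  expect_equal(thq(adi_veg(8.48, "lettuce", params), params), 0.535,
               tolerance = 5e-3)
  expect_equal(thq(adi_veg(8.97, "lettuce", params), params), 0.566,
               tolerance = 5e-3)
  expect_equal(cancer_risk(0, params), 0)
  expect_equal(cancer_risk(adi_veg(13.10, "lettuce", params), params),
               2.46e-5, tolerance = 5e-3)
  expect_equal(cancer_risk(adi_veg(8.48, "lettuce", params), params),
               1.59e-5, tolerance = 5e-3)
})

test_that("intake is linear in concentration", {
  set.seed(4)
  for (i in 1:10) {
    c0 <- runif(1, 1, 600); k <- runif(1, 0.1, 10); baf <- runif(1, 10, 90)
    expect_equal(adi_soil(k * c0, baf, params), k * adi_soil(c0, baf, params))
    expect_equal(adi_veg(k * c0, "carrot", params),
                 k * adi_veg(c0, "carrot", params))
  }
})

test_that("with derived averaging time, EF and ED rescaling cancels", {
  base <- adi_soil(300, 40, exposure_parameters())
  expect_equal(adi_soil(300, 40, exposure_parameters(EF = 180, ED = 30)), base)
  expect_equal(adi_veg(5, "garlic", exposure_parameters(EF = 100, ED = 10)),
               adi_veg(5, "garlic", exposure_parameters()))
  # an explicit AT breaks the cancellation
  p_at <- exposure_parameters(AT = 70 * 365)
  expect_false(isTRUE(all.equal(adi_soil(300, 40, p_at), base)))
})

test_that("stored results satisfy the THQ/CR round-trip identities exactly", {
  for (adi in c(7.36e-5, 1.87243e-3, 2.32e-4, 0)) {
    r <- risk_result("soil", adi, params)
    expect_equal(r$thq * params$RfD, r$adi, tolerance = 1e-12)
    expect_equal(r$cr / params$CSF, r$adi, tolerance = 1e-12)
  }
})

test_that("pathway combination is additive and guards treatment keys", {
  s <- risk_result("soil", 7.36e-5, params, treatment = "LNB")
  v <- risk_result("vegetable", 2.89248e-3, params, treatment = "LNB")
  cb <- combine_pathways(s, v)
  expect_equal(cb$adi, 2.97e-3, tolerance = 5e-3)
  expect_equal(cb$adi, s$adi + v$adi)
  expect_gte(cb$adi, s$adi)
  expect_gte(cb$adi, v$adi)

  s2 <- risk_result("soil", 1.54e-4, params, treatment = "HNB")
  v2 <- risk_result("vegetable", 7.83e-5, params, treatment = "HNB")
  expect_equal(combine_pathways(s2, v2)$adi, 2.32e-4, tolerance = 5e-3)

  # absent vegetable pathway (no-crop) leaves combined equal to soil
  cb0 <- combine_pathways(s)
  expect_equal(cb0$adi, s$adi)
  expect_equal(cb0$pathway, "combined")

  expect_error(combine_pathways(s, risk_result("vegetable", 1e-4, params,
                                               treatment = "HB")),
               "different treatment cells")
})

test_that("classification bands follow the published thresholds", {
  mk <- function(adi) risk_result("soil", adi, params)
  over <- classify_risk(risk_result("vegetable", 1.053 * params$RfD, params))
  expect_equal(over$thq_label, "exceeds threshold")
  expect_true(over$adi_exceeds_rfd)
  r <- mk(1.14e-6 / params$CSF)
  expect_equal(classify_risk(r)$cr_label, "moderate acceptable")
  expect_equal(classify_risk(mk(1e-7 / params$CSF))$cr_label, "negligible")
  expect_equal(classify_risk(mk(2e-4 / params$CSF))$cr_label, "unacceptable")
  # band edges: 1e-6 is moderate, 1e-4 is unacceptable
  expect_equal(classify_risk(mk(1e-6 / params$CSF))$cr_label,
               "moderate acceptable")
  expect_equal(classify_risk(mk(1e-4 / params$CSF))$cr_label, "unacceptable")
})

test_that("percent change is the signed relative difference", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(8.97, 13.10), -31.5, tolerance = 1e-3)
  expect_equal(percent_change(2 * 7, 7), 100)
  expect_error(percent_change(1, 0), "undefined")
})

test_that("aggregation averages per-replicate indices within each cell", {
  d <- generate_dataset(synthetic_spec(seed = 8))
  agg <- aggregate_treatment(d, params)
  expect_equal(nrow(agg), 16 + 12 + 16)  # soil + vegetable + combined
  # hand-computed mean for one cell
  cell <- d[d$agrisystem == "carrot" & d$pb_condition == "low" &
              d$amendment == "biochar", ]
  baf <- cell$pb_bac_gastric_mgkg / cell$pb_soil_total_mgkg * 100
  expected <- mean(adi_soil(cell$pb_soil_total_mgkg, baf, params))
  got <- agg[agg$agrisystem == "carrot" & agg$treatment == "LB" &
               agg$pathway == "soil", ]
  expect_equal(got$adi_mean, expected)
  expect_equal(got$n, 3)
  # combined = soil + vegetable per cell
  wide <- split(agg, agg$pathway)
  crop <- wide$soil$agrisystem != "no_crop"
  key <- function(x) paste(x$agrisystem, x$treatment)
  soil_adi <- wide$soil$adi_mean[match(key(wide$combined), key(wide$soil))]
  veg_adi <- wide$vegetable$adi_mean[match(key(wide$combined), key(wide$vegetable))]
  veg_adi[is.na(veg_adi)] <- 0
  expect_equal(wide$combined$adi_mean, soil_adi + veg_adi)
})

test_that("single or identical replicates yield zero SD", {
  d <- generate_dataset(degenerate_spec())
  agg <- aggregate_treatment(d, params)
  expect_true(all(agg$adi_sd == 0))
  d1 <- generate_dataset(synthetic_spec(replicates = 1, seed = 2))
  agg1 <- aggregate_treatment(d1, params)
  expect_true(all(agg1$n == 1))
  expect_true(all(agg1$adi_sd == 0))
})

test_that("empty cells are omitted with a warning", {
  d <- generate_dataset(synthetic_spec(seed = 8))
  d <- d[!(d$agrisystem == "garlic" & d$pb_condition == "low" &
             d$amendment == "biochar"), ]
  expect_warning(agg <- aggregate_treatment(d, params), "empty treatment cell")
  expect_false(any(agg$agrisystem == "garlic" & agg$treatment == "LB"))
})

test_that("mean of per-replicate intakes equals intake of mean concentration
           only when the fraction is constant", {
  conc <- c(400, 500, 600)
  baf_const <- c(45, 45, 45)
  expect_equal(mean(adi_soil(conc, baf_const, params)),
               adi_soil(mean(conc), 45, params))
  baf_var <- c(30, 45, 60)
  expect_false(isTRUE(all.equal(
    mean(adi_soil(conc, baf_var, params)),
    adi_soil(mean(conc), mean(baf_var), params))))
})
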