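test_that("degenerate SDs reproduce the cell means exactly", {
  d <- generate_dataset(degenerate_spec())
  expect_equal(nrow(d), 48)  # 16 cells x 3 replicates
  high <- d$pb_condition == "high"
  expect_true(all(d$pb_soil_total_mgkg[high] == 557.2))
  expect_true(all(d$pb_soil_total_mgkg[!high] == 250.2))
  lettuce_hnb <- d$agrisystem == "lettuce" & d$pb_condition == "high" &
    d$amendment == "control"
  expect_true(all(d$pb_veg_total_mgkg[lettuce_hnb] == 8.48))
  expect_true(all(is.na(d$pb_veg_total_mgkg[d$agrisystem == "no_crop"])))
})

test_that("identical spec and seed give identical tables", {
  spec <- synthetic_spec(seed = 42)
  expect_identical(generate_dataset(spec), generate_dataset(spec))
  expect_false(identical(generate_dataset(spec),
                         generate_dataset(spec, seed = 43)))
})

test_that("sample moments converge to spec moments (3 SE at n = 10000)", {
  n <- 10000L
  spec <- synthetic_spec(replicates = n, seed = 7)
  d <- generate_dataset(spec)
  lnb_lettuce <- d[d$agrisystem == "lettuce" & d$pb_condition == "low" &
                     d$amendment == "control", ]
  # truncation at 0 is negligible for lettuce LNB (mean 13.10, sd 3.38)
  expect_equal(mean(lnb_lettuce$pb_veg_total_mgkg), 13.10,
               tolerance = 3 * 3.38 / sqrt(n) / 13.10)
  expect_equal(sd(lnb_lettuce$pb_veg_total_mgkg), 3.38, tolerance = 0.05)
  hnb_soil <- d[d$pb_condition == "high" & d$amendment == "control" &
                  d$agrisystem == "no_crop", ]
  expect_equal(mean(hnb_soil$pb_soil_total_mgkg), 557.2,
               tolerance = 3 * 60.22 / sqrt(n) / 557.2)
})

test_that("generated values respect their domains", {
  spec <- synthetic_spec(replicates = 50, seed = 11)
  d <- generate_dataset(spec)
  expect_true(all(d$pb_soil_total_mgkg >= 0))
  expect_true(all(d$pb_bac_gastric_mgkg >= 0))
  expect_true(all(d$pb_veg_total_mgkg >= 0, na.rm = TRUE))
  baf <- d$pb_bac_gastric_mgkg / d$pb_soil_total_mgkg * 100
  expect_true(all(baf > 0 & baf <= 100))
  # gastrointestinal phase scales off the gastric phase
  expect_equal(d$pb_bac_gi_mgkg, d$pb_bac_gastric_mgkg * spec$gi_ratio)
})

test_that("consistent mode round-trips BAC/total through the fraction exactly", {
  d <- generate_dataset(synthetic_spec(replicates = 20, seed = 3))
  baf <- compute_baf(d$pb_bac_gastric_mgkg, d$pb_soil_total_mgkg)
  expect_equal(as.numeric(baf) / 100 * d$pb_soil_total_mgkg,
               d$pb_bac_gastric_mgkg, tolerance = 1e-12)
})

test_that("independent BAC mode decouples BAC from the sampled fraction", {
  spec <- synthetic_spec(replicates = 30, seed = 3, consistent_bac = FALSE)
  d <- generate_dataset(spec)
  # independent draws can exceed the total; the fraction flags, never clips
  baf <- as.numeric(suppressWarnings(
    compute_baf(d$pb_bac_gastric_mgkg, d$pb_soil_total_mgkg)))
  # with independent draws the recovered fraction is noisy, not a constant map
  expect_gt(sd(baf[d$pb_condition == "high"]), 0)
  expect_true(all(d$pb_bac_gastric_mgkg >= 0))
})

test_that("biochar multipliers shift only biochar cell means", {
  cells <- default_cell_parameters()
  cells$soil_sd <- 0; cells$baf_sd <- 0
  cells$veg_sd <- ifelse(is.na(cells$veg_sd), NA, 0)
  spec <- synthetic_spec(cells = cells, biochar_baf_mult = 0.5,
                         biochar_veg_mult = 2, seed = 1)
  d <- generate_dataset(spec)
  baf <- d$pb_bac_gastric_mgkg / d$pb_soil_total_mgkg * 100
  high <- d$pb_condition == "high"
  expect_true(all(abs(baf[high & d$amendment == "control"] - 47.80) < 1e-9))
  expect_true(all(abs(baf[high & d$amendment == "biochar"] - 23.90) < 1e-9))
  carrot <- d$agrisystem == "carrot"
  expect_true(all(d$pb_veg_total_mgkg[carrot & d$amendment == "biochar"] == 2.94))
})

test_that("invalid specs are rejected with informative errors", {
  cells <- default_cell_parameters()
  expect_error(synthetic_spec(cells = cells[-1, ]), "no cell parameters")
  bad <- cells; bad$soil_sd[1] <- -1
  expect_error(synthetic_spec(cells = bad), "negative SD")
  bad <- cells; bad$baf_mean[1] <- 120
  expect_error(synthetic_spec(cells = bad), "BAF means")
  expect_error(synthetic_spec(replicates = 0), "replicates")
})
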