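## Canonical sampling order for the varied parameters. Sampling always
## follows this order so a given seed yields the same draws regardless of
## the order ranges were supplied in.
MC_PARAMETERS <- c("concentration", "BAF", "EF", "IR", "BW")

#' Sampling range for a Monte Carlo parameter
#'
#' @param name one of `"concentration"`, `"BAF"`, `"EF"`, `"IR"`, `"BW"`.
#' @param min,max range bounds; `min <= max`. A degenerate range
#'   (`min == max`) pins the parameter to that value.
#' @param dist sampling distribution tag; only `"uniform"` is implemented.
#' @return an object of class `parameter_range`.
#' @export
parameter_range <- function(name, min, max, dist = "uniform") {
  name <- match.arg(name, MC_PARAMETERS)
  dist <- match.arg(dist, "uniform")
  if (!is.finite(min) || !is.finite(max) || min > max) {
    stop("range for '", name, "' must satisfy min <= max (finite)",
         call. = FALSE)
  }
  domain_ok <- switch(name,
    concentration = min >= 0,
    BAF = min > 0 && max <= 100,
    EF = min > 0 && max <= 366,
    IR = min > 0,
    BW = min > 0
  )
  if (!domain_ok) {
    stop("range [", min, ", ", max, "] violates the domain of '", name, "'",
         call. = FALSE)
  }
  structure(list(name = name, min = min, max = max, dist = dist),
            class = "parameter_range")
}

#' Placeholder adult exposure-parameter ranges
#'
#' Uniform ranges for exposure frequency, ingestion rate and body weight of
#' an adult receptor, for use when no site- or survey-specific ranges are
#' supplied. These are synthetic placeholders spanning plausible adult
#' values (EF 180–365 days/year; soil IR 10–100 mg/day or crop IR 50–250 g
#' fresh weight/day; BW 50–95 kg) and should be replaced with
#' survey-derived ranges for any real assessment.
#'
#' @param pathway `"soil"` or `"vegetable"` (selects the IR range).
#' @return named list of [parameter_range()] objects (`EF`, `IR`, `BW`).
#' @export
default_adult_ranges <- function(pathway = c("soil", "vegetable")) {
  pathway <- match.arg(pathway)
  ir <- if (pathway == "soil") c(10, 100) else c(50, 250)
  list(
    EF = parameter_range("EF", 180, 365),
    IR = parameter_range("IR", ir[1], ir[2]),
    BW = parameter_range("BW", 50, 95)
  )
}

#' Site-specific concentration and BAF ranges from measurements
#'
#' Builds the per-treatment-cell `concentration` (and, for the soil pathway,
#' `BAF`) ranges as the min–max of the cell's replicate measurements,
#' mirroring the use of site-specific ranges in the simulations.
#'
#' @param measurements a measurement table.
#' @param agrisystem,pb_condition,amendment treatment cell key.
#' @param pathway `"soil"` or `"vegetable"`.
#' @param phase bioaccessibility phase for the soil pathway.
#' @return named list of [parameter_range()] objects.
#' @export
ranges_from_measurements <- function(measurements, agrisystem, pb_condition,
                                     amendment,
                                     pathway = c("soil", "vegetable"),
                                     phase = c("gastric", "gastrointestinal")) {
  pathway <- match.arg(pathway)
  phase <- match.arg(phase)
  df <- measurements[measurements$agrisystem == agrisystem &
                       measurements$pb_condition == pb_condition &
                       measurements$amendment == amendment, ]
  if (nrow(df) == 0) {
    stop("no measurements for cell ", agrisystem, "/", pb_condition, "/",
         amendment, call. = FALSE)
  }
  if (pathway == "soil") {
    bac_col <- if (phase == "gastric") "pb_bac_gastric_mgkg" else "pb_bac_gi_mgkg"
    baf <- as.numeric(compute_baf(df[[bac_col]], df$pb_soil_total_mgkg))
    list(
      concentration = parameter_range("concentration",
                                      min(df$pb_soil_total_mgkg),
                                      max(df$pb_soil_total_mgkg)),
      BAF = parameter_range("BAF", min(baf), max(baf))
    )
  } else {
    veg <- df$pb_veg_total_mgkg
    if (all(is.na(veg))) {
      stop("cell has no vegetable measurements", call. = FALSE)
    }
    list(
      concentration = parameter_range("concentration",
                                      min(veg, na.rm = TRUE),
                                      max(veg, na.rm = TRUE))
    )
  }
}

## Deterministic point values for each samplable parameter of a cell.
mc_point_values <- function(cell, params) {
  c(
    concentration = cell$concentration,
    BAF = if (identical(cell$pathway, "soil")) cell$baf else NA_real_,
    EF = params$EF,
    IR = if (identical(cell$pathway, "soil")) params$IR_soil else params$IR_veg,
    BW = params$BW
  )
}

## Evaluates the intake -> hazard chain for vectors of parameter values.
mc_evaluate <- function(values, cell, params) {
  ED <- params$ED
  AT <- if (params$AT_derived) values[["EF"]] * ED else params$AT
  adi <- if (cell$pathway == "soil") {
    .adi_soil_vec(values[["concentration"]], values[["BAF"]], params$RBA,
                  values[["EF"]], ED, values[["IR"]], values[["BW"]], AT)
  } else {
    .adi_veg_vec(values[["concentration"]], params$C[[cell$crop]],
                 values[["EF"]], ED, values[["IR"]], values[["BW"]], AT)
  }
  list(adi = adi, thq = adi / params$RfD, cr = adi * params$CSF)
}

#' Describe a treatment cell for Monte Carlo simulation
#'
#' @param pathway `"soil"` or `"vegetable"`.
#' @param concentration point value of the (soil or vegetable dry-weight)
#'   Pb concentration (mg/kg).
#' @param baf point value of the bioaccessible fraction (%); soil pathway
#'   only.
#' @param crop crop name; vegetable pathway only.
#' @param treatment optional treatment label carried into results.
#' @return a list of class `mc_cell`.
#' @export
mc_cell <- function(pathway = c("soil", "vegetable"), concentration,
                    baf = NULL, crop = NULL, treatment = NULL) {
  pathway <- match.arg(pathway)
  assert_nonnegative(concentration, "concentration")
  if (pathway == "soil") {
    if (is.null(baf)) stop("soil pathway requires `baf`", call. = FALSE)
    assert_nonnegative(baf, "baf")
  } else {
    if (is.null(crop)) stop("vegetable pathway requires `crop`", call. = FALSE)
  }
  structure(list(pathway = pathway, concentration = concentration,
                 baf = baf, crop = crop, treatment = treatment),
            class = "mc_cell")
}

#' Monte Carlo uncertainty propagation for one treatment cell
#'
#' Each iteration draws every varied parameter independently from its
#' uniform range (in the fixed order concentration, BAF, EF, IR, BW),
#' holds all other parameters at their deterministic point values, and
#' evaluates the intake -> hazard chain to record ADI, THQ and CR. With all
#' ranges degenerate at the point values every draw reproduces the
#' deterministic result exactly. The same seed always reproduces the same
#' draws.
#'
#' @param cell an [mc_cell()].
#' @param ranges list of [parameter_range()] objects for the varied
#'   parameters (any subset of concentration, BAF, EF, IR, BW).
#' @param iterations number of draws (default 10000).
#' @param seed integer seed.
#' @param params an [exposure_parameters()] supplying fixed values.
#' @return an object of class `mc_result` with the draw table
#'   (`$draws`: one row per iteration with the sampled parameters and
#'   ADI/THQ/CR), `$summary` (mean, SD, quantiles of THQ), the varied
#'   parameter names, ranges, seed and iteration count.
#' @export
run_monte_carlo <- function(cell, ranges = list(), iterations = 10000,
                            seed = 1, params = exposure_parameters()) {
  stopifnot(inherits(cell, "mc_cell"), inherits(params, "exposure_parameters"))
  if (iterations < 1) stop("`iterations` must be >= 1", call. = FALSE)
  for (r in ranges) {
    if (!inherits(r, "parameter_range")) {
      stop("`ranges` must contain parameter_range objects", call. = FALSE)
    }
  }
  range_names <- vapply(ranges, function(r) r$name, character(1))
  if (anyDuplicated(range_names)) {
    stop("duplicate range for parameter(s): ",
         paste(unique(range_names[duplicated(range_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (cell$pathway == "vegetable" && "BAF" %in% range_names) {
    stop("BAF cannot be varied on the vegetable pathway", call. = FALSE)
  }
  names(ranges) <- range_names

  point <- mc_point_values(cell, params)
  n <- as.integer(iterations)
  set.seed(as.integer(seed))
  values <- list()
  for (p in MC_PARAMETERS) {
    if (p %in% range_names) {
      r <- ranges[[p]]
      u <- stats::runif(n)
      values[[p]] <- r$min + (r$max - r$min) * u
    } else {
      values[[p]] <- rep(point[[p]], n)
    }
  }

  out <- mc_evaluate(values, cell, params)
  draws <- tibble::tibble(
    concentration = values$concentration, BAF = values$BAF, EF = values$EF,
    IR = values$IR, BW = values$BW,
    adi = out$adi, thq = out$thq, cr = out$cr
  )
  structure(
    list(
      cell = cell,
      pathway = cell$pathway,
      treatment = cell$treatment,
      iterations = n,
      seed = as.integer(seed),
      varied = intersect(MC_PARAMETERS, range_names),
      ranges = ranges,
      params = params,
      draws = draws,
      summary = c(
        mean = mean(out$thq), sd = stats::sd(out$thq),
        stats::quantile(out$thq, c(0.025, 0.25, 0.5, 0.75, 0.975))
      )
    ),
    class = "mc_result"
  )
}

#' Probability that simulated THQ exceeds a threshold
#'
#' Fraction of Monte Carlo draws strictly above the threshold.
#'
#' @param result an [run_monte_carlo()] result.
#' @param threshold THQ threshold (default 1).
#' @return probability in `[0, 1]`.
#' @export
exceedance_probability <- function(result, threshold = 1) {
  stopifnot(inherits(result, "mc_result"))
  mean(result$draws$thq > threshold)
}

#' Frequency–probability histogram of simulated THQ
#'
#' Bins the THQ draws into equal-width bins spanning their range. Counts
#' sum to the draw count and probabilities to 1. Degenerate draw sets (all
#' values identical) are placed in a single bin of token width.
#'
#' @param result an [run_monte_carlo()] result.
#' @param bins number of bins (>= 1, default 20).
#' @return a tibble with `bin_lower`, `bin_upper`, `count`, `probability`.
#' @export
mc_histogram <- function(result, bins = 20) {
  stopifnot(inherits(result, "mc_result"))
  if (bins < 1) stop("`bins` must be >= 1", call. = FALSE)
  x <- result$draws$thq
  rng <- range(x)
  if (rng[1] == rng[2]) {
    half <- max(abs(rng[1]) * 1e-6, 1e-12)
    rng <- rng + c(-half, half)
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  tibble::tibble(
    bin_lower = breaks[-length(breaks)],
    bin_upper = breaks[-1],
    count = counts,
    probability = counts / length(x)
  )
}

#' Sensitivity ranking of Monte Carlo input parameters
#'
#' Ranks the varied parameters by their influence on THQ.
#'
#' Method `"swing"` (the tornado-chart construction) re-evaluates the
#' deterministic THQ at each parameter's range minimum and maximum with
#' every other parameter held at its range midpoint (point value if
#' unvaried); the contribution is `|THQ_max - THQ_min|`, the tornado bar
#' width. Method `"rank_correlation"` computes the Spearman correlation
#' between each parameter's draws and the THQ draws; influence is its
#' absolute value (the signed correlation is retained in the score column).
#'
#' Parameters with a degenerate range contribute exactly 0. Rankings sort
#' by influence descending; ties are broken by parameter name order and
#' flagged.
#'
#' @param result an [run_monte_carlo()] result.
#' @param method `"swing"` (default) or `"rank_correlation"`.
#' @return an object of class `sensitivity_ranking`: a tibble with
#'   `parameter`, `score`, `influence`, `rank`, plus attributes `method`
#'   and `ties`.
#' @export
sensitivity_analysis <- function(result, method = c("swing", "rank_correlation")) {
  stopifnot(inherits(result, "mc_result"))
  method <- match.arg(method)
  varied <- result$varied
  if (length(varied) == 0) {
    stop("no varied parameters to rank", call. = FALSE)
  }
  point <- mc_point_values(result$cell, result$params)

  if (method == "swing") {
    mids <- point
    for (p in varied) {
      r <- result$ranges[[p]]
      mids[[p]] <- (r$min + r$max) / 2
    }
    score <- vapply(varied, function(p) {
      r <- result$ranges[[p]]
      lo <- hi <- as.list(mids)
      lo[[p]] <- r$min
      hi[[p]] <- r$max
      thq_lo <- mc_evaluate(lo, result$cell, result$params)$thq
      thq_hi <- mc_evaluate(hi, result$cell, result$params)$thq
      abs(thq_hi - thq_lo)
    }, numeric(1))
    influence <- score
  } else {
    score <- vapply(varied, function(p) {
      x <- result$draws[[p]]
      if (stats::sd(x) == 0 || stats::sd(result$draws$thq) == 0) return(0)
      stats::cor(x, result$draws$thq, method = "spearman")
    }, numeric(1))
    influence <- abs(score)
  }

  ord <- order(-influence, match(varied, MC_PARAMETERS))
  ranking <- tibble::tibble(
    parameter = varied[ord],
    score = unname(score[ord]),
    influence = unname(influence[ord]),
    rank = seq_along(ord)
  )
  ties <- anyDuplicated(round(influence, 12)) > 0
  structure(ranking, method = method, ties = ties,
            class = c("sensitivity_ranking", class(ranking)))
}

#' Monte Carlo simulations across the full treatment grid
#'
#' Runs one simulation per (treatment cell, pathway): all 16 soil cells and
#' the 12 vegetable crop cells, each with site-specific concentration (and
#' soil BAF) ranges taken from the cell's measurements plus the adult
#' EF/IR/BW ranges. Sub-seeds are derived deterministically from `seed`.
#'
#' @param measurements a measurement table.
#' @param iterations draws per cell (default 10000).
#' @param seed top-level integer seed.
#' @param params an [exposure_parameters()].
#' @param phase bioaccessibility phase for the soil pathway.
#' @param adult_ranges function taking the pathway and returning the
#'   EF/IR/BW ranges (default [default_adult_ranges()]).
#' @return a tibble with one row per simulation: cell key, pathway, THQ
#'   mean/SD/quantiles, exceedance probability vs 1, and the top-ranked
#'   sensitivity parameter (swing method). The full `mc_result` objects are
#'   attached as the `results` attribute.
#' @export
run_monte_carlo_grid <- function(measurements, iterations = 10000, seed = 1,
                                 params = exposure_parameters(),
                                 phase = c("gastric", "gastrointestinal"),
                                 adult_ranges = default_adult_ranges) {
  phase <- match.arg(phase)
  agg <- aggregate_treatment(measurements, params, phase)
  cells <- agg[agg$pathway != "combined", ]
  results <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    pathway <- row$pathway
    sub <- measurements[measurements$agrisystem == row$agrisystem &
                          measurements$pb_condition == row$pb_condition &
                          measurements$amendment == row$amendment, ]
    bac_col <- if (phase == "gastric") "pb_bac_gastric_mgkg" else "pb_bac_gi_mgkg"
    if (pathway == "soil") {
      baf_vals <- as.numeric(compute_baf(sub[[bac_col]], sub$pb_soil_total_mgkg))
      cell <- mc_cell("soil", mean(sub$pb_soil_total_mgkg),
                      baf = mean(baf_vals), treatment = row$treatment)
    } else {
      cell <- mc_cell("vegetable", mean(sub$pb_veg_total_mgkg),
                      crop = row$agrisystem, treatment = row$treatment)
    }
    site <- ranges_from_measurements(measurements, row$agrisystem,
                                     row$pb_condition, row$amendment,
                                     pathway = pathway, phase = phase)
    ranges <- c(site, adult_ranges(pathway))
    # sub-seed per cell, kept within 32-bit integer range
    sub_seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    res <- run_monte_carlo(cell, ranges, iterations = iterations,
                           seed = sub_seed, params = params)
    sens <- sensitivity_analysis(res, method = "swing")
    results[[i]] <- res
    rows[[i]] <- tibble::tibble(
      agrisystem = row$agrisystem, pb_condition = row$pb_condition,
      amendment = row$amendment, treatment = row$treatment,
      pathway = pathway, iterations = res$iterations, seed = sub_seed,
      thq_mean = res$summary[["mean"]], thq_sd = res$summary[["sd"]],
      thq_q025 = res$summary[["2.5%"]], thq_median = res$summary[["50%"]],
      thq_q975 = res$summary[["97.5%"]],
      p_exceed_1 = exceedance_probability(res, 1),
      top_parameter = sens$parameter[1]
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "results") <- results
  out
}
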