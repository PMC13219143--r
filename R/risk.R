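#' Exposure parameters for the adult grower/consumer receptor
#'
#' All point values entering the daily-intake equations. Defaults describe an
#' adult (16–65 y, 70 kg) growing and consuming their own produce every day
#' of the year over a lifetime: exposure frequency EF = 365 days/year,
#' exposure duration ED = 75 years, soil ingestion IR_soil = 50 mg/day,
#' crop consumption IR_veg = 161 g fresh weight/day, averaging time
#' AT = EF x ED days (derived unless supplied), dry-to-fresh conversion
#' factors C (lettuce 0.096; carrot and garlic 0.103), the regression
#' conversion of bioaccessible fraction to relative bioavailability
#' RBA = BAF x 0.8, the oral reference dose for Pb RfD = 0.0035 mg/kg/day,
#' and the oral cancer slope factor CSF = 0.0085 (mg/kg/day)^-1.
#'
#' With the derived AT, EF and ED cancel out of the intake equations, so the
#' non-carcinogenic and carcinogenic indices share one ADI. Supplying an
#' explicit `AT` (e.g. a 70-year carcinogenic averaging time over a shorter
#' ED) breaks that cancellation deliberately.
#'
#' @param EF exposure frequency (days/year).
#' @param ED exposure duration (years).
#' @param IR_soil soil ingestion rate (mg/day).
#' @param IR_veg vegetable consumption rate (g fresh weight/day).
#' @param BW body weight (kg).
#' @param AT averaging time (days); `NULL` (default) derives EF x ED.
#' @param C named numeric vector of dry-to-fresh conversion factors per crop,
#'   each in (0, 1].
#' @param RBA multiplier converting BAF to relative bioavailability.
#' @param RfD oral reference dose (mg/kg/day).
#' @param CSF oral cancer slope factor ((mg/kg/day)^-1).
#' @return an object of class `exposure_parameters`.
#' @export
exposure_parameters <- function(EF = 365, ED = 75, IR_soil = 50, IR_veg = 161,
                                BW = 70, AT = NULL,
                                C = c(lettuce = 0.096, carrot = 0.103,
                                      garlic = 0.103),
                                RBA = 0.8, RfD = 0.0035, CSF = 0.0085) {
  for (nm in c("EF", "ED", "IR_soil", "IR_veg", "BW", "RBA", "RfD", "CSF")) {
    assert_positive(get(nm), nm)
  }
  if (any(C <= 0 | C > 1)) stop("C factors must lie in (0, 1]", call. = FALSE)
  if (is.null(names(C)) || any(!nzchar(names(C)))) {
    stop("C factors must be named by crop", call. = FALSE)
  }
  at_derived <- is.null(AT)
  if (at_derived) AT <- EF * ED else assert_positive(AT, "AT")
  structure(
    list(EF = EF, ED = ED, IR_soil = IR_soil, IR_veg = IR_veg, BW = BW,
         AT = AT, AT_derived = at_derived, C = C, RBA = RBA,
         RfD = RfD, CSF = CSF),
    class = "exposure_parameters"
  )
}

## Vectorised intake kernels shared by the deterministic pipeline and the
## Monte Carlo layer, so degenerate-range simulations reproduce the
## deterministic values bitwise.
.adi_soil_vec <- function(pb_soil, baf_pct, rba, EF, ED, IR, BW, AT) {
  pb_soil * (baf_pct / 100 * rba) * EF * ED * IR / (BW * AT) * 1e-6
}

.adi_veg_vec <- function(pb_veg, C, EF, ED, IR, BW, AT) {
  pb_veg * C * EF * ED * IR / (BW * AT) * 1e-3
}

#' Average daily intake from incidental soil ingestion
#'
#' `ADI_soil = Pb_soil x (BAF x RBA) x EF x ED x IR_soil / (BW x AT) x 1e-6`
#' in mg Pb per kg body weight per day, where BAF enters as a fraction
#' (percent / 100) and the 1e-6 factor converts mg soil to kg soil. With the
#' default derived averaging time AT = EF x ED this reduces to
#' `Pb_soil x BAF/100 x RBA x IR_soil / BW x 1e-6`.
#'
#' @param pb_soil total soil Pb (mg/kg), >= 0.
#' @param baf bioaccessible fraction (%), >= 0.
#' @param params an [exposure_parameters()].
#' @return ADI in mg/kg/day.
#' @export
#' @examples
#' adi_soil(557.2, 47.80)  # 1.52e-4 mg/kg/day
adi_soil <- function(pb_soil, baf, params = exposure_parameters()) {
  assert_nonnegative(pb_soil, "pb_soil")
  assert_nonnegative(baf, "baf")
  stopifnot(inherits(params, "exposure_parameters"))
  .adi_soil_vec(pb_soil, baf, params$RBA, params$EF, params$ED,
                params$IR_soil, params$BW, params$AT)
}

#' Average daily intake from vegetable consumption
#'
#' `ADI_veg = Pb_veg x C x EF x ED x IR_veg / (BW x AT) x 1e-3` in mg Pb per
#' kg body weight per day, where `Pb_veg` is the dry-weight concentration,
#' `C` converts it to fresh weight, `IR_veg` is in g fresh crop/day and the
#' 1e-3 factor converts g to kg. With the default derived AT this reduces to
#' `Pb_veg x C x IR_veg / BW x 1e-3`.
#'
#' @param pb_veg total vegetable Pb (mg/kg dry weight), >= 0.
#' @param crop crop name with a `C` factor in `params` (e.g. `"lettuce"`).
#' @param params an [exposure_parameters()].
#' @return ADI in mg/kg/day.
#' @export
#' @examples
#' adi_veg(8.48, "lettuce")  # 1.87e-3 mg/kg/day
adi_veg <- function(pb_veg, crop, params = exposure_parameters()) {
  assert_nonnegative(pb_veg, "pb_veg")
  stopifnot(inherits(params, "exposure_parameters"))
  if (!crop %in% names(params$C)) {
    stop("no dry-to-fresh conversion factor for crop '", crop, "'",
         call. = FALSE)
  }
  .adi_veg_vec(pb_veg, params$C[[crop]], params$EF, params$ED,
               params$IR_veg, params$BW, params$AT)
}

#' Target hazard quotient
#'
#' `THQ = ADI / RfD`; a THQ above 1 indicates non-carcinogenic risk.
#'
#' @param adi average daily intake (mg/kg/day), >= 0.
#' @param params an [exposure_parameters()] supplying `RfD`.
#' @return dimensionless THQ.
#' @export
thq <- function(adi, params = exposure_parameters()) {
  assert_nonnegative(adi, "adi")
  stopifnot(inherits(params, "exposure_parameters"))
  adi / params$RfD
}

#' Cancer slope risk
#'
#' `CR = ADI x CSF`: the upper-bound lifetime excess cancer probability.
#'
#' @param adi average daily intake (mg/kg/day), >= 0.
#' @param params an [exposure_parameters()] supplying `CSF`.
#' @return dimensionless probability.
#' @export
cancer_risk <- function(adi, params = exposure_parameters()) {
  assert_nonnegative(adi, "adi")
  stopifnot(inherits(params, "exposure_parameters"))
  adi * params$CSF
}

#' Construct a per-pathway risk result
#'
#' Bundles an ADI with the THQ and CR recomputed from it, so the identities
#' `THQ x RfD = ADI` and `CR = ADI x CSF` hold exactly for every stored
#' result.
#'
#' @param pathway `"soil"`, `"vegetable"` or `"combined"`.
#' @param adi average daily intake (mg/kg/day).
#' @param params an [exposure_parameters()].
#' @param treatment optional treatment identifier (used to guard pathway
#'   combination).
#' @return an object of class `risk_result` with fields `pathway`, `adi`,
#'   `thq`, `cr`, `treatment`, `params`.
#' @export
risk_result <- function(pathway = c("soil", "vegetable", "combined"),
                        adi, params = exposure_parameters(),
                        treatment = NULL) {
  pathway <- match.arg(pathway)
  assert_nonnegative(adi, "adi")
  structure(
    list(pathway = pathway, adi = adi,
         thq = thq(adi, params), cr = cancer_risk(adi, params),
         treatment = treatment, params = params),
    class = "risk_result"
  )
}

#' Combine soil and vegetable exposure pathways
#'
#' The combined receptor both grows (soil ingestion) and consumes
#' (vegetable ingestion) on the same plot: combined ADI is the sum of the
#' pathway ADIs, with THQ and CR recomputed from the combined ADI. A missing
#' vegetable result (no-crop cells) leaves the combined result equal to the
#' soil result.
#'
#' @param soil a `soil`-pathway [risk_result()].
#' @param veg a `vegetable`-pathway [risk_result()], or `NULL` for no-crop.
#' @return a `combined`-pathway [risk_result()].
#' @export
combine_pathways <- function(soil, veg = NULL) {
  stopifnot(inherits(soil, "risk_result"), soil$pathway == "soil")
  if (is.null(veg)) {
    return(risk_result("combined", soil$adi, soil$params, soil$treatment))
  }
  stopifnot(inherits(veg, "risk_result"), veg$pathway == "vegetable")
  if (!is.null(soil$treatment) && !is.null(veg$treatment) &&
      !identical(soil$treatment, veg$treatment)) {
    stop("cannot combine pathways from different treatment cells: '",
         soil$treatment, "' vs '", veg$treatment, "'", call. = FALSE)
  }
  risk_result("combined", soil$adi + veg$adi, soil$params, soil$treatment)
}

#' Classify a risk result against regulatory thresholds
#'
#' THQ above 1 flags non-carcinogenic risk. CR is banded: below 1e-6
#' negligible; from 1e-6 up to (but excluding) 1e-4 moderate acceptable;
#' 1e-4 and above unacceptable. The ADI is additionally flagged against the
#' oral reference dose.
#'
#' @param result a [risk_result()].
#' @param thq_threshold THQ threshold (default 1).
#' @param cr_bands length-2 ascending CR band edges (default `c(1e-6, 1e-4)`).
#' @return a list with `thq_label` (`"below threshold"`/`"exceeds threshold"`),
#'   `cr_label` (`"negligible"`/`"moderate acceptable"`/`"unacceptable"`),
#'   and `adi_exceeds_rfd` (logical).
#' @export
classify_risk <- function(result, thq_threshold = 1,
                          cr_bands = c(1e-6, 1e-4)) {
  stopifnot(inherits(result, "risk_result"))
  assert_positive(thq_threshold, "thq_threshold")
  if (length(cr_bands) != 2 || any(cr_bands <= 0) || cr_bands[1] >= cr_bands[2]) {
    stop("`cr_bands` must be two ascending positive values", call. = FALSE)
  }
  cr_label <- if (result$cr < cr_bands[1]) {
    "negligible"
  } else if (result$cr < cr_bands[2]) {
    "moderate acceptable"
  } else {
    "unacceptable"
  }
  list(
    thq_label = if (result$thq > thq_threshold) "exceeds threshold" else "below threshold",
    cr_label = cr_label,
    adi_exceeds_rfd = result$adi > result$params$RfD
  )
}

#' Signed percent change between treatments
#'
#' `(after - before) / before x 100`, e.g. the change in an index from the
#' control to the biochar treatment.
#'
#' @param after value after treatment.
#' @param before value before treatment; must be nonzero.
#' @return signed percentage.
#' @export
#' @examples
#' percent_change(8.97, 13.10)  # -31.5 %
percent_change <- function(after, before) {
  if (any(before == 0)) {
    stop("percent change is undefined for `before` = 0", call. = FALSE)
  }
  (after - before) / before * 100
}

#' Per-treatment-cell risk aggregation
#'
#' Computes per-replicate risk indices for every exposure pathway, then
#' averages within each treatment cell — the statistically standard order of
#' operations (mean of per-replicate ADIs, not ADI of the mean
#' concentration; the two differ whenever BAF varies across replicates).
#' Soil-pathway indices use the selected bioaccessibility phase; vegetable
#' indices exist only for crop cells; the combined pathway sums per-replicate
#' soil and vegetable ADIs (equal to the soil pathway for no-crop cells).
#'
#' @param measurements a measurement table (see [generate_dataset()] /
#'   [read_measurements()]).
#' @param params an [exposure_parameters()].
#' @param phase bioaccessibility phase feeding the soil pathway:
#'   `"gastric"` (default, worst case) or `"gastrointestinal"`.
#' @return a tibble with one row per (agrisystem, treatment, pathway):
#'   `n` replicates, mean and SD of ADI, THQ and CR, in the fixed reporting
#'   order. Cells with no replicates are omitted with a warning.
#' @export
aggregate_treatment <- function(measurements, params = exposure_parameters(),
                                phase = c("gastric", "gastrointestinal")) {
  phase <- match.arg(phase)
  df <- tibble::as_tibble(measurements)
  bac_col <- if (phase == "gastric") "pb_bac_gastric_mgkg" else "pb_bac_gi_mgkg"

  grid <- treatment_grid()
  present <- unique(df[, c("agrisystem", "pb_condition", "amendment")])
  absent <- dplyr::anti_join(grid, present,
                             by = c("agrisystem", "pb_condition", "amendment"))
  if (nrow(absent) > 0) {
    warning("omitting ", nrow(absent), " empty treatment cell(s)",
            call. = FALSE)
  }

  baf <- compute_baf(df[[bac_col]], df$pb_soil_total_mgkg)
  adi_s <- adi_soil(df$pb_soil_total_mgkg, as.numeric(baf), params)
  is_crop <- df$agrisystem != "no_crop"
  adi_v <- rep(NA_real_, nrow(df))
  for (crop in intersect(unique(df$agrisystem), names(params$C))) {
    rows <- df$agrisystem == crop
    adi_v[rows] <- adi_veg(df$pb_veg_total_mgkg[rows], crop, params)
  }
  unmapped <- setdiff(unique(df$agrisystem[is_crop]), names(params$C))
  if (length(unmapped) > 0) {
    stop("no dry-to-fresh conversion factor for crop(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  adi_c <- ifelse(is_crop, adi_s + adi_v, adi_s)

  long <- dplyr::bind_rows(
    dplyr::mutate(df, pathway = "soil", adi = adi_s),
    dplyr::mutate(df[is_crop, ], pathway = "vegetable", adi = adi_v[is_crop]),
    dplyr::mutate(df, pathway = "combined", adi = adi_c)
  )
  long$thq <- long$adi / params$RfD
  long$cr <- long$adi * params$CSF

  out <- long |>
    dplyr::group_by(.data$agrisystem, .data$pb_condition, .data$amendment,
                    .data$pathway) |>
    dplyr::summarise(
      n = dplyr::n(),
      adi_mean = mean(.data$adi), adi_sd = stats::sd(.data$adi),
      thq_mean = mean(.data$thq), thq_sd = stats::sd(.data$thq),
      cr_mean = mean(.data$cr), cr_sd = stats::sd(.data$cr),
      .groups = "drop"
    )
  out$adi_sd[out$n == 1] <- 0
  out$thq_sd[out$n == 1] <- 0
  out$cr_sd[out$n == 1] <- 0
  out$treatment <- treatment_code(out$pb_condition, out$amendment)
  out <- out[order(
    match(out$pathway, c("soil", "vegetable", "combined")),
    match(out$agrisystem, AGRISYSTEMS),
    match(out$treatment, TREATMENT_CODES)
  ), ]
  cols <- c("agrisystem", "pb_condition", "amendment", "treatment", "pathway",
            "n", "adi_mean", "adi_sd", "thq_mean", "thq_sd", "cr_mean", "cr_sd")
  tibble::as_tibble(out[, cols])
}
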