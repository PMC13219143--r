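#' Specification for the synthetic pot-experiment generator
#'
#' Builds a validated specification describing, for every treatment cell of
#' the 2 Pb-condition x 2 amendment x 4 agrisystem design, the distribution
#' parameters from which replicate-level measurements are drawn: mean/SD of
#' total soil Pb (mg/kg), mean/SD of the gastric-phase bioaccessible fraction
#' (BAF, %), and mean/SD of total vegetable Pb (mg/kg dry weight; `NA` for
#' no-crop cells). Optional pH and soil organic matter (SOM) covariates may be
#' included.
#'
#' The bioaccessible concentration (BAC) is by default *derived* as
#' `total x BAF/100` from the sampled BAF, which guarantees that recomputing
#' the bioaccessible fraction from a generated table recovers the sampled
#' value exactly. Setting `consistent_bac = FALSE` instead samples BAC
#' independently of the total, which deliberately breaks that identity and is
#' intended for exercising QC and invariant-failure paths.
#'
#' @param cells a data frame with one row per treatment cell and columns
#'   `agrisystem`, `pb_condition`, `amendment`, `soil_mean`, `soil_sd`,
#'   `baf_mean`, `baf_sd`, `veg_mean`, `veg_sd` (the last two `NA` for
#'   no-crop), and optionally `ph_mean`, `ph_sd`, `som_mean`, `som_sd`.
#'   Defaults to [default_cell_parameters()].
#' @param replicates replicates per cell (default 3, the 36-pot design).
#' @param biochar_baf_mult multiplicative biochar effect applied to the BAF
#'   mean of biochar cells (default 1 = no effect).
#' @param biochar_veg_mult multiplicative biochar effect applied to the
#'   vegetable Pb mean of biochar cells (default 1).
#' @param consistent_bac logical; derive BAC from total x BAF (default `TRUE`)
#'   or sample it independently (`FALSE`).
#' @param gi_ratio ratio of gastrointestinal-phase to gastric-phase BAC
#'   (default 0.5; a synthetic placeholder — the assay's gastrointestinal
#'   phase typically solubilises less Pb than the gastric phase).
#' @param seed integer random seed stored with the spec.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(cells = default_cell_parameters(),
                           replicates = 3L,
                           biochar_baf_mult = 1,
                           biochar_veg_mult = 1,
                           consistent_bac = TRUE,
                           gi_ratio = 0.5,
                           seed = 1L) {
  cells <- tibble::as_tibble(cells)
  required <- c(
    "agrisystem", "pb_condition", "amendment",
    "soil_mean", "soil_sd", "baf_mean", "baf_sd", "veg_mean", "veg_sd"
  )
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop("cell parameter table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  grid <- treatment_grid()
  key <- function(d) paste(d$agrisystem, d$pb_condition, d$amendment, sep = "/")
  absent <- setdiff(key(grid), key(cells))
  if (length(absent) > 0) {
    stop("no cell parameters for treatment cell(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  sd_cols <- intersect(c("soil_sd", "baf_sd", "veg_sd", "ph_sd", "som_sd"), names(cells))
  for (col in sd_cols) {
    if (any(cells[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative SD in column `%s`", col), call. = FALSE)
    }
  }
  if (any(cells$baf_mean <= 0 | cells$baf_mean > 100)) {
    stop("BAF means must lie in (0, 100]", call. = FALSE)
  }
  crop_rows <- cells$agrisystem != "no_crop"
  if (any(is.na(cells$veg_mean[crop_rows]))) {
    stop("crop cells must have a vegetable Pb mean", call. = FALSE)
  }
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  assert_positive(gi_ratio, "gi_ratio")
  assert_positive(biochar_baf_mult, "biochar_baf_mult")
  assert_positive(biochar_veg_mult, "biochar_veg_mult")

  structure(
    list(
      cells = cells,
      replicates = as.integer(replicates),
      biochar_baf_mult = biochar_baf_mult,
      biochar_veg_mult = biochar_veg_mult,
      consistent_bac = isTRUE(consistent_bac),
      gi_ratio = gi_ratio,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Default per-cell distribution parameters
#'
#' Synthetic defaults emulating the pot experiment's measured condition-level
#' moments. Total soil Pb and gastric BAF use condition-level mean/SD
#' (high: 557.2 +/- 60.22 mg/kg, BAF 47.80 +/- 6.79 %; low: 250.2 +/- 61.29
#' mg/kg, BAF 43.16 +/- 10.62 %) applied uniformly across agrisystems.
#' Vegetable Pb uses cell-level means where measured ones are available
#' (all four lettuce cells; the two low-Pb garlic cells) and crop-level means
#' elsewhere (carrot 1.47, garlic 0.23 mg/kg), with crop-level SDs throughout
#' (lettuce 3.38, carrot 0.90, garlic 0.12). pH/SOM covariate defaults are
#' condition-level round numbers. Per-cell soil values are *interpolated*
#' synthetic defaults, not measured cell means.
#'
#' @return a tibble suitable for the `cells` argument of [synthetic_spec()].
#' @export
default_cell_parameters <- function() {
  grid <- treatment_grid()
  high <- grid$pb_condition == "high"
  grid$soil_mean <- ifelse(high, 557.2, 250.2)
  grid$soil_sd <- ifelse(high, 60.22, 61.29)
  grid$baf_mean <- ifelse(high, 47.80, 43.16)
  grid$baf_sd <- ifelse(high, 6.79, 10.62)

  veg_mean <- rep(NA_real_, nrow(grid))
  veg_sd <- rep(NA_real_, nrow(grid))
  lettuce_means <- c(HNB = 8.48, HB = 7.45, LNB = 13.10, LB = 8.97)
  for (i in seq_len(nrow(grid))) {
    ag <- grid$agrisystem[i]
    tr <- grid$treatment[i]
    if (ag == "lettuce") {
      veg_mean[i] <- lettuce_means[[tr]]
      veg_sd[i] <- 3.38
    } else if (ag == "carrot") {
      veg_mean[i] <- 1.47
      veg_sd[i] <- 0.90
    } else if (ag == "garlic") {
      veg_mean[i] <- if (tr == "LNB") 0.09 else if (tr == "LB") 0.18 else 0.23
      veg_sd[i] <- 0.12
    }
  }
  grid$veg_mean <- veg_mean
  grid$veg_sd <- veg_sd
  grid$ph_mean <- 8.3
  grid$ph_sd <- 0.12
  grid$som_mean <- 8.4
  grid$som_sd <- 0.8
  grid[, setdiff(names(grid), "treatment")]
}

#' Generate a replicate-level synthetic measurement table
#'
#' Draws one row per (treatment cell, replicate). Total soil Pb, vegetable Pb,
#' pH and SOM are drawn from normal distributions truncated at 0; the gastric
#' BAF is drawn from a normal truncated to (0, 100]. In the default
#' consistent mode the gastric BAC is `total x BAF/100` and the
#' gastrointestinal BAC is `gastric x gi_ratio`. No-crop cells carry `NA`
#' vegetable Pb. The same spec and seed always reproduce the identical table.
#'
#' @param spec a [synthetic_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return a measurement tibble with columns `sample_id`, `agrisystem`,
#'   `pb_condition`, `amendment`, `replicate`, `pb_soil_total_mgkg`,
#'   `pb_bac_gastric_mgkg`, `pb_bac_gi_mgkg`, `pb_veg_total_mgkg`, `ph`,
#'   `som`.
#' @export
#' @examples
#' spec <- synthetic_spec(seed = 42)
#' head(generate_dataset(spec))
generate_dataset <- function(spec, seed = NULL) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("`spec` must be built with synthetic_spec()", call. = FALSE)
  }
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)

  grid <- treatment_grid()
  cells <- dplyr::left_join(
    grid, spec$cells,
    by = c("agrisystem", "pb_condition", "amendment")
  )
  n <- spec$replicates
  has_ph <- all(c("ph_mean", "ph_sd") %in% names(cells))
  has_som <- all(c("som_mean", "som_sd") %in% names(cells))

  rows <- vector("list", nrow(cells))
  set.seed(seed)
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    biochar <- cell$amendment == "biochar"
    baf_mean <- cell$baf_mean * if (biochar) spec$biochar_baf_mult else 1
    baf_mean <- min(baf_mean, 100)

    soil <- rtruncnorm(n, cell$soil_mean, cell$soil_sd, lower = 0)
    baf <- rtruncnorm(n, baf_mean, cell$baf_sd, lower = 0, upper = 100)
    if (spec$consistent_bac) {
      bac <- soil * baf / 100
    } else {
      ## independent BAC draw: intentionally decoupled from the sampled BAF
      bac <- rtruncnorm(n, cell$soil_mean * baf_mean / 100,
                        cell$soil_sd * baf_mean / 100, lower = 0)
    }

    if (cell$agrisystem == "no_crop") {
      veg <- rep(NA_real_, n)
    } else {
      veg_mean <- cell$veg_mean * if (biochar) spec$biochar_veg_mult else 1
      veg <- rtruncnorm(n, veg_mean, cell$veg_sd, lower = 0)
    }
    ph <- if (has_ph) rtruncnorm(n, cell$ph_mean, cell$ph_sd, lower = 0) else rep(NA_real_, n)
    som <- if (has_som) rtruncnorm(n, cell$som_mean, cell$som_sd, lower = 0) else rep(NA_real_, n)

    code <- treatment_code(cell$pb_condition, cell$amendment)
    rows[[i]] <- tibble::tibble(
      sample_id = sprintf("%s_%s_r%d", code, cell$agrisystem, seq_len(n)),
      agrisystem = cell$agrisystem,
      pb_condition = cell$pb_condition,
      amendment = cell$amendment,
      replicate = seq_len(n),
      pb_soil_total_mgkg = soil,
      pb_bac_gastric_mgkg = bac,
      pb_bac_gi_mgkg = bac * spec$gi_ratio,
      pb_veg_total_mgkg = veg,
      ph = ph,
      som = som
    )
  }
  dplyr::bind_rows(rows)
}
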