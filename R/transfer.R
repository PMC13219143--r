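#' Bioconcentration factor (BCF)
#'
#' Ratio of total vegetable Pb to total soil Pb, both on a dry-weight
#' mg/kg basis: `BCF = Pb_veg / Pb_soil`. A BCF strictly greater than 1
#' marks a hyperaccumulator; the flag is attached as the
#' `"hyperaccumulator"` attribute.
#'
#' @param pb_veg total vegetable Pb (mg/kg dry weight), >= 0.
#' @param pb_soil total soil Pb (mg/kg), > 0.
#' @return numeric BCF with logical attribute `hyperaccumulator`.
#' @export
#' @examples
#' compute_bcf(9.72, 557.2)  # 0.0174
compute_bcf <- function(pb_veg, pb_soil) {
  if (any(!is.finite(pb_soil)) || any(pb_soil <= 0)) {
    stop("`pb_soil` must be > 0", call. = FALSE)
  }
  assert_nonnegative(pb_veg, "pb_veg")
  bcf <- pb_veg / pb_soil
  attr(bcf, "hyperaccumulator") <- bcf > 1  # strict: BCF == 1 is not flagged
  bcf
}

#' Regulatory guideline set
#'
#' Screening limits for soil and crop Pb: the soil screening value defaults
#' to the UK Category 4 Screening Level for allotments (80 mg/kg), and the
#' food limits to the international maxima of 0.3 mg/kg for leaf vegetables
#' and 0.1 mg/kg for root/bulb vegetables, with the crop-category map
#' lettuce -> leaf; carrot, garlic -> root/bulb.
#'
#' @param soil_limit soil screening value (mg/kg).
#' @param leaf_limit leaf-vegetable food limit (mg/kg).
#' @param root_bulb_limit root/bulb-vegetable food limit (mg/kg).
#' @param categories named character vector mapping each crop to `"leaf"` or
#'   `"root_bulb"`.
#' @return an object of class `guideline_set`.
#' @export
guideline_set <- function(soil_limit = 80,
                          leaf_limit = 0.3,
                          root_bulb_limit = 0.1,
                          categories = c(lettuce = "leaf",
                                         carrot = "root_bulb",
                                         garlic = "root_bulb")) {
  assert_positive(soil_limit, "soil_limit")
  assert_positive(leaf_limit, "leaf_limit")
  assert_positive(root_bulb_limit, "root_bulb_limit")
  if (!all(categories %in% c("leaf", "root_bulb"))) {
    stop("crop categories must be 'leaf' or 'root_bulb'", call. = FALSE)
  }
  structure(
    list(
      soil_limit = soil_limit,
      food_limits = c(leaf = leaf_limit, root_bulb = root_bulb_limit),
      categories = categories
    ),
    class = "guideline_set"
  )
}

#' Screen measurements against regulatory guidelines
#'
#' Flags soil and vegetable concentrations exceeding their limits.
#' Exceedance is strict (`value > limit`); a value exactly at the limit
#' passes. Food limits are compared against dry-weight vegetable
#' concentrations by default; `basis = "fresh"` first converts with the
#' crop's dry-to-fresh factor `C` (fresh = dry x C), the conventional basis
#' for the food limits.
#'
#' @param measurements a data frame with columns `agrisystem` and
#'   `pb_soil_total_mgkg`, plus `pb_veg_total_mgkg` for crop rows.
#' @param guidelines a [guideline_set()].
#' @param basis `"dry"` (default) or `"fresh"`.
#' @param params an [exposure_parameters()] supplying the `C` factors when
#'   `basis = "fresh"`.
#' @return the input with added columns `soil_exceeds`, `soil_margin`
#'   (value - limit), `veg_limit`, `veg_exceeds`, `veg_margin` (`NA` for
#'   no-crop rows).
#' @export
screen_guidelines <- function(measurements, guidelines = guideline_set(),
                              basis = c("dry", "fresh"),
                              params = exposure_parameters()) {
  basis <- match.arg(basis)
  stopifnot(inherits(guidelines, "guideline_set"))
  df <- tibble::as_tibble(measurements)

  crops <- setdiff(unique(df$agrisystem), "no_crop")
  unmapped <- setdiff(crops, names(guidelines$categories))
  if (length(unmapped) > 0) {
    stop("no guideline category for crop(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }

  df$soil_exceeds <- df$pb_soil_total_mgkg > guidelines$soil_limit
  df$soil_margin <- df$pb_soil_total_mgkg - guidelines$soil_limit

  is_crop <- df$agrisystem != "no_crop"
  veg_limit <- rep(NA_real_, nrow(df))
  veg_value <- rep(NA_real_, nrow(df))
  if (any(is_crop)) {
    cat_i <- guidelines$categories[df$agrisystem[is_crop]]
    veg_limit[is_crop] <- guidelines$food_limits[cat_i]
    value <- df$pb_veg_total_mgkg[is_crop]
    if (basis == "fresh") {
      value <- value * params$C[df$agrisystem[is_crop]]
    }
    veg_value[is_crop] <- value
  }
  df$veg_limit <- veg_limit
  df$veg_exceeds <- veg_value > veg_limit
  df$veg_margin <- veg_value - veg_limit
  df
}
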