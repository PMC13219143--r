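#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Fixed vocabularies of the 2 x 2 x 4 pot-experiment design.
AGRISYSTEMS <- c("no_crop", "lettuce", "carrot", "garlic")
PB_CONDITIONS <- c("high", "low")
AMENDMENTS <- c("control", "biochar")
CROPS <- c("lettuce", "carrot", "garlic")

## Treatment short codes used throughout the risk tables:
## HNB = high Pb / no biochar, HB = high Pb / biochar,
## LNB = low Pb / no biochar, LB = low Pb / biochar.
TREATMENT_CODES <- c("HNB", "HB", "LNB", "LB")

#' Treatment short code from condition and amendment
#'
#' Maps (pb_condition, amendment) pairs onto the conventional four-letter
#' treatment codes: `HNB` (high Pb, control), `HB` (high Pb, biochar),
#' `LNB` (low Pb, control), `LB` (low Pb, biochar).
#'
#' @param pb_condition character vector, `"high"` or `"low"`.
#' @param amendment character vector, `"control"` or `"biochar"`.
#' @return character vector of treatment codes.
#' @export
#' @examples
#' treatment_code("high", "control")  # "HNB"
treatment_code <- function(pb_condition, amendment) {
  stopifnot(all(pb_condition %in% PB_CONDITIONS), all(amendment %in% AMENDMENTS))
  paste0(
    ifelse(pb_condition == "high", "H", "L"),
    ifelse(amendment == "control", "NB", "B")
  )
}

#' The full treatment design grid
#'
#' One row per treatment cell of the pot experiment: 4 agrisystems
#' (no-crop, lettuce, carrot, garlic) crossed with 2 Pb conditions and
#' 2 amendment levels, in the fixed reporting order used by the risk
#' tables (agrisystems in the order above; within each, HNB, HB, LNB, LB).
#'
#' @return a tibble with columns `agrisystem`, `pb_condition`, `amendment`,
#'   `treatment`.
#' @export
treatment_grid <- function() {
  grid <- expand.grid(
    amendment = AMENDMENTS,
    pb_condition = PB_CONDITIONS,
    agrisystem = AGRISYSTEMS,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("agrisystem", "pb_condition", "amendment")]
  grid$treatment <- treatment_code(grid$pb_condition, grid$amendment)
  tibble::as_tibble(grid)
}

## Orders a data frame by the canonical reporting order.
order_cells <- function(df) {
  df[order(
    match(df$agrisystem, AGRISYSTEMS),
    match(df$treatment, TREATMENT_CODES)
  ), , drop = FALSE]
}
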