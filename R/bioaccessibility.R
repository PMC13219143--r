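#' Bioaccessible fraction (BAF)
#'
#' The fraction of the total Pb concentration solubilised under simulated
#' digestion: `BAF = BAC / total x 100%`. Values above 100% indicate a
#' measurement inconsistency (the assay recovered more Pb than the total
#' digest); these are returned unchanged but flagged via the
#' `"inconsistent"` attribute and a warning, never clipped.
#'
#' @param bac bioaccessible concentration (mg/kg), >= 0.
#' @param total total concentration (mg/kg), > 0.
#' @return numeric vector of percentages, with attribute `inconsistent`
#'   (logical, `TRUE` where BAF > 100).
#' @export
#' @examples
#' compute_baf(260.9, 557.2)  # 46.82 %
compute_baf <- function(bac, total) {
  if (any(!is.finite(total)) || any(total <= 0)) {
    stop("`total` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(bac)) || any(bac < 0)) {
    stop("`bac` must be >= 0", call. = FALSE)
  }
  baf <- bac / total * 100
  inconsistent <- baf > 100
  if (any(inconsistent)) {
    warning(sum(inconsistent),
            " BAF value(s) exceed 100% (bioaccessible > total); flagged, not clipped",
            call. = FALSE)
  }
  attr(baf, "inconsistent") <- inconsistent
  baf
}

#' Select an extraction phase from UBM records
#'
#' The in vitro assay yields two sequential phases. The default policy keeps
#' gastric-phase records only — the worst-case (highest solubilisation)
#' convention for risk analysis; `"gastrointestinal"` keeps the other phase.
#'
#' @param records a data frame with a `phase` column taking values
#'   `"gastric"` or `"gastrointestinal"`.
#' @param policy `"gastric"` (default) or `"gastrointestinal"`.
#' @return the filtered records; warns if the result is empty.
#' @export
select_phase <- function(records, policy = c("gastric", "gastrointestinal")) {
  policy <- tryCatch(match.arg(policy), error = function(e) {
    stop("unknown phase policy: ", paste(policy, collapse = ", "), call. = FALSE)
  })
  if (!"phase" %in% names(records)) {
    stop("records must carry a `phase` column", call. = FALSE)
  }
  bad <- setdiff(unique(records$phase), c("gastric", "gastrointestinal"))
  if (length(bad) > 0) {
    stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- records[records$phase == policy, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no records match phase policy '", policy, "'", call. = FALSE)
  }
  out
}

#' Batch quality-control evaluation for UBM records
#'
#' Computes the three batch QC metrics used with the assay: certified
#' reference recovery (measured / certified x 100, averaged over reference
#' records), duplicate relative standard deviation (SD / mean x 100 per
#' duplicated `sample_id`, then averaged across pairs), and the
#' blank-to-sample ratio (mean blank concentration / mean sample
#' concentration x 100). Each metric is compared against a configurable
#' threshold to produce pass/fail flags.
#'
#' @param batch a data frame of role-labelled records with columns
#'   `sample_id`, `role` (`sample`, `blank`, `reference`, `duplicate`) and
#'   `pb_bac_mgkg`. Duplicate records share a `sample_id` with the sample
#'   row they duplicate.
#' @param certified certified reference concentration (mg/kg) for the
#'   reference material.
#' @param thresholds list with `recovery` (acceptable % range, length 2),
#'   `rsd_max` (max duplicate RSD %), `blank_max` (max blank ratio %).
#' @return a list of class `qc_report`: `recovery_pct`, `duplicate_rsd_pct`,
#'   `blank_ratio_pct`, and logical `flags` (`NA` where a metric could not
#'   be computed, e.g. no reference record).
#' @export
qc_evaluate <- function(batch, certified,
                        thresholds = list(recovery = c(70, 130),
                                          rsd_max = 10,
                                          blank_max = 5)) {
  required <- c("sample_id", "role", "pb_bac_mgkg")
  missing_cols <- setdiff(required, names(batch))
  if (length(missing_cols) > 0) {
    stop("QC batch is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  assert_positive(certified, "certified")

  refs <- batch$pb_bac_mgkg[batch$role == "reference"]
  recovery <- if (length(refs) == 0) NA_real_ else mean(refs / certified * 100)

  ## duplicate pairs: the duplicate row plus the sample row with the same id
  dup_ids <- unique(batch$sample_id[batch$role == "duplicate"])
  if (length(dup_ids) == 0) {
    rsd <- NA_real_
  } else {
    per_pair <- vapply(dup_ids, function(id) {
      vals <- batch$pb_bac_mgkg[batch$sample_id == id &
                                  batch$role %in% c("sample", "duplicate")]
      if (length(vals) < 2) return(NA_real_)
      m <- mean(vals)
      if (m == 0) return(0)
      stats::sd(vals) / m * 100
    }, numeric(1))
    rsd <- mean(per_pair, na.rm = TRUE)
  }

  blanks <- batch$pb_bac_mgkg[batch$role == "blank"]
  samples <- batch$pb_bac_mgkg[batch$role == "sample"]
  blank_ratio <- if (length(blanks) == 0 || length(samples) == 0) {
    NA_real_
  } else {
    mean(blanks) / mean(samples) * 100
  }

  flag <- function(value, ok) if (is.na(value)) NA else ok
  structure(
    list(
      recovery_pct = recovery,
      duplicate_rsd_pct = rsd,
      blank_ratio_pct = blank_ratio,
      flags = list(
        recovery = flag(recovery, !is.na(recovery) &&
                          recovery >= thresholds$recovery[1] &&
                          recovery <= thresholds$recovery[2]),
        duplicate_rsd = flag(rsd, !is.na(rsd) && rsd <= thresholds$rsd_max),
        blank_ratio = flag(blank_ratio,
                           !is.na(blank_ratio) && blank_ratio <= thresholds$blank_max)
      ),
      thresholds = thresholds
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "missing" else sprintf("%.2f%%", v)
  cat("UBM batch QC report\n")
  cat("  reference recovery: ", fmt(x$recovery_pct), "\n", sep = "")
  cat("  duplicate RSD:      ", fmt(x$duplicate_rsd_pct), "\n", sep = "")
  cat("  blank/sample ratio: ", fmt(x$blank_ratio_pct), "\n", sep = "")
  invisible(x)
}
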