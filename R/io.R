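MEASUREMENT_COLUMNS <- c(
  "sample_id", "agrisystem", "pb_condition", "amendment", "replicate",
  "pb_soil_total_mgkg", "pb_bac_gastric_mgkg", "pb_bac_gi_mgkg",
  "pb_veg_total_mgkg"
)

#' Read and validate a replicate-level measurement table
#'
#' Reads the CSV schema written by [write_measurements()] /
#' [generate_dataset()] and validates it: required columns present,
#' categorical fields drawn from their fixed vocabularies, concentrations
#' non-negative, the (agrisystem, pb_condition, amendment, replicate) key
#' unique, and vegetable Pb present exactly for crop rows (empty only for
#' no-crop). Violations are reported with the offending CSV line numbers
#' (header = line 1).
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return a validated measurement tibble.
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("measurement file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_measurements(df)
}

#' Validate an in-memory measurement table
#'
#' @param df a data frame with the measurement schema.
#' @return the validated tibble; stops with per-line messages otherwise.
#' @export
validate_measurements <- function(df) {
  df <- tibble::as_tibble(df)
  line <- seq_len(nrow(df)) + 1L  # CSV line numbers; header is line 1
  problems <- character(0)
  note <- function(lines, msg) {
    sprintf("line %d: %s", lines, msg)
  }

  bad <- !df$agrisystem %in% AGRISYSTEMS
  if (any(bad)) {
    problems <- c(problems, note(line[bad], paste0(
      "bad agrisystem '", df$agrisystem[bad], "'")))
  }
  bad <- !df$pb_condition %in% PB_CONDITIONS
  if (any(bad)) {
    problems <- c(problems, note(line[bad], paste0(
      "bad pb_condition '", df$pb_condition[bad], "'")))
  }
  bad <- !df$amendment %in% AMENDMENTS
  if (any(bad)) {
    problems <- c(problems, note(line[bad], paste0(
      "bad amendment '", df$amendment[bad], "'")))
  }
  for (col in c("pb_soil_total_mgkg", "pb_bac_gastric_mgkg",
                "pb_bac_gi_mgkg", "pb_veg_total_mgkg")) {
    bad <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(bad)) {
      problems <- c(problems, note(line[bad], paste0("negative ", col)))
    }
  }
  bad <- is.na(df$pb_soil_total_mgkg) | is.na(df$pb_bac_gastric_mgkg)
  if (any(bad)) {
    problems <- c(problems, note(line[bad], "missing soil concentration"))
  }
  is_crop <- df$agrisystem %in% AGRISYSTEMS & df$agrisystem != "no_crop"
  bad <- is_crop & is.na(df$pb_veg_total_mgkg)
  if (any(bad)) {
    problems <- c(problems, note(line[bad], "crop row missing pb_veg_total_mgkg"))
  }
  bad <- df$agrisystem == "no_crop" & !is.na(df$pb_veg_total_mgkg)
  if (any(bad)) {
    problems <- c(problems, note(line[bad], "no_crop row carries a vegetable value"))
  }
  key <- paste(df$agrisystem, df$pb_condition, df$amendment, df$replicate)
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- c(problems, note(line[dup], "duplicate treatment/replicate key"))
  }

  if (length(problems) > 0) {
    stop("invalid measurement table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Write a measurement table to CSV
#'
#' @param df a measurement tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_measurements <- function(df, path) {
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Render publication-style risk tables
#'
#' Formats the per-cell aggregation into the three headline tables
#' (soil-only, vegetable-only, combined) with ADI/THQ/CR in
#' 3-significant-figure scientific notation, plus the signed percent change
#' of mean ADI from the control to the biochar treatment within each
#' (agrisystem, Pb condition) pair, printed on the control row. A missing
#' biochar cell leaves the percent change missing, not 0.
#'
#' @param agg output of [aggregate_treatment()].
#' @return a named list of three tibbles (`soil`, `vegetable`, `combined`)
#'   with columns `agrisystem`, `treatment`, `ADI`, `THQ`, `CR`,
#'   `pct_change`.
#' @export
render_risk_tables <- function(agg) {
  render_one <- function(sub) {
    sub <- order_cells(sub)
    pct <- rep(NA_real_, nrow(sub))
    for (i in seq_len(nrow(sub))) {
      if (sub$amendment[i] != "control") next
      j <- which(sub$agrisystem == sub$agrisystem[i] &
                   sub$pb_condition == sub$pb_condition[i] &
                   sub$amendment == "biochar")
      if (length(j) == 1) {
        pct[i] <- percent_change(sub$adi_mean[j], sub$adi_mean[i])
      }
    }
    tibble::tibble(
      agrisystem = sub$agrisystem,
      treatment = sub$treatment,
      ADI = format_sci(sub$adi_mean),
      THQ = format_sci(sub$thq_mean),
      CR = format_sci(sub$cr_mean),
      pct_change = ifelse(is.na(pct), NA_character_, sprintf("%+.1f", pct))
    )
  }
  list(
    soil = render_one(agg[agg$pathway == "soil", ]),
    vegetable = render_one(agg[agg$pathway == "vegetable", ]),
    combined = render_one(agg[agg$pathway == "combined", ])
  )
}

PIPELINE_STAGES <- c("simulate", "bioaccessibility", "transfer",
                     "exposure_risk", "uncertainty")

#' Run the full risk-assessment pipeline
#'
#' Executes the requested stages in their fixed order — simulate (or load) a
#' measurement table, bioaccessibility accounting and QC, transfer factors
#' and guideline screening, deterministic risk tables, Monte Carlo
#' uncertainty — and writes every output plus a run log under `out_dir`.
#' Identical configuration and seed reproduce an identical bundle.
#'
#' @param config a named list, or a path to a YAML/JSON file, with entries:
#'   `out_dir` (required); `seed` (default 1); `stages` (default all);
#'   `input_csv` (path to measurements; omitted = synthetic generation);
#'   `phase` (`"gastric"` default); `iterations` (MC draws, default 10000);
#'   `replicates` (synthetic replicates per cell, default 3); `qc_csv` and
#'   `qc_certified` (optional UBM QC batch).
#' @return invisibly, a list with the measurement table, aggregation, tables
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config must name `out_dir`", call. = FALSE)
  stages <- config$stages %||% PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0) {
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  seed <- as.integer(config$seed %||% 1L)
  phase <- config$phase %||% "gastric"
  iterations <- config$iterations %||% 10000
  params <- exposure_parameters()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## input: synthetic generation or a provided CSV
  if ("simulate" %in% stages || is.null(config$input_csv)) {
    measurements <- run_stage("simulate", {
      spec <- synthetic_spec(replicates = config$replicates %||% 3L,
                             seed = seed)
      generate_dataset(spec)
    })
    paths$measurements <- file.path(config$out_dir, "measurements.csv")
    write_measurements(measurements, paths$measurements)
  } else {
    measurements <- run_stage("load", read_measurements(config$input_csv))
  }

  out <- list(measurements = measurements, paths = paths)

  if ("bioaccessibility" %in% stages) {
    run_stage("bioaccessibility", {
      baf_g <- suppressWarnings(
        compute_baf(measurements$pb_bac_gastric_mgkg,
                    measurements$pb_soil_total_mgkg))
      baf_gi <- suppressWarnings(
        compute_baf(measurements$pb_bac_gi_mgkg,
                    measurements$pb_soil_total_mgkg))
      baf_tab <- tibble::tibble(
        sample_id = measurements$sample_id,
        baf_gastric_pct = as.numeric(baf_g),
        baf_gi_pct = as.numeric(baf_gi),
        inconsistent = attr(baf_g, "inconsistent")
      )
      out$baf <- baf_tab
      paths$baf <- file.path(config$out_dir, "baf.csv")
      readr::write_csv(baf_tab, paths$baf)

      if (!is.null(config$qc_csv)) {
        batch <- readr::read_csv(config$qc_csv, show_col_types = FALSE,
                                 progress = FALSE)
        qc <- qc_evaluate(batch, certified = config$qc_certified)
      } else {
        ## no QC rows available: metrics report as missing, never zero
        batch <- tibble::tibble(sample_id = measurements$sample_id,
                                role = "sample",
                                pb_bac_mgkg = measurements$pb_bac_gastric_mgkg)
        qc <- qc_evaluate(batch, certified = config$qc_certified %||% 1)
      }
      out$qc <- qc
      paths$qc <- file.path(config$out_dir, "qc_report.txt")
      writeLines(utils::capture.output(print(qc)), paths$qc)
    })
  }

  if ("transfer" %in% stages) {
    run_stage("transfer", {
      screened <- screen_guidelines(measurements, params = params)
      crop_rows <- screened$agrisystem != "no_crop"
      bcf <- rep(NA_real_, nrow(screened))
      bcf[crop_rows] <- as.numeric(compute_bcf(
        screened$pb_veg_total_mgkg[crop_rows],
        screened$pb_soil_total_mgkg[crop_rows]))
      screened$bcf <- bcf
      screened$hyperaccumulator <- !is.na(bcf) & bcf > 1
      out$transfer <- screened
      paths$transfer <- file.path(config$out_dir, "transfer_screening.csv")
      readr::write_csv(screened, paths$transfer)
    })
  }

  if ("exposure_risk" %in% stages) {
    run_stage("exposure_risk", {
      agg <- aggregate_treatment(measurements, params, phase)
      tables <- render_risk_tables(agg)
      out$aggregation <- agg
      out$tables <- tables
      paths$aggregation <- file.path(config$out_dir, "risk_aggregation.csv")
      readr::write_csv(agg, paths$aggregation)
      for (nm in names(tables)) {
        p <- file.path(config$out_dir, paste0("risk_table_", nm, ".csv"))
        paths[[paste0("table_", nm)]] <- p
        readr::write_csv(tables[[nm]], p, na = "")
      }
    })
  }

  if ("uncertainty" %in% stages) {
    run_stage("uncertainty", {
      mc <- run_monte_carlo_grid(measurements, iterations = iterations,
                                 seed = seed, params = params, phase = phase)
      out$mc <- mc
      paths$mc <- file.path(config$out_dir, "mc_summary.csv")
      readr::write_csv(mc, paths$mc)

      sens_rows <- lapply(attr(mc, "results"), function(res) {
        rank_tab <- sensitivity_analysis(res, "swing")
        tibble::tibble(treatment = res$treatment, pathway = res$pathway,
                       parameter = rank_tab$parameter, score = rank_tab$score,
                       rank = rank_tab$rank)
      })
      sens <- dplyr::bind_rows(sens_rows)
      out$sensitivity <- sens
      paths$sensitivity <- file.path(config$out_dir, "sensitivity.csv")
      readr::write_csv(sens, paths$sensitivity)
    })
  }

  ## run log: configuration actually used (no timestamps, so identical
  ## config + seed yields a byte-identical bundle)
  paths$log <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    paste0("pbagrisk ", as.character(utils::packageVersion("pbagrisk"))),
    paste0("seed: ", seed),
    paste0("phase: ", phase),
    paste0("iterations: ", iterations),
    paste0("stages: ", paste(stages, collapse = ", ")),
    paste0("EF=", params$EF, " ED=", params$ED, " IR_soil=", params$IR_soil,
           " IR_veg=", params$IR_veg, " BW=", params$BW, " AT=", params$AT),
    paste0("RBA=", params$RBA, " RfD=", params$RfD, " CSF=", params$CSF),
    paste0("C: ", paste(names(params$C), params$C, sep = "=", collapse = ", "))
  ), paths$log)

  out$paths <- paths
  invisible(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
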