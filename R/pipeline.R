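#' Load the packaged patient-characteristics table
#'
#' The 26-patient cohort table shipped with the package: sex, age, disease
#' duration, preoperative UPDRS-III on/off medication, levodopa equivalent
#' daily dose, motor subtype (AR = akinetic-rigid, T = tremor-dominant),
#' main disabling symptoms and the chronic stimulation contact labels per
#' lead (C0--C3 left, C8--C11 right).
#'
#' @param path optional CSV path; defaults to the packaged fixture.
#' @return validated data.frame with 26 rows.
#' @export
load_table1 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "patient_table.csv", package = "stnbeta")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "sex", "age", "duration_y", "updrs3_on_med",
            "updrs3_off_med", "ledd", "subtype", "main_symptoms",
            "contact_left", "contact_right")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("patient table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(df) == 0) stopf("patient table is empty")
  if (!all(df$subtype %in% c("AR", "T"))) stopf("subtype must be AR or T")
  # contact labels must be valid for their side
  invisible(contact_index(df$contact_left, "left"))
  invisible(contact_index(df$contact_right, "right"))
  df
}

#' Cohort summary statistics
#'
#' Mean and sample (n - 1) SD of age, disease duration and OFF-medication
#' UPDRS-III, plus sex and motor-subtype counts, computed from a patient
#' table as loaded by \code{\link{load_table1}}.
#'
#' @param tbl patient table.
#' @return list of summary statistics.
#' @export
cohort_summary <- function(tbl) {
  if (nrow(tbl) == 0) stopf("empty patient table")
  ms <- function(x) c(mean = mean(x), sd = stats::sd(x))
  list(n = nrow(tbl),
       age = ms(tbl$age),
       duration = ms(tbl$duration_y),
       updrs3_off_med = ms(tbl$updrs3_off_med),
       updrs3_on_med = ms(tbl$updrs3_on_med),
       n_women = sum(tbl$sex == "F"),
       n_tremor_dominant = sum(tbl$subtype == "T"))
}

#' Extract normalized spectral features from one recording
#'
#' Runs the estimation chain on a single side: common-average reference,
#' artifact-window screening, LOWESS detrending, Welch PSD, relative-power
#' normalization, band powers, per-band maxima across contacts, and the
#' 10--35 Hz peak frequency of the broad-beta argmax contact.
#'
#' @param rec an \code{lfp_recording}.
#' @param pp_cfg a \code{preprocess_config}.
#' @return one-row data.frame of \code{power_*}, \code{contact_*} per band,
#'   \code{peak_freq_hz}, \code{n_segments}, \code{n_rejected_windows}.
#' @export
extract_side_features <- function(rec, pp_cfg = preprocess_config()) {
  pp <- preprocess_recording(rec, pp_cfg)
  psd <- compute_psd(pp$recording, accepted = pp$accepted)
  spec <- normalize_spectrum(psd)
  bp <- band_powers(spec)
  out <- data.frame(patient_id = rec$patient_id, side = rec$side,
                    stringsAsFactors = FALSE)
  for (bn in band_definitions()$band) {
    mx <- max_across_contacts(bp, bn)
    out[[paste0("power_", bn)]] <- mx$power
    out[[paste0("contact_", bn)]] <- mx$contact_index
    out[[paste0("tie_", bn)]] <- mx$tie
  }
  pk <- peak_frequency(spec, c(10, 35), contact = out$contact_broad_beta)
  out$peak_freq_hz <- pk$peak_hz
  out$n_segments <- psd$n_segments
  out$n_rejected_windows <- length(pp$rejected)
  out
}

#' Assemble the analysis-ready side table
#'
#' Joins per-side spectral features, active-contact metadata, UPDRS-derived
#' efficacies (each STN paired with its contralateral hemibody) and patient
#' covariates into one row per quality-passing side, with contact distances
#' and inclusion flags.
#'
#' @param features data.frame of per-side features (\code{power_*},
#'   \code{contact_*}), keyed by \code{patient_id, side}.
#' @param sides side metadata with \code{patient_id, side, active_contact,
#'   poor_quality}.
#' @param updrs long UPDRS item table (see \code{\link{read_updrs}}).
#' @param metadata patient-level covariates.
#' @return data.frame with one row per analyzable side, efficacies in
#'   percent.
#' @export
assemble_cohort <- function(features, sides, updrs, metadata) {
  lead <- lead_model()
  tab <- merge(features, sides, by = c("patient_id", "side"))
  tab <- tab[!tab$poor_quality, , drop = FALSE]
  tab$side_id <- paste0(tab$patient_id, "_", tab$side)
  tab$dist_low_beta_mm <- contact_distance(tab$active_contact,
                                           tab$contact_low_beta, lead)
  tab$dist_high_beta_mm <- contact_distance(tab$active_contact,
                                            tab$contact_high_beta, lead)
  eff <- function(pid, hemi, domain) {
    sub <- function(stim) {
      ex <- updrs[updrs$patient == pid & updrs$med_state == "OFF" &
                    updrs$stim_state == stim, , drop = FALSE]
      if (nrow(ex) == 0) stopf("no med-OFF/stim-%s exam for %s", stim, pid)
      ss <- updrs_subscores(ex)
      ss[[domain]][ss$hemibody == hemi]
    }
    off <- sub("OFF"); on <- sub("ON")
    stimulation_efficacy(off, on, domain, hemi)
  }
  n <- nrow(tab)
  tab$eff_brady <- tab$eff_tremor <- tab$eff_axial <- NA_real_
  tab$tremor_included <- FALSE
  tab$tremor_off <- NA_real_
  for (i in seq_len(n)) {
    hemi <- contralateral_hemibody(tab$side[i])
    eb <- eff(tab$patient_id[i], hemi, "brady_rigidity")
    et <- eff(tab$patient_id[i], hemi, "tremor")
    ea <- eff(tab$patient_id[i], hemi, "axial")
    tab$eff_brady[i] <- eb$value
    tab$eff_tremor[i] <- et$value
    tab$eff_axial[i] <- ea$value
    tab$tremor_included[i] <- et$included
    ex_off <- updrs[updrs$patient == tab$patient_id[i] &
                      updrs$med_state == "OFF" &
                      updrs$stim_state == "OFF", , drop = FALSE]
    ss <- updrs_subscores(ex_off)
    tab$tremor_off[i] <- ss$tremor[ss$hemibody == hemi]
  }
  tab <- merge(tab, metadata, by = "patient_id")
  tab[order(tab$patient_id, tab$side), ]
}

#' Validate a cohort bundle on disk
#'
#' Checks every recording (4 contacts, labels consistent with the lead
#' side, equal channel lengths) and the UPDRS table (items 20--31 present
#' per patient, hemibody items on both sides, no negative scores). All
#' violations are collected and returned, never just the first.
#'
#' @param dir bundle directory as written by \code{\link{generate_cohort}}.
#' @return data.frame with columns \code{file, check, message}; zero rows
#'   when the bundle is clean.
#' @export
validate_inputs <- function(dir) {
  bad <- list()
  note <- function(file, check, message)
    bad[[length(bad) + 1]] <<- data.frame(file = file, check = check,
                                          message = message,
                                          stringsAsFactors = FALSE)
  sides_path <- file.path(dir, "sides.csv")
  if (!file.exists(sides_path)) {
    note("sides.csv", "exists", "side metadata file missing")
  } else {
    sides <- utils::read.csv(sides_path, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sides))) {
      f <- file.path(dir, "recordings", paste0(sides$side_id[i], ".csv"))
      if (!file.exists(f)) {
        if (!sides$poor_quality[i])
          note(basename(f), "exists", "recording file missing")
        next
      }
      hdr <- names(utils::read.csv(f, nrows = 1, check.names = FALSE))
      if (length(hdr) != 4)
        note(basename(f), "channels",
             sprintf("expected 4 contacts, found %d", length(hdr)))
      ok <- tryCatch({contact_index(hdr, sides$side[i]); TRUE},
                     error = function(e) e$message)
      if (!isTRUE(ok)) note(basename(f), "labels", ok)
    }
  }
  upd_path <- file.path(dir, "updrs.csv")
  if (!file.exists(upd_path)) {
    note("updrs.csv", "exists", "UPDRS table missing")
  } else {
    upd <- tryCatch(read_updrs(upd_path), error = function(e) e)
    if (inherits(upd, "error")) {
      note("updrs.csv", "schema", conditionMessage(upd))
    } else {
      for (pid in unique(upd$patient))
        for (stim in c("OFF", "ON")) {
          ex <- upd[upd$patient == pid & upd$med_state == "OFF" &
                      upd$stim_state == stim, , drop = FALSE]
          res <- tryCatch({updrs_subscores(ex); NULL},
                          error = function(e) conditionMessage(e))
          if (!is.null(res))
            note("updrs.csv", "completeness",
                 sprintf("%s stim-%s: %s", pid, stim, res))
        }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(file = character(), check = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' @param output_dir directory for the cohort bundle and result files.
#' @param seed root seed for the simulation stage.
#' @param sim a \code{sim_config}; its seed defaults to \code{seed}.
#' @param preprocess a \code{preprocess_config}.
#' @param stages subset of
#'   \code{c("simulate", "validate", "extract", "associate", "report")}.
#' @param strict abort on any per-side failure instead of collecting it.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(output_dir, seed = 1L, sim = NULL,
                       preprocess = preprocess_config(),
                       stages = c("simulate", "validate", "extract",
                                  "associate", "report"),
                       strict = FALSE) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(output_dir = output_dir, seed = as.integer(seed), sim = sim,
                 preprocess = preprocess, stages = stages, strict = strict),
            class = "run_config")
}

#' Run the pipeline end to end
#'
#' Stages, in order: \code{simulate} writes a synthetic cohort bundle;
#' \code{validate} checks it; \code{extract} estimates per-side spectral
#' features from the recordings; \code{associate} joins features with
#' UPDRS outcomes, computes the band-by-domain and covariate grids and the
#' two-predictor regression of bradykinesia-rigidity improvement (as a
#' fraction) on maximum high-beta power and contact distance;
#' \code{report} writes a markdown summary. Fully deterministic given the
#' seed.
#'
#' @param cfg a \code{run_config}.
#' @return invisibly, a list with the assembled cohort table, the two
#'   association grids and the \code{regression_result} (elements are NULL
#'   for stages not run).
#' @export
run_pipeline <- function(cfg) {
  dir <- cfg$output_dir
  res <- list(cohort = NULL, table2 = NULL, table3 = NULL, regression = NULL,
              validation = NULL)
  if ("simulate" %in% cfg$stages)
    generate_cohort(cfg$sim, dir)
  if ("validate" %in% cfg$stages) {
    res$validation <- validate_inputs(dir)
    if (cfg$strict && nrow(res$validation) > 0)
      stopf("validation failed: %s (%s)", res$validation$message[1],
            res$validation$file[1])
  }
  if ("extract" %in% cfg$stages) {
    sides <- utils::read.csv(file.path(dir, "sides.csv"),
                             stringsAsFactors = FALSE)
    feats <- list()
    for (i in seq_len(nrow(sides))) {
      if (sides$poor_quality[i]) next
      f <- file.path(dir, "recordings", paste0(sides$side_id[i], ".csv"))
      row <- tryCatch({
        rec <- read_lfp_csv(f, cfg$sim$fs, sides$patient_id[i],
                            sides$side[i])
        extract_side_features(rec, cfg$preprocess)
      }, error = function(e) e)
      if (inherits(row, "error")) {
        if (cfg$strict) stopf("extract failed for side %s: %s",
                              sides$side_id[i], conditionMessage(row))
        warning(sprintf("side %s skipped: %s", sides$side_id[i],
                        conditionMessage(row)))
        next
      }
      feats[[length(feats) + 1]] <- row
    }
    features <- do.call(rbind, feats)
    utils::write.csv(features, file.path(dir, "features.csv"),
                     row.names = FALSE)
  }
  if ("associate" %in% cfg$stages) {
    features <- utils::read.csv(file.path(dir, "features.csv"),
                                stringsAsFactors = FALSE)
    sides <- utils::read.csv(file.path(dir, "sides.csv"),
                             stringsAsFactors = FALSE)
    updrs <- read_updrs(file.path(dir, "updrs.csv"))
    meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                            stringsAsFactors = FALSE)
    cohort <- assemble_cohort(features, sides, updrs, meta)
    utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
    res$cohort <- cohort
    res$table2 <- run_table2(cohort)
    res$table3 <- run_table3(cohort)
    utils::write.csv(res$table2, file.path(dir, "band_domain_grid.csv"),
                     row.names = FALSE)
    utils::write.csv(res$table3, file.path(dir, "covariate_grid.csv"),
                     row.names = FALSE)
    res$regression <- ols_fit(cohort$eff_brady / 100,
                              cohort[, c("power_high_beta",
                                         "dist_high_beta_mm")])
    reg <- res$regression
    class(reg) <- NULL
    jsonlite::write_json(reg, file.path(dir, "regression.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if ("report" %in% cfg$stages && !is.null(res$cohort)) {
    lines <- c(
      "# Cohort analysis report", "",
      sprintf("Analyzable sides: %d", nrow(res$cohort)),
      sprintf("Tremor analysis set: %d sides",
              sum(res$cohort$tremor_included)),
      sprintf("Axial analysis set: %d patients",
              length(unique(res$cohort$patient_id))), "",
      "## Regression (brady-rigidity improvement fraction)",
      sprintf("R^2 = %.3f, F(%d, %d) = %.3f, p = %.3g",
              res$regression$r_squared, res$regression$df1,
              res$regression$df2, res$regression$f_stat,
              res$regression$p_overall), "",
      "## Band-by-domain grid", "",
      paste(utils::capture.output(print(res$table2, digits = 3)),
            collapse = "\n"))
    writeLines(lines, file.path(dir, "report.md"))
  }
  invisible(res)
}
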