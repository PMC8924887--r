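#' Read and write session signal files
#'
#' Signals are stored as plain CSV with columns `time_s`, `ecg_mv`,
#' `pulse_au`.  On reading, the sampling rate is inferred from the median
#' time step; non-monotone time, missing columns, or runs of missing
#' samples longer than 1 s are rejected with informative errors.
#'
#' @param path File path.
#' @return `read_signal_csv` returns a list with `time`, `ecg`, `pulse`,
#'   `fs`.
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ecg_mv", "pulse_au")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("signal file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stop("non-monotone time in ", path, " at row(s) ",
         paste(utils::head(which(dt <= 0) + 1L, 5), collapse = ", "))
  }
  fs <- 1 / stats::median(dt)
  for (col in c("ecg_mv", "pulse_au")) {
    na <- is.na(df[[col]])
    if (any(na)) {
      r <- rle(na)
      run_len <- max(r$lengths[r$values])
      if (run_len > fs) {
        first_bad <- which(na)[1]
        stop("run of ", run_len, " missing ", col, " samples (> 1 s) in ",
             path, " starting at row ", first_bad)
      }
      df[[col]][na] <- stats::approx(df$time_s[!na], df[[col]][!na],
                                     xout = df$time_s[na], rule = 2)$y
    }
  }
  list(time = df$time_s, ecg = df$ecg_mv, pulse = df$pulse_au,
       fs = round(fs, 6))
}

#' @rdname read_signal_csv
#' @param recording List with `time`, `ecg`, `pulse`.
#' @export
write_signal_csv <- function(recording, path) {
  utils::write.csv(data.frame(time_s = recording$time,
                              ecg_mv = recording$ecg,
                              pulse_au = recording$pulse),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write beat annotations as CSV
#'
#' One row per accepted R-peak: `beat_index`, `r_time_s`, `nn_ms` (interval
#' ending at this beat; `NA` for the first), `pat_ms` (`NA` unmatched),
#' `accepted_flag`.
#'
#' @param ann A `beat_annotations` list.
#' @param path File path.
#' @export
write_beats_csv <- function(ann, path) {
  n <- length(ann$r_times)
  nn <- rep(NA_real_, n)
  idx <- match(round(ann$nn_times, 9), round(ann$r_times, 9))
  nn[idx[!is.na(idx)]] <- ann$nn[!is.na(idx)]
  pat <- if (length(ann$pat) == n) ann$pat else rep(NA_real_, n)
  utils::write.csv(data.frame(beat_index = seq_len(n),
                              r_time_s = ann$r_times, nn_ms = nn,
                              pat_ms = pat,
                              accepted_flag = !is.na(nn) | seq_len(n) == 1L),
                   path, row.names = FALSE)
  invisible(path)
}

# Polynomial rolling hash over a string (mod 2^31 - 1); stamps outputs
# with a short config fingerprint.
string_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  string_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA))
}

#' Write a synthetic cohort bundle to disk
#'
#' Materializes a cohort as the on-disk layout consumed by
#' [run_pipeline()]: `profiles.csv`, `groups.csv`, `reference.csv`,
#' `bp.csv`, `ground_truth.json`, and one directory per subject holding
#' `rs.csv` / `pfs.csv` signal files (written only when `render = TRUE`).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param render Render and write raw waveform CSVs (slow for large
#'   cohorts; the statistical stages do not need them).
#' @param fs Sampling rate for rendered signals.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, render = FALSE, fs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$groups, file.path(dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$reference, file.path(dir, "reference.csv"),
                   row.names = FALSE)
  bp <- cohort$bp
  names(bp)[names(bp) == "sbp"] <- "sbp_mmhg"
  names(bp)[names(bp) == "dbp"] <- "dbp_mmhg"
  utils::write.csv(bp, file.path(dir, "bp.csv"), row.names = FALSE)
  jsonlite::write_json(list(groups = cohort$groups, targets = cohort$targets),
                       file.path(dir, "ground_truth.json"), digits = NA)
  if (render) {
    for (sid in names(cohort$beats)) {
      sdir <- file.path(dir, sid)
      dir.create(sdir, showWarnings = FALSE)
      for (state in names(cohort$beats[[sid]])) {
        rec <- render_session(cohort, sid, state, fs = fs)
        write_signal_csv(rec, file.path(sdir, paste0(tolower(state),
                                                     ".csv")))
      }
    }
  }
  invisible(dir)
}

#' Run the full fatigue-assessment pipeline
#'
#' Orchestrates every stage over a synthetic cohort (or one read back from
#' disk): beat annotation, phase measures, subparameter construction,
#' CMJ-based grouping, leave-one-out stump screening, and linear boundary
#' training, writing one artifact per stage into `out_dir` (each stamped
#' with the resolved-config hash).  By default the measurement stage uses
#' the cohort's stored beat-level series; with `detect = TRUE` the raw
#' waveforms are rendered and pushed through the full detection chain
#' instead, and subjects whose detection fails are excluded and listed in
#' `exclusions.csv`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param detect Run waveform rendering + detection (slow) instead of using
#'   stored beat annotations.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "measure", "features", "screen", "train", "report")`
#'   (stages are always executed in this order; earlier results are reused
#'   from memory).
#' @param feature_set Screened feature subset (default
#'   [reference_feature_set()]; `NULL` for the full grammar).
#' @param svm_cost Soft-margin cost for the boundary.
#' @return Invisibly, a list with `cohort`, `measures`, `features`,
#'   `groups`, `fit` (a [fatigue_classifier()]), `tables`, and `out_dir`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         detect = FALSE,
                         stages = c("simulate", "measure", "features",
                                    "screen", "train", "report"),
                         feature_set = reference_feature_set(),
                         svm_cost = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "pipeline.log")
  logline <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n", file = log_path,
        append = TRUE)
  }
  jsonlite::write_json(c(unclass(config), list(hash = hash)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  logline("simulate: cohort of", config$n_subjects, "subjects, seed",
          config$seed)
  cohort <- simulate_cohort(config)
  excl <- character(0)

  if (detect) {
    logline("detect: rendering + detection at", config$fs, "Hz")
    beats_dir <- file.path(out_dir, "beats")
    dir.create(beats_dir, showWarnings = FALSE)
    for (sid in names(cohort$beats)) {
      for (state in c("RS", "PFS")) {
        ann <- tryCatch({
          rec <- render_session(cohort, sid, state)
          annotate_beats(rec)
        }, error = function(e) e)
        if (inherits(ann, "error")) {
          logline("detect: excluding", sid, state, "-",
                  conditionMessage(ann))
          excl <- c(excl, paste(sid, state))
          cohort$beats[[sid]][[state]] <- NULL
        } else {
          cohort$beats[[sid]][[state]] <- ann
          write_beats_csv(ann, file.path(beats_dir,
                                         paste0(sid, "_", state, ".csv")))
        }
      }
      if (length(cohort$beats[[sid]]) < 2L) cohort$beats[[sid]] <- NULL
    }
    if (length(excl)) {
      utils::write.csv(data.frame(excluded = excl, config_hash = hash),
                       file.path(out_dir, "exclusions.csv"),
                       row.names = FALSE)
    }
  }

  out <- list(cohort = cohort, out_dir = out_dir, config_hash = hash)
  if (!any(c("measure", "features", "screen", "train", "report")
           %in% stages)) {
    return(invisible(out))
  }

  logline("measure: phase measures")
  meas <- cohort_measures(cohort)
  meas$config_hash <- hash
  utils::write.csv(meas, file.path(out_dir, "measures.csv"),
                   row.names = FALSE)
  out$measures <- meas
  if (!any(c("features", "screen", "train", "report") %in% stages)) {
    return(invisible(out))
  }

  logline("features: subparameter matrix")
  X <- feature_matrix(meas, feature_set = feature_set)
  utils::write.csv(cbind(subject_id = rownames(X), X, config_hash = hash),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(feature_dictionary(),
                       file.path(out_dir, "feature_dictionary.json"),
                       auto_unbox = TRUE)
  out$features <- X
  if (!any(c("screen", "train", "report") %in% stages)) {
    return(invisible(out))
  }

  logline("screen/train: grouping, stump screening, boundary")
  keep <- cohort$groups$subject_id %in% rownames(X)
  grp <- assign_groups(stats::setNames(cohort$groups$cmj_change[keep],
                                       cohort$groups$subject_id[keep]))
  utils::write.csv(grp, file.path(out_dir, "groups.csv"), row.names = FALSE)
  out$groups <- grp
  fit <- fatigue_classifier(X[grp$subject_id, , drop = FALSE], grp$label,
                            cost = svm_cost)
  scr <- fit$screening
  scr$config_hash <- hash
  utils::write.table(scr, file.path(out_dir, "screening.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(features = fit$features,
                            w1 = fit$boundary$w1, w2 = fit$boundary$w2,
                            b = fit$boundary$b, cost = svm_cost,
                            equation = fit$boundary$equation,
                            positive_class = "significant",
                            tie_rules = "leaf ties -> significant; threshold ties -> smaller",
                            config_hash = hash),
                       file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  out$fit <- fit

  if ("report" %in% stages) {
    logline("report: summary tables")
    tabs <- summary_tables(cohort$reference, meas, cohort$profiles)
    chg <- parameter_changes(cohort$reference, meas)
    cmat <- correlation_matrix(chg[, -1, drop = FALSE])
    utils::write.csv(tabs$reference,
                     file.path(out_dir, "reference_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(tabs$cardiovascular,
                     file.path(out_dir, "cv_summary.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cmat),
                     file.path(out_dir, "correlations.csv"))
    rep_md <- c(
      paste0("# Fatigue pipeline report (config ", hash, ")"),
      "", "## Top screened subparameters", "",
      utils::capture.output(print(utils::head(fit$screening, 5),
                                  row.names = FALSE)),
      "", "## Decision boundary", "", fit$boundary$equation, "")
    writeLines(rep_md, file.path(out_dir, "report.md"))
    out$tables <- tabs
  }
  invisible(out)
}
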