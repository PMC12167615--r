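#' Quantify one patient end to end
#'
#' Runs SUV conversion (if the input is an activity-concentration volume),
#' automated VOI placement in each organ at risk, and the tumour-burden
#' metrics, producing one cohort-table row.  A failing organ (missing mask,
#' organ too small) is recorded as `NA` with a warning and the run
#' continues, mirroring how missing organs are handled in practice
#' (splenectomy, parotids outside the field of view).
#'
#' @param pet A [pet_volume()] (activity or SUV).
#' @param organ_masks Named list of logical masks; expected names among
#'   `kidneys`, `liver`, `parotids`, `spleen`. A missing or `NULL` entry
#'   yields `NA` for that organ.
#' @param meta A [scan_meta()].
#' @param lesions Optional [lesion_set()]; when absent the burden columns
#'   are 0.
#' @param patient_id Identifier written into the row.
#' @param per_component,hot_mult,edge_margin_mm Placement options, see
#'   [place_and_measure()] and [organ_region()].
#' @return Object of class `patient_result`: `row` (one-row data frame with
#'   per-organ SUVmean and burden metrics), `measurements` (long data frame,
#'   one row per organ: suv_mean, center, score, median_score,
#'   n_candidates, flagged_hot), `placements` (list of
#'   [place_and_measure()] results).
#' @export
run_patient <- function(pet, organ_masks, meta, lesions = NULL,
                        patient_id = "P0001", per_component = FALSE,
                        hot_mult = 2, edge_margin_mm = 5) {
  stopifnot(inherits(pet, "pet_volume"), inherits(meta, "scan_meta"))
  suv <- if (pet$kind == "activity") to_suv(pet, meta) else pet

  placements <- list()
  meas <- list()
  suv_means <- stats::setNames(rep(NA_real_, length(.ORGANS)), .ORGANS)
  for (o in .ORGANS) {
    m <- organ_masks[[o]]
    if (is.null(m)) {
      warning(sprintf("organ '%s' missing; recorded as NA", o))
      next
    }
    res <- tryCatch({
      reg <- organ_region(o, m, edge_margin_mm = edge_margin_mm)
      place_and_measure(suv, reg, per_component = per_component,
                        hot_mult = hot_mult)
    }, error = function(e) {
      warning(sprintf("organ '%s' failed (%s); recorded as NA",
                      o, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    placements[[o]] <- res
    suv_means[[o]] <- res$suv_mean
    meas[[o]] <- data.frame(organ = o, suv_mean = res$suv_mean,
                            center_x_mm = res$center_world_mm[1],
                            center_y_mm = res$center_world_mm[2],
                            center_z_mm = res$center_world_mm[3],
                            n_candidates = res$n_candidates,
                            score = res$score,
                            median_score = res$median_score,
                            flagged_hot = res$flagged_hot)
  }

  tlv <- 0; tlu <- 0
  if (!is.null(lesions)) {
    tlv <- compute_tlv(lesions, suv$spacing)
    tlu <- compute_tlu(suv, lesions)
  }
  row <- data.frame(patient_id = patient_id,
                    kidneys = suv_means[["kidneys"]],
                    liver = suv_means[["liver"]],
                    parotids = suv_means[["parotids"]],
                    spleen = suv_means[["spleen"]],
                    tlv = tlv, tlu = tlu,
                    pct_injected = pct_injected_activity(tlu, meta))
  row$tlv_group <- stratify_tlv(row$tlv)
  structure(list(row = row,
                 measurements = do.call(rbind, meas),
                 placements = placements),
            class = "patient_result")
}

#' @export
print.patient_result <- function(x, ...) {
  cat("Patient", x$row$patient_id, "\n")
  print(x$row[, c("kidneys", "liver", "parotids", "spleen",
                  "tlv", "tlu", "pct_injected")], row.names = FALSE)
  invisible(x)
}

#' Run the cohort analysis and assemble the report bundle
#'
#' Thin orchestration over [run_cohort_analysis()]: validates the cohort
#' table, runs the analysis and attaches a run manifest (package version,
#' settings hash, timestamp).  Identical inputs and settings produce an
#' identical settings hash and identical numerical outputs.
#'
#' @param table Cohort data frame (one row per patient, see
#'   [run_cohort_analysis()]).
#' @param ... Passed to [run_cohort_analysis()].
#' @return A `cohort_report` with a `manifest` element.
#' @export
run_cohort <- function(table, ...) {
  if (!is.data.frame(table)) stop("cohort table must be a data frame")
  if (nrow(table) < 3L) stop("need at least 3 patients")
  if (nrow(table) < 10L)
    warning("fewer than 10 patients: correlations are low-powered")
  report <- run_cohort_analysis(table, ...)
  report$manifest <- list(
    package = "psmasink",
    version = as.character(utils::packageVersion("psmasink")),
    n_patients = nrow(table),
    settings_hash = .settings_hash(report$settings),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  report
}

.settings_hash <- function(settings) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(settings), f)
  unname(tools::md5sum(f))
}

#' Write a cohort report bundle to disk
#'
#' Emits tidy CSVs (`correlations.csv`, `strata.csv`, `strata_counts.csv`,
#' `organ_summary.csv`, `scatter.csv`) and a JSON manifest+summary
#' (`report.json`).  The timestamp in the manifest is the only
#' run-dependent field.
#'
#' @param report A `cohort_report` from [run_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$strata, file.path(dir, "strata.csv"),
                   row.names = FALSE)
  utils::write.csv(report$strata_counts, file.path(dir, "strata_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$organ_summary, file.path(dir, "organ_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$scatter, file.path(dir, "scatter.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(manifest = report$manifest,
         settings = report$settings[c("tumour_only", "quartile_type",
                                      "log_base", "n_patients")],
         organ_summary = report$organ_summary,
         correlations = report$correlations,
         strata_counts = report$strata_counts),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
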