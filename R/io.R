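#' Write a simulated cohort to a plain-text study bundle
#'
#' Serialises a [simulate_cohort()] result to a directory of long-format
#' CSV files plus a JSON manifest: subjects, per-site concentrations and
#' enrichments, blood flow, biopsies, plasma-protein enrichments,
#' hormones, meal/protocol metadata, and the simulation truth tables.
#' Times are integer minutes relative to the meal; all numeric values are
#' written at 6 significant digits, which is the comparison precision of
#' the determinism guarantees.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig <- function(df) dplyr::mutate(
    df, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  stack <- function(extract) {
    purrr::imap_dfr(cohort$subjects, function(s, key) {
      dplyr::bind_cols(
        s$subject[rep(1, nrow(extract(s))),
                  c("subject_id", "visit", "group")],
        extract(s)
      )
    })
  }
  tables <- list(
    subjects = cohort$index,
    concentrations = stack(function(s) s$concentrations),
    enrichments = stack(function(s) s$enrichments),
    flow = stack(function(s) s$flow),
    biopsies = stack(function(s) s$biopsy),
    plasma_proteins = stack(function(s) s$plasma_protein),
    hormones = stack(function(s) s$hormones),
    truth_fluxes = stack(function(s) s$truth$fluxes),
    truth_av = stack(function(s) s$truth$av),
    truth_fsr = stack(function(s) s$truth$fsr),
    truth_pars = stack(function(s) s$truth$pars)
  )
  meal <- cohort$config$meal
  tables$meal <- tibble::as_tibble(meal[c("casein_grams", "d5_to_tracee_ratio_r",
                                          "total_phe_ingested", "energy_kcal",
                                          "volume_ml", "ingestion_time")])
  tables$protocols <- purrr::imap_dfr(
    cohort$subjects,
    function(s, key) purrr::map_dfr(s$protocols, function(p) {
      tibble::tibble(subject_id = s$subject$subject_id, visit = s$subject$visit,
                     tracer_id = p$tracer_id, prime = p$prime,
                     continuous_rate_nominal = p$continuous_rate_nominal,
                     infusate_concentration = p$infusate_concentration,
                     pump_flow = p$pump_flow)
    })
  )
  files <- list()
  for (nm in names(tables)) {
    fn <- paste0(nm, ".csv")
    readr::write_csv(sig(tables[[nm]]), file.path(dir, fn), progress = FALSE)
    files[[nm]] <- fn
  }
  manifest <- list(schema_version = "1", seed = cohort$seed, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

.validate_series_times <- function(df, keys, file) {
  bad <- df |>
    dplyr::summarise(ok = !is.unsorted(.data$time, strictly = TRUE),
                     .by = dplyr::all_of(keys))
  if (any(!bad$ok)) {
    off <- bad[!bad$ok, keys, drop = FALSE]
    stop("read_study_bundle: non-monotone times in ", file, " for ",
         paste(utils::capture.output(print(utils::head(off, 3))), collapse = " "),
         call. = FALSE)
  }
}

#' Read a study bundle back from disk
#'
#' Reads the manifest and all CSV tables written by
#' [write_study_bundle()], validating the schema version, the referenced
#' files, site labels, time monotonicity within each series, and value
#' signs. Returns the tables as a named list of tibbles (class
#' `study_bundle`).
#'
#' @param dir Bundle directory.
#' @return A list of class `study_bundle`.
#' @export
read_study_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) {
    stop("read_study_bundle: no manifest.json in ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, "1")) {
    stop("read_study_bundle: unrecognised schema version '",
         manifest$schema_version, "'", call. = FALSE)
  }
  out <- list()
  for (nm in names(manifest$files)) {
    path <- file.path(dir, manifest$files[[nm]])
    if (!file.exists(path)) {
      stop("read_study_bundle: manifest references missing file ", path,
           call. = FALSE)
    }
    out[[nm]] <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  known_sites <- c("artery", "femoral_vein", "epigastric_vein", "antecubital")
  for (nm in c("concentrations", "enrichments")) {
    if (!is.null(out[[nm]]$site)) {
      bad <- setdiff(unique(out[[nm]]$site), known_sites)
      if (length(bad) > 0) {
        stop("read_study_bundle: unknown site label(s) in ", nm, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (!is.null(out$concentrations) &&
      any(out$concentrations$concentration < 0, na.rm = TRUE)) {
    stop("read_study_bundle: negative concentrations", call. = FALSE)
  }
  if (!is.null(out$flow)) {
    if (any(out$flow$flow <= 0, na.rm = TRUE)) {
      stop("read_study_bundle: non-positive blood flow", call. = FALSE)
    }
    .validate_series_times(out$flow, c("subject_id", "visit"), "flow.csv")
  }
  if (!is.null(out$concentrations)) {
    .validate_series_times(out$concentrations,
                           c("subject_id", "visit", "site", "analyte"),
                           "concentrations.csv")
  }
  if (!is.null(out$enrichments)) {
    .validate_series_times(out$enrichments,
                           c("subject_id", "visit", "site", "analyte",
                             "isotopologue"),
                           "enrichments.csv")
  }
  structure(c(out, list(seed = manifest$seed)), class = "study_bundle")
}
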