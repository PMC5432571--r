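#' Read a current trace from CSV
#'
#' Traces are stored as human-auditable CSV with header columns `time_s`,
#' `current_pA`, `voltage_mV`; extra metadata columns are preserved
#' untouched. Time must be strictly increasing.
#'
#' @param path CSV file path.
#' @return A `current_trace` tibble.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(paste0("trace file not found: ", path))
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "current_pA", "voltage_mV")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) {
    abort(paste0("trace is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(diff(tr$time_s) <= 0)
  if (length(bad) > 0) {
    abort(paste0("time column is not strictly increasing at row ",
                 bad[1] + 1L, "."))
  }
  sr <- 1 / stats::median(diff(tr$time_s))
  structure(tr, sample_rate = sr,
            class = c("current_trace", class(tr)))
}

#' Write a current trace to CSV
#'
#' @param trace A `current_trace` (or any data frame with the required
#'   columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  need <- c("time_s", "current_pA", "voltage_mV")
  if (!all(need %in% names(trace))) {
    abort(paste0("trace must have columns ", paste(need, collapse = ", "), "."))
  }
  readr::write_csv(as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' Write a cohort to disk (CSV traces + JSON manifest)
#'
#' One CSV per sweep plus a JSON manifest recording cell ids, file paths,
#' concentrations, quality metadata, the master seed and the ground-truth
#' block parameters — enough to regenerate or audit the cohort.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sw <- cohort$sweeps
  files <- character(nrow(sw))
  for (i in seq_len(nrow(sw))) {
    files[i] <- file.path(dir, sprintf("%s_%gul_%s_%s.csv", sw$cell[i],
                                       sw$conc_uM[i], sw$role[i],
                                       sw$direction[i]))
    write_trace(sw$trace[[i]], files[i])
  }
  manifest <- list(
    seed = cohort$truth$seed,
    glycine_uM = cohort$truth$glycine,
    conc_grid_uM = cohort$truth$conc_grid,
    voltages_mV = cohort$truth$voltages,
    cells = cohort$cells,
    sweeps = mutate(select(sw, -"trace"), file = files),
    truth = jsonlite::fromJSON(scheme_to_json(cohort$truth$scheme)),
    config = unclass(cohort$truth$config)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
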