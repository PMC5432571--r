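#' Receptor-subtype presets
#'
#' Ready-made gating and block parameter sets emulating the qualitative
#' behaviour of the GlyR subtypes studied with niflumic acid: `alpha1`
#' (shallow site, two-molecule block, outwardly rectifying), `alpha2` (deep
#' site, one-molecule block, inwardly rectifying), `alpha3` (alpha2-like pore
#' with fast desensitisation, outwardly rectifying), `G254A` (alpha1 pore
#' mutant, intermediate depth) and the heteromer-like variants. Fractional
#' electrical distances and zero-voltage IC50 anchors follow the values
#' reported for 30 uM glycine; kinetic rates are conventions (only
#' equilibrium quantities are experimentally constrained).
#'
#' @param subtype One of `"alpha1"`, `"alpha2"`, `"alpha3"`, `"G254A"`,
#'   `"alpha1beta"`, `"alpha2beta"`.
#' @param n_sites Override the preset's number of blocking sites (e.g. force
#'   a one-site scheme for fractional-distance recovery studies).
#' @param temperature Kelvin.
#'
#' @return A list with `scheme` ([build_block_scheme()]), `glycine`
#'   (working agonist concentration, uM) and `label`.
#' @export
glyr_preset <- function(subtype = c("alpha1", "alpha2", "alpha3", "G254A",
                                    "alpha1beta", "alpha2beta"),
                        n_sites = NULL, temperature = 295.15) {
  subtype <- match.arg(subtype)
  p <- switch(subtype,
    alpha1 = list(delta = 0.16, Kd0 = 280, n_sites = 2L, rect_slope = 40,
                  glycine = 30, desens = 0),
    alpha2 = list(delta = 0.65, Kd0 = 40, n_sites = 1L, rect_slope = -40,
                  glycine = 30, desens = 0),
    alpha3 = list(delta = 0.6, Kd0 = 40, n_sites = 1L, rect_slope = 40,
                  glycine = 100, desens = 0.3),
    G254A = list(delta = 0.37, Kd0 = 120, n_sites = 2L, rect_slope = 40,
                 glycine = 30, desens = 0),
    alpha1beta = list(delta = 0.2, Kd0 = 250, n_sites = 2L, rect_slope = 40,
                      glycine = 30, desens = 0),
    alpha2beta = list(delta = 0.45, Kd0 = 60, n_sites = 1L, rect_slope = 40,
                      glycine = 30, desens = 0)
  )
  n_sites <- n_sites %||% p$n_sites
  gat <- gating_params(beta_max = 4000, alpha = 100,
                       EC50_gate = if (subtype == "alpha3") 100 else 34,
                       rect_Vhalf = 0, rect_slope = p$rect_slope,
                       desens_rate = p$desens)
  ## for a two-site preset, split the anchor IC50 into stepwise constants
  ## with modest positive cooperativity (K1 > K2)
  Kd0 <- if (n_sites == 2L) c(4 * p$Kd0, p$Kd0 / 2) else p$Kd0
  blk <- block_params(n_sites = n_sites, Kd0 = Kd0, delta = p$delta,
                      koff0 = 500)
  list(scheme = build_block_scheme(n_sites, gat, blk, temperature),
       glycine = p$glycine, label = subtype)
}

#' Recover the fractional electrical distance from a synthetic cohort
#'
#' The full analysis chain applied to a cohort: quality filtering, ramp-pair
#' fraction-remaining curves, per-voltage Hill fits (IC50(V) table), per-cell
#' Woodhull regression and per-cell aggregation of delta.
#'
#' @param cohort A [generate_cohort()] object.
#' @param vgrid Analysis voltages, mV (defaults to the cohort's grid).
#' @param temperature Kelvin.
#' @param apply_quality_filter Drop cells failing [quality_filter()].
#'
#' @return A list with `delta` (the [aggregate_delta()] tibble), `per_cell`
#'   (per-cell Woodhull results), `ic50_table`, `dose_table`,
#'   `stoichiometry` (from [infer_stoichiometry()] on the pooled nH values).
#' @export
analyze_cohort <- function(cohort, vgrid = NULL, temperature = 295.15,
                           apply_quality_filter = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  vgrid <- vgrid %||% cohort$truth$voltages
  cells <- quality_filter(cohort$cells)
  kept <- if (apply_quality_filter) cells$cell[cells$keep] else cells$cell
  if (length(kept) == 0) abort("no cells pass the quality filter.")
  dose <- cohort_dose_table(cohort, voltages = vgrid)
  dose <- filter(dose, .data$cell %in% kept)
  ic50 <- ic50_voltage_table(dose, vgrid = vgrid)
  per_cell <- woodhull_by_cell(ic50, temperature = temperature)
  agg <- aggregate_delta(per_cell)
  stoich <- infer_stoichiometry(filter(ic50, .data$converged))
  list(delta = agg, per_cell = per_cell, ic50_table = ic50,
       dose_table = dose, cells = cells, stoichiometry = stoich)
}

#' Run the full synthetic-block pipeline
#'
#' Simulate a cohort for a subtype preset (or an explicit scheme), analyse it
#' (fraction remaining, IC50(V), Woodhull delta, stoichiometry heuristic) and
#' optionally write the result bundle to disk: per-subtype delta and
#' per-voltage IC50/nH CSV tables and a JSON summary whose content is a
#' deterministic function of the configuration and seed.
#'
#' @param config A list with elements `subtype` (see [glyr_preset()]) or
#'   `scheme` + `glycine`, `n_cells`, `conc_grid`, `voltages`, `seed`, and
#'   optionally `n_sites`, `noise` (list passed to [recording_config()]),
#'   `temperature`, `out_dir`.
#'
#' @return A list with `summary` (one-row tibble), `delta`, `per_cell`,
#'   `ic50_table`, `stoichiometry`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(list(subtype = "alpha2", n_sites = 1, n_cells = 2,
#'                          conc_grid = c(10, 30, 100, 300),
#'                          voltages = c(-80, -30, 30, 80), seed = 7))
#' res$summary
#' }
run_pipeline <- function(config) {
  need <- c("n_cells", "conc_grid", "voltages", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) {
    abort(paste0("config is missing field(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.null(config$out_dir) && !is.null(config$in_dir)) {
    abort("give either `out_dir` or `in_dir`, not both.")
  }
  if (!is.null(config$in_dir) && !dir.exists(config$in_dir)) {
    abort(paste0("input path does not exist: ", config$in_dir))
  }
  temperature <- config$temperature %||% 295.15
  if (!is.null(config$scheme)) {
    scheme <- config$scheme
    glycine <- config$glycine %||% 30
    label <- config$label %||% "custom"
  } else {
    preset <- glyr_preset(config$subtype %||% "alpha1",
                          n_sites = config$n_sites, temperature = temperature)
    scheme <- preset$scheme
    glycine <- config$glycine %||% preset$glycine
    label <- preset$label
  }
  noise <- config$noise %||% list(amp_noise_cv = 0.05, noise_sd_pA = 2)
  rc <- do.call(recording_config, c(noise, list(seed = config$seed)))
  cohort <- generate_cohort(config$n_cells, scheme, config$conc_grid,
                            config$voltages, rc, glycine = glycine,
                            include_long = isTRUE(config$include_long))
  res <- analyze_cohort(cohort, vgrid = config$voltages,
                        temperature = temperature)
  summary <- tibble(
    subtype = label,
    glycine_uM = glycine,
    delta = res$delta$mean_delta,
    delta_sem = res$delta$sem_delta,
    n_cells = res$delta$n,
    delta_truth = scheme$block$delta,
    n_sites_truth = scheme$block$n_sites,
    n_sites_inferred = res$stoichiometry$n_sites,
    mean_nH = res$stoichiometry$mean_nH,
    seed = config$seed
  )
  manifest <- list(
    seed = config$seed, subtype = label, glycine_uM = glycine,
    n_cells = config$n_cells, conc_grid = config$conc_grid,
    voltages = config$voltages, temperature = temperature,
    config_hash = rlang::hash({
      cfg <- config[setdiff(names(config), c("out_dir", "in_dir"))]
      cfg[order(names(cfg))]
    }),
    package_version = as.character(utils::packageVersion("glyrblock"))
  )
  out <- list(summary = summary, delta = res$delta, per_cell = res$per_cell,
              ic50_table = res$ic50_table, stoichiometry = res$stoichiometry,
              manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(summary, file.path(config$out_dir, "delta_table.csv"),
                     progress = FALSE)
    readr::write_csv(res$ic50_table,
                     file.path(config$out_dir, "ic50_nh_table.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      c(manifest, list(summary = summary)),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}
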