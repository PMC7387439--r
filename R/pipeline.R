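#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis pipeline with its
#' default, plus the scenario parameters of the synthetic front end. The
#' configuration round-trips through YAML unchanged, so a run is fully
#' described by its config file and seed.
#'
#' @param seed Integer seed governing all random streams (sub-generators
#'   receive deterministic offsets of it).
#' @param scenario Named list of [incubation_scenario()] arguments.
#' @param otu Named list of [sim_otu_table()] arguments.
#' @param analysis_day Incubation day analyzed for rates and fractions
#'   (must be one of the scenario timepoints).
#' @param F_nat_C,F_nat_N Natural-abundance atom fractions.
#' @param threshold_C,threshold_N Activity thresholds (atom fractions).
#' @param min_rois Minimum ROI count for `f_0` determinability.
#' @param alpha Per-OTU significance level for decontamination.
#' @param alignment_window Scan-alignment search half-width in pixels.
#' @param porosity,henry_solubility,carbon_per_cell Geochemical budget
#'   constants (see [oxygen_inventory()], [oxygen_equilibrium()],
#'   [toc_supportable_biomass()]).
#' @param output_dir Optional directory; when set, [run_pipeline()]
#'   writes its report files there.
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(seed = 1,
                            scenario = list(),
                            otu = list(),
                            analysis_day = 21,
                            F_nat_C = F_NAT_C_DEFAULT,
                            F_nat_N = F_NAT_N_DEFAULT,
                            threshold_C = THRESHOLD_C_DEFAULT,
                            threshold_N = THRESHOLD_N_DEFAULT,
                            min_rois = 10,
                            alpha = 0.05,
                            alignment_window = 10,
                            porosity = 0.73,
                            henry_solubility = 0.032,
                            carbon_per_cell = 10,
                            output_dir = NULL) {
  cfg <- list(seed = as.integer(seed), scenario = scenario, otu = otu,
              analysis_day = analysis_day,
              F_nat_C = F_nat_C, F_nat_N = F_nat_N,
              threshold_C = threshold_C, threshold_N = threshold_N,
              min_rois = min_rois, alpha = alpha,
              alignment_window = alignment_window,
              porosity = porosity, henry_solubility = henry_solubility,
              carbon_per_cell = carbon_per_cell,
              output_dir = output_dir)
  if (cfg$porosity <= 0 || cfg$porosity >= 1) abort("`porosity` must lie in (0, 1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (cfg$min_rois < 1) abort("`min_rois` must be at least 1")
  if (cfg$alignment_window < 1) abort("`alignment_window` must be at least 1")
  frs <- c(cfg$F_nat_C, cfg$F_nat_N, cfg$threshold_C, cfg$threshold_N)
  if (any(frs <= 0 | frs >= 1)) abort("atom fractions must lie in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes, deterministically for a given config: (1) simulation of an
#' incubation with known ground truth; (2) an imaging stage on a subset
#' of the sampled cells — Poisson ion-count stack with scan drift, scan
#' alignment, ROI measurement; (3) activity classification, growth and
#' biomass generation rates, and the originally active fraction at the
#' configured analysis day; (4) sequential negative-control OTU
#' decontamination; (5) a report bundle with the growth table, aggregate
#' statistics and the geochemical budget.
#'
#' @param cfg A [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return A list of class `pipeline_report`: `simulation`, `imaging`
#'   (shifts and measured ROI tibble), `result` (the
#'   [analyze_incubation()] object), `growth_table`, `aggregates`,
#'   `decontamination`, `geochem`, `config`.
#' @export
#' @examples
#' rep <- run_pipeline(pipeline_config(seed = 7))
#' rep$growth_table
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))

  # stage 1: simulate (sub-seeds split deterministically from the master)
  scen_args <- cfg$scenario
  scen_args$seed <- cfg$seed + 1L
  scen_args$F_nat_C <- scen_args$F_nat_C %||% cfg$F_nat_C
  scen_args$F_nat_N <- scen_args$F_nat_N %||% cfg$F_nat_N
  scenario <- do.call(incubation_scenario, scen_args)
  sim <- sim_incubation(scenario)
  if (!cfg$analysis_day %in% scenario$timepoints) {
    abort("`analysis_day` must be one of the scenario timepoints")
  }

  # stage 2: imaging round trip on a subset of the analysis-day cells
  day_cells <- dplyr::filter(sim$cells, .data$day == cfg$analysis_day)
  n_img <- min(9L, nrow(day_cells))
  img_cells <- dplyr::slice_head(day_cells, n = n_img)
  specs <- cell_grid(n_img, field_size = 96, lambda_C = 200, lambda_CN = 200)
  specs$F_C <- img_cells$F_t_C
  specs$F_N <- img_cells$F_t_N
  stack_sim <- sim_image_stack(specs, field_size = 96, n_scans = 3,
                               drift = c(1, 1), seed = cfg$seed + 2L)
  aligned <- align_scans(stack_sim$stack, window = cfg$alignment_window)
  meas <- measure_rois(aligned, stack_sim$roi_mask)
  imaging <- list(shifts = aligned$shifts, rois = meas,
                  truth = dplyr::select(specs, "cell_id", "F_C", "F_N"))

  # stage 3: classify / rates / fractions on the full simulated cell table
  setup <- incubation_setup(
    sample_id = "synthetic", substrate = "mixed",
    t = cfg$analysis_day,
    F_label_C = scenario$F_label_C, F_label_N = scenario$F_label_N,
    F_nat_C = scenario$F_nat_C, F_nat_N = scenario$F_nat_N,
    threshold_C = cfg$threshold_C, threshold_N = cfg$threshold_N
  )
  meas_day <- tibble::tibble(
    roi_id = day_cells$cell_id,
    F_C = day_cells$F_t_C, F_N = day_cells$F_t_N,
    defined_C = TRUE, defined_N = TRUE
  )
  result <- analyze_incubation(meas_day, sim$counts, setup,
                               min_rois = cfg$min_rois)
  growth_table <- glance(result)

  # stage 4: decontaminate a synthetic OTU table
  otu_args <- cfg$otu
  otu_args$seed <- cfg$seed + 3L
  otu_sim <- do.call(sim_otu_table, otu_args)
  decon <- decontaminate(otu_sim$table, alpha = cfg$alpha)
  decon$truth <- otu_sim$contaminants

  # stage 5: report bundle
  inventory <- oxygen_inventory(1.5, 15, cfg$porosity)
  geochem <- list(
    oxygen_inventory_nmol = inventory,
    oxygen_equilibrium = oxygen_equilibrium(inventory, 35, 15 * cfg$porosity,
                                            cfg$henry_solubility),
    toc_supportable_cells_per_cm3 =
      toc_supportable_biomass(1e-4, carbon_per_cell = cfg$carbon_per_cell)
  )
  aggregates <- summarize_incubations(growth_table)$aggregates

  report <- structure(
    list(simulation = sim, imaging = imaging, result = result,
         growth_table = growth_table, aggregates = aggregates,
         decontamination = decon, geochem = geochem, config = cfg),
    class = "pipeline_report"
  )
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_growth_table(growth_table,
                       file.path(cfg$output_dir, "growth_table.tsv"))
    write_roi_table(meas, file.path(cfg$output_dir, "roi_measurements.tsv"))
    write_cell_counts(sim$counts, file.path(cfg$output_dir, "cell_counts.csv"))
    yaml::write_yaml(
      list(aggregates = as.list(aggregates),
           geochem = list(
             oxygen_inventory_nmol = geochem$oxygen_inventory_nmol,
             equilibrated_O2_nM = geochem$oxygen_equilibrium$aqueous_nM,
             toc_supportable_cells_per_cm3 = geochem$toc_supportable_cells_per_cm3
           ),
           removed_otus = decon$removed,
           seed = cfg$seed),
      file.path(cfg$output_dir, "report.yml")
    )
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  recovered shifts: %s\n",
              paste(sprintf("(%d,%d)", x$imaging$shifts$d_row,
                            x$imaging$shifts$d_col), collapse = " ")))
  print(x$result)
  cat(sprintf("  OTUs removed by decontamination: %d (truth: %d)\n",
              length(x$decontamination$removed),
              length(x$decontamination$truth)))
  cat(sprintf("  O2 inventory: %.1f nmol; equilibrated: %.1f nM; TOC biomass: %.2g cells/cm3\n",
              x$geochem$oxygen_inventory_nmol,
              x$geochem$oxygen_equilibrium$aqueous_nM,
              x$geochem$toc_supportable_cells_per_cm3))
  invisible(x)
}
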