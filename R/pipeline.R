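#' Seeded pipeline commands with self-describing output bundles
#'
#' Each `run_*` command executes one pipeline stage and writes an output
#' bundle into `out_dir`: a results JSON, tidy tables where applicable, and
#' an echo of the configuration (including the seed and the pinned RNG
#' algorithm) so the bundle can be reproduced bit-for-bit. Stochastic stages
#' require an explicit seed.
#'
#' @name pipeline
NULL

write_bundle <- function(out_dir, results, config_echo, tables = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  jsonlite::write_json(config_echo, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  for (nm in names(tables)) {
    utils::write.table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

config_echo <- function(config, extra = list()) {
  c(list(mode = config$mode,
         window_um = c(config$window$width_um, config$window$height_um),
         target_density = config$target_density,
         soma_diameter_um = config$soma_diameter_um,
         arbor_params = config$arbor_params,
         cluster_params = config$cluster_params,
         clone_params = config$clone_params,
         seed = config$seed, max_attempts = config$max_attempts,
         rng = config$rng), extra)
}

#' @rdname pipeline
#' @param config A [sim_config()] with a seed.
#' @param out_dir Output bundle directory.
#' @return The primary object of the stage, invisibly (bundle paths are
#'   written as a side effect).
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  out <- switch(config$mode,
    hardcore_random = list(field = simulate_hardcore(config)),
    exclusion_mosaic = simulate_exclusion_mosaic(config),
    clustered = list(field = simulate_clustered(config)),
    clone_field = {
      cf <- generate_clone_field(config)
      list(field = cf$cells, columns = cf$columns, truth = cf$truth)
    })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_soma_csv(out$field, file.path(out_dir, "somata.csv"))
  if (!is.null(out$arbors)) {
    save_polygons_json(out$arbors, file.path(out_dir, "arbors.json"))
  }
  if (!is.null(out$columns)) {
    cols <- lapply(seq_along(out$columns), function(i) {
      arbor_territory(paste0("col", i), out$columns[[i]])
    })
    save_polygons_json(cols, file.path(out_dir, "columns.json"))
  }
  tables <- if (!is.null(out$truth)) list(truth = out$truth) else list()
  write_bundle(out_dir,
               results = list(n_cells = nrow(out$field$points),
                              density_mm2 = field_density(out$field)),
               config_echo = config_echo(config), tables = tables)
  invisible(out)
}

#' @rdname pipeline
#' @param field A [soma_field()] (commands also accept a CSV path plus
#'   `window`).
#' @param window Required when `field` is a path.
#' @param bin_width_um,max_radius_um DRP parameters.
#' @export
run_drp <- function(field, out_dir, bin_width_um = 5, max_radius_um = 150,
                    window = NULL) {
  if (is.character(field)) field <- load_soma_csv(field, window)
  drp <- compute_drp(field, bin_width_um, max_radius_um)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_drp_tsv(drp, file.path(out_dir, "drp_bins.tsv"))
  write_bundle(out_dir,
               results = list(effective_radius_um = drp$effective_radius_um,
                              global_density_mm2 = drp$global_density_mm2,
                              n = drp$n),
               config_echo = list(command = "drp",
                                  bin_width_um = bin_width_um,
                                  max_radius_um = max_radius_um))
  invisible(drp)
}

#' @rdname pipeline
#' @export
run_vdri <- function(field, out_dir, window = NULL) {
  if (is.character(field)) field <- load_soma_csv(field, window)
  v <- compute_vdri(field)
  write_bundle(out_dir,
               results = list(vdri = v$vdri, n_interior = v$n_interior,
                              mean_area_um2 = v$mean_area_um2,
                              sd_area_um2 = v$sd_area_um2,
                              degenerate = v$degenerate),
               config_echo = list(command = "vdri"))
  invisible(v)
}

#' @rdname pipeline
#' @param n_sims Number of matched random simulations.
#' @param seed Integer master seed.
#' @export
run_battery <- function(field, out_dir, n_sims = 5, seed,
                        bin_width_um = 5, max_radius_um = 150,
                        window = NULL) {
  if (is.character(field)) field <- load_soma_csv(field, window)
  b <- random_reference_battery(field, n_sims = n_sims, seed = seed,
                                bin_width_um = bin_width_um,
                                max_radius_um = max_radius_um)
  smry <- cbind(statistic = rownames(b$summary), b$summary)
  write_bundle(out_dir,
               results = list(observed = b$observed,
                              sim_mean = as.list(stats::setNames(
                                b$summary$sim_mean, rownames(b$summary))),
                              z = as.list(stats::setNames(
                                b$summary$z, rownames(b$summary)))),
               config_echo = list(command = "battery", n_sims = n_sims,
                                  seed = seed, rng = "Mersenne-Twister"),
               tables = list(battery_summary = smry))
  invisible(b)
}

#' @rdname pipeline
#' @param arbors List of [arbor_territory()] (or a polygons JSON path).
#' @param fields Named list of [soma_field()] (or a named character vector
#'   of CSV paths plus `window`).
#' @param population_filter,nucleus_diameter_um See [count_enclosed()].
#' @export
run_enclosure <- function(arbors, fields, out_dir, population_filter = NULL,
                          nucleus_diameter_um = NULL, window = NULL) {
  if (is.character(arbors)) arbors <- load_polygons_json(arbors)
  if (is.character(fields)) {
    fields <- stats::setNames(
      lapply(fields, load_soma_csv, window = window), names(fields))
  }
  recs <- build_unmatched(arbors, fields, population_filter,
                          nucleus_diameter_um)
  tab <- data.frame(
    reference_id = vapply(recs, function(r) r$arbor$reference_id,
                          character(1)),
    area_um2 = vapply(recs, function(r) r$arbor$area_um2, numeric(1)),
    real_count = vapply(recs, `[[`, integer(1), "real_count"),
    n_unmatched = vapply(recs, function(r) length(r$unmatched_counts),
                         integer(1)),
    unmatched_mean_zero_excluded = vapply(recs, `[[`, numeric(1),
                                          "unmatched_mean_zero_excluded"),
    eci = vapply(recs, `[[`, numeric(1), "eci"),
    stringsAsFactors = FALSE)
  test <- tryCatch(eci_median_test(recs), error = function(e) NULL)
  dist <- enclosure_distributions(recs)
  write_bundle(out_dir,
               results = list(
                 n_arbors = length(recs),
                 eci_median = if (is.null(test)) NULL else test$median,
                 eci_p_value = if (is.null(test)) NULL else test$p_value,
                 chisq = dist$chisq),
               config_echo = list(command = "enclosure",
                                  population_filter = population_filter,
                                  nucleus_diameter_um = nucleus_diameter_um),
               tables = list(enclosure_records = tab,
                             frequency_curves = dist$curve))
  invisible(list(records = recs, test = test, distributions = dist))
}

#' @rdname pipeline
#' @param tips Tip data.frame (or CSV path with `tip_id`, `x_um`, `y_um`).
#' @param tolerance_um Contact tolerance.
#' @export
run_contact <- function(tips, field, out_dir, tolerance_um = 0.5,
                        window = NULL) {
  if (is.character(tips)) tips <- utils::read.csv(tips,
                                                  stringsAsFactors = FALSE)
  if (is.character(field)) field <- load_soma_csv(field, window)
  real <- contact_fraction(tips, field, tolerance_um)
  flip <- flipped_contact_control(tips, field, tolerance_um)
  as_row <- function(r) data.frame(
    condition = r$condition, n_tips = r$n_tips,
    n_contacting = r$n_contacting, fraction = r$fraction,
    ci_low = r$ci_low, ci_high = r$ci_high, stringsAsFactors = FALSE)
  write_bundle(out_dir,
               results = list(real = unclass(real), flipped = unclass(flip)),
               config_echo = list(command = "contact",
                                  tolerance_um = tolerance_um),
               tables = list(contacts = rbind(as_row(real), as_row(flip))))
  invisible(list(real = real, flipped = flip))
}

#' @rdname pipeline
#' @param cells A [soma_field()] of clone-labelled cells (or CSV path).
#' @param columns Column polygons (or a polygons JSON path).
#' @export
run_disperse <- function(cells, columns, out_dir, window = NULL) {
  if (is.character(cells)) cells <- load_soma_csv(cells, window)
  if (is.character(columns)) {
    columns <- lapply(load_polygons_json(columns), `[[`, "vertices")
  }
  d <- dispersion_metrics(cells, columns)
  write_bundle(out_dir,
               results = list(n_cells = d$n_cells,
                              n_outside_columns = d$n_outside_columns,
                              fraction_outside = d$fraction_outside,
                              median_distance_um =
                                if (length(d$distances_um))
                                  stats::median(d$distances_um) else NULL),
               config_echo = list(command = "disperse"),
               tables = list(distances = data.frame(
                 distance_um = d$distances_um)))
  invisible(d)
}
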