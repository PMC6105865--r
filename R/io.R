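# Plain-text I/O: GeoJSON for geometry, CSV for tables, YAML for
# configurations. Geometry coordinates are planar miles (no CRS).

closed_ring <- function(xy) {
  ring <- rbind(xy, xy[1, ])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Write dissemination areas as GeoJSON
#'
#' FeatureCollection of polygons with `da_id`, `population` and the
#' covariates as feature properties.
#'
#' @param das Tessellation tibble (covariates optional).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_das_geojson <- function(das, path) {
  props <- intersect(c("da_id", "population", covariate_names()), names(das))
  features <- purrr::map(seq_len(nrow(das)), function(i) {
    list(type = "Feature",
         properties = as.list(das[i, props]),
         geometry = list(type = "Polygon",
                         coordinates = list(closed_ring(das$polygon[[i]]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read dissemination areas from GeoJSON
#'
#' Inverse of [write_das_geojson()]; recomputes `area`, centroids and drops
#' the closing vertex.
#'
#' @param path GeoJSON file.
#' @return Tessellation tibble.
#' @export
read_das_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- purrr::map(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    xy <- xy[-nrow(xy), , drop = FALSE]
    cent <- polygon_centroid(xy)
    c(list(polygon = list(xy), area = polygon_area(xy),
           centroid_x = cent[1], centroid_y = cent[2]),
      f$properties)
  })
  tibble::as_tibble(purrr::map_dfr(rows, tibble::as_tibble))
}

#' Write / read the user table
#' @param users User tibble.
#' @param path CSV file.
#' @return `path` (write) or the tibble (read).
#' @export
write_users_csv <- function(users, path) {
  readr::write_csv(users, path)
  invisible(path)
}

#' @rdname write_users_csv
#' @export
read_users_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    user_id = readr::col_character(),
    x = readr::col_double(), y = readr::col_double(),
    da_id = readr::col_character(),
    shows_location = readr::col_logical()))
}

#' Serialize a campaign configuration to YAML
#'
#' A spatially varying `p_hidden` function is not serializable and is stored
#' as `NA` with a note.
#'
#' @param config A [campaign_config()].
#' @param path YAML file.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  sim <- config$sim
  lst <- list(
    sim = list(rng_seed = sim$rng_seed, n_das = sim$n_das,
               beta = as.list(sim$beta),
               p_hidden = if (is.function(sim$p_hidden)) NA else sim$p_hidden,
               covariate_smoothing_bandwidth =
                 sim$covariate_smoothing_bandwidth,
               slot_effects = as.list(sim$slot_effects)),
    region = unclass(config$region),
    spacing = config$spacing, radius = config$radius,
    grid_origin = config$grid_origin, max_list = config$max_list,
    n_audit_locations = config$n_audit_locations,
    n_profiles_per_location = config$n_profiles_per_location)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' Read a campaign configuration from YAML
#' @param path YAML file written by [write_config_yaml()].
#' @return A [campaign_config()].
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- sim_config(
    rng_seed = lst$sim$rng_seed, n_das = lst$sim$n_das,
    beta = unlist(lst$sim$beta),
    p_hidden = lst$sim$p_hidden,
    covariate_smoothing_bandwidth = lst$sim$covariate_smoothing_bandwidth,
    slot_effects = unlist(lst$sim$slot_effects))
  campaign_config(
    sim = sim,
    region = do.call(study_region, lst$region),
    spacing = lst$spacing, radius = lst$radius,
    grid_origin = unlist(lst$grid_origin), max_list = lst$max_list,
    n_audit_locations = lst$n_audit_locations,
    n_profiles_per_location = lst$n_profiles_per_location)
}

disc_ring <- function(x, y, r, n_arc = 64L) {
  th <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
  cbind(x + r * cos(th), y + r * sin(th))
}

#' Export sampling buffers (and outlier flags) as GeoJSON
#'
#' FeatureCollection of buffer discs (64-gon rings) with the observation,
#' fit and outlier diagnostics as properties.
#'
#' @param buffers Buffer observations.
#' @param path Output file.
#' @param outliers Optional outlier report ([bonferroni_outlier_test()]),
#'   joined by `point_id`.
#' @param radius Buffer radius in miles.
#' @return `path`, invisibly.
#' @export
export_buffers_geojson <- function(buffers, path, outliers = NULL,
                                   radius = 1) {
  tab <- buffers
  tab$slot <- as.character(tab$slot)
  if (!is.null(outliers)) {
    tab <- dplyr::left_join(
      tab, outliers[, c("point_id", "fitted", "std_resid", "outlier")],
      by = "point_id")
  }
  features <- purrr::map(seq_len(nrow(tab)), function(i) {
    props <- as.list(tab[i, setdiff(names(tab), c("x", "y"))])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(closed_ring(
                           disc_ring(tab$x[i], tab$y[i], radius)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write all pipeline artifacts to a directory
#'
#' Writes the synthetic world (GeoJSON + CSV + YAML config), buffer
#' observations, design matrix, descriptive and IRR tables, model
#' comparison, outlier reports, buffer GeoJSON and a manifest.
#'
#' @param result A `density_pipeline` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_config_yaml(result$config, p("config.yaml"))
  write_das_geojson(result$world$das, p("dissemination_areas.geojson"))
  write_users_csv(result$world$users, p("users.csv"))
  buf <- result$buffers
  buf$slot <- as.character(buf$slot)
  readr::write_csv(buf, p("buffer_observations.csv"))
  des <- result$design
  des$slot <- as.character(des$slot)
  readr::write_csv(des, p("design_matrix.csv"))
  readr::write_csv(result$table1, p("table1_descriptives.csv"))
  readr::write_csv(result$table2, p("table2_irr.csv"))
  comparison <- tibble::tibble(
    model = c("density_only", "selected"),
    aic = c(result$fits$density_only$aic, result$fits$selected$aic),
    log_likelihood = c(result$fits$density_only$log_likelihood,
                       result$fits$selected$log_likelihood),
    pseudo_r2 = result$pseudo_r2$pseudo_r2,
    lrt_statistic = if (is.null(result$lrt)) NA_real_ else
      result$lrt$statistic,
    lrt_df = if (is.null(result$lrt)) NA_real_ else result$lrt$df,
    lrt_p_value = if (is.null(result$lrt)) NA_real_ else result$lrt$p_value)
  readr::write_csv(comparison, p("model_comparison.csv"))
  readr::write_csv(result$outliers$density_only,
                   p("outliers_density_only.csv"))
  readr::write_csv(result$outliers$selected, p("outliers_selected.csv"))
  readr::write_csv(result$audit, p("privacy_audit.csv"))
  export_buffers_geojson(result$buffers, p("buffers.geojson"),
                         outliers = result$outliers$selected,
                         radius = result$config$radius)
  manifest <- result$manifest
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
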