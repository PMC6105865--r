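# End-to-end orchestration: simulate -> sample -> weight -> model -> report,
# plus the standalone privacy audit.

#' Build a campaign configuration
#'
#' Bundles the simulation configuration with the sampling-design parameters.
#' Stage seeds are derived deterministically from `sim$rng_seed`, so a
#' configuration fully determines every output artifact.
#'
#' @param sim A [sim_config()].
#' @param region A [study_region()].
#' @param spacing Grid spacing in miles.
#' @param radius Buffer (counting) radius in miles; a warning is issued when
#'   `spacing < 2 * radius` (overlapping buffers).
#' @param grid_origin Lattice origin, inside the region.
#' @param max_list Listing truncation length.
#' @param n_audit_locations,n_profiles_per_location Privacy-audit design
#'   (default: 500 profiles across 5 spatially diverse locations).
#' @return A `campaign_config` list.
#' @export
campaign_config <- function(sim = sim_config(),
                            region = study_region(),
                            spacing = 2,
                            radius = 1,
                            grid_origin = c(0.5, 0.5),
                            max_list = 100L,
                            n_audit_locations = 5L,
                            n_profiles_per_location = 100L) {
  if (spacing < 2 * radius) {
    warning("spacing < 2 * radius: sampling buffers overlap")
  }
  structure(list(sim = sim, region = region, spacing = spacing,
                 radius = radius, grid_origin = grid_origin,
                 max_list = as.integer(max_list),
                 n_audit_locations = as.integer(n_audit_locations),
                 n_profiles_per_location = as.integer(n_profiles_per_location),
                 seeds = list(world = sim$rng_seed,
                              slots = sim$rng_seed + 3L,
                              campaign = sim$rng_seed + 4L)),
            class = "campaign_config")
}

#' Run the full analysis pipeline
#'
#' Simulates the synthetic world, runs the sampling campaign, aggregates the
#' areal covariates, fits the density-only and the AIC-selected multivariable
#' Poisson models (both forcing the sampling-time block), and produces the
#' comparison statistics, the descriptive and IRR tables, both outlier
#' reports, and the privacy audit.
#'
#' @param config A [campaign_config()].
#' @param out_dir Optional directory; when given, all artifacts are written
#'   there ([write_pipeline_outputs()]).
#' @param verbose Log stage progress to stderr.
#' @return A `density_pipeline` list (world, buffers, design, fits, tables,
#'   reports, manifest).
#' @export
run_pipeline <- function(config = campaign_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  say("simulate", "generating synthetic world")
  world <- step("simulate", simulate_world(config$sim, config$region))
  say("simulate", sprintf("%d DAs, %d users", nrow(world$das),
                          nrow(world$users)))
  say("sample", "building grid and running campaign")
  points <- step("sample", assign_slots(
    build_grid(config$region, config$spacing, config$grid_origin),
    rng_seed = config$seeds$slots))
  buffers <- step("sample", sample_campaign(
    points, world$users, world$das, radius = config$radius,
    max_list = config$max_list, slot_effects = config$sim$slot_effects,
    rng_seed = config$seeds$campaign))
  say("sample", sprintf("%d buffers, %d users counted", nrow(buffers),
                        sum(buffers$user_count)))
  say("weight", "areal covariate aggregation")
  design <- step("weight", build_design_matrix(buffers, world$das,
                                               radius = config$radius))
  table1 <- step("weight", summarize_covariates(world$das))
  say("model", "fitting Poisson models")
  null_fit <- step("model", fit_poisson(design, character(0)))
  density_only <- step("model",
                       fit_poisson(design, c("slot", "pop_density_100")))
  full <- step("model", fit_poisson(design))
  selected <- step("model", backward_eliminate_aic(design))
  # compare the selected model with the density-only model; if elimination
  # dropped population density the pair is not nested, so compare the full
  # model instead
  lrt <- tryCatch(likelihood_ratio_test(selected, density_only),
                  error = function(e) likelihood_ratio_test(full,
                                                            density_only))
  r2 <- tibble::tibble(
    model = c("density_only", "selected"),
    pseudo_r2 = c(mcfadden_r2(density_only, null_fit),
                  mcfadden_r2(selected, null_fit)))
  outliers_density_only <- step("model", bonferroni_outlier_test(density_only))
  outliers_selected <- step("model", bonferroni_outlier_test(selected))
  table2 <- step("model", irr_table(selected))
  say("audit", "privacy audit")
  audit <- step("audit", run_privacy_audit(world$users, points, config))
  manifest <- list(
    seeds = config$seeds,
    n_das = nrow(world$das), n_users = nrow(world$users),
    n_points = nrow(points), n_buffers = nrow(buffers),
    total_counted = sum(buffers$user_count),
    spacing = config$spacing, radius = config$radius,
    max_list = config$max_list,
    selected_terms = selected$terms)
  out <- structure(list(config = config, world = world, points = points,
                        buffers = buffers, design = design, table1 = table1,
                        fits = list(null = null_fit,
                                    density_only = density_only,
                                    full = full,
                                    selected = selected),
                        lrt = lrt, pseudo_r2 = r2,
                        outliers = list(density_only = outliers_density_only,
                                        selected = outliers_selected),
                        table2 = table2, audit = audit, manifest = manifest),
                   class = "density_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.density_pipeline <- function(x, ...) {
  cat(sprintf("Density pipeline: %d DAs, %d users, %d buffers, %d counted\n",
              x$manifest$n_das, x$manifest$n_users, x$manifest$n_buffers,
              x$manifest$total_counted))
  cat("Selected terms:", paste(x$fits$selected$terms, collapse = ", "), "\n")
  cat(sprintf("Pseudo r2: density-only %.3f, selected %.3f\n",
              x$pseudo_r2$pseudo_r2[1], x$pseudo_r2$pseudo_r2[2]))
  if (!is.null(x$lrt)) {
    cat(sprintf("LRT selected vs density-only: stat %.2f, df %d, p %.3g\n",
                x$lrt$statistic, x$lrt$df, x$lrt$p_value))
  }
  cat(sprintf("Outliers: density-only %d, selected %d\n",
              sum(x$outliers$density_only$outlier),
              sum(x$outliers$selected$outlier)))
  invisible(x)
}

# Spatially diverse audit locations: grid points nearest the region centre
# and the four quarter-points.
audit_locations <- function(points, region, n = 5L) {
  fx <- c(0.5, 0.25, 0.75, 0.25, 0.75)
  fy <- c(0.5, 0.25, 0.25, 0.75, 0.75)
  tx <- region$x_min + fx * (region$x_max - region$x_min)
  ty <- region$y_min + fy * (region$y_max - region$y_min)
  idx <- unique(vapply(seq_along(tx), function(i) {
    which.min((points$x - tx[i])^2 + (points$y - ty[i])^2)
  }, integer(1)))
  # top up with farthest-apart extras if targets collide
  while (length(idx) < n && length(idx) < nrow(points)) {
    d <- rowSums(vapply(idx, function(i) {
      sqrt((points$x - points$x[i])^2 + (points$y - points$y[i])^2)
    }, numeric(nrow(points))))
    idx <- c(idx, which.max(d))
  }
  points[idx[seq_len(min(n, length(idx)))], ]
}

run_privacy_audit <- function(users, points, config) {
  locs <- audit_locations(points, config$region, config$n_audit_locations)
  listings <- purrr::map(seq_len(nrow(locs)), function(i) {
    classify_listing(
      build_listing(users, locs$x[i], locs$y[i],
                    max_list = config$n_profiles_per_location),
      radius = config$radius)
  })
  privacy_audit(listings = listings)
}

#' Privacy audit of location-withheld profiles
#'
#' Quantifies how often profiles withhold their distance and how often that
#' withholding actually leaves their inclusion ambiguous. Supply either
#' classified listings or the recorded counts.
#'
#' @param listings List of classified listings ([classify_listing()] output
#'   with `shows_location`).
#' @param counts Alternatively, a named numeric vector
#'   `c(total = , hidden = , ambiguous = )`.
#' @return One-row tibble: `total_profiles`, `hidden_count`,
#'   `ambiguous_count`, `unambiguous_hidden_count`, `hidden_percent`,
#'   `ambiguous_percent_of_hidden` (`NA` when nothing is hidden), and (from
#'   listings) per-location ranges `hidden_min`/`hidden_max`,
#'   `ambiguous_min`/`ambiguous_max`.
#' @examples
#' privacy_audit(counts = c(total = 500, hidden = 127, ambiguous = 7))
#' @export
privacy_audit <- function(listings = NULL, counts = NULL) {
  if (is.null(listings) && is.null(counts)) {
    stop("supply `listings` or `counts`")
  }
  if (!is.null(listings)) {
    if (!length(listings)) stop("`listings` is empty")
    per <- purrr::map_dfr(listings, function(l) {
      tibble::tibble(total = nrow(l),
                     hidden = sum(!l$shows_location),
                     ambiguous = sum(l$status == "ambiguous"))
    })
    total <- sum(per$total); hidden <- sum(per$hidden)
    ambiguous <- sum(per$ambiguous)
    ranges <- tibble::tibble(hidden_min = min(per$hidden),
                             hidden_max = max(per$hidden),
                             ambiguous_min = min(per$ambiguous),
                             ambiguous_max = max(per$ambiguous))
  } else {
    total <- counts[["total"]]; hidden <- counts[["hidden"]]
    ambiguous <- counts[["ambiguous"]]
    ranges <- tibble::tibble(hidden_min = NA_real_, hidden_max = NA_real_,
                             ambiguous_min = NA_real_, ambiguous_max = NA_real_)
  }
  if (ambiguous > hidden) stop("ambiguous profiles must be a subset of hidden")
  dplyr::bind_cols(
    tibble::tibble(
      total_profiles = total,
      hidden_count = hidden,
      ambiguous_count = ambiguous,
      unambiguous_hidden_count = hidden - ambiguous,
      hidden_percent = 100 * hidden / total,
      ambiguous_percent_of_hidden = if (hidden > 0) 100 * ambiguous / hidden
        else NA_real_),
    ranges)
}
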