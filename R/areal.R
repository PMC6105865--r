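# Combined area and population weighted aggregation of DA-level covariates
# to buffer level, plus descriptive summaries. For buffer i and DA j the
# weight is w_ij = P_j * a_ij / A_j, with a_ij the DA area inside the buffer,
# A_j the DA area and P_j the DA population; the buffer covariate is
# sum_j w_ij x_j / sum_j w_ij.

#' Fraction of a DA inside a sampling radius
#'
#' `area(polygon intersect disc) / area(polygon)`, computed exactly.
#'
#' @param polygon DA vertex matrix.
#' @param x,y Sampling-point coordinates.
#' @param radius Disc radius (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
intersection_fraction <- function(polygon, x, y, radius) {
  a <- polygon_area(polygon)
  if (a <= 0) stop("zero-area polygon")
  min(max(disc_polygon_area(x, y, radius, polygon) / a, 0), 1)
}

#' Areal weights linking buffers to dissemination areas
#'
#' One row per (buffer, DA) pair with positive intersection:
#' `fraction = a_ij / A_j` and `weight = population_j * fraction`.
#'
#' @param buffers Buffer observations (needs `point_id`, `x`, `y`).
#' @param das Tessellation with `population`.
#' @param radius Buffer radius in miles.
#' @return Tibble: `point_id`, `da_id`, `fraction`, `weight`.
#' @export
areal_weights <- function(buffers, das, radius = 1) {
  stopifnot("population" %in% names(das))
  out <- purrr::map(seq_len(nrow(buffers)), function(i) {
    x <- buffers$x[i]; y <- buffers$y[i]
    fr <- vapply(das$polygon, function(p) {
      cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
      reach <- sqrt(max((p[, 1] - cx)^2 + (p[, 2] - cy)^2))
      if (sqrt((cx - x)^2 + (cy - y)^2) > radius + reach + 1e-9) return(0)
      intersection_fraction(p, x, y, radius)
    }, numeric(1))
    keep <- which(fr > 0)
    tibble::tibble(point_id = buffers$point_id[i],
                   da_id = das$da_id[keep],
                   fraction = fr[keep],
                   weight = das$population[keep] * fr[keep])
  })
  dplyr::bind_rows(out)
}

#' Population-and-area weighted buffer covariates
#'
#' Aggregates each raw DA covariate to buffer level with the combined
#' weights; by the convex-combination form the result always lies within the
#' range of the contributing DA values.
#'
#' @param weights Output of [areal_weights()].
#' @param das Tessellation with covariates.
#' @param covariates Raw covariate names to aggregate.
#' @return Tibble with `point_id` and one column per covariate. Buffers whose
#'   weights are all zero are flagged via attribute `"excluded"` and omitted.
#' @export
weighted_covariates <- function(weights, das, covariates = covariate_names()) {
  stopifnot(all(covariates %in% names(das)))
  joined <- dplyr::left_join(weights,
                             das[, c("da_id", covariates)], by = "da_id")
  totals <- dplyr::summarise(
    dplyr::group_by(joined, .data$point_id), w = sum(.data$weight))
  bad <- totals$point_id[totals$w <= 0]
  ok <- dplyr::filter(joined, !.data$point_id %in% bad)
  out <- dplyr::summarise(
    dplyr::group_by(ok, .data$point_id),
    dplyr::across(dplyr::all_of(covariates),
                  ~ sum(.x * .data$weight) / sum(.data$weight)))
  out <- dplyr::ungroup(out)
  attr(out, "excluded") <- bad
  out
}

#' Build the regression design matrix
#'
#' Joins the buffer outcomes to the weighted covariates, applies the model
#' scalings (population density per 100 persons/km^2, income per Can $1000),
#' and carries the sampling-slot factor (reference: Monday before 8 pm).
#'
#' @param buffers Buffer observations from [sample_campaign()].
#' @param das Tessellation with population and covariates.
#' @param radius Buffer radius used in the campaign.
#' @param covariates Raw covariate names to include.
#' @return Tibble: `point_id`, `slot`, scaled covariate columns, `density`,
#'   plus `user_count` and `land_area` kept for the offset variant.
#' @export
build_design_matrix <- function(buffers, das, radius = 1,
                                covariates = covariate_names()) {
  w <- areal_weights(buffers, das, radius)
  wc <- weighted_covariates(w, das, covariates)
  scaled <- apply_model_scaling_partial(wc, covariates)
  out <- dplyr::inner_join(
    buffers[, c("point_id", "slot", "sample_order", "user_count",
                "land_area", "density")],
    scaled, by = "point_id")
  excluded <- attr(wc, "excluded")
  if (length(excluded)) {
    warning(sprintf("excluded %d buffer(s) with all-zero areal weights",
                    length(excluded)))
  }
  if (anyNA(out)) stop("design matrix contains missing cells")
  dplyr::arrange(out, .data$sample_order)
}

# Model scalings restricted to whatever covariates are present.
apply_model_scaling_partial <- function(df, covariates) {
  out <- df
  if ("pop_density" %in% covariates) {
    out$pop_density <- out$pop_density / 100
    names(out)[names(out) == "pop_density"] <- "pop_density_100"
  }
  if ("med_income_male" %in% covariates) {
    out$med_income_male <- out$med_income_male / 1000
    names(out)[names(out) == "med_income_male"] <- "med_income_1000"
  }
  out
}

#' Descriptive covariate summary (median and quartiles)
#'
#' Per-column median and Q1-Q3 using the linear-interpolation quantile rule
#' (`stats::quantile` type 7).
#'
#' @param df Data frame (DA table or design matrix).
#' @param columns Columns to summarise; defaults to every numeric covariate
#'   column present.
#' @return Tibble: `variable`, `median`, `q1`, `q3`.
#' @export
summarize_covariates <- function(df, columns = intersect(covariate_names(),
                                                         names(df))) {
  if (nrow(df) < 4) stop("need at least 4 rows to summarise quartiles")
  purrr::map_dfr(columns, function(cl) {
    q <- stats::quantile(df[[cl]], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(variable = cl, median = q[2], q1 = q[1], q3 = q[3])
  })
}
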