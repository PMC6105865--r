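# Synthetic study geography: a Voronoi tessellation standing in for census
# dissemination areas, spatially autocorrelated census-style covariates, and
# an inhomogeneous Poisson process of app users whose log-intensity is linear
# in the model-scaled covariates.

KM2_PER_MI2 <- 2.589988

#' Define a rectangular study region
#'
#' All geometry in the package is planar Cartesian in statute miles; the
#' region stands in for a metropolitan extent.
#'
#' @param x_min,x_max,y_min,y_max Region bounds in miles.
#' @return A `study_region` object.
#' @examples
#' study_region(0, 10, 0, 10)
#' @export
study_region <- function(x_min = 0, x_max = 32, y_min = 0, y_max = 32) {
  stopifnot(x_max > x_min, y_max > y_min)
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "study_region")
}

region_polygon <- function(region) {
  matrix(c(region$x_min, region$y_min,
           region$x_max, region$y_min,
           region$x_max, region$y_max,
           region$x_min, region$y_max),
         ncol = 2, byrow = TRUE)
}

region_area <- function(region) {
  (region$x_max - region$x_min) * (region$y_max - region$y_min)
}

# Census-style covariate catalogue: plausible metropolitan medians and
# quartiles (persons/km^2, years, Can$, percentages, persons per dwelling).
# Fields are centred on the median with half-IQR dispersion; population
# density is generated on the log scale to get the heavy right tail real
# density surfaces have.
covariate_catalogue <- function() {
  tibble::tribble(
    ~name,                  ~median, ~q1,    ~q3,     ~dist,
    "pop_density",          331.6,   59.2,   1807.0,  "lognormal",
    "pct_male",             49.3,    48.6,   50.5,    "normal",
    "avg_age_male",         41.1,    38.2,   44.1,    "normal",
    "med_income_male",      48567,   42816,  55826,   "normal",
    "pct_not_married",      35.4,    30.9,   40.5,    "normal",
    "pct_postsecondary",    57.6,    48.9,   62.0,    "normal",
    "pct_unemployed",       5.1,     3.4,    6.1,     "normal",
    "pct_lico",             7.0,     4.9,    11.1,    "normal",
    "pct_immigrants",       27.2,    18.4,   38.8,    "normal",
    "pct_visible_minority", 26.0,    12.4,   46.8,    "normal",
    "avg_household_size",   2.8,     2.6,    3.0,     "normal"
  )
}

#' Names of the dissemination-area covariates
#'
#' @param scaled If `TRUE`, return the model-scale names (population density
#'   per 100 persons/km^2, income per Can $1000); otherwise the raw names.
#' @return Character vector of 11 covariate names.
#' @export
covariate_names <- function(scaled = FALSE) {
  nm <- covariate_catalogue()$name
  if (scaled) {
    nm[nm == "pop_density"] <- "pop_density_100"
    nm[nm == "med_income_male"] <- "med_income_1000"
  }
  nm
}

# Apply the model scalings (density per 100; income per Can $1000) to a data
# frame of raw covariates; returns a tibble with the scaled names.
apply_model_scaling <- function(df) {
  out <- tibble::as_tibble(df[, covariate_names(), drop = FALSE])
  out$pop_density <- out$pop_density / 100
  out$med_income_male <- out$med_income_male / 1000
  names(out) <- covariate_names(scaled = TRUE)
  out
}

#' Default generative coefficients
#'
#' Log-scale coefficients on the scaled covariates for the synthetic user
#' intensity; the nonzero entries are the incidence-rate-ratio magnitudes a
#' metropolitan app-user density surface exhibits (positive density,
#' not-married, postsecondary and immigrant gradients; negative age, income,
#' LICO and household-size gradients), with zeros for covariates that carry
#' no independent signal.
#'
#' @return Named numeric vector: `intercept` plus one entry per scaled
#'   covariate name.
#' @export
default_beta <- function() {
  c(intercept = 3.1,
    pop_density_100 = log(1.03),
    pct_male = 0,
    avg_age_male = log(0.93),
    med_income_1000 = log(0.96),
    pct_not_married = log(1.08),
    pct_postsecondary = log(1.06),
    pct_unemployed = 0,
    pct_lico = log(0.93),
    pct_immigrants = log(1.04),
    pct_visible_minority = 0,
    avg_household_size = log(0.26))
}

#' Default sampling-slot activity effects
#'
#' Log-scale relative activity of the six weekday-evening sampling slots
#' (Mon/Tue/Wed crossed with before / after 8 pm), reference `mon_pre8`.
#' Users are thinned at sampling time with probability
#' `exp(effect - max(effect))`, so the fitted slot contrasts recover the
#' differences between these effects.
#'
#' @return Named numeric vector over the six slot labels.
#' @export
default_slot_effects <- function() {
  c(mon_pre8 = log(1), mon_post8 = log(2.16),
    tue_pre8 = log(2.00), tue_post8 = log(2.28),
    wed_pre8 = log(1.15), wed_post8 = log(1.13))
}

#' Slot labels in chronological order
#' @return Character vector of length 6.
#' @export
slot_levels <- function() {
  c("mon_pre8", "mon_post8", "tue_pre8", "tue_post8", "wed_pre8", "wed_post8")
}

#' Build a simulation configuration
#'
#' @param rng_seed Integer seed controlling every random draw downstream.
#' @param n_das Number of dissemination areas (Voronoi cells), >= 3.
#' @param beta Named generative coefficient vector (`intercept` + scaled
#'   covariate names); see [default_beta()].
#' @param p_hidden Probability a user withholds their distance, or a
#'   `function(x, y)` returning per-user probabilities (spatially varying
#'   privacy hook).
#' @param covariate_smoothing_bandwidth Gaussian kernel bandwidth (miles) for
#'   the covariate random fields.
#' @param slot_effects Named log-scale activity vector over [slot_levels()].
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(rng_seed = 1, n_das = 50)
#' @export
sim_config <- function(rng_seed = 1L,
                       n_das = 400L,
                       beta = default_beta(),
                       p_hidden = 0.254,
                       covariate_smoothing_bandwidth = 3,
                       slot_effects = default_slot_effects()) {
  stopifnot(n_das >= 3, covariate_smoothing_bandwidth > 0)
  if (!is.function(p_hidden)) {
    stopifnot(p_hidden >= 0, p_hidden <= 1)
  }
  if (!all(is.finite(beta))) stop("`beta` must be finite")
  need <- c("intercept", covariate_names(scaled = TRUE))
  missing <- setdiff(need, names(beta))
  if (length(missing)) {
    beta[missing] <- 0
  }
  structure(list(rng_seed = as.integer(rng_seed),
                 n_das = as.integer(n_das),
                 beta = beta[need],
                 p_hidden = p_hidden,
                 covariate_smoothing_bandwidth = covariate_smoothing_bandwidth,
                 slot_effects = slot_effects[slot_levels()]),
            class = "sim_config")
}

# Voronoi cell of seeds[i, ] within the region rectangle, by successive
# half-plane clips against perpendicular bisectors. Neighbours are visited
# nearest-first so clipping can stop once no remaining seed can cut the cell
# (bisector distance exceeds the cell's current radius around the seed).
voronoi_cell <- function(i, seeds, region) {
  cell <- region_polygon(region)
  si <- seeds[i, ]
  d2 <- (seeds[, 1] - si[1])^2 + (seeds[, 2] - si[2])^2
  ord <- order(d2)
  ord <- ord[d2[ord] > 0]
  for (j in ord) {
    maxr2 <- max((cell[, 1] - si[1])^2 + (cell[, 2] - si[2])^2)
    if (d2[j] > 4 * maxr2) break
    sj <- seeds[j, ]
    nx <- sj[1] - si[1]; ny <- sj[2] - si[2]
    cc <- (sum(sj^2) - sum(si^2)) / 2
    cell <- clip_halfplane(cell, nx, ny, cc)
    if (nrow(cell) < 3) break
  }
  cell
}

#' Generate a Voronoi tessellation emulating dissemination areas
#'
#' Draws `n_das` uniform seed points in the region and returns their Voronoi
#' cells clipped to the region; the cells partition the region exactly.
#' Degenerate draws (a seed whose cell collapses) are re-drawn a bounded
#' number of times.
#'
#' @param region A [study_region()].
#' @param n_das Number of cells (>= 3).
#' @param rng_seed Optional integer seed.
#' @return Tibble with one row per dissemination area: `da_id`, `polygon`
#'   (list column of vertex matrices), `seed_x`, `seed_y`, `centroid_x`,
#'   `centroid_y`, `area` (sq mi).
#' @examples
#' das <- generate_tessellation(study_region(0, 10, 0, 10), 4, rng_seed = 1)
#' sum(das$area)  # 100
#' @export
generate_tessellation <- function(region, n_das, rng_seed = NULL) {
  stopifnot(inherits(region, "study_region"))
  if (n_das < 3) stop("`n_das` must be at least 3")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  for (attempt in 1:10) {
    seeds <- cbind(stats::runif(n_das, region$x_min, region$x_max),
                   stats::runif(n_das, region$y_min, region$y_max))
    cells <- lapply(seq_len(n_das), voronoi_cell, seeds = seeds, region = region)
    areas <- vapply(cells, polygon_area, numeric(1))
    if (all(vapply(cells, nrow, integer(1)) >= 3) && all(areas > 0)) {
      cents <- t(vapply(cells, polygon_centroid, numeric(2)))
      return(tibble::tibble(
        da_id = sprintf("DA%04d", seq_len(n_das)),
        polygon = cells,
        seed_x = seeds[, 1], seed_y = seeds[, 2],
        centroid_x = cents[, 1], centroid_y = cents[, 2],
        area = areas))
    }
  }
  stop("degenerate seed configuration persisted after 10 re-draws")
}

# Kernel-smoothed standard-normal random field sampled at DA centroids.
# Returns one standardized value per DA; a constant field (infinite-bandwidth
# limit) standardizes to all zeros.
smoothed_field <- function(cx, cy, bandwidth) {
  n <- length(cx)
  e <- stats::rnorm(n)
  d2 <- outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
  w <- exp(-d2 / (2 * bandwidth^2))
  z <- as.numeric(w %*% e)
  s <- stats::sd(z)
  if (!is.finite(s) || s < 1e-12) return(rep(0, n))
  pmin(pmax((z - mean(z)) / s, -2.5), 2.5)
}

#' Assign census-style covariates and population to a tessellation
#'
#' Each covariate is an independent kernel-smoothed Gaussian random field
#' evaluated at the DA centroids and affinely mapped onto a plausible
#' metropolitan range: centred on the catalogue median with half-IQR
#' dispersion (population density on the log scale). Population is made
#' internally consistent with the density covariate:
#' `population = pop_density * area * 2.589988` (km^2 per sq mi).
#'
#' @param das Tessellation tibble from [generate_tessellation()].
#' @param config A [sim_config()]; uses its bandwidth and, when `rng_seed`
#'   is not `NULL`, seeds the field draws.
#' @param rng_seed Optional seed overriding the config's.
#' @return `das` with `population` and one column per covariate appended.
#' @export
assign_covariates <- function(das, config, rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  cat_ <- covariate_catalogue()
  h <- config$covariate_smoothing_bandwidth
  out <- das
  for (k in seq_len(nrow(cat_))) {
    z <- smoothed_field(das$centroid_x, das$centroid_y, h)
    if (cat_$dist[k] == "lognormal") {
      s <- 0.5 * (log(cat_$q3[k]) - log(cat_$q1[k])) / 1.349
      val <- exp(log(cat_$median[k]) + s * z)
    } else {
      s <- 0.5 * (cat_$q3[k] - cat_$q1[k]) / 1.349
      val <- cat_$median[k] + s * z
    }
    if (startsWith(cat_$name[k], "pct_")) val <- pmin(pmax(val, 0), 100)
    out[[cat_$name[k]]] <- val
  }
  out$population <- out$pop_density * out$area * KM2_PER_MI2
  out
}

# Per-DA peak intensity (users per sq mi) implied by the config's beta.
da_intensity <- function(das, beta) {
  x <- as.matrix(apply_model_scaling(das))
  eta <- beta[["intercept"]] + as.numeric(x %*% beta[colnames(x)])
  lambda <- exp(eta)
  if (!all(is.finite(lambda))) stop("non-finite user intensity; check `beta`")
  lambda
}

# Uniform points inside a polygon by bounding-box rejection.
sample_in_polygon <- function(n, xy) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  got <- matrix(numeric(0), 0, 2)
  while (nrow(got) < n) {
    m <- max(2L * (n - nrow(got)), 16L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    ok <- point_in_polygon(px, py, xy)
    got <- rbind(got, cbind(px[ok], py[ok]))
  }
  got[seq_len(n), , drop = FALSE]
}

#' Simulate app users as an inhomogeneous Poisson point process
#'
#' For each DA `j` the user count is Poisson with mean `lambda_j * area_j`,
#' where `log lambda_j` is linear in the scaled covariates (`config$beta`),
#' and points are uniform within the DA polygon. Each user independently
#' withholds their location with probability `p_hidden`.
#'
#' @param das Tessellation with covariates ([assign_covariates()]).
#' @param config A [sim_config()].
#' @param rng_seed Optional seed overriding the config's.
#' @return Tibble: `user_id`, `x`, `y`, `da_id`, `shows_location`.
#' @export
simulate_users <- function(das, config, rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  lambda <- da_intensity(das, config$beta)
  counts <- stats::rpois(nrow(das), lambda * das$area)
  pts <- purrr::map2(counts, das$polygon, sample_in_polygon)
  users <- tibble::tibble(
    da_id = rep(das$da_id, counts),
    x = unlist(purrr::map(pts, ~ .x[, 1]), use.names = FALSE),
    y = unlist(purrr::map(pts, ~ .x[, 2]), use.names = FALSE))
  n <- nrow(users)
  p_hide <- if (is.function(config$p_hidden)) {
    config$p_hidden(users$x, users$y)
  } else {
    rep(config$p_hidden, n)
  }
  users$shows_location <- stats::runif(n) >= p_hide
  users$user_id <- sprintf("U%06d", seq_len(n))
  users[, c("user_id", "x", "y", "da_id", "shows_location")]
}

#' Generate the full synthetic world
#'
#' Convenience wrapper: tessellation, covariates, then users, all driven by
#' `config$rng_seed`.
#'
#' @param config A [sim_config()].
#' @param region A [study_region()].
#' @return List with elements `das` and `users`.
#' @export
simulate_world <- function(config, region = study_region()) {
  das <- generate_tessellation(region, config$n_das, rng_seed = config$rng_seed)
  das <- assign_covariates(das, config, rng_seed = config$rng_seed + 1L)
  users <- simulate_users(das, config, rng_seed = config$rng_seed + 2L)
  list(das = das, users = users, region = region)
}

#' Build a distance-ordered profile listing at a point
#'
#' Emulates the app screen seen at a virtual sampling location: users sorted
#' by ascending Euclidean distance (ties broken by user id), truncated to the
#' `max_list` nearest, with the distance displayed only for users who share
#' their location. The true `distance` column is retained for validation;
#' classification uses only `displayed_distance` and position.
#'
#' @param users User tibble (`user_id`, `x`, `y`, `shows_location`).
#' @param x,y Sampling-point coordinates (miles).
#' @param max_list Listing truncation length (>= 1); screens of a typical
#'   grid app show on the order of 100 nearby profiles.
#' @return Tibble: `position`, `user_id`, `distance`, `displayed_distance`
#'   (`NA` when hidden), `shows_location`.
#' @examples
#' u <- tibble::tibble(user_id = c("a", "b"), x = c(0, 1), y = c(0.5, 0),
#'                     shows_location = c(TRUE, FALSE))
#' build_listing(u, 0, 0)
#' @export
build_listing <- function(users, x, y, max_list = 100L) {
  stopifnot(max_list >= 1)
  if (nrow(users) == 0) {
    return(tibble::tibble(position = integer(), user_id = character(),
                          distance = numeric(), displayed_distance = numeric(),
                          shows_location = logical()))
  }
  d <- sqrt((users$x - x)^2 + (users$y - y)^2)
  ord <- order(d, users$user_id)
  ord <- ord[seq_len(min(length(ord), max_list))]
  tibble::tibble(
    position = seq_along(ord),
    user_id = users$user_id[ord],
    distance = d[ord],
    displayed_distance = ifelse(users$shows_location[ord], d[ord], NA_real_),
    shows_location = users$shows_location[ord])
}
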