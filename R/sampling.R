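# The virtual sampling protocol: a systematic grid of sampling points, a
# distance-ordered listing at each point, the positional inclusion rule for
# location-withheld profiles, land-area denominators, and the rounded
# density outcome.

#' Round half away from zero
#'
#' `round()` in R rounds half to even; densities here use the convention a
#' field researcher would apply by hand, half away from zero (5.5 -> 6).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Build the systematic sampling grid
#'
#' All lattice points `origin + (i * spacing, j * spacing)` that fall inside
#' the region (bounds inclusive), in row-major order (south to north, west to
#' east) before randomization.
#'
#' @param region A [study_region()].
#' @param spacing Lattice spacing in miles (> 0); the default 2-mile spacing
#'   with a 1-mile counting radius gives tangent, interior-disjoint buffers.
#' @param origin Length-2 numeric, a lattice point inside the region.
#' @return Tibble: `point_id`, `x`, `y`.
#' @examples
#' build_grid(study_region(0, 10, 0, 10), spacing = 2, origin = c(1, 1))
#' @export
build_grid <- function(region, spacing = 2, origin = c(0.5, 0.5)) {
  stopifnot(inherits(region, "study_region"))
  if (spacing <= 0) stop("`spacing` must be positive")
  if (origin[1] < region$x_min || origin[1] > region$x_max ||
      origin[2] < region$y_min || origin[2] > region$y_max) {
    stop("`origin` must lie inside the region")
  }
  eps <- 1e-9
  ix <- seq(ceiling((region$x_min - origin[1]) / spacing - eps),
            floor((region$x_max - origin[1]) / spacing + eps))
  iy <- seq(ceiling((region$y_min - origin[2]) / spacing - eps),
            floor((region$y_max - origin[2]) / spacing + eps))
  g <- expand.grid(x = origin[1] + ix * spacing, y = origin[2] + iy * spacing)
  tibble::tibble(point_id = sprintf("P%04d", seq_len(nrow(g))),
                 x = g$x, y = g$y)
}

#' Randomize sampling order and assign time slots
#'
#' Draws a uniform random permutation as the sampling order, then partitions
#' the permuted sequence across the six weekday-evening slots in
#' chronological order (Mon before 8 pm first), with slot sizes differing by
#' at most one.
#'
#' @param points Grid tibble from [build_grid()].
#' @param rng_seed Optional integer seed.
#' @return `points` with `sample_order` and `slot` (factor over
#'   [slot_levels()]) appended.
#' @export
assign_slots <- function(points, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(points)
  points$sample_order <- sample.int(n)
  sizes <- rep(n %/% 6L, 6L)
  extra <- n %% 6L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  slot_of_rank <- rep(slot_levels(), times = sizes)
  points$slot <- factor(slot_of_rank[points$sample_order],
                        levels = slot_levels())
  points
}

#' Classify listing entries against the counting radius
#'
#' Displayed distances decide inclusion directly (`<= radius` in,
#' `> radius` out). Location-withheld entries are resolved positionally:
#' hidden entries listed before the last displayed entry within the radius
#' must also be within it (the list is distance-ordered); hidden entries
#' after the first displayed entry beyond the radius must be beyond it;
#' hidden entries between those anchors (or with no resolving anchor, e.g. a
#' fully hidden listing) are ambiguous and are not counted.
#'
#' @param listing Listing tibble ([build_listing()] or same schema: at least
#'   `position` and `displayed_distance`, `NA` meaning hidden).
#' @param radius Counting radius in miles.
#' @return The listing with a `status` column
#'   (`"included"`/`"excluded"`/`"ambiguous"`).
#' @examples
#' l <- tibble::tibble(position = 1:4,
#'                     displayed_distance = c(0.5, NA, 0.9, 1.4))
#' classify_listing(l, radius = 1)$status
#' @export
classify_listing <- function(listing, radius = 1) {
  n <- nrow(listing)
  if (n == 0) {
    listing$status <- character(0)
    return(listing)
  }
  d <- listing$displayed_distance
  shown <- which(!is.na(d))
  if (is.unsorted(d[shown])) {
    stop("displayed distances must be non-decreasing along the listing")
  }
  status <- rep(NA_character_, n)
  status[shown] <- ifelse(d[shown] <= radius, "included", "excluded")
  last_in <- if (any(d[shown] <= radius)) max(shown[d[shown] <= radius]) else -Inf
  first_out <- if (any(d[shown] > radius)) min(shown[d[shown] > radius]) else Inf
  hid <- which(is.na(d))
  status[hid] <- dplyr::case_when(
    hid < last_in ~ "included",
    hid > first_out ~ "excluded",
    TRUE ~ "ambiguous")
  listing$status <- status
  listing
}

#' Summarize a classified listing
#' @param classified Output of [classify_listing()].
#' @return Tibble with `included`, `excluded`, `ambiguous` counts.
#' @export
classification_counts <- function(classified) {
  tibble::tibble(
    included = sum(classified$status == "included"),
    excluded = sum(classified$status == "excluded"),
    ambiguous = sum(classified$status == "ambiguous"))
}

#' Count users in one buffer with campaign-level deduplication
#'
#' Counts the included entries of a classified listing, skipping user ids
#' already counted at an earlier point in the sampling order (users are
#' blocked so they are never counted twice in a campaign). Ambiguous entries
#' are never counted.
#'
#' @param classified Classified listing (with `user_id`).
#' @param seen_ids Character vector of ids counted earlier in the campaign.
#' @return List: `user_count`, `ambiguous_count`, `counted_ids`.
#' @export
count_buffer <- function(classified, seen_ids = character()) {
  inc <- classified$user_id[classified$status == "included"]
  new <- setdiff(inc, seen_ids)
  list(user_count = length(new),
       ambiguous_count = sum(classified$status == "ambiguous"),
       counted_ids = new)
}

#' Land area within a sampling radius
#'
#' Area of the intersection of the disc around a sampling point with the
#' union of DA polygons; territory outside the tessellation counts as
#' non-land (water / outside the study region). Computed exactly per DA cell
#' and summed (cells have disjoint interiors).
#'
#' @param x,y Sampling-point coordinates (miles).
#' @param das Tessellation tibble.
#' @param radius Disc radius in miles (> 0).
#' @return Land area in sq mi (0 when the disc misses the tessellation; such
#'   buffers are dropped by [sample_campaign()]).
#' @export
land_area <- function(x, y, das, radius = 1) {
  if (radius <= 0) stop("`radius` must be positive")
  # prune cells that cannot reach the disc
  reach <- vapply(das$polygon, function(p) {
    sqrt(max((p[, 1] - mean(range(p[, 1])))^2 + (p[, 2] - mean(range(p[, 2])))^2))
  }, numeric(1))
  bx <- vapply(das$polygon, function(p) mean(range(p[, 1])), numeric(1))
  by <- vapply(das$polygon, function(p) mean(range(p[, 2])), numeric(1))
  cand <- which(sqrt((bx - x)^2 + (by - y)^2) <= radius + reach + 1e-9)
  if (!length(cand)) return(0)
  sum(vapply(das$polygon[cand],
             function(p) disc_polygon_area(x, y, radius, p), numeric(1)))
}

#' Rounded app-user density
#'
#' Users counted in a buffer divided by the land area within the sampling
#' radius, rounded half away from zero to the nearest integer.
#'
#' @param user_count Non-negative count.
#' @param land Land area in sq mi (> 0).
#' @return Non-negative integer density (users per sq mi).
#' @examples
#' compute_density(10, pi)  # 3
#' compute_density(11, 2)   # 6
#' @export
compute_density <- function(user_count, land) {
  if (any(land <= 0)) stop("`land` must be positive")
  as.integer(round_half_away(user_count / land))
}

#' Run a full virtual sampling campaign
#'
#' Visits the sampling points in `sample_order`; at each visit the user pool
#' is thinned by the slot's activity probability
#' (`exp(slot_effects - max(slot_effects))`, emulating how many users are
#' online in that time slot), a distance-ordered listing is built and
#' classified, and included users not counted at an earlier visit are
#' counted. Buffers whose land area is zero are dropped with a warning.
#'
#' @param points Grid with `sample_order` and `slot` ([assign_slots()]).
#' @param users User tibble.
#' @param das Tessellation tibble (for land area).
#' @param radius Counting radius in miles.
#' @param max_list Listing truncation length.
#' @param slot_effects Named log-scale activity vector over [slot_levels()],
#'   or `NULL` for no thinning (all users always online).
#' @param rng_seed Optional seed for the thinning draws.
#' @return Tibble of buffer observations in sampling order: `point_id`, `x`,
#'   `y`, `slot`, `sample_order`, `user_count`, `ambiguous_count`,
#'   `land_area`, `density`.
#' @export
sample_campaign <- function(points, users, das, radius = 1, max_list = 100L,
                            slot_effects = default_slot_effects(),
                            rng_seed = NULL) {
  stopifnot(all(c("sample_order", "slot") %in% names(points)))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  p_active <- if (is.null(slot_effects)) {
    stats::setNames(rep(1, 6), slot_levels())
  } else {
    exp(slot_effects[slot_levels()] - max(slot_effects))
  }
  ord <- order(points$sample_order)
  seen <- character(0)
  rows <- vector("list", length(ord))
  dropped <- 0L
  for (k in seq_along(ord)) {
    pt <- points[ord[k], ]
    land <- land_area(pt$x, pt$y, das, radius)
    p <- p_active[[as.character(pt$slot)]]
    active <- if (p >= 1) users else users[stats::runif(nrow(users)) < p, ]
    listing <- build_listing(active, pt$x, pt$y, max_list)
    cls <- classify_listing(listing, radius)
    cnt <- count_buffer(cls, seen)
    if (land <= 0) {
      dropped <- dropped + 1L
      next
    }
    seen <- c(seen, cnt$counted_ids)
    rows[[k]] <- tibble::tibble(
      point_id = pt$point_id, x = pt$x, y = pt$y,
      slot = pt$slot, sample_order = pt$sample_order,
      user_count = cnt$user_count, ambiguous_count = cnt$ambiguous_count,
      land_area = land,
      density = compute_density(cnt$user_count, land))
  }
  if (dropped > 0) {
    warning(sprintf("dropped %d buffer(s) with zero land area", dropped))
  }
  dplyr::bind_rows(rows)
}
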