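test_that("grid construction enumerates exactly the interior lattice points", {
  region <- study_region(0, 10, 0, 10)
  g <- build_grid(region, spacing = 2, origin = c(1, 1))
  expect_equal(nrow(g), 25)
  expect_setequal(unique(g$x), c(1, 3, 5, 7, 9))
  g1 <- build_grid(region, spacing = 50, origin = c(4, 6))
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$x, g1$y), c(4, 6))
  expect_error(build_grid(region, spacing = 0), "positive")
  expect_error(build_grid(region, spacing = 2, origin = c(-1, 5)), "inside")

  # brute-force enumeration over a bounding superset of lattice indices
  set.seed(83)
  for (rep in 1:5) {
    bounds <- sort(runif(2, 0, 20)); by <- sort(runif(2, 0, 20))
    reg <- study_region(bounds[1], bounds[2] + 1, by[1], by[2] + 1)
    sp <- runif(1, 0.7, 3)
    org <- c(runif(1, reg$x_min, reg$x_max), runif(1, reg$y_min, reg$y_max))
    g <- build_grid(reg, sp, org)
    all_pts <- expand.grid(i = -60:60, j = -60:60)
    ax <- org[1] + all_pts$i * sp
    ay <- org[2] + all_pts$j * sp
    inside <- ax >= reg$x_min & ax <= reg$x_max &
      ay >= reg$y_min & ay <= reg$y_max
    expect_equal(nrow(g), sum(inside))
    expect_setequal(paste(round(g$x, 9), round(g$y, 9)),
                    paste(round(ax[inside], 9), round(ay[inside], 9)))
  }
})

test_that("slot assignment is a balanced partition of a random permutation", {
  g6 <- tibble::tibble(point_id = as.character(1:6), x = 1:6, y = 1)
  a6 <- assign_slots(g6, rng_seed = 2)
  expect_setequal(as.character(a6$slot), slot_levels())
  expect_setequal(a6$sample_order, 1:6)

  g <- tibble::tibble(point_id = as.character(1:263), x = 1:263, y = 1)
  a <- assign_slots(g, rng_seed = 9)
  sizes <- table(a$slot)
  expect_lte(max(sizes) - min(sizes), 1)
  # chronological partition: earlier sample_order means same-or-earlier slot
  ord <- a[order(a$sample_order), ]
  expect_true(!is.unsorted(as.integer(ord$slot)))
  expect_identical(assign_slots(g, rng_seed = 9), a)
})

test_that("listing classification applies the positional hidden-profile rule", {
  l1 <- tibble::tibble(position = 1:4, user_id = c("A", "B", "C", "D"),
                       displayed_distance = c(0.5, NA, 0.9, 1.4))
  c1 <- classify_listing(l1, radius = 1)
  expect_equal(c1$status, c("included", "included", "included", "excluded"))

  l2 <- tibble::tibble(position = 1:3, user_id = c("A", "B", "C"),
                       displayed_distance = c(0.5, NA, 1.4))
  c2 <- classify_listing(l2, radius = 1)
  expect_equal(c2$status, c("included", "ambiguous", "excluded"))
  expect_equal(unlist(classification_counts(c2)),
               c(included = 1L, excluded = 1L, ambiguous = 1L))

  # fully displayed listings are never ambiguous
  set.seed(19)
  for (i in 1:20) {
    l <- random_listing(sample(1:12, 1), p_hidden = 0)
    expect_true(all(classify_listing(l, 1)$status != "ambiguous"))
  }
  # fully hidden listings are entirely ambiguous
  lh <- tibble::tibble(position = 1:3, user_id = c("A", "B", "C"),
                       displayed_distance = NA_real_)
  expect_true(all(classify_listing(lh, 1)$status == "ambiguous"))
  expect_error(
    classify_listing(tibble::tibble(position = 1:2,
                                    displayed_distance = c(1.2, 0.3)), 1),
    "non-decreasing")
})

test_that("classification equals the constraint-satisfaction oracle on random listings", {
  set.seed(23)
  for (i in 1:300) {
    l <- random_listing(sample(1:12, 1), p_hidden = runif(1, 0.1, 0.9))
    got <- classify_listing(l, radius = 1)$status
    expect_identical(got, csp_classify(l$displayed_distance, 1))
  }
})

test_that("buffer counting excludes ambiguous entries and deduplicates across the campaign", {
  l2 <- classify_listing(
    tibble::tibble(position = 1:3, user_id = c("A", "B", "C"),
                   displayed_distance = c(0.5, NA, 1.4)), 1)
  cnt <- count_buffer(l2)
  expect_equal(cnt$user_count, 1)
  expect_equal(cnt$ambiguous_count, 1)
  expect_equal(count_buffer(l2, seen_ids = "A")$user_count, 0)
  empty <- count_buffer(classify_listing(build_listing(
    tibble::tibble(user_id = character(), x = numeric(), y = numeric(),
                   shows_location = logical()), 0, 0), 1))
  expect_equal(c(empty$user_count, empty$ambiguous_count), c(0, 0))
})

test_that("a user in two overlapping buffers is counted only at the earlier visit", {
  region <- study_region(0, 4, 0, 4)
  das <- generate_tessellation(region, 4, rng_seed = 1)
  das$population <- rep(100, 4)
  # one user equidistant from two sampling points 1 mile apart
  users <- tibble::tibble(user_id = "solo", x = 2, y = 2,
                          da_id = "DA0001", shows_location = TRUE)
  points <- tibble::tibble(point_id = c("P1", "P2"), x = c(1.6, 2.4),
                           y = 2, sample_order = c(2L, 1L),
                           slot = factor(c("mon_pre8", "mon_post8"),
                                         levels = slot_levels()))
  buf <- suppressWarnings(
    sample_campaign(points, users, das, radius = 1, slot_effects = NULL))
  expect_equal(sum(buf$user_count), 1)
  # counted at the earlier sample_order (P2)
  expect_equal(buf$user_count[buf$point_id == "P2"], 1)
  expect_equal(buf$user_count[buf$point_id == "P1"], 0)
})

test_that("adding a displayed in-radius user never decreases the count", {
  set.seed(29)
  for (i in 1:25) {
    users <- tibble::tibble(
      user_id = sprintf("u%02d", 1:20),
      x = runif(20, -2, 2), y = runif(20, -2, 2),
      shows_location = runif(20) > 0.3)
    base <- count_buffer(classify_listing(build_listing(users, 0, 0), 1))
    th <- runif(1, 0, 2 * pi); rr <- runif(1, 0, 0.99)
    extra <- tibble::tibble(user_id = "zzz_new", x = rr * cos(th),
                            y = rr * sin(th), shows_location = TRUE)
    more <- count_buffer(classify_listing(
      build_listing(dplyr::bind_rows(users, extra), 0, 0), 1))
    expect_gte(more$user_count, base$user_count)
  }
})

test_that("land area handles interior, coastline and off-map buffers", {
  region <- study_region(0, 12, 0, 12)
  das <- generate_tessellation(region, 15, rng_seed = 13)
  expect_equal(land_area(6, 6, das, radius = 1), pi, tolerance = 1e-9)
  # tessellation boundary: half the disc is off-map
  expect_equal(land_area(6, 0, das, radius = 1), pi / 2, tolerance = 1e-9)
  expect_equal(land_area(40, 40, das, radius = 1), 0)
  expect_error(land_area(6, 6, das, radius = 0), "positive")
})

test_that("zero-land buffers are dropped with a warning", {
  region <- study_region(0, 6, 0, 6)
  das <- generate_tessellation(region, 5, rng_seed = 3)
  das$population <- rep(10, 5)
  users <- tibble::tibble(user_id = "u1", x = 3, y = 3, da_id = "DA0001",
                          shows_location = TRUE)
  points <- tibble::tibble(point_id = c("in", "out"), x = c(3, 50),
                           y = c(3, 50), sample_order = 1:2,
                           slot = factor(c("mon_pre8", "mon_pre8"),
                                         levels = slot_levels()))
  expect_warning(buf <- sample_campaign(points, users, das, radius = 1,
                                        slot_effects = NULL),
                 "zero land area")
  expect_equal(buf$point_id, "in")
})

test_that("density is count over land area, rounded half away from zero", {
  expect_equal(compute_density(0, pi), 0L)
  expect_equal(compute_density(10, pi), 3L)   # 3.183 -> 3
  expect_equal(compute_density(11, 2), 6L)    # 5.5 -> 6
  expect_error(compute_density(1, 0), "positive")
  expect_equal(round_half_away(c(0.5, 1.5, -0.5, 2.5)), c(1, 2, -1, 3))
  expect_equal(round_half_away(5.5118, 1), 5.5)
})

test_that("default 2-mile grid with 1-mile buffers is interior-disjoint", {
  g <- build_grid(study_region(), spacing = 2, origin = c(0.5, 0.5))
  d <- as.matrix(dist(cbind(g$x, g$y)))
  diag(d) <- Inf
  expect_gte(min(d), 2)  # tangency at exactly twice the radius
})
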