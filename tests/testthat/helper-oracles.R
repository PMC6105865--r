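# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Monte-Carlo integration for areas, interval
# constraint propagation for listing classification, brute-force summation
# and sorting, and generic numerical likelihood maximization.

# Monte-Carlo area of disc(c, r) intersected with a polygon.
mc_disc_polygon_area <- function(cx, cy, r, xy, n = 1e5) {
  px <- runif(n, cx - r, cx + r)
  py <- runif(n, cy - r, cy + r)
  in_disc <- (px - cx)^2 + (py - cy)^2 <= r^2
  inside <- appdensity:::point_in_polygon(px, py, xy)
  4 * r^2 * mean(in_disc & inside)
}

# Monte-Carlo intersection fraction, sampling inside the polygon's bounding
# box (robust for discs much larger than the polygon).
mc_intersection_fraction <- function(cx, cy, r, xy, n = 1e5) {
  px <- runif(n, min(xy[, 1]), max(xy[, 1]))
  py <- runif(n, min(xy[, 2]), max(xy[, 2]))
  inside <- appdensity:::point_in_polygon(px, py, xy)
  in_disc <- (px - cx)^2 + (py - cy)^2 <= r^2
  sum(inside & in_disc) / sum(inside)
}

# Constraint-satisfaction classification oracle: a hidden entry at position i
# can take any distance in [max displayed before i, min displayed after i]
# (the ordering constraint); it is included iff no consistent assignment
# puts it beyond the radius, excluded iff none puts it within, ambiguous
# otherwise. Displayed entries classify by their own distance.
csp_classify <- function(displayed, radius) {
  n <- length(displayed)
  out <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(displayed[i])) {
      out[i] <- if (displayed[i] <= radius) "included" else "excluded"
    } else {
      before <- displayed[seq_len(i - 1)]
      after <- if (i < n) displayed[(i + 1):n] else numeric(0)
      lo <- if (any(!is.na(before))) max(before, na.rm = TRUE) else 0
      hi <- if (any(!is.na(after))) min(after, na.rm = TRUE) else Inf
      out[i] <- if (hi <= radius) "included"
        else if (lo > radius) "excluded"
        else "ambiguous"
    }
  }
  out
}

# Random listing with continuous sorted distances around the radius.
random_listing <- function(len, radius = 1, p_hidden = 0.4) {
  d <- sort(runif(len, 0, 2 * radius))
  hidden <- runif(len) < p_hidden
  tibble::tibble(position = seq_len(len),
                 user_id = sprintf("u%02d", seq_len(len)),
                 distance = d,
                 displayed_distance = ifelse(hidden, NA_real_, d),
                 shows_location = !hidden)
}

# Direct Poisson log-likelihood maximization (independent of glm/IRLS).
optim_poisson <- function(X, y, offset = NULL) {
  if (is.null(offset)) offset <- rep(0, length(y))
  negll <- function(b) {
    eta <- as.numeric(X %*% b) + offset
    -sum(y * eta - exp(eta))
  }
  grad <- function(b) {
    eta <- as.numeric(X %*% b) + offset
    -as.numeric(t(X) %*% (y - exp(eta)))
  }
  fit <- optim(rep(0, ncol(X)), negll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Type-7 (linear interpolation) quantile computed from first principles.
interp_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

# Small world shared by several tests (cached per session).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(rng_seed = 99, n_das = 80,
                        covariate_smoothing_bandwidth = 2.5)
      cache <<- simulate_world(cfg, study_region(0, 16, 0, 16))
    }
    cache
  }
})
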