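# Poisson regression of buffer density with a forced sampling-time block,
# backward AIC elimination, likelihood ratio testing, McFadden pseudo r2,
# IRR reporting, and Bonferroni outlier detection.

#' Fit a Poisson density model
#'
#' Maximizes the Poisson log-likelihood with a log link by iteratively
#' reweighted least squares (deviance convergence 1e-8, at most 100
#' iterations); the covariance is the inverse Fisher information at the
#' optimum. The default outcome is the rounded integer density; with
#' `offset_mode = TRUE` the raw buffer count is modelled with an
#' `offset(log(land_area))` instead (non-default variant).
#'
#' @param design Design-matrix tibble from [build_design_matrix()].
#' @param terms Character vector of model terms (column names; `"slot"`
#'   expands to the 5 slot contrasts). Empty gives the intercept-only model.
#' @param offset_mode Model `user_count` with a log land-area offset instead
#'   of the rounded density.
#' @return A `density_fit` object wrapping the `glm` fit.
#' @examples
#' d <- tibble::tibble(density = c(3L, 5L, 4L))
#' coef(fit_poisson(d, character(0))$glm)  # log(4)
#' @export
fit_poisson <- function(design, terms = c("slot", covariate_names(scaled = TRUE)),
                        offset_mode = FALSE) {
  rhs <- if (length(terms)) terms else "1"
  fml <- if (offset_mode) {
    stats::reformulate(c(rhs, "offset(log(land_area))"),
                       response = "user_count")
  } else {
    stats::reformulate(rhs, response = "density")
  }
  fit <- stats::glm(fml, family = stats::poisson(link = "log"), data = design,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; inestimable terms: ",
         paste(bad, collapse = ", "))
  }
  if (!fit$converged) stop("IRLS did not converge in 100 iterations")
  # make the stored call self-contained so refits (e.g. drop/update-based
  # tools) do not depend on this function's local scope
  fit$call$data <- design
  k <- length(stats::coef(fit))
  if (nrow(design) <= k) stop("need more observations than parameters")
  structure(list(glm = fit, terms = terms, data = design,
                 offset_mode = offset_mode,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 aic = -2 * as.numeric(stats::logLik(fit)) + 2 * k,
                 n_obs = nrow(design), k = k),
            class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat("Poisson density model:",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
      "\n")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AIC = %.3f\n",
              x$n_obs, x$k, x$log_likelihood, x$aic))
  invisible(x)
}

#' Tidy a density model fit
#'
#' Broom-style coefficient table on the log (coefficient) scale.
#'
#' @param x A `density_fit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
#' @export
tidy.density_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Model-level summary of a density fit
#'
#' @param x A `density_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_obs`, `k`, `log_likelihood`, `aic`,
#'   `deviance`, `dispersion` (quasi-Poisson Pearson scale, diagnostic
#'   only), `converged`.
#' @exportS3Method generics::glance
#' @export
glance.density_fit <- function(x, ...) {
  pearson <- sum(stats::residuals(x$glm, type = "pearson")^2)
  tibble::tibble(n_obs = x$n_obs, k = x$k,
                 log_likelihood = x$log_likelihood, aic = x$aic,
                 deviance = stats::deviance(x$glm),
                 dispersion = pearson / stats::df.residual(x$glm),
                 converged = x$glm$converged)
}

#' Incidence rate ratios with Wald 95% intervals
#'
#' Exponentiates each coefficient with `exp(beta -/+ 1.96 * SE)` interval
#' endpoints and the percent-change reading `100 * (IRR - 1)`.
#'
#' @param fit A `density_fit`.
#' @param include_intercept Keep the intercept row (off by default; it is a
#'   baseline rate, not a rate ratio).
#' @return Tibble: `term`, `estimate`, `irr`, `ci_low`, `ci_high`,
#'   `percent_change`.
#' @export
irr_table <- function(fit, include_intercept = FALSE) {
  td <- tidy.density_fit(fit)
  if (!include_intercept) td <- td[td$term != "(Intercept)", ]
  tibble::tibble(term = td$term,
                 estimate = td$estimate,
                 irr = exp(td$estimate),
                 ci_low = exp(td$estimate - 1.96 * td$std.error),
                 ci_high = exp(td$estimate + 1.96 * td$std.error),
                 percent_change = 100 * (exp(td$estimate) - 1))
}

#' Percent change implied by an incidence rate ratio
#'
#' `100 * (irr - 1)`, rounded (half away from zero) to the nearest integer
#' percent as customarily reported: an IRR of 0.26 per added household
#' member reads as a 74% decrease in density.
#'
#' @param irr Positive rate ratio(s).
#' @param digits Decimal places of the reported percent.
#' @return Numeric percent change(s).
#' @examples
#' irr_to_percent_change(c(0.26, 1.08))  # -74, 8
#' @export
irr_to_percent_change <- function(irr, digits = 0) {
  if (any(irr <= 0)) stop("`irr` must be positive")
  round_half_away(100 * (irr - 1), digits)
}

#' Backward elimination by AIC with forced terms
#'
#' From the full model, repeatedly drops the removable term whose deletion
#' gives the lowest AIC, as long as that AIC improves on the current model;
#' the intercept and `forced` terms (the sampling-time block by default) are
#' never dropped. Ties (within 1e-10) resolve to the earliest-listed
#' candidate.
#'
#' @param design Design-matrix tibble.
#' @param candidates Removable terms, in priority order.
#' @param forced Terms always kept.
#' @param offset_mode Passed to [fit_poisson()].
#' @return The final `density_fit`, with attribute `"path"`: a tibble of the
#'   drops taken (`step`, `dropped`, `aic`).
#' @export
backward_eliminate_aic <- function(design,
                                   candidates = covariate_names(scaled = TRUE),
                                   forced = "slot",
                                   offset_mode = FALSE) {
  current <- candidates
  fit <- fit_poisson(design, c(forced, current), offset_mode = offset_mode)
  path <- list(tibble::tibble(step = 0L, dropped = NA_character_,
                              aic = fit$aic))
  step <- 0L
  while (length(current)) {
    aics <- vapply(seq_along(current), function(i) {
      fit_poisson(design, c(forced, current[-i]), offset_mode = offset_mode)$aic
    }, numeric(1))
    best <- min(aics)
    if (best >= fit$aic - 1e-10) break
    i <- which(aics <= best + 1e-10)[1]
    step <- step + 1L
    path[[step + 1L]] <- tibble::tibble(step = step, dropped = current[i],
                                        aic = aics[i])
    current <- current[-i]
    fit <- fit_poisson(design, c(forced, current), offset_mode = offset_mode)
  }
  attr(fit, "path") <- dplyr::bind_rows(path)
  fit
}

#' Likelihood ratio test for nested density models
#'
#' @param full,reduced `density_fit` objects on the same observations with
#'   the reduced model's terms a subset of the full model's.
#' @return One-row tibble: `statistic` (`2 * (llf - llr)`), `df`, `p_value`
#'   (chi-squared upper tail).
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$n_obs != reduced$n_obs) {
    stop("models were fitted to different numbers of observations")
  }
  if (!all(reduced$terms %in% full$terms)) {
    stop("models are not nested: reduced terms must be a subset of full terms")
  }
  stat <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  df <- full$k - reduced$k
  if (df <= 0) {
    return(tibble::tibble(statistic = stat, df = df, p_value = 1))
  }
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' McFadden likelihood-based pseudo r-squared
#'
#' `1 - logLik(fit) / logLik(null)` against the intercept-only model on the
#' same observations.
#'
#' @param fit A `density_fit`.
#' @param null_fit Intercept-only `density_fit` on the same data.
#' @return Value in `[0, 1)`.
#' @export
mcfadden_r2 <- function(fit, null_fit) {
  if (null_fit$k != 1) stop("`null_fit` must be the intercept-only model")
  if (fit$n_obs != null_fit$n_obs) stop("models use different observations")
  if (abs(null_fit$log_likelihood) < .Machine$double.eps) {
    stop("degenerate null log-likelihood of zero")
  }
  1 - fit$log_likelihood / null_fit$log_likelihood
}

#' Bonferroni outlier test
#'
#' Studentized deviance residuals `r_i = d_i / sqrt(1 - h_i)` (with `h_i`
#' the GLM hat values) referred to the standard normal, two-sided p-values
#' Bonferroni-multiplied by the number of observations, flagged at the
#' adjusted level `alpha`. Flags mark buffers with statistically unexpected
#' densities given the model.
#'
#' @param fit A `density_fit`.
#' @param alpha Family-wise significance level.
#' @return Tibble: `point_id` (when available), `observed`, `fitted`,
#'   `std_resid`, `p_value`, `p_bonferroni`, `outlier`.
#' @export
bonferroni_outlier_test <- function(fit, alpha = 0.05) {
  if (fit$n_obs < 3) stop("need at least 3 observations")
  h <- stats::hatvalues(fit$glm)
  if (any(h >= 1 - 1e-12)) stop("degenerate leverage (h = 1)")
  r <- stats::residuals(fit$glm, type = "deviance") / sqrt(1 - h)
  p <- 2 * stats::pnorm(-abs(r))
  pb <- pmin(1, fit$n_obs * p)
  tibble::tibble(
    point_id = if ("point_id" %in% names(fit$data)) fit$data$point_id else
      as.character(seq_len(fit$n_obs)),
    observed = fit$glm$y,
    fitted = stats::fitted(fit$glm),
    std_resid = as.numeric(r),
    p_value = as.numeric(p),
    p_bonferroni = as.numeric(pb),
    outlier = as.numeric(pb) < alpha)
}
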