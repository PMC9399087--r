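# Four-parameter logistic (4PL) dose-response fitting for coculture
# activation assays (e.g. supernatant IL-2 versus peptide concentration):
#   Y = bottom + (top - bottom) / (1 + (ec50 / X)^h)
# with a minimum-estimate convention for curves that never reach a plateau.

.fourpl <- function(x, bottom, top, le50, h) {
  bottom + (top - bottom) / (1 + exp(h * (le50 - log(x))))
}

#' Evaluate a four-parameter logistic curve
#'
#' @param x Doses (positive, linear scale).
#' @param bottom,top Lower and upper asymptotes (response units).
#' @param ec50 Half-maximal effective concentration (same units as `x`).
#' @param h Hill slope (dimensionless; steepness at the midpoint).
#' @return Responses `bottom + (top - bottom) / (1 + (ec50/x)^h)`.
#' @export
fourpl <- function(x, bottom, top, ec50, h) {
  .fourpl(x, bottom, top, log(ec50), h)
}

#' Fit a four-parameter dose-response curve
#'
#' Least-squares 4PL fit, parameterized on log-EC50 internally for optimizer
#' stability and reported on the linear scale. Zero-dose control wells are
#' excluded from the fit (log dose undefined) and reported alongside.
#' Confidence intervals for EC50 and the Hill slope come from a seeded
#' parametric bootstrap (refitting data resampled from the fitted curve plus
#' Gaussian noise at the residual standard deviation).
#'
#' A curve counts as having reached its plateau when the bootstrap CI width
#' of `top` is below half the fitted `top` and the mean response at the
#' highest dose reaches at least 90 percent of the fitted `top`; otherwise
#' the reported EC50 is only a minimum estimate
#' (`ec50_is_minimum_estimate = TRUE`).
#'
#' @param doses Positive doses (>= 4 distinct values required).
#' @param responses Responses, same length.
#' @param n_boot Bootstrap resamples for the CIs (default 1000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return A `fourpl_fit` list: `ec50`, `h`, `top`, `bottom`, `ec50_ci`,
#'   `h_ci`, `top_ci`, `plateau_reached`, `ec50_is_minimum_estimate`,
#'   `residual_sd`, `zero_dose_responses`, `data`.
#' @export
fit_4pl <- function(doses, responses, n_boot = 1000L, seed = 1L,
                    conf_level = 0.95) {
  stopifnot(length(doses) == length(responses))
  zero <- doses == 0
  zero_dose_responses <- responses[zero]
  dat <- tibble(x = doses[!zero], y = responses[!zero])
  if (length(unique(dat$x)) < 4) {
    stop("at least 4 distinct positive doses are required", call. = FALSE)
  }
  if (any(dat$x < 0)) stop("doses must be nonnegative", call. = FALSE)
  means <- dat |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$x)
  if (stats::cor(log(means$x), means$y) < 0) {
    warning("responses decrease with dose; check the response sign",
            call. = FALSE)
  }

  core <- .fit_4pl_core(dat)
  est <- core$est
  fitted_at <- function(x) .fourpl(x, est["bottom"], est["top"],
                                   est["le50"], est["h"])
  mu <- fitted_at(dat$x)
  resid_sd <- sqrt(sum((dat$y - mu)^2) / max(nrow(dat) - 4, 1))
  # immunoassay noise scales with the signal (roughly constant CV), so the
  # parametric bootstrap resamples with multiplicative lognormal noise at
  # the CV estimated from relative residuals on well-determined points
  span <- max(abs(mu))
  mask <- abs(mu) > 0.02 * span
  cv_hat <- sqrt(sum((dat$y[mask] / mu[mask] - 1)^2) /
                   max(sum(mask) - 4, 1))
  sdlog <- sqrt(log(1 + cv_hat^2))

  boot <- .with_seed(seed, {
    replicate(n_boot, {
      yb <- mu * stats::rlnorm(nrow(dat), -sdlog^2 / 2, sdlog)
      eb <- tryCatch(
        .fit_4pl_core(tibble(x = dat$x, y = yb), start = est)$est,
        error = function(e) rep(NA_real_, 4) |>
          setNames(c("bottom", "top", "le50", "h"))
      )
      c(ec50 = exp(eb[["le50"]]), h = eb[["h"]], top = eb[["top"]])
    })
  })
  alpha <- (1 - conf_level) / 2
  qr_ <- function(row) unname(stats::quantile(boot[row, ],
                                              c(alpha, 1 - alpha),
                                              na.rm = TRUE))
  ec50_ci <- qr_("ec50"); h_ci <- qr_("h"); top_ci <- qr_("top")

  top_hat <- est[["top"]]
  max_dose_resp <- means$y[nrow(means)]
  plateau <- (diff(top_ci) < 0.5 * abs(top_hat)) &&
    (max_dose_resp >= 0.9 * top_hat)

  structure(
    list(ec50 = exp(est[["le50"]]), h = est[["h"]],
         top = top_hat, bottom = est[["bottom"]],
         ec50_ci = ec50_ci, h_ci = h_ci, top_ci = top_ci,
         conf_level = conf_level,
         plateau_reached = plateau,
         ec50_is_minimum_estimate = !plateau,
         residual_sd = resid_sd,
         zero_dose_responses = zero_dose_responses,
         data = dat),
    class = "fourpl_fit"
  )
}

.fit_4pl_core <- function(dat, start = NULL) {
  if (is.null(start)) {
    rng <- range(dat$y)
    mid <- mean(rng)
    # dose whose mean response is closest to the midpoint
    means <- dat |>
      dplyr::group_by(.data$x) |>
      dplyr::summarise(y = mean(.data$y), .groups = "drop")
    le50_0 <- log(means$x[which.min(abs(means$y - mid))])
    start <- c(bottom = rng[1], top = rng[2], le50 = le50_0, h = 1)
  }
  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + exp(h * (le50 - log(x)))),
    data = dat,
    start = as.list(start),
    control = minpack.lm::nls.lm.control(maxiter = 300)
  )
  list(est = stats::coef(fit), fit = fit)
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> EC50 = %.4g%s [%.4g, %.4g], h = %.3g [%.3g, %.3g], top = %.4g, bottom = %.4g\n",
    x$ec50, if (x$ec50_is_minimum_estimate) " (minimum estimate)" else "",
    x$ec50_ci[1], x$ec50_ci[2], x$h, x$h_ci[1], x$h_ci[2],
    x$top, x$bottom))
  invisible(x)
}

#' Simulate a dose-response assay
#'
#' Responses follow the 4PL curve times multiplicative lognormal noise with
#' mean 1 and the given coefficient of variation; deterministic given `seed`.
#'
#' @param doses Positive doses.
#' @param bottom,top,ec50,h True curve parameters.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicate wells per dose.
#' @param seed Integer seed.
#' @return Tibble with `dose`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(doses, bottom = 0, top = 1000,
                                   ec50 = 49, h = 1,
                                   noise_cv = 0.1, n_replicates = 2L,
                                   seed = 1L) {
  stopifnot(all(doses > 0), noise_cv >= 0, n_replicates >= 1)
  grid <- tidyr::expand_grid(dose = doses,
                             replicate = seq_len(n_replicates))
  mu <- fourpl(grid$dose, bottom, top, ec50, h)
  noise <- if (noise_cv == 0) rep(1, nrow(grid)) else .with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  tibble(dose = grid$dose, replicate = grid$replicate,
         response = mu * noise)
}
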