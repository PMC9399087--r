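# Two-phase receptor-ligand binding model for a disulfide-capable TCR-pMHC
# pair: reversible noncovalent binding (kon, koff) feeding an irreversible
# covalent (disulfide) state at rate kcov. With C the analyte concentration,
#
#   dB_nc/dt = kon * C * (rmax - B_nc - B_cov) - (koff + kcov) * B_nc
#   dB_cov/dt = kcov * B_nc
#
# C is piecewise-constant over an injection schedule; the covalent state has
# no reverse rate (a reducing agent such as DTT is modelled as kcov = 0).

#' Two-phase binding model parameters
#'
#' @param kon Association rate constant (per molar per second).
#' @param koff Noncovalent dissociation rate constant (per second).
#' @param kcov Covalent (disulfide) conversion rate constant (per second);
#'   0 models a reducing agent that prevents bond formation.
#' @param rmax Maximal response (RU), proportional to immobilized receptor.
#' @return A `kinetic_params` list; the derived equilibrium constant
#'   `keq = koff/kon` (molar) is available via [keq()].
#' @export
kinetic_params <- function(kon, koff, kcov = 0, rmax = 100) {
  stopifnot(kon >= 0, koff >= 0, kcov >= 0, rmax >= 0)
  structure(list(kon = kon, koff = koff, kcov = kcov, rmax = rmax),
            class = "kinetic_params")
}

#' Equilibrium dissociation constant of the noncovalent phase
#'
#' @param params A [kinetic_params()].
#' @return `koff / kon` (molar); lower means higher affinity.
#' @export
keq <- function(params) params$koff / params$kon

#' Injection schedule for a sensorgram
#'
#' @param concentrations Analyte concentrations (molar), one per segment.
#' @param durations Segment durations (seconds), positive.
#' @param dissociation Duration (seconds) of the buffer-only dissociation
#'   tail appended after the last segment.
#' @return An `injection_schedule` with a `segments` tibble (the tail is a
#'   zero-concentration segment).
#' @export
injection_schedule <- function(concentrations, durations,
                               dissociation = 0) {
  stopifnot(length(concentrations) == length(durations),
            all(durations > 0), all(concentrations >= 0),
            dissociation >= 0)
  segments <- tibble(concentration = concentrations, duration = durations)
  if (dissociation > 0) {
    segments <- dplyr::bind_rows(
      segments, tibble(concentration = 0, duration = dissociation))
  }
  segments$t_end <- cumsum(segments$duration)
  structure(list(segments = segments), class = "injection_schedule")
}

#' The study's five-step titration schedule
#'
#' Sequential 1-minute injections at 1.5, 4.4, 13.3, 40 and 120 uM (a 1-in-3
#' dilution series) followed by a dissociation tail; state carries over
#' between segments without reset.
#'
#' @param dissociation Tail duration in seconds.
#' @return An `injection_schedule`.
#' @export
titration_schedule <- function(dissociation = 120) {
  injection_schedule(
    concentrations = c(1.5, 4.4, 13.3, 40, 120) * 1e-6,
    durations = rep(60, 5),
    dissociation = dissociation
  )
}

.two_state_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    free <- rmax - Bnc - Bcov
    list(c(
      Bnc = kon * conc * free - (koff + kcov) * Bnc,
      Bcov = kcov * Bnc
    ))
  })
}

#' Simulate a sensorgram under the two-phase model
#'
#' Integrates the two-state linear ODE segment by segment with an adaptive
#' stiff solver (lsoda); `dt` sets only the reporting grid, the solver
#' refines its internal steps as needed. State carries across segments, so a
#' sequential titration accumulates covalent complexes.
#'
#' @param params A [kinetic_params()].
#' @param schedule An [injection_schedule()].
#' @param dt Reporting grid spacing (seconds).
#' @param state0 Optional starting state `c(Bnc = , Bcov = )` in RU.
#' @return A `sensorgram` tibble: `time`, `response`, `bound_noncovalent`,
#'   `bound_covalent`, plus the segment concentration.
#' @export
simulate_sensorgram <- function(params, schedule, dt = 0.1,
                                state0 = c(Bnc = 0, Bcov = 0)) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "injection_schedule"),
            dt > 0)
  segs <- schedule$segments
  state <- state0
  t0 <- 0
  pieces <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    times <- seq(0, segs$duration[i], by = dt)
    if (segs$duration[i] - times[length(times)] > 1e-9 * segs$duration[i]) {
      times <- c(times, segs$duration[i])
    } else {
      times[length(times)] <- segs$duration[i]
    }
    sol <- deSolve::ode(
      y = state, times = times, func = .two_state_rhs,
      parms = c(kon = params$kon, koff = params$koff, kcov = params$kcov,
                rmax = params$rmax, conc = segs$concentration[i]),
      method = "lsoda", rtol = 1e-9, atol = 1e-9 * max(params$rmax, 1)
    )
    state <- c(Bnc = sol[nrow(sol), "Bnc"], Bcov = sol[nrow(sol), "Bcov"])
    names(state) <- c("Bnc", "Bcov")
    pieces[[i]] <- tibble(
      time = t0 + sol[, "time"],
      bound_noncovalent = pmax(sol[, "Bnc"], 0),
      bound_covalent = pmax(sol[, "Bcov"], 0),
      concentration = segs$concentration[i]
    )
    # drop the duplicated segment-boundary point from the next piece
    if (i > 1) pieces[[i]] <- pieces[[i]][-1, , drop = FALSE]
    if (i == 1) pieces[[i]] <- pieces[[i]]
    t0 <- t0 + segs$duration[i]
  }
  out <- dplyr::bind_rows(pieces)
  out$response <- out$bound_noncovalent + out$bound_covalent
  structure(
    out[, c("time", "response", "bound_noncovalent", "bound_covalent",
            "concentration")],
    class = c("sensorgram", class(out))
  )
}

#' Equilibrium binding of the noncovalent phase (1:1 Langmuir)
#'
#' @param params A [kinetic_params()].
#' @param concentration Analyte concentration(s), molar.
#' @return Equilibrium response `rmax * C / (keq + C)` in RU.
#' @export
langmuir_eq <- function(params, concentration) {
  params$rmax * concentration / (keq(params) + concentration)
}

#' Fraction of end-of-injection binding that persists
#'
#' Simulates a single injection of the given duration and concentration from
#' an empty surface and returns the fraction of the response at injection end
#' that never decays: covalent complexes plus the share of noncovalent
#' complexes destined to convert rather than dissociate,
#' `(B_cov + B_nc * kcov/(koff+kcov)) / (B_nc + B_cov)`. Zero when
#' `kcov = 0`; strictly increasing in injection duration otherwise.
#'
#' @param params A [kinetic_params()].
#' @param injection_duration Seconds.
#' @param concentration Molar.
#' @return Fraction in `[0, 1]`.
#' @export
persistent_fraction <- function(params, injection_duration, concentration) {
  sg <- simulate_sensorgram(
    params,
    injection_schedule(concentration, injection_duration),
    dt = min(1, injection_duration / 50)
  )
  last <- sg[nrow(sg), ]
  bnc <- last$bound_noncovalent
  bcov <- last$bound_covalent
  if (bnc + bcov == 0) return(0)
  conv <- if (params$koff + params$kcov > 0) {
    params$kcov / (params$koff + params$kcov)
  } else 0
  (bcov + bnc * conv) / (bnc + bcov)
}

#' Equilibrium responses at the end of each injection segment
#'
#' @param sensorgram A simulated or observed `sensorgram` tibble.
#' @param schedule The matching [injection_schedule()].
#' @return Tibble with `concentration` and the response at each nonzero
#'   segment's end.
#' @export
steady_state_responses <- function(sensorgram, schedule) {
  segs <- schedule$segments[schedule$segments$concentration > 0, ]
  resp <- vapply(segs$t_end, function(te) {
    i <- which.min(abs(sensorgram$time - te))
    sensorgram$response[i]
  }, numeric(1))
  tibble(concentration = segs$concentration, response = resp)
}

#' Fit the 1:1 Langmuir steady-state model
#'
#' Least-squares fit of `R_eq = rmax * C / (keq + C)` to per-concentration
#' equilibrium responses, returning the equilibrium constant and maximal
#' response with standard errors. Degenerate inputs (flat responses, or a
#' series that never approaches saturation so `rmax` is unidentifiable) are
#' flagged with a warning status rather than rejected.
#'
#' @param concentrations Analyte concentrations (molar), >= 3 distinct.
#' @param eq_responses Equilibrium responses (RU), same length.
#' @return A `steady_state_fit` list: `keq`, `rmax`, `se_keq`, `se_rmax`,
#'   `status` (`"ok"`, `"degenerate"` or `"non_saturating"`), `data`.
#' @export
fit_steady_state <- function(concentrations, eq_responses) {
  stopifnot(length(concentrations) == length(eq_responses))
  if (length(unique(concentrations)) < 3) {
    stop("at least 3 distinct concentrations are required", call. = FALSE)
  }
  dat <- tibble(C = concentrations, R = eq_responses)
  if (stats::sd(dat$R) < 1e-12 * max(abs(dat$R), 1)) {
    warning("steady-state responses are flat; keq unidentifiable",
            call. = FALSE)
    return(structure(
      list(keq = NA_real_, rmax = NA_real_, se_keq = NA_real_,
           se_rmax = NA_real_, status = "degenerate", data = dat),
      class = "steady_state_fit"))
  }
  fit <- minpack.lm::nlsLM(
    R ~ rmax * C / (keq + C), data = dat,
    start = list(rmax = max(dat$R) * 1.5, keq = stats::median(dat$C)),
    lower = c(rmax = 0, keq = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  status <- "ok"
  if (!is.finite(se[["rmax"]]) || se[["rmax"]] > 0.5 * est[["rmax"]] ||
      max(dat$R) < 0.5 * est[["rmax"]]) {
    status <- "non_saturating"
    warning("responses far from saturation; rmax (and keq) poorly identified",
            call. = FALSE)
  }
  structure(
    list(keq = est[["keq"]], rmax = est[["rmax"]],
         se_keq = se[["keq"]], se_rmax = se[["rmax"]],
         status = status, data = dat),
    class = "steady_state_fit"
  )
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("<steady_state_fit> keq = %.4g M (se %.2g), rmax = %.4g RU (se %.2g), status: %s\n",
              x$keq, x$se_keq, x$rmax, x$se_rmax, x$status))
  invisible(x)
}

#' Occupancy normalization of response units
#'
#' Converts a control equilibrium response into the response corresponding to
#' 100 percent receptor occupancy using the 1:1 Langmuir relation: at analyte
#' concentration C the equilibrium occupancy is `C / (keq + C)`, so the
#' full-occupancy response is `(keq + C) / C` times the observed equilibrium
#' response. Used to compare surfaces with different amounts of immobilized
#' receptor.
#'
#' @param ru_control_eq Equilibrium response of the control analyte (RU).
#' @param keq_ref Reference equilibrium constant (molar).
#' @param concentration Control analyte concentration (molar), > 0.
#' @param responses Optional responses to normalize (RU).
#' @return List with `factor` (`(keq_ref + C)/C`), `ru_full_occupancy`
#'   (`factor * ru_control_eq`) and, when given, `normalized` =
#'   `responses / ru_full_occupancy`.
#' @examples
#' normalized_ru(50, keq_ref = 64.1e-6, concentration = 100e-6)$factor # 1.641
#' @export
normalized_ru <- function(ru_control_eq, keq_ref, concentration,
                          responses = NULL) {
  if (concentration <= 0) {
    stop("concentration must be positive", call. = FALSE)
  }
  factor <- (keq_ref + concentration) / concentration
  ru_full <- factor * ru_control_eq
  out <- list(factor = factor, ru_full_occupancy = ru_full)
  if (!is.null(responses)) out$normalized <- responses / ru_full
  out
}

#' Decompose a dissociation phase into fast decay plus persistent plateau
#'
#' Least-squares fit of `R(t) = A * exp(-lambda * (t - t0)) + P` to the
#' post-injection window, separating short-lived noncovalent complexes (fast
#' amplitude `A`, half-life `ln 2 / lambda`) from the persistent, covalently
#' bound plateau `P`. A non-monotone post-injection signal beyond 2 percent
#' of the window range triggers a fit-quality warning.
#'
#' @param sensorgram A `sensorgram` tibble (or any tibble with `time`,
#'   `response`).
#' @param window_start Start of the dissociation window (seconds).
#' @return A `dissociation_decomposition` list: `fast_amplitude`,
#'   `decay_rate`, `persistent_plateau`, `half_life`, `status`.
#' @export
decompose_dissociation <- function(sensorgram, window_start) {
  w <- sensorgram[sensorgram$time >= window_start, ]
  if (nrow(w) < 4) {
    stop("dissociation window has too few points", call. = FALSE)
  }
  rng <- diff(range(w$response))
  status <- "ok"
  if (any(diff(w$response) > 0.02 * max(rng, 1e-12))) {
    status <- "non_monotone"
    warning("post-injection signal is not monotonically decreasing; ",
            "decomposition may be unreliable", call. = FALSE)
  }
  t0 <- w$time[1]
  p0 <- min(w$response)
  a0 <- max(w$response[1] - p0, 1e-9)
  # crude rate start from the early log-linear slope
  early <- w[w$response - p0 > 0.05 * a0, ]
  lam0 <- if (nrow(early) >= 2) {
    s <- stats::coef(stats::lm(log(early$response - p0 + 1e-12) ~ early$time))[2]
    max(-s, 1e-4)
  } else 1 / max(diff(range(w$time)), 1e-6)
  fit <- minpack.lm::nlsLM(
    response ~ A * exp(-lambda * (time - t0)) + P,
    data = w,
    start = list(A = a0, lambda = lam0, P = p0),
    lower = c(A = 0, lambda = 1e-9, P = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  structure(
    list(fast_amplitude = est[["A"]], decay_rate = est[["lambda"]],
         persistent_plateau = est[["P"]],
         half_life = log(2) / est[["lambda"]], status = status),
    class = "dissociation_decomposition"
  )
}

#' @export
print.dissociation_decomposition <- function(x, ...) {
  cat(sprintf("<dissociation_decomposition> A = %.3g RU, lambda = %.3g /s (half-life %.3g s), plateau = %.3g RU [%s]\n",
              x$fast_amplitude, x$decay_rate, x$half_life,
              x$persistent_plateau, x$status))
  invisible(x)
}

#' Tetramer dissociation with rebinding blocked
#'
#' Models percent tetramer staining remaining after an anti-MHC blocker
#' prevents rebinding: bound receptors either dissociate at `koff` or
#' covalently convert at `kcov` (after which they never release), with no
#' association term. With `f_cov` the covalently bound fraction at blocker
#' addition,
#' `remaining(t) = 100 * (f_cov + (1 - f_cov) * exp(-(koff+kcov) t)
#'   + (1 - f_cov) * kcov/(koff+kcov) * (1 - exp(-(koff+kcov) t)))`.
#' Reduces to pure exponential decay when `kcov = 0` and `f_cov = 0`.
#'
#' @param params A [kinetic_params()]; only `koff` and `kcov` are used.
#' @param timepoints_min Timepoints in minutes after blocker addition.
#' @param f_cov Covalently bound fraction at time zero.
#' @return Numeric vector of percent remaining at each timepoint.
#' @export
simulate_tetramer_decay <- function(params, timepoints_min, f_cov = 0) {
  stopifnot(f_cov >= 0, f_cov <= 1, all(timepoints_min >= 0))
  t <- timepoints_min * 60
  ktot <- params$koff + params$kcov
  conv <- if (ktot > 0) params$kcov / ktot else 0
  decay <- exp(-ktot * t)
  100 * (f_cov + (1 - f_cov) * decay + (1 - f_cov) * conv * (1 - decay))
}
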