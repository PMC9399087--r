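test_that("the simulator matches the matrix-exponential closed form", {
  sched <- injection_schedule(c(10e-6, 100e-6), c(60, 60),
                              dissociation = 120)
  for (kon in c(1e3, 1e4)) {
    for (koff in c(0.1, 0.7)) {
      for (kcov in c(0, 1e-3)) {
        kp <- kinetic_params(kon, koff, kcov, rmax = 100)
        sg <- simulate_sensorgram(kp, sched, dt = 1)
        exact <- oracle_two_state(kp, sched, sg$time)
        expect_lt(max(abs(sg$bound_noncovalent - exact[, "Bnc"])),
                  1e-3 * kp$rmax)
        expect_lt(max(abs(sg$bound_covalent - exact[, "Bcov"])),
                  1e-3 * kp$rmax)
      }
    }
  }
})

test_that("conservation holds and the covalent pool never shrinks", {
  kp <- kinetic_params(5e3, 0.5, 5e-4, rmax = 80)
  sg <- simulate_sensorgram(kp, titration_schedule(dissociation = 600),
                            dt = 0.5)
  expect_true(all(sg$response <= kp$rmax * (1 + 1e-9)))
  expect_true(all(sg$bound_noncovalent >= -1e-9))
  expect_true(all(diff(sg$bound_covalent) >= -1e-9))
  expect_equal(sg$response,
               sg$bound_noncovalent + sg$bound_covalent)
})

test_that("without covalent conversion the surface returns to baseline", {
  kp <- kinetic_params(1e4, 0.7, kcov = 0, rmax = 100)
  sched <- injection_schedule(100e-6, 60, dissociation = 10 / kp$koff)
  sg <- simulate_sensorgram(kp, sched, dt = 0.1)
  expect_lt(sg$response[nrow(sg)], 1e-3 * kp$rmax)
})

test_that("a long constant injection plateaus at the Langmuir occupancy", {
  kp <- kinetic_params(1e4, 0.7, kcov = 0, rmax = 100)
  C <- 50e-6
  sg <- simulate_sensorgram(kp, injection_schedule(C, 600), dt = 0.5)
  expect_equal(sg$response[nrow(sg)], langmuir_eq(kp, C),
               tolerance = 1e-6)
})

test_that("persistent fraction behaves as the two-phase model predicts", {
  kp <- kinetic_params(1e4, 0.7, kcov = 1e-3, rmax = 100)
  # no conversion, no persistence
  expect_equal(persistent_fraction(kinetic_params(1e4, 0.7, 0, 100),
                                   60, 100e-6), 0)
  # at vanishing injection time the fraction approaches the per-event
  # conversion probability kcov / (koff + kcov) ~ 1.43e-3: most binding
  # events do not form the covalent bond
  conv <- kp$kcov / (kp$koff + kp$kcov)
  expect_equal(conv, 1.43e-3, tolerance = 5e-3)
  expect_equal(persistent_fraction(kp, 0.05, 100e-6), conv,
               tolerance = 0.05)
  # strictly increasing across the 1 / 5 / 20 minute injections
  pf <- vapply(c(60, 300, 1200), persistent_fraction,
               numeric(1), params = kp, concentration = 100e-6)
  expect_true(all(diff(pf) > 0))
  # and non-decreasing in kcov
  pf_k <- vapply(c(1e-4, 1e-3, 1e-2), function(kc) {
    persistent_fraction(kinetic_params(1e4, 0.7, kc, 100), 300, 100e-6)
  }, numeric(1))
  expect_true(all(diff(pf_k) > 0))
})

test_that("steady-state fitting recovers the equilibrium constant", {
  conc <- c(1.5, 4.4, 13.3, 40, 120) * 1e-6
  kp <- kinetic_params(kon = 1e4, koff = 0.123, kcov = 0, rmax = 150)
  fit <- fit_steady_state(conc, langmuir_eq(kp, conc))
  expect_equal(fit$keq, keq(kp), tolerance = 1e-3)
  expect_equal(fit$rmax, kp$rmax, tolerance = 1e-3)
  expect_equal(fit$status, "ok")
  # equilibria read off a long-injection simulation give the same answer
  eqs <- vapply(conc, function(C) {
    sg <- simulate_sensorgram(kp, injection_schedule(C, 400), dt = 1)
    sg$response[nrow(sg)]
  }, numeric(1))
  fit2 <- fit_steady_state(conc, eqs)
  expect_equal(fit2$keq, keq(kp), tolerance = 1e-3)
})

test_that("noisy steady-state fits stay accurate in the median", {
  conc <- c(1.5, 4.4, 13.3, 40, 120) * 1e-6
  true_keq <- 12.3e-6
  clean <- 100 * conc / (true_keq + conc)
  set.seed(41)
  rel_err <- replicate(100, {
    fit <- fit_steady_state(conc, clean * (1 + rnorm(5, 0, 0.02)))
    abs(fit$keq - true_keq) / true_keq
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("degenerate steady-state inputs are flagged, not fitted", {
  expect_warning(
    fit <- fit_steady_state(c(1e-6, 1e-5, 1e-4), c(50, 50, 50)),
    "flat")
  expect_equal(fit$status, "degenerate")
  expect_true(is.na(fit$keq))
  expect_error(fit_steady_state(c(1e-6, 1e-6), c(1, 2)), "3 distinct")
})

test_that("occupancy normalization follows the Langmuir relation", {
  # the worked example: keq 64.1 uM at 100 uM analyte -> factor 1.641
  nr <- normalized_ru(50, keq_ref = 64.1e-6, concentration = 100e-6)
  expect_equal(nr$factor, 1.641)
  expect_equal(nr$ru_full_occupancy, 82.05)
  # saturation: factor -> 1 as C >> keq
  expect_equal(normalized_ru(1, 64.1e-6, 1)$factor, 1, tolerance = 1e-4)
  # half occupancy at C = keq
  expect_equal(normalized_ru(1, 5e-6, 5e-6)$factor, 2)
  expect_error(normalized_ru(1, 5e-6, 0), "positive")
  nr2 <- normalized_ru(50, 64.1e-6, 100e-6, responses = c(82.05, 41.025))
  expect_equal(nr2$normalized, c(1, 0.5))
})

test_that("dissociation decomposition separates decay from plateau", {
  t <- seq(0, 12, by = 0.05)
  synth <- tibble::tibble(time = t, response = 50 * exp(-0.7 * t) + 20)
  d <- decompose_dissociation(synth, window_start = 0)
  expect_equal(d$fast_amplitude, 50, tolerance = 1e-6)
  expect_equal(d$decay_rate, 0.7, tolerance = 1e-6)
  expect_equal(d$persistent_plateau, 20, tolerance = 1e-6)
  expect_equal(d$half_life, log(2) / 0.7, tolerance = 1e-6)
})

test_that("decomposition of simulations recovers the generating rates", {
  # koff chosen so the noncovalent half-life is below a second
  kp <- kinetic_params(1e4, 0.8, kcov = 2e-3, rmax = 100)
  sched <- injection_schedule(100e-6, 300, dissociation = 30)
  sg <- simulate_sensorgram(kp, sched, dt = 0.02)
  d <- decompose_dissociation(sg, window_start = 300)
  expect_equal(d$decay_rate, kp$koff + kp$kcov, tolerance = 0.02)
  expect_lt(d$half_life, 1)
  # the plateau is the covalent pool
  expect_equal(d$persistent_plateau,
               sg$bound_covalent[nrow(sg)], tolerance = 0.02)
  # with conversion disabled (the reducing-agent condition) no plateau
  kp0 <- kinetic_params(1e4, 0.8, kcov = 0, rmax = 100)
  sg0 <- simulate_sensorgram(kp0, sched, dt = 0.02)
  d0 <- decompose_dissociation(sg0, window_start = 300)
  expect_lt(d0$persistent_plateau, 1e-3 * kp0$rmax)
})

test_that("tetramer decay has a covalent floor and dominates pure decay", {
  kp0 <- kinetic_params(1e4, koff = 0.002, kcov = 0)
  tp <- c(10, 30, 60)
  expect_equal(simulate_tetramer_decay(kp0, tp, f_cov = 0),
               100 * exp(-0.002 * tp * 60))
  kp <- kinetic_params(1e4, koff = 0.002, kcov = 5e-4)
  expect_gte(min(simulate_tetramer_decay(kp, c(tp, 1e6), f_cov = 0.5)), 50)
  # conversion strictly slows apparent dissociation at every timepoint
  expect_true(all(simulate_tetramer_decay(kp, tp) >
                    simulate_tetramer_decay(kp0, tp)))
})
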