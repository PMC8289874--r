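mk_series <- function(t, m, s = pmax(0, max(m) - 1 - m)) {
  tibble::tibble(run = 1L, t = t, m = as.integer(m), s = as.integer(s))
}

test_that("monotone state timeline uses last-departure semantics", {
  # strictly decreasing raw series passes through unchanged
  ev <- mk_series(t = c(0, 1, 2.5, 4), m = c(3, 2, 1, 0))
  ss <- state_series(ev)
  expect_equal(ss$m, c(3L, 2L, 1L))
  expect_equal(ss$t, c(1, 2.5, 4))
  # re-crossing 5 -> 4 -> 5 -> 4: one departure, at the final 5 -> 4 time
  ev2 <- mk_series(t = c(0, 1, 2, 3, 10), m = c(5, 4, 5, 4, 3))
  ss2 <- state_series(ev2)
  expect_equal(ss2$t[ss2$m == 5], 3)
  expect_equal(ss2$t[ss2$m == 4], 10)
  # monotone: departure times increase as the level decreases
  expect_true(all(diff(ss2$t) > 0))
  expect_error(state_series(mk_series(numeric(0), integer(0), integer(0))),
               "empty")
})

test_that("waiting times average residence per state over runs", {
  # uniform dwell tau at every state -> W(m) = tau everywhere
  N <- 12; tau <- 0.7
  ens <- dplyr::bind_rows(lapply(1:3, function(r)
    dplyr::mutate(mk_series(t = seq(0, N) * tau, m = seq(N, 0)), run = r)))
  prof <- waiting_times(ens)
  expect_equal(prof$W[prof$m >= 1 & prof$m <= N], rep(tau, N),
               tolerance = 1e-12)
  expect_equal(prof$V[prof$m == 5], 1 / tau, tolerance = 1e-12)
  expect_true(all(prof$n == 3))
  # residence counts every visit, including re-crossings
  ev <- mk_series(t = c(0, 1, 2, 3.5, 4), m = c(5, 4, 5, 4, 3))
  prof2 <- waiting_times(ev)
  expect_equal(prof2$W[prof2$m == 5], 1 + 1.5)   # two visits at state 5
  expect_equal(prof2$W[prof2$m == 4], 1 + 0.5)
  # total dwell partitions the span
  expect_equal(sum(prof2$W), max(ev$t) - min(ev$t))
})

test_that("deterministic theory fixtures reproduce the model speed exactly", {
  tp <- theory_params()
  spec <- fixture_spec(N = 64, D = 8, params = tp, dwell = "deterministic")
  prof <- waiting_times(generate_event_series(spec))
  m <- prof$m[prof$m >= 1 & prof$m <= 64]
  expect_equal(prof$V[match(m, prof$m)],
               ejectr:::fixture_speed(spec, m), tolerance = 1e-10)
})

test_that("critical-size detection finds the speed minimum or flags none", {
  tp <- theory_params()
  spec <- fixture_spec(N = 512, D = 16, params = tp, dwell = "deterministic")
  prof <- waiting_times(generate_event_series(spec))
  det <- detect_Nstar(prof)
  expect_false(det$no_minimum)
  # brute-force argmin of the model over the interior states
  vm <- ejectr:::fixture_speed(spec, 2:511)
  m_brute <- (2:511)[which.min(vm)]
  expect_lte(abs(det$m_star - m_brute), 2)   # within the smoothing window
  # monotone translocation profile has no interior minimum
  specInf <- fixture_spec(N = 128, D = Inf, params = tp,
                          dwell = "deterministic")
  detInf <- detect_Nstar(waiting_times(generate_event_series(specInf)))
  expect_true(detInf$no_minimum)
  expect_true(is.na(detInf$m_star))
})

test_that("nucleation trimming removes the entering plateau", {
  # identity normalisation when nothing is trimmed
  ens <- mk_series(t = c(0, 1, 2, 3, 4), m = c(4, 3, 2, 1, 0))
  tr <- trim_nucleation(ens, m_n = 0, tau_n = 0, phi0 = 0, m_p = 1)
  expect_equal(range(tr$m_tilde), c(0, 1))
  expect_equal(range(tr$t_tilde), c(0, 1))
  # dense start: the high-phi0 rule sets both trims to zero
  tr2 <- trim_nucleation(ens, phi0 = 0.3, m_p = 1)
  expect_equal(tr2$m_tilde, tr$m_tilde)
  expect_equal(tr2$t_tilde, tr$t_tilde)
  # staircase with an m_p-long initial stall: trimming restores a clean ramp
  m_p <- 3
  ev <- mk_series(t = c(0, 10, 10.5, 11, 12, 13, 14, 15),
                  m = c(8, 7, 6, 5, 4, 3, 2, 0),
                  s = c(0, 0, 0, 1, 2, 3, 4, 8))
  tr3 <- trim_nucleation(ev, phi0 = 0.01, m_p = m_p)
  # tau_n is the first arrival in the semi-space (t = 11)
  expect_equal(min(tr3$t_tilde[tr3$m <= 8 - m_p]), 0)
  expect_true(max(tr3$m_tilde) <= 1)
  expect_error(trim_nucleation(ens, m_n = 0, tau_n = 100, phi0 = 0),
               "below")
})

test_that("stage decomposition recovers crafted segment times exactly", {
  # N = 12, m_p = 1, Nstar = 4; crafted first-passage times:
  # s reaches 1 at t = 2; m <= 4 at t = 9; m <= floor(11/2) = 5 at t = 8;
  # m = 0 at t = 14; final record (s = N) at t = 15.
  N <- 12
  t <- c(0, 2, 3, 4, 5, 6, 8, 9, 10, 11, 12, 13, 14, 15)
  m <- c(11, 10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0, 0, 0)
  s <- pmax(0, N - 1 - m); s[length(s)] <- N
  ev <- tibble::tibble(run = 1L, t = t, m = as.integer(m),
                       s = as.integer(s))
  st <- decompose_stages(ev, Nstar = 4, m_p = 1)
  expect_equal(st$tau_ent, 2)
  expect_equal(st$tau1, 9 - 2)
  expect_equal(st$tau2E, 0)         # Nstar < (N - m_p)/2: no second barrier
  expect_equal(st$tau2P, 13 - 9)
  expect_equal(st$tau_leav, 15 - 13)
  expect_equal(st$tau_ej, st$tau1 + st$tau2E + st$tau2P)
  expect_equal(st$tau_ent + st$tau_ej + st$tau_leav, st$tau_total)

  # Nstar above the middle: the escape segment is crossed first
  st2 <- decompose_stages(ev, Nstar = 8, m_p = 1)
  expect_equal(st2$tau1, 4 - 2)     # m <= 8 at t = 4
  expect_equal(st2$tau2E, 8 - 4)    # m <= 5 at t = 8
  expect_equal(st2$tau2P, 13 - 8)
  expect_equal(st2$tau_ent + st2$tau_ej + st2$tau_leav, st2$tau_total)
  expect_error(decompose_stages(ev, Nstar = 40), "outside")
})

test_that("stage decomposition of theory fixtures matches the regime table", {
  tp <- theory_params()
  # long chain at moderate density: N - m_p > 2 Nstar -> tau2E = 0
  spec <- fixture_spec(N = 256, D = 10, params = tp,
                       dwell = "deterministic")
  Nstar <- critical_number(10)
  st <- decompose_stages(generate_event_series(spec), Nstar = Nstar)
  expect_equal(st$tau2E, 0)
  expect_gt(st$tau1, 0)
  expect_gt(st$tau2P, 0)
})

test_that("power-law fitting recovers exponents on the standard windows", {
  x <- seq(0.01, 1, length.out = 80)
  d <- tibble::tibble(x = x, y = 3 * x^1.5)
  f <- fit_power_law(d, x, y)
  expect_equal(tidy(f)$estimate[1], 1.5, tolerance = 1e-12)
  expect_equal(exp(tidy(f)$estimate[2]), 3, tolerance = 1e-10)
  # window honoured and stored verbatim
  fw <- fit_power_law(d, x, y, window = c(0.01, 0.5))
  expect_equal(fw$window, c(0.01, 0.5))
  expect_true(fw$n < f$n)
  # noisy Monte-Carlo: exponent recovered within +-0.05 for 95% of seeds
  hits <- sapply(1:40, function(sd) {
    set.seed(sd)
    xs <- exp(runif(50, log(0.02), log(1)))
    ys <- xs^(-1.43) * exp(rnorm(50, 0, 0.05))
    abs(tidy(fit_power_law(tibble::tibble(x = xs, y = ys), x, y))$estimate[1] -
          (-1.43)) <= 0.05
  })
  expect_gte(mean(hits), 0.9)
  expect_error(fit_power_law(d[1:2, ], x, y), ">= 3")
  expect_error(fit_power_law(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               "degenerate")
})

test_that("exponential fit of entering times matches the Kramers picture", {
  lp <- 1:5
  tau <- 2 * exp(1.3 * lp)
  f <- fit_entering_exponential(lp, tau)
  expect_equal(unname(f$estimate["a_n"]), 2, tolerance = 1e-8)
  expect_equal(unname(f$estimate["b_n"]), 1.3, tolerance = 1e-8)
  # entering_time() in the Arrhenius regime: b_n approaches dmu_cp / kT
  tpA <- theory_params(dmu_cp = 3)
  tauA <- sapply(1:5, function(l) entering_time(tpA, l))
  fA <- fit_entering_exponential(1:5, tauA)
  expect_equal(unname(fA$estimate["b_n"]), 3, tolerance = 0.1)
  # weaker drive gives a smaller growth rate
  tauB <- sapply(1:5, function(l) entering_time(theory_params(dmu_cp = 1.5), l))
  fB <- fit_entering_exponential(1:5, tauB)
  expect_lt(fB$estimate["b_n"], fA$estimate["b_n"])
  expect_error(fit_entering_exponential(1:5, c(-1, 1, 2, 3, 4)), "positive")
})

test_that("rescaled speed is flat at the true exponents and tilts off them", {
  tp <- theory_params(B2 = 0)
  N <- 512
  spec <- fixture_spec(N = N, D = 12, params = tp, dwell = "deterministic")
  prof <- waiting_times(generate_event_series(spec))
  Nstar <- critical_number(12)
  conf <- function(z1) {
    r <- rescale_speed(prof, N, x1 = 0.5, z1 = z1, z2P = 1.5)
    flatness_score(r$V_conf_rescaled[r$m > 1.1 * Nstar & r$m < 0.95 * N])
  }
  expect_lt(conf(2), 0.02)
  # perturbing the confined exponent tilts the plateau, monotonically
  expect_true(conf(2.2) > conf(2.1))
  expect_true(conf(2.1) > conf(2))
  expect_true(conf(1.8) > conf(1.9))
  # a wrong friction exponent x1 breaks the fixed-phi0 collapse across N
  # (at fixed phi0 the cavity diameter grows with N and the confined
  # plateau level is N-independent only at the true x1)
  profs <- lapply(c(256, 512), function(n) {
    D <- system_params(N = n, phi0 = 0.15)$D
    list(N = n, Nstar = critical_number(D),
         prof = waiting_times(generate_event_series(
           fixture_spec(N = n, D = D, params = tp,
                        dwell = "deterministic"))))
  })
  two_N <- function(x1) {
    vals <- unlist(lapply(profs, function(pp) {
      r <- rescale_speed(pp$prof, pp$N, x1 = x1, z1 = 2, z2P = 1.5)
      r$V_conf_rescaled[r$m > 1.1 * pp$Nstar & r$m < 0.95 * pp$N]
    }))
    flatness_score(vals)
  }
  expect_lt(two_N(0.5), 0.02)
  expect_true(two_N(0.6) > two_N(0.5))
  expect_true(two_N(0.4) > two_N(0.5))
  # pulling branch flat at the true z2P
  r <- rescale_speed(prof, N, x1 = 0.5, z1 = 2, z2P = 1.5)
  expect_lt(flatness_score(r$V_pull_rescaled[r$m > 1 & r$m < 0.9 * Nstar]),
            0.02)
})
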