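test_that("exponent identities hold in exact arithmetic", {
  e2 <- predicted_exponents(2, 0.75)
  expect_equal(e2$x1, 0.5)
  expect_equal(e2$z1, 2.0)
  expect_equal(e2$z2P, 1.5)
  expect_equal(e2$y2P, 0.5)
  expect_equal(e2$zeta1, 1.0)
  expect_equal(e2$zeta2, 0.4)
  expect_equal(e2$exp_tauej_fixed_phi0, 0.5 + 2 / 1.5)
  expect_equal(e2$exp_tau2P_fixed_phi0, 2.5 / 1.5)
  expect_equal(e2$exp_tau2P_fixed_D, 2.5)
  e3 <- predicted_exponents(3, 3 / 5)
  expect_equal(e3$z1, 1.25)
  expect_equal(e3$z2P, 1.2)
  expect_error(predicted_exponents(2, 0.5), "breaks down")
})

test_that("critical number scales as D^(1/nu) and as (N/phi0)^(2/3)", {
  expect_equal(critical_number(2) / critical_number(1 + 1e-12), 2^(4 / 3),
               tolerance = 1e-6)
  expect_error(critical_number(0.5))
  # at fixed phi0 the derived D gives N* ~ (N/phi0)^(1/(d nu)) ~ N^(2/3)
  Ns <- 2^(5:9)
  nst <- sapply(Ns, function(n)
    critical_number(system_params(N = n, phi0 = 0.15)$D))
  sl <- coef(lm(log(nst) ~ log(Ns)))[2]
  expect_equal(unname(sl), 2 / 3, tolerance = 0.01)
})

test_that("combined speed model reduces to two power laws when B2 = 0", {
  tp0 <- theory_params(B2 = 0)
  m <- 1:256
  v <- speed_model(m, 256, 10, tp0)
  conf <- tp0$A1 * m^2 / (256^0.5 * 10^4)
  pull <- tp0$A2 * m^(-1.5)
  expect_equal(v, conf + pull, tolerance = 1e-12)
  # second virial only ever boosts the speed
  vB <- speed_model(m, 256, 10, theory_params(B2 = 0.01))
  expect_true(all(vB >= v))
  # translocation limit keeps only the pulling term
  expect_equal(speed_model(m, 256, Inf, tp0), pull, tolerance = 1e-12)
  # model minimum found by exhaustive scan is interior
  i <- which.min(speed_model(1:512, 512, 16, theory_params()))
  expect_gt(i, 1)
  expect_lt(i, 512)
})

test_that("kinetics right-hand side has the stated structure", {
  tp <- theory_params(B2 = 0)
  # confined branch: pure m^z1 power law
  r1 <- kinetics_rhs(10, 256, 16, tp, "CONFINED")
  r2 <- kinetics_rhs(20, 256, 16, tp, "CONFINED")
  expect_equal(r2 / r1, 2^tp$z1, tolerance = 1e-12)
  expect_true(r1 < 0)
  # entropic terms cancel exactly at m = s
  N <- 101; m_eq <- (N - tp$m_p) / 2
  expect_equal(kinetics_rhs(m_eq, N, Inf, tp, "NONCONFINED"), 0)
  expect_error(kinetics_rhs(m_eq + 1, N, Inf, tp, "NONCONFINED"),
               "m < s")
})

test_that("closed-form m(t) solutions match numeric integration", {
  skip_if_not_installed("deSolve")
  N <- 256; D <- 16
  tp <- theory_params(B2 = 0)
  # confined stage, forward from m = N
  rhs <- function(t, y, parms)
    list(kinetics_rhs(y, N, D, tp, "CONFINED"))
  tt <- seq(0, 2000, by = 5)
  sol <- deSolve::ode(y = N, times = tt, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  closed <- m_of_t_confined(tt, N, D, tp)
  expect_lt(max(abs(sol[, 2] / N - closed) / closed), 1e-4)
  expect_equal(m_of_t_confined(0, N, D, tp), 1)

  # entropic-pulling stage, backward from m = 0 at tau_ej (m << s limit,
  # unit kinetic prefactor); integrate in u = tau_ej - t
  tau <- 100
  rhs2 <- function(u, y, parms) list(y^(-tp$z2P))
  uu <- c(1e-8, 5, 20, 50, 99)
  sol2 <- deSolve::ode(y = 1e-9, times = uu, func = rhs2, parms = NULL,
                       rtol = 1e-10, atol = 1e-12)
  closed2 <- m_of_t_nonconfined(tau - uu, tau, N = 1, tp)
  expect_lt(max(abs(sol2[-1, 2] - closed2[-1]) / closed2[-1]), 1e-3)
  expect_equal(m_of_t_nonconfined(tau, tau, N = 64, tp), 0)
  expect_error(m_of_t_nonconfined(tau + 1, tau, 64, tp))
})

test_that("entering time reproduces the three Kramers limits", {
  # flat potential: the diffusive crossing time, exactly
  tp0 <- theory_params(dmu_cp = 0)
  for (lp in c(1, 2, 5))
    expect_equal(entering_time(tp0, lp), tp0$eta0 * lp^2 / 2,
                 tolerance = 1e-6)
  # high barrier: Arrhenius growth exp(m_p dmu) with a constant prefactor
  tpA <- theory_params(dmu_cp = 5)
  ratio <- sapply(c(4, 6, 8), function(mp)
    entering_time(tpA, mp) / exp(5 * mp))
  expect_lt(max(abs(ratio / ratio[1] - 1)), 0.15)
  # strong downhill drive: linear in the pore length
  tpD <- theory_params(dmu_cp = -10)
  lin <- sapply(c(2, 4, 8), function(mp) entering_time(tpD, mp) / mp)
  expect_lt(max(abs(lin / lin[1] - 1)), 0.10)
  # agreement with the closed-form linear-potential MFPT
  tpm <- theory_params(dmu_cp = 2.5)
  expect_equal(entering_time(tpm, 3), mfpt_linear_exact(2.5, 3),
               tolerance = 1e-5)
  # quadrature is converged: halving the grid moves the result < 0.1%
  expect_lt(abs(entering_time(tpm, 3, n = 2001) /
                  entering_time(tpm, 3, n = 4001) - 1), 1e-3)
  expect_error(entering_time(tp0, lp = -1))
})

test_that("stage-time predictions follow the regime table", {
  tp <- theory_params()
  # long chain: no thermal-escape barrier
  long <- stage_time_predictions(256, 16, tp)
  expect_equal(long$regime_row, 3L)
  expect_equal(long$tau2E, 0)
  # short chain: never confined
  short <- stage_time_predictions(16, 16, tp)
  expect_equal(short$regime_row, 1L)
  expect_equal(short$tau1, 0)
  expect_gt(short$tau2E, 0)
  # intermediate: all three components present
  mid <- stage_time_predictions(64, 16, tp)
  expect_equal(mid$regime_row, 2L)
  expect_true(all(c(mid$tau1, mid$tau2E, mid$tau2P) > 0))
  expect_equal(mid$tau_ej, mid$tau1 + mid$tau2E + mid$tau2P)

  # tau1 closed form equals direct integration of the confined kinetics
  # (unit kinetic prefactor, as in the prediction table)
  skip_if_not_installed("deSolve")
  N <- 256; D <- 16
  Nstar <- critical_number(D)
  rhs <- function(t, y, parms)
    list(kinetics_rhs(y, N, D, theory_params(B2 = 0), "CONFINED",
                      prefactor = 1))
  root <- function(t, y, parms) y - Nstar
  sol <- deSolve::ode(y = N, times = c(0, 1e7), func = rhs, parms = NULL,
                      rootfun = root, method = "lsodar",
                      rtol = 1e-10, atol = 1e-8)
  t_num <- sol[nrow(sol), 1]
  expect_equal(long$tau1, unname(t_num), tolerance = 1e-3)

  # all times scale linearly with the characteristic time dt0
  tp2 <- theory_params(eta0 = 2)
  expect_equal(stage_time_predictions(64, 16, tp2)$tau_ej,
               2 * mid$tau_ej, tolerance = 1e-10)
})

test_that("leaving time is linear in pore length and inverse in the drive", {
  tp <- theory_params(dmu_ps = -1)
  expect_equal(leaving_time(tp, 2), 2 * leaving_time(tp, 1))
  expect_equal(leaving_time(theory_params(dmu_ps = -2), 1),
               leaving_time(tp, 1) / 2)
  expect_equal(leaving_time(tp, 1), 1)  # m_p = 1, |dmu| = kT -> dt0
  expect_error(leaving_time(theory_params(dmu_ps = 0.5)), "negative")
})

test_that("free-energy landscape is continuous and regime-labelled", {
  tp <- theory_params()
  # regime I: dense start, monotone downhill everywhere
  tpI <- theory_params(dmu_cp = -2)
  l1 <- build_landscape(128, 10, params = tpI, ds = 0.01)
  expect_equal(attr(l1, "regime"), "I")
  expect_true(all(diff(l1$F) < 1e-9))
  # regime IV: single merged barrier peaking at the middle
  l4 <- build_landscape(16, 16, params = tp, ds = 0.01)
  expect_equal(attr(l4, "regime"), "IV")
  s_peak <- l4$s[which.max(l4$F)]
  expect_equal(s_peak, (16 - tp$m_p) / 2, tolerance = 0.1)
  # regime II: entering barrier only, downhill after s = 0
  l2 <- build_landscape(512, 30, params = tp, ds = 0.01)
  expect_equal(attr(l2, "regime"), "II")
  # continuity across junctions: refining the grid shrinks the largest step
  for (l in list(l1, l4, l2))
    expect_lt(max(abs(diff(l$F))), 0.2)
  expect_equal(l2$F[l2$s == 0], 0)
  # regime boundaries partition the (N, D) plane consistently
  tp0 <- theory_params()
  for (N in c(16, 64, 256)) for (D in c(6, 10, 16)) {
    r <- attr(build_landscape(N, D, params = tp0, ds = 1), "regime")
    Nstar <- critical_number(D)
    expected <- if (volume_fraction(N, D) >= tp0$phi_p) "I"
      else if (N - 1 < Nstar) "IV"
      else if (N - 1 <= 2 * Nstar) "III"
      else "II"
    expect_equal(r, expected)
  }
})
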