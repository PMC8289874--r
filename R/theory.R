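#' Scaling exponents of the ejection theory
#'
#' From the Flory exponent \eqn{\nu} and the space dimension d the theory
#' fixes every kinetic exponent: the confined-stage speed exponent
#' \eqn{z_1 = 1/(d\nu - 1)} (des Cloizeaux), the friction exponent
#' \eqn{x_1 = 1/d}, the entropic-pulling exponents \eqn{y_{2P} = 2\nu - 1}
#' and \eqn{z_{2P} = 2\nu}, and the closed-form decay exponents
#' \eqn{\zeta_1 = 1/(z_1 - 1)}, \eqn{\zeta_2 = 1/(z_{2P} + 1)}. Composite
#' processing-time exponents at fixed \eqn{\phi_0} are also returned:
#' \eqn{x_1 + 2/(d\nu)} (confined-dominated ejection time vs N),
#' \eqn{(1 + z_{2P})/(d\nu)} (entropic-pulling time vs N), and
#' \eqn{1 + z_{2P}}.
#'
#' @param d spatial dimension (2 or 3).
#' @param nu Flory exponent; default \eqn{3/(d+2)}.
#' @return one-row tibble of exponents.
#' @examples
#' predicted_exponents(2)       # z1 = 2, z2P = 1.5, zeta2 = 0.4
#' predicted_exponents(3, 0.6)  # z1 = 1.25
#' @export
predicted_exponents <- function(d = 2, nu = 3 / (d + 2)) {
  if (d * nu <= 1) abort("need d*nu > 1 (theory breaks down).")
  z1 <- 1 / (d * nu - 1)
  z2P <- 2 * nu
  tibble::tibble(
    d = d, nu = nu,
    x1 = 1 / d,
    z1 = z1,
    y2P = 2 * nu - 1,
    z2P = z2P,
    zeta1 = 1 / (z1 - 1),
    zeta2 = 1 / (z2P + 1),
    exp_tauej_fixed_phi0 = 1 / d + 2 / (d * nu),
    exp_tau2P_fixed_phi0 = (1 + z2P) / (d * nu),
    exp_tau2P_fixed_D = 1 + z2P)
}

#' Theory parameters
#'
#' Bundles the exponents (from [predicted_exponents()]), the chemical
#' potential differences, friction, and the speed-model prefactors.
#'
#' @param d,nu dimension and Flory exponent.
#' @param gamma1 entropic (surface) exponent; defaults 0.955 (d = 2) /
#'   0.687 (d = 3).
#' @param q effective coordination number; enters the free energy only
#'   through an m-independent term and cancels in all kinetics (default 1).
#' @param z2E thermal-escape speed exponent (empirical default 1.18).
#' @param dmu_cp chemical potential difference cavity -> pore (kT units;
#'   positive when the pore is less favourable than the cavity).
#' @param dmu_ps pore -> semi-space difference (negative).
#' @param eta0 monomer friction coefficient; the characteristic time is
#'   \eqn{\Delta t_0 = \eta_0 \sigma^2 / k_BT}.
#' @param A1,A2,B2 combined-speed-model prefactors.
#' @param Nstar_prefactor prefactor c in \eqn{N_* = c (D/\sigma)^{1/\nu}}.
#' @param m_p pore occupancy. @param rp pore radius (for \eqn{\phi_p}).
#' @return object of class `theory_params`.
#' @export
theory_params <- function(d = 2, nu = 3 / (d + 2),
                          gamma1 = if (d == 2) 0.955 else 0.687,
                          q = 1, z2E = 1.18,
                          dmu_cp = 1, dmu_ps = -1, eta0 = 1,
                          A1 = 3.04, A2 = 0.20, B2 = 0.010,
                          Nstar_prefactor = 1, m_p = 1L, rp = 0.75) {
  ex <- predicted_exponents(d, nu)
  structure(
    c(as.list(ex),
      list(gamma1 = gamma1, q = q, z2E = z2E, y2E = z2E - 1,
           dmu_cp = dmu_cp, dmu_ps = dmu_ps, eta0 = eta0,
           dt0 = eta0,  # eta0 * sigma^2 / kT in reduced units
           A1 = A1, A2 = A2, B2 = B2,
           Nstar_prefactor = Nstar_prefactor,
           m_p = as.integer(m_p), rp = rp, phi_p = phi_pore(rp))),
    class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat("<theory_params> d =", x$d, " nu =", x$nu, " z1 =", x$z1,
      " z2P =", x$z2P, " x1 =", x$x1, "\n  A1 =", x$A1, " A2 =", x$A2,
      " B2 =", x$B2, " dmu_cp =", x$dmu_cp, " dmu_ps =", x$dmu_ps, "\n")
  invisible(x)
}

#' Critical monomer number separating confined and non-confined kinetics
#'
#' \eqn{N_* = c\,(D/\sigma)^{1/\nu}}: the chain stops feeling the cavity once
#' fewer than \eqn{N_*} monomers remain inside.
#'
#' @param D cavity diameter (sigma units).
#' @param nu Flory exponent. @param c prefactor (default 1).
#' @export
critical_number <- function(D, nu = 0.75, c = 1) {
  if (any(D <= 1)) abort("`D` must exceed one monomer diameter.")
  c * D^(1 / nu)
}

#' Combined model for the mean ejection speed
#'
#' Single-equation approximation across the whole main ejection stage:
#' \deqn{V_{ej} = v_0\left\{A_1 \frac{m^{z_1}}{N^{x_1} (D/\sigma)^{d z_1}}
#'   \left[1 + B_2 \frac{m^{z_1+1}}{(D/\sigma)^{d z_1}}\right]
#'   + A_2\, m^{-z_{2P}}\right\}}
#' with \eqn{v_0 = \sigma/\Delta t_0}. The first term is the confined-stage
#' compression speed (the \eqn{B_2} factor is the second-virial correction
#' responsible for the upturn near m = N); the second is the entropic-pulling
#' speed. `D = Inf` leaves only the pulling term (translocation mode).
#'
#' @param m monomers remaining in the cavity (vectorised).
#' @param N chain length. @param D cavity diameter.
#' @param params a [theory_params()] object.
#' @return speeds in sigma/t_u.
#' @export
speed_model <- function(m, N, D, params = theory_params()) {
  stopifnot(all(m >= 1), all(m <= N))
  p <- params
  v0 <- 1 / p$dt0
  confined <- if (is.finite(D)) {
    Dd <- D^(p$d * p$z1)
    p$A1 * m^p$z1 / (N^p$x1 * Dd) * (1 + p$B2 * m^(p$z1 + 1) / Dd)
  } else 0
  v0 * (confined + p$A2 * m^(-p$z2P))
}

#' Kinetics right-hand side dm/dt
#'
#' Confined stage (Onsager kinetics from blob free energy, with optional
#' second-virial correction):
#' \deqn{\dot m = -\frac{p}{\Delta t_0 N^{x_1}} \frac{m^{z_1}}{N_*^{z_1+1}}
#'   \left[1 + B_2 (m/N_*)^{z_1+1}\right].}
#' Non-confined stage (tethered-chain entropy on both sides, friction
#' \eqn{\eta_0 m^{y_{2P}}} from the drifting cis segment):
#' \deqn{\dot m = -\frac{p}{\Delta t_0\, m^{y_{2P}}}
#'   \left[\frac{1}{m+1} - \frac{1}{s+1}\right], \quad s = N - m_p - m,}
#' valid only for \eqn{m < s}; for \eqn{m \ll s} it reduces to
#' \eqn{-m^{-z_{2P}}/\Delta t_0}. Scaling relations fix only the structure;
#' the order-one prefactor `prefactor` defaults to \eqn{z_1 + 1} (confined)
#' and 1 (non-confined).
#'
#' @param m monomers in the cavity (> 0, continuous).
#' @param N chain length. @param D cavity diameter.
#' @param params a [theory_params()] object.
#' @param regime `"CONFINED"` or `"NONCONFINED"`.
#' @param prefactor order-one kinetic prefactor; `NULL` = regime default.
#' @return dm/dt (negative).
#' @export
kinetics_rhs <- function(m, N, D, params = theory_params(),
                         regime = c("CONFINED", "NONCONFINED"),
                         prefactor = NULL) {
  regime <- match.arg(regime)
  p <- params
  stopifnot(all(m > 0))
  if (regime == "CONFINED") {
    pf <- if (is.null(prefactor)) p$z1 + 1 else prefactor
    Nstar <- critical_number(D, p$nu, p$Nstar_prefactor)
    -pf / (p$dt0 * N^p$x1) * m^p$z1 / Nstar^(p$z1 + 1) *
      (1 + p$B2 * (m / Nstar)^(p$z1 + 1))
  } else {
    pf <- if (is.null(prefactor)) 1 else prefactor
    s <- N - p$m_p - m
    if (any(m > s))
      abort("non-confined kinetics require m < s, i.e. m < (N - m_p)/2.")
    -pf / (p$dt0 * m^p$y2P) * (1 / (m + 1) - 1 / (s + 1))
  }
}

#' Closed-form decrease of m in the confined stage
#'
#' Solving the confined kinetics (without second virial) from m = N at t = 0:
#' \deqn{\tilde m = (1 + t/t_0)^{-\zeta_1},\qquad
#'  t_0 = \frac{N_*^{1+z_1} N^{1-z_1+x_1}}{p\,(z_1-1)}\,\Delta t_0,}
#' with \eqn{\zeta_1 = 1/(z_1-1)} and p the kinetic prefactor of
#' [kinetics_rhs()].
#'
#' @param t time (>= 0, t_u units).
#' @param N,D chain length and cavity diameter.
#' @param params a [theory_params()] object.
#' @param prefactor kinetic prefactor (default \eqn{z_1 + 1}).
#' @return normalised count \eqn{\tilde m = m/N}.
#' @export
m_of_t_confined <- function(t, N, D, params = theory_params(),
                            prefactor = params$z1 + 1) {
  stopifnot(all(t >= 0), params$z1 > 1)
  p <- params
  Nstar <- critical_number(D, p$nu, p$Nstar_prefactor)
  t0 <- Nstar^(1 + p$z1) * N^(1 - p$z1 + p$x1) * p$dt0 /
    (prefactor * (p$z1 - 1))
  (1 + t / t0)^(-p$zeta1)
}

#' Closed-form decrease of m near complete ejection
#'
#' Backward solution of the entropic-pulling kinetics from m = 0 at
#' \eqn{t = \tau_{ej}}:
#' \deqn{\tilde m = \frac{1}{N}\left(\frac{\tau_{ej}-t}{\zeta_2 \Delta t_0}
#'  \right)^{\zeta_2},\qquad \zeta_2 = 1/(z_{2P}+1).}
#'
#' @param t time (<= `tau_ej`).
#' @param tau_ej main-ejection completion time.
#' @param N chain length. @param params a [theory_params()] object.
#' @export
m_of_t_nonconfined <- function(t, tau_ej, N, params = theory_params()) {
  if (any(t > tau_ej)) abort("`t` must not exceed `tau_ej`.")
  p <- params
  ((tau_ej - t) / (p$zeta2 * p$dt0))^p$zeta2 / N
}

#' Piecewise free-energy landscape of an ejection process
#'
#' F(s) over the ejection coordinate \eqn{s \in [-m_p, N]} in kT units,
#' anchored at F(0) = 0: a linear entering segment of slope
#' \eqn{\Delta\mu_{cp}}, the confined blob free energy
#' \eqn{(m/N_*)^{z_1+1}} (plus optional second-virial term) while
#' \eqn{m > N_*}, the two-sided tethered-chain entropy
#' \eqn{(1-\gamma_1)[\ln(m+1) + \ln(s+1)]} beyond, and a linear leaving
#' segment of slope \eqn{\Delta\mu_{ps} < 0}. Junction constants enforce
#' continuity. The landscape is labelled with one of four regimes:
#' I (\eqn{\phi_0 \ge \phi_p}: monotone descent), II (entering barrier
#' only, \eqn{N - m_p > 2N_*}), III (second barrier in the non-confined
#' stage, \eqn{N_* < N - m_p < 2N_*}), IV (\eqn{N - m_p < N_*}: both escapes
#' merge into a single barrier peaking at \eqn{s = (N - m_p)/2}).
#'
#' @param N chain length. @param D cavity diameter (possibly `Inf`).
#' @param phi0 initial volume fraction (consistent with N, D unless
#'   `D = Inf`). @param params a [theory_params()] object.
#' @param ds grid spacing along s.
#' @return `ejection_landscape`: tibble (s, m, F, stage) with attributes
#'   `regime`, `Nstar`.
#' @export
build_landscape <- function(N, D = NULL, phi0 = NULL,
                            params = theory_params(), ds = 0.1) {
  p <- params
  if (is.null(D) && is.null(phi0)) abort("give D and/or phi0.")
  if (is.null(D)) D <- system_params(N = N, phi0 = phi0)$D
  if (is.null(phi0)) phi0 <- if (is.finite(D)) volume_fraction(N, D) else 0
  if (is.finite(D) &&
      abs(volume_fraction(N, D) - phi0) > 1e-6 * max(phi0, 1e-12))
    abort("inconsistent (N, D, phi0) triple.")
  Nstar <- if (is.finite(D)) critical_number(D, p$nu, p$Nstar_prefactor) else 0
  Nm <- N - p$m_p
  regime <- if (phi0 >= p$phi_p) "I"
    else if (Nm < Nstar) "IV"
    else if (Nm <= 2 * Nstar) "III"
    else "II"

  s <- seq(-p$m_p, N, by = ds)
  F <- numeric(length(s))
  stage <- character(length(s))

  g_conf <- function(m) (m / Nstar)^(p$z1 + 1) +
    p$B2 / 2 * (m / Nstar)^(2 * (p$z1 + 1))
  g_nc <- function(m, s) (1 - p$gamma1) * (log(m + 1) + log(s + 1))

  s_star <- Nm - Nstar  # confined/non-confined junction (if it exists)
  use_conf <- is.finite(D) && Nm > Nstar

  main_F <- function(si) {
    mi <- Nm - si
    if (use_conf && si <= s_star) {
      g_conf(mi) - g_conf(Nm)
    } else if (use_conf) {
      (g_nc(mi, si) - g_nc(Nstar, s_star)) + (g_conf(Nstar) - g_conf(Nm))
    } else {
      g_nc(mi, si) - g_nc(Nm, 0)
    }
  }
  ent <- s < 0
  leav <- s > Nm
  main <- !ent & !leav
  F[ent] <- p$dmu_cp * s[ent]
  stage[ent] <- "entering"
  F[main] <- vapply(s[main], main_F, numeric(1))
  stage[main] <- ifelse(use_conf & s[main] <= s_star, "confined",
                        "nonconfined")
  F_end <- main_F(Nm)
  F[leav] <- F_end + (s[leav] - Nm) * p$dmu_ps
  stage[leav] <- "leaving"
  if (!all(is.finite(F))) abort("non-finite landscape values.")

  structure(tibble::tibble(s = s, m = pmax(Nm - s, 0), F = F, stage = stage),
            regime = regime, Nstar = Nstar, N = N, D = D, phi0 = phi0,
            class = c("ejection_landscape", class(tibble::tibble())))
}

#' @export
print.ejection_landscape <- function(x, ...) {
  cat("<ejection_landscape> regime", attr(x, "regime"),
      " N =", attr(x, "N"), " D =", format(attr(x, "D"), digits = 5),
      " N* =", format(attr(x, "Nstar"), digits = 5), "\n")
  NextMethod()
}

# mean first-passage time over potential U (kT units) on [a, b] with
# reflecting boundary at a, absorbing at b, diffusion coefficient Dc:
#   tau = (1/Dc) int_a^b e^{U(x)} int_a^x e^{-U(y)} dy dx
mfpt_quadrature <- function(U, a, b, Dc = 1, n = 4001) {
  x <- seq(a, b, length.out = n)
  u <- U(x)
  u <- u - min(u)  # overflow guard; shifts cancel between the two factors
  inner <- pracma::cumtrapz(x, exp(-u))[, 1]
  pracma::trapz(x, exp(u) * inner) / Dc
}

#' Mean entering time across the pore channel
#'
#' The head monomer's traversal of the pore is a Kramers first-passage
#' problem: drift-diffusion over a linear potential of slope
#' \eqn{\Delta\mu_{cp}/\sigma} on \eqn{[-\ell_p, 0]}, reflecting at the
#' entrance, absorbing at the exit, with diffusion coefficient
#' \eqn{k_BT/\eta}. The numeric double-integral reproduces the three limits:
#' Arrhenius growth \eqn{\propto \eta\,e^{m_p\Delta\mu_{cp}/k_BT}} for a high
#' barrier, the diffusive time \eqn{\eta\ell_p^2/(2k_BT)} at
#' \eqn{\Delta\mu_{cp} = 0}, and drift-dominated linear-in-\eqn{m_p} entry
#' for strongly negative \eqn{\Delta\mu_{cp}}.
#'
#' @param params a [theory_params()] object (uses `dmu_cp`, `eta0`).
#' @param lp pore length (sigma units).
#' @param n quadrature grid size.
#' @return mean first-passage time (t_u units).
#' @export
entering_time <- function(params = theory_params(), lp = 1, n = 4001) {
  if (lp <= 0) abort("`lp` must be positive.")
  mu <- params$dmu_cp  # kT per sigma of pore advanced
  mfpt_quadrature(function(x) mu * x, a = -lp, b = 0,
                  Dc = 1 / params$eta0, n = n)
}

#' Predicted stage times of the main ejection
#'
#' Selects the prediction row by the position of \eqn{N - m_p} relative to
#' \eqn{N_*} and \eqn{2N_*}:
#' confined time
#' \eqn{\tau_1 = \frac{N^{x_1}}{z_1-1} N_*^2 [1 - (N_*/N)^{z_1-1}]} (zero when
#' the process never starts confined), thermal-escape time \eqn{\tau_{2E}}
#' computed as a numeric mean first-passage time over the non-confined
#' free-energy barrier between \eqn{s^*} and \eqn{(N-m_p)/2} with friction
#' \eqn{\eta_0 N^{x_1}} (zero when the barrier top is already passed at the
#' confined/non-confined junction), and entropic-pulling time
#' \eqn{\tau_{2P} = \frac{1}{1+z_{2P}} (N/2)^{1+z_{2P}}} or
#' \eqn{\frac{1}{1+z_{2P}} N_*^{1+z_{2P}}} in the long-chain regime.
#' All in \eqn{\Delta t_0} units. Boundary ties resolve to the middle row.
#'
#' @param N chain length. @param D cavity diameter (possibly `Inf`).
#' @param params a [theory_params()] object.
#' @return one-row tibble: regime_row, tau1, tau2E, tau2P, tau_ej.
#' @export
stage_time_predictions <- function(N, D, params = theory_params()) {
  p <- params
  Nstar <- if (is.finite(D)) critical_number(D, p$nu, p$Nstar_prefactor)
           else 0
  Nm <- N - p$m_p
  row <- if (Nm < Nstar) 1L else if (Nm <= 2 * Nstar) 2L else 3L

  tau1 <- if (row == 1L) 0 else
    N^p$x1 / (p$z1 - 1) * Nstar^2 * (1 - (Nstar / N)^(p$z1 - 1))

  tau2E <- if (row == 3L) 0 else {
    s_lo <- max(Nm - Nstar, 0)
    s_mid <- Nm / 2
    U <- function(s) (1 - p$gamma1) * (log(pmax(Nm - s, 0) + 1) +
                                         log(s + 1))
    if (s_mid > s_lo)
      mfpt_quadrature(U, s_lo, s_mid, Dc = 1 / N^p$x1) else 0
  }

  tau2P <- if (row == 3L) Nstar^(1 + p$z2P) / (1 + p$z2P)
           else (N / 2)^(1 + p$z2P) / (1 + p$z2P)

  tau1 <- tau1 * p$dt0
  tau2E <- tau2E * p$dt0
  tau2P <- tau2P * p$dt0
  tibble::tibble(regime_row = row, tau1 = tau1, tau2E = tau2E,
                 tau2P = tau2P, tau_ej = tau1 + tau2E + tau2P)
}

#' Mean leaving time of the chain tail through the pore
#'
#' The tail is pulled through the channel by the chemical potential drop
#' \eqn{\Delta\mu_{ps} < 0}:
#' \eqn{\tau_{leav} \approx m_p (k_BT/|\Delta\mu_{ps}|)\,\Delta t_0},
#' linear in the pore length and independent of \eqn{\phi_0}.
#'
#' @param params a [theory_params()] object (uses `dmu_ps`).
#' @param lp pore length.
#' @export
leaving_time <- function(params = theory_params(), lp = 1) {
  if (params$dmu_ps >= 0) abort("`dmu_ps` must be negative.")
  lp * (1 / abs(params$dmu_ps)) * params$dt0
}
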