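#' Specification for synthetic event-series fixtures
#'
#' Event series sampled from the theory kinetics, so the whole analysis
#' pipeline can be exercised in milliseconds without molecular dynamics.
#' Dwell times at each state m have mean \eqn{\sigma / V(m)} where V is
#' either the piecewise kinetics speed (confined compression for
#' \eqn{m > N_*}, entropic pulling below - the default, whose minimum sits
#' exactly at \eqn{N_*}) or the combined single-equation model
#' ([speed_model()]). Dwell noise is exponential (memoryless Markov states),
#' gamma (over-dispersed), or zero ("deterministic").
#'
#' @param N chain length. @param D cavity diameter or `Inf`.
#' @param params a [theory_params()] object.
#' @param dwell dwell-noise model.
#' @param model speed model used for the dwell means.
#' @param n_runs runs to generate. @param seed RNG seed.
#' @param tau_ent_mean mean entering-stage plateau added to the dwell at
#'   m = N (0 = none).
#' @param tau_leav_mean mean leaving-stage tail after m reaches 0.
#' @param gamma_shape shape parameter of the gamma dwell model.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(N, D = Inf, params = theory_params(),
                         dwell = c("exponential", "deterministic", "gamma"),
                         model = c("piecewise", "combined"),
                         n_runs = 1, seed = 1,
                         tau_ent_mean = 0, tau_leav_mean = 0,
                         gamma_shape = 4) {
  dwell <- match.arg(dwell)
  model <- match.arg(model)
  stopifnot(N >= 2, n_runs >= 1, tau_ent_mean >= 0, tau_leav_mean >= 0)
  if (params$z1 <= 1 || params$z2P <= 0) abort("invalid exponents.")
  structure(list(N = as.integer(N), D = D, params = params, dwell = dwell,
                 model = model, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), tau_ent_mean = tau_ent_mean,
                 tau_leav_mean = tau_leav_mean, gamma_shape = gamma_shape),
            class = "fixture_spec")
}

# model speed at state m (vectorised)
fixture_speed <- function(spec, m) {
  p <- spec$params
  if (spec$model == "combined") return(speed_model(m, spec$N, spec$D, p))
  v0 <- 1 / p$dt0
  if (is.finite(spec$D)) {
    Nstar <- critical_number(spec$D, p$nu, p$Nstar_prefactor)
    Dd <- spec$D^(p$d * p$z1)
    conf <- p$A1 * m^p$z1 / (spec$N^p$x1 * Dd) *
      (1 + p$B2 * m^(p$z1 + 1) / Dd)
    ifelse(m > Nstar, v0 * conf, v0 * p$A2 * m^(-p$z2P))
  } else {
    v0 * p$A2 * m^(-p$z2P)
  }
}

#' Generate synthetic event series from a fixture specification
#'
#' Each run walks m from N down to 0; the state s advances as
#' \eqn{\max(0, N - m_p - m)}, and a final record at s = N closes the run
#' after the leaving tail. Deterministic under a fixed seed, and the output
#' satisfies every `ejection_ensemble` invariant of the simulator.
#'
#' @param spec a [fixture_spec()].
#' @return an `ejection_ensemble` tibble (run, t, m, s).
#' @export
generate_event_series <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  m_states <- seq(spec$N, 1)               # dwell occurs at these states
  means <- 1 / fixture_speed(spec, m_states)
  m_p <- spec$params$m_p
  draw <- function(mu, n = length(mu)) {
    if (any(mu <= 0)) abort("non-positive dwell mean.")
    switch(spec$dwell,
           deterministic = mu,
           exponential = rexp(n, rate = 1 / mu),
           gamma = stats::rgamma(n, shape = spec$gamma_shape,
                                 scale = mu / spec$gamma_shape))
  }
  one <- function(run) {
    dw <- draw(means)
    if (spec$tau_ent_mean > 0)
      dw[1] <- dw[1] + draw(spec$tau_ent_mean, 1)
    t_rec <- c(0, cumsum(dw))               # times at which m = N, N-1, .., 0
    m_rec <- c(spec$N, m_states - 1L)
    s_rec <- pmax(0L, spec$N - m_p - m_rec)
    if (spec$tau_leav_mean > 0) {
      t_rec <- c(t_rec, t_rec[length(t_rec)] + draw(spec$tau_leav_mean, 1))
      m_rec <- c(m_rec, 0L)
      s_rec <- c(s_rec, spec$N)
    } else {
      s_rec[length(s_rec)] <- spec$N
    }
    tibble::tibble(run = run, t = t_rec, m = as.integer(m_rec),
                   s = as.integer(s_rec))
  }
  out <- dplyr::bind_rows(lapply(seq_len(spec$n_runs), one))
  structure(out, spec = spec,
            params = list(N = spec$N, D = spec$D, m_p = m_p,
                          phi0 = if (is.finite(spec$D))
                            volume_fraction(spec$N, spec$D) else 0),
            class = c("ejection_ensemble", class(out)))
}

#' Tiny deterministic bead configurations for force/energy unit checks
#'
#' A dimer at bond distance sigma in the open slit, an 8-bead zig-zag chain
#' inside the cavity, and a head-at-entrance configuration. Coordinates are
#' fixed constants (bitwise stable).
#'
#' @param params a [system_params()] object providing the geometry frame.
#' @return named list of `chain_state` objects.
#' @export
tiny_md_configs <- function(params = system_params(N = 8, D = 8)) {
  g <- geometry(params)
  zc <- params$H / 2
  dimer <- chain_state(rbind(c(g$x_exit + 20, 0, zc),
                             c(g$x_exit + 21, 0, zc)))
  th <- (0:7) * (1 / 2.2)          # arc of radius 2.2, ~unit bead spacing
  chain8 <- chain_state(cbind(2.2 * cos(th), 2.2 * sin(th),
                              zc + 0.1 * (-1)^(1:8)))
  head_entry <- chain_state(rbind(c(g$x_ent - 0.01, 0, zc),
                                  c(g$x_ent - 1.0, 0.2, zc),
                                  c(g$x_ent - 1.9, 0.5, zc - 0.1)))
  list(dimer = dimer, chain8 = chain8, head_at_entrance = head_entry)
}
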