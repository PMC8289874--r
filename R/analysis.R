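#' Monotone state timeline of a single event series
#'
#' Raw (t, m) records may re-cross a state value (m can transiently
#' re-increase when a monomer diffuses back into the cavity). For
#' first-passage analysis each level v is assigned the time of its *last*
#' downward crossing - the moment the chain leaves states >= v for good -
#' which yields a monotone non-increasing m(t).
#'
#' @param ev an `event_series` tibble (columns t, m) for one run.
#' @return tibble with columns `m` (the level departed) and `t` (last
#'   departure time), ordered by decreasing m.
#' @export
state_series <- function(ev) {
  if (!nrow(ev)) abort("empty event series.")
  m <- ev$m; t <- ev$t
  m_final <- m[length(m)]
  levels <- seq(max(m), m_final + 1)
  if (!length(levels)) return(tibble::tibble(m = integer(), t = numeric()))
  tt <- vapply(levels, function(v) {
    idx <- which(m[-length(m)] >= v & m[-1] < v)
    if (!length(idx)) NA_real_ else t[max(idx) + 1]
  }, numeric(1))
  out <- tibble::tibble(m = as.integer(levels), t = tt)
  out[!is.na(out$t), ]
}

# last-departure crossing time of level v (m < v for good); NA if never
cross_time <- function(ss, v) {
  hit <- ss$t[ss$m >= v]
  if (!length(hit)) NA_real_ else max(hit)
}

#' Waiting-time function and ejection speed of an ensemble
#'
#' The waiting time W(m) is the mean over runs of the total residence time
#' at state m (every visit counts, re-crossings included); the ejection
#' speed is \eqn{V_{ej}(m) = \sigma / W(m)}. States visited by no run are
#' absent from the table (never zero-filled).
#'
#' @param ensemble an `ejection_ensemble` (columns run, t, m, s).
#' @return `speed_profile` tibble: m, W, V, n (runs contributing).
#' @export
waiting_times <- function(ensemble) {
  if (!nrow(ensemble)) abort("need at least one uncensored run.")
  prof <- ensemble |>
    dplyr::group_by(.data$run) |>
    dplyr::mutate(dwell = dplyr::lead(.data$t) - .data$t) |>
    dplyr::filter(!is.na(.data$dwell)) |>
    dplyr::group_by(.data$run, .data$m) |>
    dplyr::summarise(res = sum(.data$dwell), .groups = "drop") |>
    dplyr::group_by(.data$m) |>
    dplyr::summarise(W = mean(.data$res), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(V = 1 / .data$W) |>
    dplyr::select("m", "W", "V", "n") |>
    dplyr::arrange(.data$m)
  structure(prof, params = attr(ensemble, "params"),
            class = c("speed_profile", class(prof)))
}

#' Detect the critical monomer number from a speed profile
#'
#' Locates the minimum of the smoothed ejection speed restricted to
#' 1 < m < N; the smoother is a centred moving geometric mean (positive
#' speeds, multiplicative noise). A minimum sitting at the edge of the
#' profile indicates a monotone, translocation-like profile and is flagged
#' `no_minimum` (detection is then meaningless: there is no confined
#' branch).
#'
#' @param profile a `speed_profile`.
#' @param window odd smoothing window (states), default 5.
#' @return one-row tibble: `m_star` (NA when flagged), `no_minimum`.
#' @export
detect_Nstar <- function(profile, window = 5) {
  prof <- dplyr::arrange(profile, .data$m)
  N_top <- max(prof$m)
  prof <- dplyr::filter(prof, .data$m > 1, .data$m < N_top)
  if (nrow(prof) < 5) abort("profile must cover at least 5 states.")
  h <- window %/% 2
  logv <- log(prof$V)
  sm <- vapply(seq_along(logv), function(i) {
    j <- max(1, i - h):min(length(logv), i + h)
    mean(logv[j])
  }, numeric(1))
  i_min <- which.min(sm)
  edge <- i_min <= h || i_min > length(sm) - h
  tibble::tibble(m_star = if (edge) NA_integer_ else prof$m[i_min],
                 no_minimum = edge)
}

#' Ensemble-mean descent of m and nucleation trimming
#'
#' `mean_m_curve()` averages, over runs, the monotone last-departure time of
#' each state (see [state_series()]). `trim_nucleation()` removes the
#' entering-stage plateau - the critical nucleus of `m_n` monomers stalled
#' while the head traverses the pore - and rescales to
#' \eqn{\tilde m = (m - m_n)/(N - m_n)},
#' \eqn{\tilde t = (\langle t\rangle - \tau_n)/(\langle\tau\rangle - \tau_n)}.
#' By default `m_n = m_p` and `tau_n =` mean entering time when
#' \eqn{\phi_0 < \phi_p}, and both are zero when \eqn{\phi_0 \ge \phi_p}
#' (no stall at high density).
#'
#' @param ensemble an `ejection_ensemble`.
#' @param m_n critical nucleus size (monomers); NULL = rule above.
#' @param tau_n nucleation time; NULL = rule above.
#' @param phi0 initial volume fraction (default from ensemble params).
#' @param m_p pore occupancy (default from ensemble params, else 1).
#' @param phi_p pore volume fraction threshold.
#' @return tibble m, t_mean, m_tilde, t_tilde.
#' @export
trim_nucleation <- function(ensemble, m_n = NULL, tau_n = NULL,
                            phi0 = NULL, m_p = NULL,
                            phi_p = phi_pore(0.75)) {
  p <- attr(ensemble, "params")
  if (is.null(phi0)) phi0 <- if (!is.null(p)) p$phi0 else 0
  if (is.null(m_p)) m_p <- if (!is.null(p)) p$m_p else 1L
  curve <- mean_m_curve(ensemble)
  N <- max(curve$m)
  if (is.null(m_n)) m_n <- if (phi0 >= phi_p) 0L else m_p
  if (is.null(tau_n))
    tau_n <- if (phi0 >= phi_p) 0 else mean_entering_time(ensemble)
  if (m_n < 0 || tau_n < 0) abort("m_n and tau_n must be non-negative.")
  tau <- max(curve$t_mean)
  if (tau_n >= tau) abort("tau_n must be below the mean total time.")
  dplyr::mutate(curve,
                m_tilde = (.data$m - m_n) / (N - m_n),
                t_tilde = (.data$t_mean - tau_n) / (tau - tau_n))
}

#' @rdname trim_nucleation
#' @export
mean_m_curve <- function(ensemble) {
  N <- max(ensemble$m)
  ensemble |>
    dplyr::group_by(.data$run) |>
    dplyr::group_modify(~ {
      ss <- state_series(.x)
      # arrival convention: the chain reaches state v - 1 when it departs
      # level v for good; the start state N is reached at t = 0
      tibble::tibble(m = c(N, ss$m - 1L), t = c(min(.x$t), ss$t))
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$m) |>
    dplyr::summarise(t_mean = mean(.data$t), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m))
}

mean_entering_time <- function(ensemble) {
  ent <- ensemble |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(tau_ent = {
      hit <- .data$t[.data$s >= 1]
      if (length(hit)) min(hit) else NA_real_
    }, .groups = "drop")
  mean(ent$tau_ent, na.rm = TRUE)
}

#' Decompose each run into the five processing stages
#'
#' The total processing time splits as
#' \eqn{\tau = \tau_{ent} + \tau_{ej} + \tau_{leav}} with
#' \eqn{\tau_{ej} = \tau_1 + \tau_{2E} + \tau_{2P}}. Boundaries (on the
#' monotone last-departure timeline): the entering stage ends at the first
#' arrival of a monomer in the semi-space (s = 1); the confined stage at
#' first passage \eqn{m \le N_*}; the thermal-escape stage at first passage
#' \eqn{m \le (N - m_p)/2} (it has zero length when \eqn{N_*} lies below the
#' middle, i.e. the free energy has no second barrier); the entropic-pulling
#' stage at m = 0; the leaving stage at the final record (s = N).
#'
#' @param ensemble an `ejection_ensemble` (or single `event_series` with a
#'   `run` column).
#' @param Nstar critical monomer number (e.g. from [detect_Nstar()] or
#'   [critical_number()]); use 0 for translocation mode.
#' @param m_p pore occupancy (default from ensemble params, else 1).
#' @return `stage_times` tibble, one row per run: tau_ent, tau1, tau2E,
#'   tau2P, tau_leav, tau_ej, tau_total.
#' @export
decompose_stages <- function(ensemble, Nstar, m_p = NULL) {
  p <- attr(ensemble, "params")
  if (is.null(m_p)) m_p <- if (!is.null(p)) p$m_p else 1L
  N <- max(ensemble$m)
  if (Nstar < 0 || Nstar > N) abort("Nstar outside [0, N].")
  v_star <- floor(Nstar) + 1      # m <= Nstar  <=>  m < v_star
  v_half <- floor((N - m_p) / 2) + 1
  one <- function(ev) {
    ss <- state_series(ev)
    tau_total <- max(ev$t)
    ent_hit <- ev$t[ev$s >= 1]
    tau_ent <- if (length(ent_hit)) min(ent_hit) else NA_real_
    t_star <- cross_time(ss, v_star)
    t_zero <- cross_time(ss, 1)
    if (is.na(t_star)) t_star <- tau_ent   # started below Nstar
    t_star <- max(t_star, tau_ent)
    no_escape <- Nstar < (N - m_p) / 2     # barrier top before the junction
    t_half <- if (no_escape) t_star else max(cross_time(ss, v_half), t_star)
    tibble::tibble(
      tau_ent = tau_ent,
      tau1 = t_star - tau_ent,
      tau2E = t_half - t_star,
      tau2P = t_zero - t_half,
      tau_leav = tau_total - t_zero,
      tau_ej = t_zero - tau_ent,
      tau_total = tau_total)
  }
  out <- ensemble |>
    dplyr::group_by(.data$run) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  structure(out, Nstar = Nstar,
            class = c("stage_times", class(out)))
}

#' Power-law fit on a log-log window
#'
#' Least squares of \eqn{\log y} on \eqn{\log x} restricted to
#' `window` (inclusive bounds on x). The standard scaling windows used for
#' speed profiles are `0.01 < m/N < 0.5` (entropic pulling) and
#' `0.5 < m/N < 0.95` (confined / thermal escape), applied to x = m/N.
#'
#' @param data a data frame.
#' @param x,y unquoted column names (positive values).
#' @param window numeric length-2 range of x to keep (NULL = all).
#' @return `ejection_fit` object; see [tidy.ejection_fit()].
#' @export
fit_power_law <- function(data, x, y, window = NULL) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv) & xv > 0 & yv > 0
  if (!is.null(window)) keep <- keep & xv >= window[1] & xv <= window[2]
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) abort("need >= 3 points in the fit window.")
  if (diff(range(xv)) == 0) abort("degenerate x (zero spread).")
  fit <- lm(log(yv) ~ log(xv))
  sm <- suppressWarnings(summary(fit))  # zero-residual data warns benignly
  new_ejection_fit(
    tag = "power-law",
    estimate = c(exponent = unname(coef(fit)[2]),
                 log_prefactor = unname(coef(fit)[1])),
    se = c(exponent = sm$coefficients[2, 2],
           log_prefactor = sm$coefficients[1, 2]),
    window = window, n = length(xv),
    resid_norm = sqrt(sum(fit$residuals^2)),
    r_squared = sm$r.squared)
}

#' Exponential fit of the entering time against pore length
#'
#' Nonlinear least squares of \eqn{\tau_{ent} = a_n \exp(b_n \ell_p)}
#' (Arrhenius growth of the Kramers entering time with the pore length),
#' initialised from the log-linear fit.
#'
#' @param lp pore lengths (>= 3 values).
#' @param tau_ent mean entering times (positive).
#' @return `ejection_fit` with parameters `a_n`, `b_n`.
#' @export
fit_entering_exponential <- function(lp, tau_ent) {
  if (length(lp) < 3) abort("need >= 3 pore lengths.")
  if (any(tau_ent <= 0)) abort("entering times must be positive.")
  init <- coef(lm(log(tau_ent) ~ lp))
  fit <- nls(tau_ent ~ a * exp(b * lp),
             start = list(a = exp(unname(init[1])), b = unname(init[2])),
             control = stats::nls.control(maxiter = 200, scaleOffset = 1))
  sm <- summary(fit)
  new_ejection_fit(
    tag = "exponential",
    estimate = c(a_n = unname(coef(fit)["a"]), b_n = unname(coef(fit)["b"])),
    se = c(a_n = sm$coefficients["a", 2], b_n = sm$coefficients["b", 2]),
    window = range(lp), n = length(lp),
    resid_norm = sqrt(sum(stats::resid(fit)^2)),
    r_squared = 1 - sum(stats::resid(fit)^2) /
      sum((tau_ent - mean(tau_ent))^2))
}

#' Rescaled speed curves for exponent diagnostics
#'
#' Multiplying the speed by \eqn{N^{x_1+z_1} m^{-z_1}} flattens the confined
#' branch at the true exponents, and by \eqn{N^{x_1+z_1} m^{z_{2P}}} the
#' non-confined branch; deviations tilt the plateau. The flatness score of a
#' window is the coefficient of variation of the rescaled speed (smaller is
#' flatter).
#'
#' @param profile a `speed_profile`.
#' @param N chain length.
#' @param x1,z1,z2P exponents to test.
#' @return the profile with columns `V_conf_rescaled`, `V_pull_rescaled`.
#' @export
rescale_speed <- function(profile, N, x1, z1, z2P) {
  stopifnot(is.finite(x1), is.finite(z1), is.finite(z2P))
  dplyr::mutate(profile,
                V_conf_rescaled = .data$V * N^(x1 + z1) * .data$m^(-z1),
                V_pull_rescaled = .data$V * N^(x1 + z1) * .data$m^z2P)
}

#' @rdname rescale_speed
#' @param x rescaled values over the diagnostic window.
#' @export
flatness_score <- function(x) {
  x <- x[is.finite(x)]
  sd(x) / mean(x)
}
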