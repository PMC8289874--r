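#' @title Chain state constructor (internal use and fixtures)
#' @description Positions and velocities of the N beads plus phase
#'   bookkeeping. Phases follow the three-step protocol: LOADING,
#'   EQUILIBRATION (head monomer fixed at the pore entrance), EJECTION.
#' @param positions,velocities N x 3 matrices.
#' @param time elapsed simulation time.
#' @param phase one of "LOADING", "EQUILIBRATION", "EJECTION".
#' @return object of class `chain_state`.
#' @export
chain_state <- function(positions, velocities = NULL, time = 0,
                        phase = "LOADING") {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  structure(list(positions = positions, velocities = velocities,
                 time = time, phase = phase),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat("<chain_state> N =", nrow(x$positions), " phase =", x$phase,
      " t =", format(x$time, digits = 6), "\n")
  invisible(x)
}

# one call into the C++ BAOAB engine; returns updated state + extras
run_md <- function(state, params, n_steps, seed, head_fixed = FALSE,
                   reflect = FALSE, record = FALSE, terminate = FALSE,
                   fmax = 0, ke_stride = 0L, dt = params$dt,
                   damp = params$damp, temperature = params$temperature) {
  geom <- geometry(params)
  out <- cpp_simulate(state$positions, state$velocities, engine_geom(geom),
                      as.double(n_steps), dt, damp,
                      temperature, state$time, as.integer(seed),
                      head_fixed, reflect, record, terminate, fmax,
                      as.integer(ke_stride))
  state$positions <- out$positions
  state$velocities <- out$velocities
  state$time <- out$time
  list(state = state, status = out$status, steps = out$steps,
       events = out$events, kinetic = out$kinetic)
}

#' Single Langevin step (exposed for integrator-contract checks)
#'
#' One BAOAB step of underdamped Langevin dynamics at friction
#' \eqn{\gamma = m/\mathrm{damp}} with Gaussian noise satisfying
#' fluctuation-dissipation at the thermostat temperature. With `damp <= 0`
#' the noise and friction vanish and the scheme reduces to velocity Verlet.
#'
#' @param state a `chain_state`. @param params a [system_params()] object.
#' @param seed integer seed for the noise stream.
#' @param n_steps number of steps to take (default 1).
#' @return updated `chain_state`.
#' @export
langevin_step <- function(state, params, seed, n_steps = 1) {
  run_md(state, params, n_steps, seed)$state
}

# Archimedean spiral filling of the disk-like cavity: consecutive beads at
# arc spacing `a`, successive turns at radial gap `a`, alternating small z
# offsets so dense chains can stagger between the slit walls.
spiral_positions <- function(n, R, a, H, z_off) {
  pts <- matrix(0, 0, 3)
  b <- a / (2 * pi)        # r = b * theta
  theta <- a / b           # skip the singular centre
  i <- 0
  while (b * theta <= R) {
    r <- b * theta
    i <- i + 1
    z <- H / 2 + z_off * (-1)^i
    pts <- rbind(pts, c(r * cos(theta), r * sin(theta), z))
    theta <- theta + a / r
  }
  if (nrow(pts) < n) return(NULL)
  pts <- pts[rev(seq_len(n)), , drop = FALSE]  # outer end first
  # rotate so the outer end faces the pore entrance (+x)
  phi <- atan2(pts[1, 2], pts[1, 1])
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  pts[, 1:2] <- pts[, 1:2] %*% rot
  pts
}

#' Load the chain into the cavity
#'
#' Places the head monomer just inside the pore entrance and coils the rest
#' of the chain into the cavity along a compact spiral (a deterministic
#' stand-in for the pumping process: the only contract is a self-avoiding
#' confined chain with the head at the entrance), then relaxes briefly with
#' capped forces and the head held fixed. Fails with advice to lower
#' `phi0` if the requested density cannot be placed; densities above the
#' close-pack bound [close_pack_phi0()] are rejected outright.
#'
#' In translocation mode (`D = Inf`) the chain is laid along the pore axis on
#' the cis side and relaxed the same way.
#'
#' @param params a [system_params()] object.
#' @param seed integer seed for the relaxation noise.
#' @param relax_time duration of the capped-force relaxation (t_u).
#' @return a `chain_state` with phase LOADING complete.
#' @export
load_chain <- function(params, seed = 1, relax_time = 10) {
  N <- params$N
  H <- params$H
  geom <- geometry(params)
  head <- c(geom$x_ent - 0.01, 0, H / 2)

  if (is.finite(params$D)) {
    if (params$phi0 >= close_pack_phi0(H))
      abort(paste0("phi0 = ", signif(params$phi0, 3),
                   " exceeds the close-pack bound ",
                   signif(close_pack_phi0(H), 4),
                   "; lower phi0 (or increase D)."))
    R <- params$D / 2 - 0.55
    if (R <= 0.5) abort("cavity too small to hold the chain.")
    # loosest arc spacing that still fits N - 1 beads, hard floor 0.82 sigma
    a_try <- rev(seq(0.82, 1.0, by = 0.02))
    pos <- NULL
    for (a in a_try) {
      z_off <- if (a < 0.95) 0.28 else 0
      body <- spiral_positions(N - 1, R, a, H, z_off)
      if (!is.null(body)) { pos <- rbind(head, body); break }
    }
    if (is.null(pos))
      abort("cannot place the chain at this density; lower phi0.")
  } else {
    xs <- head[1] - seq_len(N - 1) * 0.98
    pos <- rbind(head, cbind(xs, 0, H / 2))
  }
  rownames(pos) <- NULL

  st <- chain_state(pos, time = 0, phase = "LOADING")
  # two-step relaxation with the head fixed: an overdamped zero-temperature
  # quench heals placement contacts without inertia build-up, then plain
  # thermal dynamics settle the packing
  st <- run_md(st, params, 5000, seed, head_fixed = TRUE,
               fmax = 1e4, dt = 1e-4, damp = 0.05, temperature = 0)$state
  st$velocities[] <- 0
  out <- run_md(st, params, ceiling(relax_time / 0.002), seed + 1,
                head_fixed = TRUE, dt = 0.002)
  if (out$status == 2) abort("loading relaxation diverged; lower phi0.")
  st <- out$state
  d <- min_pair_distance(st$positions)
  if (d < 0.9) {
    out <- run_md(st, params, ceiling(relax_time / 0.002), seed + 2,
                  head_fixed = TRUE, dt = 0.002)
    st <- out$state
    d <- min_pair_distance(st$positions)
  }
  if (d < 0.85)
    abort("loading failed to relax overlaps; lower phi0.")
  st$time <- 0
  st$phase <- "LOADING"
  st
}

min_pair_distance <- function(pos) {
  if (nrow(pos) < 2) return(Inf)
  min(stats::dist(pos))
}

#' Equilibrate the loaded chain with the head monomer fixed
#'
#' Samples Maxwell-Boltzmann velocities and runs Langevin dynamics for
#' `duration` with bead 1 frozen at the pore entrance, which blocks the only
#' exit. The default duration is the larger of 10 Rouse-time estimates
#' \eqn{N^2\sigma^2\,\mathrm{damp}/(3\pi^2 T)} and 100 t_u.
#'
#' @param state a `chain_state` from [load_chain()].
#' @param params a [system_params()] object.
#' @param duration equilibration time (t_u).
#' @param seed integer seed.
#' @return a `chain_state` with phase EQUILIBRATION complete and an attribute
#'   `kinetic` holding total kinetic energy sampled every 100 steps.
#' @export
equilibrate <- function(state, params,
                        duration = max(100, 10 * params$N^2 * params$damp /
                                         (3 * pi^2 * params$temperature)),
                        seed = 1) {
  N <- nrow(state$positions)
  set.seed(seed)
  state$velocities <- matrix(
    rnorm(3 * N, sd = sqrt(params$temperature / params$mass)), N, 3)
  state$velocities[1, ] <- 0
  out <- run_md(state, params, ceiling(duration / params$dt), seed + 1,
                head_fixed = TRUE, ke_stride = 100L)
  if (out$status == 2) abort("equilibration diverged (overlap/NaN).")
  st <- out$state
  st$phase <- "EQUILIBRATION"
  attr(st, "kinetic") <- out$kinetic
  st
}

#' Run the ejection phase and record the event series
#'
#' Frees the head monomer (reflective entrance wall active) and integrates
#' until the last bead passes the pore exit plane. Every step the region
#' counts are recomputed and a record `(t, m, s)` is appended whenever m
#' (beads in the cavity) or s (beads in the semi-space) changes; the pore
#' count is `N - m - s`, so the bookkeeping identity holds at every frame.
#' Runs exceeding `step_budget` are returned flagged censored.
#'
#' @param state an equilibrated `chain_state`.
#' @param params a [system_params()] object.
#' @param seed integer seed.
#' @param step_budget maximum number of integration steps.
#' @return an `event_series` tibble with columns t, m, s and attributes
#'   `seed`, `params`, `censored`, `steps`.
#' @export
run_ejection <- function(state, params, seed = 1, step_budget = 5e7) {
  state$time <- 0
  out <- run_md(state, params, step_budget, seed,
                reflect = TRUE, record = TRUE, terminate = TRUE)
  if (out$status == 2) abort("ejection run diverged (overlap/NaN).")
  ev <- tibble::as_tibble(out$events)
  structure(ev, seed = seed, params = params,
            censored = out$status == 0, steps = out$steps,
            class = c("event_series", class(ev)))
}

#' Run an ensemble of independent ejection simulations
#'
#' Each run loads, equilibrates and ejects with its own seed
#' (`base_seed + i`). Censored runs (step budget exhausted) are kept in the
#' log but their events excluded from the returned table.
#'
#' @param params a [system_params()] object.
#' @param n_runs number of independent runs.
#' @param base_seed integer; run i uses seed `base_seed + i`.
#' @param equil_time passed to [equilibrate()].
#' @param step_budget passed to [run_ejection()].
#' @param progress print per-run progress to stderr.
#' @return tibble with columns run, t, m, s (class `ejection_ensemble`);
#'   attributes `params` and `log` (tibble run, seed, censored, steps,
#'   tau_total).
#' @export
run_ensemble <- function(params, n_runs, base_seed = 1,
                         equil_time = NULL, step_budget = 5e7,
                         progress = FALSE) {
  stopifnot(n_runs >= 1)
  runs <- vector("list", n_runs)
  log <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    sd_i <- (base_seed + i) %% .Machine$integer.max
    st <- load_chain(params, seed = sd_i)
    st <- if (is.null(equil_time)) equilibrate(st, params, seed = sd_i + 1L)
          else equilibrate(st, params, duration = equil_time,
                           seed = sd_i + 1L)
    ev <- run_ejection(st, params, seed = sd_i + 2L,
                       step_budget = step_budget)
    cens <- attr(ev, "censored")
    log[[i]] <- tibble::tibble(run = i, seed = sd_i, censored = cens,
                               steps = attr(ev, "steps"),
                               tau_total = if (cens) NA_real_ else max(ev$t))
    runs[[i]] <- if (cens) NULL else dplyr::mutate(ev, run = i,
                                                   .before = 1)
    if (progress)
      message(sprintf("run %d/%d %s", i, n_runs,
                      if (cens) "(censored)" else ""))
  }
  out <- dplyr::bind_rows(runs)
  structure(out, params = params, log = dplyr::bind_rows(log),
            class = c("ejection_ensemble", class(out)))
}

#' Write / read an ensemble as CSV event tables with JSON sidecars
#'
#' One `run-<i>.csv` per run with header `t,m,s` and a `run-<i>.json`
#' sidecar holding the seed, parameters and censoring flag.
#'
#' @param ensemble an `ejection_ensemble`.
#' @param dir output directory (created if missing).
#' @return `write_event_series()`: `dir`, invisibly.
#'   `read_event_series()`: an `ejection_ensemble`.
#' @export
write_event_series <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log <- attr(ensemble, "log")
  p <- attr(ensemble, "params")
  for (i in unique(ensemble$run)) {
    ev <- dplyr::filter(ensemble, .data$run == i)[, c("t", "m", "s")]
    utils::write.csv(ev, file.path(dir, sprintf("run-%04d.csv", i)),
                     row.names = FALSE)
    meta <- list(run = i, params = unclass(p))
    if (!is.null(log)) meta <- c(meta, as.list(log[log$run == i, ]))
    jsonlite::write_json(meta, file.path(dir, sprintf("run-%04d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_event_series
#' @export
read_event_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "^run-\\d+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) abort("no run-*.csv files found.")
  runs <- purrr::map2(files, seq_along(files), function(f, i) {
    ev <- utils::read.csv(f)
    dplyr::mutate(ev, run = i, .before = 1)
  })
  out <- tibble::as_tibble(dplyr::bind_rows(runs))
  structure(out, class = c("ejection_ensemble", class(out)))
}
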