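#' Shifted-truncated Lennard-Jones 12-6 pair energy (WCA)
#'
#' \eqn{U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma}, zero beyond: purely repulsive excluded volume,
#' continuous at the cutoff.
#'
#' @param r pair distance (> 0).
#' @param eps,sigma interaction strength and length.
#' @return energy in eps units (vectorised).
#' @export
pair_energy <- function(r, eps = 1, sigma = 1) {
  if (any(r <= 0)) abort("pair distance must be positive (overlap).")
  rc <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  ifelse(r < rc, 4 * eps * (s6^2 - s6) + eps, 0)
}

#' Harmonic bond energy
#'
#' \eqn{U(b) = \tfrac12 k (b - b_0)^2}.
#'
#' @param b bond length (>= 0).
#' @param k spring constant. @param b0 equilibrium length.
#' @export
bond_energy <- function(b, k = 600, b0 = 1) {
  if (any(b < 0)) abort("bond length must be non-negative.")
  0.5 * k * (b - b0)^2
}

#' LJ 9-3 wall energy, shifted to zero at its minimum
#'
#' \eqn{U_w(r) = \epsilon_w[\tfrac{2}{15}(\sigma_w/r)^9 - (\sigma_w/r)^3] +
#' \Delta} for \eqn{r < (2/5)^{1/6}\sigma_w}, zero beyond; the shift
#' \eqn{\Delta = \tfrac23\sqrt{5/2}\,\epsilon_w \approx 1.05409\,\epsilon_w}
#' places the truncation at the potential minimum, leaving a purely repulsive,
#' continuous wall. With \eqn{\epsilon_w = 3\epsilon} the energy reaches
#' \eqn{k_BT} at \eqn{r \approx 0.76\sigma}, i.e. an effective wall thickness
#' of 0.26 sigma.
#'
#' @param r distance from the wall surface (> 0).
#' @param eps_w,sigma_w wall strength and length.
#' @export
wall_energy <- function(r, eps_w = 3, sigma_w = 1) {
  if (any(r <= 0)) abort("wall distance must be positive.")
  rc <- (2 / 5)^(1 / 6) * sigma_w
  x3 <- (sigma_w / r)^3
  ifelse(r < rc, eps_w * ((2 / 15) * x3^3 - x3) + wall_shift(eps_w), 0)
}

#' @rdname wall_energy
#' @export
wall_shift <- function(eps_w = 3) (2 / 3) * sqrt(5 / 2) * eps_w

#' Total potential energy and forces of a chain configuration
#'
#' Sums WCA pair interactions over all non-bonded pairs within the cutoff,
#' harmonic bonds between chain neighbours, and LJ 9-3 wall repulsion from
#' every confining surface (slit planes, cavity sphere of diameter D + 0.52,
#' pore cylinder of diameter dp + 0.52, membrane faces in translocation
#' mode). Forces are the exact negative gradient of this energy.
#'
#' @param positions N x 3 matrix of bead centres.
#' @param geom an [geometry()] object.
#' @return `total_energy()`: scalar energy. `total_force()`: N x 3 matrix;
#'   aborts if any pair distance falls below the 0.3 sigma hard floor.
#' @export
total_energy <- function(positions, geom) {
  cpp_total_energy(as.matrix(positions), engine_geom(geom))
}

#' @rdname total_energy
#' @export
total_force <- function(positions, geom) {
  res <- cpp_total_forces(as.matrix(positions), engine_geom(geom))
  if (isTRUE(res$overlap))
    abort("bead overlap below 0.3 sigma: configuration is unphysical.")
  res$forces
}

#' Reflective wall at the pore entrance for the head monomer
#'
#' During ejection a reflective boundary prevents the head monomer (bead 1)
#' from falling back into the cavity: when its centre crosses the entrance
#' plane toward the cavity, the position is mirrored about the plane and the
#' normal velocity component reversed. All other beads are unaffected.
#'
#' @param state a `chain_state` (see [load_chain()]).
#' @param geom an [geometry()] object.
#' @return the (possibly) updated `chain_state`.
#' @export
reflect_head <- function(state, geom) {
  if (state$positions[1, 1] < geom$x_ent) {
    state$positions[1, 1] <- 2 * geom$x_ent - state$positions[1, 1]
    state$velocities[1, 1] <- -state$velocities[1, 1]
  }
  state
}
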