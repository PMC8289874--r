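#' Initial volume fraction of a chain in the disk-like cavity
#'
#' The cavity is the intersection of a sphere of diameter `D` with a slit of
#' gap height `H`. Its volume is \eqn{\pi H D^2/4\,[1 - (H/D)^2/3]}, so the
#' volume fraction occupied by `N` monomer spheres of diameter \eqn{\sigma} is
#' \deqn{\phi_0 = N (\sigma/D)^2 \frac{2\sigma}{3H\,[1 - (H/D)^2/3]}.}
#' For \eqn{H \ll D} this reduces to the planar packing \eqn{N(\sigma/D)^2}
#' times \eqn{2\sigma/(3H)}.
#'
#' @param N monomer count (>= 1).
#' @param D cavity diameter (sigma units). `Inf` gives 0.
#' @param H slit gap height (sigma units); must satisfy `D > H > 0`.
#' @return volume fraction (dimensionless scalar, vectorised over inputs).
#' @examples
#' volume_fraction(32, 10, 1.5)
#' @export
volume_fraction <- function(N, D, H = 1.5) {
  if (any(N < 1)) abort("`N` must be >= 1.")
  if (any(H <= 0) || any(D <= H)) abort("need D > H > 0.")
  ifelse(is.infinite(D), 0,
         N * (1 / D)^2 * 2 / (3 * H * (1 - (H / D)^2 / 3)))
}

#' Cavity diameter for a generation number
#'
#' Chain lengths and densities are organised on a binary grid
#' \eqn{N = 2^{g_N}}, \eqn{\phi_0 = 0.3 \times 2^{-g_F}}; the diameter
#' generation is \eqn{g_D = g_N + g_F} and
#' \deqn{D_{g_D} = \sigma\sqrt{2^{g_D}/0.3}\,
#'   \sqrt{2\sigma/(3H) + \tfrac13 (H/\sigma)^2\, 0.3\times 2^{-g_D}},}
#' which inverts [volume_fraction()] exactly on that grid.
#'
#' @param gD generation number for D (integer >= 0; fractional values allowed).
#' @param H slit gap height.
#' @param base_fraction density at generation zero (default 0.3).
#' @return cavity diameter in sigma units.
#' @examples
#' diameter_for_generation(3)                     # 3.5499
#' volume_fraction(2^5, diameter_for_generation(5))  # 0.3
#' @export
diameter_for_generation <- function(gD, H = 1.5, base_fraction = 0.3) {
  if (any(gD < 0)) abort("`gD` must be >= 0.")
  sqrt(2^gD / base_fraction) *
    sqrt(2 / (3 * H) + (H^2 / 3) * base_fraction * 2^(-gD))
}

#' Local volume fraction of a monomer inside the pore channel
#'
#' One monomer sphere in a pore cylinder section of radius `rp` and unit
#' length occupies \eqn{\phi_p = \frac{\pi\sigma^3/6}{\pi r_p^2 \sigma}
#'  = \sigma^2/(6 r_p^2)}. Ejections starting with \eqn{\phi_0 \ge \phi_p}
#' need no thermal activation to push the head monomer through the pore.
#'
#' @param rp pore radius (sigma units).
#' @return dimensionless volume fraction.
#' @examples
#' phi_pore(0.75)  # ~0.296
#' @export
phi_pore <- function(rp) {
  if (any(rp <= 0)) abort("`rp` must be positive.")
  1 / (6 * rp^2)
}

#' Close-packing bound on the initial volume fraction in the slit
#'
#' A hexagonal close pack of disks covers \eqn{\phi^{(2D)}_{cl} =
#' \pi/(2\sqrt 3) = 0.9069} of the plane; in the quasi-2D slit the
#' corresponding volume fraction is \eqn{\phi^{(2D)}_{cl} \cdot 2\sigma/(3H)}.
#' Loading a chain denser than this bound is geometrically impossible.
#'
#' @param H slit gap height (sigma units).
#' @return maximum feasible volume fraction.
#' @examples
#' close_pack_phi0(1.5)  # ~0.403
#' @export
close_pack_phi0 <- function(H = 1.5) {
  if (any(H <= 0)) abort("`H` must be positive.")
  (pi / (2 * sqrt(3))) * 2 / (3 * H)
}

#' System parameters in reduced units
#'
#' Collects all physical constants and the cavity-pore-slit dimensions.
#' Exactly one of `D` and `phi0` must be given; the other is derived through
#' the cavity-volume relation (see [volume_fraction()]). `D = Inf` selects the
#' translocation reference mode (no cavity sphere; a flat membrane with a pore
#' separates the two halves of the slit).
#'
#' @param N number of beads (integer >= 2).
#' @param D cavity diameter (sigma units) or `Inf`.
#' @param phi0 initial volume fraction (alternative to `D`).
#' @param H slit gap height. @param lp pore length.
#' @param dp pore effective diameter (< 2 sigma: single file).
#' @param k_spring harmonic bond constant (eps/sigma^2).
#' @param b0 equilibrium bond length.
#' @param eps_w,sigma_w wall interaction strength and length.
#' @param temperature thermostat temperature (eps/kB).
#' @param damp thermostat relaxation time (t_u).
#' @param dt integration time step (t_u).
#' @return object of class `system_params` (a named list) with derived fields
#'   `m_p` (pore occupancy), `rp` (pore radius) and both `D` and `phi0`.
#' @examples
#' p <- system_params(N = 32, phi0 = 0.3)
#' p$D
#' @export
system_params <- function(N, D = NULL, phi0 = NULL, H = 1.5, lp = 1.0,
                          dp = 1.5, k_spring = 600, b0 = 1.0, eps_w = 3.0,
                          sigma_w = 1.0, temperature = 1.0, damp = 1.0,
                          dt = 0.005) {
  if (!is.numeric(N) || length(N) != 1 || N < 2 || N != round(N))
    abort("`N` must be a single integer >= 2.")
  if (is.null(D) == is.null(phi0))
    abort("give exactly one of `D` and `phi0`.")
  stopifnot(H > 0, lp > 0, dp > 0, k_spring > 0, b0 > 0, eps_w > 0,
            sigma_w > 0, temperature > 0, dt > 0)
  if (dp >= 2) abort("`dp` must be < 2 sigma (single-file pore).")

  if (is.null(D)) {
    if (phi0 <= 0) abort("`phi0` must be positive (use D = Inf for phi0 = 0).")
    # invert phi0 = N/D^2 * 2/(3H (1 - H^2/(3 D^2))) for D
    a <- 2 * N / (3 * H * phi0)
    D <- sqrt(a + H^2 / 3)
  } else if (is.infinite(D)) {
    phi0 <- 0
  } else {
    if (D <= H) abort("`D` must exceed `H`.")
    phi0 <- volume_fraction(N, D, H)
  }
  m_p <- as.integer(round(lp / 1))
  if (m_p < 1) abort("pore must hold at least one monomer (lp >= 1 sigma).")

  p <- structure(
    list(N = as.integer(N), sigma = 1, eps = 1, mass = 1, D = D, H = H,
         lp = lp, dp = dp, rp = dp / 2, k_spring = k_spring, b0 = b0,
         eps_w = eps_w, sigma_w = sigma_w, temperature = temperature,
         damp = damp, dt = dt, phi0 = phi0, m_p = m_p),
    class = "system_params")
  if (is.finite(D)) {
    rel <- abs(volume_fraction(N, D, H) - phi0) / max(phi0, 1e-300)
    if (rel > 1e-9) abort("phi0/D/H/N inconsistent.")   # defensive
  }
  p
}

#' @export
print.system_params <- function(x, ...) {
  cat("<system_params> N =", x$N, " D =", format(x$D, digits = 6),
      " phi0 =", format(x$phi0, digits = 4), "\n",
      " H =", x$H, " lp =", x$lp, " dp =", x$dp, " m_p =", x$m_p,
      " T =", x$temperature, " dt =", x$dt, "\n")
  invisible(x)
}

#' Cavity-pore-slit geometry derived from system parameters
#'
#' Canonical frame: slit planes at z = 0 and z = H; cavity centre at
#' (0, 0, H/2); pore axis along +x with the entrance plane tangent to the
#' sphere of diameter D at x = D/2 and the exit plane at x = D/2 + lp.
#' Wall surfaces carry the 0.26 sigma effective thickness per face: the
#' cavity wall sits on a sphere of diameter `D + 0.52` and the pore wall on a
#' cylinder of diameter `dp + 0.52`.
#'
#' @param params a [system_params()] object.
#' @return object of class `ejection_geometry`.
#' @export
geometry <- function(params) {
  stopifnot(inherits(params, "system_params"))
  x_ent <- if (is.finite(params$D)) params$D / 2 else 0
  structure(
    list(H = params$H,
         D = params$D,
         cavity_wall_diameter = params$D + 0.52,
         Rcw = (params$D + 0.52) / 2,
         x_ent = x_ent,
         x_exit = x_ent + params$lp,
         rp = params$rp,
         rpw = (params$dp + 0.52) / 2,
         lp = params$lp,
         eps_w = params$eps_w, sigma_w = params$sigma_w,
         k_spring = params$k_spring, b0 = params$b0,
         centre = c(0, 0, params$H / 2)),
    class = "ejection_geometry")
}

#' Classify bead positions into cavity, pore and semi-space regions
#'
#' Partition used for the (m, m_p, s) bookkeeping: a centre belongs to
#' `CAVITY` when on the cavity side of the entrance plane, `PORE` when in the
#' half-open slab `[entrance, exit)` within the pore radius of the axis, and
#' `SEMI` at or beyond the exit plane. Positions between the planes but
#' outside the pore radius, or outside the accessible space, are flagged
#' `WALL` (diagnostic; they never occur in a valid trajectory).
#'
#' @param positions numeric matrix (n x 3) or data frame with columns x, y, z.
#' @param geom an [geometry()] object.
#' @return factor with levels CAVITY, PORE, SEMI, WALL.
#' @export
classify_region <- function(positions, geom) {
  stopifnot(inherits(geom, "ejection_geometry"))
  if (is.data.frame(positions))
    positions <- as.matrix(positions[, c("x", "y", "z")])
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  if (!all(is.finite(positions))) abort("positions must be finite.")
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  rho <- sqrt(y^2 + (z - geom$H / 2)^2)
  lab <- character(length(x))
  in_slit <- z > 0 & z < geom$H
  lab[x < geom$x_ent] <- "CAVITY"
  lab[x >= geom$x_ent & x < geom$x_exit] <- ifelse(
    rho[x >= geom$x_ent & x < geom$x_exit] <= geom$rp, "PORE", "WALL")
  lab[x >= geom$x_exit] <- "SEMI"
  if (is.finite(geom$D)) {
    r_c <- sqrt((x - geom$centre[1])^2 + (y - geom$centre[2])^2 +
                  (z - geom$centre[3])^2)
    near_axis <- rho <= geom$rp
    lab[lab == "CAVITY" & r_c > geom$D / 2 & !near_axis] <- "WALL"
  }
  lab[!in_slit] <- "WALL"
  factor(lab, levels = c("CAVITY", "PORE", "SEMI", "WALL"))
}

# geometry list handed to the C++ engine
engine_geom <- function(geom) {
  list(H = geom$H, x_ent = geom$x_ent, x_exit = geom$x_exit, rpw = geom$rpw,
       Rcw = geom$Rcw, eps_w = geom$eps_w, sigma_w = geom$sigma_w,
       k_spring = geom$k_spring, b0 = geom$b0)
}
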