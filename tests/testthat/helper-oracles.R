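# shared helpers: finite-difference gradient oracle and small systems

fd_gradient <- function(positions, geom, h = 1e-6) {
  grad <- positions * 0
  for (i in seq_len(nrow(positions))) {
    for (k in 1:3) {
      xp <- positions; xm <- positions
      xp[i, k] <- xp[i, k] + h
      xm[i, k] <- xm[i, k] - h
      grad[i, k] <- (total_energy(xp, geom) - total_energy(xm, geom)) /
        (2 * h)
    }
  }
  grad
}

# exact MFPT for drift-diffusion over a linear potential of slope mu (kT per
# length) on [-L, 0], reflecting at -L, absorbing at 0, D = kT/eta:
#   tau = (eta/kT) * [ (exp(mu L) - 1)/mu^2 - L/mu ]    (mu != 0)
mfpt_linear_exact <- function(mu, L, eta = 1) {
  if (mu == 0) return(eta * L^2 / 2)
  eta * ((exp(mu * L) - 1) / mu^2 - L / mu)
}

params_tiny <- function(N = 8, D = 8, ...) system_params(N = N, D = D, ...)
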