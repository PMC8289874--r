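#!/usr/bin/env Rscript
# Scaled-down simulation campaign for the fitted scaling exponents:
#   z2P, z2E      from the D = Inf (translocation) speed profile
#   N* ~ D^a      from speed-minimum detection across a D grid
#   tau_ent ~ lp^b at phi0 = 0.3 (diffusive entering regime)
#   tau_leav ~ lp^c
# Reduced ensembles (N <= 128, ~100 runs per condition); expect several
# hours of wall time at full size.  `--runs` and `--N` shrink it further.
#
# Usage: Rscript scripts/overnight_exponents.R [--seed S] [--runs K]
#          [--N 64] [--out results/overnight.json]

suppressPackageStartupMessages({
  library(ejectr)
  library(dplyr)
})

args <- commandArgs(trailingOnly = TRUE)
get_flag <- function(name, default) {
  i <- which(args == name)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_flag("--seed", "1"))
n_runs <- as.integer(get_flag("--runs", "100"))
N_big <- as.integer(get_flag("--N", "64"))
out_path <- get_flag("--out", "results/overnight.json")

res <- list()
slope <- function(x, y) unname(coef(lm(log(y) ~ log(x)))[2])

message("[1/4] translocation speed profile, N = ", N_big)
pInf <- system_params(N = N_big, D = Inf)
ensInf <- run_ensemble(pInf, n_runs = n_runs, base_seed = seed,
                       step_budget = 2e8, progress = TRUE)
prof <- waiting_times(ensInf) |> mutate(mn = m / N_big)
f_pull <- fit_power_law(prof, mn, V, window = c(0.01, 0.5))
f_esc <- fit_power_law(prof, mn, V, window = c(0.5, 0.95))
res$z2P <- -tidy(f_pull)$estimate[1]
res$z2E <- -tidy(f_esc)$estimate[1]
message("    z2P = ", round(res$z2P, 3), "  z2E = ", round(res$z2E, 3))

message("[2/4] N*(D) from speed minima, N = ", N_big)
gs <- 3:6
ns <- Ds <- numeric(0)
for (g in gs) {
  D <- diameter_for_generation(g + log2(N_big) - 5)  # phi0 ~ 0.3 * 2^-(..)
  if (D >= N_big^0.75) next                          # need Nstar < N
  p <- system_params(N = N_big, D = D)
  ens <- run_ensemble(p, n_runs = n_runs, base_seed = seed + 17 * g,
                      step_budget = 1e8, progress = TRUE)
  det <- detect_Nstar(waiting_times(ens))
  if (!det$no_minimum) { ns <- c(ns, det$m_star); Ds <- c(Ds, D) }
}
res$Nstar_D_exponent <- if (length(ns) >= 3) slope(Ds, ns) else NA
message("    N* ~ D^", round(res$Nstar_D_exponent, 3))

lp_grid <- c(1, 2, 3, 4, 5)
stage_scan <- function(phi0) {
  sapply(lp_grid, function(lp) {
    p <- system_params(N = 32, phi0 = phi0, lp = lp)
    ens <- run_ensemble(p, n_runs = n_runs,
                        base_seed = seed + round(1e3 * phi0) + 31 * lp,
                        step_budget = 5e7, progress = TRUE)
    st <- glance(decompose_stages(ens, Nstar = 0))
    c(tau_ent = st$tau_ent, tau_leav = st$tau_leav)
  })
}

message("[3/4] entering/leaving time vs pore length, phi0 = 0.3")
s03 <- stage_scan(0.3)
res$tau_ent_lp_exponent_phi0.3 <- slope(lp_grid, s03["tau_ent", ])
res$tau_leav_lp_exponent <- slope(lp_grid, s03["tau_leav", ])

message("[4/4] entering time vs pore length, phi0 = 0.25 (exponential regime)")
s025 <- stage_scan(0.25)
fexp <- fit_entering_exponential(lp_grid, s025["tau_ent", ])
res$b_n_phi0.25 <- unname(fexp$estimate["b_n"])

dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(res, out_path, auto_unbox = TRUE, digits = NA)
message("wrote ", out_path)
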