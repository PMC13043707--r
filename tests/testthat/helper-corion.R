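# Shared fixtures: all built in code, no stored data.

# A single homogeneous slab as a cornea_stack (sigma in S/m, k in W/mK).
slab_stack <- function(thickness_um = 500, sigma = 1, k = 0.02,
                       rho = 1000, c = 4000, area_cm2 = 1) {
  cornea_stack(data.frame(name = "slab", thickness_um = thickness_um,
                          sigma_S_per_m = sigma, k_W_mK = k,
                          rho_kg_m3 = rho, c_J_kgK = c),
               area_cm2 = area_cm2)
}

insulated_boundary <- function(T0 = 34) {
  thermal_boundary(h_conv = 0, e_evap = 0, T_ambient = T0, T_body = T0,
                   h_post = 0)
}

dirichlet_boundary <- function(Tb) {
  # Robin with a huge exchange coefficient pins the boundary nodes to Tb
  thermal_boundary(h_conv = 1e9, e_evap = 0, T_ambient = Tb, T_body = Tb,
                   h_post = 1e9)
}

# Analytic Fourier-series solution of the homogeneous heat equation on
# [0, L] with both ends held at Tb and uniform initial temperature T0.
fourier_slab <- function(x_m, t_s, L_m, alpha, T0, Tb, nmax = 399) {
  n <- seq(1, nmax, by = 2)
  out <- vapply(x_m, function(x) {
    Tb + (T0 - Tb) * sum(4 / (pi * n) * sin(n * pi * x / L_m) *
                           exp(-n^2 * pi^2 * alpha * t_s / L_m^2))
  }, numeric(1))
  out
}

# Full FTIR processing chain on n generated replicates of a preset group.
process_ftir_group <- function(group, n = 10, seed = 7, noise_sd = 0.002) {
  reps <- lapply(seq_len(n), function(i)
    gen_ftir_spectrum(group, seed = seed * 1000 + i, noise_sd = noise_sd,
                      replicate = i))
  smoothed <- lapply(reps, function(s) savgol_smooth(baseline_correct(s)))
  second_derivative(average_group(smoothed))
}
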