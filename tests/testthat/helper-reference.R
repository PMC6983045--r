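# Published reference values for the PPD / DMSO / water system, used as
# expected values in tests. All at T = 298.2, 303.2, 308.2, 313.2, 318.2 K
# and m = 0.0 ... 1.0.

ref_temps <- c(298.2, 303.2, 308.2, 313.2, 318.2)
ref_ms <- seq(0, 1, by = 0.1)

# activity coefficients gamma_i, 11 compositions x 5 temperatures
ref_gamma <- matrix(c(
  9460.000, 8800.000, 8020.000, 7340.000, 6340.000,
  3036.053, 2863.900, 2671.535, 2464.940, 2173.383,
  1007.450, 967.752, 895.279, 849.738, 764.882,
  325.566, 319.655, 298.478, 291.063, 269.649,
  109.123, 106.877, 103.965, 100.798, 94.754,
  35.637, 35.245, 34.901, 34.347, 32.997,
  11.761, 11.865, 11.885, 11.884, 11.617,
  3.802, 3.905, 3.985, 4.038, 4.026,
  1.266, 1.320, 1.359, 1.398, 1.425,
  0.417, 0.435, 0.457, 0.477, 0.496,
  0.137, 0.146, 0.156, 0.165, 0.175),
  nrow = 11, byrow = TRUE, dimnames = list(ref_ms, ref_temps))

# apparent thermodynamics per composition (kJ/mol, kJ/mol, J/mol/K)
ref_thermo <- data.frame(
  m = ref_ms,
  dH0 = c(31.35, 28.75, 26.59, 23.28, 21.22, 18.68, 16.21, 13.51, 11.20,
          8.90, 6.10),
  dG0 = c(29.89, 27.06, 24.30, 21.51, 18.77, 15.98, 13.22, 10.42, 7.68,
          4.89, 2.14),
  dS0 = c(4.74, 5.49, 7.44, 5.73, 7.97, 8.78, 9.69, 10.02, 11.43, 13.01,
          12.85))

# Yalkowsky-Roseman log10 predictions on the mixture grid (9 x 5)
ref_yalkowsky_log10 <- matrix(c(
  -4.75, -4.68, -4.60, -4.52, -4.43,
  -4.26, -4.20, -4.13, -4.06, -3.97,
  -3.78, -3.72, -3.66, -3.59, -3.51,
  -3.29, -3.24, -3.19, -3.13, -3.06,
  -2.81, -2.76, -2.71, -2.66, -2.60,
  -2.33, -2.29, -2.24, -2.20, -2.15,
  -1.84, -1.81, -1.77, -1.74, -1.69,
  -1.36, -1.33, -1.30, -1.27, -1.24,
  -0.88, -0.85, -0.83, -0.81, -0.78),
  nrow = 9, byrow = TRUE, dimnames = list(ref_ms[2:10], ref_temps))

# A small complete synthetic-style grid with x_e strictly increasing in
# both m and T, for validator tests.
make_toy_grid <- function(n_m = 3, n_T = 4) {
  ms <- seq(0, 1, length.out = n_m)
  temps <- seq(290, 320, length.out = n_T)
  g <- expand.grid(m = ms, T_K = temps)
  g$x_e <- exp(-12 + 6 * g$m + 0.05 * (g$T_K - 290))
  g
}

# Closed-form OLS via the normal equations, independent of lm/qr.
normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}
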