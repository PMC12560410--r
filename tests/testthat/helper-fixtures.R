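# independent straight-line oracle: explicit normal equations, no lm()
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = b[1L], slope = b[2L])
}

# noiseless 1:1 static-quenching titration: F = f0 / (1 + ka [Q])
noiseless_series <- function(ka, f0 = 1000,
                             conc = seq(3e-5, 1.8e-4, length.out = 6),
                             temperature_K = 295, label = "blank") {
  titration_series(temperature_K, conc, f0 / (1 + ka * conc), f0,
                   label = label)
}

# published Stern-Volmer constants (L/mol) at the five study temperatures
table1_ksv <- data.frame(
  temperature_K = c(285, 290, 295, 303, 308),
  ksv = c(11100, 9635, 7096, 5288, 3800)
)

# published per-temperature binding constants and Gibbs energies
table2 <- data.frame(
  temperature_K = c(285, 290, 295, 303, 308),
  log10_ka = c(4.3833, 4.2414, 4.1174, 3.8404, 3.6665),
  ka = c(24171, 17434, 13103, 6924, 4639),
  n = c(1.072, 1.077, 1.086, 1.066, 1.055),
  dG_kJ = c(-23.915, -23.546, -23.252, -22.276, -21.618)
)
table2_dH <- -52434   # J/mol
table2_dS <- -99.63   # J/mol/K

# published site-marker log Ka at 295 K
table3_log_ka <- c(blank = 4.1593, indomethacin = 4.2494, diazepam = 3.4424)

gaussian_spectrum <- function(center, width, grid, amp = 1,
                              axis_kind = "wavelength_nm") {
  spectrum(grid, amp * exp(-(grid - center)^2 / (2 * width^2)),
           axis_kind = axis_kind)
}
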