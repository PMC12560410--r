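test_that("double-log fit recovers Ka and n exactly from the 1:1 static model", {
  # (f0 - F)/F = Ka [Q] algebraically, so the log-log line is exact
  res <- double_log_fit(noiseless_series(2e4))
  expect_equal(res$n_sites, 1, tolerance = 1e-9)
  expect_equal(res$ka, 2e4, tolerance = 2e-5)   # 1e-9 on the log scale
  expect_equal(res$log10_ka, log10(2e4), tolerance = 1e-9)
  expect_equal(res$ka, 10^res$log10_ka)
  expect_equal(res$fit$r, 1, tolerance = 1e-12)
})

test_that("a squared-law titration doubles the fitted site number", {
  conc <- seq(3e-5, 1.8e-4, length.out = 6)
  ka <- 5000
  # construct F so that (f0-F)/F = (ka [Q])^2
  f0 <- 1000
  f <- f0 / (1 + (ka * conc)^2)
  res <- double_log_fit(titration_series(295, conc, f, f0))
  expect_equal(res$n_sites, 2, tolerance = 1e-9)
  expect_equal(res$log10_ka, 2 * log10(ka), tolerance = 1e-9)
})

test_that("double-log fit excludes unusable points and matches the oracle", {
  conc <- seq(3e-5, 1.8e-4, length.out = 6)
  f <- c(1001, 900, 800, 700, 600, 500)   # first point above f0
  s <- titration_series(295, conc, f, f0 = 1000)
  expect_warning(res <- double_log_fit(s), "excluded")
  expect_equal(res$fit$n_points, 5L)
  orc <- ols_oracle(log10(conc[-1]), log10((1000 - f[-1]) / f[-1]))
  expect_equal(res$log10_ka, unname(orc["intercept"]), tolerance = 1e-10)
  expect_equal(res$n_sites, unname(orc["slope"]), tolerance = 1e-10)

  mostly_flat <- titration_series(295, conc, c(1000, 1000, 1000, 1000, 900, 800),
                                  f0 = 1000)
  expect_warning(expect_error(double_log_fit(mostly_flat), "at least 3"))
})

test_that("van't Hoff fit reproduces the published enthalpy and entropy from
           the tabulated binding constants", {
  vh <- vant_hoff_fit(table2[, c("temperature_K", "ka")])
  # printed Ka are rounded, so agreement is sub-percent, not exact
  expect_equal(vh$delta_H, table2_dH, tolerance = 0.005)
  expect_equal(vh$delta_S, table2_dS, tolerance = 0.005)
  # cross-check against the independent normal-equations oracle
  orc <- ols_oracle(1 / table2$temperature_K, log(table2$ka))
  expect_equal(vh$delta_H, unname(-8.314 * orc["slope"]), tolerance = 1e-12)
  expect_equal(vh$delta_S, unname(8.314 * orc["intercept"]), tolerance = 1e-12)
})

test_that("van't Hoff generator/fitter round trip is exact", {
  for (pars in list(c(-52434, -99.63), c(-40000, -80), c(20000, 150))) {
    temps <- c(285, 290, 295, 303, 308)
    ka <- exp(-pars[1] / (8.314 * temps) + pars[2] / 8.314)
    vh <- vant_hoff_fit(data.frame(temperature_K = temps, ka = ka))
    expect_equal(vh$delta_H, pars[1], tolerance = 1e-9)
    expect_equal(vh$delta_S, pars[2], tolerance = 1e-9)
  }
  flat <- data.frame(temperature_K = c(285, 295, 305), ka = rep(100, 3))
  expect_equal(vant_hoff_fit(flat)$delta_H, 0, tolerance = 1e-9)

  expect_error(vant_hoff_fit(data.frame(temperature_K = c(285, 285, 295),
                                        ka = c(1, 2, 3))), "duplicate")
  expect_error(vant_hoff_fit(data.frame(temperature_K = c(285, 290, 295),
                                        ka = c(1, -2, 3))), "positive")
})

test_that("Gibbs energy routes behave and agree on van't Hoff-consistent data", {
  # frozen from -8.314 * T * log(ka): the published column values
  expect_equal(gibbs_from_ka(24171, 285) / 1000, -23.915, tolerance = 1e-4)
  expect_equal(gibbs_from_ka(4639, 308) / 1000, -21.618, tolerance = 1e-4)
  expect_equal(gibbs_from_ka(1, 300), 0)
  expect_error(gibbs_from_ka(-1, 300))
  expect_error(gibbs_from_ka(10, 0))

  expect_equal(gibbs_from_enthalpy(0, 0, 300), 0)
  expect_equal(gibbs_from_enthalpy(-10000, 0, 300), -10000)
  expect_equal(gibbs_from_enthalpy(-52434, -99.63, 285) / 1000, -24.03945,
               tolerance = 1e-6)

  # strictly decreasing in ka; negative iff ka > 1
  ka <- c(0.1, 0.5, 1, 2, 10, 1e4)
  g <- gibbs_from_ka(ka, 295)
  expect_true(all(diff(g) < 0))
  expect_identical(g < 0, ka > 1)

  # the two routes coincide when the constants lie exactly on the line
  temps <- c(285, 290, 295, 303, 308)
  ka_line <- exp(-(-30000) / (8.314 * temps) + (-50) / 8.314)
  vh <- vant_hoff_fit(data.frame(temperature_K = temps, ka = ka_line))
  expect_equal(gibbs_from_ka(ka_line, temps),
               gibbs_from_enthalpy(vh$delta_H, vh$delta_S, temps),
               tolerance = 1e-9)
})

test_that("binding-force classification follows the thermodynamic sign rules", {
  expect_equal(classify_forces(-52434, -99.63), "hbond_vdw")
  expect_equal(classify_forces(5000, 30), "hydrophobic")
  expect_equal(classify_forces(-5000, 30), "electrostatic")
  expect_equal(classify_forces(0, -10), "indeterminate")
  expect_equal(classify_forces(-10, 0), "indeterminate")
  expect_equal(classify_forces(5000, -30), "indeterminate")
})

test_that("thermo_analysis assembles a consistent thermodynamic summary", {
  br <- lapply(seq_len(nrow(table2)), function(i) {
    binding_result(table2$log10_ka[i], table2$temperature_K[i])
  })
  th <- thermo_analysis(br)
  expect_s3_class(th, "thermo_result")
  expect_equal(th$delta_H / 1000, -52.434, tolerance = 0.005)
  expect_equal(th$delta_S, -99.63, tolerance = 0.005)
  expect_equal(th$force_call, "hbond_vdw")
  expect_true(th$spontaneous)
  expect_equal(unname(th$delta_G_by_T / 1000), table2$dG_kJ, tolerance = 1e-4)
})
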