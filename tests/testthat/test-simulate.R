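test_that("simulated binding constants follow the van't Hoff forward model", {
  spec <- simulation_spec()
  # frozen from exp(-dH/(RT) + dS/R) with the default (-52434, -99.63)
  expect_equal(ka_of_T(spec, 285), 25473.93, tolerance = 1e-6)
  flat <- simulation_spec(delta_H = 0, delta_S = 0)
  expect_equal(ka_of_T(flat, 300), 1)
  # strictly decreasing in T for exothermic binding
  expect_true(all(diff(ka_of_T(spec, c(285, 290, 295, 303, 308))) < 0))
})

test_that("generation is deterministic and substream-isolated", {
  spec <- simulation_spec(seed = 42L)
  a <- generate_titration(spec, 295)
  b <- generate_titration(spec, 295)
  expect_identical(a$intensity, b$intensity)

  other_seed <- generate_titration(simulation_spec(seed = 43L), 295)
  expect_false(identical(a$intensity, other_seed$intensity))

  # noise multipliers differ across temperatures (independent substreams)
  spec0 <- simulation_spec(seed = 42L, noise_cv = 0)
  mult_285 <- generate_titration(spec, 285)$intensity /
    generate_titration(spec0, 285)$intensity
  mult_295 <- generate_titration(spec, 295)$intensity /
    generate_titration(spec0, 295)$intensity
  expect_false(isTRUE(all.equal(mult_285, mult_295)))

  # adding a condition does not perturb the blank's noise
  only_blank <- generate_competition_dataset(spec, temperature_K = 295)
  with_probe <- generate_competition_dataset(spec, c(diazepam = 0.2),
                                             temperature_K = 295)
  expect_identical(only_blank[[1L]]$intensity, with_probe[[1L]]$intensity)

  # generation leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_titration(spec, 295)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless generator output is fitted exactly by every stage", {
  spec <- simulation_spec(noise_cv = 0)
  series <- generate_temperature_series(spec)

  for (s in series) {
    ka_true <- ka_of_T(spec, s$temperature_K)
    expect_equal(stern_volmer_fit(s)$ksv, ka_true,
                 tolerance = 1e-9 * ka_true)
    bl <- double_log_fit(s)
    expect_equal(bl$ka, ka_true, tolerance = 1e-7)
    expect_equal(bl$n_sites, 1, tolerance = 1e-9)
  }

  vh <- vant_hoff_fit(data.frame(
    temperature_K = spec$temperatures,
    ka = vapply(series, function(s) double_log_fit(s)$ka, numeric(1L))
  ))
  expect_equal(vh$delta_H, spec$delta_H, tolerance = 1e-9)
  expect_equal(vh$delta_S, spec$delta_S, tolerance = 1e-9)
})

test_that("static and dynamic mechanisms classify as themselves under mild
           noise", {
  n_ok_static <- 0L
  n_ok_dynamic <- 0L
  for (seed in 1:25) {
    st <- simulation_spec(noise_cv = 0.02, mechanism = "static",
                          seed = seed)
    calls <- classify_mechanism(lapply(generate_temperature_series(st),
                                       stern_volmer_fit))
    n_ok_static <- n_ok_static + (calls$call == "static")

    # the dynamic stand-in's Ksv rises only ~7% per temperature step, so
    # the strict-monotonicity requirement tolerates less noise than the
    # static direction, whose constants fall 25-40% per step
    dy <- simulation_spec(noise_cv = 0.01, mechanism = "dynamic",
                          seed = seed)
    calls <- classify_mechanism(lapply(generate_temperature_series(dy),
                                       stern_volmer_fit))
    n_ok_dynamic <- n_ok_dynamic + (calls$call == "dynamic")
  }
  expect_gte(n_ok_static, 24L)
  expect_gte(n_ok_dynamic, 24L)
})

test_that("estimator dispersion shrinks with the noise level", {
  disp <- vapply(c(0.03, 0.01, 0.003), function(cv) {
    err <- vapply(1:40, function(seed) {
      spec <- simulation_spec(noise_cv = cv, seed = seed)
      s <- generate_titration(spec, 295)
      abs(double_log_fit(s)$ka / ka_of_T(spec, 295) - 1)
    }, numeric(1L))
    stats::median(err)
  }, numeric(1L))
  expect_true(all(diff(disp) < 0))
})

test_that("optional inner-filter attenuation damps the generated intensities", {
  plain <- simulation_spec(noise_cv = 0)
  ife <- simulation_spec(noise_cv = 0,
                         ife_absorbance_per_molar = c(100, 100))
  f_plain <- generate_titration(plain, 295)$intensity
  f_ife <- generate_titration(ife, 295)$intensity
  q <- plain$conc_grid
  expect_equal(f_ife, f_plain * 10^(-q * 100), tolerance = 1e-12)
})

test_that("generated spectrum pairs carry the requested shift and quench", {
  g <- seq(250, 350, by = 0.5)
  pair <- generate_spectrum_pair(300, 2, 10, 0.5, g)
  expect_equal(max(pair$bound$intensity) / max(pair$free$intensity), 0.5,
               tolerance = 1e-6)
  ps <- peak_shift(pair$free, pair$bound)
  expect_equal(ps$shift, 2, tolerance = 0.1)
  expect_equal(ps$direction, "red")

  nil <- generate_spectrum_pair(300, 0, 10, 0.3, g)
  expect_equal(peak_shift(nil$free, nil$bound)$shift, 0, tolerance = 1e-9)

  expect_error(generate_spectrum_pair(300, 80, 10, 0.3, g), "cover")
})

test_that("competition generator drives the full site-assignment pipeline", {
  spec <- simulation_spec(seed = 5L)
  sets <- generate_competition_dataset(
    spec, c(diazepam = 0.19, indomethacin = 1.2), temperature_K = 295
  )
  expect_equal(vapply(sets, `[[`, character(1L), "label"),
               c("blank", "diazepam", "indomethacin"))

  fits <- lapply(sets, double_log_fit)
  out <- compare_conditions(fits[[1L]], fits[-1L])
  site <- assign_site(out, c(diazepam = "site_II", indomethacin = "site_I"))
  expect_equal(site$site, "site_II")

  blank_only <- generate_competition_dataset(spec, temperature_K = 295)
  expect_length(blank_only, 1L)

  null_probe <- generate_competition_dataset(
    simulation_spec(noise_cv = 0), c(x = 1.0), temperature_K = 295
  )
  fits0 <- lapply(null_probe, double_log_fit)
  expect_equal(compare_conditions(fits0[[1L]], fits0[-1L])[[1L]]$effect,
               "unchanged")
})

test_that("simulation specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("delta_H: -40000", "delta_S: -80", "noise_cv: 0.02",
               "seed: 7", "mechanism: static",
               "temperatures: [285, 295, 305]"), path)
  spec <- read_simulation_spec(path)
  expect_equal(spec$delta_H, -40000)
  expect_equal(spec$temperatures, c(285, 295, 305))
  expect_equal(spec$seed, 7L)
  expect_equal(spec$noise_cv, 0.02)
})
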