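test_that("generators are deterministic under a fixed seed", {
  cfg <- scenario_config(seed = 42, noise_cv = 0.05)
  a <- gen_kinetics_dataset(100, 250, c(5, 50, 500), hydrolysis_rate = 3,
                            config = cfg)
  b <- gen_kinetics_dataset(100, 250, c(5, 50, 500), hydrolysis_rate = 3,
                            config = cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$standard_curve, b$standard_curve)

  d1 <- file.path(tempdir(), "gen_a"); d2 <- file.path(tempdir(), "gen_b")
  cfg1 <- scenario_config(seed = 42, noise_cv = 0.05, output_dir = d1)
  cfg2 <- scenario_config(seed = 42, noise_cv = 0.05, output_dir = d2)
  gen_itc_titration(6.1, -5.02, 0.6, 70, 1000, config = cfg1)
  gen_itc_titration(6.1, -5.02, 0.6, 70, 1000, config = cfg2)
  f1 <- file.path(d1, "itc_titration.tsv"); f2 <- file.path(d2, "itc_titration.tsv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("noiseless kinetics velocities sit exactly on the hyperbola", {
  cfg <- scenario_config(seed = 1, noise_cv = 0)
  S <- c(5, 10, 50, 100, 500, 1000)
  ds <- gen_kinetics_dataset(113.1, 282.1, S, hydrolysis_rate = 0, config = cfg)
  cal <- fit_standard_curve(ds$standard_curve$gdp_pmol,
                            ds$standard_curve$luminescence)
  v <- correct_and_convert(ds, cal)
  expect_equal(v$velocity, 282.1 * v$acceptor_conc_uM /
                 (113.1 + v$acceptor_conc_uM), tolerance = 1e-9)
})

test_that("zero Vmax leaves only the hydrolysis background", {
  cfg <- scenario_config(seed = 1, noise_cv = 0)
  ds <- gen_kinetics_dataset(100, 0, c(5, 50, 500), hydrolysis_rate = 7,
                             config = cfg)
  cal <- fit_standard_curve(ds$standard_curve$gdp_pmol,
                            ds$standard_curve$luminescence)
  sig <- ds$data[!ds$data$is_blank, ]
  pmol <- gdp_from_luminescence(cal, sig$luminescence)
  mass_mg <- 100 * 10 * 58000 * 1e-12
  v_raw <- pmol / 1000 / (30 * mass_mg)
  expect_equal(v_raw, rep(7, nrow(sig)), tolerance = 1e-9)
})

test_that("an effectively infinite Km yields velocities linear in S", {
  cfg <- scenario_config(seed = 1, noise_cv = 0)
  S <- c(5, 10, 50, 100, 500, 1000)
  ds <- gen_kinetics_dataset(1e6, 282.1, S, config = cfg)
  cal <- fit_standard_curve(ds$standard_curve$gdp_pmol,
                            ds$standard_curve$luminescence)
  v <- correct_and_convert(ds, cal)
  line <- 282.1 * v$acceptor_conc_uM / 1e6
  expect_true(all(abs(v$velocity - line) / line < 1e-3))
})

test_that("generator rejects invalid kinetic parameters", {
  cfg <- scenario_config(1)
  expect_error(gen_kinetics_dataset(-1, 100, c(5, 50), config = cfg), "Km")
  expect_error(gen_kinetics_dataset(100, -5, c(5, 50), config = cfg), "Vmax")
  expect_error(gen_kinetics_dataset(100, 100, numeric(0), config = cfg))
})

test_that("noiseless ITC heats reproduce the one-site closed form exactly", {
  cfg <- scenario_config(seed = 3, noise_cv = 0)
  ser <- gen_itc_titration(6.1, -5.02, 0.60, 70, 1000, config = cfg)
  expect_equal(ser$heats_ucal,
               wiseman_heats(6.1, -5.02, 0.60, 70, 1000, rep(2, 19), 200),
               tolerance = 1e-12)
})

test_that("zero-enthalpy titrations carry only the dilution offset", {
  cfg <- scenario_config(seed = 1, noise_cv = 0)
  ser <- gen_itc_titration(10, 0, 1, 70, 1000, dilution_offset = -0.1,
                           config = cfg)
  expect_equal(ser$heats_ucal, rep(-0.1 * 1000 * 2 * 1e-3, 19),
               tolerance = 1e-12)
})

test_that("total heat approaches n*M0*V0*dH under a saturating titration", {
  h <- wiseman_heats(0.05, -5, 1, 10, 2000, rep(0.1, 30), 200)
  total <- 1 * 10 * 200 * (-5) * 1e-3
  expect_lt(abs(sum(h) - total) / abs(total), 0.01)
})

test_that("extreme c-values are flagged in the ground truth", {
  cfg <- scenario_config(1, noise_cv = 0)
  ser <- gen_itc_titration(Kd = 1e6, dH = -5, n = 1, cell_conc = 70,
                           syringe_conc = 1000, config = cfg)
  expect_true(ser$ground_truth$c_value_warning)
  ser2 <- gen_itc_titration(6.1, -5, 1, 70, 1000, config = cfg)
  expect_false(ser2$ground_truth$c_value_warning)
})

test_that("STD generator honours the saturated limit and the initial slope", {
  cfg <- scenario_config(1, noise_cv = 0)
  s <- gen_std_buildup("H1", STDmax = 0.08, ksat = 1e6, config = cfg)[["H1"]]
  expect_equal(s$std_amplitude, rep(0.08, 7), tolerance = 1e-9)

  s2 <- gen_std_buildup("H1", STDmax = 0.08, ksat = 0.9,
                        sat_times = c(0.001, 1, 2, 3, 4), config = cfg)[["H1"]]
  fd <- s2$std_amplitude[1] / s2$sat_times[1]
  expect_lt(abs(fd - 0.08 * 0.9) / (0.08 * 0.9), 0.01)
})

test_that("NOE initial slopes follow the r^-6 law", {
  cfg <- scenario_config(1, noise_cv = 0)
  ser <- gen_noe_buildup(c("ref", "same", "double"),
                         distances = c(2.58, 2.58, 5.16),
                         ref_pair = "ref", ref_distance = 2.58, config = cfg)
  gt <- attr(ser, "ground_truth")
  expect_equal(gt$slopes[2], gt$slopes[1])
  expect_equal(gt$slopes[3] / gt$slopes[1], 1 / 64, tolerance = 1e-12)
  # the generated curves themselves scale the same way
  expect_equal(ser[["double"]]$integrals / ser[["ref"]]$integrals,
               rep(1 / 64, 10), tolerance = 1e-12)
})

test_that("glycopeptide feature generator validates its profiles", {
  cfg <- scenario_config(1, noise_cv = 0)
  expect_error(gen_glycopeptide_features(
    list(N1 = c(Hex5HexNAc2 = 0.5)), c(N1 = 1000), config = cfg), "sum to 1")
  expect_error(gen_glycopeptide_features(
    list(N1 = c(Xyl3 = 1)), c(N1 = 1000), config = cfg), "unknown")
  ft <- gen_glycopeptide_features(list(N1 = c(Hex5HexNAc2 = 1)),
                                  c(N1 = 1000), config = cfg)
  expect_true(all(ft$glycosite == "N1"))
  expect_equal(sum(ft$intensity), 1e8)
})

test_that("zero ppm error makes generated m/z exactly invertible", {
  cfg <- scenario_config(1, noise_cv = 0)
  pep <- peptide_mass("KVANKT")
  ft <- gen_glycopeptide_features(
    list(N65 = c(Hex5HexNAc2dHex1 = 0.9, Hex5HexNAc2 = 0.1)),
    c(N65 = pep), ppm_error_sd = 0, config = cfg)
  for (i in seq_len(nrow(ft))) {
    comp <- parse_composition(ft$glycoform[i])
    bl <- default_building_blocks()
    theo <- pep + sum(comp * bl$mass[match(names(comp), bl$block)])
    expect_equal(neutral_mass(ft$mz[i], ft$charge[i]), theo,
                 tolerance = 1e-9)
  }
})
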