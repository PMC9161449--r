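test_that("standard curve recovers a known line and inverts correctly", {
  cal <- fit_standard_curve(c(0, 10, 20, 40), 2 * c(0, 10, 20, 40) + 5)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 5, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(gdp_from_luminescence(cal, 45), 20, tolerance = 1e-12)

  expect_error(fit_standard_curve(c(0, 10), c(5, 25)), "3 distinct")
  expect_error(fit_standard_curve(c(0, 20, 10), c(5, 45, 25)), "monotone")
  expect_error(fit_standard_curve(c(0, 10, 20), c(-1, 25, 45)), "negative")
})

test_that("noisy standard curves recover the true slope within 2 SE", {
  set.seed(1)
  pmol <- seq(0, 1000, by = 100)
  lum <- 2 * pmol + 50 + rnorm(length(pmol), 0, 15)
  cal <- fit_standard_curve(pmol, lum)
  expect_lt(abs(cal$slope - 2), 2 * cal$slope_se)
})

test_that("blank correction zeroes a signal equal to the blank", {
  df <- data.frame(substrate_id = "x",
                   acceptor_conc_uM = c(10, 100, 0, 0),
                   replicate = c(1, 1, 1, 2),
                   luminescence = c(105, 105, 105, 105),
                   is_blank = c(FALSE, FALSE, TRUE, TRUE))
  ds <- kinetics_dataset(df)
  cal <- fit_standard_curve(c(0, 25, 50), c(5, 55, 105))
  expect_warning(v <- correct_and_convert(ds, cal), "zero")
  expect_equal(v$velocity, c(0, 0))
})

test_that("hydrolysis background is removed by the no-acceptor control", {
  cfg <- scenario_config(seed = 7, noise_cv = 0)
  S <- c(5, 10, 50, 100, 500, 1000)
  ds <- gen_kinetics_dataset(113.1, 282.1, S, hydrolysis_rate = 25,
                             config = cfg)
  cal <- fit_standard_curve(ds$standard_curve$gdp_pmol,
                            ds$standard_curve$luminescence)
  v <- correct_and_convert(ds, cal)
  expect_equal(v$velocity,
               282.1 * v$acceptor_conc_uM / (113.1 + v$acceptor_conc_uM),
               tolerance = 1e-9)
})

test_that("missing blanks are rejected", {
  df <- data.frame(substrate_id = "x", acceptor_conc_uM = c(10, 100),
                   replicate = 1, luminescence = c(50, 100),
                   is_blank = FALSE)
  expect_error(kinetics_dataset(df), "blank")
})

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  S <- c(5, 10, 25, 50, 100, 250, 500, 1000)
  fit <- fit_michaelis_menten(
    data.frame(acceptor_conc_uM = S, velocity = 282.1 * S / (113.1 + S)))
  expect_true(fit$saturable)
  expect_equal(fit$Km, 113.1, tolerance = 1e-7)
  expect_equal(fit$Vmax, 282.1, tolerance = 1e-7)
  expect_equal(fit$kcat, 282.1 * 58000 * 1e-6, tolerance = 1e-7)
  expect_equal(fit$efficiency, fit$kcat / fit$Km, tolerance = 1e-12)
  # fitted curve passes through Vmax/2 at S = Km
  expect_equal(predict(fit, data.frame(acceptor_conc_uM = fit$Km)),
               fit$Vmax / 2, tolerance = 1e-9)
})

test_that("velocities linear in concentration are declared non-saturable", {
  S <- c(5, 10, 25, 50, 100, 250, 500, 1000)
  fit <- fit_michaelis_menten(
    data.frame(acceptor_conc_uM = S, velocity = 0.05 * S))
  expect_false(fit$saturable)
  expect_error(catalytic_efficiency(fit), "non-saturable")
  expect_output(print(fit), "NOT saturable")
})

test_that("nonlinear fit beats a grid-search oracle on random instances", {
  set.seed(11)
  S <- c(5, 15, 40, 90, 200, 450, 1000)
  for (i in 1:20) {
    Km <- runif(1, 20, 400); Vmax <- runif(1, 50, 400)
    v <- (Vmax * S / (Km + S)) * (1 + rnorm(length(S), 0, 0.05))
    dat <- data.frame(acceptor_conc_uM = S, velocity = v)
    fit <- fit_michaelis_menten(dat)
    if (!fit$saturable) next
    sse_fit <- sum((v - predict(fit))^2)
    grid <- expand.grid(Km = seq(5, 800, length.out = 60),
                        Vmax = seq(10, 600, length.out = 60))
    sse_grid <- min(vapply(seq_len(nrow(grid)), function(j)
      sum((v - grid$Vmax[j] * S / (grid$Km[j] + S))^2), numeric(1)))
    expect_gte(sse_grid, sse_fit - 1e-8)
  }
})

test_that("catalytic efficiency reproduces the reference values", {
  expect_equal(catalytic_efficiency(list(kcat = 14.17, Km = 14.56)), 0.97)
  expect_equal(catalytic_efficiency(list(kcat = 15.62, Km = 113.1)), 0.14)
  expect_equal(catalytic_efficiency(list(kcat = 13.03, Km = 133.1)), 0.1)
  expect_equal(catalytic_efficiency(list(kcat = 5, Km = 5)), 1)
})

test_that("efficiency is invariant under concentration unit rescaling", {
  S <- c(5, 10, 25, 50, 100, 250, 500, 1000)
  v <- 282.1 * S / (113.1 + S)
  fit_uM <- fit_michaelis_menten(data.frame(acceptor_conc_uM = S, velocity = v))
  fit_mM <- fit_michaelis_menten(data.frame(acceptor_conc_uM = S / 1000,
                                            velocity = v))
  expect_equal(fit_mM$Km, fit_uM$Km / 1000, tolerance = 1e-6)
  expect_equal(fit_mM$kcat / fit_mM$Km, 1000 * fit_uM$kcat / fit_uM$Km,
               tolerance = 1e-6)
})

test_that("initial-velocity fold comparisons behave like ratios", {
  eq <- compare_initial_velocities(c(G0 = 10, M3N2pep = 10), "G0")
  expect_equal(eq$fold_worse, c(1, 1))

  set.seed(5)
  v_ref <- 100 * (1 + rnorm(50, 0, 0.03))
  v_sub <- (100 / 3.6) * (1 + rnorm(50, 0, 0.03))
  folds <- v_ref / v_sub
  expect_lt(abs(median(folds) - 3.6) / 3.6, 0.05)

  ab <- compare_initial_velocities(c(A = 8, B = 2), "A")$fold_worse[2]
  ba <- compare_initial_velocities(c(A = 8, B = 2), "B")$fold_worse[1]
  expect_equal(ab * ba, 1, tolerance = 1e-12)
  expect_error(compare_initial_velocities(c(A = 1, B = 0), "A"), "zero")
})

test_that("Km recovery stays within 10% median error at 3% noise", {
  S <- c(5, 10, 25, 50, 100, 250, 500, 1000)
  errs <- vapply(1:30, function(seed) {
    cfg <- scenario_config(seed, noise_cv = 0.03)
    ds <- gen_kinetics_dataset(113.1, 282.1, S, hydrolysis_rate = 5,
                               config = cfg)
    cal <- fit_standard_curve(ds$standard_curve$gdp_pmol,
                              ds$standard_curve$luminescence)
    fit <- fit_michaelis_menten(suppressWarnings(correct_and_convert(ds, cal)))
    abs(fit$Km - 113.1) / 113.1
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
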