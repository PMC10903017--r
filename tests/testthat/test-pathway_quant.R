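# Stoichiometric interconversion, yields, annualization, and initial rates.

test_that("stoichiometric conversion follows molar-mass ratios", {
  expect_equal(stoich_convert(600, "L-Phe", "styrene"),
               600 * 104.15 / 165.19)
  expect_equal(round(stoich_convert(600, "L-Phe", "styrene")), 378)
  expect_equal(stoich_convert(100, "L-Phe", "tCA"), 100 * 148.16 / 165.19)
  expect_equal(round(stoich_convert(100, "L-Phe", "tCA"), 1), 89.7)
  expect_equal(stoich_convert(0, "tCA", "styrene"), 0)
  expect_error(stoich_convert(10, "glucose", "styrene"),
               class = "consenzyme_input_error")
  # case-insensitive compound resolution and aliases
  expect_equal(stoich_convert(50, "phe", "STYRENE"),
               stoich_convert(50, "L-Phe", "styrene"))
})

test_that("conversion round trips and chains are consistent", {
  set.seed(2)
  x <- runif(20, 0, 1000)
  back <- stoich_convert(stoich_convert(x, "L-Phe", "tCA"), "tCA", "L-Phe")
  expect_equal(back, x)
  chained <- stoich_convert(stoich_convert(x, "L-Phe", "tCA"),
                            "tCA", "styrene")
  expect_equal(chained, stoich_convert(x, "L-Phe", "styrene"))
})

test_that("yield per substrate divides mg product by g substrate", {
  expect_equal(yield_per_substrate(221, 5), 44.2)
  expect_equal(signif(yield_per_substrate(221, 5), 2), 44)
  expect_equal(yield_per_substrate(0, 4), 0)
  expect_equal(yield_per_substrate(100, 4), 25)
  expect_error(yield_per_substrate(100, 0),
               class = "consenzyme_input_error")
})

test_that("conversion fraction compares product to stoichiometric maximum", {
  expect_equal(conversion_fraction(100, stoich_convert(100, "L-Phe", "tCA"),
                                   "L-Phe", "tCA"), 1.0)
  expect_equal(round(conversion_fraction(100, 87, "L-Phe", "tCA"), 3), 0.970)
  expect_equal(conversion_fraction(100, 0, "L-Phe", "tCA"), 0)
  expect_error(conversion_fraction(0, 10, "L-Phe", "tCA"),
               class = "consenzyme_input_error")
  expect_warning(f <- conversion_fraction(100, 95, "L-Phe", "tCA"),
                 "exceeds 1")
  expect_true(isTRUE(attr(f, "exceeds_unity")))
  expect_gt(f, 1)  # flagged, not clamped
})

test_that("annualization rounds to significant figures", {
  expect_equal(annualize(8.5), 3100)
  expect_equal(annualize(0), 0)
  expect_equal(annualize(1, sig_figs = NULL), 365)
})

test_that("initial rate equals the analytic OLS slope", {
  s <- bioconversion_series(c(0, 1, 2), c(100, 75, 50), "L-Phe")
  expect_equal(initial_rate(s), -25)
  # noiseless lines of any slope/window recover exactly
  set.seed(19)
  for (rep in 1:10) {
    slope <- runif(1, -40, 40)
    t <- sort(runif(6, 0, 3))
    t[1] <- 0
    y <- pmax(0, 100 + slope * t)
    if (any(y == 0)) next
    s <- bioconversion_series(t, y, "x")
    w <- runif(1, t[2], 3)
    inw <- t <= w
    expect_equal(initial_rate(s, window_h = w),
                 oracle_ols_slope(t[inw], y[inw]))
  }
})

test_that("the rate window boundary is inclusive", {
  s <- bioconversion_series(c(0, 2, 4), c(100, 50, 0), "L-Phe")
  expect_equal(initial_rate(s, window_h = 2), -25)  # uses the 2 h point
})

test_that("too few in-window samples raise an insufficient-data error", {
  s <- bioconversion_series(c(0, 5, 10), c(100, 50, 0), "L-Phe")
  expect_error(initial_rate(s, window_h = 2),
               class = "consenzyme_insufficient_data_error")
})

test_that("series validation rejects malformed inputs", {
  expect_error(bioconversion_series(c(0, 0), c(1, 2)),
               class = "consenzyme_input_error")
  expect_error(bioconversion_series(c(0, 1), c(-1, 2)),
               class = "consenzyme_input_error")
})

test_that("time series round trip through the CSV dialect", {
  sim <- simulate_bioconversion(kinetics_sim_config(noise_sd = 1.5,
                                                    seed = 4))
  f <- tempfile(fileext = ".csv")
  write_bioconversion_csv(sim, f)
  back <- read_bioconversion_csv(f)
  expect_setequal(names(back), c("L-Phe", "tCA"))
  expect_equal(back[["L-Phe"]]$samples$conc_mg_l,
               sim$substrate$samples$conc_mg_l, tolerance = 1e-6)
})
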