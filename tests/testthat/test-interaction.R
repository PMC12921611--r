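test_that("number density and volume fraction match the lysozyme table", {
  expect_equal(number_density(4.91, paper_mw) / 1e17, 2.068,
               tolerance = 5e-4)
  expect_equal(number_density(table2_conc, paper_mw) / 1e17,
               table2_n / 1e17, tolerance = 5e-4)
  expect_equal(100 * volume_fraction(2.45, 1.46), 0.168,
               tolerance = 5e-3)
  expect_error(number_density(0, paper_mw), "> 0")
  expect_error(volume_fraction(1, 0), "> 0")
  expect_equal(number_density(2 * 4.91, paper_mw),
               2 * number_density(4.91, paper_mw))
  expect_equal(volume_fraction(1.46 * 1000, 1.46), 1)
})

test_that("fit_virial recovers an exact dilute line to high precision", {
  b <- 0.37
  y <- b * (1 - 2 * paper_b22 * table2_n)
  i0 <- y * table2_n
  v <- fit_virial(table2_n, i0, mw = paper_mw)
  expect_equal(v$b22_mL, paper_b22, tolerance = 1e-10)
  expect_equal(v$intercept_b, b, tolerance = 1e-10)

  # flat line: ideal solution
  v0 <- fit_virial(table2_n, b * table2_n)
  expect_equal(v0$b22_mL, 0, tolerance = 1e-12)
  expect_equal(v0$s0, rep(1, length(table2_n)))

  expect_error(fit_virial(table2_n[1:2], i0[1:2]), ">= 3")
  expect_error(fit_virial(table2_n, -i0), "> 0")
  # I(0)/n proportional to n extrapolates to a zero intercept
  expect_error(fit_virial(c(1, 2, 3), 1e-3 * c(1, 2, 3)^2),
               "unphysical intercept")
})

test_that("B22 unit conversions reproduce the published figures", {
  conv <- convert_b22(paper_b22, paper_mw)
  expect_equal(conv$mL_per_mol, -22900, tolerance = 0.005)
  expect_equal(conv$mol_mL_per_g2, -1.12e-4, tolerance = 0.005)
  expect_equal(convert_b22(0, paper_mw),
               list(mL_per_mol = 0, mol_mL_per_g2 = 0))
  # round trip mL -> mL/mol -> mL
  expect_equal(conv$mL_per_mol / 6.02214076e23, paper_b22)
})

test_that("s_zero and xi obey their algebra", {
  expect_equal(s_zero(7.818e17, paper_b22), 1.0594, tolerance = 1e-4)
  expect_equal(s_zero(1e17, 0), 1)
  expect_error(s_zero(1e20, 1e-20), "validity")
  expect_equal(xi(1), 0)
  expect_error(xi(0), "> 0")

  # identity xi(S(0)) == -nB22/(1-2nB22) across seeded random inputs
  set.seed(11)
  for (k in 1:50) {
    n <- runif(1, 1e16, 1e18)
    b22 <- runif(1, -8e-20, 4e-21)
    # tolerance limited by cancellation in s0 - 1 when n b22 is tiny
    expect_equal(xi(s_zero(n, b22)), xi_dilute(n, b22, "exact"),
                 tolerance = 1e-8)
  }

  # first-order vs exact at n|B22| = 0.03 (attractive): < 7% apart
  nb <- 0.03
  ex <- xi_dilute(nb / 8e-20, -8e-20, "exact")
  fo <- xi_dilute(nb / 8e-20, -8e-20, "first")
  expect_equal(ex, nb / 1.06, tolerance = 1e-12)
  expect_lt(abs(fo - ex) / ex, 0.07)
})

test_that("fit_interaction recovers the published line exactly", {
  x <- -table2_n * paper_b22
  y <- 168 + 1431 * x
  f <- fit_interaction(x, y)
  expect_equal(f$ri2, 1431, tolerance = 1e-10)
  expect_equal(f$rg0_2, 168, tolerance = 1e-10)
  expect_equal(f$rg0, sqrt(168), tolerance = 1e-12)  # 12.96 ~ 13.0
  expect_equal(f$ratio, f$ri / f$rg0)

  # no interaction signal: all Rg,obs equal
  f0 <- suppressWarnings(fit_interaction(x, rep(169, length(x))))
  expect_equal(f0$ri2, 0, tolerance = 1e-9)
  expect_equal(f0$rg0, 13, tolerance = 1e-9)

  # negative slope is reported with ri flagged undefined
  expect_warning(fneg <- fit_interaction(x, 168 - 1431 * x),
                 "undefined")
  expect_false(fneg$ri_defined)
  expect_true(is.na(fneg$ri))
  expect_equal(fneg$ri2, -1431, tolerance = 1e-8)

  expect_error(fit_interaction(x[1:2], y[1:2]), ">= 3")
  expect_error(fit_interaction(rep(0.01, 4), y[1:4]), "singular")

  # confidence band is centred on the fitted line
  xx <- seq(0, 0.03, length.out = 5)
  band <- f$ci95_band(xx)
  expect_equal(band$fit, 168 + 1431 * xx, tolerance = 1e-9)
  expect_true(all(band$lo <= band$fit & band$fit <= band$hi))
})

test_that("noiseless end-to-end analysis recovers the forward model", {
  cfg <- simulation_config(noise_frac = 0)
  ser <- simulate_series(cfg)
  an <- suppressMessages(analyze_series(ser, x_axis = "xi"))
  expect_equal(an$virial$b22_mL, cfg$b22_mL, tolerance = 1e-7)
  expect_equal(an$interaction$ri, cfg$ri, tolerance = 1e-7)
  expect_equal(an$interaction$rg0, cfg$rg0, tolerance = 1e-7)

  # default -nB22 axis carries only the small linearisation bias
  an2 <- suppressMessages(analyze_series(ser))
  expect_equal(an2$interaction$ri, cfg$ri, tolerance = 0.05)

  # b22 = 0: no signal, ri undefined or ~0, rg0 = rg_obs
  cfg0 <- simulation_config(b22_mL = 0, noise_frac = 0)
  an0 <- suppressWarnings(suppressMessages(
    analyze_series(simulate_series(cfg0))))
  expect_equal(an0$interaction$rg0, cfg0$rg0, tolerance = 1e-6)
  expect_equal(an0$table$rg_obs, rep(cfg0$rg0, 6), tolerance = 1e-8)
})

test_that("sign law: attraction raises Rg,obs with n, repulsion lowers it", {
  att <- suppressMessages(analyze_series(
    simulate_series(simulation_config(b22_mL = -3.8e-20, noise_frac = 0))))
  expect_true(all(diff(att$table$rg_obs) > 0))
  rep_ <- suppressMessages(analyze_series(
    simulate_series(simulation_config(b22_mL = +3.8e-20, noise_frac = 0))))
  expect_true(all(diff(rep_$table$rg_obs) < 0))
})
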