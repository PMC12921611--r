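test_that("hard-sphere quadrature matches the closed forms", {
  hs <- pair_potential("hard_sphere", sigma = 10)
  r <- ri_from_potential(hs)
  expect_equal(r$ri, sqrt(3 / 5) * 10, tolerance = 1e-8)

  refs <- hard_sphere_refs(5)  # R_HS = sigma/2
  expect_equal(refs$ratio, 2)
  expect_equal(refs$rg_hs, sqrt(3 / 5) * 5)
  expect_equal(refs$ri_hs, sqrt(3 / 5) * 10)
  expect_equal(r$ri / refs$rg_hs, 2, tolerance = 1e-8)
  expect_equal(hard_sphere_refs(16.77)$rg_hs, 12.99, tolerance = 1e-3)

  b <- b22_from_potential(hs)
  expect_equal(b$b22_A3, (2 * pi / 3) * 10^3, tolerance = 1e-8)
  expect_equal(b$b22_mL, b$b22_A3 * 1e-24)
})

test_that("scale covariance: lengths scale Ri by k and B22 by k^3", {
  for (k in c(0.5, 3)) {
    h1 <- pair_potential("gaussian_well", epsilon = 0.4, lambda = 8)
    h2 <- pair_potential("gaussian_well", epsilon = 0.4, lambda = 8 * k)
    expect_equal(ri_from_potential(h2)$ri, k * ri_from_potential(h1)$ri,
                 tolerance = 1e-7)
    expect_equal(b22_from_potential(h2)$b22_A3,
                 k^3 * b22_from_potential(h1)$b22_A3, tolerance = 1e-7)
  }
})

test_that("weak mode converges to Mayer mode at first order in depth", {
  # Gaussian well: the two weights genuinely differ at O(epsilon)
  diffs <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    pot <- pair_potential("gaussian_well", epsilon = eps, lambda = 10)
    abs(ri_from_potential(pot, "mayer")$ri -
          ri_from_potential(pot, "weak", r_range = c(0, 80))$ri)
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
  # first-order convergence: tenfold shallower -> ~tenfold closer
  expect_equal(diffs[1] / diffs[2], 10, tolerance = 0.1)
  expect_equal(diffs[2] / diffs[3], 10, tolerance = 0.1)

  # square well restricted to the well region: constant weight cancels,
  # so the two modes agree identically at any depth
  sw <- pair_potential("square_well", sigma = 10, epsilon = 0.01,
                       lambda = 2)
  rm <- ri_from_potential(sw, "mayer", r_range = c(10, 20))
  rw <- ri_from_potential(sw, "weak", r_range = c(10, 20))
  expect_equal(rm$ri, rw$ri, tolerance = 1e-9)

  # weak mode over a hard core is refused
  expect_error(ri_from_potential(sw, "weak"), "hard core")
})

test_that("degenerate potentials yield the ill-conditioned error", {
  zero <- pair_potential("tabulated", r = c(0, 10, 20), v = c(0, 0, 0))
  expect_error(ri_from_potential(zero), "ill-conditioned")
  # V == 0 gives B22 = 0
  expect_equal(b22_from_potential(zero)$b22_A3, 0, tolerance = 1e-12)
})

test_that("square-well B22 sign follows the attraction/core balance", {
  # analytic square-well virial: B22 = (2*pi/3) sigma^3 [1 - (e^eps - 1)(lambda^3 - 1)]
  swb <- function(sigma, eps, lambda) {
    (2 * pi / 3) * sigma^3 * (1 - expm1(eps) * (lambda^3 - 1))
  }
  for (par in list(c(30, 0.5, 1.5), c(30, 0.05, 1.5), c(10, 1.2, 2))) {
    pot <- pair_potential("square_well", sigma = par[1], epsilon = par[2],
                          lambda = par[3])
    got <- b22_from_potential(pot)$b22_A3
    expect_equal(got, swb(par[1], par[2], par[3]), tolerance = 1e-8)
  }
  # depth 0.5 kT, range 1.5 sigma: attraction dominates the core
  expect_lt(b22_from_potential(
    pair_potential("square_well", sigma = 30, epsilon = 0.5,
                   lambda = 1.5))$b22_A3, 0)
})

test_that("tabulated potentials convert absolute energies via kT", {
  kT_J <- 1.380649e-23 * 300
  pot <- pair_potential("tabulated", r = c(5, 10, 20, 30),
                        v = kT_J * c(-0.5, -0.25, -0.05, 0),
                        energy_unit = "J", temperature = 300)
  expect_equal(pot$v(10), -0.25, tolerance = 1e-12)
  expect_equal(pot$v(2), Inf)  # below first tabulated r: hard core
  expect_equal(pot$v(40), 0)
})

test_that("low-Q asymptote s_low_q obeys its limits", {
  q <- seq(0, 0.1, length.out = 11)
  expect_equal(s_low_q(q, 1, 38), rep(1, 11))
  expect_equal(s_low_q(0, 1.0594, 38), 1.0594)
  # ln S slope at small Q equals -(1/6) (s0-1)/s0 ri^2
  s0 <- 1.05; ri <- 38
  qs <- c(1e-4, 2e-4)
  sl <- diff(log(s_low_q(qs, s0, ri))) / diff(qs^2)
  expect_equal(sl, -(1 / 6) * ((s0 - 1) / s0) * ri^2, tolerance = 1e-6)
})

test_that("numeric Fourier transform of h reproduces known S(Q)", {
  # h == 0 -> S == 1
  h0 <- correlation_function(fun = function(r) rep(0, length(r)),
                             r_max = 50)
  expect_equal(structure_factor_numeric(h0, 1e-6, c(0, 0.05, 0.1)),
               rep(1, 3))

  # dilute hard sphere: S(0) = 1 - (4 pi / 3) n sigma^3 = 1 - 2 n B22
  sigma <- 10; n <- 1e-6  # n sigma^3 = 1e-3
  hs_h <- correlation_function(
    fun = function(r) ifelse(r < sigma, -1, 0),
    knots = sigma, r_max = 3 * sigma)
  s0 <- structure_factor_numeric(hs_h, n, 0)
  expect_equal(s0, 1 - (4 * pi / 3) * n * sigma^3, tolerance = 1e-9)
  b22 <- b22_from_potential(pair_potential("hard_sphere",
                                           sigma = sigma))$b22_A3
  expect_equal(s0, 1 - 2 * n * b22, tolerance = 1e-9)
})

test_that("central oracle: transform vs exponential asymptote slopes", {
  # Guinier-style fit of ln S over Q Ri < 0.5 recovers Ri within 1%
  sigma <- 10; n <- 1e-6
  ri_true <- sqrt(3 / 5) * sigma
  hs_h <- correlation_function(
    fun = function(r) ifelse(r < sigma, -1, 0),
    knots = sigma, r_max = 3 * sigma)
  q <- seq(0.005, 0.5 / ri_true, length.out = 25)
  S <- structure_factor_numeric(hs_h, n, q)
  fit <- stats::lm(log(S) ~ I(q^2))
  slope <- unname(stats::coef(fit)[2])
  s0 <- 1 - (4 * pi / 3) * n * sigma^3
  ri_rec2 <- -6 * slope * s0 / (s0 - 1)
  expect_equal(sqrt(ri_rec2), ri_true, tolerance = 0.01)

  # and the asymptote itself agrees pointwise in that window
  expect_equal(S, s_low_q(q, s0, ri_true), tolerance = 2e-4)
})

test_that("mayer_h links potentials to correlation functions", {
  pot <- pair_potential("square_well", sigma = 10, epsilon = 0.3,
                        lambda = 1.5)
  h <- mayer_h(pot)
  expect_s3_class(h, "correlation_fn")
  expect_equal(h$fun(5), -1)
  expect_equal(h$fun(12), expm1(0.3), tolerance = 1e-12)
  expect_equal(h$fun(h$r_max), 0)
  # S(0) from the transform matches 1 - 2 n B22 from the virial integral
  n <- 5e-7
  b22 <- b22_from_potential(pot)$b22_A3
  expect_equal(structure_factor_numeric(h, n, 0), 1 - 2 * n * b22,
               tolerance = 1e-8)
})
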