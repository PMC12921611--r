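# Fixtures are built in code; no data files.

# Pure Guinier-exponential curve, optionally with seeded Gaussian noise.
make_exp_profile <- function(i0 = 7.3, rg = 13,
                             q = seq(0.01, 0.12, length.out = 60),
                             noise = 0, seed = NULL, ...) {
  i <- i0 * exp(-q^2 * rg^2 / 3)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    di <- noise * i
    i <- i + rnorm(length(q), 0, di)
    scattering_profile(q, i, di, ...)
  } else {
    scattering_profile(q, i, ...)
  }
}

# Uniform-sphere form factor curve (closed-form amplitude squared).
make_sphere_profile <- function(R = 16.77, scale = 1,
                                q = seq(0.005, 0.2, length.out = 200)) {
  x <- q * R
  amp <- 3 * (sin(x) - x * cos(x)) / x^3
  scattering_profile(q, scale * amp^2)
}

# Minimal guinier_result carrying only residuals, for diagnostics tests.
mock_guinier_result <- function(res) {
  structure(list(residuals = res), class = "guinier_result")
}

table2_conc <- c(2.45, 4.91, 7.40, 9.94, 14.21, 18.56)
table2_n <- c(1.030, 2.068, 3.117, 4.187, 5.985, 7.818) * 1e17
paper_b22 <- -3.80e-20
paper_mw <- 14300
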