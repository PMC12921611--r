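## Boltzmann constant (J/K) and molar gas constant (J/mol/K), SI exact.
.K_BOLTZMANN <- 1.380649e-23
.R_GAS <- 8.314462618

#' Specify an isotropic pair potential
#'
#' Builds a `pair_potential` object consumed by the quadrature routines
#' [ri_from_potential()] and [b22_from_potential()]. Energies are held in
#' units of kT internally; tabulated input in absolute units is converted
#' on ingestion using `temperature`.
#'
#' Supported forms:
#' \describe{
#'   \item{hard_sphere}{infinite for r < `sigma`, zero beyond.}
#'   \item{square_well}{hard core `sigma`, depth `-epsilon` kT on
#'     `sigma <= r < lambda * sigma` (`lambda` > 1, dimensionless range).}
#'   \item{gaussian_well}{V(r) = -`epsilon` exp(-(r/`lambda`)^2), with
#'     `lambda` the range in Angstrom; no hard core.}
#'   \item{yukawa}{hard core `sigma`, screened attraction
#'     V(r) = -`epsilon` (`sigma`/r) exp(-(r - `sigma`)/`lambda`) for
#'     r >= `sigma`, `lambda` the decay length in Angstrom.}
#'   \item{tabulated}{piecewise-linear interpolation of (`r`, `v`); `r`
#'     strictly increasing starting at 0 or at contact (the region below
#'     `r[1]` is treated as a hard core when `r[1]` > 0); V = 0 beyond the
#'     last tabulated point.}
#' }
#'
#' A potential of mean force omega(r) may be supplied through the
#' tabulated pathway; the quadrature is identical, only the physical
#' interpretation differs.
#'
#' @param form One of `"hard_sphere"`, `"square_well"`, `"gaussian_well"`,
#'   `"yukawa"`, `"tabulated"`.
#' @param sigma Contact diameter, Angstrom (where applicable).
#' @param epsilon Well depth, kT units, >= 0.
#' @param lambda Range parameter (dimensionless multiple of sigma for
#'   `square_well`; Angstrom for `gaussian_well` and `yukawa`).
#' @param r,v Tabulated radii (Angstrom) and energies for
#'   `form = "tabulated"`.
#' @param energy_unit Unit of tabulated `v`: `"kT"` (default), `"J"`,
#'   `"kJ/mol"` or `"kcal/mol"`.
#' @param temperature Absolute temperature in K, used only to convert
#'   absolute-energy tabulated input to kT.
#' @return An object of class `pair_potential` with elements `form`,
#'   `v` (function of r returning V/kT, possibly `Inf`), `core`
#'   (hard-core radius, 0 if none), `knots` (discontinuity radii),
#'   `scale` (characteristic length for tail truncation) and
#'   `temperature`.
#' @examples
#' hs <- pair_potential("hard_sphere", sigma = 10)
#' sw <- pair_potential("square_well", sigma = 30, epsilon = 0.5,
#'                      lambda = 1.5)
#' @export
pair_potential <- function(form = c("hard_sphere", "square_well",
                                    "gaussian_well", "yukawa",
                                    "tabulated"),
                           sigma = NULL, epsilon = NULL, lambda = NULL,
                           r = NULL, v = NULL,
                           energy_unit = c("kT", "J", "kJ/mol", "kcal/mol"),
                           temperature = 298.15) {
  form <- match.arg(form)
  energy_unit <- match.arg(energy_unit)
  .assert_scalar_pos(temperature, "temperature")
  out <- switch(form,
    hard_sphere = {
      .assert_scalar_pos(sigma, "sigma")
      list(v = function(r) ifelse(r < sigma, Inf, 0),
           core = sigma, knots = sigma, scale = sigma)
    },
    square_well = {
      .assert_scalar_pos(sigma, "sigma")
      .assert_scalar_pos(lambda, "lambda")
      if (lambda <= 1) stop("`lambda` must be > 1 for square_well",
                            call. = FALSE)
      if (is.null(epsilon) || epsilon < 0) {
        stop("`epsilon` (well depth, kT) must be >= 0", call. = FALSE)
      }
      list(v = function(r) ifelse(r < sigma, Inf,
                                  ifelse(r < lambda * sigma, -epsilon, 0)),
           core = sigma, knots = c(sigma, lambda * sigma),
           scale = lambda * sigma)
    },
    gaussian_well = {
      .assert_scalar_pos(lambda, "lambda")
      if (is.null(epsilon) || epsilon < 0) {
        stop("`epsilon` (well depth, kT) must be >= 0", call. = FALSE)
      }
      list(v = function(r) -epsilon * exp(-(r / lambda)^2),
           core = 0, knots = numeric(), scale = lambda)
    },
    yukawa = {
      .assert_scalar_pos(sigma, "sigma")
      .assert_scalar_pos(lambda, "lambda")
      if (is.null(epsilon) || epsilon < 0) {
        stop("`epsilon` (well depth, kT) must be >= 0", call. = FALSE)
      }
      list(v = function(r) ifelse(r < sigma, Inf,
             -epsilon * (sigma / r) * exp(-(r - sigma) / lambda)),
           core = sigma, knots = sigma, scale = sigma + 5 * lambda)
    },
    tabulated = {
      r <- as.numeric(r); v <- as.numeric(v)
      if (length(r) < 2L || length(r) != length(v)) {
        stop("tabulated form needs equal-length r, v with >= 2 points",
             call. = FALSE)
      }
      if (any(r < 0) || is.unsorted(r, strictly = TRUE)) {
        stop("tabulated r must be >= 0 and strictly increasing",
             call. = FALSE)
      }
      kT <- switch(energy_unit,
                   "kT" = 1,
                   "J" = .K_BOLTZMANN * temperature,
                   "kJ/mol" = .R_GAS * temperature / 1000,
                   "kcal/mol" = .R_GAS * temperature / 4184)
      vkt <- v / kT
      core <- if (r[1L] > 0) r[1L] else 0
      vf <- function(x) {
        out <- rep(0, length(x))
        out[x < core] <- Inf
        inside <- x >= r[1L] & x <= r[length(r)]
        out[inside] <- stats::approx(r, vkt, xout = x[inside])$y
        out
      }
      list(v = vf, core = core, knots = c(core, r[length(r)]),
           scale = r[length(r)])
    })
  structure(c(out, list(form = form, temperature = temperature)),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat(sprintf("<pair_potential> %s%s, T = %g K\n", x$form,
              if (x$core > 0) sprintf(" (hard core %g Ang)", x$core)
              else "", x$temperature))
  invisible(x)
}

## Piecewise adaptive quadrature with mandatory subdivision knots;
## hard cores and well edges break global adaptive schemes otherwise.
.quad_piecewise <- function(f, lower, upper, knots = numeric(),
                            rel_tol = 1e-9) {
  pts <- sort(unique(c(lower, upper, knots[knots > lower & knots < upper])))
  total <- 0
  for (k in seq_len(length(pts) - 1L)) {
    piece <- stats::integrate(f, pts[k], pts[k + 1L], rel.tol = rel_tol,
                              abs.tol = rel_tol,
                              subdivisions = 400L, stop.on.error = FALSE)
    if (!piece$message %in% c("OK", "maximum number of subdivisions reached")) {
      stop("quadrature failed on [", pts[k], ", ", pts[k + 1L], "]: ",
           piece$message, call. = FALSE)
    }
    total <- total + piece$value
  }
  total
}

## Choose an integration cutoff: start past all structure, double until
## the r^4-weighted integral of |w| is stable.
.adaptive_rmax <- function(w, pot, rel_tol = 1e-9) {
  r0 <- max(c(pot$knots, pot$scale, 1)) * 4
  f <- function(r) abs(w(r)) * r^4
  prev <- .quad_piecewise(f, 0, r0, pot$knots, rel_tol = 1e-7)
  for (iter in 1:30) {
    cur <- .quad_piecewise(f, 0, 2 * r0, pot$knots, rel_tol = 1e-7)
    if (abs(cur - prev) <= 1e-10 * (abs(cur) + 1e-300)) return(2 * r0)
    prev <- cur
    r0 <- 2 * r0
  }
  stop("integrand does not decay: potential tail too long-ranged",
       call. = FALSE)
}

#' Radius of interparticle interaction from a pair potential
#'
#' Computes Ri^2 as the ratio of radial integrals
#' `int w(r) r^4 dr / int w(r) r^2 dr` with weight `w = exp(-V/kT) - 1`
#' (`mode = "mayer"`, the dilute total correlation function) or `w = V/kT`
#' (`mode = "weak"`, the weak-potential linearization). The square root is
#' returned when Ri^2 > 0; otherwise the result is flagged undefined.
#'
#' @param pot A [pair_potential()].
#' @param mode `"mayer"` (default) or `"weak"`. Weak mode is undefined on
#'   a domain containing an infinite hard core.
#' @param r_range Optional integration domain `c(lo, hi)` in Angstrom;
#'   defaults to `[0, r_max]` with `r_max` chosen adaptively (doubled
#'   until the tail contribution is negligible).
#' @param rel_tol Quadrature relative and absolute tolerance.
#' @return A list with `ri` (Angstrom, `NA` when undefined), `ri2`,
#'   `defined`, `mode`, `num`, `den`, `r_range`.
#' @examples
#' ri_from_potential(pair_potential("hard_sphere", sigma = 10))$ri
#' # sqrt(3/5) * 10 = 7.745967
#' @export
ri_from_potential <- function(pot, mode = c("mayer", "weak"),
                              r_range = NULL, rel_tol = 1e-9) {
  stopifnot(inherits(pot, "pair_potential"))
  mode <- match.arg(mode)
  w <- switch(mode,
              mayer = function(r) expm1(-pot$v(r)),
              weak = function(r) pot$v(r))
  if (is.null(r_range)) {
    rmax <- .adaptive_rmax(function(r) expm1(-pot$v(r)), pot,
                           rel_tol = rel_tol)
    r_range <- c(0, rmax)
  }
  if (mode == "weak" && pot$core > r_range[1L]) {
    stop("weak mode is undefined over an infinite hard core; ",
         "restrict `r_range` to the finite region", call. = FALSE)
  }
  num <- .quad_piecewise(function(r) w(r) * r^4, r_range[1L], r_range[2L],
                         pot$knots, rel_tol = rel_tol)
  den <- .quad_piecewise(function(r) w(r) * r^2, r_range[1L], r_range[2L],
                         pot$knots, rel_tol = rel_tol)
  scale <- .quad_piecewise(function(r) abs(w(r)) * r^2, r_range[1L],
                           r_range[2L], pot$knots, rel_tol = rel_tol)
  if (abs(den) <= 1e-9 * max(scale, 1e-300) || scale == 0) {
    stop("ill-conditioned Ri: the normalizing integral of the ",
         "interaction weight is (numerically) zero", call. = FALSE)
  }
  ri2 <- num / den
  defined <- ri2 > 0
  if (!defined) {
    warning("Ri^2 <= 0 for this potential; Ri is undefined",
            call. = FALSE)
  }
  list(ri = if (defined) sqrt(ri2) else NA_real_, ri2 = ri2,
       defined = defined, mode = mode, num = num, den = den,
       r_range = r_range)
}

#' Hard-sphere reference values
#'
#' For uniform hard spheres of radius `r_hs` (diameter sigma = 2 r_hs)
#' the closed forms are Rg = sqrt(3/5) r_hs and Ri = sqrt(3/5) sigma,
#' hence Ri = 2 Rg exactly.
#'
#' @param r_hs Hard-sphere radius, Angstrom.
#' @return List with `rg_hs`, `ri_hs` (Angstrom) and `ratio` (= 2).
#' @export
hard_sphere_refs <- function(r_hs) {
  .assert_scalar_pos(r_hs, "r_hs")
  rg <- sqrt(3 / 5) * r_hs
  list(rg_hs = rg, ri_hs = 2 * rg, ratio = 2)
}

#' Second virial coefficient from a pair potential
#'
#' B22 = -1/2 int (exp(-V/kT) - 1) 4 pi r^2 dr, the standard virial
#' integral, returned in Angstrom^3 and mL.
#'
#' @param pot A [pair_potential()].
#' @param r_max Optional integration cutoff, Angstrom (adaptive default).
#' @param rel_tol Quadrature tolerance.
#' @return List with `b22_A3`, `b22_mL` (= A3 * 1e-24) and `r_max`.
#' @examples
#' b22_from_potential(pair_potential("hard_sphere", sigma = 10))$b22_A3
#' # (2*pi/3) * 1000
#' @export
b22_from_potential <- function(pot, r_max = NULL, rel_tol = 1e-9) {
  stopifnot(inherits(pot, "pair_potential"))
  w <- function(r) expm1(-pot$v(r))
  if (is.null(r_max)) {
    r_max <- .adaptive_rmax(w, pot, rel_tol = rel_tol)
  } else if (abs(w(r_max)) > 1e-8) {
    stop(sprintf(
      "truncation error: |exp(-V)-1| = %.2g at r_max = %g is not negligible",
      abs(w(r_max)), r_max), call. = FALSE)
  }
  val <- -0.5 * 4 * pi *
    .quad_piecewise(function(r) w(r) * r^2, 0, r_max, pot$knots,
                    rel_tol = rel_tol)
  list(b22_A3 = val, b22_mL = val * 1e-24, r_max = r_max)
}

#' Low-Q exponential asymptote of the structure factor
#'
#' S(Q) = S(0) exp(-(1/6) ((S(0)-1)/S(0)) Q^2 Ri^2), the
#' structure-factor analogue of the Guinier law.
#'
#' @param q Momentum transfer grid, 1/Angstrom.
#' @param s0 Forward structure factor, > 0.
#' @param ri Radius of interparticle interaction, Angstrom, >= 0.
#' @return S(Q) on the grid.
#' @export
s_low_q <- function(q, s0, ri) {
  if (any(s0 <= 0)) stop("s0 must be > 0", call. = FALSE)
  if (any(ri < 0)) stop("ri must be >= 0", call. = FALSE)
  s0 * exp(-(1 / 6) * ((s0 - 1) / s0) * q^2 * ri^2)
}

#' Represent a total correlation function h(r)
#'
#' @param fun Function of r (Angstrom) returning h(r); or `NULL` when a
#'   table is given.
#' @param r,h Tabulated representation (piecewise linear, 0 beyond the
#'   last point).
#' @param knots Radii of discontinuities (mandatory quadrature
#'   subdivision points).
#' @param r_max Radius beyond which h is treated as 0; required for
#'   functional input.
#' @return An object of class `correlation_fn`.
#' @export
correlation_function <- function(fun = NULL, r = NULL, h = NULL,
                                 knots = numeric(), r_max = NULL) {
  if (is.null(fun)) {
    r <- as.numeric(r); h <- as.numeric(h)
    if (length(r) < 2L || length(r) != length(h)) {
      stop("tabulated h needs equal-length r, h with >= 2 points",
           call. = FALSE)
    }
    if (is.unsorted(r, strictly = TRUE) || any(r < 0)) {
      stop("r must be >= 0 and strictly increasing", call. = FALSE)
    }
    r_max <- r[length(r)]
    fun_ <- function(x) {
      out <- rep(0, length(x))
      inside <- x >= r[1L] & x <= r_max
      out[inside] <- stats::approx(r, h, xout = x[inside])$y
      out
    }
    knots <- unique(c(knots, r[1L], r_max))
  } else {
    if (is.null(r_max)) {
      stop("`r_max` is required for functional h", call. = FALSE)
    }
    fun_ <- fun
  }
  hv <- fun_(seq(0.01 * r_max, r_max, length.out = 64L))
  if (any(hv < -1 - 1e-9)) {
    stop("h(r) must be >= -1 everywhere", call. = FALSE)
  }
  structure(list(fun = fun_, knots = knots, r_max = r_max),
            class = "correlation_fn")
}

#' Dilute total correlation function of a pair potential
#'
#' h(r) = exp(-V/kT) - 1, the Mayer function, valid in the dilute limit.
#'
#' @param pot A [pair_potential()].
#' @param r_max Cutoff radius (adaptive default).
#' @return A [correlation_function()].
#' @export
mayer_h <- function(pot, r_max = NULL) {
  stopifnot(inherits(pot, "pair_potential"))
  w <- function(r) expm1(-pot$v(r))
  if (is.null(r_max)) r_max <- .adaptive_rmax(w, pot)
  correlation_function(fun = w, knots = pot$knots, r_max = r_max)
}

#' Structure factor by numeric radial Fourier transform
#'
#' S(Q) = 1 + 4 pi n int_0^rmax h(r) r^2 sin(Qr)/(Qr) dr, with the sinc
#' limit handled at Q = 0. This is the reference transform against which
#' the exponential asymptote [s_low_q()] is validated.
#'
#' @param h A [correlation_function()].
#' @param n Number density in 1/Angstrom^3 (note the unit: consistent
#'   with the Angstrom r-grid).
#' @param q Momentum-transfer grid, 1/Angstrom.
#' @param rel_tol Quadrature tolerance.
#' @return S(Q) values on the grid.
#' @export
structure_factor_numeric <- function(h, n, q, rel_tol = 1e-9) {
  stopifnot(inherits(h, "correlation_fn"))
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  tail <- abs(h$fun(h$r_max * c(0.999, 1)))
  if (any(tail > 1e-6)) {
    stop("h(r) has not decayed at r_max; truncation would bias S(Q)",
         call. = FALSE)
  }
  vapply(q, function(qq) {
    f <- if (qq == 0) {
      function(r) h$fun(r) * r^2
    } else {
      function(r) {
        x <- qq * r
        sinc <- ifelse(x == 0, 1, sin(x) / x)
        h$fun(r) * r^2 * sinc
      }
    }
    1 + 4 * pi * n *
      .quad_piecewise(f, 0, h$r_max, h$knots, rel_tol = rel_tol)
  }, numeric(1L))
}
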