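#' Number density from mass concentration
#'
#' n = (c / 1000) / M_W * N_A, in particles per mL.
#'
#' @param c Mass concentration, mg/mL. Vectorized.
#' @param mw Molecular weight, g/mol.
#' @return Number density, 1/mL.
#' @examples
#' number_density(4.91, 14300)  # ~2.068e17 /mL for lysozyme
#' @export
number_density <- function(c, mw) {
  .assert_scalar_pos(mw, "mw")
  if (any(!is.finite(c)) || any(c <= 0)) {
    stop("`c` must be finite and > 0", call. = FALSE)
  }
  (c / 1000) / mw * .N_AVOGADRO
}

#' Volume fraction from mass concentration
#'
#' phi = (c / 1000) / rho, dimensionless.
#'
#' @param c Mass concentration, mg/mL. Vectorized.
#' @param rho Solute mass density, g/cm^3.
#' @return Volume fraction.
#' @examples
#' 100 * volume_fraction(2.45, 1.46)  # 0.168 vol%
#' @export
volume_fraction <- function(c, rho) {
  .assert_scalar_pos(rho, "rho")
  if (any(!is.finite(c)) || any(c <= 0)) {
    stop("`c` must be finite and > 0", call. = FALSE)
  }
  (c / 1000) / rho
}

#' Second virial coefficient from a forward-scattering series
#'
#' Fits a line to I(0)/n versus n and computes B22 = -a / (2 b), where `a`
#' is the slope and `b` the intercept. Under the dilute expansion
#' I(0)/n = P(0) S(0) = P(0) (1 - 2 n B22), so the ratio of slope to
#' intercept isolates B22 in units of mL per particle pair. The 1-sigma
#' uncertainty is propagated by the delta method from the full (a, b)
#' covariance, including their correlation.
#'
#' @param n Number densities, 1/mL.
#' @param i0 Forward intensities I(0) from Guinier fits.
#' @param i0_err Optional 1-sigma uncertainties of `i0`; when supplied the
#'   fit is weighted with sigma_y = i0_err / n.
#' @param mw Optional molecular weight (g/mol) used to populate the molar
#'   and per-mass unit conversions.
#' @return An object of class `virial_result`: `b22_mL`, `b22_err_mL`,
#'   `slope_a`, `intercept_b`, `covariance`, `s0` (per-point S(0) = 1 -
#'   2 n B22), and when `mw` is given `b22_mL_per_mol`,
#'   `b22_mol_mL_per_g2` and their errors.
#' @export
fit_virial <- function(n, i0, i0_err = NULL, mw = NULL) {
  if (length(n) < 3L) {
    stop("fit_virial needs >= 3 points", call. = FALSE)
  }
  stopifnot(length(i0) == length(n))
  if (any(n <= 0) || any(i0 <= 0)) {
    stop("all n and i0 must be > 0", call. = FALSE)
  }
  y <- i0 / n
  sig <- if (!is.null(i0_err)) {
    stopifnot(length(i0_err) == length(n))
    i0_err / n
  } else NULL
  fit <- .wls_line(n, y, sigma = sig)
  a <- fit$slope; b <- fit$intercept
  if (b <= 0) {
    stop("unphysical intercept: fitted I(0)/n at n = 0 is <= 0",
         call. = FALSE)
  }
  b22 <- -a / (2 * b)
  ## delta method: dB/da = -1/(2b), dB/db = a/(2b^2)
  g <- c(a / (2 * b^2), -1 / (2 * b))  # order (intercept, slope)
  b22_err <- sqrt(drop(t(g) %*% fit$cov %*% g))
  out <- list(b22_mL = b22, b22_err_mL = b22_err, slope_a = a,
              intercept_b = b, covariance = fit$cov,
              s0 = 1 - 2 * n * b22, n = n, weighted = fit$weighted)
  if (!is.null(mw)) {
    conv <- convert_b22(b22, mw)
    out$b22_mL_per_mol <- conv$mL_per_mol
    out$b22_mol_mL_per_g2 <- conv$mol_mL_per_g2
    out$b22_err_mL_per_mol <- b22_err * .N_AVOGADRO
    out$b22_err_mol_mL_per_g2 <- b22_err * .N_AVOGADRO / mw^2
    out$mw <- mw
  }
  structure(out, class = "virial_result")
}

#' @export
print.virial_result <- function(x, ...) {
  cat(sprintf("<virial_result> B22 = %.3g +/- %.2g mL\n",
              x$b22_mL, x$b22_err_mL))
  if (!is.null(x$b22_mL_per_mol)) {
    cat(sprintf("  = %.3g +/- %.2g mL/mol = %.3g +/- %.2g mol mL/g^2\n",
                x$b22_mL_per_mol, x$b22_err_mL_per_mol,
                x$b22_mol_mL_per_g2, x$b22_err_mol_mL_per_g2))
  }
  cat(sprintf("  I(0)/n fit: slope = %.4g, intercept = %.4g (%s)\n",
              x$slope_a, x$intercept_b,
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Convert B22 between common unit systems
#'
#' @param b22_mL B22 in mL per particle pair.
#' @param mw Molecular weight, g/mol.
#' @return List with `mL_per_mol` (= b22_mL * N_A) and `mol_mL_per_g2`
#'   (= mL_per_mol / mw^2).
#' @examples
#' convert_b22(-3.80e-20, 14300)
#' @export
convert_b22 <- function(b22_mL, mw) {
  .assert_scalar_pos(mw, "mw")
  per_mol <- b22_mL * .N_AVOGADRO
  list(mL_per_mol = per_mol, mol_mL_per_g2 = per_mol / mw^2)
}

#' Forward structure factor from the dilute virial expansion
#'
#' S(0) = 1 - 2 n B22, valid while 2 n B22 < 1.
#'
#' @param n Number density, 1/mL. Vectorized.
#' @param b22_mL B22, mL.
#' @return S(0).
#' @export
s_zero <- function(n, b22_mL) {
  val <- 1 - 2 * n * b22_mL
  if (any(val <= 0)) {
    stop("2 n B22 >= 1: beyond dilute-expansion validity (S(0) <= 0)",
         call. = FALSE)
  }
  val
}

#' Structure-factor prefactor xi
#'
#' xi = (S(0) - 1) / (2 S(0)) multiplies Ri^2 in the modified Guinier law
#' Rg,obs^2 = Rg,0^2 + xi Ri^2.
#'
#' @param s0 Forward structure factor, > 0. Vectorized.
#' @return xi.
#' @export
xi <- function(s0) {
  if (any(s0 <= 0)) stop("s0 must be > 0", call. = FALSE)
  (s0 - 1) / (2 * s0)
}

#' xi in the dilute limit
#'
#' `order = "exact"` returns -n B22 / (1 - 2 n B22), identical to
#' `xi(s_zero(n, b22))`; `order = "first"` returns the small-n limit
#' -n B22.
#'
#' @param n Number density, 1/mL. Vectorized.
#' @param b22_mL B22, mL.
#' @param order `"exact"` or `"first"`.
#' @return xi.
#' @export
xi_dilute <- function(n, b22_mL, order = c("exact", "first")) {
  order <- match.arg(order)
  if (order == "first") return(-n * b22_mL)
  -n * b22_mL / s_zero(n, b22_mL)
}

#' Modified-Guinier linear fit: Ri^2 and Rg,0^2
#'
#' Weighted straight-line fit of Rg,obs^2 against the interaction
#' abscissa x (either -n B22 in the dilute limit, or the exact xi). The
#' slope estimates Ri^2, the radius of interparticle interaction squared;
#' the intercept estimates Rg,0^2, the infinite-dilution radius of
#' gyration squared.
#'
#' A negative fitted slope (Ri^2 < 0) is reported with `ri` flagged
#' undefined and a warning, not suppressed: it usually signals data
#' inadequacy or a repulsion/attraction mismatch, which the user should
#' see.
#'
#' @param x Abscissa values (dimensionless).
#' @param rg_obs2 Observed Rg^2 values, Angstrom^2.
#' @param rg_obs2_err Optional 1-sigma uncertainties of `rg_obs2`
#'   (typically 2 Rg sigma_Rg propagated from the Guinier fits).
#' @return An object of class `interaction_result`: `ri2`, `ri2_err`,
#'   `rg0_2`, `rg0_2_err`, `ri`, `ri_err`, `rg0`, `rg0_err`, `ratio`
#'   (ri/rg0), `ri_defined`, `covariance`, and `ci95_band`, a function of
#'   x returning a data frame (`x`, `fit`, `lo`, `hi`) with the 95%
#'   confidence band of the fitted line.
#' @export
fit_interaction <- function(x, rg_obs2, rg_obs2_err = NULL) {
  if (length(x) < 3L) {
    stop("fit_interaction needs >= 3 points", call. = FALSE)
  }
  stopifnot(length(rg_obs2) == length(x))
  fit <- .wls_line(x, rg_obs2, sigma = rg_obs2_err)
  ri2 <- fit$slope; rg0_2 <- fit$intercept
  ri2_err <- sqrt(fit$cov[2L, 2L])
  rg0_2_err <- sqrt(fit$cov[1L, 1L])
  if (rg0_2 <= 0) {
    stop("unphysical intercept: fitted Rg,0^2 <= 0", call. = FALSE)
  }
  ri_defined <- ri2 > 0
  if (!ri_defined) {
    warning("fitted Ri^2 <= 0: Ri is undefined for this series",
            call. = FALSE)
  }
  ri <- if (ri_defined) sqrt(ri2) else NA_real_
  ri_err <- if (ri_defined) ri2_err / (2 * ri) else NA_real_
  rg0 <- sqrt(rg0_2)
  rg0_err <- rg0_2_err / (2 * rg0)
  zc <- if (fit$weighted) stats::qnorm(0.975)
        else stats::qt(0.975, df = max(fit$df, 1L))
  cov <- fit$cov
  band <- function(xx) {
    se <- sqrt(cov[1L, 1L] + 2 * xx * cov[1L, 2L] + xx^2 * cov[2L, 2L])
    fitv <- rg0_2 + ri2 * xx
    data.frame(x = xx, fit = fitv, lo = fitv - zc * se,
               hi = fitv + zc * se)
  }
  structure(
    list(ri2 = ri2, ri2_err = ri2_err, rg0_2 = rg0_2,
         rg0_2_err = rg0_2_err, ri = ri, ri_err = ri_err, rg0 = rg0,
         rg0_err = rg0_err, ratio = if (ri_defined) ri / rg0 else NA_real_,
         ri_defined = ri_defined, covariance = cov, ci95_band = band,
         weighted = fit$weighted, n_points = length(x)),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> Ri^2 = %.4g +/- %.2g Ang^2, Rg,0^2 = %.4g +/- %.2g Ang^2\n",
              x$ri2, x$ri2_err, x$rg0_2, x$rg0_2_err))
  if (x$ri_defined) {
    cat(sprintf("  Ri = %.3g +/- %.2g Ang, Rg,0 = %.3f +/- %.2g Ang, Ri/Rg,0 = %.2f\n",
                x$ri, x$ri_err, x$rg0, x$rg0_err, x$ratio))
  } else {
    cat(sprintf("  Ri undefined (Ri^2 <= 0); Rg,0 = %.3f +/- %.2g Ang\n",
                x$rg0, x$rg0_err))
  }
  invisible(x)
}

#' Full modified-Guinier analysis of a concentration series
#'
#' Runs the two-stage workflow: a classical Guinier fit per profile, a
#' weighted fit of I(0)/n versus n to obtain B22, then the
#' modified-Guinier linear fit of Rg,obs^2 against x to obtain Ri^2 and
#' Rg,0^2. The default abscissa is x = -n B22 (the dilute form); `x_axis
#' = "xi"` uses the exact xi = -n B22 / (1 - 2 n B22).
#'
#' @param series A [build_series()] or [simulate_series()] result.
#' @param q_lo,q_hi Guinier window, 1/Angstrom.
#' @param weighted Weight both linear stages by propagated uncertainties.
#' @param x_axis `"nb22"` (default) or `"xi"`.
#' @return An object of class `sas_analysis`: `guinier` (list of
#'   per-profile results), `virial`, `interaction`, `x_axis`, and `table`,
#'   a per-concentration data frame with columns `c`, `n`, `i0`, `i0_err`,
#'   `rg_obs`, `rg_obs_err`, `s0`, `x`.
#' @export
analyze_series <- function(series, q_lo = 0.015, q_hi = 0.07,
                           weighted = TRUE, x_axis = c("nb22", "xi")) {
  stopifnot(inherits(series, "sas_series"))
  x_axis <- match.arg(x_axis)
  gf <- lapply(seq_along(series$profiles), function(k) {
    tryCatch(
      guinier_fit(series$profiles[[k]], q_lo, q_hi, weighted = weighted),
      error = function(e) stop(sprintf(
        "stage guinier_fit failed for profile %d (%s): %s", k,
        series$profiles[[k]]$label, conditionMessage(e)), call. = FALSE))
  })
  n <- series$table$n
  i0 <- vapply(gf, `[[`, numeric(1L), "i0")
  i0_err <- vapply(gf, `[[`, numeric(1L), "i0_err")
  use_w <- weighted && all(i0_err > 0)
  vir <- tryCatch(
    fit_virial(n, i0, i0_err = if (use_w) i0_err else NULL,
               mw = series$manifest$molecular_weight),
    error = function(e) stop("stage fit_virial failed: ",
                             conditionMessage(e), call. = FALSE))
  x <- switch(x_axis,
              nb22 = -n * vir$b22_mL,
              xi = xi_dilute(n, vir$b22_mL, order = "exact"))
  rg <- vapply(gf, `[[`, numeric(1L), "rg_obs")
  rg_err <- vapply(gf, `[[`, numeric(1L), "rg_obs_err")
  rg2_err <- 2 * rg * rg_err
  inter <- tryCatch(
    fit_interaction(x, rg^2,
                    rg_obs2_err = if (weighted && all(rg2_err > 0))
                      rg2_err else NULL),
    error = function(e) stop("stage fit_interaction failed: ",
                             conditionMessage(e), call. = FALSE))
  structure(
    list(guinier = gf, virial = vir, interaction = inter, x_axis = x_axis,
         table = data.frame(
           c = series$table$c, n = n, i0 = i0, i0_err = i0_err,
           rg_obs = rg, rg_obs_err = rg_err,
           s0 = 1 - 2 * n * vir$b22_mL, x = x)),
    class = "sas_analysis"
  )
}

#' @export
print.sas_analysis <- function(x, ...) {
  cat(sprintf("<sas_analysis> %d concentrations, x-axis = %s\n",
              nrow(x$table), x$x_axis))
  print(x$table, row.names = FALSE, digits = 4)
  print(x$virial)
  print(x$interaction)
  invisible(x)
}
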