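#' Classical Zimm form
#'
#' n/I(Q) = (1 + 2 n B22) / P(0) * (1 + Q^2 Rg^2 / 3), the reciprocal
#' intensity expansion linear in Q^2 and n.
#'
#' @param q Momentum transfer, 1/Angstrom. Recycled against `n`.
#' @param n Number density, 1/mL.
#' @param p0 Forward form-factor scale P(0), > 0.
#' @param rg Radius of gyration, Angstrom.
#' @param b22_mL Second virial coefficient, mL.
#' @return n/I values.
#' @export
zimm_classic <- function(q, n, p0, rg, b22_mL) {
  .assert_scalar_pos(p0, "p0")
  (1 + 2 * n * b22_mL) / p0 * (1 + q^2 * rg^2 / 3)
}

#' Modified Zimm form with the interaction radius
#'
#' n/I(Q) = (1 + 2 n B22) / P(0) * (1 + Q^2 Rg0^2 / 3) *
#' (1 - n B22 Q^2 Ri^2 / 3). The extra factor, absent from the classical
#' form, carries the concentration-dependent apparent-size shift through
#' Ri. Setting `ri = 0` or `b22_mL = 0` recovers [zimm_classic()]
#' exactly.
#'
#' @inheritParams zimm_classic
#' @param rg0 Infinite-dilution radius of gyration, Angstrom.
#' @param ri Radius of interparticle interaction, Angstrom.
#' @return n/I values.
#' @export
zimm_modified <- function(q, n, p0, rg0, ri, b22_mL) {
  .assert_scalar_pos(p0, "p0")
  (1 + 2 * n * b22_mL) / p0 * (1 + q^2 * rg0^2 / 3) *
    (1 - n * b22_mL * q^2 * ri^2 / 3)
}

#' Fit the classical or modified Zimm form to an observed surface
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of n/I(Q) triples to
#' [zimm_classic()] (parameters p0, rg, b22) or [zimm_modified()]
#' (parameters p0, rg0, ri, b22). The modified fit's (b22, ri) product is
#' identifiable only with at least 3 distinct concentrations, which is
#' enforced. This estimator is a cross-check of the two-stage
#' modified-Guinier route, not a replacement for it.
#'
#' @param data Data frame with columns `q` (1/Angstrom), `n` (1/mL) and
#'   `y` (= n/I).
#' @param modified Fit the modified form.
#' @param start Optional named list of starting values (`p0`, `rg` or
#'   `rg0`, `ri`, `b22`); defaults are derived from the data.
#' @return An object of class `zimm_fit`: `coefficients` (named vector),
#'   `se` (1-sigma errors), `modified`, `fit` (the `nls` object).
#' @export
fit_zimm <- function(data, modified = FALSE, start = NULL) {
  stopifnot(is.data.frame(data), all(c("q", "n", "y") %in% names(data)))
  nq <- length(unique(data$q)); nn <- length(unique(data$n))
  if (nq < 3L) {
    stop("fit_zimm needs >= 3 distinct q values", call. = FALSE)
  }
  if (nn < 2L) {
    stop("fit_zimm needs >= 2 distinct n values", call. = FALSE)
  }
  if (modified && nn < 3L) {
    stop("the modified Zimm fit needs >= 3 distinct n values to ",
         "identify the (b22, ri) product", call. = FALSE)
  }
  if (any(data$y <= 0)) stop("n/I values must be > 0", call. = FALSE)
  ## starting values: intercept at smallest q & n approximates 1/p0;
  ## low-q slope in q^2 approximates rg^2/3
  nmin <- min(data$n)
  low <- data[data$n == nmin, ]
  lf <- .wls_line(low$q^2, low$y)
  p0_0 <- 1 / max(lf$intercept, min(data$y))
  rg_0 <- sqrt(max(3 * lf$slope / max(lf$intercept, 1e-12), 25))
  b22_0 <- {
    qmin <- min(data$q)
    at_q <- data[data$q == qmin, ]
    if (nrow(at_q) >= 2L) {
      sl <- .wls_line(at_q$n, at_q$y)
      sl$slope / (2 * max(sl$intercept, 1e-12))
    } else 0
  }
  if (!modified) {
    st <- list(p0 = p0_0, rg = rg_0, b22 = b22_0)
    if (!is.null(start)) st[names(start)] <- start
    fit <- minpack.lm::nlsLM(
      y ~ (1 + 2 * n * b22) / p0 * (1 + q^2 * rg^2 / 3),
      data = data, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    st <- list(p0 = p0_0, rg0 = rg_0, ri = 2 * rg_0, b22 = b22_0)
    if (!is.null(start)) st[names(start)] <- start
    fit <- minpack.lm::nlsLM(
      y ~ (1 + 2 * n * b22) / p0 * (1 + q^2 * rg0^2 / 3) *
        (1 - n * b22 * q^2 * ri^2 / 3),
      data = data, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  sm <- summary(fit)
  structure(
    list(coefficients = stats::coef(fit),
         se = sm$coefficients[, "Std. Error"],
         modified = modified, fit = fit),
    class = "zimm_fit"
  )
}

#' @export
print.zimm_fit <- function(x, ...) {
  cat(sprintf("<zimm_fit> %s form\n",
              if (x$modified) "modified" else "classical"))
  co <- x$coefficients
  for (nm in names(co)) {
    cat(sprintf("  %s = %.6g +/- %.2g\n", nm, co[[nm]], x$se[[nm]]))
  }
  invisible(x)
}
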