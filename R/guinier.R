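#' Classical Guinier fit of a single profile
#'
#' Fits the Guinier law I(Q) = I(0) exp(-Q^2 Rg^2 / 3) by linear least
#' squares of ln I versus Q^2 over the window `[q_lo, q_hi]`. With
#' `weighted = TRUE` (default) and uncertainties present, each point is
#' weighted by the delta-method sigma of ln I, di/i, and the parameter
#' covariance is the known-sigma (X'WX)^-1; otherwise an unweighted fit
#' with residual-variance errors is used. In-window points with i <= 0
#' (possible after background subtraction) are excluded and counted.
#'
#' The default window 0.015-0.07 1/Angstrom suits small globular proteins;
#' a warning is emitted when Q_max * Rg exceeds the conventional validity
#' guard of 1.3.
#'
#' @param profile A [scattering_profile()].
#' @param q_lo,q_hi Fit window, 1/Angstrom.
#' @param weighted Use di-based weights when available.
#' @return An object of class `guinier_result` with elements `rg_obs`,
#'   `rg_obs_err`, `i0`, `i0_err`, `q_lo`, `q_hi`, `n_points`,
#'   `n_excluded`, `q_rg_max`, `residuals` (standardized, of ln I),
#'   `covariance` (2x2 of ln I(0) and Rg^2), `weighted`, `label`,
#'   `concentration`.
#' @examples
#' q <- seq(0.015, 0.07, length.out = 30)
#' p <- scattering_profile(q, 7.3 * exp(-q^2 * 169 / 3))
#' guinier_fit(p)
#' @export
guinier_fit <- function(profile, q_lo = 0.015, q_hi = 0.07,
                        weighted = TRUE) {
  stopifnot(inherits(profile, "sas_profile"))
  if (!(q_lo < q_hi)) stop("q_lo must be < q_hi", call. = FALSE)
  inwin <- profile$q >= q_lo & profile$q <= q_hi
  pos <- inwin & profile$i > 0
  n_excluded <- sum(inwin) - sum(pos)
  if (sum(pos) < 5L) {
    stop(sprintf(
      "guinier_fit needs >= 5 usable points in [%g, %g]; found %d",
      q_lo, q_hi, sum(pos)), call. = FALSE)
  }
  q <- profile$q[pos]; i <- profile$i[pos]; di <- profile$di[pos]
  use_w <- isTRUE(weighted) && profile$has_di && all(di > 0)
  if (isTRUE(weighted) && !use_w) {
    message("guinier_fit: no usable uncertainties; using unweighted fit")
  }
  sig <- if (use_w) di / i else NULL
  fit <- .wls_line(q^2, log(i), sigma = sig)
  if (fit$slope >= 0) {
    stop("no Guinier decay: fitted slope of ln I vs Q^2 is >= 0",
         call. = FALSE)
  }
  rg2 <- -3 * fit$slope
  rg <- sqrt(rg2)
  rg2_err <- 3 * sqrt(fit$cov[2L, 2L])
  rg_err <- rg2_err / (2 * rg)
  i0 <- exp(fit$intercept)
  i0_err <- i0 * sqrt(fit$cov[1L, 1L])
  ## covariance of (ln I0, Rg^2): linear map (1, 0; 0, -3)
  J <- diag(c(1, -3))
  cov2 <- J %*% fit$cov %*% t(J)
  q_rg_max <- q_hi * rg
  if (q_rg_max > 1.3) {
    warning(sprintf(
      "Q_max * Rg = %.2f exceeds the Guinier validity guard of 1.3",
      q_rg_max), call. = FALSE)
  }
  structure(
    list(rg_obs = rg, rg_obs_err = rg_err, i0 = i0, i0_err = i0_err,
         q_lo = q_lo, q_hi = q_hi, n_points = length(q),
         n_excluded = n_excluded, q_rg_max = q_rg_max,
         residuals = fit$std_residuals, covariance = cov2,
         weighted = use_w, label = profile$label,
         concentration = profile$concentration),
    class = "guinier_result"
  )
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "<guinier_result> Rg,obs = %.3f +/- %.3f Ang, I(0) = %.4g +/- %.2g\n",
    x$rg_obs, x$rg_obs_err, x$i0, x$i0_err))
  cat(sprintf("  window [%g, %g] 1/Ang, %d points (%d excluded), Qmax*Rg = %.2f, %s\n",
              x$q_lo, x$q_hi, x$n_points, x$n_excluded, x$q_rg_max,
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Guinier-window sensitivity sweep
#'
#' Repeats [guinier_fit()] over every (lo, hi) pair from the supplied
#' grids, recording the fitted values and flagging windows whose
#' preconditions fail instead of aborting. The spread (max - min) of
#' Rg,obs across valid windows, a standard robustness diagnostic, is
#' attached as an attribute.
#'
#' @param profile A `sas_profile`.
#' @param q_lo_grid,q_hi_grid Candidate window edges, 1/Angstrom.
#' @param weighted Passed to [guinier_fit()].
#' @return A data frame (class `guinier_sweep`) with one row per window:
#'   `q_lo`, `q_hi`, `ok`, `rg_obs`, `rg_obs_err`, `i0`, `i0_err`,
#'   `n_points`, `q_rg_max`, `note`; attribute `rg_spread`.
#' @export
window_sweep <- function(profile, q_lo_grid, q_hi_grid, weighted = TRUE) {
  stopifnot(inherits(profile, "sas_profile"))
  if (length(q_lo_grid) == 0L || length(q_hi_grid) == 0L) {
    stop("window grids must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(q_lo = q_lo_grid, q_hi = q_hi_grid)
  grid <- grid[grid$q_lo < grid$q_hi, , drop = FALSE]
  if (nrow(grid) == 0L) stop("no window has q_lo < q_hi", call. = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    lo <- grid$q_lo[k]; hi <- grid$q_hi[k]
    r <- tryCatch(
      suppressWarnings(guinier_fit(profile, lo, hi, weighted = weighted)),
      error = function(e) e)
    if (inherits(r, "error")) {
      data.frame(q_lo = lo, q_hi = hi, ok = FALSE, rg_obs = NA_real_,
                 rg_obs_err = NA_real_, i0 = NA_real_, i0_err = NA_real_,
                 n_points = NA_integer_, q_rg_max = NA_real_,
                 note = conditionMessage(r))
    } else {
      data.frame(q_lo = lo, q_hi = hi, ok = TRUE, rg_obs = r$rg_obs,
                 rg_obs_err = r$rg_obs_err, i0 = r$i0, i0_err = r$i0_err,
                 n_points = r$n_points, q_rg_max = r$q_rg_max, note = "")
    }
  })
  out <- do.call(rbind, rows)
  valid <- out$rg_obs[out$ok]
  attr(out, "rg_spread") <- if (length(valid)) max(valid) - min(valid)
                            else NA_real_
  class(out) <- c("guinier_sweep", "data.frame")
  out
}

#' Residual diagnostics for a Guinier fit
#'
#' Summarizes the standardized ln-I residuals: a Wald-Wolfowitz runs test
#' on the residual signs (randomness about zero), the residual mean, and a
#' "smile" flag. The smile shape -- both window ends systematically above
#' the fit and the centre below, beyond one standard error -- is the
#' classic qualitative signature of aggregates contaminating a Guinier
#' region.
#'
#' @param result A `guinier_result` with at least 5 residuals.
#' @return A list with `runs_p` (normal-approximation p-value, `NA` when
#'   degenerate), `mean`, `smile` (logical), `degenerate` (logical; all
#'   residuals zero or single-signed).
#' @export
residual_diagnostics <- function(result) {
  stopifnot(inherits(result, "guinier_result"))
  r <- result$residuals
  if (length(r) < 5L) {
    stop("need >= 5 residuals for diagnostics", call. = FALSE)
  }
  s <- sign(r[r != 0])
  degenerate <- length(s) == 0L || all(s > 0) || all(s < 0)
  runs_p <- NA_real_
  if (!degenerate) {
    n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
    runs <- 1L + sum(s[-1L] != s[-length(s)])
    mu <- 1 + 2 * n1 * n2 / n
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    runs_p <- if (v > 0) 2 * stats::pnorm(-abs(runs - mu) / sqrt(v)) else NA_real_
  }
  ## thirds of the window: ends vs centre, each mean vs its standard error
  k <- length(r)
  b <- floor(k / 3)
  lo <- r[seq_len(b)]
  hi <- r[seq.int(k - b + 1L, k)]
  mid <- r[seq.int(b + 1L, k - b)]
  ## residuals are standardized, so the mean of m of them has se 1/sqrt(m)
  zmean <- function(x) mean(x) * sqrt(length(x))
  smile <- zmean(lo) > 1 && zmean(hi) > 1 && zmean(mid) < -1
  list(runs_p = runs_p, mean = mean(r), smile = smile,
       degenerate = degenerate)
}
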