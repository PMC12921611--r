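#' Construct a reduced 1D scattering profile
#'
#' A `sas_profile` holds one reduced small-angle scattering curve: the
#' momentum-transfer grid Q (in inverse Angstrom), the scattered intensity
#' I(Q) in arbitrary but internally consistent units, and the 1-sigma
#' intensity uncertainties.
#'
#' @param q Momentum transfer magnitudes, 1/Angstrom. Must be positive; if
#'   not strictly increasing the points are re-sorted with a warning.
#' @param i Scattered intensity, same length as `q`.
#' @param di 1-sigma uncertainties of `i` (same units). `NULL` means no
#'   uncertainties are available; a zero sentinel is stored and the profile
#'   is flagged accordingly.
#' @param label Free-text label for the curve.
#' @param concentration Mass concentration in mg/mL, or `NA` if unknown.
#' @return An object of class `sas_profile`: a list with elements `q`, `i`,
#'   `di`, `label`, `concentration`, `has_di` and `meta`.
#' @examples
#' p <- scattering_profile(q = seq(0.01, 0.1, by = 0.01),
#'                         i = exp(-seq(0.01, 0.1, by = 0.01)^2 * 169 / 3))
#' @export
scattering_profile <- function(q, i, di = NULL, label = "",
                               concentration = NA_real_) {
  q <- as.numeric(q); i <- as.numeric(i)
  if (length(q) < 3L) {
    stop("a profile needs at least 3 points", call. = FALSE)
  }
  if (length(i) != length(q)) {
    stop("`q` and `i` must have equal length", call. = FALSE)
  }
  has_di <- !is.null(di)
  di <- if (has_di) as.numeric(di) else rep(0, length(q))
  if (length(di) != length(q)) {
    stop("`di` must match the length of `q`", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(!is.finite(i)) || any(!is.finite(di))) {
    stop("q, i, di must be finite", call. = FALSE)
  }
  if (any(q <= 0)) stop("all q must be > 0", call. = FALSE)
  if (any(di < 0)) stop("di must be >= 0", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE)) {
    if (anyDuplicated(q)) stop("duplicate q values", call. = FALSE)
    warning("q not strictly increasing; re-sorting rows", call. = FALSE)
    o <- order(q)
    q <- q[o]; i <- i[o]; di <- di[o]
  }
  structure(
    list(q = q, i = i, di = di, label = as.character(label)[1L],
         concentration = as.numeric(concentration)[1L],
         has_di = has_di, meta = list()),
    class = "sas_profile"
  )
}

#' @export
print.sas_profile <- function(x, ...) {
  cat(sprintf(
    "<sas_profile> %s: %d points, Q in [%g, %g] 1/Ang%s%s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$q), min(x$q), max(x$q),
    if (!x$has_di) ", no uncertainties" else "",
    if (is.finite(x$concentration))
      sprintf(", c = %g mg/mL", x$concentration) else ""
  ))
  if (!is.null(x$meta$background)) {
    cat(sprintf("  background subtracted: %g (window %g-%g)\n",
                x$meta$background, x$meta$background_window[1L],
                x$meta$background_window[2L]))
  }
  invisible(x)
}

#' @export
length.sas_profile <- function(x) length(x$q)

#' Read a reduced 1D scattering profile from a delimited ASCII file
#'
#' Accepts the common reduced-SAS ASCII dialects: whitespace- or
#' comma-delimited numeric columns in the order Q, I, dI, (dQ), with `#` or
#' `;` comment prefixes. A fourth dQ column is parsed but ignored (no
#' resolution smearing is performed). Rows containing non-finite values are
#' dropped with a message giving the count.
#'
#' @param path Path to the file.
#' @param q_unit Unit of the Q column: `"A^-1"` (default) or `"nm^-1"`
#'   (values are rescaled by 0.1 on read). No unit auto-detection is
#'   attempted.
#' @param label Label for the profile; defaults to the file name.
#' @param concentration Optional mass concentration in mg/mL.
#' @return A [scattering_profile()] object. Two-column files yield a
#'   profile flagged as having no uncertainties.
#' @export
read_profile <- function(path, q_unit = c("A^-1", "nm^-1"),
                         label = basename(path),
                         concentration = NA_real_) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#;]|$)", raw)
  body <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(body) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(gsub(",", " ", body)), "\\s+")
  ncol <- vapply(fields, length, integer(1L))
  if (any(ncol < 2L)) {
    bad <- which(ncol < 2L)[1L]
    stop(sprintf("cannot parse %s: line %d has fewer than 2 columns",
                 path, lineno[bad]), call. = FALSE)
  }
  nc <- min(ncol)
  if (nc > 4L) nc <- 4L
  mat <- matrix(NA_real_, nrow = length(fields), ncol = nc)
  for (j in seq_len(nc)) {
    col <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", j)))
    if (all(is.na(col))) {
      bad <- 1L
      stop(sprintf("cannot parse %s: line %d, column %d is not numeric",
                   path, lineno[bad], j), call. = FALSE)
    }
    mat[, j] <- col
  }
  finite <- rowSums(!is.finite(mat[, seq_len(min(nc, 3L)), drop = FALSE])) == 0
  ndrop <- sum(!finite)
  if (ndrop > 0L) {
    message(sprintf("read_profile: dropped %d row(s) with non-finite values",
                    ndrop))
    mat <- mat[finite, , drop = FALSE]
  }
  if (nrow(mat) < 3L) {
    stop("fewer than 3 usable rows in ", path, call. = FALSE)
  }
  q <- mat[, 1L]
  if (q_unit == "nm^-1") q <- q * 0.1
  di <- if (nc >= 3L) mat[, 3L] else NULL
  p <- scattering_profile(q, mat[, 2L], di, label = label,
                          concentration = concentration)
  if (nc >= 4L) p$meta$dq <- mat[, 4L][order(mat[, 1L])]
  p$meta$source <- path
  p
}

#' Write a profile as 3-column ASCII
#'
#' Writes the `# Q I dI` dialect read back by [read_profile()].
#'
#' @param profile A `sas_profile`.
#' @param path Output path.
#' @param digits Significant digits for formatting.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, digits = 10L) {
  stopifnot(inherits(profile, "sas_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", profile$label), con)
  writeLines("# Q I dI", con)
  writeLines(sprintf("%.*g %.*g %.*g", digits, profile$q, digits,
                     profile$i, digits, profile$di), con)
  invisible(path)
}

#' Subtract a flat background estimated from a high-Q window
#'
#' The mean intensity over `[window_lo, window_hi]` is subtracted from the
#' whole curve; the uncertainties are unchanged and the subtracted constant
#' is recorded in the profile metadata. The defaults follow standard SANS
#' practice of averaging the flat incoherent tail, here 0.35-0.45
#' 1/Angstrom.
#'
#' @param profile A `sas_profile`.
#' @param window_lo,window_hi Averaging window in 1/Angstrom; must overlap
#'   at least 3 data points.
#' @return A copy of `profile` with the background removed.
#' @export
subtract_background <- function(profile, window_lo = 0.35,
                                window_hi = 0.45) {
  stopifnot(inherits(profile, "sas_profile"))
  if (!(window_lo < window_hi)) {
    stop("window_lo must be < window_hi", call. = FALSE)
  }
  if (window_lo > max(profile$q) || window_hi < min(profile$q)) {
    stop(sprintf(
      "background window [%g, %g] lies outside the data range [%g, %g]",
      window_lo, window_hi, min(profile$q), max(profile$q)), call. = FALSE)
  }
  sel <- profile$q >= window_lo & profile$q <= window_hi
  if (sum(sel) < 3L) {
    stop("background window overlaps fewer than 3 points", call. = FALSE)
  }
  bg <- mean(profile$i[sel])
  out <- profile
  out$i <- profile$i - bg
  out$meta$background <- bg
  out$meta$background_window <- c(window_lo, window_hi)
  out
}

#' Describe a concentration series
#'
#' A manifest maps profile identifiers to mass concentrations and carries
#' the solute constants needed downstream: the molecular weight (used for
#' number densities), the protein mass density (used for volume fractions)
#' and the temperature.
#'
#' @param entries A data frame with columns `id` (profile label or file
#'   path) and `c_mg_per_mL` (mass concentration, mg/mL).
#' @param molecular_weight Solute molecular weight, g/mol.
#' @param mass_density Solute mass density, g/cm^3. The default 1.46 is
#'   appropriate for a small protein such as lysozyme.
#' @param temperature Absolute temperature, K.
#' @return An object of class `sas_manifest`.
#' @export
series_manifest <- function(entries, molecular_weight,
                            mass_density = 1.46, temperature = 298.15) {
  if (!is.data.frame(entries) ||
      !all(c("id", "c_mg_per_mL") %in% names(entries))) {
    stop("`entries` must be a data frame with columns id, c_mg_per_mL",
         call. = FALSE)
  }
  cc <- as.numeric(entries$c_mg_per_mL)
  if (nrow(entries) < 3L) {
    stop("a concentration series needs >= 3 entries ",
         "(two-stage linear fits downstream)", call. = FALSE)
  }
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    stop("all concentrations must be finite and > 0", call. = FALSE)
  }
  if (anyDuplicated(cc)) {
    stop("concentrations must be distinct", call. = FALSE)
  }
  if (anyDuplicated(entries$id)) {
    stop("duplicate profile ids in manifest", call. = FALSE)
  }
  .assert_scalar_pos(molecular_weight, "molecular_weight")
  .assert_scalar_pos(mass_density, "mass_density")
  .assert_scalar_pos(temperature, "temperature")
  structure(
    list(entries = data.frame(id = as.character(entries$id),
                              c_mg_per_mL = cc),
         molecular_weight = molecular_weight,
         mass_density = mass_density,
         temperature = temperature),
    class = "sas_manifest"
  )
}

#' Read a series manifest from a plain-text file
#'
#' The format is line-oriented: lines of the form `key = value` set the
#' global constants (`molecular_weight_Da`, `mass_density_g_per_cm3`,
#' `temperature_K`), all other non-comment lines are `<file> <c_mg_per_mL>`
#' pairs (whitespace- or comma-delimited). `#` and `;` start comments.
#'
#' @param path Path to the manifest file.
#' @return A [series_manifest()] object.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*([#;]|$)", raw)]
  keys <- list()
  ids <- character(); conc <- numeric()
  for (ln in raw) {
    if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      keys[[trimws(kv[1L])]] <- trimws(paste(kv[-1L], collapse = "="))
    } else {
      f <- strsplit(trimws(gsub(",", " ", ln)), "\\s+")[[1L]]
      if (length(f) < 2L) {
        stop("cannot parse manifest line: ", ln, call. = FALSE)
      }
      ids <- c(ids, f[1L])
      conc <- c(conc, suppressWarnings(as.numeric(f[2L])))
    }
  }
  need <- "molecular_weight_Da"
  if (is.null(keys[[need]])) {
    stop("manifest is missing the key molecular_weight_Da", call. = FALSE)
  }
  series_manifest(
    data.frame(id = ids, c_mg_per_mL = conc),
    molecular_weight = as.numeric(keys[["molecular_weight_Da"]]),
    mass_density = if (!is.null(keys[["mass_density_g_per_cm3"]]))
      as.numeric(keys[["mass_density_g_per_cm3"]]) else 1.46,
    temperature = if (!is.null(keys[["temperature_K"]]))
      as.numeric(keys[["temperature_K"]]) else 298.15
  )
}

#' Assemble a validated, ordered concentration series
#'
#' Matches profiles to manifest entries by label, annotates each with its
#' mass concentration, number density and volume fraction, and returns the
#' series sorted by ascending concentration.
#'
#' @param manifest A [series_manifest()].
#' @param profiles A list of `sas_profile` objects whose labels (or list
#'   names) match the manifest `id` column.
#' @return An object of class `sas_series`: list with `profiles` (sorted),
#'   `manifest`, and a summary data frame `table` with columns `id`, `c`,
#'   `n` (1/mL) and `phi`.
#' @export
build_series <- function(manifest, profiles) {
  stopifnot(inherits(manifest, "sas_manifest"))
  if (!is.list(profiles) ||
      !all(vapply(profiles, inherits, logical(1L), "sas_profile"))) {
    stop("`profiles` must be a list of sas_profile objects", call. = FALSE)
  }
  labels <- vapply(profiles, function(p) p$label, character(1L))
  if (!is.null(names(profiles)) && all(nzchar(names(profiles)))) {
    labels <- names(profiles)
  }
  ids <- manifest$entries$id
  idx <- match(ids, labels)
  if (anyDuplicated(labels[!is.na(match(labels, ids))])) {
    stop("manifest id resolves to more than one profile", call. = FALSE)
  }
  if (any(is.na(idx))) {
    stop("manifest entries without a matching profile: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  o <- order(manifest$entries$c_mg_per_mL)
  cc <- manifest$entries$c_mg_per_mL[o]
  idx <- idx[o]
  ann <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    p <- profiles[[idx[k]]]
    p$concentration <- cc[k]
    p$meta$n_per_mL <- number_density(cc[k], manifest$molecular_weight)
    p$meta$phi <- volume_fraction(cc[k], manifest$mass_density)
    ann[[k]] <- p
  }
  structure(
    list(profiles = ann, manifest = manifest,
         table = data.frame(
           id = ids[o], c = cc,
           n = vapply(ann, function(p) p$meta$n_per_mL, numeric(1L)),
           phi = vapply(ann, function(p) p$meta$phi, numeric(1L)))),
    class = "sas_series"
  )
}

#' @export
print.sas_series <- function(x, ...) {
  cat(sprintf("<sas_series> %d profiles, M_W = %g g/mol, rho = %g g/cm^3\n",
              length(x$profiles), x$manifest$molecular_weight,
              x$manifest$mass_density))
  print(x$table, row.names = FALSE)
  invisible(x)
}
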