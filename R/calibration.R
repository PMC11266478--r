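#' Field reference panel
#'
#' Per-band reflectance factor of the field standard used for reflectance
#' calibration. Spectralon-type panels are near-Lambertian with a nominal
#' reflectance of about 0.99 across the visible-NIR range.
#'
#' @param rho_s per-band reflectance factor, strictly positive and <= 1.
#'   A scalar is recycled across bands at calibration time.
#' @return object of class `reference_panel`.
#' @export
reference_panel <- function(rho_s = 0.99) {
  rho_s <- as.numeric(rho_s)
  if (any(rho_s <= 0) || any(rho_s > 1)) stop("panel reflectance must be in (0, 1]")
  structure(list(rho_s = rho_s), class = "reference_panel")
}

#' Target/panel radiance pair
#'
#' The reflected spectral radiant flux of the target (taken at time t1) and
#' the incident-proxy flux measured off the reference panel (taken at t0).
#' Under field protocols the two measurements should be fewer than 15
#' minutes apart so illumination can be assumed stable; a larger gap raises
#' a warning, not an error.
#'
#' @param phi_r per-band reflected flux of the target.
#' @param phi_i per-band incident-proxy flux from the panel; strictly positive.
#' @param dt_minutes |t0 - t1| in minutes.
#' @return object of class `radiance_pair`.
#' @export
radiance_pair <- function(phi_r, phi_i, dt_minutes = 0) {
  phi_r <- as.numeric(phi_r); phi_i <- as.numeric(phi_i)
  if (length(phi_r) != length(phi_i)) stop("phi_r and phi_i must share a band grid")
  bad <- which(phi_i <= 0)
  if (length(bad)) {
    stop(sprintf("incident flux must be strictly positive; offending band(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (dt_minutes >= 15) {
    warning(sprintf("panel and target measurements %.1f min apart (>= 15 min); illumination stability is doubtful",
                    dt_minutes))
  }
  structure(list(phi_r = phi_r, phi_i = phi_i, dt_minutes = dt_minutes),
            class = "radiance_pair")
}

#' Reference-panel reflectance calibration
#'
#' Converts target radiance to reflectance against a field standard,
#' correcting for the panel's non-Lambertian behaviour:
#' \deqn{\rho_{corr}(\lambda) = \Phi_r(\lambda, t_1)\,\rho_s(\lambda) / \Phi_i(\lambda, t_0)}
#' i.e. the panel reflectance factor is applied to the incident flux before
#' ratioing with the reflected radiance.
#'
#' @param pair a [radiance_pair].
#' @param panel a [reference_panel]; a scalar `rho_s` is recycled per band.
#' @return per-band corrected reflectance.
#' @examples
#' p <- radiance_pair(phi_r = rep(2, 4), phi_i = rep(4, 4))
#' calibrate_reflectance(p, reference_panel(0.99)) # 0.495 on every band
#' @export
calibrate_reflectance <- function(pair, panel = reference_panel()) {
  stopifnot(inherits(pair, "radiance_pair"), inherits(panel, "reference_panel"))
  rho_s <- panel$rho_s
  if (length(rho_s) == 1) rho_s <- rep(rho_s, length(pair$phi_r))
  if (length(rho_s) != length(pair$phi_r)) {
    stop("panel reflectance length does not match the band grid")
  }
  pair$phi_r * rho_s / pair$phi_i
}

#' NDVI-threshold vegetation mask
#'
#' Programmatic replacement for manual background masking: keeps pixels
#' whose NDVI exceeds a threshold. Water, soil and calibration-panel pixels
#' have flat or blue-shifted spectra with NDVI well below typical canopy
#' values, so a threshold around 0.4 excludes them.
#'
#' @param cube reflectance [hsi_cube].
#' @param red_nm,nir_nm band targets for the NDVI ratio (defaults 670/800 nm).
#' @param threshold NDVI cut in (-1, 1); default 0.4.
#' @return logical M x N matrix, `TRUE` = vegetation pixel kept.
#' @export
vegetation_mask <- function(cube, red_nm = 670, nir_nm = 800, threshold = 0.4) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (cube$kind != "reflectance") stop("vegetation_mask expects a reflectance cube")
  if (threshold <= -1 || threshold >= 1) stop("threshold must lie in (-1, 1)")
  w <- as.numeric(cube$axis)
  if (red_nm < min(w) || red_nm > max(w) || nir_nm < min(w) || nir_nm > max(w)) {
    stop("requested red/NIR wavelengths fall outside the spectral axis")
  }
  nd <- ndvi(cube, red_nm = red_nm, nir_nm = nir_nm)
  keep <- !is.na(nd) & nd > threshold
  keep
}

#' Representative spectrum of the kept pixels
#'
#' Band-wise summary of the masked pixels of a scene; the default strategy
#' is the mean spectrum, with the per-band standard deviation reported
#' alongside. `strategy = "median"` substitutes the pixelwise median.
#'
#' @param cube an [hsi_cube].
#' @param mask logical M x N matrix; at least one `TRUE` pixel.
#' @param strategy `"mean"` (default) or `"median"`.
#' @return list with numeric vectors `mean` (or median, under the same
#'   name), `sd`, and the number of pixels used `n`.
#' @export
representative_spectrum <- function(cube, mask, strategy = c("mean", "median")) {
  stopifnot(inherits(cube, "hsi_cube"))
  strategy <- match.arg(strategy)
  d <- dim(cube$values)
  if (!is.logical(mask) || nrow(mask) != d[1] || ncol(mask) != d[2]) {
    stop("mask must be a logical matrix matching the cube's spatial dims")
  }
  n <- sum(mask)
  if (n == 0) stop("mask keeps no pixels; cannot extract a representative spectrum")
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  kept <- flat[as.vector(mask), , drop = FALSE]
  ctr <- if (strategy == "mean") colMeans(kept) else apply(kept, 2, stats::median)
  sdv <- if (n > 1) apply(kept, 2, stats::sd) else rep(0, d[3])
  list(mean = ctr, sd = sdv, n = n)
}

#' Pixel spectra as a samples x bands matrix
#'
#' Convenience accessor: rows are the masked pixels (column-major pixel
#' order), columns the bands.
#'
#' @param cube an [hsi_cube].
#' @param mask optional logical matrix; default keeps every pixel.
#' @return numeric matrix, pixels x bands.
#' @export
pixel_spectra <- function(cube, mask = NULL) {
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  if (is.null(mask)) flat else flat[as.vector(mask), , drop = FALSE]
}
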