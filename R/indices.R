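#' Vegetation indices
#'
#' Named-band ratio indices computed either per pixel on an [hsi_cube]
#' (returning an M x N map) or on a single spectrum (returning a scalar).
#' Bands are resolved to the nearest axis entry via [nearest_band()]; by
#' default a single band instantiates each named wavelength, with an
#' optional +/- 1-band average (`band_avg = TRUE`).
#'
#' * NDVI = (rho_NIR - rho_RED) / (rho_NIR + rho_RED), defaults 800/670 nm.
#' * PRI  = (rho_531 - rho_570) / (rho_531 + rho_570).
#' * PSRI = (rho_680 - rho_500) / rho_750.
#'
#' Pixels where the denominator vanishes are returned as `NA` (flagged
#' undefined), never silently zero.
#'
#' @param x an [hsi_cube], or a numeric spectrum (then `wavelengths` is
#'   required).
#' @param red_nm,nir_nm NDVI band targets in nm.
#' @param wavelengths spectral axis for the default (vector) method.
#' @param band_avg average each named band with its two neighbours.
#' @return matrix (cube input) or scalar (spectrum input).
#' @examples
#' ndvi(c(0.1, 0.5), wavelengths = c(670, 800)) # 0.667
#' @name vegetation_indices
NULL

band_value <- function(flat, axis, target_nm, band_avg = FALSE) {
  i <- nearest_band(axis, target_nm)
  if (!band_avg) return(flat[, i])
  idx <- intersect(c(i - 1L, i, i + 1L), seq_len(n_bands(axis)))
  rowMeans(flat[, idx, drop = FALSE])
}

index_input <- function(x, wavelengths) {
  if (inherits(x, "hsi_cube")) {
    d <- dim(x$values)
    list(flat = matrix(x$values, d[1] * d[2], d[3]), axis = x$axis, dims = d[1:2])
  } else {
    if (is.null(wavelengths)) stop("a spectrum input needs its `wavelengths`")
    if (length(x) != length(as.numeric(wavelengths))) {
      stop("spectrum and wavelengths lengths differ")
    }
    list(flat = matrix(as.numeric(x), 1), axis = spectral_axis(wavelengths),
         dims = NULL)
  }
}

ratio_index <- function(num, den, dims) {
  out <- ifelse(abs(den) < .Machine$double.eps * 4, NA_real_, num / den)
  if (!is.null(dims)) matrix(out, dims[1], dims[2]) else as.numeric(out)
}

#' @rdname vegetation_indices
#' @export
ndvi <- function(x, red_nm = 670, nir_nm = 800, wavelengths = NULL,
                 band_avg = FALSE) {
  inp <- index_input(x, wavelengths)
  red <- band_value(inp$flat, inp$axis, red_nm, band_avg)
  nir <- band_value(inp$flat, inp$axis, nir_nm, band_avg)
  ratio_index(nir - red, nir + red, inp$dims)
}

#' @rdname vegetation_indices
#' @export
pri <- function(x, wavelengths = NULL, band_avg = FALSE) {
  inp <- index_input(x, wavelengths)
  r531 <- band_value(inp$flat, inp$axis, 531, band_avg)
  r570 <- band_value(inp$flat, inp$axis, 570, band_avg)
  ratio_index(r531 - r570, r531 + r570, inp$dims)
}

#' @rdname vegetation_indices
#' @export
psri <- function(x, wavelengths = NULL, band_avg = FALSE) {
  inp <- index_input(x, wavelengths)
  r680 <- band_value(inp$flat, inp$axis, 680, band_avg)
  r500 <- band_value(inp$flat, inp$axis, 500, band_avg)
  r750 <- band_value(inp$flat, inp$axis, 750, band_avg)
  ratio_index(r680 - r500, r750, inp$dims)
}

#' Mean spectral profile and coefficient of variation
#'
#' Band-wise mean and coefficient of variation (sample sd / mean, reported
#' in percent) over a set of spectra — the standard summary of within-library
#' spectral variability.
#'
#' @param spectra samples x bands numeric matrix, >= 2 rows.
#' @return list with `mean` and `cv_pct` per band; bands with zero mean get
#'   `NA` CV and a warning.
#' @examples
#' mean_cv_profile(rbind(c(0.2, 0.3), c(0.4, 0.3)))
#' @export
mean_cv_profile <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2) stop("need at least 2 spectra for a CV profile")
  mu <- colMeans(spectra)
  sdv <- apply(spectra, 2, stats::sd)
  cv <- rep(NA_real_, length(mu))
  ok <- abs(mu) > .Machine$double.eps * 4
  if (!all(ok)) warning("zero-mean band(s): CV undefined there, returned as NA")
  cv[ok] <- 100 * sdv[ok] / mu[ok]
  list(mean = mu, cv_pct = cv)
}
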