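#' Spectral axis
#'
#' An ordered vector of band-centre wavelengths in nanometres. The axis is
#' the contract between every named-wavelength formula (vegetation indices,
#' calibration, masking) and the cube it is paired with.
#'
#' @param wavelengths_nm numeric vector of band centres in nm, strictly
#'   increasing.
#' @return An object of class `spectral_axis` (a numeric vector).
#' @examples
#' ax <- spectral_axis(seq(400, 1000, length.out = 204))
#' n_bands(ax)
#' @export
spectral_axis <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) == 0) stop("spectral axis must contain at least one band")
  if (anyNA(w) || any(!is.finite(w))) stop("wavelengths must be finite")
  if (is.unsorted(w, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  structure(w, class = "spectral_axis")
}

#' @rdname spectral_axis
#' @param axis a `spectral_axis`.
#' @export
n_bands <- function(axis) length(unclass(axis))

#' @export
print.spectral_axis <- function(x, ...) {
  w <- unclass(x)
  cat(sprintf("<spectral_axis> %d bands, %.1f-%.1f nm\n",
              length(w), min(w), max(w)))
  invisible(x)
}

#' Find the band nearest a target wavelength
#'
#' Returns the index of the band whose centre is closest to `target_nm`;
#' ties resolve to the lower index. A warning is raised when the nearest
#' band is more than 10 nm away, since a named-wavelength index computed
#' that far off-band is suspect.
#'
#' @param axis a [spectral_axis] (or plain numeric wavelength vector).
#' @param target_nm target wavelength in nm.
#' @param warn_tol_nm distance beyond which a warning is raised (default 10).
#' @return integer band index.
#' @examples
#' ax <- spectral_axis(seq(400, 1000, by = 3))
#' nearest_band(ax, 531)
#' @export
nearest_band <- function(axis, target_nm, warn_tol_nm = 10) {
  w <- as.numeric(axis)
  if (length(w) == 0) stop("empty spectral axis")
  d <- abs(w - target_nm)
  i <- which.min(d) # which.min returns first (lower) index on ties
  if (d[i] > warn_tol_nm) {
    warning(sprintf("nearest band to %.1f nm is %.1f nm away (band %d at %.1f nm)",
                    target_nm, d[i], i, w[i]))
  }
  i
}
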