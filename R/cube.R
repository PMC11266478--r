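#' Hyperspectral cube
#'
#' The universal carrier between pipeline stages: an M x N x D array of
#' per-pixel spectra plus its spectral axis. `kind` records whether values
#' are at-sensor radiance (arbitrary units) or reflectance (unitless,
#' nominally 0-1 with tolerance to ~1.5 for specular glint).
#'
#' @param values M x N x D numeric array (rows x cols x bands).
#' @param wavelengths_nm spectral axis ([spectral_axis] or numeric vector),
#'   length D.
#' @param kind `"reflectance"` or `"radiance"`.
#' @param metadata named list of free-form acquisition metadata strings.
#' @return object of class `hsi_cube`: list with elements `values`, `axis`,
#'   `kind`, `metadata`.
#' @examples
#' cube <- hsi_cube(array(0.3, c(4, 4, 5)), seq(400, 800, 100))
#' dim(cube$values)
#' @export
hsi_cube <- function(values, wavelengths_nm,
                     kind = c("reflectance", "radiance"),
                     metadata = list()) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("values must be an M x N x D array")
  }
  if (any(dim(values) == 0)) stop("cube must contain at least one pixel and band")
  axis <- if (inherits(wavelengths_nm, "spectral_axis")) wavelengths_nm
          else spectral_axis(wavelengths_nm)
  if (dim(values)[3] != n_bands(axis)) {
    stop(sprintf("cube depth (%d) does not match axis bands (%d)",
                 dim(values)[3], n_bands(axis)))
  }
  if (anyNA(values) || any(!is.finite(values))) stop("cube values must be finite")
  if (any(values < 0)) stop("cube values must be nonnegative")
  if (kind == "reflectance" && any(values > 1.5)) {
    stop("reflectance values above 1.5 (specular-glint tolerance) found; is this radiance?")
  }
  structure(list(values = values, axis = axis, kind = kind, metadata = metadata),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%s), %.0f-%.0f nm\n",
              d[1], d[2], d[3], x$kind, min(x$axis), max(x$axis)))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

#' Label map for a hyperspectral scene
#'
#' Integer per-pixel labels; 0 marks background/unlabelled pixels, values
#' 1..Z index treatment classes.
#'
#' @param labels M x N integer matrix in 0..Z.
#' @param class_names character vector of Z class names.
#' @return object of class `label_map`.
#' @export
label_map <- function(labels, class_names) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (anyNA(labels) || any(labels < 0)) stop("labels must be nonnegative integers")
  z <- length(class_names)
  if (max(labels) > z) stop("label exceeds number of class names")
  structure(list(labels = labels, class_names = as.character(class_names)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d classes, %d labelled pixels\n",
              nrow(x$labels), ncol(x$labels), length(x$class_names),
              sum(x$labels > 0)))
  invisible(x)
}
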