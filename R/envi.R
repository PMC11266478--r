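#' Read an ENVI hyperspectral cube
#'
#' Reads the ASCII `.hdr` header plus the raw binary cube it describes.
#' Supported interleaves are BSQ, BIL and BIP and data types 4 (float32),
#' 5 (float64) and 12 (uint16); values are returned in band-ascending
#' (rows, cols, bands) order regardless of file interleave.
#'
#' @param header_path path to the `.hdr` file. The binary cube is looked up
#'   at the path named by the header's `data file` key, or at the header
#'   path minus its `.hdr` extension.
#' @param kind value kind of the stored cube, see [hsi_cube].
#' @return an [hsi_cube].
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path, kind = c("reflectance", "radiance")) {
  kind <- match.arg(kind)
  hdr <- parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave")) {
    if (is.null(hdr[[key]])) stop(sprintf("ENVI header missing required key '%s'", key))
  }
  if (is.null(hdr[["wavelength"]])) {
    stop("ENVI header has no wavelength list; a spectral axis is required")
  }
  ns <- as.integer(hdr[["samples"]]); nl <- as.integer(hdr[["lines"]])
  nb <- as.integer(hdr[["bands"]])
  wl <- as.numeric(hdr[["wavelength"]])
  if (length(wl) != nb) {
    stop(sprintf("header declares %d bands but lists %d wavelengths", nb, length(wl)))
  }
  interleave <- tolower(hdr[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop(sprintf("unsupported interleave '%s'", interleave))
  }
  dtype <- as.integer(hdr[["data type"]])
  endian <- if (!is.null(hdr[["byte order"]]) && as.integer(hdr[["byte order"]]) == 1)
    "big" else "little"

  data_path <- hdr[["data file"]]
  if (is.null(data_path)) data_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(data_path)) stop(sprintf("ENVI data file '%s' not found", data_path))

  n_values <- ns * nl * nb
  elt_size <- switch(as.character(dtype), "4" = 4L, "5" = 8L, "12" = 2L,
                     stop(sprintf("unsupported ENVI data type %d", dtype)))
  expected <- as.numeric(n_values) * elt_size
  actual <- file.size(data_path)
  if (actual != expected) {
    stop(sprintf("file size %d does not match %d x %d x %d values of data type %d (%d bytes expected)",
                 actual, nl, ns, nb, dtype, expected))
  }
  con <- file(data_path, "rb"); on.exit(close(con))
  raw_vals <- switch(as.character(dtype),
    "4"  = readBin(con, "numeric", n = n_values, size = 4L, endian = endian),
    "5"  = readBin(con, "numeric", n = n_values, size = 8L, endian = endian),
    "12" = as.numeric(readBin(con, "integer", n = n_values, size = 2L,
                              signed = FALSE, endian = endian)))
  # file order -> (rows, cols, bands); lines are rows, samples are columns
  values <- switch(interleave,
    bsq = aperm(array(raw_vals, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(raw_vals, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(raw_vals, c(nb, ns, nl)), c(3, 2, 1)))
  meta <- hdr[setdiff(names(hdr), c("samples", "lines", "bands", "data type",
                                    "interleave", "byte order", "wavelength",
                                    "data file"))]
  hsi_cube(values, spectral_axis(wl), kind = kind, metadata = meta)
}

#' Write an ENVI hyperspectral cube
#'
#' Writes a standard ENVI `.hdr` ASCII header (samples/lines/bands/data
#' type/interleave/byte order/wavelength) plus the raw binary cube.
#'
#' @param cube an [hsi_cube].
#' @param header_path output `.hdr` path; the binary cube is written to the
#'   same path minus the `.hdr` extension.
#' @param interleave one of `"bsq"` (default), `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 4 = float32 (default), 5 = float64.
#' @return `header_path`, invisibly.
#' @export
write_envi <- function(cube, header_path, interleave = c("bsq", "bil", "bip"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) stop("writer supports data types 4 (float32) and 5 (float64)")
  if (!grepl("\\.hdr$", header_path)) header_path <- paste0(header_path, ".hdr")
  data_path <- sub("\\.hdr$", "", header_path)
  d <- dim(cube$values)
  wl <- as.numeric(cube$axis)

  hdr <- c(
    "ENVI",
    "description = {hsistress export}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(wl, trim = TRUE, digits = 10),
                                   collapse = ", "), "}"))
  writeLines(hdr, header_path)

  file_order <- switch(interleave,
    bsq = aperm(cube$values, c(2, 1, 3)),
    bil = aperm(cube$values, c(2, 3, 1)),
    bip = aperm(cube$values, c(3, 2, 1)))
  con <- file(data_path, "wb"); on.exit(close(con))
  writeBin(as.numeric(file_order), con,
           size = if (data_type == 4L) 4L else 8L, endian = "little")
  invisible(header_path)
}

#' Write / read a label map as a single-band ENVI integer raster
#'
#' Class names are carried in the standard ENVI `class names` header field.
#'
#' @param labels a [label_map].
#' @param header_path `.hdr` path.
#' @return `read_label_envi` returns a [label_map].
#' @export
write_label_envi <- function(labels, header_path) {
  stopifnot(inherits(labels, "label_map"))
  if (!grepl("\\.hdr$", header_path)) header_path <- paste0(header_path, ".hdr")
  data_path <- sub("\\.hdr$", "", header_path)
  m <- labels$labels
  hdr <- c(
    "ENVI",
    "description = {hsistress label map}",
    sprintf("samples = %d", ncol(m)),
    sprintf("lines = %d", nrow(m)),
    "bands = 1",
    "header offset = 0",
    "file type = ENVI Classification",
    "data type = 12",
    "interleave = bsq",
    "byte order = 0",
    sprintf("classes = %d", length(labels$class_names) + 1L),
    paste0("class names = {background, ",
           paste(labels$class_names, collapse = ", "), "}"))
  writeLines(hdr, header_path)
  con <- file(data_path, "wb"); on.exit(close(con))
  writeBin(as.integer(t(m)), con, size = 2L, endian = "little")
  invisible(header_path)
}

#' @rdname write_label_envi
#' @export
read_label_envi <- function(header_path) {
  hdr <- parse_envi_header(header_path)
  ns <- as.integer(hdr[["samples"]]); nl <- as.integer(hdr[["lines"]])
  data_path <- sub("\\.hdr$", "", header_path)
  con <- file(data_path, "rb"); on.exit(close(con))
  v <- readBin(con, "integer", n = ns * nl, size = 2L, signed = FALSE,
               endian = "little")
  cn <- hdr[["class names"]]
  if (is.null(cn)) stop("label header has no class names")
  cn <- trimws(cn)
  label_map(t(matrix(v, ns, nl)), class_names = cn[-1]) # drop background entry
}

# Parse an ENVI ASCII header into a named list; braced {} values become
# character vectors split on commas.
parse_envi_header <- function(path) {
  if (!file.exists(path)) stop(sprintf("header '%s' not found", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*ENVI", txt)) stop("not an ENVI header (missing ENVI magic)")
  out <- list()
  # braced entries (possibly multi-line)
  m <- gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1] != -1) {
    starts <- m; lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
      key <- tolower(trimws(sub("=.*$", "", piece)))
      val <- sub("^[^{]*\\{", "", piece); val <- sub("\\}\\s*$", "", val)
      out[[key]] <- trimws(strsplit(val, ",")[[1]])
    }
  }
  txt_flat <- gsub("\\{[^}]*\\}", "", txt)
  for (line in strsplit(txt_flat, "\n")[[1]]) {
    if (!grepl("=", line)) next
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(val) && !key %in% names(out)) out[[key]] <- val
  }
  out
}
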