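#' Hyperspectral cube
#'
#' An H x W x B array of nonnegative scattered-light intensities bound to a
#' wavelength grid. The canonical in-memory layout is band-last; interleave
#' (BSQ/BIL/BIP) is purely an I/O concern.
#'
#' @param data Numeric array with `dim = c(height, width, bands)`.
#' @param grid A [wavelength_grid()] with `n_samples == dim(data)[3]`.
#' @return A `hyper_cube` object.
#' @export
hyper_cube <- function(data, grid) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("cube data must be a 3-d array (rows, cols, bands)", call. = FALSE)
  stopifnot(inherits(grid, "wavelength_grid"))
  if (dim(data)[3] != grid$n_samples)
    stop("band count does not match wavelength grid", call. = FALSE)
  if (!all(is.finite(data)))
    stop("cube contains non-finite values", call. = FALSE)
  structure(list(data = data, grid = grid), class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%g..%g nm)\n",
              d[1], d[2], d[3], x$grid$start_nm, x$grid$end_nm))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

# ENVI numeric data-type codes <-> R read/write parameters
.envi_types <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE, mode = "int"),
  `2`  = list(what = "integer", size = 2L, signed = TRUE,  mode = "int"),
  `3`  = list(what = "integer", size = 4L, signed = TRUE,  mode = "int"),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE,  mode = "float"),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE,  mode = "float"),
  `12` = list(what = "integer", size = 2L, signed = FALSE, mode = "int"))

parse_envi_header <- function(header_path) {
  txt <- readChar(header_path, file.size(header_path), useBytes = TRUE)
  if (!grepl("^\\s*ENVI", txt))
    stop("not an ENVI header (missing ENVI magic)", call. = FALSE)
  txt <- sub("^\\s*ENVI", "", txt)
  # key = value pairs; brace-delimited values may span lines
  m <- gregexpr("([A-Za-z][A-Za-z0-9 _]*?)[ \t]*=[ \t]*(\\{[^}]*\\}|[^\r\n]*)",
                txt, perl = TRUE)[[1]]
  out <- list()
  for (i in seq_along(m)) {
    piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    if (startsWith(val, "{"))
      val <- trimws(gsub("[{}]", "", val))
    out[[key]] <- val
  }
  out
}

#' Read an ENVI hyperspectral cube
#'
#' Supports the plain ENVI dialect: ASCII `key = value` header plus raw
#' binary with BSQ/BIL/BIP interleave, integer or IEEE float sample types,
#' either byte order. Wavelengths are taken from the header and validated to
#' be uniform; non-uniform axes are rejected rather than resampled.
#'
#' @param header_path Path to the `.hdr` file.
#' @param data_path Path to the binary file; defaults to `header_path`
#'   without its `.hdr` extension.
#' @param grid Optional [wavelength_grid()] used when the header carries no
#'   wavelength list; a header wavelength list that disagrees is an error.
#' @return A [hyper_cube()].
#' @export
read_envi <- function(header_path, data_path = NULL, grid = NULL) {
  h <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("ENVI header missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples <- as.integer(h[["samples"]])  # width (columns)
  lines   <- as.integer(h[["lines"]])    # height (rows)
  bands   <- as.integer(h[["bands"]])
  dtype   <- .envi_types[[h[["data type"]]]]
  if (is.null(dtype))
    stop("unsupported ENVI data type: ", h[["data type"]], call. = FALSE)
  interleave <- tolower(h[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave: ", interleave, call. = FALSE)
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  offset <- if (!is.null(h[["header offset"]])) as.integer(h[["header offset"]]) else 0L

  if (is.null(data_path)) {
    data_path <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
    if (identical(data_path, header_path))
      stop("cannot derive data path from header path", call. = FALSE)
  }
  n <- samples * lines * bands
  con <- file(data_path, "rb"); on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", offset)
  v <- readBin(con, dtype$what, n = n, size = dtype$size,
               signed = dtype$signed, endian = endian)
  if (length(v) != n)
    stop("ENVI data file truncated: expected ", n, " values, got ", length(v),
         call. = FALSE)
  arr <- switch(interleave,
    # read order (fastest..slowest): bsq sample,line,band; bil sample,band,line;
    # bip band,sample,line. Canonical layout is (row, col, band).
    bsq = aperm(array(v, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(bands, samples, lines)), c(3L, 2L, 1L)))
  storage.mode(arr) <- "double"

  if (!is.null(h[["wavelength"]])) {
    wl <- as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
    if (length(wl) != bands)
      stop("header wavelength list length != bands", call. = FALSE)
    d <- diff(wl)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-6)
      stop("invalid grid: header wavelengths not uniformly increasing",
           call. = FALSE)
    gh <- wavelength_grid(wl[1], wl[length(wl)], length(wl))
    if (!is.null(grid) && !grids_equal(grid, gh))
      stop("supplied grid disagrees with header wavelengths", call. = FALSE)
    grid <- gh
  } else if (is.null(grid)) {
    stop("header has no wavelength list and no grid was supplied",
         call. = FALSE)
  }
  hyper_cube(arr, grid)
}

#' Write an ENVI hyperspectral cube
#'
#' @param cube A [hyper_cube()].
#' @param header_path Output `.hdr` path.
#' @param data_path Output binary path; defaults to `header_path` without
#'   `.hdr`.
#' @param interleave One of `"bsq"` (default), `"bil"`, `"bip"`.
#' @param data_type ENVI type code: 4 = float32 (default), 5 = float64,
#'   1/2/3/12 = integer types.
#' @return Invisibly, `c(header_path, data_path)`.
#' @export
write_envi <- function(cube, header_path, data_path = NULL,
                       interleave = c("bsq", "bil", "bip"), data_type = 4L) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  dtype <- .envi_types[[as.character(data_type)]]
  if (is.null(dtype))
    stop("unsupported ENVI data type: ", data_type, call. = FALSE)
  if (is.null(data_path)) {
    data_path <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
    if (identical(data_path, header_path))
      stop("cannot derive data path from header path", call. = FALSE)
  }
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {hsmad export}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = nm",
    sprintf("wavelength = {%s}",
            paste(format(cube$grid$values, digits = 10, trim = TRUE,
                         scientific = FALSE), collapse = ", ")))
  writeLines(hdr, header_path)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube$data, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube$data, c(3L, 2L, 1L))))
  con <- file(data_path, "wb"); on.exit(close(con))
  if (dtype$mode == "int") {
    writeBin(as.integer(round(v)), con, size = dtype$size, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = dtype$size, endian = "little")
  }
  invisible(c(header_path, data_path))
}

#' Lamp-normalize a cube by a reference spectrum
#'
#' Divides every pixel's spectrum band-wise by the lamp reference, removing
#' the illuminant's spectral profile.
#'
#' @param cube A [hyper_cube()].
#' @param ref Reference spectrum, length = band count, strictly positive.
#' @return A lamp-normalized [hyper_cube()].
#' @export
lamp_normalize <- function(cube, ref) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (length(ref) != cube$grid$n_samples)
    stop("reference length does not match cube bands", call. = FALSE)
  if (!all(is.finite(ref)) || any(ref <= 0))
    stop("invalid reference: lamp spectrum must be strictly positive",
         call. = FALSE)
  d <- dim(cube$data)
  scaled <- cube$data / rep(ref, each = d[1] * d[2])
  hyper_cube(scaled, cube$grid)
}

#' Extract the pixel-by-band matrix view of a cube
#'
#' Rows are pixels in raster (row-major) order; columns are bands.
#' @param cube A [hyper_cube()].
#' @return Matrix of dimension `(H*W) x B`.
#' @export
cube_to_matrix <- function(cube) {
  d <- dim(cube$data)
  m <- cube$data
  dim(m) <- c(d[1] * d[2], d[3])
  # column-major pixel order is (row fastest); reorder rows to raster order
  ord <- as.vector(t(matrix(seq_len(d[1] * d[2]), d[1], d[2])))
  m[ord, , drop = FALSE]
}

# raster-order row index for pixel (r, c) in an H x W image
raster_index <- function(r, c, width) (r - 1L) * width + c
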