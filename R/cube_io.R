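#' Construct a hyperspectral cube
#'
#' A `hyper_cube` is a 3-D reflectance raster (lines x samples x bands) with a
#' strictly increasing wavelength vector in nanometres and free-form metadata
#' (acquisition id, condition, imaging day, ...).
#'
#' @param values numeric array, lines x samples x bands; all values finite.
#' @param wavelengths_nm numeric vector, one wavelength per band, strictly
#'   increasing.
#' @param meta named list of free-form metadata.
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavelengths_nm, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (lines x samples x bands)")
  if (dim(values)[3] != length(wavelengths_nm))
    stop("band count (", dim(values)[3], ") does not match wavelength vector (",
         length(wavelengths_nm), ")")
  if (any(!is.finite(values))) stop("cube values must be finite")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(values = values, wavelengths_nm = as.numeric(wavelengths_nm),
                 meta = meta),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d lines x %d samples x %d bands, %.1f-%.1f nm\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

## ENVI data-type codes supported for reflectance payloads
.envi_dtypes <- data.frame(
  code = c(4L, 5L), what = c("numeric", "numeric"), size = c(4L, 8L),
  stringsAsFactors = FALSE
)

.envi_data_path <- function(header_path) {
  stem <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  for (cand in c(stem, paste0(stem, ".dat"), paste0(stem, ".img"))) {
    if (file.exists(cand) && !identical(cand, header_path)) return(cand)
  }
  stem
}

.parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1]))
    stop("not an ENVI header: ", header_path)
  body <- paste(txt[-1], collapse = "\n")
  ## join brace-delimited multi-line values before splitting into fields
  fields <- list()
  pat <- "(?s)([A-Za-z ][A-Za-z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1] == -1) stop("empty ENVI header: ", header_path)
  starts <- as.vector(m); lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    kv <- substr(body, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", kv, fixed = TRUE)
    key <- tolower(trimws(substr(kv, 1L, eq - 1L)))
    val <- trimws(substr(kv, eq + 1L, nchar(kv)))
    fields[[key]] <- val
  }
  fields
}

.envi_list <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

#' Read an ENVI cube (header + binary payload)
#'
#' Supports `bil`, `bip` and `bsq` interleaves and floating-point data types
#' (ENVI codes 4 and 5). The returned band order always matches the header's
#' wavelength list, irrespective of interleave.
#'
#' @param header_path path to the `.hdr` text header; the payload is located
#'   by dropping the extension (or `.dat`/`.img` alongside).
#' @return a [hyper_cube()].
#' @export
read_envi <- function(header_path) {
  h <- .parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header missing field(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(h[["wavelength"]]))
    stop("ENVI header has no wavelength list")
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  wl <- .envi_list(h[["wavelength"]])
  if (length(wl) != nb)
    stop("header declares ", nb, " bands but ", length(wl), " wavelengths")
  dt <- as.integer(h[["data type"]])
  row <- .envi_dtypes[.envi_dtypes$code == dt, ]
  if (!nrow(row)) stop("unsupported ENVI data type: ", dt)
  il <- tolower(trimws(h[["interleave"]]))
  if (!il %in% c("bil", "bip", "bsq")) stop("unsupported interleave: ", il)
  dpath <- .envi_data_path(header_path)
  if (!file.exists(dpath)) stop("ENVI payload not found for ", header_path)
  n <- ns * nl * nb
  if (file.size(dpath) != n * row$size)
    stop("corrupt ENVI file: payload is ", file.size(dpath),
         " bytes, header implies ", n * row$size)
  con <- file(dpath, "rb"); on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = row$size,
               endian = "little")
  vals <- switch(il,
    ## fastest-varying axis first in each layout
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3L, 2L, 1L)))
  meta <- h[setdiff(names(h), c(need, "wavelength", "byte order",
                                "header offset", "file type"))]
  hyper_cube(vals, wl, meta = meta)
}

#' Write a cube as an ENVI header + binary payload pair
#'
#' @param cube a [hyper_cube()].
#' @param path payload path; the header is written to `<path>.hdr`.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data-type code: 4 (float32, default) or 5 (float64).
#' @return invisibly, a character vector `c(header, data)` of the files
#'   written.
#' @export
write_envi <- function(cube, path, interleave = "bsq", data_type = 4L) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  if (any(d == 0L)) stop("refusing to write an empty cube")
  interleave <- tolower(interleave)
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop("unsupported interleave: ", interleave)
  row <- .envi_dtypes[.envi_dtypes$code == as.integer(data_type), ]
  if (!nrow(row)) stop("unsupported ENVI data type: ", data_type)
  nl <- d[1]; ns <- d[2]; nb <- d[3]
  v <- switch(interleave,
    bsq = aperm(cube$values, c(2L, 1L, 3L)),
    bil = aperm(cube$values, c(2L, 3L, 1L)),
    bip = aperm(cube$values, c(3L, 2L, 1L)))
  hdr_path <- paste0(path, ".hdr")
  hdr <- c(
    "ENVI",
    paste0("samples = ", ns),
    paste0("lines = ", nl),
    paste0("bands = ", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", as.integer(data_type)),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {", paste(format(cube$wavelengths_nm, trim = TRUE,
                                          digits = 12), collapse = ", "), "}")
  )
  for (k in names(cube$meta)) {
    val <- cube$meta[[k]]
    if (length(val) == 1L && (is.character(val) || is.numeric(val)))
      hdr <- c(hdr, paste0(k, " = ", val))
  }
  writeLines(hdr, hdr_path)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.vector(v), con, size = row$size, endian = "little")
  invisible(c(header = hdr_path, data = path))
}

#' White/dark reflectance calibration
#'
#' Converts raw digital numbers to unitless reflectance band-wise:
#' `R = factor * (raw - dark) / (white - dark)`. The default factor 1.0
#' treats the white target as a perfect reflector; pass 0.99 to correct for
#' a 99%-reflectance Spectralon puck.
#'
#' @param raw_cube a [hyper_cube()] of raw digital numbers.
#' @param white_frame,dark_frame per-band reference vectors (length = bands).
#' @param white_reflectance_factor reflectance of the white target, default 1.
#' @return a [hyper_cube()] of reflectance.
#' @export
calibrate_reflectance <- function(raw_cube, white_frame, dark_frame,
                                  white_reflectance_factor = 1.0) {
  stopifnot(inherits(raw_cube, "hyper_cube"))
  nb <- dim(raw_cube$values)[3]
  if (length(white_frame) != nb || length(dark_frame) != nb)
    stop("reference frames must have one value per band")
  denom <- white_frame - dark_frame
  if (any(denom <= 0))
    stop("degenerate reference: white <= dark at band(s) ",
         paste(which(denom <= 0)[1:min(3, sum(denom <= 0))], collapse = ", "))
  r <- sweep(sweep(raw_cube$values, 3L, dark_frame, "-"), 3L, denom, "/")
  hyper_cube(r * white_reflectance_factor, raw_cube$wavelengths_nm,
             meta = raw_cube$meta)
}

#' Construct a plant-mask object
#'
#' @param grid integer/logical matrix of 0/1, lines x samples.
#' @return an object of class `mask_file` with fields `grid` and
#'   `plant_pixel_count`.
#' @export
mask_file <- function(grid) {
  grid <- as.matrix(grid)
  if (!all(grid %in% c(0, 1))) stop("mask grid must be binary (0/1)")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, plant_pixel_count = sum(grid)),
            class = "mask_file")
}

#' @export
print.mask_file <- function(x, ...) {
  cat(sprintf("<mask_file> %d x %d, %d plant pixels\n",
              nrow(x$grid), ncol(x$grid), x$plant_pixel_count))
  invisible(x)
}

#' Write a plant mask as a headerless 0/1 CSV
#'
#' One CSV row per image line, comma-separated 0/1, LF line endings; the
#' plant-pixel count is written to a companion `<path>.count.txt`.
#'
#' @param mask a [mask_file()] or binary matrix.
#' @param path output CSV path.
#' @return invisibly, the CSV path.
#' @export
write_mask_csv <- function(mask, path) {
  if (!inherits(mask, "mask_file")) mask <- mask_file(mask)
  lines <- apply(mask$grid, 1L, paste, collapse = ",")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  writeLines(as.character(mask$plant_pixel_count),
             paste0(path, ".count.txt"))
  invisible(path)
}

#' Read a plant-mask CSV written by [write_mask_csv()]
#'
#' @param path CSV path.
#' @return a [mask_file()].
#' @export
read_mask_csv <- function(path) {
  rows <- strsplit(readLines(path, warn = FALSE), ",", fixed = TRUE)
  ncol <- length(rows[[1]])
  if (any(vapply(rows, length, 1L) != ncol))
    stop("ragged mask CSV: ", path)
  v <- suppressWarnings(as.numeric(unlist(rows)))
  if (any(is.na(v)) || !all(v %in% c(0, 1)))
    stop("mask CSV must contain only 0 and 1: ", path)
  mask_file(matrix(v, nrow = length(rows), byrow = TRUE))
}
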