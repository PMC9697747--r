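#' @title ENVI cube I/O
#' @description Reader and writer for the ENVI header + flat-binary raster
#'   dialect emitted by line-scan spectral cameras. Supported data types are
#'   unsigned 16-bit counts (ENVI code 12) and 32/64-bit IEEE floats (codes
#'   4 and 5); BIL, BIP and BSQ interleaves; little- and big-endian byte
#'   order per the header.
#' @name envi_io
NULL

# ENVI data type code <-> storage description
.envi_dtypes <- list(
  `4`  = list(what = "double", size = 4L, signed = TRUE),
  `5`  = list(what = "double", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^\\s*ENVI\\s*$", lines[[1L]]))
    stop("not an ENVI header (missing 'ENVI' magic line): ", header_path,
         call. = FALSE)
  # Join multi-line { ... } blocks, then split on first '='
  txt <- paste(lines[-1L], collapse = "\n")
  fields <- list()
  pos <- 1L
  # tokenise: key = value (value may be a braced block spanning lines)
  pat <- "(?m)^\\s*([^=\\n]+?)\\s*=\\s*"
  m <- gregexpr(pat, txt, perl = TRUE)[[1L]]
  if (m[1L] == -1L) stop("malformed ENVI header: no key = value pairs",
                         call. = FALSE)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keys <- character(length(starts))
  vals <- character(length(starts))
  for (i in seq_along(starts)) {
    keyblock <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    keys[i] <- trimws(sub("=\\s*$", "", keyblock))
    vstart <- starts[i] + lens[i]
    vend <- if (i < length(starts)) starts[i + 1L] - 1L else nchar(txt)
    vals[i] <- trimws(substr(txt, vstart, vend))
  }
  for (i in seq_along(keys)) {
    v <- vals[i]
    if (startsWith(v, "{")) {
      v <- sub("^\\{", "", v)
      v <- sub("\\}\\s*$", "", v)
      v <- trimws(gsub("\\s+", " ", v))
    }
    fields[[tolower(keys[i])]] <- v
  }
  fields
}

.header_int <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop("ENVI header missing required field '", key, "'",
                       call. = FALSE)
  as.integer(v)
}

#' Read an ENVI hyperspectral cube
#'
#' Parses the text header, locates the companion binary (same stem with
#' `.raw`, `.dat`, `.img` or no extension), and returns the cube with data
#' laid out `[rows x cols x bands]` regardless of the stored interleave.
#'
#' @param header_path Path to the `.hdr` file.
#' @return A [spectral_cube()]. The `kind` is taken from a `data kind`
#'   header field when present, else inferred from the data type (integer
#'   counts vs float reflectance).
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path))
    stop("header file not found: ", header_path, call. = FALSE)
  fields <- .parse_envi_header(header_path)

  samples <- .header_int(fields, "samples")  # columns
  lines_n <- .header_int(fields, "lines")    # rows
  bands <- .header_int(fields, "bands")
  dtype <- as.character(.header_int(fields, "data type"))
  interleave <- toupper(fields[["interleave"]] %||% "BSQ")
  byte_order <- .header_int(fields, "byte order")
  offset <- if (is.null(fields[["header offset"]])) 0L else
    .header_int(fields, "header offset")

  spec <- .envi_dtypes[[dtype]]
  if (is.null(spec))
    stop("unsupported ENVI data type code ", dtype,
         " (supported: 4, 5, 12)", call. = FALSE)
  if (!interleave %in% c("BIL", "BIP", "BSQ"))
    stop("unsupported interleave '", interleave, "'", call. = FALSE)

  wl_txt <- fields[["wavelength"]]
  if (is.null(wl_txt))
    stop("ENVI header declares no wavelength list", call. = FALSE)
  wavelengths <- as.numeric(strsplit(wl_txt, ",")[[1L]])
  if (length(wavelengths) != bands)
    stop(sprintf("header declares %d bands but lists %d wavelengths",
                 bands, length(wavelengths)), call. = FALSE)

  stem <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  candidates <- c(paste0(stem, c(".raw", ".dat", ".img")), stem)
  bin_path <- candidates[file.exists(candidates)][1L]
  if (is.na(bin_path))
    stop("companion binary not found for ", header_path, call. = FALSE)

  n <- as.numeric(samples) * lines_n * bands
  expected_size <- offset + n * spec$size
  actual_size <- file.size(bin_path)
  if (!isTRUE(actual_size == expected_size))
    stop(sprintf(
      "binary size %d does not match declared dimensions (%d x %d x %d, %d bytes/value%s)",
      actual_size, lines_n, samples, bands, spec$size,
      if (offset > 0L) sprintf(", offset %d", offset) else ""), call. = FALSE)

  con <- file(bin_path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  endian <- if (byte_order == 1L) "big" else "little"
  buf <- readBin(con, what = spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = endian)
  if (length(buf) != n)
    stop("binary file truncated", call. = FALSE)
  buf <- as.double(buf)   # cubes always carry doubles in memory

  data <- switch(interleave,
    BSQ = aperm(array(buf, dim = c(samples, lines_n, bands)), c(2L, 1L, 3L)),
    BIL = aperm(array(buf, dim = c(samples, bands, lines_n)), c(3L, 1L, 2L)),
    BIP = aperm(array(buf, dim = c(bands, samples, lines_n)), c(3L, 2L, 1L))
  )

  kind <- fields[["data kind"]]
  if (is.null(kind))
    kind <- if (dtype == "12") "raw_counts" else "reflectance"

  reserved <- c("samples", "lines", "bands", "data type", "interleave",
                "byte order", "header offset", "wavelength",
                "wavelength units", "file type", "data kind")
  meta <- fields[!names(fields) %in% reserved]

  spectral_cube(data, wavelengths, kind = kind, meta = meta)
}

#' Write an ENVI hyperspectral cube
#'
#' Writes `<path>.hdr` and `<path>.raw` such that [read_envi_cube()] inverts
#' the pair bit-exactly for the chosen data type. Raw-count cubes are stored
#' as unsigned 16-bit integers (values must be whole numbers within
#' 0--65535); reflectance cubes as 64-bit floats unless `data_type = 4`.
#' Meta keys must be ASCII (non-ASCII keys are rejected, matching the
#' constructor).
#'
#' @param cube A [spectral_cube()].
#' @param path Output stem or `.hdr` path; the extension is replaced.
#' @param interleave `"BIL"`, `"BIP"` or `"BSQ"` (default).
#' @param data_type ENVI type code: 12 (uint16), 4 (float32) or 5 (float64).
#'   Default: 12 for raw counts, 5 for reflectance.
#' @param byte_order 0 little-endian (default) or 1 big-endian.
#' @return Invisibly, the header path.
#' @export
write_envi_cube <- function(cube, path, interleave = c("BSQ", "BIL", "BIP"),
                            data_type = NULL, byte_order = 0L) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  if (is.null(data_type))
    data_type <- if (cube$kind == "raw_counts") 12L else 5L
  spec <- .envi_dtypes[[as.character(data_type)]]
  if (is.null(spec))
    stop("unsupported ENVI data type code ", data_type, call. = FALSE)
  if (data_type == 12L &&
      (any(cube$data != round(cube$data)) || any(cube$data > 65535)))
    stop("data type 12 (uint16) requires whole values in [0, 65535]",
         call. = FALSE)
  stem <- sub("\\.(hdr|raw|dat|img)$", "", path, ignore.case = TRUE)
  hdr_path <- paste0(stem, ".hdr")
  bin_path <- paste0(stem, ".raw")

  d <- dim(cube$data)
  flat <- switch(interleave,
    BSQ = as.vector(aperm(cube$data, c(2L, 1L, 3L))),
    BIL = as.vector(aperm(cube$data, c(2L, 3L, 1L))),
    BIP = as.vector(aperm(cube$data, c(3L, 2L, 1L)))
  )
  endian <- if (byte_order == 1L) "big" else "little"
  con <- file(bin_path, "wb")
  on.exit(close(con))
  if (spec$what == "integer") {
    writeBin(as.integer(flat), con, size = spec$size, endian = endian)
  } else {
    writeBin(as.double(flat), con, size = spec$size, endian = endian)
  }

  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", tolower(interleave)),
    sprintf("byte order = %d", byte_order),
    sprintf("data kind = %s", cube$kind),
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 15),
                 collapse = ", "), " }")
  )
  if (length(cube$meta)) {
    hdr <- c(hdr, vapply(names(cube$meta), function(k)
      sprintf("%s = %s", k, as.character(cube$meta[[k]])), character(1)))
  }
  writeLines(hdr, hdr_path)
  invisible(hdr_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
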