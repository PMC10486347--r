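# Cube, texture-table, and model-archive I/O.
#
# Two cube formats:
#  * portable - this package's self-describing pair: an ASCII header (the path
#    given) plus a flat little-endian float64 band-sequential raster in
#    "<path>.bin". Lossless round trip.
#  * envi     - ENVI-compatible layer: "<path>.hdr" ASCII header + raw raster;
#    BSQ/BIL/BIP and common data types read, BSQ float64 written.

PORTABLE_MAGIC <- "CARPTEX-CUBE"
PORTABLE_VERSION <- 1L

#' Write a spectral cube to disk
#'
#' @param cube A `spectral_cube`.
#' @param path Header path; the raster is written next to it (`.bin` for the
#'   portable format, the bare path with an `.hdr` sidecar for ENVI).
#' @param format "portable" (lossless, default) or "envi".
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("portable", "envi")) {
  format <- match.arg(format)
  stopifnot(inherits(cube, "spectral_cube"))
  # re-validate before write: constructors can be bypassed with direct edits
  cube <- spectral_cube(cube$data, cube$wavelengths, cube$kind, cube$meta)
  d <- dim(cube$data)
  # BSQ, row-major within band: column index varies fastest
  bsq <- as.vector(aperm(cube$data, c(2, 1, 3)))
  if (format == "portable") {
    hdr <- c(
      paste0("magic: ", PORTABLE_MAGIC),
      paste0("version: ", PORTABLE_VERSION),
      paste0("rows: ", d[1]),
      paste0("cols: ", d[2]),
      paste0("bands: ", d[3]),
      paste0("kind: ", cube$kind),
      paste0("wavelengths: ", paste(format(cube$wavelengths, digits = 17,
                                           scientific = FALSE, trim = TRUE),
                                    collapse = ","))
    )
    writeLines(hdr, path)
    con <- file(paste0(path, ".bin"), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(bsq, con, size = 8, endian = "little")
  } else {
    hdr <- c(
      "ENVI",
      "description = {carptex export}",
      paste0("samples = ", d[2]),
      paste0("lines = ", d[1]),
      paste0("bands = ", d[3]),
      "header offset = 0",
      "file type = ENVI Standard",
      "data type = 5",
      "interleave = bsq",
      "byte order = 0",
      paste0("wavelength = {", paste(format(cube$wavelengths, digits = 17,
                                            scientific = FALSE, trim = TRUE),
                                     collapse = ", "), "}")
    )
    writeLines(hdr, paste0(path, ".hdr"))
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(bsq, con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a spectral cube from disk
#'
#' @param path Path as given to [write_cube()] (portable header path, or ENVI
#'   raster path / `.hdr` path).
#' @param format "auto", "portable" or "envi".
#' @param kind Cube kind to stamp on the result ("reflectance" or "raw");
#'   portable headers carry their own kind and ignore this.
#' @return A `spectral_cube`.
#' @export
read_cube <- function(path, format = c("auto", "portable", "envi"),
                      kind = "reflectance") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(path) && !dir.exists(path) &&
                  identical(readLines(path, n = 1, warn = FALSE),
                            paste0("magic: ", PORTABLE_MAGIC))) {
      "portable"
    } else "envi"
  }
  if (format == "portable") read_cube_portable(path) else read_cube_envi(path, kind)
}

read_cube_portable <- function(path) {
  if (!file.exists(path)) stop("cube header not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("garbled portable header: missing '", k, "'", call. = FALSE)
    vals[i]
  }
  if (!identical(get("magic"), PORTABLE_MAGIC)) {
    stop("not a portable cube header: ", path, call. = FALSE)
  }
  if (as.integer(get("version")) > PORTABLE_VERSION) {
    stop("portable cube format version newer than this package supports",
         call. = FALSE)
  }
  rows <- as.integer(get("rows")); cols <- as.integer(get("cols"))
  bands <- as.integer(get("bands"))
  wl <- as.numeric(strsplit(get("wavelengths"), ",", fixed = TRUE)[[1]])
  if (length(wl) != bands) {
    stop("header inconsistency: ", bands, " bands but ", length(wl),
         " wavelength entries", call. = FALSE)
  }
  bin <- paste0(path, ".bin")
  if (!file.exists(bin)) stop("cube raster not found: ", bin, call. = FALSE)
  n <- rows * cols * bands
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(x) != n) {
    stop("header inconsistency: raster holds ", length(x),
         " values, header implies ", n, call. = FALSE)
  }
  data <- aperm(array(x, dim = c(cols, rows, bands)), c(2, 1, 3))
  spectral_cube(data, wl, kind = get("kind"))
}

# Parse an ENVI ASCII header into a named list; brace values may span lines.
parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^ENVI", lines[1])) {
    stop("not an ENVI header (missing ENVI magic): ", hdr_path, call. = FALSE)
  }
  out <- list()
  i <- 2
  while (i <= length(lines)) {
    line <- lines[i]
    if (!grepl("=", line, fixed = TRUE)) { i <- i + 1; next }
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (startsWith(val, "{")) {
      while (!grepl("}", val, fixed = TRUE)) {
        i <- i + 1
        if (i > length(lines)) {
          stop("garbled ENVI header: unclosed '{'", call. = FALSE)
        }
        val <- paste(val, trimws(lines[i]))
      }
      val <- sub("}.*$", "", sub("^\\{", "", val))
    }
    out[[key]] <- trimws(val)
    i <- i + 1
  }
  out
}

envi_read_type <- function(code) {
  switch(as.character(code),
    "1" = list(what = "integer", size = 1, signed = FALSE),
    "2" = list(what = "integer", size = 2, signed = TRUE),
    "3" = list(what = "integer", size = 4, signed = TRUE),
    "4" = list(what = "double", size = 4, signed = TRUE),
    "5" = list(what = "double", size = 8, signed = TRUE),
    "12" = list(what = "integer", size = 2, signed = FALSE),
    stop("unsupported ENVI data type: ", code, call. = FALSE)
  )
}

read_cube_envi <- function(path, kind = "reflectance") {
  if (grepl("\\.hdr$", path)) {
    hdr_path <- path
    img_path <- sub("\\.hdr$", "", path)
  } else {
    hdr_path <- paste0(path, ".hdr")
    img_path <- path
  }
  if (!file.exists(hdr_path)) {
    alt <- sub("\\.[^.]+$", ".hdr", img_path)
    if (file.exists(alt)) hdr_path <- alt
    else stop("ENVI header not found for: ", path, call. = FALSE)
  }
  if (!file.exists(img_path)) stop("ENVI raster not found: ", img_path, call. = FALSE)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    stop("garbled ENVI header: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cols <- as.integer(h$samples); rows <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  wl <- if (!is.null(h$wavelength)) {
    as.numeric(trimws(strsplit(h$wavelength, ",")[[1]]))
  } else {
    stop("ENVI header carries no wavelength block", call. = FALSE)
  }
  if (length(wl) != bands) {
    stop("header inconsistency: ", bands, " bands declared but ",
         length(wl), " wavelength entries", call. = FALSE)
  }
  type <- envi_read_type(h[["data type"]])
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  n <- rows * cols * bands
  con <- file(img_path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, type$what, n = n, size = type$size,
               signed = type$signed, endian = endian)
  if (length(x) != n) {
    stop("header inconsistency: raster holds ", length(x),
         " values, header implies ", n, call. = FALSE)
  }
  interleave <- tolower(h$interleave)
  data <- switch(interleave,
    bsq = aperm(array(x, dim = c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(x, dim = c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(x, dim = c(bands, cols, rows)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave, call. = FALSE)
  )
  spectral_cube(data, wl, kind = kind)
}

#' Read a texture profile analysis table
#'
#' Expects a UTF-8 comma-separated file with header columns `sample_id`,
#' `region`, and the eight TPA indicators (see [texture_indicators()]); one
#' row per (sample, region).
#'
#' @param path CSV path.
#' @return Tibble with validated columns.
#' @export
read_texture_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  validate_texture_table(tibble::as_tibble(df))
}

#' Validate a texture table
#'
#' Checks the schema (sample_id, region, all 8 indicators), the region
#' vocabulary, and finiteness of every indicator value.
#'
#' @param df Data frame to validate.
#' @return The validated tibble (invisibly coerced).
#' @export
validate_texture_table <- function(df) {
  need <- c("sample_id", "region", texture_indicators())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("texture table schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$region), muscle_regions())
  if (length(bad)) {
    stop("texture table vocabulary error: unknown region(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[texture_indicators()])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("texture table contains missing or non-finite indicator values",
         call. = FALSE)
  }
  if (anyDuplicated(df[c("sample_id", "region")])) {
    stop("texture table has duplicated (sample_id, region) rows", call. = FALSE)
  }
  tibble::as_tibble(df[c(need)])
}

#' Write a texture table to CSV
#' @param df Texture table (validated).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_texture_table <- function(df, path) {
  df <- validate_texture_table(df)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

MODEL_ARCHIVE_VERSION <- 1L

#' Save a fitted model archive
#'
#' Single-file serialization with a format-version tag; [read_model()] refuses
#' archives written by a future format version.
#'
#' @param model A fitted model (class `carptex_model`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "carptex_model"))
  saveRDS(list(format = "carptex-model", version = MODEL_ARCHIVE_VERSION,
               model = model), path, version = 2)
  invisible(path)
}

#' Load a fitted model archive
#' @param path Archive path written by [write_model()].
#' @return The fitted model.
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "carptex-model")) {
    stop("not a carptex model archive: ", path, call. = FALSE)
  }
  if (obj$version > MODEL_ARCHIVE_VERSION) {
    stop("model archive version ", obj$version,
         " is newer than this package supports", call. = FALSE)
  }
  obj$model
}
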