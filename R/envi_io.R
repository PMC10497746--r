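#' Write a cube in ENVI format
#'
#' Writes a text `.hdr` header plus a flat binary data file. Data type 4
#' (32-bit float) or 5 (64-bit double), little endian, interleave `bsq`,
#' `bil` or `bip`; the wavelength vector is stored in the header.
#'
#' @param cube A [hyper_cube()].
#' @param path Path of the binary data file; the header is written next to it
#'   as `<path>.hdr` (the conventional sidecar name).
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type 4 (float) or 5 (double).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) stop("data_type must be 4 (float) or 5 (double)")
  d <- dim(cube$data)  # rows (lines), cols (samples), bands
  hdr <- c(
    "ENVI",
    "description = { seedhsi export }",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength units = nm"),
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, scientific = FALSE),
                 collapse = ", "), " }")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # internal layout is (row, col, band); ENVI is sample-fastest
  a <- cube$data
  v <- switch(interleave,
    bsq = as.vector(aperm(a, c(2L, 1L, 3L))),   # sample, line, band
    bil = as.vector(aperm(a, c(2L, 3L, 1L))),   # sample, band, line
    bip = as.vector(aperm(a, c(3L, 2L, 1L))))   # band, sample, line
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(v), con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  invisible(path)
}

# parse an ENVI header file into a named list of strings
parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  # join { ... } blocks, then split into key = value lines
  out <- list()
  pat <- gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt)
  m <- regmatches(txt, pat)[[1]]
  for (kv in m) {
    eq <- regexpr("=", kv)
    key <- tolower(trimws(substr(kv, 1, eq - 1)))
    val <- trimws(substr(kv, eq + 1, nchar(kv)))
    out[[key]] <- val
  }
  out
}

#' Read an ENVI cube
#'
#' Accepts `.dat`/`.raw` (or any) data-file extension with a `<file>.hdr`
#' sidecar (also found if the extension is replaced rather than appended).
#' The header must carry a wavelength block unless `wavelengths` is supplied.
#'
#' @param path Path to the binary data file.
#' @param wavelengths Optional wavelength vector overriding/supplying the
#'   header's.
#' @return A [hyper_cube()].
#' @export
read_envi <- function(path, wavelengths = NULL) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- paste0(sub("\\.[^.]*$", "", path), ".hdr")
  if (!file.exists(hdr_path)) stop("no ENVI header found for ", path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  if (!all(need %in% names(h)))
    stop("ENVI header missing field(s): ",
         paste(setdiff(need, names(h)), collapse = ", "))
  ns <- as.integer(h$samples); nl <- as.integer(h$lines); nb <- as.integer(h$bands)
  dt <- as.integer(h$`data type`)
  if (!dt %in% c(4L, 5L)) stop("unsupported ENVI data type ", dt)
  byte_order <- if (!is.null(h$`byte order`)) as.integer(h$`byte order`) else 0L
  il <- tolower(h$interleave)
  if (is.null(wavelengths)) {
    if (is.null(h$wavelength))
      stop("header has no wavelength block; supply `wavelengths`")
    wavelengths <- as.numeric(strsplit(gsub("[{}]", "", h$wavelength),
                                       ",")[[1]])
  }
  offset <- if (!is.null(h$`header offset`)) as.integer(h$`header offset`) else 0L
  con <- file(path, "rb"); on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  v <- readBin(con, "numeric", n = ns * nl * nb,
               size = if (dt == 4L) 4L else 8L,
               endian = if (byte_order == 0L) "little" else "big")
  if (length(v) != ns * nl * nb) stop("ENVI data file truncated")
  a <- switch(il,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3L, 2L, 1L)),
    stop("unsupported interleave ", il))
  hyper_cube(a, wavelengths)
}

#' Write a label mask as plain-text PGM (P2)
#'
#' P2 is ASCII and supports 16-bit values, so instance labels survive intact
#' and the file stays diff- and repository-friendly.
#'
#' @param mask A [seed_mask()] or an integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  lab <- if (inherits(mask, "seed_mask")) mask$labels else mask
  stopifnot(is.matrix(lab))
  maxv <- max(1L, max(lab))
  if (maxv > 65535L) stop("labels exceed 16-bit PGM range")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(lab), nrow(lab)), as.character(maxv)), con)
  apply(lab, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read a plain-text PGM (P2) label mask
#'
#' @param path Path to a P2 PGM file.
#' @return A [seed_mask()].
#' @export
read_mask_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  seed_mask(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
}

#' Write a spectral table as CSV
#'
#' Header row is `seed_id,label,<nm1>,<nm2>,...` with one row per seed.
#'
#' @param tab A `spectral_table` (see [mean_spectra()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_table <- function(tab, path) {
  stopifnot(inherits(tab, "spectral_table"))
  lab <- if (is.null(tab$class_labels)) rep(NA, nrow(tab$spectra)) else tab$class_labels
  df <- data.frame(seed_id = tab$seed_ids, label = lab,
                   tab$spectra, check.names = FALSE)
  names(df) <- c("seed_id", "label",
                 format(tab$wavelengths, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral table CSV
#'
#' @param path CSV written by [write_spectral_table()] (or matching its
#'   `seed_id,label,<nm...>` layout).
#' @return A `spectral_table`.
#' @export
read_spectral_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("seed_id", "label")))
    stop("expected columns seed_id,label,<wavelengths...>")
  wl <- as.numeric(names(df)[-(1:2)])
  if (anyNA(wl)) stop("non-numeric wavelength column names")
  spec <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(spec) <- list(NULL, paste0("nm", wl))
  cls <- df$label
  if (all(is.na(cls))) cls <- NULL
  structure(list(spectra = spec, wavelengths = wl, seed_ids = df$seed_id,
                 class_labels = cls),
            class = "spectral_table")
}
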