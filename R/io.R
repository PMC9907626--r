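# File formats: ENVI-style header + band-sequential binary for cubes, a
# compressed single-file container, and tidy CSV interchange for spectra,
# landmarks, effects and groupings.

#' Write a reflectance cube to disk
#'
#' Two formats: an ENVI-style pair (`<path>` binary + `<path>.hdr` text
#' header, band-sequential interleave, 64-bit little-endian floats by
#' default) selected by any extension other than `.rds`/`.rds.gz`, or a
#' compressed single-file container (serialized, gzip) selected by an
#' `.rds`/`.rds.gz` extension. Both round-trip voxel-exactly.
#'
#' @param cube a [reflectance_cube()].
#' @param path output path.
#' @param data_type ENVI data type: 5 (float64, default, lossless) or 4
#'   (float32).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, data_type = 5) {
  if (grepl("\\.rds(\\.gz)?$", path)) {
    con <- gzfile(path, "wb")
    on.exit(close(con))
    serialize(list(values = cube$values,
                   wavelengths_nm = cube$axis$wavelengths_nm,
                   bandwidth_fwhm_nm = cube$axis$bandwidth_fwhm_nm,
                   provenance = cube$provenance, ceiling = cube$ceiling),
              con, version = 2)
    return(invisible(path))
  }
  d <- dim(cube$values)
  if (!data_type %in% c(4, 5)) stop_format("data_type must be 4 or 5")
  hdr <- c("ENVI",
           "file type = ENVI Standard",
           sprintf("samples = %d", d[3]),
           sprintf("lines = %d", d[2]),
           sprintf("bands = %d", d[1]),
           "header offset = 0",
           sprintf("data type = %d", data_type),
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = Nanometers",
           sprintf("wavelength = { %s }",
                   paste(sprintf("%.12g", cube$axis$wavelengths_nm),
                         collapse = ", ")),
           sprintf("fwhm = { %s }",
                   paste(rep(cube$axis$bandwidth_fwhm_nm, d[1]), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band-major, then line-major (row), then sample (col)
  for (b in seq_len(d[1]))
    writeBin(as.vector(t(cube$values[b, , ])), con,
             size = if (data_type == 5) 8 else 4, endian = "little")
  invisible(path)
}

#' Read a reflectance cube written by [write_cube()] or another ENVI writer
#'
#' @param path path to the binary file (with `<path>.hdr` next to it) or to
#'   an `.rds`/`.rds.gz` container.
#' @return A [reflectance_cube()].
#' @export
read_cube <- function(path) {
  if (grepl("\\.rds(\\.gz)?$", path)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    x <- unserialize(con)
    return(reflectance_cube(x$values,
                            spectral_axis(x$wavelengths_nm, x$bandwidth_fwhm_nm),
                            provenance = x$provenance,
                            ceiling = if (is.null(x$ceiling)) 1.2 else x$ceiling))
  }
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path)) stop_format("no header file found for '%s'", path)
  hdr <- parse_envi_header(hdr_path)
  for (f in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(hdr[[f]])) stop_format("ENVI header missing field '%s'", f)
  if (tolower(hdr$interleave) != "bsq")
    stop_format("only band-sequential (bsq) interleave is supported, got '%s'",
                hdr$interleave)
  nb <- as.integer(hdr$bands); nr <- as.integer(hdr$lines)
  nc <- as.integer(hdr$samples)
  dtype <- as.integer(hdr[["data type"]])
  if (!dtype %in% c(4, 5)) stop_format("unsupported ENVI data type %d", dtype)
  wl <- if (!is.null(hdr$wavelength)) as.numeric(strsplit(hdr$wavelength, ",")[[1]])
  else stop_format("ENVI header missing field 'wavelength'")
  if (length(wl) != nb)
    stop_format("wavelength list length (%d) does not match bands (%d)",
                length(wl), nb)
  fwhm <- if (!is.null(hdr$fwhm)) as.numeric(strsplit(hdr$fwhm, ",")[[1]])[1] else 32
  offset <- if (!is.null(hdr[["header offset"]])) as.integer(hdr[["header offset"]]) else 0L
  con <- file(path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  n <- nb * nr * nc
  v <- readBin(con, "double", n = n, size = if (dtype == 5) 8 else 4,
               endian = "little")
  if (length(v) != n) stop_format("binary file truncated: got %d of %d values",
                                  length(v), n)
  vals <- array(NA_real_, c(nb, nr, nc))
  per_band <- nr * nc
  for (b in seq_len(nb)) {
    # stored line-major within band
    vals[b, , ] <- matrix(v[((b - 1) * per_band + 1):(b * per_band)],
                          nr, nc, byrow = TRUE)
  }
  reflectance_cube(vals, spectral_axis(wl, fwhm),
                   provenance = list(source = path))
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^ENVI", lines[1]))
    stop_format("'%s' is not an ENVI header (missing ENVI magic)", path)
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  # split on newlines but re-join lines inside braces
  joined <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in strsplit(txt, "\n")[[1]]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    open <- lengths(regmatches(buf, gregexpr("\\{", buf))) >
      lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (!open) { joined <- c(joined, buf); buf <- "" }
  }
  for (ln in joined) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- trimws(gsub("[{}]", "", val))
    out[[key]] <- val
  }
  out
}

#' Read / write a two-column reflectance spectrum CSV
#'
#' Format: header row `wavelength_nm,reflectance`, reflectance as fractions.
#' On read, a file whose reflectance values look like percentages (any
#' value above 1.5) is divided by 100 with a warning.
#'
#' @param spectrum a [reflectance_spectrum()].
#' @param path file path.
#' @return `read_spectrum_csv` returns a [reflectance_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- data.frame(wavelength_nm = spectrum$wavelengths_nm,
                   reflectance = spectrum$reflectance)
  if (!is.null(spectrum$sigma)) df$sigma <- spectrum$sigma
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("wavelength", first, ignore.case = TRUE))
    stop_format("spectrum CSV '%s' is missing its header row", path)
  df <- read.csv(path)
  if (!all(c("wavelength_nm", "reflectance") %in% names(df)))
    stop_format("spectrum CSV needs columns wavelength_nm, reflectance")
  r <- df$reflectance
  if (any(r > 1.5)) {
    warning("reflectance values look like percentages; dividing by 100",
            call. = FALSE)
    r <- r / 100
  }
  reflectance_spectrum(df$wavelength_nm, r,
                       sigma = if ("sigma" %in% names(df)) df$sigma else NULL)
}

#' Read / write a 68-point landmark CSV (`index,row,col`)
#'
#' @param landmarks a [landmark_set()].
#' @param path file path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  write.csv(landmarks$points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @param image_shape optional bounds check on read.
#' @export
read_landmarks_csv <- function(path, image_shape = NULL) {
  landmark_set(read.csv(path), image_shape = image_shape, source = "fixture")
}

#' Read / write the tidy effects CSV
#'
#' Columns: `model,product,repetition,operator,instrument,dL,da,db,dE`.
#' @param effects effect-record data frame.
#' @param path file path.
#' @export
write_effects_csv <- function(effects, path) {
  write.csv(effects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effects_csv
#' @export
read_effects_csv <- function(path) {
  df <- read.csv(path)
  need <- c("model", "product", "repetition", "operator", "instrument",
            "dL", "da", "db", "dE")
  if (!all(need %in% names(df)))
    stop_format("effects CSV needs columns %s", paste(need, collapse = ", "))
  df
}

#' Write the grouping and correlation tables of a replication analysis
#'
#' @param replication an [run_replication()] result.
#' @param dir output directory.
#' @return Paths of the written CSVs, invisibly.
#' @export
write_replication_csv <- function(replication, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if (!is.null(replication$groupings)) {
    p <- file.path(dir, "groupings.csv")
    write.csv(replication$groupings, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(replication$correlations)) {
    p <- file.path(dir, "correlations.csv")
    write.csv(replication$correlations, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
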