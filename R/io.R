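#' Read a single-plane greyscale TIFF
#'
#' Accepts 8/16-bit unsigned integer or 32-bit float, single-channel,
#' single-page TIFFs. Integer data are returned as raw counts (no \[0, 1\]
#' rescaling); float data are returned as stored, including negative
#' values. Multi-page or multi-channel (RGB) files are rejected with an
#' instructive message.
#'
#' @param path file path.
#' @return numeric matrix; if the file carries an x-resolution tag, the
#'   pixel size is attached as attribute `"pixel_size"` (units per pixel).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (length(pages) != 1)
    stop("multi-page TIFF (", length(pages),
         " planes); extract the plane of interest first")
  img <- pages[[1]]
  if (length(dim(img)) == 3)
    stop("multi-channel (e.g. RGB) TIFF; extract a single grey channel first")
  res <- attr(img, "x.resolution")
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (!is.null(res) && is.finite(res) && res > 0)
    attr(img, "pixel_size") <- 1 / res
  img
}

# Minimal single-strip uncompressed 32-bit float TIFF writer (SampleFormat
# IEEE float, little-endian). No installed R package writes float TIFFs;
# reading back goes through tiff::readTIFF, which serves as the independent
# check of this writer.
write_float_tiff <- function(img, path) {
  m <- nrow(img); n <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)    # header, IFD at byte 8
  n_entries <- 9L
  data_offset <- 8L + 2L + n_entries * 12L + 4L
  w2(n_entries)
  entry(256L, 4L, 1L, n)                 # ImageWidth
  entry(257L, 4L, 1L, m)                 # ImageLength
  entry(258L, 3L, 1L, 32L)               # BitsPerSample
  entry(259L, 3L, 1L, 1L)                # Compression: none
  entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)       # StripOffsets
  entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
  entry(279L, 4L, 1L, m * n * 4L)        # StripByteCounts
  entry(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
  w4(0L)                                 # no further IFD
  writeBin(as.numeric(t(img)), con, size = 4, endian = "little")
  invisible(path)
}

#' Write an image to TIFF
#'
#' `type = "float"` writes a 32-bit IEEE float TIFF preserving values
#' exactly (including negatives, to float32 precision); `type = "uint16"`
#' clips at 0, rounds, and stores 16-bit unsigned counts (values above
#' 65535 saturate).
#'
#' @param img numeric matrix.
#' @param path output path.
#' @param type `"float"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, type = c("float", "uint16")) {
  type <- match.arg(type)
  img <- as.matrix(img)
  if (type == "float") {
    write_float_tiff(img, path)
  } else {
    x <- pmin(pmax(round(img), 0), 65535)
    tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(path)
}

#' Write an anisotropy spectrum to CSV
#'
#' Plain CSV with columns `ring_index`, `freq_per_pixel`, `gamma_c`,
#' `gamma_s`, `n_samples`, preceded by `#`-comment header lines recording
#' the mode and source image shape. Round-trips through [read_spectrum()]
#' losslessly to full double precision.
#'
#' @param spec an `anisotropy_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "anisotropy_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# fourd anisotropy spectrum",
    paste0("# mode=", spec$mode),
    paste0("# source_shape=", spec$source_shape[1], "x",
           spec$source_shape[2])), con)
  df <- as.data.frame(spec)
  writeLines(paste(colnames(df), collapse = ","), con)
  writeLines(apply(df, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ",")), con)
  invisible(path)
}

#' Read an anisotropy spectrum from CSV
#'
#' @param path a file written by [write_spectrum()] (or hand-written with
#'   the same columns; missing columns raise a schema error).
#' @return an `anisotropy_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  if (!length(body)) stop("spectrum file has no data rows")
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("ring_index", "gamma_c", "gamma_s")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("spectrum file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(df)) stop("spectrum file has no data rows")
  mode <- sub("^# mode=", "", grep("^# mode=", hdr, value = TRUE))
  shape_str <- sub("^# source_shape=", "",
                   grep("^# source_shape=", hdr, value = TRUE))
  shape <- if (length(shape_str))
    as.integer(strsplit(shape_str, "x")[[1]]) else c(NA_integer_, NA_integer_)
  structure(list(
    frequencies = df$ring_index,
    gamma_c = df$gamma_c, gamma_s = df$gamma_s,
    n_samples = if ("n_samples" %in% colnames(df)) df$n_samples
                else rep(NA_integer_, nrow(df)),
    mode = if (length(mode)) mode else "single",
    source_shape = shape), class = "anisotropy_spectrum")
}

#' Write the ground-truth fibre table of a simulated field
#'
#' CSV sidecar with one row per fibre (`fibre_id`, `angle_deg`,
#' `length_px`, `row`, `col`, `multiplier`), where `multiplier` is the
#' polarisation brightness factor the render applied.
#'
#' @param field a `fibre_field`.
#' @param path output path.
#' @param settings the [polarisation()] settings used at render time
#'   (`NULL` for none).
#' @return `path`, invisibly.
#' @export
write_truth <- function(field, path, settings = NULL) {
  stopifnot(inherits(field, "fibre_field"))
  recipe <- attr(field, "recipe")
  scale <- if (!is.null(settings) && settings$gradient)
    field$col / recipe$canvas_px[2] else 1
  df <- as.data.frame(field)[c("fibre_id", "angle_deg", "length_px",
                               "row", "col")]
  df$multiplier <- polarisation_factor(field$angle_deg, settings,
                                       strength_scale = scale)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
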