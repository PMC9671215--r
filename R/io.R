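# Readers/writers for the plain-text and image formats the pipeline touches.
# All table readers validate headers strictly and error on empty files.

.read_strict_csv <- function(path, required_cols) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) .stopf("cannot read '%s': %s", path, conditionMessage(e)))
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols))
    .stopf("'%s' lacks required column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) .stopf("'%s' contains no data rows", path)
  df
}

#' Profile, correlogram, replicate and binodal CSV I/O
#'
#' Strict readers/writers for the package's tabular formats:
#' radial profiles (`r_nm,intensity`), DLS correlograms (`lag_s,g2`, with
#' instrument metadata in `# key=value` comment lines), zeta replicates
#' (`zeta_mV`) and binodal boundary curves
#' (`w_water,w_methanol,w_chloroform`). Readers validate headers and reject
#' empty files; writers round-trip values at full precision.
#'
#' @param path File path.
#' @param profile A [radial_profile()].
#' @param trace A `correlogram_trace`.
#' @param values_mV Numeric vector of zeta replicates.
#' @return Readers return the corresponding object; writers return the path
#'   invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_profile_csv <- function(path) {
  df <- .read_strict_csv(path, c("r_nm", "intensity"))
  radial_profile(df$r_nm, df$intensity, provenance = list(source = path))
}

#' @rdname table_io
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(r_nm = profile$distances,
                              intensity = profile$intensities),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_correlogram_csv <- function(path) {
  meta <- list()
  for (ln in readLines(path, n = 20L)) {
    if (!startsWith(ln, "#")) break
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  df <- .read_strict_csv(path, c("lag_s", "g2"))
  structure(list(lags = df$lag_s, g2 = df$g2,
                 q = if (!is.null(meta[["q_1/m"]])) meta[["q_1/m"]]
                     else scattering_vector(),
                 beta = if (!is.null(meta[["beta"]])) meta[["beta"]] else NULL,
                 medium = water_medium()),
            class = "correlogram_trace")
}

#' @rdname table_io
#' @export
write_correlogram_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q_1/m=%.10e", trace$q), con)
  if (!is.null(trace$beta)) writeLines(sprintf("# beta=%g", trace$beta), con)
  utils::write.csv(data.frame(lag_s = trace$lags, g2 = trace$g2),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_zeta_csv <- function(path) .read_strict_csv(path, "zeta_mV")$zeta_mV

#' @rdname table_io
#' @export
write_zeta_csv <- function(values_mV, path) {
  utils::write.csv(data.frame(zeta_mV = values_mV), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_binodal_csv <- function(path) {
  df <- .read_strict_csv(path, c("w_water", "w_methanol", "w_chloroform"))
  sums <- df$w_water + df$w_methanol + df$w_chloroform
  if (any(abs(sums - 100) > 1e-6))
    .stopf("binodal rows must sum to 100 weight-%%")
  df
}

#' Grayscale image I/O
#'
#' `read_image()` loads an 8- or 16-bit grayscale TIFF or PNG as a numeric
#' matrix on the \[0, 1\] scale (color images are rejected); the mandatory
#' pixel size is attached as an attribute. `write_image()` writes a \[0, 1\]
#' matrix as 16-bit TIFF (default) or PNG by file extension.
#'
#' @param path Image path (`.tif`/`.tiff`/`.png`).
#' @param pixel_size_nm Pixel size in nm/px (mandatory on read).
#' @param image Numeric matrix with values in \[0, 1\].
#' @param bits Bit depth for TIFF output (8 or 16).
#' @return `read_image()`: matrix with attribute `pixel_size_nm`;
#'   `write_image()`: the path, invisibly.
#' @export
read_image <- function(path, pixel_size_nm) {
  .check_positive_scalar(pixel_size_nm, "pixel_size_nm")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                .stopf("unsupported image format '.%s'", ext))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 2L) .stopf("color images are not supported")
    img <- img[, , 1]   # gray + alpha: keep gray
  }
  attr(img, "pixel_size_nm") <- pixel_size_nm
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path, bits = 16) {
  stopifnot(is.matrix(image))
  if (!bits %in% c(8, 16)) .stopf("bit depth must be 8 or 16")
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
         png = png::writePNG(img, path),
         .stopf("unsupported image format '.%s'", ext))
  invisible(path)
}
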