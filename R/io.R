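# Spectrum import/export: minimal JCAMP-DX (single spectrum, AFFN
# X++(Y..Y)) and CSV.

#' Write a spectrum to a JCAMP-DX file
#'
#' Minimal JCAMP-DX 4.24 writer: one NMR SPECTRUM block with an
#' X++(Y..Y) AFFN data table on the uniform frequency axis.
#'
#' @param spec a `spectrum`.
#' @param path output file.
#' @param title TITLE record.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spec, path, title = "parashim spectrum") {
  stopifnot(inherits(spec, "spectrum"))
  f <- spec$axis_hz
  y <- spec$intensities
  n <- length(y)
  yfac <- max(abs(y)) / 32767
  if (yfac == 0) yfac <- 1
  yi <- y / yfac
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  wr("##TITLE=%s", title)
  wr("##JCAMP-DX=4.24")
  wr("##DATA TYPE=NMR SPECTRUM")
  wr("##XUNITS=HZ")
  wr("##YUNITS=ARBITRARY UNITS")
  wr("##FIRSTX=%.10g", f[1])
  wr("##LASTX=%.10g", f[n])
  wr("##NPOINTS=%d", n)
  wr("##XFACTOR=1")
  wr("##YFACTOR=%.10g", yfac)
  wr("##FIRSTY=%.10g", y[1])
  wr("##XYDATA=(X++(Y..Y))")
  per <- 6L
  for (lo in seq(1L, n, by = per)) {
    hi <- min(lo + per - 1L, n)
    wr("%s %s", format(f[lo], digits = 10),
       paste(format(yi[lo:hi], digits = 8), collapse = " "))
  }
  wr("##END=")
  invisible(path)
}

#' Read a spectrum from a JCAMP-DX file written by [write_jcamp()]
#'
#' Supports the single-block AFFN X++(Y..Y) layout with XFACTOR/YFACTOR
#' scaling and a uniform axis reconstructed from FIRSTX/LASTX/NPOINTS.
#'
#' @param path JCAMP-DX file.
#' @return a `spectrum`.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  field <- function(key) {
    ln <- grep(paste0("^##", key, "="), lines, value = TRUE)[1]
    if (is.na(ln)) stop("JCAMP-DX field missing: ", key)
    sub(paste0("^##", key, "="), "", ln)
  }
  n <- as.integer(field("NPOINTS"))
  firstx <- as.numeric(field("FIRSTX"))
  lastx <- as.numeric(field("LASTX"))
  yfac <- as.numeric(field("YFACTOR"))
  start <- grep("^##XYDATA=", lines)[1]
  end <- grep("^##END=", lines)[1]
  if (is.na(start) || is.na(end)) stop("no XYDATA table found")
  y <- numeric(0)
  for (ln in lines[(start + 1):(end - 1)]) {
    vals <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    y <- c(y, vals[-1])
  }
  if (length(y) != n) stop("NPOINTS mismatch: expected ", n, ", got ",
                           length(y))
  new_spectrum(y * yfac, seq(firstx, lastx, length.out = n))
}

#' Write a spectrum to CSV (columns axis_hz, intensity)
#' @param spec a `spectrum`.
#' @param path output file.
#' @export
write_spectrum_csv <- function(spec, path) {
  data.table::fwrite(data.table::data.table(axis_hz = spec$axis_hz,
                                            intensity = spec$intensities),
                     path)
  invisible(path)
}

#' Read a spectrum from CSV written by [write_spectrum_csv()]
#' @param path CSV file.
#' @export
read_spectrum_csv <- function(path) {
  d <- data.table::fread(path)
  new_spectrum(d$intensity, d$axis_hz)
}
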