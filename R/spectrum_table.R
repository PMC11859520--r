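#' Read a plain-text spectrum table
#'
#' The exchange format for user-supplied spectra: comment lines start with
#' `#`, a header comment `# units: cm^-1` or `# units: m^-1` declares the
#' coefficient unit (mandatory), and data rows hold two whitespace-separated
#' columns, wavelength in nm and the coefficient value.
#'
#' @param path file to read.
#' @return a data.frame with columns `wavelength_nm`, `value` and a `units`
#'   attribute.
#' @export
read_spectrum_table <- function(path) {
  lines <- readLines(path)
  unit_line <- grep("^#\\s*units\\s*:", lines, value = TRUE)
  if (length(unit_line) == 0)
    stop("spectrum table must declare its units with a '# units: cm^-1' or '# units: m^-1' line")
  units <- trimws(sub("^#\\s*units\\s*:", "", unit_line[1]))
  if (!(units %in% c("cm^-1", "m^-1")))
    stop(sprintf("unsupported units '%s' in spectrum table (use cm^-1 or m^-1)", units))
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(data_lines), "\\s+")
  if (any(lengths(fields) < 2)) stop("spectrum table rows need two columns: wavelength_nm value")
  df <- data.frame(wavelength_nm = as.numeric(vapply(fields, `[`, "", 1L)),
                   value = as.numeric(vapply(fields, `[`, "", 2L)))
  if (any(!is.finite(df$wavelength_nm)) || any(!is.finite(df$value)))
    stop("spectrum table contains non-numeric entries")
  df <- df[order(df$wavelength_nm), , drop = FALSE]
  if (any(diff(df$wavelength_nm) <= 0)) stop("duplicate wavelengths in spectrum table")
  rownames(df) <- NULL
  attr(df, "units") <- units
  df
}

#' Write a plain-text spectrum table
#'
#' @param df data.frame with columns `wavelength_nm` and `value`.
#' @param path destination file.
#' @param units coefficient unit of `value` (`"m^-1"` or `"cm^-1"`).
#' @param comment optional comment string written at the top.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(df, path, units = c("m^-1", "cm^-1"),
                                 comment = NULL) {
  units <- match.arg(units)
  stopifnot(all(c("wavelength_nm", "value") %in% names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(sprintf("# units: %s", units), con)
  writeLines(sprintf("%.10g %.10g", df$wavelength_nm, df$value), con)
  invisible(path)
}
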