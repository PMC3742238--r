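#' @importFrom stats approx cor lm coef rnorm sd
#' @importFrom pracma trapz
NULL

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`, which must lie within the spectrum's
#' support. Kind and metadata are preserved.
#'
#' @param spectrum a [Spectrum-class]
#' @param grid strictly increasing target wavelengths (nm), within the
#'   spectrum's wavelength range
#' @return a [Spectrum-class] on `grid`
#' @export
resample <- function(spectrum, grid) {
    stopifnot(is(spectrum, "Spectrum"))
    grid <- as.numeric(grid)
    wl <- spectrum@wavelength
    if (min(grid) < min(wl) || max(grid) > max(wl))
        stop(sprintf("resample: grid [%g, %g] outside spectrum support [%g, %g]",
                     min(grid), max(grid), min(wl), max(wl)))
    v <- approx(wl, spectrum@values, xout = grid)$y
    Spectrum(grid, v, kind = spectrum@kind, meta = spectrum@meta)
}

#' Trapezoidal integral of a spectrum over a wavelength window
#'
#' Integrates the readings over `[lo, hi]` on the native grid (endpoints are
#' obtained by linear interpolation when they fall between grid points).
#' Result is in value-times-nm units.
#'
#' @param spectrum a [Spectrum-class]
#' @param lo,hi integration bounds (nm); default full support
#' @return the integral (numeric scalar)
#' @export
integrateSpectrum <- function(spectrum,
                              lo = min(spectrum@wavelength),
                              hi = max(spectrum@wavelength)) {
    stopifnot(is(spectrum, "Spectrum"))
    wl <- spectrum@wavelength
    if (lo >= hi)
        stop("integrateSpectrum: lo must be < hi")
    if (lo < min(wl) || hi > max(wl))
        stop(sprintf("integrateSpectrum: window [%g, %g] outside support [%g, %g]",
                     lo, hi, min(wl), max(wl)))
    inner <- wl[wl > lo & wl < hi]
    x <- c(lo, inner, hi)
    y <- approx(wl, spectrum@values, xout = x)$y
    trapz(x, y)
}

#' Locate the band maximum in a wavelength window
#'
#' Returns the grid point of maximum reading within `[lo, hi]`. Ties are
#' broken toward the shorter wavelength, so repeated calls on a fixed band
#' shape report a stable peak position for the emission-shift analysis. A
#' completely flat window returns `lo` with `flat = TRUE`.
#'
#' @param spectrum a [Spectrum-class]
#' @param lo,hi window bounds (nm); default full support
#' @return list with `wavelength_nm`, `value`, and logical `flat`
#' @export
peakMax <- function(spectrum,
                    lo = min(spectrum@wavelength),
                    hi = max(spectrum@wavelength)) {
    stopifnot(is(spectrum, "Spectrum"))
    idx <- which(spectrum@wavelength >= lo & spectrum@wavelength <= hi)
    if (!length(idx))
        stop("peakMax: empty window")
    v <- spectrum@values[idx]
    if (max(v) == min(v) && length(v) > 1L)
        return(list(wavelength_nm = spectrum@wavelength[idx[1]],
                    value = v[1], flat = TRUE))
    i <- idx[which.max(v)]   # which.max returns the first (shortest-wavelength) tie
    list(wavelength_nm = spectrum@wavelength[i],
         value = spectrum@values[i], flat = FALSE)
}

#' Pointwise difference of two spectra
#'
#' `a - b` on the union of both grids restricted to the common support; both
#' spectra must have the same kind. Used for difference absorption spectra
#' (complex minus free ligand).
#'
#' @param a,b [Spectrum-class] objects of identical kind with overlapping
#'   wavelength support
#' @return a [Spectrum-class] holding `a - b`
#' @export
differenceSpectrum <- function(a, b) {
    stopifnot(is(a, "Spectrum"), is(b, "Spectrum"))
    if (a@kind != b@kind)
        stop(sprintf("differenceSpectrum: kind mismatch ('%s' vs '%s')",
                     a@kind, b@kind))
    lo <- max(min(a@wavelength), min(b@wavelength))
    hi <- min(max(a@wavelength), max(b@wavelength))
    if (lo >= hi)
        stop("differenceSpectrum: spectra have no overlapping support")
    grid <- sort(unique(c(a@wavelength, b@wavelength)))
    grid <- grid[grid >= lo & grid <= hi]
    va <- approx(a@wavelength, a@values, xout = grid)$y
    vb <- approx(b@wavelength, b@values, xout = grid)$y
    d <- va - vb
    ## a difference of nonnegative-kind spectra can legitimately go negative;
    ## retag as generic a.u. in that case so the nonnegativity invariant holds
    kind <- a@kind
    if (kind %in% .NONNEG_KINDS && any(d < 0)) kind <- "emission_au"
    meta <- a@meta
    meta$difference_of <- a@kind
    Spectrum(grid, d, kind = kind, meta = meta)
}

#' Common overlap grid of two spectra
#'
#' Union of both wavelength grids restricted to the intersection of their
#' supports. Internal helper for the overlap integral and difference spectra.
#' @noRd
.commonGrid <- function(a, b) {
    lo <- max(min(a@wavelength), min(b@wavelength))
    hi <- min(max(a@wavelength), max(b@wavelength))
    if (lo >= hi)
        stop("spectra have no overlapping support")
    grid <- sort(unique(c(a@wavelength, b@wavelength)))
    grid[grid >= lo & grid <= hi]
}

## ---- CSV I/O ------------------------------------------------------------

#' Read / write spectra as annotated two-column CSV
#'
#' The format is a plain CSV with header `wavelength_nm,value`, preceded by
#' `#`-prefixed comment lines carrying the kind and metadata:
#' ```
#' # kind: emission_au
#' # meta temperature_K: 298
#' wavelength_nm,value
#' 300,0.12
#' ```
#' The round trip `readSpectrumCsv(writeSpectrumCsv(s))` preserves
#' wavelengths and values to full double precision.
#'
#' @param path file path
#' @return `readSpectrumCsv` returns a [Spectrum-class]
#' @export
readSpectrumCsv <- function(path) {
    if (!file.exists(path))
        stop(sprintf("readSpectrumCsv: no such file: %s", path))
    lines <- readLines(path)
    kind <- "emission_au"
    meta <- list()
    header_i <- NA_integer_
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (grepl("^\\s*#", ln)) {
            body <- sub("^\\s*#\\s*", "", ln)
            if (grepl("^kind:", body)) {
                kind <- trimws(sub("^kind:", "", body))
            } else if (grepl("^meta ", body)) {
                kv <- sub("^meta ", "", body)
                key <- trimws(sub(":.*$", "", kv))
                val <- trimws(sub("^[^:]*:", "", kv))
                num <- suppressWarnings(as.numeric(val))
                meta[[key]] <- if (!is.na(num)) num else val
            }
        } else {
            header_i <- i
            break
        }
    }
    if (is.na(header_i) || !grepl("^\\s*wavelength_nm\\s*,\\s*value\\s*$",
                                  lines[header_i]))
        stop(sprintf("readSpectrumCsv: missing 'wavelength_nm,value' header at line %d",
                     if (is.na(header_i)) length(lines) else header_i))
    data_lines <- lines[-seq_len(header_i)]
    data_lines <- data_lines[nzchar(trimws(data_lines))]
    parts <- strsplit(data_lines, ",", fixed = TRUE)
    bad <- which(vapply(parts, length, 0L) != 2L)
    if (length(bad))
        stop(sprintf("readSpectrumCsv: malformed row at line %d",
                     header_i + bad[1]))
    wl <- as.numeric(vapply(parts, `[[`, "", 1L))
    v <- as.numeric(vapply(parts, `[[`, "", 2L))
    nafail <- which(is.na(wl) | is.na(v) | !is.finite(wl) | !is.finite(v))
    if (length(nafail))
        stop(sprintf("readSpectrumCsv: non-numeric or non-finite value at line %d",
                     header_i + nafail[1]))
    nonmono <- which(diff(wl) <= 0)
    if (length(nonmono))
        stop(sprintf("readSpectrumCsv: wavelengths not strictly increasing at line %d",
                     header_i + nonmono[1] + 1L))
    Spectrum(wl, v, kind = kind, meta = meta)
}

#' @rdname readSpectrumCsv
#' @param spectrum a [Spectrum-class] to write
#' @export
writeSpectrumCsv <- function(spectrum, path) {
    stopifnot(is(spectrum, "Spectrum"))
    lines <- c(sprintf("# kind: %s", spectrum@kind))
    for (key in names(spectrum@meta)) {
        val <- spectrum@meta[[key]]
        if (is.numeric(val) && length(val) == 1L)
            lines <- c(lines, sprintf("# meta %s: %.17g", key, val))
        else if (is.character(val) && length(val) == 1L)
            lines <- c(lines, sprintf("# meta %s: %s", key, val))
    }
    lines <- c(lines, "wavelength_nm,value",
               sprintf("%.17g,%.17g", spectrum@wavelength, spectrum@values))
    writeLines(lines, path)
    invisible(path)
}
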