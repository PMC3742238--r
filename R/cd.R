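#' Mean residue ellipticity at a wavelength
#'
#' Converts observed circular dichroism (millidegrees) to mean residue
#' ellipticity: MRE = theta_obs / (10 * Cp * n_res * l), in
#' deg cm^2 dmol^-1. The observed signal at the requested wavelength is
#' obtained by linear interpolation on the instrument grid.
#'
#' @param measurement a [CDMeasurement-class]
#' @param wavelength_nm wavelength within the spectrum's support
#' @return MRE in deg cm^2 dmol^-1
#' @export
mre <- function(measurement, wavelength_nm) {
    stopifnot(is(measurement, "CDMeasurement"))
    sp <- measurement@spectrum
    if (wavelength_nm < min(sp@wavelength) || wavelength_nm > max(sp@wavelength))
        stop(sprintf("mre: %g nm outside spectrum support [%g, %g]",
                     wavelength_nm, min(sp@wavelength), max(sp@wavelength)))
    theta <- approx(sp@wavelength, sp@values, xout = wavelength_nm)$y
    theta / (10 * measurement@Cp_M * measurement@n_res * measurement@path_cm)
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' helix(%) = (-MRE208 - 4000) * 100 / (33000 - 4000), where -4000 and
#' -33000 deg cm^2 dmol^-1 are the 208 nm reference values of pure random
#' coil and pure alpha-helix. The raw value can leave [0, 100] on noisy
#' data; the reported `percent` is clamped, `raw` is not.
#'
#' @param MRE208 mean residue ellipticity at 208 nm (deg cm^2 dmol^-1)
#' @return list with `percent` (clamped to [0, 100]) and `raw`
#' @examples
#' helixPercent(-20385)$percent   # 56.5
#' @export
helixPercent <- function(MRE208) {
    raw <- (-MRE208 - 4000) * 100 / (33000 - 4000)
    list(percent = min(100, max(0, raw)), raw = raw)
}

#' Helix content across a series of CD measurements
#'
#' Applies [mre()] at 208 nm and [helixPercent()] to each measurement; when
#' the labels are ordered by increasing ligand:protein ratio the
#' `monotone_decrease` attribute reports whether helicity falls along the
#' series, the usual signature of ligand-induced secondary-structure loss.
#'
#' @param measurements named list of [CDMeasurement-class] (names are the
#'   sample labels, e.g. molar ratios)
#' @return data.frame with columns `label`, `MRE208`, `helix_percent`,
#'   `helix_raw`; attribute `monotone_decrease`
#' @export
helixSeries <- function(measurements) {
    stopifnot(length(measurements) >= 1L)
    labels <- names(measurements)
    if (is.null(labels)) labels <- as.character(seq_along(measurements))
    rows <- lapply(seq_along(measurements), function(i) {
        m208 <- mre(measurements[[i]], 208)
        hp <- helixPercent(m208)
        data.frame(label = labels[i], MRE208 = m208,
                   helix_percent = hp$percent, helix_raw = hp$raw,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "monotone_decrease") <-
        length(out$helix_percent) > 1L && all(diff(out$helix_percent) < 0)
    out
}

#' Read a CD measurement from an annotated spectrum CSV
#'
#' The spectrum CSV must carry `# meta Cp_M:`, and may carry `# meta n_res:`
#' and `# meta path_cm:` (defaults 583 and 1).
#'
#' @param path file path
#' @return a [CDMeasurement-class]
#' @export
readCDMeasurementCsv <- function(path) {
    sp <- readSpectrumCsv(path)
    if (sp@kind != "cd_mdeg")
        stop(sprintf("readCDMeasurementCsv: expected kind cd_mdeg, got %s", sp@kind))
    if (is.null(sp@meta$Cp_M))
        stop("readCDMeasurementCsv: missing '# meta Cp_M:' line")
    CDMeasurement(sp, Cp_M = sp@meta$Cp_M,
                  n_res = if (is.null(sp@meta$n_res)) 583 else sp@meta$n_res,
                  path_cm = if (is.null(sp@meta$path_cm)) 1 else sp@meta$path_cm)
}
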