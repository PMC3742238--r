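#' @import methods
NULL

## Recognised spectrum kinds; absorptivity/absorbance must be nonnegative.
.SPECTRUM_KINDS <- c("emission_au", "molar_absorptivity_M_cm",
                     "absorbance_au", "cd_mdeg")
.NONNEG_KINDS <- c("molar_absorptivity_M_cm", "absorbance_au")

#' Spectrum: values on a strictly increasing wavelength grid
#'
#' The common currency of all analysis stages: a wavelength axis in nm, one
#' reading per grid point, a `kind` tag identifying the physical quantity
#' (fluorescence emission in arbitrary units, molar absorptivity in
#' M^-1 cm^-1, absorbance, or circular dichroism in millidegrees), and
#' free-form metadata (temperature, sample id, synchronous-scan offset, ...).
#'
#' @slot wavelength numeric, strictly increasing wavelengths in nm (length >= 2)
#' @slot values numeric, same length as `wavelength`
#' @slot kind one of `"emission_au"`, `"molar_absorptivity_M_cm"`,
#'   `"absorbance_au"`, `"cd_mdeg"`
#' @slot meta named list of annotations
#' @exportClass Spectrum
setClass("Spectrum",
         slots = c(wavelength = "numeric", values = "numeric",
                   kind = "character", meta = "list"))

setValidity("Spectrum", function(object) {
    wl <- object@wavelength
    v <- object@values
    if (length(wl) < 2L)
        return("wavelength grid must have at least 2 points")
    if (length(v) != length(wl))
        return("wavelength and values must have equal length")
    if (any(!is.finite(wl)) || any(!is.finite(v)))
        return("wavelengths and values must be finite")
    if (any(diff(wl) <= 0))
        return("wavelengths must be strictly increasing")
    if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
        return(sprintf("kind must be one of: %s",
                       paste(.SPECTRUM_KINDS, collapse = ", ")))
    if (object@kind %in% .NONNEG_KINDS && any(v < 0))
        return(sprintf("values must be >= 0 for kind '%s'", object@kind))
    TRUE
})

#' Construct a Spectrum
#'
#' @param wavelength strictly increasing wavelengths (nm)
#' @param values readings, same length
#' @param kind spectrum kind tag
#' @param meta named list of annotations
#' @return a [Spectrum-class] object
#' @examples
#' s <- Spectrum(300:400, dnorm(300:400, 340, 15), kind = "emission_au")
#' peakMax(s)
#' @export
Spectrum <- function(wavelength, values, kind = "emission_au", meta = list()) {
    new("Spectrum", wavelength = as.numeric(wavelength),
        values = as.numeric(values), kind = kind, meta = meta)
}

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum <%s>: %d points, %.6g-%.6g nm\n",
                object@kind, length(object@wavelength),
                min(object@wavelength), max(object@wavelength)))
    if (length(object@meta))
        cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

#' Fluorescence titration series at one temperature
#'
#' Quencher concentration series with observed intensities and the paired
#' excitation/emission absorbances needed for the inner-filter correction.
#' The first point has zero quencher and defines F0. `ligandEpsilon` is the
#' ligand molar absorptivity (at the excitation wavelength unless noted) used
#' by the ligand-absorbance correction, `pathCm` the cuvette path length.
#'
#' @slot T_K temperature (K)
#' @slot Q_M quencher concentrations (mol/L), strictly increasing, first 0
#' @slot F_obs observed intensities (a.u.), > 0
#' @slot A_ex,A_em absorbances at excitation / emission wavelength (>= 0)
#' @slot ligandEpsilon ligand molar absorptivity (M^-1 cm^-1)
#' @slot pathCm cuvette path length (cm)
#' @slot meta free-form annotations
#' @exportClass TitrationSeries
setClass("TitrationSeries",
         slots = c(T_K = "numeric", Q_M = "numeric", F_obs = "numeric",
                   A_ex = "numeric", A_em = "numeric",
                   ligandEpsilon = "numeric", pathCm = "numeric",
                   meta = "list"))

setValidity("TitrationSeries", function(object) {
    q <- object@Q_M
    n <- length(q)
    if (n < 2L) return("need at least 2 titration points")
    if (length(object@F_obs) != n || length(object@A_ex) != n ||
        length(object@A_em) != n)
        return("Q_M, F_obs, A_ex, A_em must have equal length")
    if (q[1] != 0) return("first point must have Q_M = 0 (defines F0)")
    if (any(diff(q) <= 0)) return("Q_M must be strictly increasing")
    if (any(object@F_obs <= 0)) return("intensities must be > 0")
    if (any(object@A_ex < 0) || any(object@A_em < 0))
        return("absorbances must be >= 0")
    if (length(object@T_K) != 1L || !is.finite(object@T_K) || object@T_K <= 0)
        return("T_K must be a single positive number")
    if (object@ligandEpsilon < 0 || object@pathCm <= 0)
        return("ligandEpsilon must be >= 0 and pathCm > 0")
    TRUE
})

#' Construct a TitrationSeries
#'
#' @param T_K temperature in K
#' @param Q_M quencher concentrations, first must be 0
#' @param F_obs observed intensities
#' @param A_ex,A_em per-point absorbances (default 0)
#' @param ligandEpsilon ligand molar absorptivity, M^-1 cm^-1 (default 0)
#' @param pathCm path length in cm (default 1)
#' @param meta annotation list
#' @return a [TitrationSeries-class]
#' @export
TitrationSeries <- function(T_K, Q_M, F_obs,
                            A_ex = rep(0, length(Q_M)),
                            A_em = rep(0, length(Q_M)),
                            ligandEpsilon = 0, pathCm = 1, meta = list()) {
    new("TitrationSeries", T_K = as.numeric(T_K), Q_M = as.numeric(Q_M),
        F_obs = as.numeric(F_obs), A_ex = as.numeric(A_ex),
        A_em = as.numeric(A_em), ligandEpsilon = as.numeric(ligandEpsilon),
        pathCm = as.numeric(pathCm), meta = meta)
}

setMethod("show", "TitrationSeries", function(object) {
    cat(sprintf("TitrationSeries: %d points, T = %g K, [Q] %.3g-%.3g M\n",
                length(object@Q_M), object@T_K,
                min(object@Q_M), max(object@Q_M)))
})

## ---- fit result classes -------------------------------------------------

#' Stern-Volmer fit result
#'
#' Slope of F0/F against quencher concentration (Ksv, M^-1); the bimolecular
#' quenching rate constant kq = Ksv / tau0 is enforced by construction.
#'
#' @slot Ksv_per_M Stern-Volmer constant (M^-1)
#' @slot kq_per_M_s bimolecular quenching rate constant (M^-1 s^-1)
#' @slot tau0_s unquenched fluorophore lifetime (s)
#' @slot intercept free regression intercept (the model form predicts 1)
#' @slot r_pearson Pearson correlation of the regression
#' @slot T_K temperature of the series
#' @exportClass SternVolmerFit
setClass("SternVolmerFit",
         slots = c(Ksv_per_M = "numeric", kq_per_M_s = "numeric",
                   tau0_s = "numeric", intercept = "numeric",
                   r_pearson = "numeric", T_K = "numeric"))

setValidity("SternVolmerFit", function(object) {
    if (!isTRUE(all.equal(object@kq_per_M_s,
                          object@Ksv_per_M / object@tau0_s,
                          tolerance = 1e-12)))
        return("kq_per_M_s must equal Ksv_per_M / tau0_s")
    if (abs(object@r_pearson) > 1 + 1e-12)
        return("r_pearson must lie in [-1, 1]")
    TRUE
})

setMethod("show", "SternVolmerFit", function(object) {
    cat(sprintf(paste0("SternVolmerFit (T = %g K): Ksv = %.4g /M, ",
                       "kq = %.4g /M/s (tau0 = %g s), r = %.4f\n"),
                object@T_K, object@Ksv_per_M, object@kq_per_M_s,
                object@tau0_s, object@r_pearson))
})

#' Modified Stern-Volmer fit result
#'
#' From the F0/dF versus 1/[Q] linearization: `fa` is the accessible
#' fluorophore fraction (1/intercept), `Ka` the effective quenching constant
#' (intercept/slope). `valid` is FALSE when the slope is nonpositive
#' (unphysical).
#'
#' @slot Ka_per_M effective quenching constant (M^-1)
#' @slot fa accessible fraction (dimensionless)
#' @slot r_pearson Pearson correlation
#' @slot T_K temperature
#' @slot valid logical validity flag
#' @exportClass ModifiedSVFit
setClass("ModifiedSVFit",
         slots = c(Ka_per_M = "numeric", fa = "numeric",
                   r_pearson = "numeric", T_K = "numeric",
                   valid = "logical"))

setMethod("show", "ModifiedSVFit", function(object) {
    cat(sprintf("ModifiedSVFit (T = %g K): Ka = %.4g /M, fa = %.4f, r = %.4f%s\n",
                object@T_K, object@Ka_per_M, object@fa, object@r_pearson,
                if (object@valid) "" else "  [INVALID]"))
})

#' Double-logarithm binding fit result
#'
#' From log10((F0-F)/F) versus log10[Q]: binding constant `Kb` (10^intercept)
#' and binding-site number `n` (slope).
#'
#' @slot Kb_per_M binding constant (M^-1)
#' @slot n_sites number of binding sites (slope)
#' @slot r_pearson Pearson correlation
#' @slot T_K temperature
#' @exportClass DoubleLogFit
setClass("DoubleLogFit",
         slots = c(Kb_per_M = "numeric", n_sites = "numeric",
                   r_pearson = "numeric", T_K = "numeric"))

setValidity("DoubleLogFit", function(object) {
    if (object@n_sites <= 0) return("n_sites must be > 0")
    TRUE
})

setMethod("show", "DoubleLogFit", function(object) {
    cat(sprintf("DoubleLogFit (T = %g K): Kb = %.4g /M, n = %.4f, r = %.4f\n",
                object@T_K, object@Kb_per_M, object@n_sites,
                object@r_pearson))
})

#' Van't Hoff thermodynamics result
#'
#' Enthalpy and entropy from the ln K versus 1/T regression, Gibbs energies
#' per temperature (dG = dH - T dS by construction), and the classified
#' binding forces.
#'
#' @slot dH_J_mol enthalpy change (J/mol)
#' @slot dS_J_molK entropy change (J/(mol K))
#' @slot dG_J_mol named numeric, Gibbs energy per temperature (J/mol)
#' @slot r_pearson correlation of the Van't Hoff regression
#' @slot forces character subset of hydrophobic / electrostatic /
#'   hydrogen_bond_vdw
#' @slot narrative matched classification rule, human readable
#' @exportClass ThermoResult
setClass("ThermoResult",
         slots = c(dH_J_mol = "numeric", dS_J_molK = "numeric",
                   dG_J_mol = "numeric", r_pearson = "numeric",
                   forces = "character", narrative = "character"))

setValidity("ThermoResult", function(object) {
    Ts <- suppressWarnings(as.numeric(names(object@dG_J_mol)))
    if (length(object@dG_J_mol) && any(is.na(Ts)))
        return("dG_J_mol must be named by temperature")
    for (i in seq_along(object@dG_J_mol)) {
        expected <- object@dH_J_mol - Ts[i] * object@dS_J_molK
        tol <- 1e-9 * max(1, abs(expected))
        if (abs(object@dG_J_mol[i] - expected) > tol)
            return("dG_J_mol inconsistent with dH - T*dS")
    }
    TRUE
})

setMethod("show", "ThermoResult", function(object) {
    cat(sprintf("ThermoResult: dH = %.2f kJ/mol, dS = %.2f J/(mol K), r = %.4f\n",
                object@dH_J_mol / 1000, object@dS_J_molK, object@r_pearson))
    for (i in seq_along(object@dG_J_mol))
        cat(sprintf("  dG(%s K) = %.2f kJ/mol\n",
                    names(object@dG_J_mol)[i], object@dG_J_mol[i] / 1000))
    cat("  forces:", paste(object@forces, collapse = " + "), "\n")
})

#' Forster resonance energy transfer result
#'
#' @slot J_cm3_L_mol spectral overlap integral (cm^3 L mol^-1)
#' @slot R0_cm Forster radius (cm)
#' @slot E transfer efficiency, in [0, 1]
#' @slot r_cm donor-acceptor distance (cm)
#' @slot flags logical: `r_below_8nm`, `within_half_to_1p5_R0`
#' @exportClass FretResult
setClass("FretResult",
         slots = c(J_cm3_L_mol = "numeric", R0_cm = "numeric",
                   E = "numeric", r_cm = "numeric", flags = "logical"))

setValidity("FretResult", function(object) {
    if (object@E < 0 || object@E > 1) return("E must lie in [0, 1]")
    if (object@J_cm3_L_mol < 0) return("J must be >= 0")
    if (object@R0_cm < 0 || object@r_cm < 0)
        return("R0 and r must be >= 0")
    TRUE
})

setMethod("show", "FretResult", function(object) {
    cat(sprintf(paste0("FretResult: J = %.4g cm^3 L/mol, R0 = %.3f nm, ",
                       "E = %.4f, r = %.3f nm\n"),
                object@J_cm3_L_mol, object@R0_cm * 1e7, object@E,
                object@r_cm * 1e7))
    cat(sprintf("  r < 8 nm: %s; 0.5 R0 < r < 1.5 R0: %s\n",
                object@flags[["r_below_8nm"]],
                object@flags[["within_half_to_1p5_R0"]]))
})

#' Circular dichroism measurement
#'
#' An observed CD spectrum in millidegrees together with the metadata needed
#' to convert it to mean residue ellipticity: protein molar concentration,
#' residue count (583 for bovine serum albumin) and cell path length.
#'
#' @slot spectrum a [Spectrum-class] of kind `cd_mdeg`
#' @slot Cp_M protein molar concentration (mol/L)
#' @slot n_res number of amino-acid residues
#' @slot path_cm cell path length (cm)
#' @exportClass CDMeasurement
setClass("CDMeasurement",
         slots = c(spectrum = "Spectrum", Cp_M = "numeric",
                   n_res = "numeric", path_cm = "numeric"))

setValidity("CDMeasurement", function(object) {
    if (object@spectrum@kind != "cd_mdeg")
        return("spectrum kind must be cd_mdeg")
    if (object@Cp_M <= 0) return("Cp_M must be > 0")
    if (object@n_res < 1) return("n_res must be >= 1")
    if (object@path_cm <= 0) return("path_cm must be > 0")
    TRUE
})

#' Construct a CDMeasurement
#'
#' @param spectrum CD spectrum (kind `cd_mdeg`, observed millidegrees)
#' @param Cp_M protein concentration (mol/L)
#' @param n_res residue count (default 583, bovine serum albumin)
#' @param path_cm path length in cm (default 1)
#' @return a [CDMeasurement-class]
#' @export
CDMeasurement <- function(spectrum, Cp_M, n_res = 583, path_cm = 1) {
    new("CDMeasurement", spectrum = spectrum, Cp_M = as.numeric(Cp_M),
        n_res = as.numeric(n_res), path_cm = as.numeric(path_cm))
}

setMethod("show", "CDMeasurement", function(object) {
    cat(sprintf("CDMeasurement: Cp = %.3g M, %d residues, %g cm path\n",
                object@Cp_M, as.integer(object@n_res), object@path_cm))
})
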