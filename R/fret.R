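#' Spectral overlap integral between donor emission and acceptor absorption
#'
#' J = integral(F(l) eps(l) l^4 dl) / integral(F(l) dl) over the common
#' wavelength range of the two spectra, evaluated by trapezoid on the union
#' grid. The fourth power of wavelength is taken with the wavelength in cm
#' (l_cm = l_nm * 1e-7) — the single place wavelengths leave nm — so that
#' with eps in M^-1 cm^-1 the result carries cm^3 L mol^-1; the grid spacing
#' itself cancels between numerator and denominator.
#'
#' @param donor_emission [Spectrum-class] of kind `emission_au`
#' @param acceptor_epsilon [Spectrum-class] of kind
#'   `molar_absorptivity_M_cm`
#' @return J in cm^3 L mol^-1
#' @export
overlapIntegral <- function(donor_emission, acceptor_epsilon) {
    stopifnot(is(donor_emission, "Spectrum"),
              is(acceptor_epsilon, "Spectrum"))
    grid <- .commonGrid(donor_emission, acceptor_epsilon)
    if (length(grid) < 2L)
        stop("overlapIntegral: common grid too small")
    Fd <- resample(donor_emission, grid)@values
    eps <- resample(acceptor_epsilon, grid)@values
    denom <- trapz(grid, Fd)
    if (denom <= 0)
        stop("overlapIntegral: donor emission integrates to zero on the overlap")
    lam_cm <- grid * 1e-7
    trapz(grid, Fd * eps * lam_cm^4) / denom
}

#' Forster radius from the overlap integral
#'
#' R0^6 = 8.79e-25 * K2 * n^-4 * phi * J, with J in cm^3 L mol^-1 and R0 in
#' cm. Defaults are the conventional values for tryptophan-donor systems in
#' aqueous protein solution: orientation factor K2 = 2/3, refractive index
#' 1.36, donor quantum yield 0.15.
#'
#' @param J_cm3_L_mol overlap integral (cm^3 L mol^-1)
#' @param K2 dipole orientation factor (0 < K2 <= 4)
#' @param n_refractive medium refractive index (>= 1)
#' @param phi donor fluorescence quantum yield (0 < phi <= 1)
#' @return R0 in cm
#' @export
forsterRadius <- function(J_cm3_L_mol, K2 = 2/3, n_refractive = 1.36,
                          phi = 0.15) {
    stopifnot(J_cm3_L_mol >= 0, K2 > 0, K2 <= 4, n_refractive >= 1,
              phi > 0, phi <= 1)
    (8.79e-25 * K2 * n_refractive^-4 * phi * J_cm3_L_mol)^(1/6)
}

#' Energy transfer efficiency from donor intensities
#'
#' E = 1 - F/F0: the fractional loss of donor fluorescence in the presence
#' of the acceptor.
#'
#' @param F donor intensity with acceptor present (0 < F <= F0)
#' @param F0 donor intensity without acceptor
#' @return E in [0, 1)
#' @export
transferEfficiency <- function(F, F0) {
    stopifnot(F0 > 0)
    if (any(F > F0))
        stop("transferEfficiency: F exceeds F0")
    if (any(F <= 0))
        stop("transferEfficiency: F must be > 0")
    1 - F / F0
}

#' Donor-acceptor distance from efficiency and Forster radius
#'
#' Inverts E = R0^6 / (R0^6 + r^6): r = R0 * ((1 - E)/E)^(1/6). Also
#' evaluates the two standard validity conditions for resonance energy
#' transfer: the distance must be below 8 nm, and should fall between
#' 0.5 R0 and 1.5 R0 for the sixth-power law to be informative.
#'
#' @param E transfer efficiency, strictly between 0 and 1
#' @param R0_cm Forster radius in cm
#' @return list with `r_cm` and logical `flags` (`r_below_8nm`,
#'   `within_half_to_1p5_R0`)
#' @export
donorAcceptorDistance <- function(E, R0_cm) {
    stopifnot(R0_cm > 0)
    if (E <= 0 || E >= 1)
        stop("donorAcceptorDistance: E must lie strictly between 0 and 1")
    r <- R0_cm * ((1 - E) / E)^(1/6)
    list(r_cm = r,
         flags = c(r_below_8nm = r < 8e-7,
                   within_half_to_1p5_R0 = (r > 0.5 * R0_cm) && (r < 1.5 * R0_cm)))
}

#' Complete Forster resonance energy transfer analysis
#'
#' Overlap integral from the two spectra, Forster radius from the optical
#' constants, efficiency from the donor intensity pair, distance from the
#' sixth-power law, with validity flags.
#'
#' @inheritParams overlapIntegral
#' @inheritParams forsterRadius
#' @param F,F0 donor intensity with / without acceptor (at the equimolar
#'   titration point in the standard experiment design)
#' @return a [FretResult-class]
#' @export
fretAnalysis <- function(donor_emission, acceptor_epsilon, F, F0,
                         K2 = 2/3, n_refractive = 1.36, phi = 0.15) {
    J <- overlapIntegral(donor_emission, acceptor_epsilon)
    R0 <- forsterRadius(J, K2 = K2, n_refractive = n_refractive, phi = phi)
    E <- transferEfficiency(F, F0)
    da <- donorAcceptorDistance(E, R0)
    new("FretResult", J_cm3_L_mol = J, R0_cm = R0, E = E,
        r_cm = da$r_cm, flags = da$flags)
}
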