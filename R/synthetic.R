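#' @importFrom withr with_seed
NULL

.R_GAS <- 8.314   # J/(mol K)

#' Ground truth for the synthetic spectroscopy generator
#'
#' Bundles every parameter needed to simulate the full experiment with known
#' ground truth: binding thermodynamics (which set the temperature-dependent
#' association constant through the Van't Hoff relation), the titration
#' design, donor emission and ligand absorptivity band shapes, CD mixture
#' fractions and the noise model. Defaults emulate a serum-albumin /
#' flavonoid titration: 3e-7 M protein titrated with ligand up to 1.6e-6 M
#' at 288/298/308 K, excitation at 280 nm, donor emission band at 340 nm,
#' ligand absorption bands at 220 and 340 nm, and CD recorded at 5e-7 M
#' protein over a 1 cm path.
#'
#' An exothermic default (`dH_J_mol < 0`) makes the association constant
#' fall with temperature, i.e. static-quenching behaviour; use
#' `dynamicPreset()` for the opposite trend.
#'
#' @param dH_J_mol binding enthalpy (J/mol); default -24020
#' @param dS_J_molK binding entropy (J/(mol K)); default 25.31
#' @param n_sites stoichiometry exponent of the quenching law; default 1
#' @param temperatures_K temperatures (K); default c(288, 298, 308)
#' @param quencher_M quencher concentration series (mol/L), strictly
#'   increasing with first element 0
#' @param donor_peak_nm,donor_width_nm,donor_amplitude Gaussian emission
#'   band: centre (nm), standard deviation (nm), peak intensity (a.u.)
#' @param ligand_bands matrix with columns center_nm, width_nm,
#'   epsilon_peak_M_cm; one row per absorptivity band
#' @param excitation_nm excitation wavelength (nm); default 280
#' @param helix_fractions CD mixture fractions in [0, 1]
#' @param Cp_M,n_res,path_cm CD record metadata (protein concentration,
#'   residue count, path length)
#' @param sync_shift_nm_per_step synchronous-scan peak shift per titration
#'   step (nm); default 0 (no microenvironment change)
#' @param noise_rel relative multiplicative Gaussian noise level; default 0
#' @param seed integer seed driving all randomness
#' @return an object of class `simTruth` (a validated list)
#' @examples
#' tr <- simTruth(noise_rel = 0.01, seed = 7)
#' s <- makeTitration(tr, 298)
#' fitSternVolmer(s)
#' @export
simTruth <- function(dH_J_mol = -24020,
                     dS_J_molK = 25.31,
                     n_sites = 1,
                     temperatures_K = c(288, 298, 308),
                     quencher_M = c(0, 2, 4, 6, 8, 10, 12, 14, 16) * 1e-7,
                     donor_peak_nm = 340,
                     donor_width_nm = 15,
                     donor_amplitude = 1000,
                     ligand_bands = rbind(c(220, 12, 18000),
                                          c(340, 20, 10000)),
                     excitation_nm = 280,
                     helix_fractions = c(0.565, 0.541, 0.515, 0.442),
                     Cp_M = 5e-7, n_res = 583, path_cm = 1,
                     sync_shift_nm_per_step = 0,
                     noise_rel = 0,
                     seed = 1L) {
    ligand_bands <- matrix(as.numeric(ligand_bands), ncol = 3,
                           dimnames = list(NULL, c("center_nm", "width_nm",
                                                   "epsilon_peak_M_cm")))
    truth <- list(dH_J_mol = dH_J_mol, dS_J_molK = dS_J_molK,
                  n_sites = n_sites, temperatures_K = temperatures_K,
                  quencher_M = quencher_M, donor_peak_nm = donor_peak_nm,
                  donor_width_nm = donor_width_nm,
                  donor_amplitude = donor_amplitude,
                  ligand_bands = ligand_bands,
                  excitation_nm = excitation_nm,
                  helix_fractions = helix_fractions,
                  Cp_M = Cp_M, n_res = n_res, path_cm = path_cm,
                  sync_shift_nm_per_step = sync_shift_nm_per_step,
                  noise_rel = noise_rel, seed = as.integer(seed))
    q <- truth$quencher_M
    if (q[1] != 0 || any(q < 0) || any(diff(q) <= 0))
        stop("simTruth: quencher_M must be nonnegative, strictly increasing, starting at 0")
    if (any(truth$helix_fractions < 0) || any(truth$helix_fractions > 1))
        stop("simTruth: helix_fractions must lie in [0, 1]")
    if (truth$noise_rel < 0)
        stop("simTruth: noise_rel must be >= 0")
    if (truth$n_sites <= 0)
        stop("simTruth: n_sites must be > 0")
    if (any(truth$ligand_bands[, "center_nm"] < 200) ||
        any(truth$ligand_bands[, "center_nm"] > 500))
        stop("simTruth: ligand bands must lie within 200-500 nm")
    class(truth) <- "simTruth"
    truth
}

#' Dynamic-quenching preset
#'
#' A ground truth whose association constant rises with temperature and whose
#' implied kq stays below the diffusion-controlled ceiling, producing
#' collisional (dynamic) quenching behaviour for classifier tests. The small
#' positive enthalpy drives K upward with T; the entropy and the millimolar
#' quencher range put Ksv at order 1e2 M^-1, so kq (at tau0 = 1e-8 s) stays
#' under the 2e10 /M/s ceiling.
#'
#' @param ... overrides passed to [simTruth()]
#' @return a `simTruth` object
#' @export
dynamicPreset <- function(...) {
    args <- list(dH_J_mol = +15000,
                 dS_J_molK = 85,
                 quencher_M = c(0, 2, 4, 6, 8, 10, 12, 14, 16) * 1e-3)
    override <- list(...)
    args[names(override)] <- override
    do.call(simTruth, args)
}

#' Association constant at a temperature from the ground truth
#'
#' Evaluates the Van't Hoff relation generatively:
#' K(T) = exp(-dH/(R T) + dS/R) with R = 8.314 J/(mol K).
#'
#' @param truth a [simTruth()] object
#' @param T_K temperature in K (> 0)
#' @return K in M^-1
#' @export
equilibriumConstantAt <- function(truth, T_K) {
    stopifnot(inherits(truth, "simTruth"), T_K > 0)
    exp(-truth$dH_J_mol / (.R_GAS * T_K) + truth$dS_J_molK / .R_GAS)
}

#' Ligand molar absorptivity spectrum from the ground truth
#'
#' Sum of Gaussian bands on a 1 nm grid spanning 200-500 nm.
#'
#' @param truth a [simTruth()] object
#' @return a [Spectrum-class] of kind `molar_absorptivity_M_cm`
#' @export
makeLigandAbsorptivity <- function(truth) {
    stopifnot(inherits(truth, "simTruth"))
    wl <- seq(200, 500, by = 1)
    eps <- rep(0, length(wl))
    for (i in seq_len(nrow(truth$ligand_bands))) {
        b <- truth$ligand_bands[i, ]
        eps <- eps + b["epsilon_peak_M_cm"] *
            exp(-(wl - b["center_nm"])^2 / (2 * b["width_nm"]^2))
    }
    Spectrum(wl, eps, kind = "molar_absorptivity_M_cm",
             meta = list(source = "synthetic"))
}

#' Donor (protein) emission spectrum from the ground truth
#'
#' Single Gaussian band on a 1 nm grid, 200-500 nm, normalised so the peak
#' reading equals `donor_amplitude`.
#'
#' @param truth a [simTruth()] object
#' @return a [Spectrum-class] of kind `emission_au`
#' @export
makeDonorEmission <- function(truth) {
    stopifnot(inherits(truth, "simTruth"))
    wl <- seq(200, 500, by = 1)
    v <- truth$donor_amplitude *
        exp(-(wl - truth$donor_peak_nm)^2 / (2 * truth$donor_width_nm^2))
    Spectrum(wl, v, kind = "emission_au", meta = list(source = "synthetic"))
}

## epsilon of the synthetic ligand at one wavelength (closed form, no grid)
.ligandEpsilonAt <- function(truth, wl) {
    eps <- 0
    for (i in seq_len(nrow(truth$ligand_bands))) {
        b <- truth$ligand_bands[i, ]
        eps <- eps + b[["epsilon_peak_M_cm"]] *
            exp(-(wl - b[["center_nm"]])^2 / (2 * b[["width_nm"]]^2))
    }
    eps
}

#' Simulate one temperature's fluorescence titration
#'
#' For each quencher concentration the true quenched intensity follows the
#' static complexation law F = F0 / (1 + K(T) [Q]^n) with K(T) from
#' [equilibriumConstantAt()]. Per-point excitation/emission absorbances are
#' the ligand's absorptivity at the excitation wavelength and at the donor
#' peak times [Q] and the path length. The OBSERVED intensity is the true
#' intensity attenuated by the exact inverse of the inner-filter and
#' ligand-absorbance corrections, so applying [correctSeries()] with default
#' settings recovers the true quenched intensities exactly. Multiplicative
#' Gaussian noise (1 + noise_rel * z) is applied last; all randomness is
#' reproducible from the truth's seed (offset by the temperature index so
#' different temperatures draw independent noise).
#'
#' @param truth a [simTruth()] object
#' @param T_K one of `truth$temperatures_K`
#' @return a [TitrationSeries-class]; ground-truth quantities (K, F_true)
#'   are attached in `meta`
#' @export
makeTitration <- function(truth, T_K) {
    stopifnot(inherits(truth, "simTruth"))
    if (!T_K %in% truth$temperatures_K)
        stop(sprintf("makeTitration: T = %g K not in truth$temperatures_K", T_K))
    K <- equilibriumConstantAt(truth, T_K)
    Q <- truth$quencher_M
    F0 <- truth$donor_amplitude
    Ftrue <- F0 / (1 + K * Q^truth$n_sites)
    epsEx <- .ligandEpsilonAt(truth, truth$excitation_nm)
    epsEm <- .ligandEpsilonAt(truth, truth$donor_peak_nm)
    Aex <- epsEx * Q * truth$path_cm
    Aem <- epsEm * Q * truth$path_cm
    ## inverse of: Fcor = Fobs exp((Aex+Aem)/2); F = Fcor exp(-2.303 eps l Q)
    Fobs <- Ftrue * exp(-(Aex + Aem) / 2 + 2.303 * epsEx * truth$path_cm * Q)
    if (truth$noise_rel > 0) {
        ti <- match(T_K, truth$temperatures_K)
        Fobs <- withr::with_seed(truth$seed + 1000L * ti, {
            Fobs * (1 + truth$noise_rel * rnorm(length(Fobs)))
        })
        if (any(Fobs <= 0))
            stop("makeTitration: noise drove an intensity nonpositive; lower noise_rel")
    }
    TitrationSeries(T_K = T_K, Q_M = Q, F_obs = Fobs,
                    A_ex = Aex, A_em = Aem,
                    ligandEpsilon = epsEx, pathCm = truth$path_cm,
                    meta = list(K_true_per_M = K, F_true = Ftrue,
                                n_sites_true = truth$n_sites,
                                source = "synthetic"))
}

#' Simulate a synchronous-scan series
#'
#' One band spectrum per quencher concentration at a fixed
#' excitation-emission offset (15 nm probes tyrosine, 60 nm tryptophan).
#' Peak intensities scale with the same quenching factor as
#' [makeTitration()]; the peak wavelength is constant unless
#' `sync_shift_nm_per_step` is nonzero, in which case the band centre moves
#' by that amount per titration step (emulating a polarity change around the
#' probed residues).
#'
#' @param truth a [simTruth()] object
#' @param delta_lambda_nm scan offset (nm), conventionally 15 or 60
#' @param T_K temperature, one of `truth$temperatures_K`
#' @return list of [Spectrum-class], one per quencher concentration, each
#'   annotated with `Q_M` and `delta_lambda_nm`
#' @export
makeSynchronous <- function(truth, delta_lambda_nm, T_K) {
    stopifnot(inherits(truth, "simTruth"))
    K <- equilibriumConstantAt(truth, T_K)
    ## tyrosine band near 300 nm for the 15 nm offset, tryptophan near the
    ## donor peak for 60 nm; other offsets fall back to the donor band
    center0 <- if (delta_lambda_nm == 15) 300 else truth$donor_peak_nm
    window <- if (delta_lambda_nm == 15) c(255, 400) else c(300, 400)
    wl <- seq(window[1], window[2], by = 1)
    lapply(seq_along(truth$quencher_M), function(i) {
        Q <- truth$quencher_M[i]
        quench <- 1 / (1 + K * Q^truth$n_sites)
        center <- center0 + truth$sync_shift_nm_per_step * (i - 1L)
        v <- truth$donor_amplitude * quench *
            exp(-(wl - center)^2 / (2 * (truth$donor_width_nm / 2)^2))
        Spectrum(wl, v, kind = "emission_au",
                 meta = list(Q_M = Q, delta_lambda_nm = delta_lambda_nm,
                             T_K = T_K, source = "synthetic"))
    })
}

## CD basis signals (mean residue ellipticity, deg cm^2 dmol^-1) on a
## 200-250 nm grid. The helix basis has the two characteristic negative
## bands at 208 and 222 nm and is pinned to -33000 at 208 nm; the random
## coil basis is pinned to -4000 at 208 nm.
.cdBasisGrid <- function() seq(200, 250, by = 0.5)

.helixBasisMRE <- function(wl) {
    shape <- exp(-(wl - 208)^2 / (2 * 6.5^2)) +
        0.88 * exp(-(wl - 222)^2 / (2 * 7^2))
    at208 <- exp(0) + 0.88 * exp(-(222 - 208)^2 / (2 * 7^2))
    -33000 * shape / at208
}

.coilBasisMRE <- function(wl) {
    -4000 * exp(-(wl - 208)^2 / (2 * 9^2))
}

#' Simulate a CD measurement with known helix fraction
#'
#' The mean-residue-ellipticity spectrum is a two-state mixture,
#' f * helix + (1 - f) * coil, of basis signals pinned to -33000 and -4000
#' deg cm^2 dmol^-1 at 208 nm respectively. It is converted to observed
#' millidegrees by inverting the MRE normalisation (observed = MRE * 10 *
#' Cp * n_res * l) so that [mre()] followed by [helixPercent()] recovers
#' `100 * helix_fraction` exactly on noiseless data.
#'
#' @param truth a [simTruth()] object (supplies Cp, residue count, path)
#' @param helix_fraction mixture fraction in [0, 1]
#' @return a [CDMeasurement-class]
#' @export
makeCD <- function(truth, helix_fraction) {
    stopifnot(inherits(truth, "simTruth"),
              helix_fraction >= 0, helix_fraction <= 1)
    wl <- .cdBasisGrid()
    mre <- helix_fraction * .helixBasisMRE(wl) +
        (1 - helix_fraction) * .coilBasisMRE(wl)
    mdeg <- mre * 10 * truth$Cp_M * truth$n_res * truth$path_cm
    sp <- Spectrum(wl, mdeg, kind = "cd_mdeg",
                   meta = list(helix_fraction_true = helix_fraction,
                               source = "synthetic"))
    CDMeasurement(sp, Cp_M = truth$Cp_M, n_res = truth$n_res,
                  path_cm = truth$path_cm)
}

## ---- dataset export -----------------------------------------------------

#' Write a complete synthetic dataset to disk
#'
#' One titration CSV per temperature (columns Q_M, F_obs, Aex, Aem with
#' metadata comments), donor-emission and ligand-absorptivity spectrum CSVs,
#' CD spectrum CSVs (one per helix fraction), and a ground-truth JSON.
#' Output is byte-identical for identical truth (including seed).
#'
#' @param truth a [simTruth()] object
#' @param dir output directory (created if absent)
#' @return invisibly, the vector of files written
#' @export
simulateDataset <- function(truth, dir) {
    stopifnot(inherits(truth, "simTruth"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    for (T_K in truth$temperatures_K) {
        s <- makeTitration(truth, T_K)
        f <- file.path(dir, sprintf("titration_%gK.csv", T_K))
        writeTitrationCsv(s, f)
        written <- c(written, f)
    }
    f <- file.path(dir, "donor_emission.csv")
    writeSpectrumCsv(makeDonorEmission(truth), f)
    written <- c(written, f)
    f <- file.path(dir, "ligand_absorptivity.csv")
    writeSpectrumCsv(makeLigandAbsorptivity(truth), f)
    written <- c(written, f)
    for (i in seq_along(truth$helix_fractions)) {
        m <- makeCD(truth, truth$helix_fractions[i])
        f <- file.path(dir, sprintf("cd_%02d.csv", i))
        sp <- m@spectrum
        sp@meta$Cp_M <- m@Cp_M
        sp@meta$n_res <- m@n_res
        sp@meta$path_cm <- m@path_cm
        writeSpectrumCsv(sp, f)
        written <- c(written, f)
    }
    f <- file.path(dir, "ground_truth.json")
    gt <- truth
    class(gt) <- NULL
    jsonlite::write_json(gt, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
    invisible(written)
}
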