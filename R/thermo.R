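#' Van't Hoff regression of binding constants on temperature
#'
#' Ordinary least squares of ln K against 1/T: the enthalpy change is
#' -R * slope and the entropy change R * intercept, with
#' R = 8.314 J/(mol K). Assumes the enthalpy is constant over the (narrow)
#' temperature range analysed.
#'
#' @param T_K temperatures (K), at least 2 distinct values
#' @param K_per_M positive binding constants, one per temperature
#' @return list with `dH_J_mol`, `dS_J_molK`, `r_pearson`
#' @examples
#' fitVantHoff(c(288, 298, 308), c(1.679e6, 1.230e6, 0.857e6))
#' @export
fitVantHoff <- function(T_K, K_per_M) {
    stopifnot(length(T_K) == length(K_per_M), length(T_K) >= 2L,
              all(T_K > 0), all(K_per_M > 0))
    if (anyDuplicated(T_K))
        stop("fitVantHoff: duplicate temperatures")
    x <- 1 / T_K
    y <- log(K_per_M)
    fit <- lm(y ~ x)
    r <- if (sd(y) == 0) 0 else cor(x, y)   # flat series: no correlation
    list(dH_J_mol = -.R_GAS * unname(coef(fit)[2]),
         dS_J_molK = .R_GAS * unname(coef(fit)[1]),
         r_pearson = r)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T * dS` (all in SI: J/mol, J/(mol K), K). Vectorised over
#' temperature.
#'
#' @param dH_J_mol enthalpy change (J/mol)
#' @param dS_J_molK entropy change (J/(mol K))
#' @param T_K temperature(s), K (> 0)
#' @return Gibbs energy change(s), J/mol
#' @examples
#' gibbs(-24020, 25.31, c(288, 298, 308)) / 1000   # kJ/mol
#' @export
gibbs <- function(dH_J_mol, dS_J_molK, T_K) {
    stopifnot(all(T_K > 0))
    dH_J_mol - T_K * dS_J_molK
}

#' Classify the dominant binding forces from the thermodynamic signature
#'
#' The sign pattern of the enthalpy and entropy changes is the standard
#' evidence for the dominant non-covalent interaction in ligand-protein
#' binding: a positive entropy change indicates hydrophobic contacts; an
#' enthalpy near zero with positive entropy is characteristic of
#' electrostatic interactions; a clearly negative enthalpy together with
#' positive entropy points to both hydrophobic and electrostatic
#' contributions; negative enthalpy with negative entropy indicates
#' hydrogen bonding and Van der Waals contacts. "Near zero" is
#' `near_zero_J_mol` (default 2 kJ/mol, configurable).
#'
#' @param dH_J_mol enthalpy change (J/mol)
#' @param dS_J_molK entropy change (J/(mol K))
#' @param near_zero_J_mol half-width of the near-zero enthalpy band (J/mol)
#' @return list with `forces` (character vector, possibly empty) and
#'   `narrative` naming the matched rule
#' @examples
#' classifyForces(-24020, 25.31)
#' @export
classifyForces <- function(dH_J_mol, dS_J_molK, near_zero_J_mol = 2000) {
    if (abs(dH_J_mol) <= near_zero_J_mol && dS_J_molK > 0)
        return(list(forces = "electrostatic",
                    narrative = "dH near zero with dS > 0: electrostatic interactions dominate"))
    if (dH_J_mol < -near_zero_J_mol && dS_J_molK > 0)
        return(list(forces = c("hydrophobic", "electrostatic"),
                    narrative = paste("dH < 0 with dS > 0: hydrophobic and electrostatic",
                                      "interactions both contribute")))
    if (dH_J_mol > near_zero_J_mol && dS_J_molK > 0)
        return(list(forces = "hydrophobic",
                    narrative = "dH > 0 with dS > 0: hydrophobic interactions dominate"))
    if (dH_J_mol < 0 && dS_J_molK < 0)
        return(list(forces = "hydrogen_bond_vdw",
                    narrative = "dH < 0 with dS < 0: hydrogen bonding and Van der Waals forces"))
    list(forces = character(),
         narrative = "no rule matched (dH > 0 with dS <= 0, or dS = 0): indeterminate")
}

#' Full thermodynamic analysis of a binding-constant series
#'
#' Runs [fitVantHoff()], evaluates [gibbs()] at every input temperature, and
#' classifies the binding forces; returns a validated [ThermoResult-class]
#' whose stored Gibbs energies satisfy dG = dH - T dS by construction.
#'
#' @inheritParams fitVantHoff
#' @param near_zero_J_mol passed to [classifyForces()]
#' @return a [ThermoResult-class]
#' @export
thermoAnalysis <- function(T_K, K_per_M, near_zero_J_mol = 2000) {
    vh <- fitVantHoff(T_K, K_per_M)
    dG <- gibbs(vh$dH_J_mol, vh$dS_J_molK, T_K)
    names(dG) <- as.character(T_K)
    fc <- classifyForces(vh$dH_J_mol, vh$dS_J_molK, near_zero_J_mol)
    new("ThermoResult", dH_J_mol = vh$dH_J_mol, dS_J_molK = vh$dS_J_molK,
        dG_J_mol = dG, r_pearson = vh$r_pearson,
        forces = fc$forces, narrative = fc$narrative)
}
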