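#' Inner-filter correction of an observed fluorescence intensity
#'
#' Re-excitation and emission attenuation by sample absorbance are undone
#' with the standard half-absorbance correction
#' `F_cor = F_obs * exp((A_ex + A_em) / 2)`.
#'
#' @param F_obs observed intensity (a.u.); vectorised
#' @param A_ex,A_em absorbance at the excitation / emission wavelength
#' @return corrected intensity
#' @examples
#' correctInnerFilter(100, 0.10, 0.05)   # 100 * exp(0.075)
#' @export
correctInnerFilter <- function(F_obs, A_ex, A_em) {
    stopifnot(all(is.finite(A_ex)), all(is.finite(A_em)))
    F_obs * exp((A_ex + A_em) / 2)
}

#' Ligand-absorbance correction of a fluorescence intensity
#'
#' Corrects for light absorbed by the titrated ligand itself:
#' `F = F_u * exp(sign * 2.303 * epsilon * path * L0)`. The published form
#' of this correction carries a negative exponent (`sign = "as_printed"`,
#' attenuating); the amplifying convention is available as
#' `sign = "inverted"`, and the two compose to the identity.
#'
#' @param F_u intensity before this correction (a.u.); vectorised
#' @param epsilon_M_cm ligand molar absorptivity (M^-1 cm^-1)
#' @param path_cm path length (cm)
#' @param L0_M ligand concentration (mol/L)
#' @param sign `"as_printed"` (exponent -2.303 eps l L0) or `"inverted"`
#' @return corrected intensity
#' @export
correctLigandAbsorbance <- function(F_u, epsilon_M_cm, path_cm, L0_M,
                                    sign = c("as_printed", "inverted")) {
    sign <- match.arg(sign)
    stopifnot(epsilon_M_cm >= 0, path_cm >= 0, all(L0_M >= 0))
    s <- if (sign == "as_printed") -1 else +1
    F_u * exp(s * 2.303 * epsilon_M_cm * path_cm * L0_M)
}

#' Apply both intensity corrections to a titration series
#'
#' Inner-filter correction first, then the ligand-absorbance correction
#' using the series' stored molar absorptivity, path length and each point's
#' quencher concentration as the absorber concentration.
#'
#' @param series a [TitrationSeries-class]
#' @param eq12_sign sign convention for the ligand-absorbance correction
#' @return numeric vector of corrected intensities, one per point
#' @export
correctSeries <- function(series, eq12_sign = c("as_printed", "inverted")) {
    stopifnot(is(series, "TitrationSeries"))
    eq12_sign <- match.arg(eq12_sign)
    f <- correctInnerFilter(series@F_obs, series@A_ex, series@A_em)
    correctLigandAbsorbance(f, series@ligandEpsilon, series@pathCm,
                            series@Q_M, sign = eq12_sign)
}

## Pearson r with a zero-variance guard (flat series: no correlation)
.safeCor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
}

## corrected intensities + F0, shared by the three fits
.correctedF <- function(series, correct, eq12_sign) {
    f <- if (correct) correctSeries(series, eq12_sign) else series@F_obs
    if (any(f <= 0))
        stop("nonpositive intensity after correction")
    list(f = f, f0 = f[1])
}

#' Stern-Volmer quenching fit
#'
#' Ordinary least squares of F0/F against quencher concentration (all points
#' including the zero-concentration one, whose ratio is exactly 1). The
#' slope is the Stern-Volmer constant Ksv; the intercept is left free and
#' reported (the model form predicts 1). The bimolecular quenching rate
#' constant kq = Ksv / tau0 uses the unquenched lifetime `tau0_s`, of order
#' 1e-8 s for tryptophan fluorescence in serum albumin.
#'
#' @param series a [TitrationSeries-class]
#' @param tau0_s unquenched fluorophore lifetime in s (default 1e-8)
#' @param correct apply [correctSeries()] first (default TRUE)
#' @param eq12_sign sign convention passed to the ligand-absorbance
#'   correction
#' @return a [SternVolmerFit-class]
#' @export
fitSternVolmer <- function(series, tau0_s = 1e-8, correct = TRUE,
                           eq12_sign = "as_printed") {
    stopifnot(is(series, "TitrationSeries"))
    if (sum(series@Q_M > 0) < 3L)
        stop("fitSternVolmer: need at least 3 points with Q_M > 0")
    cf <- .correctedF(series, correct, eq12_sign)
    ratio <- cf$f0 / cf$f
    fit <- lm(ratio ~ series@Q_M)
    new("SternVolmerFit",
        Ksv_per_M = unname(coef(fit)[2]),
        kq_per_M_s = unname(coef(fit)[2]) / tau0_s,
        tau0_s = tau0_s,
        intercept = unname(coef(fit)[1]),
        r_pearson = .safeCor(series@Q_M, ratio),
        T_K = series@T_K)
}

#' Modified Stern-Volmer fit
#'
#' Ordinary least squares of F0/(F0 - F) against 1/[Q] over the nonzero
#' quencher points. The accessible fluorophore fraction is fa =
#' 1/intercept and the effective quenching constant Ka = intercept/slope.
#' A nonpositive slope or Ka marks the fit invalid (unphysical).
#'
#' @inheritParams fitSternVolmer
#' @return a [ModifiedSVFit-class]
#' @export
fitModifiedSV <- function(series, correct = TRUE, eq12_sign = "as_printed") {
    stopifnot(is(series, "TitrationSeries"))
    cf <- .correctedF(series, correct, eq12_sign)
    pos <- which(series@Q_M > 0)
    if (length(pos) < 2L)
        stop("fitModifiedSV: need at least 2 points with Q_M > 0")
    dF <- cf$f0 - cf$f[pos]
    bad <- which(dF <= 0)
    if (length(bad))
        stop(sprintf("fitModifiedSV: F0 - F <= 0 at point %d (Q = %g M)",
                     pos[bad[1]], series@Q_M[pos[bad[1]]]))
    y <- cf$f0 / dF
    x <- 1 / series@Q_M[pos]
    fit <- lm(y ~ x)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    new("ModifiedSVFit",
        Ka_per_M = intercept / slope,
        fa = 1 / intercept,
        r_pearson = .safeCor(x, y),
        T_K = series@T_K,
        valid = slope > 0 && intercept / slope > 0)
}

#' Double-logarithm binding fit
#'
#' Ordinary least squares of log10((F0 - F)/F) against log10([Q]) over the
#' nonzero quencher points: the slope is the number of binding sites n and
#' 10^intercept the binding constant Kb.
#'
#' @inheritParams fitSternVolmer
#' @return a [DoubleLogFit-class]
#' @export
fitDoubleLog <- function(series, correct = TRUE, eq12_sign = "as_printed") {
    stopifnot(is(series, "TitrationSeries"))
    cf <- .correctedF(series, correct, eq12_sign)
    pos <- which(series@Q_M > 0)
    if (length(pos) < 2L)
        stop("fitDoubleLog: need at least 2 points with Q_M > 0 (underdetermined)")
    dF <- cf$f0 - cf$f[pos]
    bad <- which(dF <= 0)
    if (length(bad))
        stop(sprintf("fitDoubleLog: F0 - F <= 0 at point %d (Q = %g M)",
                     pos[bad[1]], series@Q_M[pos[bad[1]]]))
    y <- log10(dF / cf$f[pos])
    x <- log10(series@Q_M[pos])
    fit <- lm(y ~ x)
    new("DoubleLogFit",
        Kb_per_M = 10^unname(coef(fit)[1]),
        n_sites = unname(coef(fit)[2]),
        r_pearson = .safeCor(x, y),
        T_K = series@T_K)
}

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Static (ground-state complex) quenching shows a Stern-Volmer constant
#' that falls with temperature and apparent kq far above the
#' diffusion-controlled ceiling for biopolymer quenching
#' (2.0e10 M^-1 s^-1); dynamic (collisional) quenching shows the opposite
#' trend with kq at or below the ceiling. Anything else is reported
#' indeterminate, naming the failed condition. Monotonicity is strict by
#' default; `trend_rtol` relaxes it to a relative tolerance.
#'
#' @param fits list of [SternVolmerFit-class] at two or more temperatures
#' @param kq_ceiling_per_M_s diffusion-controlled ceiling (default 2.0e10)
#' @param trend_rtol relative tolerance for the temperature trend
#'   (default 0: strict)
#' @return list with `mechanism` (`"static"`, `"dynamic"` or
#'   `"indeterminate"`) and `rationale`
#' @export
classifyMechanism <- function(fits, kq_ceiling_per_M_s = 2.0e10,
                              trend_rtol = 0) {
    stopifnot(length(fits) >= 2L,
              all(vapply(fits, is, TRUE, "SternVolmerFit")))
    Ts <- vapply(fits, function(f) f@T_K, 0)
    ord <- order(Ts)
    if (anyDuplicated(Ts))
        stop("classifyMechanism: duplicate temperatures")
    ksv <- vapply(fits, function(f) f@Ksv_per_M, 0)[ord]
    kq <- vapply(fits, function(f) f@kq_per_M_s, 0)[ord]
    d <- diff(ksv)
    tol <- trend_rtol * abs(ksv[-length(ksv)])
    decreasing <- all(d < -tol)
    increasing <- all(d > tol)
    above <- all(kq > kq_ceiling_per_M_s)
    below <- all(kq <= kq_ceiling_per_M_s)
    if (decreasing && above)
        return(list(mechanism = "static",
                    rationale = paste("Ksv strictly decreases with temperature and",
                                      "all kq exceed the diffusion-controlled ceiling")))
    if (increasing && below)
        return(list(mechanism = "dynamic",
                    rationale = paste("Ksv strictly increases with temperature and",
                                      "all kq lie at or below the diffusion-controlled ceiling")))
    failed <- c(
        if (!decreasing && !increasing) "no strict temperature trend in Ksv",
        if (decreasing && !above) "Ksv decreases but some kq <= ceiling",
        if (increasing && !below) "Ksv increases but some kq > ceiling")
    list(mechanism = "indeterminate",
         rationale = paste(failed, collapse = "; "))
}

## ---- titration CSV I/O --------------------------------------------------

#' Read / write titration series as annotated CSV
#'
#' Columns `Q_M,F_obs,Aex,Aem`; temperature, ligand absorptivity and path
#' length travel in `#` comment lines (`# T_K: 298` etc.).
#'
#' @param path file path
#' @return `readTitrationCsv` returns a [TitrationSeries-class]
#' @export
readTitrationCsv <- function(path) {
    if (!file.exists(path))
        stop(sprintf("readTitrationCsv: no such file: %s", path))
    lines <- readLines(path)
    meta <- list(T_K = NA_real_, epsilon_M_cm = 0, path_cm = 1)
    header_i <- NA_integer_
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (grepl("^\\s*#", ln)) {
            body <- sub("^\\s*#\\s*", "", ln)
            key <- trimws(sub(":.*$", "", body))
            val <- suppressWarnings(as.numeric(trimws(sub("^[^:]*:", "", body))))
            if (key %in% names(meta)) meta[[key]] <- val
        } else {
            header_i <- i
            break
        }
    }
    if (is.na(header_i) ||
        !grepl("^\\s*Q_M\\s*,\\s*F_obs\\s*,\\s*Aex\\s*,\\s*Aem\\s*$", lines[header_i]))
        stop(sprintf("readTitrationCsv: missing 'Q_M,F_obs,Aex,Aem' header at line %d",
                     if (is.na(header_i)) length(lines) else header_i))
    if (is.na(meta$T_K))
        stop("readTitrationCsv: missing '# T_K:' metadata line")
    df <- utils::read.csv(text = lines[-seq_len(header_i)],
                          header = FALSE,
                          col.names = c("Q_M", "F_obs", "Aex", "Aem"))
    TitrationSeries(T_K = meta$T_K, Q_M = df$Q_M, F_obs = df$F_obs,
                    A_ex = df$Aex, A_em = df$Aem,
                    ligandEpsilon = meta$epsilon_M_cm,
                    pathCm = meta$path_cm)
}

#' @rdname readTitrationCsv
#' @param series a [TitrationSeries-class] to write
#' @export
writeTitrationCsv <- function(series, path) {
    stopifnot(is(series, "TitrationSeries"))
    lines <- c(sprintf("# T_K: %.17g", series@T_K),
               sprintf("# epsilon_M_cm: %.17g", series@ligandEpsilon),
               sprintf("# path_cm: %.17g", series@pathCm),
               "Q_M,F_obs,Aex,Aem",
               sprintf("%.17g,%.17g,%.17g,%.17g",
                       series@Q_M, series@F_obs, series@A_ex, series@A_em))
    writeLines(lines, path)
    invisible(path)
}
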