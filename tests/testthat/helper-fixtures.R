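## shared fixtures, built in code

# Gaussian band spectrum on a regular grid
gaussSpectrum <- function(center, sigma, amplitude, from = 200, to = 500,
                          by = 1, kind = "emission_au") {
    wl <- seq(from, to, by = by)
    Spectrum(wl, amplitude * exp(-(wl - center)^2 / (2 * sigma^2)),
             kind = kind)
}

# noiseless default ground truth (study conditions)
defaultTruth <- function(...) simTruth(...)

# titration built directly from the static quenching law, no corrections
lawTitration <- function(K, Q = c(0, 2, 4, 6, 8, 10, 12, 14, 16) * 1e-7,
                         F0 = 1000, n = 1, T_K = 298) {
    TitrationSeries(T_K = T_K, Q_M = Q, F_obs = F0 / (1 + K * Q^n))
}
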