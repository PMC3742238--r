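test_that("Spectrum validity rejects malformed grids", {
    expect_error(Spectrum(c(300, 300, 310), c(1, 2, 3)), "increasing")
    expect_error(Spectrum(c(300, 310), c(1, NaN)), "finite")
    expect_error(Spectrum(300, 1), "at least 2")
    expect_error(Spectrum(c(300, 310), c(-1, 1),
                          kind = "molar_absorptivity_M_cm"), ">= 0")
    expect_error(Spectrum(c(300, 310), c(1, 1), kind = "nonsense"), "kind")
})

test_that("resample is the identity on the native grid and linear between points", {
    s <- gaussSpectrum(340, 15, 100)
    expect_identical(resample(s, s@wavelength)@values, s@values)
    two <- Spectrum(c(300, 400), c(0, 100))
    expect_equal(resample(two, c(300, 350))@values, c(0, 50))
    expect_error(resample(two, c(250, 350)), "outside")
})

test_that("resampling a 1 nm Gaussian band to 0.25 nm tracks the closed form", {
    s <- gaussSpectrum(340, 15, 100)
    fine <- seq(300, 380, by = 0.25)
    r <- resample(s, fine)
    truth <- 100 * exp(-(fine - 340)^2 / (2 * 15^2))
    expect_lt(max(abs(r@values - truth)) / 100, 0.005)
    expect_identical(r@kind, s@kind)
})

test_that("trapezoidal integration matches rectangles, zero, and a unit-area Gaussian", {
    flat <- Spectrum(seq(300, 400, 5), rep(7, 21))
    expect_equal(integrateSpectrum(flat, 310, 370), 7 * 60)
    expect_equal(integrateSpectrum(flat, 312.5, 364.2), 7 * (364.2 - 312.5))
    zero <- Spectrum(300:400, rep(0, 101))
    expect_equal(integrateSpectrum(zero), 0)
    wl <- seq(250, 450, by = 0.1)
    g <- Spectrum(wl, exp(-(wl - 340)^2 / (2 * 10^2)) / (10 * sqrt(2 * pi)))
    expect_equal(integrateSpectrum(g), 1, tolerance = 1e-4)
    expect_error(integrateSpectrum(flat, 370, 310), "lo must be")
    expect_error(integrateSpectrum(flat, 100, 200), "outside")
})

test_that("integration is additive over adjacent subintervals", {
    set.seed(11)
    for (i in 1:5) {
        wl <- sort(runif(80, 300, 400))
        wl <- wl[c(TRUE, diff(wl) > 0)]
        s <- Spectrum(wl, runif(length(wl), 0, 10))
        lo <- min(wl); hi <- max(wl); mid <- (lo + hi) / 2
        whole <- integrateSpectrum(s, lo, hi)
        parts <- integrateSpectrum(s, lo, mid) + integrateSpectrum(s, mid, hi)
        expect_equal(parts, whole, tolerance = 1e-12)
    }
})

test_that("peak location is stable under quenching and ties break short", {
    tri <- Spectrum(c(330, 340, 350), c(1, 5, 1))
    expect_equal(peakMax(tri)$wavelength_nm, 340)
    # fixed band shape scaled down: identical peak position across the series
    s0 <- gaussSpectrum(340, 15, 100)
    peaks <- vapply(c(1, 0.8, 0.6, 0.4),
                    function(f) peakMax(Spectrum(s0@wavelength,
                                                 s0@values * f))$wavelength_nm, 0)
    expect_true(all(peaks == 340))
    twin <- Spectrum(c(320, 330, 340, 350, 360), c(0, 9, 3, 9, 0))
    expect_equal(peakMax(twin)$wavelength_nm, 330)
    flat <- Spectrum(300:310, rep(2, 11))
    pk <- peakMax(flat, 302, 308)
    expect_true(pk$flat)
    expect_equal(pk$wavelength_nm, 302)
})

test_that("difference spectrum recovers a mixture component and rejects mismatches", {
    protein <- gaussSpectrum(280, 10, 0.8, kind = "absorbance_au")
    ligand <- gaussSpectrum(340, 20, 0.5, kind = "absorbance_au")
    complexSp <- Spectrum(protein@wavelength, protein@values + ligand@values,
                          kind = "absorbance_au")
    d <- differenceSpectrum(complexSp, ligand)
    expect_equal(d@values, protein@values, tolerance = 1e-9)
    self <- differenceSpectrum(ligand, ligand)
    expect_true(all(self@values == 0))
    expect_error(differenceSpectrum(protein, gaussSpectrum(340, 20, 1)),
                 "kind mismatch")
    a <- Spectrum(300:310, rep(1, 11)); b <- Spectrum(400:410, rep(1, 11))
    expect_error(differenceSpectrum(a, b), "overlap")
})

test_that("spectrum CSV round trip is lossless and bad files name the line", {
    s <- gaussSpectrum(340, 15, 123.456, kind = "cd_mdeg")
    s@meta <- list(temperature_K = 298, sample = "free protein")
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectrumCsv(s, path)
    r <- readSpectrumCsv(path)
    expect_equal(r@wavelength, s@wavelength, tolerance = 1e-12)
    expect_equal(r@values, s@values, tolerance = 1e-12)
    expect_identical(r@kind, "cd_mdeg")
    expect_equal(r@meta$temperature_K, 298)
    expect_identical(r@meta$sample, "free protein")

    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("wavelength_nm,value", "400,1", "300,2"), bad)
    expect_error(readSpectrumCsv(bad), "line 3")
    writeLines(c("300,1", "310,2"), bad)
    expect_error(readSpectrumCsv(bad), "header")
    writeLines(c("wavelength_nm,value", "300,1", "310,NaN"), bad)
    expect_error(readSpectrumCsv(bad), "line 3")
})
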