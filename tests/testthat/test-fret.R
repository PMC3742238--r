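test_that("overlap integral: zero acceptor, delta-band limit, fine-grid oracle", {
    donor <- gaussSpectrum(340, 15, 100)
    zero <- Spectrum(donor@wavelength, rep(0, length(donor@wavelength)),
                     kind = "molar_absorptivity_M_cm")
    expect_equal(overlapIntegral(donor, zero), 0)

    # narrow emission band against constant epsilon: J -> eps0 * lambda^4
    eps0 <- 1e4
    flat_eps <- Spectrum(seq(200, 500, 1), rep(eps0, 301),
                         kind = "molar_absorptivity_M_cm")
    narrow <- gaussSpectrum(340, 0.5, 100, from = 330, to = 350, by = 0.05)
    expect_equal(overlapIntegral(narrow, flat_eps), eps0 * (340e-7)^4,
                 tolerance = 1e-4)

    # 1 nm grid vs a 0.01 nm Riemann-sum oracle, within 0.1%
    acceptor <- gaussSpectrum(340, 20, 1e4, kind = "molar_absorptivity_M_cm")
    J <- overlapIntegral(donor, acceptor)
    wl <- seq(200, 500, by = 0.01)
    Fd <- 100 * exp(-(wl - 340)^2 / (2 * 15^2))
    ep <- 1e4 * exp(-(wl - 340)^2 / (2 * 20^2))
    J_oracle <- sum(Fd * ep * (wl * 1e-7)^4) / sum(Fd)
    expect_equal(J, J_oracle, tolerance = 1e-3)

    allzero <- Spectrum(300:400, rep(0, 101), kind = "emission_au")
    expect_error(overlapIntegral(allzero, acceptor), "zero")
})

test_that("overlap integral is invariant to emission scaling, linear in epsilon, grid-stable", {
    donor <- gaussSpectrum(340, 15, 100)
    acceptor <- gaussSpectrum(345, 20, 1e4, kind = "molar_absorptivity_M_cm")
    J <- overlapIntegral(donor, acceptor)
    scaled <- Spectrum(donor@wavelength, donor@values * 37)
    expect_equal(overlapIntegral(scaled, acceptor), J, tolerance = 1e-12)
    eps2 <- Spectrum(acceptor@wavelength, acceptor@values * 2.5,
                     kind = "molar_absorptivity_M_cm")
    expect_equal(overlapIntegral(donor, eps2), 2.5 * J, tolerance = 1e-12)
    # halved grid changes J by < 0.1% for smooth bands
    donor_h <- gaussSpectrum(340, 15, 100, by = 0.5)
    acceptor_h <- gaussSpectrum(345, 20, 1e4, by = 0.5,
                                kind = "molar_absorptivity_M_cm")
    expect_equal(overlapIntegral(donor_h, acceptor_h), J, tolerance = 1e-3)
})

test_that("Forster radius follows the sixth-root law and the direct evaluation", {
    expect_equal(forsterRadius(0), 0)
    J <- 1.79e-14
    R0 <- forsterRadius(J)   # K2 = 2/3, n = 1.36, phi = 0.15
    expect_equal(R0, 2.778312e-7, tolerance = 1e-6)
    expect_equal(forsterRadius(64 * J), 2 * R0, tolerance = 1e-12)
})

test_that("transfer efficiency closed forms and bounds", {
    expect_equal(transferEfficiency(100, 100), 0)
    expect_equal(transferEfficiency(50, 100), 0.5)
    expect_equal(transferEfficiency(1e-9, 100), 1, tolerance = 1e-9)
    expect_error(transferEfficiency(110, 100), "exceeds")
})

test_that("distance inverts the sixth-power efficiency law over a wide range", {
    R0 <- 2.78e-7
    expect_equal(donorAcceptorDistance(0.5, R0)$r_cm, R0, tolerance = 1e-12)
    for (ratio in c(0.3, 0.5, 0.8, 1, 1.5, 2, 3)) {
        r <- ratio * R0
        E <- R0^6 / (R0^6 + r^6)
        expect_equal(donorAcceptorDistance(E, R0)$r_cm, r, tolerance = 1e-9)
    }
    # near-total transfer: r collapses toward zero
    expect_lt(donorAcceptorDistance(1 - 1e-9, R0)$r_cm, 0.04 * R0)
    expect_error(donorAcceptorDistance(0, R0), "strictly between")
    expect_error(donorAcceptorDistance(1, R0), "strictly between")
})

test_that("the printed radius/distance pair is mutually consistent through the law", {
    ## with R0 = 1.56 nm, a distance of 1.64 nm corresponds to E = 0.4256;
    ## feeding that E back recovers r by direct formula evaluation
    R0 <- 1.56e-7
    E <- R0^6 / (R0^6 + (1.64e-7)^6)
    expect_equal(E, 0.4256, tolerance = 1e-3)
    expect_equal(donorAcceptorDistance(E, R0)$r_cm * 1e7, 1.64,
                 tolerance = 1e-6)
    flags <- donorAcceptorDistance(E, R0)$flags
    expect_true(flags[["r_below_8nm"]])
    expect_true(flags[["within_half_to_1p5_R0"]])
})

test_that("full FRET analysis returns a valid result object", {
    tr <- defaultTruth()
    res <- fretAnalysis(makeDonorEmission(tr), makeLigandAbsorptivity(tr),
                        F = 90, F0 = 100)
    expect_s4_class(res, "FretResult")
    expect_equal(res@E, 0.1, tolerance = 1e-12)
    expect_gt(res@J_cm3_L_mol, 0)
    expect_true(res@flags[["r_below_8nm"]])
})
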