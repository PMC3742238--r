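test_that("inner-filter correction is an identity at zero absorbance and monotone", {
    expect_equal(correctInnerFilter(100, 0, 0), 100)
    expect_equal(correctInnerFilter(100, 0.10, 0.05), 100 * exp(0.075))
    expect_equal(correctInnerFilter(100, 0.10, 0.05), 107.7884, tolerance = 1e-6)
    a <- seq(0, 1, 0.1)
    expect_true(all(diff(correctInnerFilter(100, a, 0.2)) > 0))
    expect_true(all(diff(correctInnerFilter(100, 0.2, a)) > 0))
})

test_that("ligand-absorbance correction signs compose to the identity", {
    expect_equal(correctLigandAbsorbance(100, 0, 1, 1e-5), 100)
    got <- correctLigandAbsorbance(100, 5000, 1, 1e-5, sign = "as_printed")
    expect_equal(got, 100 * exp(-0.11515))
    expect_equal(got, 89.12324, tolerance = 1e-6)
    back <- correctLigandAbsorbance(got, 5000, 1, 1e-5, sign = "inverted")
    expect_equal(back, 100, tolerance = 1e-12)
})

test_that("Stern-Volmer fit recovers a known slope and scales linearly", {
    s <- lawTitration(7.60e5, T_K = 288)
    fit <- fitSternVolmer(s)
    expect_equal(fit@Ksv_per_M, 7.60e5, tolerance = 1e-9)
    expect_equal(fit@kq_per_M_s, 7.60e13, tolerance = 1e-9)
    expect_equal(fit@intercept, 1, tolerance = 1e-9)
    expect_equal(fit@r_pearson, 1, tolerance = 1e-9)
    # constant F: zero slope
    flat <- TitrationSeries(298, c(0, 1e-7, 2e-7, 3e-7), rep(500, 4))
    expect_equal(fitSternVolmer(flat)@Ksv_per_M, 0, tolerance = 1e-12)
    # doubling [Q] on the same ratios halves the slope
    s2 <- TitrationSeries(288, s@Q_M * 2, s@F_obs)
    expect_equal(fitSternVolmer(s2)@Ksv_per_M, 7.60e5 / 2, tolerance = 1e-9)
    expect_error(fitSternVolmer(TitrationSeries(298, c(0, 1e-7), c(10, 9))),
                 "at least 3")
})

test_that("modified Stern-Volmer recovers Ka and the accessible fraction", {
    s <- lawTitration(5.54e5)
    fit <- fitModifiedSV(s)
    expect_equal(fit@Ka_per_M, 5.54e5, tolerance = 1e-9)
    expect_equal(fit@fa, 1, tolerance = 1e-9)
    expect_true(fit@valid)
    # half the fluorophores inaccessible: F = F0 (1 - fa + fa/(1+K Q))
    K <- 5e5; fa <- 0.5
    Q <- c(0, 2, 4, 6, 8, 10) * 1e-7
    Fv <- 1000 * (1 - fa + fa / (1 + K * Q))
    fit2 <- fitModifiedSV(TitrationSeries(298, Q, Fv))
    expect_equal(1 / fit2@fa, 2, tolerance = 1e-9)   # intercept = 1/fa
    expect_equal(fit2@Ka_per_M, K, tolerance = 1e-6)
    # rising intensities: negative slope flagged invalid or dF error
    bad <- TitrationSeries(298, c(0, 1e-7, 2e-7, 3e-7), c(100, 110, 120, 130))
    expect_error(fitModifiedSV(bad), "F0 - F")
})

test_that("double-log fit recovers Kb and n, and is exact on its own model", {
    s <- lawTitration(1.23e6)
    fit <- fitDoubleLog(s)
    expect_equal(fit@n_sites, 1, tolerance = 1e-9)
    expect_equal(fit@Kb_per_M, 1.23e6, tolerance = 1e-6)
    # data generated directly on the double-log line with n = 2
    Q <- c(0, 2, 4, 6, 8, 10) * 1e-7
    Kb <- 1e8; n <- 2
    Fv <- 1000 / (1 + Kb * Q^n)
    fit2 <- fitDoubleLog(TitrationSeries(298, Q, Fv))
    expect_equal(fit2@n_sites, 2, tolerance = 1e-9)
    expect_equal(fit2@Kb_per_M, 1e8, tolerance = 1e-6)
    expect_error(fitDoubleLog(TitrationSeries(298, c(0, 1e-7), c(10, 9))),
                 "underdetermined")
})

test_that("the three linearizations agree on noiseless single-site data", {
    tr <- defaultTruth()
    for (T in tr$temperatures_K) {
        s <- makeTitration(tr, T)
        K <- equilibriumConstantAt(tr, T)
        expect_equal(fitSternVolmer(s)@Ksv_per_M, K, tolerance = 1e-6)
        msv <- fitModifiedSV(s)
        expect_equal(msv@Ka_per_M, K, tolerance = 1e-6)
        expect_equal(msv@fa, 1, tolerance = 1e-6)
        dl <- fitDoubleLog(s)
        expect_equal(dl@Kb_per_M, K, tolerance = 1e-6)
        expect_equal(dl@n_sites, 1, tolerance = 1e-6)
    }
})

test_that("Pearson r of every fit lies in [-1, 1] across noisy replicates", {
    for (i in 1:10) {
        tr <- simTruth(noise_rel = 0.02, seed = 500 + i)
        s <- makeTitration(tr, 298)
        rs <- c(fitSternVolmer(s)@r_pearson, fitModifiedSV(s)@r_pearson,
                fitDoubleLog(s)@r_pearson)
        expect_true(all(abs(rs) <= 1))
    }
})

test_that("mechanism classification follows the trend/ceiling rule table", {
    mk <- function(K, T, tau0 = 1e-8)
        fitSternVolmer(lawTitration(K, T_K = T), tau0_s = tau0)
    # falling Ksv, kq far above the ceiling: static
    static_fits <- Map(mk, c(7.60e5, 6.63e5, 6.21e5), c(288, 298, 308))
    out <- classifyMechanism(static_fits)
    expect_identical(out$mechanism, "static")
    # rising Ksv but kq above the ceiling: indeterminate, condition named
    odd <- Map(mk, c(1e3, 2e3, 3e3), c(288, 298, 308))
    out2 <- classifyMechanism(odd)   # kq = 1e11 .. 3e11 > 2e10
    expect_identical(out2$mechanism, "indeterminate")
    expect_match(out2$rationale, "ceiling")
    # rising Ksv with kq below the ceiling: dynamic
    dyn <- Map(mk, c(1e1, 2e1, 3e1), c(288, 298, 308))
    expect_identical(classifyMechanism(dyn)$mechanism, "dynamic")
    # no trend: indeterminate
    tie <- Map(mk, c(5e5, 5e5), c(288, 298))
    expect_identical(classifyMechanism(tie)$mechanism, "indeterminate")
    expect_match(classifyMechanism(tie)$rationale, "trend")
})

test_that("titration CSV round trip preserves data and metadata", {
    tr <- defaultTruth()
    s <- makeTitration(tr, 298)
    path <- withr::local_tempfile(fileext = ".csv")
    writeTitrationCsv(s, path)
    r <- readTitrationCsv(path)
    expect_equal(r@T_K, 298)
    expect_equal(r@Q_M, s@Q_M, tolerance = 1e-12)
    expect_equal(r@F_obs, s@F_obs, tolerance = 1e-12)
    expect_equal(r@ligandEpsilon, s@ligandEpsilon, tolerance = 1e-12)
    # the re-read series fits identically
    expect_equal(fitSternVolmer(r)@Ksv_per_M, fitSternVolmer(s)@Ksv_per_M,
                 tolerance = 1e-12)
    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("Q_M,F_obs,Aex,Aem", "0,100,0,0", "1e-7,90,0,0"), bad)
    expect_error(readTitrationCsv(bad), "T_K")
    expect_error(readTitrationCsv("/nonexistent/titration.csv"), "no such file")
})
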