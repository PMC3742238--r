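#' Default analysis configuration
#'
#' Returns the configuration list understood by [runAnalysis()]. In
#' `mode = "synthetic"` the `truth` block holds overrides passed to
#' [simTruth()]; in `mode = "files"` the `files` block names the input CSVs
#' (`titrations`: character vector, `donor_emission`, `acceptor_epsilon`,
#' `cd`: character vector).
#'
#' @param ... top-level overrides merged over the defaults
#' @return a named list (class `specbindConfig`)
#' @export
defaultConfig <- function(...) {
    cfg <- list(
        mode = "synthetic",
        seed = 1L,
        tau0_s = 1e-8,
        vant_hoff_source = "Kb",       # one of Kb, Ka, Ksv
        eq12_sign = "as_printed",
        near_zero_J_mol = 2000,
        fret = list(K2 = 2/3, n_refractive = 1.36, phi = 0.15,
                    acceptor_M = 3e-7, temperature_K = 298),
        truth = list(),
        files = list())
    override <- list(...)
    for (k in names(override)) {
        cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(override[[k]]))
            utils::modifyList(cfg[[k]], override[[k]]) else override[[k]]
    }
    class(cfg) <- "specbindConfig"
    cfg
}

#' Read a configuration from YAML
#'
#' @param path YAML file; keys as in [defaultConfig()]
#' @return a merged configuration list
#' @export
readConfig <- function(path) {
    if (!file.exists(path))
        stop(sprintf("readConfig: no such file: %s", path))
    do.call(defaultConfig, yaml::read_yaml(path))
}

## deterministic 32-bit FNV-1a hash of a string, for config provenance
.fnv1a <- function(s) {
    bytes <- utf8ToInt(s)
    h <- 2166136261
    for (b in bytes) {
        ## xor the byte into the low 8 bits (doubles can't feed bitwXor directly)
        low <- h %% 256
        h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
        ## 32-bit multiply by 16777619 = 0x1000193, split to stay in double range
        h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.reportJSON <- function(report) {
    jsonlite::toJSON(report, auto_unbox = TRUE, digits = 15, pretty = TRUE)
}

.stage <- function(name, expr) {
    message(sprintf("[specbind] stage: %s", name))
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full binding analysis
#'
#' Orchestrates data acquisition (synthetic generation or CSV input),
#' intensity corrections, the three quenching linearizations per
#' temperature, quenching-mechanism classification, Van't Hoff
#' thermodynamics with binding-force assignment, the resonance
#' energy-transfer analysis at the equimolar point, synchronous-scan peak
#' tables and the CD helix series, into one provenance-stamped report.
#' Deterministic given an identical configuration (including seed): two runs
#' produce byte-identical JSON.
#'
#' @param config a configuration list from [defaultConfig()] /
#'   [readConfig()], or a path to a YAML config
#' @param out_dir optional directory; when given, the JSON report (and in
#'   synthetic mode the generated CSV dataset) is written there
#' @return the report, a nested list (class `specbindReport`); serialise
#'   with [writeReport()]
#' @export
runAnalysis <- function(config = defaultConfig(), out_dir = NULL) {
    if (is.character(config)) config <- readConfig(config)
    if (!inherits(config, "specbindConfig"))
        config <- do.call(defaultConfig, config)

    truth <- NULL
    if (config$mode == "synthetic") {
        targs <- config$truth
        if (is.null(targs$seed)) targs$seed <- config$seed
        truth <- .stage("simulate", do.call(simTruth, targs))
        series_list <- .stage("simulate", lapply(truth$temperatures_K,
                                                 function(T) makeTitration(truth, T)))
        donor <- makeDonorEmission(truth)
        acceptor <- makeLigandAbsorptivity(truth)
        cd_meas <- lapply(truth$helix_fractions,
                          function(f) makeCD(truth, f))
        names(cd_meas) <- sprintf("sample_%02d", seq_along(cd_meas))
        sync <- list(
            d15 = makeSynchronous(truth, 15, truth$temperatures_K[1]),
            d60 = makeSynchronous(truth, 60, truth$temperatures_K[1]))
    } else if (config$mode == "files") {
        fl <- config$files
        series_list <- .stage("read titrations", {
            if (!length(fl$titrations)) stop("no titration files configured")
            lapply(fl$titrations, readTitrationCsv)
        })
        donor <- if (!is.null(fl$donor_emission))
            .stage("read spectra", readSpectrumCsv(fl$donor_emission)) else NULL
        acceptor <- if (!is.null(fl$acceptor_epsilon))
            .stage("read spectra", readSpectrumCsv(fl$acceptor_epsilon)) else NULL
        cd_meas <- if (length(fl$cd))
            .stage("read cd", {
                out <- lapply(fl$cd, readCDMeasurementCsv)
                names(out) <- basename(unlist(fl$cd))
                out
            }) else list()
        sync <- NULL
    } else stop(sprintf("unknown mode '%s'", config$mode))

    ## quenching fits per temperature
    fits <- .stage("quenching fits", lapply(series_list, function(s) {
        list(T_K = s@T_K,
             sv = fitSternVolmer(s, tau0_s = config$tau0_s,
                                 eq12_sign = config$eq12_sign),
             msv = fitModifiedSV(s, eq12_sign = config$eq12_sign),
             dlog = fitDoubleLog(s, eq12_sign = config$eq12_sign))
    }))

    mech <- .stage("mechanism", classifyMechanism(lapply(fits, `[[`, "sv")))

    ## thermodynamics from the configured constant
    Ks <- vapply(fits, function(f) switch(config$vant_hoff_source,
                                          Kb = f$dlog@Kb_per_M,
                                          Ka = f$msv@Ka_per_M,
                                          Ksv = f$sv@Ksv_per_M), 0)
    Ts <- vapply(fits, `[[`, 0, "T_K")
    thermo <- .stage("thermodynamics",
                     thermoAnalysis(Ts, Ks,
                                    near_zero_J_mol = config$near_zero_J_mol))

    ## FRET at the equimolar point, using the Stern-Volmer line at the
    ## configured temperature to interpolate F/F0
    fret <- NULL
    if (!is.null(donor) && !is.null(acceptor)) {
        fret <- .stage("fret", {
            Tf <- config$fret$temperature_K
            i <- which.min(abs(Ts - Tf))
            sv <- fits[[i]]$sv
            ratio0 <- sv@intercept + sv@Ksv_per_M * config$fret$acceptor_M
            if (ratio0 <= 1)
                stop("no quenching at the equimolar point; E undefined")
            fretAnalysis(donor, acceptor,
                         F = 1 / ratio0, F0 = 1,
                         K2 = config$fret$K2,
                         n_refractive = config$fret$n_refractive,
                         phi = config$fret$phi)
        })
    }

    cd_tab <- if (length(cd_meas))
        .stage("cd", helixSeries(cd_meas)) else NULL

    sync_report <- if (!is.null(sync)) .stage("synchronous", list(
        delta_15 = peakShiftTable(sync$d15),
        delta_60 = peakShiftTable(sync$d60))) else NULL

    cfg_plain <- unclass(config)
    report <- list(
        schema_version = "1.0",
        provenance = list(
            package = "SpecBind",
            package_version = as.character(utils::packageVersion("SpecBind")),
            seed = config$seed,
            config_hash = .fnv1a(as.character(jsonlite::toJSON(
                cfg_plain, auto_unbox = TRUE, digits = 15))),
            config = cfg_plain),
        quenching = lapply(fits, function(f) list(
            T_K = f$T_K,
            stern_volmer = list(Ksv_per_M = f$sv@Ksv_per_M,
                                kq_per_M_s = f$sv@kq_per_M_s,
                                tau0_s = f$sv@tau0_s,
                                intercept = f$sv@intercept,
                                r = f$sv@r_pearson),
            modified_sv = list(Ka_per_M = f$msv@Ka_per_M, fa = f$msv@fa,
                               r = f$msv@r_pearson, valid = f$msv@valid),
            double_log = list(Kb_per_M = f$dlog@Kb_per_M,
                              n_sites = f$dlog@n_sites,
                              r = f$dlog@r_pearson))),
        mechanism = mech,
        thermo = list(
            van_t_hoff = list(dH_kJ_mol = thermo@dH_J_mol / 1000,
                              dS_J_molK = thermo@dS_J_molK,
                              r = thermo@r_pearson,
                              source = config$vant_hoff_source),
            gibbs_kJ_mol = as.list(thermo@dG_J_mol / 1000),
            forces = thermo@forces,
            narrative = thermo@narrative),
        fret = if (!is.null(fret)) list(
            J_cm3_L_mol = fret@J_cm3_L_mol,
            R0_nm = fret@R0_cm * 1e7,
            E = fret@E,
            r_nm = fret@r_cm * 1e7,
            flags = as.list(fret@flags)),
        cd = if (!is.null(cd_tab)) list(
            table = cd_tab,
            monotone_decrease = attr(cd_tab, "monotone_decrease")),
        synchronous = sync_report)
    report <- report[!vapply(report, is.null, TRUE)]
    class(report) <- "specbindReport"

    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        if (!is.null(truth)) simulateDataset(truth, out_dir)
        writeReport(report, file.path(out_dir, "report.json"))
    }
    report
}

#' Serialise an analysis report to JSON
#'
#' Deterministic serialisation (fixed key order, 15 significant digits, no
#' timestamps): identical config and seed give byte-identical files.
#'
#' @param report a report from [runAnalysis()]
#' @param path output file
#' @return invisibly, the path
#' @export
writeReport <- function(report, path) {
    writeLines(as.character(.reportJSON(unclass(report))), path)
    invisible(path)
}

#' Structural validation of an analysis report
#'
#' Checks the report against the published schema
#' (`inst/schema/report-schema.json`): required sections present, numeric
#' fields finite, schema version stamped.
#'
#' @param report a report list (or path to a report JSON)
#' @return TRUE invisibly; otherwise an error naming the violation
#' @export
validateReport <- function(report) {
    if (is.character(report)) report <- jsonlite::read_json(report)
    report <- unclass(report)
    need <- c("schema_version", "provenance", "quenching", "mechanism",
              "thermo")
    missing <- setdiff(need, names(report))
    if (length(missing))
        stop(sprintf("report missing section(s): %s",
                     paste(missing, collapse = ", ")))
    if (!length(report$quenching))
        stop("report has no per-temperature quenching fits")
    nums <- unlist(report[c("quenching", "thermo", "fret")], use.names = TRUE)
    nums <- suppressWarnings(as.numeric(nums[!is.na(suppressWarnings(as.numeric(nums)))]))
    if (any(!is.finite(nums)))
        stop("report contains non-finite numeric fields")
    if (!report$mechanism$mechanism %in% c("static", "dynamic", "indeterminate"))
        stop("invalid mechanism label")
    invisible(TRUE)
}

#' Peak positions across a spectrum series
#'
#' Tabulates [peakMax()] over a list of spectra (e.g. a synchronous-scan
#' series), reporting each member's peak wavelength and intensity and the
#' total peak shift across the series — the quantity inspected for
#' microenvironment changes around the probed residues.
#'
#' @param spectra list of [Spectrum-class]; a `Q_M` meta entry, when
#'   present, is carried into the table
#' @param lo,hi optional window bounds (nm)
#' @return data.frame with columns `Q_M`, `peak_nm`, `peak_value`;
#'   attribute `total_shift_nm`
#' @export
peakShiftTable <- function(spectra, lo = NULL, hi = NULL) {
    stopifnot(length(spectra) >= 1L)
    rows <- lapply(spectra, function(s) {
        pk <- peakMax(s,
                      lo = if (is.null(lo)) min(s@wavelength) else lo,
                      hi = if (is.null(hi)) max(s@wavelength) else hi)
        data.frame(Q_M = if (is.null(s@meta$Q_M)) NA_real_ else s@meta$Q_M,
                   peak_nm = pk$wavelength_nm, peak_value = pk$value)
    })
    out <- do.call(rbind, rows)
    attr(out, "total_shift_nm") <- out$peak_nm[nrow(out)] - out$peak_nm[1]
    out
}
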