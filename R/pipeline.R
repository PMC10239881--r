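# End-to-end orchestration on synthetic data: simulate a mixed-ploidy
# study, call ploidy from fluorescence, genotype from reads, filter and
# thin, estimate relatedness and PCoA, scan K and classify introgression,
# infer the inheritance mode, and summarise niche-raster overlap. One
# global seed fans out to per-stage seeds by fixed offsets so toggling a
# stage never perturbs another stage's draws.

#' Pipeline configuration
#'
#' @param sim a \code{\link{simConfig}}
#' @param filter a \code{\link{filterConfig}}
#' @param bandTolerance RF band half-width (relative)
#' @param Ks K values for the admixture scan
#' @param nReps replicate fits per K
#' @param nRestarts EM restarts per fit
#' @param thresholds introgression q cut-offs
#' @param purity max-q floor for the inheritance-mode sample
#' @param voteCutoff presence threshold on vote rasters
#' @param seed global seed
#' @return list of class \code{mixploidy_pipeline_config}
#' @export
pipelineConfig <- function(sim = studyConfig(),
                           filter = filterConfig(),
                           bandTolerance = 0.15,
                           Ks = 1:6, nReps = 4, nRestarts = 1,
                           thresholds = c(0.05, 0.10, 0.15),
                           purity = 0.9, voteCutoff = 0.6,
                           seed = 1L) {
    structure(list(sim = sim, filter = filter,
                   bandTolerance = bandTolerance, Ks = Ks,
                   nReps = nReps, nRestarts = nRestarts,
                   thresholds = thresholds, purity = purity,
                   voteCutoff = voteCutoff, seed = as.integer(seed)),
              class = "mixploidy_pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param outDir optional directory; when given, stage outputs are
#'   written (VCF, TSVs, provenance JSON)
#' @return a bundle list: truth, ploidyCalls, dosages (filtered+thinned),
#'   coancestry, pcoa, kScan, kSelection, bestFit, introgression,
#'   modeCall, areaSummary, provenance
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
    stopifnot(inherits(config, "mixploidy_pipeline_config"))
    seed <- config$seed
    simc <- config$sim
    simc$seed <- seed
    truth <- simulateTruth(simc)

    # flow cytometry -> ploidy calls
    rf <- simulateFluorescence(truth$ploidy, simc$rfBands,
                               replicates = 2, seed = seed + 11L)
    known <- rf$rf[rf$ploidyTrue == 2L]
    center <- calibrateBand(known)
    calls <- callPloidy(rf, center, tolerance = config$bandTolerance)

    # reads -> dosage genotypes
    trueDose <- simulateDosages(simc, truth, seed = seed + 23L)
    reads <- simulateReads(trueDose, simc$meanDepth, simc$errorRate,
                           seed = seed + 37L)
    geno <- genotypeAll(reads, minDepth = config$filter$minDepth)
    rowData(geno)$qual <- rep(1000, nrow(geno))  # simulated calls: high QUAL
    filt <- filterSites(geno, config$filter)
    thin <- thinOnePerWindow(filt, config$filter$windowBp)

    # relatedness + PCoA
    cm <- pairwiseCoancestry(thin)
    pc <- pcoaRelatedness(cm, nAxes = 3)

    # admixture scan, delta-K, introgression
    scan <- runAdmixtureScan(thin, Ks = config$Ks, nReps = config$nReps,
                             seed = seed + 53L,
                             nRestarts = config$nRestarts)
    ksel <- selectK(scan)
    bestK <- if (is.na(ksel$chosenK)) max(config$Ks) else ksel$chosenK
    fit <- fitAdmixture(thin, bestK, seed = seed + 71L,
                        nRestarts = max(config$nRestarts, 3))
    intro <- classifyIntrogression(fit, config$thresholds)

    # inheritance mode of the tetraploids
    spectrum <- buildSpectrum(thin, fit = fit, purity = config$purity)
    mode <- classifyMode(spectrum)

    # niche rasters
    grids <- simulateVoteGrids(pattern = "overlap", overlapFraction = 0.25,
                               seed = seed + 97L)
    cls <- mergeModels(thresholdVotes(grids[[1]], config$voteCutoff),
                       thresholdVotes(grids[[2]], config$voteCutoff))
    areas <- areaSummary(cls)

    bundle <- list(truth = truth, ploidyCalls = calls,
                   dosages = thin, coancestry = cm, pcoa = pc,
                   kScan = scan, kSelection = ksel, bestFit = fit,
                   introgression = intro, spectrum = spectrum,
                   modeCall = mode, areaSummary = areas,
                   provenance = list(seed = seed,
                                     nIndividuals = ncol(thin),
                                     nSitesRetained = nrow(thin),
                                     timestamp = format(Sys.time())))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeDosageVcf(thin, file.path(outDir, "dosages.vcf"))
        writeCoancestryTsv(cm, file.path(outDir, "coancestry.tsv"))
        writeQMatrixTsv(fit, file.path(outDir, "qmatrix.tsv"))
        jsonlite::write_json(bundle$provenance,
                             file.path(outDir, "provenance.json"),
                             auto_unbox = TRUE)
    }
    class(bundle) <- "mixploidy_bundle"
    bundle
}

#' Human-readable pipeline report
#'
#' Renders the ploidy-call tally, filter retention, chosen K, the
#' introgression percentage table, the inheritance-mode call and the
#' area summary. Missing stages are marked absent.
#'
#' @param bundle output of \code{\link{runPipeline}}
#' @return character vector of report lines (invisibly printed)
#' @export
reportBundle <- function(bundle) {
    line <- function(...) sprintf(...)
    out <- c("== mixploidy pipeline report ==")
    if (!is.null(bundle$ploidyCalls)) {
        tab <- table(bundle$ploidyCalls$call)
        out <- c(out, line("Ploidy calls: %s",
            paste(names(tab), tab, sep = "=", collapse = ", ")))
    } else out <- c(out, "Ploidy calls: [absent]")
    if (!is.null(bundle$dosages))
        out <- c(out, line("Sites retained after filtering/thinning: %d",
                           nrow(bundle$dosages)))
    else out <- c(out, "Filtered dosages: [absent]")
    if (!is.null(bundle$kSelection))
        out <- c(out, line("Best-fit K (delta-K): %s",
                           bundle$kSelection$chosenK))
    else out <- c(out, "K selection: [absent]")
    if (!is.null(bundle$introgression)) {
        out <- c(out, "Introgression (% of home cluster, by threshold):")
        tab <- bundle$introgression$table
        out <- c(out, utils::capture.output(print(tab, row.names = FALSE)))
    } else out <- c(out, "Introgression: [absent]")
    if (!is.null(bundle$modeCall))
        out <- c(out, line("Inheritance mode: %s (LLR %.1f, %d classes)",
                           bundle$modeCall$mode, bundle$modeCall$llr,
                           bundle$modeCall$classesObserved))
    else out <- c(out, "Inheritance mode: [absent]")
    if (!is.null(bundle$areaSummary)) {
        a <- bundle$areaSummary
        out <- c(out, line(
            "Niche areas (km^2): A-only %.0f, B-only %.0f, co-occurring %.0f, total %.0f (overlap %.0f%%)",
            a["areaA"], a["areaB"], a["areaCo"], a["total"],
            100 * a["overlapShare"]))
    } else out <- c(out, "Area summary: [absent]")
    cat(out, sep = "\n")
    invisible(out)
}
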