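# Ploidy inference from flow-cytometry relative fluorescence (RF).
# RF = sample channel mean / internal-standard channel mean; tetraploids
# fluoresce at about twice the diploid band, so calls are made against a
# diploid band centre and its doubling, with everything else ambiguous.

#' Relative fluorescence ratio
#'
#' @param sampleMean mean fluorescence of the sample peak
#' @param referenceMean mean fluorescence of the internal standard peak
#' @return sampleMean / referenceMean
#' @export
computeRF <- function(sampleMean, referenceMean) {
    if (any(!is.finite(sampleMean)) || any(!is.finite(referenceMean)) ||
        any(sampleMean <= 0) || any(referenceMean <= 0))
        stop("channel means must be finite and positive")
    sampleMean / referenceMean
}

#' Robust diploid band centre from known-diploid RF values
#'
#' The median of RF measurements from individuals of known diploid
#' cytotype anchors the calling bands; the median keeps a stray
#' tetraploid contaminant from dragging the centre.
#'
#' @param knownDiploidRFs numeric vector of at least 3 RF values
#' @return the band centre (median)
#' @export
calibrateBand <- function(knownDiploidRFs) {
    knownDiploidRFs <- knownDiploidRFs[is.finite(knownDiploidRFs)]
    if (length(knownDiploidRFs) < 3)
        stop("at least 3 known-diploid RF values are required")
    median(knownDiploidRFs)
}

#' Call ploidy from replicated RF measurements
#'
#' An individual is called diploid if its mean RF falls within
#' \code{bandCenter2x * (1 +/- tolerance)}, tetraploid if within
#' \code{2 * bandCenter2x * (1 +/- tolerance)}, and ambiguous otherwise
#' (the analogue of field samples with inconclusive RF values, which are
#' excluded downstream). The coefficient of variation across replicates is
#' reported, and values above \code{cvFlag} set a quality flag without
#' forcing ambiguity.
#'
#' @param rf data.frame with columns \code{sampleId} and \code{rf}
#'   (replicated measurements, at least one per individual), e.g. from
#'   \code{\link{simulateFluorescence}}
#' @param bandCenter2x diploid band centre (e.g. from
#'   \code{\link{calibrateBand}})
#' @param tolerance relative half-width of each band, in (0, 0.5)
#' @param cvFlag replicate-CV threshold for the quality flag
#' @return data.frame: sampleId, meanRF, cv, call (diploid / tetraploid /
#'   ambiguous), inferred ploidy (NA if ambiguous), highCV flag
#' @export
callPloidy <- function(rf, bandCenter2x, tolerance = 0.15, cvFlag = 0.05) {
    stopifnot(is.data.frame(rf), all(c("sampleId", "rf") %in% names(rf)),
              bandCenter2x > 0, tolerance > 0, tolerance < 0.5)
    if (nrow(rf) == 0) stop("no RF measurements supplied")
    if (any(rf$rf <= 0)) stop("RF values must be positive")
    ids <- unique(rf$sampleId)
    mu <- vapply(ids, function(s) mean(rf$rf[rf$sampleId == s]), numeric(1))
    cv <- vapply(ids, function(s) {
        x <- rf$rf[rf$sampleId == s]
        if (length(x) < 2) NA_real_ else sd(x) / mean(x)
    }, numeric(1))
    lo2 <- bandCenter2x * (1 - tolerance); hi2 <- bandCenter2x * (1 + tolerance)
    lo4 <- 2 * bandCenter2x * (1 - tolerance)
    hi4 <- 2 * bandCenter2x * (1 + tolerance)
    call <- ifelse(mu >= lo2 & mu <= hi2, "diploid",
            ifelse(mu >= lo4 & mu <= hi4, "tetraploid", "ambiguous"))
    data.frame(sampleId = ids, meanRF = unname(mu), cv = unname(cv),
               call = unname(call),
               ploidy = unname(ifelse(call == "diploid", 2L,
                               ifelse(call == "tetraploid", 4L, NA_integer_))),
               highCV = unname(!is.na(cv) & cv > cvFlag))
}
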