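#' @import methods
#' @importFrom stats dbinom rbinom rbeta rpois rnorm runif rexp cor
#'   median sd wilcox.test hclust as.dist setNames quantile
#' @importFrom utils read.table write.table head
#' @useDynLib mixploidy, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData "rowData<-" "colData<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

#' ReadCountSet: per-individual, per-site allele read counts
#'
#' A \linkS4class{SummarizedExperiment} with two assays, \code{total} and
#' \code{alt} (reads supporting the alternate allele), sites as rows and
#' individuals as columns. \code{rowData} carries \code{chrom}, \code{pos}
#' (1-based), \code{ref}, \code{alt}, per-site \code{errorRate} and optional
#' \code{qual}; \code{colData} carries per-individual \code{ploidy}
#' (2 or 4).
#'
#' @export
setClass("ReadCountSet", contains = "SummarizedExperiment")

setValidity("ReadCountSet", function(object) {
    msg <- character()
    if (!all(c("total", "alt") %in% names(assays(object))))
        msg <- c(msg, "assays 'total' and 'alt' are required")
    else {
        n <- assay(object, "total"); a <- assay(object, "alt")
        if (any(a > n, na.rm = TRUE))
            msg <- c(msg, "alt reads exceed total reads")
        if (any(n < 0 | a < 0, na.rm = TRUE))
            msg <- c(msg, "negative read counts")
    }
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(rowData(object))))
        msg <- c(msg, "rowData must carry chrom, pos, ref, alt")
    if (!"ploidy" %in% names(colData(object)))
        msg <- c(msg, "colData must carry ploidy")
    else if (!all(colData(object)$ploidy %in% c(2L, 4L)))
        msg <- c(msg, "ploidy must be 2 or 4")
    if ("errorRate" %in% names(rowData(object))) {
        e <- rowData(object)$errorRate
        if (any(!is.finite(e)) || any(e < 0 | e >= 0.5))
            msg <- c(msg, "errorRate must be finite and in [0, 0.5)")
    }
    if (length(msg)) msg else TRUE
})

#' DosageSet: individuals x sites integer allele-dosage matrix
#'
#' A \linkS4class{SummarizedExperiment} with one assay, \code{dosage}
#' (integer alternate-allele copies, \code{NA} = missing), sites as rows
#' and individuals as columns. Dosage at every cell is bounded by the
#' individual's ploidy. \code{rowData}: \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, optional \code{qual}; \code{colData}:
#' \code{ploidy}.
#'
#' @export
setClass("DosageSet", contains = "SummarizedExperiment")

setValidity("DosageSet", function(object) {
    msg <- character()
    if (!"dosage" %in% names(assays(object)))
        msg <- c(msg, "assay 'dosage' is required")
    if (!"ploidy" %in% names(colData(object)))
        msg <- c(msg, "colData must carry ploidy")
    else if (!all(colData(object)$ploidy %in% c(2L, 4L)))
        msg <- c(msg, "ploidy must be 2 or 4")
    else if ("dosage" %in% names(assays(object))) {
        d <- assay(object, "dosage")
        v <- rep(colData(object)$ploidy, each = nrow(d))
        if (any(d < 0 | d > v, na.rm = TRUE))
            msg <- c(msg, "dosage outside 0..ploidy")
    }
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(rowData(object))))
        msg <- c(msg, "rowData must carry chrom, pos, ref, alt")
    if (length(msg)) msg else TRUE
})

#' CoancestryMatrix: pairwise relatedness estimates
#'
#' Symmetric individuals-by-individuals matrix of ploidy-rescaled
#' method-of-moments relatedness coefficients, with the per-pair count of
#' loci the estimate used. Values below 0 or above 1 are legitimate
#' statistical noise, not errors.
#'
#' @slot relatedness symmetric numeric matrix of r-hat values
#' @slot nLoci integer matrix: pairwise-complete loci per pair
#' @export
setClass("CoancestryMatrix",
    representation(relatedness = "matrix", nLoci = "matrix"))

setValidity("CoancestryMatrix", function(object) {
    r <- object@relatedness
    msg <- character()
    if (nrow(r) != ncol(r)) msg <- c(msg, "matrix must be square")
    else if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8,
                               check.attributes = FALSE)))
        msg <- c(msg, "matrix must be symmetric")
    if (!identical(dim(r), dim(object@nLoci)))
        msg <- c(msg, "nLoci dimensions must match")
    if (length(msg)) msg else TRUE
})

#' QMatrix: admixture proportions from model-based clustering
#'
#' Individuals-by-K matrix of ancestry proportions; each row sums to one.
#'
#' @slot q numeric matrix, N x K, rows sum to 1
#' @slot logLik log-likelihood of the fitted model
#' @slot clusterFreqs K x L alternate-allele frequencies of the clusters
#' @slot converged logical convergence flag
#' @slot seed seed used for the run
#' @slot llTrace per-iteration log-likelihood trace of the winning restart
#' @export
setClass("QMatrix",
    representation(q = "matrix", logLik = "numeric",
                   clusterFreqs = "matrix", converged = "logical",
                   seed = "integer", llTrace = "numeric"),
    prototype(logLik = NA_real_, converged = NA, seed = NA_integer_,
              llTrace = numeric(0)))

setValidity("QMatrix", function(object) {
    q <- object@q
    msg <- character()
    if (any(q < -1e-8 | q > 1 + 1e-8)) msg <- c(msg, "q entries outside [0,1]")
    if (any(abs(rowSums(q) - 1) > 1e-8))
        msg <- c(msg, "q rows must sum to 1 within 1e-8")
    f <- object@clusterFreqs
    if (length(f) && (any(f < -1e-12) || any(f > 1 + 1e-12)))
        msg <- c(msg, "cluster frequencies outside [0,1]")
    if (length(msg)) msg else TRUE
})

#' PresenceGrid: raster of normalised vote fractions or presence calls
#'
#' A 2-D grid of random-forest style normalised vote counts in [0,1] (or
#' booleans after thresholding) with a uniform nominal cell area in square
#' kilometres. \code{NA} cells are no-data.
#'
#' @slot votes numeric matrix (votes in [0,1], or 0/1 after thresholding)
#' @slot cellArea area of one cell in km^2
#' @slot scenario climate-scenario label
#' @export
setClass("PresenceGrid",
    representation(votes = "matrix", cellArea = "numeric",
                   scenario = "character"),
    prototype(cellArea = 1, scenario = "contemporary"))

setValidity("PresenceGrid", function(object) {
    msg <- character()
    v <- object@votes
    if (any(v < 0 | v > 1, na.rm = TRUE))
        msg <- c(msg, "votes must lie in [0,1]")
    if (length(object@cellArea) != 1 || object@cellArea <= 0)
        msg <- c(msg, "cellArea must be a single positive number")
    if (length(msg)) msg else TRUE
})
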