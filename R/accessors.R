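#' Construct a ReadCountSet
#'
#' @param total,alt integer matrices (sites x individuals) of total and
#'   alternate-allele read counts
#' @param ploidy integer vector of per-individual ploidy (2 or 4)
#' @param chrom,pos,ref,alt_allele per-site metadata; sensible defaults are
#'   generated when omitted
#' @param errorRate per-site sequencing error rate in [0, 0.5)
#' @param qual optional per-site quality score
#' @return a \linkS4class{ReadCountSet}
#' @export
ReadCountSet <- function(total, alt, ploidy,
                         chrom = NULL, pos = NULL,
                         ref = NULL, alt_allele = NULL,
                         errorRate = 0.001, qual = NULL) {
    total <- as.matrix(total); alt <- as.matrix(alt)
    L <- nrow(total); N <- ncol(total)
    if (is.null(chrom)) chrom <- rep("chr1", L)
    if (is.null(pos)) pos <- seq_len(L) * 1000L
    if (is.null(ref)) ref <- rep("A", L)
    if (is.null(alt_allele)) alt_allele <- rep("T", L)
    rd <- DataFrame(chrom = chrom, pos = as.integer(pos),
                    ref = ref, alt = alt_allele,
                    errorRate = rep_len(errorRate, L))
    if (!is.null(qual)) rd$qual <- rep_len(qual, L)
    if (is.null(colnames(total)))
        colnames(total) <- colnames(alt) <- sprintf("ind%03d", seq_len(N))
    if (is.null(rownames(total)))
        rownames(total) <- rownames(alt) <- paste0(chrom, "_", pos)
    new("ReadCountSet", SummarizedExperiment(
        assays = list(total = total, alt = alt),
        rowData = rd,
        colData = DataFrame(ploidy = as.integer(ploidy),
                            row.names = colnames(total))))
}

#' Construct a DosageSet
#'
#' @param dosage integer matrix (sites x individuals) of alternate-allele
#'   dosage, \code{NA} for missing calls
#' @param ploidy per-individual ploidy vector (2 or 4)
#' @param chrom,pos,ref,alt_allele,qual per-site metadata
#' @return a \linkS4class{DosageSet}
#' @export
DosageSet <- function(dosage, ploidy, chrom = NULL, pos = NULL,
                      ref = NULL, alt_allele = NULL, qual = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    L <- nrow(dosage); N <- ncol(dosage)
    if (is.null(chrom)) chrom <- rep("chr1", L)
    if (is.null(pos)) pos <- seq_len(L) * 1000L
    if (is.null(ref)) ref <- rep("A", L)
    if (is.null(alt_allele)) alt_allele <- rep("T", L)
    rd <- DataFrame(chrom = chrom, pos = as.integer(pos),
                    ref = ref, alt = alt_allele)
    if (!is.null(qual)) rd$qual <- rep_len(qual, L)
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("ind%03d", seq_len(N))
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0(chrom, "_", pos)
    new("DosageSet", SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = rd,
        colData = DataFrame(ploidy = as.integer(ploidy),
                            row.names = colnames(dosage))))
}

#' Construct a PresenceGrid
#'
#' @param votes numeric matrix of normalised vote fractions in [0,1]
#'   (NA = no data)
#' @param cellArea uniform cell area in km^2
#' @param scenario climate-scenario label
#' @export
PresenceGrid <- function(votes, cellArea = 1,
                         scenario = "contemporary") {
    new("PresenceGrid", votes = as.matrix(votes),
        cellArea = cellArea, scenario = scenario)
}

#' Per-individual ploidy
#' @param object a ReadCountSet or DosageSet
#' @return integer vector of ploidy levels
#' @export
setGeneric("ploidy", function(object) standardGeneric("ploidy"))

#' @rdname ploidy
#' @export
setMethod("ploidy", "SummarizedExperiment",
          function(object) colData(object)$ploidy)

#' Dosage matrix (sites x individuals)
#' @param object a DosageSet
#' @return integer matrix of alternate-allele dosages, NA where missing
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "DosageSet", function(object) assay(object, "dosage"))

#' Relatedness matrix accessor
#' @param object a CoancestryMatrix
#' @return symmetric numeric matrix of r-hat values
#' @export
setGeneric("relatedness", function(object) standardGeneric("relatedness"))

#' @rdname relatedness
#' @export
setMethod("relatedness", "CoancestryMatrix",
          function(object) object@relatedness)

#' Admixture-proportion matrix accessor
#' @param object a QMatrix
#' @return N x K numeric matrix, rows summing to 1
#' @export
setGeneric("qvalues", function(object) standardGeneric("qvalues"))

#' @rdname qvalues
#' @export
setMethod("qvalues", "QMatrix", function(object) object@q)

#' Cluster allele-frequency accessor
#' @param object a QMatrix
#' @return K x L matrix of alternate-allele frequencies
#' @export
setGeneric("clusterFreqs", function(object) standardGeneric("clusterFreqs"))

#' @rdname clusterFreqs
#' @export
setMethod("clusterFreqs", "QMatrix", function(object) object@clusterFreqs)

#' Vote/presence matrix accessor
#' @param object a PresenceGrid
#' @return numeric matrix of votes (or 0/1 presence)
#' @export
setGeneric("votes", function(object) standardGeneric("votes"))

#' @rdname votes
#' @export
setMethod("votes", "PresenceGrid", function(object) object@votes)

#' Cell area accessor
#' @param object a PresenceGrid
#' @return cell area in km^2
#' @export
setGeneric("cellArea", function(object) standardGeneric("cellArea"))

#' @rdname cellArea
#' @export
setMethod("cellArea", "PresenceGrid", function(object) object@cellArea)

setMethod("show", "CoancestryMatrix", function(object) {
    r <- object@relatedness
    off <- r[upper.tri(r)]
    cat("CoancestryMatrix:", nrow(r), "individuals\n")
    cat(sprintf("  off-diagonal r-hat: mean %.3f, range [%.3f, %.3f]\n",
                mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
                max(off, na.rm = TRUE)))
    cat(sprintf("  mean self r-hat: %.3f\n", mean(diag(r), na.rm = TRUE)))
})

setMethod("show", "QMatrix", function(object) {
    cat("QMatrix:", nrow(object@q), "individuals x",
        ncol(object@q), "clusters\n")
    cat(sprintf("  logLik %.2f, converged: %s\n",
                object@logLik, object@converged))
})

setMethod("show", "PresenceGrid", function(object) {
    v <- object@votes
    cat(sprintf("PresenceGrid [%s]: %d x %d cells, %.0f km^2 each\n",
                object@scenario, nrow(v), ncol(v), object@cellArea))
    cat(sprintf("  %d no-data cells; vote range [%.2f, %.2f]\n",
                sum(is.na(v)), suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE))))
})
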