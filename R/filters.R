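# Variant-filter cascade for ddRAD dosage data: biallelic sites only,
# QUAL > 100, per-cell depth already enforced at genotyping (DP > 5),
# site missingness <= 10%, ploidy-weighted alternate allele frequency
# > 0.04, and one SNP per 139-bp window to damp linkage.

#' Filter configuration
#'
#' Defaults follow the standard ddRAD cascade: at most 10 percent missing
#' individuals per site, QUAL strictly above 100, per-cell depth strictly
#' above 5 (applied at genotyping), alternate allele frequency strictly
#' above 0.04, and 139-bp thinning windows (the read length, hence one
#' SNP per ddRAD locus).
#'
#' @param maxMissingFrac maximum fraction of missing individuals per site
#' @param minQual site quality threshold (strict >)
#' @param minDepth per-cell depth threshold (strict >), used at genotyping
#' @param minAltFreq alternate-allele frequency threshold (strict >)
#' @param windowBp thinning window width in bp
#' @param biallelicOnly drop sites whose ref/alt are not single bases
#' @return list of class \code{mixploidy_filter_config}
#' @export
filterConfig <- function(maxMissingFrac = 0.10, minQual = 100,
                         minDepth = 5, minAltFreq = 0.04,
                         windowBp = 139, biallelicOnly = TRUE) {
    stopifnot(maxMissingFrac >= 0, minQual >= 0, minDepth >= 0,
              minAltFreq >= 0, windowBp >= 1)
    structure(list(maxMissingFrac = maxMissingFrac, minQual = minQual,
                   minDepth = minDepth, minAltFreq = minAltFreq,
                   windowBp = as.integer(windowBp),
                   biallelicOnly = biallelicOnly),
              class = "mixploidy_filter_config")
}

# ploidy-weighted alternate allele frequency over non-missing calls
altAlleleFreq <- function(d, v) {
    miss <- is.na(d)
    copies <- colSums((!t(miss)) * v)          # per site: sum of ploidies
    alt <- rowSums(d, na.rm = TRUE)
    ifelse(copies > 0, alt / copies, NA_real_)
}

#' Site-level filter cascade
#'
#' Retains sites that are biallelic, have QUAL strictly above
#' \code{minQual}, missing fraction at most \code{maxMissingFrac}, and
#' ploidy-weighted alternate allele frequency (alternate dosage sum over
#' total allele copies among non-missing calls) strictly above
#' \code{minAltFreq}. Rules are evaluated on the input matrix and applied
#' jointly; per-rule retention counts are stored in the result metadata.
#'
#' @param dosageSet a \linkS4class{DosageSet}; \code{rowData$qual} is used
#'   when present (sites lacking QUAL pass that rule)
#' @param config a \code{\link{filterConfig}}
#' @return filtered \linkS4class{DosageSet}; \code{metadata()$filterLog}
#'   records sites passing each rule
#' @export
filterSites <- function(dosageSet, config = filterConfig()) {
    stopifnot(is(dosageSet, "DosageSet"),
              inherits(config, "mixploidy_filter_config"))
    d <- dosages(dosageSet)
    if (nrow(d) == 0) {
        warning("empty dosage matrix: nothing to filter")
        return(dosageSet)
    }
    v <- ploidy(dosageSet)
    rd <- rowData(dosageSet)
    passBi <- if (config$biallelicOnly)
        nchar(rd$ref) == 1 & nchar(rd$alt) == 1 &
            rd$ref %in% c("A", "C", "G", "T") &
            rd$alt %in% c("A", "C", "G", "T")
    else rep(TRUE, nrow(d))
    passQual <- if ("qual" %in% names(rd)) rd$qual > config$minQual
                else rep(TRUE, nrow(d))
    missFrac <- rowMeans(is.na(d))
    passMiss <- missFrac <= config$maxMissingFrac
    af <- altAlleleFreq(d, v)
    passAF <- !is.na(af) & af > config$minAltFreq
    keep <- passBi & passQual & passMiss & passAF
    out <- dosageSet[keep, ]
    metadata(out)$filterLog <- c(input = nrow(d),
                                 biallelic = sum(passBi),
                                 qual = sum(passQual),
                                 missingness = sum(passMiss),
                                 altFreq = sum(passAF),
                                 retained = sum(keep))
    out
}

#' Intersect diploid and tetraploid site sets
#'
#' Shared variants between two per-ploidy call sets, keyed on
#' (chrom, pos, ref, alt); the diploid set's original order is preserved.
#'
#' @param diploidSites,tetraploidSites data.frames (or DataFrame) with
#'   columns chrom, pos, ref, alt
#' @return the rows of \code{diploidSites} whose keys also occur in
#'   \code{tetraploidSites}
#' @export
intersectPloidySets <- function(diploidSites, tetraploidSites) {
    key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = "\r")
    diploidSites[key(diploidSites) %in% key(tetraploidSites), , drop = FALSE]
}

#' Thin to one SNP per window
#'
#' Greedy left-to-right per chromosome: the window starts at the first
#' unconsumed SNP; among SNPs within [start, start + windowBp - 1] the one
#' with the least missingness is kept (ties to the lowest position), and
#' scanning resumes past the window.
#'
#' @param dosageSet a \linkS4class{DosageSet}
#' @param windowBp window width in bp
#' @return thinned \linkS4class{DosageSet}
#' @export
thinOnePerWindow <- function(dosageSet, windowBp = 139) {
    stopifnot(is(dosageSet, "DosageSet"), windowBp >= 1)
    rd <- rowData(dosageSet)
    if (nrow(dosageSet) == 0) return(dosageSet)
    ord <- order(rd$chrom, rd$pos)
    if (!identical(ord, seq_len(nrow(dosageSet)))) {
        warning("sites not sorted by (chrom, pos): sorting internally")
        dosageSet <- dosageSet[ord, ]
        rd <- rowData(dosageSet)
    }
    miss <- rowMeans(is.na(dosages(dosageSet)))
    keep <- logical(nrow(dosageSet))
    for (ch in unique(rd$chrom)) {
        idx <- which(rd$chrom == ch)
        pos <- rd$pos[idx]
        i <- 1L
        while (i <= length(idx)) {
            inWin <- which(pos >= pos[i] & pos <= pos[i] + windowBp - 1L)
            inWin <- inWin[inWin >= i]
            best <- inWin[order(miss[idx[inWin]], pos[inWin])][1]
            keep[idx[best]] <- TRUE
            i <- max(inWin) + 1L
        }
    }
    dosageSet[keep, ]
}
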