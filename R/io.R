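# File interchange: ploidy-aware VCF (GT like 0/0/0/1 encodes dosage; AD
# carries ref,alt read depths), and plain TSV for matrices. VCF parsing
# goes through vcfR; writing is plain-text so mixed-ploidy GT strings are
# fully controlled.

#' Write a DosageSet (optionally with read counts) to VCF
#'
#' GT encodes dosage as sorted allele calls over ploidy copies
#' (e.g. dosage 1 at ploidy 4 is 0/0/0/1); missing calls are "./.". When a
#' matching \linkS4class{ReadCountSet} is given, per-cell AD (ref,alt) is
#' written and per-site error rates go to the INFO field (ERR).
#'
#' @param dosageSet a \linkS4class{DosageSet}
#' @param path output .vcf path
#' @param reads optional \linkS4class{ReadCountSet} of identical shape
#' @export
writeDosageVcf <- function(dosageSet, path, reads = NULL) {
    stopifnot(is(dosageSet, "DosageSet"))
    d <- dosages(dosageSet)
    v <- ploidy(dosageSet)
    rd <- rowData(dosageSet)
    L <- nrow(d); N <- ncol(d)
    gtStr <- function(dose, vp) {
        if (is.na(dose)) return(paste(rep(".", vp), collapse = "/"))
        paste(c(rep("0", vp - dose), rep("1", dose)), collapse = "/")
    }
    fmt <- if (is.null(reads)) "GT" else "GT:AD"
    qual <- if ("qual" %in% names(rd)) rd$qual else rep(".", L)
    info <- if (!is.null(reads) && "errorRate" %in% names(rowData(reads)))
        sprintf("ERR=%g", rowData(reads)$errorRate) else rep(".", L)
    body <- vapply(seq_len(L), function(l) {
        cells <- vapply(seq_len(N), function(i) {
            g <- gtStr(d[l, i], v[i])
            if (is.null(reads)) g
            else {
                n <- assay(reads, "total")[l, i]
                a <- assay(reads, "alt")[l, i]
                paste0(g, ":", n - a, ",", a)
            }
        }, character(1))
        paste(c(rd$chrom[l], rd$pos[l], ".", rd$ref[l], rd$alt[l],
                qual[l], "PASS", info[l], fmt, cells), collapse = "\t")
    }, character(1))
    hdr <- c("##fileformat=VCFv4.2",
             "##source=mixploidy",
             "##INFO=<ID=ERR,Number=1,Type=Float,Description=\"Per-site error rate\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", colnames(d)),
                   collapse = "\t"))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a ploidy-aware VCF into a DosageSet
#'
#' Dosage is the count of non-reference alleles in GT (any separator);
#' ploidy per individual is the modal GT length. Fully-missing GT becomes
#' NA.
#'
#' @param path a .vcf file
#' @return a \linkS4class{DosageSet} (with \code{qual} when present)
#' @export
readDosageVcf <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fix <- vcfR::getFIX(vcf)
    alleles <- function(g) strsplit(g, "[/|]")
    doseOf <- function(g) {
        if (is.na(g)) return(NA_integer_)
        a <- alleles(g)[[1]]
        if (all(a == ".")) return(NA_integer_)
        sum(a != "0" & a != ".")
    }
    plOf <- function(col) {
        lens <- vapply(alleles(col[!is.na(col)]), length, integer(1))
        if (!length(lens)) return(2L)
        as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    }
    d <- apply(gt, c(1, 2), doseOf)
    pl <- apply(gt, 2, plOf)
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    DosageSet(d, ploidy = pl,
              chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
              ref = fix[, "REF"], alt_allele = fix[, "ALT"],
              qual = if (all(is.na(qual))) NULL else qual)
}

#' Read allele depths from a VCF into a ReadCountSet
#'
#' Uses the AD field (ref,alt) and the ERR INFO key when present.
#'
#' @param path a .vcf file with AD
#' @param ploidy optional per-individual ploidy; inferred from GT lengths
#'   when omitted
#' @return a \linkS4class{ReadCountSet}
#' @export
readReadCountVcf <- function(path, ploidy = NULL) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(vcf, element = "AD")
    fix <- vcfR::getFIX(vcf)
    split2 <- function(x) {
        parts <- strsplit(x, ",")
        t(vapply(parts, function(p)
            suppressWarnings(as.integer(p[1:2])), integer(2)))
    }
    refm <- altm <- matrix(NA_integer_, nrow(ad), ncol(ad))
    for (j in seq_len(ncol(ad))) {
        s <- split2(ad[, j])
        refm[, j] <- s[, 1]; altm[, j] <- s[, 2]
    }
    if (is.null(ploidy)) {
        gt <- vcfR::extract.gt(vcf, element = "GT")
        ploidy <- apply(gt, 2, function(col) {
            lens <- vapply(strsplit(col[!is.na(col)], "[/|]"),
                           length, integer(1))
            if (!length(lens)) 2L
            else as.integer(names(sort(table(lens), decreasing = TRUE))[1])
        })
    }
    err <- rep(1e-3, nrow(ad))
    info <- vcf@fix[, "INFO"]
    em <- regmatches(info, regexpr("ERR=[0-9.eE+-]+", info))
    if (length(em) == nrow(ad) && all(nzchar(em)))
        err <- as.numeric(sub("ERR=", "", em))
    colnames(refm) <- colnames(altm) <- colnames(ad)
    ReadCountSet(refm + altm, altm, ploidy = ploidy,
                 chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                 errorRate = err)
}

#' Write a dosage matrix as TSV (sites x individuals)
#' @param dosageSet a \linkS4class{DosageSet}
#' @param path output path
#' @export
writeDosageTsv <- function(dosageSet, path) {
    rd <- rowData(dosageSet)
    out <- data.frame(chrom = rd$chrom, pos = rd$pos,
                      ref = rd$ref, alt = rd$alt,
                      as.data.frame(dosages(dosageSet)),
                      check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a coancestry matrix as TSV with sample IDs on both margins
#' @param cm a \linkS4class{CoancestryMatrix}
#' @param path output path
#' @export
writeCoancestryTsv <- function(cm, path) {
    write.table(relatedness(cm), path, sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = NA)
    invisible(path)
}

#' Write a q-matrix as TSV (sample plus one column per cluster)
#' @param fit a \linkS4class{QMatrix}
#' @param path output path
#' @export
writeQMatrixTsv <- function(fit, path) {
    q <- qvalues(fit)
    out <- data.frame(sample = if (is.null(rownames(q)))
                          seq_len(nrow(q)) else rownames(q), q)
    names(out)[-1] <- paste0("q", seq_len(ncol(q)))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
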