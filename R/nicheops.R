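# Presence-raster post-processing: threshold normalised vote counts at a
# strict cutoff, merge two subspecies niche models into presence classes,
# tally class areas on a uniform cell size, and express habitat change as
# percent loss against a reference scenario.

#' Threshold normalised votes into presence/absence
#'
#' Presence iff vote strictly exceeds the cutoff; no-data cells stay NA.
#'
#' @param grid a \linkS4class{PresenceGrid} of votes in [0,1]
#' @param cutoff vote cutoff in [0,1]
#' @return a \linkS4class{PresenceGrid} of 0/1 presence
#' @export
thresholdVotes <- function(grid, cutoff = 0.6) {
    stopifnot(is(grid, "PresenceGrid"))
    if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0,1]")
    v <- votes(grid)
    PresenceGrid((v > cutoff) + 0, cellArea(grid), grid@scenario)
}

#' Merge two presence models into a class grid
#'
#' Per cell: 3 = co-occurring (both present), 1 = A only, 2 = B only,
#' 0 = absent; NA where either model has no data.
#'
#' @param gridA,gridB boolean \linkS4class{PresenceGrid}s of equal shape,
#'   mask and cell area
#' @return integer class matrix with attribute \code{cellArea}
#' @export
mergeModels <- function(gridA, gridB) {
    a <- votes(gridA); b <- votes(gridB)
    if (!identical(dim(a), dim(b))) stop("grids differ in shape")
    if (!identical(is.na(a), is.na(b))) stop("grids differ in no-data mask")
    if (cellArea(gridA) != cellArea(gridB))
        stop("grids differ in cell area")
    if (!all(a %in% c(0, 1) | is.na(a)) || !all(b %in% c(0, 1) | is.na(b)))
        stop("grids must be thresholded to 0/1 first")
    cls <- matrix(0L, nrow(a), ncol(a))
    cls[a == 1 & b == 0] <- 1L
    cls[a == 0 & b == 1] <- 2L
    cls[a == 1 & b == 1] <- 3L
    cls[is.na(a)] <- NA_integer_
    attr(cls, "cellArea") <- cellArea(gridA)
    cls
}

#' Class areas of a merged presence grid
#'
#' @param classGrid matrix from \code{\link{mergeModels}}
#' @param cellArea cell area in km^2 (defaults to the grid's attribute)
#' @return named numeric vector: areaA, areaB, areaCo, total (km^2) and
#'   overlapShare (co-occurring / total suitable, in [0,1])
#' @export
areaSummary <- function(classGrid, cellArea = attr(classGrid, "cellArea")) {
    if (is.null(cellArea)) cellArea <- 1
    nA <- sum(classGrid == 1L, na.rm = TRUE)
    nB <- sum(classGrid == 2L, na.rm = TRUE)
    nCo <- sum(classGrid == 3L, na.rm = TRUE)
    areas <- c(areaA = nA, areaB = nB, areaCo = nCo,
               total = nA + nB + nCo) * cellArea
    share <- if (areas["total"] > 0) unname(areas["areaCo"] / areas["total"])
             else NA_real_
    c(areas, overlapShare = share)
}

#' Percent habitat loss against a reference scenario
#'
#' 100 (reference - scenario) / reference, rounded half-up to 2 decimals;
#' negative values indicate gain.
#'
#' @param areaReference reference-scenario area (> 0)
#' @param areaScenario comparison-scenario area
#' @return percent loss, 2 dp
#' @export
percentLoss <- function(areaReference, areaScenario) {
    if (any(areaReference <= 0)) stop("reference area must be positive")
    x <- 100 * (areaReference - areaScenario) / areaReference
    floor(x * 100 + 0.5) / 100   # round half-up
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a .asc file
#' @param scenario scenario label to attach
#' @return a \linkS4class{PresenceGrid}; header cellsize (assumed km) is
#'   squared into the cell area
#' @export
readAsciiGrid <- function(path, scenario = "contemporary") {
    lines <- readLines(path, n = 6L)
    kv <- strsplit(trimws(lines), "\\s+")
    hdr <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                    tolower(vapply(kv, `[`, "", 1)))
    vals <- scan(path, skip = 6, quiet = TRUE)
    m <- matrix(vals, nrow = hdr["nrows"], ncol = hdr["ncols"],
                byrow = TRUE)
    if (!is.na(hdr["nodata_value"]))
        m[m == hdr["nodata_value"]] <- NA_real_
    PresenceGrid(m, cellArea = unname(hdr["cellsize"])^2,
                 scenario = scenario)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a \linkS4class{PresenceGrid}
#' @param path output path
#' @param nodata value encoding NA cells
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
    v <- votes(grid)
    hdr <- c(paste("ncols", ncol(v)),
             paste("nrows", nrow(v)),
             "xllcorner 0", "yllcorner 0",
             paste("cellsize", sqrt(cellArea(grid))),
             paste("NODATA_value", nodata))
    v[is.na(v)] <- nodata
    body <- apply(v, 1, paste, collapse = " ")
    writeLines(c(hdr, body), path)
    invisible(path)
}
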