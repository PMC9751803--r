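#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' OtuTable: an OTU count table with taxonomy and sample metadata
#'
#' `OtuTable` extends \linkS4class{SummarizedExperiment}. The single assay
#' `"counts"` holds non-negative integer counts (rows = OTUs, columns =
#' samples); `rowData` carries the parsed taxonomic lineage (kingdom through
#' genus, missing ranks as `"Unclassified"`); `colData` carries at least a
#' `group` column and optionally `timepoint`.
#'
#' @slot .
#'   Inherited from SummarizedExperiment; no additional slots.
#' @seealso [readOtuTable()], [prevalenceFilter()], [logRelativeAbundance()]
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

setValidity("OtuTable", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate OTU ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "OTU and sample ids are required as dimnames")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (!all(TAX_RANKS %in% colnames(SummarizedExperiment::rowData(object))))
        msg <- c(msg, "rowData must contain the six taxonomic rank columns")
    if (length(msg)) msg else TRUE
})

#' AbundanceMatrix: log-transformed relative abundances
#'
#' Relative abundances are computed against each sample's *full* library
#' size (the denominator is taken before any OTU filtering, preserving the
#' compositional interpretation of the retained rows), zeros are replaced
#' according to a recorded policy, and values are log10-transformed.
#'
#' @slot values numeric matrix, rows = retained OTUs, columns = samples.
#'   May contain `NA` when `zeroStrategy = "na"` (pairwise-complete mode).
#' @slot zeroStrategy character, the zero-replacement policy used.
#' @slot pseudoAbundance numeric, the pseudo relative abundance substituted
#'   for zeros (NA_real_ when not applicable).
#' @export
setClass("AbundanceMatrix",
    representation(values = "matrix",
                   zeroStrategy = "character",
                   pseudoAbundance = "numeric"))

setValidity("AbundanceMatrix", function(object) {
    v <- object@values
    if (object@zeroStrategy != "na" && any(!is.finite(v)))
        return("values must be finite under the pseudo-count strategy")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("values must carry OTU and sample dimnames")
    TRUE
})

#' SimilarityMatrix: pairwise Pearson correlation of OTU profiles
#'
#' @slot r symmetric numeric matrix of correlations, unit diagonal.
#' @slot nSamples integer, number of samples the correlations were
#'   computed across.
#' @slot method character, "pearson" or "spearman".
#' @export
setClass("SimilarityMatrix",
    representation(r = "matrix", nSamples = "integer", method = "character"))

setValidity("SimilarityMatrix", function(object) {
    r <- object@r
    if (nrow(r) != ncol(r)) return("correlation matrix must be square")
    if (max(abs(r - t(r))) > 1e-10) return("correlation matrix must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-10) return("diagonal must be 1")
    if (max(abs(r)) > 1 + 1e-10) return("|r| must not exceed 1")
    if (is.null(rownames(r))) return("OTU ids required as dimnames")
    TRUE
})

#' ThresholdScan: RMT threshold-scan evidence
#'
#' One row per candidate similarity threshold: the size of the thresholded
#' matrix, the number of unfolded nearest-neighbour spacings, chi-square
#' statistics of the spacing histogram against the Poisson law
#' P(d) = exp(-d) and the Goe Wigner surmise, the Poisson goodness-of-fit
#' p-value, and whether the scan point was usable (enough distinct
#' eigenvalues/spacings).
#'
#' @slot scan data.frame with columns threshold, n_nodes, n_spacings,
#'   chi2_poisson, p_poisson, chi2_goe, usable.
#' @slot selected numeric, the selected threshold (NA before selection).
#' @export
setClass("ThresholdScan",
    representation(scan = "data.frame", selected = "numeric"))

setValidity("ThresholdScan", function(object) {
    sc <- object@scan
    need <- c("threshold", "n_nodes", "n_spacings",
              "chi2_poisson", "p_poisson", "chi2_goe", "usable")
    if (!all(need %in% colnames(sc)))
        return(paste("scan must contain columns:", paste(need, collapse = ", ")))
    if (is.unsorted(sc$threshold, strictly = TRUE))
        return("thresholds must be strictly increasing")
    TRUE
})

#' CoNetwork: a signed co-occurrence network
#'
#' An undirected igraph whose vertices are OTUs (attribute `phylum`) and
#' whose edges are OTU pairs with |r| at or above the similarity threshold
#' (attributes `weight` = r, `sign` = +1/-1). Isolated nodes are dropped at
#' construction.
#'
#' @slot graph igraph object.
#' @slot threshold numeric similarity threshold used.
#' @slot group character group label ("" when unset).
#' @export
setClass("CoNetwork",
    representation(graph = "ANY", threshold = "numeric", group = "character"))

setValidity("CoNetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph must be an igraph object")
    if (igraph::is_directed(g)) return("graph must be undirected")
    if (any(igraph::which_loop(g))) return("self-loops are not allowed")
    if (igraph::vcount(g) > 0 && min(igraph::degree(g)) == 0)
        return("isolated nodes must be removed at construction")
    if (igraph::ecount(g) > 0) {
        w <- igraph::E(g)$weight
        if (is.null(w)) return("edges must carry a 'weight' attribute")
        if (any(abs(w) < object@threshold - 1e-12))
            return("every edge must satisfy |r| >= threshold")
    }
    TRUE
})

#' RobustnessResult: network robustness under a node-removal scheme
#'
#' @slot values numeric vector, per-repetition fraction of the original
#'   nodes surviving removal plus secondary extinction; each in [0, 1].
#' @slot scheme character, "random_nodes" or "targeted_keystones".
#' @slot fraction numeric, fraction removed.
#' @slot repetitions integer.
#' @export
setClass("RobustnessResult",
    representation(values = "numeric", scheme = "character",
                   fraction = "numeric", repetitions = "integer"))

setValidity("RobustnessResult", function(object) {
    if (any(object@values < 0 | object@values > 1))
        return("robustness values must lie in [0, 1]")
    if (!object@scheme %in% c("random_nodes", "targeted_keystones"))
        return("unknown removal scheme")
    if (object@fraction <= 0 || object@fraction >= 1)
        return("fraction must lie in (0, 1)")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "OtuTable", function(object) {
    cat("OtuTable:", nrow(object), "OTUs x", ncol(object), "samples\n")
    grp <- table(SummarizedExperiment::colData(object)$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
    phy <- SummarizedExperiment::rowData(object)$phylum
    top <- sort(table(phy), decreasing = TRUE)
    cat("  top phyla:", paste(utils::head(names(top), 3), collapse = ", "), "\n")
})

setMethod("show", "AbundanceMatrix", function(object) {
    cat("AbundanceMatrix:", nrow(object@values), "OTUs x",
        ncol(object@values), "samples (log10 relative abundance)\n")
    cat("  zero strategy:", object@zeroStrategy,
        if (!is.na(object@pseudoAbundance))
            sprintf("(pseudo-abundance %.3g)", object@pseudoAbundance) else "", "\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
    cat("SimilarityMatrix:", nrow(object@r), "OTUs,", object@method,
        "correlation over", object@nSamples, "samples\n")
})

setMethod("show", "ThresholdScan", function(object) {
    sc <- object@scan
    cat("ThresholdScan:", nrow(sc), "candidate thresholds in [",
        min(sc$threshold), ",", max(sc$threshold), "],",
        sum(sc$usable), "usable\n")
    if (!is.na(object@selected))
        cat("  selected threshold:", object@selected, "\n")
})

setMethod("show", "CoNetwork", function(object) {
    g <- object@graph
    sgn <- if (igraph::ecount(g)) igraph::E(g)$sign else integer()
    cat(sprintf("CoNetwork%s: %d nodes, %d edges (%.1f%% positive), threshold %.3f\n",
        if (nzchar(object@group)) paste0(" [", object@group, "]") else "",
        igraph::vcount(g), igraph::ecount(g),
        if (length(sgn)) 100 * mean(sgn > 0) else NA_real_, object@threshold))
})

setMethod("show", "RobustnessResult", function(object) {
    cat(sprintf("RobustnessResult (%s, fraction %.2f, %d repetitions): mean %.3f, sd %.3f\n",
        object@scheme, object@fraction, object@repetitions,
        mean(object@values), stats::sd(object@values)))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for MicEcoNet classes
#'
#' @param object an object of the documented class.
#' @return `otuCounts` the counts matrix; `taxonomyTable` a data.frame of
#'   taxonomic ranks; `sampleGroups` the per-sample group factor;
#'   `abundanceValues` the log10 abundance matrix; `similarityValues` the
#'   correlation matrix; `scanTable` the threshold-scan data.frame;
#'   `selectedThreshold` the chosen threshold; `networkGraph` the igraph
#'   object; `robustnessValues` the per-repetition robustness vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
otuCounts <- function(object) SummarizedExperiment::assay(object, "counts")

#' @rdname accessors
#' @export
taxonomyTable <- function(object)
    as.data.frame(SummarizedExperiment::rowData(object)[, TAX_RANKS])

#' @rdname accessors
#' @export
sampleGroups <- function(object)
    as.character(SummarizedExperiment::colData(object)$group)

#' @rdname accessors
#' @export
abundanceValues <- function(object) object@values

#' @rdname accessors
#' @export
similarityValues <- function(object) object@r

#' @rdname accessors
#' @export
scanTable <- function(object) object@scan

#' @rdname accessors
#' @export
selectedThreshold <- function(object) object@selected

#' @rdname accessors
#' @export
networkGraph <- function(object) object@graph

#' @rdname accessors
#' @export
robustnessValues <- function(object) object@values
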