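#' Read an OTU table and its sample metadata
#'
#' Reads a tab-separated OTU table whose first column is the OTU id, whose
#' last column is a taxonomy lineage string, and whose remaining columns are
#' integer counts per sample. Greengenes-style (`k__Bacteria; p__Firmicutes;
#' ...`) and Silva-style (`D_0__Bacteria;D_1__Proteobacteria;...`) rank
#' prefixes are both accepted. Comment lines starting with `#` before the
#' header are skipped; a `#OTU ID` header line is tolerated.
#'
#' @param path OTU table TSV.
#' @param metadata_path sample metadata TSV with columns `sample_id`,
#'   `group` and optionally `timepoint`. Samples in the table without a
#'   metadata row are an error.
#' @return an [OtuTable-class] object.
#' @examples
#' tab <- generateCommunity(communitySpec(n_otus = 20, n_samples = 6, seed = 1))$table
#' tab
#' @export
readOtuTable <- function(path, metadata_path) {
    raw <- readLines(path)
    hdr <- grep("^#", raw)
    ## the last leading comment line may itself be the '#OTU ID' header
    skip <- 0L
    if (length(hdr) && hdr[1] == 1L) {
        block <- seq_len(max(which(hdr == seq_along(hdr))))
        skip <- max(block)
        if (grepl("OTU", raw[skip], ignore.case = TRUE)) skip <- skip - 1L
    }
    df <- utils::read.delim(path, skip = skip, header = TRUE,
                            check.names = FALSE, comment.char = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop("OTU table must have id, at least one count column, and taxonomy")
    otu_ids <- as.character(df[[1]])
    if (anyDuplicated(otu_ids))
        stop("duplicate OTU ids in ", path)
    lineage <- as.character(df[[ncol(df)]])
    sample_ids <- colnames(df)[-c(1, ncol(df))]   # before data.frame
    if (anyDuplicated(sample_ids))               # subsetting mangles dups
        stop("duplicate sample ids in ", path)
    cts <- as.matrix(df[, -c(1, ncol(df)), drop = FALSE])
    colnames(cts) <- sample_ids
    if (!is.numeric(cts) || any(is.na(cts)) || any(cts < 0) ||
        any(cts != round(cts)))
        stop("counts must be non-negative integers")
    storage.mode(cts) <- "integer"
    rownames(cts) <- otu_ids

    md <- utils::read.delim(metadata_path, header = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% colnames(md)))
        stop("metadata must contain 'sample_id' and 'group' columns")
    missing <- setdiff(colnames(cts), md$sample_id)
    if (length(missing))
        stop("samples without metadata: ", paste(missing, collapse = ", "))
    md <- md[match(colnames(cts), md$sample_id), , drop = FALSE]
    if (!"timepoint" %in% colnames(md)) md$timepoint <- NA_character_

    makeOtuTable(cts, parseLineages(lineage),
                 group = md$group, timepoint = md$timepoint)
}

#' @keywords internal
makeOtuTable <- function(counts, taxonomy, group, timepoint = NULL) {
    if (is.null(timepoint)) timepoint <- rep(NA_character_, ncol(counts))
    methods::new("OtuTable", SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(taxonomy, row.names = rownames(counts)),
        colData = S4Vectors::DataFrame(group = group, timepoint = timepoint,
                                       row.names = colnames(counts))))
}

#' Parse taxonomy lineage strings into rank columns
#'
#' @param lineage character vector of `;`-separated lineages with
#'   `k__`/`p__`/... or `D_0__`/`D_1__`/... prefixes.
#' @return data.frame with columns kingdom..genus; unparseable lineages
#'   yield `"Unclassified"` at every rank (with one warning).
#' @export
parseLineages <- function(lineage) {
    out <- matrix("Unclassified", nrow = length(lineage), ncol = length(TAX_RANKS),
                  dimnames = list(NULL, TAX_RANKS))
    gg_pref <- c("k__", "p__", "c__", "o__", "f__", "g__")
    bad <- logical(length(lineage))
    for (i in seq_along(lineage)) {
        parts <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
        parts <- parts[nzchar(parts)]
        hit <- FALSE
        for (p in parts) {
            if (grepl("^D_[0-9]+__", p)) {
                lev <- as.integer(sub("^D_([0-9]+)__.*$", "\\1", p)) + 1L
                val <- sub("^D_[0-9]+__", "", p)
            } else {
                lev <- match(substr(p, 1, 3), gg_pref)
                val <- sub("^[a-z]__", "", p)
            }
            if (!is.na(lev) && lev >= 1L && lev <= length(TAX_RANKS) && nzchar(val)) {
                out[i, lev] <- val
                hit <- TRUE
            }
        }
        if (!hit && length(parts)) bad[i] <- TRUE
    }
    if (any(bad))
        warning(sum(bad), " lineage(s) could not be parsed; set to Unclassified")
    as.data.frame(out, stringsAsFactors = FALSE)
}

#' Filter OTUs by prevalence
#'
#' Prevalence is the fraction of samples in which an OTU has a nonzero
#' count. OTUs whose prevalence is *at least* `min_prevalence` are kept
#' (an OTU present in exactly half the samples is retained under the
#' default 0.5, i.e. only OTUs present in *less than* half the samples are
#' removed). Filtering is intended to run within the sample subset that a
#' network will be built from, one group at a time.
#'
#' @param table an [OtuTable-class].
#' @param min_prevalence fraction in (0, 1], default 0.5.
#' @return the filtered [OtuTable-class]; samples unchanged.
#' @export
prevalenceFilter <- function(table, min_prevalence = 0.5) {
    stopifnot(methods::is(table, "OtuTable"),
              min_prevalence > 0, min_prevalence <= 1)
    cts <- otuCounts(table)
    prev <- rowMeans(cts > 0)
    keep <- prev >= min_prevalence - 1e-12
    if (!any(keep))
        stop("no OTUs survive the prevalence filter at min_prevalence = ",
             min_prevalence)
    table[keep, ]
}

#' Log10 relative abundance with zero replacement
#'
#' Relative abundance of each OTU is its count divided by the sample's
#' total count over *all* OTUs of the input table. Zeros are replaced
#' before the log according to `zero_strategy`:
#' \describe{
#'   \item{pseudo}{(default) zeros become 0.01 x the smallest nonzero
#'     relative abundance observed anywhere in the matrix.}
#'   \item{na}{zeros become `NA`; downstream correlation then uses
#'     pairwise-complete observations.}
#' }
#'
#' @param table an [OtuTable-class].
#' @param zero_strategy "pseudo" or "na".
#' @return an [AbundanceMatrix-class] of log10 values.
#' @export
logRelativeAbundance <- function(table, zero_strategy = c("pseudo", "na")) {
    zero_strategy <- match.arg(zero_strategy)
    cts <- otuCounts(table)
    tot <- colSums(cts)
    if (any(tot == 0))
        stop("sample(s) with zero total count: ",
             paste(colnames(cts)[tot == 0], collapse = ", "))
    p <- sweep(cts, 2, tot, "/")
    pseudo <- NA_real_
    if (any(p == 0)) {
        if (zero_strategy == "pseudo") {
            pseudo <- 0.01 * min(p[p > 0])
            p[p == 0] <- pseudo
        } else {
            p[p == 0] <- NA_real_
        }
    }
    methods::new("AbundanceMatrix", values = log10(p),
                 zeroStrategy = zero_strategy, pseudoAbundance = pseudo)
}

#' Shannon diversity index
#'
#' H = -sum p_i log_base(p_i) over nonzero proportions; the input vector is
#' normalised internally. Base 2 by default (bits).
#'
#' @param p non-negative abundance vector with positive sum.
#' @param base logarithm base, default 2.
#' @export
shannonIndex <- function(p, base = 2) {
    stopifnot(all(p >= 0))
    if (sum(p) <= 0) stop("abundance vector sums to zero")
    p <- p[p > 0] / sum(p)
    -sum(p * log(p, base = base))
}

#' Gini-Simpson diversity index
#'
#' D = 1 - sum p_i^2, in [0, 1]; 0 for a single-taxon community.
#'
#' @param p non-negative abundance vector with positive sum.
#' @export
simpsonIndex <- function(p) {
    stopifnot(all(p >= 0))
    if (sum(p) <= 0) stop("abundance vector sums to zero")
    p <- p / sum(p)
    1 - sum(p^2)
}

#' Per-sample alpha diversity of an OTU table
#'
#' @param table an [OtuTable-class].
#' @param base Shannon log base, default 2.
#' @return data.frame with columns sample, shannon, simpson, group.
#' @export
alphaDiversity <- function(table, base = 2) {
    cts <- otuCounts(table)
    data.frame(sample = colnames(cts),
               shannon = apply(cts, 2, shannonIndex, base = base),
               simpson = apply(cts, 2, simpsonIndex),
               group = sampleGroups(table),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA comparison of a per-sample statistic across groups
#'
#' Classical (equal-variance) one-way ANOVA; with two groups the F
#' statistic equals the square of the pooled-variance t statistic.
#'
#' @param values numeric vector of per-sample values.
#' @param group group label per value.
#' @return list with `F`, `p`, `df`, and per-group means.
#' @export
compareAlpha <- function(values, group) {
    group <- factor(group)
    if (any(table(group) < 2))
        stop("every group needs at least 2 samples")
    fit <- stats::oneway.test(values ~ group, var.equal = TRUE)
    list(F = unname(fit$statistic), p = unname(fit$p.value),
         df = unname(fit$parameter),
         means = tapply(values, group, mean))
}
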