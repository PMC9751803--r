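#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same objects;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI.
#' @export
adjustedRand <- function(a, b) {
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    n <- length(a)
    sum_ij <- sum(choose(tab, 2))
    sum_a <- sum(choose(rowSums(tab), 2))
    sum_b <- sum(choose(colSums(tab), 2))
    expected <- sum_a * sum_b / choose(n, 2)
    max_idx <- (sum_a + sum_b) / 2
    if (max_idx == expected) return(1)
    (sum_ij - expected) / (max_idx - expected)
}

## Deterministic per-stage seed derived from a master seed; kept within
## 32-bit integer range.
#' @keywords internal
deriveSeed <- function(master, group_index, stage) {
    as.integer((as.numeric(master) * 1009 + 97 * group_index + stage) %%
               2147483647)
}
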