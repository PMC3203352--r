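## Expression preprocessing: replicate averaging, gene-mean imputation and
## the three-level mean/SD discretization used by the structure learner.

.exprsMatrix <- function(se) {
    if (is.matrix(se)) return(se)
    SummarizedExperiment::assay(se, "exprs")
}

.asSE <- function(m) {
    SummarizedExperiment::SummarizedExperiment(assays = list(exprs = m))
}

#' Average replicate samples by condition
#'
#' Replicate samples belonging to the same condition/time point are
#' averaged into one column. Missing replicate values are dropped from the
#' mean; a cell is missing in the output only when every replicate is
#' missing.
#'
#' @param se expression `SummarizedExperiment` (assay `"exprs"`) or matrix.
#' @param groups named character vector mapping every sample label to its
#'   condition; output columns follow the order of first appearance.
#' @return A `SummarizedExperiment` with one column per condition.
#' @export
averageReplicates <- function(se, groups) {
    m <- .exprsMatrix(se)
    if (!all(colnames(m) %in% names(groups)))
        stop("unassigned sample(s): ",
             paste(setdiff(colnames(m), names(groups)), collapse = ", "))
    g <- groups[colnames(m)]
    conds <- unique(g)
    if (any(!conds %in% g)) stop("empty group")
    out <- vapply(conds, function(cc) {
        rowMeans(m[, g == cc, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(m)))
    out[is.nan(out)] <- NA_real_
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), conds))
    .asSE(out)
}

#' Impute missing expression values by the gene mean
#'
#' Each missing cell is replaced by the mean of the gene's non-missing
#' values. A gene with no observed value at all is an error.
#'
#' @param se expression `SummarizedExperiment` or matrix.
#' @return A `SummarizedExperiment` with no missing values.
#' @export
imputeMissing <- function(se) {
    m <- .exprsMatrix(se)
    allMissing <- rowSums(!is.na(m)) == 0L
    if (any(allMissing))
        stop("gene(s) with no observed value: ",
             paste(rownames(m)[allMissing], collapse = ", "))
    if (anyNA(m)) {
        mu <- rowMeans(m, na.rm = TRUE)
        idx <- which(is.na(m), arr.ind = TRUE)
        m[idx] <- mu[idx[, 1L]]
    }
    .asSE(m)
}

#' Discretize expression into three levels per gene
#'
#' For each gene the mean \eqn{\mu} and sample standard deviation SD over
#' all samples are computed; a value below \eqn{\mu - SD} becomes 0, a
#' value above \eqn{\mu + SD} becomes 2, and values in the closed interval
#' \eqn{[\mu - SD, \mu + SD]} (including both boundaries, and the entire
#' row of a constant gene where SD = 0) become 1. The transform is
#' invariant under positive affine rescaling of a gene's row.
#'
#' @param se expression `SummarizedExperiment` or matrix; must contain no
#'   missing values (run [imputeMissing()] first).
#' @return A [DiscretizedExperiment-class] with assay `"levels"`.
#' @examples
#' m <- rbind(g1 = c(0, 0, 0, 10), g2 = c(5, 5, 5, 5))
#' levelMatrix(discretizeExpression(m))
#' @export
discretizeExpression <- function(se) {
    m <- .exprsMatrix(se)
    if (anyNA(m))
        stop("missing values present; run imputeMissing() first")
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)          # sample SD (n - 1 denominator)
    sd[is.na(sd)] <- 0                      # single-sample edge case
    lv <- matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m))
    lv[m < mu - sd] <- 0L
    lv[m > mu + sd] <- 2L
    new("DiscretizedExperiment",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(levels = lv)))
}

#' Write a discretized matrix as an integer TSV (for audit)
#'
#' @param de a [DiscretizedExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDiscretized <- function(de, path) {
    m <- levelMatrix(de)
    out <- cbind(gene = rownames(m),
                 matrix(as.character(m), nrow(m), ncol(m),
                        dimnames = dimnames(m)))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
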