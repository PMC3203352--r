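## Flat-file readers/writers. No science here: parsing, validation and
## lossless round-trips only. Readers report (never silently drop) skipped
## records via message().

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample labels and a first column of gene
#' identifiers. Cells equal to `missingToken` become `NA` in the assay.
#'
#' @param path TSV file path.
#' @param missingToken string marking missing cells (default `"NA"`).
#' @return A [SummarizedExperiment::SummarizedExperiment-class] with assay
#'   `"exprs"` (genes x samples; `NA` marks missing values).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1.5\tNA", "g2\t0.2\t3.1"), tf)
#' se <- readExpression(tf)
#' SummarizedExperiment::assay(se, "exprs")
#' @seealso [writeExpression()], [discretizeExpression()]
#' @export
readExpression <- function(path, missingToken = "NA") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "",
                            na.strings = character(0))
    if (ncol(df) < 2L) stop("expression TSV needs a gene column and >= 1 sample")
    genes <- df[[1L]]
    if (anyDuplicated(genes))
        stop("duplicated gene identifier(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- as.matrix(df[, -1L, drop = FALSE])
    miss <- vals == missingToken
    vals[miss] <- NA_character_
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    bad <- is.na(num) & !miss
    if (any(bad))
        stop("non-numeric cell(s) at gene ",
             paste(unique(genes[which(bad, arr.ind = TRUE)[, 1L]]),
                   collapse = ", "))
    dimnames(num) <- list(genes, colnames(vals))
    SummarizedExperiment::SummarizedExperiment(assays = list(exprs = num))
}

## format a numeric matrix cell-wise without losing its shape (apply() would
## simplify single-row matrices to vectors)
.formatCells <- function(m, missingToken = NULL) {
    out <- matrix(format(m, digits = 15, trim = TRUE,
                         scientific = FALSE),
                  nrow(m), ncol(m), dimnames = dimnames(m))
    if (!is.null(missingToken)) out[is.na(m)] <- missingToken
    out
}

#' Write an expression matrix to TSV
#'
#' @param se a `SummarizedExperiment` with assay `"exprs"` (or a plain
#'   numeric matrix).
#' @param path output path.
#' @param missingToken string written for `NA` cells.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(se, path, missingToken = "NA") {
    m <- if (is.matrix(se)) se else SummarizedExperiment::assay(se, "exprs")
    out <- cbind(gene = rownames(m), .formatCells(m, missingToken))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an OBO-format ontology
#'
#' Minimal OBO dialect: only `[Term]` stanzas with `id:`, `is_a:`,
#' `relationship: part_of` and `is_obsolete:` lines are honoured;
#' `part_of` is treated as a parent link like `is_a`. Obsolete terms are
#' skipped (and counted in a message). Everything else is ignored.
#'
#' @param path OBO file path.
#' @return An [OntologyDAG-class]; errors if the term graph is cyclic,
#'   naming the terms on the cycle.
#' @export
readOBO <- function(path) {
    lines <- readLines(path, warn = FALSE)
    parents <- list()
    cur <- NULL; curParents <- character(0); obsolete <- FALSE
    obsoleteIds <- character(0)
    flush <- function() {
        if (is.null(cur)) return()
        if (obsolete) obsoleteIds <<- c(obsoleteIds, cur)
        else parents[[cur]] <<- unique(c(parents[[cur]], curParents))
    }
    inTerm <- FALSE
    for (ln in lines) {
        ln <- sub("!.*$", "", ln)
        ln <- trimws(ln)
        if (ln == "[Term]") {
            flush(); cur <- NULL; curParents <- character(0)
            obsolete <- FALSE; inTerm <- TRUE
        } else if (grepl("^\\[", ln)) {
            flush(); cur <- NULL; inTerm <- FALSE
        } else if (inTerm) {
            if (grepl("^id:", ln)) {
                cur <- trimws(sub("^id:", "", ln))
            } else if (grepl("^is_a:", ln)) {
                curParents <- c(curParents, trimws(sub("^is_a:", "", ln)))
            } else if (grepl("^relationship:\\s*part_of\\s", ln)) {
                curParents <- c(curParents,
                    trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
            } else if (grepl("^is_obsolete:\\s*true", ln)) {
                obsolete <- TRUE
            }
        }
    }
    flush()
    if (length(parents) == 0L) stop("no terms found in ", path)
    ## drop parent links pointing at obsolete (hence absent) terms; terms
    ## referenced only as parents get empty parent sets inside OntologyDAG()
    parents <- lapply(parents, function(p) setdiff(p, obsoleteIds))
    known <- names(parents)
    extra <- setdiff(unique(unlist(parents, use.names = FALSE)), known)
    full <- c(parents, stats::setNames(rep(list(character(0)),
                                           length(extra)), extra))
    if (is.null(.topoOrder(names(full), full))) {
        onCycle <- .findCycleTerms(parents)
        stop("cycle among ontology terms: ",
             paste(onCycle, collapse = " -> "))
    }
    if (length(obsoleteIds) > 0L)
        message("readOBO: skipped ", length(obsoleteIds),
                " obsolete term(s)")
    OntologyDAG(parents)
}

## return one set of terms that cannot be topologically ordered
.findCycleTerms <- function(parents) {
    terms <- union(names(parents), unlist(parents, use.names = FALSE))
    full <- stats::setNames(rep(list(character(0)), length(terms)), terms)
    full[names(parents)] <- parents
    remaining <- terms
    repeat {
        removable <- remaining[vapply(full[remaining], function(p)
            !any(p %in% remaining), logical(1))]
        if (!length(removable)) return(sort(remaining))
        remaining <- setdiff(remaining, removable)
        if (!length(remaining)) return(character(0))
    }
}

#' Read gene-to-term annotations (gene2go-style TSV)
#'
#' Two tab-separated columns: gene id, term id. Header lines starting with
#' `#` are skipped. Records whose term is absent from `onto` are dropped
#' with a message (never silently).
#'
#' @param path TSV path.
#' @param onto an [OntologyDAG-class] used to validate terms.
#' @return Named list: gene id -> character vector of term ids.
#' @export
readAnnotations <- function(path, onto) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", comment.char = "#",
                            quote = "")
    if (ncol(df) < 2L) stop("annotation TSV needs two columns")
    keep <- df[[2L]] %in% ontoTerms(onto)
    if (any(!keep))
        message("readAnnotations: dropped ", sum(!keep),
                " record(s) with unknown terms")
    df <- df[keep, , drop = FALSE]
    ann <- split(df[[2L]], df[[1L]])
    lapply(ann, unique)
}

#' Read gene-to-abstract citations (gene2pubmed-style TSV)
#'
#' Two tab-separated columns: gene id, abstract id. The corpus size `N` is
#' read from `totalAbstracts` if given, else from a one-line sidecar file
#' `<path>.total` containing a single integer.
#'
#' @param path TSV path.
#' @param totalAbstracts optional corpus size `N`.
#' @return A [CitationIndex-class].
#' @export
readCitations <- function(path, totalAbstracts = NULL) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", comment.char = "#",
                            quote = "")
    if (ncol(df) < 2L) stop("citation TSV needs two columns")
    if (is.null(totalAbstracts)) {
        sidecar <- paste0(path, ".total")
        if (!file.exists(sidecar))
            stop("totalAbstracts not given and sidecar ", sidecar,
                 " not found")
        totalAbstracts <- as.integer(readLines(sidecar, n = 1L))
    }
    CitationIndex(split(df[[2L]], df[[1L]]), totalAbstracts)
}

#' Read a two-column gene-pair table
#'
#' @param path TSV path with two columns of gene identifiers (optional
#'   header detected when the first line repeats in no data row is NOT
#'   attempted: files are headerless; lines starting with `#` are skipped).
#' @param directed if `FALSE`, pairs are canonicalized (lexicographic
#'   order) and deduplicated; if `TRUE`, ordered pairs are kept distinct.
#' @return Character matrix with two columns (and the input order of first
#'   appearance). Self-pairs raise an error.
#' @export
readPairTable <- function(path, directed = FALSE) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", comment.char = "#",
                            quote = "")
    if (ncol(df) < 2L) stop("pair table needs two columns")
    a <- df[[1L]]; b <- df[[2L]]
    if (any(a == b))
        stop("self-pair(s) not allowed: ",
             paste(unique(a[a == b]), collapse = ", "))
    m <- cbind(a, b)
    if (!directed) {
        swap <- m[, 1L] > m[, 2L]
        m[swap, ] <- m[swap, c(2L, 1L)]
    }
    m <- m[!duplicated(paste(m[, 1L], m[, 2L])), , drop = FALSE]
    dimnames(m) <- list(NULL, c("gene_a", "gene_b"))
    m
}

#' Write an averaged network as SIF + weight matrix
#'
#' Writes a Cytoscape-compatible SIF edge list (`source regulates target`)
#' for every directed edge with weight strictly above `threshold`, plus a
#' full TSV weight matrix at `<path>.weights.tsv`.
#'
#' @param avg an [AveragedNetwork-class].
#' @param path SIF output path.
#' @param threshold weight cutoff in \[0,1\] (default 0.5).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(avg, path, threshold = 0.5) {
    stopifnot(threshold >= 0, threshold <= 1)
    w <- edgeWeights(avg)
    idx <- which(w > threshold, arr.ind = TRUE)
    lines <- if (nrow(idx)) {
        ord <- order(w[idx], decreasing = TRUE)
        idx <- idx[ord, , drop = FALSE]
        sprintf("%s\tregulates\t%s", rownames(w)[idx[, 1L]],
                colnames(w)[idx[, 2L]])
    } else character(0)
    writeLines(lines, path)
    wm <- cbind(gene = rownames(w), .formatCells(w))
    utils::write.table(wm, paste0(path, ".weights.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read back a weight matrix written by [writeNetwork()]
#'
#' @param path the `<path>.weights.tsv` file.
#' @return An [AveragedNetwork-class].
#' @export
readNetworkWeights <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, quote = "")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    AveragedNetwork(m)
}
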