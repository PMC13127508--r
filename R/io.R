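#' Read a MatrixMarket count matrix with gene and barcode files
#'
#' Reads a 10x-style triplet of files (MatrixMarket coordinate matrix plus
#' one-entry-per-line gene and barcode TSVs) into an
#' \linkS4class{ExoExperiment}. Orientation on disk is auto-detected by
#' matching the matrix dimensions to the lengths of the gene and barcode
#' files; in memory genes are always rows and cells columns.
#'
#' @param matrixPath path to the MatrixMarket \code{.mtx} file.
#' @param genesPath path to the gene symbol file (first column used).
#' @param barcodesPath path to the cell barcode file (first column used).
#' @return An \linkS4class{ExoExperiment} with \code{counts} populated, no
#'   \code{lognorm} assay, and \code{n_genes_detected} computed.
#' @export
readCountsMtx <- function(matrixPath, genesPath, barcodesPath) {
    m <- Matrix::readMM(matrixPath)
    if (methods::is(m, "nMatrix"))  # pattern matrix (e.g. empty file)
        m <- methods::as(m, "dMatrix")
    genes <- .readLabelColumn(genesPath)
    barcodes <- .readLabelColumn(barcodesPath)
    dm <- dim(m)
    if (dm[1] == length(genes) && dm[2] == length(barcodes)) {
        # genes x cells as stored
    } else if (dm[1] == length(barcodes) && dm[2] == length(genes)) {
        m <- Matrix::t(m)
    } else {
        stop(sprintf(
            "matrix dimensions %d x %d match neither %d genes x %d barcodes nor its transpose",
            dm[1], dm[2], length(genes), length(barcodes)))
    }
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
    if (length(v) && (any(v < 0) || any(v != round(v))))
        stop("count matrix has negative or non-integer entries")
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(genes, barcodes)
    ExoExperiment(m)
}

.readLabelColumn <- function(path) {
    x <- readLines(path)
    x <- x[nzchar(x)]
    vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write an ExoExperiment's counts as MTX + gene/barcode files
#'
#' @param x an \linkS4class{ExoExperiment}.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Invisibly, the three file paths written.
#' @export
writeCountsMtx <- function(x, dir, prefix = "") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cts <- methods::as(SummarizedExperiment::assay(x, "counts"),
                       "CsparseMatrix")
    paths <- file.path(dir, paste0(prefix,
                                   c("matrix.mtx", "genes.tsv",
                                     "barcodes.tsv")))
    Matrix::writeMM(cts, paths[1])
    writeLines(rownames(cts), paths[2])
    writeLines(colnames(cts), paths[3])
    invisible(paths)
}

#' Attach per-cell metadata from a TSV file
#'
#' Reads a cell metadata table (required column \code{cell_id}; standard
#' columns \code{donor}, \code{context}, \code{sample}, \code{pct_mito},
#' \code{pct_ribo}, \code{contamination}) and attaches it to the matching
#' cells of an \linkS4class{ExoExperiment}.
#'
#' @param x an \linkS4class{ExoExperiment}.
#' @param path TSV file with a header.
#' @return \code{x} with augmented \code{colData}.
#' @export
readCellMeta <- function(x, path) {
    meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"cell_id" %in% colnames(meta))
        stop("cell metadata must have a 'cell_id' column")
    if (!all(colnames(x) %in% meta$cell_id))
        stop("cell metadata is missing entries for some cells")
    meta <- meta[match(colnames(x), meta$cell_id), ]
    for (cn in setdiff(colnames(meta), c("cell_id", "n_genes_detected")))
        SummarizedExperiment::colData(x)[[cn]] <- meta[[cn]]
    methods::validObject(x)
    x
}

#' Library-size log-normalization
#'
#' Computes \code{lognorm[g, c] = ln(1 + counts[g, c] / total[c] *
#' scaleFactor)}, the natural log of library-size-scaled counts. Cells with
#' zero total counts must be removed beforehand (by QC filtering) and raise
#' an error naming the offending cell.
#'
#' @param x an \linkS4class{ExoExperiment} with counts populated.
#' @param scaleFactor positive scale factor (default 10,000).
#' @return \code{x} with the \code{lognorm} assay added.
#' @examples
#' m <- matrix(c(1L, 1L), nrow = 2, dimnames = list(c("g1", "g2"), "c1"))
#' lognorm(logNormalize(ExoExperiment(m)))  # both entries ln(1 + 5000)
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
    stopifnot(scaleFactor > 0)
    cts <- SummarizedExperiment::assay(x, "counts")
    tot <- Matrix::colSums(cts)
    if (any(tot == 0))
        stop("cell(s) with zero total counts: ",
             paste(head(colnames(x)[tot == 0], 5), collapse = ", "))
    if (methods::is(cts, "sparseMatrix")) {
        ln <- cts %*% Matrix::Diagonal(x = scaleFactor / tot)
        ln <- methods::as(ln, "CsparseMatrix")
        ln@x <- log1p(ln@x)
    } else {
        ln <- log1p(sweep(cts, 2, tot / scaleFactor, "/"))
    }
    dimnames(ln) <- dimnames(cts)
    SummarizedExperiment::assay(x, "lognorm") <- ln
    methods::validObject(x)
    x
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields are name, description, then gene
#' symbols, tab-separated. Duplicate genes within a set are de-duplicated
#' with a warning; an empty set is a format error.
#'
#' @param path GMT file path.
#' @param kind collection kind (\code{axis_panel}, \code{gene_module},
#'   \code{nmf_signature}).
#' @return A \linkS4class{GeneSetList}.
#' @export
readGeneSets <- function(path, kind = c("axis_panel", "gene_module",
                                        "nmf_signature")) {
    kind <- match.arg(kind)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("GMT format error: set '", f[1], "' is empty")
        genes <- f[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (!length(genes))
            stop("GMT format error: set '", f[1], "' is empty")
        if (anyDuplicated(genes)) {
            warning("duplicate genes in set '", f[1], "' de-duplicated")
            genes <- unique(genes)
        }
        sets[[f[1]]] <- genes
    }
    GeneSetList(sets, kind)
}

#' Write a GeneSetList to a GMT file
#'
#' @param x a \linkS4class{GeneSetList}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneSets <- function(x, path) {
    lines <- vapply(names(geneSets(x)), function(n) {
        paste(c(n, "na", geneSets(x)[[n]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a regulon from a 4-column TSV
#'
#' Expects a header line with columns \code{tf}, \code{target}, \code{mode}
#' (-1 or +1) and \code{weight} (> 0). Duplicated (tf, target) rows keep the
#' first occurrence with a warning.
#'
#' @param path TSV file path.
#' @return A \linkS4class{Regulon}.
#' @export
readRegulon <- function(path) {
    e <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("tf", "target", "mode", "weight")
    if (!all(req %in% colnames(e)))
        stop("regulon TSV must have header columns tf, target, mode, weight")
    if (!all(e$mode %in% c(-1, 1)))
        stop("regulon format error: mode outside {-1, +1}")
    dup <- duplicated(e[, c("tf", "target")])
    if (any(dup)) {
        warning(sum(dup), " duplicated (tf, target) row(s) dropped")
        e <- e[!dup, ]
    }
    Regulon(e)
}

#' Write a Regulon to TSV
#'
#' @param x a \linkS4class{Regulon}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeRegulon <- function(x, path) {
    write.table(regulonEdges(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
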