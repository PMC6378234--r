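#' Read a gene-by-sample expression matrix from TSV
#'
#' The file must have gene identifiers in the first column and sample
#' identifiers in the header row.  Parsing is locale-independent (dot
#' decimal separator).  Duplicate gene or sample identifiers and
#' non-numeric cells are rejected with informative errors.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, genes in rows, samples in columns.
#' @seealso [writeExpressionMatrix()], [collapseProbes()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("G1","G2","G3"), c("s1","s2")))
#' writeExpressionMatrix(m, f)
#' readExpressionMatrix(f)
readExpressionMatrix <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 2L)
        stop("expression file needs a gene-id column plus >= 1 sample")
    genes <- raw[[1L]]
    samples <- colnames(raw)[-1L]
    if (anyDuplicated(genes))
        stop("duplicate gene id(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    if (anyDuplicated(samples))
        stop("duplicate sample id(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    bad <- which(is.na(num) & !(vals %in% c("NA", "NaN")), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     vals[bad[1L, 1L], bad[1L, 2L]],
                     genes[bad[1L, 1L]], samples[bad[1L, 2L]]))
    }
    if (any(!is.finite(num)))
        stop("expression matrix contains non-finite values")
    dimnames(num) <- list(genes, samples)
    num
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpressionMatrix()]: genes in rows (first column
#' \code{gene}), samples in the header.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(mat, path) {
    stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Collapse a probe-level matrix to gene level by arithmetic mean
#'
#' Probes mapping to the same gene are averaged (arithmetic mean, the
#' standard convention for re-annotated microarray probes).  Probes absent
#' from the map are dropped with a message; a probe mapped to more than one
#' gene violates the uniquely-mapped contract and is an error.
#'
#' @param mat numeric matrix, probes in rows.
#' @param probeMap data.frame whose first two columns are probe id and gene
#'   id (a 2-column probe-to-gene TSV read with \code{read.delim} works
#'   as-is).
#' @return numeric matrix with one row per gene.
#' @export
#' @examples
#' m <- rbind(p1 = c(2, 4), p2 = c(4, 6))
#' colnames(m) <- c("s1", "s2")
#' collapseProbes(m, data.frame(probe = c("p1","p2"), gene = c("G","G")))
collapseProbes <- function(mat, probeMap) {
    stopifnot(is.matrix(mat), ncol(probeMap) >= 2L)
    probe <- as.character(probeMap[[1L]])
    gene <- as.character(probeMap[[2L]])
    multi <- unique(probe[!duplicated(paste(probe, gene)) &
                          probe %in% probe[duplicated(probe)]])
    # a probe listed twice with the same gene is harmless; different genes not
    tab <- unique(data.frame(probe = probe, gene = gene,
                             stringsAsFactors = FALSE))
    multi <- unique(tab$probe[duplicated(tab$probe)])
    if (length(multi))
        stop("probe(s) mapped to more than one gene: ",
             paste(multi, collapse = ", "))
    map <- stats::setNames(tab$gene, tab$probe)
    keep <- rownames(mat) %in% names(map)
    if (any(!keep))
        message(sum(!keep), " probe(s) absent from the probe map; dropped")
    if (!any(keep))
        stop("no probe of the matrix is present in the probe map")
    m <- mat[keep, , drop = FALSE]
    g <- map[rownames(m)]
    sums <- rowsum(m, group = g)
    counts <- as.vector(table(g)[rownames(sums)])
    sums / counts
}

#' Read a per-sample clinical/survival table from TSV
#'
#' Mandatory columns: \code{sample}, \code{time}, \code{event}; optional:
#' \code{endpoint} (OS/PFS/DFS), \code{age}, \code{stage}, \code{grade},
#' \code{residual}, \code{lymph}.  Missing covariate values are allowed and
#' propagated; operations that need a covariate drop and log them.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with sample ids as rownames.
#' @export
readClinicalTable <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample", "time", "event")
    if (!all(need %in% colnames(df)))
        stop("clinical table must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(df$sample))
        stop("duplicate sample id(s): ",
             paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
    if (any(!is.finite(df$time)) || any(df$time <= 0))
        stop("all survival times must be finite and > 0")
    if (!all(df$event %in% c(0, 1)))
        stop("event must be 0 or 1")
    rownames(df) <- df$sample
    df$sample <- NULL
    df
}

#' Build a CohortBundle by aligning expression and survival data
#'
#' Restricts both inputs to their common samples (same order) and wraps
#' them in a \linkS4class{CohortBundle}.  Samples present on only one side
#' are dropped with a message.  Alignment is idempotent: bundling an
#' already-aligned pair changes nothing.
#'
#' @param expression numeric gene-by-sample matrix.
#' @param survival data.frame with sample rownames (or a \code{sample}
#'   column) and at least \code{time} and \code{event}.
#' @param name cohort label.
#' @param log2p1 if \code{TRUE}, apply \code{log2(x + 1)} to the expression
#'   values (useful for raw RNA-seq quantifications).
#' @return a \linkS4class{CohortBundle}.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1","g2"), c("s1","s2","s3")))
#' cl <- data.frame(time = c(5, 10, 2), event = c(1, 0, 1),
#'                  row.names = c("s2", "s3", "s4"))
#' b <- CohortBundle(m, cl, name = "toy")   # aligned to {s2, s3}
CohortBundle <- function(expression, survival, name = "cohort",
                         log2p1 = FALSE) {
    expression <- as.matrix(expression)
    if (!is.null(survival$sample)) {
        rownames(survival) <- survival$sample
        survival$sample <- NULL
    }
    shared <- intersect(colnames(expression), rownames(survival))
    if (length(shared) == 0L)
        stop("expression and survival share no samples")
    dropE <- ncol(expression) - length(shared)
    dropS <- nrow(survival) - length(shared)
    if (dropE > 0L || dropS > 0L)
        message("aligned cohort '", name, "': dropped ", dropE,
                " expression-only and ", dropS, " survival-only sample(s)")
    expression <- expression[, shared, drop = FALSE]
    survival <- survival[shared, , drop = FALSE]
    if (log2p1) {
        if (any(expression < 0))
            stop("log2p1 requires non-negative expression values")
        expression <- log2(expression + 1)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = expression),
        colData = S4Vectors::DataFrame(survival))
    obj <- methods::new("CohortBundle", se)
    S4Vectors::metadata(obj)$name <- name
    methods::validObject(obj)
    obj
}

#' Read / write gene sets in GMT format
#'
#' \code{readGMT} parses a GMT file into a named list of member vectors
#' (set name -> members); \code{writeGMT} writes one.  Used for candidate
#' TF-lncRNA binding sets and for exported regulons.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param description description field written as second GMT column.
#' @return \code{readGMT}: named list; \code{writeGMT}: invisibly,
#'   \code{path}.
#' @export
readGMT <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    fgsea::gmtPathways(path)
}

#' @rdname readGMT
#' @export
writeGMT <- function(sets, path, description = "na") {
    stopifnot(is.list(sets), !is.null(names(sets)))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
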