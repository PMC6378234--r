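#' Pearson correlation with a two-sided t-transform p-value
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return list with \code{r} and \code{p} (two-sided, t distribution with
#'   n - 2 degrees of freedom).
#' @export
#' @examples
#' pearsonCorrelation(c(1, 2, 3), c(1, 2, 4))   # r ~ 0.982
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 3L)
        stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance: correlation undefined")
    ht <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ht$estimate), p = ht$p.value)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted values: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and returned
#' in the input order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted values in [0, 1], input order preserved.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
bhAdjust <- function(pvals) {
    if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

#' Build the correlation-filtered TF-lncRNA regulon network
#'
#' Every candidate TF-lncRNA binding pair whose members are present (and
#' non-constant) in the expression matrix is tested by Pearson correlation
#' between the TF's and the lncRNA's expression across samples.  Retained
#' edges satisfy \code{r > rMin} and \code{fdr < fdrMax}, with the FDR
#' computed by Benjamini-Hochberg over all tested pairs in one family
#' (optionally per TF).  TFs whose regulon ends up empty are removed.
#'
#' Filtering is monotone: relaxing either threshold can only add edges.
#'
#' @param bundle a \linkS4class{CohortBundle} (or a bare expression matrix).
#' @param candidates named list: TF id -> character vector of candidate
#'   lncRNA target ids (e.g. from [readGMT()]).
#' @param rMin minimum correlation, strict (default 0: positive
#'   co-expression only).
#' @param fdrMax FDR threshold, strict (default 0.05).
#' @param family \code{"global"} (one BH family over all candidate pairs,
#'   default) or \code{"per_tf"}.
#' @return a \linkS4class{TFTargetNetwork}.
#' @export
buildNetwork <- function(bundle, candidates, rMin = 0, fdrMax = 0.05,
                         family = c("global", "per_tf")) {
    family <- match.arg(family)
    expr <- if (methods::is(bundle, "CohortBundle")) exprMatrix(bundle)
            else as.matrix(bundle)
    stopifnot(is.list(candidates), !is.null(names(candidates)))
    n <- ncol(expr)
    if (n < 3L)
        stop("need at least 3 samples to test correlations")
    rowSd <- apply(expr, 1L, stats::sd)
    constant <- rownames(expr)[rowSd == 0]
    if (length(constant))
        message(length(constant),
                " constant expression row(s) excluded from testing")
    usable <- setdiff(rownames(expr), constant)

    tfs <- names(candidates)
    missTF <- setdiff(tfs, usable)
    if (length(missTF))
        message(length(missTF),
                " candidate TF(s) absent from expression; dropped")
    edges <- do.call(rbind, lapply(setdiff(tfs, missTF), function(tf) {
        lncs <- setdiff(unique(candidates[[tf]]), tf)
        present <- intersect(lncs, usable)
        if (length(present) < length(lncs))
            message("TF ", tf, ": ", length(lncs) - length(present),
                    " candidate target(s) not testable; dropped")
        if (!length(present)) return(NULL)
        data.frame(tf = tf, lnc = present, stringsAsFactors = FALSE)
    }))
    if (is.null(edges) || nrow(edges) == 0L)
        stop("no candidate TF-lncRNA pair is testable in this cohort")

    ## vectorized correlation: center/scale rows once, pairwise dot products
    z <- expr[unique(c(edges$tf, edges$lnc)), , drop = FALSE]
    z <- sweep(z, 1L, rowMeans(z))
    z <- z / sqrt(rowSums(z^2))
    r <- rowSums(z[edges$tf, , drop = FALSE] * z[edges$lnc, , drop = FALSE])
    r <- pmin(1, pmax(-1, r))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    edges$r <- r
    edges$p <- p
    edges$fdr <- if (family == "global") bhAdjust(p)
                 else stats::ave(p, edges$tf, FUN = bhAdjust)
    edges$kept <- edges$r > rMin & edges$fdr < fdrMax

    regs <- split(edges$lnc[edges$kept], edges$tf[edges$kept])
    regs <- lapply(regs, unique)
    regs <- regs[lengths(regs) > 0L]
    methods::new("TFTargetNetwork", edges = edges, regulons = regs,
                 params = list(rMin = rMin, fdrMax = fdrMax,
                               family = family))
}

#' Write a TFTargetNetwork to disk
#'
#' Writes the retained regulons as GMT (set name = TF) and the full tested
#' edge table as TSV (\code{tf, lnc, r, p, fdr, kept}).
#'
#' @param network a \linkS4class{TFTargetNetwork}.
#' @param gmtPath,tsvPath output paths (either may be \code{NULL} to skip).
#' @return invisibly, the network.
#' @export
writeNetwork <- function(network, gmtPath = NULL, tsvPath = NULL) {
    stopifnot(methods::is(network, "TFTargetNetwork"))
    if (!is.null(gmtPath))
        writeGMT(regulons(network), gmtPath, description = "regulon")
    if (!is.null(tsvPath))
        utils::write.table(edgeTable(network), tsvPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(network)
}
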