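#' Accessors for CohortBundle objects
#'
#' \code{exprMatrix} returns the gene-by-sample expression matrix,
#' \code{survTable} the per-sample survival/clinical table (rownames are
#' sample ids), and \code{cohortName} the cohort label.
#'
#' @param x a \linkS4class{CohortBundle}.
#' @return see above.
#' @name CohortBundle-accessors
#' @aliases exprMatrix survTable cohortName
#' @examples
#' b <- exampleBundle()
#' dim(exprMatrix(b))
#' head(survTable(b))
#' cohortName(b)
NULL

#' @rdname CohortBundle-accessors
#' @export
setMethod("exprMatrix", "CohortBundle", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname CohortBundle-accessors
#' @export
setMethod("survTable", "CohortBundle", function(x) {
    df <- as.data.frame(SummarizedExperiment::colData(x))
    rownames(df) <- colnames(x)
    df
})

#' @rdname CohortBundle-accessors
#' @export
setMethod("cohortName", "CohortBundle", function(x) {
    nm <- S4Vectors::metadata(x)$name
    if (is.null(nm)) "cohort" else nm
})

#' Accessors for TFTargetNetwork objects
#'
#' \code{regulons} returns the named list TF -> retained lncRNA targets;
#' \code{edgeTable} the full table of tested candidate edges with their
#' correlation statistics and keep flags.
#'
#' @param x a \linkS4class{TFTargetNetwork}.
#' @return see above.
#' @name TFTargetNetwork-accessors
#' @aliases regulons edgeTable
NULL

#' @rdname TFTargetNetwork-accessors
#' @export
setMethod("regulons", "TFTargetNetwork", function(x) x@regulons)

#' @rdname TFTargetNetwork-accessors
#' @export
setMethod("edgeTable", "TFTargetNetwork", function(x) x@edges)

#' Accessors for RiskModel objects
#'
#' @param x a \linkS4class{RiskModel}.
#' @return \code{tfId}: the TF the model belongs to; \code{lncIds}: the
#'   signature lncRNAs; \code{coefs}: their univariate Cox coefficients
#'   (named by lncRNA); \code{cutpoint}: the training median risk score.
#' @name RiskModel-accessors
#' @aliases tfId lncIds coefs cutpoint
NULL

#' @rdname RiskModel-accessors
#' @export
setMethod("tfId", "RiskModel", function(x) x@tfId)

#' @rdname RiskModel-accessors
#' @export
setMethod("lncIds", "RiskModel", function(x) x@lncIds)

#' @rdname RiskModel-accessors
#' @export
setMethod("coefs", "RiskModel", function(x)
    stats::setNames(x@betas, x@lncIds))

#' @rdname RiskModel-accessors
#' @export
setMethod("cutpoint", "RiskModel", function(x) x@cutpoint)

setMethod("show", "CohortBundle", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("CohortBundle '", cohortName(object), "': ",
        nrow(object), " genes x ", ncol(object), " samples; ",
        sum(cd$event == 1), " events / ", sum(cd$event == 0),
        " censored\n", sep = "")
    ep <- unique(as.character(cd$endpoint))
    if (length(ep) && !all(is.na(ep)))
        cat("endpoint:", paste(ep, collapse = ","), "\n")
    extra <- setdiff(colnames(cd), c("time", "event", "endpoint"))
    if (length(extra))
        cat("covariates:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "TFTargetNetwork", function(object) {
    e <- object@edges
    cat("TFTargetNetwork:", sum(e$kept), "edges retained of",
        nrow(e), "tested;", length(object@regulons), "TFs,",
        length(unique(e$lnc[e$kept])), "lncRNAs\n")
    cat(sprintf("thresholds: r > %g, FDR < %g (%s family)\n",
                object@params$rMin, object@params$fdrMax,
                object@params$family))
})

setMethod("show", "RiskModel", function(object) {
    cat("RiskModel for TF '", object@tfId, "' (",
        length(object@lncIds), " lncRNAs; trained on '",
        object@trainingCohort, "', endpoint ", object@endpoint,
        ")\n", sep = "")
    cat(sprintf("cut-point (training median score): %.4g\n",
                object@cutpoint))
    if (length(object@dropped))
        cat("dropped during fit:", paste(object@dropped, collapse = ", "),
            "\n")
})
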