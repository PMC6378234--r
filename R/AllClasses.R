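#' CohortBundle: aligned expression and survival data for one cohort
#'
#' A \code{CohortBundle} extends
#' \linkS4class{SummarizedExperiment}: the \code{"exprs"} assay holds the
#' gene-by-sample expression matrix and \code{colData} holds the per-sample
#' survival table (columns \code{time}, \code{event}, optionally
#' \code{endpoint}, \code{age}, \code{stage}, \code{grade}, \code{residual},
#' \code{lymph}).  The constructor restricts both sides to their common
#' samples, in the same order, so downstream operations never need to
#' re-match identifiers.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [CohortBundle()] for construction and alignment,
#'   [exprMatrix()], [survTable()], [cohortName()].
#' @exportClass CohortBundle
setClass("CohortBundle", contains = "SummarizedExperiment")

setValidity("CohortBundle", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("time", "event") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'time' and 'event'")
    } else {
        if (any(!is.finite(cd$time)) || any(cd$time <= 0))
            msg <- c(msg, "all survival times must be finite and > 0")
        if (!all(cd$event %in% c(0, 1)))
            msg <- c(msg, "event must be 0 (censored) or 1 (event)")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    if (length(msg)) msg else TRUE
})

#' TFTargetNetwork: correlation-filtered TF to lncRNA regulons
#'
#' Built by [buildNetwork()].  The edge table records every candidate pair
#' that was tested (TF, lncRNA, Pearson r, p, global BH FDR and whether the
#' edge passed the r and FDR thresholds); the regulons are the per-TF lists
#' of retained target lncRNAs.
#'
#' @slot edges data.frame with columns \code{tf}, \code{lnc}, \code{r},
#'   \code{p}, \code{fdr}, \code{kept}.
#' @slot regulons named list, TF id -> character vector of retained lncRNA
#'   ids (no duplicates).
#' @slot params list of the thresholds used (\code{rMin}, \code{fdrMax},
#'   \code{family}).
#' @seealso [buildNetwork()], [regulons()], [edgeTable()], [writeNetwork()].
#' @exportClass TFTargetNetwork
setClass("TFTargetNetwork",
    slots = c(edges = "data.frame", regulons = "list", params = "list"))

setValidity("TFTargetNetwork", function(object) {
    msg <- character()
    need <- c("tf", "lnc", "r", "p", "fdr", "kept")
    if (!all(need %in% colnames(object@edges)))
        msg <- c(msg, sprintf("edge table must have columns %s",
                              paste(need, collapse = ", ")))
    if (any(vapply(object@regulons, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "regulons must not contain duplicate targets")
    if (length(object@regulons) && any(lengths(object@regulons) == 0L))
        msg <- c(msg, "TFs with empty regulons must be removed")
    if (length(msg)) msg else TRUE
})

#' RiskModel: a trained lncRNA risk-score signature for one TF
#'
#' Holds everything needed to score a new cohort: the ordered regulon
#' members, their univariate Cox coefficients, the training median risk
#' score used as the high/low cut-point, and the training score mean and
#' standard deviation used to place the cut-point on the z scale when the
#' model is transferred to an independent cohort.
#'
#' @slot tfId TF identifier the regulon belongs to.
#' @slot lncIds ordered lncRNA ids entering the score.
#' @slot betas univariate Cox log hazard ratios, one per lncRNA.
#' @slot cutpoint median risk score in the training cohort.
#' @slot scoreCenter,scoreScale mean and sd (n-1) of the training scores.
#' @slot trainingCohort,endpoint provenance labels.
#' @slot dropped regulon members excluded during fitting (absent or
#'   degenerate in the training matrix).
#' @seealso [fitRiskModel()], [computeRiskScores()], [validateTransfer()].
#' @exportClass RiskModel
setClass("RiskModel",
    slots = c(tfId = "character", lncIds = "character", betas = "numeric",
              cutpoint = "numeric", scoreCenter = "numeric",
              scoreScale = "numeric", trainingCohort = "character",
              endpoint = "character", dropped = "character"))

setValidity("RiskModel", function(object) {
    msg <- character()
    if (length(object@lncIds) < 1L)
        msg <- c(msg, "a risk model needs at least one lncRNA")
    if (length(object@betas) != length(object@lncIds))
        msg <- c(msg, "betas and lncIds must have equal length")
    if (!all(is.finite(object@betas)))
        msg <- c(msg, "all betas must be finite")
    if (length(object@cutpoint) != 1L || !is.finite(object@cutpoint))
        msg <- c(msg, "cutpoint must be a single finite number")
    if (length(object@scoreScale) == 1L && !is.na(object@scoreScale) &&
        object@scoreScale <= 0)
        msg <- c(msg, "scoreScale must be > 0")
    if (length(msg)) msg else TRUE
})
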