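#' Baseline screen: univariate Cox on each TF's own expression
#'
#' The pre-model comparison point: how prognostic is the TF's own
#' expression, before any regulon scoring?  TFs absent from the expression
#' matrix or constant are skipped with a message.
#'
#' @param bundle a \linkS4class{CohortBundle}.
#' @param tfIds character vector of TF ids (expression row names).
#' @return data.frame: \code{tf}, \code{beta}, \code{hr}, \code{ciLow},
#'   \code{ciHigh}, \code{p}, one row per screened TF.
#' @export
baselineTFScreen <- function(bundle, tfIds) {
    stopifnot(methods::is(bundle, "CohortBundle"))
    expr <- exprMatrix(bundle)
    sv <- survTable(bundle)
    tfIds <- unique(as.character(tfIds))
    present <- intersect(tfIds, rownames(expr))
    if (length(present) < length(tfIds))
        message(length(tfIds) - length(present),
                " TF(s) absent from expression; skipped")
    rows <- lapply(present, function(tf) {
        x <- expr[tf, ]
        if (stats::sd(x) == 0) {
            message("TF ", tf, " constant; skipped")
            return(NULL)
        }
        f <- .coxUni(sv$time, sv$event, x)
        z <- stats::qnorm(0.975)
        data.frame(tf = tf, beta = f$beta, hr = exp(f$beta),
                   ciLow = exp(f$beta - z * f$se),
                   ciHigh = exp(f$beta + z * f$se), p = f$p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(tf = character(), beta = numeric(),
                          hr = numeric(), ciLow = numeric(),
                          ciHigh = numeric(), p = numeric())
    rownames(out) <- NULL
    out
}

#' Screen every TF with the lncRNA risk-score model
#'
#' For each TF regulon: fit the risk model on the training cohort
#' ([fitRiskModel()]) and evaluate it — in-sample on the training cohort
#' (median split of the training scores; the primary workflow), or, when
#' \code{evalBundle} is supplied, on a held-out cohort with the training
#' coefficients and z-transferred cut-point ([validateTransfer()]), which
#' gives calibrated p-values.
#'
#' TFs are ranked by the log-rank p-value of the high/low split
#' (ascending), ties broken by |log HR| (descending) then TF id; a BH
#' adjusted q-value across the TF family is reported alongside the raw
#' ranking.  TFs that cannot be fitted or evaluated are skipped with a
#' message.
#'
#' @param bundle training \linkS4class{CohortBundle}.
#' @param network a \linkS4class{TFTargetNetwork}, or a plain named list
#'   TF id -> lncRNA ids.
#' @param evalBundle optional held-out \linkS4class{CohortBundle}.
#' @return data.frame of class \code{"TFScreenResult"} ordered by rank:
#'   \code{tf}, \code{nTargets}, \code{hrPerSd}, \code{ciLow},
#'   \code{ciHigh}, \code{logrankP}, \code{coxP}, \code{bhQ}, \code{rank}.
#' @export
screenTFs <- function(bundle, network, evalBundle = NULL) {
    regs <- if (methods::is(network, "TFTargetNetwork")) regulons(network)
            else network
    stopifnot(is.list(regs), !is.null(names(regs)))
    if (!length(regs))
        stop("no TF with a non-empty regulon")
    rows <- lapply(sort(names(regs)), function(tf) {
        ev <- tryCatch({
            model <- fitRiskModel(bundle, tf, regs[[tf]])
            if (is.null(evalBundle)) evaluateSignature(model, bundle)
            else validateTransfer(model, evalBundle)
        }, error = function(e) {
            message("TF ", tf, " skipped: ", conditionMessage(e))
            NULL
        })
        if (is.null(ev)) return(NULL)
        data.frame(tf = tf, nTargets = length(regs[[tf]]),
                   hrPerSd = ev$hrPerSd, ciLow = ev$ciLow,
                   ciHigh = ev$ciHigh, logrankP = ev$logrank$p,
                   coxP = ev$coxP, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        stop("no TF could be screened")
    out$bhQ <- bhAdjust(out$logrankP)
    ord <- order(out$logrankP, -abs(log(out$hrPerSd)), out$tf)
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    class(out) <- c("TFScreenResult", "data.frame")
    out
}

#' Keep the top k ranked TFs
#'
#' @param results a screen result from [screenTFs()].
#' @param k number of TFs to keep (default 10).
#' @return the first \code{k} rows by rank; if \code{k} exceeds the number
#'   of screened TFs, all rows with a warning.
#' @export
topK <- function(results, k = 10L) {
    stopifnot(is.data.frame(results), "rank" %in% colnames(results))
    if (k < 1L) stop("k must be >= 1")
    if (k > nrow(results)) {
        warning("k = ", k, " exceeds the ", nrow(results),
                " screened TFs; returning all")
        k <- nrow(results)
    }
    results[order(results$rank)[seq_len(k)], , drop = FALSE]
}
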