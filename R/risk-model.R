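#' Fit the lncRNA risk-score model for one TF regulon
#'
#' For each regulon lncRNA present in the training cohort, a univariate Cox
#' model of survival on that lncRNA's expression alone is fitted; its
#' coefficient becomes the lncRNA's weight \eqn{\beta_i}.  The per-patient
#' risk score is the linear combination
#' \deqn{RiskScore_s = \sum_i \beta_i \, Exp(lnc_i, s)}
#' and the cut-point stored in the model is the median training score.
#' The training score mean and standard deviation are also stored so that
#' the cut-point can be transferred to independent cohorts on the z scale
#' (see [validateTransfer()]).
#'
#' Regulon members absent from the expression matrix, constant, or with a
#' degenerate Cox fit are dropped with a message and recorded in the
#' model's \code{dropped} slot.
#'
#' @param bundle training \linkS4class{CohortBundle}.
#' @param tfId TF identifier (label only; the TF's own expression is not
#'   used by the model).
#' @param regulon character vector of lncRNA ids regulated by the TF.
#' @param ties tie handling for the Cox fits.
#' @return a \linkS4class{RiskModel}.
#' @export
fitRiskModel <- function(bundle, tfId, regulon, ties = "efron") {
    stopifnot(methods::is(bundle, "CohortBundle"))
    expr <- exprMatrix(bundle)
    sv <- survTable(bundle)
    if (sum(sv$event) == 0)
        stop("training cohort has no observed events")
    regulon <- unique(as.character(regulon))
    present <- intersect(regulon, rownames(expr))
    absent <- setdiff(regulon, present)
    x <- expr[present, , drop = FALSE]
    constant <- present[apply(x, 1L, stats::sd) == 0]
    usable <- setdiff(present, constant)
    if (length(absent) || length(constant))
        message("TF ", tfId, ": dropped ", length(absent),
                " absent and ", length(constant),
                " constant regulon member(s)")
    if (!length(usable))
        stop("TF ", tfId, ": no usable regulon member in this cohort")

    betas <- vapply(usable, function(g)
        .coxUni(sv$time, sv$event, expr[g, ], ties = ties)$beta, 0)
    bad <- usable[!is.finite(betas)]
    if (length(bad)) {
        message("TF ", tfId, ": dropped ", length(bad),
                " member(s) with degenerate Cox fit")
        usable <- setdiff(usable, bad)
        betas <- betas[usable]
        if (!length(usable))
            stop("TF ", tfId, ": no regulon member with a valid Cox fit")
    }
    scores <- as.vector(betas %*% expr[usable, , drop = FALSE])
    endpoint <- if (!is.null(sv$endpoint)) as.character(sv$endpoint[1L])
                else NA_character_
    methods::new("RiskModel",
        tfId = tfId, lncIds = usable, betas = unname(betas),
        cutpoint = stats::median(scores),
        scoreCenter = mean(scores),
        scoreScale = stats::sd(scores),
        trainingCohort = cohortName(bundle),
        endpoint = endpoint,
        dropped = c(absent, constant, bad))
}

#' Compute per-sample risk scores from a trained model
#'
#' Plain weighted sum of expression: model members absent from the matrix
#' are dropped with a warning and the remaining weights are used as-is
#' (no renormalization).
#'
#' @param model a \linkS4class{RiskModel}.
#' @param expr expression matrix or \linkS4class{CohortBundle}.
#' @return named numeric vector of risk scores (one per sample).
#' @export
computeRiskScores <- function(model, expr) {
    stopifnot(methods::is(model, "RiskModel"))
    if (methods::is(expr, "CohortBundle"))
        expr <- exprMatrix(expr)
    present <- intersect(model@lncIds, rownames(expr))
    if (!length(present))
        stop("no model lncRNA present in the expression matrix")
    if (length(present) < length(model@lncIds))
        warning(length(model@lncIds) - length(present),
                " model lncRNA(s) absent from the matrix; dropped")
    b <- stats::setNames(model@betas, model@lncIds)[present]
    as.vector(b %*% expr[present, , drop = FALSE]) |>
        stats::setNames(colnames(expr))
}

#' Assign high/low risk groups at a cut-point
#'
#' Scores strictly above the cut-point go to the high-risk group; scores
#' at or below it to the low-risk group, so with the within-cohort median
#' as cut-point and an odd number of distinct scores the low group gets
#' the extra sample (e.g. 200 low / 199 high at n = 399).
#'
#' @param scores named numeric vector of risk scores.
#' @param cutpoint a number, or \code{"median"} (default) for the
#'   within-cohort median score.
#' @return data.frame with columns \code{sample}, \code{score},
#'   \code{group} (factor low/high).
#' @export
#' @examples
#' assignGroups(c(s1 = 1, s2 = 2, s3 = 3))   # s2 goes to 'low'
assignGroups <- function(scores, cutpoint = "median") {
    if (length(scores) < 2L)
        stop("need at least two samples to split")
    if (identical(cutpoint, "median"))
        cutpoint <- stats::median(scores)
    stopifnot(is.numeric(cutpoint), length(cutpoint) == 1L)
    if (length(unique(scores)) == 1L)
        stop("all risk scores identical: no split possible")
    grp <- factor(ifelse(scores > cutpoint, "high", "low"),
                  levels = c("low", "high"))
    data.frame(sample = if (is.null(names(scores)))
                   as.character(seq_along(scores)) else names(scores),
               score = unname(scores), group = grp,
               stringsAsFactors = FALSE)
}

## Shared evaluation core: given scores, groups and survival, produce the
## log-rank / per-SD Cox / KM summary used by every evaluation mode.
.evaluateScores <- function(scores, groups, time, event, cohort = "cohort") {
    if (nlevels(droplevels(groups)) < 2L)
        stop("degenerate split: one risk group is empty")
    lr <- logrankTest(time, event, groups)
    zscore <- (scores - mean(scores)) / stats::sd(scores)
    cox <- coxFit(time, event, cbind(riskScore = zscore))
    hi <- groups == "high"
    structure(list(
        logrank = lr,
        cox = cox,
        hrPerSd = cox$table$hr[1L],
        ciLow = cox$table$ciLow[1L],
        ciHigh = cox$table$ciHigh[1L],
        coxP = cox$table$p[1L],
        kmHigh = kmEstimate(time[hi], event[hi]),
        kmLow = kmEstimate(time[!hi], event[!hi]),
        assignment = data.frame(sample = names(scores),
                                score = unname(scores),
                                group = groups, time = time, event = event,
                                stringsAsFactors = FALSE),
        nHigh = sum(hi), nLow = sum(!hi), cohort = cohort),
        class = "SignatureEvaluation")
}

#' @export
print.SignatureEvaluation <- function(x, ...) {
    cat(sprintf(
        "Signature evaluation on '%s': n = %d (high %d / low %d)\n",
        x$cohort, x$nHigh + x$nLow, x$nHigh, x$nLow))
    cat(sprintf("log-rank: chi2 = %.4g, p = %.3g\n",
                x$logrank$chi2, x$logrank$p))
    cat(sprintf("Cox per-SD score: HR = %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
                x$hrPerSd, x$ciLow, x$ciHigh, x$coxP))
    invisible(x)
}

#' Evaluate a risk signature on a cohort
#'
#' Scores the cohort with the model, splits at the within-cohort median
#' risk score (the in-sample evaluation used during screening; pass a
#' number to use a fixed cut-point instead), and summarizes the split by a
#' log-rank test, Kaplan-Meier curves per group, and a Cox fit of the
#' standardized continuous score, whose hazard ratio is reported per
#' standard deviation of the score.
#'
#' @param model a \linkS4class{RiskModel}.
#' @param bundle a \linkS4class{CohortBundle} to evaluate on.
#' @param cutpoint \code{"median"} (default) or a fixed numeric cut-point
#'   on the raw score scale.
#' @return an object of class \code{"SignatureEvaluation"}: list with
#'   \code{logrank}, \code{cox} (continuous per-SD score fit),
#'   \code{hrPerSd}, \code{ciLow}, \code{ciHigh}, \code{coxP},
#'   \code{kmHigh}, \code{kmLow}, \code{assignment} (per-sample score,
#'   group, time, event), \code{nHigh}, \code{nLow}.
#' @export
evaluateSignature <- function(model, bundle, cutpoint = "median") {
    stopifnot(methods::is(bundle, "CohortBundle"))
    scores <- computeRiskScores(model, bundle)
    asg <- assignGroups(scores, cutpoint)
    sv <- survTable(bundle)
    .evaluateScores(scores, asg$group, sv$time, sv$event,
                    cohort = cohortName(bundle))
}

#' Serialize / restore a RiskModel as JSON
#'
#' @param model a \linkS4class{RiskModel}.
#' @param path file path.
#' @return \code{writeRiskModel}: invisibly, \code{path};
#'   \code{readRiskModel}: the restored \linkS4class{RiskModel}.
#' @export
writeRiskModel <- function(model, path) {
    stopifnot(methods::is(model, "RiskModel"))
    jsonlite::write_json(list(
        tfId = model@tfId, lncIds = model@lncIds, betas = model@betas,
        cutpoint = model@cutpoint, scoreCenter = model@scoreCenter,
        scoreScale = model@scoreScale,
        trainingCohort = model@trainingCohort, endpoint = model@endpoint,
        dropped = model@dropped),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeRiskModel
#' @export
readRiskModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("RiskModel",
        tfId = j$tfId, lncIds = as.character(j$lncIds),
        betas = as.numeric(j$betas), cutpoint = j$cutpoint,
        scoreCenter = j$scoreCenter, scoreScale = j$scoreScale,
        trainingCohort = j$trainingCohort,
        endpoint = if (is.null(j$endpoint)) NA_character_ else j$endpoint,
        dropped = as.character(j$dropped))
}
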