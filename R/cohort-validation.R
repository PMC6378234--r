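#' Validate a TF signature in an independent cohort by refitting
#'
#' Repeats the full model construction inside the validation cohort: the
#' univariate Cox coefficients and the median cut-point are re-estimated
#' there, exactly as in the training cohort (the primary validation mode).
#'
#' @param bundle validation \linkS4class{CohortBundle}.
#' @param tfId TF label.
#' @param regulon lncRNA ids regulated by the TF.
#' @return a \code{"SignatureEvaluation"} (see [evaluateSignature()]).
#' @seealso [validateTransfer()] for the fixed-coefficient mode.
#' @export
validateRefit <- function(bundle, tfId, regulon) {
    model <- fitRiskModel(bundle, tfId, regulon)
    evaluateSignature(model, bundle)
}

#' Validate a trained signature by cut-point transfer
#'
#' Scores the validation cohort with the TRAINING coefficients, z-score
#' normalizes the scores within the cohort (sample standard deviation,
#' n - 1), and splits at the training cut-point placed on the same z scale
#' (training median, z-transformed with the training score mean/sd).  When
#' the validation cohort is the training cohort itself this reproduces the
#' training median split exactly, and any uniform affine transformation of
#' the cohort's expression leaves the groups unchanged.
#'
#' @param model trained \linkS4class{RiskModel}.
#' @param bundle validation \linkS4class{CohortBundle}.
#' @return a \code{"SignatureEvaluation"}; the \code{assignment} scores are
#'   on the cohort z scale.
#' @export
validateTransfer <- function(model, bundle) {
    stopifnot(methods::is(model, "RiskModel"),
              methods::is(bundle, "CohortBundle"))
    scores <- computeRiskScores(model, bundle)
    s <- stats::sd(scores)
    if (!is.finite(s) || s == 0)
        stop("zero score variance in the validation cohort")
    z <- (scores - mean(scores)) / s
    zcut <- (model@cutpoint - model@scoreCenter) / model@scoreScale
    asg <- assignGroups(z, cutpoint = zcut)
    sv <- survTable(bundle)
    .evaluateScores(z, asg$group, sv$time, sv$event,
                    cohort = cohortName(bundle))
}

#' Partition a cohort by a clinical variable
#'
#' Stratification rules: \code{age} splits at the cohort median age
#' (younger = at or below); \code{grade} into G1/G2 vs G3/G4 (codes <= 2 vs
#' >= 3); \code{stage} into I/II vs III/IV; \code{residual} into residual
#' tumour diameter <= 10 mm vs > 10 mm.  Samples missing the variable are
#' excluded with a message; an empty stratum is dropped with a warning.
#'
#' @param bundle a \linkS4class{CohortBundle}.
#' @param variable one of \code{"age"}, \code{"grade"}, \code{"stage"},
#'   \code{"residual"}.
#' @return named list of sample-id character vectors (the strata; disjoint,
#'   union = samples with the variable observed).
#' @export
stratifyCohort <- function(bundle,
                           variable = c("age", "grade", "stage",
                                        "residual")) {
    variable <- match.arg(variable)
    sv <- survTable(bundle)
    if (!variable %in% colnames(sv))
        stop("variable '", variable, "' not present in this cohort")
    v <- sv[[variable]]
    ok <- !is.na(v)
    if (any(!ok))
        message(sum(!ok), " sample(s) missing '", variable,
                "'; excluded from stratification")
    ids <- rownames(sv)[ok]
    v <- v[ok]
    strata <- switch(variable,
        age = {
            m <- stats::median(v)
            list("age<=median" = ids[v <= m], "age>median" = ids[v > m])
        },
        grade = list("grade G1/G2" = ids[v <= 2],
                     "grade G3/G4" = ids[v >= 3]),
        stage = list("stage I/II" = ids[v <= 2],
                     "stage III/IV" = ids[v >= 3]),
        residual = list("residual<=10mm" = ids[v <= 10],
                        "residual>10mm" = ids[v > 10]))
    empty <- names(strata)[lengths(strata) == 0L]
    if (length(empty))
        warning("empty stratum(ta) skipped: ",
                paste(empty, collapse = ", "))
    strata[lengths(strata) > 0L]
}

#' Evaluate a signature within clinical strata
#'
#' Applies [validateRefit()] (or [validateTransfer()] with a trained
#' model) within each stratum of [stratifyCohort()].  Strata in which the
#' model cannot be fitted or evaluated are skipped with a message.
#'
#' @param bundle a \linkS4class{CohortBundle}.
#' @param variable stratification variable, see [stratifyCohort()].
#' @param tfId,regulon signature specification (refit mode), or
#' @param model a trained \linkS4class{RiskModel} (transfer mode).
#' @return named list of \code{"SignatureEvaluation"} per stratum.
#' @export
evaluateStrata <- function(bundle, variable, tfId = NULL, regulon = NULL,
                           model = NULL) {
    strata <- stratifyCohort(bundle, variable)
    out <- lapply(names(strata), function(nm) {
        sub <- bundle[, strata[[nm]]]
        tryCatch({
            if (!is.null(model)) validateTransfer(model, sub)
            else validateRefit(sub, tfId, regulon)
        }, error = function(e) {
            message("stratum '", nm, "' skipped: ", conditionMessage(e))
            NULL
        })
    })
    names(out) <- names(strata)
    out[!vapply(out, is.null, TRUE)]
}

#' Multivariate Cox adjustment of the risk score for clinical covariates
#'
#' Joint Cox fit of the (standardized) risk score together with clinical
#' covariates, one hazard ratio per variable; age enters continuously, the
#' ordinal variables (stage, grade, residual, lymph) as integer scores.
#' Samples missing any requested covariate are dropped with a message.
#' Perfectly collinear covariate pairs are an error naming the pair.
#'
#' @param bundle a \linkS4class{CohortBundle}.
#' @param scores named per-sample risk scores (names = sample ids).
#' @param covariates subset of \code{c("age", "stage", "grade",
#'   "residual", "lymph")} present in the cohort's clinical table.
#' @param minEvents minimum number of events required (default 10).
#' @return a \code{"CoxResult"} (see [coxFit()]); the risk score row is
#'   named \code{riskScore} and reported per SD of the score.
#' @export
multivariateAdjust <- function(bundle, scores,
                               covariates = c("age", "stage", "grade",
                                              "residual", "lymph"),
                               minEvents = 10L) {
    stopifnot(methods::is(bundle, "CohortBundle"))
    sv <- survTable(bundle)
    covariates <- intersect(covariates, colnames(sv))
    if (!length(covariates))
        stop("none of the requested covariates is present")
    scores <- scores[rownames(sv)]
    if (any(is.na(scores)))
        stop("scores must cover every sample of the cohort")
    X <- cbind(riskScore = (scores - mean(scores)) / stats::sd(scores),
               as.matrix(sv[, covariates, drop = FALSE]))
    keep <- stats::complete.cases(X)
    if (any(!keep))
        message(sum(!keep), " sample(s) missing a covariate; dropped")
    X <- X[keep, , drop = FALSE]
    time <- sv$time[keep]
    event <- sv$event[keep]
    if (sum(event) < minEvents)
        stop("fewer than ", minEvents, " events after covariate filtering")
    cc <- stats::cor(X)
    cc[!upper.tri(cc)] <- 0
    hit <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)
    if (nrow(hit))
        stop("collinear covariates: ",
             paste(colnames(X)[hit[1L, 1L]], colnames(X)[hit[1L, 2L]],
                   sep = " ~ "))
    coxFit(time, event, X)
}

#' Cross-cohort risk-direction consistency of lncRNA coefficients
#'
#' For each lncRNA, compares the sign of its univariate Cox coefficient
#' (its risk direction: risk factor if positive, protective if negative)
#' across per-cohort risk models.  A lncRNA is retained as consistent only
#' if it was fitted in every cohort and all its coefficient signs agree
#' and are nonzero.  Adding a cohort can therefore only shrink the
#' retained set.
#'
#' @param models named list of \linkS4class{RiskModel}, one per cohort.
#' @param lncUniverse lncRNA ids to evaluate; defaults to the union of the
#'   models' members.
#' @return data.frame: \code{lnc}, one sign column per cohort (+1/-1, NA
#'   if absent), \code{consistent}.
#' @export
riskDirectionConsistency <- function(models, lncUniverse = NULL) {
    stopifnot(is.list(models), length(models) >= 2L)
    if (is.null(names(models)))
        names(models) <- paste0("cohort", seq_along(models))
    if (is.null(lncUniverse))
        lncUniverse <- Reduce(union, lapply(models, lncIds))
    signs <- vapply(models, function(m) {
        b <- coefs(m)[lncUniverse]
        sign(b)
    }, numeric(length(lncUniverse)))
    signs <- matrix(signs, nrow = length(lncUniverse),
                    dimnames = list(lncUniverse, names(models)))
    consistent <- apply(signs, 1L, function(s)
        !any(is.na(s)) && all(s != 0) && length(unique(s)) == 1L)
    out <- data.frame(lnc = lncUniverse, signs, consistent = consistent,
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
    out
}
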