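#' Time-dependent ROC curve for a censored survival outcome
#'
#' Cumulative/dynamic definition at horizon \code{t}: cases are samples
#' with an observed event by \code{t}; controls are samples still under
#' observation beyond \code{t}.  Two estimators:
#' \describe{
#'   \item{\code{exclude_censored}}{(default) samples censored at or before
#'     \code{t} are dropped; the curve and AUC are the empirical
#'     (unweighted) ones.}
#'   \item{\code{ipcw}}{all classifiable samples are kept and weighted by
#'     the inverse Kaplan-Meier censoring survival — cases by
#'     \eqn{1/\hat G(T_i^-)}, controls by \eqn{1/\hat G(t)} — the
#'     statistically consistent estimator under independent censoring.}
#' }
#' The AUC equals the trapezoidal area under the empirical curve; tied
#' scores contribute 1/2.  Both estimators coincide exactly when there is
#' no censoring before \code{t}.
#'
#' @param scores numeric marker (higher = predicted higher risk).
#' @param time,event survival outcome.
#' @param horizon evaluation time; default is the Kaplan-Meier median
#'   survival time of the cohort.
#' @param estimator \code{"exclude_censored"} or \code{"ipcw"}.
#' @return an object of class \code{"ROCCurve"}: list with \code{horizon},
#'   \code{thresholds}, \code{tpr}, \code{fpr}, \code{auc},
#'   \code{nCases}, \code{nControls}, \code{estimator}.
#' @export
tdROC <- function(scores, time, event, horizon = NULL,
                  estimator = c("exclude_censored", "ipcw")) {
    estimator <- match.arg(estimator)
    stopifnot(length(scores) == length(time),
              length(time) == length(event))
    if (is.null(horizon)) {
        horizon <- kmEstimate(time, event)$median
        if (is.na(horizon))
            stop("median survival not reached; supply a horizon")
    }
    if (horizon <= 0 || horizon > max(time))
        stop("horizon outside the observed time range")
    case <- time <= horizon & event == 1
    control <- time > horizon
    if (!any(case) || !any(control))
        stop("need at least one case and one control at the horizon")

    if (estimator == "exclude_censored") {
        wCase <- rep(1, sum(case))
        wControl <- rep(1, sum(control))
    } else {
        cens <- survival::survfit(
            survival::Surv(time, 1 - event) ~ 1, conf.type = "none")
        Gleft <- stats::stepfun(cens$time, c(1, cens$surv), right = TRUE)
        Gright <- stats::stepfun(cens$time, c(1, cens$surv), right = FALSE)
        wCase <- 1 / Gleft(time[case])
        wControl <- rep(1 / Gright(horizon), sum(control))
        if (any(!is.finite(c(wCase, wControl))))
            stop("IPCW weight undefined (censoring survival reached 0)")
    }
    sCase <- scores[case]
    sControl <- scores[control]
    gt <- outer(sCase, sControl, ">")
    eq <- outer(sCase, sControl, "==")
    ww <- outer(wCase, wControl)
    auc <- sum((gt + 0.5 * eq) * ww) / sum(ww)

    thr <- sort(unique(c(sCase, sControl)), decreasing = TRUE)
    tpr <- vapply(thr, function(th) sum(wCase[sCase >= th]), 0) / sum(wCase)
    fpr <- vapply(thr, function(th) sum(wControl[sControl >= th]), 0) /
        sum(wControl)
    structure(list(horizon = horizon,
                   thresholds = c(Inf, thr), tpr = c(0, tpr),
                   fpr = c(0, fpr), auc = auc,
                   nCases = sum(case), nControls = sum(control),
                   estimator = estimator),
              class = "ROCCurve")
}

#' @export
print.ROCCurve <- function(x, ...) {
    cat(sprintf(
        "Time-dependent ROC at t = %.4g (%s): AUC = %.3f (%d cases / %d controls)\n",
        x$horizon, x$estimator, x$auc, x$nCases, x$nControls))
    invisible(x)
}

#' Compare the time-dependent AUC of several candidate markers
#'
#' Evaluates each candidate score vector (a signature risk score, a raw
#' clinical variable such as age, stage or grade, or an alternative lncRNA
#' panel scored with [computeRiskScores()]) with [tdROC()] on the samples
#' shared by all candidates, at a common horizon.
#'
#' @param bundle a \linkS4class{CohortBundle}.
#' @param candidates named list of numeric score vectors, each named by
#'   sample id (missing values allowed; such samples are excluded from the
#'   common set).
#' @param horizon common evaluation time; default: KM median survival of
#'   the common sample set.
#' @param estimator passed to [tdROC()].
#' @return data.frame: \code{candidate}, \code{auc}, \code{nCases},
#'   \code{nControls}, \code{horizon}, ordered by decreasing AUC.
#' @export
compareSignatures <- function(bundle, candidates, horizon = NULL,
                              estimator = c("exclude_censored", "ipcw")) {
    estimator <- match.arg(estimator)
    stopifnot(methods::is(bundle, "CohortBundle"),
              is.list(candidates), length(candidates) >= 2L,
              !is.null(names(candidates)))
    sv <- survTable(bundle)
    ids <- rownames(sv)
    for (nm in names(candidates)) {
        v <- candidates[[nm]]
        if (is.null(names(v)))
            stop("candidate '", nm, "' must be named by sample id")
        ids <- intersect(ids, names(v)[!is.na(v)])
    }
    if (length(ids) < 2L)
        stop("too few samples shared by all candidates")
    dropped <- nrow(sv) - length(ids)
    if (dropped > 0L)
        message(dropped, " sample(s) not covered by every candidate; dropped")
    time <- sv[ids, "time"]
    event <- sv[ids, "event"]
    if (is.null(horizon)) {
        horizon <- kmEstimate(time, event)$median
        if (is.na(horizon))
            stop("median survival not reached; supply a horizon")
    }
    out <- do.call(rbind, lapply(names(candidates), function(nm) {
        roc <- tdROC(candidates[[nm]][ids], time, event,
                     horizon = horizon, estimator = estimator)
        data.frame(candidate = nm, auc = roc$auc, nCases = roc$nCases,
                   nControls = roc$nControls, horizon = horizon,
                   stringsAsFactors = FALSE)
    }))
    out[order(-out$auc), , drop = FALSE]
}
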