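#' Plot-ready tables for a signature evaluation
#'
#' Converts a \code{"SignatureEvaluation"} into tidy long-format tables
#' sufficient to redraw the standard panels: the per-group Kaplan-Meier
#' step functions with censored samples marked (the "+" marks of a KM
#' plot), and the risk-score distribution with scores centred by the
#' cohort median (score minus median), ordered by score.
#'
#' @param evaluation a \code{"SignatureEvaluation"} from
#'   [evaluateSignature()], [validateRefit()] or [validateTransfer()].
#' @return list with two data.frames: \code{km} (\code{group},
#'   \code{time}, \code{survival}, \code{censorMark}) and \code{scores}
#'   (\code{sample}, \code{scoreMinusMedian}, \code{group}, \code{time},
#'   \code{event}).
#' @export
kmPlotTable <- function(evaluation) {
    stopifnot(inherits(evaluation, "SignatureEvaluation"))
    asg <- evaluation$assignment
    km <- do.call(rbind, lapply(levels(asg$group), function(g) {
        sel <- asg$group == g
        fit <- survival::survfit(
            survival::Surv(asg$time[sel], asg$event[sel]) ~ 1,
            conf.type = "none")
        steps <- data.frame(group = g, time = c(0, fit$time),
                            survival = c(1, fit$surv),
                            censorMark = FALSE, stringsAsFactors = FALSE)
        ## one mark row per censored sample, at its censoring time
        ct <- sort(asg$time[sel & asg$event == 0])
        if (length(ct)) {
            sf <- stats::stepfun(fit$time, c(1, fit$surv))
            marks <- data.frame(group = g, time = ct, survival = sf(ct),
                                censorMark = TRUE,
                                stringsAsFactors = FALSE)
            steps <- rbind(steps, marks)
        }
        steps[order(steps$time, steps$censorMark), ]
    }))
    rownames(km) <- NULL
    scores <- asg[order(asg$score), ]
    scores <- data.frame(sample = scores$sample,
                         scoreMinusMedian =
                             scores$score - stats::median(asg$score),
                         group = scores$group, time = scores$time,
                         event = scores$event, stringsAsFactors = FALSE)
    rownames(scores) <- NULL
    list(km = km, scores = scores)
}

#' Write a TF screen result to TSV
#'
#' @param results a \code{"TFScreenResult"} from [screenTFs()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeScreenTable <- function(results, path) {
    stopifnot(is.data.frame(results))
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Summarize validation evaluations across cohorts as one table
#'
#' @param evaluations named list of \code{"SignatureEvaluation"} (one per
#'   cohort), e.g. from [validateRefit()]/[validateTransfer()].
#' @param mode label recorded in the \code{mode} column.
#' @return data.frame: \code{cohort}, \code{mode}, \code{hrPerSd},
#'   \code{ciLow}, \code{ciHigh}, \code{coxP}, \code{logrankP},
#'   \code{nHigh}, \code{nLow}.
#' @export
validationTable <- function(evaluations, mode = "refit") {
    stopifnot(is.list(evaluations), length(evaluations) >= 1L)
    if (is.null(names(evaluations)))
        names(evaluations) <- paste0("cohort", seq_along(evaluations))
    out <- do.call(rbind, lapply(names(evaluations), function(nm) {
        ev <- evaluations[[nm]]
        data.frame(cohort = nm, mode = mode, hrPerSd = ev$hrPerSd,
                   ciLow = ev$ciLow, ciHigh = ev$ciHigh, coxP = ev$coxP,
                   logrankP = ev$logrank$p, nHigh = ev$nHigh,
                   nLow = ev$nLow, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
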