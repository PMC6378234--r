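#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: samples censored at an event time are still counted
#' at risk at that time.  The reported median is the first event time at
#' which the survival curve drops to 0.5 or below, \code{NA} if the curve
#' never reaches 0.5.
#'
#' @param time positive event/censoring times.
#' @param event 1 = event observed, 0 = censored.
#' @return an object of class \code{"KMCurve"}: list with \code{times}
#'   (distinct event times), \code{surv}, \code{nRisk}, \code{nEvent},
#'   and \code{median}.
#' @export
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
#' km$surv   # 2/3 after t = 1, 0 after t = 3
kmEstimate <- function(time, event) {
    if (length(time) == 0L)
        stop("empty survival input")
    stopifnot(length(time) == length(event), all(time > 0),
              all(event %in% c(0, 1)))
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             conf.type = "none")
    ev <- fit$n.event > 0
    times <- fit$time[ev]
    surv <- fit$surv[ev]
    med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1L]] else NA_real_
    structure(list(times = times, surv = surv,
                   nRisk = fit$n.risk[ev], nEvent = fit$n.event[ev],
                   n = length(time), nCensored = sum(event == 0),
                   median = med),
              class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
    cat("Kaplan-Meier curve: n =", x$n, "(", x$nCensored, "censored ),",
        length(x$times), "event times; median =",
        if (is.na(x$median)) "not reached" else format(x$median), "\n")
    invisible(x)
}

#' Log-rank (Mantel-Cox) test between survival groups
#'
#' Observed-versus-expected event counts over the distinct event times with
#' hypergeometric variance; the statistic is chi-square distributed with
#' (number of groups - 1) degrees of freedom under the null.
#'
#' @param time,event as in [kmEstimate()].
#' @param group group labels (>= 2 groups).
#' @return an object of class \code{"LogRankResult"}: list with
#'   \code{chi2}, \code{df}, \code{p}, \code{observed}, \code{expected}
#'   (per group, named), and \code{n}.
#' @export
#' @examples
#' logrankTest(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    if (nlevels(droplevels(group)) < 2L)
        stop("log-rank test needs at least two groups")
    stopifnot(length(time) == length(event), length(time) == length(group))
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    df <- length(sd$n) - 1L
    p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
    structure(list(chi2 = unname(sd$chisq), df = df, p = p,
                   observed = stats::setNames(sd$obs, levels(droplevels(group))),
                   expected = stats::setNames(sd$exp, levels(droplevels(group))),
                   n = length(time)),
              class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
    cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.3g (n = %d)\n",
                x$chi2, x$df, x$p, x$n))
    invisible(x)
}

## Fast univariate Cox fit used in the screening loops; identical model and
## tie handling as coxFit() but skips formula/model-frame overhead.
.coxUni <- function(time, event, x, ties = "efron") {
    fit <- survival::coxph.fit(matrix(x, ncol = 1L),
                               survival::Surv(time, event),
                               strata = NULL, offset = NULL, init = 0,
                               control = survival::coxph.control(
                                   eps = 1e-9, iter.max = 50L),
                               weights = NULL, method = ties,
                               rownames = NULL)
    beta <- unname(fit$coefficients)
    se <- sqrt(fit$var[1L, 1L])
    list(beta = beta, se = se,
         p = 2 * stats::pnorm(-abs(beta / se)),
         loglik = fit$loglik[2L], iter = fit$iter)
}

#' Cox proportional-hazards regression
#'
#' Maximum partial-likelihood fit (Newton iterations, Efron tie handling by
#' default) with Wald standard errors from the inverse observed
#' information.  95\% confidence intervals are Wald intervals on the
#' log-hazard-ratio scale.  Monotone-likelihood (separation) is flagged
#' when any \eqn{|\hat\beta|} exceeds 15; a degenerate (e.g. constant)
#' covariate yields an \code{NA} coefficient flagged in the table.
#'
#' @param time,event as in [kmEstimate()].
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return an object of class \code{"CoxResult"}: list with \code{table}
#'   (one row per covariate: \code{beta}, \code{se}, \code{hr},
#'   \code{ciLow}, \code{ciHigh}, \code{p}, \code{degenerate}),
#'   \code{loglik} (log partial likelihood at the optimum),
#'   \code{converged}, \code{separation}, \code{iter}, \code{n},
#'   \code{nEvents}.
#' @export
#' @examples
#' fit <- coxFit(c(1, 3, 2, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
#' fit$table$beta   # ~0.941
coxFit <- function(time, event, covariates, ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    x <- as.matrix(covariates)
    storage.mode(x) <- "double"
    if (is.null(colnames(x)))
        colnames(x) <- paste0("x", seq_len(ncol(x)))
    stopifnot(length(time) == nrow(x), length(time) == length(event),
              all(event %in% c(0, 1)))
    if (!all(is.finite(x)))
        stop("non-finite covariate value(s)")
    if (sum(event) == 0)
        stop("no events observed; Cox model undefined")
    if (length(time) <= ncol(x))
        stop("more covariates than samples")
    fit <- suppressWarnings(survival::coxph.fit(
        x, survival::Surv(time, event), strata = NULL, offset = NULL,
        init = rep(0, ncol(x)),
        control = survival::coxph.control(eps = 1e-9, iter.max = 50L),
        weights = NULL, method = ties, rownames = NULL))
    beta <- as.vector(fit$coefficients)
    se <- sqrt(diag(as.matrix(fit$var)))
    degenerate <- is.na(beta) | !is.finite(se) | se == 0
    z <- qnorm(0.975)
    tab <- data.frame(
        term = colnames(x), beta = beta, se = se,
        hr = exp(beta), ciLow = exp(beta - z * se),
        ciHigh = exp(beta + z * se),
        p = 2 * stats::pnorm(-abs(beta / se)),
        degenerate = degenerate,
        stringsAsFactors = FALSE, row.names = NULL)
    structure(list(table = tab,
                   loglik = fit$loglik[length(fit$loglik)],
                   converged = fit$iter < 50L,
                   separation = any(abs(beta) > 15, na.rm = TRUE),
                   iter = fit$iter, ties = ties,
                   n = length(time), nEvents = sum(event)),
              class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
    cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, loglik = %.4g\n",
                x$ties, x$n, x$nEvents, x$loglik))
    print(x$table, digits = 4)
    if (!x$converged) cat("WARNING: not converged\n")
    if (x$separation) cat("WARNING: possible monotone likelihood/separation\n")
    invisible(x)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
#' @examples
#' tTest(c(1, 2, 3), c(4, 5, 6))
tTest <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least two observations")
    pooledVar <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
        (length(x) + length(y) - 2)
    if (pooledVar == 0) {
        if (mean(x) == mean(y))
            return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
        stop("zero pooled variance with unequal means: t undefined")
    }
    ht <- stats::t.test(x, y, var.equal = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}
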