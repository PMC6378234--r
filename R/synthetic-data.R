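#' Configuration for the multi-cohort survival simulator
#'
#' Defaults mirror the study design the pipeline targets: four ovarian
#' cancer cohorts of 399/107/278/75 patients, 145 TFs with overlapping
#' regulons drawn from 1234 lncRNAs (about 30 candidate targets per TF),
#' within-regulon co-expression weight 0.6, one planted prognostic TF whose
#' targets carry a log-hazard effect of 0.3 per SD of expression,
#' exponential survival with about 50\% censoring, and cohort-specific
#' affine location/scale shifts of the expression values.
#'
#' @param seed integer master seed; a hierarchical seed tree (one derived
#'   seed per cohort) makes every cohort individually reproducible.
#' @param nCohorts,nSamples number of cohorts and per-cohort sample sizes
#'   (recycled to \code{nCohorts}).
#' @param nLnc,nTF numbers of lncRNAs and TFs.
#' @param targetsPerTF,decoysPerTF true regulon size and number of
#'   non-coexpressed decoy candidates per TF.
#' @param w within-regulon co-expression weight in [0, 1): each target is
#'   \code{w * activity + sqrt(1 - w^2) * noise}, so two targets of the
#'   same TF correlate at about \code{w^2}.
#' @param tfNoiseSd sd of the noise separating a TF's measured expression
#'   from its latent activity.
#' @param plantedTF id(s) of the prognostic TF(s) (\code{character(0)} for
#'   a global null).
#' @param gamma log-hazard effect per SD of expression for each planted
#'   target (scalar recycled).
#' @param h0 baseline hazard (per month).
#' @param censoringRate target censoring fraction in (0, 1); the
#'   independent exponential censoring rate is calibrated by the closed
#'   form of [expectedCensoringRate()] at the null.
#' @param shiftRange,scaleRange ranges of the per-cohort affine expression
#'   shift and scale.
#' @param baseline \code{"exponential"} (default) or \code{"weibull"}
#'   survival baseline; \code{weibullShape} applies to the latter.
#' @param endpoint endpoint label written to the clinical tables.
#' @return a \code{"SimulationConfig"} list.
#' @export
simulationConfig <- function(seed = 1L,
                             nCohorts = 4L,
                             nSamples = c(399L, 107L, 278L, 75L),
                             nLnc = 1234L,
                             nTF = 145L,
                             targetsPerTF = 30L,
                             decoysPerTF = 30L,
                             w = 0.6,
                             tfNoiseSd = 0.5,
                             plantedTF = "TF001",
                             gamma = 0.3,
                             h0 = 0.015,
                             censoringRate = 0.5,
                             shiftRange = c(-1, 1),
                             scaleRange = c(0.75, 1.5),
                             baseline = c("exponential", "weibull"),
                             weibullShape = 1.2,
                             endpoint = "OS") {
    baseline <- match.arg(baseline)
    cfg <- list(seed = as.integer(seed), nCohorts = as.integer(nCohorts),
                nSamples = rep_len(as.integer(nSamples), nCohorts),
                nLnc = as.integer(nLnc), nTF = as.integer(nTF),
                targetsPerTF = as.integer(targetsPerTF),
                decoysPerTF = as.integer(decoysPerTF),
                w = w, tfNoiseSd = tfNoiseSd,
                plantedTF = as.character(plantedTF), gamma = gamma,
                h0 = h0, censoringRate = censoringRate,
                shiftRange = shiftRange, scaleRange = scaleRange,
                baseline = baseline, weibullShape = weibullShape,
                endpoint = endpoint)
    with(cfg, {
        stopifnot(nCohorts >= 1L, all(nSamples >= 1L), nLnc >= 1L,
                  nTF >= 1L, targetsPerTF >= 1L, decoysPerTF >= 0L,
                  w >= 0, w^2 < 1, tfNoiseSd >= 0, h0 > 0,
                  targetsPerTF + decoysPerTF <= nLnc)
        if (censoringRate <= 0 || censoringRate >= 1)
            stop("censoring target must lie strictly in (0, 1)")
        if (length(plantedTF) && !all(grepl("^TF", plantedTF)))
            stop("plantedTF must use the simulator's TF ids (TF001, ...)")
    })
    structure(cfg, class = "SimulationConfig")
}

#' Expected censoring fraction for independent exponentials
#'
#' With event times ~ Exp(\code{h0}) and censoring times ~ Exp(\code{c}),
#' the probability that censoring precedes the event is
#' \code{c / (h0 + c)}.  Inverted, it calibrates the censoring rate needed
#' to hit a target fraction at the null.
#'
#' @param h0,c positive rates.
#' @return expected censoring fraction in (0, 1).
#' @export
#' @examples
#' expectedCensoringRate(1, 3)   # 0.75
expectedCensoringRate <- function(h0, c) {
    stopifnot(h0 > 0, c > 0)
    c / (h0 + c)
}

.tfIdFmt <- function(i) sprintf("TF%03d", i)
.lncIdFmt <- function(i) sprintf("LNC%04d", i)

## One cohort: latent TF activities -> TF/lncRNA expression with planted
## regulon co-expression -> proportional-hazards survival on standardized
## expression -> cohort-specific affine shift/scale -> CohortBundle.
.simulateCohort <- function(cfg, n, targets, gammaTruth, cohortSeed, name) {
    set.seed(cohortSeed)
    tfIds <- .tfIdFmt(seq_len(cfg$nTF))
    lncIds <- .lncIdFmt(seq_len(cfg$nLnc))
    act <- matrix(stats::rnorm(cfg$nTF * n), cfg$nTF, n,
                  dimnames = list(tfIds, NULL))
    tfExpr <- act + matrix(stats::rnorm(cfg$nTF * n, sd = cfg$tfNoiseSd),
                           cfg$nTF, n)
    lncExpr <- matrix(stats::rnorm(cfg$nLnc * n), cfg$nLnc, n,
                      dimnames = list(lncIds, NULL))
    regulators <- split(rep(names(targets), lengths(targets)),
                        unlist(targets, use.names = FALSE))
    for (lnc in names(regulators)) {
        tfs <- regulators[[lnc]]
        a <- colMeans(act[tfs, , drop = FALSE]) * sqrt(length(tfs))
        lncExpr[lnc, ] <- cfg$w * a +
            sqrt(1 - cfg$w^2) * stats::rnorm(n)
    }

    planted <- names(gammaTruth)[gammaTruth != 0]
    lp <- rep(0, n)
    if (length(planted)) {
        x <- lncExpr[planted, , drop = FALSE]
        x <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
        lp <- as.vector(gammaTruth[planted] %*% x)
    }
    haz <- cfg$h0 * exp(lp)
    crate <- cfg$h0 * cfg$censoringRate / (1 - cfg$censoringRate)
    if (cfg$baseline == "exponential") {
        tEvent <- stats::rexp(n, rate = haz)
        tCens <- stats::rexp(n, rate = crate)
    } else {
        k <- cfg$weibullShape
        tEvent <- (stats::rexp(n) / haz)^(1 / k)
        tCens <- (stats::rexp(n) / crate)^(1 / k)
    }
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)

    expr <- rbind(tfExpr, lncExpr)
    scale <- stats::runif(1L, cfg$scaleRange[1L], cfg$scaleRange[2L])
    shift <- stats::runif(1L, cfg$shiftRange[1L], cfg$shiftRange[2L])
    expr <- expr * scale + shift
    samples <- sprintf("%s_s%03d", name, seq_len(n))
    colnames(expr) <- samples

    clin <- data.frame(
        time = time, event = event, endpoint = cfg$endpoint,
        age = round(stats::rnorm(n, 60, 10), 1),
        stage = sample(1:4, n, replace = TRUE,
                       prob = c(0.05, 0.10, 0.70, 0.15)),
        grade = sample(1:4, n, replace = TRUE,
                       prob = c(0.05, 0.25, 0.60, 0.10)),
        residual = sample(c(0, 5, 10, 20, 30), n, replace = TRUE,
                          prob = c(0.3, 0.2, 0.2, 0.2, 0.1)),
        lymph = stats::rbinom(n, 1, 0.5),
        row.names = samples)
    suppressMessages(CohortBundle(expr, clin, name = name))
}

#' Simulate a multi-cohort expression + survival study
#'
#' Per cohort: each TF has a standard-normal latent activity per sample;
#' the TF's measured expression is activity plus noise; each of its target
#' lncRNAs is \code{w * activity + sqrt(1 - w^2) * noise} (targets shared
#' by several TFs mix their activities), and non-targets are independent
#' standard normal.  Survival follows a proportional-hazards model
#' \code{h0 * exp(sum_j gamma_j x_j)} on the standardized expression of the
#' planted TF's targets, with independent exponential censoring calibrated
#' to the target censoring fraction; a cohort-specific affine shift/scale
#' is then applied to all expression values.  Fully reproducible from the
#' master seed.
#'
#' @param config a \code{"SimulationConfig"} from [simulationConfig()].
#' @return an object of class \code{"SimulatedStudy"}: list with
#'   \code{cohorts} (named list of \linkS4class{CohortBundle}),
#'   \code{candidates} (TF -> candidate targets incl. decoys, the input a
#'   binding resource would provide), \code{networkTruth} (data.frame
#'   \code{tf}, \code{lnc}, \code{true}), \code{gammaTruth} (named vector
#'   over all lncRNAs), \code{plantedTF}, and \code{config}.
#' @export
#' @examples
#' study <- simulateStudy(simulationConfig(
#'     seed = 7, nCohorts = 1, nSamples = 60, nLnc = 40, nTF = 5,
#'     targetsPerTF = 4, decoysPerTF = 4))
#' study$cohorts[[1]]
simulateStudy <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    cfg <- config
    set.seed(cfg$seed)
    tfIds <- .tfIdFmt(seq_len(cfg$nTF))
    lncIds <- .lncIdFmt(seq_len(cfg$nLnc))
    targets <- lapply(tfIds, function(tf)
        sample(lncIds, cfg$targetsPerTF))
    names(targets) <- tfIds
    decoys <- lapply(tfIds, function(tf)
        sample(setdiff(lncIds, targets[[tf]]), cfg$decoysPerTF))
    names(decoys) <- tfIds

    gammaTruth <- stats::setNames(rep(0, cfg$nLnc), lncIds)
    planted <- intersect(cfg$plantedTF, tfIds)
    if (length(cfg$plantedTF) && !length(planted))
        stop("plantedTF not among the simulated TF ids")
    for (tf in planted)
        gammaTruth[targets[[tf]]] <-
            rep_len(cfg$gamma, cfg$targetsPerTF)

    cohortSeeds <- sample.int(.Machine$integer.max - 1L, cfg$nCohorts)
    names <- paste0("cohort", seq_len(cfg$nCohorts))
    cohorts <- mapply(function(n, sd, nm)
        .simulateCohort(cfg, n, targets, gammaTruth, sd, nm),
        cfg$nSamples, cohortSeeds, names, SIMPLIFY = FALSE)
    names(cohorts) <- names

    networkTruth <- data.frame(
        tf = c(rep(tfIds, lengths(targets)), rep(tfIds, lengths(decoys))),
        lnc = c(unlist(targets, use.names = FALSE),
                unlist(decoys, use.names = FALSE)),
        true = rep(c(TRUE, FALSE),
                   c(sum(lengths(targets)), sum(lengths(decoys)))),
        stringsAsFactors = FALSE)
    candidates <- mapply(function(t, d) c(t, d), targets, decoys,
                         SIMPLIFY = FALSE)
    structure(list(cohorts = cohorts, candidates = candidates,
                   targets = targets, networkTruth = networkTruth,
                   gammaTruth = gammaTruth, plantedTF = planted,
                   config = cfg),
              class = "SimulatedStudy")
}

#' Simulate a global-null study
#'
#' [simulateStudy()] with all planted effects forced to zero: survival is
#' independent of every expression value.
#'
#' @param config a \code{"SimulationConfig"}.
#' @return a \code{"SimulatedStudy"} with \code{plantedTF} empty and
#'   \code{gammaTruth} identically zero.
#' @export
simulateNullStudy <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    config$plantedTF <- character(0)
    config$gamma <- 0
    simulateStudy(config)
}

#' @export
print.SimulatedStudy <- function(x, ...) {
    cat("SimulatedStudy:", length(x$cohorts), "cohort(s) [",
        paste(vapply(x$cohorts, ncol, 0L), collapse = ", "),
        "samples ];", x$config$nTF, "TFs,", x$config$nLnc, "lncRNAs\n")
    if (length(x$plantedTF))
        cat("planted TF(s):", paste(x$plantedTF, collapse = ", "),
            "with gamma =", x$config$gamma, "\n")
    else cat("global null (no planted effect)\n")
    invisible(x)
}

#' Write a simulated study to standard cohort files
#'
#' Per cohort: expression TSV and clinical TSV (as read back by
#' [readExpressionMatrix()] / [readClinicalTable()]); plus the candidate
#' TF target sets as GMT and the true edge labels and effects as TSVs, so
#' the full pipeline can be exercised from files alone.
#'
#' @param study a \code{"SimulatedStudy"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeStudy <- function(study, dir) {
    stopifnot(inherits(study, "SimulatedStudy"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    for (nm in names(study$cohorts)) {
        b <- study$cohorts[[nm]]
        fe <- file.path(dir, paste0(nm, "_expression.tsv"))
        writeExpressionMatrix(exprMatrix(b), fe)
        fc <- file.path(dir, paste0(nm, "_clinical.tsv"))
        sv <- survTable(b)
        utils::write.table(cbind(sample = rownames(sv), sv), fc,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, fe, fc)
    }
    fg <- file.path(dir, "candidates.gmt")
    writeGMT(study$candidates, fg, description = "candidate_targets")
    ft <- file.path(dir, "network_truth.tsv")
    utils::write.table(study$networkTruth, ft, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fx <- file.path(dir, "gamma_truth.tsv")
    utils::write.table(
        data.frame(lnc = names(study$gammaTruth),
                   gamma = unname(study$gammaTruth)),
        fx, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(files, fg, ft, fx))
}

#' A small deterministic example cohort
#'
#' One simulated cohort (fixed seed) used in documentation examples.
#'
#' @param n samples (default 80).
#' @return a \linkS4class{CohortBundle}.
#' @export
exampleBundle <- function(n = 80L) {
    study <- simulateStudy(simulationConfig(
        seed = 20260101L, nCohorts = 1L, nSamples = n, nLnc = 60L,
        nTF = 6L, targetsPerTF = 5L, decoysPerTF = 5L))
    study$cohorts[[1L]]
}
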