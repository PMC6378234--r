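test_that("refit validation on the training cohort reproduces the training evaluation", {
    study <- smallPlantedStudy(seed = 401, n = 150)
    b <- study$cohorts[[1]]
    reg <- study$targets[["TF001"]]
    model <- fitRiskModel(b, "TF001", reg)
    ev <- evaluateSignature(model, b)
    evR <- validateRefit(b, "TF001", reg)
    expect_equal(evR$logrank$chi2, ev$logrank$chi2)
    expect_equal(evR$hrPerSd, ev$hrPerSd)
})

test_that("transfer validation is a fixed point on the training cohort", {
    study <- smallPlantedStudy(seed = 411, n = 151)
    b <- study$cohorts[[1]]
    model <- fitRiskModel(b, "TF001", study$targets[["TF001"]])
    ev <- evaluateSignature(model, b)
    evT <- validateTransfer(model, b)
    expect_identical(as.character(evT$assignment$group),
                     as.character(ev$assignment$group))
    expect_equal(evT$logrank$chi2, ev$logrank$chi2)
})

test_that("transfer groups are invariant to global affine expression maps", {
    study <- smallPlantedStudy(seed = 421, n = 140, nCohorts = 2)
    model <- fitRiskModel(study$cohorts[[1]], "TF001",
                          study$targets[["TF001"]])
    val <- study$cohorts[[2]]
    ev1 <- validateTransfer(model, val)
    val2 <- CohortBundle(2 * exprMatrix(val) + 5, survTable(val),
                         name = "affine")
    ev2 <- validateTransfer(model, val2)
    expect_identical(as.character(ev2$assignment$group),
                     as.character(ev1$assignment$group))
    expect_equal(ev2$logrank$chi2, ev1$logrank$chi2, tolerance = 1e-12)
})

test_that("stratification applies the clinical cut rules and partitions samples", {
    n <- 8
    expr <- matrix(rnorm(n), 1, n, dimnames = list("g1", paste0("s", 1:n)))
    cl <- data.frame(time = rexp(n) + 1, event = rep(1, n),
                     age = c(50, 60, 70, 80, 55, 65, 75, 85),
                     grade = c(1, 2, 3, 4, 1, 2, 3, 4),
                     stage = c(1, 2, 3, 4, 1, 2, 3, 4),
                     residual = c(5, 10, 15, 0, 20, 10, 5, 30),
                     row.names = paste0("s", 1:n))
    b <- CohortBundle(expr, cl)

    sAge <- stratifyCohort(b, "age")
    expect_setequal(sAge[["age<=median"]], c("s1", "s2", "s5", "s6"))
    sGrade <- stratifyCohort(b, "grade")
    expect_setequal(sGrade[["grade G1/G2"]], c("s1", "s2", "s5", "s6"))
    expect_setequal(sGrade[["grade G3/G4"]], c("s3", "s4", "s7", "s8"))
    sStage <- stratifyCohort(b, "stage")
    expect_setequal(sStage[["stage I/II"]], c("s1", "s2", "s5", "s6"))
    sRes <- stratifyCohort(b, "residual")
    expect_setequal(sRes[["residual<=10mm"]],
                    c("s1", "s2", "s4", "s6", "s7"))
    expect_setequal(sRes[["residual>10mm"]], c("s3", "s5", "s8"))

    # partition property: disjoint, union = samples with the variable
    for (v in c("age", "grade", "stage", "residual")) {
        st <- stratifyCohort(b, v)
        expect_length(intersect(st[[1]], st[[2]]), 0)
        expect_setequal(unlist(st), paste0("s", 1:n))
    }

    # missing values are excluded with a message
    cl$grade[2] <- NA
    b2 <- CohortBundle(expr, cl)
    expect_message(st2 <- stratifyCohort(b2, "grade"), "missing")
    expect_false("s2" %in% unlist(st2))
    expect_error(stratifyCohort(b, "lymph"), "should be one of")
})

test_that("stratified evaluation runs the signature within each stratum", {
    study <- smallPlantedStudy(seed = 431, n = 240, gamma = 0.5)
    b <- study$cohorts[[1]]
    evs <- suppressMessages(
        evaluateStrata(b, "age", tfId = "TF001",
                       regulon = study$targets[["TF001"]]))
    expect_true(all(vapply(evs, inherits, TRUE, "SignatureEvaluation")))
    expect_setequal(names(evs), c("age<=median", "age>median"))
})

test_that("multivariate adjustment keeps a real signal and catches collinearity", {
    study <- smallPlantedStudy(seed = 441, n = 300, gamma = 0.5)
    b <- study$cohorts[[1]]
    model <- fitRiskModel(b, "TF001", study$targets[["TF001"]])
    sc <- computeRiskScores(model, b)

    fit <- multivariateAdjust(b, sc)
    tab <- fit$table
    expect_identical(tab$term[1], "riskScore")
    expect_lt(tab$p[1], 0.05)

    # adjusted HR close to unadjusted when covariates are pure noise
    un <- coxFit(survTable(b)$time, survTable(b)$event,
                 cbind(riskScore = scale(sc)[, 1]))
    expect_gt(tab$hr[1], un$table$ciLow)
    expect_lt(tab$hr[1], un$table$ciHigh)

    # duplicated covariate: error naming the pair
    sv <- survTable(b)
    sv$age2 <- sv$age
    b2 <- CohortBundle(exprMatrix(b), sv)
    expect_error(
        multivariateAdjust(b2, sc, covariates = c("age", "age2")),
        "age ~ age2")

    expect_error(
        multivariateAdjust(b, sc, covariates = "nothere"),
        "none of the requested")
})

test_that("risk-direction consistency requires one nonzero sign in every cohort", {
    mk <- function(betas) {
        new("RiskModel", tfId = "TF", lncIds = names(betas),
            betas = unname(betas), cutpoint = 0, scoreCenter = 0,
            scoreScale = 1, trainingCohort = "x", endpoint = "OS",
            dropped = character(0))
    }
    models <- list(
        c1 = mk(c(L1 = 0.5, L2 = 0.2, L3 = -0.1)),
        c2 = mk(c(L1 = 0.3, L2 = -0.4, L3 = -0.2)),
        c3 = mk(c(L1 = 0.8, L2 = 0.1, L3 = -0.6)))
    rc <- riskDirectionConsistency(models)
    expect_true(rc$consistent[rc$lnc == "L1"])    # (+,+,+)
    expect_false(rc$consistent[rc$lnc == "L2"])   # (+,-,+)
    expect_true(rc$consistent[rc$lnc == "L3"])    # (-,-,-)

    # absent from one cohort: excluded
    models$c4 <- mk(c(L1 = 0.1, L2 = 0.1))
    rc4 <- riskDirectionConsistency(models)
    expect_false(rc4$consistent[rc4$lnc == "L3"])

    # monotone: adding a cohort never grows the retained set
    expect_true(all(rc4$consistent <= rc$consistent[match(rc4$lnc, rc$lnc)]))
    expect_error(riskDirectionConsistency(models["c1"]), "length")
})
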