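test_that("risk score is the Cox-weighted sum of expression (worked arithmetic)", {
    model <- new("RiskModel", tfId = "TF", lncIds = c("L1", "L2"),
                 betas = c(0.5, -0.2), cutpoint = 0,
                 scoreCenter = 0, scoreScale = 1,
                 trainingCohort = "toy", endpoint = "OS",
                 dropped = character(0))
    expr <- rbind(L1 = c(2, 1), L2 = c(3, 2))
    colnames(expr) <- c("s1", "s2")
    sc <- computeRiskScores(model, expr)
    expect_equal(unname(sc), c(0.5 * 2 - 0.2 * 3, 0.5 * 1 - 0.2 * 2))

    # all-zero weights give all-zero scores
    model0 <- model; model0@betas <- c(0, 0)
    expect_equal(unname(computeRiskScores(model0, expr)), c(0, 0))

    # appending a zero-weight member leaves scores unchanged (linearity)
    model3 <- new("RiskModel", tfId = "TF",
                  lncIds = c("L1", "L2", "L3"), betas = c(0.5, -0.2, 0),
                  cutpoint = 0, scoreCenter = 0, scoreScale = 1,
                  trainingCohort = "toy", endpoint = "OS",
                  dropped = character(0))
    expr3 <- rbind(expr, L3 = c(9, 9))
    expect_equal(computeRiskScores(model3, expr3), sc)

    # missing member: dropped with a warning, no renormalization
    expect_warning(sc2 <- computeRiskScores(model, expr[1, , drop = FALSE]),
                   "dropped")
    expect_equal(unname(sc2), c(1, 0.5))
    expect_error(computeRiskScores(model, expr3["L3", , drop = FALSE]),
                 "no model lncRNA")
})

test_that("single-member regulon reduces to the univariate Cox fit", {
    set.seed(41)
    n <- 60
    expr <- rbind(L1 = rnorm(n))
    tm <- rexp(n, 0.2 * exp(0.5 * expr["L1", ]))
    b <- makeBundle(tm, rbinom(n, 1, 0.8), expr = expr)
    sv <- survTable(b)
    model <- fitRiskModel(b, "TF", "L1")
    expect_equal(unname(coefs(model)),
                 coxFit(sv$time, sv$event, exprMatrix(b)["L1", ])$table$beta,
                 tolerance = 1e-9)
    expect_equal(unname(computeRiskScores(model, b)),
                 unname(coefs(model) * exprMatrix(b)["L1", ]))
    expect_equal(cutpoint(model),
                 median(computeRiskScores(model, b)))
})

test_that("degenerate regulon members are dropped during fitting", {
    set.seed(52)
    n <- 40
    expr <- rbind(L1 = rnorm(n), L2 = rep(1, n))
    b <- makeBundle(rexp(n) + 0.1, rbinom(n, 1, 0.7), expr = expr)
    expect_message(model <- fitRiskModel(b, "TF", c("L1", "L2")),
                   "constant")
    expect_identical(lncIds(model), "L1")
    expect_true("L2" %in% model@dropped)
    expect_error(suppressMessages(fitRiskModel(b, "TF", "L2")), "usable")
})

test_that("median split obeys the tie rule and balances distinct scores", {
    g <- assignGroups(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
    expect_equal(as.character(g$group), c("low", "low", "high", "high"))

    # odd n: the sample at the median goes low
    g3 <- assignGroups(c(s1 = 1, s2 = 2, s3 = 3))
    expect_equal(as.character(g3$group[2]), "low")

    # n = 399 with distinct scores: 200 low / 199 high
    set.seed(63)
    sc <- setNames(rnorm(399), paste0("s", 1:399))
    g399 <- assignGroups(sc)
    expect_equal(unname(table(g399$group)["low"]), 200, ignore_attr = TRUE)
    expect_equal(unname(table(g399$group)["high"]), 199, ignore_attr = TRUE)

    expect_error(assignGroups(c(a = 1, b = 1)), "identical")
    expect_error(assignGroups(c(a = 1)), "two samples")
})

test_that("scores are affine-equivariant in a member's expression", {
    study <- smallPlantedStudy(seed = 71, n = 120)
    b <- study$cohorts[[1]]
    model <- fitRiskModel(b, "TF001", study$targets[["TF001"]])
    expr <- exprMatrix(b)
    sc <- computeRiskScores(model, expr)
    shifted <- expr
    g1 <- lncIds(model)[1]
    shifted[g1, ] <- shifted[g1, ] + 3
    sc2 <- computeRiskScores(model, shifted)
    expect_equal(sc2, sc + coefs(model)[[g1]] * 3)
})

test_that("signature evaluation is rank-based and symmetric in the score sign", {
    study <- smallPlantedStudy(seed = 81, n = 150)
    b <- study$cohorts[[1]]
    model <- fitRiskModel(b, "TF001", study$targets[["TF001"]])
    ev <- evaluateSignature(model, b)
    expect_s3_class(ev, "SignatureEvaluation")
    expect_equal(ev$nHigh + ev$nLow, ncol(b))

    # strictly increasing transform of the scores: same split, same chi2
    sc <- computeRiskScores(model, b)
    sv <- survTable(b)
    trans <- exp(sc / max(abs(sc)))
    asg <- assignGroups(trans)
    lr <- logrankTest(sv$time, sv$event, asg$group)
    expect_equal(lr$chi2, ev$logrank$chi2, tolerance = 1e-12)

    # negating all betas flips the groups, chi2 unchanged
    neg <- model; neg@betas <- -model@betas
    neg@cutpoint <- -model@cutpoint; neg@scoreCenter <- -model@scoreCenter
    evN <- evaluateSignature(neg, b)
    expect_equal(evN$logrank$chi2, ev$logrank$chi2, tolerance = 1e-9)
    expect_equal(sum(evN$assignment$group == "high") +
                 sum(ev$assignment$group == "high"), ncol(b))
})

test_that("planted positive effects yield positive fitted coefficients", {
    hits <- vapply(1:5, function(s) {
        study <- smallPlantedStudy(seed = 200 + s, n = 250, gamma = 0.3)
        model <- fitRiskModel(study$cohorts[[1]], "TF001",
                              study$targets[["TF001"]])
        mean(coefs(model) > 0)
    }, 0)
    expect_gte(mean(hits), 0.9)
})

test_that("risk models serialize to JSON and back", {
    study <- smallPlantedStudy(seed = 91, n = 100)
    model <- fitRiskModel(study$cohorts[[1]], "TF001",
                          study$targets[["TF001"]])
    f <- withr::local_tempfile(fileext = ".json")
    writeRiskModel(model, f)
    back <- readRiskModel(f)
    expect_equal(coefs(back), coefs(model))
    expect_equal(cutpoint(back), cutpoint(model))
    expect_identical(tfId(back), tfId(model))
})
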