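test_that("Kaplan-Meier estimator matches hand product-limit results", {
    # no censoring: 1 - empirical CDF at event times
    km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
    expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
    expect_equal(km$median, 2)

    # (1E, 2C, 3E): S = 2/3 after t = 1, still 2/3 at t = 2, 0 after t = 3
    km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
    sf <- stepfun(km2$times, c(1, km2$surv))
    expect_equal(sf(c(1, 2, 3)), c(2 / 3, 2 / 3, 0))

    # all censored: curve stays at 1, median undefined
    km3 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
    expect_length(km3$times, 0)
    expect_true(is.na(km3$median))

    expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier equals 1 - ECDF whenever there is no censoring", {
    set.seed(8)
    for (i in 1:10) {
        tm <- round(rexp(40, 0.2) + 0.01, 2)
        km <- kmEstimate(tm, rep(1, 40))
        ec <- ecdf(tm)
        expect_equal(km$surv, 1 - ec(km$times))
    }
})

test_that("log-rank test reproduces the hand-computed Mantel-Cox statistic", {
    # groups (1,2) vs (3,4), all events: O - E = 7/6, V = 17/36
    res <- logrankTest(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
    expect_equal(res$chi2, (7 / 6)^2 / (17 / 36), tolerance = 1e-10)
    expect_equal(res$p, pchisq(49 / 17, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(res$df, 1L)

    # label symmetry
    res2 <- logrankTest(c(1, 2, 3, 4), rep(1, 4), c("B", "B", "A", "A"))
    expect_equal(res2$chi2, res$chi2)
    expect_equal(res2$p, res$p)

    # identical survival data duplicated into two groups
    tm <- c(1, 2, 3, 4, 1, 2, 3, 4)
    ev <- c(1, 0, 1, 1, 1, 0, 1, 1)
    res3 <- logrankTest(tm, ev, rep(c("A", "B"), each = 4))
    expect_equal(res3$chi2, 0, tolerance = 1e-12)
    expect_equal(res3$p, 1, tolerance = 1e-12)

    expect_error(logrankTest(c(1, 2), c(1, 1), c("A", "A")), "two groups")
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
    # interleaved two-group fixture
    time <- c(1, 3, 2, 4); event <- rep(1, 4); x <- c(1, 1, 0, 0)
    fit <- coxFit(time, event, x)
    expect_equal(fit$table$beta, gridSearchBeta(time, event, x),
                 tolerance = 1e-3)
    expect_equal(fit$table$hr, exp(fit$table$beta))
    expect_true(fit$converged)
    expect_false(fit$separation)

    # further 4-8 sample fixtures, continuous and binary covariates
    set.seed(3)
    for (i in 1:6) {
        n <- sample(4:8, 1)
        tm <- sample(seq_len(20), n)   # untied
        ev <- rep(1, n)
        xv <- round(rnorm(n), 2)
        beta <- coxFit(tm, ev, xv)$table$beta
        if (abs(beta) < 4.5)  # inside the oracle grid
            expect_equal(beta, gridSearchBeta(tm, ev, xv),
                         tolerance = 1e-3)
    }
})

test_that("Cox fit depends on survival times only through their ranks", {
    set.seed(14)
    n <- 50
    x <- rnorm(n)
    tm <- rexp(n, exp(0.5 * x))
    ev <- rbinom(n, 1, 0.7)
    f1 <- coxFit(tm, ev, x)
    f2 <- coxFit(rank(tm), ev, x)
    expect_equal(f1$table$beta, f2$table$beta, tolerance = 1e-8)
})

test_that("Cox fit flags degenerate and separated problems and rejects bad input", {
    fit <- coxFit(c(1, 2, 3, 4), rep(1, 4),
                  cbind(a = c(1, 1, 0, 0), b = rep(0, 4)))
    expect_true(fit$table$degenerate[fit$table$term == "b"])
    # group A's events all precede group B's: monotone likelihood
    expect_true(fit$separation)

    expect_error(coxFit(c(1, 2), c(0, 0), c(1, 0)), "no events")
    expect_error(coxFit(c(1, 2, 3), c(1, 1, 0), c(1, NA, 0)),
                 "non-finite")
})

test_that("Wald and log-rank chi-squares agree asymptotically for a binary split", {
    set.seed(22)
    n <- 400
    g <- rep(0:1, each = n / 2)
    tm <- rexp(n, 0.1 * exp(0.5 * g))
    cens <- rexp(n, 0.05)
    time <- pmin(tm, cens); ev <- as.integer(tm <= cens)
    fit <- coxFit(time, ev, g)
    wald <- (fit$table$beta / fit$table$se)^2
    lr <- logrankTest(time, ev, g)$chi2
    expect_lt(abs(wald - lr) / lr, 0.15)
})

test_that("Cox p-values are uniform under the null", {
    set.seed(33)
    n <- 100
    pv <- replicate(2000, {
        x <- rnorm(n)
        tm <- rexp(n, 0.1)
        cens <- rexp(n, 0.1)
        coxFit(pmin(tm, cens), as.integer(tm <= cens), x)$table$p
    })
    ks <- max(abs(sort(pv) - (seq_along(pv) - 0.5) / length(pv)))
    expect_lt(ks, 0.05)
})

test_that("pooled t-test matches the hand computation and its edge cases", {
    res <- tTest(c(1, 2, 3), c(4, 5, 6))
    # pooled sd = 1, se = sqrt(2/3), t = -3/sqrt(2/3), df = 4
    expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
    expect_equal(res$df, 4)
    expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-10)

    # antisymmetry
    expect_equal(tTest(c(4, 5, 6), c(1, 2, 3))$t, -res$t)

    # x = y: t = 0, p = 1 (also when variance is zero)
    expect_equal(tTest(c(2, 2), c(2, 2)), list(t = 0, df = 2L, p = 1))
    same <- c(1, 2, 3)
    expect_equal(tTest(same, same)$t, 0)
    expect_error(tTest(c(1, 1), c(2, 2)), "zero pooled variance")
    expect_error(tTest(1, c(1, 2)), "two observations")
})
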