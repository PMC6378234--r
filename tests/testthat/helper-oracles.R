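# Independent oracles and tiny fixture builders shared across tests.

# Log partial likelihood for untied survival data with one covariate
# (Breslow = Efron when there are no ties); used as a grid-search oracle
# against the Newton-based fit.
partialLoglik <- function(beta, time, event, x) {
    lp <- beta * x
    sum(vapply(which(event == 1), function(i) {
        riskSet <- time >= time[i]
        lp[i] - log(sum(exp(lp[riskSet])))
    }, 0))
}

gridSearchBeta <- function(time, event, x, lower = -5, upper = 5,
                           by = 1e-4) {
    grid <- seq(lower, upper, by = by)
    ll <- vapply(grid, partialLoglik, 0, time = time, event = event, x = x)
    grid[which.max(ll)]
}

# Literal Benjamini-Hochberg step-up definition: sort ascending,
# q_(i) = min_{j >= i} p_(j) * m / j, cap at 1, return in input order.
bhBruteForce <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(ps[i:m] * m / (i:m)))
    out <- numeric(m)
    out[ord] <- q
    out
}

# Minimal cohort from explicit survival data; expression defaults to one
# random gene so the bundle validates.
makeBundle <- function(time, event, expr = NULL, name = "toy",
                       covariates = NULL) {
    n <- length(time)
    samples <- paste0("s", seq_len(n))
    if (is.null(expr)) {
        expr <- matrix(seq_len(n) + 0.5, nrow = 1,
                       dimnames = list("g1", samples))
    } else {
        colnames(expr) <- samples
    }
    cl <- data.frame(time = time, event = event, row.names = samples)
    if (!is.null(covariates))
        cl <- cbind(cl, covariates)
    suppressMessages(CohortBundle(expr, cl, name = name))
}

# Small planted-signal study used by several module tests.
smallPlantedStudy <- function(seed, n = 200, nTF = 6, m = 5,
                              gamma = 0.4, nCohorts = 1) {
    simulateStudy(simulationConfig(
        seed = seed, nCohorts = nCohorts, nSamples = n, nLnc = 80,
        nTF = nTF, targetsPerTF = m, decoysPerTF = m,
        plantedTF = "TF001", gamma = gamma))
}
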