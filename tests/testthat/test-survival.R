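test_that("the product-limit estimator matches hand computation", {
    ## all events, no censoring: S = 2/3, 1/3, 0
    km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km@survival, c(2/3, 1/3, 0))
    expect_equal(km@finalRate, 0)
    ## censored-only data: flat at 1
    flat <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
    expect_length(flat@time, 0)
    expect_equal(flat@finalRate, 1)
    ## censoring before the first event changes risk sets, not values:
    ## with subjects {0.5+ censored, 1, 2, 3 events} S = 2/3, 1/3, 0 still
    km2 <- kmEstimate(c(0.5, 1, 2, 3), c(0, 1, 1, 1))
    expect_equal(km2@survival, km@survival)
    expect_equal(km2@nRisk, c(3, 2, 1))
    expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("KM agrees with an independent implementation on mixed data", {
    skip_if_not_installed("survival")
    set.seed(1)
    t <- round(rexp(40, 0.2), 2)
    e <- rbinom(40, 1, 0.7)
    km <- kmEstimate(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    ref <- summary(sf, times = km@time)
    expect_equal(km@survival, ref$surv, tolerance = 1e-12)
    expect_equal(kmRate(km, 3), ref$surv[max(which(km@time <= 3))])
})

test_that("the log-rank statistic matches a hand O/E/V tabulation", {
    ## groups {1,3,5} and {2,4,6}, all events: O1 = 3, E1 = 2.2333...,
    ## V = 1.21222..., chi2 = (O-E)^2 / V
    lr <- logrankTest(c(1, 3, 5), c(1, 1, 1), c(2, 4, 6), c(1, 1, 1))
    E1 <- 1/2 + 2/5 + 2/4 + 1/3 + 1/2
    V <- 1/4 + 6/25 + 1/4 + 2/9 + 1/4
    expect_equal(lr@chi2, (3 - E1)^2 / V, tolerance = 1e-10)
    ## identical groups: chi2 = 0, p = 1
    same <- logrankTest(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
    expect_equal(same@chi2, 0)
    expect_equal(same@p, 1)
    ## invariant under swapping the groups
    set.seed(2)
    t1 <- round(rexp(15, 0.3), 2); e1 <- rbinom(15, 1, 0.8)
    t2 <- round(rexp(20, 0.6), 2); e2 <- rbinom(20, 1, 0.8)
    a <- logrankTest(t1, e1, t2, e2)
    b <- logrankTest(t2, e2, t1, e1)
    expect_equal(a@chi2, b@chi2, tolerance = 1e-12)
    expect_error(logrankTest(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("log-rank agrees with an independent implementation under ties", {
    skip_if_not_installed("survival")
    set.seed(3)
    t1 <- round(rexp(25, 0.3), 1); e1 <- rbinom(25, 1, 0.7)
    t2 <- round(rexp(25, 0.8), 1); e2 <- rbinom(25, 1, 0.7)
    mine <- logrankTest(t1, e1, t2, e2)
    sd <- survival::survdiff(
        survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(25, 25)))
    expect_equal(mine@chi2, sd$chisq, tolerance = 1e-10)
})

test_that("the Cox partial likelihood is maximized (1-D brute force, no ties)", {
    set.seed(4)
    z <- c(0, 1, 0, 1, 1)
    t <- c(1.1, 2.3, 3.7, 4.1, 5.9)
    e <- c(1, 1, 0, 1, 1)
    fit <- coxFit(cbind(z = z), t, e)
    opt <- optimize(function(b) -coxLoglik1d(b, z, t, e), c(-10, 10),
                    tol = 1e-10)
    expect_equal(coxTable(fit)$beta, opt$minimum, tolerance = 1e-6)
})

test_that("Cox with Efron and Breslow ties matches survival::coxph", {
    skip_if_not_installed("survival")
    set.seed(5)
    n <- 120
    z1 <- rbinom(n, 1, 0.4)
    z2 <- rnorm(n)
    t <- round(rexp(n, 0.1 * exp(0.8 * z1 - 0.4 * z2)), 1)  # heavy ties
    e <- rbinom(n, 1, 0.75)
    for (ties in c("efron", "breslow")) {
        mine <- coxFit(cbind(z1 = z1, z2 = z2), t, e, ties = ties)
        ref <- survival::coxph(survival::Surv(t, e) ~ z1 + z2, ties = ties)
        expect_equal(coxTable(mine)$beta, unname(coef(ref)), tolerance = 1e-6)
        expect_equal(coxTable(mine)$se,
                     unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    }
})

test_that("degenerate Cox inputs are rejected or flagged", {
    t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 0)
    expect_error(coxFit(cbind(z = rep(1, 4)), t, e), "constant covariate")
    expect_error(coxFit(cbind(z = rnorm(4)), t, rep(0, 4)), "no events")
    ## perfect separation: monotone likelihood flagged as a classed error
    zs <- c(0, 0, 0, 1, 1, 1)
    ts <- c(1, 2, 3, 10, 11, 12)
    err <- tryCatch(coxFit(cbind(z = zs), ts, rep(1, 6)),
                    coxConvergenceError = function(e) e)
    expect_s3_class(err, "coxConvergenceError")
})

test_that("the survival report separates arms and runs the subgroup", {
    sig <- GeneSignature("s", sprintf("SIG%03d", 1:30))
    co <- simulateTumorCohort(sig, nPatients = 88, nProbesets = 150, seed = 7)
    ev <- runEvaluation(co$expr, co$clinical, sig, seed = 7,
                        stability = FALSE)
    rep <- ev$survival
    expect_lt(rep$full$os$logrank@p, 0.01)
    expect_gt(rep$full$os$rate_good, rep$full$os$rate_poor)
    cf <- coxTable(rep$full$cox)
    expect_true("nbhypo_poor" %in% rownames(cf))
    expect_gt(cf["nbhypo_poor", "hr"], 1)
    ## the subgroup model drops the MYCN covariate
    expect_false("mycn_amplified" %in% rownames(coxTable(rep$mycn_normal$cox)))
    ## degenerate stratification errors
    one <- new("ClusterAssignment",
               cluster = setNames(rep(c(1L, 2L), c(87, 1)), co$clinical$id),
               wss = 1, prognosis = c("poor", "good"))
    expect_error(survivalReport(co$clinical[1:87, ], one), "cover|one prognosis")
})

test_that("only the planted prognosis covariate comes out significant", {
    sig <- GeneSignature("s", sprintf("SIG%03d", 1:30))
    hitCluster <- 0L; hitOthers <- 0L
    for (s in 1:40) {
        co <- simulateTumorCohort(sig, nPatients = 88, nProbesets = 120,
                                  seed = 200 + s)
        ev <- runEvaluation(co$expr, co$clinical, sig, seed = s,
                            stability = FALSE)
        cf <- coxTable(ev$survival$full$cox)
        if (cf["nbhypo_poor", "p"] < 0.05) hitCluster <- hitCluster + 1L
        hitOthers <- hitOthers +
            sum(cf[c("stage4", "age_ge1", "mycn_amplified"), "p"] < 0.05)
    }
    expect_gte(hitCluster, 36L)           # >= 90%
    expect_lte(hitOthers / (3 * 40), 0.2) # nominal 5% each
})
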