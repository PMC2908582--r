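#' Kaplan-Meier product-limit estimator
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return a [KMCurve-class]; with censored-only data the curve is flat at 1.
#' @export
kmEstimate <- function(times, events) {
    if (!length(times)) stop("empty input")
    if (length(times) != length(events)) stop("times/events length mismatch")
    if (any(times < 0) || anyNA(times)) stop("times must be >= 0")
    if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
    ut <- sort(unique(times[events == 1]))
    nRisk <- vapply(ut, function(t) sum(times >= t), numeric(1))
    nEvent <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
    surv <- cumprod(1 - nEvent / nRisk)
    new("KMCurve", time = ut, nRisk = nRisk, nEvent = nEvent,
        survival = surv,
        finalRate = if (length(surv)) surv[length(surv)] else 1,
        n = length(times), nEvents = as.integer(sum(events)))
}

#' Kaplan-Meier estimate at a horizon
#'
#' @param curve a [KMCurve-class].
#' @param time horizon; `Inf` (default) gives the estimate at the largest
#'   observed time, the single-number arm summary reported throughout.
#' @return survival probability at the horizon.
#' @export
kmRate <- function(curve, time = Inf) {
    idx <- sum(curve@time <= time)
    if (idx == 0L) 1 else curve@survival[idx]
}

#' Two-group log-rank test
#'
#' The standard observed-minus-expected statistic with hypergeometric
#' variance, summed over the distinct event times of the pooled sample;
#' chi-square with 1 df, invariant to swapping the groups.
#'
#' @param times1,events1 follow-up and 0/1 event indicator, group 1.
#' @param times2,events2 likewise, group 2.
#' @return a [LogRankResult-class].
#' @export
logrankTest <- function(times1, events1, times2, events2) {
    if (!length(times1) || !length(times2)) stop("both groups must be non-empty")
    times <- c(times1, times2)
    events <- c(events1, events2)
    if (!any(events == 1)) stop("no events at all: log-rank undefined")
    g <- rep(1:2, c(length(times1), length(times2)))
    ut <- sort(unique(times[events == 1]))
    O1 <- E1 <- V <- 0
    for (t in ut) {
        atRisk <- times >= t
        n1 <- sum(atRisk & g == 1L)
        nj <- sum(atRisk)
        dj <- sum(times == t & events == 1)
        d1 <- sum(times == t & events == 1 & g == 1L)
        O1 <- O1 + d1
        E1 <- E1 + dj * n1 / nj
        if (nj > 1L)
            V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
    }
    chi2 <- (O1 - E1)^2 / V
    new("LogRankResult", chi2 = chi2,
        p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
        n1 = length(times1), n2 = length(times2))
}

## log partial likelihood, gradient and information at beta
.coxDeriv <- function(beta, Z, times, events, ties) {
    eta <- drop(Z %*% beta)
    w <- exp(eta)
    p <- ncol(Z)
    ll <- 0
    grad <- numeric(p)
    info <- matrix(0, p, p)
    for (t in sort(unique(times[events == 1]))) {
        R <- which(times >= t)
        D <- which(times == t & events == 1)
        d <- length(D)
        ZR <- Z[R, , drop = FALSE]
        wR <- w[R]
        S0R <- sum(wR)
        S1R <- colSums(wR * ZR)
        S2R <- crossprod(ZR, wR * ZR)
        ZD <- Z[D, , drop = FALSE]
        wD <- w[D]
        S0D <- sum(wD)
        S1D <- colSums(wD * ZD)
        S2D <- crossprod(ZD, wD * ZD)
        ll <- ll + sum(eta[D])
        grad <- grad + colSums(ZD)
        phis <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
        for (phi in phis) {
            S0 <- S0R - phi * S0D
            S1 <- S1R - phi * S1D
            S2 <- S2R - phi * S2D
            ll <- ll - log(S0)
            m <- S1 / S0
            grad <- grad - m
            info <- info + S2 / S0 - tcrossprod(m)
        }
    }
    list(loglik = ll, grad = grad, info = info)
}

#' Multivariate Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton-Raphson with step-halving,
#' using the Efron tie correction by default (Breslow available). Standard
#' errors come from the inverse observed information; Wald p-values are
#' two-sided and the 95% CI is `exp(beta +/- 1.96 se)`.
#'
#' @param covariates n x m numeric matrix (binary or real), column names
#'   become coefficient names.
#' @param times,events follow-up and 0/1 event indicator.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol,maxIter convergence when `max |delta beta| < tol` (default
#'   1e-8) within `maxIter` (default 50) iterations.
#' @return a [CoxFit-class]. Non-convergence or a monotone likelihood
#'   (perfect separation) raises a condition of class `coxConvergenceError`
#'   carrying the last iterate.
#' @export
coxFit <- function(covariates, times, events, ties = c("efron", "breslow"),
                   tol = 1e-8, maxIter = 50) {
    ties <- match.arg(ties)
    Z <- as.matrix(covariates)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("x", seq_len(ncol(Z)))
    n <- nrow(Z)
    if (length(times) != n || length(events) != n)
        stop("covariates, times and events must agree in length")
    if (!any(events == 1)) stop("no events: partial likelihood undefined")
    if (any(apply(Z, 2L, function(v) max(v) == min(v))))
        stop("singular information: constant covariate")
    if (sum(events) < ncol(Z))
        warning("fewer events than covariates; the information matrix may be singular")
    beta <- numeric(ncol(Z))
    cur <- .coxDeriv(beta, Z, times, events, ties)
    it <- 0L
    converged <- FALSE
    while (it < maxIter) {
        it <- it + 1L
        delta <- tryCatch(solve(cur$info, cur$grad), error = function(e)
            stop("singular information matrix in Newton step", call. = FALSE))
        step <- 1
        repeat {
            cand <- beta + step * delta
            new <- .coxDeriv(cand, Z, times, events, ties)
            if (new$loglik >= cur$loglik - 1e-12 || step < 1 / 1024) break
            step <- step / 2
        }
        beta <- cand
        cur <- new
        if (max(abs(beta)) > 15) {
            cond <- structure(
                class = c("coxConvergenceError", "error", "condition"),
                list(message = "monotone partial likelihood (perfect separation?)",
                     call = sys.call(-1), beta = beta))
            stop(cond)
        }
        if (max(abs(step * delta)) < tol) {
            converged <- TRUE
            break
        }
    }
    if (!converged) {
        cond <- structure(
            class = c("coxConvergenceError", "error", "condition"),
            list(message = sprintf("Newton-Raphson did not converge in %d iterations",
                                   maxIter),
                 call = sys.call(-1), beta = beta))
        stop(cond)
    }
    se <- sqrt(diag(solve(cur$info)))
    z <- beta / se
    cf <- data.frame(beta = beta, se = se, hr = exp(beta),
                     lower95 = exp(beta - 1.96 * se),
                     upper95 = exp(beta + 1.96 * se),
                     p = 2 * stats::pnorm(-abs(z)),
                     row.names = colnames(Z))
    new("CoxFit", coefficients = cf, loglik = cur$loglik, converged = TRUE,
        iterations = it, n = as.integer(n),
        nEvents = as.integer(sum(events)), ties = ties)
}

## one endpoint (times/events) analyzed for a poor/good split
.endpointAnalysis <- function(times, events, poor) {
    kmPoor <- kmEstimate(times[poor], events[poor])
    kmGood <- kmEstimate(times[!poor], events[!poor])
    lr <- tryCatch(logrankTest(times[poor], events[poor],
                               times[!poor], events[!poor]),
                   error = function(e) conditionMessage(e))
    list(km_poor = kmPoor, km_good = kmGood,
         rate_poor = kmPoor@finalRate, rate_good = kmGood@finalRate,
         logrank = if (is(lr, "LogRankResult")) lr else NULL,
         flag = if (is.character(lr)) lr else NULL)
}

.cohortAnalysis <- function(clin, prognosis, withMycn) {
    poor <- prognosis[clin$id] == "poor"
    if (length(unique(poor)) < 2L)
        return(list(flag = "degenerate stratification: one prognosis group"))
    out <- list(n = nrow(clin), n_poor = sum(poor), n_good = sum(!poor))
    out$os <- .endpointAnalysis(clin$time_years, clin$event, poor)
    if (all(c("efs_time_years", "efs_event") %in% names(clin)))
        out$efs <- .endpointAnalysis(clin$efs_time_years, clin$efs_event, poor)
    Z <- cbind(nbhypo_poor = as.numeric(poor),
               stage4 = as.numeric(clin$inss == "4"),
               age_ge1 = as.numeric(clin$age_group == "ge1"))
    if (withMycn)
        Z <- cbind(Z, mycn_amplified = as.numeric(clin$mycn == "amplified"))
    coxRes <- tryCatch(coxFit(Z, clin$time_years, clin$event),
                       error = function(e) conditionMessage(e))
    if (is(coxRes, "CoxFit")) {
        out$cox <- coxRes
    } else {
        out$cox <- NULL
        out$cox_flag <- coxRes
    }
    out
}

#' Survival report for a stratified cohort
#'
#' For the full cohort and for the MYCN-not-amplified subgroup: Kaplan-Meier
#' curves and final survival rates per prognosis arm, the log-rank test, and
#' a multivariate Cox model with the prognosis label (poor vs good), INSS
#' stage (4 vs not 4), age (>= 1 year vs < 1) and, in the full cohort only,
#' MYCN status (amplified vs normal); covariates are coded so that a hazard
#' ratio above 1 means higher risk. Event-free survival is analyzed
#' alongside overall survival when `efs_time_years` / `efs_event` columns
#' are present. Degenerate pieces (a subgroup with no events, an arm
#' missing) are flagged instead of fitted.
#'
#' @param clinical validated clinical table (see [readClinicalTable()]).
#' @param assignment a prognosis-labeled [ClusterAssignment-class] covering
#'   every patient id.
#' @return nested list with components `full` and `mycn_normal`.
#' @export
survivalReport <- function(clinical, assignment) {
    clinical <- validateClinicalTable(clinical)
    prog <- prognosisLabels(assignment)
    if (!all(clinical$id %in% names(prog)))
        stop("assignment does not cover every patient")
    poorAll <- prog[clinical$id] == "poor"
    if (length(unique(poorAll)) < 2L)
        stop("degenerate stratification: all patients fall in one prognosis group")
    sub <- clinical[clinical$mycn == "normal", , drop = FALSE]
    list(full = .cohortAnalysis(clinical, prog, withMycn = TRUE),
         mycn_normal = if (nrow(sub) >= 2L &&
                           length(unique(prog[sub$id])) == 2L)
             .cohortAnalysis(sub, prog, withMycn = FALSE)
         else list(flag = "MYCN-normal subgroup degenerate; not analyzed"))
}
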