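#' Simulate a paired normoxic/hypoxic cell-line experiment
#'
#' Expression is simulated on the log2 scale and exponentiated, so the
#' normalization chain and fold-change logic see realistic positive data.
#' Each probeset gets a baseline `N(baselineLog2Mean, baselineLog2Sd^2)`;
#' the `nResponsive` planted probesets add, to their hypoxic sample of line
#' `l`, a shift `s_g * effectLog2 + N(0, lineSd^2)` where the sign `s_g` is
#' +1 for an induced and -1 for a repressed probeset (an even mixture by
#' default; set `upOnly = TRUE` for an induction-only program, the pattern
#' hypoxia signatures predominantly show). Every measurement carries
#' residual log2 noise `N(0, noiseSd^2)`. Defaults match the derivation
#' conditions used throughout the package: 11 lines, 2000 probesets of which
#' 50 respond with a 1.5 log2-fold shift over 0.5 noise, and between-line
#' heterogeneity at half the mean effect (`lineSd = 0.75`) -- hypoxic
#' response differs strongly between cell lines, and this setting puts the
#' selection task in the realistic regime of a small but nonzero
#' leave-one-out error rather than one where any single probeset separates
#' the classes perfectly.
#'
#' Generation is a pure function of `seed`.
#'
#' @param nLines number of cell lines (>= 2); each contributes a normoxic
#'   and a hypoxic array.
#' @param nProbesets,nResponsive chip size and planted responsive subset.
#' @param effectLog2 mean absolute log2 fold change of planted probesets.
#' @param lineSd between-line sd of the planted effect.
#' @param noiseSd residual log2 noise sd.
#' @param baselineLog2Mean,baselineLog2Sd baseline distribution.
#' @param upOnly plant induced probesets only.
#' @param seed integer seed.
#' @return list with `expr` (linear-scale [ProbesetExperiment-class]),
#'   `design` ([PairedDesign-class]) and `truth` (planted probeset ids).
#' @export
simulateCellLinePairs <- function(nLines = 11, nProbesets = 2000,
                                  nResponsive = 50, effectLog2 = 1.5,
                                  lineSd = 0.75, noiseSd = 0.5,
                                  baselineLog2Mean = 8, baselineLog2Sd = 1.5,
                                  upOnly = FALSE, seed = 1) {
    if (nLines < 2L) stop("need at least 2 cell lines")
    if (nResponsive > nProbesets)
        stop("nResponsive cannot exceed nProbesets")
    if (lineSd < 0 || noiseSd <= 0 || baselineLog2Sd < 0)
        stop("invalid noise configuration")
    if (effectLog2 < 0) stop("effectLog2 must be >= 0")
    withr::with_seed(seed, {
        ids <- sprintf("PS%05d", seq_len(nProbesets))
        lines <- sprintf("CL%02d", seq_len(nLines))
        truth <- sort(sample(ids, nResponsive))
        signs <- stats::setNames(
            if (upOnly) rep(1, nResponsive)
            else sample(c(-1, 1), nResponsive, replace = TRUE), truth)
        baseline <- stats::rnorm(nProbesets, baselineLog2Mean, baselineLog2Sd)
        normox <- matrix(stats::rnorm(nProbesets * nLines, 0, noiseSd),
                         nProbesets, nLines) + baseline
        hypox <- matrix(stats::rnorm(nProbesets * nLines, 0, noiseSd),
                        nProbesets, nLines) + baseline
        shift <- matrix(0, nProbesets, nLines, dimnames = list(ids, lines))
        if (nResponsive > 0)
            shift[truth, ] <- signs * effectLog2 +
                matrix(stats::rnorm(nResponsive * nLines, 0, lineSd),
                       nResponsive, nLines)
        hypox <- hypox + shift
        vals <- 2^cbind(normox, hypox)
        dimnames(vals) <- list(ids, c(paste0(lines, "_N"), paste0(lines, "_H")))
    })
    list(expr = ProbesetExperiment(vals, scale = "linear"),
         design = PairedDesign(lines, paste0(lines, "_N"), paste0(lines, "_H")),
         truth = truth)
}

#' Simulate a tumor cohort whose survival is driven by a hypoxia signature
#'
#' A latent hypoxia indicator `H ~ Bernoulli(hypoxiaFraction)` shifts the
#' signature probesets of hypoxic tumors up by `sigEffectLog2` on the log2
#' scale; all other probesets are uninformative background. Overall-survival
#' times are exponential with hazard
#' `baselineHazard * trueHr^H * prod(covariateHr^covariate)` and censoring
#' is independent exponential with rate `censorRate` (0 disables censoring);
#' times are rounded to `roundDigits` decimals so ties are exercised.
#' Binary risk covariates (MYCN amplification, INSS stage 4, age >= 1 year)
#' are drawn independently with the given prevalences, matching a typical
#' high-risk-enriched neuroblastoma cohort; by default they do not act on
#' the hazard, so the signature is the only prognostic driver. Non-stage-4
#' patients are spread over stages 1, 2, 3 and 4S.
#'
#' Generation is a pure function of `seed`.
#'
#' @param signature a [GeneSignature-class] or character vector of probeset
#'   ids; must be non-empty.
#' @param nPatients cohort size.
#' @param nProbesets total probesets on the simulated chip (the signature's
#'   are included in the count).
#' @param hypoxiaFraction latent hypoxic fraction in (0, 1).
#' @param sigEffectLog2 log2 up-shift of signature probesets in hypoxic
#'   tumors.
#' @param noiseSd,baselineLog2Mean,baselineLog2Sd background expression
#'   model.
#' @param trueHr hazard ratio of hypoxic vs non-hypoxic tumors.
#' @param baselineHazard events per year in the non-hypoxic group.
#' @param censorRate exponential censoring rate (per year), `>= 0`.
#' @param covariatePrevalence named prevalences for `mycn`, `stage4`,
#'   `age_ge1`.
#' @param covariateHr hazard ratios of the three covariates (default all 1).
#' @param roundDigits decimals survival times are rounded to.
#' @param seed integer seed.
#' @return list with `expr` (linear-scale [ProbesetExperiment-class]),
#'   `clinical` (validated clinical table) and `truth` (0/1 hypoxia labels
#'   named by patient id).
#' @export
simulateTumorCohort <- function(signature, nPatients = 88, nProbesets = 1000,
                                hypoxiaFraction = 0.24, sigEffectLog2 = 1.5,
                                noiseSd = 1, baselineLog2Mean = 8,
                                baselineLog2Sd = 1.5, trueHr = 4,
                                baselineHazard = 0.09, censorRate = 0.09,
                                covariatePrevalence = c(mycn = 0.18,
                                                        stage4 = 0.455,
                                                        age_ge1 = 0.716),
                                covariateHr = c(mycn = 1, stage4 = 1,
                                                age_ge1 = 1),
                                roundDigits = 3, seed = 1) {
    sigIds <- if (is(signature, "GeneSignature")) sigProbesets(signature)
              else as.character(signature)
    if (!length(sigIds)) stop("config error: empty signature")
    if (hypoxiaFraction <= 0 || hypoxiaFraction >= 1)
        stop("hypoxiaFraction must lie in (0, 1)")
    if (trueHr <= 0 || !is.finite(trueHr)) stop("trueHr must be finite and > 0")
    if (baselineHazard <= 0) stop("baselineHazard must be > 0")
    if (censorRate < 0) stop("censorRate must be >= 0")
    if (any(covariatePrevalence < 0 | covariatePrevalence > 1))
        stop("prevalences must lie in [0, 1]")
    nBg <- nProbesets - length(sigIds)
    if (nBg < 0) stop("nProbesets must be at least the signature size")
    withr::with_seed(seed, {
        ids <- c(sigIds, sprintf("BG%05d", seq_len(nBg)))
        pts <- sprintf("PT%03d", seq_len(nPatients))
        H <- stats::rbinom(nPatients, 1L, hypoxiaFraction)
        vals <- matrix(stats::rnorm(nProbesets * nPatients, 0, noiseSd),
                       nProbesets, nPatients, dimnames = list(ids, pts)) +
            stats::rnorm(nProbesets, baselineLog2Mean, baselineLog2Sd)
        vals[sigIds, H == 1L] <- vals[sigIds, H == 1L] + sigEffectLog2
        mycn <- stats::rbinom(nPatients, 1L, covariatePrevalence[["mycn"]])
        stage4 <- stats::rbinom(nPatients, 1L, covariatePrevalence[["stage4"]])
        age1 <- stats::rbinom(nPatients, 1L, covariatePrevalence[["age_ge1"]])
        hazard <- baselineHazard * trueHr^H *
            covariateHr[["mycn"]]^mycn * covariateHr[["stage4"]]^stage4 *
            covariateHr[["age_ge1"]]^age1
        T <- stats::rexp(nPatients, hazard)
        C <- if (censorRate > 0) stats::rexp(nPatients, censorRate)
             else rep(Inf, nPatients)
        time <- round(pmin(T, C), roundDigits)
        event <- as.integer(T <= C)
        inss <- ifelse(stage4 == 1L, "4",
                       sample(c("1", "2", "3", "4S"), nPatients,
                              replace = TRUE, prob = c(8, 15, 13, 12)))
    })
    clinical <- data.frame(
        id = pts, time_years = time, event = event,
        mycn = ifelse(mycn == 1L, "amplified", "normal"),
        inss = inss, age_group = ifelse(age1 == 1L, "ge1", "lt1"),
        stringsAsFactors = FALSE)
    list(expr = ProbesetExperiment(
             2^vals, scale = "linear",
             colData = DataFrame(clinical, row.names = clinical$id)),
         clinical = validateClinicalTable(clinical),
         truth = stats::setNames(H, pts))
}
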