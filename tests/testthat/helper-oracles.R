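# Independent oracles and small fixture builders used across the suite.

# Brute-force maximizer of the binomial partition likelihood
# Binom(k; n, 1 - e^-lambda): staged grid refinement, no calculus and no
# closed form, so it is independent of the estimator under test.  The
# likelihood is ranked via stable increments between adjacent grid points
# (raw log-likelihood values are flat to double precision near the optimum).
gridMaxLambda <- function(n, k, lo = 1e-9, hi = 15, points = 400L,
                          stages = 5L) {
  for (s in seq_len(stages)) {
    grid <- seq(lo, hi, length.out = points)
    d <- diff(grid)
    g1 <- grid[-length(grid)]
    # LL(g+d) - LL(g) = k log((1 - e^-(g+d))/(1 - e^-g)) - (n - k) d
    inc <- k * log1p(exp(-g1) * (-expm1(-d)) / (1 - exp(-g1))) - (n - k) * d
    ll <- c(0, cumsum(inc))
    i <- which.max(ll)
    step <- grid[2L] - grid[1L]
    lo <- max(grid[i] - step, 1e-12)
    hi <- grid[i] + step
  }
  (lo + hi) / 2
}

# Two-sided Fisher exact p-value by full hypergeometric enumeration of all
# tables with the observed margins.
fisherEnumerate <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); kcol <- sum(tab[, 1L])
  support <- max(0L, kcol - n):min(kcol, m)
  probs <- stats::dhyper(support, m, n, kcol)
  pObs <- stats::dhyper(tab[1L, 1L], m, n, kcol)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Parametric bootstrap interval for lambda from one well's counts.
bootstrapLambdaCI <- function(n, k, alpha = 0.05, B = 4000L) {
  lam <- -log((n - k) / n)
  kStar <- stats::rbinom(B, n, 1 - exp(-lam))
  kStar <- pmin(pmax(kStar, 1L), n - 1L)
  lamStar <- -log((n - kStar) / n)
  stats::quantile(lamStar, c(alpha / 2, 1 - alpha / 2), names = FALSE)
}

# ConcentrationEstimate with an exactly specified concentration, for
# threshold-logic tests where the droplet counts are irrelevant.
fixedConc <- function(conc, sampleId = "S1", channel = "FAM",
                      n = 15000L, alpha = 0.05) {
  lam <- conc * 1e-3
  k <- max(1L, min(n - 1L, as.integer(round(n * (1 - exp(-lam))))))
  new("ConcentrationEstimate", sampleId = sampleId, channel = channel,
      lambda = lam, conc = conc, ciLow = conc * 0.9, ciHigh = conc * 1.1,
      nTotal = n, nPositive = k, nWells = 1L, alpha = alpha,
      dropletVolumeNl = 1, saturated = FALSE, flags = character(0))
}

# CnvEstimate with exactly specified point estimate and bounds.
fixedCnv <- function(cnv, cnvMin, cnvMax, sampleId = "S1") {
  new("CnvEstimate", sampleId = sampleId, cnv = cnv, cnvMin = cnvMin,
      cnvMax = cnvMax, ratio = cnv / 2, ciMethod = "log_delta")
}

# Minimal cohort records for association-test logic.
makeRecords <- function(diagnosis, duplication,
                        braf = rep("Non-mutated", length(diagnosis)),
                        exon12 = rep(NA_character_, length(diagnosis)),
                        exon14 = rep(NA_character_, length(diagnosis))) {
  data.frame(
    sample_id = sprintf("S%02d", seq_along(diagnosis)),
    diagnosis = diagnosis, braf_status = braf,
    fgfr1_duplication = duplication,
    ihc_pfgfr1 = NA_character_,
    fgfr1_exon12 = exon12, fgfr1_exon14 = exon14,
    fgfr1_exon12_class = classifyMutation(exon12),
    fgfr1_exon14_class = classifyMutation(exon14),
    stringsAsFactors = FALSE
  )
}
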