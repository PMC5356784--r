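# Poisson partition statistics for droplet counts.
#
# A well partitions the reaction into n droplets; template molecules land in
# droplets as a Poisson process, so a droplet is negative with probability
# exp(-lambda) and the number of positives is Binomial(n, 1 - exp(-lambda)).
# Everything downstream (concentration, CNV) derives from lambda.

CHANNELS <- c(target = "FAM", reference = "HEX")

#' Estimate mean template copies per droplet
#'
#' Maximum-likelihood estimate of the Poisson partition parameter from
#' droplet end-point counts: \eqn{\hat\lambda = -\ln(n_{neg}/n_{tot})},
#' the maximizer of the binomial likelihood
#' \eqn{Binom(n_{pos}; n_{tot}, 1 - e^{-\lambda})}.
#'
#' @param nTotal integer vector, accepted droplets per well (>= 1).
#' @param nPositive integer vector, positive droplets (0 <= nPositive <=
#'   nTotal).
#' @return Numeric vector of \eqn{\hat\lambda} values (copies per droplet).
#'   Exactly 0 when no droplet is positive.
#' @section Errors: an all-positive well is saturated: every droplet carries
#'   template and the counts put no upper bound on \eqn{\lambda}, so the
#'   function stops.  Use [estimateConcentration()] for a flagged one-sided
#'   treatment, or merge wells first.
#' @examples
#' estimateLambda(15000, 74)    # ~0.004946 copies/droplet
#' estimateLambda(15000, 0)     # 0
#' @seealso [lambdaCI()], [estimateConcentration()]
#' @export
estimateLambda <- function(nTotal, nPositive) {
  checkCounts(nTotal, nPositive)
  if (any(nPositive == nTotal))
    stop("saturated well (all droplets positive): lambda is unbounded; ",
         "merge wells or use estimateConcentration() for a flagged bound")
  -log((nTotal - nPositive) / nTotal)
}

checkCounts <- function(nTotal, nPositive) {
  if (length(nTotal) == 0L || length(nPositive) == 0L)
    stop("empty droplet counts")
  if (any(!is.finite(nTotal)) || any(!is.finite(nPositive)))
    stop("droplet counts must be finite")
  if (any(nTotal < 1))
    stop("invalid input: nTotal must be >= 1")
  if (any(nPositive < 0) || any(nPositive > nTotal))
    stop("invalid input: need 0 <= nPositive <= nTotal")
  invisible(TRUE)
}

# Delta-method variance of lambda-hat: with p_neg the observed negative
# fraction, var(p_neg) = p(1-p)/n and d lambda / d p_neg = -1/p_neg, giving
# var(lambda) = (1 - p_neg) / (n * p_neg).
lambdaVariance <- function(nTotal, nPositive) {
  pNeg <- (nTotal - nPositive) / nTotal
  (1 - pNeg) / (nTotal * pNeg)
}

#' Poisson-based confidence interval for copies per droplet
#'
#' Delta-method normal interval on the log scale:
#' \eqn{CI = \hat\lambda \exp(\pm z_{1-\alpha/2} \sqrt{var}/\hat\lambda)}
#' with \eqn{var(\hat\lambda) = (1 - \hat p_{neg}) / (n \hat p_{neg})}.
#' The log-scale construction keeps both bounds strictly positive and is
#' approximately symmetric on the log scale, matching standard digital-PCR
#' practice.  Interval width shrinks as \eqn{1/\sqrt{n}} at a fixed positive
#' fraction.
#'
#' Degenerate wells get one-sided exact (Clopper-Pearson style) bounds and a
#' flag rather than an error: with zero positives the interval is
#' \eqn{[0, -\ln(\alpha)/n]}; with all positives it is
#' \eqn{[-\ln(1 - \alpha^{1/n}), \infty)}.
#'
#' @inheritParams estimateLambda
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @return A data.frame with one row per well: \code{lambda}, \code{low},
#'   \code{high}, \code{flag} (\code{""}, \code{"zero_positive"} or
#'   \code{"saturated_well"}).
#' @examples
#' lambdaCI(15000, 74)
#' lambdaCI(15000, 0)      # one-sided upper bound
#' @seealso [estimateLambda()], [estimateConcentration()]
#' @export
lambdaCI <- function(nTotal, nPositive, alpha = 0.05) {
  checkCounts(nTotal, nPositive)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  n <- length(nTotal)
  nPositive <- rep_len(nPositive, n)
  lam <- low <- high <- numeric(n)
  flag <- character(n)
  z <- stats::qnorm(1 - alpha / 2)

  zero <- nPositive == 0
  sat <- nPositive == nTotal
  reg <- !zero & !sat

  lam[zero] <- 0
  low[zero] <- 0
  high[zero] <- -log(alpha) / nTotal[zero]
  flag[zero] <- "zero_positive"

  lam[sat] <- Inf
  low[sat] <- -log(1 - alpha^(1 / nTotal[sat]))
  high[sat] <- Inf
  flag[sat] <- "saturated_well"

  if (any(reg)) {
    l <- -log((nTotal[reg] - nPositive[reg]) / nTotal[reg])
    v <- lambdaVariance(nTotal[reg], nPositive[reg])
    half <- z * sqrt(v) / l
    lam[reg] <- l
    low[reg] <- l * exp(-half)
    high[reg] <- l * exp(half)
  }
  data.frame(lambda = lam, low = low, high = high, flag = flag,
             stringsAsFactors = FALSE)
}

#' Absolute quantification of one channel in copies per microlitre
#'
#' Converts droplet counts into a [ConcentrationEstimate-class]:
#' \eqn{c = \hat\lambda / V} with \eqn{V} the droplet volume in
#' \eqn{\mu}l, CI bounds transformed by the same scale factor.  Degenerate
#' wells (zero or all positives) are returned flagged with one-sided bounds
#' instead of erroring, so callers can decide whether merging additional
#' wells rescues the sample.
#'
#' @inheritParams lambdaCI
#' @param spec a [DropletSpec-class] giving the droplet volume.
#' @param sampleId,channel optional identifiers stored in the result.
#' @param nWells number of wells the counts were merged from.
#' @return A [ConcentrationEstimate-class].
#' @examples
#' est <- estimateConcentration(15000, 74)
#' concentration(est)     # ~4.95 copies/ul
#' ciLow(est); ciHigh(est)
#' @seealso [mergeWells()], [quantifySamples()]
#' @export
estimateConcentration <- function(nTotal, nPositive, spec = DropletSpec(),
                                  alpha = 0.05, sampleId = NA_character_,
                                  channel = NA_character_, nWells = 1L) {
  stopifnot(is(spec, "DropletSpec"), length(nTotal) == 1L,
            length(nPositive) == 1L)
  ci <- lambdaCI(nTotal, nPositive, alpha)
  volUl <- spec@dropletVolumeNl * 1e-3
  flags <- if (nzchar(ci$flag)) ci$flag else character(0)
  new("ConcentrationEstimate",
      sampleId = as.character(sampleId), channel = as.character(channel),
      lambda = ci$lambda, conc = ci$lambda / volUl,
      ciLow = ci$low / volUl, ciHigh = ci$high / volUl,
      nTotal = as.integer(nTotal), nPositive = as.integer(nPositive),
      nWells = as.integer(nWells), alpha = alpha,
      dropletVolumeNl = spec@dropletVolumeNl,
      saturated = ci$flag == "saturated_well", flags = flags)
}

#' Merge replicate wells of one sample and channel
#'
#' Pools accepted and positive droplet counts across wells so the pooled
#' Poisson estimate uses every droplet.  Merging k equal wells reproduces
#' the estimate of a single well with k-fold droplets and shrinks the
#' CNVmax - CNVmin spread roughly by \eqn{1/\sqrt{k}}, which is how low-DNA
#' samples are rescued in practice.
#'
#' @param wells data.frame in the wells schema (\code{sample_id},
#'   \code{well_id}, \code{channel}, \code{n_total}, \code{n_positive}); all
#'   rows must share one sample and one channel.
#' @return A one-row data.frame in the same schema with summed counts and a
#'   \code{n_wells} column.
#' @examples
#' w <- data.frame(sample_id = "S1", well_id = c("A1", "A2"),
#'                 channel = "FAM", n_total = c(15000, 15000),
#'                 n_positive = c(100, 110))
#' mergeWells(w)
#' @export
mergeWells <- function(wells) {
  wells <- validateWells(wells)
  if (nrow(wells) == 0L) stop("invalid merge: no wells supplied")
  if (length(unique(wells$sample_id)) != 1L)
    stop("invalid merge: wells span multiple samples: ",
         paste(unique(wells$sample_id), collapse = ", "))
  if (length(unique(wells$channel)) != 1L)
    stop("invalid merge: wells span multiple channels: ",
         paste(unique(wells$channel), collapse = ", "))
  data.frame(
    sample_id = wells$sample_id[1L],
    well_id = paste(wells$well_id, collapse = "+"),
    channel = wells$channel[1L],
    n_total = sum(wells$n_total),
    n_positive = sum(wells$n_positive),
    n_wells = nrow(wells),
    stringsAsFactors = FALSE
  )
}

#' Quantify every sample x channel of a well table
#'
#' Merges replicate wells per sample and channel and runs the Poisson
#' quantification on the pooled counts.
#'
#' @param wells data.frame in the wells schema (see [readWells()]).
#' @param spec a [DropletSpec-class].
#' @param alpha CI significance level.
#' @return A data.frame with one row per sample x channel:
#'   \code{sample_id}, \code{channel}, \code{n_wells}, \code{n_total},
#'   \code{n_positive}, \code{lambda}, \code{conc_copies_per_ul},
#'   \code{ci_low}, \code{ci_high}, \code{flags} (semicolon-separated).
#' @examples
#' sim <- simulateSample("S1", trueFraction = 0.5, referenceConc = 50)
#' quantifySamples(sim)
#' @seealso [callSamples()]
#' @export
quantifySamples <- function(wells, spec = DropletSpec(), alpha = 0.05) {
  wells <- validateWells(wells)
  groups <- split(wells, list(wells$sample_id, wells$channel), drop = TRUE)
  rows <- lapply(groups, function(g) {
    m <- mergeWells(g)
    est <- estimateConcentration(m$n_total, m$n_positive, spec = spec,
                                 alpha = alpha, sampleId = m$sample_id,
                                 channel = m$channel, nWells = m$n_wells)
    data.frame(
      sample_id = m$sample_id, channel = m$channel, n_wells = m$n_wells,
      n_total = m$n_total, n_positive = m$n_positive,
      lambda = est@lambda, conc_copies_per_ul = est@conc,
      ci_low = est@ciLow, ci_high = est@ciHigh,
      flags = paste(est@flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$channel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Schema check shared by every consumer of the wells table.
validateWells <- function(wells) {
  need <- c("sample_id", "well_id", "channel", "n_total", "n_positive")
  if (!is.data.frame(wells))
    stop("wells must be a data.frame")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("wells table is missing columns: ", paste(miss, collapse = ", "))
  wells$channel <- normalizeChannel(wells$channel)
  checkCounts(wells$n_total, wells$n_positive)
  wells
}

normalizeChannel <- function(x) {
  x <- toupper(as.character(x))
  x[x == "TARGET_FAM"] <- "FAM"
  x[x == "REFERENCE_HEX"] <- "HEX"
  bad <- !x %in% CHANNELS
  if (any(bad))
    stop("unknown channel value(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected FAM or HEX)")
  x
}
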