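# Seeded synthetic droplet-count generator with known ground truth.
#
# Ideal Poisson partitioning: a well with n droplets of volume V ul at
# template concentration c copies/ul has positives ~ Binomial(n, 1 - e^(-cV)).
# The duplex assay is emulated with a monoallelic-duplication mixture: a
# fraction f of cells carries one extra target copy, so target
# concentration = reference * (2 + f)/2 and the expected CNV is 2 + f.

#' Simulate droplet end-point counts for one well
#'
#' Draws the positive-droplet count of a single well under ideal Poisson
#' partitioning: \code{n_positive ~ Binomial(nDroplets, 1 - exp(-c V))}
#' with \code{V} the droplet volume in \eqn{\mu}l.
#'
#' @param conc template concentration in copies/\eqn{\mu}l (>= 0).
#' @param nDroplets accepted droplets in the well.
#' @param volumeNl droplet volume in nanolitres (default 1).
#' @param sampleId,wellId,channel identifiers written into the result.
#' @return A one-row data.frame in the wells schema (\code{sample_id},
#'   \code{well_id}, \code{channel}, \code{n_total}, \code{n_positive}).
#' @examples
#' set.seed(1)
#' simulateWell(50, 15000)
#' @seealso [simulateSample()], [simulateCohort()]
#' @export
simulateWell <- function(conc, nDroplets, volumeNl = 1,
                         sampleId = "S1", wellId = "W1", channel = "FAM") {
  if (length(conc) != 1L || !is.finite(conc) || conc < 0)
    stop("invalid input: conc must be a single non-negative number")
  if (nDroplets < 1) stop("invalid input: nDroplets must be >= 1")
  p <- 1 - exp(-conc * volumeNl * 1e-3)
  data.frame(
    sample_id = sampleId, well_id = wellId,
    channel = normalizeChannel(channel),
    n_total = as.integer(nDroplets),
    n_positive = stats::rbinom(1L, as.integer(nDroplets), p),
    stringsAsFactors = FALSE
  )
}

# Accepted-droplet counts per well: fixed value, or log-uniform over the
# observed per-assay range (only range and median of the real instrument
# output are known, so no finer distributional claim is made).
drawDroplets <- function(nWells, dropletsPerWell, dropletRange) {
  if (!is.null(dropletsPerWell))
    return(rep_len(as.integer(dropletsPerWell), nWells))
  as.integer(round(exp(stats::runif(nWells, log(dropletRange[1L]),
                                    log(dropletRange[2L])))))
}

#' Simulate a duplex ddPCR sample with known ground truth
#'
#' Emulates the two-channel FGFR1 assay for one sample carrying a
#' monoallelic duplication in a fraction \code{trueFraction} of cells:
#' the reference (HEX) channel sees \code{referenceConc * degradation}
#' copies/\eqn{\mu}l and the target (FAM) channel
#' \code{referenceConc * (2 + trueFraction)/2 * degradation *
#' channelImbalance}.  With \code{channelImbalance = 1} the expected CNV of
#' the downstream pipeline is \code{2 + trueFraction}; the imbalance factor
#' exists to inject the target-only dropout artefacts seen in FFPE material
#' (e.g. 0.75 at \code{trueFraction = 0} gives an expected CNV of 1.5,
#' exercising the artefact flag).
#'
#' @param sampleId sample identifier.
#' @param trueFraction duplicated-cell fraction in \[0, 1\].
#' @param referenceConc amplifiable reference concentration in
#'   copies/\eqn{\mu}l.
#' @param nWells wells per channel (default 1).
#' @param dropletsPerWell fixed accepted-droplet count, or \code{NULL}
#'   (default) to draw each well log-uniformly over \code{dropletRange}.
#' @param dropletRange range for the accepted-droplet draw
#'   (default 7177 to 47840, the observed per-assay range).
#' @param volumeNl droplet volume in nanolitres.
#' @param degradation amplifiable-fraction multiplier in (0, 1\] applied to
#'   both channels (FFPE degradation; leaves the expected CNV unchanged).
#' @param channelImbalance target-channel-only multiplier (artefact
#'   injector, default 1).
#' @return A data.frame of \code{2 * nWells} rows in the wells schema.
#' @examples
#' set.seed(1)
#' simulateSample("S1", trueFraction = 0.25, referenceConc = 40,
#'                dropletsPerWell = 15000)
#' @export
simulateSample <- function(sampleId = "S1", trueFraction = 0,
                           referenceConc = 50, nWells = 1L,
                           dropletsPerWell = NULL,
                           dropletRange = c(7177L, 47840L),
                           volumeNl = 1, degradation = 1,
                           channelImbalance = 1) {
  stopifnot(trueFraction >= 0, trueFraction <= 1, referenceConc >= 0,
            degradation > 0, degradation <= 1, channelImbalance >= 0,
            nWells >= 1)
  refC <- referenceConc * degradation
  tgtC <- referenceConc * (2 + trueFraction) / 2 * degradation *
    channelImbalance
  nd <- drawDroplets(nWells, dropletsPerWell, dropletRange)
  rows <- lapply(seq_len(nWells), function(i) {
    rbind(
      simulateWell(tgtC, nd[i], volumeNl, sampleId,
                   sprintf("%s_W%02d", sampleId, i), "FAM"),
      simulateWell(refC, nd[i], volumeNl, sampleId,
                   sprintf("%s_W%02d", sampleId, i), "HEX")
    )
  })
  do.call(rbind, rows)
}

# Expected call given the generating truth: mirrors the conclusiveness floor
# and the dual threshold applied to the noise-free expected values.
expectedCall <- function(trueFraction, referenceConc, degradation,
                         channelImbalance = 1,
                         thresholds = CallThresholds()) {
  refC <- referenceConc * degradation
  tgtC <- referenceConc * (2 + trueFraction) / 2 * degradation *
    channelImbalance
  if (min(refC, tgtC) < thresholds@minConc) return("inconclusive")
  expCnv <- 2 * tgtC / refC
  if (expCnv > thresholds@cnvCutoff) "duplicated" else "non_duplicated"
}

#' Simulate a full cohort with linked truth table
#'
#' Generates a seeded synthetic cohort emulating the 36-sample study
#' composition (12 DNT, 2 PTO, 3 PDA, 14 GG, 5 PA) with FGFR1 duplication
#' confined to DNT at a prevalence of 5/12 by default.  Per-group
#' duplicated counts are deterministic (\code{round(n * prevalence)});
#' which samples carry the duplication is randomized.  Duplicated samples
#' draw their duplicated-cell fraction uniformly from
#' \code{duplicatedFractionRange} (default 0.75 to 1, the clonal band where
#' observed duplicated CNVs cluster); reference concentrations are drawn
#' log-uniformly over \code{referenceConcRange}, whose default spans
#' sub-threshold FFPE extractions (2 copies/\eqn{\mu}l) to well-preserved
#' material (200 copies/\eqn{\mu}l).
#'
#' @param nPerGroup named integer vector, samples per diagnosis.
#' @param duplicationPrevalence named numeric vector, per-diagnosis
#'   duplication prevalence.
#' @param referenceConcRange range of the log-uniform reference
#'   concentration draw, copies/\eqn{\mu}l.
#' @param duplicatedFractionRange range of the duplicated-cell fraction for
#'   duplicated samples.
#' @param nWells wells per channel and sample.
#' @param dropletsPerWell,dropletRange,volumeNl as in [simulateSample()].
#' @param seed optional integer seed for reproducibility.
#' @return A list with \code{wells} (wells-schema data.frame) and
#'   \code{truth} (one row per sample: \code{sample_id}, \code{diagnosis},
#'   \code{true_fraction}, \code{reference_conc}, \code{degradation},
#'   \code{expected_call}).
#' @examples
#' coh <- simulateCohort(seed = 1)
#' table(coh$truth$diagnosis, coh$truth$expected_call)
#' @export
simulateCohort <- function(nPerGroup = c(DNT = 12L, PTO = 2L, PDA = 3L,
                                         GG = 14L, PA = 5L),
                           duplicationPrevalence = c(DNT = 5 / 12, PTO = 0,
                                                     PDA = 0, GG = 0,
                                                     PA = 0),
                           referenceConcRange = c(2, 200),
                           duplicatedFractionRange = c(0.75, 1),
                           nWells = 1L, dropletsPerWell = NULL,
                           dropletRange = c(7177L, 47840L), volumeNl = 1,
                           seed = NULL) {
  stopifnot(all(nPerGroup >= 0), !is.null(names(nPerGroup)))
  if (!is.null(seed)) set.seed(seed)
  truth <- do.call(rbind, lapply(names(nPerGroup), function(dx) {
    n <- nPerGroup[[dx]]
    if (n == 0L) return(NULL)
    prev <- if (dx %in% names(duplicationPrevalence))
      duplicationPrevalence[[dx]] else 0
    nDup <- round(n * prev)
    dup <- rep(FALSE, n)
    dup[sample.int(n, nDup)] <- TRUE
    data.frame(
      sample_id = sprintf("%s%02d", dx, seq_len(n)),
      diagnosis = dx,
      true_fraction = ifelse(dup,
        stats::runif(n, duplicatedFractionRange[1L],
                     duplicatedFractionRange[2L]), 0),
      reference_conc = exp(stats::runif(n, log(referenceConcRange[1L]),
                                        log(referenceConcRange[2L]))),
      degradation = 1,
      stringsAsFactors = FALSE
    )
  }))
  truth$expected_call <- vapply(seq_len(nrow(truth)), function(i)
    expectedCall(truth$true_fraction[i], truth$reference_conc[i],
                 truth$degradation[i]), character(1))
  wells <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
    simulateSample(truth$sample_id[i], truth$true_fraction[i],
                   truth$reference_conc[i], nWells = nWells,
                   dropletsPerWell = dropletsPerWell,
                   dropletRange = dropletRange, volumeNl = volumeNl,
                   degradation = truth$degradation[i])))
  rownames(wells) <- rownames(truth) <- NULL
  list(wells = wells, truth = truth)
}
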