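# Synthetic droplet generator: partitioning noise model and cohort plumbing.

test_that("simulated wells follow binomial partitioning moments", {
  set.seed(41)
  expect_identical(simulateWell(0, 15000)$n_positive, 0L)
  expect_error(simulateWell(-1, 15000), "non-negative")
  # conc 50 copies/ul, 1 nL droplets: p = 1 - e^-0.05
  k <- replicate(10000, simulateWell(50, 15000)$n_positive)
  expect_equal(mean(k), 15000 * (1 - exp(-0.05)), tolerance = 0.002)
  expect_equal(sd(k), sqrt(15000 * (1 - exp(-0.05)) * exp(-0.05)),
               tolerance = 0.05)
  # saturation limit
  expect_identical(simulateWell(1e9, 1000)$n_positive, 1000L)
})

test_that("sample simulation encodes the mixture model in expectation", {
  set.seed(42)
  # f = 0.25 on a 40 copies/ul background: expected target 45, CNV 2.25
  wells <- do.call(rbind, lapply(1:400, function(i)
    simulateSample(paste0("S", i), 0.25, 40, dropletsPerWell = 15000)))
  q <- quantifySamples(wells)
  expect_equal(mean(q$conc_copies_per_ul[q$channel == "FAM"]), 45,
               tolerance = 0.01)
  expect_equal(mean(q$conc_copies_per_ul[q$channel == "HEX"]), 40,
               tolerance = 0.01)
  calls <- callSamples(wells)
  expect_equal(mean(calls$cnv), 2.25, tolerance = 0.01)
})

test_that("shared degradation cancels in the CNV ratio", {
  runCnv <- function(degr, seed) {
    set.seed(seed)
    wells <- do.call(rbind, lapply(1:300, function(i)
      simulateSample(paste0("S", i), 0, 100, dropletsPerWell = 15000,
                     degradation = degr)))
    mean(callSamples(wells)$cnv)
  }
  expect_equal(runCnv(1, 43), 2, tolerance = 0.01)
  expect_equal(runCnv(0.5, 44), 2, tolerance = 0.01)
})

test_that("channel imbalance injects the low-CNV artefact", {
  set.seed(45)
  wells <- do.call(rbind, lapply(1:200, function(i)
    simulateSample(paste0("S", i), 0, 100, dropletsPerWell = 15000,
                   channelImbalance = 0.75)))
  expect_equal(mean(callSamples(wells)$cnv), 1.5, tolerance = 0.01)
  # a stronger imbalance at high droplet counts pushes CNVmax below 1.5
  art <- callSamples(simulateSample("A1", 0, 120, nWells = 4,
                                    dropletsPerWell = 15000,
                                    channelImbalance = 0.65))
  expect_match(art$flags, "low_cnv_artefact")
})

test_that("cohort generator reproduces the study composition and truth", {
  coh <- simulateCohort(seed = 7)
  expect_identical(nrow(coh$truth), 36L)
  expect_identical(as.vector(table(factor(coh$truth$diagnosis,
    levels = c("DNT", "PTO", "PDA", "GG", "PA")))),
    c(12L, 2L, 3L, 14L, 5L))
  # duplication confined to DNT at deterministic prevalence 5/12
  dup <- coh$truth$true_fraction > 0
  expect_identical(sum(dup & coh$truth$diagnosis == "DNT"), 5L)
  expect_identical(sum(dup & coh$truth$diagnosis != "DNT"), 0L)
  # linked tables share ids; wells carry both channels per sample
  expect_setequal(unique(coh$wells$sample_id), coh$truth$sample_id)
  # at high concentration every duplicated sample is expected duplicated
  rich <- simulateCohort(seed = 8, referenceConcRange = c(50, 200))
  expect_identical(
    sum(rich$truth$expected_call == "duplicated" &
          rich$truth$diagnosis == "DNT"), 5L)
  expect_identical(sum(rich$truth$expected_call == "duplicated" &
                         rich$truth$diagnosis != "DNT"), 0L)
  # all-zero prevalence: nothing expected duplicated
  none <- simulateCohort(seed = 9,
                         duplicationPrevalence = c(DNT = 0, PTO = 0,
                                                   PDA = 0, GG = 0, PA = 0))
  expect_false(any(none$truth$expected_call == "duplicated"))
  # sub-threshold concentrations are expected inconclusive
  expect_identical(none$truth$expected_call[none$truth$reference_conc < 5],
    rep("inconclusive", sum(none$truth$reference_conc < 5)))
})

test_that("fixed seeds reproduce the cohort exactly", {
  a <- simulateCohort(seed = 123)
  b <- simulateCohort(seed = 123)
  expect_identical(a, b)
  c <- simulateCohort(seed = 124)
  expect_false(identical(a$wells, c$wells))
})
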