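# CNV computation, interval propagation and the dual-threshold call rule.

test_that("CNV is twice the target/reference concentration ratio", {
  expect_equal(cnv(computeCnv(37.5, 37.5)), 2)
  expect_equal(cnv(computeCnv(45, 40)), 2.25)     # ratio 1.125
  expect_equal(cnv(computeCnv(60, 40)), 3)        # ratio 1.5, fully clonal
  expect_error(computeCnv(50, 0), "reference")
})

test_that("CNV bounds bracket the estimate and bound_ratio is conservative", {
  t <- estimateConcentration(15000, 1060, sampleId = "S1", channel = "FAM")
  r <- estimateConcentration(15000, 730, sampleId = "S1", channel = "HEX")
  ld <- computeCnv(t, r, ciMethod = "log_delta")
  br <- computeCnv(t, r, ciMethod = "bound_ratio")
  expect_equal(cnv(ld), 2 * concentration(t) / concentration(r))
  expect_equal(cnv(ld), cnv(br))
  expect_true(cnvMin(ld) < cnv(ld) && cnv(ld) < cnvMax(ld))
  expect_lte(cnvMin(br), cnvMin(ld))
  expect_gte(cnvMax(br), cnvMax(ld))
  # log-scale symmetry of the delta interval
  expect_equal(log(cnvMax(ld)) - log(cnv(ld)),
               log(cnv(ld)) - log(cnvMin(ld)), tolerance = 1e-10)
})

test_that("saturated or empty channels refuse a CNV", {
  sat <- estimateConcentration(1000, 1000, channel = "FAM")
  ok <- estimateConcentration(15000, 730, channel = "HEX")
  expect_error(computeCnv(sat, ok), "saturated")
  zero <- estimateConcentration(15000, 0, channel = "FAM")
  expect_error(computeCnv(zero, ok), "target")
})

test_that("dual-threshold rule maps estimates to calls deterministically", {
  th <- CallThresholds()
  # clear duplication at adequate concentration
  call <- classify(fixedCnv(2.9, 2.6, 3.2), fixedConc(50),
                   fixedConc(48, channel = "HEX"), th)
  expect_identical(callStatus(call), "duplicated")
  expect_length(callFlags(call), 0L)
  # low target concentration is inconclusive regardless of CNV
  low <- classify(fixedCnv(2.9, 2.6, 3.2), fixedConc(3),
                  fixedConc(48, channel = "HEX"), th)
  expect_identical(callStatus(low), "inconclusive")
  expect_true("low_target_conc" %in% callFlags(low))
  # disagreeing cutoffs are borderline-inconclusive, never non-duplicated
  bord <- classify(fixedCnv(2.3, 1.9, 2.8), fixedConc(50),
                   fixedConc(48, channel = "HEX"), th)
  expect_identical(callStatus(bord), "inconclusive")
  expect_true("borderline" %in% callFlags(bord))
  # plain diploid sample
  neg <- classify(fixedCnv(2.0, 1.85, 2.16), fixedConc(50),
                  fixedConc(48, channel = "HEX"), th)
  expect_identical(callStatus(neg), "non_duplicated")
  expect_length(callFlags(neg), 0L)
})

test_that("cutoffs are strict inequalities", {
  th <- CallThresholds()
  at <- classify(fixedCnv(2.25, 2.0, 2.5), fixedConc(50),
                 fixedConc(48, channel = "HEX"), th)
  expect_false(callStatus(at) == "duplicated")
})

test_that("low CNVmax flags deletion and artefact only at adequate DNA", {
  th <- CallThresholds()
  del <- classify(fixedCnv(1.8, 1.65, 1.95), fixedConc(40),
                  fixedConc(44, channel = "HEX"), th)
  expect_identical(callStatus(del), "non_duplicated")
  expect_true("possible_deletion" %in% callFlags(del))
  expect_false("low_cnv_artefact" %in% callFlags(del))
  art <- classify(fixedCnv(1.3, 1.2, 1.42), fixedConc(40),
                  fixedConc(60, channel = "HEX"), th)
  expect_true(all(c("possible_deletion", "low_cnv_artefact") %in%
                    callFlags(art)))
  # with low DNA the same CNV is not interpreted as deletion
  lowDna <- classify(fixedCnv(1.8, 1.65, 1.95), fixedConc(2),
                     fixedConc(3, channel = "HEX"), th)
  expect_identical(callStatus(lowDna), "inconclusive")
  expect_false("possible_deletion" %in% callFlags(lowDna))
})

test_that("low-concentration flags force inconclusive by construction", {
  expect_error(new("SampleCall", sampleId = "S1", status = "duplicated",
                   flags = "low_target_conc", reasons = character(0),
                   cnv = NULL), "inconclusive")
})

test_that("tumor fraction inverts the monoallelic mixture model", {
  expect_equal(tumorFraction(2.25), 0.25)
  expect_equal(tumorFraction(2), 0)
  expect_equal(tumorFraction(3), 1)
  expect_equal(tumorFraction(c(1.5, 3.4)), c(0, 1))   # clamped
  expect_equal(tumorFraction(fixedCnv(2.5, 2.3, 2.7)), 0.5)
})

test_that("pipeline recovers the generating fraction within its interval", {
  set.seed(31)
  for (f in c(0, 0.5, 1)) {
    inCi <- vapply(1:40, function(i) {
      row <- callSamples(simulateSample("S1", trueFraction = f,
                                        referenceConc = 80, nWells = 4,
                                        dropletsPerWell = 15000))
      tumorFraction(row$cnv_min) <= f & f <= tumorFraction(row$cnv_max)
    }, logical(1))
    # nominal ~95% interval coverage; 0.85 keeps the small-n check stable
    expect_gte(mean(inCi), 0.85)
  }
})

test_that("callSamples handles degenerate channels without aborting", {
  wells <- rbind(
    data.frame(sample_id = "SAT", well_id = "W1", channel = c("FAM", "HEX"),
               n_total = 1000L, n_positive = c(1000L, 500L)),
    data.frame(sample_id = "OK", well_id = "W1", channel = c("FAM", "HEX"),
               n_total = 15000L, n_positive = c(800L, 700L))
  )
  calls <- callSamples(wells)
  satRow <- calls[calls$sample_id == "SAT", ]
  expect_true(is.na(satRow$cnv))
  expect_identical(satRow$status, "inconclusive")
  expect_match(satRow$flags, "saturated_well")
  expect_false(is.na(calls$cnv[calls$sample_id == "OK"]))
  # missing channel is a hard error naming the sample
  expect_error(callSamples(wells[wells$channel == "FAM", ]), "HEX")
})
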