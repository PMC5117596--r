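test_that("generated database honors configured composition and labels", {
    cfg <- generatorConfig(nHostProteins = 5, nSymbiontProteins = 3,
                           nVariantFamilies = 0, spectraPerSample = 100)
    db <- generateDatabase(cfg)
    expect_length(db$database, 8L)
    taxon <- S4Vectors::mcols(db$database)$taxon
    expect_identical(sum(taxon == "host"), 5L)
    expect_identical(sum(taxon == "symbiont"), 3L)
    expect_false(anyDuplicated(names(db$database)) > 0)
    lens <- Biostrings::width(db$database)
    expect_true(all(lens >= 150 & lens <= 450))
})

test_that("variant families sit at or above the clustering threshold", {
    cfg <- generatorConfig(nHostProteins = 4, nSymbiontProteins = 3,
                           nVariantFamilies = 2, variantIdentity = 0.95,
                           spectraPerSample = 100, rngSeed = 5L)
    db <- generateDatabase(cfg)
    fam <- as.data.frame(familyMap(db$truth))
    expect_identical(nrow(fam), 2L)
    for (i in seq_len(nrow(fam))) {
        ident <- pairwiseIdentity(
            as.character(db$database[[fam$variant_id[i]]]),
            as.character(db$database[[fam$base_id[i]]]))
        expect_gte(ident, 0.9)
        expect_lt(ident, 1)
    }
    # and they co-cluster at the 0.9 threshold
    grp <- greedyCluster(db$database, threshold = 0.9)
    mm <- membershipMap(grp)
    expect_identical(unname(mm[fam$variant_id]), unname(mm[fam$base_id]))
})

test_that("identical seeds give identical outputs, different seeds differ", {
    cfg <- tinyConfig()
    db1 <- generateDatabase(cfg)
    db2 <- generateDatabase(cfg)
    expect_identical(as.character(db1$database), as.character(db2$database))
    f1 <- tempfile(fileext = ".faa"); f2 <- tempfile(fileext = ".faa")
    writeProteinFasta(db1$database, f1)
    writeProteinFasta(db2$database, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))

    s1 <- simulatePSMs(db1$database, db1$truth, cfg)
    s2 <- simulatePSMs(db2$database, db2$truth, cfg)
    expect_identical(s1$psms, s2$psms)
    cfgB <- tinyConfig(rngSeed = 12L)
    dbB <- generateDatabase(cfgB)
    sB <- simulatePSMs(dbB$database, dbB$truth, cfgB)
    expect_false(identical(s1$psms$peptide, sB$psms$peptide))
})

test_that("per-sample spectra counts and decoy appending follow the config", {
    cfg <- tinyConfig(decoyFractionOfMatches = 0.1)
    db <- generateDatabase(cfg)
    sim <- simulatePSMs(db$database, db$truth, cfg)
    byS <- split(sim$psms, sim$psms$sample_id)
    for (d in byS) {
        expect_identical(sum(!d$is_decoy), 2000L)
        expect_equal(mean(d$is_decoy), 0.1, tolerance = 0.01)
    }
    # decoy scores are stochastically lower than target scores
    expect_gt(mean(sim$psms$score[!sim$psms$is_decoy]),
              mean(sim$psms$score[sim$psms$is_decoy]) + 1)

    cfg0 <- tinyConfig(decoyFractionOfMatches = 0)
    db0 <- generateDatabase(cfg0)
    sim0 <- simulatePSMs(db0$database, db0$truth, cfg0)
    expect_false(any(sim0$psms$is_decoy))
})

test_that("degenerate symbiont fractions behave as configured", {
    cfg <- tinyConfig(conditions = c(none = 0, all = 1), nReplicates = 2)
    db <- generateDatabase(cfg)
    sim <- simulatePSMs(db$database, db$truth, cfg)
    tr <- as.data.frame(truthSamples(sim$truth))
    expect_true(all(tr$realized_fraction[tr$condition == "none"] == 0))
    expect_true(all(tr$realized_fraction[tr$condition == "all"] == 1))
    # spectra of the symbiont-free condition map only to host proteins
    hostSeqs <- as.character(db$database)[
        S4Vectors::mcols(db$database)$taxon == "host"]
    nonePep <- unique(sim$psms$peptide[
        sim$psms$sample_id == "none_r1" & !sim$psms$is_decoy])
    inHost <- vapply(nonePep, function(p)
        any(grepl(p, hostSeqs, fixed = TRUE)), logical(1))
    expect_true(all(inHost))
})

test_that("realized symbiont fractions track the configured fraction", {
    cfg <- generatorConfig(conditions = c(fresh = 0.295),
                           nReplicates = 3, spectraPerSample = 50000,
                           replicateNoiseSd = 0.03, rngSeed = 21L)
    db <- generateDatabase(cfg)
    sim <- simulatePSMs(db$database, db$truth, cfg)
    tr <- as.data.frame(truthSamples(sim$truth))
    expect_true(all(abs(tr$realized_fraction - 0.295) <= 0.10))
    # binomial sampling stays within 3 sd of the perturbed fraction
    binSd <- sqrt(tr$perturbed_fraction * (1 - tr$perturbed_fraction) / 50000)
    expect_true(all(abs(tr$realized_fraction - tr$perturbed_fraction) <=
                    3 * binSd + 1e-12))
})

test_that("fast realized-fraction path matches the generator's noise model", {
    cfg <- generatorConfig(conditions = c(a = 0.3, b = 0.3),
                           nReplicates = 50, spectraPerSample = 10000,
                           replicateNoiseSd = 0.03, rngSeed = 33L)
    fr <- simulateRealizedFractions(cfg)
    expect_identical(nrow(fr), 100L)
    expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
    # mean over many replicates converges to the configured fraction
    expect_equal(mean(fr$fraction), 0.3, tolerance = 0.01)
    # spread is dominated by the multiplicative noise (sd ~ 0.3 * 0.03)
    expect_gt(sd(fr$fraction), 0.004)
    expect_lt(sd(fr$fraction), 0.02)
})

test_that("invalid configurations fail with the offending field named", {
    expect_error(generatorConfig(nHostProteins = 0), "nHostProteins")
    expect_error(generatorConfig(variantIdentity = 1.2), "variantIdentity")
    expect_error(generatorConfig(proteinLengthRange = c(10, 50)),
                 "proteinLengthRange")
    expect_error(generatorConfig(decoyFractionOfMatches = 1),
                 "decoyFractionOfMatches")
    expect_error(generatorConfig(conditions = c(0.3, 0.2)), "conditions")
})

test_that("simulation refuses a demanded taxon with no proteins", {
    cfg <- tinyConfig()
    db <- generateDatabase(cfg)
    hostOnly <- db$database[S4Vectors::mcols(db$database)$taxon == "host"]
    truth <- db$truth
    expect_error(simulatePSMs(hostOnly, truth, cfg), "symbiont")
})

test_that("fixture bundles round-trip exactly and load end-to-end", {
    cfg <- tinyConfig()
    db <- generateDatabase(cfg)
    sim <- simulatePSMs(db$database, db$truth, cfg)
    dir <- tempfile("bundle")
    writeFixtureBundle(db$database, sim$psms, sim$truth, dir)
    back <- readFixtureBundle(dir)

    expect_identical(as.character(back$database), as.character(db$database))
    expect_identical(S4Vectors::mcols(back$database)$taxon,
                     S4Vectors::mcols(db$database)$taxon)
    expect_identical(back$psms$peptide, sim$psms$peptide)
    expect_identical(back$psms$score, sim$psms$score)  # exact, full precision
    expect_identical(back$psms$is_decoy, sim$psms$is_decoy)
    expect_equal(as.data.frame(truthSamples(back$truth)),
                 as.data.frame(truthSamples(sim$truth)))
    expect_equal(unname(back$truth@probs), unname(sim$truth@probs))

    # the bundle drives the full pipeline without errors
    qm <- suppressWarnings(quantifyHolobiont(back$psms, back$database,
                                             design = back$design))
    expect_s4_class(qm, "QuantMatrix")
    expect_identical(ncol(qm), 6L)

    expect_error(writeFixtureBundle(Biostrings::AAStringSet(), sim$psms,
                                    sim$truth, tempfile()),
                 "empty")
})
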