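test_that("pairwise identity matches hand-aligned examples", {
    expect_equal(pairwiseIdentity("ACDEFGHIK", "ACDEFGHIK"), 1)
    expect_equal(pairwiseIdentity("ACDEFGHIK", "ACDEFGHIR"), 8 / 9)
    expect_equal(pairwiseIdentity("ACDEF", "ACDEFGGGGG"), 1)  # containment
    # symmetric
    set.seed(3)
    a <- randomProteinSeq(40); b <- randomProteinSeq(55)
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
    expect_error(pairwiseIdentity("", "ACD"), "non-empty")
    expect_error(pairwiseIdentity("AC1D", "ACD"), "non-amino-acid")
})

test_that("X residues never count as identical", {
    expect_equal(pairwiseIdentity("AXDEF", "AXDEF"), 4 / 5)
})

test_that("greedy clustering handles forced cases", {
    s <- randomProteinSeq(30)
    three <- setNames(c(s, s, s), c("a", "b", "c"))
    grp <- greedyCluster(three, threshold = 0.9)
    expect_length(grp, 1L)
    expect_identical(sort(unname(unlist(memberIds(grp)))), c("a", "b", "c"))

    set.seed(17)
    seqs <- randomProteinSet(2, lenRange = c(100, 100), nVariants = 1,
                             identity = 0.95)
    # p01 (100 aa), p01v (95% identical), p02 (unrelated)
    grp2 <- greedyCluster(seqs[c("p01", "p01v", "p02")], threshold = 0.9)
    mm <- membershipMap(grp2)
    expect_identical(unname(mm[["p01v"]]), "p01")
    expect_identical(unname(mm[["p02"]]), "p02")
    expect_identical(sort(groupIds(grp2)), c("p01", "p02"))

    distinct <- randomProteinSet(5, lenRange = c(30, 50))
    grpAll <- greedyCluster(distinct, threshold = 1)
    expect_length(grpAll, length(distinct))
})

test_that("groups satisfy the seed invariants", {
    set.seed(23)
    seqs <- randomProteinSet(8, lenRange = c(40, 90), nVariants = 3)
    grp <- greedyCluster(seqs, threshold = 0.9)
    w <- nchar(seqs)
    for (i in seq_along(grp)) {
        mem <- unlist(memberIds(grp)[i])
        seed <- seedIds(grp)[i]
        expect_true(seed %in% mem)
        expect_true(all(w[mem] <= w[seed]))
        for (m in setdiff(mem, seed))
            expect_gte(pairwiseIdentity(seqs[[seed]], seqs[[m]]), 0.9)
    }
})

test_that("greedy clustering agrees with the brute-force oracle", {
    set.seed(31)
    for (i in 1:20) {
        n <- sample(3:12, 1)
        seqs <- randomProteinSet(n, lenRange = c(30, 60),
                                 nVariants = sample(0:min(3, n), 1))
        grp <- greedyCluster(seqs, threshold = 0.9)
        expect_identical(membershipMap(grp)[names(seqs)],
                         oracleGreedyCluster(seqs, 0.9))
    }
})

test_that("peptide uniqueness is assessed at the group level", {
    db <- c(A1 = "MSSSSKAAAQRLLLLK", A2 = "MSSSSKAAAQRLLLLR",
            B = "MWWWWKDDDQRVVVVK")
    grp <- greedyCluster(db, threshold = 0.9)  # A1+A2 cluster, B alone
    expect_length(grp, 2L)
    u <- reassessUniqueness(c("LLLLK", "MSSSSK", "DDDQR"), grp)
    # peptide in one protein only -> unique to its group
    expect_identical(u$status[u$peptide == "LLLLK"], "unique")
    # peptide in two proteins of the same group -> still unique
    expect_identical(u$status[u$peptide == "MSSSSK"], "unique")
    expect_identical(u$status[u$peptide == "DDDQR"], "unique")

    dbX <- c(A = "MSSSSKAAAQRLLLLK", B = "MTTTTKAAAQRVVVVK")
    grpX <- greedyCluster(dbX, threshold = 0.99)
    uX <- reassessUniqueness("AAAQR", grpX)
    expect_identical(uX$status, "shared")
    expect_setequal(unlist(uX$groups), c("A", "B"))

    expect_warning(uo <- reassessUniqueness("WWWWWWWW", grpX), "orphan")
    expect_identical(uo$status, "orphan")
})

test_that("shared spectra are balanced by unique evidence", {
    db <- c(A = "MSSSSKAAAQRLLLLK", B = "MTTTTKAAAQRVVVVK")
    grp <- greedyCluster(db, threshold = 0.99)
    uniq <- reassessUniqueness(c("LLLLK", "VVVVK", "AAAQR", "MSSSSK"), grp)

    # unique evidence 2 vs 1, shared count 6 -> allocations 4 and 2
    pc <- data.frame(peptide = c("LLLLK", "LLLLK", "VVVVK", "AAAQR"),
                     sample_id = "s1", count = c(1, 1, 1, 6))
    bal <- balanceSpectra(pc, uniq)
    expect_equal(bal["A", "s1"], 2 + 4)
    expect_equal(bal["B", "s1"], 1 + 2)

    # all-zero unique evidence -> equal split
    pc0 <- data.frame(peptide = "AAAQR", sample_id = "s1", count = 6)
    bal0 <- balanceSpectra(pc0, uniq)
    expect_equal(bal0["A", "s1"], 3)
    expect_equal(bal0["B", "s1"], 3)

    # one-sided unique evidence takes everything
    pc1 <- data.frame(peptide = c("MSSSSK", "AAAQR"), sample_id = "s1",
                      count = c(3, 6))
    bal1 <- balanceSpectra(pc1, uniq)
    expect_equal(bal1["A", "s1"], 9)
    expect_equal(bal1["B", "s1"], 0)

    expect_error(balanceSpectra(
        data.frame(peptide = "LLLLK", sample_id = "s1", count = -1), uniq),
        ">= 0")
})

test_that("balancing conserves per-sample spectral totals", {
    set.seed(53)
    for (i in 1:10) {
        nGrp <- sample(2:6, 1)
        nPep <- sample(3:12, 1)
        groups <- sprintf("g%d", seq_len(nGrp))
        # random sharing structure, including occasional all-shared cases
        uniq <- S4Vectors::DataFrame(
            peptide = sprintf("PEP%d", seq_len(nPep)),
            status = NA_character_,
            groups = IRanges::CharacterList(lapply(seq_len(nPep), function(j)
                sample(groups, sample(1:nGrp, 1)))))
        uniq$status <- ifelse(lengths(uniq$groups) == 1L, "unique", "shared")
        pc <- expand.grid(peptide = uniq$peptide,
                          sample_id = c("s1", "s2"),
                          stringsAsFactors = FALSE)
        pc$count <- rpois(nrow(pc), 4)
        bal <- balanceSpectra(pc, uniq)
        tot <- tapply(pc$count, pc$sample_id, sum)
        expect_equal(colSums(bal)[names(tot)], tot, tolerance = 1e-9,
                     ignore_attr = TRUE)
    }
})

test_that("merging groups never loses unique peptides", {
    db <- c(A1 = "MSSSSKAAAQRLLLLK", A2 = "MSSSSKAAAQRLLLLR",
            B = "MWWWWKDDDQRVVVVK")
    peps <- c("MSSSSK", "AAAQR", "LLLLK", "LLLLR", "DDDQR")
    split2 <- greedyCluster(db, threshold = 0.999)  # A1, A2 apart
    merged <- greedyCluster(db, threshold = 0.9)    # A1+A2 together
    uSplit <- reassessUniqueness(peps, split2)
    uMerged <- reassessUniqueness(peps, merged)
    nUniqueSplit <- sum(uSplit$status == "unique" &
                        unlist(lapply(uSplit$groups, `[`, 1)) %in%
                            c("A1", "A2"))
    mergedSeed <- membershipMap(merged)[["A1"]]
    nUniqueMerged <- sum(uMerged$status == "unique" &
                         unlist(lapply(uMerged$groups, `[`, 1)) == mergedSeed)
    expect_gte(nUniqueMerged, nUniqueSplit)
})

test_that("nSpC normalization follows the NSAF formula", {
    cnt <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
    qm <- computeNSpC(cnt, seedLengths = c(g1 = 100, g2 = 400),
                      taxon = c(g1 = "host", g2 = "host"),
                      universe = "all", scale = "fraction")
    expect_equal(unname(nspc(qm)[, "s1"]), c(2 / 3, 1 / 3))

    # equal counts, equal lengths -> even split; per_10000 scale
    cnt2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s1"))
    qm2 <- computeNSpC(cnt2, seedLengths = c(a = 50, b = 50),
                       taxon = c(a = "host", b = "host"), universe = "all")
    expect_equal(unname(nspc(qm2)[, "s1"]), c(5000, 5000))

    # single-group universe -> 1 regardless of counts
    cnt3 <- matrix(7, 1, 2, dimnames = list("only", c("s1", "s2")))
    qm3 <- computeNSpC(cnt3, seedLengths = c(only = 123),
                       taxon = c(only = "host"), universe = "all",
                       scale = "fraction")
    expect_equal(unname(nspc(qm3)["only", ]), c(1, 1))
})

test_that("normalization universes behave and zero signal warns", {
    cnt <- matrix(c(10, 20, 5), 3, 1,
                  dimnames = list(c("h", "s", "c"), "s1"))
    L <- c(h = 100, s = 100, c = 100)
    tx <- c(h = "host", s = "symbiont", c = "contaminant")
    qh <- computeNSpC(cnt, L, tx, universe = "host", scale = "per_10000")
    expect_equal(nspc(qh)["h", "s1"], 10000)
    # rows outside the universe share the same scale factor
    expect_equal(nspc(qh)["s", "s1"], 20000)
    qholo <- computeNSpC(cnt, L, tx, universe = "holobiont",
                         scale = "fraction")
    expect_equal(sum(nspc(qholo)[c("h", "s"), "s1"]), 1, tolerance = 1e-12)
    expect_equal(nspc(qholo)["c", "s1"], 5 / 30)

    zero <- matrix(0, 1, 1, dimnames = list("h", "s1"))
    expect_warning(qz <- computeNSpC(zero, c(h = 10), c(h = "host")),
                   "zero total SAF")
    expect_equal(nspc(qz)["h", "s1"], 0)
})

test_that("taxon fractions are nSpC ratios with contaminants excluded", {
    cnt <- matrix(c(80, 20, 30), 3, 1,
                  dimnames = list(c("h", "s", "c"), "s1"))
    L <- c(h = 100, s = 100, c = 100)
    tx <- c(h = "host", s = "symbiont", c = "contaminant")
    qm <- computeNSpC(cnt, L, tx)
    expect_equal(taxonFractions(qm)$fraction, 0.2)

    # no symbiont signal -> 0%
    cnt0 <- matrix(c(80, 0), 2, 1, dimnames = list(c("h", "s"), "s1"))
    qm0 <- computeNSpC(cnt0, L[1:2], tx[1:2])
    expect_equal(taxonFractions(qm0)$fraction, 0)

    # fraction is invariant to the normalization universe and scale
    qmHost <- computeNSpC(cnt, L, tx, universe = "host", scale = "fraction")
    expect_equal(taxonFractions(qmHost)$fraction, 0.2)
})
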