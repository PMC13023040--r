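# Screen statistics: guide assignment, filtering, Fisher tests, directional
# ranking, RRA, permutation p-values, library integration and hit calling.

toyManifest <- function(n = 4L) {
  data.frame(guide_id = sprintf("g%02d", 1:n),
             gene = rep(c("GENEA", "GENEB"), length.out = n),
             category = "gene",
             guide_sequence = c("ACGTACGTACGTACGTACGT",
                                "TTTTCCCCGGGGAAAATTTT",
                                "GATCGATCGATCGATCGATC",
                                "CCCGGGAAATTTCCCGGGAA")[1:n],
             guide_offset = 0L, stringsAsFactors = FALSE)
}

test_that("reads assign to guides only on exact positional match", {
  man <- toyManifest()
  reads <- c(paste0(man$guide_sequence[1], "GTTTT"),   # exact
             paste0(man$guide_sequence[2], "GTTTT"))   # exact
  reads[3] <- paste0(sub("^A", "C", man$guide_sequence[1]), "GTTTT")  # 1 mm
  res <- assignReadsToGuides(reads, man)
  expect_identical(res$assignments$guide_id[1], "g01")
  expect_identical(res$assignments$guide_id[2], "g02")
  expect_true(is.na(res$assignments$guide_id[3]))
  expect_identical(unname(res$counts[["unmatched"]]), 1L)
  dup <- man
  dup$guide_sequence[2] <- dup$guide_sequence[1]
  expect_error(assignReadsToGuides(reads, dup), "duplicate")
})

test_that("generated guide reads assign perfectly round-trip", {
  man <- genScreenManifest(screenSpec(nGenes = 20, nMirna = 5,
                                      nNontarget = 10), seed = 3)
  reads <- genGuideReads(man, nPerGuide = 2L, seed = 4)
  res <- assignReadsToGuides(reads, man)
  expect_identical(res$assignments$guide_id, names(reads))
  expect_identical(unname(res$counts[["unmatched"]]), 0L)
})

test_that("guide filtering applies the read-support boundary", {
  counts <- data.frame(
    guide_id = c("g01", "g02", "g03"),
    pattern = "1bp Ins",
    count = c(10L, 11L, 0L))
  man <- toyManifest(3L)
  rec <- guideRecords(counts, man)
  flt <- filterGuides(rec)
  expect_identical(flt$kept$guide_id, "g02")           # 11 reads kept
  expect_setequal(flt$excluded$guide_id, c("g01", "g03"))  # 10 reads out
  expect_identical(flt$excluded$reason[flt$excluded$guide_id == "g03"],
                   "no_detectable_mutations")
  # 500 reads but all unedited: total_edited is 0 -> excluded
  rec2 <- rec
  rec2[rec2$guide_id == "g02", repairPatterns()] <- 0L
  rec2$total_edited <- 0L
  expect_identical(nrow(filterGuides(rec2)$kept), 0L)
})

test_that("Fisher tails and log2FC match the enumeration oracle", {
  r <- guideOutcomeTest(30, 70, 10, 90)
  expect_equal(r$log2fc, log2(0.30 / 0.10), tolerance = 1e-12)
  o <- oracleFisherTails(30, 70, 10, 90)
  expect_equal(r$p_right, o$p_right, tolerance = 1e-12)
  expect_equal(r$p_left, o$p_left, tolerance = 1e-12)
  # identical frequencies: no effect
  expect_equal(guideOutcomeTest(10, 90, 10, 90)$log2fc, 0)
  # zero cell: pseudo-counted effect, small left tail
  z <- guideOutcomeTest(0, 50, 10, 90)
  oz <- oracleFisherTails(0, 50, 10, 90)
  expect_lt(z$log2fc, 0)
  expect_true(is.finite(z$log2fc))
  expect_equal(z$p_left, oz$p_left, tolerance = 1e-12)
  expect_error(guideOutcomeTest(5, 5, 0, 0), "empty control")
})

test_that("directional ranking prioritizes consistent guides and penalizes the rest", {
  st <- data.frame(guide_id = c("g1", "g2", "g3", "g4"),
                   gene = "G", category = "gene",
                   log2fc = c(-1, 0.5, 0.2, 0.8),
                   p_left = c(0.001, 0.6, 0.4, 0.9),
                   p_right = c(0.999, 0.4, 0.6, 0.1))
  rk <- rankGuidesDirectional(st, "promoting")
  expect_identical(rk$guide_id[1], "g1")
  expect_equal(rk$rank[1], 1 / 4)
  # inconsistent guides: appended in descending p_left order
  expect_identical(rk$guide_id[-1], c("g4", "g2", "g3"))
  # all inconsistent -> ordering purely by descending tail p
  st2 <- st
  st2$log2fc <- abs(st2$log2fc)
  rk2 <- rankGuidesDirectional(st2, "promoting")
  expect_identical(rk2$guide_id, st$guide_id[order(-st$p_left)])
})

test_that("rank tie-breaks are deterministic over all permutations of tied guides", {
  st <- data.frame(guide_id = c("gA", "gB", "gC"),
                   gene = "G", category = "gene",
                   log2fc = c(-0.2, -0.9, -0.9),
                   p_left = c(0.05, 0.05, 0.05),
                   p_right = 0.95)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    rk <- rankGuidesDirectional(st[p, ], "promoting")
    # tie in p: larger |log2fc| first, then guide_id lexically
    expect_identical(rk$guide_id, c("gB", "gC", "gA"))
  }
})

test_that("RRA scores equal the beta order-statistic closed forms", {
  expect_equal(rraGeneScore(0.2), 0.2, tolerance = 1e-12)
  expect_equal(rraGeneScore(c(0.1, 0.5)), min(1 - 0.9^2, pbeta(0.5, 2, 1)),
               tolerance = 1e-12)
  expect_equal(rraGeneScore(c(0.1, 0.5)), 0.19, tolerance = 1e-12)
  expect_equal(rraGeneScore(rep(1, 6)), 1)
})

test_that("permutation p-values match the analytic null for k = 1 and are bounded", {
  set.seed(8)
  null1 <- rraNullDistribution(1L, 20000L)
  for (rho in c(0.02, 0.2, 0.5)) {
    p <- permutationPvalue(rho, 1L, null = null1)
    mcSd <- sqrt(rho * (1 - rho) / 20000)
    expect_lt(abs(p - rho), 3 * mcSd + 2 / 20001)
  }
  expect_gte(permutationPvalue(0, 1L, null = null1), 1 / 20001)
  expect_equal(permutationPvalue(1, 3L, nPerm = 500L), 1, tolerance = 3 / 501)
})

test_that("library integration matches the weighted Stouffer closed form", {
  sc <- function(p, lfc) data.frame(gene = "G", pattern = "1bp Ins",
                                    direction = "promoting", n_guides = 6L,
                                    rra_rho = 0.1, p_empirical = p,
                                    log2fc = lfc)
  m <- integrateLibraries(sc(0.05, 1), sc(0.05, 1), 1, 1)
  zc <- 2 * qnorm(0.95) / sqrt(2)
  expect_equal(m$p_combined, 1 - pnorm(zc), tolerance = 1e-12)
  expect_equal(round(m$p_combined, 4), 0.0100)
  # equal effects combine to themselves under any weights
  m2 <- integrateLibraries(sc(0.2, 0.42), sc(0.01, 0.42), 0.3, 1.7)
  expect_equal(m2$combined_log2fc, 0.42)
  # symmetry under swapping libraries with their weights
  mAB <- integrateLibraries(sc(0.2, 0.1), sc(0.01, 0.9), 0.3, 1.7)
  mBA <- integrateLibraries(sc(0.01, 0.9), sc(0.2, 0.1), 1.7, 0.3)
  expect_equal(mAB$combined_log2fc, mBA$combined_log2fc)
  expect_equal(mAB$p_combined, mBA$p_combined)
  # weight limit: combined values approach library B's
  mLim <- integrateLibraries(sc(0.2, 0.1), sc(0.01, 0.9), 1e-9, 1)
  expect_equal(mLim$combined_log2fc, 0.9, tolerance = 1e-6)
  expect_equal(mLim$p_combined, 0.01, tolerance = 1e-3)
})

test_that("hit calling applies strict thresholds", {
  gs <- data.frame(gene = c("a", "b", "c"),
                   combined_log2fc = c(0.6, 0.5, 1.2),
                   p_combined = c(0.01, 0.01, 0.06))
  h <- callHits(gs)
  expect_identical(h$is_hit, c(TRUE, FALSE, FALSE))
})

test_that("gene scores separate a strong planted effect from the background", {
  spc <- screenSpec(nGenes = 40, nMirna = 0, nNontarget = 25,
                    plantedEffects = data.frame(gene = "GENE00005",
                                                pattern = "MH Small Del",
                                                fc = 3))
  ds <- genScreenDataset(spc, seed = 21)
  rec <- filterGuides(guideRecords(ds$counts, ds$manifest))$kept
  sc <- screenScores(rec, "MH Small Del", "inhibiting", nPerm = 2000L)
  expect_identical(sc$gene[which.min(sc$rra_rho)], "GENE00005")
  expect_lt(sc$p_empirical[sc$gene == "GENE00005"], 0.01)
  expect_gt(sc$log2fc[sc$gene == "GENE00005"], 0.5)
})
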