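# Generators: determinism, planted microhomology, spectrum round-trips,
# time-course composition and screen count tables.

test_that("generators are seed-deterministic", {
  l1 <- genTargetLocus(seed = 42)
  l2 <- genTargetLocus(seed = 42)
  expect_identical(as.character(refSequence(l1)), as.character(refSequence(l2)))
  expect_false(identical(as.character(refSequence(genTargetLocus(seed = 43))),
                         as.character(refSequence(l1))))
  sp <- fullSpectrum()
  r1 <- genEditedReads(l1, sp, 100, seed = 5)
  r2 <- genEditedReads(l2, sp, 100, seed = 5)
  expect_identical(as.character(r1), as.character(r2))
  d1 <- genScreenDataset(screenSpec(nGenes = 10, nMirna = 2, nNontarget = 5),
                         seed = 9)
  d2 <- genScreenDataset(screenSpec(nGenes = 10, nMirna = 2, nNontarget = 5),
                         seed = 9)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$manifest, d2$manifest)
})

test_that("planted microhomology sites close the loop with the detector", {
  loc <- genTargetLocus(mhDesign = data.frame(offset = c(-3, -5),
                                              len = c(6, 8), mh = c(2, 4)),
                        seed = 13)
  sites <- attr(loc, "mh_sites")
  ref <- as.character(refSequence(loc))
  for (i in seq_len(nrow(sites))) {
    d <- leftNormalize(data.frame(kind = "deletion", start = sites$start[i],
                                  length = sites$len[i], seq = "", ref = ""),
                       ref)
    expect_identical(detectMicrohomology(ref, d$start, d$length), sites$mh[i])
  }
  # plain locus: no design, NGG PAM present at the annotated position
  plain <- genTargetLocus(seed = 3)
  expect_identical(substr(as.character(refSequence(plain)), 72, 73), "GG")
  expect_error(genTargetLocus(mhDesign = data.frame(offset = -2, len = 4,
                                                    mh = 6), seed = 1),
               "incompatible")
})

test_that("an all-unedited spectrum reproduces the reference", {
  loc <- genTargetLocus(seed = 2)
  sp <- spectrumSpec(c(Unedited = 1))
  reads <- genEditedReads(loc, sp, 50, seed = 1)
  expect_true(all(as.character(reads) == as.character(refSequence(loc))))
})

test_that("classifier recovers generator proportions within binomial error", {
  loc <- mhTestLocus()
  probs <- c("1bp Ins" = 0.4, "MH Small Del" = 0.4, "Mut" = 0.2)
  sp <- spectrumSpec(probs)
  n <- 4000L
  reads <- genEditedReads(loc, sp, n, seed = 19)
  at <- classifyReads(reads, loc)
  spec <- summarizeSpectrum(at)
  for (pat in names(probs)) {
    se <- sqrt(probs[[pat]] * (1 - probs[[pat]]) / n)
    expect_lt(abs(patternProportions(spec)[[pat]] - probs[[pat]]), 3 * se)
  }
})

test_that("truth labels agree with classifier output almost perfectly", {
  loc <- mhTestLocus()
  reads <- genEditedReads(loc, fullSpectrum(), 1500, seed = 23)
  at <- classifyReads(reads, loc)
  truth <- sub(".*pattern=", "", names(reads))
  pred <- at$pattern[match(as.character(reads), at$allele_seq)]
  expect_gte(mean(truth == pred), 0.99)
})

test_that("time-course generation uses the default grid and converges with depth", {
  p <- c(k_cut = 0.3, k_err = 0.13, k_perf = 1e-6, f_max = 0.8)
  tc <- genTimecourseCounts(p, seed = 1)
  expect_identical(tc$edited_fraction$time_h, c(0, 3, 6, 12, 18, 24, 36, 48, 60, 72))
  expect_identical(length(tc$edited_fraction$time_h), 10L)
  # law of large numbers: at depth 1e6 observed fractions track the model
  tcBig <- genTimecourseCounts(p, depth = 1000000L, seed = 2)
  expect_lt(max(abs(tcBig$edited_fraction$edited_fraction - tc$truth$F)),
            0.005)
  # no cutting: everything stays unedited
  p0 <- c(k_cut = 0, k_err = 0.1, k_perf = 0, f_max = 0.8)
  tc0 <- genTimecourseCounts(p0, depth = 1000L, seed = 3)
  expect_true(all(tc0$edited_fraction$edited_fraction == 0))
})

test_that("screen manifests have the specified composition", {
  spc <- screenSpec(nGenes = 12, guidesPerGene = 6, nMirna = 4,
                    guidesPerMirna = 4, nNontarget = 7)
  man <- genScreenManifest(spc, seed = 1)
  expect_identical(nrow(man), 12L * 6L + 4L * 4L + 7L)
  expect_identical(sum(man$category == "nontarget"), 7L)
  expect_false(anyDuplicated(man$guide_sequence) > 0)
  expect_identical(unique(table(man$gene[man$category == "gene"])), 6L)
})

test_that("planted effects shift the planted pattern's frequency multiplicatively", {
  spc <- screenSpec(nGenes = 30, nMirna = 0, nNontarget = 20,
                    readsPerGuideMean = 500,
                    plantedEffects = data.frame(gene = "GENE00003",
                                                pattern = "MH Large Del",
                                                fc = 3))
  ds <- genScreenDataset(spc, seed = 33)
  rec <- guideRecords(ds$counts, ds$manifest)
  planted <- rec[rec$gene == "GENE00003", ]
  others <- rec[rec$category == "nontarget", ]
  fP <- sum(planted[["MH Large Del"]]) / sum(planted$total_edited)
  fN <- sum(others[["MH Large Del"]]) / sum(others$total_edited)
  base <- spc$baselineProbs[["MH Large Del"]]
  expected <- 3 * base / (1 + 2 * base)  # renormalized multiplicative shift
  expect_equal(fP, expected, tolerance = 0.15 * expected)
  expect_equal(fN, base, tolerance = 0.15 * base)
})
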