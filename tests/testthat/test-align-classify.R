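# Alignment, event extraction, normalization, microhomology detection and
# the seven-pattern classification.

refLocus48 <- function() {
  # 48-mer with protospacer [0,20), PAM at 20 -> cut at 17
  TargetLocus("ACGTACGTACGTACGTACGTGGGACGTACGTACGTACGTACGTACGTA",
              protospacerStart = 0, pamStart = 20)
}

test_that("an identical read yields no events", {
  loc <- refLocus48()
  ev <- alignRead(as.character(refSequence(loc)), loc)
  expect_identical(nrow(ev), 0L)
  expect_true(attr(ev, "alignable"))
})

test_that("single insertion and deletion are recovered at the expected coordinates", {
  ref <- "ACGTACGTACGT"
  # extra T at inter-base coordinate 6
  ev <- alignRead("ACGTACTGTACGT", ref)
  expect_identical(ev$kind, "insertion")
  expect_identical(ev$start, 6L)
  expect_identical(ev$length, 1L)
  expect_identical(ev$seq, "T")
  # reference positions 5-7 missing
  read <- paste0(substr(ref, 1, 5), substr(ref, 9, 12))
  ev <- alignRead(read, ref)
  expect_identical(ev$kind, "deletion")
  expect_identical(ev$start, 5L)
  expect_identical(ev$length, 3L)
})

test_that("extracted events are score-optimal against a Gotoh DP oracle", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(12:20, 1)
    ref <- randomRef(n)
    # random edit: substitution, short insertion or short deletion
    kind <- sample(c("sub", "ins", "del"), 1)
    read <- if (kind == "sub") {
      p <- sample(n, 1)
      ch <- strsplit(ref, "")[[1]]
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    } else if (kind == "ins") {
      p <- sample(0:n, 1)
      paste0(substr(ref, 1, p), randomRef(sample(1:3, 1)),
             substr(ref, p + 1, n))
    } else {
      L <- sample(1:3, 1)
      p <- sample(0:(n - L), 1)
      paste0(substr(ref, 1, p), substr(ref, p + L + 1, n))
    }
    ev <- alignRead(read, ref)
    expect_equal(impliedEventScore(ev, nchar(ref)),
                 oracleAlignScore(read, ref))
    expect_identical(applyEvents(ref, ev), read)
  }
})

test_that("left normalization finds the leftmost equivalent placement", {
  ref <- "AAATGCTTTTGCAAAT"
  d <- leftNormalize(data.frame(kind = "deletion", start = 6L, length = 6L,
                                seq = "", ref = "TTTTGC"), ref)
  # oracle: enumerate all placements that give the same edited string
  placements <- oracleDeletionPlacements(ref, 6, 6)
  expect_identical(d$start, min(placements))
  expect_identical(d$start, 3L)
  # no equivalent left placement -> unchanged
  d2 <- leftNormalize(data.frame(kind = "deletion", start = 3L, length = 2L,
                                 seq = "", ref = "GT"), "ACGGTTCA")
  expect_identical(d2$start, 3L)
  # insertion inside a homopolymer run anchors at the run start
  ref3 <- "CGTAAACGT"
  i3 <- leftNormalize(data.frame(kind = "insertion", start = 6L, length = 1L,
                                 seq = "A", ref = ""), ref3)
  expect_identical(i3$start, 3L)
})

test_that("left normalization is idempotent and allele-preserving", {
  set.seed(17)
  for (i in 1:200) {
    ref <- randomRef(30)
    kind <- sample(c("deletion", "insertion"), 1)
    L <- sample(1:6, 1)
    s <- sample(0:(30 - L), 1)
    ev <- if (kind == "deletion")
      data.frame(kind = kind, start = s, length = L, seq = "",
                 ref = substr(ref, s + 1, s + L))
    else
      data.frame(kind = kind, start = s, length = L, seq = randomRef(L),
                 ref = "")
    norm1 <- leftNormalize(ev, ref)
    norm2 <- leftNormalize(norm1, ref)
    expect_identical(norm1, norm2)
    expect_identical(applyEvents(ref, norm1), applyEvents(ref, ev))
    expect_lte(norm1$start, ev$start)
  }
})

test_that("microhomology detection matches the enumeration oracle", {
  expect_identical(detectMicrohomology("ACGGTTCA", 3, 2), 0L)
  expect_identical(detectMicrohomology("CCTAGCGGTAGCAA", 2, 6), 4L)
  # the repeat-rich case: left-normalized placement, span 3
  expect_identical(detectMicrohomology("AAATGCTTTTGCAAAT", 3, 6),
                   oracleMH("AAATGCTTTTGCAAAT", 3, 6))
  set.seed(99)
  for (i in 1:500) {
    ref <- randomRef(30)
    L <- sample(1:8, 1)
    s <- sample(0:(30 - L), 1)
    d <- leftNormalize(data.frame(kind = "deletion", start = s, length = L,
                                  seq = "", ref = ""), ref)
    expect_identical(detectMicrohomology(ref, d$start, d$length),
                     oracleMH(ref, s, L))
  }
})

test_that("the cut-site window keeps overlapping events and drops distant ones", {
  cut <- 17L
  mk <- function(kind, start, length) data.frame(kind = kind, start = start,
                                                 length = length, seq = "A",
                                                 ref = "C")
  expect_identical(nrow(callRepairEvents(mk("substitution", cut + 3L, 1L), cut)), 1L)
  expect_identical(nrow(callRepairEvents(mk("substitution", cut + 20L, 1L), cut)), 0L)
  # deletion spanning cut-8 .. cut+2 overlaps the window
  expect_identical(nrow(callRepairEvents(mk("deletion", cut - 8L, 10L), cut)), 1L)
  # insertion anchored just inside / outside
  expect_identical(nrow(callRepairEvents(mk("insertion", cut - 5L, 2L), cut)), 1L)
  expect_identical(nrow(callRepairEvents(mk("insertion", cut - 6L, 2L), cut)), 0L)
})

test_that("classification maps event sets to the seven patterns", {
  ref <- "AAATGCTTTTGCAAAT"
  ins1 <- data.frame(kind = "insertion", start = 8L, length = 1L, seq = "T",
                     ref = "")
  expect_identical(classifyAllele(ins1, ref)$pattern, "1bp Ins")
  ins4 <- data.frame(kind = "insertion", start = 8L, length = 4L,
                     seq = "CCGG", ref = "")
  expect_identical(classifyAllele(ins4, ref)$pattern, "Large Ins")
  # 3 bp deletion flanked by a CGT repeat: junction homology 3 -> MH
  del3 <- data.frame(kind = "deletion", start = 2L, length = 3L, seq = "",
                     ref = "")
  cl <- classifyAllele(del3, "AACGTCGTAA")
  expect_identical(cl$pattern, "MH Small Del")
  expect_identical(cl$mh_len, 3L)
  # 8 bp deletion with no junction homology -> NonMH Large Del
  del8 <- data.frame(kind = "deletion", start = 1L, length = 8L, seq = "",
                     ref = "")
  cl8 <- classifyAllele(del8, "ACGTGATCCGTAGGCT")
  expect_identical(cl8$pattern, "NonMH Large Del")
  expect_identical(cl8$mh_len, 0L)
  sub <- data.frame(kind = "substitution", start = 5L, length = 1L,
                    seq = "A", ref = "C")
  expect_identical(classifyAllele(sub, ref)$pattern, "Mut")
  expect_identical(classifyAllele(sub[0, ], ref)$pattern, "Unedited")
})

test_that("complex alleles classify by the dominant indel, deterministically", {
  ref <- "ACGTGATCCGTAGGCTAAGG"
  ev <- rbind(
    data.frame(kind = "insertion", start = 9L, length = 2L, seq = "TT", ref = ""),
    data.frame(kind = "deletion", start = 4L, length = 2L, seq = "", ref = ""),
    data.frame(kind = "substitution", start = 12L, length = 1L, seq = "A", ref = "G"))
  # tie at length 2: deletion wins over insertion; substitution never
  # triggers Mut when an indel is present
  base <- classifyAllele(ev, ref)
  expect_match(base$pattern, "Del$")
  set.seed(3)
  for (i in 1:10) {
    shuffled <- ev[sample(nrow(ev)), ]
    expect_identical(classifyAllele(shuffled, ref), base)
  }
  # longer insertion dominates the deletion
  ev2 <- rbind(
    data.frame(kind = "insertion", start = 9L, length = 4L, seq = "TTCC", ref = ""),
    data.frame(kind = "deletion", start = 4L, length = 2L, seq = "", ref = ""))
  expect_identical(classifyAllele(ev2, ref)$pattern, "Large Ins")
})

test_that("templated insertions are recognized from either flank", {
  ref <- "ACGTGATCCGTAGGCTAAGG"
  # right flank copy at inter-base 8: ref[8..9] = "CG"
  evR <- data.frame(kind = "insertion", start = 8L, length = 2L, seq = "CG",
                    ref = "")
  expect_true(classifyAllele(evR, ref)$templated)
  evL <- data.frame(kind = "insertion", start = 8L, length = 2L, seq = "TC",
                    ref = "")
  expect_true(classifyAllele(evL, ref)$templated)
  evN <- data.frame(kind = "insertion", start = 8L, length = 2L, seq = "AA",
                    ref = "")
  expect_false(classifyAllele(evN, ref)$templated)
})

test_that("spectrum summary arithmetic, flags and proportions", {
  df <- data.frame(pattern = c("1bp Ins", "MH Small Del", "Mut"),
                   read_count = c(30L, 50L, 20L))
  sp <- summarizeSpectrum(df)
  expect_equal(unname(patternProportions(sp)[c("1bp Ins", "MH Small Del", "Mut")]),
               c(0.3, 0.5, 0.2))
  expect_equal(sum(patternProportions(sp)), 1, tolerance = 1e-9)
  expect_equal(editingFraction(sp), 1)
  allUn <- data.frame(pattern = "Unedited", read_count = 100L)
  spu <- summarizeSpectrum(allUn)
  expect_identical(spu@flags, "no_edited_reads")
  expect_equal(editingFraction(spu), 0)
})

test_that("breakpoint profile measures PAM-distal enrichment", {
  loc <- refLocus48()
  cut <- cutSite(loc)
  sym <- data.frame(allele_seq = "x", pattern = "NonMH Small Del",
                    mh_len = 0L, templated = FALSE,
                    events = sprintf("D:%d:4", cut - 2L),
                    read_count = 10L, frequency = 1)
  expect_equal(breakpointProfile(sym, loc)$ratio, 1)
  distal <- sym
  distal$events <- sprintf("D:%d:4", cut - 6L)  # strictly 5' of the cut
  bp <- breakpointProfile(distal, loc)
  expect_identical(bp$ratio, Inf)
  expect_identical(bp$flag, "no_proximal_bases")
  # 70/30 split of deleted bases -> ratio near 7/3
  mix <- rbind(sym, distal)
  mix$read_count <- c(30L, 70L)
  expect_equal(breakpointProfile(mix, loc)$ratio, (70 * 4 + 30 * 2) / (30 * 2),
               tolerance = 1e-12)
})

test_that("reads with N near the cut are excluded but counted", {
  loc <- refLocus48()
  ref <- as.character(refSequence(loc))
  ch <- strsplit(ref, "")[[1]]
  ch[cutSite(loc)] <- "N"
  withN <- paste(ch, collapse = "")
  at <- classifyReads(c(ref, withN), loc)
  expect_setequal(at$pattern, c("Unedited", "Ambiguous"))
  expect_true(is.na(at$frequency[at$pattern == "Ambiguous"]))
})
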