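## Seed-deterministic generators for every input the pipeline consumes:
## target loci with planted microhomology, edited amplicon reads, kinetic
## time courses, and pooled-screen count tables with planted effects.
## Read names and truth tables carry machine-readable ground truth.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

.randomBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Generate a target locus with optional planted microhomology
#'
#' Builds a random amplicon with an NGG PAM immediately 3' of the
#' protospacer and, optionally, planted exact-repeat flanks so that
#' specific deletions carry a requested microhomology length. Each planted
#' site is verified post hoc: left-normalizing the designed deletion and
#' running [detectMicrohomology()] must return exactly the requested MH
#' length, otherwise bases are re-drawn.
#'
#' @param length amplicon length (default 120).
#' @param protospacerStart 0-based protospacer start (default 50).
#' @param mhDesign optional data.frame with columns `offset` (deletion
#'   start relative to the cut site, typically negative), `len` (deletion
#'   length) and `mh` (requested microhomology length, `>= 0`).
#' @param seed RNG seed.
#' @return a [TargetLocus] with attribute `mh_sites` (the realized design:
#'   absolute `start`, `len`, `mh`).
#' @export
genTargetLocus <- function(length = 120L, protospacerStart = 50L,
                           mhDesign = NULL, seed = 1L) {
  pamStart <- protospacerStart + 20L
  if (length < pamStart + 3L + 10L)
    stop("amplicon too short for protospacer + PAM + flank")
  .withSeed(seed, {
    cut <- locateCutSite(protospacerStart, 20L, pamStart, "+")
    for (attempt in 1:200) {
      ref <- .randomBases(length)
      ref[(pamStart + 2L):(pamStart + 3L)] <- c("G", "G")  # NGG PAM
      sites <- NULL
      ok <- TRUE
      if (!is.null(mhDesign)) {
        sites <- data.frame(start = as.integer(cut + mhDesign$offset),
                            len = as.integer(mhDesign$len),
                            mh = as.integer(mhDesign$mh))
        for (i in seq_len(nrow(sites))) {
          s <- sites$start[i]; L <- sites$len[i]; m <- sites$mh[i]
          if (s < 2L || s + L + m + 1L > length || m > L) {
            stop("incompatible mh design at row ", i)
          }
          if (m > 0L)  # copy the MH seed downstream of the deletion
            ref[(s + L + 1L):(s + L + m)] <- ref[(s + 1L):(s + m)]
          # break the homology at k = m and prevent left-slippage
          ref[s + L + m + 1L] <- setdiff(c("A", "C", "G", "T"),
                                         ref[s + m + 1L])[1L]
          ref[s] <- setdiff(c("A", "C", "G", "T"), ref[s + L])[1L]
        }
        # verify the realized design through the real pipeline
        refStr <- paste(ref, collapse = "")
        for (i in seq_len(nrow(sites))) {
          d <- leftNormalize(.eventRow("deletion", sites$start[i],
                                       sites$len[i]), refStr)
          got <- detectMicrohomology(refStr, d$start, d$length)
          if (d$start != sites$start[i] || got != sites$mh[i]) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        loc <- TargetLocus(paste(ref, collapse = ""), protospacerStart,
                           20L, pamStart, "+")
        attr(loc, "mh_sites") <- sites
        return(loc)
      }
    }
  })
  stop("could not realize the requested mh design")
}

#' Spectrum specification for read generation
#'
#' @param probs named probabilities over [repairPatterns()] plus
#'   `"Unedited"`; must sum to 1.
#' @param insertionTemplatedFraction fraction of 1 bp insertions copied
#'   from the adjacent flank (default 0.75, matching the dominance of
#'   templated single-base insertions at Cas9 breaks).
#' @param errorRate optional per-base substitution error rate (default 0:
#'   reads are error-free so classifier correctness is isolated from noise
#'   handling).
#' @return validated spectrum spec (list).
#' @export
spectrumSpec <- function(probs, insertionTemplatedFraction = 0.75,
                         errorRate = 0) {
  full <- setNames(numeric(8L), repairPatterns(TRUE))
  stopifnot(all(names(probs) %in% names(full)))
  full[names(probs)] <- probs
  if (abs(sum(full) - 1) > 1e-9) stop("spectrum probabilities must sum to 1")
  list(probs = full, insertionTemplatedFraction = insertionTemplatedFraction,
       errorRate = errorRate)
}

## deletions spanning/abutting the cut whose junction homology is >= mhMin,
## found by scanning the actual reference (used when no planted site fits)
.naturalMHSites <- function(refStr, cut, small, mhMin = 2L, windowBp = 5L) {
  lens <- if (small) 2:5 else 6:15
  out <- list()
  for (L in lens) {
    # any placement whose span overlaps the cut-site window qualifies
    for (s in max(0L, cut - windowBp - L):(cut + windowBp)) {
      if (s + L > nchar(refStr)) next
      d <- leftNormalize(.eventRow("deletion", s, L), refStr)
      mh <- detectMicrohomology(refStr, d$start, d$length)
      if (mh >= mhMin)
        out[[length(out) + 1L]] <- c(start = s, len = L, mh = mh)
    }
  }
  if (length(out)) as.data.frame(do.call(rbind, out)) else
    data.frame(start = integer(), len = integer(), mh = integer())
}

## draw a deletion spanning the cut with the required size class and
## (non-)MH status against the actual reference
.drawDeletion <- function(refChars, cut, small, wantMH, mhSites, mhMin = 2L) {
  refStr <- paste(refChars, collapse = "")
  if (wantMH) {
    cand <- mhSites[mhSites$mh >= mhMin &
                    (if (small) mhSites$len <= 5L else mhSites$len > 5L), ,
                    drop = FALSE]
    if (nrow(cand) == 0L)
      stop("spectrum requests MH deletions but the locus has no suitable MH site near the cut")
    i <- if (nrow(cand) == 1L) 1L else sample.int(nrow(cand), 1L)
    return(c(start = cand$start[i], len = cand$len[i]))
  }
  for (try in 1:100) {
    L <- if (small) sample(1:5, 1L) else sample(6:15, 1L)
    s <- sample(max(0L, cut - L):(cut - 0L), 1L)  # spans or abuts the cut
    if (s + L > length(refChars)) next
    d <- leftNormalize(.eventRow("deletion", s, L), refStr)
    if (detectMicrohomology(refStr, d$start, d$length) < mhMin)
      return(c(start = s, len = L))
  }
  stop("could not draw a non-MH deletion at this locus")
}

#' Generate edited amplicon reads with known pattern labels
#'
#' Draws each read's outcome from the spectrum, applies the corresponding
#' edit at or around the cut site, and records the true pattern in the read
#' name (`read000001|pattern=...`) for truth tracking. MH deletions use the
#' locus's planted MH sites; non-MH deletions are sampled and verified
#' against [detectMicrohomology()]; 1 bp insertions are templated from the
#' flank with the configured probability; `Mut` reads carry 1-3
#' substitutions within 5 bp of the cut.
#'
#' @param locus a [TargetLocus] from [genTargetLocus()].
#' @param spectrum a [spectrumSpec()].
#' @param nReads number of reads.
#' @param seed RNG seed.
#' @return a [Biostrings::DNAStringSet] with truth-carrying names.
#' @export
genEditedReads <- function(locus, spectrum, nReads, seed = 1L) {
  refChars <- strsplit(as.character(locus@refSeq), "")[[1]]
  cut <- locus@cutSite
  mhSites <- attr(locus, "mh_sites")
  if (is.null(mhSites)) mhSites <- data.frame(start = integer(),
                                              len = integer(), mh = integer())
  refStr <- paste(refChars, collapse = "")
  # ensure each requested MH size class has at least one usable site,
  # scanning the reference for natural junction homology if none is planted
  for (small in c(TRUE, FALSE)) {
    pat <- if (small) "MH Small Del" else "MH Large Del"
    if (spectrum$probs[[pat]] > 0 &&
        !any(mhSites$mh >= 2L &
             (if (small) mhSites$len <= 5L else mhSites$len > 5L)))
      mhSites <- rbind(mhSites, .naturalMHSites(refStr, cut, small))
  }
  labels <- names(spectrum$probs)
  .withSeed(seed, {
    draws <- sample(labels, nReads, replace = TRUE, prob = spectrum$probs)
    seqs <- character(nReads)
    for (i in seq_len(nReads)) {
      pat <- draws[i]
      ev <- switch(pat,
        "Unedited" = .emptyEvents(),
        "1bp Ins" = {
          base <- if (runif(1) < spectrum$insertionTemplatedFraction)
            refChars[cut] else sample(c("A", "C", "G", "T"), 1L)
          .eventRow("insertion", cut, 1L, seq = base)
        },
        "Large Ins" = {
          L <- sample(2:8, 1L)
          .eventRow("insertion", cut, L,
                    seq = paste(.randomBases(L), collapse = ""))
        },
        "MH Small Del" = {
          d <- .drawDeletion(refChars, cut, small = TRUE, wantMH = TRUE, mhSites)
          .eventRow("deletion", d["start"], d["len"])
        },
        "MH Large Del" = {
          d <- .drawDeletion(refChars, cut, small = FALSE, wantMH = TRUE, mhSites)
          .eventRow("deletion", d["start"], d["len"])
        },
        "NonMH Small Del" = {
          d <- .drawDeletion(refChars, cut, small = TRUE, wantMH = FALSE, mhSites)
          .eventRow("deletion", d["start"], d["len"])
        },
        "NonMH Large Del" = {
          d <- .drawDeletion(refChars, cut, small = FALSE, wantMH = FALSE, mhSites)
          .eventRow("deletion", d["start"], d["len"])
        },
        "Mut" = {
          nSub <- sample(1:3, 1L)
          pos <- sample(max(0L, cut - 5L):min(length(refChars) - 1L, cut + 4L),
                        nSub)
          do.call(rbind, lapply(pos, function(p) {
            alt <- sample(setdiff(c("A", "C", "G", "T"), refChars[p + 1L]), 1L)
            .eventRow("substitution", p, 1L, seq = alt, ref = refChars[p + 1L])
          }))
        })
      s <- applyEvents(locus@refSeq, ev)
      if (spectrum$errorRate > 0) {
        ch <- strsplit(s, "")[[1]]
        hit <- runif(length(ch)) < spectrum$errorRate
        if (any(hit))
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        s <- paste(ch, collapse = "")
      }
      seqs[i] <- s
    }
    out <- DNAStringSet(seqs)
    names(out) <- sprintf("read%06d|pattern=%s", seq_len(nReads), draws)
    out
  })
}

#' Generate a kinetic time course with binomial sampling noise
#'
#' Simulates the edited fraction from the three-state model, samples
#' `depth` reads per timepoint binomially, and splits edited reads over the
#' seven patterns with a time-varying mixture in which 1 bp insertions peak
#' early and MH deletions accumulate late (interpolating between an early
#' NHEJ-dominated mix and a late MMEJ-shifted mix with weight
#' `1 - exp(-t / 24)`).
#'
#' @param params kinetic parameters (see [simulateRepairODE()]).
#' @param times time grid in hours (default [defaultTimeGrid()]).
#' @param depth reads per timepoint.
#' @param patternMix optional function `t -> named probabilities` over
#'   [repairPatterns()] overriding the default mixture.
#' @param seed RNG seed.
#' @return list with `counts` (long data.frame `time_h`, `pattern`,
#'   `count`, including `"Unedited"` rows), `edited_fraction` (data.frame
#'   `time_h`, `edited_fraction`), and `truth` (params and the noise-free
#'   `F(t)`).
#' @export
genTimecourseCounts <- function(params, times = defaultTimeGrid(),
                                depth = 5000L, patternMix = NULL,
                                seed = 1L) {
  sim <- simulateRepairODE(params, times, method = "analytic")
  if (is.null(patternMix)) {
    early <- c("1bp Ins" = 0.45, "Large Ins" = 0.04, "MH Small Del" = 0.08,
               "NonMH Small Del" = 0.28, "MH Large Del" = 0.03,
               "NonMH Large Del" = 0.06, "Mut" = 0.06)
    late <- c("1bp Ins" = 0.18, "Large Ins" = 0.06, "MH Small Del" = 0.30,
              "NonMH Small Del" = 0.16, "MH Large Del" = 0.14,
              "NonMH Large Del" = 0.10, "Mut" = 0.06)
    patternMix <- function(t) {
      w <- 1 - exp(-t / 24)
      (1 - w) * early + w * late
    }
  }
  .withSeed(seed, {
    rows <- list()
    obs <- numeric(length(times))
    for (i in seq_along(times)) {
      nEd <- rbinom(1L, depth, sim$F[i])
      obs[i] <- nEd / depth
      mix <- patternMix(times[i])
      cnt <- if (nEd > 0L) as.integer(rmultinom(1L, nEd, mix[repairPatterns()]))
             else integer(7L)
      rows[[i]] <- data.frame(time_h = times[i],
                              pattern = c(repairPatterns(), "Unedited"),
                              count = c(cnt, depth - nEd),
                              stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, rows),
         edited_fraction = data.frame(time_h = times, edited_fraction = obs),
         truth = list(params = params, F = sim$F))
  })
}

#' Screen specification
#'
#' Defaults emulate a genome-scale knockout library composition scaled by
#' `scale`: at `scale = 1` the manifest holds 19,050 genes x 6 guides,
#' 1,864 miRNAs x 4 guides and 1,000 non-targeting controls (122,756
#' rows). Reads per guide follow a negative binomial with mean 200
#' (read counts concentrating between 100 and 300).
#'
#' @param nGenes,guidesPerGene,nMirna,guidesPerMirna,nNontarget library
#'   composition.
#' @param readsPerGuideMean,readsPerGuideDispersion negative-binomial mean
#'   and size for per-guide edited read depth.
#' @param baselineProbs baseline outcome probabilities over
#'   [repairPatterns()] shared by all guides.
#' @param plantedEffects optional data.frame `gene`, `pattern`, `fc`:
#'   multiply that pattern's baseline probability by `fc` for the gene's
#'   guides and renormalize.
#' @param scale convenience scaling of the full-size composition.
#' @return validated screen spec (list).
#' @export
screenSpec <- function(nGenes = round(19050 * scale),
                       guidesPerGene = 6L,
                       nMirna = round(1864 * scale),
                       guidesPerMirna = 4L,
                       nNontarget = round(1000 * scale),
                       readsPerGuideMean = 200,
                       readsPerGuideDispersion = 10,
                       baselineProbs = c("1bp Ins" = 0.20, "Large Ins" = 0.03,
                                         "MH Small Del" = 0.26,
                                         "NonMH Small Del" = 0.20,
                                         "MH Large Del" = 0.12,
                                         "NonMH Large Del" = 0.13,
                                         "Mut" = 0.06),
                       plantedEffects = NULL,
                       scale = 1) {
  stopifnot(setequal(names(baselineProbs), repairPatterns()),
            abs(sum(baselineProbs) - 1) < 1e-9)
  list(nGenes = as.integer(nGenes), guidesPerGene = as.integer(guidesPerGene),
       nMirna = as.integer(nMirna), guidesPerMirna = as.integer(guidesPerMirna),
       nNontarget = as.integer(nNontarget),
       readsPerGuideMean = readsPerGuideMean,
       readsPerGuideDispersion = readsPerGuideDispersion,
       baselineProbs = baselineProbs[repairPatterns()],
       plantedEffects = plantedEffects)
}

#' Generate a guide-library manifest
#'
#' @param spec a [screenSpec()].
#' @param seed RNG seed (guide sequences are random unique 20-mers).
#' @param guideOffset 0-based position of the guide in the read layout.
#' @return data.frame `guide_id`, `gene`, `category`, `guide_sequence`,
#'   `guide_offset` with `nGenes*guidesPerGene + nMirna*guidesPerMirna +
#'   nNontarget` rows.
#' @export
genScreenManifest <- function(spec, seed = 1L, guideOffset = 0L) {
  nG <- spec$nGenes * spec$guidesPerGene
  nM <- spec$nMirna * spec$guidesPerMirna
  nN <- spec$nNontarget
  n <- nG + nM + nN
  drawSeqs <- function(m)
    do.call(paste0, as.data.frame(matrix(.randomBases(20L * m), ncol = 20L),
                                  stringsAsFactors = FALSE))
  .withSeed(seed, {
    seqs <- drawSeqs(n)
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- drawSeqs(length(dup))
    }
    data.frame(
      guide_id = sprintf("g%06d", seq_len(n)),
      gene = c(rep(sprintf("GENE%05d", seq_len(spec$nGenes)),
                   each = spec$guidesPerGene),
               rep(sprintf("MIR%04d", seq_len(spec$nMirna)),
                   each = spec$guidesPerMirna),
               sprintf("NT%04d", seq_len(nN))),
      category = c(rep("gene", nG), rep("miRNA", nM), rep("nontarget", nN)),
      guide_sequence = seqs,
      guide_offset = as.integer(guideOffset),
      stringsAsFactors = FALSE)
  })
}

#' Generate a pooled-screen dataset with planted effects
#'
#' Produces the manifest, a long guide x pattern count table and a truth
#' table. All guides share the baseline outcome probabilities; guides of a
#' planted-effect gene have the stated pattern's probability multiplied by
#' the fold change and the vector renormalized. Per-guide edited depth is
#' negative-binomial.
#'
#' @param spec a [screenSpec()].
#' @param seed RNG seed.
#' @return list with `manifest`, `counts` (long data.frame `guide_id`,
#'   `pattern`, `count`), and `truth` (`plantedEffects`, `baselineProbs`).
#' @export
genScreenDataset <- function(spec, seed = 1L) {
  manifest <- genScreenManifest(spec, seed = seed)
  .withSeed(seed + 1L, {
    n <- nrow(manifest)
    depth <- rnbinom(n, mu = spec$readsPerGuideMean,
                     size = spec$readsPerGuideDispersion)
    probs <- matrix(rep(spec$baselineProbs, each = n), nrow = n,
                    dimnames = list(NULL, repairPatterns()))
    pe <- spec$plantedEffects
    if (!is.null(pe)) {
      for (i in seq_len(nrow(pe))) {
        sel <- manifest$gene == pe$gene[i]
        if (!any(sel)) stop("planted gene not in manifest: ", pe$gene[i])
        probs[sel, pe$pattern[i]] <- probs[sel, pe$pattern[i]] * pe$fc[i]
      }
      probs <- probs / rowSums(probs)
    }
    cnt <- matrix(0L, nrow = n, ncol = 7L,
                  dimnames = list(NULL, repairPatterns()))
    pos <- depth > 0L
    cnt[pos, ] <- t(vapply(which(pos), function(i)
      as.integer(rmultinom(1L, depth[i], probs[i, ])), integer(7L)))
    counts <- data.frame(
      guide_id = rep(manifest$guide_id, times = 7L),
      pattern = rep(repairPatterns(), each = n),
      count = as.integer(cnt),
      stringsAsFactors = FALSE)
    counts <- counts[counts$count > 0L, , drop = FALSE]
    rownames(counts) <- NULL
    list(manifest = manifest, counts = counts,
         truth = list(plantedEffects = pe,
                      baselineProbs = spec$baselineProbs))
  })
}

#' Generate reads carrying guide sequences for assignment testing
#'
#' Emits `nPerGuide` reads per manifest guide with the guide sequence at
#' its declared offset, flanked by fixed vector context, so that
#' [assignReadsToGuides()] can be exercised round-trip.
#'
#' @param manifest a guide manifest.
#' @param nPerGuide reads per guide.
#' @param flank3 3' flanking sequence appended after the guide.
#' @param seed RNG seed (used only to shuffle read order).
#' @return character vector of reads named by true guide_id.
#' @export
genGuideReads <- function(manifest, nPerGuide = 2L,
                          flank3 = "GTTTTAGAGCTAGAAATAGC", seed = 1L) {
  reads <- rep(paste0(manifest$guide_sequence, flank3), each = nPerGuide)
  names(reads) <- rep(manifest$guide_id, each = nPerGuide)
  .withSeed(seed, {
    o <- sample.int(length(reads))
    reads[o]
  })
}
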