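## Core amplicon operations: cut-site geometry, read alignment, event
## extraction and normalization, microhomology detection, and the
## seven-pattern classification.

#' Locate the blunt Cas9 cut site from protospacer/PAM coordinates
#'
#' SpCas9 cleaves bluntly 3 nt 5' of the PAM on the protospacer strand. With
#' 0-based coordinates and an inter-base cut coordinate, a plus-strand
#' protospacer at `[s, s + len)` with PAM at `s + len` cuts at
#' `s + len - 3`; the convention is mirrored on the minus strand.
#'
#' @param protospacerStart 0-based protospacer start (plus-strand coords).
#' @param protospacerLen protospacer length (typically 20).
#' @param pamStart 0-based start of the 3-nt PAM (plus-strand coords).
#' @param pamStrand `"+"` or `"-"`.
#' @return the 0-based inter-base cut coordinate.
#' @examples
#' locateCutSite(0, 20, 20, "+")   # 17
#' locateCutSite(13, 20, 10, "-")  # 16
#' @export
locateCutSite <- function(protospacerStart, protospacerLen, pamStart,
                          pamStrand = "+") {
  protospacerStart <- as.integer(protospacerStart)
  protospacerLen <- as.integer(protospacerLen)
  pamStart <- as.integer(pamStart)
  if (pamStrand == "+") {
    if (pamStart != protospacerStart + protospacerLen)
      stop("PAM is not immediately 3' of the protospacer on '+' strand")
    protospacerStart + protospacerLen - 3L
  } else if (pamStrand == "-") {
    if (protospacerStart != pamStart + 3L)
      stop("PAM is not immediately 3' of the protospacer on '-' strand")
    protospacerStart + 3L
  } else stop("pamStrand must be '+' or '-'")
}

## empty event table with the canonical columns
.emptyEvents <- function() {
  data.frame(kind = character(), start = integer(), length = integer(),
             seq = character(), ref = character(), stringsAsFactors = FALSE)
}

.eventRow <- function(kind, start, length, seq = "", ref = "") {
  data.frame(kind = kind, start = as.integer(start),
             length = as.integer(length), seq = seq, ref = ref,
             stringsAsFactors = FALSE)
}

## Walk two equal-length gapped strings (read over reference) and emit
## insertion / deletion / substitution events in 0-based ref coordinates.
## Consecutive gap columns of one kind are merged into a single event.
.eventsFromGapped <- function(readGapped, refGapped) {
  p <- strsplit(readGapped, "")[[1]]
  s <- strsplit(refGapped, "")[[1]]
  stopifnot(length(p) == length(s))
  out <- list()
  r <- 0L                      # reference positions consumed so far
  i <- 1L
  n <- length(p)
  nmatch <- 0L
  while (i <= n) {
    if (s[i] == "-") {         # insertion relative to reference
      j <- i
      while (j < n && s[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- .eventRow("insertion", r, j - i + 1L,
                                           seq = paste(p[i:j], collapse = ""))
      i <- j + 1L
    } else if (p[i] == "-") {  # deletion
      j <- i
      while (j < n && p[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- .eventRow("deletion", r, j - i + 1L,
                                           ref = paste(s[i:j], collapse = ""))
      r <- r + (j - i + 1L)
      i <- j + 1L
    } else {
      if (p[i] == s[i]) nmatch <- nmatch + 1L
      else out[[length(out) + 1L]] <- .eventRow("substitution", r, 1L,
                                                seq = p[i], ref = s[i])
      r <- r + 1L
      i <- i + 1L
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else .emptyEvents()
  attr(ev, "identity") <- nmatch / n
  ev
}

#' Alignment scoring parameters
#'
#' Affine-gap scoring used by [alignRead()] and [classifyReads()]. Defaults
#' are typical for short amplicons; `minIdentity` is the fraction of matched
#' alignment columns below which a read is flagged unalignable.
#'
#' @param match,mismatch,gapOpen,gapExtend scoring values (penalties
#'   positive).
#' @param minIdentity alignability floor in `[0, 1]`.
#' @return a named list of scoring parameters.
#' @export
alignScoring <- function(match = 2, mismatch = -3, gapOpen = 8,
                         gapExtend = 1, minIdentity = 0.6) {
  list(match = match, mismatch = mismatch, gapOpen = gapOpen,
       gapExtend = gapExtend, minIdentity = minIdentity)
}

.substMatrix <- function(scoring) {
  m <- nucleotideSubstitutionMatrix(match = scoring$match,
                                    mismatch = scoring$mismatch,
                                    baseOnly = FALSE)
  # N carries no information: never rewarded as a match
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

#' Align a read to the reference amplicon and extract repair events
#'
#' Performs a global pairwise alignment with affine gap penalties and walks
#' the gapped alignment to emit insertion, deletion and substitution events
#' in 0-based reference coordinates. Indels are left-normalized to their
#' leftmost equivalent placement.
#'
#' @param read a single read (character or [Biostrings::DNAString]).
#' @param locus a [TargetLocus] (or a plain reference sequence).
#' @param scoring see [alignScoring()].
#' @return a data.frame of events (columns `kind`, `start`, `length`, `seq`,
#'   `ref`) with attributes `identity` (fraction of matched columns) and
#'   `alignable` (logical). An identical read yields zero rows.
#' @examples
#' loc <- TargetLocus(paste(rep("ACGT", 12), collapse = ""),
#'                    protospacerStart = 0, pamStart = 20)
#' alignRead("ACGTACTGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT", loc)
#' @export
alignRead <- function(read, locus, scoring = alignScoring()) {
  refSeq <- if (is(locus, "TargetLocus")) locus@refSeq else DNAString(as.character(locus))
  read <- DNAString(as.character(read))
  if (length(read) == length(refSeq) && read == refSeq) {
    ev <- .emptyEvents()
    attr(ev, "identity") <- 1
    attr(ev, "alignable") <- TRUE
    return(ev)
  }
  aln <- pairwiseAlignment(read, refSeq, type = "global",
                           substitutionMatrix = .substMatrix(scoring),
                           gapOpening = scoring$gapOpen,
                           gapExtension = scoring$gapExtend)
  ev <- .eventsFromGapped(as.character(alignedPattern(aln)),
                          as.character(alignedSubject(aln)))
  ident <- attr(ev, "identity")
  ev <- leftNormalize(ev, refSeq)
  attr(ev, "identity") <- ident
  attr(ev, "alignable") <- ident >= scoring$minIdentity
  ev
}

#' Shift indel events to their leftmost equivalent placement
#'
#' An ambiguously placed indel (one whose edited sequence is unchanged when
#' the event slides along a repeat) is moved to the smallest equivalent
#' start coordinate. Substitutions are returned unchanged. The operation is
#' idempotent and preserves the edited allele.
#'
#' @param events event data.frame as produced by [alignRead()].
#' @param refSeq reference sequence (character or `DNAString`).
#' @return the event data.frame with normalized `start` (and rotated
#'   inserted/deleted sequence where the placement moved), re-sorted by
#'   `start`.
#' @export
leftNormalize <- function(events, refSeq) {
  if (nrow(events) == 0L) return(events)
  ref <- strsplit(as.character(refSeq), "")[[1]]
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]
    s <- events$start[i]
    L <- events$length[i]
    if (kind == "deletion") {
      # slide left while the base entering the deletion equals the one leaving
      while (s > 0L && ref[s] == ref[s + L]) s <- s - 1L
      events$start[i] <- s
      events$ref[i] <- paste(ref[(s + 1L):(s + L)], collapse = "")
    } else if (kind == "insertion") {
      q <- strsplit(events$seq[i], "")[[1]]
      while (s > 0L && ref[s] == q[L]) {
        q <- c(ref[s], q[-L])
        s <- s - 1L
      }
      events$start[i] <- s
      events$seq[i] <- paste(q, collapse = "")
    }
  }
  events[order(events$start, events$kind), , drop = FALSE]
}

#' Microhomology length of a deletion
#'
#' For a deletion of length `L` starting at 0-based position `start`, the
#' microhomology (MH) length is the longest `k` such that the first `k`
#' deleted bases equal the `k` bases immediately downstream of the deletion:
#' `ref[start .. start+k-1] == ref[start+L .. start+L+k-1]`. On a
#' left-normalized deletion this equals the placement-ambiguity span of the
#' deletion, i.e. the junction homology exploited by microhomology-mediated
#' end joining. Out-of-bounds positions are not compared.
#'
#' @param refSeq reference sequence (character or `DNAString`).
#' @param start 0-based deletion start (left-normalized).
#' @param length deletion length in bp.
#' @return integer MH length (>= 0).
#' @examples
#' detectMicrohomology("CCTAGCGGTAGCAA", 2, 6)  # 4
#' detectMicrohomology("ACGGTTCA", 3, 2)        # 0
#' @export
detectMicrohomology <- function(refSeq, start, length) {
  ref <- strsplit(as.character(refSeq), "")[[1]]
  n <- base::length(ref)
  L <- as.integer(length)
  s <- as.integer(start)
  k <- 0L
  # k may exceed L inside a homopolymer/repeat run; it always equals the
  # placement-ambiguity span of the (left-normalized) deletion
  while (s + L + k < n && ref[s + k + 1L] == ref[s + L + k + 1L]) {
    k <- k + 1L
  }
  k
}

#' Retain events at the cleavage site
#'
#' Repair events are sequence alterations overlapping or adjacent to the
#' Cas9 cleavage site. An event is kept when its reference span overlaps
#' the window `[cutSite - windowBp, cutSite + windowBp]` (interval-overlap
#' semantics on the inter-base cut coordinate). Insertions occupy their
#' anchor junction.
#'
#' @param events left-normalized event data.frame.
#' @param cutSite inter-base cut coordinate.
#' @param windowBp window half-width in bp (default 5, matching the
#'   clustering of substitutions within 5 bp of the cleavage site).
#' @return the subset of `events` within the window.
#' @export
callRepairEvents <- function(events, cutSite, windowBp = 5L) {
  if (nrow(events) == 0L) return(events)
  lo <- cutSite - windowBp
  hi <- cutSite + windowBp
  spanStart <- events$start
  spanEnd <- ifelse(events$kind == "insertion", events$start,
                    events$start + events$length)
  keep <- spanEnd >= lo & spanStart <= hi
  events[keep, , drop = FALSE]
}

#' Classify an allele into one of the seven indel patterns
#'
#' Given the cut-site-window events of one allele, assigns one of the seven
#' edited pattern labels or `"Unedited"`:
#' * no events: `Unedited`;
#' * substitutions only: `Mut`;
#' * otherwise the dominant indel (longest event; ties favor deletions over
#'   insertions, then the leftmost) decides: a 1 bp insertion is `1bp Ins`,
#'   an insertion of >= 2 bp is `Large Ins`; deletions of 1-5 bp are
#'   `Small Del` and > 5 bp `Large Del`, prefixed `MH` when the
#'   microhomology length reaches `mhMin` and `NonMH` otherwise.
#'
#' Insertions are additionally flagged `templated` when the inserted
#' sequence equals either adjacent equal-length reference flank.
#'
#' @param events left-normalized, window-restricted event data.frame.
#' @param refSeq reference sequence.
#' @param mhMin minimum junction homology (bp) for the MH label (default 2;
#'   a single shared base is treated as non-MH).
#' @return list with `pattern`, `mh_len`, `templated`.
#' @export
classifyAllele <- function(events, refSeq, mhMin = 2L) {
  if (nrow(events) == 0L)
    return(list(pattern = "Unedited", mh_len = 0L, templated = FALSE))
  indels <- events[events$kind != "substitution", , drop = FALSE]
  if (nrow(indels) == 0L)
    return(list(pattern = "Mut", mh_len = 0L, templated = FALSE))
  # dominant event: longest; tie -> deletion over insertion; then leftmost
  kindRank <- ifelse(indels$kind == "deletion", 0L, 1L)
  o <- order(-indels$length, kindRank, indels$start)
  dom <- indels[o[1L], ]
  if (dom$kind == "insertion") {
    templ <- .isTemplatedInsertion(refSeq, dom$start, dom$seq)
    pattern <- if (dom$length == 1L) "1bp Ins" else "Large Ins"
    return(list(pattern = pattern, mh_len = 0L, templated = templ))
  }
  mh <- detectMicrohomology(refSeq, dom$start, dom$length)
  size <- if (dom$length <= 5L) "Small" else "Large"
  prefix <- if (mh >= mhMin) "MH" else "NonMH"
  list(pattern = paste(prefix, size, "Del"), mh_len = mh, templated = FALSE)
}

## inserted sequence equals an equal-length flank adjacent to the anchor
.isTemplatedInsertion <- function(refSeq, start, seq) {
  ref <- as.character(refSeq)
  L <- nchar(seq)
  left <- if (start - L >= 0L) substr(ref, start - L + 1L, start) else NULL
  right <- if (start + L <= nchar(ref)) substr(ref, start + 1L, start + L) else NULL
  isTRUE(seq == left) || isTRUE(seq == right)
}

#' Serialize / parse compact event strings
#'
#' Events are written as `D:start:len` (deletion), `I:start:len:SEQ`
#' (insertion) and `S:pos:REF>ALT` (substitution), joined with `;`.
#' Coordinates are 0-based.
#'
#' @param events event data.frame.
#' @return `formatEvents`: a single character string; `parseEvents`: the
#'   event data.frame.
#' @export
formatEvents <- function(events) {
  if (nrow(events) == 0L) return("")
  parts <- vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    switch(e$kind,
           deletion = sprintf("D:%d:%d", e$start, e$length),
           insertion = sprintf("I:%d:%d:%s", e$start, e$length, e$seq),
           substitution = sprintf("S:%d:%s>%s", e$start, e$ref, e$seq))
  }, character(1))
  paste(parts, collapse = ";")
}

#' @rdname formatEvents
#' @param x compact event string.
#' @export
parseEvents <- function(x) {
  if (is.na(x) || x == "") return(.emptyEvents())
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (f[1] == "D") .eventRow("deletion", as.integer(f[2]), as.integer(f[3]))
    else if (f[1] == "I") .eventRow("insertion", as.integer(f[2]),
                                    as.integer(f[3]), seq = f[4])
    else {
      ra <- strsplit(f[3], ">", fixed = TRUE)[[1]]
      .eventRow("substitution", as.integer(f[2]), 1L, seq = ra[2], ref = ra[1])
    }
  })
  do.call(rbind, rows)
}

#' Apply events to a reference sequence
#'
#' Reconstructs the edited allele implied by a set of events; the inverse of
#' [alignRead()] up to indel placement ambiguity.
#'
#' @param refSeq reference sequence.
#' @param events event data.frame (0-based reference coordinates).
#' @return the edited sequence as a character string.
#' @export
applyEvents <- function(refSeq, events) {
  ref <- strsplit(as.character(refSeq), "")[[1]]
  if (nrow(events) == 0L) return(paste(ref, collapse = ""))
  ev <- events[order(-events$start), , drop = FALSE]  # right-to-left: stable coords
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$kind == "deletion") {
      ref <- ref[-((e$start + 1L):(e$start + e$length))]
    } else if (e$kind == "insertion") {
      ref <- append(ref, strsplit(e$seq, "")[[1]], after = e$start)
    } else {
      ref[e$start + 1L] <- e$seq
    }
  }
  paste(ref, collapse = "")
}

#' Classify a set of amplicon reads
#'
#' Aligns each unique read to the locus reference, restricts events to the
#' cut-site window, classifies the allele, and tabulates the results.
#' Unalignable reads (identity below the scoring floor) and alleles with an
#' ambiguous base (N) inside the window are excluded from the spectrum but
#' counted.
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of reads.
#' @param locus a [TargetLocus].
#' @param windowBp cut-site window half-width (default 5).
#' @param mhMin MH threshold passed to [classifyAllele()] (default 2).
#' @param scoring see [alignScoring()].
#' @return a data.frame (the allele table) with one row per unique allele:
#'   `allele_seq`, `pattern`, `mh_len`, `templated`, `events`, `read_count`,
#'   `frequency` (among classified reads). Excluded reads appear with
#'   pattern `"Unalignable"` or `"Ambiguous"` and `frequency = NA`.
#' @seealso [summarizeSpectrum()]
#' @export
classifyReads <- function(reads, locus, windowBp = 5L, mhMin = 2L,
                          scoring = alignScoring()) {
  reads <- as.character(reads)
  tab <- table(reads)
  alleles <- names(tab)
  counts <- as.integer(tab)
  refSeq <- locus@refSeq
  refStr <- as.character(refSeq)
  cut <- locus@cutSite
  # one batched alignment call for all unique alleles
  isRef <- alleles == refStr
  gapped <- vector("list", length(alleles))
  if (any(!isRef)) {
    aln <- pairwiseAlignment(DNAStringSet(alleles[!isRef]), refSeq,
                             type = "global",
                             substitutionMatrix = .substMatrix(scoring),
                             gapOpening = scoring$gapOpen,
                             gapExtension = scoring$gapExtend)
    ap <- as.character(alignedPattern(aln))
    as_ <- as.character(alignedSubject(aln))
    gapped[!isRef] <- Map(list, ap, as_)
  }
  res <- lapply(seq_along(alleles), function(ai) {
    if (isRef[ai]) {
      ev <- .emptyEvents()
      attr(ev, "identity") <- 1
      attr(ev, "alignable") <- TRUE
    } else {
      ev <- .eventsFromGapped(gapped[[ai]][[1]], gapped[[ai]][[2]])
      ident <- attr(ev, "identity")
      ev <- leftNormalize(ev, refStr)
      attr(ev, "identity") <- ident
      attr(ev, "alignable") <- ident >= scoring$minIdentity
    }
    if (!attr(ev, "alignable"))
      return(list(pattern = "Unalignable", mh_len = NA_integer_,
                  templated = NA, events = ""))
    win <- callRepairEvents(ev, cut, windowBp)
    if (any(grepl("N", c(win$seq, win$ref), fixed = TRUE)))
      return(list(pattern = "Ambiguous", mh_len = NA_integer_,
                  templated = NA, events = formatEvents(win)))
    cl <- classifyAllele(win, refStr, mhMin)
    list(pattern = cl$pattern, mh_len = cl$mh_len, templated = cl$templated,
         events = formatEvents(win))
  })
  out <- data.frame(
    allele_seq = alleles,
    pattern = vapply(res, `[[`, character(1), "pattern"),
    mh_len = vapply(res, `[[`, integer(1), "mh_len"),
    templated = vapply(res, `[[`, logical(1), "templated"),
    events = vapply(res, `[[`, character(1), "events"),
    read_count = counts,
    stringsAsFactors = FALSE
  )
  classified <- !out$pattern %in% c("Unalignable", "Ambiguous")
  nClassified <- sum(out$read_count[classified])
  out$frequency <- ifelse(classified, out$read_count / nClassified, NA_real_)
  out[order(-out$read_count), , drop = FALSE]
}

#' Summarize an allele table into an outcome spectrum
#'
#' Tabulates pattern counts and the proportional distribution over the
#' seven edited patterns. Unedited reads are reported through the editing
#' fraction `edited / (edited + unedited)`; excluded reads (unalignable or
#' ambiguous) are counted but enter neither proportions nor the editing
#' fraction.
#'
#' @param calls an allele table from [classifyReads()], or any data.frame
#'   with `pattern` and (optionally) `read_count` columns.
#' @return an [OutcomeSpectrum-class] object.
#' @examples
#' df <- data.frame(pattern = c("1bp Ins", "MH Small Del", "Mut"),
#'                  read_count = c(30, 50, 20))
#' summarizeSpectrum(df)
#' @export
summarizeSpectrum <- function(calls) {
  stopifnot(nrow(calls) > 0L)
  if (is.null(calls$read_count)) calls$read_count <- 1L
  labs <- repairPatterns(TRUE)
  counts <- setNames(integer(length(labs)), labs)
  agg <- tapply(calls$read_count, calls$pattern, sum)
  known <- intersect(names(agg), labs)
  counts[known] <- as.integer(agg[known])
  edited <- counts[repairPatterns()]
  totalEdited <- sum(edited)
  flags <- character()
  if (totalEdited > 0L) {
    props <- edited / totalEdited
  } else {
    props <- setNames(rep(NA_real_, 7L), repairPatterns())
    flags <- c(flags, "no_edited_reads")
  }
  denom <- totalEdited + counts[["Unedited"]]
  editFrac <- if (denom > 0L) totalEdited / denom else NA_real_
  new("OutcomeSpectrum",
      counts = counts,
      proportions = props,
      totalEdited = as.integer(totalEdited),
      editingFraction = editFrac,
      alleleTable = if (!is.null(calls$allele_seq)) calls else data.frame(),
      flags = flags)
}

#' Deletion breakpoint profile around the cut site
#'
#' Histograms the deleted reference bases relative to the cut site and
#' reports the PAM-distal : PAM-proximal ratio of deleted bases (the
#' signature of asymmetric end resection away from the PAM).
#'
#' @param alleleTable allele table from [classifyReads()] (uses the `events`
#'   and `read_count` columns).
#' @param locus a [TargetLocus]; determines the cut site and which side is
#'   PAM-proximal.
#' @return list with `histogram` (data.frame `offset`, `deleted_bases`;
#'   offset 0 is the first base 3' of the cut), `ratio`
#'   (distal / proximal deleted bases; `Inf` with flag when no proximal
#'   bases), and `flag`.
#' @export
breakpointProfile <- function(alleleTable, locus) {
  cut <- locus@cutSite
  offs <- integer()
  wts <- integer()
  for (i in seq_len(nrow(alleleTable))) {
    ev <- parseEvents(alleleTable$events[i])
    del <- ev[ev$kind == "deletion", , drop = FALSE]
    for (j in seq_len(nrow(del))) {
      pos <- del$start[j]:(del$start[j] + del$length[j] - 1L)
      offs <- c(offs, pos - cut)
      wts <- c(wts, rep(alleleTable$read_count[i], length(pos)))
    }
  }
  if (length(offs) == 0L)
    return(list(histogram = data.frame(offset = integer(),
                                       deleted_bases = integer()),
                ratio = NA_real_, flag = "no_deletions"))
  hist <- aggregate(wts, by = list(offset = offs), FUN = sum)
  names(hist)[2] <- "deleted_bases"
  hist <- hist[order(hist$offset), ]
  # '+' strand: PAM lies 3' of the cut, so offsets >= 0 are PAM-proximal
  proximalSide <- if (locus@pamStrand == "+") hist$offset >= 0L else hist$offset < 0L
  proximal <- sum(hist$deleted_bases[proximalSide])
  distal <- sum(hist$deleted_bases[!proximalSide])
  if (proximal == 0L)
    return(list(histogram = hist, ratio = Inf, flag = "no_proximal_bases"))
  list(histogram = hist, ratio = distal / proximal, flag = character())
}
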