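## Pooled-screen statistics: read-to-guide assignment, per-guide Fisher
## tests against the pooled non-targeting control, directional ranking,
## Robust Rank Aggregation with permutation null distributions, and
## cross-library integration by weighted z-scores.

#' Assign reads to library guides by exact positional match
#'
#' Each read carries the library guide sequence at a fixed offset
#' (`guide_offset`, 0-based) in the read layout. Assignment is strict:
#' the guide region must match a manifest guide sequence exactly (no
#' mismatches). Unmatched reads are binned separately.
#'
#' @param reads character vector or `DNAStringSet`.
#' @param manifest data.frame with columns `guide_id`, `gene`, `category`,
#'   `guide_sequence` and `guide_offset` (a single shared offset).
#' @return list with `assignments` (data.frame `read`, `guide_id`;
#'   `guide_id` is `NA` for unmatched reads) and `counts` (named vector of
#'   reads per guide plus `"unmatched"`).
#' @export
assignReadsToGuides <- function(reads, manifest) {
  reads <- as.character(reads)
  if (anyDuplicated(manifest$guide_sequence))
    stop("duplicate guide sequences in manifest")
  off <- unique(manifest$guide_offset)
  if (length(off) != 1L)
    stop("a single shared guide offset is required")
  glen <- unique(nchar(manifest$guide_sequence))
  if (length(glen) != 1L)
    stop("guide sequences must have equal length")
  region <- substr(reads, off + 1L, off + glen)
  idx <- match(region, manifest$guide_sequence)
  gid <- manifest$guide_id[idx]
  counts <- table(factor(gid, levels = manifest$guide_id))
  counts <- c(as.integer(counts), sum(is.na(gid)))
  names(counts) <- c(manifest$guide_id, "unmatched")
  list(assignments = data.frame(read = reads, guide_id = gid,
                                stringsAsFactors = FALSE),
       counts = counts)
}

#' Build per-guide outcome-count records from a long count table
#'
#' @param counts long data.frame with columns `guide_id`, `pattern`,
#'   `count`.
#' @param manifest guide manifest (`guide_id`, `gene`, `category`).
#' @return data.frame with one row per guide: `guide_id`, `gene`,
#'   `category`, one column per edited pattern, and `total_edited`.
#' @export
guideRecords <- function(counts, manifest) {
  pats <- repairPatterns()
  wide <- matrix(0L, nrow = nrow(manifest), ncol = length(pats),
                 dimnames = list(manifest$guide_id, pats))
  sub <- counts[counts$pattern %in% pats, ]
  if (nrow(sub)) {
    i <- match(sub$guide_id, manifest$guide_id)
    j <- match(sub$pattern, pats)
    ok <- !is.na(i)
    for (r in which(ok)) wide[i[r], j[r]] <- wide[i[r], j[r]] + sub$count[r]
  }
  out <- data.frame(guide_id = manifest$guide_id, gene = manifest$gene,
                    category = manifest$category, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(wide, check.names = FALSE))
  out$total_edited <- as.integer(rowSums(wide))
  rownames(out) <- NULL
  out
}

#' Filter guides by read support
#'
#' Drops guides with `total_edited <= minReads` or without any detectable
#' edited allele, mirroring standard screen quality control.
#'
#' @param records output of [guideRecords()].
#' @param minReads exclusion boundary (default 10; a guide with exactly 10
#'   edited reads is excluded).
#' @return list with `kept` (filtered records) and `excluded` (data.frame
#'   `guide_id`, `reason`).
#' @export
filterGuides <- function(records, minReads = 10L) {
  lowReads <- records$total_edited <= minReads
  noEdit <- records$total_edited == 0L
  drop <- lowReads | noEdit
  reason <- ifelse(noEdit, "no_detectable_mutations", "low_reads")[drop]
  list(kept = records[!drop, , drop = FALSE],
       excluded = data.frame(guide_id = records$guide_id[drop],
                             reason = reason, stringsAsFactors = FALSE))
}

#' Pool non-targeting control counts
#'
#' @param records output of [guideRecords()] (post-filter).
#' @return named integer vector of pattern counts summed over all
#'   non-targeting guides.
#' @export
controlPool <- function(records) {
  nt <- records[records$category == "nontarget", repairPatterns(),
                drop = FALSE]
  if (nrow(nt) == 0L) stop("no non-targeting guides in records")
  colSums(nt)
}

## vectorized one-tailed hypergeometric p-values and log2FC for
## a/(a+b) vs c/(c+d); Haldane +0.5 on all cells for the log2FC when any
## cell is zero, raw counts for the exact test
.fisherTails <- function(a, b, c, d) {
  K <- a + c          # pattern reads overall
  N <- a + b + c + d
  n1 <- a + b         # guide reads
  pLeft <- phyper(a, K, N - K, n1)
  pRight <- phyper(a - 1, K, N - K, n1, lower.tail = FALSE)
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  h <- ifelse(zero, 0.5, 0)
  lfc <- log2(((a + h) / (a + b + 2 * h)) / ((c + h) / (c + d + 2 * h)))
  data.frame(log2fc = lfc, p_left = pLeft, p_right = pRight)
}

#' Fisher exact test of one guide's outcome frequency against controls
#'
#' Builds the 2x2 table `[[guide pattern, guide other], [control pattern,
#' control other]]` and computes the exact hypergeometric left-tail
#' (depletion) and right-tail (enrichment) p-values together with the
#' log2 fold change of outcome frequencies (guide vs control), using a
#' Haldane +0.5 pseudo-count for the fold change only when any cell is
#' zero.
#'
#' @param patternCount,otherCount edited reads of the guide in / out of the
#'   pattern.
#' @param controlPatternCount,controlOtherCount same for the pooled
#'   non-targeting control.
#' @return list with `log2fc`, `p_left`, `p_right`.
#' @examples
#' guideOutcomeTest(30, 70, 10, 90)
#' @export
guideOutcomeTest <- function(patternCount, otherCount,
                             controlPatternCount, controlOtherCount) {
  if (controlPatternCount + controlOtherCount == 0)
    stop("empty control pool")
  if (controlPatternCount == 0 || controlOtherCount == 0)
    stop("control pool must contain reads both in and out of the pattern")
  r <- .fisherTails(patternCount, otherCount,
                    controlPatternCount, controlOtherCount)
  list(log2fc = r$log2fc, p_left = r$p_left, p_right = r$p_right)
}

#' Per-guide statistics for one pattern across the screen
#'
#' Runs [guideOutcomeTest()] for every targeting guide against the pooled
#' non-targeting control.
#'
#' @param records filtered [guideRecords()].
#' @param pattern one of [repairPatterns()].
#' @param control pooled control counts from [controlPool()].
#' @return data.frame `guide_id`, `gene`, `category`, `log2fc`, `p_left`,
#'   `p_right` (targeting guides only).
#' @export
guideStats <- function(records, pattern, control = controlPool(records)) {
  stopifnot(pattern %in% repairPatterns())
  tg <- records[records$category != "nontarget", , drop = FALSE]
  a <- tg[[pattern]]
  b <- tg$total_edited - a
  cc <- control[[pattern]]
  dd <- sum(control) - cc
  if (cc == 0 || dd == 0)
    stop("control pool must contain reads both in and out of the pattern")
  res <- .fisherTails(a, b, cc, dd)
  cbind(tg[, c("guide_id", "gene", "category")], res)
}

#' Directional global ranking of guides
#'
#' For the promoting direction (knockout depletes the outcome),
#' direction-consistent guides (`log2fc < 0`) come first, sorted by
#' ascending left-tail p; inconsistent guides are appended, penalized by
#' sorting on descending left-tail p. The inhibiting direction mirrors this
#' with `log2fc > 0` and the right tail. Ties break by descending
#' `|log2fc|`, then lexically by `guide_id`. Ranks are normalized to
#' `position / n` in `(0, 1]`.
#'
#' @param stats guide statistics from [guideStats()].
#' @param direction `"promoting"` or `"inhibiting"`.
#' @return `stats` with added `rank` (normalized, in rank order of the
#'   returned rows).
#' @export
rankGuidesDirectional <- function(stats,
                                  direction = c("promoting", "inhibiting")) {
  direction <- match.arg(direction)
  stopifnot(nrow(stats) > 0L)
  if (direction == "promoting") {
    consistent <- stats$log2fc < 0
    p <- stats$p_left
  } else {
    consistent <- stats$log2fc > 0
    p <- stats$p_right
  }
  key <- ifelse(consistent, p, -p)  # consistent asc p first, then desc p
  o <- order(!consistent, key, -abs(stats$log2fc), stats$guide_id)
  out <- stats[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out)) / nrow(out)
  rownames(out) <- NULL
  out
}

#' Robust Rank Aggregation score for one gene
#'
#' Given the k normalized ranks of a gene's guides, sorts them and takes
#' the minimum over j of `pbeta(r_(j), j, k - j + 1)` -- the probability
#' that the j-th smallest of k independent uniforms falls at or below
#' `r_(j)`. Small scores indicate that the gene's guides sit unusually high
#' in the ranking.
#'
#' @param ranks normalized ranks in `(0, 1]`.
#' @return the RRA score (rho) in `(0, 1]`.
#' @examples
#' rraGeneScore(0.2)               # k = 1: rho equals the rank
#' rraGeneScore(c(0.1, 0.5))       # 0.19
#' @export
rraGeneScore <- function(ranks) {
  k <- length(ranks)
  stopifnot(k >= 1L, all(ranks > 0), all(ranks <= 1))
  r <- sort(ranks)
  min(pbeta(r, seq_len(k), k - seq_len(k) + 1L))
}

#' Simulated null distribution of the RRA score
#'
#' Draws `nPerm` sets of k independent uniform ranks and computes the RRA
#' score of each; the null depends only on k, so one simulation serves all
#' genes with the same number of guides.
#'
#' @param k guides per gene.
#' @param nPerm permutations (default 20000).
#' @return numeric vector of `nPerm` null RRA scores.
#' @export
rraNullDistribution <- function(k, nPerm = 20000L) {
  u <- matrix(runif(k * nPerm), nrow = k)
  u <- apply(u, 2L, sort)
  if (k == 1L) u <- matrix(u, nrow = 1L)
  betas <- pbeta(u, seq_len(k), k - seq_len(k) + 1L)
  if (k == 1L) as.numeric(betas) else apply(betas, 2L, min)
}

#' Empirical permutation p-value of an RRA score
#'
#' `p = (1 + #\{rho_null <= rho_obs\}) / (nPerm + 1)`; the add-one keeps
#' p-values strictly positive.
#'
#' @param rhoObserved observed RRA score(s).
#' @param k guides per gene (ignored when `null` is supplied).
#' @param nPerm permutations.
#' @param null optional precomputed [rraNullDistribution()].
#' @return empirical p-value(s), same length as `rhoObserved`.
#' @export
permutationPvalue <- function(rhoObserved, k, nPerm = 20000L, null = NULL) {
  if (is.null(null)) null <- rraNullDistribution(k, nPerm)
  sorted <- sort(null)
  (1 + findInterval(rhoObserved, sorted)) / (length(sorted) + 1)
}

#' Gene-level screen scores for one pattern and direction
#'
#' Full per-pattern pipeline: guide statistics versus the pooled
#' non-targeting control, directional global ranking, per-gene RRA score
#' over the gene's guide ranks, and an empirical permutation p-value.
#' The gene-level log2 fold change is the mean of the gene's guide-level
#' values.
#'
#' @param records filtered [guideRecords()].
#' @param pattern one of [repairPatterns()].
#' @param direction `"promoting"` or `"inhibiting"`.
#' @param nPerm permutations for the empirical p-value (default 20000).
#' @param nulls optional named list of precomputed null distributions,
#'   keyed by `k` (as character), to share across calls.
#' @return data.frame `gene`, `pattern`, `direction`, `n_guides`,
#'   `rra_rho`, `p_empirical`, `log2fc`.
#' @export
screenScores <- function(records, pattern,
                         direction = c("promoting", "inhibiting"),
                         nPerm = 20000L, nulls = NULL) {
  direction <- match.arg(direction)
  stats <- guideStats(records, pattern)
  ranked <- rankGuidesDirectional(stats, direction)
  byGene <- split(seq_len(nrow(ranked)), ranked$gene)
  genes <- names(byGene)
  ks <- vapply(byGene, length, integer(1))
  rho <- vapply(byGene, function(ix) rraGeneScore(ranked$rank[ix]), numeric(1))
  lfc <- vapply(byGene, function(ix) mean(ranked$log2fc[ix]), numeric(1))
  pEmp <- numeric(length(genes))
  for (k in unique(ks)) {
    null <- if (!is.null(nulls) && !is.null(nulls[[as.character(k)]]))
      nulls[[as.character(k)]] else rraNullDistribution(k, nPerm)
    sel <- ks == k
    pEmp[sel] <- permutationPvalue(rho[sel], k, nPerm, null = null)
  }
  out <- data.frame(gene = genes, pattern = pattern, direction = direction,
                    n_guides = ks, rra_rho = rho, p_empirical = pEmp,
                    log2fc = lfc, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$rra_rho, out$gene), , drop = FALSE]
}

#' Integrate two target-site libraries
#'
#' For genes present in both libraries, combines effect sizes by weighted
#' average and one-tailed p-values by weighted Stouffer z-scores:
#' `z_i = qnorm(1 - p_i)`, `z = (wA zA + wB zB) / sqrt(wA^2 + wB^2)`,
#' `p_combined = 1 - pnorm(z)`. Default weights are each library's overall
#' frequency of the pattern being tested.
#'
#' @param scoresA,scoresB outputs of [screenScores()] for the same pattern
#'   and direction in two libraries.
#' @param weightA,weightB positive weights (e.g. the pattern's overall
#'   outcome frequency in each library).
#' @return data.frame `gene`, `pattern`, `direction`, `combined_log2fc`,
#'   `p_combined`, plus the per-library columns; genes absent from one
#'   library are dropped (reported via the `dropped` attribute).
#' @examples
#' # equal weights, p = 0.05 in both libraries -> p_combined ~ 0.0100
#' @export
integrateLibraries <- function(scoresA, scoresB, weightA = 1, weightB = 1) {
  stopifnot(weightA > 0, weightB > 0)
  key <- c("gene", "pattern", "direction")
  m <- merge(scoresA, scoresB, by = key, suffixes = c("_A", "_B"))
  droppedGenes <- setdiff(union(scoresA$gene, scoresB$gene), m$gene)
  pmin_ <- .Machine$double.xmin
  pA <- pmin(pmax(m$p_empirical_A, pmin_), 1 - 1e-16)
  pB <- pmin(pmax(m$p_empirical_B, pmin_), 1 - 1e-16)
  zA <- qnorm(1 - pA)
  zB <- qnorm(1 - pB)
  z <- (weightA * zA + weightB * zB) / sqrt(weightA^2 + weightB^2)
  out <- data.frame(
    gene = m$gene, pattern = m$pattern, direction = m$direction,
    combined_log2fc = (weightA * m$log2fc_A + weightB * m$log2fc_B) /
      (weightA + weightB),
    p_combined = 1 - pnorm(z),
    rra_rho_A = m$rra_rho_A, rra_rho_B = m$rra_rho_B,
    p_empirical_A = m$p_empirical_A, p_empirical_B = m$p_empirical_B,
    log2fc_A = m$log2fc_A, log2fc_B = m$log2fc_B,
    stringsAsFactors = FALSE)
  out <- out[order(out$p_combined, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- droppedGenes
  out
}

#' Call significant pattern-associated genes
#'
#' A gene is a hit for a pattern/direction when `|combined_log2fc| >
#' lfcThreshold` and `p_combined < pThreshold` (both strict).
#'
#' @param geneScores output of [integrateLibraries()] (or any data.frame
#'   with `combined_log2fc` and `p_combined`).
#' @param lfcThreshold effect-size threshold (default 0.5).
#' @param pThreshold significance threshold (default 0.05).
#' @param adjust apply Benjamini-Hochberg to `p_combined` before
#'   thresholding (off by default, matching permutation-p + effect-size
#'   practice).
#' @return `geneScores` with an added logical `is_hit` column (and
#'   `p_adjusted` when `adjust = TRUE`).
#' @export
callHits <- function(geneScores, lfcThreshold = 0.5, pThreshold = 0.05,
                     adjust = FALSE) {
  p <- geneScores$p_combined
  if (adjust) {
    geneScores$p_adjusted <- p.adjust(p, method = "BH")
    p <- geneScores$p_adjusted
  }
  geneScores$is_hit <- abs(geneScores$combined_log2fc) > lfcThreshold &
    p < pThreshold
  geneScores
}

#' Overall frequency of a pattern in a library
#'
#' The default integration weight: the pattern's share of all edited reads
#' across the library's (filtered) guides.
#'
#' @param records filtered [guideRecords()].
#' @param pattern one of [repairPatterns()].
#' @return a single frequency in `[0, 1]`.
#' @export
patternFrequency <- function(records, pattern) {
  stopifnot(pattern %in% repairPatterns())
  sum(records[[pattern]]) / sum(records$total_edited)
}
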