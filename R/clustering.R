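## Top-gene selection, effect-matrix standardization, average-linkage
## clustering and the gene-gene Pearson correlation matrix.

#' Select top pattern-associated genes and build the effect matrix
#'
#' For each of the seven patterns, takes the `nTop` best promoting and
#' `nTop` best inhibiting genes by gene-level p-value (ties broken by RRA
#' score, then gene name). The selection list therefore has
#' `7 * 2 * nTop` slots; genes selected for several patterns appear once
#' per selection but only once as a row of the effect matrix, whose entries
#' are the combined log2 fold changes across all seven patterns.
#'
#' @param geneScores integrated gene scores covering both directions for
#'   all patterns (columns `gene`, `pattern`, `direction`,
#'   `combined_log2fc`, `p_combined`).
#' @param nTop genes per direction per pattern (default 50).
#' @return list with `selection` (data.frame `gene`, `pattern`,
#'   `direction`, `p_combined`) and `matrix` (deduplicated genes x patterns
#'   log2FC matrix).
#' @export
selectTopGenes <- function(geneScores, nTop = 50L) {
  pats <- intersect(repairPatterns(), unique(geneScores$pattern))
  sel <- list()
  for (pat in pats) {
    for (dir in c("promoting", "inhibiting")) {
      sub <- geneScores[geneScores$pattern == pat &
                        geneScores$direction == dir, , drop = FALSE]
      sub <- sub[order(sub$p_combined, sub$rra_rho_A %||% sub$p_combined,
                       sub$gene), , drop = FALSE]
      if (nrow(sub) < nTop)
        warning(sprintf("only %d candidates for %s/%s (wanted %d)",
                        nrow(sub), pat, dir, nTop))
      take <- head(sub, nTop)
      sel[[length(sel) + 1L]] <- data.frame(
        gene = take$gene, pattern = pat, direction = dir,
        p_combined = take$p_combined, stringsAsFactors = FALSE)
    }
  }
  selection <- do.call(rbind, sel)
  genes <- sort(unique(selection$gene))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(pats),
                dimnames = list(genes, pats))
  # effect sizes are direction-independent; either direction's row serves
  eff <- unique(geneScores[, c("gene", "pattern", "combined_log2fc")])
  eff <- eff[eff$gene %in% genes, , drop = FALSE]
  mat[cbind(match(eff$gene, genes), match(eff$pattern, pats))] <-
    eff$combined_log2fc
  list(selection = selection, matrix = mat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize effect profiles per gene
#'
#' Z-scores each row (gene) of an effect matrix across the patterns.
#' Constant rows cannot be standardized; they become all-zero and are
#' reported via the `constant` attribute.
#'
#' @param mat genes x patterns matrix of log2 fold changes.
#' @return the standardized matrix (row means 0, row SDs 1 except constant
#'   rows), with attribute `constant` naming the flagged rows.
#' @export
standardizeProfiles <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, sd)
  const <- s < 1e-12
  s[const] <- 1
  z <- sweep(sweep(mat, 1L, mu, "-"), 1L, s, "/")
  z[const, ] <- 0
  attr(z, "constant") <- rownames(mat)[const]
  z
}

#' Average-linkage hierarchical clustering of effect profiles
#'
#' Agglomerative clustering with average linkage on Euclidean distances
#' between standardized profiles (rows) or between patterns (columns).
#' Merges are deterministic; equal-distance ties resolve to the pair with
#' the lower original index.
#'
#' @param mat effect matrix (standardize first via [standardizeProfiles()]
#'   if rows are on different scales).
#' @param axis `"rows"` (genes) or `"cols"` (patterns).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @return list with `hclust` (the [stats::hclust] object), `merges`
#'   (data.frame `step`, `left`, `right`, `height`, `size`) and `order`
#'   (leaf labels in dendrogram order).
#' @export
hclusterProfiles <- function(mat, axis = c("rows", "cols"),
                             distance = c("euclidean", "correlation")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  x <- if (axis == "rows") mat else t(mat)
  if (nrow(x) < 2L) stop("need at least two profiles to cluster")
  if (anyNA(x))
    stop("NA values in profiles: ",
         paste(rownames(x)[apply(is.na(x), 1L, any)], collapse = ", "))
  d <- if (distance == "euclidean") dist(x) else as.dist(1 - cor(t(x)))
  hc <- hclust(d, method = "average")
  sizes <- integer(nrow(hc$merge))
  sz <- function(i) if (i < 0) 1L else sizes[i]
  for (s in seq_len(nrow(hc$merge)))
    sizes[s] <- sz(hc$merge[s, 1]) + sz(hc$merge[s, 2])
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height, size = sizes)
  list(hclust = hc, merges = merges, order = rownames(x)[hc$order])
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlates every pair of gene effect profiles across the patterns.
#' Constant rows have undefined correlations; their entries are `NA` and
#' the rows are reported via the `constant` attribute.
#'
#' @param mat genes x patterns effect matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonMatrix <- function(mat) {
  stopifnot(nrow(mat) >= 2L)
  s <- apply(mat, 1L, sd)
  const <- s < 1e-12
  r <- suppressWarnings(cor(t(mat)))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- 1
  attr(r, "constant") <- rownames(mat)[const]
  r
}
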