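## File interchange (TSV / FASTA / FASTQ), barcode demultiplexing,
## configuration and the end-to-end screen pipeline.
## TSV dialect everywhere: tab-separated, header row, UTF-8, '.' decimal;
## lines starting with '#' are metadata (producing stage + config hash).

#' Read and write pipeline TSV tables
#'
#' All pipeline tables are tab-separated with a header row; comment lines
#' (`#`) carry provenance (producing stage and configuration hash) and are
#' skipped on read.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @param stage producing stage name recorded in the header comment.
#' @param configHash configuration hash recorded in the header comment.
#' @return `readPipelineTsv`: a data.frame; `writePipelineTsv`: `path`,
#'   invisibly.
#' @export
readPipelineTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname readPipelineTsv
#' @export
writePipelineTsv <- function(x, path, stage = "repairmap",
                             configHash = "") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s config=%s", stage, configHash), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reads from FASTA or FASTQ
#'
#' @param path file path; format inferred from the extension
#'   (`.fq`/`.fastq` vs FASTA otherwise).
#' @return a [Biostrings::DNAStringSet].
#' @export
readReads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  readDNAStringSet(path, format = fmt)
}

#' Write reads as FASTQ (constant quality) or FASTA
#'
#' @param reads a `DNAStringSet` (or named character vector).
#' @param path output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
writeReads <- function(reads, path) {
  if (!is(reads, "DNAStringSet")) reads <- DNAStringSet(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) {
    quals <- Biostrings::BStringSet(vapply(width(reads), function(w)
      paste(rep("I", w), collapse = ""), character(1)))
    writeXStringSet(reads, path, format = "fastq", qualities = quals)
  } else {
    writeXStringSet(reads, path, format = "fasta")
  }
  invisible(path)
}

#' Demultiplex reads by exact barcode prefix
#'
#' Barcodes must be unique and equal-length. A read is assigned to the
#' sample whose barcode matches its prefix with at most `maxMismatch`
#' mismatches (default 0, exact); the barcode is stripped. Ambiguous
#' matches (possible only with `maxMismatch > 0`) and non-matching reads
#' go to the `unmatched` bin.
#'
#' @param reads `DNAStringSet` or character vector.
#' @param barcodes named character vector (names = sample ids).
#' @param maxMismatch 0 (default) or 1.
#' @return named list of character vectors of barcode-stripped reads, one
#'   per sample, plus `unmatched` (reads kept intact).
#' @export
demultiplexByBarcode <- function(reads, barcodes, maxMismatch = 0L) {
  reads <- as.character(reads)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L) stop("barcodes must have equal length")
  stopifnot(maxMismatch %in% c(0L, 1L))
  prefix <- substr(reads, 1L, bl)
  if (maxMismatch == 0L) {
    idx <- match(prefix, barcodes)
  } else {
    mm <- vapply(barcodes, function(b) {
      bb <- strsplit(b, "")[[1]]
      pm <- matrix(unlist(strsplit(prefix, ""), use.names = FALSE),
                   nrow = bl)
      colSums(pm != bb)
    }, numeric(length(reads)))
    mm <- matrix(mm, nrow = length(reads))
    hits <- mm <= maxMismatch
    nHits <- rowSums(hits)
    idx <- ifelse(nHits == 1L, max.col(hits, ties.method = "first"),
                  NA_integer_)
  }
  out <- lapply(seq_along(barcodes), function(i) {
    r <- reads[which(idx == i)]
    substr(r, bl + 1L, nchar(r))
  })
  names(out) <- names(barcodes)
  out$unmatched <- reads[is.na(idx)]
  out
}

#' Assemble and validate a run configuration
#'
#' Collects the tunable thresholds of the pipeline with their defaults,
#' validates ranges, and attaches a hash used to stamp output tables.
#' Round-trips losslessly through YAML.
#'
#' @param ... named overrides of the defaults (`window_bp`, `mh_min`,
#'   `min_reads`, `n_perm`, `seed`, `lfc_threshold`, `p_threshold`,
#'   `n_top`, alignment scores, and I/O paths such as `manifest`,
#'   `counts`, `counts2`, `out_dir`).
#' @return a `runConfig` list with attribute `hash`.
#' @export
runConfig <- function(...) {
  cfg <- list(window_bp = 5L, mh_min = 2L, min_reads = 10L,
              n_perm = 20000L, seed = 1L, lfc_threshold = 0.5,
              p_threshold = 0.05, n_top = 50L,
              align_match = 2, align_mismatch = -3, align_gap_open = 8,
              align_gap_extend = 1, min_identity = 0.6,
              manifest = NULL, counts = NULL, counts2 = NULL,
              reads = NULL, reference = NULL, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$window_bp >= 0, cfg$mh_min >= 1, cfg$min_reads >= 0,
            cfg$n_perm >= 100, cfg$p_threshold > 0, cfg$p_threshold < 1,
            cfg$lfc_threshold >= 0, cfg$min_identity > 0,
            cfg$min_identity <= 1)
  attr(cfg, "hash") <- configHash(cfg)
  cfg
}

#' @rdname runConfig
#' @param cfg a config list.
#' @param path YAML file path.
#' @export
writeConfigYaml <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML config files")
  yaml::write_yaml(Filter(Negate(is.null), cfg), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readConfigYaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML config files")
  do.call(runConfig, yaml::read_yaml(path))
}

#' @rdname runConfig
#' @export
configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), tmp)
  unname(md5sum(tmp))
}

.logLine <- function(con, stage, ...) {
  fields <- list(...)
  extra <- if (length(fields))
    paste0(vapply(names(fields), function(nm) {
      v <- fields[[nm]]
      sprintf(',"%s":%s', nm,
              if (is.character(v)) sprintf('"%s"', v) else as.character(v))
    }, character(1)), collapse = "") else ""
  msg <- sprintf('{"stage":"%s","time":"%s"%s}', stage,
                 format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), extra)
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

#' Run the end-to-end screen pipeline
#'
#' Orchestrates the screen stages: (optionally) classify reads per guide,
#' build and filter guide records, test every pattern in both directions,
#' aggregate with RRA + permutation p-values, integrate a second library
#' when present, call hits, and select/cluster top genes. Writes TSV
#' artifacts plus a JSON-lines run log to `out_dir` when configured; every
#' table header names the producing stage and the config hash.
#'
#' @param config a [runConfig()]. Inputs may be file paths (read via the
#'   package readers) or in-memory objects: `manifest` (data.frame),
#'   `counts`/`counts2` (long count data.frames).
#' @param patterns patterns to analyze (default all seven).
#' @return list with `records`, `excluded`, `geneScores` (integrated or
#'   single-library), `hits`, `topGenes` (selection + matrix; `NULL` when
#'   too few genes), and `config`.
#' @export
runPipeline <- function(config, patterns = repairPatterns()) {
  hash <- attr(config, "hash") %||% configHash(config)
  outDir <- config$out_dir
  logCon <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logCon <- file(file.path(outDir, "run_log.jsonl"), "w")
    on.exit(close(logCon))
  }
  .logLine(logCon, "config", hash = hash, seed = config$seed)
  loadTable <- function(x, what) {
    if (is.null(x)) stop("config is missing required input: ", what)
    if (is.character(x)) {
      if (!file.exists(x)) stop("missing ", what, " file: ", x)
      readPipelineTsv(x)
    } else x
  }
  manifest <- loadTable(config$manifest, "manifest")
  counts <- loadTable(config$counts, "counts")
  set.seed(config$seed)
  records <- guideRecords(counts, manifest)
  flt <- filterGuides(records, config$min_reads)
  .logLine(logCon, "filter", kept = nrow(flt$kept),
           excluded = nrow(flt$excluded))
  scoreLibrary <- function(recs) {
    nulls <- list()
    for (k in unique(table(recs$gene[recs$category != "nontarget"])))
      nulls[[as.character(k)]] <- rraNullDistribution(k, config$n_perm)
    do.call(rbind, lapply(patterns, function(pat) {
      do.call(rbind, lapply(c("promoting", "inhibiting"), function(dir)
        screenScores(recs, pat, dir, nPerm = config$n_perm, nulls = nulls)))
    }))
  }
  scoresA <- scoreLibrary(flt$kept)
  if (!is.null(config$counts2)) {
    counts2 <- loadTable(config$counts2, "counts2")
    records2 <- guideRecords(counts2, manifest)
    flt2 <- filterGuides(records2, config$min_reads)
    scoresB <- scoreLibrary(flt2$kept)
    integrated <- do.call(rbind, lapply(patterns, function(pat) {
      wA <- patternFrequency(flt$kept, pat)
      wB <- patternFrequency(flt2$kept, pat)
      do.call(rbind, lapply(c("promoting", "inhibiting"), function(dir)
        integrateLibraries(scoresA[scoresA$pattern == pat &
                                   scoresA$direction == dir, ],
                           scoresB[scoresB$pattern == pat &
                                   scoresB$direction == dir, ],
                           wA, wB)))
    }))
    geneScores <- integrated
  } else {
    # single library: the per-library values stand in for the combined ones
    geneScores <- scoresA
    geneScores$combined_log2fc <- geneScores$log2fc
    geneScores$p_combined <- geneScores$p_empirical
  }
  hits <- callHits(geneScores, config$lfc_threshold, config$p_threshold)
  .logLine(logCon, "hits", n_hits = sum(hits$is_hit))
  topGenes <- NULL
  nCandidates <- length(unique(geneScores$gene))
  if (nCandidates >= 2L) {
    topGenes <- tryCatch(suppressWarnings(
      selectTopGenes(geneScores, min(config$n_top, nCandidates))),
      error = function(e) NULL)
    if (!is.null(topGenes) && nrow(topGenes$matrix) >= 2L &&
        ncol(topGenes$matrix) >= 2L && !anyNA(topGenes$matrix)) {
      z <- standardizeProfiles(topGenes$matrix)
      topGenes$clustering <- hclusterProfiles(z, "rows")
      topGenes$correlation <- pearsonMatrix(topGenes$matrix)
    }
  }
  if (!is.null(outDir)) {
    writePipelineTsv(hits, file.path(outDir, "gene_scores.tsv"),
                     "screen_stats", hash)
    writePipelineTsv(flt$excluded, file.path(outDir, "excluded_guides.tsv"),
                     "filter_guides", hash)
    if (!is.null(topGenes)) {
      writePipelineTsv(topGenes$selection,
                       file.path(outDir, "top_genes.tsv"),
                       "select_top_genes", hash)
      if (!is.null(topGenes$clustering))
        writePipelineTsv(topGenes$clustering$merges,
                         file.path(outDir, "cluster_merges.tsv"),
                         "hcluster_profiles", hash)
    }
    .logLine(logCon, "done", out_dir = outDir)
  }
  list(records = flt$kept, excluded = flt$excluded, geneScores = geneScores,
       hits = hits, topGenes = topGenes, config = config)
}
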