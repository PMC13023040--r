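## S4 containers for the central objects: the target locus, a sample's
## outcome spectrum, and a kinetic model fit.

#' @rdname TargetLocus
#' @export
setClass("TargetLocus",
  slots = c(
    refSeq           = "DNAString",
    protospacerStart = "integer",
    protospacerLen   = "integer",
    pamStart         = "integer",
    pamStrand        = "character",
    cutSite          = "integer"
  )
)

setValidity("TargetLocus", function(object) {
  msgs <- character()
  n <- length(object@refSeq)
  ps <- object@protospacerStart
  pl <- object@protospacerLen
  pam <- object@pamStart
  if (!object@pamStrand %in% c("+", "-"))
    msgs <- c(msgs, "pamStrand must be '+' or '-'")
  if (ps < 0L || ps + pl > n)
    msgs <- c(msgs, "protospacer outside reference")
  if (pam < 0L || pam + 3L > n)
    msgs <- c(msgs, "PAM outside reference")
  if (object@pamStrand == "+" && pam != ps + pl)
    msgs <- c(msgs, "on '+' strand the PAM must immediately follow the protospacer")
  if (object@pamStrand == "-" && ps != pam + 3L)
    msgs <- c(msgs, "on '-' strand the PAM must immediately precede the protospacer")
  if (object@cutSite <= 0L || object@cutSite >= n)
    msgs <- c(msgs, "cut site must lie strictly inside the reference")
  if (length(msgs)) msgs else TRUE
})

#' Target locus: reference amplicon with protospacer, PAM and cut site
#'
#' A `TargetLocus` holds the reference amplicon sequence together with the
#' protospacer and PAM coordinates and the inferred blunt cut site. All
#' coordinates are 0-based; intervals are half-open; the cut site is an
#' inter-base coordinate (the junction between reference positions
#' `cutSite - 1` and `cutSite`). SpCas9 cuts bluntly 3 nt 5' of the PAM on
#' the protospacer strand, which [locateCutSite()] mirrors on either strand.
#'
#' @param refSeq reference amplicon, a [Biostrings::DNAString] or character.
#' @param protospacerStart 0-based start of the protospacer on `refSeq`.
#' @param protospacerLen protospacer length (default 20).
#' @param pamStart 0-based start of the 3-nt PAM on `refSeq` (plus-strand
#'   coordinates regardless of `pamStrand`).
#' @param pamStrand `"+"` if the protospacer/PAM read on the given strand,
#'   `"-"` if on the reverse complement.
#' @return a `TargetLocus` object.
#' @examples
#' loc <- TargetLocus("ATGCATGCATGCATGCATGCAGGTACGTAC",
#'                    protospacerStart = 0, pamStart = 20)
#' cutSite(loc)
#' @seealso [locateCutSite()]
#' @export
TargetLocus <- function(refSeq, protospacerStart, protospacerLen = 20L,
                        pamStart, pamStrand = "+") {
  if (is.character(refSeq)) refSeq <- DNAString(refSeq)
  cut <- locateCutSite(protospacerStart, protospacerLen, pamStart, pamStrand)
  new("TargetLocus",
      refSeq = refSeq,
      protospacerStart = as.integer(protospacerStart),
      protospacerLen = as.integer(protospacerLen),
      pamStart = as.integer(pamStart),
      pamStrand = pamStrand,
      cutSite = as.integer(cut))
}

#' @rdname TargetLocus
#' @param object,x a `TargetLocus`.
#' @export
setGeneric("cutSite", function(x) standardGeneric("cutSite"))

#' @rdname TargetLocus
#' @export
setMethod("cutSite", "TargetLocus", function(x) x@cutSite)

#' @rdname TargetLocus
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname TargetLocus
#' @export
setMethod("refSequence", "TargetLocus", function(x) x@refSeq)

#' @rdname TargetLocus
#' @export
setGeneric("pamStrand", function(x) standardGeneric("pamStrand"))

#' @rdname TargetLocus
#' @export
setMethod("pamStrand", "TargetLocus", function(x) x@pamStrand)

setMethod("show", "TargetLocus", function(object) {
  cat("TargetLocus of length", length(object@refSeq), "\n")
  cat("  protospacer: [", object@protospacerStart, ",",
      object@protospacerStart + object@protospacerLen, ") ",
      "PAM: [", object@pamStart, ",", object@pamStart + 3L, ") on '",
      object@pamStrand, "'\n", sep = "")
  cat("  cut site (inter-base):", object@cutSite, "\n")
})

#' @rdname summarizeSpectrum
#' @export
setClass("OutcomeSpectrum",
  slots = c(
    counts          = "integer",    # named, over repairPatterns(TRUE)
    proportions     = "numeric",    # named, over the 7 edited patterns
    totalEdited     = "integer",
    editingFraction = "numeric",
    alleleTable     = "data.frame",
    flags           = "character"
  )
)

setValidity("OutcomeSpectrum", function(object) {
  msgs <- character()
  if (!all(repairPatterns(TRUE) %in% names(object@counts)))
    msgs <- c(msgs, "counts must be named over the eight labels")
  if (object@totalEdited > 0L &&
      abs(sum(object@proportions) - 1) > 1e-9)
    msgs <- c(msgs, "edited-pattern proportions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname summarizeSpectrum
#' @param x an `OutcomeSpectrum`.
#' @export
setGeneric("patternCounts", function(x) standardGeneric("patternCounts"))

#' @rdname summarizeSpectrum
#' @export
setMethod("patternCounts", "OutcomeSpectrum", function(x) x@counts)

#' @rdname summarizeSpectrum
#' @export
setGeneric("patternProportions", function(x) standardGeneric("patternProportions"))

#' @rdname summarizeSpectrum
#' @export
setMethod("patternProportions", "OutcomeSpectrum", function(x) x@proportions)

#' @rdname summarizeSpectrum
#' @export
setGeneric("editingFraction", function(x) standardGeneric("editingFraction"))

#' @rdname summarizeSpectrum
#' @export
setMethod("editingFraction", "OutcomeSpectrum", function(x) x@editingFraction)

#' @rdname summarizeSpectrum
#' @export
setGeneric("alleleTable", function(x) standardGeneric("alleleTable"))

#' @rdname summarizeSpectrum
#' @export
setMethod("alleleTable", "OutcomeSpectrum", function(x) x@alleleTable)

setMethod("show", "OutcomeSpectrum", function(object) {
  cat("OutcomeSpectrum:", object@totalEdited, "edited reads, editing fraction",
      signif(object@editingFraction, 4), "\n")
  if (object@totalEdited > 0L) {
    df <- data.frame(count = object@counts[repairPatterns()],
                     proportion = round(object@proportions[repairPatterns()], 4))
    print(df)
  }
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname fitRepairODE
#' @export
setClass("KineticFit",
  slots = c(
    params    = "numeric",     # k_cut, k_err, k_perf, f_max (h^-1, fraction)
    rSquared  = "numeric",
    residuals = "numeric",
    flags     = "character",
    details   = "list"
  )
)

setValidity("KineticFit", function(object) {
  msgs <- character()
  need <- c("k_cut", "k_err", "k_perf", "f_max")
  if (!all(need %in% names(object@params)))
    msgs <- c(msgs, "params must contain k_cut, k_err, k_perf, f_max")
  else {
    if (any(object@params[c("k_cut", "k_err", "k_perf")] < 0))
      msgs <- c(msgs, "rate constants must be non-negative")
    if (object@params[["f_max"]] <= 0 || object@params[["f_max"]] > 1)
      msgs <- c(msgs, "f_max must be in (0, 1]")
  }
  if (length(object@rSquared) && object@rSquared > 1 + 1e-12)
    msgs <- c(msgs, "r_squared cannot exceed 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname fitRepairODE
#' @param x a `KineticFit`.
#' @export
setGeneric("kineticParams", function(x) standardGeneric("kineticParams"))

#' @rdname fitRepairODE
#' @export
setMethod("kineticParams", "KineticFit", function(x) x@params)

#' @rdname fitRepairODE
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname fitRepairODE
#' @export
setMethod("rSquared", "KineticFit", function(x) x@rSquared)

#' @rdname fitRepairODE
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))

#' @rdname fitRepairODE
#' @export
setMethod("fitFlags", "KineticFit", function(x) x@flags)

setMethod("show", "KineticFit", function(object) {
  cat("KineticFit\n")
  cat(sprintf("  k_cut  = %.4g /h\n  k_err  = %.4g /h\n  k_perf = %.4g /h\n  f_max  = %.4g\n",
              object@params[["k_cut"]], object@params[["k_err"]],
              object@params[["k_perf"]], object@params[["f_max"]]))
  cat("  R^2 =", signif(object@rSquared, 6), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
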