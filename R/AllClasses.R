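#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet BStringSet reverseComplement
#'   matchPattern vmatchPattern consensusMatrix readDNAStringSet
#'   writeXStringSet startIndex
#' @importFrom S4Vectors mcols
#' @importFrom BiocGenerics start width
NULL

.VALID_BASES <- c("A", "C", "G", "T")

#' Amplicon reference with protospacer, PAM and editing-region coordinates
#'
#' Holds an amplicon sequence normalised to protospacer orientation, the
#' 1-based coordinates of the protospacer, the PAM immediately 3' of it, and
#' the fixed-length editing region whose exact flanking sequences anchor read
#' extraction. All reporting downstream is in PAM-relative coordinates:
#' offset -1 is the protospacer base adjacent to the PAM, offset -k lies k
#' bases 5' of the PAM.
#'
#' @slot amplicon [Biostrings::DNAString] amplicon in protospacer orientation.
#' @slot protospacerStart,protospacerLen integer, 1-based start and length of
#'   the protospacer within `amplicon`.
#' @slot pamStart,pamLen integer, 1-based start and length of the PAM
#'   (immediately 3' of the protospacer).
#' @slot strand `"plus"` if the protospacer was found on the input amplicon as
#'   given, `"minus"` if the input was reverse-complemented at ingest.
#' @slot regionStart,regionEnd integer, 1-based closed interval of the
#'   fixed-length editing region; it contains the protospacer.
#' @slot leftFlank,rightFlank character, the amplicon subsequences immediately
#'   outside the region, used as exact extraction anchors.
#'
#' @seealso [buildReference()], [offsetToIndex()], [targetCytidines()]
#' @export
setClass("AmpliconReference",
  representation(
    amplicon = "DNAString",
    protospacerStart = "integer",
    protospacerLen = "integer",
    pamStart = "integer",
    pamLen = "integer",
    strand = "character",
    regionStart = "integer",
    regionEnd = "integer",
    leftFlank = "character",
    rightFlank = "character"
  )
)

setValidity("AmpliconReference", function(object) {
  amp <- as.character(object@amplicon)
  msgs <- character()
  if (grepl("[^ACGT]", amp))
    msgs <- c(msgs, "amplicon must contain only uppercase A/C/G/T")
  ps <- object@protospacerStart
  pe <- ps + object@protospacerLen - 1L
  pamEnd <- object@pamStart + object@pamLen - 1L
  if (ps < 1L || pamEnd > nchar(amp))
    msgs <- c(msgs, "protospacer/PAM outside amplicon")
  if (object@pamStart != pe + 1L)
    msgs <- c(msgs, "PAM must be immediately 3' of the protospacer")
  if (!object@strand %in% c("plus", "minus"))
    msgs <- c(msgs, "strand must be 'plus' or 'minus'")
  if (object@regionStart > ps || object@regionEnd < pe)
    msgs <- c(msgs, "editing region must contain the protospacer")
  lf <- object@leftFlank
  rf <- object@rightFlank
  if (nchar(lf) == 0L || nchar(rf) == 0L)
    msgs <- c(msgs, "flanks must be non-empty")
  if (object@regionStart - nchar(lf) < 1L ||
      object@regionEnd + nchar(rf) > nchar(amp))
    msgs <- c(msgs, "flanks extend outside the amplicon")
  else {
    if (substr(amp, object@regionStart - nchar(lf), object@regionStart - 1L) != lf)
      msgs <- c(msgs, "leftFlank does not match the amplicon")
    if (substr(amp, object@regionEnd + 1L, object@regionEnd + nchar(rf)) != rf)
      msgs <- c(msgs, "rightFlank does not match the amplicon")
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of sequencing reads for one sample
#'
#' A thin wrapper over a [Biostrings::DNAStringSet] with optional Phred+33
#' qualities and a sample label. Qualities of length zero mean "absent".
#'
#' @slot sequences [Biostrings::DNAStringSet] of read sequences (named by
#'   read id).
#' @slot qualities [Biostrings::BStringSet] of Phred+33 quality strings,
#'   parallel to `sequences`, or length zero when absent.
#' @slot sampleId character(1) sample label.
#'
#' @seealso [ReadSet()], [readFastqReads()], [demultiplex()]
#' @export
setClass("ReadSet",
  representation(
    sequences = "DNAStringSet",
    qualities = "BStringSet",
    sampleId = "character"
  )
)

setValidity("ReadSet", function(object) {
  msgs <- character()
  if (any(Biostrings::width(object@sequences) == 0L))
    msgs <- c(msgs, "read sequences must be non-empty")
  nq <- length(object@qualities)
  if (nq > 0L) {
    if (nq != length(object@sequences))
      msgs <- c(msgs, "qualities must be absent or parallel to sequences")
    else if (any(Biostrings::width(object@qualities) !=
                 Biostrings::width(object@sequences)))
      msgs <- c(msgs, "quality strings must match sequence lengths")
  }
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Extracted fixed-length editing regions with rejection accounting
#'
#' Result of [extractRegions()]: the editing-region segments of all reads in
#' which both flanks matched exactly, each occurring once, framing a segment
#' of exactly the reference region length, plus counters for every rejection
#' cause. `nInput = nMatched + nRejectedFlank + nRejectedLength +
#' nRejectedAmbiguous` always holds.
#'
#' @slot regions [Biostrings::DNAStringSet], all of the reference region width.
#' @slot nInput,nMatched,nRejectedFlank,nRejectedLength,nRejectedAmbiguous
#'   integer counters.
#' @export
setClass("EditingRegionSet",
  representation(
    regions = "DNAStringSet",
    nInput = "integer",
    nMatched = "integer",
    nRejectedFlank = "integer",
    nRejectedLength = "integer",
    nRejectedAmbiguous = "integer"
  )
)

setValidity("EditingRegionSet", function(object) {
  msgs <- character()
  if (object@nInput != object@nMatched + object@nRejectedFlank +
      object@nRejectedLength + object@nRejectedAmbiguous)
    msgs <- c(msgs, "counters must partition nInput")
  if (object@nMatched != length(object@regions))
    msgs <- c(msgs, "nMatched must equal the number of stored regions")
  w <- unique(Biostrings::width(object@regions))
  if (length(w) > 1L)
    msgs <- c(msgs, "all regions must have identical width")
  if (length(msgs)) msgs else TRUE
})

#' Indel classification summary
#'
#' Result of [classifyIndels()]: reads are scanned for two exactly matching
#' flanking anchors; included reads whose enclosed segment has exactly the
#' reference region length carry no indel, any other length is an indel.
#' `indelFrequency` is `nIndel / (nIndel + nNoIndel)`, `NA` when no read was
#' included.
#'
#' @slot nScanned,nNoIndel,nIndel,nExcludedFlank integer counters.
#' @slot indelFrequency numeric(1) fraction in `[0, 1]` or `NA`.
#' @export
setClass("IndelSummary",
  representation(
    nScanned = "integer",
    nNoIndel = "integer",
    nIndel = "integer",
    nExcludedFlank = "integer",
    indelFrequency = "numeric"
  )
)

setValidity("IndelSummary", function(object) {
  msgs <- character()
  if (object@nScanned != object@nNoIndel + object@nIndel + object@nExcludedFlank)
    msgs <- c(msgs, "counters must partition nScanned")
  den <- object@nNoIndel + object@nIndel
  if (den > 0L) {
    if (abs(object@indelFrequency - object@nIndel / den) > 1e-12)
      msgs <- c(msgs, "indelFrequency inconsistent with counts")
  } else if (!is.na(object@indelFrequency)) {
    msgs <- c(msgs, "indelFrequency must be NA when no read is included")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-position base substitution matrix
#'
#' Result of [conversionMatrix()]: for every position of the editing region,
#' the count and frequency of each base among the matched reads. Frequencies
#' use the total number of matched reads as denominator. Positions inside the
#' protospacer (and any region position 5' of it) also carry their
#' PAM-relative offset.
#'
#' @slot counts integer matrix, 4 rows (A/C/G/T) by region width.
#' @slot freq numeric matrix of the same shape, `counts / nReads`; every
#'   column sums to 1.
#' @slot offsets integer vector of PAM-relative offsets per region position
#'   (`NA` for positions at or 3' of the PAM).
#' @slot refBases character vector of reference bases per position.
#' @slot nReads integer(1) denominator.
#' @export
setClass("ConversionMatrix",
  representation(
    counts = "matrix",
    freq = "matrix",
    offsets = "integer",
    refBases = "character",
    nReads = "integer"
  )
)

setValidity("ConversionMatrix", function(object) {
  msgs <- character()
  if (!identical(rownames(object@counts), .VALID_BASES) ||
      !identical(rownames(object@freq), .VALID_BASES))
    msgs <- c(msgs, "rows must be A, C, G, T")
  if (object@nReads > 0L &&
      any(abs(colSums(object@freq) - 1) > 1e-9))
    msgs <- c(msgs, "base frequencies must sum to 1 at every position")
  if (ncol(object@counts) != length(object@refBases) ||
      ncol(object@counts) != length(object@offsets))
    msgs <- c(msgs, "offsets/refBases must be parallel to matrix columns")
  if (length(msgs)) msgs else TRUE
})

#' Edited-product (haplotype) distribution over the target cytidines
#'
#' Result of [productDistribution()]: every matched read is mapped to the
#' pattern of its edited target positions, recording the observed base at
#' each edited position. Pattern labels list edits 5' to 3'
#' (e.g. `"T-19T-18"`); the unedited product is labelled `"unedited"`.
#'
#' @slot table data.frame with columns `pattern`, `count`, `fracReads`
#'   (fraction of all matched reads) and `fracEdited` (fraction of edited
#'   reads, `NA` for the unedited row).
#' @slot targets integer vector of target offsets (PAM-relative).
#' @slot nReads integer(1), equals `sum(table$count)`.
#' @export
setClass("ProductDistribution",
  representation(
    table = "data.frame",
    targets = "integer",
    nReads = "integer"
  )
)

setValidity("ProductDistribution", function(object) {
  msgs <- character()
  if (sum(object@table$count) != object@nReads)
    msgs <- c(msgs, "pattern counts must sum to nReads")
  if (anyDuplicated(object@table$pattern))
    msgs <- c(msgs, "pattern keys must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Product purity summary
#'
#' Per target cytidine, the fractions of matched reads carrying T, A, G or
#' the retained C, plus the fraction of edited reads containing any non-T
#' edited base (the impure products).
#'
#' @slot perPosition data.frame with columns `offset`, `cToT`, `cToA`,
#'   `cToG`, `cRetained` (fractions of all matched reads; they sum to 1 per
#'   row).
#' @slot nonTEditedFraction numeric(1) fraction of edited reads with at least
#'   one non-T edit, `NA` when no read is edited.
#' @export
setClass("PuritySummary",
  representation(
    perPosition = "data.frame",
    nonTEditedFraction = "numeric"
  )
)

#' Editing window of a C-to-T profile
#'
#' The minimal contiguous PAM-relative interval containing every position
#' whose activity reaches a stated fraction of the profile maximum. The rule
#' is recorded alongside the number because the width depends on it.
#'
#' @slot offsets integer vector, the contiguous interval (empty for an
#'   all-zero profile).
#' @slot width integer(1), `length(offsets)`.
#' @slot rule character(1) description of the threshold rule applied.
#' @slot threshold numeric(1) the relative threshold used.
#' @export
setClass("EditingWindow",
  representation(
    offsets = "integer",
    width = "integer",
    rule = "character",
    threshold = "numeric"
  )
)

#' Generative parameters of a simulated base editor
#'
#' The simulator's editor model: a per-read latent engagement event (the
#' editor acted on the molecule) followed by independent per-position
#' conditional edits, so that the marginal edit probability at offset o is
#' `engagement * condEdit[o]` and edits at different positions are positively
#' correlated within a read, reproducing multi-edit products.
#'
#' @slot engagement numeric(1) probability a read's molecule was engaged.
#' @slot condEdit named numeric, conditional C-to-T edit probability per
#'   target offset given engagement (names are PAM-relative offsets).
#' @slot purityRho numeric(1) probability an edited base is A or G (split
#'   equally) instead of T.
#' @slot indelRate numeric(1) per-read probability of a single indel of
#'   uniform size 1-3 nt (insertion or deletion, equiprobable) at a uniform
#'   position within the region.
#' @slot seqError numeric(1) per-base uniform substitution error rate.
#' @slot seed integer(1) default RNG seed (`NA` to leave the RNG alone).
#' @seealso [editorProfile()], [editorPresets()], [simulateReads()]
#' @export
setClass("EditorProfile",
  representation(
    engagement = "numeric",
    condEdit = "numeric",
    purityRho = "numeric",
    indelRate = "numeric",
    seqError = "numeric",
    seed = "integer"
  )
)

setValidity("EditorProfile", function(object) {
  msgs <- character()
  p <- c(object@engagement, object@condEdit, object@purityRho,
         object@indelRate, object@seqError)
  if (any(p < 0 | p > 1))
    msgs <- c(msgs, "all probabilities must lie in [0, 1]")
  if (length(object@condEdit) == 0L || is.null(names(object@condEdit)))
    msgs <- c(msgs, "condEdit must be a named vector keyed by offset")
  else if (anyNA(suppressWarnings(as.integer(names(object@condEdit)))))
    msgs <- c(msgs, "condEdit names must be integer offsets")
  if (length(msgs)) msgs else TRUE
})
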