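# Flank-anchored region extraction and length-based indel classification.
#
# Both operations share one anchoring rule: the left and right flanks must
# each occur exactly once in the read (multiple occurrences are ambiguous),
# and the leftmost left-flank occurrence must end before the right-flank
# occurrence starts, framing the enclosed segment.

# Per-read anchoring status. Returns list(status, segStart, segEnd) where
# status is one of "ok", "flank", "ambiguous"; segStart/segEnd frame the
# enclosed segment (1-based, segEnd = segStart - 1 for an empty segment).
.anchorReads <- function(seqs, leftFlank, rightFlank) {
  n <- length(seqs)
  lHits <- Biostrings::startIndex(Biostrings::vmatchPattern(leftFlank, seqs))
  rHits <- Biostrings::startIndex(Biostrings::vmatchPattern(rightFlank, seqs))
  status <- character(n)
  segStart <- integer(n)
  segEnd <- integer(n)
  lf <- nchar(leftFlank)
  for (i in seq_len(n)) {
    l <- lHits[[i]]; r <- rHits[[i]]
    if (length(l) > 1L || length(r) > 1L) {
      status[i] <- "ambiguous"
    } else if (length(l) == 0L || length(r) == 0L) {
      status[i] <- "flank"
    } else {
      s <- l[1L] + lf
      if (r[1L] < s) {
        status[i] <- "flank"  # flanks present but do not frame a segment
      } else {
        status[i] <- "ok"
        segStart[i] <- s
        segEnd[i] <- r[1L] - 1L
      }
    }
  }
  list(status = status, segStart = segStart, segEnd = segEnd)
}

#' Extract fixed-length editing regions by exact flank anchoring
#'
#' Scans every read for the reference's two flanking anchor sequences. A
#' read is matched iff both flanks occur exactly once, the left flank
#' precedes the right flank, and the enclosed segment has exactly the
#' reference region length; the segment is then collected. Reads failing
#' these conditions are counted by cause (missing/ill-ordered flank,
#' multiple flank occurrences, wrong segment length), so indel-containing
#' and imperfectly matching reads are excluded by construction.
#'
#' @param reads A [ReadSet-class], already in reference orientation.
#' @param ref An [AmpliconReference-class].
#' @return An [EditingRegionSet-class].
#' @export
extractRegions <- function(reads, ref) {
  n <- readCount(reads)
  regLen <- regionWidth(ref)
  a <- .anchorReads(reads@sequences, ref@leftFlank, ref@rightFlank)
  segLen <- a$segEnd - a$segStart + 1L
  ok <- a$status == "ok" & segLen == regLen
  lenBad <- a$status == "ok" & segLen != regLen
  regions <- substr(as.character(reads@sequences[ok]),
                    a$segStart[ok], a$segEnd[ok])
  new("EditingRegionSet",
      regions = Biostrings::DNAStringSet(regions),
      nInput = n,
      nMatched = sum(ok),
      nRejectedFlank = sum(a$status == "flank"),
      nRejectedLength = sum(lenBad),
      nRejectedAmbiguous = sum(a$status == "ambiguous"))
}

#' Classify reads as indel-containing by flank-to-flank length
#'
#' Scans each read for two exactly matching `flankLen`-bp sequences flanking
#' the editing region. Reads lacking either exact flank (or with ambiguous
#' multiple occurrences) are excluded from further analysis. For included
#' reads the enclosed segment length is compared with the reference region
#' length: equal means no indel (substitutions are allowed), any other
#' length means an indel. The indel frequency is computed over included
#' reads only and is `NA` when none is included.
#'
#' @param reads A [ReadSet-class].
#' @param ref An [AmpliconReference-class].
#' @param flankLen integer(1) anchor length, default 10 bp.
#' @return An [IndelSummary-class].
#' @export
classifyIndels <- function(reads, ref, flankLen = 10L) {
  flankLen <- as.integer(flankLen)
  if (flankLen < 1L) stop("flankLen must be >= 1", call. = FALSE)
  amp <- as.character(ref@amplicon)
  if (ref@regionStart - flankLen < 1L ||
      ref@regionEnd + flankLen > nchar(amp))
    stop("amplicon provides fewer than flankLen bases outside the region",
         call. = FALSE)
  lF <- substr(amp, ref@regionStart - flankLen, ref@regionStart - 1L)
  rF <- substr(amp, ref@regionEnd + 1L, ref@regionEnd + flankLen)
  a <- .anchorReads(reads@sequences, lF, rF)
  included <- a$status == "ok"
  segLen <- a$segEnd - a$segStart + 1L
  nNo <- sum(included & segLen == regionWidth(ref))
  nIn <- sum(included & segLen != regionWidth(ref))
  new("IndelSummary",
      nScanned = readCount(reads),
      nNoIndel = nNo,
      nIndel = nIn,
      nExcludedFlank = sum(!included),
      indelFrequency = if (nNo + nIn > 0L) nIn / (nNo + nIn) else NA_real_)
}

#' @describeIn extractRegions Accessor: the matched region sequences.
#' @param x An [EditingRegionSet-class].
#' @export
editingRegions <- function(x) x@regions

#' @describeIn extractRegions Accessor: number of matched reads.
#' @export
matchedCount <- function(x) x@nMatched

setMethod("show", "EditingRegionSet", function(object) {
  cat("EditingRegionSet: ", object@nMatched, "/", object@nInput,
      " reads matched\n", sep = "")
  cat("  rejected: flank=", object@nRejectedFlank,
      ", length=", object@nRejectedLength,
      ", ambiguous=", object@nRejectedAmbiguous, "\n", sep = "")
  if (length(object@regions))
    cat("  region width: ", Biostrings::width(object@regions)[1L],
        " nt\n", sep = "")
})

setMethod("show", "IndelSummary", function(object) {
  cat("IndelSummary: ", object@nScanned, " reads scanned, ",
      object@nExcludedFlank, " excluded (flank)\n", sep = "")
  cat("  indels: ", object@nIndel, "/", object@nIndel + object@nNoIndel,
      " included reads; frequency = ",
      if (is.na(object@indelFrequency)) "NA"
      else sprintf("%.4g", object@indelFrequency), "\n", sep = "")
})
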