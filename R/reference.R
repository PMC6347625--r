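# Reference model: amplicon, protospacer, PAM, PAM-relative coordinates.

.checkSeq <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " must contain only uppercase A/C/G/T (no ambiguity codes)",
         call. = FALSE)
  x
}

# IUPAC-aware match of a fixed-length PAM pattern against a concrete triplet
.pamMatches <- function(observed, pattern) {
  if (nchar(observed) != nchar(pattern)) return(FALSE)
  map <- Biostrings::IUPAC_CODE_MAP
  obs <- strsplit(observed, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  all(mapply(function(o, p) {
    if (!p %in% names(map)) stop("invalid PAM pattern symbol: ", p, call. = FALSE)
    grepl(o, map[[p]], fixed = TRUE)
  }, obs, pat))
}

#' Build an amplicon reference around a protospacer
#'
#' Locates `protospacerSeq` (or its reverse complement) in `ampliconSeq`,
#' requires a PAM matching `pamPattern` immediately 3' of it, and lays out a
#' fixed-length editing region of `regionHalfwidth` extra bases on each side
#' of the protospacer+PAM, anchored by `flankLen`-nt exact flanks. A
#' minus-strand hit is normalised by reverse complement at ingest so that all
#' downstream reporting is in protospacer orientation.
#'
#' @param ampliconSeq character(1) amplicon sequence (uppercase A/C/G/T).
#' @param protospacerSeq character(1) protospacer sequence (default length 20).
#' @param pamPattern character(1) IUPAC PAM pattern 3' of the protospacer,
#'   default `"NGG"` (SpCas9).
#' @param regionHalfwidth integer(1) bases added 5' of the protospacer and 3'
#'   of the PAM to form the editing region.
#' @param flankLen integer(1) length of the exact anchoring flanks
#'   immediately outside the region (default 10, the length also used by the
#'   indel scan).
#' @return An [AmpliconReference-class] object.
#' @examples
#' proto <- "GATTACAGATTACAGATTAC"
#' amp <- paste0("TTGACTGGTCAAGTCA", proto, "TGG", "CATGGACTAAGGCCTA")
#' ref <- buildReference(amp, proto, regionHalfwidth = 2, flankLen = 8)
#' ref
#' @export
buildReference <- function(ampliconSeq, protospacerSeq, pamPattern = "NGG",
                           regionHalfwidth = 5L, flankLen = 10L) {
  amp <- .checkSeq(ampliconSeq, "ampliconSeq")
  proto <- .checkSeq(protospacerSeq, "protospacerSeq")
  regionHalfwidth <- as.integer(regionHalfwidth)
  flankLen <- as.integer(flankLen)
  if (flankLen < 1L) stop("flankLen must be >= 1", call. = FALSE)
  if (regionHalfwidth < 0L) stop("regionHalfwidth must be >= 0", call. = FALSE)

  ampDNA <- Biostrings::DNAString(amp)
  fwd <- Biostrings::matchPattern(proto, ampDNA)
  rev <- Biostrings::matchPattern(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(proto))),
    ampDNA)
  nHits <- length(fwd) + length(rev)
  if (nHits == 0L) stop("protospacer not found", call. = FALSE)
  if (nHits > 1L) stop("ambiguous protospacer", call. = FALSE)

  if (length(fwd) == 1L) {
    strand <- "plus"
    protoStart <- BiocGenerics::start(fwd)[1L]
  } else {
    strand <- "minus"
    # normalise: report everything in protospacer orientation
    hitStart <- BiocGenerics::start(rev)[1L]
    ampDNA <- Biostrings::reverseComplement(ampDNA)
    amp <- as.character(ampDNA)
    protoStart <- nchar(amp) - (hitStart + nchar(proto) - 1L) + 1L
  }
  protoLen <- nchar(proto)
  pamStart <- protoStart + protoLen
  pamLen <- nchar(pamPattern)
  pamEnd <- pamStart + pamLen - 1L
  if (pamEnd > nchar(amp) ||
      !.pamMatches(substr(amp, pamStart, pamEnd), pamPattern))
    stop("no adjacent PAM", call. = FALSE)

  regionStart <- protoStart - regionHalfwidth
  regionEnd <- pamEnd + regionHalfwidth
  if (regionStart - flankLen < 1L || regionEnd + flankLen > nchar(amp))
    stop("amplicon too short for the requested region and flanks", call. = FALSE)

  new("AmpliconReference",
      amplicon = ampDNA,
      protospacerStart = protoStart,
      protospacerLen = protoLen,
      pamStart = pamStart,
      pamLen = pamLen,
      strand = strand,
      regionStart = regionStart,
      regionEnd = regionEnd,
      leftFlank = substr(amp, regionStart - flankLen, regionStart - 1L),
      rightFlank = substr(amp, regionEnd + 1L, regionEnd + flankLen))
}

#' Convert PAM-relative offsets to amplicon indices (and back)
#'
#' Offset -1 is the protospacer base immediately 5' of the PAM; offset -k
#' lies k bases 5' of the PAM, in protospacer orientation. Indices are
#' 1-based into the normalised amplicon. `offsetToIndex` and `indexToOffset`
#' are mutually inverse.
#'
#' @param ref An [AmpliconReference-class].
#' @param offsets integer vector of negative PAM-relative offsets.
#' @param within `"protospacer"` restricts offsets to
#'   `[-protospacerLen, -1]`; `"region"` accepts any offset whose base lies
#'   inside the editing region (the deaminase window can reach slightly 5'
#'   of a 20-nt protospacer).
#' @return `offsetToIndex`: integer vector of 1-based amplicon indices.
#' @export
offsetToIndex <- function(ref, offsets, within = c("protospacer", "region")) {
  within <- match.arg(within)
  offsets <- as.integer(offsets)
  if (any(offsets >= 0L)) stop("offsets must be negative", call. = FALSE)
  idx <- ref@pamStart + offsets
  bad <- if (within == "protospacer")
    offsets < -ref@protospacerLen
  else
    idx < ref@regionStart | idx > ref@regionEnd
  if (any(bad))
    stop(if (within == "protospacer") "offset outside protospacer"
         else "offset outside editing region", call. = FALSE)
  idx
}

#' @rdname offsetToIndex
#' @param indices integer vector of 1-based amplicon indices.
#' @return `indexToOffset`: integer vector of PAM-relative offsets.
#' @export
indexToOffset <- function(ref, indices, within = c("protospacer", "region")) {
  within <- match.arg(within)
  indices <- as.integer(indices)
  off <- indices - ref@pamStart
  bad <- if (within == "protospacer")
    off < -ref@protospacerLen | off > -1L
  else
    indices < ref@regionStart | indices > ref@regionEnd | off > -1L
  if (any(bad)) stop("index outside protospacer", call. = FALSE)
  off
}

#' Target cytidines of a reference
#'
#' Returns the PAM-relative offsets at which the reference base is C, sorted
#' with the PAM-proximal position first. By default the protospacer is
#' scanned; an explicit `range` (e.g. `c(-21, -1)` for a nonacytidine motif
#' extending one base 5' of a 20-nt protospacer) scans any offsets whose
#' bases lie inside the editing region.
#'
#' @param ref An [AmpliconReference-class].
#' @param range optional length-2 integer, the most-negative and
#'   least-negative offsets to scan.
#' @return Integer vector of offsets (possibly empty), sorted decreasing.
#' @export
targetCytidines <- function(ref, range = NULL) {
  if (is.null(range)) {
    offs <- seq.int(-1L, -ref@protospacerLen)
    within <- "protospacer"
  } else {
    range <- as.integer(range)
    offs <- seq.int(max(range), min(range))
    within <- "region"
  }
  idx <- offsetToIndex(ref, offs, within = within)
  bases <- strsplit(as.character(ref@amplicon), "")[[1]][idx]
  offs[bases == "C"]
}

#' @describeIn buildReference Reference sequence of the editing region.
#' @param ref An [AmpliconReference-class].
#' @export
regionSequence <- function(ref) {
  substr(as.character(ref@amplicon), ref@regionStart, ref@regionEnd)
}

#' @describeIn buildReference Protospacer sequence (protospacer orientation).
#' @export
protospacerSequence <- function(ref) {
  substr(as.character(ref@amplicon), ref@protospacerStart,
         ref@protospacerStart + ref@protospacerLen - 1L)
}

#' @describeIn buildReference Width of the editing region in nt.
#' @export
regionWidth <- function(ref) ref@regionEnd - ref@regionStart + 1L

setMethod("show", "AmpliconReference", function(object) {
  amp <- as.character(object@amplicon)
  cat("AmpliconReference (", nchar(amp), " nt, strand ", object@strand, ")\n",
      sep = "")
  cat("  protospacer: ", protospacerSequence(object),
      " [", object@protospacerStart, "-",
      object@protospacerStart + object@protospacerLen - 1L, "]\n", sep = "")
  cat("  PAM:         ",
      substr(amp, object@pamStart, object@pamStart + object@pamLen - 1L),
      " [", object@pamStart, "-", object@pamStart + object@pamLen - 1L,
      "]\n", sep = "")
  cat("  region:      [", object@regionStart, "-", object@regionEnd, "] (",
      regionWidth(object), " nt), flanks ", nchar(object@leftFlank), "/",
      nchar(object@rightFlank), " nt\n", sep = "")
  tc <- targetCytidines(object)
  cat("  target Cs:   ",
      if (length(tc)) paste(tc, collapse = ", ") else "(none)", "\n", sep = "")
})
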