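# ReadSet construction, FASTQ I/O, demultiplexing and quality filtering.

#' Construct a ReadSet
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of read
#'   sequences; names are used as read ids (generated when absent).
#' @param qualities optional character vector or [Biostrings::BStringSet] of
#'   Phred+33 quality strings parallel to `sequences`.
#' @param sampleId character(1) sample label.
#' @return A [ReadSet-class] object.
#' @export
ReadSet <- function(sequences, qualities = NULL, sampleId = "sample") {
  seqs <- if (is(sequences, "DNAStringSet")) sequences
          else Biostrings::DNAStringSet(sequences)
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    names(seqs) <- sprintf("read_%06d", seq_along(seqs))
  quals <- if (is.null(qualities)) Biostrings::BStringSet(character(0))
           else if (is(qualities, "BStringSet")) qualities
           else Biostrings::BStringSet(qualities)
  if (length(quals)) names(quals) <- names(seqs)
  new("ReadSet", sequences = seqs, qualities = quals, sampleId = sampleId)
}

#' @describeIn ReadSet Number of reads.
#' @param x A [ReadSet-class].
#' @export
readCount <- function(x) length(x@sequences)

#' @describeIn ReadSet Logical: are quality strings present?
#' @export
hasQualities <- function(x) length(x@qualities) > 0L

#' @describeIn ReadSet Subset a ReadSet by index or logical vector.
#' @param i index vector.
#' @export
subsetReads <- function(x, i) {
  new("ReadSet", sequences = x@sequences[i],
      qualities = if (hasQualities(x)) x@qualities[i] else x@qualities,
      sampleId = x@sampleId)
}

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet '", object@sampleId, "': ", readCount(object), " reads",
      if (hasQualities(object)) " (with qualities)" else "", "\n", sep = "")
})

#' Read and write FASTQ read sets
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] (Phred+33; gzip handled transparently on
#' input).
#'
#' @param path FASTQ file path.
#' @param sampleId sample label to attach.
#' @return `readFastqReads`: a [ReadSet-class].
#' @export
readFastqReads <- function(path, sampleId = basename(path)) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  ReadSet(seqs, S4Vectors::mcols(seqs)$qualities, sampleId = sampleId)
}

#' @rdname readFastqReads
#' @param reads A [ReadSet-class]; constant Q40 qualities are written when
#'   absent.
#' @export
writeFastqReads <- function(reads, path) {
  quals <- if (hasQualities(reads)) reads@qualities
           else Biostrings::BStringSet(strrep("I", Biostrings::width(reads@sequences)))
  Biostrings::writeXStringSet(reads@sequences, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Demultiplex reads by exact index-tag match
#'
#' Assigns every read to exactly one sample by exact match of its index tag
#' at the stated location; the tag is stripped from assigned reads.
#' Unassigned reads are returned unmodified under the reserved
#' `"undetermined"` bin, so the bins always partition the input.
#'
#' @param reads A [ReadSet-class].
#' @param indexTable named character vector or two-column data.frame
#'   (`tag`, `sample_id`) mapping distinct, equal-length tags to sample ids.
#' @param tagLocation `"prefix"` (default) or `"suffix"`.
#' @return Named list of [ReadSet-class] objects, one per sample plus
#'   `"undetermined"`.
#' @export
demultiplex <- function(reads, indexTable, tagLocation = c("prefix", "suffix")) {
  tagLocation <- match.arg(tagLocation)
  if (is.data.frame(indexTable)) {
    tags <- as.character(indexTable[[1L]])
    samples <- as.character(indexTable[[2L]])
  } else {
    tags <- names(indexTable)
    samples <- unname(as.character(indexTable))
  }
  if (length(tags) == 0L) stop("empty index table", call. = FALSE)
  if (anyDuplicated(tags)) stop("duplicate index tags", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  L <- unique(nchar(tags))
  if (length(L) != 1L) stop("index tags must have equal length", call. = FALSE)
  if ("undetermined" %in% samples)
    stop("'undetermined' is a reserved bin name", call. = FALSE)

  seqs <- as.character(reads@sequences)
  w <- nchar(seqs)
  observed <- if (tagLocation == "prefix") substr(seqs, 1L, L)
              else substr(seqs, pmax(w - L + 1L, 1L), w)
  observed[w < L] <- NA_character_
  hit <- match(observed, tags)

  stripTag <- function(s) {
    if (tagLocation == "prefix") substring(s, L + 1L)
    else substr(s, 1L, nchar(s) - L)
  }
  out <- vector("list", length(samples) + 1L)
  names(out) <- c(samples, "undetermined")
  for (j in seq_along(samples)) {
    sel <- which(!is.na(hit) & hit == j)
    sub <- subsetReads(reads, sel)
    out[[j]] <- ReadSet(
      stats::setNames(stripTag(as.character(sub@sequences)),
                      names(sub@sequences)),
      if (hasQualities(sub)) stripTag(as.character(sub@qualities)) else NULL,
      sampleId = samples[j])
  }
  und <- subsetReads(reads, which(is.na(hit)))
  und@sampleId <- "undetermined"
  out[["undetermined"]] <- und
  out
}

#' Filter reads by mean base quality
#'
#' Retains reads whose mean Phred+33 quality is at least `minMeanQ`. A
#' pass-through when the ReadSet carries no qualities or `minMeanQ <= 0`.
#' Reads with malformed quality strings (characters below '!') are rejected;
#' their number is attached as attribute `"nMalformed"` and reported via a
#' message.
#'
#' @param reads A [ReadSet-class].
#' @param minMeanQ numeric(1) minimum mean Phred quality.
#' @return A filtered [ReadSet-class].
#' @export
qualityFilter <- function(reads, minMeanQ) {
  if (!hasQualities(reads) || minMeanQ <= 0) return(reads)
  q <- as.character(reads@qualities)
  meanQ <- vapply(q, function(s) {
    v <- as.integer(charToRaw(s)) - 33L
    if (any(v < 0L)) NA_real_ else mean(v)
  }, numeric(1), USE.NAMES = FALSE)
  malformed <- is.na(meanQ)
  if (any(malformed))
    message(sum(malformed), " read(s) with malformed quality strings rejected")
  keep <- !malformed & meanQ >= minMeanQ
  out <- subsetReads(reads, which(keep))
  attr(out, "nMalformed") <- sum(malformed)
  out
}
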