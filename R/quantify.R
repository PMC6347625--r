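# Per-position conversion statistics, C-to-T profiles, edited-product
# distributions and product purity.

#' Per-position base substitution frequencies among matched reads
#'
#' Counts, for every position of the editing region, how often each base is
#' observed across the matched reads, and divides by the total number of
#' matched reads (not the number of edited reads). Positions 5' of the PAM
#' carry their PAM-relative offset.
#'
#' @param regions An [EditingRegionSet-class] (or a
#'   [Biostrings::DNAStringSet] of equal-width regions).
#' @param ref An [AmpliconReference-class].
#' @return A [ConversionMatrix-class].
#' @export
conversionMatrix <- function(regions, ref) {
  regs <- if (is(regions, "EditingRegionSet")) regions@regions else regions
  n <- length(regs)
  if (n == 0L) stop("no matched reads", call. = FALSE)
  L <- regionWidth(ref)
  if (any(Biostrings::width(regs) != L))
    stop("regions must all have the reference region width", call. = FALSE)
  cm <- Biostrings::consensusMatrix(regs)
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(.VALID_BASES, NULL))
  present <- intersect(rownames(cm), .VALID_BASES)
  counts[present, ] <- cm[present, , drop = FALSE]
  ampIdx <- seq.int(ref@regionStart, ref@regionEnd)
  offsets <- ampIdx - ref@pamStart
  offsets[offsets >= 0L] <- NA_integer_
  refBases <- strsplit(regionSequence(ref), "")[[1]]
  new("ConversionMatrix",
      counts = counts,
      freq = counts / n,
      offsets = as.integer(offsets),
      refBases = refBases,
      nReads = as.integer(n))
}

.offsetColumn <- function(matrix, offset) {
  col <- which(!is.na(matrix@offsets) & matrix@offsets == offset)
  if (length(col) != 1L)
    stop("offset ", offset, " absent from conversion matrix", call. = FALSE)
  col
}

#' C-to-T editing profile over the target cytidines
#'
#' Projects a [ConversionMatrix-class] onto the target positions: the
#' fraction of all matched reads carrying T at each target C. This is the
#' "% of C-to-T editing" quantity.
#'
#' @param matrix A [ConversionMatrix-class].
#' @param targets integer vector of PAM-relative target offsets (all must be
#'   reference Cs present in the matrix).
#' @return Named numeric vector, names = offsets, values = C-to-T fractions.
#' @export
cToTProfile <- function(matrix, targets) {
  targets <- as.integer(targets)
  vals <- vapply(targets, function(o) {
    col <- .offsetColumn(matrix, o)
    if (matrix@refBases[col] != "C")
      stop("reference base at offset ", o, " is not C", call. = FALSE)
    matrix@freq["T", col]
  }, numeric(1))
  stats::setNames(vals, targets)
}

# Pattern label for one read: edited target bases 5'->3', e.g. "T-19T-18".
.patternLabels <- function(baseMat, targetsAsc) {
  apply(baseMat, 1L, function(b) {
    e <- b != "C"
    if (!any(e)) "unedited" else paste0(b[e], targetsAsc[e], collapse = "")
  })
}

#' Edited-product (haplotype) distribution
#'
#' Maps every matched read to the pattern of its edited target cytidines
#' (base different from C at a target offset, recording the observed base)
#' and tabulates pattern counts, fractions of all reads and fractions of
#' edited reads. With an empty target set all reads fall into the single
#' `"unedited"` bucket.
#'
#' @param regions An [EditingRegionSet-class] (or equal-width
#'   [Biostrings::DNAStringSet]).
#' @param ref An [AmpliconReference-class].
#' @param targets integer vector of PAM-relative target offsets; defaults to
#'   [targetCytidines()] of the reference.
#' @return A [ProductDistribution-class].
#' @export
productDistribution <- function(regions, ref, targets = targetCytidines(ref)) {
  regs <- if (is(regions, "EditingRegionSet")) regions@regions else regions
  n <- length(regs)
  if (n == 0L) stop("no matched reads", call. = FALSE)
  targets <- as.integer(targets)
  if (length(targets) == 0L) {
    tab <- data.frame(pattern = "unedited", count = n,
                      fracReads = 1, fracEdited = NA_real_,
                      stringsAsFactors = FALSE)
    return(new("ProductDistribution", table = tab,
               targets = integer(0), nReads = as.integer(n)))
  }
  targetsAsc <- sort(targets)
  relIdx <- offsetToIndex(ref, targetsAsc, within = "region") - ref@regionStart + 1L
  regChars <- as.character(regs)
  baseMat <- vapply(relIdx, function(j) substr(regChars, j, j),
                    character(length(regChars)))
  if (length(regChars) == 1L) baseMat <- matrix(baseMat, nrow = 1L)
  labels <- .patternLabels(baseMat, targetsAsc)
  counts <- table(labels)
  tab <- data.frame(pattern = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  nEdited <- sum(tab$count[tab$pattern != "unedited"])
  tab$fracReads <- tab$count / n
  tab$fracEdited <- ifelse(tab$pattern == "unedited", NA_real_,
                           if (nEdited > 0L) tab$count / nEdited else NA_real_)
  tab <- tab[order(-tab$count, tab$pattern), ]
  tab <- rbind(tab[tab$pattern == "unedited", , drop = FALSE],
               tab[tab$pattern != "unedited", , drop = FALSE])
  rownames(tab) <- NULL
  new("ProductDistribution", table = tab,
      targets = sort(targets, decreasing = TRUE), nReads = as.integer(n))
}

#' Fraction of edited products carrying exactly one C-to-T edit at a position
#'
#' The count of the pattern consisting of exactly one T at `position`,
#' divided by the count of all edited (non-empty) patterns. `NA` when no
#' read is edited.
#'
#' @param dist A [ProductDistribution-class].
#' @param position integer(1) PAM-relative target offset.
#' @return numeric(1) fraction of edited reads, or `NA`.
#' @export
singleEditFraction <- function(dist, position) {
  position <- as.integer(position)
  if (!position %in% dist@targets)
    stop("position ", position, " is not a target offset", call. = FALSE)
  tab <- dist@table
  nEdited <- sum(tab$count[tab$pattern != "unedited"])
  if (nEdited == 0L) return(NA_real_)
  lab <- paste0("T", position)
  hit <- tab$count[tab$pattern == lab]
  (if (length(hit)) hit else 0L) / nEdited
}

#' Product purity per target cytidine
#'
#' Per target position, the fractions of matched reads carrying T, A, G or
#' the retained C (these sum to 1), plus the fraction of edited reads
#' containing at least one non-T edited base.
#'
#' @param matrix A [ConversionMatrix-class].
#' @param dist A [ProductDistribution-class] over the same reads.
#' @param targets integer vector of target offsets; defaults to the
#'   distribution's targets.
#' @return A [PuritySummary-class].
#' @export
puritySummary <- function(matrix, dist, targets = dist@targets) {
  targets <- as.integer(targets)
  if (length(targets) == 0L) {
    pp <- data.frame(offset = integer(0), cToT = numeric(0),
                     cToA = numeric(0), cToG = numeric(0),
                     cRetained = numeric(0))
    return(new("PuritySummary", perPosition = pp,
               nonTEditedFraction = NA_real_))
  }
  pp <- do.call(rbind, lapply(targets, function(o) {
    col <- .offsetColumn(matrix, o)
    data.frame(offset = o,
               cToT = matrix@freq["T", col],
               cToA = matrix@freq["A", col],
               cToG = matrix@freq["G", col],
               cRetained = matrix@freq["C", col])
  }))
  tab <- dist@table
  edited <- tab$pattern != "unedited"
  nEdited <- sum(tab$count[edited])
  nonT <- if (nEdited > 0L)
    sum(tab$count[edited & grepl("A-|G-", tab$pattern)]) / nEdited
  else NA_real_
  new("PuritySummary", perPosition = pp, nonTEditedFraction = nonT)
}

#' One-call quantification of a sample
#'
#' Convenience wrapper: extracts regions, builds the conversion matrix, the
#' C-to-T profile, the product distribution, the purity summary and the
#' indel summary for one ReadSet.
#'
#' @param reads A [ReadSet-class].
#' @param ref An [AmpliconReference-class].
#' @param targets target offsets, default [targetCytidines()] of `ref`.
#' @param indelFlankLen anchor length for the indel scan (default 10).
#' @return A named list with elements `regions`, `matrix`, `profile`,
#'   `distribution`, `purity`, `indels`.
#' @export
quantifySample <- function(reads, ref, targets = targetCytidines(ref),
                           indelFlankLen = 10L) {
  regions <- extractRegions(reads, ref)
  mat <- conversionMatrix(regions, ref)
  dist <- productDistribution(regions, ref, targets)
  list(regions = regions,
       matrix = mat,
       profile = cToTProfile(mat, targets),
       distribution = dist,
       purity = puritySummary(mat, dist, targets),
       indels = classifyIndels(reads, ref, flankLen = indelFlankLen))
}

#' Tabular and serialized views of quantification results
#'
#' `conversionToDf`/`productToDf` return plain data.frames;
#' `writeConversionTSV`/`writeProductTSV` write them as TSV;
#' `conversionToJSON`/`productToJSON` return JSON strings (via jsonlite).
#'
#' @param matrix A [ConversionMatrix-class].
#' @return `conversionToDf`: data.frame with one row per region position
#'   (region index, PAM-relative offset, reference base, A/C/G/T fractions,
#'   denominator).
#' @export
conversionToDf <- function(matrix) {
  data.frame(position = seq_along(matrix@refBases),
             offset = matrix@offsets,
             refBase = matrix@refBases,
             A = matrix@freq["A", ],
             C = matrix@freq["C", ],
             G = matrix@freq["G", ],
             T = matrix@freq["T", ],
             n = matrix@nReads,
             check.names = FALSE)
}

#' @rdname conversionToDf
#' @param dist A [ProductDistribution-class].
#' @export
productToDf <- function(dist) {
  tab <- dist@table
  data.frame(pattern = tab$pattern, count = tab$count,
             pctReads = 100 * tab$fracReads,
             pctEdited = 100 * tab$fracEdited)
}

#' @rdname conversionToDf
#' @param path output file path.
#' @export
writeConversionTSV <- function(matrix, path) {
  utils::write.table(conversionToDf(matrix), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname conversionToDf
#' @export
writeProductTSV <- function(dist, path) {
  utils::write.table(productToDf(dist), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname conversionToDf
#' @export
conversionToJSON <- function(matrix) {
  jsonlite::toJSON(conversionToDf(matrix), dataframe = "rows", digits = NA,
                   na = "null")
}

#' @rdname conversionToDf
#' @export
productToJSON <- function(dist) {
  jsonlite::toJSON(productToDf(dist), dataframe = "rows", digits = NA,
                   na = "null")
}

setMethod("show", "ConversionMatrix", function(object) {
  cat("ConversionMatrix: ", ncol(object@freq), " positions x 4 bases over ",
      object@nReads, " reads\n", sep = "")
  offC <- object@offsets[object@refBases == "C" & !is.na(object@offsets)]
  if (length(offC)) {
    ct <- object@freq["T", match(offC, object@offsets)]
    cat("  C-to-T at target Cs: ",
        paste0(offC, ": ", sprintf("%.3f", ct), collapse = ", "), "\n",
        sep = "")
  }
})

setMethod("show", "ProductDistribution", function(object) {
  cat("ProductDistribution over ", length(object@targets),
      " target Cs, ", object@nReads, " reads\n", sep = "")
  print(utils::head(productToDf(object), 8L), row.names = FALSE)
})

setMethod("show", "PuritySummary", function(object) {
  cat("PuritySummary (fractions of all matched reads):\n")
  print(object@perPosition, row.names = FALSE)
  cat("  non-T fraction of edited reads: ",
      if (is.na(object@nonTEditedFraction)) "NA"
      else sprintf("%.4g", object@nonTEditedFraction), "\n", sep = "")
})
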