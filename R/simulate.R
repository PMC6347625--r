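# Parametric base-editor simulator: reads and diploid colonies with known
# ground truth.
#
# Model: a per-read latent "engagement" event (the editor acted on this
# molecule); given engagement, each target C is edited independently with
# its conditional probability. Marginal edit probability at offset o is
# engagement * condEdit[o], and the shared latent event induces the positive
# co-editing correlation seen in multi-edit products. Edited bases are T
# with probability 1 - purityRho, else A or G equiprobably. A single indel
# (uniform size 1-3, insertion or deletion, uniform position in the region)
# occurs with indelRate; uniform per-base substitution errors are applied
# last over the whole read.

#' Construct an editor profile
#'
#' @param engagement probability the editor acted on a read's molecule.
#' @param condEdit named numeric: conditional C-to-T edit probability per
#'   PAM-relative target offset, given engagement.
#' @param purityRho probability an edited base is A or G instead of T.
#' @param indelRate per-read probability of a single 1-3 nt indel.
#' @param seqError per-base uniform substitution error rate.
#' @param seed default RNG seed for simulations with this profile (`NA`
#'   leaves the RNG state alone).
#' @return An [EditorProfile-class].
#' @examples
#' editorProfile(0.6, c("-18" = 0.9, "-17" = 0.2))
#' @export
editorProfile <- function(engagement, condEdit, purityRho = 0,
                          indelRate = 0, seqError = 0, seed = NA_integer_) {
  new("EditorProfile", engagement = engagement,
      condEdit = condEdit, purityRho = purityRho,
      indelRate = indelRate, seqError = seqError,
      seed = as.integer(seed))
}

#' Illustrative editor presets
#'
#' Three generative profiles spanning the qualitative behaviours of
#' interest, for an oligo(C) target with cytidines at offsets -13 to -21:
#' `"broad"` engages often and edits the whole nine-nt stretch almost
#' uniformly (BE3-like flat window, multi-edit products); `"full_length"`
#' concentrates activity over -16 to -19 (full-length CDA1-like);
#' `"truncated"` peaks sharply at -18 with weak activity at the neighbours
#' (truncated-CDA1-like), giving predominantly single-edit products. The
#' parameter values are this package's own choices for plausible study
#' conditions, not measurements.
#'
#' @param name one of `"broad"`, `"full_length"`, `"truncated"`.
#' @return An [EditorProfile-class].
#' @export
editorPresets <- function(name = c("broad", "full_length", "truncated")) {
  name <- match.arg(name)
  offs <- as.character(seq.int(-13L, -21L))
  switch(name,
    broad = editorProfile(
      engagement = 0.7,
      condEdit = stats::setNames(rep(0.8, 9L), offs),
      purityRho = 0.05, indelRate = 0.01, seqError = 0.001),
    full_length = editorProfile(
      engagement = 0.65,
      condEdit = stats::setNames(
        c(0.05, 0.1, 0.2, 0.7, 0.8, 0.8, 0.7, 0.1, 0.05), offs),
      purityRho = 0.02, indelRate = 0.005, seqError = 0.001),
    truncated = editorProfile(
      engagement = 0.6,
      condEdit = stats::setNames(
        c(0.02, 0.02, 0.05, 0.1, 0.3, 0.9, 0.15, 0.05, 0.02), offs),
      purityRho = 0.02, indelRate = 0.005, seqError = 0.001))
}

.randomBases <- function(n) sample(.VALID_BASES, n, replace = TRUE)

#' Simulate amplicon reads from an editor profile
#'
#' Each read is the full amplicon with its editing region rewritten by the
#' editor model (engagement, conditional per-position edits, purity, one
#' optional indel) and uniform sequencing errors applied last over the whole
#' read. Constant Q40 qualities are emitted. Fully reproducible under the
#' seed; a per-read ground-truth record is returned alongside the reads.
#'
#' @param ref An [AmpliconReference-class]; all `condEdit` offsets must be
#'   reference Cs within the editing region.
#' @param profile An [EditorProfile-class].
#' @param n number of reads.
#' @param seed RNG seed; defaults to the profile's seed (`NA` = leave RNG).
#' @param sampleId sample label for the ReadSet.
#' @return list with elements `reads` (a [ReadSet-class]) and `truth`
#'   (data.frame: `id`, `engaged`, `editedOffsets`, `editedBases`, `indel`,
#'   `indelSize`, `nErrors`; attribute `"marginal"` holds the per-offset
#'   marginal edit probabilities `engagement * condEdit`).
#' @export
simulateReads <- function(ref, profile, n, seed = profile@seed,
                          sampleId = "sim") {
  stopifnot(n >= 1L)
  if (!is.na(seed)) set.seed(seed)
  targets <- as.integer(names(profile@condEdit))
  idx <- offsetToIndex(ref, targets, within = "region")
  amp <- as.character(ref@amplicon)
  refChars <- strsplit(amp, "")[[1]]
  if (any(refChars[idx] != "C"))
    stop("condEdit references offset(s) whose reference base is not C",
         call. = FALSE)
  rs <- ref@regionStart; re <- ref@regionEnd
  regLen <- re - rs + 1L
  relIdx <- idx - rs + 1L
  k <- length(targets)

  engaged <- stats::runif(n) < profile@engagement
  editMat <- matrix(FALSE, n, k)
  baseMat <- matrix(NA_character_, n, k)
  for (j in seq_len(k)) {
    e <- engaged & (stats::runif(n) < profile@condEdit[j])
    editMat[, j] <- e
    ne <- sum(e)
    if (ne > 0L) {
      b <- rep("T", ne)
      impure <- stats::runif(ne) < profile@purityRho
      if (any(impure))
        b[impure] <- sample(c("A", "G"), sum(impure), replace = TRUE)
      baseMat[e, j] <- b
    }
  }

  regMat <- matrix(refChars[rs:re], n, regLen, byrow = TRUE)
  for (j in seq_len(k)) {
    sel <- editMat[, j]
    if (any(sel)) regMat[sel, relIdx[j]] <- baseMat[sel, j]
  }
  regionSeqs <- do.call(paste0, lapply(seq_len(regLen),
                                       function(p) regMat[, p]))

  hasIndel <- stats::runif(n) < profile@indelRate
  indelSize <- integer(n)
  for (i in which(hasIndel)) {
    sz <- sample.int(3L, 1L)
    s <- regionSeqs[i]
    if (stats::runif(1) < 0.5) {  # deletion
      pos <- sample.int(regLen - sz + 1L, 1L)
      regionSeqs[i] <- paste0(substr(s, 1L, pos - 1L),
                              substr(s, pos + sz, regLen))
      indelSize[i] <- -sz
    } else {                      # insertion
      pos <- sample.int(regLen + 1L, 1L)
      regionSeqs[i] <- paste0(substr(s, 1L, pos - 1L),
                              paste(.randomBases(sz), collapse = ""),
                              substr(s, pos, regLen))
      indelSize[i] <- sz
    }
  }

  readSeqs <- paste0(substr(amp, 1L, rs - 1L), regionSeqs,
                     substr(amp, re + 1L, nchar(amp)))
  lens <- nchar(readSeqs)
  nErr <- stats::rbinom(n, lens, profile@seqError)
  for (i in which(nErr > 0L)) {
    pos <- sample.int(lens[i], nErr[i])
    ch <- strsplit(readSeqs[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(.VALID_BASES, ch[p]), 1L)
    readSeqs[i] <- paste(ch, collapse = "")
  }

  ids <- sprintf("read_%06d", seq_len(n))
  truth <- data.frame(
    id = ids,
    engaged = engaged,
    editedOffsets = apply(editMat, 1L, function(e)
      paste(targets[e], collapse = ",")),
    editedBases = vapply(seq_len(n), function(i)
      paste(baseMat[i, editMat[i, ]], collapse = ","), character(1)),
    indel = hasIndel,
    indelSize = indelSize,
    nErrors = nErr,
    stringsAsFactors = FALSE)
  attr(truth, "marginal") <- stats::setNames(
    profile@engagement * profile@condEdit, targets)

  reads <- ReadSet(stats::setNames(readSeqs, ids),
                   strrep("I", lens), sampleId = sampleId)
  list(reads = reads, truth = truth)
}

# Draw one allele: named base vector over the target offsets.
.drawAllele <- function(targets, profile) {
  bases <- stats::setNames(rep("C", length(targets)), targets)
  if (stats::runif(1) < profile@engagement) {
    key <- names(profile@condEdit)
    e <- stats::runif(length(key)) < profile@condEdit
    for (j in which(e)) {
      b <- if (stats::runif(1) < profile@purityRho)
        sample(c("A", "G"), 1L) else "T"
      bases[key[j]] <- b
    }
  }
  bases
}

#' Simulate canavanine-resistant diploid colonies
#'
#' Each colony carries two alleles drawn independently from the editor
#' model. Resistance is recessive: a colony is canavanine-resistant iff BOTH
#' alleles carry at least one edit (non-C base) among the inactivating
#' offsets. Resistant colonies are produced by rejection sampling; an error
#' is raised after `maxAttempts` draws when the profile cannot produce
#' resistance (e.g. zero engagement).
#'
#' @param profile An [EditorProfile-class].
#' @param targets integer vector of target offsets the alleles are typed at
#'   (defaults to the profile's condEdit offsets).
#' @param inactivatingOffsets offsets whose editing inactivates the gene
#'   (default `c(-18, -19)`).
#' @param nColonies number of resistant colonies to produce.
#' @param seed RNG seed; defaults to the profile's seed.
#' @param maxAttempts rejection-sampling bound.
#' @return list with `colonies` (named list of allele pairs, as consumed by
#'   [tabulateGenotypes()]) and `truth` (data.frame of per-colony draw
#'   records, including the number of rejected draws in attribute
#'   `"nRejected"`).
#' @export
simulateColonies <- function(profile,
                             targets = as.integer(names(profile@condEdit)),
                             inactivatingOffsets = c(-18L, -19L),
                             nColonies, seed = profile@seed,
                             maxAttempts = 10000L * nColonies) {
  stopifnot(nColonies >= 1L)
  targets <- as.integer(targets)
  inactivatingOffsets <- as.integer(inactivatingOffsets)
  if (!all(inactivatingOffsets %in% targets))
    stop("inactivatingOffsets must be a subset of targets", call. = FALSE)
  if (!all(as.integer(names(profile@condEdit)) %in% targets))
    stop("condEdit offsets must be a subset of targets", call. = FALSE)
  if (!is.na(seed)) set.seed(seed)
  inactKey <- as.character(inactivatingOffsets)
  inactivated <- function(allele) any(allele[inactKey] != "C")

  colonies <- vector("list", nColonies)
  got <- 0L
  attempts <- 0L
  while (got < nColonies) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("no resistant colony obtained after ", maxAttempts,
           " attempts; resistance probability may be 0 under this profile",
           call. = FALSE)
    a1 <- .drawAllele(targets, profile)
    a2 <- .drawAllele(targets, profile)
    if (inactivated(a1) && inactivated(a2)) {
      got <- got + 1L
      colonies[[got]] <- list(allele1 = a1, allele2 = a2)
    }
  }
  names(colonies) <- sprintf("colony_%03d", seq_len(nColonies))
  truth <- data.frame(
    colony_id = names(colonies),
    pattern1 = vapply(colonies, function(col)
      .allelePattern(col$allele1, inactivatingOffsets), character(1)),
    pattern2 = vapply(colonies, function(col)
      .allelePattern(col$allele2, inactivatingOffsets), character(1)),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  attr(truth, "nRejected") <- attempts - nColonies
  list(colonies = colonies, truth = truth)
}

#' Exact allele-pattern distribution conditioned on resistance
#'
#' Closed-form enumeration of the per-allele edited/unedited pattern over
#' two inactivating offsets (assuming `purityRho = 0`), conditioned on the
#' allele being inactivating. Used as an independent oracle for
#' [simulateColonies()].
#'
#' @param profile An [EditorProfile-class] (purityRho must be 0).
#' @param inactivatingOffsets two offsets present in `condEdit`.
#' @return Named numeric: conditional probabilities of the patterns
#'   `"both"`, `"firstOnly"`, `"secondOnly"` (edited at both, only the
#'   first, only the second inactivating offset).
#' @export
alleleResistanceDistribution <- function(profile,
                                         inactivatingOffsets = c(-18L, -19L)) {
  if (profile@purityRho != 0)
    stop("closed form assumes purityRho = 0", call. = FALSE)
  key <- as.character(as.integer(inactivatingOffsets))
  if (!all(key %in% names(profile@condEdit)))
    stop("inactivatingOffsets must be condEdit offsets", call. = FALSE)
  p1 <- profile@condEdit[[key[1L]]]
  p2 <- profile@condEdit[[key[2L]]]
  g <- profile@engagement
  pInact <- g * (1 - (1 - p1) * (1 - p2))
  if (pInact == 0) stop("resistance probability is 0", call. = FALSE)
  c(both = g * p1 * p2 / pInact,
    firstOnly = g * p1 * (1 - p2) / pInact,
    secondOnly = g * (1 - p1) * p2 / pInact)
}

setMethod("show", "EditorProfile", function(object) {
  cat("EditorProfile: engagement ", object@engagement,
      ", purityRho ", object@purityRho,
      ", indelRate ", object@indelRate,
      ", seqError ", object@seqError, "\n", sep = "")
  cat("  condEdit: ",
      paste0(names(object@condEdit), ": ", object@condEdit, collapse = ", "),
      "\n", sep = "")
})
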