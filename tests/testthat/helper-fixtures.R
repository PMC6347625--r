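# Shared fixtures and independent naive oracles used across the suite.

# fixed C-free contexts (left ends in C, giving an offset -21 target when
# the protospacer itself starts with Cs)
LEFT_CTX <- "GTGAAGTTAGAGGATTAGTGATTGAGTGAAGGATTAGTAC"
RIGHT_CTX <- "TAGTAGGATTGATGAGATTGAAGTGAGTTAGAGATTGATG"

mkAmplicon <- function(proto, pam = "TGG") {
  paste0(LEFT_CTX, proto, pam, RIGHT_CTX)
}

mkReference <- function(proto, ...) {
  buildReference(mkAmplicon(proto), proto, ...)
}

# protospacer with Cs only at offsets -15 and -16 (positions 5 and 6)
PROTO_C1516 <- "ATGACCATGAGTTAGATGAG"
# protospacer without any C
PROTO_NOC <- "ATGGATTAGAGTTAGATGAG"

# build full reads around a set of region sequences (reference context)
readsFromRegions <- function(ref, regionSeqs, sampleId = "test") {
  amp <- as.character(ref@amplicon)
  ReadSet(paste0(substr(amp, 1, ref@regionStart - 1), regionSeqs,
                 substr(amp, ref@regionEnd + 1, nchar(amp))),
          sampleId = sampleId)
}

# --- independent naive oracles -------------------------------------------

# per-column base tally by direct looping over reads and positions
naiveConversionCounts <- function(regionSeqs) {
  L <- nchar(regionSeqs[1])
  m <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in regionSeqs) {
    for (j in seq_len(L)) {
      b <- substr(s, j, j)
      m[b, j] <- m[b, j] + 1L
    }
  }
  m
}

# brute-force per-read haplotype dictionary over the target positions
naiveProductCounts <- function(regionSeqs, relIdx, targetsAsc) {
  counts <- list()
  for (s in regionSeqs) {
    bases <- vapply(relIdx, function(j) substr(s, j, j), character(1))
    e <- bases != "C"
    lab <- if (!any(e)) "unedited"
           else paste0(bases[e], targetsAsc[e], collapse = "")
    counts[[lab]] <- (if (is.null(counts[[lab]])) 0L else counts[[lab]]) + 1L
  }
  unlist(counts)
}

# parse a pattern label into (base, offset) tokens
patternTokens <- function(pattern) {
  if (pattern == "unedited") return(data.frame(base = character(0),
                                               offset = integer(0)))
  tok <- regmatches(pattern, gregexpr("[ACGT]-[0-9]+", pattern))[[1]]
  data.frame(base = substr(tok, 1, 1),
             offset = as.integer(substring(tok, 2)))
}

patternHasBaseAt <- function(pattern, base, offset) {
  tok <- patternTokens(pattern)
  any(tok$base == base & tok$offset == offset)
}

# random allele for property tests: bases over given offsets
randomAllele <- function(offsets) {
  stats::setNames(sample(c("C", "C", "C", "T", "T", "A", "G"),
                         length(offsets), replace = TRUE),
                  as.character(offsets))
}
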