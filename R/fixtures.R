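# Built-in toy reference, reference-spec / index-table I/O, and the
# self-contained fixture bundle used by the test suite and documentation.

#' Built-in oligo(C) toy reference
#'
#' A fixed ~100-nt amplicon whose protospacer carries a nonacytidine motif:
#' cytidines at PAM-relative offsets -13 to -21 (eight inside the 20-nt
#' protospacer plus one immediately 5' of it), followed by a TGG PAM. This
#' is the worst-case substrate for window measurements: every position of a
#' nine-nt editing window is a potential target.
#'
#' @param regionHalfwidth,flankLen forwarded to [buildReference()].
#' @return An [AmpliconReference-class].
#' @examples
#' ref <- c9Reference()
#' targetCytidines(ref, range = c(-21, -1))
#' @export
c9Reference <- function(regionHalfwidth = 5L, flankLen = 10L) {
  protospacer <- "CCCCCCCCATGGATTAGAGT"   # Cs at -13..-20, no other C
  leftCtx  <- "GTGAAGTTAGAGGATTAGTGATTGAGTGAAGGATTAGTAC"  # ends in C: offset -21
  rightCtx <- "TAGTAGGATTGATGAGATTGAAGTGAGTTAGAGATTGATG"
  buildReference(paste0(leftCtx, protospacer, "TGG", rightCtx),
                 protospacer, pamPattern = "NGG",
                 regionHalfwidth = regionHalfwidth, flankLen = flankLen)
}

#' Read a reference specification file
#'
#' Key-value YAML with fields `fasta` (path, relative to the spec file),
#' `record` (FASTA record id; the first record when omitted),
#' `protospacer`, `pam` (default `"NGG"`), `region_halfwidth` and
#' `flank_len`.
#'
#' @param path YAML file path.
#' @return An [AmpliconReference-class].
#' @export
readReferenceSpec <- function(path) {
  spec <- yaml::read_yaml(path)
  for (field in c("fasta", "protospacer"))
    if (is.null(spec[[field]]))
      stop("reference spec lacks field '", field, "'", call. = FALSE)
  fasta <- spec$fasta
  if (!file.exists(fasta))
    fasta <- file.path(dirname(path), spec$fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  rec <- if (is.null(spec$record)) 1L else {
    hit <- which(names(seqs) == spec$record)
    if (length(hit) != 1L)
      stop("record '", spec$record, "' not found in ", fasta, call. = FALSE)
    hit
  }
  buildReference(as.character(seqs[[rec]]), spec$protospacer,
                 pamPattern = if (is.null(spec$pam)) "NGG" else spec$pam,
                 regionHalfwidth = if (is.null(spec$region_halfwidth)) 5L
                                   else spec$region_halfwidth,
                 flankLen = if (is.null(spec$flank_len)) 10L
                            else spec$flank_len)
}

#' Read a demultiplexing index table
#'
#' Two-column TSV (`tag`, `sample_id`), as consumed by [demultiplex()].
#'
#' @param path TSV file path.
#' @return data.frame with columns `tag` and `sample_id`.
#' @export
readIndexTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("tag", "sample_id") %in% names(df)))
    stop("index table must have columns 'tag' and 'sample_id'", call. = FALSE)
  df[c("tag", "sample_id")]
}

#' Write a self-contained toy dataset
#'
#' Emits, under `outDir`: the toy reference (FASTA + YAML spec), a
#' demultiplexing index table, one multiplexed FASTQ with four tagged
#' samples (three editor presets plus an unengaged control), a colony
#' genotype TSV from the truncated-editor preset, and a ground-truth JSON
#' recording the generative parameters and per-read/per-colony truth.
#' Byte-identical across runs for a fixed seed.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer RNG seed.
#' @param readsPerSample reads per sample in the multiplexed FASTQ.
#' @param nColonies colonies in the genotype table.
#' @return Named character vector of the files written (the manifest).
#' @export
writeFixtureBundle <- function(outDir, seed = 101L, readsPerSample = 300L,
                               nColonies = 24L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ref <- c9Reference()
  amp <- Biostrings::DNAStringSet(as.character(ref@amplicon))
  names(amp) <- "amplicon"

  paths <- c(
    fasta = file.path(outDir, "reference.fasta"),
    spec = file.path(outDir, "reference.yaml"),
    index = file.path(outDir, "index.tsv"),
    fastq = file.path(outDir, "reads.fastq"),
    colonies = file.path(outDir, "colonies.tsv"),
    truth = file.path(outDir, "truth.json"))

  Biostrings::writeXStringSet(amp, paths[["fasta"]])
  yaml::write_yaml(list(fasta = "reference.fasta", record = "amplicon",
                        protospacer = protospacerSequence(ref),
                        pam = "NGG", region_halfwidth = 5L, flank_len = 10L),
                   paths[["spec"]])

  samples <- c("broad", "full_length", "truncated", "control")
  tags <- c(broad = "ACGTACGT", full_length = "TGCATGCA",
            truncated = "GATCGATC", control = "CTAGCTAG")
  utils::write.table(
    data.frame(tag = unname(tags), sample_id = samples),
    paths[["index"]], sep = "\t", quote = FALSE, row.names = FALSE)

  profiles <- list(
    broad = editorPresets("broad"),
    full_length = editorPresets("full_length"),
    truncated = editorPresets("truncated"),
    control = editorProfile(0, c("-18" = 0), seqError = 0.001))

  allSeqs <- character(0)
  allQuals <- character(0)
  allIds <- character(0)
  truthBySample <- list()
  for (i in seq_along(samples)) {
    s <- samples[i]
    sim <- simulateReads(ref, profiles[[s]], readsPerSample,
                         seed = seed + i, sampleId = s)
    tagged <- paste0(tags[[s]], as.character(sim$reads@sequences))
    allSeqs <- c(allSeqs, tagged)
    allQuals <- c(allQuals, strrep("I", nchar(tagged)))
    allIds <- c(allIds, paste0(s, "_", names(sim$reads@sequences)))
    truthBySample[[s]] <- list(
      profile = list(engagement = profiles[[s]]@engagement,
                     condEdit = as.list(profiles[[s]]@condEdit),
                     purityRho = profiles[[s]]@purityRho,
                     indelRate = profiles[[s]]@indelRate,
                     seqError = profiles[[s]]@seqError),
      marginal = as.list(attr(sim$truth, "marginal")),
      nIndelReads = sum(sim$truth$indel),
      nEngaged = sum(sim$truth$engaged))
  }
  writeFastqReads(ReadSet(stats::setNames(allSeqs, allIds), allQuals,
                          sampleId = "multiplexed"), paths[["fastq"]])

  colSim <- simulateColonies(profiles$truncated,
                             targets = seq.int(-21L, -13L),
                             inactivatingOffsets = c(-18L, -19L),
                             nColonies = nColonies, seed = seed + 99L)
  writeColonyTable(colSim$colonies, paths[["colonies"]])

  jsonlite::write_json(
    list(seed = seed, readsPerSample = readsPerSample,
         nColonies = nColonies, samples = truthBySample,
         colonyPatterns = colSim$truth[c("colony_id", "pattern1", "pattern2")]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
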