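# Canavanine-selection statistics and diploid colony genotype tables.

#' Mutation frequency from plate counts
#'
#' The mutation frequency is the ratio of the colony count on
#' canavanine-containing plates to the colony count on rich-media (YPAD)
#' plates. Vectorised over replicates; `NA` where the rich-plate count is
#' zero (never reported as 0).
#'
#' @param nCanavanine,nRich non-negative integer vectors of colony counts.
#' @return Numeric vector of frequencies.
#' @export
mutationFrequency <- function(nCanavanine, nRich) {
  if (any(nCanavanine < 0) || any(nRich < 0))
    stop("colony counts must be non-negative", call. = FALSE)
  ifelse(nRich > 0, nCanavanine / nRich, NA_real_)
}

#' Mean and standard deviation across biological replicates
#'
#' Sample mean and (n-1)-denominator sample standard deviation, the summary
#' used for replicate error bars. With a single value the sd is `NA`.
#'
#' @param values numeric vector of replicate values (length >= 1).
#' @return Named list with `mean`, `sd` and `n`.
#' @export
replicateSummary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("no replicate values", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       n = length(values))
}

# Pattern label of one allele over the focal offsets, 5'->3':
# e.g. c(`-19` = "C", `-18` = "T") -> "C-19T-18"
.allelePattern <- function(allele, focalOffsets) {
  key <- as.character(focalOffsets)
  if (!all(key %in% names(allele)))
    stop("incomplete genotype: allele lacks offset(s) ",
         paste(setdiff(key, names(allele)), collapse = ", "), call. = FALSE)
  ord <- sort(as.integer(focalOffsets))
  paste0(allele[as.character(ord)], ord, collapse = "")
}

#' Classify a diploid colony genotype at focal offsets
#'
#' A colony is homozygous when its two alleles carry identical bases at all
#' focal offsets (label: the shared pattern), heterozygous otherwise (label:
#' the unordered pair of patterns). The classification does not depend on
#' the order in which the alleles are given. Bases other than C/T (rare
#' C-to-G/A products) keep their own symbols, so residual categories are
#' labelled explicitly.
#'
#' @param allele1,allele2 named character vectors, observed base per target
#'   offset; names are offsets, e.g. `c("-19" = "C", "-18" = "T")`.
#' @param focalOffsets integer vector of offsets used for classification
#'   (default `c(-18, -19)`, the inactivating positions of the Can1 locus).
#' @return character(1) category label, e.g. `"C-19T-18 homozygous"` or
#'   `"C-19T-18/T-19T-18 heterozygous"`.
#' @export
classifyGenotype <- function(allele1, allele2, focalOffsets = c(-18L, -19L)) {
  p1 <- .allelePattern(allele1, focalOffsets)
  p2 <- .allelePattern(allele2, focalOffsets)
  if (p1 == p2) paste(p1, "homozygous")
  else paste(paste(sort(c(p1, p2)), collapse = "/"), "heterozygous")
}

#' Tabulate colony genotype categories
#'
#' Classifies every colony with [classifyGenotype()] and counts the
#' categories. Categories are generated from the observed patterns (not
#' hard-coded), so rare products appear under their own explicit labels; the
#' counts always sum to the number of colonies.
#'
#' @param colonies list of colonies, each a list/pair of two allele vectors
#'   as accepted by [classifyGenotype()].
#' @param focalOffsets offsets used for classification.
#' @return data.frame with columns `category` and `count`, sorted by
#'   decreasing count.
#' @export
tabulateGenotypes <- function(colonies, focalOffsets = c(-18L, -19L)) {
  if (length(colonies) == 0L) stop("no colonies supplied", call. = FALSE)
  labels <- vapply(colonies, function(col)
    classifyGenotype(col[[1L]], col[[2L]], focalOffsets), character(1))
  counts <- table(labels)
  out <- data.frame(category = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$category), ]
  rownames(out) <- NULL
  out
}

#' Read and write colony genotype tables
#'
#' Long-format TSV with columns `colony_id`, `offset`, `allele_1_base`,
#' `allele_2_base`; one row per colony and target offset.
#'
#' @param path TSV file path.
#' @return `readColonyTable`: a named list of colonies (pairs of allele
#'   vectors) as consumed by [tabulateGenotypes()].
#' @export
readColonyTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("colony_id", "offset", "allele_1_base", "allele_2_base")
  if (!all(need %in% names(df)))
    stop("colony table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$colony_id), function(d) {
    key <- as.character(d$offset)
    list(allele1 = stats::setNames(d$allele_1_base, key),
         allele2 = stats::setNames(d$allele_2_base, key))
  })
}

#' @rdname readColonyTable
#' @param colonies named list of colonies (pairs of allele vectors).
#' @export
writeColonyTable <- function(colonies, path) {
  ids <- names(colonies)
  if (is.null(ids)) ids <- sprintf("colony_%03d", seq_along(colonies))
  rows <- do.call(rbind, lapply(seq_along(colonies), function(i) {
    a1 <- colonies[[i]][[1L]]
    a2 <- colonies[[i]][[2L]]
    data.frame(colony_id = ids[i], offset = as.integer(names(a1)),
               allele_1_base = unname(a1),
               allele_2_base = unname(a2[names(a1)]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read plate-count tables
#'
#' TSV with columns `replicate`, `n_canavanine`, `n_rich`.
#'
#' @param path TSV file path.
#' @return data.frame with an added `frequency` column
#'   (see [mutationFrequency()]).
#' @export
readPlateCounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("replicate", "n_canavanine", "n_rich")
  if (!all(need %in% names(df)))
    stop("plate-count table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df$frequency <- mutationFrequency(df$n_canavanine, df$n_rich)
  df
}
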