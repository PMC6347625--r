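test_that("conversionMatrix counts per-position bases over all matched reads", {
  ref <- mkReference(PROTO_C1516)
  regSeq <- regionSequence(ref)
  # all-reference regions: every off-reference frequency is 0
  m0 <- conversionMatrix(Biostrings::DNAStringSet(rep(regSeq, 10)), ref)
  expect_identical(m0@nReads, 10L)
  for (j in seq_along(m0@refBases))
    expect_identical(unname(m0@freq[m0@refBases[j], j]), 1)

  # 4 of 10 regions carry T at offset -18 -> C-to-T 40% there, 0 elsewhere
  ref18 <- mkReference("CCCCCCCCATGGATTAGAGT")  # Cs at -13..-20
  rs <- regionSequence(ref18)
  j18 <- offsetToIndex(ref18, -18L) - ref18@regionStart + 1L
  edited <- paste0(substr(rs, 1, j18 - 1), "T",
                   substr(rs, j18 + 1, nchar(rs)))
  m <- conversionMatrix(Biostrings::DNAStringSet(c(rep(edited, 4),
                                                   rep(rs, 6))), ref18)
  prof <- cToTProfile(m, targetCytidines(ref18))
  expect_identical(unname(prof[["-18"]]), 0.4)
  expect_identical(unname(sum(prof)), 0.4)

  expect_error(conversionMatrix(Biostrings::DNAStringSet(character(0)), ref),
               "no matched reads")
})

test_that("conversionMatrix equals a naive per-column tally on simulated reads", {
  ref <- c9Reference()
  prof <- editorPresets("truncated")
  sim <- simulateReads(ref, prof, 200, seed = 5)
  regs <- extractRegions(sim$reads, ref)
  m <- conversionMatrix(regs, ref)
  naive <- naiveConversionCounts(as.character(editingRegions(regs)))
  expect_identical(unname(m@counts), unname(naive))
  expect_equal(unname(m@freq), unname(naive / matchedCount(regs)))
})

test_that("cToTProfile projects the T row at target Cs and validates inputs", {
  ref <- mkReference(PROTO_C1516)
  m <- conversionMatrix(Biostrings::DNAStringSet(rep(regionSequence(ref), 3)),
                        ref)
  prof <- cToTProfile(m, c(-15L, -16L))
  expect_identical(unname(prof), c(0, 0))
  expect_error(cToTProfile(m, -4L), "not C")       # ref base A at -4
  # offset absent from the matrix
  expect_error(cToTProfile(m, -40L), "absent")
})

test_that("productDistribution tabulates edit patterns with both denominators", {
  ref <- mkReference("CCCCCCCCATGGATTAGAGT")
  rs <- regionSequence(ref)
  setBase <- function(s, offset, b) {
    j <- offsetToIndex(ref, offset) - ref@regionStart + 1L
    paste0(substr(s, 1, j - 1), b, substr(s, j + 1, nchar(s)))
  }
  single <- setBase(rs, -18L, "T")
  double <- setBase(single, -17L, "T")
  regs <- Biostrings::DNAStringSet(c(rep(single, 5), rep(double, 3),
                                     rep(rs, 2)))
  d <- productDistribution(regs, ref, targetCytidines(ref))
  tab <- d@table
  expect_identical(sum(tab$count), 10L)
  expect_identical(tab$fracReads[tab$pattern == "T-18"], 0.5)
  expect_identical(tab$fracReads[tab$pattern == "T-18T-17"], 0.3)
  expect_identical(tab$fracReads[tab$pattern == "unedited"], 0.2)
  expect_identical(tab$fracEdited[tab$pattern == "T-18"], 5 / 8)
  expect_true(is.na(tab$fracEdited[tab$pattern == "unedited"]))

  # all-reference reads: single unedited bucket with fraction 1
  d0 <- productDistribution(Biostrings::DNAStringSet(rep(rs, 4)), ref,
                            targetCytidines(ref))
  expect_identical(d0@table$pattern, "unedited")
  expect_identical(d0@table$fracReads, 1)

  # empty target set: everything is unedited
  dEmpty <- productDistribution(regs, ref, integer(0))
  expect_identical(dEmpty@table$count, 10L)
})

test_that("productDistribution equals a brute-force haplotype dictionary", {
  ref <- c9Reference()
  targets <- targetCytidines(ref, range = c(-21, -1))
  prof <- editorPresets("broad")  # multi-edit products populate 2^9 space
  sim <- simulateReads(ref, prof, 800, seed = 13)
  regs <- extractRegions(sim$reads, ref)
  d <- productDistribution(regs, ref, targets)
  targetsAsc <- sort(targets)
  relIdx <- offsetToIndex(ref, targetsAsc, within = "region") -
    ref@regionStart + 1L
  naive <- naiveProductCounts(as.character(editingRegions(regs)),
                              relIdx, targetsAsc)
  expect_identical(sort(names(naive)), sort(d@table$pattern))
  expect_identical(unname(naive[d@table$pattern]), d@table$count)
})

test_that("singleEditFraction is the single-T pattern share of edited reads", {
  ref <- mkReference("CCCCCCCCATGGATTAGAGT")
  rs <- regionSequence(ref)
  setBase <- function(s, offset, b) {
    j <- offsetToIndex(ref, offset) - ref@regionStart + 1L
    paste0(substr(s, 1, j - 1), b, substr(s, j + 1, nchar(s)))
  }
  single <- setBase(rs, -18L, "T")
  double <- setBase(setBase(rs, -18L, "T"), -19L, "T")
  d <- productDistribution(
    Biostrings::DNAStringSet(c(rep(single, 6), rep(double, 4))),
    ref, targetCytidines(ref))
  expect_identical(singleEditFraction(d, -18L), 0.6)
  # only single-T-at--18 edited reads -> 1.0
  d1 <- productDistribution(Biostrings::DNAStringSet(rep(single, 3)),
                            ref, targetCytidines(ref))
  expect_identical(singleEditFraction(d1, -18L), 1)
  # no edited reads -> NA
  dNA <- productDistribution(Biostrings::DNAStringSet(rep(rs, 3)),
                             ref, targetCytidines(ref))
  expect_true(is.na(singleEditFraction(dNA, -18L)))
  expect_error(singleEditFraction(d, -3L), "not a target")
})

test_that("higher co-editing lowers the single-edit fraction", {
  ref <- c9Reference()
  targets <- targetCytidines(ref, range = c(-21, -1))
  mk <- function(p19) {
    ce <- stats::setNames(c(rep(0.02, 5), 0.9, p19, 0.02, 0.02),
                          as.character(-13:-21))
    editorProfile(0.6, ce)
  }
  fracs <- vapply(c(0.05, 0.3, 0.7), function(p19) {
    sim <- simulateReads(ref, mk(p19), 3000, seed = 99)
    d <- productDistribution(extractRegions(sim$reads, ref), ref, targets)
    singleEditFraction(d, -18L)
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})

test_that("puritySummary splits edits into T/A/G outcomes", {
  ref <- mkReference("CCCCCCCCATGGATTAGAGT")
  rs <- regionSequence(ref)
  setBase <- function(s, offset, b) {
    j <- offsetToIndex(ref, offset) - ref@regionStart + 1L
    paste0(substr(s, 1, j - 1), b, substr(s, j + 1, nchar(s)))
  }
  tEdit <- setBase(rs, -18L, "T")
  gEdit <- setBase(rs, -18L, "G")
  regs <- Biostrings::DNAStringSet(c(rep(tEdit, 9), gEdit))
  m <- conversionMatrix(regs, ref)
  d <- productDistribution(regs, ref, targetCytidines(ref))
  p <- puritySummary(m, d)
  row <- p@perPosition[p@perPosition$offset == -18, ]
  expect_identical(row$cToT, 0.9)
  expect_identical(row$cToG, 0.1)
  expect_identical(row$cToT + row$cToA + row$cToG + row$cRetained, 1)
  # 1 of 10 edited reads carries a non-T edit
  expect_identical(p@nonTEditedFraction, 0.1)

  # all edits C-to-T -> non-T fraction 0
  pT <- puritySummary(conversionMatrix(Biostrings::DNAStringSet(rep(tEdit, 5)),
                                       ref),
                      productDistribution(Biostrings::DNAStringSet(rep(tEdit, 5)),
                                          ref, targetCytidines(ref)))
  expect_identical(pT@nonTEditedFraction, 0)
})

test_that("simulated impure edits are recovered at the purity parameter", {
  ref <- c9Reference()
  prof <- editorProfile(1, c("-18" = 1), purityRho = 0.1)
  sim <- simulateReads(ref, prof, 5000, seed = 17)
  regs <- extractRegions(sim$reads, ref)
  m <- conversionMatrix(regs, ref)
  row <- which(m@offsets == -18L)
  nonT <- m@freq["A", row] + m@freq["G", row]
  tol <- 3 * sqrt(0.1 * 0.9 / matchedCount(regs))
  expect_lt(abs(nonT - 0.1), tol)
})

test_that("base frequencies sum to one and counts match the T profile exactly", {
  ref <- c9Reference()
  targets <- targetCytidines(ref, range = c(-21, -1))
  for (preset in c("broad", "full_length", "truncated")) {
    sim <- simulateReads(ref, editorPresets(preset), 500,
                         seed = match(preset, c("broad", "full_length",
                                                "truncated")))
    regs <- extractRegions(sim$reads, ref)
    m <- conversionMatrix(regs, ref)
    expect_true(all(abs(colSums(m@freq) - 1) < 1e-9))
    d <- productDistribution(regs, ref, targets)
    # count-level identity: patterns with T at p sum to the T count at p
    for (p in targets) {
      patSum <- sum(d@table$count[vapply(d@table$pattern, patternHasBaseAt,
                                         logical(1), base = "T", offset = p)])
      expect_identical(patSum, unname(m@counts["T", m@offsets == p &
                                                 !is.na(m@offsets)]))
    }
  }
})
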