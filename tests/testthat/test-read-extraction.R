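test_that("demultiplex partitions reads by exact tag match and strips tags", {
  tab <- data.frame(tag = c("ACGT", "TGCA"), sample_id = c("s1", "s2"))
  reads <- ReadSet(c(r1 = "ACGTAAAA", r2 = "TGCAGGGG",
                     r3 = "ACGTTTTT", r4 = "TGCACCCC"),
                   qualities = rep("IIIIIIII", 4))
  bins <- demultiplex(reads, tab)
  expect_named(bins, c("s1", "s2", "undetermined"))
  expect_identical(readCount(bins$s1), 2L)
  expect_identical(readCount(bins$s2), 2L)
  expect_identical(readCount(bins$undetermined), 0L)
  expect_identical(as.character(bins$s1@sequences), c(r1 = "AAAA", r3 = "TTTT"))
  expect_identical(as.character(bins$s1@qualities), c(r1 = "IIII", r3 = "IIII"))

  # unknown prefix goes to the undetermined bin, unmodified
  reads2 <- ReadSet(c(r1 = "ACGTAAAA", rx = "GGGGTTTT"))
  bins2 <- demultiplex(reads2, tab)
  expect_identical(readCount(bins2$undetermined), 1L)
  expect_identical(as.character(bins2$undetermined@sequences),
                   c(rx = "GGGGTTTT"))

  # suffix tags
  bins3 <- demultiplex(ReadSet(c(r1 = "AAAAACGT")), tab,
                       tagLocation = "suffix")
  expect_identical(as.character(bins3$s1@sequences), c(r1 = "AAAA"))

  expect_error(demultiplex(reads, data.frame(tag = c("ACGT", "ACGT"),
                                             sample_id = c("a", "b"))),
               "duplicate")
  expect_error(demultiplex(reads, data.frame(tag = character(0),
                                             sample_id = character(0))),
               "empty")
})

test_that("demultiplex recovers the simulator's ground-truth assignment", {
  set.seed(11)
  tags <- c("AACCGGTT", "TTGGCCAA", "ACACACAC", "GTGTGTGT")
  tab <- data.frame(tag = tags, sample_id = paste0("s", 1:4))
  truthSample <- sample(1:4, 1000, replace = TRUE)
  body <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
  reads <- ReadSet(paste0(tags[truthSample], body))
  bins <- demultiplex(reads, tab)
  for (j in 1:4)
    expect_identical(readCount(bins[[paste0("s", j)]]),
                     sum(truthSample == j))
  # partition completeness
  expect_identical(sum(vapply(bins, readCount, integer(1))), 1000L)
})

test_that("extractRegions applies the exact flank-and-length rule", {
  ref <- mkReference(PROTO_C1516)
  amp <- as.character(ref@amplicon)
  regSeq <- regionSequence(ref)
  regLen <- regionWidth(ref)

  # identity read is matched and yields the reference region
  ident <- readsFromRegions(ref, regSeq)
  res <- extractRegions(ident, ref)
  expect_identical(matchedCount(res), 1L)
  expect_identical(unname(as.character(editingRegions(res))), unname(regSeq))

  # 1-nt deletion inside the region, flanks intact -> length rejection
  del1 <- readsFromRegions(ref, substr(regSeq, 2, regLen))
  expect_identical(extractRegions(del1, ref)@nRejectedLength, 1L)

  # 3 exact, 1 mutated flank base, 1 with a 2-nt insertion -> 3/1/1
  badFlank <- sub("^.", ifelse(substr(ref@leftFlank, 1, 1) == "A", "G", "A"),
                  ref@leftFlank)
  flankRead <- paste0(substr(amp, 1, ref@regionStart - 11), badFlank,
                      regSeq, substr(amp, ref@regionEnd + 1, nchar(amp)))
  ins2 <- paste0(substr(regSeq, 1, 4), "AT", substr(regSeq, 5, regLen))
  five <- ReadSet(c(as.character(readsFromRegions(ref, rep(regSeq, 3))@sequences),
                    flankRead,
                    as.character(readsFromRegions(ref, ins2)@sequences)))
  res5 <- extractRegions(five, ref)
  expect_identical(res5@nMatched, 3L)
  expect_identical(res5@nRejectedFlank, 1L)
  expect_identical(res5@nRejectedLength, 1L)
  expect_identical(res5@nInput,
                   res5@nMatched + res5@nRejectedFlank +
                   res5@nRejectedLength + res5@nRejectedAmbiguous)

  # a read with a duplicated left flank is ambiguous
  dup <- paste0(ref@leftFlank, as.character(ident@sequences[[1]]))
  expect_identical(extractRegions(ReadSet(dup), ref)@nRejectedAmbiguous, 1L)
})

test_that("classifyIndels uses flank-to-flank length, NA on empty denominator", {
  ref <- mkReference(PROTO_C1516)
  regSeq <- regionSequence(ref)
  regLen <- regionWidth(ref)
  subst <- paste0("T", substr(regSeq, 2, regLen))  # substitution, same length
  longer <- paste0(regSeq, "AT")                   # +2 nt
  reads <- readsFromRegions(ref, c(subst, longer))
  s <- classifyIndels(reads, ref)
  expect_identical(s@nNoIndel, 1L)
  expect_identical(s@nIndel, 1L)
  expect_identical(s@indelFrequency, 0.5)

  # no read with intact flanks -> frequency NA, not 0
  none <- ReadSet("ACGTACGTACGTACGTACGTACGT")
  sNA <- classifyIndels(none, ref)
  expect_identical(sNA@nExcludedFlank, 1L)
  expect_true(is.na(sNA@indelFrequency))
})

test_that("classifyIndels recovers a simulated indel rate", {
  ref <- c9Reference()
  prof <- editorProfile(0.5, c("-18" = 0.9), indelRate = 0.02, seqError = 0)
  sim <- simulateReads(ref, prof, 4000, seed = 21)
  s <- classifyIndels(sim$reads, ref)
  expect_identical(s@nExcludedFlank, 0L)
  tol <- 3 * sqrt(0.02 * 0.98 / 4000)
  expect_lt(abs(s@indelFrequency - 0.02), tol)
  # and the classification agrees with the simulator's per-read truth
  expect_identical(s@nIndel, sum(sim$truth$indel))
})

test_that("regions matched by extractRegions are classified as indel-free", {
  ref <- c9Reference()
  prof <- editorPresets("truncated")
  sim <- simulateReads(ref, prof, 1500, seed = 31)
  res <- extractRegions(sim$reads, ref)
  s <- classifyIndels(sim$reads, ref, flankLen = 10)
  expect_gte(s@nNoIndel, matchedCount(res))
  # determinism: identical inputs give identical outputs
  res2 <- extractRegions(sim$reads, ref)
  expect_identical(as.character(editingRegions(res)),
                   as.character(editingRegions(res2)))
})

test_that("qualityFilter retains reads by mean Phred quality", {
  ref <- mkReference(PROTO_C1516)
  q <- function(qval, len) strrep(intToUtf8(33L + qval), len)
  reads <- ReadSet(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                   qualities = c(q(10, 8), q(20, 8), q(30, 8)))
  # threshold 0 is the identity
  expect_identical(readCount(qualityFilter(reads, 0)), 3L)
  # known means {10, 20, 30}, threshold 20 -> exactly 2 retained
  kept <- qualityFilter(reads, 20)
  expect_identical(names(kept@sequences), c("b", "c"))
  # all-Q40 read passes threshold 20
  expect_identical(readCount(qualityFilter(
    ReadSet("ACGT", qualities = "IIII"), 20)), 1L)
  # pass-through when qualities are absent
  nq <- ReadSet(c("ACGTACGT"))
  expect_identical(readCount(qualityFilter(nq, 30)), 1L)
  # malformed quality strings are rejected with a logged count
  bad <- ReadSet(c(a = "ACGT", b = "ACGT"),
                 qualities = c("III ", "IIII"))
  expect_message(out <- qualityFilter(bad, 20), "malformed")
  expect_identical(readCount(out), 1L)
})
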