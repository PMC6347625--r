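---
title: "Quantifying cytidine base-editing outcomes from amplicon reads"
author: "ampliconBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytidine base-editing outcomes from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconBE)
```

## The measurement problem

Cytidine base editors — fusions of a Cas9 nickase with a cytidine deaminase
(plus a uracil glycosylase inhibitor) — convert C·G pairs to T·A without a
double-strand break. Their practical limitation is the *editing window*:
any C within a several-nucleotide stretch of the protospacer can be
deaminated, so engineering efforts that narrow the window need a
quantitative readout of *where* and *how often* each C is edited, *which
combinations* of Cs co-occur within single molecules, and *how pure* the
products are (C→T versus rare C→A/C→G), together with the indel side-product
rate.

ampliconBE implements that readout for targeted amplicon deep sequencing.
It deliberately avoids alignment: reads are admitted to the analysis only
if two exact flanking anchor sequences frame a segment of exactly the
reference length, which excludes indel-containing and imperfectly matching
reads by construction and lets every retained read be treated as a gapless
column-wise alignment. The same anchoring, applied separately, *is* the
indel classifier: a read with both anchors intact but a different enclosed
length carries an indel.

All positions are reported PAM-relative: offset $-1$ is the protospacer
base adjacent to the PAM and offset $-k$ lies $k$ bases 5' of it. This is
the frame in which editor behaviour is comparable across loci. Amplicons
whose protospacer lies on the reverse strand are reverse-complemented at
ingest so that one reporting frame serves everything downstream.

## The pipeline

For a sample the pipeline is

1. **demultiplex** — exact index-tag match at a stated read end, tag
   stripped, unassigned reads kept in an `undetermined` bin so the bins
   always partition the input;
2. **extractRegions** — exact flank anchoring as above, with full rejection
   accounting (`flank`, `length`, `ambiguous`);
3. **conversionMatrix** — per-position counts of A/C/G/T over all matched
   reads; frequencies use the *total matched reads* as denominator;
4. **productDistribution** — each read mapped to its edited-product
   haplotype over the target Cs (observed base recorded per edited
   position, so purity is recoverable from the distribution); fractions are
   reported both of all reads and of edited reads, since both denominators
   are in routine use;
5. **windowWidth / positionalSelectivity / editorComparison** — scalar
   summaries for comparing editors;
6. **classifyIndels** — the flank-to-flank length rule.

A read with sequencing errors in a flank is rejected (exactness is the
filter); errors *inside* the region at non-target positions do not reject a
read — they simply appear in the conversion matrix. Frequencies with a zero
denominator are reported as `NA`, never as 0.

## Definitions that needed a decision

**Window width.** Published width statements ("4–5 nt", "up to 9 nt") come
without a formal rule. This package defines the window as the minimal
contiguous interval of offsets containing every position with activity at
least a fraction $t$ (default $t = 0.3$) of the profile maximum, and its
width as that interval's length. The rule is scale-free (invariant under
multiplying the profile by any positive constant), reproduces the expected
flat-vs-peaked ordering, and is always emitted alongside the number so the
width is never quoted rule-free.

**Positional selectivity.** The fold preference of a focal C is its
activity divided by the best neighbouring activity. When the neighbours are
all zero the fold is unbounded; it is reported as a capped value
(activity/ε, flagged `capped`), never as infinity, to keep serialisation
stable.

**Flank multiplicity.** "Exactly matching" flanks leave open what to do
when a flank occurs more than once in a read. Such reads are rejected as
ambiguous rather than resolved heuristically — exactness is preserved.
Flanks that occur out of order are counted as flank rejections (they fail
to frame a region). One flank-length parameter (default 10 nt, the length
used for the indel scan) serves both extraction and indel classification,
which makes the two consistent: every extracted region is, by construction,
classified indel-free.

**Genotype categories.** Diploid colony genotypes are classified at focal
offsets (default $\{-18, -19\}$, the inactivating positions of the yeast
*CAN1* assay): homozygous when the two alleles agree there, heterozygous
otherwise, with the unordered pair as label. Categories are generated from
the observed patterns rather than hard-coded, so rare C→G/A products form
their own explicit residual categories and other loci reuse the machinery
unchanged.

## The simulator and what it does (not) emulate

`simulateReads()` draws, per read: an *engagement* event with probability
$g$ (the editor acted on this molecule); given engagement, an independent
edit at each target offset $o$ with conditional probability $p_o$; each
edited base is T with probability $1-\rho$ and A or G (equiprobably)
otherwise; a single indel (size 1–3 nt, insertion or deletion equiprobable,
uniform position within the region) with probability $r$; and uniform
per-base substitution errors at rate $e$ applied last over the whole read.
Constant Q40 qualities are emitted (quality modelling is not part of the
procedure; a degraded-quality path exists only to exercise the quality
filter).

The single latent engagement variable is the simplest mechanism that both
produces the correlated multi-C products seen in real editor data and keeps
closed forms: the marginal edit frequency at $o$ is $g\,p_o$ and the
covariance of edits at $a, b$ is $g(1-g)p_a p_b$. Both identities are
checked against the simulator's truth records in the test suite. What the
simulator does *not* emulate: PCR bias and chimeras, position-dependent
Illumina error profiles, paired-end structure, and multi-indel reads.
Passing tests therefore demonstrate correctness of the *quantification*
under a known generative model, not robustness to every artefact of real
libraries.

`simulateColonies()` draws two alleles per colony from the same edit model
and retains colonies by rejection sampling under a *recessive* selection
rule: a colony is canavanine-resistant only when **both** alleles carry at
least one edit among the inactivating offsets. Recessiveness is stated here
as an explicit model assumption — it is implied by the diploid host and by
resistant colonies being biallelically edited, but it is a modelling
choice of this package. The conditional allele-pattern distribution has a
closed form (`alleleResistanceDistribution()`, $\rho = 0$) used as the
independent oracle for the sampler.

### Study conditions (chosen once)

The built-in `c9Reference()` is a 103-nt amplicon whose protospacer carries
a nonacytidine stretch: target Cs at offsets $-13$ to $-21$, eight inside
the 20-nt protospacer and one immediately 5' of it — the worst-case
substrate where every window position is a potential target. (This is also
why target scanning accepts offsets slightly outside the protospacer, via
`targetCytidines(range =)`.) Simulated samples use 20,000 reads — real
samples run larger, but at 20,000 the binomial standard error of a
frequency near 0.5 is already $\approx 0.35$ percentage points, ample for
every comparison made here — on a ~100-nt amplicon emulating 150-bp reads.

Three illustrative presets (`editorPresets()`) span the behaviours of
interest and are labelled illustrative because per-editor co-editing
strength is not a published quantity:

| preset | engagement | condEdit | ρ | indel | error |
|---|---|---|---|---|---|
| `broad` | 0.70 | 0.8 flat over −13…−21 | 0.05 | 0.01 | 0.001 |
| `full_length` | 0.65 | 0.7–0.8 over −16…−19 | 0.02 | 0.005 | 0.001 |
| `truncated` | 0.60 | 0.9 at −18, 0.3 at −17, ≤0.1 elsewhere | 0.02 | 0.005 | 0.001 |

## Numerical conventions

* Conversion-matrix columns sum to 1 exactly by construction (counts over a
  common denominator); the invariant is asserted to $10^{-9}$.
* All counters are integers end to end; frequency identities used in tests
  (e.g. haplotype counts with T at $p$ summing to the C→T count at $p$) are
  checked at count level, exactly, not within tolerance.
* Undefined ratios (no included reads, no edited reads, zero rich-plate
  colony count) are `NA`.
* Simulations are reproducible: one seed determines FASTQ bytes
  identically; the fixture bundle (`writeFixtureBundle()`) is byte-stable
  across runs.
* Ties in the product table are broken by pattern label (after count) so
  output ordering is deterministic.

## Limitations

* No fuzzy flank matching or adaptor trimming: upstream cleaning is assumed
  (as in commercial demultiplexed deliverables). High error rates in flanks
  reduce the matched fraction rather than biasing frequencies.
* Indels are detected as presence/absence by length only; their position
  and size distribution are not estimated.
* No statistical inference between editors is attempted — the outputs are
  descriptive frequencies with optional replicate mean/sd
  (`replicateSummary()`); Sanger chromatogram interpretation is upstream of
  the colony module, whose inputs are explicit allele pairs.

## A compact end-to-end run

```{r example, eval = FALSE}
ref <- c9Reference()
targets <- targetCytidines(ref, range = c(-21, -1))
sim <- simulateReads(ref, editorPresets("truncated"), 20000, seed = 42)
q <- quantifySample(sim$reads, ref, targets = targets)
round(q$profile, 3)
windowWidth(q$profile)
positionalSelectivity(q$profile, -18)
singleEditFraction(q$distribution, -18)
q$indels
```
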