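---
title: "Methods: two-enzyme GBS components in gbskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-enzyme GBS components in gbskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model of the pipeline

`gbskit` provides the computational stages of a two-enzyme
genotyping-by-sequencing (GBS) workflow as independently testable
components. In a two-enzyme library, genomic DNA is digested with a rare
cutter (PstI, CTGCA^G) and a common cutter (MspI, C^CGG); only fragments
with one rare and one common end are amplified and sequenced, which
reduces genome complexity evenly and keeps most repeats out of the
library. Reads carry an inline barcode on the rare side, followed by the
restriction-site remnant (`TGCAG`); the mate starts with the common-side
remnant (`CGG`). Downstream, per-sample variant calls are merged into a
dosage matrix, filtered, and summarised as distances, trees, and
population-level checks.

The wet-lab stages, read trimming, alignment and pileup variant calling
are deliberately out of scope: the package consumes their outputs (FASTQ,
VCF, BED) and implements everything around them.

# In silico digestion

`findSites()` scans a single strand for IUPAC recognition-site matches,
reporting *all* occurrences, including overlapping ones: short
degenerate sites such as `GCWGC` can overlap themselves, and dropping
overlaps would under-count cut sites. All three built-in enzymes have
palindromic sites under IUPAC complement, so one strand suffices; this
is asserted by a reverse-complement property test rather than assumed.
`N` in the input never matches a non-`N` pattern letter, so assembly
gaps cannot create phantom sites.

Cuts are placed at `site + cutOffset` using top-strand chemistry
(PstI CTGCA^G, MspI C^CGG, ApeKI G^CWGC). Fragments are emitted as a
`GRanges` that tiles each input sequence exactly — the tiling invariant
(fragment lengths sum to sequence length) is checked on fuzzed inputs.
Cuts that fall on a sequence boundary would create empty fragments and
are discarded. A coordinate cut by *both* enzymes of a pair is reported
as an error rather than silently attributed to one of them, since the
fragment-class bookkeeping would become ambiguous.

`compareProtocols()` contrasts a one-enzyme protocol against a
rare+common pair. By default it counts internal (`SINGLE-SINGLE`)
fragments on the one-enzyme side against `RARE-COMMON` fragments — the
class a two-enzyme library actually sequences — and reports the relative
reduction `1 - two/one`. Because the literature is not always explicit
about which classes enter such comparisons, the counted class is
configurable (`"rare-common"`, `"internal"`, `"all"`). No fragment-size
selection window is applied by default; `minLength`/`maxLength` are
available for protocols that size-select.

# Demultiplexing

A pair is assigned to a sample when read1 starts with the sample's
barcode immediately followed by the exact rare remnant, and read2 starts
with the exact common remnant. Design choices:

* **Mismatch tolerance defaults to 0.** Real barcode sets are designed
  with Hamming separation; `maxMismatch` is exposed (applying to the
  barcode only, never the remnant) for lower-quality data.
* **The remnant is retained after trimming.** It is genome-adjacent
  sequence and aligners expect it; only the barcode is removed.
* **Longest-barcode-first matching.** With variable-length barcodes a
  read may match a short barcode and a longer one; the longer, more
  specific match wins. Two hits at the *same* length are unresolvable
  and rejected as `ambiguous`.
* **Only read starts are validated.** Internal restriction sites
  (chimeras) are not scanned; that is a quality-trimming concern.
* **Prefix safety at load time.** A barcode equal to another barcode
  plus the first remnant base could never be assigned unambiguously, so
  such tables are rejected before any read is processed.

Every decision is accounted: `assigned + rejected = input` holds by
construction and is validated on the result object, with rejects
classified as `no_barcode`, `bad_rare_remnant`, `bad_common_remnant` or
`ambiguous`. Technical replicates are merged by relabelling after
demultiplexing, preserving read ids, since replicate yields are too
uneven to treat separately before variant calling.

# The genotype matrix and filter cascade

`mergeVcfs()` builds a sites-by-samples dosage matrix (0/1/2 alternate
allele copies, `NA` missing) over the *union* of site keys
`(seq, pos, ref, alt)`; a sample without a record at a key is missing
there. Multi-allelic records and indels are excluded with counts logged —
the downstream statistics are defined for biallelic SNPs. Conflicting
reference alleles at one position across files indicate mixed references
and are a hard error. The container extends
`RangedSummarizedExperiment`, so masking is an interval overlap and all
standard accessors apply.

The cascade runs repeat masking, then missingness, then MAF, then LD
pruning — masking first because repeat-region calls are suspected
artefacts that should not influence the later frequency-based stages.
Boundary semantics, chosen once and tested explicitly:

* Missingness "more than 20%" is a **strict** comparison: a site or
  sample at exactly 0.20 is kept. Sites are filtered before samples so
  that removing bad sites can rescue borderline samples; sample
  missingness is computed on the surviving sites.
* MAF: `p` is the dosage sum over called samples divided by `2 ×
  called`; a site with `MAF` exactly at the threshold is **kept**
  (`>=`), and sites with zero called genotypes are removed.
* LD pruning is a greedy left-to-right scan per sequence: a site is
  kept unless its squared Pearson correlation of dosages
  (pairwise-complete) with one of the 50 most recently *kept* sites
  exceeds 0.80. Pairs with fewer than 3 shared called samples, or with
  a monomorphic member, contribute r² = 0 — there is no meaningful
  correlation estimate there. The window is counted in kept sites,
  which keeps the scan linear; 50 sites is ample for marker densities
  where GBS markers are quasi-independent beyond tens of sites.

Genotype-dosage correlation is used for r² rather than haplotype-based
LD: GBS data of selfing species are unphased and nearly homozygous, so
the composite measure is the appropriate one. Every stage appends an
accounting row (`sitesIn − sitesRemoved = sitesOut`, samples in/out) and
stages compose; re-applying any filter to its own output removes
nothing under the missing-at-random regimes the tests generate. A
site-quality predicate (minimum QUAL/depth) is intentionally *not*
applied by default: "low-quality SNP" definitions vary between callers,
and silent quality filtering would make the accounting misleading.

# Distances, neighbour joining, bootstrap

The pairwise distance is allele sharing: the mean over
pairwise-complete sites of `|dosage_i − dosage_j| / 2`, bounded in
[0, 1] (0 identical, 1 opposite homozygotes everywhere). It is defined
on unfiltered matrices with missing data, which is exactly where
replicate-authenticity checks operate; per-pair shared-site counts are
kept alongside, and pairs below `minSharedSites` are an error rather
than a silent noisy estimate.

`njTree()` is the Saitou–Nei agglomeration with the Studier–Keppler
criterion `Q(i,j) = (n−2) d(i,j) − r_i − r_j`. Numerical choices:

* Ties in `Q` are broken deterministically toward the lowest index pair
  in current input order, so runs are reproducible byte-for-byte.
* The recursion stops at three nodes, closed by the exact three-point
  formulas, yielding the conventional unrooted basal trifurcation.
* Negative branch-length estimates (possible on non-additive input) are
  clamped to 0 on output — Newick consumers reject negatives — with the
  original values retained in `attr(tree, "clampedEdges")`.
* Branch lengths are serialised at full double precision, so additive
  matrices are recovered to arithmetic tolerance (the tests demand
  1e-9 on cophenetic distances; observed error is at machine epsilon).

On additive input NJ is consistent, which the tests exploit: random
trees with 4–12 leaves are converted to their cophenetic matrices and
must be recovered with Robinson–Foulds distance 0. An independent NJ
implementation (`ape::nj`) serves as a cross-check in the tests only —
it is never called by the package code.

`bootstrapSupport()` resamples site columns with replacement,
recomputes distance and NJ per replicate, and maps bipartition
frequencies onto the full-data tree (counting via `ape::prop.clades`,
with unmatched bipartitions at 0). Replicate pairs that lose all shared
sites under resampling receive the maximum distance 1 and are counted
on the result; with realistic site numbers this path is never taken.
The root label of the unrooted tree is `NA`, as the basal "bipartition"
is not informative.

# Population checks

`deltaK()` implements the Evanno second-order statistic over external
clustering log-likelihoods: `L'(K)` and `|L''(K)|` are computed from
per-K means, and `ΔK = |L''(K)| / sd(L(K))`. It reads a plain
`(K, replicate, logL)` table so any clustering program's output can
feed it — the MCMC itself is consumed, not implemented. Zero standard
deviation yields an infinite ΔK with a warning rather than an error:
that is a degenerate but informative outcome. ΔK depends only on
differences of `L`, so it is invariant under constant shifts, which is
tested.

`checkReplicates()` operationalises the visual "does this sample sit in
its labelled clade?" judgment as a k-nearest-neighbour taxon vote on
the distance matrix. With well-separated groups and at most `⌊k/2⌋`
mislabels among a sample's k nearest neighbours, the majority vote is
immune to the mislabels themselves — so `k` should be chosen near the
expected group size (the default `k = 1` is the strictest,
single-neighbour variant). A sample is `MISCLASSIFIED` when the vote
disagrees with its recorded taxon, and `REPLICATE_DISCORDANT` when a
replicate of its accession exists but is not its nearest same-taxon
neighbour — the signature of run-to-run variation dominating genetic
identity. Neighbour ties are broken by sample id and reported.

# Synthetic data: what it emulates, and what not

`makeGenome()` rejection-samples background sequence free of both
recognition patterns, then implants concrete sites at recorded,
well-separated positions; the construction is verified by re-scanning,
so the digest truth is exact. `makeReads()` assembles
`barcode + TGCAG + fragment prefix` / `CGG + reverse-complemented
suffix` pairs from rare–common fragments, with per-sample counts
proportional to depth multipliers — the simplest model of the
DNA-quality-driven yield bias seen in real multiplexed libraries.

`makePopulation()` draws genotypes from the Balding–Nichols model: per
pool and site, allele frequencies are Beta-distributed around a shared
ancestral frequency (uniform on [0.05, 0.95]) with a single divergence
parameter `F`. It is the simplest structured-population model with one
interpretable knob. Defaults are chosen once as the conditions the
package is exercised under:

* `fst = 0.3` — strong, species-level divergence, appropriate for
  groups spanning a crop and its wild relatives;
* `inbreeding = 0.98` — a selfing legume; expected heterozygosity
  `(1 − 0.98) · 2p(1−p)` lands in the sub-percent range observed in
  such data (the generated matrices come out near 0.5% heterozygous);
* `missingRate = 0.05` plus `runDropout = 0.05` over 2 runs —
  low-coverage GBS loses loci per run as a set, not independently per
  sample, which is what makes replicates from different runs drift
  apart; the run-dropout term models exactly that;
* 4 pools × 10 samples × 2,000 sites in the end-to-end checks — small
  enough to run in seconds, large enough that pool recovery is not
  borderline.

Not modelled: sequencing error profiles, PCR duplicates, GC bias,
fragment-length bias, reference/ascertainment bias. Passing tests
therefore demonstrate algorithmic correctness under a clean, explicit
generative model — not robustness to every artefact of real data. In
particular, real wild-relative data mapped against a single reference
genome will under-sample divergent material in ways no parameter here
reproduces.

# Problem sizes and determinism

The test suite and the acceptance script size their simulations to run
on a single CPU in minutes: 100 random 10 kb sequences plus 20
implanted genomes for scanner/oracle equivalence, 10,000 read pairs
over 48 barcodes for the demultiplexing round trip, 200-site × 100-sample
matrices for filter/brute-force agreement, 50 random additive trees for
NJ exactness, and 200 bootstrap replicates on the 40-sample population
for support recovery. Every generator takes an explicit seed, every
seeded entry point is byte-reproducible, and the command-line driver is
tested for byte-identical output across repeated invocations.

# Known limitations

* Only biallelic SNPs are represented; multi-allelic sites are dropped
  at merge rather than decomposed.
* The LD window is counted in sites, not base pairs; for very uneven
  marker densities a physical window could behave differently.
* `filterMissing()`'s sites-then-samples order is a fixed pipeline
  choice; when sample removal is substantial, a re-run can remove
  further sites (the accounting makes this visible).
* NJ is quadratic in memory and cubic in time in the number of samples;
  it is intended for germplasm panels (tens to hundreds of samples),
  not thousands.
* The authenticity audit automates only the distance/topology evidence
  for misclassification; morphology and crossing records are outside
  computation.
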