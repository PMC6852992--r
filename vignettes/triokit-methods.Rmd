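---
title: "Trio genome analysis with triokit: models, filters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio genome analysis with triokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triokit)
```

## What the package computes

triokit analyses father–mother–offspring trio genomes: it detects de novo
SNVs and indels with a stringent filter cascade, converts the detected
counts into a per-site per-generation germline mutation rate through a
callability denominator, merges two CNV callers' output into a concordant
call set, detects de novo CNVs with depth-based parental re-genotyping,
classifies CNV sharing across populations, scans for variant-density
hotspots, classifies novel insertions by inheritance and archaic-hominin
sharing, and phases trio genotypes deterministically by transmission.
A synthetic-data generator with complete ground truth backs every one of
these claims with parameter-recovery and exactness tests.

All coordinates are handled in two conventions, converted only at I/O
boundaries: VCF positions are 1-based; every internal interval (and BED
I/O) is 0-based half-open.  Analysis is restricted to autosomes; X/Y
records are dropped at load time because the inheritance models used here
(two transmitted alleles, one per parent) are autosomal.

## De novo SNV/indel detection

A candidate site must pass, in order:

1. **criterion i** — the locus lies outside every user-supplied exclusion
   mask (poor mappability, low complexity, aberrant-SNP enrichment; the
   package accepts any BED set and hard-codes none);
2. **criterion ii** — offspring read depth within [10, 120] and allele
   balance (alt reads / informative reads) within [0.3, 0.7].  Both
   intervals are closed: a 9/30 = 0.30 call passes.  The depth ceiling and
   the balance window guard against collapsed paralogs and CNV regions
   where reads from near-identical copies pile up;
3. **criterion iii** — Phred genotype quality ≥ 50 in the offspring *and*
   both parents;
4. **criterion iv** — zero reads supporting the alternative allele in each
   parent;
5. **criterion v** — both parents called homozygous reference and the
   offspring carries the alternative allele.

The audit table records every per-criterion outcome; the rejection
`reason` is the first failed criterion in the order above (sites with any
missing member genotype are non-evaluable and labelled `missing`).  The
same thresholds are applied to SNVs and indels.

Indel records are restricted to biallelic alleles under 100 bp; anything
at 100 bp or larger belongs to the CNV pipeline, which conversely drops
segments of 100 bp or less.  Multiallelic VCF records are split into one
biallelic record per alternative allele before any filter (other
alternative alleles are recoded as reference and AD fields re-indexed);
records that cannot be resolved are dropped with a warning.  When a
caller omits DP, it is reconstructed as AD ref + alt — caller dialects
disagree on whether DP counts uninformative reads, and an explicit
precedence keeps the depth filter deterministic.

## Callability-based mutation rate

Counting de novo calls and dividing by the genome length would understate
the rate, because many sites could never have yielded a passing call in
the first place (low depth, low GQ, stray parental reads).  Instead, each
site contributes its *callability* C_k(s): the probability that a true de
novo mutation at site s in family k would have survived the filters.  The
family's rate is

    mu_k = (# de novo mutations in family k) / (2 * sum_s C_k(s))

with the factor 2 counting the two transmitted haploid genomes.

C_k(s) factorises into a deterministic gate times a stochastic term:

* gate = 1 only if the site is unmasked, all three members' depths lie in
  [10, 120], parental (and, when supplied, offspring) GQ ≥ 50, and both
  parents show zero alternative reads — exactly the deterministic filters;
* the stochastic term is the probability that a true heterozygote at the
  offspring's observed depth d shows a passing allele balance:
  the exact Binomial(d, 1/2) mass on {x : 0.3 ≤ x/d ≤ 0.7}, bounds
  inclusive.  At d = 10 this is the mass on x ∈ {3,…,7}, i.e. 0.890625.

Because the gate is evaluated on the same observed parental data that the
detection filters see, numerator and denominator are subject to the same
censoring and the estimator is consistent; the parameter-recovery test
below confirms the absence of bias empirically.  The one asymmetry —
detection does not gate on *parental* depth while callability does — is
deliberate: a parental depth above 120 cannot mimic a de novo call, it
only signals an unreliable region, and with 30× data the disagreement is
numerically negligible (Poisson(30) mass above 120 is ~1e-36).

## CNV ensemble pipeline

CNVs (deletions with copy number < 2, duplications with copy number > 2,
length > 100 bp, autosomal) enter as two per-caller call tables per
sample.  The ensemble filter retains a call only when

1. a same-type call from the other caller attains ≥ 50% *reciprocal*
   overlap (the shared span covers at least half of both intervals);
2. it does not touch (≥ 1 bp) any repetitive/low-complexity region — this
   criterion is deliberately any-overlap, as stated, while
3. the union of gap and segmental-duplication masks covers < 50% of its
   length.

Each concordant pair is emitted once with the preferred caller's
breakpoints (`prefer_caller`, default A); which caller's breakpoints to
keep is a presentation choice the source methods leave open.  Novelty
against a reference database (a DGV-like table) is < 50% reciprocal
overlap with every record; records of any type are compared by default
(`match_svtype = TRUE` restricts to same-type) since database CNV type
annotations are frequently heterogeneous.

De novo CNV detection runs a three-step cascade per trio:

1. drop offspring calls matched in either parent (same type, ≥ 50%
   reciprocal overlap);
2. re-genotype survivors in both parents from windowed depth: estimated
   copy number = round(2 × mean depth in the interval / that parent's
   autosomal mean depth); drop the call when a parent's estimate is
   consistent with the offspring's type (CN < 2 for a DEL, CN > 2 for a
   DUP).  This replaces the original caller's genotyper, whose internals
   are out of scope, with a transparent depth-ratio estimator;
3. emit survivors with a per-call evidence report (parental depth ratios
   and copy-number estimates) supporting the manual review such calls
   ultimately deserve.  Without depth profiles step 2 is skipped and
   calls are flagged unverified.

The de novo CNV rate is de novo count / total offspring CNVs, reported to
one significant digit — the presentation convention for such rates.

Sharing classes are assigned to regions (same-type calls linked by ≥ 50%
reciprocal overlap, single linkage; a trio is present when any member
contributed a call) with a fixed precedence: MLS (≥ 1 Orang Asli and ≥ 1
North Bornean trio) before OA (all of BTQ, MDQ, SMI) before NGO (BTQ and
MDQ) before NB (DSN and MRT) before private (exactly one trio) before
other.  Precedence makes the classification a partition: every presence
pattern maps to exactly one class.

## Hotspot scan, summaries and novel insertions

The hotspot scan tiles each chromosome with non-overlapping 1 Mb windows
anchored at position 0; a final partial window is kept when at least
0.5 Mb (the tiling anchor and partial-window rule are not dictated by the
definition, so the simplest deterministic choice is used).  Windows
overlapping telomere/centromere intervals extended by 1 Mb are excluded.
Variants are counted after the same GQ ≥ 50, depth 10–120 and allele
balance 0.3–0.7 screen used for de novo detection, pooled across samples
by default; SNVs and indels are scanned independently.  The top
ceiling(1% × eligible windows) by count are reported, extended through
ties at the cutoff so the result cannot depend on input order.

Supporting summaries: heterozygosity proportion = het / (het + hom-alt);
Ti/Tv = transitions (A↔G, C↔T) over transversions; novelty = fraction of
(chrom, pos, ref, alt)-exact variants absent from a known-variant table —
exact identity, no positional fuzziness, so indel representation must be
normalised upstream.

Novel insertions arrive as a presence table (per-sample 0/1 flags plus
Neanderthal/Denisovan presence).  An insertion is *inherited* when
present in the offspring and at least one parent — offspring-only
presence is more plausibly an assembly or calling artefact than a de novo
insertion.  Archaic classes partition insertions into
Neanderthal-specific, Denisovan-specific, both, or none; "archaic-like"
is the union of the first three, so the archaic-like tally always equals
the sum of the three classes — an identity the test suite
asserts both on randomly generated presence tables and on the reference
per-population tallies entered as fixtures, where the two specific
counts never exhaust the archaic-like total.

## Trio phasing

Before phasing, sites are removed when the missing-genotype fraction
across all samples exceeds 10% or a Mendelian error appears in two or
more trios (a single-trio error may be a genuine de novo event and is
retained).  With both parents genotyped, every configuration that is not
triply heterozygous phases deterministically by identity by descent:
child homozygotes trivially, and a heterozygous child whenever at least
one parent is homozygous, because that parent's transmitted allele is
forced.  The triple-heterozygous residue would require a statistical
population model (an external tool's job) and is emitted unphased and
counted.  Output order is paternal|maternal — a documented convention,
not an inference.  CNV presence/absence genotypes phase through the same
logic.

## The synthetic generator, and what passing tests do not show

`simulate_trio_cohort()` / `simulate_trio_sites()` draw, per site: a
population allele frequency uniform on [0.05, 0.95]; parental genotypes
Hardy–Weinberg at that frequency; one transmitted allele per parent, with
transmitted *reference* alleles flipping to de novo alternatives at the
configured per-site rate; per-member depth Poisson(30) truncated at 1;
alternative-read counts Binomial(depth, 1/2) for heterozygotes and
Binomial(depth, error_rate) stray reads for homozygotes; and a genotype
quality GQ = min(99, round(3.3 × depth)), degraded to 20 below depth 8 —
a monotone surrogate whose exact shape nothing depends on, only its
threshold crossings.  Defaults mirror a 30× short-read trio study:
de novo SNV rate 1.2e-8 and indel rate 2e-9 per site per generation
(inside the ranges such studies report), stray-read rate 1e-3.

`simulate_cnv_callsets()` plants inherited CNVs from a shared population
locus pool (carriers heterozygous, transmitting with probability 1/2) and
offspring-only de novo deletions, then emits two pseudo-caller call sets
with per-breakpoint jitter (default ±10% of length) and per-call dropout
(default 10%), plus windowed depth profiles encoding the planted copy
numbers so the re-genotyping step is exercisable.  Defaults: 1200 loci at
mean population frequency 0.3, 80% deletions, on average two de novo
CNVs per offspring.

The generator intentionally omits linkage disequilibrium, recombination
maps, mapping artefacts, indel length realism, batch effects and
read-level data.  Passing tests therefore demonstrate *algorithmic*
correctness — the filters compute what they claim on data satisfying
their stated error model — not robustness to the full messiness of real
alignments, which is why masks and the manual-review report exist in the
first place.

## Validation design and problem sizes

* **Rate recovery**: 5 trios × 1e7 sites, planted SNV rate 1e-6, 20
  seeds; the pooled estimator's mean must sit within 3 standard errors of
  truth.  The planted rate is far above realistic so each replicate
  detects a meaningful count at a site count a desk machine handles; the
  estimator is scale-free in the rate.  This runs through a streaming C++
  accumulator that consumes the identical RNG stream as the materialised
  simulate→classify path; their exact equivalence is itself a test.
* **Exactness**: zero-error, zero-rate data must yield zero calls; every
  planted event at a hom-ref × hom-ref site passing criteria i–iii must
  be recovered.
* **Oracles**: merge concordance, hotspot selection, mask coverage and
  Mendelian consistency are each checked against brute-force
  re-implementations (double loops, per-base counting, sort-and-slice,
  transmission enumeration) on ≥ 50 random instances.
* **Phasing**: on simulated trios every phased site must match the
  recorded transmission exactly, and the unphased residue must be exactly
  the triple-heterozygous set.
* Smaller module tests use 2e4–2e5 sites — large enough that every filter
  branch is exercised hundreds of times, small enough to keep the suite
  fast.

Numerical details worth knowing: allele-balance bounds are compared after
an epsilon-guarded ceiling/floor when converting to integer read counts,
so 0.3 × depth landing on an integer is included; `signif(x, 1)` performs
the one-significant-digit rate rounding; ties in the hotspot cutoff are
resolved by inclusion (never truncation); the region clustering
represents each cluster by its earliest member call's interval.

## Limitations

Breakpoint refinement, read-level CNV discovery, statistical phasing of
triple heterozygotes, somatic/mosaic models, parent-of-origin assignment
and paternal-age effects are out of scope.  The callability model treats
the offspring's observed depth as fixed rather than integrating over the
depth distribution; that is the natural conditional estimator when, as
here, a depth is observed at every site.
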