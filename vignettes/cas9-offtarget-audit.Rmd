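---
title: "Auditing Cas9 off-target mutagenesis in whole-genome sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing Cas9 off-target mutagenesis in whole-genome sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas9audit)
```

## The problem

When Cas9 is used to make knockout founder animals, each ribonucleoprotein
complex is programmed by a 20-nt protospacer and cleaves DNA three bases 5'
of an NGG (or, with reduced efficiency, NAG) protospacer-adjacent motif
(PAM). The enzyme tolerates a handful of guide-target mismatches and single
unpaired bases ("bulges") in the guide-target duplex, so every guide has a
set of candidate off-target loci. Whether cutting at those loci actually
occurs at a rate that matters is an empirical question, and in inbred
colonies it must be answered against a substantial background: inbred mice
are not isogenic in practice — spontaneous de novo mutation (on the order
of 25 SNVs and 1-2 indels per generation) and substrain divergence leave
each animal carrying on the order of a thousand variants private to itself
or its colony.

`cas9audit` implements a whole-genome audit of this question as a reusable
pipeline: enumerate candidate off-target sites per guide, call a founder's
de novo variants by a conservative filter cascade against unedited
controls, intersect the two, classify what overlaps, confirm the intended
on-target deletion, and calibrate the incidental-overlap rate with a seeded
resampling null in the controls. A synthetic cohort generator with a full
truth ledger makes every stage testable without any sequencing data.

## Off-target site enumeration

A site is anchored at a PAM occurrence: three genomic bases matching
N[G/A]G immediately 3' of the candidate protospacer window. For each PAM
position, on each strand, the guide is aligned to the adjacent window in
three modes:

* no bulge — a 20-nt window, substitutions only;
* one DNA bulge — a 21-nt window with one internal genomic base unpaired
  (window positions 2-20);
* one RNA bulge — a 19-nt window with one internal guide base unpaired
  (guide positions 2-19).

At most one bulge of either kind is allowed per site. The PAM's first
position is never counted as a mismatch, and windows containing any
non-ACGT base never match. When several alignments explain one locus, the
minimal-cost alignment under the lexicographic cost (bulge size,
mismatches) is kept, with ties broken by preferring no bulge, then a DNA
over an RNA bulge, then the PAM-distal gap. This canonicalization makes
output deterministic; a terminal "bulge" is indistinguishable from a
shifted unbulged window, which is why gap placements are restricted to
internal positions.

Two free choices deserve a note. First, whether a single site may carry one
DNA *and* one RNA bulge simultaneously is ambiguous in common usage of
bulge-aware predictors; we cap the total at one bulge and treat the per-type
caps as caps under that total. Second, the prediction default is 5
mismatches with bulges enabled; the classification stage re-bins hits at
ceilings of 4, 5 and 6 so that sensitivity to the ceiling can be inspected,
and 6 is the ceiling used for sensitivity re-analysis.

The scanner is compiled code: all gap placements at one PAM are scored in
O(1) each from prefix sums of three per-offset mismatch vectors, so a
genome scan is linear in PAM occurrences. Its correctness is pinned to
`oracleEnumerate()`, an exhaustive pure-R re-derivation that tries every
window and every gap placement with no pruning (guarded to genomes under
100 kb); the test suite asserts exact set equality between the two across
randomized genomes, ceilings, PAM rules and N-content, and property tests
assert monotonicity in the ceiling, NGG ⊂ NGG+NAG nesting, strand-mirror
symmetry, and planted-locus recovery.

Mitochondrial and non-canonical contigs are excluded from enumeration
output by default (configurable patterns; anything not matching
`chr1..chrN/chrX/chrY`).

## The variant filter cascade

Small variants are read per sample from VCF, split per ALT allele before
any filtering, and identified throughout by the left-normalized tuple
(contig, pos, ref, alt). The cascade applies, in order:

1. **Quality**: QUAL > 30, DP > 9, GQ > 30, AF > 0.1 — all strict
   inequalities, exactly as printed in the protocol the package
   reimplements; boundary tests lock the operators in.
2. **Repeats**: any overlap of the variant's reference span with a repeat
   interval padded by 2 bp on both sides removes the record. The padding
   exists because left-anchored indels can straddle repeat boundaries.
3. **Known variants**: records whose normalized tuple appears in the
   known-variant database (the stand-in for dbSNP/EVA) are removed.
   Whether the original filter matched full alleles or positions only is
   not documented; tuple matching is the default (conservative) and
   positional matching is available via `filterConfig(known_match =
   "position")`.
4. **Het allele ratio**: heterozygous records with
   `ad_alt / (ad_ref + ad_alt) < 0.2` are excluded; records without AD
   fall back to the AF field, and records with neither are retained with a
   warning rather than silently dropped.
5. **Callable intersection**: the per-sample callable intervals are
   intersected across *all* samples and a variant must lie entirely inside
   the intersection. Requiring the full reference span (rather than the
   anchor base) is deliberate: a variant partially outside commonly
   callable space is not confidently comparable across samples.
6. **Secondary (uniqueness) filter**: any tuple observed in two or more
   distinct samples is eliminated from every sample. This removes
   substrain-fixed and otherwise shared variation and leaves each animal's
   unique variants; a tuple duplicated within one sample counts once.

Every stage reports in/removed/out per sample in a `FilterReport` whose
validity method enforces exact reconciliation. Stages 2 and 3 are pure
removals and commute; a test asserts this.

Structural variants pass a consensus filter: genotypes `./.` and `0/0`
are dropped, then records need 2+ independent callers, 3+ supporting
reads, and a length strictly between 200 bp and 5 kb. Shared SVs across
samples are removed by breakpoint-pair matching (same type, both
breakpoints within a tolerance, strand ignored). The tolerance is not
stated by the protocol; 100 bp per breakpoint is the default, chosen as
typical caller breakpoint jitter, and is configurable.

## Intersection, classification, on-target confirmation

A founder is audited only against the predicted sites of its own guides
(each founder is made with 2-4 guides); on-target loci are excluded. A hit
is any (site, variant) pair whose intervals overlap by at least one base —
the default semantics of interval intersection tools, since the protocol
names the tool without flags. A small-variant *deletion* contained in an
SV deletion hit at the same site is counted once (one biological event);
insertions are never deduplicated. Hits are classified by variant class ×
PAM class × mismatch bin (≤4, 5, 6) and by genic context: exonic if the
variant overlaps an exon, else intronic if inside a gene body, else
intergenic (upstream/downstream counts as intergenic).

The intended on-target deletion spans the outermost guide cut sites (blunt
cut 3 bp 5' of the PAM). A founder is confirmed when a consensus-passing
SV deletion overlaps that interval, or a small-variant deletion covers at
least half of it. A deletion seen by a single caller does not pass
consensus and therefore does not confirm — the audit deliberately
reproduces this failure mode, which occurs in practice when one caller
quality-filters a true event.

`compareSiteSets()` supports three-way comparisons of site lists from
different prediction sources (e.g. in silico enumeration vs an empirical
capture assay vs WGS-detected loci): sites match within a 10 bp tolerance,
matches are merged into connected components, and the seven Venn region
counts are reported.

## The resampling null and cohort statistics

Observed overlap in founders means little without the chance rate at which
a control animal's (Cas9-naive) variants land on predicted sites. For each
control, the null draws the *median* number of predicted sites per
experimental sample (medians, rounded half up, to be robust to guide sets
with very different site totals) uniformly from the pooled predictions,
without replacement, then intersects the draw with that control's filtered
variants under the same overlap rule as the founder audit. Each control
has its own fixed seed — control *i* uses seed *i*, seeds 1..28 under the
default cohort — so every draw is exactly reproducible, and the draw
indices are returned as a manifest.

Under the synthetic generator the null has a closed-form expectation: a
control's variants are uniform over the eligible anchor space *A* (the
genome minus padded repeats and potential uncallable zones), so a drawn
site with window [a, b] catches a variant of reference-span ℓ with
probability |[a−ℓ+1, b] ∩ A| / |A|. The acceptance suite checks the pooled
observed count against this expectation within three standard errors
(Poisson-scale), across the 28 per-control seeds.

Group summaries compare per-sample counts (total, SNV, indel, zygosity and
genic classes) between controls and founders with two-sided Wilcoxon
rank-sum tests and Bonferroni correction at α = 0.05. The Bonferroni
family is the set of panels compared in one figure-level analysis — the
family is whatever columns are handed to `summarizeGroupCounts()`, since
the original analysis does not enumerate its family. A type-I simulation
(both groups drawn from identical count distributions, 100 seeded
replicates) checks that the family-wise error stays at or below the
nominal level.

Colony heterogeneity is summarized as the pairwise percentage of shared
variants between *primary-filtered* (pre-uniqueness) call sets. The
original heatmap does not define its denominator; we use percent Jaccard
(100·|Vi∩Vj|/|Vi∪Vj|) because it is symmetric and bounded, matching the
heatmap's structure, and expose `denominator = "min"` as an alternative.
Clustering uses the named heatmap package's defaults — Euclidean distance
between matrix rows, complete linkage — and the 2-cluster cut is compared
against substrain labels.

## The synthetic cohort

`generateCohort()` builds the entire study from one seed. Defaults are the
study conditions: 28 controls and 50 founders; a 3 × 300 kb genome; 2-4
plus-strand guides per founder flanking the critical exon of that
founder's target gene; per-mouse private variation with Poisson means 756
SNVs and 276 indels (~3:1, 80% heterozygous); de novo Poisson means 25
SNVs and 1.5 indels; two substrains each fixed for 60 homozygous variants;
a 300-variant ancestral pool carried by every mouse of which half is in
the known-variant database; 5% of the genome as embedded low-complexity
repeat runs; and per-sample callable space of ~95%, built by dropping a
per-sample random half of a fixed pool of "gap zones" covering 10% of the
genome.

Several generator choices are engineering for exactness rather than
biology, and are worth stating plainly:

* All planted variant anchors are drawn from a single global position pool
  that avoids padded repeats and all gap zones, without replacement. This
  guarantees that private variants are genuinely private (no accidental
  cross-sample tuple collisions), that they survive the repeat and
  callable filters in every sample, and therefore that filter-cascade
  recovery can be asserted *exactly*, category by category, rather than
  approximately.
* Variants destined for removal are planted per category: inside repeat
  runs (repeat stage), in the known database (known stage), or in pools
  shared across samples (secondary stage).
* Quality annotations are drawn from passing distributions (DP ~
  Pois(35) floored at 12, matching ~35-40× coverage; QUAL ~ N(200, 50)
  floored above threshold; het AD ~ Binomial(DP, 0.5) kept within
  0.3-0.7) with a configurable failure tail: a fraction of records
  (default 2%) gets exactly one deliberately failing annotation, chosen
  uniformly among the QUAL/DP/GQ/AF stages plus the het-ratio stage for
  heterozygous records. The truth ledger records which records pass, so
  recovery tests condition on it. Setting the fraction to 0 makes the
  cascade's behaviour on the cohort exactly predictable.

Guides are taken from the genome itself (so the on-target is an exact NGG
match) and checked against the design rule used for real guide selection —
no second NGG-adjacent locus at fewer than 3 mismatches. Because a random
~1 Mb genome essentially never contains near-matches by chance, each guide
also gets planted decoy loci at controlled mismatch distances: NAG-adjacent
at 1-2 mismatches (which the NGG-only design rule does not forbid) and
NGG-adjacent at 3-6, on random strands. These give the search stage known
positives at every distance without violating the design rule.

Cas9 outcomes: every founder receives its on-target deletion between the
outermost cut sites as an SV DEL observed by a random subset of a 4-caller
panel (per-caller detection probability 0.9); exactly one founder (the
last) is forced to a single-caller observation, so the default cohort
contains the consensus-miss failure mode deterministically. Off-target
indels are injected at each predicted site of the founder's own guides
with probability decaying in mismatch count — 1, 0.25, 0.05, 0.01 for 0-3
mismatches and 0.001 at ≥4. **These decay values are synthetic
stand-ins**: no per-mismatch cutting-rate function is established by the
data the package reimplements (which shows only that ≥4-mismatch events
are rare); the defaults are chosen once so that positive and negative
cases both occur at the default cohort size. Injection is restricted to
cut sites in non-repetitive, always-callable space, and the planned
deletion region is excluded (an edit inside the deleted interval is not a
separate off-target event); this makes "every injected, quality-passing
edit at a ≤4-mismatch site is recovered" a recall-1.0 statement rather
than a statistical one.

What the generator does *not* emulate: read-level errors and alignment
artifacts (no FASTQ/BAM), realistic mutational signatures or repeat
families, pedigree structure beyond one generation, polymorphic hotspots,
and any center-specific batch structure (center labels exist but carry no
signal — so clustering tests can only validate substrain recovery).
Passing tests on this cohort therefore validate the pipeline's logic and
bookkeeping, not the behaviour of upstream callers on real data.

## Numerical and interface choices

* Interval arithmetic uses `GRanges` (1-based, closed) internally — the
  idiomatic container in this ecosystem — and converts to/from BED's
  0-based half-open convention only at the I/O boundary; round-trip
  identity is tested.
* Printed percentages follow the reporting convention of the audit being
  reproduced: below 1% three decimals, 1-10% one decimal, above 10%
  integers; per-founder rates one decimal; rounding half-up. (A uniform
  one-decimal rule fails to reproduce the printed values.) Every ratio
  object stores its numerator and denominator and re-derives itself at
  render time; zero denominators render as undefined, never as 0.
* The filter order is quality → repeats → known → het-ratio → callable →
  secondary; reports reconcile exactly at every stage and per-stage output
  feeds the next stage's input.
* Problem sizes in the test and acceptance runs are the default study
  conditions (28 + 50 samples, 3 × 300 kb genome, ~150 guides); the
  search-oracle cross-validation uses 50 randomized ≤2 kb genomes across
  ceilings 0-6, and the brute-force oracle refuses genomes over 100 kb.

## Known limitations

* The enumeration is exact but not genome-scale-optimized (no FM-index);
  a mouse-genome run with 163 guides is outside the intended desk scale.
* No off-target *scoring* (CFD/MIT-style) is provided; sites are
  enumerated, not ranked.
* CIRCLE-seq-style empirical site lists enter only as external site
  tables for set comparison; read-level processing of such assays is out
  of scope, as are Sanger/ICE validation and SnpEff-style effect
  prediction (genic context is interval-based).
* Causal attribution of SNVs at polymorphic loci is left to the user: the
  audit reports hits with their variant class and context and does not
  decide whether an SNV at a predicted site was Cas9-induced.
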