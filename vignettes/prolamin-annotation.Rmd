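---
title: "Annotating prolamin gene families: models, rules and validation"
author: "prolaminr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating prolamin gene families: models, rules and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolaminr)
```

## The problem

Prolamins — the gliadins and glutenins of wheat-group grasses — are the seed
storage proteins behind dough viscoelasticity and, less happily, behind
celiac disease (CD). They form large, fast-evolving gene families: tandemly
duplicated, riddled with pseudogenes, organized in tight clusters on the
short arm of homologous group 1 (γ- and ω-gliadins, LMW glutenin subunits),
the long arm of group 1 (HMW glutenin subunits) and group 6 (α-gliadins).
Characterizing such a family in a newly assembled genome involves a chain of
small, error-prone steps: homology search, full-length gene extraction,
subfamily classification, pseudogene calling, physicochemical annotation,
tandem-duplication clustering, micro-collinearity comparison, CD-epitope
profiling, and developmental expression profiling.

`prolaminr` implements that chain as a tested, reusable pipeline. Because the assemblies and curated sequence sets behind any particular
survey are rarely redistributable, the package treats validation as a
first-class problem: a
synthetic-genome generator plants prolamin-like gene families with known
truth labels, and every stage of the pipeline is exercised against that
truth.

## Locus discovery

`scan_homology()` is a seed–chain–extend nucleotide search. Exact k-mers
(default k = 11) shared between query and genome are grouped per
chromosome/strand into diagonal bands (band width 32), bands define
candidate windows, and each window is aligned to the query with an
affine-gap Smith–Waterman (match +1, mismatch −2, gap open 5, gap extend 2 —
blastn-like scoring at desk scale). Hits are filtered by an expected
random-hit count in Karlin–Altschul form,
$E = K \, m \, n \, e^{-\lambda S}$, with $\lambda$ solved numerically for
the chosen scores under uniform base frequencies, $n$ the genome length and
a default cutoff of $10^{-10}$.

Two guards matter in practice and are exposed as parameters:

* **High-frequency k-mer masking** (`max_kmer_hits`, default 100): prolamin
  repeat regions and polyglutamine tracts are built from a tiny codon
  vocabulary; their k-mers occur thousands of times and would otherwise
  seed quadratically many spurious bands.
* **Window clamping**: a real hit cannot be much longer than the query, so
  candidate windows wider than the query plus flanks are clamped to the
  densest seed region. Low-complexity seed chains can otherwise snake
  across tens of kilobases and make alignment cost unbounded.

`merge_to_loci()` unions hits within 2 kb (prolamin genes are intronless
and compact) and reports the longest ATG→stop open reading frame within
±1 kb of each locus; a locus without a complete ORF is kept with an empty
ORF span — that is exactly the signal later used for pseudogene candidates.

On synthetic genomes the scan recovers 100% of planted loci at 8%
query divergence (the package asserts ≥ 95% at ≤ 10% divergence), and the
reported alignment score is tested for exact equality against an
independent dynamic-programming implementation on pairs up to 2 kb.

## Subfamily classification

Gene-family surveys of this kind classify by homology to curated queries
plus manual inspection. To make that reproducible, `classify_subfamily()` uses an
explicit, overridable rule set (`subfamily_rules()`): per subfamily, a
repeat-motif regular expression with a minimum overlap-aware occurrence
count, an expected cysteine-count range, a length window, and specific
extras — two polyglutamine tracts for α-gliadins, an N-terminal SHIPGL-type
mature start for LMW subunits, and the x/y split of HMW subunits by
cysteines in the first 120 residues (y ≥ 5, x < 5). Among satisfied rules
the highest motif evidence relative to its threshold wins; everything else
is `unclassified`. The defaults are:

| subfamily | motif | min hits | cysteines | length (aa) |
|-----------|-------|----------|-----------|-------------|
| alpha | `PQPQP[FY]` | 5 | 5–7 | 250–350 |
| gamma | `PQQP[FY]PQ` | 5 | 8–9 | 250–350 |
| omega | `PQQP[FY]` | 8 | 0–1 | 300–450 |
| delta | `PQQQF` | 3 | 7 | 180–300 |
| LMW | `QQ.PPFS` + SHIPGL | 4 | 7–9 | 280–400 |
| HMW x/y | `G[YQ][YQ]P[TG][SQ]` | 15 | x < 5 / y ≥ 5 in aa 1–120 | 600–1000 |

The α-cysteine range is 5–7 rather than exactly 6 so that near-canonical
variants still classify; all thresholds are plain configuration values.

## Pseudogene calling

`call_status()` deduces functionality from ORF integrity: missing ATG
(`no_start`), premature stop codons (`internal_stop`), missing terminal stop
(`no_terminal_stop`), length not divisible by three (`frameshift`), and —
only when the sequence itself is intact — failure to satisfy any subfamily
rule (`structure_incomplete`). A gene is functional iff its defect list is
empty. Structural completeness is deliberately not assessed on broken
reading frames: the translation downstream of a frameshift is noise, and
reporting `structure_incomplete` there would double-count one underlying
lesion.

A frameshifted pseudogene also defeats the motif classifier. In the
pipeline (`run_full()`/`run_identify()`) such genes inherit the subfamily of
their closest classified relative by CDS alignment — ranked by alignment
score with coverage > 50% and identity > 50% required, because percent
identity alone of an ends-free alignment can be 100% over a short spurious
overlap of polyglutamine codons. This mirrors how homology-based surveys
keep pseudogenes inside their family when counting.

`pseudogene_rate()` reports pseudogenes/total at one decimal, round half
up — the printed-precision convention of gene-family surveys (16/19 prints
as 84.2, 7/9 as 77.8).

## Molecular weight and isoelectric point

`compute_mw()` sums average residue masses plus one water (18.0153 Da).
`compute_pi()` finds the zero of the Henderson–Hasselbalch net-charge
function over the free termini and the D, E, C, Y, H, K, R side chains by
bisection on pH 0–14 to 0.01 pH units, using the Bjellqvist pKa set
(residue-specific N-terminal pKa, C-terminal 3.55 with D/E exceptions) as
used by the classical web calculators; the set is stored as data and
swappable, since bit-compatibility with any published MW/pI table is
pKa-set dependent. Both functions refuse sequences containing X — mass and
charge are undefined for pseudogene translations, which is why the pipeline
reports NA there. The bisection is tested against an independent fine-grid
(ΔpH = 10⁻⁴) charge-zero search and for monotonicity under basic/acidic
residue additions.

## Tandem duplication and collinearity

A gene pair is tandem iff all three of the classical criteria hold
strictly: same chromosome with an inner gap below 100 kb, the shorter
aligned sequence covering more than 70% of the longer, and more than 70%
identity of the aligned sequences. Identity counts matches over all
alignment columns including gaps (one declared convention); distance is the
inner gap between feature boundaries, the strictest common reading of
"distance between two genes", and both choices are configurable.
`cluster_tandem()` takes connected components of the pairwise relation, so
A–B and B–C tandem pairs place A and C in one cluster even when the A–C
pair fails the rules. `tandem_proportion()` always carries an explicit
numerator and denominator, because printed proportions in the literature do
not always state theirs (a printed 50% over five genes has no integer
numerator).

`chain_collinear()` decomposes reciprocal-best anchors between two ordered
gene lists into strictly monotone chains, extracted greedily by length with
forward preferred on ties, labelling each block forward or inverted;
leftovers are isolated anchors (the "one isolated ω-gliadin gene" pattern).
Anchors come from `anchor_pairs()`, which takes mutual best hits by
alignment score with identity above 50% — a stand-in for an external
collinearity tool's c-score filter. The chainer is tested against
brute-force enumeration for up to 10 anchors and for the duality that
reversing one genome's order swaps forward and inverted blocks.

## CD epitope profiling

`scan_epitopes()` counts exact, overlap-aware occurrences of each epitope
peptide in deduced functional proteins (pseudogene translations are refused
unless forced, matching how such retrievals are defined on functional
sequences). The shipped definitions are DQ2.5-glia-α1a (PFPQPQLPY),
DQ2.5-glia-α1b (PYPQPQLPY), DQ2.5-glia-α2 (PQPQLPYPQ), DQ2.5-glia-α3,
DQ8-glia-α1/DQ8.5-glia-α1 (QGSFQPSQQ) and the 33-mer
(LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF). Two spellings of DQ2.5-glia-α3
circulate (9-mer FRPQQPYPQ and 10-mer FRPQQQPYPQ); both ship, the 9-mer is
active by default, and `default_epitopes("10mer")` switches. Matching is
literal — no deamidation modelling — and the 33-mer necessarily contains
1/2/3 copies of α1a/α1b/α2, which the tests pin against a sliding-window
oracle. `summarize_genome()` reports one-decimal carrier fractions over
functional α-gliadins, including the α1a-or-α3 union and the
"only DQ8 and nothing else" fraction (the 33-mer, being a container
peptide, does not count as a separate type there).

## Expression profiling

`compute_tpm()` is the standard transcripts-per-million: per-gene counts
divided by effective length (spliced CDS length — prolamins are
intronless), rescaled per sample to sum to 10⁶. `profile_stages()` averages
replicates within each of the six grain-development stages (young spike,
pre-flowering, flowering, ovary expansion, half grain, grain) and labels
each gene's pattern:

* `rise_then_fall` — interior peak with both neighbors ≥ 20% below it;
* `rising` — non-decreasing within a 5% relative tolerance **and** dynamic
  range above the flatness ratio (without the second condition every
  constant profile would be "rising");
* `flat` — max/min ≤ 1.5;
* `other` — everything else.

The 20% drop, 1.5 flatness ratio and 5% rise tolerance are configuration
values; the source literature describes these patterns only verbally.
Replicate means are taken before pattern assessment.

## The synthetic-data generator

`generate_gene()` builds each subfamily from an explicit grammar: signal
peptide, subfamily repeat units (e.g. `PQPQPF` for α, `PQQPF` for ω,
GYYPTS/GQQPGQ hexapeptides for HMW), polyglutamine tracts, and a
cysteine-bearing C-terminal domain with the diagnostic cysteine count.
Repeat counts are drawn within the rule-set length ranges, so generated
genes classify to their own subfamily by construction (a closed loop the
tests assert). Each subfamily uses a distinct C-terminal filler unit;
with a shared filler, cross-subfamily CDS identity would exceed the 70%
duplication threshold, which real prolamin subfamilies do not do.

Design choices worth knowing:

* **Intra-array divergence is synonymous.** Tandem copies are diverged by
  third-codon-position substitutions only, so nucleotide identity drops
  (exercising the 70% rules) while the protein — and with it every
  protein-level truth label: subfamily, epitopes, functional status —
  stays exact. Requested divergence is therefore capped by the fraction of
  degenerate sites (about a third). Unconstrained substitution
  (`mutate_sequence()`) remains available for homology-scan and alignment
  exercises where frame integrity is irrelevant.
* **Defect planting is exact-count.** Reproducing a printed rate of 16/19
  requires exactly 16 defects, so `round(p·n)` genes are defective, cycling
  through internal stop, frameshift and missing start; per-array exact
  counts (e.g. an all-pseudogene cluster) override the rate.
* **The intergenic background is an order-2 Markov chain fitted to the
  gene set**, i.e. GC- and dinucleotide-matched. A uniform-random
  background would make homology-scan specificity trivially easy; the
  matched background is also what forced the k-mer masking and window
  clamping described above, since it is as polyglutamine-codon-rich as the
  genes.
* **Placement**: array members sit 5–20 kb apart (well inside 100 kb);
  everything else is separated by more than 100 kb, so the truth-table
  cluster structure is exactly the tandem structure the rules should
  recover.
* **Counts include a background transcriptome.** `generate_counts()` draws
  negative-binomial counts (default dispersion 0.1, three replicates,
  log-normal library-size factors) from planted stage-mean templates —
  early-peaking for α/LMW/x-type HMW, rising into the grain stage for
  γ/y-type HMW — plus, by default, 300 stage-constant background genes.
  TPM is compositional: in a matrix containing only prolamins, the
  per-sample normalization redistributes every stage swing across all
  genes and distorts the planted shapes; the background plays the role of
  the rest of the transcriptome, which a real experiment always has.

What passing these synthetic tests does **not** show about real data: the
generator has no transposable elements, no introns, no segmental
duplications, no assembly gaps, and its pseudogenes carry exactly one
planted lesion each — real pseudogenes accumulate many. Recovery rates on
real genomes will be bounded above by the synthetic ones.

Planted flat expression profiles sit exactly on the max/min ≤ 1.5 flatness
boundary, where discrimination from `other` is noise-limited at dispersion
0.1 (the ratio of noisy replicate means exceeds 1.5 about half the time
under a truly flat gene); the ≥ 95% pattern-recovery property is therefore
stated over the strongly patterned profiles, and flat recovery is reported
but not asserted.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run everything on genomes of
roughly 3–4 Mb with 10–60 planted genes, chosen as the smallest sizes at
which every rule (100 kb windows, array structure, background specificity)
is non-trivially exercised; a full suite runs in about a minute on one
core. Alignment scoring follows the gap-of-length-L = open + L·extend
convention so scores are directly comparable with `Biostrings`
`pairwiseAlignment`, which the tests use as the independent oracle. pI
bisection tolerance is 0.01 pH; percentages print at one decimal, round
half up; `N` bases never count as matches and codons containing them
translate to X, keeping pseudogene calling conservative. Ambiguity codes
other than N are coerced to N on input.

## Known limitations

* Classification is rule-based; a subfamily whose repeat structure deviates
  far from the canonical grammars (e.g. chimeric genes from unequal
  crossover) will land in `unclassified` and, if intact, be called a
  `structure_incomplete` pseudogene.
* The homology scan is exact-seed based; sensitivity decays quickly beyond
  ~15% divergence, where a translated-search strategy would be needed.
* Epitope matching is literal; deamidation-dependent epitopes are out of
  scope.
* Micro-collinearity works on ordered gene lists, not genomic coordinates;
  it answers "is the order conserved / inverted", not "how long is the
  syntenic DNA".
* The package starts from a count matrix; read QC, alignment and
  transcript assembly live upstream of its boundary.
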