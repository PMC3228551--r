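---
title: "Searching gene structures for mutually exclusive spliced exons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching gene structures for mutually exclusive spliced exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxescan)
```

## The problem and the model

Mutually exclusive exons (MXEs) are clusters of internal exons of which each
mature transcript retains exactly one. Because the members of a cluster
substitute for each other in the same position of the encoded protein, they
are constrained in three ways that can be exploited for prediction directly
from a genome and one annotated transcript, without transcript evidence:

1. **Length**: members encode the same structural element, so their lengths
   are similar. A candidate may differ from the query exon by at most
   `allowed_length_difference` amino acids (default 20 aa), and the DNA
   length difference must be a multiple of three.
2. **Splice sites and frame**: a member must splice into the same flanking
   exons, so its bounding dinucleotides must be compatible with the donors
   and acceptors of the introns around the query exon. Exactly four intron
   patterns are admitted: `GT—AG`, `GC—AG`, `GG—AG` and `AT—AC`; an `AT`
   donor pairs only with an `AC` acceptor. Because the candidate inherits
   the query's start phase and its length is congruent mod 3, split codons
   in the query remain split codons in the candidate.
3. **Homology**: the candidate, translated in the query's reading frame,
   must align to the query translation. Scoring is Gotoh global alignment
   with affine gaps and Blosum62; the raw score is divided by the query's
   self-alignment score, giving a *relative score* with identity at 1.0.
   Candidates below `min_score` (default 0.15) are rejected. Translations
   with an in-frame stop codon are rejected outright.

For each query exon the two surrounding introns are scanned (optionally all
introns and the up-/downstream windows of `region_size` nt). Start sites are
the positions right after an admissible acceptor dinucleotide, end sites the
positions of an admissible donor dinucleotide; overlapping occurrences all
count. Terminal exons are anchored differently: first-exon candidates must
start with `ATG` (enabled automatically when the protein starts with
methionine), last-exon candidates must be followed by a stop codon (enabled
automatically when the annotated last exon is). Accepted candidates of one
query exon are overlap-resolved greedily — highest relative score first,
then longest, then leftmost — and the survivors form the query's cluster.

Clusters are classified by the position of the query exon: internal queries
give `internal_mxe`; first and last exons give `multiple_promoter_like` and
`multiple_polyA_like`, since alternative terminal exons are usually selected
by transcription initiation or 3'-end processing rather than by splicing.
When the all-introns scope is enabled, parallel ordered groups of candidates
across two or more consecutive query exons — one candidate per query, in
query order, within `region_size` of each other and with no annotated exon
between them — are re-labelled `group_pattern`: they are the signature of
tandemly arrayed gene duplications and of trans-spliced exon groups, not of
mutually exclusive splicing. The package deliberately does not decide
*which* of the two a group is; that needs locus-level judgement.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `allowed_length_difference` | 20 | aa | length window around the query |
| `min_score` | 0.15 | fraction | relative-score acceptance threshold |
| `min_exon_length` | 15 | aa | shorter query exons are skipped |
| `max_recursion_depth` | 0 | rounds | re-search with found candidates |
| `search_all_introns` | off | — | scope beyond the surrounding introns |
| `search_updownstream` | off | — | scan the gene flanks |
| `region_size` | 10000 | nt | flank window size |
| `search_with_start_codon` | auto | — | ATG anchoring of first exons |
| `search_with_stop_codon` | auto | — | stop anchoring of last exons |
| `min_new_intron_length` | 4 | nt | floor for the implied introns |
| gap open / extend | −10 / −2 | score | affine gap model |

The gap model charges a run of $L$ gap positions
$\mathrm{open} + (L-1)\cdot\mathrm{extend}$, i.e. −10 for the first position
and −2 for each further one; terminal gaps are charged like internal ones.
The published description of the method does not fix whether the opening
penalty is additive to the first extension; this package pins the convention
above and its tests pin it numerically (`"MA"` vs `"M"` scores −5).
Relative scores are compared to `min_score` with a $10^{-9}$ tolerance so
that threshold equality is not at the mercy of floating-point rounding.

`region_size` has no published default; 10 kb covers typical insect and
vertebrate tandem-duplicate spacing while keeping flank scans cheap.
`min_new_intron_length` defaults to the permissive floor of 4 nt — just
room for the two splice dinucleotides — because no lower bound is published;
both are configurable.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 I/O converts to and
  from 1-based inclusive. Exon and intron indices in the R API are 1-based.
* Minus-strand transcripts are reverse-complement-normalized at load, so
  the search itself is strand-free; strand invariance is a tested property
  rather than a second code path.
* Split codons at exon edges are completed with nucleotides from the
  flanking constitutive exons. The completions are those of the query exon,
  hence identical for the query and every candidate of its cluster, which
  keeps scores comparable. The alternative (dropping partial codons) is not
  offered.
* `N` is tolerated in introns; any candidate whose body or bounding
  dinucleotides contain `N` is rejected at enumeration (codons with `N` are
  untranslatable). Annotated exons containing `N` are structural errors.
* Candidates translating to more than 50% `X` are rejected as degenerate.
* Overlap means sharing at least one genomic base. Ties after score and
  length are broken by the leftmost start, making overlap resolution
  invariant under permutation of its input.
* Queries with a non-positive self-score (pathological, e.g. all-`X`) are
  skipped with a logged warning, as are query exons flanked by
  non-canonical splice dinucleotides (empty target set) — a real phenomenon
  in curated gene structures, not an error.
* Recursion (depth 1–3) re-searches the same regions with every accepted
  candidate as a query, deduplicates new hits by exact genomic interval,
  and lets existing members win all overlaps, so the member set grows
  monotonically with depth and never loses an earlier member.

## The synthetic-data generator

`random_gene()` builds genomes with one multi-exon gene: uniform-composition
flanks and intron interiors at a chosen GC fraction, canonical `GT…AG`
introns, a CDS that starts with `ATG`, contains no in-frame stop and is
followed immediately by `TAA`. `implant_homolog()` plants homologous exon
copies inside an intron, framed by splice dinucleotides compatible with the
query's context: substitutions operate per codon and always change the
amino acid (sampled uniformly over the 19 alternatives — a deliberately
simple null with no Blosum bias, so recovery curves are interpretable);
indels insert or delete whole codons, so implants are frame-compatible by
construction. `make_tandem_array()` and `make_trans_spliced_fixture()`
produce the two architectures that mimic MXE clusters: tandem gene
duplicates downstream of the annotated copy, and a hidden parallel exon
group inside the first intron whose last member is followed by a stop codon
(an alternative terminal exon). All randomness flows from one explicit seed
and the global RNG state is restored afterwards.

What the generator does *not* emulate: realistic splice-site strength,
branch points, codon usage, GC heterogeneity, or the RNA secondary-structure
docking elements thought to drive mutually exclusive choice. Passing tests
on these fixtures therefore demonstrate the correctness of the search logic
— enumeration, frame bookkeeping, scoring, thresholds, overlap and group
resolution — not field performance on real genomes, where splice-site
realism and annotation quality dominate.

## Problem sizes used by the tests and the acceptance script

The enumeration oracle is checked on 1,000 random regions of 50–2,000 nt
against a direct brute-force scan of all dinucleotide index pairs; the
aligner is checked against exhaustive alignment-path enumeration on all
sequence pairs of length ≤ 4 over a four-letter alphabet, plus hand-derived
scores. Implant recovery runs 200 seeded fixtures with 1–5 copies at
divergence 0–0.2 (recovery must be exact-border and 100% at divergence 0,
and non-increasing in divergence). The acceptance script re-runs smaller
batteries (60 fixtures per divergence level, a 10-gene synthetic screen,
15 group-pattern fixtures) and writes the measured rates as JSON. These
sizes keep a full run on one CPU within minutes while leaving every rate
estimated from dozens of independent fixtures.

## Known limitations

* Sensitivity/specificity bookkeeping against an annotation uses exact
  exon borders; near-miss candidates are reported in a separate
  overlap-only column but never matched.
* The neighbour-exon similarity scan normalizes by the upstream exon of
  each pair; the published description does not fix a direction, and for
  strongly asymmetric self-scores the two directions can differ slightly.
* The screen consumes CDS coordinates from the annotation as given; it does
  not re-map proteins to the genome first, so exact counts on public
  annotations can differ marginally from pipelines that do.
* Single-exon transcripts are searchable only with both terminal anchors
  and flank scanning enabled; by default they yield no clusters.
* Recursion re-searches the same region scope as the top-level run (the
  alternative — restricting later rounds to the region where each new query
  was found — would only shrink the result).
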