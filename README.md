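# mxescan

Prediction of mutually exclusive spliced exons (MXEs) from a genomic
sequence and an annotated exon–intron gene structure.

MXEs are clusters of internal exons of which every mature transcript
retains exactly one. Because cluster members replace each other in the same
position of the protein, they are similar in length, compatible in splice
sites and reading frame, and homologous in sequence. `mxescan` turns these
constraints into a search that needs no transcript evidence. For a query
exon with upstream intron donor $d$ and downstream intron acceptor $a$, a
candidate interval $[s, e)$ in a scanned region must satisfy

* the dinucleotide before $s$ is an acceptor compatible with $d$, and the
  dinucleotide at $e$ a donor compatible with $a$ — only the intron
  patterns GT—AG, GC—AG, GG—AG and AT—AC are admitted;
* $(e - s) \equiv \ell_q \pmod 3$ and $|e - s - \ell_q| \le 3\Delta$, where
  $\ell_q$ is the query exon length and $\Delta$ the allowed length
  difference in amino acids (default 20);
* the in-frame translation (split codons completed from the flanking
  exons) has no stop codon; and
* the relative alignment score
  $S_\mathrm{rel} = S(\text{cand}, \text{query}) / S(\text{query},
  \text{query})$ — Gotoh global alignment, Blosum62, gap open −10, gap
  extend −2 — reaches the threshold (default 0.15).

Non-overlapping accepted candidates form the query exon's cluster. First
and last exons are anchored at ATG / stop codons instead of splice sites,
and their clusters are classified as multiple-promoter-like /
multiple-poly(A)-like rather than as true internal MXE clusters. An
optional all-introns + flank scan detects parallel ordered candidate groups
across consecutive exons — the signature of tandem gene duplications and
trans-spliced exon groups — and flags those clusters instead of reporting
them as MXEs. An optional recursive mode (up to three rounds) re-searches
with found candidates as queries to pick up divergent cluster members.

## Worked example

```r
library(mxescan)

# a seeded synthetic gene: 3 exons, two identical copies of exon 2
# implanted into intron 1 with compatible splice sites
fx <- random_gene(fixture_spec(
  seed = 7, exon_aa_lengths = c(30L, 40L, 30L),
  intron_lengths = c(400L, 400L),
  implants = data.frame(exon_index = 2, n_copies = 2,
                        substitution_rate = 0, indel_codon_rate = 0)))

res <- search_transcript(fx$gene)
res
#> mxescan search of synth.t1: 1 cluster(s)
#>   exon 2 [internal_mxe]: 3 member(s)
#>   log: 2 entries

res$clusters[[1]]$members[, c("start", "end", "relative_score", "is_query")]
#>   start  end relative_score is_query
#> 1   399  519              1    FALSE
#> 2   532  652              1    FALSE
#> 3   790  910              1     TRUE
```

The cluster for query exon 2 (at 790–910) contains both implanted copies
with exact borders and relative score 1 (identical translation). The two
log entries record that exons 1 and 3 produced no candidates. Results can
be written as GFF3, YAML and TSV (`write_gff3()`, `write_result_yaml()`,
`write_tsv()`), and `chromosome_screen()` runs the same search over every
transcript of an annotation and reports agreement statistics against
annotation-defined MXE clusters.

A command-line interface wraps the same functions:

```sh
Rscript inst/exec/mxescan simulate --out fx --seed 7
Rscript inst/exec/mxescan search --genome fx/simple.fa --gff3 fx/simple.gff3 \
    --out results --min-score 15%
```

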