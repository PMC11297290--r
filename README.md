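# isochar

Isoform characterization and splicing-event annotation for long-read
transcriptomes.

## The problem

Deep targeted long-read sequencing (PacBio Iso-Seq, Oxford Nanopore cDNA)
of a gene panel yields thousands of transcript models per gene — far more
than short-read splicing tools can describe.  `isochar` takes a reference
annotation (GTF) and a collapsed long-read transcript catalog (GTF with
per-isoform gene assignments, plus a full-length read count matrix) and
answers, for every isoform and every gene:

* **Which known exons does each isoform use?**  Every gene's reference
  transcripts are *flattened* into one set of merged, non-overlapping
  exons numbered in transcription order (exon 1 = 5'-most).  Overlapping
  reference exons with different boundaries become one flat exon whose
  distinct boundary pairs are retained as *variants*.
* **Which alternative-splicing events does each isoform carry?**
  Exon skipping (ES: a flat exon inside the isoform's matched span with
  no overlapping isoform exon), intron retention (IR: one isoform exon
  spanning ≥ 2 flat exons), alternative 5'/3' splice sites (A5/A3: an
  internal exon boundary more than τ = 10 bp from every annotated
  boundary — an offset of exactly 10 bp still matches, 11 bp is an
  event), cryptic exons (CE: wholly intronic), novel exons outside the
  gene span (NE), alternative first/last exons (AF/AL) and alternative
  promoters/terminators (AP/AT: TSS/TTS more than 50 bp from every
  annotated end).
* **How does each isoform relate to the catalog?**  SQANTI-style
  structural categories: FSM (junction chain equals a reference
  transcript's), ISM (contiguous sub-chain), NIC (annotated sites, novel
  combination), NNC (≥ 1 novel splice site).
* **How is expression distributed across isoforms?**  Rare-transcript
  filtering (summed count of the top five samples ≥ 10), CPM or
  median-of-ratios normalization, isoform fractions (IF), dominant and
  major isoforms (relative proportion > 0.5), and differential
  transcript usage: *total change* (100 × ½·Σ|ΔIF|, the half-L1 distance
  between group-mean IF vectors), *podium change* (dominant-isoform
  switch) and a label-permutation p-value.
* **What protein does each isoform make?**  Longest ATG-initiated ORF,
  premature-termination/NMD candidacy (stop > 50 nt upstream of the last
  exon–exon junction), cryptic-exon frame effects, and collapsing of
  transcripts with identical protein sequences (most abundant transcript
  as representative).

A first-class synthetic-data module (`make_gene()`, `make_isoforms()`,
`make_counts()`, `simulate_dataset()`) generates reference annotations,
isoform catalogs with implanted events and exact ground-truth labels,
and negative-binomial count matrices, so every claim the package makes
is testable without external data.

## Worked example

```r
library(isochar)

# a gene with two reference transcripts; the second skips exon 2
ref <- exon_table(chrom = "chr1",
                  start = c(100, 300, 500, 700,  100, 500, 700),
                  end   = c(200, 400, 600, 800,  200, 600, 800),
                  strand = "+",
                  transcript_id = c(rep("Clu-201", 4), rep("Clu-202", 3)),
                  gene_id = "Clu")
model <- flatten_gene(ref)
flat_model_to_table(model)
#>   gene exon chrom start end n_variants ever_first ever_last
#> 1  Clu    1  chr1   100 200          1       TRUE     FALSE
#> 2  Clu    2  chr1   300 400          1      FALSE     FALSE
#> 3  Clu    3  chr1   500 600          1      FALSE     FALSE
#> 4  Clu    4  chr1   700 800          1      FALSE      TRUE

# one long-read isoform: acceptor of exon 2 shifted 11 bp, and one exon
# running from there through exon 3 (a retained intron)
iso <- exon_table("chr1", c(100, 289, 700), c(200, 600, 800), "+",
                  "LR.Clu.1", "Clu")
ev <- call_events(iso, model)
ev$A3                          #   exon offset        (11 bp > τ = 10)
#> 1    2     11
ev$IR                          #   first last n       (spans exons 2-3)
#> 1     2    3 2
classify_structural_category(iso, ref, model)$category
#> [1] "NNC"
```

The per-isoform table from `characterize_isoforms()` pools everything
(note the FSM copy of Clu-202 still carries an ES call against the
flattened model — known isoforms contribute to event counts):

```r
res <- characterize_isoforms(rbind(iso,
  exon_table("chr1", c(100, 500, 700), c(200, 600, 800), "+",
             "LR.Clu.2", "Clu")), ref)
res$table[, c("isoform", "category", "ref_match", "n_A3", "n_ES", "n_IR")]
#>    isoform category ref_match n_A3 n_ES n_IR
#> 1 LR.Clu.1      NNC              1    0    1
#> 2 LR.Clu.2      FSM   Clu-202    0    1    0
```

`run_characterize()` / `run_quantify()` (or the `exec/isochar` command
line: `characterize`, `quantify`, `simulate` subcommands) wrap the whole
workflow and write event tables, per-gene summaries, exon-presence
matrices, ORF/NMD tables, DTU results and a checksummed run manifest.

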