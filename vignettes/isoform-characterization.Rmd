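---
title: "Characterizing long-read isoform catalogs against a flattened gene model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing long-read isoform catalogs against a flattened gene model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isochar)
```

## The model

Long-read sequencing of a targeted gene panel produces a transcript
catalog whose size dwarfs the reference annotation: thousands of
isoforms per gene, most of them rare, differing by combinations of
splice-site shifts, skipped exons, retained introns and novel exons.
`isochar` describes every isoform in a single shared coordinate frame:
the *flattened gene model*.

All reference transcripts of a gene are merged into one ordered set of
non-overlapping exons.  Two reference exons that overlap are collapsed
into one flat exon spanning their union, and each distinct reference
`(start, end)` pair is kept as a *variant* of that flat exon.  This
separation matters: gene-level summaries and exon-presence matrices want
one column per "known exon" (the union view), while splice-site calls
must be measured against genuinely annotated boundaries (the variants),
not against a synthetic union boundary.  Flat exons are numbered in
transcription order (exon 1 is 5'-most; on the minus strand it has the
highest genomic coordinates).  From the same pass we catalog the gene's
known donors, acceptors, junctions, transcription start sites (TSS) and
termination sites (TTS).

Internally all coordinates are 0-based half-open; GTF and BED files are
read and written in their native conventions.  Gene assignment of
long-read isoforms is taken from the input GTF attributes as produced by
upstream collapse/annotation tools, not re-derived by overlap — the
assignment step precedes characterization in the pipelines this package
serves.

### Event calling

Each isoform exon is matched against the flat exons by interval overlap
and receives exactly one class: `exact`, `tolerant` or `alt_boundary`
(one flat exon overlapped; distinguished by boundary offsets),
`spanning` (≥ 2 flat exons overlapped), `cryptic` (zero overlap, inside
the gene span) or `novel_upstream`/`novel_downstream` (outside the
span, in transcription orientation).  The principal matched exon is the
one with the largest overlap; ties break toward the lower transcription
index.  Events follow from the matches:

* **A5/A3** — an *internal* exon boundary whose distance to every
  annotated boundary on that side of the gene exceeds the splice
  tolerance τ.  The comparison is strict ("more than"): an offset equal
  to τ matches the known site.  We state explicitly, because the
  two-letter shorthand is ambiguous in the field: A5 is the donor-side
  boundary (the transcription 3' edge of an exon), A3 the acceptor-side
  boundary (the transcription 5' edge).  An isoform's transcription
  start and end edges are never A5/A3 candidates; they are governed by
  the AP/AT calls.
* **ES** — a flat exon strictly between the isoform's first and last
  matched flat exons, overlapped by no isoform exon and not inside a
  retained-intron span.  Exons outside the matched span are never ES;
  they belong to alternative first/last exon territory.  Skipping is
  counted per exon (a three-exon gap yields three ES events), which
  keeps "number of exons skipped" additive across isoforms.
* **IR** — each spanning exon yields one IR event recording the first
  and last flat exon spanned and their count; two spanning exons in one
  isoform are two events.
* **CE/NE** — cryptic exons are wholly intronic isoform exons; novel
  exons lie outside the flattened span and are labeled with their
  transcription-orientation side.
* **AF/AL** — the flat exon matched by the isoform's terminal exon is
  never the first (respectively last) exon of any reference transcript,
  or the terminal exon is cryptic/novel.
* **AP/AT** — the isoform TSS (TTS) is more than the window *w* from
  every annotated TSS (TTS).

Events are always computed against the flattened model, independent of
structural category.  A consequence worth stating: an FSM isoform whose
matched reference transcript itself skips a flat exon carries an ES
call.  This is intentional — known isoforms contribute to per-gene event
totals, and the exon-presence matrix must show their skipping pattern.

### Structural categories

FSM: the isoform's junction chain (ordered donor/acceptor pairs,
compared at exact coordinates) equals a reference transcript's chain.
ISM: it is a contiguous sub-chain of one.  Otherwise NIC when every
donor and acceptor is annotated, NNC when at least one splice site is
novel.  τ plays no role here; tolerance applies only to event labeling.
Mono-exonic isoforms have no junctions, so the chain test degenerates:
they are FSM when contained in a mono-exonic reference transcript's
exon, ISM when contained in any reference exon, and otherwise labeled
NIC with an explicit `mono_exon` flag rather than guessing.

In per-gene summaries "known" defaults to FSM only — the conservative
reading of a known/novel split — with FSM+ISM available as a switch,
since ISM models are frequently 5'-degradation artifacts rather than
genuine short isoforms.

### Quantification and differential transcript usage

Full-length read counts proxy transcript abundance.  The
rare-transcript filter retains an isoform when the sum of its
`rare_n_samples` largest per-sample counts reaches `rare_min_reads`
("≥ 10 reads across any five samples").  The phrase also admits a
stricter per-sample reading — at least five samples each with ≥ 10
reads — which is implemented behind `semantics = "per_sample"`; the
summed form is the default because it is the weaker condition consistent
with the phrase.  Gene-level counts are aggregated *before* filtering,
so rare isoforms still contribute to gene expression.

Normalization is CPM or the DESeq-style median-of-ratios (rows
containing zeros are excluded from factor estimation).  Isoform
fractions divide each isoform's normalized count by its gene total;
zero-total gene/sample pairs are undefined (NA) and excluded from
means.  The dominant isoform maximizes mean IF (ties break
lexicographically and are logged); major isoforms exceed
`major_fraction` of the dominant's IF, strictly.

For DTU between two groups we report *total change* — 100 times half
the L1 distance between group-mean IF vectors, a number in [0, 100]
interpretable as "percentage points of usage redistributed" — and
*podium change*, a switch of the dominant isoform.  Significance comes
from label permutation with the standard add-one estimator
`(1 + #{perm ≥ obs}) / (1 + n_perm)`, which is never zero and is
super-uniform under the null.  Total change is this package's own
documented metric: published analyses often quote a "total change" from
external DTU tooling whose exact computation is not reproducible from
their descriptions, so ours is a stand-in with a stated formula, not a
re-implementation.  Model-based differential expression (negative
binomial Wald tests, genotype × age interactions) is deliberately out of
scope; the normalized matrices are suitable input for dedicated DE
packages.

### ORFs, NMD and protein collapsing

The ORF is the longest ATG-initiated reading frame ending at an in-frame
stop (ties resolve to the 5'-most start; with no in-frame stop the frame
runs to the last complete codon and is flagged `has_stop = FALSE`).
This is a transparent rule, not a coding-potential model; when an
external coding-potential score table is supplied, coding status instead
follows `score > coding_score_threshold` (default 0.44, the published
mouse recommendation for CPAT scores).  NMD candidacy uses the canonical
50-nt rule — a stop codon ending more than `nmd_distance_nt` upstream of
the last exon–exon junction — with the distance configurable and
reported signed, and mono-exonic transcripts flagged rather than
called.  Cryptic exons inside the ORF are classified `frameshift`
(length ≢ 0 mod 3), `in_frame_with_stop` (the ORF's stop falls inside
the cryptic exon) or `in_frame_no_stop`; cryptic exons outside the ORF
are `UTR`.  Transcripts with identical predicted proteins collapse into
one group represented by the most abundant member (ties by id);
transcripts without stop codons are excluded from collapsing and
reported separately, so the unique-protein count is not inflated by
truncated frames.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `splice_tolerance_bp` (τ) | 10 | bp | A5/A3 boundary tolerance, strict `>` |
| `tss_tts_window_bp` (w) | 50 | bp | AP/AT window around annotated ends |
| `rare_min_reads` | 10 | reads | rare-transcript filter threshold |
| `rare_n_samples` | 5 | samples | samples entering the filter rule |
| `major_fraction` | 0.5 | – | major-isoform proportion (strict `>`) |
| `minor_filter_fc` | 0.5 | – | pre-DTU minor-isoform filter |
| `nmd_distance_nt` | 50 | nt | PTC-to-last-junction distance |
| `coding_score_threshold` | 0.44 | – | external coding-score cut |
| `random_seed` | 1 | – | permutations and simulation |

The first seven are the working defaults of deep targeted long-read
analyses; all are exposed through `iso_config()`, a flat `key=value`
configuration file, and the command-line flags of `exec/isochar`.

## The synthetic-data generator

`make_gene()` builds a gene on the plus strand — exon and intron lengths
drawn from configurable ranges — with up to three reference transcripts:
the full-length model, an alternative-first-exon model, and a model
skipping one internal exon that also carries an annotated boundary
variant (41–80 bp inward).  Minus-strand genes are produced by
coordinate reflection plus strand flip, which preserves all
transcription-order semantics and doubles as the substrate for the
strand-symmetry property tests.

`make_isoforms()` emits a canonical copy, a copy of the skipping
reference (an FSM isoform that legitimately carries ES), and isoforms
with independent implants: 5'-end modification (ISM-like truncation with
optional first-exon shortening, a novel upstream exon, or a promoter
extension), 3'-end modification (last-exon drop, novel downstream exon,
terminator extension), per-exon skipping, one retained-intron run, 5'/3'
splice-site shrinks and one cryptic exon.  Implants are placed so that
they are unambiguous by construction: splice-site offsets are drawn from
11–30 bp (strictly beyond τ yet strictly below the 41–80 bp annotated
variants), cryptic exons keep ≥ 30 bp of intron on either side, novel
exons sit 100–200 bp outside the span, and promoter/terminator
extensions exceed w.  Ground-truth labels are recorded with the same
`as_event_set()` container the caller emits — including truth offsets
measured against the full annotated boundary set, since the caller
reports the distance to the *nearest* annotated boundary.

`make_counts()` draws negative-binomial counts (variance
μ + dispersion·μ²; dispersion 0 degenerates to Poisson) with
multiplicative group effects on selected isoforms.  The defaults — mean
100, dispersion 0.1, 8 + 10 samples in two groups across four ages —
emulate deep targeted long-read counts over biological replicates of a
two-genotype, four-age design.

What the generator does **not** emulate: alignment and collapse
artifacts (mis-mapped junctions, intrapriming), 5'-degradation beyond
clean exon-boundary truncation, correlated event co-occurrence,
cell-type composition shifts, and sequence-dependent biases.  Passing
the recovery suites therefore demonstrates that the calling logic is
exact on well-formed transcript models, not that upstream long-read
processing is error-free.

## Numerical choices and degenerate inputs

* Strict boundaries throughout: offset τ matches, τ + 1 is an event;
  proportion 0.5 is minor, > 0.5 major; PTC distance d_nmd is not NMD,
  d_nmd + 1 is.
* Ties: principal matched exon → lower transcription index; dominant
  isoform → lexicographic id (logged); protein-group representative →
  id order after abundance.
* Adjacent (bookended) reference exons are not merged when flattening;
  only true overlaps are.
* Reference transcripts occupying disjoint loci under one gene id are
  flattened jointly with a warning — no rule exists for splitting them,
  and joint flattening is the least surprising behavior.
* Exon-presence matrices use four states (present / skipped / IR /
  absent); rows are ordered by average-linkage clustering of the binary
  Jaccard distance on indicator-expanded state vectors (`stats::dist`
  `method = "binary"`), with rows pre-sorted by id so dendrograms are
  deterministic and identical isoforms are adjacent.
* Zero-total genes give NA isoform fractions; all-zero count matrices
  are rejected where a cumulative distribution would be meaningless.
* Permutation p-values use the add-one estimator; the DTU test requires
  at least two samples per group and renormalizes fractions within the
  retained isoform set after minor-isoform filtering.
* Burden log2 fold changes use a pseudocount of 1 (logged in output) so
  genes with zero carrier abundance in one group remain finite.

## Problem sizes used in the test suite

The property suites run 1000 synthetic genes (≈ 8000 isoforms) for
event-label recovery, 150 genes against the brute-force category
oracle, 200 reflected gene pairs for strand symmetry (40 of them with
genome-level ORF/NMD checks), a 0–30 bp exhaustive tolerance sweep,
100 seeded replicates for DTU detection power with 199 permutations,
1000 null simulations for calibration, and 1000 random sequences
against the exhaustive ORF scanner.  These sizes give the recovery and
calibration statements enough resolution (binomial SE ≤ 2 percentage
points) while keeping a full `testthat` run in minutes on one core.

## Known limitations

* Events are exact-coordinate comparisons after the τ rule; the package
  does not model sequencing-error-induced junction wobble beyond τ.
* The total-change metric is not numerically comparable to external DTU
  tools' statistics, only rank-comparable in typical cases.
* ORF selection is a longest-ORF rule; upstream ORFs, non-ATG starts
  and internal ribosome entry are out of scope, as is any
  coding-potential model (external scores can be ingested instead).
* CAGE/TSS evidence is consumed only as a proximity flag; no peak
  re-calling is performed.
* Mono-exonic genes are accepted but most event types are undefined for
  them; calls degenerate to the flagged mono-exon paths described above.
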