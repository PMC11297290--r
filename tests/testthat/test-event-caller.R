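cfg <- iso_config()
model_G <- flatten_gene(gene_G())
model_Gm <- flatten_gene(gene_G("-"))

test_that("exon matching assigns exactly one class per exon", {
  # identity match
  m <- match_exons(iso_G(300, 400), model_G, cfg)
  expect_equal(m$class, "exact")
  expect_equal(c(m$off_start, m$off_end), c(0L, 0L))

  # one exon over flat exons 2-3 spans the intron (IR candidate)
  m <- match_exons(iso_G(300, 600), model_G, cfg)
  expect_equal(m$class, "spanning")
  expect_equal(c(m$first_row, m$last_row), c(2L, 3L))

  # zero-overlap intronic exon is cryptic
  m <- match_exons(iso_G(430, 470), model_G, cfg)
  expect_equal(m$class, "cryptic")

  # every exon gets exactly one class; class counts partition the exons
  m <- match_exons(iso_G(c(40, 100, 430, 500), c(90, 200, 470, 600)),
                   model_G, cfg)
  expect_equal(nrow(m), 4)
  expect_equal(sort(m$class),
               sort(c("novel_upstream", "exact", "cryptic", "exact")))

  expect_error(match_exons(iso_G(300, 400, strand = "-"), model_G, cfg),
               "strand")
})

test_that("the splice tolerance is strict: 10 bp matches, 11 bp is an event", {
  # acceptor of exon 2 annotated at 300 (0-based); isoform exon preceded
  # by an exon ending at the annotated donor
  iso10 <- iso_G(c(100, 290), c(200, 400))
  m <- match_exons(iso10, model_G, cfg)
  aa <- call_alt_splice_sites(m, model_G, cfg)
  expect_null(aa$A3)

  iso11 <- iso_G(c(100, 289), c(200, 400))
  aa <- call_alt_splice_sites(match_exons(iso11, model_G, cfg), model_G, cfg)
  expect_equal(aa$A3, data.frame(exon = 2L, offset = 11L))

  iso0 <- iso_G(c(100, 300), c(200, 400))
  aa <- call_alt_splice_sites(match_exons(iso0, model_G, cfg), model_G, cfg)
  expect_null(aa$A3)
  expect_null(aa$A5)

  # exhaustive sweep 0-30 bp on both edges of internal exon 2
  for (d in 0:30) {
    aa3 <- call_alt_splice_sites(
      match_exons(iso_G(c(100, 300 + d, 500), c(200, 400, 600)),
                  model_G, cfg), model_G, cfg)
    aa5 <- call_alt_splice_sites(
      match_exons(iso_G(c(100, 300, 500), c(200, 400 - d, 600)),
                  model_G, cfg), model_G, cfg)
    if (d <= 10) {
      expect_null(aa3$A3, info = paste("A3 offset", d))
      expect_null(aa5$A5, info = paste("A5 offset", d))
    } else {
      expect_equal(aa3$A3$offset, d, info = paste("A3 offset", d))
      expect_equal(aa5$A5$offset, d, info = paste("A5 offset", d))
    }
  }

  # on the minus strand the same genomic edges swap labels
  aa <- call_alt_splice_sites(
    match_exons(iso_G(c(100, 285, 500), c(200, 400, 600), strand = "-"),
                model_Gm, cfg), model_Gm, cfg)
  expect_equal(aa$A5$offset, 15L)
  expect_null(aa$A3)
})

test_that("terminal edges are never A5/A3 (they belong to AP/AT)", {
  # large offsets at the isoform TSS and TTS edges
  iso <- iso_G(c(130, 300), c(200, 440))
  aa <- call_alt_splice_sites(match_exons(iso, model_G, cfg), model_G, cfg)
  expect_null(aa$A3)  # TSS edge offset 30 ignored
  expect_equal(aa$A5, NULL)  # TTS edge offset 40 ignored
})

test_that("exon skipping follows the span rule and respects IR", {
  es <- function(starts, ends) {
    call_exon_skipping(match_exons(iso_G(starts, ends), model_G, cfg),
                       model_G)
  }
  expect_equal(es(c(100, 500, 700), c(200, 600, 800)), 2L)
  # exon 3 spanned by a retained intron is not skipped
  expect_equal(es(c(100, 300, 700), c(200, 600, 800)), integer(0))
  # exons 1 and 4 outside the span are never ES
  expect_equal(es(c(300, 500), c(400, 600)), integer(0))
  # two exons skipped -> counted per exon
  expect_equal(es(c(100, 700), c(200, 800)), c(2L, 3L))

  # brute-force oracle over random single-skip isoforms
  for (k in 2:3) {
    keep <- setdiff(1:4, k)
    starts <- c(100, 300, 500, 700)[keep]
    ends <- c(200, 400, 600, 800)[keep]
    m <- match_exons(iso_G(starts, ends), model_G, cfg)
    oracle <- Filter(function(r) {
      r > min(keep) && r < max(keep) &&
        !any(starts < c(200, 400, 600, 800)[r] &
               c(100, 300, 500, 700)[r] < ends)
    }, 1:4)
    expect_equal(call_exon_skipping(m, model_G), as.integer(oracle))
  }
})

test_that("each spanning exon yields one IR event with its span width", {
  ir <- call_intron_retention(
    match_exons(iso_G(c(100, 300, 700), c(200, 600, 800)), model_G, cfg),
    model_G)
  expect_equal(ir, data.frame(first = 2L, last = 3L, n = 2L))

  # two separate spanning exons -> two IR events
  ir <- call_intron_retention(
    match_exons(iso_G(c(100, 500), c(400, 800)), model_G, cfg), model_G)
  expect_equal(nrow(ir), 2)
  expect_equal(ir$n, c(2L, 2L))

  # a single exon across all four flat exons
  ir <- call_intron_retention(
    match_exons(iso_G(100, 800), model_G, cfg), model_G)
  expect_equal(ir, data.frame(first = 1L, last = 4L, n = 4L))
})

test_that("cryptic and novel exons are localized by region", {
  nv <- call_novel_exons(
    match_exons(iso_G(c(100, 430, 500), c(200, 470, 600)), model_G, cfg),
    model_G)
  expect_equal(nv$CE, data.frame(start = 430L, end = 470L))
  expect_equal(nrow(nv$NE), 0)

  nv <- call_novel_exons(
    match_exons(iso_G(c(40, 100), c(90, 200)), model_G, cfg), model_G)
  expect_equal(nv$NE$side, "upstream")
  expect_equal(c(nv$NE$start, nv$NE$end), c(40L, 90L))

  # 10 bp overlap with flat exon 3: alt_boundary path, not CE
  m <- match_exons(iso_G(430, 510), model_G, cfg)
  expect_equal(m$class, "alt_boundary")
  nv <- call_novel_exons(m, model_G)
  expect_equal(nrow(nv$CE), 0)

  # downstream novel exon on '-' strand is transcription-upstream
  nv <- call_novel_exons(
    match_exons(iso_G(c(700, 900), c(800, 950), strand = "-"),
                model_Gm, cfg), model_Gm)
  expect_equal(nv$NE$side, "upstream")
})

test_that("AF/AL/AP/AT follow the ever-first/ever-last and window rules", {
  fl <- function(starts, ends, strand = "+") {
    model <- if (strand == "+") model_G else model_Gm
    call_first_last(match_exons(iso_G(starts, ends, strand = strand),
                                model, cfg), model, cfg)
  }
  # starting at exon 2 (never first): AF and AP (|300-100| > 50)
  r <- fl(c(300, 500, 700), c(400, 600, 800))
  expect_true(r$AF); expect_true(r$AP)
  expect_equal(r$first_exon, 2L)
  expect_false(r$AL); expect_false(r$AT)

  # canonical start
  r <- fl(c(100, 300), c(200, 400))
  expect_false(r$AF); expect_false(r$AP)
  expect_true(r$AL)   # exon 2 is never last
  expect_true(r$AT)   # TTS at 400 far from 800

  # TSS offset 39 <= 50: no AP, still not AF (exon 1 is ever-first)
  r <- fl(c(139, 300, 500, 700), c(200, 400, 600, 800))
  expect_false(r$AP); expect_false(r$AF)

  # TSS offset 51 -> AP
  r <- fl(c(151, 300, 500, 700), c(200, 400, 600, 800))
  expect_true(r$AP)

  # minus strand: transcription-first exon is the genomic-last one
  r <- fl(c(100, 300, 500, 700), c(200, 400, 600, 800), strand = "-")
  expect_false(r$AF); expect_false(r$AP)
  expect_equal(r$first_exon, 1L)
})

test_that("structural categories follow the FSM/ISM/NIC/NNC definitions", {
  g <- gene_G()
  cat_of <- function(starts, ends) {
    classify_structural_category(iso_G(starts, ends), g, model_G)
  }
  # full chain of T1
  r <- cat_of(c(100, 300, 500, 700), c(200, 400, 600, 800))
  expect_equal(r$category, "FSM")
  expect_equal(r$ref_match, "T1")
  # suffix of T1 -> ISM
  r <- cat_of(c(320, 500, 700), c(400, 600, 800))
  expect_equal(r$category, "ISM")
  expect_equal(r$ref_match, "T1")
  # known sites, novel combination (1-2 junction + 3-4 junction, skip by
  # a junction that no reference contains as a contiguous pair)
  r <- cat_of(c(100, 300, 700), c(200, 400, 800))
  expect_equal(r$category, "NIC")
  # exon 2 skip equals T2's chain -> FSM of T2
  r <- cat_of(c(100, 500, 700), c(200, 600, 800))
  expect_equal(r$category, "FSM")
  expect_equal(r$ref_match, "T2")
  # one novel donor -> NNC
  r <- cat_of(c(100, 300, 500, 700), c(200, 385, 600, 800))
  expect_equal(r$category, "NNC")

  # mono-exonic: inside a reference exon -> ISM (flagged)
  r <- cat_of(320, 380)
  expect_equal(r$category, "ISM")
  expect_true(r$mono_exon)
  # mono-exonic outside any exon -> NIC with flag
  r <- cat_of(420, 480)
  expect_equal(r$category, "NIC")
  expect_true(r$mono_exon)
})

test_that("FSM isoforms carry no A5/A3/CE/NE; span events reflect the reference", {
  # T2's FSM copy legitimately skips flat exon 2
  iso <- iso_G(c(100, 500, 700), c(200, 600, 800), id = "t2copy")
  ev <- call_events(iso, model_G, cfg)
  ct <- classify_structural_category(iso, gene_G(), model_G)
  expect_equal(ct$category, "FSM")
  expect_equal(ev$ES, 2L)
  expect_equal(nrow(ev$A5) + nrow(ev$A3) + nrow(ev$CE) + nrow(ev$NE), 0L)
})

test_that("gene summaries pool A5A3 and count isoforms vs events", {
  res <- characterize_isoforms(
    rbind(iso_G(c(100, 289, 500, 700), c(200, 385, 600, 800), id = "i1"),
          iso_G(c(100, 289, 500, 700), c(200, 400, 600, 800), id = "i2"),
          iso_G(c(100, 300, 500, 700), c(200, 400, 600, 800), id = "i3")),
    gene_G())
  s <- summarize_gene(res, "G")$summary
  expect_equal(s$n_isoforms, 3)
  expect_equal(s$a5a3_isoforms, 2)   # i1 has A3+A5, i2 has A3 only
  expect_equal(s$a5a3_events, 3)
  expect_equal(s$a5a3_pct, 66.7)
  expect_equal(s$n_known, 1)         # i3 is FSM
})

test_that("summary accounting reproduces the published event proportions", {
  # 7162 isoforms: 6082 carry 10,396 pooled A5A3 events; 134 carry 135
  # IR events.  Shared templates keep construction cheap.
  ev_a5x2 <- as_event_set("x", A5 = data.frame(exon = c(2, 3),
                                               offset = c(15, 20)))
  ev_a5x1 <- as_event_set("x", A5 = data.frame(exon = 2, offset = 15))
  ev_ir1 <- as_event_set("x", IR = data.frame(first = 2, last = 3, n = 2))
  ev_ir2 <- as_event_set("x", IR = data.frame(first = c(1, 3),
                                              last = c(2, 4), n = c(2, 2)))
  ev_0 <- as_event_set("x")
  events <- c(rep(list(ev_a5x2), 4314), rep(list(ev_a5x1), 1768),
              rep(list(ev_ir1), 133), rep(list(ev_ir2), 1),
              rep(list(ev_0), 946))
  names(events) <- sprintf("i%05d", seq_along(events))
  res <- list(
    events = events,
    categories = stats::setNames(
      rep(list(list(category = "NNC", ref_match = NA, mono_exon = FALSE)),
          length(events)), names(events)),
    models = list(G = model_G),
    gene_of = stats::setNames(rep("G", length(events)), names(events))
  )
  s <- summarize_gene(res, "G")$summary
  expect_equal(s$n_isoforms, 7162)
  expect_equal(s$a5a3_isoforms, 6082)
  expect_equal(s$a5a3_events, 10396)
  expect_equal(s$a5a3_pct, 84.9)
  expect_equal(s$ir_isoforms, 134)
  expect_equal(s$ir_events, 135)
  expect_equal(round(100 * s$ir_isoforms / s$n_isoforms, 2), 1.87)
})

test_that("exon matrices encode present/skipped/IR and cluster duplicates together", {
  res <- characterize_isoforms(
    rbind(iso_G(c(100, 500, 700), c(200, 600, 800), id = "skip2a"),
          iso_G(c(100, 500, 700), c(200, 600, 800), id = "skip2b"),
          iso_G(c(100, 300, 700), c(200, 600, 800), id = "ir23"),
          iso_G(c(100, 300, 500, 700), c(200, 400, 600, 800), id = "full")),
    gene_G())
  m <- build_exon_matrix(res, "G")
  expect_equal(unname(m["skip2a", ]),
               c("present", "skipped", "present", "present"))
  expect_equal(unname(m["ir23", ]), c("present", "IR", "IR", "present"))
  expect_equal(unname(m["full", ]), rep("present", 4))
  # identical isoforms are adjacent rows (zero distance)
  expect_equal(abs(diff(match(c("skip2a", "skip2b"), rownames(m)))), 1)
})

test_that("junction support marks isoform junctions from an SJ table", {
  sj <- data.frame(chrom = "chr1", start = 200L, end = 300L, strand = "+",
                   unique_reads = 12L)
  iso <- iso_G(c(100, 300, 500), c(200, 400, 600))
  out <- junction_support(iso, sj)
  expect_equal(out$supported, c(TRUE, FALSE))
  expect_equal(out$unique_reads, c(12L, 0L))
})
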