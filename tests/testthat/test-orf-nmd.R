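cfg <- iso_config()

test_that("spliced sequences concatenate exons and honor strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGCCCAAA"))
  plus <- exon_table("chr1", c(0, 6), c(3, 9), "+", "t1", "g1")
  expect_equal(spliced_sequence(plus, genome), "ATGAAA")
  minus <- exon_table("chr1", c(0, 6), c(3, 9), "-", "t2", "g1")
  expect_equal(spliced_sequence(minus, genome), "TTTCAT")

  # length property over random transcripts
  set.seed(17)
  genome <- Biostrings::DNAStringSet(c(chrR = random_dna(5000)))
  for (i in 1:20) {
    n <- sample(1:5, 1)
    lens <- sample(30:200, n, replace = TRUE)
    gaps <- sample(50:300, n, replace = TRUE)
    starts <- cumsum(c(10, (lens + gaps)[-n]))
    iso <- exon_table("chrR", starts, starts + lens,
                      sample(c("+", "-"), 1), "t", "g")
    expect_equal(nchar(spliced_sequence(iso, genome)), sum(lens))
  }

  expect_error(spliced_sequence(exon_table("chrZ", 0, 9, "+", "t", "g"),
                                genome), "chrZ")
})

test_that("ORF finding picks the longest ATG-initiated frame", {
  o <- find_orf("ATGAAATAG")
  expect_equal(o$orf_length, 9L)
  expect_equal(o$protein, "MK")
  expect_true(o$has_stop)

  expect_null(find_orf("CCCCCC"))

  # two ORFs of 30 and 21 nt: the longer wins (verified by the scanner)
  s <- paste0("GG", "ATG", strrep("GCA", 8), "TAA",   # 30 nt ORF at 3
              "T", "ATG", strrep("GCT", 5), "TGA")    # 21 nt ORF
  o <- find_orf(s)
  b <- orf_oracle(s)
  expect_equal(o$orf_length, 30L)
  expect_equal(o$orf_start, b$start)
  expect_equal(o$orf_end, b$end)

  # no in-frame stop: runs to the last complete codon, has_stop FALSE
  o <- find_orf("ATGAAAAACC")
  expect_false(o$has_stop)
  expect_equal(o$orf_length %% 3, 0)

  # agreement with the exhaustive three-frame scanner on random sequences
  set.seed(23)
  for (i in 1:400) {
    s <- random_dna(sample(20:400, 1))
    a <- find_orf(s); b <- orf_oracle(s)
    expect_equal(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_equal(a$orf_start, b$start)
      expect_equal(a$orf_end, b$end)
      expect_equal(a$has_stop, b$has_stop)
    }
  }
})

test_that("NMD candidacy follows the distance-to-last-junction rule", {
  # stop ending 80 nt upstream of the last junction -> candidate
  orf <- list(orf_start = 1, orf_end = 120, has_stop = TRUE)
  r <- predict_nmd(orf, exon_lengths = c(150, 50, 100), cfg)
  expect_true(r$nmd_candidate)
  expect_equal(r$ptc_to_last_junction_nt, 80L)

  # 20 nt upstream -> not a candidate
  r <- predict_nmd(list(orf_start = 1, orf_end = 180, has_stop = TRUE),
                   c(150, 50, 100), cfg)
  expect_false(r$nmd_candidate)

  # boundary: exactly d_nmd is not a candidate, d_nmd + 1 is
  r <- predict_nmd(list(orf_start = 1, orf_end = 150, has_stop = TRUE),
                   c(150, 50, 100), cfg)
  expect_equal(r$ptc_to_last_junction_nt, 50L)
  expect_false(r$nmd_candidate)
  r <- predict_nmd(list(orf_start = 1, orf_end = 149, has_stop = TRUE),
                   c(150, 50, 100), cfg)
  expect_true(r$nmd_candidate)

  # stop in the last exon -> never a candidate
  r <- predict_nmd(list(orf_start = 1, orf_end = 210, has_stop = TRUE),
                   c(150, 50, 100), cfg)
  expect_false(r$nmd_candidate)

  # mono-exonic transcripts are flagged, not guessed
  r <- predict_nmd(list(orf_start = 1, orf_end = 30, has_stop = TRUE),
                   300, cfg)
  expect_false(r$nmd_candidate)
  expect_true(r$mono_exon)
})

test_that("cryptic exon frame effects are called from the ORF", {
  # build a transcript whose middle exon is the cryptic one
  make_tx <- function(ce_seq) {
    up <- paste0("ATG", strrep("GCA", 10))          # 33 nt, no stop
    down <- paste0(strrep("GCC", 10), "TAATT")      # stop at end
    genome <- Biostrings::DNAStringSet(c(chrC = paste0(
      up, "GGGGG", ce_seq, "GGGGG", down)))
    l1 <- nchar(up); lc <- nchar(ce_seq); l3 <- nchar(down)
    iso <- exon_table("chrC",
                      start = c(0, l1 + 5, l1 + 10 + lc),
                      end = c(l1, l1 + 5 + lc, l1 + 10 + lc + l3),
                      strand = "+", transcript_id = "t", gene_id = "g")
    list(iso = iso, genome = genome,
         ce = data.frame(start = l1 + 5, end = l1 + 5 + lc))
  }

  # 42 nt cryptic exon, no stop: in frame, ORF runs through it
  tx <- make_tx(strrep("GCT", 14))
  orf <- find_orf(spliced_sequence(tx$iso, tx$genome))
  expect_equal(cryptic_exon_frame(tx$iso, tx$ce, orf), "in_frame_no_stop")

  # 40 nt -> frameshift
  tx <- make_tx(paste0(strrep("GCT", 13), "G"))
  orf <- find_orf(spliced_sequence(tx$iso, tx$genome))
  expect_equal(cryptic_exon_frame(tx$iso, tx$ce, orf), "frameshift")

  # 42 nt containing an in-frame TAA -> premature stop inside the CE
  tx <- make_tx(paste0(strrep("GCT", 6), "TAA", strrep("GCT", 7)))
  orf <- find_orf(spliced_sequence(tx$iso, tx$genome))
  expect_equal(cryptic_exon_frame(tx$iso, tx$ce, orf), "in_frame_with_stop")
})

test_that("protein collapsing picks the most abundant representative", {
  orfs <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    protein = c("MKV", "MKV", "MKW"),
    has_stop = TRUE, coding = TRUE, stringsAsFactors = FALSE)
  cp <- collapse_proteins(orfs, c(t1 = 100, t2 = 20, t3 = 5))
  expect_equal(nrow(cp$groups), 2)
  expect_equal(cp$groups$representative[cp$groups$protein == "MKV"], "t1")
  expect_equal(cp$accounting$n_redundant, 1)

  # all distinct -> nothing redundant; group sizes conserve transcripts
  orfs$protein <- c("MA", "MB", "MC")
  cp <- collapse_proteins(orfs, c(t1 = 1, t2 = 1, t3 = 1))
  expect_equal(cp$accounting$n_redundant, 0)
  expect_equal(sum(cp$groups$n_members), cp$accounting$n_coding)

  # published accounting: 5596 coding, 3841 unique -> 1755 redundant,
  # of which 1248 NNC = 71.1%
  expect_equal(5596 - 3841, 1755)
  expect_equal(round(100 * 1248 / 1755, 1), 71.1)
})

test_that("ORF annotation integrates NMD and coding calls over a catalog", {
  genome <- Biostrings::DNAStringSet(c(chrQ = paste0(
    strrep("C", 100), "ATG", strrep("GCA", 20), "TAA", strrep("GC", 200))))
  # two-exon transcript with the stop upstream of the junction
  iso <- exon_table("chrQ", c(90, 400), c(190, 500), "+",
                    c("t1", "t1"), "g1")
  orfs <- annotate_orfs(iso, genome, cfg)
  expect_equal(nrow(orfs), 1)
  expect_true(orfs$has_stop)
  expect_true(orfs$coding)

  # external scores override the ORF-based call
  orfs2 <- annotate_orfs(iso, genome, cfg,
                         coding_scores = c(t1 = 0.2))
  expect_false(orfs2$coding)
  expect_equal(orfs2$coding_call, "external_score")
  orfs3 <- annotate_orfs(iso, genome, cfg, coding_scores = c(t1 = 0.45))
  expect_true(orfs3$coding)
})
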