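cfg <- iso_config()

test_that("rare-transcript filter implements both boundary semantics", {
  m <- rbind(a = c(3, 3, 2, 1, 1, 0),   # top-5 sum 10 -> retained
             b = c(3, 3, 2, 1, 0, 0),   # top-5 sum 9  -> removed
             c = c(10, 10, 10, 10, 10, 0),
             d = c(10, 10, 10, 10, 0, 0))
  colnames(m) <- paste0("s", 1:6)
  flt <- filter_rare(m, cfg)
  expect_setequal(rownames(flt$counts), c("a", "c", "d"))
  expect_equal(flt$n_removed, 1)
  expect_equal(flt$pct_removed, 25.0)

  # per-sample semantics: five samples must each reach the threshold
  flt2 <- filter_rare(m, cfg, semantics = "per_sample")
  expect_setequal(rownames(flt2$counts), "c")

  # removal-report arithmetic at the published scale
  expect_equal(round(100 * 74411 / 81221, 1), 91.6)

  # monotonicity: raising the threshold never grows the retained set
  set.seed(5)
  big <- matrix(rnbinom(600, mu = 4, size = 0.5), ncol = 6,
                dimnames = list(sprintf("i%03d", 1:100), paste0("s", 1:6)))
  kept_prev <- NULL
  for (thr in c(5, 10, 20, 40)) {
    kept <- rownames(filter_rare(big, iso_config(rare_min_reads = thr))$counts)
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }

  expect_warning(filter_rare(m[, 1:3], cfg), "fewer samples")
})

test_that("normalization matches hand-computed factors", {
  cnt <- matrix(c(2, 4, 4, 8), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  nm <- normalize_counts(cnt)
  expect_equal(unname(attr(nm, "size_factors")),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4)

  # all-equal columns -> equal factors
  cnt2 <- matrix(rep(c(5, 9, 2), 3), ncol = 3,
                 dimnames = list(letters[1:3], paste0("s", 1:3)))
  sf <- attr(normalize_counts(cnt2), "size_factors")
  expect_true(all(abs(sf - sf[1]) < 1e-12))

  # cpm factor = column sum / 1e6
  cnt3 <- matrix(c(2e6, 0, 0), ncol = 1, dimnames = list(letters[1:3], "s1"))
  expect_equal(unname(attr(normalize_counts(cnt3, "cpm"), "size_factors")), 2)

  expect_error(normalize_counts(matrix(c(0, 1, 1, 0), 2,
                                       dimnames = list(c("a", "b"), NULL))),
               "no rows")
})

test_that("isoform fractions sum to one and flag undefined samples", {
  cnt <- matrix(c(60, 0, 30, 0, 10, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  gm <- stats::setNames(rep("g1", 3), c("A", "B", "C"))
  ift <- isoform_fractions(cnt, gm)
  expect_equal(unname(ift$IF[, "s1"]), c(0.6, 0.3, 0.1))
  expect_true(all(is.na(ift$IF[, "s2"])))       # zero-total sample
  expect_equal(unname(ift$mean_if), c(0.6, 0.3, 0.1))  # NA excluded

  # property: per-gene, per-sample sums are 1 wherever defined
  set.seed(9)
  cnt <- matrix(rnbinom(300, mu = 40, size = 1), nrow = 30,
                dimnames = list(sprintf("i%02d", 1:30), paste0("s", 1:10)))
  gm <- stats::setNames(rep(paste0("g", 1:6), each = 5), rownames(cnt))
  ift <- isoform_fractions(cnt, gm)
  sums <- rowsum(ift$IF, gm)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
})

test_that("dominant and major isoforms use the strict > 0.5 rule", {
  cnt <- matrix(c(100, 51, 50), ncol = 1,
                dimnames = list(c("A", "B", "C"), "s1"))
  gm <- stats::setNames(rep("g1", 3), c("A", "B", "C"))
  ift <- isoform_fractions(cnt, gm)
  dm <- dominant_and_major(ift, cfg)
  expect_equal(dm$dominant, "A")
  expect_equal(dm$major, "A;B")   # 0.51 > 0.5 in; 0.50 out (strict)

  single <- isoform_fractions(matrix(7, 1, 1, dimnames = list("X", "s1")),
                              c(X = "g"))
  dm <- dominant_and_major(single, cfg)
  expect_equal(dm$major, "X")

  tied <- isoform_fractions(matrix(c(5, 5), 2, 1,
                                   dimnames = list(c("b", "a"), "s1")),
                            c(a = "g", b = "g"))
  expect_message(dm <- dominant_and_major(tied, cfg), "tie")
  expect_equal(dm$dominant, "a")
  expect_true(dm$tie)
})

test_that("minor isoform filter tracks the fold-change threshold", {
  cnt <- matrix(c(100, 60, 10), ncol = 1,
                dimnames = list(c("A", "B", "C"), "s1"))
  gm <- stats::setNames(rep("g1", 3), c("A", "B", "C"))
  ift <- isoform_fractions(cnt, gm)
  expect_equal(minor_isoform_filter(ift, cfg), c("A", "B"))
  expect_equal(minor_isoform_filter(ift, iso_config(minor_filter_fc = 0)),
               c("A", "B", "C"))
  expect_equal(minor_isoform_filter(ift, iso_config(minor_filter_fc = 1)),
               "A")
})

test_that("DTU total change is the half-L1 distance and is symmetric", {
  ifm <- cbind(s1 = c(0.6, 0.3, 0.1), s2 = c(0.6, 0.3, 0.1),
               s3 = c(0.3, 0.5, 0.2), s4 = c(0.3, 0.5, 0.2))
  rownames(ifm) <- c("A", "B", "C")
  r <- isochar:::.dtu_one(ifm, 1:2, 3:4, 0, 1)
  expect_equal(r$total_change, 30)
  expect_true(r$podium_change)
  r2 <- isochar:::.dtu_one(ifm, 3:4, 1:2, 0, 1)
  expect_equal(r2$total_change, 30)   # symmetric in groups

  # identical groups: zero change, p about 1
  ifm0 <- ifm[, c(1, 2, 1, 2)]
  r <- isochar:::.dtu_one(ifm0, 1:2, 3:4, 199, 7)
  expect_equal(r$total_change, 0)
  expect_false(r$podium_change)
  expect_equal(r$permutation_p, 1)

  expect_error(
    dtu_metrics(isoform_fractions(ifm, c(A = "g", B = "g", C = "g")),
                factor(c("x", "x", "x", "y"))),
    ">= 2 samples")
})

test_that("gene aggregation precedes filtering and conserves counts", {
  cnt <- matrix(c(5, 3, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "s"))
  gm <- c(a = "g1", b = "g1", c = "g1")
  expect_equal(unname(gene_level_counts(cnt, gm)[1, 1]), 10)

  set.seed(31)
  cnt <- matrix(rnbinom(200, mu = 20, size = 1), nrow = 40,
                dimnames = list(sprintf("i%02d", 1:40), paste0("s", 1:5)))
  gm <- stats::setNames(sample(paste0("g", 1:7), 40, replace = TRUE),
                        rownames(cnt))
  gc <- gene_level_counts(cnt, gm)
  expect_equal(colSums(gc), colSums(cnt))
  expect_error(gene_level_counts(cnt, gm[-1]), "i01")
})

test_that("cumulative read proportions are ordered and end at one", {
  cnt <- matrix(c(500, 300, 150, 50), ncol = 1,
                dimnames = list(c("w", "x", "y", "z"), "s"))
  cp <- cumulative_read_proportion(cnt)
  expect_equal(cp$cumulative_proportion, c(0.5, 0.8, 0.95, 1.0))

  single <- matrix(10, 1, 1, dimnames = list("only", "s"))
  expect_equal(cumulative_read_proportion(single)$cumulative_proportion, 1)

  set.seed(3)
  cnt <- matrix(rnbinom(80, mu = 30, size = 1), nrow = 20,
                dimnames = list(sprintf("i%02d", 1:20), paste0("s", 1:4)))
  cnt[1, ] <- 5  # guarantee a nonzero total
  cp <- cumulative_read_proportion(cnt)
  expect_true(all(diff(cp$cumulative_proportion) >= -1e-12))
  expect_equal(cp$cumulative_proportion[nrow(cp)], 1)

  expect_error(cumulative_read_proportion(matrix(0, 2, 2,
                                                 dimnames = list(c("a", "b"), NULL))),
               "all-zero")
})

test_that("detection overlap reproduces the published fold change", {
  ov <- detection_overlap(paste0("t", 1:1255), paste0("t", 816:1270))
  expect_equal(ov$unique_a, 815)
  expect_equal(ov$unique_b, 15)
  expect_equal(ov$common, 440)
  expect_equal(ov$fold_change, 2.76)

  same <- detection_overlap(letters[1:5], letters[1:5])
  expect_equal(same$fold_change, 1.0)
  expect_equal(same$jaccard, 1.0)

  dis <- detection_overlap(letters[1:3], "z")
  expect_equal(dis$fold_change, 3.0)
  expect_equal(dis$jaccard, 0)

  expect_error(detection_overlap(character(0), character(0)), "empty")
})

test_that("event burden log2FC uses a pseudocount and two groups", {
  cnt <- matrix(c(10, 10, 20, 20), nrow = 1,
                dimnames = list("ir1", paste0("s", 1:4)))
  gr <- factor(c("WT", "WT", "TG", "TG"), levels = c("WT", "TG"))
  b <- event_burden_by_group(cnt, "ir1", gr)
  expect_equal(b$log2fc, log2(21 / 11))

  b0 <- event_burden_by_group(cnt, character(0), gr)
  expect_equal(unname(b0$burden), rep(0, 4))
  expect_equal(b0$log2fc, 0)
})
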