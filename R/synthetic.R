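# ---------------------------------------------------------------------------
# Synthetic benchmark data with ground-truth event labels.
#
# Genes are built on the '+' strand and mirrored (coordinate reflection +
# strand flip) for '-' genes, so transcription-order semantics carry over
# unchanged.  Implants are placed so they are unambiguous by
# construction: alternative splice-site offsets are drawn beyond the
# tolerance (11-30 bp), annotated boundary variants further still
# (41-80 bp), cryptic exons keep >= 30 bp of intron on either side, and
# novel/alternative promoter displacements exceed the TSS window.
# ---------------------------------------------------------------------------

#' Specification of a synthetic gene
#'
#' Defines the study conditions emulated by the generator: multi-exon
#' genes with several reference transcripts (including alternative first
#' exons, a skipping transcript and annotated boundary variants) and an
#' isoform catalog carrying implanted AF/AL/A5/A3/ES/IR/CE/NE events and
#' 5'-truncated (ISM-like) artifacts.
#'
#' @param n_exons Number of flat exons (>= 2; >= 4 recommended so
#'   internal events are possible).
#' @param exon_len,intron_len Length ranges (bp), inclusive.
#' @param strand `"+"` or `"-"`.
#' @param n_reference_transcripts 1-3 reference transcripts (the first
#'   always covers all exons; the second adds an alternative first exon;
#'   the third skips one internal exon and carries a boundary variant).
#' @param n_isoforms Number of long-read isoforms to emit.
#' @param p_es,p_ir,p_ce,p_ne,p_a5,p_a3,p_ism,p_ap,p_at,p_al Per-type
#'   implant probabilities.
#' @param seed Seed making the gene fully reproducible.
#' @return list of class `synth_gene_spec`.
#' @export
synth_gene_spec <- function(n_exons = 8, exon_len = c(80, 300),
                            intron_len = c(200, 2000), strand = "+",
                            n_reference_transcripts = 3, n_isoforms = 8,
                            p_es = 0.3, p_ir = 0.15, p_ce = 0.12,
                            p_ne = 0.08, p_a5 = 0.2, p_a3 = 0.2,
                            p_ism = 0.2, p_ap = 0.1, p_at = 0.1,
                            p_al = 0.1, seed = 1) {
  p <- c(p_es = p_es, p_ir = p_ir, p_ce = p_ce, p_ne = p_ne, p_a5 = p_a5,
         p_a3 = p_a3, p_ism = p_ism, p_ap = p_ap, p_at = p_at, p_al = p_al)
  if (any(p < 0 | p > 1)) stop("event probabilities must lie in [0, 1]")
  if (n_exons < 2) stop("junction-bearing genes need n_exons >= 2")
  if (exon_len[1] <= 0 || intron_len[1] <= 0) stop("lengths must be > 0")
  if (p_ce > 0 && intron_len[1] < 120) {
    stop("infeasible spec: cryptic exons need introns >= 120 bp")
  }
  if ((p_a5 > 0 || p_a3 > 0) && exon_len[1] < 80) {
    stop("infeasible spec: splice-site implants need exons >= 80 bp")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(c(list(n_exons = as.integer(n_exons),
                   exon_len = as.integer(exon_len),
                   intron_len = as.integer(intron_len),
                   strand = strand,
                   n_reference_transcripts = as.integer(n_reference_transcripts),
                   n_isoforms = as.integer(n_isoforms),
                   seed = as.integer(seed)),
              as.list(p)),
            class = "synth_gene_spec")
}

# internal: integer uniform draw on [lo, hi]
runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

#' Generate a synthetic reference gene
#'
#' @param spec A [synth_gene_spec()].
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @return list of class `synth_gene`: `reference` (`exon_tbl`),
#'   `layout` (canonical '+'-strand exon starts/ends, the alternative
#'   first exon, the skipped exon and boundary-variant positions),
#'   `mirror_c` (reflection constant for '-' genes, else NA), gene id,
#'   strand and spec.
#' @export
make_gene <- function(spec, gene_id = "SYNTG1", chrom = "chrS1") {
  with_seed(spec$seed, {
    n <- spec$n_exons
    lens <- runif_int(n, spec$exon_len[1], spec$exon_len[2])
    introns <- if (n > 1) runif_int(n - 1, spec$intron_len[1],
                                    spec$intron_len[2]) else integer(0)
    starts <- 2000L + cumsum(c(0L, lens[-n] + introns))
    ends <- starts + lens

    nref <- max(1L, min(3L, spec$n_reference_transcripts))
    a <- NA_integer_; s <- NA_integer_; v <- NA_integer_
    vside <- NA_character_; voff <- NA_integer_
    ref <- list(list(id = paste0(gene_id, ".ref1"), rows = seq_len(n),
                     mod = NULL))
    if (nref >= 2 && n >= 3) {
      a <- runif_int(1, 2, min(3, n - 1))
      ref[[2]] <- list(id = paste0(gene_id, ".ref2"), rows = a:n, mod = NULL)
    }
    if (nref >= 3 && n >= 4) {
      cand_s <- setdiff(2:(n - 1), a)
      s <- cand_s[runif_int(1, 1, length(cand_s))]
      mod <- NULL
      if (spec$exon_len[1] >= 71) {  # room for a 41+ bp inward variant
        cand_v <- setdiff(2:(n - 1), s)
        v <- cand_v[runif_int(1, 1, length(cand_v))]
        vside <- if (stats::runif(1) < 0.5) "start" else "end"
        voff <- runif_int(1, 41, min(80, spec$exon_len[1] - 30))
        mod <- list(row = v, side = vside, off = voff)
      }
      ref[[3]] <- list(id = paste0(gene_id, ".ref3"),
                       rows = setdiff(seq_len(n), s),
                       mod = mod)
    }

    exon_rows <- function(tr) {
      st <- starts[tr$rows]; en <- ends[tr$rows]
      if (!is.null(tr$mod)) {
        k <- match(tr$mod$row, tr$rows)
        if (!is.na(k)) {
          if (tr$mod$side == "start") st[k] <- st[k] + tr$mod$off
          else en[k] <- en[k] - tr$mod$off
        }
      }
      data.frame(start = st, end = en, transcript_id = tr$id)
    }
    refdf <- do.call(rbind, lapply(ref, exon_rows))

    mirror_c <- NA_integer_
    if (spec$strand == "-") {
      mirror_c <- as.integer(max(ends) + 2000L)
      tmp <- mirror_c - refdf$end
      refdf$end <- mirror_c - refdf$start
      refdf$start <- tmp
    }
    reference <- exon_table(chrom = chrom, start = refdf$start,
                            end = refdf$end, strand = spec$strand,
                            transcript_id = refdf$transcript_id,
                            gene_id = gene_id)
    attr(reference, "source") <- "reference"
    structure(list(
      gene_id = gene_id, chrom = chrom, strand = spec$strand,
      reference = reference,
      layout = list(starts = starts, ends = ends, n = n,
                    alt_first = a, ref_skip = s,
                    variant_row = v, variant_side = vside,
                    variant_off = voff,
                    known_first = unique(c(1L, a[!is.na(a)])),
                    known_tss = unique(c(starts[1], starts[a[!is.na(a)]])),
                    known_tts = ends[n],
                    # every annotated boundary position per side (incl.
                    # the ref3 variant), used for truth offsets
                    ref_starts = sort(unique(c(starts,
                      if (!is.na(v) && identical(vside, "start"))
                        starts[v] + voff))),
                    ref_ends = sort(unique(c(ends,
                      if (!is.na(v) && identical(vside, "end"))
                        ends[v] - voff)))),
      mirror_c = mirror_c,
      spec = spec
    ), class = "synth_gene")
  })
}

# internal: reflect an interval table for '-' genes
.mirror_intervals <- function(df, C) {
  if (nrow(df) == 0 || is.na(C)) return(df)
  tmp <- C - df$end
  df$end <- C - df$start
  df$start <- tmp
  df[order(df$start), , drop = FALSE]
}

#' Generate an isoform catalog with ground-truth event labels
#'
#' Builds `n_isoforms` long-read transcript models for a synthetic gene.
#' The first isoform is a canonical copy of the full-length reference;
#' when a skipping reference transcript exists, the second isoform copies
#' it (an FSM isoform that legitimately carries an ES call against the
#' flattened model).  Remaining isoforms receive independent implants:
#' a 5'-end modification (ISM-like truncation, a novel upstream exon, or
#' an alternative-promoter extension), a 3'-end modification (last-exon
#' drop, novel downstream exon, or terminator extension), exon skipping,
#' one retained-intron run, alternative 5'/3' splice-site shrinks and one
#' cryptic exon.
#'
#' @param gene A `synth_gene` from [make_gene()].
#' @return list: `isoforms` (`exon_tbl`), `truth` (named list of
#'   [as_event_set()] ground truth per isoform), `categories` (named
#'   character vector of expected FSM/ISM/NIC/NNC labels).
#' @export
make_isoforms <- function(gene) {
  spec <- gene$spec
  lay <- gene$layout
  n <- lay$n
  with_seed(derive_seed(spec$seed, 1L), {
    isoforms <- list()
    truths <- list()
    for (i in seq_len(spec$n_isoforms)) {
      tid <- sprintf("%s.iso%d", gene$gene_id, i)
      if (i == 1) {
        b <- .build_canonical(gene, tid, rows = seq_len(n))
      } else if (i == 2 && !is.na(lay$ref_skip)) {
        b <- .build_refskip_copy(gene, tid)
      } else {
        b <- .build_implanted(gene, tid)
      }
      isoforms[[tid]] <- b$exons
      truths[[tid]] <- b$truth
    }
    df <- do.call(rbind, isoforms)
    df <- .mirror_intervals_df(df, gene$mirror_c)
    iso_tbl <- exon_table(chrom = gene$chrom, start = df$start, end = df$end,
                          strand = gene$strand, transcript_id = df$transcript_id,
                          gene_id = gene$gene_id)
    attr(iso_tbl, "source") <- "long_read"
    truths <- lapply(truths, .mirror_truth, C = gene$mirror_c)
    cats <- vapply(names(truths), function(id) {
      .expected_category(transcript_exons(iso_tbl, id), gene)
    }, character(1))
    list(isoforms = iso_tbl, truth = truths, categories = cats)
  })
}

# mirror helper operating on the combined exon data.frame
.mirror_intervals_df <- function(df, C) {
  if (is.na(C)) return(df)
  tmp <- C - df$end
  df$end <- C - df$start
  df$start <- tmp
  df
}

# mirror the interval-bearing truth fields (CE/NE); indices are
# transcription-order and unchanged by reflection
.mirror_truth <- function(tr, C) {
  if (is.na(C)) return(tr)
  tr$CE <- {
    ce <- tr$CE
    if (nrow(ce)) {
      tmp <- C - ce$end; ce$end <- C - ce$start; ce$start <- tmp
      ce <- ce[order(ce$start), , drop = FALSE]
      rownames(ce) <- NULL
    }
    ce
  }
  tr$NE <- {
    ne <- tr$NE
    if (nrow(ne)) {
      tmp <- C - ne$end; ne$end <- C - ne$start; ne$start <- tmp
      ne <- ne[order(ne$start), , drop = FALSE]
      rownames(ne) <- NULL
    }
    ne
  }
  tr
}

.build_canonical <- function(gene, tid, rows) {
  lay <- gene$layout
  exons <- data.frame(start = lay$starts[rows], end = lay$ends[rows],
                      transcript_id = tid)
  truth <- as_event_set(tid, first_exon = rows[1],
                        last_exon = rows[length(rows)])
  list(exons = exons, truth = truth)
}

.build_refskip_copy <- function(gene, tid) {
  lay <- gene$layout
  rows <- setdiff(seq_len(lay$n), lay$ref_skip)
  st <- lay$starts[rows]; en <- lay$ends[rows]
  k <- match(lay$variant_row, rows)
  if (!is.na(k)) {
    if (lay$variant_side == "start") st[k] <- st[k] + lay$variant_off
    else en[k] <- en[k] - lay$variant_off
  }
  exons <- data.frame(start = st, end = en, transcript_id = tid)
  truth <- as_event_set(tid, first_exon = 1L, last_exon = lay$n,
                        ES = lay$ref_skip)
  list(exons = exons, truth = truth)
}

.build_implanted <- function(gene, tid) {
  spec <- gene$spec
  lay <- gene$layout
  n <- lay$n
  w <- 50L  # TSS/TTS window the implants are placed against
  st <- lay$starts; en <- lay$ends

  # --- 5' end modification (exclusive choice) -----------------------------
  u <- stats::runif(1)
  five <- if (u < spec$p_ism) "truncate"
          else if (u < spec$p_ism + spec$p_ne) "ne"
          else if (u < spec$p_ism + spec$p_ne + spec$p_ap) "ap_extend"
          else "none"
  fr <- 1L
  shorten <- 0L
  ne_up <- NULL
  ap_delta <- 0L
  if (five == "truncate" && n >= 4) {
    fr <- 1L + runif_int(1, 1, min(2, n - 3))
    if (stats::runif(1) < 0.5) shorten <- runif_int(1, 10, 60)
  } else if (five == "ne") {
    gp <- runif_int(1, 100, 200); nl <- runif_int(1, 40, 80)
    ne_up <- c(st[1] - gp - nl, st[1] - gp)
  } else if (five == "ap_extend") {
    ap_delta <- runif_int(1, 51, 150)
  }

  # --- 3' end modification -------------------------------------------------
  u <- stats::runif(1)
  three <- if (u < spec$p_al) "drop_last"
           else if (u < spec$p_al + spec$p_ne / 2) "ne"
           else if (u < spec$p_al + spec$p_ne / 2 + spec$p_at) "at_extend"
           else "none"
  lr <- n
  ne_down <- NULL
  at_delta <- 0L
  if (three == "drop_last" && (n - 1L) - fr >= 2) {
    lr <- n - 1L
  } else if (three == "drop_last") {
    three <- "none"
  }
  if (three == "ne") {
    gp <- runif_int(1, 100, 200); nl <- runif_int(1, 40, 80)
    ne_down <- c(en[n] + gp, en[n] + gp + nl)
  } else if (three == "at_extend") {
    at_delta <- runif_int(1, 51, 150)
  }

  retained <- fr:lr
  internal <- if (lr - fr >= 2) (fr + 1L):(lr - 1L) else integer(0)

  # --- exon skipping -------------------------------------------------------
  es <- internal[stats::runif(length(internal)) < spec$p_es]

  # --- one retained-intron run --------------------------------------------
  ir_run <- integer(0)
  if (length(internal) >= 2 && stats::runif(1) < spec$p_ir) {
    avail <- setdiff(internal, es)
    starts_ok <- avail[(avail + 1L) %in% avail]
    if (length(starts_ok)) {
      r0 <- starts_ok[runif_int(1, 1, length(starts_ok))]
      m <- 2L
      if ((r0 + 2L) %in% avail && stats::runif(1) < 0.5) m <- 3L
      ir_run <- r0:(r0 + m - 1L)
    }
  }

  # --- alternative splice sites -------------------------------------------
  free <- setdiff(internal, c(es, ir_run))
  a5 <- a3 <- list()
  d5 <- d3 <- stats::setNames(integer(0), character(0))
  for (r in free) {
    if (stats::runif(1) < spec$p_a5) {
      d <- runif_int(1, 11, 30)
      d5[as.character(r)] <- d
      # truth offset = distance to the nearest annotated end boundary
      a5[[length(a5) + 1]] <- data.frame(
        exon = r, offset = min(abs((en[r] - d) - lay$ref_ends)))
    }
    if (stats::runif(1) < spec$p_a3) {
      d <- runif_int(1, 11, 30)
      d3[as.character(r)] <- d
      a3[[length(a3) + 1]] <- data.frame(
        exon = r, offset = min(abs((st[r] + d) - lay$ref_starts)))
    }
  }

  # --- one cryptic exon ----------------------------------------------------
  ce <- NULL
  if (stats::runif(1) < spec$p_ce) {
    pairs <- retained[(retained + 1L) %in% retained]
    pairs <- setdiff(pairs, ir_run[-length(ir_run)])   # no intron inside a run
    pairs <- pairs[!(pairs %in% es) & !((pairs + 1L) %in% es)]
    if (length(pairs)) {
      r <- pairs[runif_int(1, 1, length(pairs))]
      clen <- runif_int(1, 30, 60)
      lo <- en[r] + 30L
      hi <- st[r + 1L] - 30L - clen
      if (hi >= lo) {
        cs <- runif_int(1, lo, hi)
        ce <- c(cs, cs + clen)
      }
    }
  }

  # --- assemble exons ------------------------------------------------------
  rows_out <- setdiff(retained, c(es, ir_run))
  ex_st <- st[rows_out]; ex_en <- en[rows_out]
  names(ex_st) <- names(ex_en) <- rows_out
  for (rch in names(d5)) ex_en[rch] <- ex_en[rch] - d5[rch]
  for (rch in names(d3)) ex_st[rch] <- ex_st[rch] + d3[rch]
  if (length(ir_run)) {
    ex_st <- c(ex_st, stats::setNames(st[ir_run[1]], "ir"))
    ex_en <- c(ex_en, stats::setNames(en[ir_run[length(ir_run)]], "ir"))
  }
  if (as.character(fr) %in% names(ex_st)) {
    if (shorten > 0) ex_st[as.character(fr)] <- ex_st[as.character(fr)] + shorten
    if (ap_delta > 0) ex_st[as.character(fr)] <- ex_st[as.character(fr)] - ap_delta
  } else if (length(ir_run) && fr == ir_run[1]) {
    if (shorten > 0) ex_st["ir"] <- ex_st["ir"] + shorten
    if (ap_delta > 0) ex_st["ir"] <- ex_st["ir"] - ap_delta
  }
  if (as.character(lr) %in% names(ex_en)) {
    if (at_delta > 0) ex_en[as.character(lr)] <- ex_en[as.character(lr)] + at_delta
  } else if (length(ir_run) && lr == ir_run[length(ir_run)]) {
    if (at_delta > 0) ex_en["ir"] <- ex_en["ir"] + at_delta
  }
  exdf <- data.frame(start = as.integer(ex_st), end = as.integer(ex_en))
  if (!is.null(ce)) exdf <- rbind(exdf, data.frame(start = ce[1], end = ce[2]))
  if (!is.null(ne_up)) exdf <- rbind(exdf, data.frame(start = ne_up[1], end = ne_up[2]))
  if (!is.null(ne_down)) exdf <- rbind(exdf, data.frame(start = ne_down[1], end = ne_down[2]))
  exdf <- exdf[order(exdf$start), , drop = FALSE]
  exdf$transcript_id <- tid

  # --- ground truth --------------------------------------------------------
  tss <- if (!is.null(ne_up)) ne_up[1]
         else st[fr] + shorten - ap_delta
  tts <- if (!is.null(ne_down)) ne_down[2]
         else en[lr] + at_delta
  truth <- as_event_set(
    tid,
    AF = !is.null(ne_up) || !(fr %in% lay$known_first),
    first_exon = if (is.null(ne_up)) fr else NA_integer_,
    AL = !is.null(ne_down) || lr != n,
    last_exon = if (is.null(ne_down)) lr else NA_integer_,
    AP = min(abs(tss - lay$known_tss)) > w,
    AT = min(abs(tts - lay$known_tts)) > w,
    A5 = if (length(a5)) do.call(rbind, a5) else NULL,
    A3 = if (length(a3)) do.call(rbind, a3) else NULL,
    ES = es,
    IR = if (length(ir_run))
      data.frame(first = ir_run[1], last = ir_run[length(ir_run)],
                 n = length(ir_run)) else NULL,
    CE = if (!is.null(ce)) data.frame(start = ce[1], end = ce[2]) else NULL,
    NE = {
      ne <- NULL
      if (!is.null(ne_up))
        ne <- data.frame(side = "upstream", start = ne_up[1], end = ne_up[2])
      if (!is.null(ne_down))
        ne <- rbind(ne, data.frame(side = "downstream", start = ne_down[1],
                                   end = ne_down[2]))
      ne
    }
  )
  list(exons = exdf, truth = truth)
}

# expected structural category, derived by construction from the emitted
# coordinates using string-encoded junction chains (independent of the
# event caller's matrix-based comparison)
.expected_category <- function(iso, gene) {
  ref <- gene$reference
  enc <- function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) return("")
    paste(sprintf("%d/%d", e$end[-nrow(e)], e$start[-1]), collapse = ",")
  }
  tids <- sort(unique(ref$transcript_id))
  if (nrow(iso) == 1) {
    for (tid in tids) {
      e <- transcript_exons(ref, tid)
      if (nrow(e) == 1 && e$start <= iso$start && iso$end <= e$end)
        return("FSM")
    }
    if (any(ref$start <= iso$start & iso$end <= ref$end)) return("ISM")
    return("NIC")
  }
  q <- enc(iso)
  chains <- vapply(tids, function(tid) enc(transcript_exons(ref, tid)),
                   character(1))
  if (any(chains == q)) return("FSM")
  if (any(grepl(paste0(",", q, ","), paste0(",", chains, ","),
                fixed = TRUE))) return("ISM")
  e <- iso[order(iso$start), , drop = FALSE]
  left <- e$end[-nrow(e)]; right <- e$start[-1]
  refj <- do.call(rbind, lapply(tids, function(tid) {
    r <- transcript_exons(ref, tid)
    if (nrow(r) < 2) return(NULL)
    data.frame(left = r$end[-nrow(r)], right = r$start[-1])
  }))
  known <- all(left %in% refj$left) && all(right %in% refj$right)
  if (known) "NIC" else "NNC"
}

#' Simulate negative-binomial full-length read counts
#'
#' Counts are drawn per isoform and sample from a negative binomial with
#' the given mean and dispersion (variance = mu + dispersion * mu^2;
#' dispersion 0 gives Poisson counts).  Isoforms named in `fold_changes`
#' carry a multiplicative mean shift in the second group.
#'
#' @param isoform_ids Isoform identifiers (row order of the result).
#' @param n_per_group Named integer vector of samples per group (two
#'   groups; defaults mirror a targeted long-read design, 8 WT / 10 TG).
#' @param baseline_mean Scalar or per-isoform named vector of means.
#' @param dispersion NB dispersion (>= 0).
#' @param fold_changes Named numeric vector of group-2 multipliers.
#' @param ages Optional vector recycled over samples within each group
#'   for the metadata sheet.
#' @param seed Seed.
#' @return list: `counts` (integer matrix), `metadata` (sample, group,
#'   age), `truth` (the applied fold changes).
#' @export
make_counts <- function(isoform_ids, n_per_group = c(WT = 8L, TG = 10L),
                        baseline_mean = 100, dispersion = 0.1,
                        fold_changes = NULL, ages = c(2, 4, 6, 8),
                        seed = 1) {
  stopifnot(length(n_per_group) == 2, all(n_per_group > 0))
  if (dispersion < 0) stop("dispersion must be >= 0")
  mu <- if (length(baseline_mean) == 1) {
    stats::setNames(rep(baseline_mean, length(isoform_ids)), isoform_ids)
  } else baseline_mean[isoform_ids]
  if (anyNA(mu) || any(mu <= 0)) stop("baseline means must be > 0 for all isoforms")
  grp <- rep(names(n_per_group), n_per_group)
  samples <- paste0(grp, "_", unlist(lapply(n_per_group, seq_len)))
  fc_row <- stats::setNames(rep(1, length(isoform_ids)), isoform_ids)
  if (!is.null(fold_changes)) {
    fc_row[names(fold_changes)] <- fold_changes
  }
  mean_mat <- matrix(rep(mu, length(samples)), nrow = length(isoform_ids),
                     dimnames = list(isoform_ids, samples))
  is_g2 <- grp == names(n_per_group)[2]
  mean_mat[, is_g2] <- mean_mat[, is_g2] * fc_row
  counts <- with_seed(seed, {
    if (dispersion == 0) {
      matrix(stats::rpois(length(mean_mat), lambda = mean_mat),
             nrow = nrow(mean_mat), dimnames = dimnames(mean_mat))
    } else {
      matrix(stats::rnbinom(length(mean_mat), mu = mean_mat,
                            size = 1 / dispersion),
             nrow = nrow(mean_mat), dimnames = dimnames(mean_mat))
    }
  })
  storage.mode(counts) <- "integer"
  metadata <- data.frame(
    sample = samples,
    group = factor(grp, levels = names(n_per_group)),
    age = unlist(lapply(n_per_group, function(k) rep_len(ages, k)),
                 use.names = FALSE),
    stringsAsFactors = FALSE
  )
  list(counts = counts, metadata = metadata,
       truth = list(fold_changes = fc_row, dispersion = dispersion,
                    baseline_mean = mu))
}

#' Generate a random genome consistent with a set of transcript models
#'
#' One random-sequence chromosome per distinct chromosome name, long
#' enough to contain every exon plus a margin.
#'
#' @param exons `exon_tbl` (reference and isoforms combined).
#' @param seed Seed.
#' @param margin Extra bases beyond the last exon.
#' @return A named `DNAStringSet`.
#' @export
make_genome <- function(exons, seed = 1, margin = 500L) {
  chroms <- sort(unique(exons$chrom))
  with_seed(seed, {
    seqs <- lapply(chroms, function(ch) {
      len <- max(exons$end[exons$chrom == ch]) + margin
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    })
    out <- Biostrings::DNAStringSet(unlist(seqs))
    names(out) <- chroms
    out
  })
}

#' Simulate a complete benchmark dataset
#'
#' Generates `n_genes` synthetic genes (each on its own chromosome, with
#' strands alternating), their isoform catalogs with ground truth, and a
#' count matrix; optionally writes reference GTF, isoform GTF, counts
#' TSV, sample metadata TSV, genome FASTA and a ground-truth JSON ledger
#' to a directory.
#'
#' @param n_genes Number of genes.
#' @param seed Master seed; per-gene seeds are derived from it.
#' @param spec_template A [synth_gene_spec()] whose per-gene seed is
#'   replaced by the derived seed.
#' @param dir Optional output directory.
#' @param dispersion,baseline_mean Passed to [make_counts()].
#' @return list: reference, isoforms (`exon_tbl`s), truth (per isoform),
#'   categories, counts, metadata, genes (the `synth_gene` objects) and,
#'   when `dir` is given, `files`.
#' @export
simulate_dataset <- function(n_genes = 20, seed = 1,
                             spec_template = synth_gene_spec(),
                             dir = NULL, dispersion = 0.1,
                             baseline_mean = 100) {
  genes <- list(); isoforms <- list(); reference <- list()
  truth <- list(); categories <- character(0)
  for (g in seq_len(n_genes)) {
    spec <- spec_template
    spec$seed <- derive_seed(seed, g)
    spec$strand <- if (g %% 2 == 0) "-" else "+"
    gid <- sprintf("SYNTG%04d", g)
    gn <- make_gene(spec, gene_id = gid, chrom = sprintf("chrS%d", g))
    iso <- make_isoforms(gn)
    genes[[gid]] <- gn
    reference[[gid]] <- gn$reference
    isoforms[[gid]] <- iso$isoforms
    truth <- c(truth, iso$truth)
    categories <- c(categories, iso$categories)
  }
  ref_tbl <- do.call(rbind, reference)
  iso_tbl <- do.call(rbind, isoforms)
  class(ref_tbl) <- class(iso_tbl) <- c("exon_tbl", "data.frame")
  cc <- make_counts(unique(iso_tbl$transcript_id),
                    baseline_mean = baseline_mean,
                    dispersion = dispersion,
                    seed = derive_seed(seed, 0L))
  out <- list(reference = ref_tbl, isoforms = iso_tbl, truth = truth,
              categories = categories, counts = cc$counts,
              metadata = cc$metadata, genes = genes)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      reference_gtf = file.path(dir, "reference.gtf"),
      isoform_gtf = file.path(dir, "isoforms.gtf"),
      counts = file.path(dir, "counts.tsv"),
      metadata = file.path(dir, "samples.tsv"),
      genome = file.path(dir, "genome.fa"),
      truth = file.path(dir, "truth.json")
    )
    write_gtf(ref_tbl, files$reference_gtf)
    write_gtf(iso_tbl, files$isoform_gtf)
    write_counts(cc$counts, files$counts)
    utils::write.table(cc$metadata, files$metadata, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(make_genome(rbind(ref_tbl, iso_tbl),
                                            seed = derive_seed(seed, 0L)),
                                files$genome)
    jsonlite::write_json(
      lapply(truth, function(tr) {
        tr$ES <- as.list(tr$ES)
        unclass(tr)
      }),
      files$truth, auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}
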