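# ---------------------------------------------------------------------------
# Alternative-splicing event calling
#
# Every isoform is compared against the flattened gene model.  Events are
# always called against the flattened model, independent of structural
# category, so known (FSM) isoforms can legitimately carry ES/IR
# annotations when their matched reference transcript itself diverges
# from the flattened model.
#
# Edge conventions (stated because the field's shorthand is ambiguous):
#   A5 = alternative donor-side boundary (transcription 3' edge of an
#        internal exon); A3 = alternative acceptor-side boundary
#        (transcription 5' edge).  An isoform's transcription-start and
#        transcription-end edges are never A5/A3 candidates; they are
#        handled by the AP/AT calls.
# ---------------------------------------------------------------------------

# empty field templates, keyed by first column name
.empty_event_df <- list(
  exon = data.frame(exon = integer(0), offset = integer(0)),
  first = data.frame(first = integer(0), last = integer(0), n = integer(0)),
  start = data.frame(start = integer(0), end = integer(0)),
  side = data.frame(side = character(0), start = integer(0),
                    end = integer(0))
)

#' Construct an (empty) per-isoform event set
#'
#' Container for all alternative-splicing calls of one isoform.  The
#' synthetic-data generator builds its ground truth with the same
#' constructor so caller output and truth are directly comparable.
#'
#' @param isoform_id Isoform identifier.
#' @param AF,AL Alternative first/last exon flags.
#' @param first_exon,last_exon Transcription-order index of the flat exon
#'   matched by the isoform's first/last exon (NA when that exon is
#'   cryptic/novel).
#' @param AP,AT Alternative promoter / terminator flags.
#' @param A5,A3 data.frames with columns `exon` (flat exon index) and
#'   `offset` (nt to the nearest annotated boundary).
#' @param ES Integer vector of skipped flat exon indices.
#' @param IR data.frame with columns `first`, `last`, `n` (flat exons
#'   spanned by one retained-intron isoform exon).
#' @param CE data.frame of intronic (cryptic) exon intervals
#'   (`start`, `end`, 0-based half-open).
#' @param NE data.frame of novel exons outside the gene span
#'   (`side` in upstream/downstream, `start`, `end`).
#' @return A list of class `as_event_set` with normalized field order.
#' @export
as_event_set <- function(isoform_id,
                         AF = FALSE, first_exon = NA_integer_,
                         AL = FALSE, last_exon = NA_integer_,
                         AP = FALSE, AT = FALSE,
                         A5 = NULL, A3 = NULL, ES = integer(0),
                         IR = NULL, CE = NULL, NE = NULL) {
  norm2 <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0) return(.empty_event_df[[cols[1]]])
    df <- df[, cols, drop = FALSE]
    for (cc in cols) df[[cc]] <- as.integer(df[[cc]])
    if (nrow(df) > 1) df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  ne <- if (is.null(NE) || nrow(NE) == 0) {
    .empty_event_df[["side"]]
  } else {
    NE$side <- as.character(NE$side)
    NE$start <- as.integer(NE$start); NE$end <- as.integer(NE$end)
    NE <- NE[order(NE$start), c("side", "start", "end"), drop = FALSE]
    rownames(NE) <- NULL
    NE
  }
  structure(list(
    isoform_id = as.character(isoform_id),
    AF = isTRUE(AF), first_exon = as.integer(first_exon),
    AL = isTRUE(AL), last_exon = as.integer(last_exon),
    AP = isTRUE(AP), AT = isTRUE(AT),
    A5 = norm2(A5, c("exon", "offset")),
    A3 = norm2(A3, c("exon", "offset")),
    ES = sort(as.integer(ES)),
    IR = norm2(IR, c("first", "last", "n")),
    CE = norm2(CE, c("start", "end")),
    NE = ne
  ), class = "as_event_set")
}

#' Compare two event sets field by field
#'
#' @param a,b `as_event_set` objects.
#' @param fields Which event fields to compare.
#' @return TRUE when all requested fields agree exactly.
#' @export
events_equal <- function(a, b,
                         fields = c("AF", "AL", "AP", "AT", "A5", "A3",
                                    "ES", "IR", "CE", "NE")) {
  for (f in fields) {
    x <- a[[f]]; y <- b[[f]]
    if (is.data.frame(x)) {
      if (nrow(x) != nrow(y)) return(FALSE)
      if (nrow(x) && !isTRUE(all.equal(as.list(x), as.list(y),
                                       check.attributes = FALSE)))
        return(FALSE)
    } else if (!identical(unname(x), unname(y))) return(FALSE)
  }
  TRUE
}

#' Match an isoform's exons against the flattened gene model
#'
#' Each isoform exon is assigned exactly one match class:
#' `exact` (both boundaries on annotated variant boundaries),
#' `tolerant` (both within the splice tolerance), `alt_boundary`
#' (at least one boundary beyond tolerance), `spanning` (overlaps two or
#' more flat exons: intron-retention candidate), `cryptic` (wholly
#' intronic, zero flat-exon overlap), `novel_upstream` /
#' `novel_downstream` (outside the gene span, transcription
#' orientation).  Boundary offsets are measured to the nearest variant
#' boundary of the principal (largest-overlap) matched exon; overlap
#' ties break toward the lower transcription index.
#'
#' @param isoform `exon_tbl` rows of one isoform (single transcript).
#' @param model A `flat_gene_model`.
#' @param cfg An [iso_config()].
#' @return data.frame with one row per isoform exon (genomic order):
#'   `exon`, `start`, `end`, `class`, `principal` (genomic row of the
#'   principal flat exon), `first_row`/`last_row` (genomic rows of the
#'   matched range), `n_matched`, `off_start`, `off_end`.
#' @export
match_exons <- function(isoform, model, cfg = iso_config()) {
  iso <- isoform[order(isoform$start), , drop = FALSE]
  if (unique(iso$strand) != model$strand ||
      unique(iso$chrom) != model$chrom) {
    stop("isoform ", iso$transcript_id[1],
         " is not on the gene's chromosome/strand")
  }
  fe <- model$exons
  n <- nrow(iso)
  out <- data.frame(
    exon = seq_len(n), start = iso$start, end = iso$end,
    class = character(n), principal = NA_integer_,
    first_row = NA_integer_, last_row = NA_integer_,
    n_matched = 0L, off_start = NA_integer_, off_end = NA_integer_
  )
  for (i in seq_len(n)) {
    s <- iso$start[i]; e <- iso$end[i]
    ovl <- pmin(fe$end, e) - pmax(fe$start, s)
    hits <- which(ovl > 0)
    out$n_matched[i] <- length(hits)
    if (length(hits) == 0) {
      if (e <= model$span[1]) {
        out$class[i] <- if (model$strand == "+") "novel_upstream"
                        else "novel_downstream"
      } else if (s >= model$span[2]) {
        out$class[i] <- if (model$strand == "+") "novel_downstream"
                        else "novel_upstream"
      } else {
        out$class[i] <- "cryptic"
      }
      next
    }
    out$first_row[i] <- min(hits)
    out$last_row[i] <- max(hits)
    # principal = largest overlap, ties toward lower transcription index
    best <- hits[order(-ovl[hits], fe$index[hits])][1]
    out$principal[i] <- best
    v <- model$variants[[best]]
    out$off_start[i] <- min(abs(s - v[, "start"]))
    out$off_end[i] <- min(abs(e - v[, "end"]))
    if (length(hits) >= 2) {
      out$class[i] <- "spanning"
    } else if (out$off_start[i] == 0 && out$off_end[i] == 0) {
      out$class[i] <- "exact"
    } else if (out$off_start[i] <= cfg$splice_tolerance_bp &&
               out$off_end[i] <= cfg$splice_tolerance_bp) {
      out$class[i] <- "tolerant"
    } else {
      out$class[i] <- "alt_boundary"
    }
  }
  out
}

# internal: gene-wide annotated boundary positions for one edge side
.side_candidates <- function(model, side = c("start", "end")) {
  side <- match.arg(side)
  if (side == "start") model$ref_starts else model$ref_ends
}

#' Call alternative 5'/3' splice sites
#'
#' Only internal splice-site boundaries are eligible (the isoform's
#' transcription-start and -end edges belong to AP/AT).  A boundary is an
#' event iff its absolute offset to every annotated reference boundary on
#' that side of the gene exceeds the splice tolerance (strict "more than"
#' rule: an offset equal to the tolerance matches the known site).
#'
#' @param matches Output of [match_exons()].
#' @param model A `flat_gene_model`.
#' @param cfg An [iso_config()].
#' @return list with data.frames `A5` and `A3`, columns `exon` (flat
#'   exon index) and `offset` (nt).
#' @export
call_alt_splice_sites <- function(matches, model, cfg = iso_config()) {
  tau <- cfg$splice_tolerance_bp
  fe <- model$exons
  n <- nrow(matches)
  a5 <- a3 <- list()
  starts <- .side_candidates(model, "start")
  ends <- .side_candidates(model, "end")
  for (i in seq_len(n)) {
    if (matches$n_matched[i] == 0) next  # cryptic/novel exons handled as CE/NE
    # genomic start edge is internal unless this is the genomic-first exon;
    # genomic end edge internal unless genomic-last (holds on both strands)
    if (i > 1) {
      off <- min(abs(matches$start[i] - starts))
      if (off > tau) {
        # attribute to the terminal spanned exon owning this edge
        row <- if (matches$n_matched[i] > 1) matches$first_row[i]
               else matches$principal[i]
        entry <- data.frame(exon = fe$index[row], offset = off)
        # '+' strand: start edge = acceptor (A3); '-' strand: donor (A5)
        if (model$strand == "+") a3[[length(a3) + 1]] <- entry
        else a5[[length(a5) + 1]] <- entry
      }
    }
    if (i < n) {
      off <- min(abs(matches$end[i] - ends))
      if (off > tau) {
        row <- if (matches$n_matched[i] > 1) matches$last_row[i]
               else matches$principal[i]
        entry <- data.frame(exon = fe$index[row], offset = off)
        if (model$strand == "+") a5[[length(a5) + 1]] <- entry
        else a3[[length(a3) + 1]] <- entry
      }
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  list(A5 = bind(a5), A3 = bind(a3))
}

#' Call exon skipping
#'
#' A flat exon is skipped iff it lies strictly between the isoform's
#' first and last matched flat exons, no isoform exon overlaps it, and it
#' is not inside any retained-intron span.  Flat exons outside the
#' matched span are never ES (they belong to alternative first/last exon
#' territory).
#'
#' @param matches Output of [match_exons()].
#' @param model A `flat_gene_model`.
#' @return Integer vector of skipped flat exon indices
#'   (transcription order).
#' @export
call_exon_skipping <- function(matches, model) {
  rows <- c(matches$first_row, matches$last_row)
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0) return(integer(0))
  lo <- min(rows); hi <- max(rows)
  if (hi - lo < 2) return(integer(0))
  fe <- model$exons
  cand <- setdiff(seq(lo + 1L, hi - 1L), unlist(
    lapply(which(!is.na(matches$first_row)), function(i)
      seq(matches$first_row[i], matches$last_row[i]))))
  if (length(cand) == 0) return(integer(0))
  # drop candidates overlapped by any isoform exon (incl. partial overlap)
  keep <- vapply(cand, function(r) {
    !any(matches$start < fe$end[r] & fe$start[r] < matches$end)
  }, logical(1))
  sort(fe$index[cand[keep]])
}

#' Call intron retention
#'
#' Every spanning exon match (one isoform exon overlapping two or more
#' flat exons, hence retaining the introns between them) yields one IR
#' event; events on distinct isoform exons are distinct.
#'
#' @param matches Output of [match_exons()].
#' @param model A `flat_gene_model`.
#' @return data.frame with columns `first`, `last` (transcription-order
#'   flat exon indices, first <= last) and `n` (flat exons spanned).
#' @export
call_intron_retention <- function(matches, model) {
  sp <- which(matches$class == "spanning")
  if (length(sp) == 0) {
    return(data.frame(first = integer(0), last = integer(0), n = integer(0)))
  }
  fe <- model$exons
  out <- do.call(rbind, lapply(sp, function(i) {
    idx <- fe$index[seq(matches$first_row[i], matches$last_row[i])]
    data.frame(first = min(idx), last = max(idx), n = length(idx))
  }))
  out[order(out$first), , drop = FALSE]
}

#' Call cryptic and novel exons
#'
#' Cryptic exons (CE) are isoform exons lying wholly within a reference
#' intron with zero overlap to any flat exon; novel exons (NE) lie
#' entirely outside the gene's flattened span and are labeled with their
#' transcription-orientation side.
#'
#' @param matches Output of [match_exons()].
#' @param model A `flat_gene_model`.
#' @return list with data.frames `CE` (`start`, `end`) and `NE`
#'   (`side`, `start`, `end`).
#' @export
call_novel_exons <- function(matches, model) {
  ce <- matches[matches$class == "cryptic", c("start", "end"), drop = FALSE]
  rownames(ce) <- NULL
  nv <- matches[matches$class %in% c("novel_upstream", "novel_downstream"), ,
                drop = FALSE]
  ne <- data.frame(side = sub("novel_", "", nv$class),
                   start = nv$start, end = nv$end)
  list(CE = ce, NE = ne)
}

#' Call alternative first/last exon and promoter/terminator use
#'
#' AF is flagged when the flat exon matched by the isoform's
#' transcription-first exon is never the first exon of any reference
#' transcript, or when that exon is cryptic/novel; AL is the mirrored
#' rule for the last exon.  AP (alternative promoter) is flagged when the
#' isoform TSS lies more than the TSS/TTS window away from every
#' annotated TSS; AT analogously for the TTS.
#'
#' @param matches Output of [match_exons()].
#' @param model A `flat_gene_model`.
#' @param cfg An [iso_config()].
#' @return list with AF, AL, AP, AT flags plus `first_exon`/`last_exon`
#'   (transcription index of the matched terminal flat exons, NA for
#'   cryptic/novel terminal exons).
#' @export
call_first_last <- function(matches, model, cfg = iso_config()) {
  fe <- model$exons
  n <- nrow(matches)
  first_i <- if (model$strand == "+") 1L else n   # transcription-first exon
  last_i <- if (model$strand == "+") n else 1L
  terminal <- function(i, flag) {
    if (matches$n_matched[i] == 0) {
      return(list(alt = TRUE, idx = NA_integer_))
    }
    rng <- seq(matches$first_row[i], matches$last_row[i])
    idx <- if (flag == "first") min(fe$index[rng]) else max(fe$index[rng])
    row <- which(fe$index == idx)
    ok <- if (flag == "first") fe$ever_first[row] else fe$ever_last[row]
    list(alt = !ok, idx = idx)
  }
  f <- terminal(first_i, "first")
  l <- terminal(last_i, "last")
  tss <- if (model$strand == "+") matches$start[1] else matches$end[n]
  tts <- if (model$strand == "+") matches$end[n] else matches$start[1]
  list(
    AF = f$alt, first_exon = f$idx,
    AL = l$alt, last_exon = l$idx,
    AP = min(abs(tss - model$known_tss)) > cfg$tss_tts_window_bp,
    AT = min(abs(tts - model$known_tts)) > cfg$tss_tts_window_bp
  )
}

# internal: junction chain of one transcript's exons (genomic order)
junction_chain <- function(exons) {
  e <- exons[order(exons$start), , drop = FALSE]
  if (nrow(e) < 2) return(matrix(integer(0), ncol = 2))
  cbind(e$end[-nrow(e)], e$start[-1])
}

# internal: is chain q a contiguous sub-chain of chain r?
.is_subchain <- function(q, r) {
  nq <- nrow(q); nr <- nrow(r)
  if (nq > nr) return(FALSE)
  for (s in seq_len(nr - nq + 1)) {
    if (all(r[seq(s, s + nq - 1), , drop = FALSE] == q)) return(TRUE)
  }
  FALSE
}

#' Assign a SQANTI-style structural category
#'
#' FSM (full splice match): the isoform's junction chain exactly equals a
#' reference transcript's chain.  ISM (incomplete splice match): the
#' chain equals a contiguous sub-chain of one reference transcript.
#' NIC (novel in catalog): all donors and acceptors are annotated but the
#' combination is new.  NNC (novel not in catalog): at least one splice
#' site is absent from the annotated donor/acceptor sets.  Category
#' matching uses exact coordinates; the splice tolerance applies only to
#' event labeling.  Mono-exonic isoforms are FSM when contained in a
#' mono-exonic reference transcript's exon, ISM when contained in any
#' reference exon, and otherwise NIC with a `mono_exon` flag (the site
#' test is degenerate without junctions).
#'
#' @param isoform `exon_tbl` rows of one isoform.
#' @param gene `exon_tbl` of the gene's reference transcripts.
#' @param model A `flat_gene_model`.
#' @return list with `category` (FSM/ISM/NIC/NNC), `ref_match`
#'   (reference transcript id for FSM/ISM, else NA) and `mono_exon`.
#' @export
classify_structural_category <- function(isoform, gene, model) {
  iso <- isoform[order(isoform$start), , drop = FALSE]
  tids <- sort(unique(gene$transcript_id))
  if (nrow(iso) == 1) {
    for (tid in tids) {
      e <- transcript_exons(gene, tid)
      if (nrow(e) == 1 && e$start <= iso$start && iso$end <= e$end) {
        return(list(category = "FSM", ref_match = tid, mono_exon = TRUE))
      }
    }
    contained <- any(gene$start <= iso$start & iso$end <= gene$end)
    if (contained) {
      return(list(category = "ISM", ref_match = NA_character_,
                  mono_exon = TRUE))
    }
    return(list(category = "NIC", ref_match = NA_character_,
                mono_exon = TRUE))
  }
  q <- junction_chain(iso)
  chains <- lapply(tids, function(tid) junction_chain(transcript_exons(gene, tid)))
  names(chains) <- tids
  for (tid in tids) {
    r <- chains[[tid]]
    if (nrow(r) == nrow(q) && all(r == q)) {
      return(list(category = "FSM", ref_match = tid, mono_exon = FALSE))
    }
  }
  for (tid in tids) {
    if (.is_subchain(q, chains[[tid]])) {
      return(list(category = "ISM", ref_match = tid, mono_exon = FALSE))
    }
  }
  if (model$strand == "+") {
    donors <- q[, 1]; acceptors <- q[, 2]
  } else {
    donors <- q[, 2]; acceptors <- q[, 1]
  }
  known <- all(donors %in% model$known_donors) &&
    all(acceptors %in% model$known_acceptors)
  list(category = if (known) "NIC" else "NNC",
       ref_match = NA_character_, mono_exon = FALSE)
}

#' Call all alternative-splicing events for one isoform
#'
#' Convenience wrapper running [match_exons()] and every event caller,
#' returning one [as_event_set()].
#'
#' @param isoform `exon_tbl` rows of one isoform.
#' @param model A `flat_gene_model`.
#' @param cfg An [iso_config()].
#' @return An `as_event_set`.
#' @export
call_events <- function(isoform, model, cfg = iso_config()) {
  m <- match_exons(isoform, model, cfg)
  events_from_matches(m, model, cfg, isoform$transcript_id[1])
}

# internal: event calling given precomputed matches
events_from_matches <- function(m, model, cfg, isoform_id) {
  aa <- call_alt_splice_sites(m, model, cfg)
  fl <- call_first_last(m, model, cfg)
  nv <- call_novel_exons(m, model)
  as_event_set(
    isoform_id = isoform_id,
    AF = fl$AF, first_exon = fl$first_exon,
    AL = fl$AL, last_exon = fl$last_exon,
    AP = fl$AP, AT = fl$AT,
    A5 = aa$A5, A3 = aa$A3,
    ES = call_exon_skipping(m, model),
    IR = call_intron_retention(m, model),
    CE = nv$CE, NE = nv$NE
  )
}

#' Characterize all isoforms of a catalog against a reference annotation
#'
#' @param isoforms `exon_tbl` of long-read transcript models (gene ids as
#'   assigned by the upstream collapse/annotation step).
#' @param reference `exon_tbl` of reference transcripts.
#' @param cfg An [iso_config()].
#' @return list with `events` (named list of `as_event_set` per isoform),
#'   `categories` (named list), `models` (per-gene `flat_gene_model`) and
#'   `table` (the per-isoform event table, see [event_table()]).
#' @export
characterize_isoforms <- function(isoforms, reference, cfg = iso_config()) {
  gids <- intersect(unique(isoforms$gene_id), unique(reference$gene_id))
  if (length(gids) == 0) {
    stop("no gene ids shared between isoform and reference annotations")
  }
  events <- list(); categories <- list(); models <- list(); matches <- list()
  for (gid in gids) {
    ref <- gene_exons(reference, gid)
    model <- flatten_gene(ref)
    models[[gid]] <- model
    iso_g <- gene_exons(isoforms, gid)
    for (tid in unique(iso_g$transcript_id)) {
      iso <- transcript_exons(iso_g, tid)
      m <- match_exons(iso, model, cfg)
      matches[[tid]] <- m
      events[[tid]] <- events_from_matches(m, model, cfg, tid)
      categories[[tid]] <- classify_structural_category(iso, ref, model)
    }
  }
  gene_of <- stats::setNames(isoforms$gene_id[!duplicated(isoforms$transcript_id)],
                             isoforms$transcript_id[!duplicated(isoforms$transcript_id)])
  res <- list(events = events, categories = categories, models = models,
              matches = matches, gene_of = gene_of[names(events)])
  res$table <- event_table(res)
  res
}

# compact string encodings used in the flat event table
.enc_pairs <- function(df, cols) {
  if (nrow(df) == 0) return("")
  paste(apply(df[, cols, drop = FALSE], 1, paste, collapse = ":"),
        collapse = ";")
}

#' Flatten characterization results into a per-isoform table
#'
#' @param res Result of [characterize_isoforms()].
#' @return data.frame with one row per isoform: gene, structural
#'   category, reference match, AF/AL/AP/AT flags, A5/A3/ES/IR/CE/NE
#'   event counts and compact encodings.
#' @export
event_table <- function(res) {
  rows <- lapply(names(res$events), function(tid) {
    ev <- res$events[[tid]]
    ct <- res$categories[[tid]]
    data.frame(
      isoform = tid,
      gene = unname(res$gene_of[tid]),
      category = ct$category,
      ref_match = ifelse(is.na(ct$ref_match), "", ct$ref_match),
      mono_exon = ct$mono_exon,
      AF = ev$AF, AL = ev$AL, AP = ev$AP, AT = ev$AT,
      n_A5 = nrow(ev$A5), n_A3 = nrow(ev$A3),
      n_ES = length(ev$ES), n_IR = nrow(ev$IR),
      n_CE = nrow(ev$CE), n_NE = nrow(ev$NE),
      A5 = .enc_pairs(ev$A5, c("exon", "offset")),
      A3 = .enc_pairs(ev$A3, c("exon", "offset")),
      ES = paste(ev$ES, collapse = ";"),
      IR = .enc_pairs(ev$IR, c("first", "last")),
      CE = .enc_pairs(ev$CE, c("start", "end")),
      NE = .enc_pairs(ev$NE, c("side", "start", "end")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a gene's isoform catalog
#'
#' Counts of isoforms and events per type, the known/novel split and the
#' per-exon skip profile.  A5 and A3 are pooled into one A5A3 column.
#' "Known" defaults to FSM-only (the conservative reading); set
#' `known = "fsm_ism"` to count ISM isoforms as known too.
#'
#' @param res Result of [characterize_isoforms()].
#' @param gene Gene id to summarize.
#' @param orf Optional ORF table from [annotate_orfs()] used for the
#'   coding/non-coding split.
#' @param known Either `"fsm"` (default) or `"fsm_ism"`.
#' @return list of class `gene_summary` with elements `summary` (one-row
#'   data.frame) and `skip_profile` (data.frame: exon, n_isoforms_skipping).
#' @export
summarize_gene <- function(res, gene, orf = NULL,
                           known = c("fsm", "fsm_ism")) {
  known <- match.arg(known)
  ids <- names(res$gene_of)[res$gene_of == gene]
  if (length(ids) == 0) stop("no isoforms for gene ", gene)
  evs <- res$events[ids]
  cats <- vapply(res$categories[ids], `[[`, character(1), "category")
  n <- length(ids)
  known_cats <- if (known == "fsm") "FSM" else c("FSM", "ISM")
  n_known <- sum(cats %in% known_cats)
  a5a3_per_iso <- vapply(evs, function(e) nrow(e$A5) + nrow(e$A3), integer(1))
  es_per_iso <- vapply(evs, function(e) length(e$ES), integer(1))
  ir_per_iso <- vapply(evs, function(e) nrow(e$IR), integer(1))
  coding <- if (!is.null(orf)) {
    sum(orf$coding[match(ids, orf$transcript_id)], na.rm = TRUE)
  } else NA_integer_
  summary <- data.frame(
    gene_id = gene,
    n_isoforms = n,
    n_known = n_known,
    n_novel = n - n_known,
    n_coding = coding,
    n_noncoding = if (is.na(coding)) NA_integer_ else n - coding,
    a5a3_isoforms = sum(a5a3_per_iso > 0),
    a5a3_events = sum(a5a3_per_iso),
    a5a3_pct = round(100 * sum(a5a3_per_iso > 0) / n, 1),
    es_isoforms = sum(es_per_iso > 0),
    es_events = sum(es_per_iso),
    es_pct = round(100 * sum(es_per_iso > 0) / n, 1),
    ir_isoforms = sum(ir_per_iso > 0),
    ir_events = sum(ir_per_iso),
    ir_pct = round(100 * sum(ir_per_iso > 0) / n, 1)
  )
  model <- res$models[[gene]]
  idx <- sort(model$exons$index)
  skips <- vapply(idx, function(k)
    sum(vapply(evs, function(e) k %in% e$ES, logical(1))), integer(1))
  structure(list(summary = summary,
                 skip_profile = data.frame(exon = idx,
                                           n_isoforms_skipping = skips)),
            class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Build the isoform-by-exon presence matrix of a gene
#'
#' Each row is an isoform, each column a flat (known) exon in
#' transcription order; cells hold `present`, `skipped`, `IR`
#' (spanned by a retained intron) or `absent` (outside the isoform's
#' span).  Rows are ordered by deterministic average-linkage
#' hierarchical clustering of the binary-expanded state vectors
#' (binary Jaccard distance), with ties broken by isoform id sort, so
#' identical isoforms cluster adjacently.
#'
#' @param res Result of [characterize_isoforms()].
#' @param gene Gene id.
#' @param cfg An [iso_config()].
#' @return Character matrix (isoform x exon) with an `hclust` attribute
#'   when more than two isoforms are present.
#' @export
build_exon_matrix <- function(res, gene, cfg = iso_config()) {
  model <- res$models[[gene]]
  if (is.null(model)) stop("no flattened model for gene ", gene)
  ids <- sort(names(res$gene_of)[res$gene_of == gene])
  fe <- model$exons
  idx <- sort(fe$index)
  states <- matrix("absent", nrow = length(ids), ncol = length(idx),
                   dimnames = list(ids, paste0("exon_", idx)))
  for (tid in ids) {
    ev <- res$events[[tid]]
    m <- res$matches[[tid]]
    for (i in which(!is.na(m$first_row))) {
      rows <- seq(m$first_row[i], m$last_row[i])
      state <- if (m$class[i] == "spanning") "IR" else "present"
      states[tid, match(fe$index[rows], idx)] <- state
    }
    if (length(ev$ES)) states[tid, match(ev$ES, idx)] <- "skipped"
  }
  if (nrow(states) > 2) {
    # binary expansion of the categorical states; base dist(method =
    # "binary") is the Jaccard distance on these indicator vectors
    lv <- c("present", "skipped", "IR")
    bin <- do.call(cbind, lapply(lv, function(s) (states == s) * 1L))
    hc <- stats::hclust(stats::dist(bin, method = "binary"),
                        method = "average")
    states <- states[hc$order, , drop = FALSE]
    attr(states, "hclust") <- hc
  }
  states
}

#' Annotate isoform junctions with short-read support
#'
#' Marks every junction of every multi-exon isoform as supported when at
#' least one uniquely-mapped short read spans it in the supplied
#' junction table (see [read_junction_table()]).
#'
#' @param isoforms `exon_tbl` of transcript models.
#' @param junctions data.frame from [read_junction_table()].
#' @return data.frame with one row per isoform junction: isoform, chrom,
#'   start, end (0-based half-open intron), unique_reads, supported.
#' @export
junction_support <- function(isoforms, junctions) {
  rows <- list()
  for (tid in unique(isoforms$transcript_id)) {
    e <- transcript_exons(isoforms, tid)
    if (nrow(e) < 2) next
    jc <- junction_chain(e)
    rows[[tid]] <- data.frame(isoform = tid, chrom = e$chrom[1],
                              start = jc[, 1], end = jc[, 2],
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(isoform = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      unique_reads = integer(0), supported = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  key <- paste(out$chrom, out$start, out$end)
  jkey <- paste(junctions$chrom, junctions$start, junctions$end)
  hit <- match(key, jkey)
  out$unique_reads <- ifelse(is.na(hit), 0L,
                             as.integer(junctions$unique_reads[hit]))
  out$supported <- out$unique_reads >= 1L
  out
}
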