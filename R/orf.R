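# ---------------------------------------------------------------------------
# ORF prediction, NMD candidacy and protein collapsing.
#
# ORF selection is the longest ATG-initiated open reading frame ending at
# an in-frame stop (5'-most on ties); when no in-frame stop exists before
# the sequence end the ORF runs to the last complete codon with
# has_stop = FALSE.  NMD candidacy follows the canonical 50-nt rule: a
# stop codon ending more than nmd_distance_nt upstream of the last
# exon-exon junction marks the transcript for nonsense-mediated decay.
# ---------------------------------------------------------------------------

#' Spliced transcript sequence from a genome
#'
#' Concatenates exon sequences in transcription order; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param isoform `exon_tbl` rows of one transcript.
#' @param genome A named `DNAStringSet` (or path to a FASTA file).
#' @return Character string with the mRNA sequence.
#' @export
spliced_sequence <- function(isoform, genome) {
  if (is.character(genome) && length(genome) == 1) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  e <- isoform[order(isoform$start), , drop = FALSE]
  chrom <- e$chrom[1]
  if (!chrom %in% names(genome)) {
    stop("chromosome ", chrom, " absent from genome")
  }
  chr <- genome[[chrom]]
  if (max(e$end) > length(chr)) {
    stop("exon beyond chromosome end for ", e$transcript_id[1])
  }
  parts <- lapply(seq_len(nrow(e)), function(i)
    Biostrings::subseq(chr, start = e$start[i] + 1L, end = e$end[i]))
  seq <- do.call(Biostrings::xscat, parts)
  if (e$strand[1] == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

#' Predict the ORF of an mRNA sequence
#'
#' @param mRNA Character mRNA sequence (A/C/G/T).
#' @param transcript_id Optional id carried into the record.
#' @return An `orf_record` list: transcript_id, orf_start, orf_end
#'   (1-based nt, inclusive; length a multiple of 3), protein (amino
#'   acids, stop excluded), has_stop; or NULL when no ATG exists.
#' @export
find_orf <- function(mRNA, transcript_id = NA_character_) {
  s <- toupper(mRNA)
  n <- nchar(s)
  if (n < 3) return(NULL)
  atg <- unlist(gregexpr("ATG", s, fixed = TRUE))
  atg <- atg[atg > 0]
  if (length(atg) == 0) return(NULL)
  # in-frame stop positions per frame (position of the codon's first nt)
  stops_by_frame <- lapply(0:2, function(f) {
    pos <- seq.int(1 + f, n - 2, by = 3)
    if (length(pos) == 0) return(integer(0))
    cod <- substring(s, pos, pos + 2)
    pos[cod %in% c("TAA", "TAG", "TGA")]
  })
  best <- NULL
  for (p in atg) {
    f <- (p - 1) %% 3
    st <- stops_by_frame[[f + 1]]
    st <- st[st > p]  # the ATG itself cannot be a stop; strictly downstream
    if (length(st)) {
      endpos <- min(st) + 2L
      has_stop <- TRUE
    } else {
      endpos <- p + 3L * ((n - p + 1L) %/% 3L) - 1L
      has_stop <- FALSE
    }
    len <- endpos - p + 1L
    if (len < 3) next
    if (is.null(best) || len > best$len ||
        (len == best$len && p < best$start)) {
      best <- list(start = p, end = endpos, len = len, has_stop = has_stop)
    }
  }
  if (is.null(best)) return(NULL)
  cds_end <- if (best$has_stop) best$end - 3L else best$end
  protein <- if (cds_end >= best$start) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, best$start, cds_end))))
  } else ""
  structure(list(
    transcript_id = transcript_id,
    orf_start = best$start,
    orf_end = best$end,
    orf_length = best$len,
    protein = protein,
    has_stop = best$has_stop
  ), class = "orf_record")
}

#' Flag nonsense-mediated decay candidates
#'
#' A transcript is an NMD candidate when its stop codon ends more than
#' `nmd_distance_nt` upstream of the last exon-exon junction (transcript
#' coordinates).  Mono-exonic transcripts and ORFs without stop codons
#' are never candidates.
#'
#' @param orf An `orf_record`.
#' @param exon_lengths Transcript exon lengths in transcription order.
#' @param cfg An [iso_config()].
#' @return list: nmd_candidate, ptc_to_last_junction_nt (signed; NA for
#'   mono-exonic transcripts), mono_exon flag.
#' @export
predict_nmd <- function(orf, exon_lengths, cfg = iso_config()) {
  if (length(exon_lengths) < 2) {
    return(list(nmd_candidate = FALSE,
                ptc_to_last_junction_nt = NA_integer_,
                mono_exon = TRUE))
  }
  if (is.null(orf) || !orf$has_stop) {
    return(list(nmd_candidate = FALSE,
                ptc_to_last_junction_nt = NA_integer_,
                mono_exon = FALSE))
  }
  last_junction <- sum(exon_lengths) - exon_lengths[length(exon_lengths)]
  d <- as.integer(last_junction - orf$orf_end)
  list(nmd_candidate = d > cfg$nmd_distance_nt,
       ptc_to_last_junction_nt = d,
       mono_exon = FALSE)
}

#' Frame effect of cryptic exons on the ORF
#'
#' For each cryptic exon of a transcript: `frameshift` when its length is
#' not a multiple of 3; otherwise `in_frame_with_stop` when the ORF's
#' stop codon falls inside the cryptic exon (the inclusion introduced a
#' premature stop) and `in_frame_no_stop` otherwise.  Cryptic exons
#' wholly outside the ORF are labeled `UTR`.
#'
#' @param isoform `exon_tbl` rows of the transcript.
#' @param ce data.frame of cryptic exon genomic intervals
#'   (`start`, `end`).
#' @param orf The transcript's `orf_record` (may be NULL).
#' @return Character vector of labels, one per cryptic exon.
#' @export
cryptic_exon_frame <- function(isoform, ce, orf) {
  if (nrow(ce) == 0) return(character(0))
  e <- isoform[order(isoform$start), , drop = FALSE]
  widths <- e$end - e$start
  # transcript-coordinate start of each exon, transcription order
  ord <- if (e$strand[1] == "+") seq_len(nrow(e)) else rev(seq_len(nrow(e)))
  tx_start <- stats::setNames(cumsum(c(0, widths[ord][-length(ord)])), ord)
  vapply(seq_len(nrow(ce)), function(j) {
    k <- which(e$start == ce$start[j] & e$end == ce$end[j])
    if (length(k) != 1) {
      stop("cryptic exon not found among transcript exons")
    }
    len <- widths[k]
    pos <- unname(tx_start[as.character(k)])
    ce_tx <- c(pos + 1L, pos + len)           # 1-based transcript interval
    if (is.null(orf) || ce_tx[1] > orf$orf_end || ce_tx[2] < orf$orf_start) {
      return("UTR")
    }
    if (len %% 3 != 0) return("frameshift")
    stop_in_ce <- orf$has_stop &&
      orf$orf_end - 2L >= ce_tx[1] && orf$orf_end <= ce_tx[2]
    if (stop_in_ce) "in_frame_with_stop" else "in_frame_no_stop"
  }, character(1))
}

#' Predict ORFs, coding status and NMD for a transcript catalog
#'
#' @param isoforms `exon_tbl` of transcript models.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param cfg An [iso_config()].
#' @param coding_scores Optional named numeric vector of external
#'   coding-potential scores; when supplied, coding is score >
#'   `coding_score_threshold`, otherwise coding means an ORF with a stop
#'   codon was found.
#' @return data.frame per transcript: transcript_id, n_exons, orf_start,
#'   orf_end, orf_length, protein, has_stop, ptc_to_last_junction_nt,
#'   nmd_candidate, coding, coding_call.
#' @export
annotate_orfs <- function(isoforms, genome, cfg = iso_config(),
                          coding_scores = NULL) {
  if (is.character(genome) && length(genome) == 1) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  tids <- unique(isoforms$transcript_id)
  rows <- lapply(tids, function(tid) {
    e <- transcript_exons(isoforms, tid)
    seq <- spliced_sequence(e, genome)
    orf <- find_orf(seq, tid)
    widths <- e$end - e$start
    ord <- if (e$strand[1] == "+") seq_len(nrow(e)) else rev(seq_len(nrow(e)))
    nmd <- predict_nmd(orf, widths[ord], cfg)
    if (!is.null(coding_scores)) {
      sc <- coding_scores[tid]
      coding <- !is.na(sc) && sc > cfg$coding_score_threshold
      call <- "external_score"
    } else {
      coding <- !is.null(orf) && orf$has_stop
      call <- if (coding) "coding" else "noncoding"
    }
    data.frame(
      transcript_id = tid,
      n_exons = nrow(e),
      orf_start = if (is.null(orf)) NA_integer_ else orf$orf_start,
      orf_end = if (is.null(orf)) NA_integer_ else orf$orf_end,
      orf_length = if (is.null(orf)) 0L else orf$orf_length,
      protein = if (is.null(orf)) "" else orf$protein,
      has_stop = !is.null(orf) && orf$has_stop,
      ptc_to_last_junction_nt = nmd$ptc_to_last_junction_nt,
      nmd_candidate = nmd$nmd_candidate,
      coding = coding,
      coding_call = call,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse coding transcripts to unique protein isoforms
#'
#' Transcripts predicted to produce an identical protein sequence
#' collapse into one group whose representative is the most abundant
#' transcript (ties broken by id).  Transcripts without a stop codon are
#' excluded from collapsing and reported separately.
#'
#' @param orfs ORF table from [annotate_orfs()].
#' @param abundance Named numeric vector of per-transcript total reads.
#' @param categories Optional named character vector of structural
#'   categories used for the redundant-transcript breakdown.
#' @return list: `groups` (data.frame protein, n_members, representative,
#'   members), `accounting` (n_coding, n_unique_proteins, n_redundant,
#'   n_no_stop and, when categories are given, redundant_by_category).
#' @export
collapse_proteins <- function(orfs, abundance, categories = NULL) {
  eligible <- orfs[orfs$coding & orfs$has_stop & nzchar(orfs$protein), ,
                   drop = FALSE]
  no_stop <- orfs$transcript_id[orfs$coding & !orfs$has_stop]
  groups <- lapply(split(eligible, eligible$protein), function(g) {
    ab <- abundance[g$transcript_id]
    ab[is.na(ab)] <- 0
    o <- order(-ab, g$transcript_id)
    data.frame(protein = g$protein[1],
               n_members = nrow(g),
               representative = g$transcript_id[o[1]],
               members = paste(sort(g$transcript_id), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, groups)
  if (is.null(groups)) {
    groups <- data.frame(protein = character(0), n_members = integer(0),
                         representative = character(0),
                         members = character(0))
  }
  rownames(groups) <- NULL
  n_coding <- nrow(eligible)
  n_unique <- nrow(groups)
  acc <- list(n_coding = n_coding,
              n_unique_proteins = n_unique,
              n_redundant = n_coding - n_unique,
              n_no_stop = length(no_stop))
  if (!is.null(categories) && acc$n_redundant > 0) {
    redundant <- setdiff(eligible$transcript_id, groups$representative)
    acc$redundant_by_category <- table(categories[redundant],
                                       useNA = "ifany")
  }
  list(groups = groups, accounting = acc)
}

#' Write protein groups as FASTA
#'
#' The representative's header carries the member count.
#'
#' @param groups Group table from [collapse_proteins()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(groups, path) {
  if (nrow(groups) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  aa <- Biostrings::AAStringSet(groups$protein)
  names(aa) <- sprintf("%s n_members=%d", groups$representative,
                       groups$n_members)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
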