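# Shared fixtures and independent brute-force oracles.

# Reference gene "G": four exons at 1-based 101-200, 301-400, 501-600,
# 701-800 on '+', with transcript T1 covering all four exons and T2
# skipping exon 2 (so the skip junction 200/500 is annotated).
# Internal coordinates are 0-based half-open.
gene_G <- function(strand = "+") {
  starts <- c(100L, 300L, 500L, 700L)
  ends <- c(200L, 400L, 600L, 800L)
  t2 <- c(1L, 3L, 4L)
  exon_table(
    chrom = "chr1",
    start = c(starts, starts[t2]),
    end = c(ends, ends[t2]),
    strand = strand,
    transcript_id = c(rep("T1", 4), rep("T2", 3)),
    gene_id = "G"
  )
}

iso_G <- function(starts, ends, id = "q1", strand = "+") {
  exon_table(chrom = "chr1", start = starts, end = ends, strand = strand,
             transcript_id = id, gene_id = "G")
}

# brute-force interval union: repeated pairwise merging until stable
merge_oracle <- function(starts, ends) {
  iv <- unique(data.frame(start = starts, end = ends))
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(iv))) {
      for (j in seq_len(nrow(iv))) {
        if (i >= j) next
        if (iv$start[i] < iv$end[j] && iv$start[j] < iv$end[i]) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv <- iv[order(iv$start), ]
  rownames(iv) <- NULL
  iv
}

# brute-force structural category oracle: enumerate every contiguous
# sub-chain of every reference transcript and look the query up
category_oracle <- function(iso, ref) {
  enc_chain <- function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) return(character(0))
    sprintf("%d/%d", e$end[-nrow(e)], e$start[-1])
  }
  tids <- sort(unique(ref$transcript_id))
  iso <- iso[order(iso$start), , drop = FALSE]
  if (nrow(iso) == 1) {
    mono_fsm <- any(vapply(tids, function(tid) {
      e <- ref[ref$transcript_id == tid, ]
      nrow(e) == 1 && e$start <= iso$start && iso$end <= e$end
    }, logical(1)))
    if (mono_fsm) return("FSM")
    if (any(ref$start <= iso$start & iso$end <= ref$end)) return("ISM")
    return("NIC")
  }
  q <- enc_chain(iso)
  full <- list(); subs <- character(0)
  for (tid in tids) {
    ch <- enc_chain(ref[ref$transcript_id == tid, ])
    full[[tid]] <- ch
    for (a in seq_along(ch)) for (b in a:length(ch)) {
      subs <- c(subs, paste(ch[a:b], collapse = ","))
    }
  }
  qs <- paste(q, collapse = ",")
  if (any(vapply(full, function(ch) identical(paste(ch, collapse = ","), qs),
                 logical(1)))) return("FSM")
  if (qs %in% subs) return("ISM")
  strand <- iso$strand[1]
  e <- iso
  left <- e$end[-nrow(e)]; right <- e$start[-1]
  rl <- unlist(lapply(tids, function(tid) {
    r <- ref[ref$transcript_id == tid, ]
    r <- r[order(r$start), ]
    if (nrow(r) < 2) return(NULL) else r$end[-nrow(r)]
  }))
  rr <- unlist(lapply(tids, function(tid) {
    r <- ref[ref$transcript_id == tid, ]
    r <- r[order(r$start), ]
    if (nrow(r) < 2) return(NULL) else r$start[-1]
  }))
  if (all(left %in% rl) && all(right %in% rr)) "NIC" else "NNC"
}

# exhaustive three-frame ORF scanner (codon walk from every ATG)
orf_oracle <- function(s) {
  n <- nchar(s)
  best <- NULL
  for (p in seq_len(max(0, n - 2))) {
    if (substr(s, p, p + 2) != "ATG") next
    q <- p; endpos <- NA; has <- FALSE
    while (q + 2 <= n) {
      cod <- substr(s, q, q + 2)
      if (q > p && cod %in% c("TAA", "TAG", "TGA")) {
        endpos <- q + 2; has <- TRUE; break
      }
      q <- q + 3
    }
    if (!has) endpos <- p + 3 * ((n - p + 1) %/% 3) - 1
    len <- endpos - p + 1
    if (len >= 3 && (is.null(best) || len > best$len)) {
      best <- list(start = p, end = endpos, len = len, has_stop = has)
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
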