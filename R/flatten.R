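# ---------------------------------------------------------------------------
# Flattened gene models
#
# All reference transcripts of a gene are merged into a single set of
# non-overlapping "flat" exons, numbered in transcription order
# (exon 1 = 5'-most).  Overlapping reference exons with different
# boundaries collapse into one flat exon whose interval is their union;
# each distinct (start, end) pair is kept as a "variant" so that
# alternative splice-site calls can be made against true annotated
# boundaries rather than the union.
# ---------------------------------------------------------------------------

#' Flatten a gene's reference transcripts into a numbered exon model
#'
#' @param gene An `exon_tbl` data.frame holding the reference exons of a
#'   single gene (one or more transcripts, one strand/chromosome).
#' @return A `flat_gene_model`: a list with the merged exon table
#'   (`exons`, genomic order, with transcription-order `index`,
#'   `ever_first`/`ever_last` flags and variant counts), per-exon
#'   `variants` (matrices of distinct reference boundary pairs), the
#'   catalogs of known donors, acceptors, junctions, TSSs and TTSs, the
#'   pooled reference boundary sets, and the gene span.
#' @details Transcription start/termination sites are recorded as the
#'   5'/3' transcript end coordinates in the internal 0-based half-open
#'   convention (`+` strand TSS = first exon start; `-` strand TSS =
#'   last exon end).  Reference transcripts occupying disjoint loci
#'   under one gene id are still flattened jointly (with a warning).
#' @export
flatten_gene <- function(gene) {
  if (is.null(gene) || nrow(gene) == 0) stop("cannot flatten an empty gene")
  strand <- unique(gene$strand)
  chrom <- unique(gene$chrom)
  if (length(strand) > 1 || length(chrom) > 1) {
    stop("gene spans multiple strands/chromosomes: ", gene$gene_id[1])
  }
  gid <- gene$gene_id[1]

  # union of overlapping reference exons (adjacency is not merged)
  ir <- IRanges::IRanges(start = gene$start + 1L, end = gene$end)
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  fstart <- IRanges::start(red) - 1L
  fend <- IRanges::end(red)
  nflat <- length(red)
  if (nflat > 1) {
    gaps <- fstart[-1] - fend[-nflat]
    # disjoint loci heuristic: all transcripts confined to one block is
    # impossible to detect from exons alone; warn on extreme gaps only
    # when no transcript bridges them
    tspan <- do.call(rbind, lapply(split(gene, gene$transcript_id), function(e)
      c(min(e$start), max(e$end))))
    for (g in which(gaps > 0)) {
      bridge <- any(tspan[, 1] < fend[g] & tspan[, 2] > fstart[g + 1])
      if (!bridge && gaps[g] > 1e6) {
        warning("reference transcripts of ", gid,
                " occupy disjoint loci; flattening jointly")
        break
      }
    }
  }

  # assign each reference exon to its flat exon
  hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
  stopifnot(length(hit) == nrow(gene))
  fe_of_exon <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]

  variants <- lapply(seq_len(nflat), function(k) {
    v <- unique(gene[fe_of_exon == k, c("start", "end")])
    as.matrix(v[order(v$start, v$end), , drop = FALSE])
  })

  # per-transcript terminal exons -> ever_first / ever_last, TSS/TTS
  tids <- unique(gene$transcript_id)
  ever_first <- ever_last <- logical(nflat)
  tss <- tts <- integer(0)
  donors <- acceptors <- integer(0)
  junctions <- matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("left", "right")))
  for (tid in tids) {
    e <- transcript_exons(gene, tid)
    rows <- fe_of_exon[which(gene$transcript_id == tid)[order(
      gene$start[gene$transcript_id == tid])]]
    if (strand == "+") {
      ever_first[rows[1]] <- TRUE
      ever_last[rows[length(rows)]] <- TRUE
      tss <- c(tss, e$start[1])
      tts <- c(tts, e$end[nrow(e)])
    } else {
      ever_first[rows[length(rows)]] <- TRUE
      ever_last[rows[1]] <- TRUE
      tss <- c(tss, e$end[nrow(e)])
      tts <- c(tts, e$start[1])
    }
    if (nrow(e) > 1) {
      j <- cbind(left = e$end[-nrow(e)], right = e$start[-1])
      junctions <- rbind(junctions, j)
      if (strand == "+") {
        donors <- c(donors, j[, "left"])
        acceptors <- c(acceptors, j[, "right"])
      } else {
        donors <- c(donors, j[, "right"])
        acceptors <- c(acceptors, j[, "left"])
      }
    }
  }

  index <- if (strand == "+") seq_len(nflat) else rev(seq_len(nflat))
  exons <- data.frame(
    index = index,
    start = fstart,
    end = fend,
    ever_first = ever_first,
    ever_last = ever_last,
    n_variants = vapply(variants, nrow, integer(1))
  )

  structure(list(
    gene_id = gid,
    chrom = chrom,
    strand = strand,
    exons = exons,
    variants = variants,
    known_donors = sort(unique(donors)),
    known_acceptors = sort(unique(acceptors)),
    known_junctions = unique(junctions),
    known_tss = sort(unique(tss)),
    known_tts = sort(unique(tts)),
    ref_starts = sort(unique(gene$start)),
    ref_ends = sort(unique(gene$end)),
    span = c(min(fstart), max(fend)),
    n_transcripts = length(tids)
  ), class = "flat_gene_model")
}

#' @export
print.flat_gene_model <- function(x, ...) {
  cat(sprintf("flat gene model %s (%s%s): %d exons from %d transcripts\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), x$n_transcripts))
  invisible(x)
}

#' Locate a genomic position relative to a flattened gene model
#'
#' @param model A `flat_gene_model`.
#' @param pos Integer genomic position (0-based).
#' @return A list with `region` (one of `"exon"`, `"intron"`,
#'   `"upstream"`, `"downstream"`) and, for exonic/intronic hits, the
#'   transcription-order exon index (`exon`) or flanking indices
#'   (`between`).  Upstream/downstream are in transcription orientation.
#' @export
classify_position <- function(model, pos) {
  ex <- model$exons
  if (pos < model$span[1]) {
    side <- if (model$strand == "+") "upstream" else "downstream"
    return(list(region = side))
  }
  if (pos >= model$span[2]) {
    side <- if (model$strand == "+") "downstream" else "upstream"
    return(list(region = side))
  }
  k <- which(ex$start <= pos & pos < ex$end)
  if (length(k) == 1) return(list(region = "exon", exon = ex$index[k]))
  r <- max(which(ex$end <= pos))  # genomic row left of pos
  ks <- sort(c(ex$index[r], ex$index[r + 1]))
  list(region = "intron", between = ks)
}

#' Export a flattened model as a single-transcript GTF
#'
#' All flat exons are written under one synthetic transcript
#' (`<gene>.flattened`) so the model can be viewed as a browser track.
#'
#' @param model A `flat_gene_model`.
#' @param path Output GTF path.
#' @return The path, invisibly.
#' @export
flat_model_to_gtf <- function(model, path) {
  tab <- exon_table(
    chrom = model$chrom,
    start = model$exons$start,
    end = model$exons$end,
    strand = model$strand,
    transcript_id = paste0(model$gene_id, ".flattened"),
    gene_id = model$gene_id
  )
  write_gtf(tab, path)
}

#' Tabulate a flattened model
#'
#' @param model A `flat_gene_model`.
#' @return data.frame with one row per flat exon: gene, exon index
#'   (transcription order), chrom, start, end, n_variants, ever_first,
#'   ever_last.
#' @export
flat_model_to_table <- function(model) {
  ex <- model$exons
  out <- data.frame(
    gene = model$gene_id,
    exon = ex$index,
    chrom = model$chrom,
    start = ex$start,
    end = ex$end,
    n_variants = ex$n_variants,
    ever_first = ex$ever_first,
    ever_last = ex$ever_last
  )
  out[order(out$exon), , drop = FALSE]
}
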