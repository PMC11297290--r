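#' @importFrom methods as is
#' @importFrom S4Vectors mcols
NULL

# ---------------------------------------------------------------------------
# Exon tables
#
# Transcript models are held as plain data.frames of exons with columns
#   chrom, start, end, strand, transcript_id, gene_id
# Coordinates are 0-based half-open internally; GTF/BED files are read and
# written in their native conventions (GTF 1-based inclusive, BED 0-based
# half-open).  Exons are stored sorted by (transcript_id, start).
# ---------------------------------------------------------------------------

#' Build an exon table
#'
#' Low-level constructor for the internal transcript representation: a
#' data.frame of exons in 0-based half-open coordinates, sorted by
#' transcript and genomic start, validated for per-transcript consistency
#' (single chromosome and strand, non-overlapping exons).
#'
#' @param chrom,start,end,strand,transcript_id,gene_id Per-exon vectors.
#'   `start`/`end` are 0-based half-open.
#' @return A data.frame of class `exon_tbl`.
#' @export
exon_table <- function(chrom, start, end, strand, transcript_id, gene_id) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    stringsAsFactors = FALSE
  )
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop("exon with start >= end for transcript ", df$transcript_id[bad])
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (tid in unique(df$transcript_id)) {
    e <- df[df$transcript_id == tid, ]
    if (length(unique(e$chrom)) > 1 || length(unique(e$strand)) > 1) {
      stop("transcript on mixed strands/chromosomes rejected: ", tid)
    }
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("overlapping exons within transcript: ", tid)
    }
  }
  class(df) <- c("exon_tbl", "data.frame")
  df
}

#' Extract one transcript's exons in genomic order
#'
#' @param x An `exon_tbl` data.frame.
#' @param tid Transcript id.
#' @return The exon rows of that transcript, sorted by start.
#' @export
transcript_exons <- function(x, tid) {
  e <- x[x$transcript_id == tid, , drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

# internal: exon rows of one gene
gene_exons <- function(x, gid) {
  x[x$gene_id == gid, , drop = FALSE]
}

# internal: sniff GTF2 vs GFF3 attribute dialect
.sniff_gff_format <- function(path) {
  ln <- readLines(path, n = 200L, warn = FALSE)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (length(ln) == 0) return("gtf")
  attrs <- vapply(strsplit(ln, "\t", fixed = TRUE),
                  function(f) if (length(f) >= 9) f[9] else "", character(1))
  if (any(grepl("\"", attrs))) "gtf" else if (any(grepl("=", attrs))) "gff3" else "gtf"
}

#' Read transcript models from a GTF/GFF file
#'
#' Exon features are grouped per transcript (sorted by genomic start) and,
#' for reference input, per gene.  Both GTF2 (`key "value";`) and GFF3
#' (`key=value`) attribute dialects are accepted.  On-disk coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention.
#'
#' @param path Path to a GTF or GFF3 file with exon features carrying
#'   `transcript_id` and `gene_id` (or `Parent`/`gene`) attributes.
#' @param source Either `"reference"` or `"long_read"`; recorded as an
#'   attribute on the returned table.
#' @return An `exon_tbl` data.frame (see [exon_table()]) with attribute
#'   `source`.
#' @export
read_gtf <- function(path, source = c("reference", "long_read")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  body <- !grepl("^#", raw) & nzchar(trimws(raw))
  nfield <- vapply(strsplit(raw[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfield < 8)) {
    stop("malformed GTF line ", which(body)[which(nfield < 8)[1]],
         " in ", path, " (fewer than 8 fields)")
  }
  fmt <- .sniff_gff_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features found in ", path)
  mc <- S4Vectors::mcols(gr)
  tid <- if ("transcript_id" %in% names(mc)) {
    as.character(mc$transcript_id)
  } else if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) as.character(p)[1], character(1))
  } else stop("exon features lack transcript_id/Parent attributes in ", path)
  gid <- if ("gene_id" %in% names(mc)) {
    as.character(mc$gene_id)
  } else if ("gene" %in% names(mc)) {
    as.character(mc$gene)
  } else stop("exon features lack gene_id attributes in ", path)
  if (anyNA(tid) || anyNA(gid)) stop("exon with missing transcript/gene id in ", path)
  tab <- exon_table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = tid,
    gene_id = gid
  )
  # a transcript must map to exactly one gene
  tg <- unique(tab[, c("transcript_id", "gene_id")])
  dup <- tg$transcript_id[duplicated(tg$transcript_id)]
  if (length(dup)) stop("transcript assigned to multiple genes: ",
                        paste(unique(dup), collapse = ", "))
  attr(tab, "source") <- source
  tab
}

#' Write transcript models to GTF
#'
#' Emits one `transcript` feature and its `exon` features per transcript,
#' in the native GTF convention (1-based inclusive).
#'
#' @param transcripts An `exon_tbl` data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  x <- transcripts[order(transcripts$gene_id, transcripts$transcript_id,
                         transcripts$start), , drop = FALSE]
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                      x$gene_id, x$transcript_id)
  exon_lines <- paste(x$chrom, "isochar", "exon", x$start + 1L, x$end, ".",
                      x$strand, ".", attr_str, sep = "\t")
  tx <- do.call(rbind, lapply(split(x, x$transcript_id), function(e) {
    data.frame(chrom = e$chrom[1], start = min(e$start), end = max(e$end),
               strand = e$strand[1], transcript_id = e$transcript_id[1],
               gene_id = e$gene_id[1], stringsAsFactors = FALSE)
  }))
  tx <- tx[order(tx$gene_id, tx$transcript_id), , drop = FALSE]
  tx_lines <- paste(tx$chrom, "isochar", "transcript", tx$start + 1L, tx$end,
                    ".", tx$strand, ".",
                    sprintf('gene_id "%s"; transcript_id "%s";',
                            tx$gene_id, tx$transcript_id), sep = "\t")
  ord <- order(c(tx$transcript_id, x$transcript_id),
               c(rep(0L, nrow(tx)), rep(1L, nrow(x))),
               c(tx$start, x$start))
  writeLines(c(tx_lines, exon_lines)[ord], path)
  invisible(path)
}

#' Write transcript models as BED12
#'
#' One BED12 line per transcript; block starts are relative to
#' `chromStart`.  `read_bed12(write_bed12(x))` reproduces `x` exactly.
#'
#' @param transcripts An `exon_tbl` data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed12 <- function(transcripts, path) {
  sp <- split(transcripts, transcripts$transcript_id)
  rows <- lapply(sp, function(e) {
    e <- e[order(e$start), , drop = FALSE]
    cs <- min(e$start)
    data.frame(
      chrom = e$chrom[1], start = cs, end = max(e$end),
      name = e$transcript_id[1], score = 0L, strand = e$strand[1],
      thickStart = cs, thickEnd = max(e$end), rgb = "0,0,0",
      blockCount = nrow(e),
      blockSizes = paste0(paste(e$end - e$start, collapse = ","), ","),
      blockStarts = paste0(paste(e$start - cs, collapse = ","), ","),
      stringsAsFactors = FALSE
    )
  })
  bed <- do.call(rbind, rows)
  bed <- bed[order(bed$chrom, bed$start, bed$name), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript models from a BED12 file
#'
#' @param path BED12 path.
#' @return An `exon_tbl` data.frame (gene ids default to transcript ids).
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  if (is.null(blocks)) {  # single-exon-only BED without block columns
    blocks <- IRanges::IRangesList(lapply(seq_along(gr), function(i)
      IRanges::IRanges(1L, GenomicRanges::width(gr)[i])))
  }
  n <- S4Vectors::elementNROWS(blocks)
  chrom <- rep(as.character(GenomicRanges::seqnames(gr)), n)
  strand <- rep(as.character(GenomicRanges::strand(gr)), n)
  name <- rep(gr$name, n)
  offs <- rep(GenomicRanges::start(gr) - 1L, n)  # 0-based chromStart
  bl <- unlist(blocks)
  exon_table(
    chrom = chrom,
    start = offs + IRanges::start(bl) - 1L,
    end = offs + IRanges::end(bl),
    strand = strand,
    transcript_id = name,
    gene_id = name
  )
}

#' Read a full-length read count table
#'
#' First column holds isoform ids, remaining columns one sample each.
#' The delimiter is auto-detected from the extension (`.csv` vs tab).
#' Counts must be non-negative integers; duplicate isoform ids and
#' missing cells are rejected.
#'
#' @param path Path to the counts table.
#' @return An integer matrix (isoforms x samples) with isoform row names.
#' @export
read_counts <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts table needs an id column plus >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate isoform id in counts table: ",
         ids[duplicated(ids)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    cell <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    stop("non-numeric count at isoform ", ids[cell],
         ", sample ", colnames(df)[bad + 1])
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing count at isoform ", ids[idx[1]],
         ", sample ", colnames(m)[idx[2]])
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative count at isoform ", ids[idx[1]],
         ", sample ", colnames(m)[idx[2]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a counts matrix
#'
#' @param counts Matrix with isoform row names.
#' @param path Output path (`.csv` for comma-separated, else tab).
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(isoform = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata sheet
#'
#' Tab-separated with at least columns `sample` and `group`; an optional
#' `age` column is kept when present.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with columns sample, group (factor) and,
#'   optionally, age.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group")
  if (!all(need %in% names(df))) {
    stop("sample sheet must contain columns: ", paste(need, collapse = ", "))
  }
  df$group <- factor(df$group)
  df
}

#' Read a splice-junction support table
#'
#' STAR `SJ.out.tab`-like layout: chromosome, 1-based intron start,
#' 1-based intron end, strand code (0 undefined / 1 `+` / 2 `-`), then
#' (for the 9-column STAR layout) intron motif, annotation flag,
#' uniquely-mapped read count.  A minimal 5-column layout
#' (chrom, start, end, strand, unique reads) is also accepted.
#'
#' @param path Path to the junction table.
#' @return data.frame with columns chrom, start, end (0-based half-open
#'   intron), strand, unique_reads.
#' @export
read_junction_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 9) {
    out <- df[, c(1, 2, 3, 4, 7)]
  } else if (ncol(df) >= 5) {
    out <- df[, 1:5]
  } else stop("junction table needs >= 5 columns")
  names(out) <- c("chrom", "start", "end", "strand", "unique_reads")
  out$strand <- ifelse(out$strand %in% c(1, "+"), "+",
                       ifelse(out$strand %in% c(2, "-"), "-", "*"))
  out$start <- as.integer(out$start) - 1L  # to 0-based half-open intron
  out$end <- as.integer(out$end)
  out
}

#' Read TSS-evidence peaks from a BED file
#'
#' @param path BED path (e.g. CAGE peaks).
#' @return data.frame with chrom, start, end (0-based half-open), strand.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read an external coding-potential score table
#'
#' Two-column TSV: transcript id, coding-potential score.
#'
#' @param path Path to the score table.
#' @return Named numeric vector of scores.
#' @export
read_coding_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("coding score table needs two columns")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
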