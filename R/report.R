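# ---------------------------------------------------------------------------
# End-to-end runs and the run manifest.  These are the programmatic
# equivalents of the command-line entry points in exec/isochar.
# ---------------------------------------------------------------------------

# internal: md5-checksummed manifest of inputs, outputs and configuration
.write_manifest <- function(path, inputs, outputs, cfg, stages) {
  sum_files <- function(files) {
    files <- files[!vapply(files, is.null, logical(1))]
    lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  }
  manifest <- list(
    tool = "isochar",
    version = as.character(utils::packageVersion("isochar")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    inputs = sum_files(inputs),
    outputs = sum_files(outputs),
    stages = stages
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Characterize a long-read isoform catalog end to end
#'
#' Reads the reference and isoform GTFs, flattens every shared gene,
#' calls all alternative-splicing events and structural categories, and
#' writes the per-isoform event table, per-gene summaries, per-gene
#' exon-presence matrices, the flattened-model tables, optionally the
#' ORF/NMD table (when a genome is given), and a checksummed run
#' manifest.
#'
#' @param ref_gtf Path to the reference annotation GTF.
#' @param iso_gtf Path to the long-read transcript GTF.
#' @param counts Optional path to a full-length count table (used for
#'   the coding-representative ordering and carried into the summary).
#' @param genome Optional FASTA path enabling ORF/NMD annotation.
#' @param cfg An [iso_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, a list with the characterization result, summary
#'   table, optional ORF table and output file paths.
#' @export
run_characterize <- function(ref_gtf, iso_gtf, counts = NULL, genome = NULL,
                             cfg = iso_config(), outdir) {
  reference <- read_gtf(ref_gtf, source = "reference")
  isoforms <- read_gtf(iso_gtf, source = "long_read")
  if (nrow(isoforms) == 0) stop("no isoforms in ", iso_gtf)
  shared <- intersect(unique(isoforms$gene_id), unique(reference$gene_id))
  if (length(shared) == 0) {
    stop("no gene ids shared between isoform and reference annotations")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cnt <- if (!is.null(counts)) read_counts(counts) else NULL

  res <- characterize_isoforms(isoforms, reference, cfg)
  orf <- NULL
  if (!is.null(genome)) {
    orf <- annotate_orfs(isoforms[isoforms$gene_id %in% shared, ],
                         genome, cfg)
  }
  summaries <- do.call(rbind, lapply(shared, function(g)
    summarize_gene(res, g, orf = orf)$summary))
  skip_profiles <- do.call(rbind, lapply(shared, function(g) {
    sp <- summarize_gene(res, g, orf = orf)$skip_profile
    cbind(gene = g, sp)
  }))

  files <- list(events = file.path(outdir, "isoform_events.tsv"),
                summary = file.path(outdir, "gene_summary.tsv"),
                skip_profile = file.path(outdir, "exon_skip_profile.tsv"),
                flat_models = file.path(outdir, "flattened_models.tsv"))
  wt <- function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(res$table, files$events)
  wt(summaries, files$summary)
  wt(skip_profiles, files$skip_profile)
  wt(do.call(rbind, lapply(res$models, flat_model_to_table)),
     files$flat_models)
  for (g in shared) {
    f <- file.path(outdir, sprintf("exon_matrix_%s.tsv", g))
    m <- build_exon_matrix(res, g, cfg)
    utils::write.table(data.frame(isoform = rownames(m), m,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[paste0("exon_matrix_", g)]] <- f
  }
  if (!is.null(orf)) {
    files$orf <- file.path(outdir, "orf_nmd.tsv")
    wt(orf, files$orf)
  }
  files$manifest <- file.path(outdir, "manifest.json")
  n_iso <- length(res$events)
  message("characterized ", n_iso, " isoforms across ", length(shared),
          " genes")
  for (g in shared) {
    message("  ", g, ": ", sum(res$gene_of == g), " isoforms")
  }
  .write_manifest(files$manifest,
                  inputs = list(ref_gtf = ref_gtf, iso_gtf = iso_gtf,
                                counts = counts, genome = genome),
                  outputs = files[names(files) != "manifest"],
                  cfg = cfg,
                  stages = list(n_genes = length(shared),
                                n_isoforms = n_iso,
                                n_orf = if (is.null(orf)) 0L else nrow(orf)))
  invisible(list(result = res, summary = summaries, orf = orf,
                 files = files))
}

#' Quantification workflow: filter, normalize, fractions, DTU
#'
#' Applies the rare-transcript filter, normalizes (median-of-ratios),
#' aggregates gene-level counts from the pre-filter matrix, computes
#' isoform fractions, the dominant/major sets, the minor-isoform filter
#' and per-gene DTU metrics with BH-adjusted permutation p-values, and
#' (when an event table is supplied) per-event-type abundance burdens.
#'
#' @param counts Count matrix or path.
#' @param metadata Sample sheet data.frame or path (columns sample,
#'   group; optional age).
#' @param gene_map Named vector isoform -> gene.
#' @param cfg An [iso_config()].
#' @param outdir Output directory.
#' @param events Optional event table from [characterize_isoforms()]
#'   (`$table`) for IR/CE burden summaries.
#' @param orf Optional ORF table for the NMD burden summary.
#' @param n_permutations Permutations for the DTU test.
#' @return Invisibly, a list of all computed tables and file paths.
#' @export
run_quantify <- function(counts, metadata, gene_map, cfg = iso_config(),
                         outdir, events = NULL, orf = NULL,
                         n_permutations = 999) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(metadata)) metadata <- read_sample_sheet(metadata)
  missing_meta <- setdiff(colnames(counts), metadata$sample)
  if (length(missing_meta)) {
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  extra <- setdiff(metadata$sample, colnames(counts))
  if (length(extra)) {
    stop("unknown sample in metadata: ", paste(extra, collapse = ", "))
  }
  metadata <- metadata[match(colnames(counts), metadata$sample), ]
  groups <- droplevels(factor(metadata$group))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  gene_counts <- gene_level_counts(counts, gene_map)  # pre-filter, by design
  flt <- filter_rare(counts, cfg)
  norm <- normalize_counts(flt$counts)
  ift <- isoform_fractions(norm, gene_map, groups)
  dm <- dominant_and_major(ift, cfg)
  retained <- minor_isoform_filter(ift, cfg)

  dtu <- NULL
  if (nlevels(groups) == 2 && all(table(groups) >= 2)) {
    dtu <- dtu_metrics(ift, groups, cfg, n_permutations = n_permutations,
                       isoforms = retained)
    dtu$p_adj <- stats::p.adjust(dtu$permutation_p, method = "BH")
  } else {
    warning("DTU skipped: need two groups with >= 2 samples each")
  }

  burdens <- NULL
  if (!is.null(events) || !is.null(orf)) {
    carrier_sets <- list()
    if (!is.null(events)) {
      carrier_sets$IR <- events$isoform[events$n_IR > 0]
      carrier_sets$CE <- events$isoform[events$n_CE > 0]
    }
    if (!is.null(orf)) {
      carrier_sets$NMD <- orf$transcript_id[orf$nmd_candidate]
    }
    if (nlevels(groups) == 2) {
      burdens <- do.call(rbind, lapply(names(carrier_sets), function(ty) {
        ids <- intersect(carrier_sets[[ty]], rownames(norm))
        per_gene <- split(ids, gene_map[ids])
        do.call(rbind, lapply(names(per_gene), function(g) {
          b <- event_burden_by_group(norm, per_gene[[g]], groups)
          data.frame(gene = g, event = ty,
                     n_isoforms = length(per_gene[[g]]),
                     log2fc = b$log2fc, stringsAsFactors = FALSE)
        }))
      }))
    }
  }

  files <- list(filtered = file.path(outdir, "counts_filtered.tsv"),
                normalized = file.path(outdir, "counts_normalized.tsv"),
                gene_counts = file.path(outdir, "gene_counts.tsv"),
                fractions = file.path(outdir, "isoform_fractions.tsv"),
                dominant = file.path(outdir, "dominant_major.tsv"))
  write_counts(flt$counts, files$filtered)
  utils::write.table(data.frame(isoform = rownames(norm),
                                round(norm, 4), check.names = FALSE),
                     files$normalized, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(gene_counts), gene_counts,
                                check.names = FALSE),
                     files$gene_counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(isoform = rownames(ift$IF),
                                gene = ift$gene,
                                mean_if = round(ift$mean_if, 6),
                                round(ift$IF, 6), check.names = FALSE),
                     files$fractions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dm, files$dominant, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dtu)) {
    files$dtu <- file.path(outdir, "dtu_results.tsv")
    utils::write.table(dtu, files$dtu, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(burdens)) {
    files$burden <- file.path(outdir, "event_burden.tsv")
    utils::write.table(burdens, files$burden, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  files$manifest <- file.path(outdir, "manifest.json")
  .write_manifest(files$manifest, inputs = list(),
                  outputs = files[names(files) != "manifest"],
                  cfg = cfg,
                  stages = list(n_detected = flt$n_detected,
                                n_removed = flt$n_removed,
                                pct_removed = flt$pct_removed,
                                n_retained_minor_filter = length(retained)))
  invisible(list(filter = flt, normalized = norm, gene_counts = gene_counts,
                 fractions = ift, dominant = dm, retained = retained,
                 dtu = dtu, burdens = burdens, files = files))
}
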