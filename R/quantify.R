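# ---------------------------------------------------------------------------
# Filtering, normalization, isoform fractions and differential transcript
# usage metrics for full-length read count matrices.
# ---------------------------------------------------------------------------

#' Filter rare transcripts
#'
#' Default semantics: a transcript is retained iff the sum of its
#' `rare_n_samples` largest per-sample counts reaches `rare_min_reads`
#' ("count >= 10 across any five samples").  The alternative
#' per-sample semantics (`semantics = "per_sample"`) instead requires at
#' least `rare_n_samples` samples to each reach `rare_min_reads`.
#' With fewer samples than `rare_n_samples` the rule uses all samples
#' and warns.
#'
#' @param counts Integer matrix (isoforms x samples).
#' @param cfg An [iso_config()].
#' @param semantics `"top_sum"` (default) or `"per_sample"`.
#' @return list with `counts` (retained rows), `removed` (dropped ids),
#'   `n_removed`, `n_detected` and `pct_removed` (one decimal).
#' @export
filter_rare <- function(counts, cfg = iso_config(),
                        semantics = c("top_sum", "per_sample")) {
  semantics <- match.arg(semantics)
  k <- cfg$rare_n_samples
  if (ncol(counts) < k) {
    warning("fewer samples (", ncol(counts), ") than rare_n_samples (",
            k, "); using all samples")
    k <- ncol(counts)
  }
  keep <- if (semantics == "top_sum") {
    apply(counts, 1, function(x)
      sum(sort(x, decreasing = TRUE)[seq_len(k)]) >= cfg$rare_min_reads)
  } else {
    apply(counts, 1, function(x) sum(x >= cfg$rare_min_reads) >= k)
  }
  removed <- rownames(counts)[!keep]
  list(counts = counts[keep, , drop = FALSE],
       removed = removed,
       n_removed = length(removed),
       n_detected = nrow(counts),
       pct_removed = round(100 * length(removed) / nrow(counts), 1))
}

#' Normalize a count matrix
#'
#' `cpm`: size factor = column sum / 1e6 (counts per million).
#' `median_of_ratios`: the DESeq-style factor, the per-sample median of
#' count-to-geometric-mean ratios over rows without zeros.
#' Normalized value = count / factor.
#'
#' @param counts Matrix (isoforms x samples).
#' @param method `"median_of_ratios"` (default) or `"cpm"`.
#' @return Numeric matrix of normalized counts with attributes
#'   `size_factors` and `method`.
#' @export
normalize_counts <- function(counts,
                             method = c("median_of_ratios", "cpm")) {
  method <- match.arg(method)
  if (method == "cpm") {
    sf <- colSums(counts) / 1e6
  } else {
    eligible <- rowSums(counts == 0) == 0
    if (!any(eligible)) {
      stop("no rows without zeros; cannot estimate median-of-ratios factors")
    }
    lgm <- rowMeans(log(counts[eligible, , drop = FALSE]))
    sf <- apply(counts[eligible, , drop = FALSE], 2, function(col)
      stats::median(exp(log(col) - lgm)))
  }
  if (any(sf <= 0)) stop("non-positive size factor estimated")
  out <- sweep(counts, 2, sf, "/")
  attr(out, "size_factors") <- sf
  attr(out, "method") <- method
  out
}

#' Per-sample and per-group isoform fractions
#'
#' The isoform fraction (IF) is each isoform's normalized count divided
#' by the summed normalized counts of all isoforms of its gene.  Samples
#' in which a gene has zero total get undefined (NA) fractions and are
#' excluded from group means.
#'
#' @param norm_counts Normalized (or, explicitly, raw) count matrix.
#' @param gene_map Named character vector isoform -> gene covering all
#'   rows.
#' @param groups Optional factor of per-sample group labels (length =
#'   ncol) used for group-mean IFs.
#' @return list of class `if_table`: `IF` (isoform x sample matrix, NA
#'   where undefined), `gene` (per-row gene), `mean_if` (grand mean per
#'   isoform over defined samples), `group_mean` (isoform x group matrix
#'   when groups given), `groups`.
#' @export
isoform_fractions <- function(norm_counts, gene_map, groups = NULL) {
  ids <- rownames(norm_counts)
  if (is.null(ids)) stop("counts must carry isoform row names")
  gene <- unname(gene_map[ids])
  if (anyNA(gene)) {
    stop("isoforms without gene assignment: ",
         paste(utils::head(ids[is.na(gene)], 5), collapse = ", "))
  }
  totals <- rowsum(norm_counts, gene)               # gene x sample
  tot_per_row <- totals[gene, , drop = FALSE]
  IF <- norm_counts / tot_per_row
  IF[tot_per_row == 0] <- NA_real_
  group_mean <- NULL
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(norm_counts))
    group_mean <- vapply(levels(groups), function(g)
      rowMeans(IF[, groups == g, drop = FALSE], na.rm = TRUE),
      numeric(nrow(IF)))
  }
  structure(list(IF = IF, gene = gene,
                 mean_if = rowMeans(IF, na.rm = TRUE),
                 group_mean = group_mean, groups = groups),
            class = "if_table")
}

#' Dominant and major isoforms per gene
#'
#' The dominant isoform has the maximal mean IF (ties broken by
#' lexicographic isoform id and logged); major isoforms are those whose
#' mean IF relative to the dominant strictly exceeds `major_fraction`
#' (the dominant is always major).
#'
#' @param ift An `if_table` from [isoform_fractions()].
#' @param cfg An [iso_config()].
#' @param group Optional group level: use that group's mean IFs instead
#'   of the grand mean.
#' @return data.frame per gene: gene, dominant, n_major, major
#'   (`;`-separated ids), tie (logical).
#' @export
dominant_and_major <- function(ift, cfg = iso_config(), group = NULL) {
  mif <- if (is.null(group)) ift$mean_if else ift$group_mean[, group]
  ids <- rownames(ift$IF)
  out <- lapply(split(seq_along(ids), ift$gene), function(ix) {
    v <- mif[ix]; nm <- ids[ix]
    o <- order(-v, nm)
    dom <- nm[o[1]]
    tie <- sum(v == max(v)) > 1
    if (tie) message("dominant-isoform tie in gene ",
                     ift$gene[ix[1]], "; lexicographic break")
    rel <- v / v[o[1]]
    major <- nm[rel > cfg$major_fraction | nm == dom]
    data.frame(gene = ift$gene[ix[1]], dominant = dom,
               n_major = length(major),
               major = paste(sort(major), collapse = ";"),
               tie = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Pre-DTU minor isoform filter
#'
#' Retains, per gene, the isoforms whose mean IF relative to the dominant
#' isoform strictly exceeds `minor_filter_fc` (the dominant always
#' retained).
#'
#' @param ift An `if_table`.
#' @param cfg An [iso_config()].
#' @return Character vector of retained isoform ids.
#' @export
minor_isoform_filter <- function(ift, cfg = iso_config()) {
  ids <- rownames(ift$IF)
  keep <- unlist(lapply(split(seq_along(ids), ift$gene), function(ix) {
    v <- ift$mean_if[ix]; nm <- ids[ix]
    o <- order(-v, nm)
    dom <- nm[o[1]]
    rel <- v / v[o[1]]
    nm[(rel > cfg$minor_filter_fc & v > 0) | nm == dom]
  }), use.names = FALSE)
  sort(keep)
}

# internal: DTU metrics for one gene's IF matrix (isoform x sample)
.dtu_one <- function(ifm, ga, gb, n_perm, seed) {
  mean_cols <- function(m, idx) {
    if (anyNA(m)) rowMeans(m[, idx, drop = FALSE], na.rm = TRUE)
    else rowMeans(m[, idx, drop = FALSE])
  }
  ma <- mean_cols(ifm, ga); mb <- mean_cols(ifm, gb)
  total_change <- 100 * 0.5 * sum(abs(ma - mb))
  ids <- rownames(ifm)
  dom <- function(v) ids[order(-v, ids)[1]]
  podium <- dom(ma) != dom(mb)
  perm_p <- NA_real_
  if (n_perm > 0) {
    ns <- ncol(ifm)
    na_ <- length(ga)
    stat <- with_seed(seed, {
      if (anyNA(ifm)) {
        vapply(seq_len(n_perm), function(p) {
          ix <- sample.int(ns, na_)
          100 * 0.5 * sum(abs(mean_cols(ifm, ix) -
                                mean_cols(ifm, setdiff(seq_len(ns), ix))))
        }, numeric(1))
      } else {
        # indicator-matrix trick: one matrix product for all permutations
        W <- vapply(seq_len(n_perm), function(p) {
          w <- numeric(ns); w[sample.int(ns, na_)] <- 1 / na_
          w
        }, numeric(ns))
        MA <- ifm %*% W
        MB <- (rowSums(ifm) - MA * na_) / (ns - na_)
        100 * 0.5 * colSums(abs(MA - MB))
      }
    })
    perm_p <- (1 + sum(stat >= total_change)) / (1 + n_perm)
  }
  list(total_change = total_change, podium_change = podium,
       permutation_p = perm_p)
}

#' Differential transcript usage metrics
#'
#' For each gene, quantifies the redistribution of expression across its
#' isoforms between two groups: `total_change` is 100 times half the L1
#' distance between the group-mean IF vectors (0-100 percentage points);
#' `podium_change` flags a switch of the dominant isoform between groups;
#' `permutation_p` is the label-shuffling permutation p-value
#' `(1 + #>=obs) / (1 + n_permutations)` of total change.
#'
#' The total-change metric is this package's documented measure of
#' isoform-usage redistribution (a half-L1 distance), not a re-derivation
#' of any external tool's internals.
#'
#' @param ift An `if_table` built with per-sample IFs.
#' @param groups Factor of length ncol with exactly two levels.
#' @param cfg An [iso_config()]; `random_seed` seeds the permutations.
#' @param n_permutations Number of label permutations (0 skips the test).
#' @param isoforms Optional subset of isoform ids (e.g. after
#'   [minor_isoform_filter()]).
#' @return data.frame per gene: gene, n_isoforms, total_change,
#'   podium_change, permutation_p.
#' @export
dtu_metrics <- function(ift, groups, cfg = iso_config(),
                        n_permutations = 999, isoforms = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("DTU requires exactly two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])
  ids <- rownames(ift$IF)
  keep <- if (is.null(isoforms)) rep(TRUE, length(ids)) else ids %in% isoforms
  out <- lapply(unique(ift$gene), function(g) {
    ix <- which(ift$gene == g & keep)
    if (length(ix) == 0) return(NULL)
    ifm <- ift$IF[ix, , drop = FALSE]
    # renormalize within the retained isoform set so fractions sum to 1
    tot <- colSums(ifm)
    ifm <- sweep(ifm, 2, ifelse(tot > 0, tot, NA_real_), "/")
    r <- .dtu_one(ifm, ga, gb, n_permutations,
                  derive_seed(cfg$random_seed, match(g, unique(ift$gene))))
    data.frame(gene = g, n_isoforms = length(ix),
               total_change = r$total_change,
               podium_change = r$podium_change,
               permutation_p = r$permutation_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate isoform counts to gene level
#'
#' Gene expression is the sum of full-length read counts over all
#' isoforms of the gene, computed on the *pre-filter* matrix
#' (aggregation precedes rare-transcript filtering).
#'
#' @param counts Pre-filter count matrix (isoforms x samples).
#' @param gene_map Named vector isoform -> gene.
#' @return Matrix gene x sample.
#' @export
gene_level_counts <- function(counts, gene_map) {
  ids <- rownames(counts)
  gene <- unname(gene_map[ids])
  if (anyNA(gene)) {
    stop("isoforms without gene assignment: ",
         paste(utils::head(ids[is.na(gene)], 5), collapse = ", "))
  }
  rowsum(counts, gene)
}

#' Cumulative read proportion across isoforms
#'
#' Isoforms sorted by total reads (descending, ties by id) with the
#' cumulative fraction of the grand total; the last value is 1.
#'
#' @param counts Count matrix.
#' @return data.frame: isoform, total, cumulative_proportion.
#' @export
cumulative_read_proportion <- function(counts) {
  tot <- rowSums(counts)
  if (sum(tot) == 0) stop("all-zero count matrix")
  o <- order(-tot, rownames(counts))
  data.frame(isoform = rownames(counts)[o],
             total = tot[o],
             cumulative_proportion = cumsum(tot[o]) / sum(tot),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detection overlap between two isoform catalogs
#'
#' @param ids_a,ids_b Character vectors of detected isoform ids.
#' @return list: unique_a, unique_b, common, fold_change
#'   (= (unique_a+common)/(unique_b+common), two decimals), jaccard.
#' @export
detection_overlap <- function(ids_a, ids_b) {
  ids_a <- unique(ids_a); ids_b <- unique(ids_b)
  if (length(ids_a) == 0 && length(ids_b) == 0) {
    stop("both id sets are empty")
  }
  common <- length(intersect(ids_a, ids_b))
  ua <- length(setdiff(ids_a, ids_b))
  ub <- length(setdiff(ids_b, ids_a))
  list(unique_a = ua, unique_b = ub, common = common,
       fold_change = round((ua + common) / (ub + common), 2),
       jaccard = common / (ua + ub + common))
}

#' Per-group abundance burden of event-carrying isoforms
#'
#' Sums the normalized abundance of all isoforms carrying a given event
#' (e.g. IR, CE or NMD flags) per sample, and reports the between-group
#' log2 fold change with a pseudocount of 1.
#'
#' @param norm_counts Normalized count matrix.
#' @param carrier_ids Isoform ids carrying the event.
#' @param groups Two-level factor of per-sample groups; the fold change
#'   is level 2 over level 1.
#' @return list: `burden` (per-sample sums), `log2fc`.
#' @export
event_burden_by_group <- function(norm_counts, carrier_ids, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("burden log2FC requires two groups")
  sel <- rownames(norm_counts) %in% carrier_ids
  burden <- if (any(sel)) colSums(norm_counts[sel, , drop = FALSE])
            else stats::setNames(numeric(ncol(norm_counts)),
                                 colnames(norm_counts))
  ma <- mean(burden[groups == levels(groups)[1]])
  mb <- mean(burden[groups == levels(groups)[2]])
  list(burden = burden, log2fc = log2((mb + 1) / (ma + 1)))
}
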