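#' Analysis configuration
#'
#' Bundles all tunable thresholds of the characterization and
#' quantification workflow.  Defaults follow the conventions of deep
#' targeted long-read transcriptome studies.
#'
#' @param splice_tolerance_bp Maximum distance (bp) from an annotated
#'   splice site at which an observed internal exon boundary is still
#'   treated as matching that site.  A boundary is called an alternative
#'   5'/3' splice site only when it differs by *more than* this value
#'   from every annotated site ("more than 10 bp" convention).
#' @param tss_tts_window_bp Window (bp) around annotated transcription
#'   start/termination sites within which an isoform 5'/3' end is
#'   considered supported; beyond it an alternative promoter (AP) /
#'   terminator (AT) is flagged.
#' @param rare_min_reads Minimum summed full-length read count for the
#'   rare-transcript filter (see [filter_rare()]).
#' @param rare_n_samples Number of samples over which the rare-transcript
#'   rule is evaluated.
#' @param major_fraction An isoform is "major" when its mean isoform
#'   fraction relative to the dominant isoform exceeds this value
#'   (strict `>`).
#' @param minor_filter_fc Fold-change threshold of the pre-DTU minor
#'   isoform filter (relative proportion to the dominant isoform).
#' @param nmd_distance_nt A stop codon ending more than this many nt
#'   upstream of the last exon-exon junction marks the transcript as a
#'   nonsense-mediated-decay candidate (canonical 50-nt rule).
#' @param coding_score_threshold When an external coding-potential score
#'   table is supplied, transcripts with score greater than this value
#'   are called coding (CPAT mouse recommendation).
#' @param random_seed Seed used for all stochastic steps (permutation
#'   tests, simulation).
#'
#' @return An object of class `iso_config` (a validated list).
#' @examples
#' cfg <- iso_config()
#' cfg$splice_tolerance_bp
#' @export
iso_config <- function(splice_tolerance_bp = 10L,
                       tss_tts_window_bp = 50L,
                       rare_min_reads = 10L,
                       rare_n_samples = 5L,
                       major_fraction = 0.5,
                       minor_filter_fc = 0.5,
                       nmd_distance_nt = 50L,
                       coding_score_threshold = 0.44,
                       random_seed = 1L) {
  cfg <- list(
    splice_tolerance_bp = as.integer(splice_tolerance_bp),
    tss_tts_window_bp = as.integer(tss_tts_window_bp),
    rare_min_reads = as.integer(rare_min_reads),
    rare_n_samples = as.integer(rare_n_samples),
    major_fraction = as.numeric(major_fraction),
    minor_filter_fc = as.numeric(minor_filter_fc),
    nmd_distance_nt = as.integer(nmd_distance_nt),
    coding_score_threshold = as.numeric(coding_score_threshold),
    random_seed = as.integer(random_seed)
  )
  num <- vapply(cfg, function(x) x >= 0, logical(1))
  if (!all(num)) {
    stop("all configuration thresholds must be >= 0: ",
         paste(names(cfg)[!num], collapse = ", "))
  }
  if (cfg$major_fraction <= 0 || cfg$major_fraction > 1) {
    stop("major_fraction must lie in (0, 1]")
  }
  structure(cfg, class = "iso_config")
}

#' @export
print.iso_config <- function(x, ...) {
  cat("isochar configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key=value`); `#` starts a
#' comment.  Unknown keys are rejected.  Values override the
#' [iso_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return An `iso_config` object.
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  defaults <- iso_config()
  vals <- list()
  for (l in ln) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed configuration line: ", l)
    key <- trimws(kv[1])
    if (!key %in% names(defaults)) stop("unknown configuration key: ", key)
    vals[[key]] <- as.numeric(trimws(kv[2]))
  }
  do.call(iso_config, utils::modifyList(unclass(defaults), vals))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so simulations are reproducible without side
#' effects.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stream-specific seed from a master seed
#'
#' Deterministic mixing of a master seed with a stream index, keeping
#' the result inside the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param i Stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}
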