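## The de novo variant discovery filter cascade. All printed thresholds are
## strict inequalities: QUAL > 30, DP > 9, GQ > 30, AF > 0.1, het allele
## ratio < 0.2 excluded, SV length > 200 and < 5000. Canonical stage order:
## quality -> repeats -> known -> het-ratio -> callable -> secondary.

#' Filter configuration
#'
#' Defaults encode the audit's published thresholds. Quality retention is
#' QUAL > \code{min_qual - 0}... precisely: \code{qual > 30}, \code{depth >=
#' min_dp} (DP > 9), \code{gq > 30}, \code{af > 0.1}; heterozygous records
#' with alt-allele ratio below \code{het_ratio_floor} are excluded; repeat
#' intervals are padded by \code{repeat_pad} on both sides; variants seen in
#' \code{shared_min_samples} or more distinct samples are eliminated; SVs
#' must be called by \code{sv_min_callers}+ programs with
#' \code{sv_min_reads}+ supporting reads and length strictly between
#' \code{sv_min_len} and \code{sv_max_len}.
#'
#' @param min_qual,min_dp,min_gq,min_af small-variant quality thresholds.
#' @param het_ratio_floor exclusive lower bound on the het allele ratio.
#' @param repeat_pad bases of padding around repeat intervals.
#' @param shared_min_samples distinct-sample count at which a variant is
#'   treated as shared.
#' @param sv_min_callers,sv_min_reads,sv_min_len,sv_max_len SV consensus
#'   thresholds (length bounds exclusive).
#' @param known_match \code{"tuple"} (contig/pos/ref/alt after
#'   left-normalization; default) or \code{"position"} for positional-only
#'   known-variant matching.
#' @param sv_breakpoint_tol tolerance (bp) per breakpoint when matching SVs
#'   across samples.
#' @return a list of class \code{cas9audit_filter_config}.
#' @export
filterConfig <- function(min_qual = 30, min_dp = 10L, min_gq = 30,
                         min_af = 0.1, het_ratio_floor = 0.2,
                         repeat_pad = 2L, shared_min_samples = 2L,
                         sv_min_callers = 2L, sv_min_reads = 3L,
                         sv_min_len = 200L, sv_max_len = 5000L,
                         known_match = c("tuple", "position"),
                         sv_breakpoint_tol = 100L) {
  known_match <- match.arg(known_match)
  stopifnot(min_qual >= 0, min_dp >= 0, min_gq >= 0, min_af >= 0,
            het_ratio_floor >= 0, repeat_pad >= 0, shared_min_samples >= 1,
            sv_min_callers >= 1, sv_min_reads >= 0,
            sv_min_len < sv_max_len)
  structure(list(min_qual = min_qual, min_dp = as.integer(min_dp),
                 min_gq = min_gq, min_af = min_af,
                 het_ratio_floor = het_ratio_floor,
                 repeat_pad = as.integer(repeat_pad),
                 shared_min_samples = as.integer(shared_min_samples),
                 sv_min_callers = as.integer(sv_min_callers),
                 sv_min_reads = as.integer(sv_min_reads),
                 sv_min_len = as.integer(sv_min_len),
                 sv_max_len = as.integer(sv_max_len),
                 known_match = known_match,
                 sv_breakpoint_tol = as.integer(sv_breakpoint_tol)),
            class = "cas9audit_filter_config")
}

.stage_rows <- function(variants, keep, stage) {
  samples <- unique(variants$sample_id)
  if (length(samples) == 0L)
    return(data.frame(stage = character(0), sample_id = character(0),
                      n_in = integer(0), n_removed = integer(0),
                      n_out = integer(0), stringsAsFactors = FALSE))
  n_in <- table(factor(variants$sample_id, levels = samples))
  n_out <- table(factor(variants$sample_id[keep], levels = samples))
  data.frame(stage = stage, sample_id = samples,
             n_in = as.integer(n_in),
             n_removed = as.integer(n_in) - as.integer(n_out),
             n_out = as.integer(n_out), stringsAsFactors = FALSE)
}

.primary_stage_order <- c("quality", "repeats", "known", "het_ratio")

#' Primary small-variant filter
#'
#' Applies, in order: (1) quality thresholds (strict inequalities); (2)
#' removal of variants whose reference span intersects any repeat interval
#' padded by \code{repeat_pad}; (3) removal of variants present in the
#' known-variant set (identity tuples after left-normalization, or
#' positional matching per config); (4) removal of heterozygous variants
#' whose alt-allele ratio \code{ad_alt/(ad_ref+ad_alt)} is below
#' \code{het_ratio_floor} (records lacking AD fall back to \code{af};
#' records lacking both are retained with a warning).
#'
#' @param variants variant table across samples (see
#'   \code{\link{validateVariants}}).
#' @param known known-variant table (or NULL to skip stage 3).
#' @param repeats \code{GRanges} of repeat intervals (or NULL to skip).
#' @param config a \code{\link{filterConfig}}.
#' @param genome optional \code{DNAStringSet} for left-normalizing the
#'   known set and the variants before tuple matching.
#' @return list with \code{variants} (survivors) and \code{report}
#'   (\linkS4class{FilterReport}).
#' @export
primaryFilter <- function(variants, known = NULL, repeats = NULL,
                          config = filterConfig(), genome = NULL) {
  validateVariants(variants)
  report <- list()

  # stage 1: quality (strict, as printed; min_dp = 10 encodes DP > 9)
  keep <- !is.na(variants$qual) & variants$qual > config$min_qual &
    !is.na(variants$depth) & variants$depth >= config$min_dp &
    !is.na(variants$gq) & variants$gq > config$min_gq &
    !is.na(variants$af) & variants$af > config$min_af
  report$quality <- .stage_rows(variants, keep, "quality")
  variants <- variants[keep, , drop = FALSE]

  # stage 2: padded repeat overlap (any overlap removes)
  if (!is.null(repeats) && length(repeats)) {
    padded <- suppressWarnings(
      GenomicRanges::resize(repeats,
                            GenomicRanges::width(repeats) +
                              2L * config$repeat_pad, fix = "center"))
    padded <- GenomicRanges::trim(padded)
    hit <- GenomicRanges::countOverlaps(variantRanges(variants), padded) > 0L
  } else hit <- rep(FALSE, nrow(variants))
  report$repeats <- .stage_rows(variants, !hit, "repeats")
  variants <- variants[!hit, , drop = FALSE]

  # stage 3: known-variant removal
  if (!is.null(known) && nrow(known)) {
    if (config$known_match == "tuple") {
      knorm <- normalizeVariants(known, genome)
      vnorm <- normalizeVariants(variants, genome)
      inknown <- variantKey(vnorm) %in% variantKey(knorm)
    } else {
      inknown <- paste(variants$contig, variants$pos) %in%
        paste(known$contig, known$pos)
    }
  } else inknown <- rep(FALSE, nrow(variants))
  report$known <- .stage_rows(variants, !inknown, "known")
  variants <- variants[!inknown, , drop = FALSE]

  # stage 4: het allele-ratio floor
  ratio <- ifelse(!is.na(variants$ad_ref) & !is.na(variants$ad_alt) &
                    (variants$ad_ref + variants$ad_alt) > 0,
                  variants$ad_alt / (variants$ad_ref + variants$ad_alt),
                  variants$af)
  het <- variants$genotype == "het"
  noinfo <- het & is.na(ratio)
  if (any(noinfo))
    warning(sum(noinfo), " het record(s) lack both AD and AF; ",
            "allele-ratio rule not applied to them")
  lowratio <- het & !is.na(ratio) & ratio < config$het_ratio_floor
  report$het_ratio <- .stage_rows(variants, !lowratio, "het_ratio")
  variants <- variants[!lowratio, , drop = FALSE]

  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  list(variants = variants,
       report = FilterReport(rep_df, .primary_stage_order))
}

#' Intersection of per-sample callable intervals
#'
#' Returns the interval set common to all samples. A sample with no
#' callable intervals empties the intersection (with a warning).
#'
#' @param callable_sets named list of per-sample \code{GRanges}.
#' @return a \code{GRanges}.
#' @export
callableIntersection <- function(callable_sets) {
  if (length(callable_sets) == 0L) stop("need at least one sample")
  empty <- vapply(callable_sets, function(g) length(g) == 0L, logical(1))
  if (any(empty))
    warning("sample(s) with no callable intervals: ",
            paste(names(callable_sets)[empty], collapse = ", "),
            "; intersection is empty")
  Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE),
    callable_sets)
}

#' Restrict variants to an interval set
#'
#' Removes any variant whose full reference span is not contained in the
#' given intervals (a variant partially outside callable space is not
#' confidently callable in every sample).
#'
#' @param variants variant table.
#' @param intervals \code{GRanges}, typically from
#'   \code{\link{callableIntersection}}.
#' @return list with \code{variants} and \code{report}.
#' @export
applyCallableFilter <- function(variants, intervals) {
  within <- GenomicRanges::countOverlaps(variantRanges(variants),
                                         GenomicRanges::reduce(intervals),
                                         type = "within") > 0L
  rep_df <- .stage_rows(variants, within, "callable")
  list(variants = variants[within, , drop = FALSE],
       report = FilterReport(rep_df, "callable"))
}

#' Secondary filter: eliminate variants observed in two or more samples
#'
#' Builds identity tuples across all samples and removes, from every
#' sample, any tuple seen in \code{shared_min_samples} or more distinct
#' samples. A tuple occurring twice within one sample (e.g. from a split
#' multi-allelic row) counts once.
#'
#' @param variants variant table across samples (post primary filter).
#' @param config a \code{\link{filterConfig}}.
#' @return list with \code{variants} (the per-sample unique variants),
#'   \code{shared} (the removed shared tuple table) and \code{report}.
#' @export
secondaryFilter <- function(variants, config = filterConfig()) {
  key <- variantKey(variants)
  nsamp <- tapply(variants$sample_id, key,
                  function(s) length(unique(s)))
  shared_keys <- names(nsamp)[nsamp >= config$shared_min_samples]
  keep <- !(key %in% shared_keys)
  rep_df <- .stage_rows(variants, keep, "secondary")
  list(variants = variants[keep, , drop = FALSE],
       shared = unique(variants[!keep, c("contig", "pos", "ref", "alt"),
                                drop = FALSE]),
       report = FilterReport(rep_df, "secondary"))
}

.sv_stage_order <- c("genotype", "consensus", "support", "length", "shared")

#' Structural-variant consensus filter
#'
#' Removes records with missing or hom-ref genotypes, then requires at
#' least \code{sv_min_callers} independent callers, \code{sv_min_reads}
#' supporting reads, and a length strictly between \code{sv_min_len} and
#' \code{sv_max_len}. Finally removes SVs shared between samples:
#' breakpoint-pair matching, both breakpoints within
#' \code{sv_breakpoint_tol}, same svtype, strand ignored.
#'
#' @param svs SV table across samples (see \code{\link{validateSVs}}).
#' @param config a \code{\link{filterConfig}}.
#' @return list with \code{svs} (survivors) and \code{report}.
#' @export
svConsensusFilter <- function(svs, config = filterConfig()) {
  validateSVs(svs)
  report <- list()

  keep <- svs$genotype %in% c("het", "hom_alt")
  report$genotype <- .stage_rows(svs, keep, "genotype")
  svs <- svs[keep, , drop = FALSE]

  ncall <- vapply(strsplit(svs$callers, ",", fixed = TRUE), function(x)
    length(unique(trimws(x[nzchar(x)]))), integer(1))
  nocall <- is.na(svs$callers) | ncall == 0L
  if (any(nocall))
    message(sum(nocall), " SV record(s) without caller annotation removed ",
            "(cannot establish consensus)")
  keep <- !nocall & ncall >= config$sv_min_callers
  report$consensus <- .stage_rows(svs, keep, "consensus")
  svs <- svs[keep, , drop = FALSE]

  keep <- !is.na(svs$support_reads) &
    svs$support_reads >= config$sv_min_reads
  report$support <- .stage_rows(svs, keep, "support")
  svs <- svs[keep, , drop = FALSE]

  keep <- svs$sv_length > config$sv_min_len &
    svs$sv_length < config$sv_max_len
  report$length <- .stage_rows(svs, keep, "length")
  svs <- svs[keep, , drop = FALSE]

  # shared-SV removal across samples (breakpoint-pair matching)
  shared <- rep(FALSE, nrow(svs))
  if (nrow(svs) > 1L) {
    tol <- config$sv_breakpoint_tol
    for (i in seq_len(nrow(svs))) {
      match_other <- svs$svtype == svs$svtype[i] &
        svs$contig == svs$contig[i] &
        svs$sample_id != svs$sample_id[i] &
        abs(svs$start - svs$start[i]) <= tol &
        abs(svs$end - svs$end[i]) <= tol
      if (any(match_other)) shared[i] <- TRUE
    }
  }
  report$shared <- .stage_rows(svs, !shared, "shared")
  svs <- svs[!shared, , drop = FALSE]

  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  list(svs = svs, report = FilterReport(rep_df, .sv_stage_order))
}
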