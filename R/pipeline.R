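## End-to-end orchestration and headline-ratio reporting.

# round half up to d decimals (printed ratios use half-up, not banker's)
.round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d

#' Format a percentage the way the audit reports print it
#'
#' Below 1\%: three decimals; 1-10\%: one decimal; 10\% and above: integer.
#' Rates (e.g. validated variants per founder) print with one decimal.
#' Rounding is half-up.
#'
#' @param x percentage value (already on the 0-100 scale).
#' @return character.
#' @export
formatPercent <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return("0.0")
    if (v < 1) sprintf("%.3f", .round_half_up(v, 3L))
    else if (v < 10) sprintf("%.1f", .round_half_up(v, 1L))
    else sprintf("%.0f", .round_half_up(v, 0L))
  }, character(1))
}

#' @rdname formatPercent
#' @export
formatRate <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    sprintf("%.1f", .round_half_up(v, 1L))
  }, character(1))
}

#' Compute headline ratios from audit counts
#'
#' Completes an \linkS4class{AuditSummary} from raw counts: each ratio is
#' \code{100 * numerator / denominator} (percent) or
#' \code{numerator / denominator} (rate), with the formatted rendering used
#' in reports. Zero denominators yield an undefined (NA) ratio, never 0.
#' Counts may come from a pipeline run or from a user-supplied counts
#' table (e.g. an external audit's published counts).
#'
#' @param counts named numeric vector or single-row data.frame/list.
#'   Recognized names: \code{n_guides}, \code{n_founders},
#'   \code{n_predicted_sites}, \code{n_sites_with_variants},
#'   \code{n_hits}, \code{n_validated}, \code{founders_with_hits},
#'   \code{founders_with_validated}, \code{guides_with_validated},
#'   \code{n_hits_nongenic}, \code{founders_confirmed}. Unknown names are
#'   carried through.
#' @return an \linkS4class{AuditSummary}.
#' @export
computeSummaryRatios <- function(counts) {
  if (is.data.frame(counts)) counts <- as.list(counts[1, , drop = FALSE])
  counts <- unlist(counts)
  g <- function(nm) if (nm %in% names(counts)) unname(counts[[nm]]) else NA
  specs <- list(
    c("pct_sites_with_variants", "n_sites_with_variants",
      "n_predicted_sites", "percent"),
    c("pct_variants_at_predicted_sites", "n_hits", "n_predicted_sites",
      "percent"),
    c("pct_founders_with_hits", "founders_with_hits", "n_founders",
      "percent"),
    c("pct_hits_validated", "n_validated", "n_hits", "percent"),
    c("pct_founders_with_validated", "founders_with_validated",
      "n_founders", "percent"),
    c("pct_guides_with_validated", "guides_with_validated", "n_guides",
      "percent"),
    c("pct_hits_nongenic", "n_hits_nongenic", "n_hits", "percent"),
    c("pct_founders_confirmed", "founders_confirmed", "n_founders",
      "percent"),
    c("validated_per_founder", "n_validated", "n_founders", "rate"))
  rows <- lapply(specs, function(s) {
    num <- g(s[2]); den <- g(s[3])
    if (is.na(num) || is.na(den)) return(NULL)
    scale <- if (s[4] == "percent") 100 else 1
    val <- if (den == 0) NA_real_ else scale * num / den
    data.frame(name = s[1], numerator = num, denominator = den,
               value = val,
               formatted = if (is.na(val)) "undefined" else
                 if (s[4] == "percent") formatPercent(val) else
                   formatRate(val),
               kind = s[4], stringsAsFactors = FALSE)
  })
  ratios <- do.call(rbind, rows)
  if (is.null(ratios))
    ratios <- data.frame(name = character(0), numerator = numeric(0),
                         denominator = numeric(0), value = numeric(0),
                         formatted = character(0), kind = character(0))
  AuditSummary(counts = counts, ratios = ratios)
}

#' Run the whole audit pipeline on a cohort
#'
#' Executes search, the primary filter cascade, callable-interval
#' restriction, the secondary (cross-sample uniqueness) filter, SV
#' consensus filtering, site-variant intersection and classification,
#' on-target confirmation, the seeded control resampling null, group
#' comparisons, and the pairwise heterogeneity matrix with clustering.
#'
#' @param cohort a \linkS4class{Cas9Cohort} (from
#'   \code{\link{generateCohort}} or \code{\link{readCohort}}).
#' @param search_config \code{\link{searchConfig}} for site enumeration.
#' @param filter_config \code{\link{filterConfig}}.
#' @param run_null,run_stats,run_heterogeneity stage toggles.
#' @param null_seeds per-control seeds for the resampling null (default
#'   1..n_controls).
#' @param out_dir optional directory to write stage outputs to.
#' @return an \linkS4class{AuditSummary}; stage artifacts are in
#'   \code{summaryDetails()}.
#' @export
runPipeline <- function(cohort, search_config = searchConfig(),
                        filter_config = filterConfig(),
                        run_null = TRUE, run_stats = TRUE,
                        run_heterogeneity = TRUE, null_seeds = NULL,
                        out_dir = NULL) {
  stopifnot(is(cohort, "Cas9Cohort"))
  samples <- sampleSheet(cohort)
  founders <- samples$sample_id[samples$group == "founder"]
  controls <- samples$sample_id[samples$group == "control"]

  ## 1. off-target site enumeration, per guide
  sites <- enumerateSites(guideTable(cohort), refGenome(cohort),
                          search_config)

  ## 2. primary filter cascade
  prim <- primaryFilter(variantCalls(cohort), known = knownVariants(cohort),
                        repeats = repeatIntervals(cohort),
                        config = filter_config, genome = refGenome(cohort))

  ## 3. callable intersection across all samples
  callable <- callableIntersection(callableIntervals(cohort))
  call_res <- applyCallableFilter(prim$variants, callable)

  ## 4. secondary filter: per-animal unique variants
  sec <- secondaryFilter(call_res$variants, filter_config)

  ## 5. SV consensus filter
  svres <- svConsensusFilter(svCalls(cohort), filter_config)

  ## 6. site-variant intersection + classification
  guide_map <- guideTable(cohort)[, c("sample_id", "guide_id")]
  hits <- intersectSitesVariants(sites, sec$variants, svres$svs, guide_map)
  hits <- classifyHits(hits, cohortAnnotation(cohort))
  hit_summary <- summarizeHits(hits, mismatch_ceiling = 6L)

  ## 7. on-target confirmation
  ontarget <- lapply(founders, function(fid)
    confirmOnTarget(fid,
                    guideTable(cohort)[guideTable(cohort)$sample_id == fid, ,
                                       drop = FALSE],
                    svres$svs, sec$variants))
  confirmed <- vapply(ontarget, `[[`, logical(1), "confirmed")

  ## 8. control resampling null
  null_res <- NULL
  site_guides <- S4Vectors::mcols(sites)$guide_id
  offtarget_sites <- sites[!S4Vectors::mcols(sites)$is_on_target]
  per_founder_sites <- vapply(founders, function(fid) {
    gids <- guide_map$guide_id[guide_map$sample_id == fid]
    sum(S4Vectors::mcols(offtarget_sites)$guide_id %in% gids)
  }, integer(1))
  if (run_null && length(controls)) {
    med <- medianSitesPerSample(per_founder_sites)
    seeds <- if (is.null(null_seeds)) seq_along(controls) else null_seeds
    null_res <- sampleNullOverlap(
      offtarget_sites, sec$variants, controls,
      nullSamplingConfig(med, seed_per_control = seeds))
  }

  ## 9. group comparisons
  stats_res <- if (run_stats)
    summarizeGroups(sec$variants, samples,
                    annotation = cohortAnnotation(cohort)) else NULL

  ## 10. heterogeneity on the pre-uniqueness (primary-filtered) sets
  het <- NULL; clus <- NULL
  if (run_heterogeneity) {
    het <- pairwiseSharedMatrix(call_res$variants, samples)
    clus <- clusterSamples(het, k = 2L)
  }

  n_sites <- length(offtarget_sites)
  counts <- c(n_guides = nrow(guideTable(cohort)),
              n_founders = length(founders),
              n_controls = length(controls),
              n_predicted_sites = n_sites,
              n_sites_with_variants = length(unique(paste(
                hits$guide_id, hits$contig, hits$site_start))),
              n_hits = nrow(hits),
              founders_with_hits = length(unique(hits$sample_id)),
              n_hits_nongenic = sum(hits$genic_context %in%
                                      c("intronic", "intergenic")),
              founders_confirmed = sum(confirmed))
  summary <- computeSummaryRatios(counts)
  summary@details <- list(sites = sites, primary = prim,
                          callable = call_res, secondary = sec,
                          svs = svres, hits = hits,
                          hit_summary = hit_summary, ontarget = ontarget,
                          per_founder_sites = per_founder_sites,
                          null = null_res, stats = stats_res,
                          heterogeneity = het, clusters = clus)
  if (!is.null(out_dir)) .write_pipeline_outputs(summary, cohort, out_dir)
  summary
}

.write_pipeline_outputs <- function(summary, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- summaryDetails(summary)
  writeSiteTable(d$sites, file.path(out_dir, "predicted_sites.tsv"))
  utils::write.table(d$hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(stageCounts(d$primary$report),
                     file.path(out_dir, "filter_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ot <- do.call(rbind, lapply(d$ontarget, function(o)
    data.frame(sample_id = o$sample_id, target_gene = o$target_gene,
               confirmed = o$confirmed,
               n_supporting_callers = o$n_supporting_callers,
               stringsAsFactors = FALSE)))
  utils::write.table(ot, file.path(out_dir, "ontarget_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(d$heterogeneity))
    utils::write.table(hetValues(d$heterogeneity),
                       file.path(out_dir, "heterogeneity.tsv"), sep = "\t",
                       quote = FALSE)
  if (!is.null(d$null)) {
    utils::write.table(d$null$per_control,
                       file.path(out_dir, "null_per_control.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(d$null$draws,
                         file.path(out_dir, "null_draws.json"))
  }
  r <- summaryRatios(summary)
  jsonlite::write_json(
    list(counts = as.list(summaryCounts(summary)),
         ratios = r),
    file.path(out_dir, "audit_summary.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(out_dir)
}
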