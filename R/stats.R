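## Control-cohort resampling null, group comparisons (Wilcoxon +
## Bonferroni) and the pairwise heterogeneity matrix with clustering.

#' Median predicted-site count per experimental sample
#'
#' The null model draws, for every control, the median number of predicted
#' sites per experimental sample (to account for differences in total
#' predicted sites across guide sets). Half-integer medians round half up.
#'
#' @param site_counts integer vector of per-sample predicted-site totals.
#' @return integer median.
#' @export
medianSitesPerSample <- function(site_counts) {
  if (length(site_counts) == 0L) stop("no experimental samples supplied")
  as.integer(floor(stats::median(site_counts) + 0.5))
}

#' Null-sampling configuration
#'
#' @param n_sites_per_control number of sites drawn per control (typically
#'   \code{\link{medianSitesPerSample}} of the experimental cohort).
#' @param seed_per_control integer vector of seeds, one per control;
#'   default assigns control i the seed i (seeds 1..n, set before each
#'   control's draw).
#' @param with_replacement draw with replacement (default FALSE, the
#'   sampling tool's default).
#' @return list of class \code{cas9audit_null_config}.
#' @export
nullSamplingConfig <- function(n_sites_per_control,
                               seed_per_control = NULL,
                               with_replacement = FALSE) {
  n_sites_per_control <- as.integer(n_sites_per_control)
  if (n_sites_per_control < 1L) stop("n_sites_per_control must be >= 1")
  if (!is.null(seed_per_control) && anyDuplicated(seed_per_control))
    stop("seeds must be unique per control")
  structure(list(n_sites_per_control = n_sites_per_control,
                 seed_per_control = seed_per_control,
                 with_replacement = isTRUE(with_replacement)),
            class = "cas9audit_null_config")
}

#' Seeded resampling null for incidental site-variant overlap
#'
#' For each control sample, sets that control's own seed, draws
#' \code{n_sites_per_control} sites uniformly from the pooled predictions
#' (without replacement by default), and intersects the draw with that
#' control's filtered variants under the same any-overlap rule as the
#' founder audit. Rerunning with the same config reproduces every draw.
#'
#' @param pooled_sites all predicted sites across guides
#'   (\linkS4class{OfftargetSites}; on-target sites are excluded here).
#' @param control_variants filtered variant table for the control samples.
#' @param control_ids character vector of control sample ids (ordered;
#'   control i uses seed i unless overridden).
#' @param config a \code{\link{nullSamplingConfig}}.
#' @return list with \code{per_control} (data.frame: sample_id, seed,
#'   n_sites_drawn, n_hits), \code{hits} (pooled hit table),
#'   \code{draws} (reproducibility manifest: list of drawn site indices)
#'   and \code{total_hits}.
#' @export
sampleNullOverlap <- function(pooled_sites, control_variants, control_ids,
                              config) {
  pooled_sites <- pooled_sites[!S4Vectors::mcols(pooled_sites)$is_on_target]
  npool <- length(pooled_sites)
  if (npool == 0L) stop("pooled site set is empty")
  nd <- config$n_sites_per_control
  if (!config$with_replacement && nd > npool)
    stop("cannot draw ", nd, " sites without replacement from a pool of ",
         npool)
  seeds <- config$seed_per_control
  if (is.null(seeds)) seeds <- seq_along(control_ids)
  if (length(seeds) != length(control_ids))
    stop("need one seed per control")
  per <- vector("list", length(control_ids))
  draws <- vector("list", length(control_ids))
  hit_rows <- list()
  for (i in seq_along(control_ids)) {
    sid <- control_ids[i]
    set.seed(seeds[i])
    idx <- sample.int(npool, nd, replace = config$with_replacement)
    draws[[i]] <- idx
    drawn <- pooled_sites[idx]
    v <- control_variants[control_variants$sample_id == sid, , drop = FALSE]
    nh <- 0L
    if (nrow(v)) {
      ov <- GenomicRanges::findOverlaps(variantRanges(v), drawn,
                                        ignore.strand = TRUE)
      nh <- length(ov)
      if (nh) {
        vi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          sample_id = sid, variant_id = variantKey(v)[vi],
          vtype = v$vtype[vi],
          site_index = idx[si],
          mismatches = S4Vectors::mcols(drawn)$mismatches[si],
          stringsAsFactors = FALSE)
      }
    }
    per[[i]] <- data.frame(sample_id = sid, seed = seeds[i],
                           n_sites_drawn = nd, n_hits = nh,
                           stringsAsFactors = FALSE)
  }
  names(draws) <- control_ids
  per_control <- do.call(rbind, per)
  list(per_control = per_control,
       hits = if (length(hit_rows)) do.call(rbind, hit_rows) else NULL,
       draws = draws,
       total_hits = sum(per_control$n_hits),
       n_controls_with_hits = sum(per_control$n_hits > 0L))
}

#' Per-sample variant count summaries and group comparisons
#'
#' Computes per-sample totals of SNVs, indels, combined, zygosity and
#' (when annotation is supplied) genic classes, then compares control vs
#' experimental groups with two-sided Wilcoxon rank-sum tests and
#' Bonferroni correction across the family of panels, evaluated at
#' \code{alpha}.
#'
#' @param variants final (secondary-filtered) variant table.
#' @param groups data.frame with \code{sample_id}, \code{group}
#'   (\code{control}/\code{founder}).
#' @param annotation optional list with \code{exons}/\code{gene_bodies} to
#'   add genic-class panels.
#' @param alpha significance level (default 0.05).
#' @return list with \code{per_sample} counts, \code{group_summary}
#'   (median/quartiles per group and panel), and \code{tests} (panel, W,
#'   p, p_adjusted, significant).
#' @export
summarizeGroups <- function(variants, groups, annotation = NULL,
                            alpha = 0.05) {
  stopifnot(all(c("sample_id", "group") %in% colnames(groups)))
  counts <- data.frame(sample_id = groups$sample_id,
                       group = groups$group, stringsAsFactors = FALSE)
  cnt <- function(flag) {
    t <- tapply(flag, factor(variants$sample_id,
                             levels = groups$sample_id), sum)
    as.integer(ifelse(is.na(t), 0L, t))
  }
  ones <- rep(TRUE, nrow(variants))
  counts$total <- cnt(ones)
  counts$SNV <- cnt(variants$vtype == "SNV")
  counts$indel <- cnt(variants$vtype == "indel")
  counts$het <- cnt(variants$genotype == "het")
  counts$hom_alt <- cnt(variants$genotype == "hom_alt")
  if (!is.null(annotation) && nrow(variants)) {
    ctx <- genicContext(variantRanges(variants), annotation)
    counts$exonic <- cnt(ctx == "exonic")
    counts$intronic <- cnt(ctx == "intronic")
    counts$intergenic <- cnt(ctx == "intergenic")
  }
  summarizeGroupCounts(counts, alpha = alpha)
}

#' Group comparisons from a per-sample count table
#'
#' The count-table interface behind \code{\link{summarizeGroups}}: one row
#' per sample, a \code{group} column, and one numeric column per panel.
#'
#' @param counts data.frame with \code{sample_id}, \code{group} and numeric
#'   panel columns.
#' @param alpha significance level.
#' @return see \code{\link{summarizeGroups}}.
#' @export
summarizeGroupCounts <- function(counts, alpha = 0.05) {
  panels <- setdiff(colnames(counts), c("sample_id", "group"))
  grps <- unique(counts$group)
  qs <- do.call(rbind, lapply(panels, function(p) {
    do.call(rbind, lapply(grps, function(g) {
      x <- counts[[p]][counts$group == g]
      data.frame(panel = p, group = g, n = length(x),
                 median = stats::median(x),
                 q1 = unname(stats::quantile(x, 0.25)),
                 q3 = unname(stats::quantile(x, 0.75)),
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- NULL
  if (length(grps) == 2L) {
    sizes <- table(counts$group)
    if (any(sizes < 2L)) {
      warning("a group has fewer than 2 samples; tests skipped")
    } else {
      tests <- do.call(rbind, lapply(panels, function(p) {
        x <- counts[[p]][counts$group == grps[1]]
        y <- counts[[p]][counts$group == grps[2]]
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
        data.frame(panel = p, W = unname(wt$statistic), p = wt$p.value,
                   stringsAsFactors = FALSE)
      }))
      tests$p_adjusted <- stats::p.adjust(tests$p, method = "bonferroni")
      tests$significant <- tests$p_adjusted < alpha
    }
  }
  list(per_sample = counts, group_summary = qs, tests = tests,
       alpha = alpha)
}

#' Pairwise percent-shared-variant matrix
#'
#' Entry (i, j) is 100 x |Vi intersect Vj| / |Vi union Vj| (percent
#' Jaccard over normalized identity tuples); the diagonal is 100. With
#' \code{denominator = "min"} the union is replaced by the smaller of the
#' two set sizes. Pairs where both samples have zero variants are defined
#' as 100 and flagged.
#'
#' @param variants primary-filtered variant table (the heterogeneity
#'   comparison runs before the cross-sample uniqueness filter).
#' @param groups sample sheet with \code{sample_id}, \code{group} and
#'   optionally \code{substrain}, \code{center}.
#' @param denominator \code{"union"} (Jaccard, default) or \code{"min"}.
#' @return a \linkS4class{HeterogeneityMatrix}.
#' @export
pairwiseSharedMatrix <- function(variants, groups,
                                 denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  ids <- groups$sample_id
  if (length(ids) < 2L) stop("need at least 2 samples")
  n <- length(ids)
  # sparse incidence: pairwise intersection sizes via one crossprod
  key <- variantKey(variants)
  si <- match(variants$sample_id, ids)
  ok <- !is.na(si)
  ki <- match(key[ok], unique(key[ok]))
  pairs <- unique(cbind(si[ok], ki))
  inc <- Matrix::sparseMatrix(i = pairs[, 1L], j = pairs[, 2L], x = 1,
                              dims = c(n, max(c(pairs[, 2L], 1L))))
  inter <- as.matrix(Matrix::tcrossprod(inc))
  sizes <- Matrix::rowSums(inc)
  den <- if (denominator == "union")
    outer(sizes, sizes, `+`) - inter else outer(sizes, sizes, pmin)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- den > 0
  m[pos] <- 100 * inter[pos] / den[pos]
  flagged <- any(!pos)
  m[!pos] <- 100                      # both sets empty
  diag(m) <- 100
  if (flagged)
    warning("pair(s) of samples with no variants; their similarity is ",
            "defined as 100")
  HeterogeneityMatrix(m, groups)
}

#' Cluster samples from a heterogeneity matrix
#'
#' Hierarchical clustering with the standard heatmap defaults: Euclidean
#' distance between matrix rows, complete linkage. Returns the leaf order
#' and the 2-cluster cut labels.
#'
#' @param x a \linkS4class{HeterogeneityMatrix}.
#' @param k number of clusters for the cut (default 2).
#' @return list with \code{order} (sample ids in dendrogram order),
#'   \code{cluster} (named cut labels) and \code{hclust}.
#' @export
clusterSamples <- function(x, k = 2L) {
  m <- hetValues(x)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = k)
  list(order = rownames(m)[hc$order], cluster = cl, hclust = hc)
}

#' Render a heterogeneity heatmap
#'
#' Thin wrapper over \pkg{pheatmap} (suggested); intended for interactive
#' inspection, not publication aesthetics.
#'
#' @param x a \linkS4class{HeterogeneityMatrix}.
#' @param ... passed to \code{pheatmap::pheatmap}.
#' @export
plotHeterogeneity <- function(x, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("install 'pheatmap' to plot heterogeneity matrices")
  ann <- hetGroups(x)
  rownames(ann) <- ann$sample_id
  ann <- ann[, setdiff(colnames(ann), "sample_id"), drop = FALSE]
  pheatmap::pheatmap(hetValues(x), annotation_row = ann, ...)
}
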