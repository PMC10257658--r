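## Site-variant intersection and downstream classification. A founder is
## audited only against its own guides' predicted sites; intersection is
## any-overlap (>= 1 base) between the site interval and the variant's
## reference span.

.hit_cols <- c("sample_id", "guide_id", "contig", "site_start", "site_end",
               "site_strand", "mismatches", "bulge_type", "pam_class",
               "variant_class", "var_start", "var_end", "variant_id",
               "mismatch_bin", "genic_context")

.empty_hits <- function() {
  out <- data.frame(sample_id = character(0), guide_id = character(0),
                    contig = character(0), site_start = integer(0),
                    site_end = integer(0), site_strand = character(0),
                    mismatches = integer(0), bulge_type = character(0),
                    pam_class = character(0), variant_class = character(0),
                    var_start = integer(0), var_end = integer(0),
                    variant_id = character(0), mismatch_bin = character(0),
                    genic_context = character(0), stringsAsFactors = FALSE)
  out
}

.mismatch_bin <- function(mm) ifelse(mm <= 4L, "<=4", as.character(mm))

#' Intersect predicted sites with filtered variants and SVs
#'
#' Emits one hit per (site, variant) pair whose intervals overlap by at
#' least one base, attributing each hit to the sample carrying the variant.
#' Each sample is only tested against the sites of the guides used in its
#' own experiment (per \code{guide_map}); on-target sites are excluded. A
#' small-variant deletion contained in an SV deletion at the same locus in
#' the same sample is dropped before counting, so one biological event is
#' not counted twice.
#'
#' @param sites an \linkS4class{OfftargetSites} for all guides.
#' @param variants post-filter small-variant table.
#' @param svs post-filter SV table (may be NULL).
#' @param guide_map data.frame with columns \code{sample_id},
#'   \code{guide_id}: which guides were used in which sample.
#' @return data.frame of hits (one row per site-variant pair).
#' @export
intersectSitesVariants <- function(sites, variants, svs = NULL, guide_map) {
  stopifnot(all(c("sample_id", "guide_id") %in% colnames(guide_map)))
  sites <- sites[!S4Vectors::mcols(sites)$is_on_target]
  if (length(sites)) {
    known_ctg <- GenomeInfoDb::seqlevels(sites)
    bad <- setdiff(unique(variants$contig), known_ctg)
    if (nrow(variants) && length(bad) && !is.na(known_ctg[1]))
      stop("variant contig(s) absent from site universe: ",
           paste(bad, collapse = ", "))
  }
  out <- list()
  site_guides <- S4Vectors::mcols(sites)$guide_id
  for (sid in unique(guide_map$sample_id)) {
    gids <- guide_map$guide_id[guide_map$sample_id == sid]
    ssub <- sites[site_guides %in% gids]
    if (length(ssub) == 0L) next
    # small variants
    v <- variants[variants$sample_id == sid, , drop = FALSE]
    if (nrow(v)) {
      ov <- GenomicRanges::findOverlaps(variantRanges(v), ssub,
                                        ignore.strand = TRUE)
      if (length(ov)) {
        vi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
        mc <- S4Vectors::mcols(ssub)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sid, guide_id = mc$guide_id[si],
          contig = as.character(GenomicRanges::seqnames(ssub))[si],
          site_start = GenomicRanges::start(ssub)[si],
          site_end = GenomicRanges::end(ssub)[si],
          site_strand = as.character(GenomicRanges::strand(ssub))[si],
          mismatches = mc$mismatches[si], bulge_type = mc$bulge_type[si],
          pam_class = mc$pam_class[si],
          variant_class = v$vtype[vi],
          var_start = v$pos[vi],
          var_end = v$pos[vi] + nchar(v$ref[vi]) - 1L,
          variant_id = variantKey(v)[vi],
          mismatch_bin = .mismatch_bin(mc$mismatches[si]),
          genic_context = NA_character_, stringsAsFactors = FALSE)
      }
    }
    # SVs
    if (!is.null(svs) && nrow(svs)) {
      s <- svs[svs$sample_id == sid & svs$svtype %in%
                 c("DEL", "DUP", "INV"), , drop = FALSE]
      if (nrow(s)) {
        sgr <- GenomicRanges::GRanges(s$contig,
                                      IRanges::IRanges(s$start, s$end))
        ov <- GenomicRanges::findOverlaps(sgr, ssub, ignore.strand = TRUE)
        if (length(ov)) {
          vi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
          mc <- S4Vectors::mcols(ssub)
          out[[length(out) + 1L]] <- data.frame(
            sample_id = sid, guide_id = mc$guide_id[si],
            contig = as.character(GenomicRanges::seqnames(ssub))[si],
            site_start = GenomicRanges::start(ssub)[si],
            site_end = GenomicRanges::end(ssub)[si],
            site_strand = as.character(GenomicRanges::strand(ssub))[si],
            mismatches = mc$mismatches[si], bulge_type = mc$bulge_type[si],
            pam_class = mc$pam_class[si],
            variant_class = paste0("SV:", tolower(s$svtype[vi])),
            var_start = s$start[vi], var_end = s$end[vi],
            variant_id = paste(s$contig[vi], s$start[vi], s$end[vi],
                               s$svtype[vi], sep = ":"),
            mismatch_bin = .mismatch_bin(mc$mismatches[si]),
            genic_context = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else .empty_hits()
  rownames(hits) <- NULL
  # deduplicate: drop a small-variant deletion contained in an SV DEL hit
  # of the same sample at the same site
  if (nrow(hits)) {
    smalldel <- hits$variant_class == "indel" &
      hits$var_end > hits$var_start          # deletions span > 1 ref base
    svdel <- hits$variant_class == "SV:del"
    drop <- rep(FALSE, nrow(hits))
    for (i in which(smalldel)) {
      j <- svdel & hits$sample_id == hits$sample_id[i] &
        hits$contig == hits$contig[i] &
        hits$var_start <= hits$var_start[i] &
        hits$var_end >= hits$var_end[i] &
        hits$site_start == hits$site_start[i]
      if (any(j)) drop[i] <- TRUE
    }
    hits <- hits[!drop, , drop = FALSE]
  }
  hits
}

#' Classify hits by genic context
#'
#' \code{exonic} if the variant interval overlaps any exon, else
#' \code{intronic} if it overlaps a gene body, else \code{intergenic}
#' (upstream/downstream positions fall in the intergenic category).
#'
#' @param hits hit table from \code{\link{intersectSitesVariants}}.
#' @param annotation list with \code{exons} and \code{gene_bodies} GRanges.
#' @return the hit table with \code{genic_context} filled in.
#' @export
classifyHits <- function(hits, annotation) {
  stopifnot(all(c("exons", "gene_bodies") %in% names(annotation)))
  if (nrow(hits) == 0L) return(hits)
  vgr <- GenomicRanges::GRanges(hits$contig,
                                IRanges::IRanges(hits$var_start,
                                                 hits$var_end))
  inex <- GenomicRanges::countOverlaps(vgr, annotation$exons,
                                       ignore.strand = TRUE) > 0L
  ingene <- GenomicRanges::countOverlaps(vgr, annotation$gene_bodies,
                                         ignore.strand = TRUE) > 0L
  hits$genic_context <- ifelse(inex, "exonic",
                               ifelse(ingene, "intronic", "intergenic"))
  hits
}

#' Genic context of arbitrary intervals (helper used by summaries)
#' @param gr a \code{GRanges}.
#' @param annotation list with \code{exons} and \code{gene_bodies}.
#' @return character vector exonic/intronic/intergenic.
#' @export
genicContext <- function(gr, annotation) {
  inex <- GenomicRanges::countOverlaps(gr, annotation$exons,
                                       ignore.strand = TRUE) > 0L
  ingene <- GenomicRanges::countOverlaps(gr, annotation$gene_bodies,
                                         ignore.strand = TRUE) > 0L
  ifelse(inex, "exonic", ifelse(ingene, "intronic", "intergenic"))
}

#' Cross-tabulate classified hits
#'
#' Counts hits by variant class, PAM class and mismatch bin, restricted to
#' sites with at most \code{mismatch_ceiling} mismatches, plus the genic
#' context proportions of the same restricted set.
#'
#' @param hits classified hit table.
#' @param mismatch_ceiling 4, 5 or 6.
#' @return list with \code{table} (counts by variant_class x pam_class x
#'   mismatch_bin), \code{genic} (context proportions) and \code{n_hits}.
#' @export
summarizeHits <- function(hits, mismatch_ceiling = 6L) {
  stopifnot(mismatch_ceiling %in% c(4L, 5L, 6L))
  h <- hits[hits$mismatches <= mismatch_ceiling, , drop = FALSE]
  classes <- c("SNV", "indel", "SV:del", "SV:dup", "SV:inv")
  bins <- c("<=4", "5", "6")
  tab <- table(variant_class = factor(h$variant_class, levels = classes),
               pam_class = factor(h$pam_class, levels = c("NGG", "NAG")),
               mismatch_bin = factor(h$mismatch_bin, levels = bins))
  genic <- table(factor(h$genic_context,
                        levels = c("exonic", "intronic", "intergenic")))
  genic_prop <- if (nrow(h)) as.numeric(genic) / nrow(h) else
    rep(0, 3L)
  names(genic_prop) <- names(genic)
  list(table = tab, genic = genic_prop, n_hits = nrow(h))
}

#' Confirm a founder's on-target deletion
#'
#' The expected deletion spans the outermost cut sites of the founder's
#' guides. The call is confirmed when a consensus-passing SV deletion (two
#' or more callers) overlaps the expected interval, or a small-variant
#' deletion covers at least half of it.
#'
#' @param sample_id founder id.
#' @param guides the founder's guide table rows; needs \code{contig} and
#'   0-based \code{cut_pos} columns (at least two guides).
#' @param svs the founder's consensus-filtered SV records (i.e. records
#'   that passed \code{\link{svConsensusFilter}}).
#' @param variants the founder's filtered small variants (may be NULL).
#' @return list (\code{OnTargetCall}): \code{sample_id},
#'   \code{target_gene}, \code{expected_interval}, \code{confirmed},
#'   \code{supporting_evidence}, \code{n_supporting_callers}.
#' @export
confirmOnTarget <- function(sample_id, guides, svs, variants = NULL) {
  if (nrow(guides) < 2L)
    stop("founder ", sample_id,
         " has fewer than 2 guides; a deletion design requires flanking guides")
  if (length(unique(guides$contig)) != 1L)
    stop("flanking guides must share a contig")
  cuts <- sort(guides$cut_pos)
  # cut_pos is 0-based; deleted bases span (cut_min, cut_max] in 1-based
  expected <- GenomicRanges::GRanges(guides$contig[1],
                                     IRanges::IRanges(min(cuts) + 1L,
                                                      max(cuts)))
  evidence <- character(0); ncall <- 0L; confirmed <- FALSE
  s <- svs[svs$sample_id == sample_id & svs$svtype == "DEL", , drop = FALSE]
  if (nrow(s)) {
    sgr <- GenomicRanges::GRanges(s$contig, IRanges::IRanges(s$start, s$end))
    ov <- GenomicRanges::countOverlaps(sgr, expected, ignore.strand = TRUE) > 0L
    if (any(ov)) {
      confirmed <- TRUE
      evidence <- paste(s$contig[ov], s$start[ov], s$end[ov], "DEL",
                        sep = ":")
      ncall <- max(vapply(strsplit(s$callers[ov], ",", fixed = TRUE),
                          length, integer(1)))
    }
  }
  if (!confirmed && !is.null(variants) && nrow(variants)) {
    v <- variants[variants$sample_id == sample_id &
                    variants$vtype == "indel" &
                    nchar(variants$ref) > nchar(variants$alt), , drop = FALSE]
    if (nrow(v)) {
      ovw <- pmax(0L, pmin(v$pos + nchar(v$ref) - 1L,
                           GenomicRanges::end(expected)) -
                    pmax(v$pos, GenomicRanges::start(expected)) + 1L)
      ovw[v$contig != as.character(GenomicRanges::seqnames(expected))] <- 0L
      frac <- ovw / GenomicRanges::width(expected)
      if (any(frac >= 0.5)) {
        confirmed <- TRUE
        evidence <- variantKey(v)[frac >= 0.5]
        ncall <- NA_integer_
      }
    }
  }
  list(sample_id = sample_id,
       target_gene = if ("target_gene" %in% colnames(guides))
         guides$target_gene[1] else NA_character_,
       expected_interval = expected, confirmed = confirmed,
       supporting_evidence = evidence, n_supporting_callers = ncall)
}

#' Three-way overlap of site lists
#'
#' Two sites match when they lie on the same contig and their intervals
#' overlap after padding by \code{tolerance}. Matching sites across the
#' three lists are merged into connected components and each component is
#' assigned to one of the 7 Venn regions by which lists contributed to it.
#'
#' @param setA,setB,setC site lists: \linkS4class{OfftargetSites} or plain
#'   \code{GRanges}.
#' @param tolerance positional slack in bp (default 10).
#' @param names labels for the three sets.
#' @return named integer vector of the 7 region counts
#'   (\code{A}, \code{B}, \code{C}, \code{AB}, \code{AC}, \code{BC},
#'   \code{ABC}).
#' @export
compareSiteSets <- function(setA, setB, setC, tolerance = 10L,
                            names = c("A", "B", "C")) {
  grs <- list(GenomicRanges::granges(setA), GenomicRanges::granges(setB),
              GenomicRanges::granges(setC))
  n <- vapply(grs, length, integer(1))
  if (sum(n) == 0L)
    return(stats::setNames(integer(7),
                           c(names, paste0(names[1], names[2]),
                             paste0(names[1], names[3]),
                             paste0(names[2], names[3]),
                             paste0(names, collapse = ""))))
  all <- suppressWarnings(c(grs[[1]], grs[[2]], grs[[3]]))
  GenomicRanges::strand(all) <- "*"
  origin <- rep(1:3, n)
  padded <- suppressWarnings(
    GenomicRanges::resize(all, GenomicRanges::width(all) + 2L * tolerance,
                          fix = "center"))
  # connected components via union-find over pairwise overlap
  ov <- GenomicRanges::findOverlaps(padded, GenomicRanges::reduce(padded))
  comp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  sig <- tapply(origin, comp, function(o)
    paste(names[sort(unique(o))], collapse = ""))
  labels <- c(names, paste0(names[1], names[2]), paste0(names[1], names[3]),
              paste0(names[2], names[3]), paste0(names, collapse = ""))
  out <- stats::setNames(integer(7), labels)
  tab <- table(factor(sig, levels = labels))
  out[] <- as.integer(tab)
  out
}
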