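## S4 containers for the audit. Sites ride on GRanges; per-record variant and
## SV tables are plain data.frames with schema validators (see io.R) so they
## compose directly with data.table/df tooling.

#' OfftargetSites: candidate Cas9 cut sites as a GRanges extension
#'
#' A \code{GRanges} subclass holding one row per candidate off-target site.
#' Ranges cover the protospacer-homologous genomic window plus the 3-nt PAM
#' (1-based, closed). Metadata columns: \code{guide_id},
#' \code{aligned_target} (genomic window in guide orientation; \code{"-"}
#' marks the gap opposite an unpaired guide base), \code{mismatches},
#' \code{bulge_type} (\code{none}/\code{DNA}/\code{RNA}), \code{bulge_size},
#' \code{gap_pos}, \code{mm_positions} (comma-separated 1-based guide
#' positions, position 20 PAM-proximal), \code{pam_seq}, \code{pam_class}
#' (\code{NGG}/\code{NAG}) and \code{is_on_target}.
#'
#' @export
setClass("OfftargetSites", contains = "GRanges")

.site_mcols <- c("guide_id", "aligned_target", "mismatches", "bulge_type",
                 "bulge_size", "gap_pos", "mm_positions", "pam_seq",
                 "pam_class", "is_on_target")

setValidity("OfftargetSites", function(object) {
  mc <- S4Vectors::mcols(object)
  miss <- setdiff(.site_mcols, colnames(mc))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  if (any(mc$mismatches < 0)) return("negative mismatch count")
  if (!all(mc$bulge_type %in% c("none", "DNA", "RNA")))
    return("bulge_type must be none/DNA/RNA")
  if (!all((mc$bulge_size == 0L) == (mc$bulge_type == "none")))
    return("bulge_size must be 0 iff bulge_type is 'none'")
  if (!all(mc$pam_class %in% c("NGG", "NAG")))
    return("pam_class must be NGG or NAG")
  p23 <- substr(mc$pam_seq, 2L, 3L)
  ok <- (mc$pam_class == "NGG" & p23 == "GG") |
        (mc$pam_class == "NAG" & p23 == "AG")
  if (!all(ok)) return("pam_class inconsistent with pam_seq positions 2-3")
  ot <- mc$is_on_target
  if (any(ot & (mc$mismatches != 0L | mc$bulge_type != "none")))
    return("on-target sites must have 0 mismatches and no bulge")
  TRUE
})

#' Construct an OfftargetSites object
#'
#' @param gr a \code{GRanges} carrying the metadata columns documented in
#'   \linkS4class{OfftargetSites}.
#' @return an \code{OfftargetSites} object.
#' @export
OfftargetSites <- function(gr = GenomicRanges::GRanges()) {
  if (length(gr) == 0L && ncol(S4Vectors::mcols(gr)) == 0L) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      guide_id = character(0), aligned_target = character(0),
      mismatches = integer(0), bulge_type = character(0),
      bulge_size = integer(0), gap_pos = integer(0),
      mm_positions = character(0), pam_seq = character(0),
      pam_class = character(0), is_on_target = logical(0))
  }
  new("OfftargetSites", gr)
}

setMethod("show", "OfftargetSites", function(object) {
  cat(sprintf("OfftargetSites with %d site(s) for %d guide(s)\n",
              length(object),
              length(unique(S4Vectors::mcols(object)$guide_id))))
  if (length(object)) {
    mc <- S4Vectors::mcols(object)
    cat("  mismatches: ", paste(sprintf("%d:%d",
        as.integer(names(table(mc$mismatches))),
        as.integer(table(mc$mismatches))), collapse = " "), "\n", sep = "")
    cat(sprintf("  bulged: %d | NAG PAM: %d | on-target: %d\n",
                sum(mc$bulge_type != "none"), sum(mc$pam_class == "NAG"),
                sum(mc$is_on_target)))
  }
  invisible(NULL)
})

#' FilterReport: per-stage, per-sample accounting of a filter cascade
#'
#' Tracks, for every stage and sample, the number of records entering,
#' removed, and surviving. The validity rule \code{n_in - n_removed ==
#' n_out} is enforced at every row.
#'
#' @slot stages data.frame with columns \code{stage}, \code{sample_id},
#'   \code{n_in}, \code{n_removed}, \code{n_out}.
#' @slot stage_order character vector giving the canonical stage order.
#' @export
setClass("FilterReport",
         representation(stages = "data.frame", stage_order = "character"))

setValidity("FilterReport", function(object) {
  st <- object@stages
  need <- c("stage", "sample_id", "n_in", "n_removed", "n_out")
  if (!all(need %in% colnames(st)))
    return("stages must have stage, sample_id, n_in, n_removed, n_out")
  if (nrow(st) && !all(st$n_in - st$n_removed == st$n_out))
    return("n_in - n_removed must equal n_out at every stage")
  if (nrow(st) && !all(st$stage %in% object@stage_order))
    return("unknown stage name in report")
  TRUE
})

FilterReport <- function(stages, stage_order) {
  new("FilterReport", stages = stages, stage_order = stage_order)
}

#' @describeIn FilterReport-class stage table accessor
#' @param x a \code{FilterReport}.
#' @export
stageCounts <- function(x) {
  stopifnot(is(x, "FilterReport"))
  st <- x@stages
  st$stage <- factor(st$stage, levels = x@stage_order)
  st[order(st$stage, st$sample_id), , drop = FALSE]
}

setMethod("show", "FilterReport", function(object) {
  st <- object@stages
  cat("FilterReport:", length(unique(st$sample_id)), "sample(s),",
      length(object@stage_order), "stage(s)\n")
  agg <- stats::aggregate(cbind(n_in, n_removed, n_out) ~ stage, data = st, sum)
  agg <- agg[match(object@stage_order, agg$stage), , drop = FALSE]
  agg <- agg[!is.na(agg$stage), , drop = FALSE]
  print(agg, row.names = FALSE)
  invisible(NULL)
})

#' HeterogeneityMatrix: pairwise percent-shared-variant matrix
#'
#' Symmetric matrix of the percentage of variants common to each pair of
#' samples (percent Jaccard by default), with a 100 diagonal, plus group
#' labels used for display and clustering.
#'
#' @slot values numeric matrix, samples x samples, in \[0, 100\].
#' @slot groups data.frame with columns \code{sample_id}, \code{group} and
#'   optionally \code{substrain}, \code{center}.
#' @export
setClass("HeterogeneityMatrix",
         representation(values = "matrix", groups = "data.frame"))

setValidity("HeterogeneityMatrix", function(object) {
  m <- object@values
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("dimnames must be identical sample ids")
  if (nrow(m)) {
    if (max(abs(m - t(m))) > 1e-8) return("matrix must be symmetric")
    if (max(abs(diag(m) - 100)) > 1e-8) return("diagonal must be 100")
    if (min(m) < -1e-8 || max(m) > 100 + 1e-8)
      return("values must lie in [0, 100]")
  }
  if (!all(rownames(m) %in% object@groups$sample_id))
    return("every sample needs a group label")
  TRUE
})

HeterogeneityMatrix <- function(values, groups) {
  new("HeterogeneityMatrix", values = values, groups = groups)
}

#' @describeIn HeterogeneityMatrix-class numeric matrix accessor
#' @param x a \code{HeterogeneityMatrix}.
#' @export
hetValues <- function(x) {
  stopifnot(is(x, "HeterogeneityMatrix"))
  x@values
}

#' @describeIn HeterogeneityMatrix-class group label accessor
#' @export
hetGroups <- function(x) {
  stopifnot(is(x, "HeterogeneityMatrix"))
  x@groups
}

setMethod("show", "HeterogeneityMatrix", function(object) {
  m <- object@values
  off <- m[upper.tri(m)]
  cat(sprintf("HeterogeneityMatrix: %d samples; off-diagonal %% shared %.2f-%.2f (median %.2f)\n",
              nrow(m), if (length(off)) min(off) else NA,
              if (length(off)) max(off) else NA,
              if (length(off)) stats::median(off) else NA))
  invisible(NULL)
})

#' AuditSummary: headline counts and ratios of an off-target audit
#'
#' Carries the raw counts (guides, founders, predicted sites, hits,
#' confirmations, ...) together with derived ratios. Every ratio stores its
#' numerator and denominator so it can be re-derived; \code{show} re-checks
#' the arithmetic at render time.
#'
#' @slot counts named numeric vector of raw counts.
#' @slot ratios data.frame with columns \code{name}, \code{numerator},
#'   \code{denominator}, \code{value}, \code{formatted}, \code{kind}
#'   (\code{percent} or \code{rate}).
#' @slot details list of stage artifacts (tables, matrices, reports).
#' @export
setClass("AuditSummary",
         representation(counts = "numeric", ratios = "data.frame",
                        details = "list"))

setValidity("AuditSummary", function(object) {
  r <- object@ratios
  if (nrow(r)) {
    need <- c("name", "numerator", "denominator", "value", "formatted", "kind")
    if (!all(need %in% colnames(r))) return("ratio table columns missing")
    def <- !is.na(r$value)
    scale <- ifelse(r$kind == "percent", 100, 1)
    recomputed <- scale[def] * r$numerator[def] / r$denominator[def]
    if (any(abs(recomputed - r$value[def]) > 1e-9))
      return("stored ratio values must equal numerator/denominator")
  }
  if (!is.null(object@counts) && length(object@counts) &&
      is.null(names(object@counts)))
    return("counts must be named")
  TRUE
})

AuditSummary <- function(counts = numeric(0),
                         ratios = data.frame(name = character(0),
                                             numerator = numeric(0),
                                             denominator = numeric(0),
                                             value = numeric(0),
                                             formatted = character(0),
                                             kind = character(0)),
                         details = list()) {
  new("AuditSummary", counts = counts, ratios = ratios, details = details)
}

#' @describeIn AuditSummary-class raw count accessor
#' @param x an \code{AuditSummary}.
#' @export
summaryCounts <- function(x) {
  stopifnot(is(x, "AuditSummary"))
  x@counts
}

#' @describeIn AuditSummary-class ratio table accessor
#' @export
summaryRatios <- function(x) {
  stopifnot(is(x, "AuditSummary"))
  x@ratios
}

#' @describeIn AuditSummary-class stage artifact accessor
#' @export
summaryDetails <- function(x) {
  stopifnot(is(x, "AuditSummary"))
  x@details
}

setMethod("show", "AuditSummary", function(object) {
  cat("AuditSummary\n counts:\n")
  cn <- object@counts
  for (nm in names(cn)) cat(sprintf("  %-28s %s\n", nm, format(cn[[nm]])))
  r <- object@ratios
  if (nrow(r)) {
    # self-check: every rendered ratio must re-derive from its counts
    scale <- ifelse(r$kind == "percent", 100, 1)
    chk <- scale * r$numerator / r$denominator
    bad <- !is.na(r$value) & abs(chk - r$value) > 1e-9
    if (any(bad)) stop("AuditSummary self-check failed for: ",
                       paste(r$name[bad], collapse = ", "))
    cat(" ratios:\n")
    for (i in seq_len(nrow(r)))
      cat(sprintf("  %-28s %s (%s/%s)\n", r$name[i], r$formatted[i],
                  format(r$numerator[i]), format(r$denominator[i])))
  }
  invisible(NULL)
})

#' Cas9Cohort: a synthetic study with ground truth
#'
#' The complete in-memory representation of one simulated study: reference
#' genome, guide designs, per-sample small-variant and SV call tables,
#' known-variant set, repeat/callable/annotation intervals, sample sheet,
#' generation config and the truth ledger used by recovery tests.
#'
#' @slot genome \code{DNAStringSet} reference.
#' @slot guides guide table (one row per guide; includes founder assignment,
#'   on-target coordinates and cut positions).
#' @slot variants small-variant call table across all samples.
#' @slot svs SV call table across all samples.
#' @slot known known-variant table (the stand-in for dbSNP/EVA).
#' @slot repeats \code{GRanges} of repeat intervals.
#' @slot callable named list of per-sample callable \code{GRanges}.
#' @slot annotation list with \code{exons} and \code{gene_bodies} GRanges.
#' @slot samples sample sheet (\code{sample_id}, \code{group},
#'   \code{substrain}, \code{center}).
#' @slot truth list of truth-ledger data.frames.
#' @slot config the generation config (including the seed).
#' @export
setClass("Cas9Cohort",
         representation(genome = "DNAStringSet", guides = "data.frame",
                        variants = "data.frame", svs = "data.frame",
                        known = "data.frame", repeats = "GRanges",
                        callable = "list", annotation = "list",
                        samples = "data.frame", truth = "list",
                        config = "list"))

setValidity("Cas9Cohort", function(object) {
  if (nrow(object@samples) &&
      !all(object@samples$group %in% c("control", "founder")))
    return("sample group must be control or founder")
  if (length(object@callable) &&
      !all(object@samples$sample_id %in% names(object@callable)))
    return("every sample needs callable intervals")
  if (nrow(object@variants) &&
      !all(object@variants$sample_id %in% object@samples$sample_id))
    return("variant sample_id not in sample sheet")
  TRUE
})

setMethod("show", "Cas9Cohort", function(object) {
  cat(sprintf("Cas9Cohort: %d contigs (%s bp), %d controls + %d founders, %d guides\n",
              length(object@genome),
              format(sum(Biostrings::width(object@genome)), big.mark = ","),
              sum(object@samples$group == "control"),
              sum(object@samples$group == "founder"),
              nrow(object@guides)))
  cat(sprintf("  %d small-variant records, %d SV records, %d known variants\n",
              nrow(object@variants), nrow(object@svs), nrow(object@known)))
  invisible(NULL)
})

#' @describeIn Cas9Cohort-class reference genome accessor
#' @param x a \code{Cas9Cohort}.
#' @export
refGenome <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@genome }

#' @describeIn Cas9Cohort-class guide table accessor
#' @export
guideTable <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@guides }

#' @describeIn Cas9Cohort-class small-variant call table accessor
#' @export
variantCalls <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@variants }

#' @describeIn Cas9Cohort-class SV call table accessor
#' @export
svCalls <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@svs }

#' @describeIn Cas9Cohort-class known-variant table accessor
#' @export
knownVariants <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@known }

#' @describeIn Cas9Cohort-class repeat interval accessor
#' @export
repeatIntervals <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@repeats }

#' @describeIn Cas9Cohort-class per-sample callable interval accessor
#' @export
callableIntervals <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@callable }

#' @describeIn Cas9Cohort-class annotation accessor (exons, gene bodies)
#' @export
cohortAnnotation <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@annotation }

#' @describeIn Cas9Cohort-class sample sheet accessor
#' @export
sampleSheet <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@samples }

#' @describeIn Cas9Cohort-class truth ledger accessor
#' @export
truthLedger <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@truth }

#' @describeIn Cas9Cohort-class generation config accessor
#' @export
cohortConfigOf <- function(x) { stopifnot(is(x, "Cas9Cohort")); x@config }
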