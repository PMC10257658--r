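## Off-target site enumeration: mismatches plus at most one bulge (DNA bulge
## = one extra genomic base in a 21-nt window; RNA bulge = one unpaired
## guide base over a 19-nt window), anchored at NGG/NAG PAMs. The fast path
## is a compiled scanner (src/scan.cpp); oracleEnumerate() is an exhaustive
## pure-R re-derivation used to validate it.

#' Search configuration
#'
#' @param max_mismatches mismatch ceiling, 0-6 (default 5, the prediction
#'   setting; classification re-bins at 4/5/6).
#' @param allow_bulge allow a single DNA or RNA bulge (one bulge total).
#' @param pam_rule \code{"NGG+NAG"} (default) or \code{"NGG-only"}.
#' @param exclude_contigs regex patterns for contigs to drop from results.
#'   \code{NULL} (default) excludes mitochondrial and non-canonical contigs:
#'   everything not matching \code{chr1..chrN/chrX/chrY} (with or without
#'   the "chr" prefix). \code{character(0)} disables exclusion.
#' @return a list of class \code{cas9audit_search_config}.
#' @export
searchConfig <- function(max_mismatches = 5L, allow_bulge = TRUE,
                         pam_rule = c("NGG+NAG", "NGG-only"),
                         exclude_contigs = NULL) {
  pam_rule <- match.arg(pam_rule)
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L || max_mismatches > 6L)
    stop("max_mismatches must be in [0, 6]")
  structure(list(max_mismatches = max_mismatches,
                 allow_bulge = isTRUE(allow_bulge),
                 pam_rule = pam_rule,
                 exclude_contigs = exclude_contigs),
            class = "cas9audit_search_config")
}

.excluded_contigs <- function(contigs, config) {
  pat <- config$exclude_contigs
  if (is.null(pat)) {
    keep <- grepl("^(chr)?([0-9]{1,2}|X|Y)$", contigs)
    return(contigs[!keep])
  }
  if (length(pat) == 0L) return(character(0))
  contigs[Reduce(`|`, lapply(pat, grepl, x = contigs))]
}

.as_guide_row <- function(guide) {
  if (is.data.frame(guide)) {
    validateGuides(guide)
    return(guide)
  }
  g <- as.data.frame(guide[c("guide_id", "protospacer", "pam_rule")],
                     stringsAsFactors = FALSE)
  validateGuides(g)
  g
}

# assemble site rows from one scan (one contig, one orientation)
.scan_to_sites <- function(hits, seq_chr, contig, strand, L, guide_id) {
  if (nrow(hits) == 0L) return(NULL)
  target <- substring(seq_chr, hits$window_start,
                      hits$window_start + hits$window_len - 1L)
  # RNA bulge: insert the gap symbol opposite the unpaired guide base
  rb <- hits$bulge == 2L
  if (any(rb)) {
    g <- hits$gap_pos[rb]
    target[rb] <- paste0(substr(target[rb], 1L, g - 1L), "-",
                         substring(target[rb], g))
  }
  pam <- substring(seq_chr, hits$pam_start, hits$pam_start + 2L)
  a <- hits$window_start          # scanned-orientation window start
  b <- hits$pam_start + 2L        # scanned-orientation PAM end
  if (strand == "+") {
    fs <- a; fe <- b
  } else {
    fs <- L - b + 1L; fe <- L - a + 1L
  }
  data.frame(contig = contig, start = fs, end = fe, strand = strand,
             guide_id = guide_id, aligned_target = target,
             mismatches = hits$mismatches,
             bulge_type = c("none", "DNA", "RNA")[hits$bulge + 1L],
             bulge_size = ifelse(hits$bulge == 0L, 0L, 1L),
             gap_pos = hits$gap_pos,
             mm_positions = hits$mm_positions,
             pam_seq = pam,
             pam_class = c("NGG", "NAG")[hits$pam_class],
             stringsAsFactors = FALSE)
}

.sites_from_frame <- function(df, genome) {
  if (is.null(df) || nrow(df) == 0L) return(OfftargetSites())
  df <- df[order(df$guide_id, df$contig, df$start, df$strand), , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  keep <- setdiff(colnames(df), c("contig", "start", "end", "strand"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, keep, drop = FALSE])
  gr$is_on_target <- gr$mismatches == 0L & gr$bulge_type == "none" &
    gr$pam_class == "NGG"
  sl <- Biostrings::width(genome)
  names(sl) <- names(genome)
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- sl
  OfftargetSites(gr)
}

#' Enumerate candidate off-target sites for guides against a genome
#'
#' Finds every locus, on either strand, where a PAM matching the configured
#' rule sits immediately 3' of a 20-nt (19/21-nt when bulged) window whose
#' best alignment to the protospacer has at most \code{max_mismatches}
#' substitutions and at most one bulge. One site is reported per (strand,
#' PAM position) with its minimal-cost alignment under the lexicographic
#' cost (bulge size, mismatches); ties prefer no bulge, then a DNA over an
#' RNA bulge, then the PAM-distal gap. Windows containing N are skipped.
#' Minus-strand sites report \code{aligned_target} and \code{pam_seq} in
#' guide orientation with coordinates on the forward strand. Exact matches
#' with an NGG PAM and no bulge are flagged \code{is_on_target}.
#'
#' @param guides a guide table (data.frame, possibly multiple rows) or a
#'   single list with \code{guide_id}, \code{protospacer}, \code{pam_rule}.
#' @param genome \code{DNAStringSet}.
#' @param config a \code{\link{searchConfig}}. The guide's own
#'   \code{pam_rule} further restricts NAG use per guide.
#' @return an \linkS4class{OfftargetSites} object.
#' @export
enumerateSites <- function(guides, genome, config = searchConfig()) {
  guides <- .as_guide_row(guides)
  drop <- .excluded_contigs(names(genome), config)
  use <- setdiff(names(genome), drop)
  fwd <- as.character(genome)
  rev <- as.character(Biostrings::reverseComplement(genome))
  out <- vector("list", 0L)
  for (gi in seq_len(nrow(guides))) {
    g <- guides[gi, ]
    nag <- config$pam_rule == "NGG+NAG" && g$pam_rule == "NGG+NAG"
    for (contig in use) {
      L <- nchar(fwd[[contig]])
      hf <- scan_guide_cpp(fwd[[contig]], g$protospacer,
                           config$max_mismatches, config$allow_bulge, nag)
      hr <- scan_guide_cpp(rev[[contig]], g$protospacer,
                           config$max_mismatches, config$allow_bulge, nag)
      out[[length(out) + 1L]] <-
        .scan_to_sites(hf, fwd[[contig]], contig, "+", L, g$guide_id)
      out[[length(out) + 1L]] <-
        .scan_to_sites(hr, rev[[contig]], contig, "-", L, g$guide_id)
    }
  }
  .sites_from_frame(do.call(rbind, out), genome)
}

#' Exhaustive brute-force site enumeration (validation oracle)
#'
#' Tries every window of lengths 19, 20 and 21 on both strands, every
#' internal single-gap placement and every PAM allowed by the rule, with no
#' indexing, pruning or early exit, then keeps the minimal-cost alignment
#' per (strand, PAM position) under the same canonicalization as
#' \code{\link{enumerateSites}}. Refuses genomes larger than 100 kb.
#'
#' @inheritParams enumerateSites
#' @return an \linkS4class{OfftargetSites} object.
#' @export
oracleEnumerate <- function(guides, genome, config = searchConfig()) {
  if (sum(Biostrings::width(genome)) > 100000L)
    stop("oracleEnumerate refuses genomes > 100 kb (",
         sum(Biostrings::width(genome)), " bp supplied)")
  guides <- .as_guide_row(guides)
  drop <- .excluded_contigs(names(genome), config)
  use <- setdiff(names(genome), drop)
  fwd <- as.character(genome)
  rev <- as.character(Biostrings::reverseComplement(genome))
  out <- vector("list", 0L)
  for (gi in seq_len(nrow(guides))) {
    g <- guides[gi, ]
    nag <- config$pam_rule == "NGG+NAG" && g$pam_rule == "NGG+NAG"
    gvec <- strsplit(g$protospacer, "")[[1]]
    for (contig in use) {
      L <- nchar(fwd[[contig]])
      for (strand in c("+", "-")) {
        s <- if (strand == "+") fwd[[contig]] else rev[[contig]]
        v <- strsplit(s, "")[[1]]
        cand <- .oracle_scan_one(v, gvec, config$max_mismatches,
                                 config$allow_bulge, nag)
        if (is.null(cand) || nrow(cand) == 0L) next
        out[[length(out) + 1L]] <-
          .scan_to_sites(cand, s, contig, strand, L, g$guide_id)
      }
    }
  }
  .sites_from_frame(do.call(rbind, out), genome)
}

# enumerate all (window, gap) candidates on one oriented sequence, then
# canonicalize per PAM position; plain vector arithmetic, no shortcuts
.oracle_scan_one <- function(v, gvec, max_mm, allow_bulge, nag) {
  L <- length(v)
  if (L < 22L) return(NULL)
  acgt <- v %in% c("A", "C", "G", "T")
  # PAM validity per start position
  pam_ok <- function(p) {
    p2 <- v[p + 1L]
    acgt[p] && !is.na(p2) && v[p + 2L] == "G" &&
      (p2 == "G" || (nag && p2 == "A"))
  }
  rows <- list()
  add <- function(ws, wlen, bulge, gap, mm) {
    rows[[length(rows) + 1L]] <<- c(ws, wlen, bulge, gap, mm)
  }
  # alignment evaluators, window given as indices ws..ws+wlen-1
  for (ws in seq_len(L)) {
    for (wlen in c(20L, 21L, 19L)) {
      if (wlen != 20L && !allow_bulge) next
      we <- ws + wlen - 1L
      p <- we + 1L                       # PAM start
      if (we > L || p + 2L > L) next
      if (!pam_ok(p)) next
      win <- v[ws:we]
      if (!all(win %in% c("A", "C", "G", "T"))) next
      if (wlen == 20L) {
        mm <- sum(win != gvec)
        if (mm <= max_mm) add(ws, 20L, 0L, 0L, mm)
      } else if (wlen == 21L) {
        for (j in 2L:20L) {              # unpaired genomic base, internal
          mm <- sum(win[-j] != gvec)
          if (mm <= max_mm) add(ws, 21L, 1L, j, mm)
        }
      } else {
        for (k in 2L:19L) {              # unpaired guide base, internal
          mm <- sum(win != gvec[-k])
          if (mm <= max_mm) add(ws, 19L, 2L, k, mm)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  m <- do.call(rbind, rows)
  cand <- data.frame(window_start = m[, 1L], window_len = m[, 2L],
                     bulge = m[, 3L], gap_pos = m[, 4L], mismatches = m[, 5L])
  cand$pam_start <- cand$window_start + cand$window_len
  # canonical choice per PAM position: (bulge_size, mm), none < DNA < RNA,
  # leftmost gap
  cand$bsize <- ifelse(cand$bulge == 0L, 0L, 1L)
  o <- order(cand$pam_start, cand$bsize, cand$mismatches, cand$bulge,
             cand$gap_pos)
  cand <- cand[o, , drop = FALSE]
  cand <- cand[!duplicated(cand$pam_start), , drop = FALSE]
  cand$pam_class <- ifelse(v[cand$pam_start + 1L] == "G", 1L, 2L)
  # mismatch positions in guide coordinates
  cand$mm_positions <- vapply(seq_len(nrow(cand)), function(i) {
    ws <- cand$window_start[i]; wlen <- cand$window_len[i]
    win <- v[ws:(ws + wlen - 1L)]
    if (cand$bulge[i] == 1L) {
      pos <- which(win[-cand$gap_pos[i]] != gvec)
    } else if (cand$bulge[i] == 2L) {
      gk <- gvec[-cand$gap_pos[i]]
      pos <- which(win != gk)
      pos <- ifelse(pos < cand$gap_pos[i], pos, pos + 1L)
    } else {
      pos <- which(win != gvec)
    }
    paste(pos, collapse = ",")
  }, character(1))
  cand[, c("pam_start", "window_start", "window_len", "mismatches", "bulge",
           "gap_pos", "pam_class", "mm_positions")]
}

#' Expected blunt-cut position of sites
#'
#' Returns, for each site, the 0-based genomic coordinate of protospacer
#' position 18 (the base on the PAM side of the blunt cut, 3 bp 5' of the
#' PAM), strand-aware. For bulged alignments the position is computed on the
#' genomic coordinates of the aligned window via its PAM.
#'
#' @param sites an \linkS4class{OfftargetSites} (or GRanges with strand).
#' @param cut_offset bases 5' of the PAM at which Cas9 cuts (default 3).
#' @return integer vector of 0-based genomic positions.
#' @export
cutSite <- function(sites, cut_offset = 3L) {
  plus <- as.character(GenomicRanges::strand(sites)) == "+"
  ifelse(plus,
         GenomicRanges::end(sites) - 3L - as.integer(cut_offset),
         GenomicRanges::start(sites) + 1L + as.integer(cut_offset))
}

#' Positional mismatch profile of a site set
#'
#' Counts mismatches at each protospacer position 1..20 (position 20
#' PAM-proximal, position 1 PAM-distal) across the given sites; bulged
#' sites additionally contribute one count to a separate \code{gap} bucket.
#'
#' @param sites an \linkS4class{OfftargetSites}.
#' @return named integer vector \code{pos1..pos20, gap}.
#' @export
mismatchPositionProfile <- function(sites) {
  prof <- stats::setNames(integer(21L), c(paste0("pos", 1:20), "gap"))
  if (length(sites) == 0L) return(prof)
  mm <- S4Vectors::mcols(sites)$mm_positions
  pos <- unlist(lapply(strsplit(mm[mm != ""], ",", fixed = TRUE), as.integer))
  if (length(pos)) {
    tab <- table(factor(pos, levels = 1:20))
    prof[1:20] <- as.integer(tab)
  }
  prof["gap"] <- sum(S4Vectors::mcols(sites)$bulge_type != "none")
  prof
}

#' Write or read a site table (TSV)
#'
#' Tab-separated with columns guide_id, contig, start, end, strand,
#' aligned_target, mismatches, bulge_type, pam_seq, pam_class (plus the
#' remaining site metadata).
#'
#' @param sites an \linkS4class{OfftargetSites}.
#' @param path file path.
#' @export
writeSiteTable <- function(sites, path) {
  df <- as.data.frame(sites)
  df <- df[, c("guide_id", "seqnames", "start", "end", "strand",
               "aligned_target", "mismatches", "bulge_type", "bulge_size",
               "gap_pos", "mm_positions", "pam_seq", "pam_class",
               "is_on_target")]
  colnames(df)[colnames(df) == "seqnames"] <- "contig"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteTable
#' @param genome \code{DNAStringSet} the sites refer to.
#' @export
readSiteTable <- function(path, genome) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .sites_from_frame(df, genome)
}

#' Export sites as BED6 for interval tooling
#' @param sites an \linkS4class{OfftargetSites}.
#' @param path output BED file.
#' @export
sitesToBed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                               IRanges::ranges(sites),
                               strand = GenomicRanges::strand(sites))
  gr$name <- S4Vectors::mcols(sites)$guide_id
  gr$score <- S4Vectors::mcols(sites)$mismatches
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
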