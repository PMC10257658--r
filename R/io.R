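## core formats: FASTA genome, VCF small variants and SVs, BED intervals,
## guide tables. Interval arithmetic everywhere else uses GRanges (1-based,
## closed); BED's 0-based half-open coordinates are converted here at the
## boundary by rtracklayer.

#' Read a reference genome from FASTA
#'
#' Sequences are returned as an uppercase \code{DNAStringSet}; record order
#' is preserved and names are truncated at the first whitespace. The
#' canonical contig list (used by default contig exclusion) is stored in
#' \code{metadata()$canonical_contigs} and defaults to all records.
#'
#' @param path FASTA file.
#' @param canonical_contigs optional character vector naming the contigs to
#'   treat as canonical.
#' @return a \code{DNAStringSet}.
#' @export
readGenome <- function(path, canonical_contigs = NULL) {
  genome <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e)
                       stop("malformed FASTA '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate contig name in FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]),
               collapse = ", "))
  if (is.null(canonical_contigs)) canonical_contigs <- names(genome)
  if (!all(canonical_contigs %in% names(genome)))
    stop("canonical_contigs must be a subset of FASTA contig names")
  S4Vectors::metadata(genome)$canonical_contigs <- canonical_contigs
  genome
}

#' Write a genome to FASTA
#' @param genome a \code{DNAStringSet}.
#' @param path output file.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' BED's native 0-based half-open coordinates are converted to the package's
#' GRanges (1-based, closed) representation; \code{writeIntervals} inverts
#' the conversion so write-then-read round-trips exactly.
#'
#' @param path BED3/BED6 file.
#' @return a \code{GRanges}.
#' @export
readIntervals <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path)
  if (any(raw[[2]] < 0)) stop("negative start coordinate in BED: ", path)
  if (any(raw[[2]] >= raw[[3]]))
    stop("start >= end in BED (empty or inverted interval): ", path)
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::metadata(gr) <- list()
  gr
}

#' Write intervals to a BED file
#' @param gr a \code{GRanges} (1-based, closed).
#' @param path output BED file.
#' @export
writeIntervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a guide table
#'
#' Tab-separated with header columns \code{guide_id}, \code{protospacer},
#' \code{pam_rule} and \code{target_gene}; extra columns (founder
#' assignment, planted coordinates) are preserved. Protospacers must be
#' exactly 20 nt of A/C/G/T and guide ids unique.
#'
#' @param path TSV file.
#' @return data.frame, one row per guide.
#' @export
readGuideTable <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateGuides(g)
  g
}

#' @rdname readGuideTable
#' @param guides guide data.frame.
#' @export
writeGuideTable <- function(guides, path) {
  validateGuides(guides)
  utils::write.table(guides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a guide table against the type invariants
#' @param guides data.frame with at least \code{guide_id},
#'   \code{protospacer}, \code{pam_rule}.
#' @return the table, invisibly; errors on violation.
#' @export
validateGuides <- function(guides) {
  need <- c("guide_id", "protospacer", "pam_rule")
  if (!all(need %in% colnames(guides)))
    stop("guide table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(guides$guide_id)) stop("guide_id values must be unique")
  if (any(nchar(guides$protospacer) != 20L))
    stop("protospacer length must be exactly 20")
  if (any(grepl("[^ACGT]", guides$protospacer)))
    stop("protospacer may contain only A/C/G/T")
  if (!all(guides$pam_rule %in% c("NGG-only", "NGG+NAG")))
    stop("pam_rule must be 'NGG-only' or 'NGG+NAG'")
  invisible(guides)
}

## ---- small-variant records ----

.variant_cols <- c("sample_id", "contig", "pos", "ref", "alt", "vtype",
                   "genotype", "qual", "depth", "gq", "af", "ad_ref",
                   "ad_alt")

#' Validate a small-variant call table
#'
#' One row per ALT allele. Checks the record invariants: \code{vtype} is
#' \code{SNV} iff both alleles have length 1, \code{pos >= 1}, \code{af} in
#' \[0, 1\], allelic depths non-negative.
#'
#' @param variants data.frame of variant records.
#' @return the table, invisibly; errors on violation.
#' @export
validateVariants <- function(variants) {
  miss <- setdiff(.variant_cols, colnames(variants))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(variants) == 0L) return(invisible(variants))
  if (any(variants$pos < 1L)) stop("pos must be >= 1")
  snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  if (!all(variants$vtype == ifelse(snv, "SNV", "indel")))
    stop("vtype must be SNV iff len(ref) == len(alt) == 1")
  if (!all(variants$genotype %in% c("het", "hom_alt", "missing")))
    stop("genotype must be het/hom_alt/missing")
  af <- variants$af[!is.na(variants$af)]
  if (length(af) && (min(af) < 0 || max(af) > 1)) stop("af must be in [0,1]")
  ad <- c(variants$ad_ref, variants$ad_alt)
  if (any(ad[!is.na(ad)] < 0)) stop("allelic depths must be >= 0")
  invisible(variants)
}

.parse_gt_field <- function(gt, key) {
  # gt: FORMAT-keyed strings "GT:AD:DP:GQ", values "0/1:10,10:20:99"
  fmt <- strsplit(gt$FORMAT, ":", fixed = TRUE)
  val <- strsplit(gt$value, ":", fixed = TRUE)
  vapply(seq_along(fmt), function(i) {
    k <- match(key, fmt[[i]])
    if (is.na(k) || k > length(val[[i]])) NA_character_ else val[[i]][k]
  }, character(1))
}

#' Read small-variant records from a VCF
#'
#' Returns one record per ALT allele: multi-allelic rows are split before
#' any downstream filtering. \code{vtype} derives from allele lengths,
#' genotypes map to het/hom_alt/missing (phased treated as unphased), and
#' \code{af} is \code{ad_alt / (ad_ref + ad_alt)} when AD is present, else
#' the AF FORMAT/INFO field.
#'
#' @param path VCF file with FORMAT fields GT, DP, GQ, AD (AF used as
#'   fallback when AD is absent).
#' @param sample_id label attributed to every record; defaults to the VCF
#'   sample column name.
#' @return data.frame of variant records (see \code{\link{validateVariants}}).
#' @export
readVariants <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)   # single-row VCF drops dims
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (is.null(n) || n == 0L) {
    out <- data.frame(sample_id = character(0), contig = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), vtype = character(0),
                      genotype = character(0), qual = numeric(0),
                      depth = integer(0), gq = numeric(0), af = numeric(0),
                      ad_ref = integer(0), ad_alt = integer(0))
    return(out)
  }
  if (ncol(v@gt) < 2L) stop("VCF has no sample genotype column: ", path)
  if (is.null(sample_id)) sample_id <- colnames(v@gt)[2L]
  gt <- data.frame(FORMAT = v@gt[, 1L], value = v@gt[, 2L],
                   stringsAsFactors = FALSE)
  gts <- .parse_gt_field(gt, "GT")
  dps <- suppressWarnings(as.integer(.parse_gt_field(gt, "DP")))
  gqs <- suppressWarnings(as.numeric(.parse_gt_field(gt, "GQ")))
  ads <- .parse_gt_field(gt, "AD")
  afs <- suppressWarnings(as.numeric(.parse_gt_field(gt, "AF")))

  rows <- lapply(seq_len(n), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    adv <- if (is.na(ads[i])) NULL else
      suppressWarnings(as.integer(strsplit(ads[i], ",", fixed = TRUE)[[1]]))
    alleles <- if (is.na(gts[i]) || gts[i] %in% c(".", "./.", ".|.")) NULL else
      suppressWarnings(as.integer(strsplit(gsub("\\|", "/", gts[i]),
                                           "/", fixed = FALSE)[[1]]))
    do.call(rbind, lapply(seq_along(alts), function(a) {
      geno <- if (is.null(alleles) || anyNA(alleles)) "missing"
              else if (sum(alleles == a) == length(alleles)) "hom_alt"
              else if (any(alleles == a)) "het"
              else return(NULL)  # this ALT not carried by the genotype
      ad_ref <- if (!is.null(adv) && length(adv) >= 1L) adv[1L] else NA_integer_
      ad_alt <- if (!is.null(adv) && length(adv) >= a + 1L) adv[a + 1L] else NA_integer_
      af <- if (!is.na(ad_ref) && !is.na(ad_alt) && ad_ref + ad_alt > 0)
        ad_alt / (ad_ref + ad_alt) else afs[i]
      data.frame(sample_id = sample_id, contig = fix$CHROM[i],
                 pos = as.integer(fix$POS[i]), ref = fix$REF[i],
                 alt = alts[a],
                 vtype = if (nchar(fix$REF[i]) == 1L && nchar(alts[a]) == 1L)
                   "SNV" else "indel",
                 genotype = geno,
                 qual = suppressWarnings(as.numeric(fix$QUAL[i])),
                 depth = dps[i], gq = gqs[i], af = af,
                 ad_ref = ad_ref, ad_alt = ad_alt,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validateVariants(out)
  out
}

#' Write small-variant records to a VCF
#'
#' Emits one VCF row per record (records that originated from a split
#' multi-allelic row are written as separate rows) with FORMAT
#' \code{GT:AD:DP:GQ}, so \code{readVariants(writeVariants(x))} preserves
#' contig, pos, ref, alt, genotype, DP, GQ and AD for every record.
#'
#' @param variants variant record data.frame.
#' @param path output VCF.
#' @param sample_id VCF sample column name; defaults to the (single)
#'   sample_id in the table.
#' @param genome optional \code{DNAStringSet} used to emit contig headers.
#' @export
writeVariants <- function(variants, path, sample_id = NULL, genome = NULL) {
  validateVariants(variants)
  if (is.null(sample_id)) {
    sample_id <- if (nrow(variants)) unique(variants$sample_id) else "sample"
    if (length(sample_id) != 1L)
      stop("supply sample_id when writing a multi-sample table")
  }
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          Biostrings::width(genome)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample_id),
                      collapse = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    v <- variants[order(variants$contig, variants$pos, variants$ref,
                        variants$alt), , drop = FALSE]
    gt <- c(het = "0/1", hom_alt = "1/1", missing = "./.")[v$genotype]
    ad <- ifelse(is.na(v$ad_ref) | is.na(v$ad_alt), ".",
                 paste(v$ad_ref, v$ad_alt, sep = ","))
    body <- paste(v$contig, v$pos, ".", v$ref, v$alt,
                  ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE)),
                  "PASS", ".", "GT:AD:DP:GQ",
                  paste(gt, ad,
                        ifelse(is.na(v$depth), ".", v$depth),
                        ifelse(is.na(v$gq), ".", v$gq), sep = ":"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- SV records ----

.sv_cols <- c("sample_id", "contig", "start", "end", "svtype", "callers",
              "support_reads", "sv_length", "genotype")

#' Validate an SV call table
#' @param svs data.frame of SV records (1-based inclusive \code{start}/
#'   \code{end}; \code{callers} a comma-separated provenance string).
#' @return the table, invisibly; errors on violation.
#' @export
validateSVs <- function(svs) {
  miss <- setdiff(.sv_cols, colnames(svs))
  if (length(miss))
    stop("SV table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(svs) == 0L) return(invisible(svs))
  if (!all(svs$svtype %in% c("DEL", "DUP", "INV", "INS", "BND")))
    stop("svtype must be DEL/DUP/INV/INS/BND")
  if (any(svs$sv_length[!is.na(svs$sv_length)] < 0))
    stop("sv_length must be >= 0")
  nb <- svs$svtype != "BND"
  if (any(svs$end[nb] < svs$start[nb])) stop("end must be >= start")
  invisible(svs)
}

.info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(?:^|;)", key, "="), info)
  out[hit] <- sub(paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1", info[hit])
  out
}

#' Read structural-variant records from a VCF
#'
#' Caller provenance is read from an INFO key (default \code{CALLERS},
#' comma-separated) and read support from another (default \code{SU});
#' SVTYPE, END and SVLEN follow the VCF SV convention.
#'
#' @param path SV VCF file.
#' @param sample_id label for the records; defaults to the sample column.
#' @param callers_key,support_key INFO key names.
#' @return data.frame of SV records (see \code{\link{validateSVs}}).
#' @export
readSVs <- function(path, sample_id = NULL, callers_key = "CALLERS",
                    support_key = "SU") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fixm)) && length(fixm)) fixm <- t(fixm)
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (is.null(nrow(fix)) || nrow(fix) == 0L) {
    return(data.frame(sample_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      svtype = character(0), callers = character(0),
                      support_reads = integer(0), sv_length = integer(0),
                      genotype = character(0)))
  }
  if (is.null(sample_id))
    sample_id <- if (ncol(v@gt) >= 2L) colnames(v@gt)[2L] else "sample"
  gtv <- if (ncol(v@gt) >= 2L) {
    gt <- data.frame(FORMAT = v@gt[, 1L], value = v@gt[, 2L],
                     stringsAsFactors = FALSE)
    .parse_gt_field(gt, "GT")
  } else rep(NA_character_, nrow(fix))
  geno <- ifelse(is.na(gtv) | gtv %in% c(".", "./.", ".|."), "missing",
          ifelse(gtv %in% c("0/0", "0|0"), "hom_ref",
          ifelse(gtv %in% c("1/1", "1|1"), "hom_alt", "het")))
  svtype <- .info_field(fix$INFO, "SVTYPE")
  endp <- suppressWarnings(as.integer(.info_field(fix$INFO, "END")))
  svlen <- suppressWarnings(as.integer(.info_field(fix$INFO, "SVLEN")))
  out <- data.frame(
    sample_id = sample_id, contig = fix$CHROM,
    start = as.integer(fix$POS),
    end = ifelse(is.na(endp), as.integer(fix$POS), endp),
    svtype = svtype,
    callers = .info_field(fix$INFO, callers_key),
    support_reads = suppressWarnings(
      as.integer(.info_field(fix$INFO, support_key))),
    sv_length = abs(svlen),
    genotype = geno, stringsAsFactors = FALSE)
  out$sv_length[is.na(out$sv_length)] <- out$end[is.na(out$sv_length)] -
    out$start[is.na(out$sv_length)] + 1L
  validateSVs(out)
  out
}

#' Write structural-variant records to a VCF
#' @param svs SV record data.frame.
#' @param path output VCF.
#' @param sample_id VCF sample column name.
#' @param genome optional \code{DNAStringSet} for contig headers.
#' @export
writeSVs <- function(svs, path, sample_id = NULL, genome = NULL) {
  validateSVs(svs)
  if (is.null(sample_id)) {
    sample_id <- if (nrow(svs)) unique(svs$sample_id) else "sample"
    if (length(sample_id) != 1L)
      stop("supply sample_id when writing a multi-sample table")
  }
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=CALLERS,Number=.,Type=String,Description="Supporting callers">',
           '##INFO=<ID=SU,Number=1,Type=Integer,Description="Supporting reads">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          Biostrings::width(genome)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample_id),
                      collapse = "\t"))
  body <- character(0)
  if (nrow(svs)) {
    s <- svs[order(svs$contig, svs$start, svs$end), , drop = FALSE]
    gt <- c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0",
            missing = "./.")[s$genotype]
    sgn <- ifelse(s$svtype == "DEL", -1L, 1L)
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;CALLERS=%s;SU=%d",
                    s$svtype, s$end, sgn * s$sv_length, s$callers,
                    s$support_reads)
    body <- paste(s$contig, s$start, ".", "N", paste0("<", s$svtype, ">"),
                  ".", "PASS", info, "GT", gt, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- identity, normalization, coordinates ----

#' Left-normalize variant alleles against a genome
#'
#' Trims shared allele suffixes, then shared prefixes (advancing
#' \code{pos}), then left-aligns pure insertions/deletions by shifting while
#' the reference base preceding the event equals the last base of the varied
#' sequence. Variant identity everywhere in the package is the normalized
#' 4-tuple (contig, pos, ref, alt).
#'
#' @param variants variant record data.frame.
#' @param genome \code{DNAStringSet} (required to left-shift indels; with
#'   \code{NULL} only prefix/suffix trimming is applied).
#' @return the table with normalized \code{pos}, \code{ref}, \code{alt}.
#' @export
normalizeVariants <- function(variants, genome = NULL) {
  if (nrow(variants) == 0L) return(variants)
  seqs <- if (!is.null(genome)) as.character(genome) else NULL
  # most records are already minimal: SNVs, and anchored indels whose
  # alleles do not share a trailing base (nothing to trim or roll)
  lr <- nchar(variants$ref); la <- nchar(variants$alt)
  lastr <- substr(variants$ref, lr, lr)
  lasta <- substr(variants$alt, la, la)
  todo <- which((lr > 1L & la > 1L) |
                  (xor(lr > 1L, la > 1L) & lastr == lasta))
  for (i in todo) {
    ref <- variants$ref[i]; alt <- variants$alt[i]; pos <- variants$pos[i]
    s <- if (!is.null(seqs)) seqs[[variants$contig[i]]] else NULL
    if (ref != alt) {
      # canonical left-alignment: trim a shared trailing base, and when an
      # allele empties extend both to the left from the reference
      repeat {
        lr <- nchar(ref); la <- nchar(alt)
        if (lr > 0L && la > 0L &&
            substr(ref, lr, lr) == substr(alt, la, la) &&
            !(lr == 1L && la == 1L)) {
          ref <- substr(ref, 1L, lr - 1L)
          alt <- substr(alt, 1L, la - 1L)
        } else if ((lr == 0L || la == 0L)) {
          if (is.null(s) || pos <= 1L) break
          prev <- substr(s, pos - 1L, pos - 1L)
          ref <- paste0(prev, ref); alt <- paste0(prev, alt)
          pos <- pos - 1L
        } else break
      }
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        # at contig start (or no genome): re-anchor on the right
        nxt <- if (!is.null(s)) substr(s, pos + nchar(ref), pos + nchar(ref))
               else "N"
        ref <- paste0(ref, nxt); alt <- paste0(alt, nxt)
      }
      # trim shared leading bases, keeping the indel anchor
      while (nchar(ref) > 1L && nchar(alt) > 1L &&
             substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
        pos <- pos + 1L
      }
    }
    variants$pos[i] <- pos; variants$ref[i] <- ref; variants$alt[i] <- alt
  }
  variants$vtype <- ifelse(nchar(variants$ref) == 1L &
                           nchar(variants$alt) == 1L, "SNV", "indel")
  variants
}

#' Variant identity tuples
#' @param variants variant record data.frame.
#' @return character key "contig:pos:ref:alt" per record.
#' @export
variantKey <- function(variants) {
  paste(variants$contig, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Reference span of variant records as GRanges
#'
#' SNVs cover a single base; indels cover \code{[pos, pos + len(ref) - 1]}
#' (the left-anchored reference span, anchor base included).
#'
#' @param variants variant record data.frame.
#' @return \code{GRanges}, one range per record.
#' @export
variantRanges <- function(variants) {
  if (nrow(variants) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(variants$contig,
                         IRanges::IRanges(variants$pos,
                                          variants$pos +
                                            nchar(variants$ref) - 1L))
}

#' Convert between GRanges and 0-based half-open (BED-style) coordinates
#'
#' Round trips are the identity; these are the only places the package
#' changes coordinate convention.
#'
#' @param gr a \code{GRanges}.
#' @return \code{toBedFrame}: data.frame with \code{contig}, \code{start}
#'   (0-based), \code{end} (exclusive); \code{fromBedFrame}: a GRanges.
#' @export
toBedFrame <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' @rdname toBedFrame
#' @param bed data.frame with 0-based half-open \code{contig}, \code{start},
#'   \code{end}.
#' @export
fromBedFrame <- function(bed) {
  GenomicRanges::GRanges(bed$contig,
                         IRanges::IRanges(bed$start + 1L, bed$end))
}
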