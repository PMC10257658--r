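## Synthetic cohort generator: a complete toy study (genome, guide designs,
## colony variation, Cas9 edits, caller-style call sets, interval files)
## with a record-for-record truth ledger, so every pipeline stage can be
## validated without any external data.

#' Cohort generation configuration
#'
#' Defaults emulate the study conditions of a multi-centre founder audit:
#' 28 controls and 50 founders on an inbred background split into two
#' substrains, ~756 private SNVs and ~276 private indels per mouse (mostly
#' heterozygous), spontaneous de novo rates of ~25 SNVs and ~1.5 indels per
#' generation, substrain-shared homozygous variants, an ancestral variant
#' pool partially present in the known-variant database, 2-4 guides per
#' founder flanking a critical exon, an on-target deletion seen by a panel
#' of 4 SV callers, and off-target indels whose probability decays with the
#' mismatch count of the predicted site. The per-mismatch decay values are
#' synthetic stand-ins (real per-mismatch rates are not established); they
#' are chosen so that both positive and negative cases occur at the default
#' cohort size.
#'
#' @param seed integer seed driving the whole generation.
#' @param n_contigs,contig_length genome shape (default 3 x 300 kb).
#' @param n_controls,n_founders cohort sizes (defaults 28, 50).
#' @param guides_per_founder integer vector sampled per founder (2-4).
#' @param shared_per_substrain homozygous variants fixed in each of the two
#'   substrains.
#' @param ancestral_pool size of the colony-ancestral variant pool carried
#'   by every mouse; a \code{known_db_fraction} of it is also listed in the
#'   known-variant database.
#' @param known_db_fraction see above.
#' @param snv_mean,indel_mean Poisson means of private variants per mouse.
#' @param het_fraction fraction of private variants that are heterozygous.
#' @param de_novo_snv,de_novo_indel Poisson means of per-generation de novo
#'   variants added to every mouse.
#' @param repeat_fraction fraction of the genome embedded as low-complexity
#'   repeat runs (with matching repeat intervals).
#' @param n_repeat_variants variants planted inside repeat runs per mouse.
#' @param callable_fraction per-sample callable fraction; uncallable gaps
#'   are drawn from a fixed pool of gap zones covering twice the
#'   complement, each zone dropped per sample with probability 1/2.
#' @param offtarget_edit_probs probability of an off-target indel at a
#'   predicted site with 0, 1, 2, 3 and >= 4 mismatches (non-increasing).
#' @param sv_caller_panel,sv_caller_detect_prob caller panel for the
#'   on-target deletion and each caller's detection probability.
#' @param n_single_caller_founders founders (taken from the end of the
#'   founder list) whose on-target deletion is deliberately observed by a
#'   single caller, emulating a consensus-filter miss.
#' @param qual_fail_fraction fraction of records given a deliberately
#'   failing quality annotation (one random stage among QUAL/DP/GQ/AF and,
#'   for hets, allele ratio); 0 disables failure tails.
#' @param enforce_design_rule reject guides with a second NGG site at < 3
#'   mismatches (the guide-design rule); disable only for testing.
#' @param search \code{\link{searchConfig}} used to enumerate the predicted
#'   sites at which off-target edits may be injected.
#' @return list of class \code{cas9audit_cohort_config}.
#' @export
cohortConfig <- function(seed = 1L, n_contigs = 3L, contig_length = 300000L,
                         n_controls = 28L, n_founders = 50L,
                         guides_per_founder = 2:4,
                         shared_per_substrain = 60L,
                         ancestral_pool = 300L, known_db_fraction = 0.5,
                         snv_mean = 756, indel_mean = 276,
                         het_fraction = 0.8,
                         de_novo_snv = 25, de_novo_indel = 1.5,
                         repeat_fraction = 0.05,
                         n_repeat_variants = 30L,
                         callable_fraction = 0.95,
                         offtarget_edit_probs = c(1, 0.25, 0.05, 0.01,
                                                  0.001),
                         sv_caller_panel = c("lumpy", "manta", "cnvkit",
                                             "wham"),
                         sv_caller_detect_prob = 0.9,
                         n_single_caller_founders = 1L,
                         qual_fail_fraction = 0.02,
                         enforce_design_rule = TRUE,
                         search = searchConfig()) {
  stopifnot(n_controls >= 1L, n_founders >= 1L,
            all(offtarget_edit_probs >= 0),
            all(offtarget_edit_probs <= 1),
            all(diff(offtarget_edit_probs) <= 0),
            length(offtarget_edit_probs) == 5L,
            known_db_fraction >= 0, known_db_fraction <= 1,
            het_fraction >= 0, het_fraction <= 1,
            callable_fraction > 0.5, callable_fraction < 1)
  structure(as.list(environment()), class = "cas9audit_cohort_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# place `n` non-overlapping widths into [lo, hi] avoiding `occupied`
# (IRanges), with `buffer`; returns IRanges (may be shorter than n if space
# runs out after max tries)
.place_regions <- function(n, width, lo, hi, occupied, buffer = 20L,
                           tries = 400L) {
  placed <- IRanges::IRanges()
  for (i in seq_len(n)) {
    done <- FALSE
    for (t in seq_len(tries)) {
      s <- sample.int(hi - lo - width + 1L, 1L) + lo - 1L
      cand <- IRanges::IRanges(s, s + width - 1L)
      pad <- IRanges::IRanges(max(1L, s - buffer), s + width - 1L + buffer)
      if (length(IRanges::findOverlaps(pad, occupied)) == 0L &&
          length(IRanges::findOverlaps(pad, placed)) == 0L) {
        placed <- c(placed, cand); done <- TRUE; break
      }
    }
    if (!done) break
  }
  placed
}

#' Generate a synthetic genome with repeats, gap zones and annotation
#'
#' Random A/C/G/T contigs; a \code{repeat_fraction} of the genome is
#' overwritten with low-complexity motif runs and recorded as repeat
#' intervals; a pool of "gap zones" (regions eligible to be uncallable in
#' individual samples) covers twice the complement of
#' \code{callable_fraction}; gene bodies with 5 exons each are placed so
#' that exonic/intronic/intergenic classification is non-trivial, one gene
#' per founder plus spares.
#'
#' Call inside a seeded context (\code{\link{generateCohort}} seeds once
#' for the whole generation).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{genome} (DNAStringSet), \code{repeats},
#'   \code{gap_zones} (GRanges), \code{annotation} (exons, gene_bodies)
#'   and \code{genes} (data.frame incl. critical exon coordinates).
#' @export
generateGenome <- function(config) {
  L <- config$contig_length
  ctgs <- paste0("chr", seq_len(config$n_contigs))
  n_genes <- config$n_founders + 6L
  gene_len <- 6000L
  if (L < 20000L) stop("contig_length too small for the requested features")
  seqs <- vapply(ctgs, function(ct) .rand_dna(L), character(1))

  rep_len_bp <- 500L
  n_rep <- max(1L, round(config$repeat_fraction * L / rep_len_bp))
  zone_len <- 1000L
  n_zone <- max(1L, round(2 * (1 - config$callable_fraction) * L / zone_len))
  motifs <- c("A", "T", "AT", "CA", "AG", "AAT", "CAG")

  repeats <- GenomicRanges::GRanges(); gaps <- GenomicRanges::GRanges()
  genes_df <- list(); exons <- GenomicRanges::GRanges()
  gene_bodies <- GenomicRanges::GRanges()
  genes_per_ctg <- diff(round(seq(0, n_genes, length.out =
                                    config$n_contigs + 1L)))
  for (ci in seq_along(ctgs)) {
    ct <- ctgs[ci]
    # largest features first so fragmentation cannot starve them
    occupied <- IRanges::IRanges()
    gb <- .place_regions(genes_per_ctg[ci], gene_len, 2000L, L - 2000L,
                         occupied, buffer = 300L)
    occupied <- c(occupied, gb)
    gz <- .place_regions(n_zone, zone_len, 1000L, L - 1000L, occupied)
    occupied <- c(occupied, gz)
    rp <- .place_regions(n_rep, rep_len_bp, 1000L, L - 1000L, occupied,
                         buffer = 50L)
    occupied <- c(occupied, rp)
    # overwrite repeat runs with low-complexity motifs
    s <- seqs[[ct]]
    for (k in seq_along(rp)) {
      motif <- sample(motifs, 1L)
      run <- strrep(motif, ceiling(rep_len_bp / nchar(motif)))
      substr(s, IRanges::start(rp)[k], IRanges::end(rp)[k]) <-
        substr(run, 1L, rep_len_bp)
    }
    seqs[[ct]] <- s
    gaps <- suppressWarnings(c(gaps, GenomicRanges::GRanges(ct, gz)))
    repeats <- suppressWarnings(c(repeats, GenomicRanges::GRanges(ct, rp)))
    gene_bodies <- suppressWarnings(
      c(gene_bodies, GenomicRanges::GRanges(ct, gb)))
    for (k in seq_along(gb)) {
      gs <- IRanges::start(gb)[k]
      ex <- IRanges::IRanges(gs + c(400L, 1600L, 2800L, 4000L, 5200L),
                             width = 200L)
      exons <- suppressWarnings(c(exons, GenomicRanges::GRanges(ct, ex)))
      genes_df[[length(genes_df) + 1L]] <- data.frame(
        gene = sprintf("gene_%s_%02d", ct, k), contig = ct,
        start = gs, end = gs + gene_len - 1L,
        crit_start = gs + 2800L, crit_end = gs + 2999L,
        stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- ctgs
  list(genome = genome, repeats = sort(repeats), gap_zones = sort(gaps),
       annotation = list(exons = sort(exons),
                         gene_bodies = sort(gene_bodies)),
       genes = do.call(rbind, genes_df))
}

#' Check the guide-design rule
#'
#' A guide passes when it has no genomic site at fewer than 3 mismatches
#' adjacent to an NGG PAM other than its own exact on-target locus.
#'
#' @param protospacer 20-nt guide sequence.
#' @param genome \code{DNAStringSet}.
#' @return TRUE/FALSE.
#' @export
checkGuideDesign <- function(protospacer, genome) {
  cfg <- searchConfig(max_mismatches = 2L, allow_bulge = FALSE,
                      pam_rule = "NGG-only", exclude_contigs = character(0))
  g <- data.frame(guide_id = "chk", protospacer = protospacer,
                  pam_rule = "NGG-only", stringsAsFactors = FALSE)
  sites <- enumerateSites(g, genome, cfg)
  sum(S4Vectors::mcols(sites)$mismatches < 3L) <= 1L
}

# pick a plus-strand guide whose cut lands within [lo, hi] on `seq`
.pick_guide <- function(seq_chr, lo, hi) {
  # PAM start p needs G at p+1 and p+2; cut0 = p - 4
  cand <- c()
  for (p in (lo + 4L):(hi + 4L)) {
    if (substr(seq_chr, p + 1L, p + 2L) == "GG") cand <- c(cand, p)
  }
  if (!length(cand)) return(NULL)
  cand <- cand[cand > 24L]
  if (!length(cand)) return(NULL)
  p <- if (length(cand) == 1L) cand else sample(cand, 1L)
  list(pam_start = p, protospacer = substr(seq_chr, p - 20L, p - 1L),
       cut0 = p - 4L)
}

#' Plant guide designs and decoy near-match loci
#'
#' For each founder, chooses 2-4 plus-strand guides from the genome itself
#' whose cuts flank the critical exon of the founder's target gene, checks
#' the design rule (no second NGG site at < 3 mismatches), and plants decoy
#' near-match loci for every guide at controlled mismatch distances
#' (NAG-adjacent at 1-2 mismatches, NGG-adjacent at 3-6; random strand) so
#' the search stage has known positives without violating the design rule.
#'
#' @param geno output of \code{\link{generateGenome}} (mutated genome is
#'   returned).
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{genome} (decoys written in), \code{guides}
#'   (guide table with founder assignment and cut positions) and
#'   \code{planted_sites} (decoy ledger).
#' @export
plantGuides <- function(geno, config) {
  founders <- sprintf("F%02d", seq_len(config$n_founders))
  genes <- geno$genes
  if (nrow(genes) < config$n_founders) stop("not enough genes for founders")
  gidx <- sample(nrow(genes), config$n_founders)
  seqs <- as.character(geno$genome)
  guides <- list(); decoys <- list()
  # reserve decoy space away from genes/repeats/gap zones
  occupied <- lapply(names(geno$genome), function(ct) {
    grl <- c(geno$repeats, geno$gap_zones, geno$annotation$gene_bodies)
    IRanges::ranges(grl[GenomicRanges::seqnames(grl) == ct])
  })
  names(occupied) <- names(geno$genome)

  for (fi in seq_along(founders)) {
    fid <- founders[fi]
    gene <- genes[gidx[fi], ]
    ct <- gene$contig
    ng <- if (length(config$guides_per_founder) == 1L)
      config$guides_per_founder else sample(config$guides_per_founder, 1L)
    # cut windows: upstream/downstream of the critical exon, well separated
    wins <- list(c(gene$crit_start - 320L, gene$crit_start - 40L),
                 c(gene$crit_end + 40L, gene$crit_end + 320L),
                 c(gene$crit_start - 650L, gene$crit_start - 360L),
                 c(gene$crit_end + 360L, gene$crit_end + 650L))[seq_len(ng)]
    for (k in seq_len(ng)) {
      gid <- sprintf("%s_g%d", fid, k)
      ok <- FALSE
      for (t in 1:40) {
        pick <- .pick_guide(seqs[[ct]], wins[[k]][1], wins[[k]][2])
        if (is.null(pick)) break
        if (grepl("[^ACGT]", pick$protospacer)) next
        if (!config$enforce_design_rule ||
            checkGuideDesign(pick$protospacer, geno$genome)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place a design-compliant guide for ", fid,
                    "; try a larger genome")
      guides[[length(guides) + 1L]] <- data.frame(
        guide_id = gid, protospacer = pick$protospacer,
        pam_rule = "NGG+NAG", target_gene = gene$gene, sample_id = fid,
        contig = ct, strand = "+", pam_start = pick$pam_start,
        cut_pos = pick$cut0, stringsAsFactors = FALSE)
      # decoys: mm 1-2 next to NAG, mm 3-6 next to NGG
      specs <- data.frame(mm = 1:6,
                          pam2 = c("A", "A", "G", "G", "G", "G"))
      for (d in seq_len(nrow(specs))) {
        mm <- specs$mm[d]
        proto <- strsplit(pick$protospacer, "")[[1]]
        at <- sample(20L, mm)
        for (p in at)
          proto[p] <- sample(setdiff(c("A", "C", "G", "T"), proto[p]), 1L)
        pam <- paste0(sample(c("A", "C", "G", "T"), 1L), specs$pam2[d], "G")
        ins <- paste0(paste(proto, collapse = ""), pam)
        dct <- sample(names(geno$genome), 1L)
        Lc <- Biostrings::width(geno$genome)[match(dct, names(geno$genome))]
        spot <- .place_regions(1L, 23L, 500L, Lc - 500L, occupied[[dct]],
                               buffer = 30L)
        if (length(spot) == 0L) stop("no free space left for decoy sites")
        occupied[[dct]] <- c(occupied[[dct]], spot)
        a <- IRanges::start(spot)
        strand <- sample(c("+", "-"), 1L)
        planted <- if (strand == "+") ins else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(ins)))
        substr(seqs[[dct]], a, a + 22L) <- planted
        decoys[[length(decoys) + 1L]] <- data.frame(
          guide_id = gid, sample_id = fid, contig = dct, start = a,
          end = a + 22L, strand = strand, mm = mm,
          pam_class = ifelse(specs$pam2[d] == "G", "NGG", "NAG"),
          cut0 = if (strand == "+") a + 15L else a + 4L,
          stringsAsFactors = FALSE)
      }
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(geno$genome)
  list(genome = genome, guides = do.call(rbind, guides),
       planted_sites = do.call(rbind, decoys))
}

# quality annotations: passing draws with configurable failure tails
.assign_quality <- function(n, genotype, fail_fraction) {
  depth <- pmax(12L, stats::rpois(n, 35))
  qual <- pmax(35, round(stats::rnorm(n, 200, 50)))
  gq <- sample(60:99, n, replace = TRUE)
  het <- genotype == "het"
  ad_alt <- ifelse(het,
                   pmin(pmax(stats::rbinom(n, depth, 0.5),
                             ceiling(0.3 * depth)), floor(0.7 * depth)),
                   depth)
  fail <- stats::runif(n) < fail_fraction
  stage <- rep(NA_character_, n)
  if (any(fail)) {
    pool <- ifelse(het, 5L, 4L)
    pick <- floor(stats::runif(sum(fail)) * pool[fail]) + 1L
    stage[fail] <- c("qual", "dp", "gq", "af", "ratio")[pick]
    i <- which(fail)
    qual[i][stage[i] == "qual"] <- round(stats::runif(
      sum(stage[i] == "qual"), 5, 29))
    j <- i[stage[i] == "dp"]
    depth[j] <- sample(3:9, length(j), replace = TRUE)
    ad_alt[j] <- ifelse(het[j], pmax(1L, round(depth[j] / 2)), depth[j])
    gq[i][stage[i] == "gq"] <- round(stats::runif(
      sum(stage[i] == "gq"), 5, 29))
    j <- i[stage[i] == "af"]
    ad_alt[j] <- pmax(1L, floor(0.06 * depth[j]))
    j <- i[stage[i] == "ratio"]
    ad_alt[j] <- pmax(2L, ceiling(0.15 * depth[j]))
  }
  ad_ref <- ifelse(genotype == "het", depth - ad_alt, 0L)
  data.frame(qual = qual, depth = depth, gq = gq,
             af = ad_alt / (ad_ref + ad_alt),
             ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt),
             passes_quality = !fail, fail_stage = stage,
             stringsAsFactors = FALSE)
}

# build allele strings for planted variants at given positions
.make_alleles <- function(seqs, contig, pos, vtype) {
  n <- length(pos)
  ref <- character(n); alt <- character(n)
  base <- vapply(seq_len(n), function(i)
    substr(seqs[[contig[i]]], pos[i], pos[i]), character(1))
  snv <- vtype == "SNV"
  alt[snv] <- vapply(which(snv), function(i)
    sample(setdiff(c("A", "C", "G", "T"), base[i]), 1L), character(1))
  ref[snv] <- base[snv]
  for (i in which(!snv)) {
    if (stats::runif(1) < 0.5) {          # deletion of 1-8 bases
      dl <- sample(1:8, 1L)
      ref[i] <- substr(seqs[[contig[i]]], pos[i], pos[i] + dl)
      alt[i] <- base[i]
    } else {                              # insertion of 1-8 bases
      il <- sample(1:8, 1L)
      ref[i] <- base[i]
      alt[i] <- paste0(base[i], .rand_dna(il))
    }
  }
  list(ref = ref, alt = alt)
}

#' Generate colony variation, known-variant database and callable space
#'
#' Plants, per mouse: all ancestral-pool variants (homozygous; a configured
#' fraction of the pool is also written to the known-variant database),
#' the mouse's substrain-shared homozygous pool, private and de novo
#' variants at globally unique positions (so cross-sample sharing is
#' controlled exactly), and variants inside repeat runs. Quality
#' annotations come from passing distributions with configurable failure
#' tails. Per-sample callable intervals are the genome minus a per-sample
#' draw of gap zones; planted variants avoid all gap zones, so they lie in
#' every sample's callable space.
#'
#' @param geno genome bundle (after \code{\link{plantGuides}} the planted
#'   genome should be substituted into it).
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{samples}, \code{variants} (including truth
#'   columns \code{category}, \code{passes_quality}, \code{fail_stage}),
#'   \code{known}, \code{callable}.
#' @export
generateColony <- function(geno, config) {
  seqs <- as.character(geno$genome)
  ctgs <- names(geno$genome)
  samples <- data.frame(
    sample_id = c(sprintf("C%02d", seq_len(config$n_controls)),
                  sprintf("F%02d", seq_len(config$n_founders))),
    group = rep(c("control", "founder"),
                c(config$n_controls, config$n_founders)),
    stringsAsFactors = FALSE)
  samples$substrain <- rep_len(c("B6N-a", "B6N-b"), nrow(samples))
  samples$center <- rep_len(paste0("center", 1:4), nrow(samples))

  # position pool outside padded repeats and gap zones (margin covers the
  # repeat pad plus the longest indel span)
  excl <- c(geno$repeats, geno$gap_zones)
  pool <- do.call(rbind, lapply(ctgs, function(ct) {
    L <- nchar(seqs[[ct]])
    ex <- IRanges::ranges(excl[GenomicRanges::seqnames(excl) == ct])
    ex <- IRanges::IRanges(pmax(1L, IRanges::start(ex) - 14L),
                           pmin(L, IRanges::end(ex) + 14L))
    cov <- IRanges::coverage(ex, width = L)
    ok <- which(as.vector(cov) == 0L)
    ok <- ok[ok > 30L & ok < L - 30L]
    data.frame(contig = ct, pos = ok, stringsAsFactors = FALSE)
  }))
  # repeat-interior pool
  rpool <- do.call(rbind, lapply(ctgs, function(ct) {
    rp <- IRanges::ranges(geno$repeats[
      GenomicRanges::seqnames(geno$repeats) == ct])
    if (length(rp) == 0L) return(NULL)
    p <- unlist(lapply(seq_along(rp), function(k)
      seq(IRanges::start(rp)[k] + 5L, IRanges::end(rp)[k] - 15L, by = 3L)))
    data.frame(contig = ct, pos = p, stringsAsFactors = FALSE)
  }))

  nsamp <- nrow(samples)
  n_priv_snv <- stats::rpois(nsamp, config$snv_mean)
  n_priv_ind <- stats::rpois(nsamp, config$indel_mean)
  n_dn_snv <- stats::rpois(nsamp, config$de_novo_snv)
  n_dn_ind <- stats::rpois(nsamp, config$de_novo_indel)

  n_anc <- config$ancestral_pool
  n_sub <- config$shared_per_substrain * 2L
  n_total <- n_anc + n_sub + sum(n_priv_snv, n_priv_ind, n_dn_snv, n_dn_ind)
  if (n_total > nrow(pool))
    stop("genome too small for the requested variant load")
  take <- pool[sample(nrow(pool), n_total), , drop = FALSE]
  cursor <- 0L
  nxt <- function(n) {
    out <- take[(cursor + 1L):(cursor + n), , drop = FALSE]
    cursor <<- cursor + n
    out
  }

  # ancestral pool: hom in every mouse; a fraction is in the known db
  anc <- nxt(n_anc)
  anc$vtype <- sample(c("SNV", "indel"), n_anc, replace = TRUE,
                      prob = c(0.75, 0.25))
  al <- .make_alleles(seqs, anc$contig, anc$pos, anc$vtype)
  anc$ref <- al$ref; anc$alt <- al$alt
  anc$known <- seq_len(n_anc) %in%
    sample(n_anc, round(config$known_db_fraction * n_anc))

  # substrain-shared pools
  sub <- nxt(n_sub)
  sub$vtype <- sample(c("SNV", "indel"), n_sub, replace = TRUE,
                      prob = c(0.75, 0.25))
  al <- .make_alleles(seqs, sub$contig, sub$pos, sub$vtype)
  sub$ref <- al$ref; sub$alt <- al$alt
  sub$substrain <- rep(c("B6N-a", "B6N-b"), each = config$shared_per_substrain)

  # repeat-run variants: per-sample positions drawn from the repeat pool
  n_rep_var <- config$n_repeat_variants
  rtake <- if (!is.null(rpool) && nsamp * n_rep_var <= nrow(rpool))
    rpool[sample(nrow(rpool), nsamp * n_rep_var), , drop = FALSE] else NULL

  rows <- list()
  for (si in seq_len(nsamp)) {
    sid <- samples$sample_id[si]
    strain <- samples$substrain[si]
    # ancestral (hom)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, contig = anc$contig, pos = anc$pos, ref = anc$ref,
      alt = anc$alt, vtype = anc$vtype, genotype = "hom_alt",
      category = ifelse(anc$known, "ancestral_known", "ancestral_shared"),
      stringsAsFactors = FALSE)
    # substrain pool (hom)
    ss <- sub[sub$substrain == strain, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, contig = ss$contig, pos = ss$pos, ref = ss$ref,
      alt = ss$alt, vtype = ss$vtype, genotype = "hom_alt",
      category = "substrain_shared", stringsAsFactors = FALSE)
    # private + de novo
    for (cat in c("private", "de_novo")) {
      ns <- if (cat == "private") n_priv_snv[si] else n_dn_snv[si]
      ni <- if (cat == "private") n_priv_ind[si] else n_dn_ind[si]
      if (ns + ni == 0L) next
      pv <- nxt(ns + ni)
      pv$vtype <- rep(c("SNV", "indel"), c(ns, ni))
      al <- .make_alleles(seqs, pv$contig, pv$pos, pv$vtype)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, contig = pv$contig, pos = pv$pos, ref = al$ref,
        alt = al$alt, vtype = pv$vtype,
        genotype = ifelse(stats::runif(ns + ni) < config$het_fraction,
                          "het", "hom_alt"),
        category = cat, stringsAsFactors = FALSE)
    }
    # repeat-run variants (SNVs; spans must stay inside the run)
    if (!is.null(rtake)) {
      rv <- rtake[((si - 1L) * n_rep_var + 1L):(si * n_rep_var), ,
                  drop = FALSE]
      al <- .make_alleles(seqs, rv$contig, rv$pos,
                          rep("SNV", nrow(rv)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, contig = rv$contig, pos = rv$pos, ref = al$ref,
        alt = al$alt, vtype = "SNV",
        genotype = ifelse(stats::runif(nrow(rv)) < config$het_fraction,
                          "het", "hom_alt"),
        category = "repeat", stringsAsFactors = FALSE)
    }
  }
  variants <- data.table::rbindlist(rows)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  q <- .assign_quality(nrow(variants), variants$genotype,
                       config$qual_fail_fraction)
  variants <- cbind(variants, q)

  # known-variant database (hom, nominal annotations)
  kn <- anc[anc$known, , drop = FALSE]
  known <- data.frame(sample_id = "known_db", contig = kn$contig,
                      pos = kn$pos, ref = kn$ref, alt = kn$alt,
                      vtype = kn$vtype, genotype = "hom_alt", qual = 100,
                      depth = 30L, gq = 99, af = 1, ad_ref = 0L,
                      ad_alt = 30L, stringsAsFactors = FALSE)

  # per-sample callable space: genome minus a private draw of gap zones
  tiles <- geno$gap_zones
  whole <- GenomicRanges::GRanges(ctgs,
                                  IRanges::IRanges(1L, nchar(seqs[ctgs])))
  callable <- lapply(seq_len(nsamp), function(si) {
    drop <- tiles[stats::runif(length(tiles)) < 0.5]
    GenomicRanges::setdiff(whole, drop, ignore.strand = TRUE)
  })
  names(callable) <- samples$sample_id

  list(samples = samples, variants = variants, known = known,
       callable = callable)
}

#' Apply Cas9 editing outcomes to the founder samples
#'
#' Injects, per founder: the on-target deletion spanning the outermost
#' guide cut sites as an SV DEL observed by a random subset of the caller
#' panel (a configured number of founders is forced to a single caller,
#' emulating a consensus miss), and, for each predicted off-target site of
#' the founder's guides, a small heterozygous indel at the cut position
#' with probability decaying in the site's mismatch count. Injected edits
#' only occur where the cut lies in confidently callable, non-repetitive
#' space.
#'
#' @param colony output of \code{\link{generateColony}}.
#' @param guides guide table from \code{\link{plantGuides}}.
#' @param sites_per_guide \linkS4class{OfftargetSites} enumerated for those
#'   guides on the planted genome.
#' @param geno genome bundle (planted genome, repeats, gap zones).
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{variants} (colony variants plus injected
#'   off-target indels), \code{svs}, \code{ontarget} truth table and
#'   \code{edits} truth table.
#' @export
applyCas9 <- function(colony, guides, sites_per_guide, geno, config) {
  seqs <- as.character(geno$genome)
  founders <- unique(guides$sample_id)
  panel <- config$sv_caller_panel
  single <- utils::tail(founders, config$n_single_caller_founders)
  excl <- GenomicRanges::reduce(c(
    GenomicRanges::resize(geno$repeats,
                          GenomicRanges::width(geno$repeats) + 28L,
                          fix = "center"),
    GenomicRanges::resize(geno$gap_zones,
                          GenomicRanges::width(geno$gap_zones) + 28L,
                          fix = "center")))
  sv_rows <- list(); ot_rows <- list(); edit_rows <- list()
  var_add <- list()
  used_keys <- variantKey(colony$variants)
  site_guide <- S4Vectors::mcols(sites_per_guide)$guide_id
  site_ot <- S4Vectors::mcols(sites_per_guide)$is_on_target
  site_mm <- S4Vectors::mcols(sites_per_guide)$mismatches
  cut0 <- cutSite(sites_per_guide)

  for (fid in founders) {
    g <- guides[guides$sample_id == fid, , drop = FALSE]
    cuts <- sort(g$cut_pos)
    del_start <- min(cuts) + 1L; del_end <- max(cuts)
    if (del_end - del_start + 1L > nchar(seqs[[g$contig[1]]]))
      stop("deletion span exceeds contig")
    det <- if (fid %in% single) sample(panel, 1L) else
      panel[stats::runif(length(panel)) < config$sv_caller_detect_prob]
    if (length(det) == 0L) det <- sample(panel, 1L)
    sv_rows[[length(sv_rows) + 1L]] <- data.frame(
      sample_id = fid, contig = g$contig[1], start = del_start,
      end = del_end, svtype = "DEL",
      callers = paste(sort(det), collapse = ","),
      support_reads = stats::rpois(1L, 20) + 3L,
      sv_length = del_end - del_start + 1L, genotype = "het",
      stringsAsFactors = FALSE)
    ot_rows[[length(ot_rows) + 1L]] <- data.frame(
      sample_id = fid, target_gene = g$target_gene[1],
      contig = g$contig[1], start = del_start, end = del_end,
      n_callers = length(det),
      callers = paste(sort(det), collapse = ","),
      stringsAsFactors = FALSE)

    # off-target indels at this founder's predicted sites
    sel <- which(site_guide %in% g$guide_id & !site_ot)
    for (i in sel) {
      mm <- site_mm[i]
      p <- config$offtarget_edit_probs[min(mm, 4L) + 1L]
      if (stats::runif(1) >= p) next
      ct <- as.character(GenomicRanges::seqnames(sites_per_guide))[i]
      cpos <- cut0[i]                     # 0-based; 1-based anchor = cpos
      if (cpos < 10L || cpos > nchar(seqs[[ct]]) - 20L) next
      # the planned deletion region is not a separate off-target locus
      if (ct == g$contig[1] && cpos >= del_start - 10L &&
          cpos <= del_end + 10L) next
      span <- GenomicRanges::GRanges(ct, IRanges::IRanges(cpos - 3L,
                                                          cpos + 12L))
      if (GenomicRanges::countOverlaps(span, excl) > 0L) next
      if (stats::runif(1) < 0.7) {        # deletion 1-6 bp
        dl <- sample(1:6, 1L)
        ref <- substr(seqs[[ct]], cpos, cpos + dl)
        alt <- substr(seqs[[ct]], cpos, cpos)
      } else {                            # insertion 1-3 bp
        ref <- substr(seqs[[ct]], cpos, cpos)
        alt <- paste0(ref, .rand_dna(sample(1:3, 1L)))
      }
      key <- paste(ct, cpos, ref, alt, sep = ":")
      if (key %in% used_keys) next
      used_keys <- c(used_keys, key)
      q <- .assign_quality(1L, "het", config$qual_fail_fraction)
      var_add[[length(var_add) + 1L]] <- cbind(
        data.frame(sample_id = fid, contig = ct, pos = cpos, ref = ref,
                   alt = alt, vtype = "indel", genotype = "het",
                   category = "offtarget_edit", stringsAsFactors = FALSE),
        q)
      edit_rows[[length(edit_rows) + 1L]] <- data.frame(
        sample_id = fid, guide_id = site_guide[i], contig = ct,
        pos = cpos, ref = ref, alt = alt, site_mm = mm,
        site_start = GenomicRanges::start(sites_per_guide)[i],
        site_end = GenomicRanges::end(sites_per_guide)[i],
        passes_quality = q$passes_quality, stringsAsFactors = FALSE)
    }
  }
  variants <- rbind(colony$variants,
                    if (length(var_add)) do.call(rbind, var_add))
  svs <- do.call(rbind, sv_rows)
  list(variants = variants, svs = svs,
       ontarget = do.call(rbind, ot_rows),
       edits = if (length(edit_rows)) do.call(rbind, edit_rows) else
         data.frame(sample_id = character(0), guide_id = character(0),
                    contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    site_mm = integer(0), site_start = integer(0),
                    site_end = integer(0), passes_quality = logical(0),
                    stringsAsFactors = FALSE))
}

#' Generate a complete synthetic cohort
#'
#' Seeds once, then runs \code{\link{generateGenome}},
#' \code{\link{plantGuides}}, \code{\link{generateColony}}, enumerates the
#' predicted sites of every planted guide, and \code{\link{applyCas9}}.
#' Identical configs (including seed) reproduce the cohort exactly.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{Cas9Cohort}.
#' @export
generateCohort <- function(config = cohortConfig()) {
  set.seed(config$seed)
  geno <- generateGenome(config)
  pg <- plantGuides(geno, config)
  geno$genome <- pg$genome
  colony <- generateColony(geno, config)
  sites <- enumerateSites(pg$guides, geno$genome, config$search)
  edited <- applyCas9(colony, pg$guides, sites, geno, config)

  truth_variants <- edited$variants[, c("sample_id", "contig", "pos", "ref",
                                        "alt", "vtype", "genotype",
                                        "category", "passes_quality",
                                        "fail_stage")]
  variants <- edited$variants[, .variant_cols]
  cfg <- config
  cfg$search <- unclass(config$search)
  new("Cas9Cohort", genome = geno$genome, guides = pg$guides,
      variants = variants, svs = edited$svs, known = colony$known,
      repeats = geno$repeats, callable = colony$callable,
      annotation = geno$annotation, samples = colony$samples,
      truth = list(variants = truth_variants,
                   planted_sites = pg$planted_sites,
                   ontarget = edited$ontarget,
                   edits = edited$edits,
                   predicted_sites = as.data.frame(sites),
                   gap_zones = geno$gap_zones),
      config = unclass(cfg))
}

#' Write a cohort to disk in standard formats
#'
#' Emits the genome FASTA, the guide table, per-sample small-variant and SV
#' VCFs, the known-variant VCF, repeat/callable/annotation BEDs, the truth
#' ledger as tab-separated files, and a JSON manifest recording the
#' generation config and seed. Re-running emission for the same cohort
#' object produces byte-identical files.
#'
#' @param cohort a \linkS4class{Cas9Cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
emitCohort <- function(cohort, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  for (d in c("variants", "svs", "callable", "annotation", "truth"))
    dir.create(file.path(dir, d), showWarnings = FALSE)
  writeGenome(cohort@genome, file.path(dir, "genome.fa"))
  writeGuideTable(cohort@guides, file.path(dir, "guides.tsv"))
  writeVariants(cohort@known, file.path(dir, "known.vcf"),
                sample_id = "known_db", genome = cohort@genome)
  writeIntervals(cohort@repeats, file.path(dir, "repeats.bed"))
  writeIntervals(cohort@annotation$exons,
                 file.path(dir, "annotation", "exons.bed"))
  writeIntervals(cohort@annotation$gene_bodies,
                 file.path(dir, "annotation", "gene_bodies.bed"))
  for (sid in cohort@samples$sample_id) {
    writeVariants(cohort@variants[cohort@variants$sample_id == sid, ,
                                  drop = FALSE],
                  file.path(dir, "variants", paste0(sid, ".vcf")),
                  sample_id = sid, genome = cohort@genome)
    writeSVs(cohort@svs[cohort@svs$sample_id == sid, , drop = FALSE],
             file.path(dir, "svs", paste0(sid, ".sv.vcf")),
             sample_id = sid, genome = cohort@genome)
    writeIntervals(cohort@callable[[sid]],
                   file.path(dir, "callable", paste0(sid, ".bed")))
  }
  utils::write.table(cohort@samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("variants", "planted_sites", "ontarget", "edits",
               "predicted_sites"))
    utils::write.table(cohort@truth[[nm]],
                       file.path(dir, "truth", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = cohort@config[setdiff(names(cohort@config),
                                                  character(0))],
                   n_samples = nrow(cohort@samples),
                   n_guides = nrow(cohort@guides))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read an emitted cohort back from disk
#'
#' @param dir directory written by \code{\link{emitCohort}}.
#' @param with_truth also load the truth ledger (default TRUE).
#' @return a \linkS4class{Cas9Cohort}.
#' @export
readCohort <- function(dir, with_truth = TRUE) {
  genome <- readGenome(file.path(dir, "genome.fa"))
  guides <- readGuideTable(file.path(dir, "guides.tsv"))
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  variants <- do.call(rbind, lapply(samples$sample_id, function(sid)
    readVariants(file.path(dir, "variants", paste0(sid, ".vcf")),
                 sample_id = sid)))
  svs <- do.call(rbind, lapply(samples$sample_id, function(sid)
    readSVs(file.path(dir, "svs", paste0(sid, ".sv.vcf")),
            sample_id = sid)))
  callable <- lapply(samples$sample_id, function(sid)
    readIntervals(file.path(dir, "callable", paste0(sid, ".bed"))))
  names(callable) <- samples$sample_id
  truth <- list()
  if (with_truth && dir.exists(file.path(dir, "truth")))
    truth <- lapply(stats::setNames(nm = c("variants", "planted_sites",
                                           "ontarget", "edits",
                                           "predicted_sites")),
                    function(nm)
                      utils::read.delim(file.path(dir, "truth",
                                                  paste0(nm, ".tsv")),
                                        stringsAsFactors = FALSE))
  new("Cas9Cohort", genome = genome, guides = guides, variants = variants,
      svs = svs,
      known = readVariants(file.path(dir, "known.vcf"),
                           sample_id = "known_db"),
      repeats = readIntervals(file.path(dir, "repeats.bed")),
      callable = callable,
      annotation = list(
        exons = readIntervals(file.path(dir, "annotation", "exons.bed")),
        gene_bodies = readIntervals(file.path(dir, "annotation",
                                              "gene_bodies.bed"))),
      samples = samples, truth = truth,
      config = list())
}
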