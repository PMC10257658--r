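# Shared fixtures, all generated in code. The default-scale cohort and its
# pipeline run are expensive, so they are built once per test run and
# memoised for every test that needs them.

.fixture_env <- new.env(parent = emptyenv())

# a random single-contig genome named so that default contig exclusion
# keeps it
random_genome <- function(L, n_contigs = 1L, withN = 0L) {
  seqs <- vapply(seq_len(n_contigs), function(i) {
    v <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (withN > 0L) v[sample(L, withN)] <- "N"
    paste(v, collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(n_contigs))
  g
}

random_protospacer <- function() {
  paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
}

guide_row <- function(protospacer, pam_rule = "NGG+NAG", id = "g1") {
  data.frame(guide_id = id, protospacer = protospacer, pam_rule = pam_rule,
             stringsAsFactors = FALSE)
}

# canonical data.frame view of a site set for set comparisons
site_frame <- function(sites) {
  df <- as.data.frame(sites)
  df <- df[, c("seqnames", "start", "end", "strand", "mismatches",
               "bulge_type", "gap_pos", "pam_class", "mm_positions")]
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# plant `insert` into a genome string at 1-based position a (forward) or as
# its reverse complement
plant_seq <- function(genome, contig, pos, insert, strand = "+") {
  s <- as.character(genome)
  if (strand == "-")
    insert <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(insert)))
  substr(s[[contig]], pos, pos + nchar(insert) - 1L) <- insert
  out <- Biostrings::DNAStringSet(s)
  names(out) <- names(genome)
  out
}

# a small but complete cohort for structural tests
small_cohort_config <- function(seed = 11L, ...) {
  defaults <- list(seed = seed, n_controls = 4L, n_founders = 4L,
                   contig_length = 120000L, snv_mean = 150, indel_mean = 50,
                   ancestral_pool = 80L, shared_per_substrain = 25L,
                   n_repeat_variants = 12L, qual_fail_fraction = 0)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(cohortConfig, defaults)
}

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generateCohort(small_cohort_config())
  }
  .fixture_env$small
}

# the default study-scale cohort (28 controls + 50 founders, 3 x 300 kb)
# and its pipeline run, shared across acceptance tests
default_cohort <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generateCohort(cohortConfig(seed = 20260919L))
  }
  .fixture_env$default
}

default_run <- function() {
  if (is.null(.fixture_env$default_run)) {
    .fixture_env$default_run <- suppressWarnings(runPipeline(default_cohort()))
  }
  .fixture_env$default_run
}

# truth-ledger edit keys "sample variantkey"
edit_keys <- function(edits) {
  paste(edits$sample_id,
        paste(edits$contig, edits$pos, edits$ref, edits$alt, sep = ":"))
}

hit_keys <- function(hits) paste(hits$sample_id, hits$variant_id)

# write a small VCF body with standard header for reader tests
write_test_vcf <- function(lines, path, sample = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, qual = 50, gt = "0/1",
                    ad = "10,10", dp = 20, gq = 99) {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT:AD:DP:GQ",
        paste(gt, ad, dp, gq, sep = ":"), sep = "\t")
}

# minimal variant record builder for filter tests
var_rec <- function(sample_id = "S1", contig = "chr1", pos = 100L,
                    ref = "A", alt = "T", genotype = "het", qual = 50,
                    depth = 20L, gq = 80, af = 0.5, ad_ref = 10L,
                    ad_alt = 10L) {
  data.frame(sample_id = sample_id, contig = contig, pos = pos, ref = ref,
             alt = alt,
             vtype = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
                            "indel"),
             genotype = genotype, qual = qual, depth = depth, gq = gq,
             af = af, ad_ref = ad_ref, ad_alt = ad_alt,
             stringsAsFactors = FALSE)
}

sv_rec <- function(sample_id = "S1", contig = "chr1", start = 1000L,
                   end = 1999L, svtype = "DEL", callers = "lumpy,manta",
                   support_reads = 5L, sv_length = end - start + 1L,
                   genotype = "het") {
  data.frame(sample_id = sample_id, contig = contig, start = start,
             end = end, svtype = svtype, callers = callers,
             support_reads = support_reads, sv_length = sv_length,
             genotype = genotype, stringsAsFactors = FALSE)
}
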