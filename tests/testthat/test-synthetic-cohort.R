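test_that("generation is deterministic given a config", {
  cfg <- small_cohort_config(seed = 77L, n_controls = 2L, n_founders = 2L,
                             contig_length = 60000L, snv_mean = 40,
                             indel_mean = 15, ancestral_pool = 30L,
                             shared_per_substrain = 10L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(as.character(refGenome(a)), as.character(refGenome(b)))
  expect_identical(variantCalls(a), variantCalls(b))
  expect_identical(svCalls(a), svCalls(b))
  expect_identical(guideTable(a), guideTable(b))
  # emission is byte-identical across runs
  d1 <- file.path(tempdir(), "emitA"); d2 <- file.path(tempdir(), "emitB")
  emitCohort(a, d1); emitCohort(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
})

test_that("genome features respect their configured geometry", {
  set.seed(1)
  cfg <- small_cohort_config()
  set.seed(cfg$seed)
  geno <- generateGenome(cfg)
  total <- sum(Biostrings::width(geno$genome))
  repfrac <- sum(GenomicRanges::width(geno$repeats)) / total
  expect_lt(abs(repfrac - cfg$repeat_fraction), 0.01)
  # every exon lies inside a gene body
  expect_true(all(GenomicRanges::countOverlaps(
    geno$annotation$exons, geno$annotation$gene_bodies,
    type = "within") > 0L))
  # repeat runs are genuinely low-complexity sequence
  s <- as.character(geno$genome[[1]])
  rp <- geno$repeats[GenomicRanges::seqnames(geno$repeats) == "chr1"][1]
  run <- substr(s, GenomicRanges::start(rp), GenomicRanges::end(rp))
  expect_lte(length(unique(strsplit(run, "")[[1]])), 3L)
})

test_that("planted guides have unique on-targets and compliant designs", {
  co <- small_cohort()
  g <- guideTable(co)
  cfg <- cohortConfigOf(co)
  expect_true(all(table(g$sample_id) >= 2L))
  # each guide has exactly one exact NGG match (its on-target locus)
  ngg0 <- searchConfig(0, allow_bulge = FALSE, pam_rule = "NGG-only")
  for (i in seq_len(min(4L, nrow(g)))) {
    s <- enumerateSites(g[i, ], refGenome(co), ngg0)
    expect_equal(sum(S4Vectors::mcols(s)$is_on_target), 1L)
  }
  # design rule: no second NGG site below 3 mismatches...
  expect_true(checkGuideDesign(g$protospacer[1], refGenome(co)))
  # ...and a planted 2-mismatch NGG decoy is rejected by the checker
  proto <- g$protospacer[1]
  pv <- strsplit(proto, "")[[1]]
  for (p in c(4, 15))
    pv[p] <- sample(setdiff(c("A", "C", "G", "T"), pv[p]), 1)
  viol <- plant_seq(refGenome(co), "chr1", 301,
                    paste0(paste(pv, collapse = ""), "TGG"))
  expect_false(checkGuideDesign(proto, viol))
})

test_that("the planted decoy ledger is recovered by the search at ceiling 6", {
  co <- small_cohort()
  decoys <- truthLedger(co)$planted_sites
  some <- decoys[decoys$guide_id %in% unique(decoys$guide_id)[1:3], ]
  cfg6 <- searchConfig(6)
  for (gid in unique(some$guide_id)) {
    g <- guideTable(co)[guideTable(co)$guide_id == gid, ]
    sites <- enumerateSites(g, refGenome(co), cfg6)
    df <- data.frame(contig = as.character(GenomicRanges::seqnames(sites)),
                     start = GenomicRanges::start(sites),
                     end = GenomicRanges::end(sites),
                     strand = as.character(GenomicRanges::strand(sites)),
                     mm = S4Vectors::mcols(sites)$mismatches)
    d <- some[some$guide_id == gid, ]
    found <- paste(d$contig, d$start, d$end, d$strand) %in%
      paste(df$contig, df$start, df$end, df$strand)
    expect_true(all(found), info = gid)
    idx <- match(paste(d$contig, d$start, d$end, d$strand),
                 paste(df$contig, df$start, df$end, df$strand))
    expect_equal(df$mm[idx], d$mm, info = gid)
  }
})

test_that("colony variants follow the configured composition", {
  co <- small_cohort()
  cfg <- cohortConfigOf(co)
  tv <- truthLedger(co)$variants
  # zygosity: shared pools homozygous; private mostly het
  expect_true(all(tv$genotype[tv$category %in%
    c("ancestral_known", "ancestral_shared", "substrain_shared")] ==
      "hom_alt"))
  priv <- tv[tv$category == "private", ]
  hetfrac <- mean(priv$genotype == "het")
  expect_lt(abs(hetfrac - cfg$het_fraction),
            3 * sqrt(0.8 * 0.2 / nrow(priv)) + 0.01)
  # class mix of private variants ~ snv_mean : indel_mean
  snvfrac <- mean(priv$vtype == "SNV")
  target <- cfg$snv_mean / (cfg$snv_mean + cfg$indel_mean)
  expect_lt(abs(snvfrac - target), 0.05)
  # substrain-mates share exactly the planted pool (plus the ancestral one)
  sheet <- sampleSheet(co)
  mates <- sheet$sample_id[sheet$substrain == "B6N-a"][1:2]
  k1 <- variantKey(tv[tv$sample_id == mates[1], ])
  k2 <- variantKey(tv[tv$sample_id == mates[2], ])
  common <- intersect(k1, k2)
  planted <- variantKey(tv[tv$sample_id == mates[1] & tv$category %in%
    c("ancestral_known", "ancestral_shared", "substrain_shared"), ])
  expect_setequal(common, planted)
  # every planted variant lies inside every sample's callable space
  vgr <- variantRanges(tv)
  for (sid in sheet$sample_id[1:3]) {
    inside <- GenomicRanges::countOverlaps(
      vgr[tv$category != "repeat"],
      GenomicRanges::reduce(callableIntervals(co)[[sid]]),
      type = "within") > 0L
    expect_true(all(inside), info = sid)
  }
})

test_that("Cas9 outcomes are injected per the edit model", {
  co <- small_cohort()
  tr <- truthLedger(co)
  sheet <- sampleSheet(co)
  founders <- sheet$sample_id[sheet$group == "founder"]
  # every founder carries exactly one on-target SV DEL
  expect_setequal(tr$ontarget$sample_id, founders)
  svs <- svCalls(co)
  expect_equal(nrow(svs), length(founders))
  expect_true(all(svs$svtype == "DEL"))
  expect_true(all(svs$sv_length > 200 & svs$sv_length < 5000))
  # the designated single-caller founder mirrors a consensus miss
  ncall <- tr$ontarget$n_callers
  expect_equal(sum(ncall == 1L), 1L)
  expect_equal(tr$ontarget$sample_id[ncall == 1L], utils::tail(founders, 1))
  # a null edit model injects nothing beyond forced 0-mismatch loci
  cfg0 <- small_cohort_config(seed = 301L, n_controls = 2L, n_founders = 2L,
                              contig_length = 60000L, snv_mean = 30,
                              indel_mean = 10, ancestral_pool = 20L,
                              shared_per_substrain = 5L,
                              offtarget_edit_probs = c(1, 0, 0, 0, 0))
  co0 <- generateCohort(cfg0)
  expect_true(all(truthLedger(co0)$edits$site_mm == 0L))
  # injected edits map to enumerable sites under the search config used
  ed <- tr$edits
  if (nrow(ed)) {
    ps <- truthLedger(co)$predicted_sites
    expect_true(all(paste(ed$guide_id, ed$contig, ed$site_start) %in%
                      paste(ps$guide_id, ps$seqnames, ps$start)))
  }
})

test_that("emitted cohorts reconcile with the truth ledger and reload", {
  co <- small_cohort()
  dir <- file.path(tempdir(), "emit_reload")
  emitCohort(co, dir)
  sheet <- sampleSheet(co)
  expect_equal(length(list.files(file.path(dir, "variants"))), nrow(sheet))
  expect_equal(length(list.files(file.path(dir, "svs"))), nrow(sheet))
  # every truth record appears in exactly one emitted VCF
  tv <- truthLedger(co)$variants
  back <- readCohort(dir)
  bk <- paste(variantCalls(back)$sample_id, variantKey(variantCalls(back)))
  tk <- paste(tv$sample_id, variantKey(tv))
  expect_setequal(bk, tk)
  expect_equal(anyDuplicated(tk), 0L)
  # reloaded records preserve annotations used by the filters
  ov <- variantCalls(co); bv <- variantCalls(back)
  o <- order(ov$sample_id, ov$contig, ov$pos, ov$ref, ov$alt)
  b <- order(bv$sample_id, bv$contig, bv$pos, bv$ref, bv$alt)
  for (col in c("genotype", "depth", "gq", "ad_ref", "ad_alt"))
    expect_equal(bv[[col]][b], ov[[col]][o], info = col)
  # intervals round-trip
  expect_equal(toBedFrame(repeatIntervals(back)),
               toBedFrame(repeatIntervals(co)))
  sid <- sheet$sample_id[1]
  expect_equal(toBedFrame(callableIntervals(back)[[sid]]),
               toBedFrame(callableIntervals(co)[[sid]]))
})
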