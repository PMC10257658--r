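test_that("quality thresholds are strict inequalities as printed", {
  # af = 0.15 passes AF > 0.1; hom-alt so the (separate) het-ratio rule
  # does not apply to this record
  pass <- var_rec(genotype = "hom_alt", qual = 31, depth = 10L, gq = 31,
                  af = 0.15, ad_ref = 17L, ad_alt = 3L)
  boundary <- rbind(
    transform(pass, qual = 30),        # QUAL > 30 fails at 30
    transform(pass, depth = 9L),       # DP > 9 fails at 9
    transform(pass, gq = 30),          # GQ > 30 fails at 30
    transform(pass, af = 0.1, ad_ref = 18L, ad_alt = 2L))  # AF > 0.1
  res <- primaryFilter(rbind(pass, boundary), config = filterConfig())
  expect_equal(nrow(res$variants), 1L)
  expect_equal(res$variants$qual, 31)
  st <- stageCounts(res$report)
  expect_equal(st$n_removed[st$stage == "quality"], 4L)
})

test_that("repeat filtering pads intervals by two bases on both sides", {
  # repeat occupies 0-based [100,110) = 1-based 101..110; a variant at
  # 0-based [110,111) = pos 111 is outside but the 2 bp pad reaches 112
  repeats <- fromBedFrame(data.frame(contig = "chr1", start = 100, end = 110))
  v <- rbind(var_rec(pos = 111L), var_rec(pos = 112L), var_rec(pos = 113L))
  res <- primaryFilter(v, repeats = repeats, config = filterConfig())
  expect_equal(res$variants$pos, 113L)
  res0 <- primaryFilter(v, repeats = repeats,
                        config = filterConfig(repeat_pad = 0L))
  expect_equal(res0$variants$pos, c(111L, 112L, 113L))
  # an indel reaching back into the pad is removed too
  vi <- var_rec(pos = 113L, ref = "ACGT", alt = "A")
  expect_equal(nrow(primaryFilter(vi, repeats = repeats,
                                  config = filterConfig())$variants), 1L)
  vi2 <- var_rec(pos = 108L, ref = "ACGTACGT", alt = "A")
  expect_equal(nrow(primaryFilter(vi2, repeats = repeats,
                                  config = filterConfig())$variants), 0L)
})

test_that("known-variant removal matches planted records exactly", {
  set.seed(31)
  v <- do.call(rbind, lapply(1:20, function(i)
    var_rec(sample_id = paste0("S", i %% 3 + 1), pos = 100L + 10L * i,
            ref = "A", alt = "T")))
  known_idx <- c(2, 5, 9, 13, 18)
  known <- v[known_idx, ]
  res <- primaryFilter(v, known = known, config = filterConfig())
  expect_equal(nrow(res$variants), 15L)
  expect_false(any(variantKey(res$variants) %in% variantKey(known)))
  st <- stageCounts(res$report)
  expect_equal(sum(st$n_removed[st$stage == "known"]), 5L)
  # positional mode matches same position, different allele
  shifted <- transform(known, alt = "G")
  res_t <- primaryFilter(shifted, known = known, config = filterConfig())
  expect_equal(nrow(res_t$variants), 5L)   # tuple mode: alleles differ
  res_p <- primaryFilter(shifted, known = known,
                         config = filterConfig(known_match = "position"))
  expect_equal(nrow(res_p$variants), 0L)
})

test_that("het allele-ratio floor removes low-ratio hets only", {
  v <- rbind(
    var_rec(ad_ref = 17L, ad_alt = 3L, af = 0.15),          # 0.15 < 0.2
    var_rec(ad_ref = 16L, ad_alt = 4L, af = 0.2),           # 0.2 kept
    var_rec(genotype = "hom_alt", ad_ref = 0L, ad_alt = 3L,
            af = 1, depth = 20L),                            # hom exempt
    var_rec(ad_ref = NA_integer_, ad_alt = NA_integer_, af = 0.15))
  res <- primaryFilter(v, config = filterConfig())
  expect_equal(nrow(res$variants), 2L)
  # row 4 lacked AD: the rule fell back to the af field (0.15 -> removed)
  expect_false(any(is.na(res$variants$ad_alt)))
  # a het with AD missing and af above the floor is retained via fallback
  norat <- var_rec(ad_ref = NA_integer_, ad_alt = NA_integer_, af = 0.5)
  expect_equal(nrow(primaryFilter(norat, config = filterConfig())$variants),
               1L)
})

test_that("callable intersection matches a per-base oracle", {
  # A = [0,100), B = [50,150) in 0-based half-open -> [50,100)
  a <- fromBedFrame(data.frame(contig = "chr1", start = 0, end = 100))
  b <- fromBedFrame(data.frame(contig = "chr1", start = 50, end = 150))
  int <- callableIntersection(list(A = a, B = b))
  expect_equal(toBedFrame(int), data.frame(contig = "chr1", start = 50,
                                           end = 100))
  expect_identical(toBedFrame(callableIntersection(list(A = a, B = a))),
                   toBedFrame(GenomicRanges::reduce(a)))
  # random sets vs per-base membership on a 1 kb contig
  set.seed(42)
  sets <- lapply(1:5, function(i) {
    st <- sort(sample(1:900, 8))
    GenomicRanges::reduce(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(st, st + sample(20:120, 8, TRUE))))
  })
  names(sets) <- paste0("S", 1:5)
  int <- callableIntersection(sets)
  member <- rep(TRUE, 1100)
  for (s in sets) {
    inset <- rep(FALSE, 1100)
    for (k in seq_along(s))
      inset[GenomicRanges::start(s)[k]:GenomicRanges::end(s)[k]] <- TRUE
    member <- member & inset
  }
  got <- rep(FALSE, 1100)
  for (k in seq_along(int))
    got[GenomicRanges::start(int)[k]:GenomicRanges::end(int)[k]] <- TRUE
  expect_identical(got, member)
  # empty sample empties the intersection with a warning
  expect_warning(empty <- callableIntersection(
    c(sets, list(Z = GenomicRanges::GRanges()))), "no callable")
  expect_length(empty, 0L)
})

test_that("callable filtering requires the full reference span inside", {
  iv <- fromBedFrame(data.frame(contig = "chr1", start = 100, end = 200))
  v <- rbind(var_rec(pos = 150L),
             var_rec(pos = 198L, ref = "ACGTT", alt = "A"),  # spills out
             var_rec(pos = 250L))
  res <- applyCallableFilter(v, iv)
  expect_equal(res$variants$pos, 150L)
})

test_that("secondary filter eliminates variants seen in 2+ samples", {
  shared <- var_rec(sample_id = "S1", pos = 500L)
  v <- rbind(shared, transform(shared, sample_id = "S2"),
             var_rec(sample_id = "S1", pos = 600L),
             # same tuple twice in ONE sample: distinct-sample count is 1
             var_rec(sample_id = "S3", pos = 700L),
             var_rec(sample_id = "S3", pos = 700L))
  res <- secondaryFilter(v, filterConfig())
  expect_false(any(res$variants$pos == 500L))
  expect_equal(sum(res$variants$pos == 700L), 2L)
  expect_equal(sum(res$variants$pos == 600L), 1L)
  expect_equal(nrow(res$shared), 1L)
})

test_that("SV consensus applies caller, support, length and genotype rules", {
  keep <- sv_rec(start = 10000L, end = 10999L, callers = "lumpy,manta",
                 support_reads = 3L)
  svs <- rbind(
    keep,
    sv_rec(start = 20000L, end = 20999L, callers = "lumpy",
           support_reads = 10L),                      # 1 caller
    sv_rec(start = 30000L, end = 30200L, sv_length = 200L),   # not > 200
    sv_rec(start = 40000L, end = 44999L, sv_length = 5000L),  # not < 5000
    sv_rec(start = 50000L, end = 50999L, genotype = "hom_ref"),
    sv_rec(start = 60000L, end = 60999L, genotype = "missing"),
    sv_rec(start = 70000L, end = 70999L, support_reads = 2L))
  res <- suppressMessages(svConsensusFilter(svs, filterConfig()))
  expect_equal(res$svs$start, 10000L)
  st <- stageCounts(res$report)
  expect_equal(st$n_removed[st$stage == "genotype"], 2L)
  expect_equal(st$n_removed[st$stage == "length"], 2L)
  # missing caller annotation is removed with a logged reason
  nocall <- sv_rec(callers = NA_character_)
  expect_message(res2 <- svConsensusFilter(rbind(keep, nocall),
                                           filterConfig()),
                 "without caller annotation")
  expect_equal(nrow(res2$svs), 1L)
  # shared-SV removal: both breakpoints within tolerance, same type,
  # different samples
  a <- sv_rec(sample_id = "S1", start = 10000L, end = 12000L)
  b <- sv_rec(sample_id = "S2", start = 10050L, end = 12060L)
  c2 <- sv_rec(sample_id = "S3", start = 10050L, end = 13000L) # end too far
  res3 <- svConsensusFilter(rbind(a, b, c2), filterConfig())
  expect_equal(res3$svs$sample_id, "S3")
})

test_that("the cascade is pure and anti-monotone with exact accounting", {
  set.seed(77)
  co <- small_cohort()
  v <- variantCalls(co)
  cfg <- filterConfig()
  r1 <- primaryFilter(v, knownVariants(co), repeatIntervals(co), cfg,
                      refGenome(co))
  r2 <- primaryFilter(v, knownVariants(co), repeatIntervals(co), cfg,
                      refGenome(co))
  expect_identical(r1$variants, r2$variants)
  expect_identical(stageCounts(r1$report), stageCounts(r2$report))
  st <- stageCounts(r1$report)
  expect_true(all(st$n_in - st$n_removed == st$n_out))
  # per-sample chaining: output of one stage is the input of the next
  for (sid in unique(st$sample_id)) {
    s <- st[st$sample_id == sid, ]
    expect_equal(s$n_in[-1], s$n_out[-nrow(s)])
  }
  expect_true(all(variantKey(r1$variants) %in% variantKey(v)))
})

test_that("known and repeat removals commute", {
  set.seed(78)
  co <- small_cohort()
  v <- variantCalls(co)[1:400, ]
  cfg <- filterConfig(min_qual = 0, min_dp = 0L, min_gq = 0, min_af = 0,
                      het_ratio_floor = 0)
  kr <- primaryFilter(
    primaryFilter(v, known = knownVariants(co), config = cfg)$variants,
    repeats = repeatIntervals(co), config = cfg)$variants
  rk <- primaryFilter(
    primaryFilter(v, repeats = repeatIntervals(co), config = cfg)$variants,
    known = knownVariants(co), config = cfg)$variants
  expect_identical(sort(variantKey(kr)), sort(variantKey(rk)))
})
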