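test_that("a planted exact protospacer+NGG locus is found as on-target", {
  set.seed(101)
  g <- random_genome(600)
  proto <- random_protospacer()
  g <- plant_seq(g, "chr1", 201, paste0(proto, "AGG"))
  cfg <- searchConfig(0, allow_bulge = FALSE, pam_rule = "NGG-only")
  sites <- enumerateSites(guide_row(proto, "NGG-only"), g, cfg)
  expect_equal(length(sites), 1L)
  mc <- S4Vectors::mcols(sites)
  expect_equal(mc$mismatches, 0L)
  expect_equal(mc$pam_class, "NGG")
  expect_true(mc$is_on_target)
  expect_equal(GenomicRanges::start(sites), 201L)
  expect_equal(GenomicRanges::end(sites), 223L)

  # a a second locus at 1 mismatch stays invisible at ceiling 0
  proto2 <- strsplit(proto, "")[[1]]
  proto2[7] <- setdiff(c("A", "C", "G", "T"), proto2[7])[1]
  g2 <- plant_seq(g, "chr1", 401, paste0(paste(proto2, collapse = ""), "TGG"))
  sites <- enumerateSites(guide_row(proto, "NGG-only"), g2, cfg)
  expect_equal(length(sites), 1L)
  expect_equal(GenomicRanges::start(sites), 201L)
  # and becomes visible at ceiling 1 with mismatches = 1
  sites <- enumerateSites(guide_row(proto, "NGG-only"), g2,
                          searchConfig(1, allow_bulge = FALSE,
                                       pam_rule = "NGG-only"))
  expect_equal(length(sites), 2L)
  expect_equal(sort(S4Vectors::mcols(sites)$mismatches), c(0L, 1L))
})

test_that("fast enumeration equals the brute-force oracle", {
  for (i in 1:8) {
    set.seed(300 + i)
    g <- random_genome(1200, withN = if (i %% 2) 0L else 6L)
    gu <- guide_row(random_protospacer())
    cfg <- searchConfig(max_mismatches = c(3L, 5L)[i %% 2 + 1L],
                        allow_bulge = i %% 3 != 0)
    expect_identical(site_frame(enumerateSites(gu, g, cfg)),
                     site_frame(oracleEnumerate(gu, g, cfg)),
                     info = paste("case", i))
  }
})

test_that("site sets are monotone in the mismatch ceiling and PAM rule", {
  set.seed(55)
  g <- random_genome(3000)
  gu <- guide_row(random_protospacer())
  keys <- function(s) paste(GenomicRanges::seqnames(s),
                            GenomicRanges::start(s),
                            GenomicRanges::strand(s))
  prev <- character(0)
  for (k in 0:6) {
    s <- enumerateSites(gu, g, searchConfig(k))
    expect_true(all(prev %in% keys(s)),
                info = paste("ceiling", k))
    prev <- keys(s)
  }
  ngg <- enumerateSites(gu, g, searchConfig(5, pam_rule = "NGG-only"))
  both <- enumerateSites(gu, g, searchConfig(5, pam_rule = "NGG+NAG"))
  expect_true(all(keys(ngg) %in% keys(both)))
  expect_true(all(S4Vectors::mcols(ngg)$pam_class == "NGG"))
})

test_that("reverse-complementing the genome mirrors the site set", {
  set.seed(77)
  g <- random_genome(2000)
  proto <- random_protospacer()
  gu <- guide_row(proto)
  # plant loci on both strands so the set is non-trivial
  pv <- strsplit(proto, "")[[1]]
  pv[c(3, 11)] <- c("A", "T")
  g <- plant_seq(g, "chr1", 401, paste0(proto, "TGG"))
  g <- plant_seq(g, "chr1", 901, paste0(paste(pv, collapse = ""), "CAG"),
                 strand = "-")
  cfg <- searchConfig(4)
  s1 <- enumerateSites(gu, g, cfg)
  expect_gt(length(s1), 1L)
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  s2 <- enumerateSites(gu, grc, cfg)
  expect_equal(length(s1), length(s2))
  L <- Biostrings::width(g)[1]
  # forward interval [s, e] maps to [L-e+1, L-s+1] with strand flipped
  m1 <- data.frame(start = L - GenomicRanges::end(s1) + 1L,
                   end = L - GenomicRanges::start(s1) + 1L,
                   strand = ifelse(as.character(
                     GenomicRanges::strand(s1)) == "+", "-", "+"),
                   mm = S4Vectors::mcols(s1)$mismatches)
  m2 <- data.frame(start = GenomicRanges::start(s2),
                   end = GenomicRanges::end(s2),
                   strand = as.character(GenomicRanges::strand(s2)),
                   mm = S4Vectors::mcols(s2)$mismatches)
  o <- function(d) { d <- d[do.call(order, d), ]; rownames(d) <- NULL; d }
  expect_identical(o(m1), o(m2))
})

test_that("planted substitution loci are recovered at their distance", {
  set.seed(88)
  proto <- random_protospacer()
  for (d in 1:5) {
    g <- random_genome(900)
    pv <- strsplit(proto, "")[[1]]
    at <- sample(20, d)
    for (p in at) pv[p] <- sample(setdiff(c("A", "C", "G", "T"), pv[p]), 1)
    strand <- sample(c("+", "-"), 1)
    g <- plant_seq(g, "chr1", 301, paste0(paste(pv, collapse = ""), "CGG"),
                   strand = strand)
    sites <- enumerateSites(guide_row(proto), g, searchConfig(5))
    mc <- S4Vectors::mcols(sites)
    planted <- GenomicRanges::start(sites) == 301L &
      as.character(GenomicRanges::strand(sites)) == strand
    expect_true(any(planted), info = paste("distance", d))
    expect_equal(mc$mismatches[planted], d)
    expect_equal(mc$bulge_type[planted], "none")
  }
})

test_that("cut positions follow blunt-cut geometry on both strands", {
  set.seed(66)
  g <- random_genome(600)
  proto <- random_protospacer()
  # plus strand: PAM at 0-based 120 (1-based 121) -> cut at 0-based 117
  gp <- plant_seq(g, "chr1", 101, paste0(proto, "AGG"))
  sp <- enumerateSites(guide_row(proto), gp, searchConfig(0))
  sp <- sp[S4Vectors::mcols(sp)$is_on_target]
  expect_equal(cutSite(sp), 117L)
  # minus strand mirror: same construct reverse-complemented in place
  gm <- plant_seq(g, "chr1", 101, paste0(proto, "AGG"), strand = "-")
  sm <- enumerateSites(guide_row(proto), gm, searchConfig(0))
  sm <- sm[S4Vectors::mcols(sm)$is_on_target]
  # site spans 101..123; PAM at forward 101..103; cut mirrors to 105
  expect_equal(cutSite(sm), 105L)
  # geometry check over random planted sites: the three bases between the
  # cut and the PAM are protospacer positions 18-20
  for (i in 1:5) {
    set.seed(900 + i)
    gi <- random_genome(500)
    a <- sample(100:300, 1)
    strand <- sample(c("+", "-"), 1)
    gi <- plant_seq(gi, "chr1", a, paste0(proto, "TGG"), strand = strand)
    s <- enumerateSites(guide_row(proto), gi, searchConfig(0))
    s <- s[S4Vectors::mcols(s)$is_on_target]
    expect_equal(cutSite(s),
                 if (strand == "+") a + 22L - 6L else a - 1L + 5L)
  }
})

test_that("mismatch position profile counts by protospacer position", {
  set.seed(44)
  g <- random_genome(700)
  proto <- random_protospacer()
  g <- plant_seq(g, "chr1", 101, paste0(proto, "AGG"))
  # PAM-distal mismatch only (position 1)
  pv <- strsplit(proto, "")[[1]]
  pv[1] <- setdiff(c("A", "C", "G", "T"), pv[1])[1]
  g <- plant_seq(g, "chr1", 301, paste0(paste(pv, collapse = ""), "AGG"))
  nb <- searchConfig(2, allow_bulge = FALSE, pam_rule = "NGG-only")
  sites <- enumerateSites(guide_row(proto, "NGG-only"), g, nb)
  exact <- sites[GenomicRanges::start(sites) == 101L &
                   GenomicRanges::end(sites) == 123L]
  distal <- sites[GenomicRanges::start(sites) == 301L &
                    GenomicRanges::end(sites) == 323L]
  # all-zero profile for the perfect site alone
  expect_true(all(mismatchPositionProfile(exact)[paste0("pos", 1:20)] == 0L))
  # the PAM-distal mismatch lands in position 1 only
  prof_d <- mismatchPositionProfile(distal)
  expect_equal(unname(prof_d["pos1"]), 1L)
  expect_equal(sum(prof_d[paste0("pos", 2:20)]), 0L)
  # conservation over a bulge-aware enumeration
  all_sites <- enumerateSites(guide_row(proto), g, searchConfig(2))
  prof <- mismatchPositionProfile(all_sites)
  expect_equal(sum(prof[paste0("pos", 1:20)]),
               sum(S4Vectors::mcols(all_sites)$mismatches))
  expect_equal(unname(prof["gap"]),
               sum(S4Vectors::mcols(all_sites)$bulge_type != "none"))
})

test_that("the oracle refuses large genomes and handles empty contigs", {
  g <- random_genome(200)
  gu <- guide_row(random_protospacer())
  expect_length(oracleEnumerate(gu, random_genome(30), searchConfig(2)), 0L)
  big <- Biostrings::DNAStringSet(strrep("A", 150000))
  names(big) <- "chr1"
  expect_error(oracleEnumerate(gu, big, searchConfig(2)), "100 kb")
})

test_that("site tables round-trip through TSV and export to BED", {
  set.seed(33)
  g <- random_genome(1500)
  gu <- guide_row(random_protospacer())
  sites <- enumerateSites(gu, g, searchConfig(5))
  path <- tempfile(fileext = ".tsv")
  writeSiteTable(sites, path)
  back <- readSiteTable(path, g)
  expect_identical(site_frame(back), site_frame(sites))
  bed <- tempfile(fileext = ".bed")
  sitesToBed(sites, bed)
  gr <- readIntervals(bed)
  expect_equal(length(gr), length(sites))
})
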