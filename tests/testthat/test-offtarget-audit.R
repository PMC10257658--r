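# shared scaffold: one guide with a planted off-target site, plus mapping
.audit_scaffold <- function(seed = 501) {
  set.seed(seed)
  g <- random_genome(3000)
  proto <- random_protospacer()
  g <- plant_seq(g, "chr1", 501, paste0(proto, "TGG"))     # on-target
  pv <- strsplit(proto, "")[[1]]
  pv[c(2, 9)] <- vapply(pv[c(2, 9)], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  g <- plant_seq(g, "chr1", 1501, paste0(paste(pv, collapse = ""), "CGG"))
  sites <- enumerateSites(guide_row(proto, id = "gA"), g, searchConfig(3))
  list(genome = g, sites = sites,
       map = data.frame(sample_id = "F1", guide_id = "gA"))
}

test_that("site-variant intersection is any-overlap with strict bounds", {
  sc <- .audit_scaffold()
  ot <- sc$sites[GenomicRanges::start(sc$sites) == 1501L]
  cut0 <- cutSite(ot)    # 0-based position inside the site
  v <- rbind(
    var_rec(sample_id = "F1", pos = cut0, ref = "GAT", alt = "G"),
    # SNV one base 3' of the site interval: no overlap
    var_rec(sample_id = "F1", pos = GenomicRanges::end(ot) + 1L),
    var_rec(sample_id = "F1", pos = GenomicRanges::start(ot) - 1L))
  v$ref[1] <- "GAT"  # indel spanning the cut
  hits <- intersectSitesVariants(sc$sites, v, NULL, sc$map)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$variant_class, "indel")
  expect_equal(hits$site_start, 1501L)
  expect_equal(hits$mismatch_bin, "<=4")
  # a variant one base inside each edge does hit
  v2 <- rbind(var_rec(sample_id = "F1", pos = GenomicRanges::end(ot)),
              var_rec(sample_id = "F1", pos = GenomicRanges::start(ot)))
  expect_equal(nrow(intersectSitesVariants(sc$sites, v2, NULL, sc$map)), 2L)
  # samples are only audited against their own guides
  other_map <- data.frame(sample_id = "F1", guide_id = "gOther")
  expect_equal(nrow(intersectSitesVariants(sc$sites, v2, NULL, other_map)),
               0L)
  # on-target sites never produce hits
  von <- var_rec(sample_id = "F1", pos = 510L)
  expect_equal(nrow(intersectSitesVariants(sc$sites, von, NULL, sc$map)), 0L)
})

test_that("SV hits are emitted and small deletions deduplicated within SVs", {
  sc <- .audit_scaffold()
  ot <- sc$sites[GenomicRanges::start(sc$sites) == 1501L]
  svs <- sv_rec(sample_id = "F1", contig = "chr1",
                start = GenomicRanges::start(ot) - 200L,
                end = GenomicRanges::end(ot) + 300L)
  hits <- intersectSitesVariants(sc$sites, var_rec(sample_id = "F1",
                                                   pos = 2900L),
                                 svs, sc$map)
  expect_equal(hits$variant_class, "SV:del")
  # a small deletion inside the SV DEL at the same site is one event
  smalldel <- var_rec(sample_id = "F1", pos = GenomicRanges::start(ot) + 5L,
                      ref = "ACGTA", alt = "A")
  both <- intersectSitesVariants(sc$sites, smalldel, svs, sc$map)
  expect_equal(nrow(both), 1L)
  expect_equal(both$variant_class, "SV:del")
  # an insertion at the same position is NOT deduplicated
  ins <- var_rec(sample_id = "F1", pos = GenomicRanges::start(ot) + 5L,
                 ref = "A", alt = "ATT")
  both2 <- intersectSitesVariants(sc$sites, ins, svs, sc$map)
  expect_setequal(both2$variant_class, c("indel", "SV:del"))
})

test_that("genic classification matches a per-base annotation oracle", {
  set.seed(611)
  ann <- list(
    exons = GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(1000, 2000), width = 200)),
    gene_bodies = GenomicRanges::GRanges("chr1",
                                         IRanges::IRanges(800, 2500)))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(sample(1:3000, 50), width = 3))
  ctx <- genicContext(gr, ann)
  oracle <- vapply(seq_along(gr), function(i) {
    bases <- GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]
    inex <- any(bases >= 1000 & bases <= 1199) ||
      any(bases >= 2000 & bases <= 2199)
    ingene <- any(bases >= 800 & bases <= 2500)
    if (inex) "exonic" else if (ingene) "intronic" else "intergenic"
  }, character(1))
  expect_identical(ctx, oracle)
  # classifyHits applies the same rule to hit tables
  hits <- data.frame(sample_id = "F1", guide_id = "g", contig = "chr1",
                     site_start = 1L, site_end = 23L, site_strand = "+",
                     mismatches = 2L, bulge_type = "none",
                     pam_class = "NGG", variant_class = "SNV",
                     var_start = c(1050L, 1500L, 2800L),
                     var_end = c(1050L, 1500L, 2800L),
                     variant_id = paste0("v", 1:3),
                     mismatch_bin = "<=4",
                     genic_context = NA_character_,
                     stringsAsFactors = FALSE)
  out <- classifyHits(hits, ann)
  expect_equal(out$genic_context, c("exonic", "intronic", "intergenic"))
})

test_that("hit summaries cross-tabulate and conserve totals", {
  empty <- summarizeHits(data.frame(mismatches = integer(0),
                                    variant_class = character(0),
                                    pam_class = character(0),
                                    mismatch_bin = character(0),
                                    genic_context = character(0)), 6L)
  expect_equal(sum(empty$table), 0L)
  h <- data.frame(
    mismatches = c(3L, 4L, 2L, 5L, 5L),
    variant_class = c("indel", "indel", "indel", "SNV", "SNV"),
    pam_class = c("NGG", "NGG", "NGG", "NAG", "NAG"),
    mismatch_bin = c("<=4", "<=4", "<=4", "5", "5"),
    genic_context = c("exonic", "intronic", "intergenic", "intronic",
                      "intergenic"), stringsAsFactors = FALSE)
  s <- summarizeHits(h, 6L)
  expect_equal(unname(s$table["indel", "NGG", "<=4"]), 3L)
  expect_equal(unname(s$table["SNV", "NAG", "5"]), 2L)
  expect_equal(sum(s$table), nrow(h))
  # restriction by ceiling is monotone and conserves marginals
  n4 <- summarizeHits(h, 4L)$n_hits
  n5 <- summarizeHits(h, 5L)$n_hits
  n6 <- summarizeHits(h, 6L)$n_hits
  expect_true(n4 <= n5 && n5 <= n6)
  expect_equal(n4, 3L)
  expect_equal(sum(summarizeHits(h, 5L)$table), n5)
})

test_that("on-target confirmation needs a consensus deletion", {
  guides <- data.frame(guide_id = c("g1", "g2"), sample_id = "F1",
                       target_gene = "Abc2", contig = "chr1",
                       cut_pos = c(1000L, 1800L), stringsAsFactors = FALSE)
  svs_ok <- sv_rec(sample_id = "F1", start = 1001L, end = 1800L,
                   callers = "lumpy,manta", support_reads = 8L)
  call <- confirmOnTarget("F1", guides, svs_ok)
  expect_true(call$confirmed)
  expect_equal(call$n_supporting_callers, 2L)
  expect_equal(GenomicRanges::start(call$expected_interval), 1001L)
  expect_equal(GenomicRanges::end(call$expected_interval), 1800L)
  # the same deletion carried by one caller does not pass consensus, so
  # confirmation must be decided on consensus-filtered records
  svs_one <- sv_rec(sample_id = "F1", start = 1001L, end = 1800L,
                    callers = "lumpy", support_reads = 8L)
  filtered <- svConsensusFilter(svs_one, filterConfig())$svs
  expect_false(confirmOnTarget("F1", guides, filtered)$confirmed)
  # fewer than 2 guides is a design error
  expect_error(confirmOnTarget("F1", guides[1, ], svs_ok), "fewer than 2")
  # a small-variant deletion covering >= 50% of the interval also confirms
  bigdel <- var_rec(sample_id = "F1", pos = 1001L,
                    ref = paste(rep("A", 500), collapse = ""), alt = "A")
  call2 <- confirmOnTarget("F1", guides, svs_one[0, ], bigdel)
  expect_true(call2$confirmed)
})

test_that("three-way site-set overlap counts match a quadratic oracle", {
  gr <- function(st) GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(st, st + 22L))
  one <- gr(100L)
  out <- compareSiteSets(one, one, one)
  expect_equal(unname(out["ABC"]), 1L)
  expect_equal(sum(out), 1L)
  out2 <- compareSiteSets(gr(100L), gr(1000L), gr(5000L))
  expect_equal(unname(out2[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_equal(sum(out2), 3L)
  # randomized sets vs brute-force transitive matching
  set.seed(99)
  for (rep in 1:5) {
    sets <- lapply(1:3, function(i)
      gr(sample(seq(1, 4000, by = 12), sample(3:10, 1))))
    got <- compareSiteSets(sets[[1]], sets[[2]], sets[[3]], tolerance = 10L)
    # oracle: union-find over all pairwise matches
    all <- suppressWarnings(c(sets[[1]], sets[[2]], sets[[3]]))
    origin <- rep(1:3, vapply(sets, length, integer(1)))
    n <- length(all)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      si <- GenomicRanges::start(all)[i]; ei <- GenomicRanges::end(all)[i]
      sj <- GenomicRanges::start(all)[j]; ej <- GenomicRanges::end(all)[j]
      if (max(si, sj) <= min(ei, ej) + 2L * 10L &&
          max(si - 10L, sj - 10L) <= min(ei + 10L, ej + 10L))
        parent[find(j)] <- find(i)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    sig <- tapply(origin, comp, function(o)
      paste(c("A", "B", "C")[sort(unique(o))], collapse = ""))
    oracle <- table(factor(sig, levels = names(got)))
    expect_equal(as.integer(oracle), unname(as.integer(got)),
                 info = paste("rep", rep))
  }
})
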