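test_that("genic region assignment follows segments, flanks and strand", {
  a <- toy_annotation(body_start = 200000L)      # 5'UTR 100, CDS 300,
  g <- a$genes; segs <- a$segments               # intron 200, CDS 300, 3'UTR 150
  expect_identical(assign_genic_region(200000L, g, segs), "5'UTR")
  expect_identical(assign_genic_region(200150L, g, segs), "CDS")
  expect_identical(assign_genic_region(200450L, g, segs), "intron")
  expect_identical(assign_genic_region(g$tts - 10L, g, segs), "3'UTR")
  expect_identical(assign_genic_region(g$tss - 1L, g, segs), "upstream")
  expect_identical(assign_genic_region(g$tts + 50000L, g, segs), "downstream")
  expect_error(assign_genic_region(g$tss - 100001L, g, segs), "outside")

  am <- toy_annotation(gene_id = "gM", strand = "-", body_start = 500000L)
  gm <- am$genes; sm <- am$segments
  expect_identical(assign_genic_region(gm$tss + 500L, gm, sm), "upstream")
  expect_identical(assign_genic_region(gm$tts - 500L, gm, sm), "downstream")
  expect_identical(assign_genic_region(gm$tts + 10L, gm, sm), "3'UTR")

  # vectorized assignment agrees with the scalar rule
  pos <- c(200000L, 200150L, g$tss - 1L, g$tts + 50000L)
  pr <- data.table::data.table(variant_id = paste0("v", 1:4),
                               gene_id = "gA", pos = pos)
  expect_identical(assign_genic_regions(pr, a),
                   vapply(pos, assign_genic_region, "", gene = g,
                          segments = segs))
})

test_that("region enrichment reproduces the ER formula on published counts", {
  # stQTL CDS line of the published per-region table
  counts <- data.table::data.table(
    region = c("CDS", "upstream"),
    N_k = c(143915L, 5591610L), Q_k = c(3949L, 50109L))
  attr(counts, "N") <- 15122700L; attr(counts, "Q") <- 142801L
  res <- region_enrichment(counts)
  expect_equal(round(res[region == "CDS", ER], 2), 2.91)
  # proportional Q_k -> ER 1 in every region
  prop <- data.table::data.table(region = c("CDS", "intron"),
                                 N_k = c(100L, 900L), Q_k = c(10L, 90L))
  attr(prop, "N") <- 1000L; attr(prop, "Q") <- 100L
  expect_equal(region_enrichment(prop)$ER, c(1, 1))
})

test_that("Fisher two-sided p equals exhaustive enumeration", {
  # all 2x2 tables with margins <= 30 appear in this sweep
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    expect_equal(fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                 fisher_enum_p(a, b, cc, d), tolerance = 1e-10)
  }
  t28 <- fisher.test(matrix(c(2, 1, 8, 9), 2))$p.value
  expect_equal(t28, fisher_enum_p(2, 8, 1, 9), tolerance = 1e-12)
})

test_that("ER and the sample odds ratio sit on the same side of 1", {
  set.seed(12)
  for (i in 1:50) {
    N <- sample(200:2000, 1); nk <- sample(10:(N / 2), 1)
    Q <- sample(20:(N / 2), 1); qk <- sample(1:min(Q - 1, nk - 1), 1)
    if ((N - nk) - (Q - qk) <= 0) next
    counts <- data.table::data.table(region = "CDS", N_k = nk, Q_k = qk)
    attr(counts, "N") <- N; attr(counts, "Q") <- Q
    r <- region_enrichment(counts)
    or <- (qk * ((N - nk) - (Q - qk))) / ((Q - qk) * (nk - qk))
    if (abs(or - 1) > 1e-9 && abs(r$ER - 1) > 1e-9)
      expect_identical(r$ER > 1, or > 1)
  }
})

test_that("positional profile windows are half-open and conserve counts", {
  all_d <- c(0, 49, 50, 100, 1999, 2000, 2050)
  qtl_d <- c(0, 2000)
  prof <- positional_profile(qtl_d, all_d, bin = 2000, step = 50)
  # window 1 covers [0, 2000): excludes the distance exactly at 2000
  expect_equal(prof$N_i[1], 5)
  expect_equal(prof$Q_i[1], 1)
  # a distance on the right edge falls in the next window
  w2 <- prof[prof$window_start == 50, ]
  expect_equal(w2$N_i, 4)  # 50,100,1999,2000 ([50, 2050) excludes 2050)
  expect_error(positional_profile(qtl_d, all_d, bin = 0), "positive")

  # proportional QTLs -> ER ~ 1; concentration -> ER = 1/f
  set.seed(5)
  bg <- runif(5000, -1000, 1000)
  prof2 <- positional_profile(bg, bg, bin = 500, step = 100)
  expect_true(all(abs(prof2$ER[prof2$N_i > 0] - 1) < 1e-12))
  conc <- positional_profile(rep(0, 100), c(rep(0, 100), rep(5000, 300)),
                             bin = 100, step = 100)
  f <- 100 / 400
  expect_equal(max(conc$ER, na.rm = TRUE), 1 / f)
})

test_that("binding-site overlap uses BED half-open convention", {
  sites <- data.table::data.table(chrom = "chr1", start = 100L, end = 110L,
                                  factor_name = "F1", type = "RBP")
  # 0-based [100,110) = 1-based positions 101..110
  pr <- function(pos) data.table::data.table(
    variant_id = paste0("v", seq_along(pos)), pos = pos, region = "CDS")
  r <- binding_site_enrichment(pr(c(101L, 110L, 111L, 100L)),
                               pr(c(101L, 110L, 111L, 100L)), sites)
  expect_equal(r$overall$n_qtl_in, 2L)   # 101 and 110 inside; 100 and 111 out
})

test_that("per-factor table matches the enumeration oracle and ER arithmetic", {
  # QTLs: 10 variants, 5 in sites; background adds 100 non-QTLs, 10 in sites
  qtl <- data.table::data.table(variant_id = sprintf("q%02d", 1:10),
                                pos = c(105:109, 300:304), region = "3'UTR")
  bg_extra <- data.table::data.table(variant_id = sprintf("b%03d", 1:100),
                                     pos = c(111:120, 500:589),
                                     region = "3'UTR")
  allp <- rbind(qtl, bg_extra)
  sites <- data.table::data.table(chrom = "chr1", start = 100L, end = 120L,
                                  factor_name = "F1", type = "RBP")
  r <- binding_site_enrichment(qtl, allp, sites)
  pf <- r$per_factor
  expect_equal(pf$qtl_in, 5L); expect_equal(pf$nonqtl_in, 10L)
  expect_equal(pf$p, fisher_enum_p(5, 5, 10, 90), tolerance = 1e-10)
  expect_equal(pf$ER, (5 / 10) / (15 / 110))
})

test_that("empty and unsorted site sets are handled", {
  qtl <- data.table::data.table(variant_id = "v1", pos = 105L, region = "CDS")
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), factor_name = character(),
                                  type = character())
  r <- binding_site_enrichment(qtl, qtl, empty)
  expect_equal(nrow(r$per_factor), 0L)
  uns <- data.table::data.table(chrom = "chr1", start = c(200L, 100L),
                                end = c(210L, 110L),
                                factor_name = "F1", type = "RBP")
  expect_warning(binding_site_enrichment(qtl, qtl, uns), "unsorted")
})

test_that("planted-site factors are recovered; decoys are not flagged", {
  hits <- 0L; seeds <- 1:15
  for (s in seeds) {
    cfg <- sim_config(n_samples = 200, n_variants = 4000, n_genes = 40,
                      seed = s, dispersion = 0, prop_transcription_qtl = 0,
                      prop_stability_qtl = 0.6, prop_sex_specific = 0,
                      effect_size_grid = c(1.0),
                      segment_length_params = list(utr5 = 200, cds_exon = 400,
                                                   intron = 3000, utr3 = 2000,
                                                   n_introns = 3L))
    ds <- simulate_dataset(cfg, stability_region = "3'UTR",
                           strict_region = TRUE)
    sites <- simulate_binding_sites(ds$annotation, ds$truth, ds$genotypes,
                                    cfg, signal_factors = c("RBP_A", "RBP_B"),
                                    decoy_factors = c("RBP_X", "RBP_Y"))
    g <- variant_qc(ds$genotypes)
    st <- infer_stability(ds$counts)
    pairs <- cis_pairs(ds$annotation, g)[gene_id %in% rownames(st)]
    tab <- associate_linear(st, g, NULL, pairs, "stability")
    pairs[, region := assign_genic_regions(pairs, ds$annotation)]
    bse <- binding_site_enrichment(pairs[tab$q < 0.05], pairs, sites)
    pf <- bse$per_factor
    ok_signal <- all(pf[factor_name %in% c("RBP_A", "RBP_B"), q] < 0.05)
    ok_decoy <- all(pf[factor_name %in% c("RBP_X", "RBP_Y"), q] >= 0.05)
    if (ok_signal && ok_decoy) hits <- hits + 1L
  }
  expect_gte(hits / length(seeds), 0.95)
})
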