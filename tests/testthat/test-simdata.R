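test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(n_haplotypes = 1), "n_haplotypes")
  expect_error(sim_config(prop_stability_qtl = 1.2), "fractions")
  expect_error(sim_config(n_genes = 10, genome_length = 1e5), "genome_length")
  expect_error(sim_config(dispersion = -1), "dispersion")
})

test_that("genotype generator is deterministic and VCF output byte-identical", {
  cfg <- sim_config(n_samples = 30, n_variants = 80, n_genes = 3, seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(g1, f1); write_vcf(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("monomorphic founder pool yields an empty post-QC set", {
  cfg <- sim_config(n_samples = 40, n_variants = 50, n_genes = 2, seed = 1,
                    n_haplotypes = 2)
  founders <- matrix(1L, nrow = 2, ncol = 50)  # every haplotype carries alt
  g <- simulate_genotypes(cfg, founders = founders)
  expect_true(all(!g$variants$pass_qc))
  expect_error(variant_qc(g), "removed every variant")
})

test_that("equi-frequent founder alleles give binomially distributed AF", {
  # 4 founders, alt on 2 of 4 -> population AF 0.5; with independent
  # founder picks the realized alt count is Binomial(2n, 0.5)
  n <- 500L
  lo <- qbinom(0.005, 2L * n, 0.5) / (2 * n)
  hi <- qbinom(0.995, 2L * n, 0.5) / (2 * n)
  inside <- vapply(1:25, function(s) {
    cfg <- sim_config(n_samples = n, n_variants = 10, n_genes = 1, seed = s)
    founders <- matrix(rep(c(1L, 1L, 0L, 0L), 10), nrow = 4)
    g <- simulate_genotypes(cfg, founders = founders)
    af <- colMeans(g$dosage) / 2
    mean(af >= lo & af <= hi)
  }, numeric(1))
  expect_gt(mean(inside), 0.97)   # ~99% expected inside the central band
})

test_that("samples are HWE-consistent and LD is blockwise", {
  cfg <- sim_config(n_samples = 400, n_variants = 400, n_genes = 10,
                    seed = 3, n_haplotypes = 30)
  g <- simulate_genotypes(cfg)
  p_hwe <- apply(g$dosage, 2, hwe_test)
  expect_gt(mean(p_hwe > 1e-6, na.rm = TRUE), 0.99)

  vr <- g$variants
  same <- outer(vr$ld_segment, vr$ld_segment, `==`)
  r2 <- suppressWarnings(cor(g$dosage))^2
  diag(r2) <- NA
  high_same <- mean(r2[same & !is.na(r2)] > 0.9, na.rm = TRUE)
  high_diff <- mean(r2[!same & !is.na(r2)] > 0.9, na.rm = TRUE)
  expect_gt(high_same, high_diff)   # ordering only, not magnitude
})

test_that("gene models respect transcription order and length arithmetic", {
  cfg <- sim_config(n_samples = 10, n_variants = 50, n_genes = 30, seed = 21)
  a <- simulate_annotation(cfg)
  expect_true(all(table(a$genes$strand) > 5))   # both strands used
  for (i in seq_len(nrow(a$genes))) {
    g <- a$genes[i]
    segs <- a$segments[gene_id == g$gene_id][order(start)]
    # disjoint, contained in the body
    expect_true(all(segs$start[-1] > head(segs$end, -1)))
    expect_true(all(segs$start >= g$start & segs$end <= g$end))
    # genomic vs transcription order of labels
    lab <- if (g$strand == "+") segs$label else rev(segs$label)
    expect_identical(lab[1], "5'UTR")
    expect_identical(lab[length(lab)], "3'UTR")
    expect_true(all(lab[-c(1, length(lab))] %in% c("CDS", "intron")))
    if (g$strand == "+") expect_lt(g$tss, g$tts) else expect_gt(g$tss, g$tts)
    if (g$strand == "-")                       # 3'UTR at lowest coordinates
      expect_identical(segs$label[1], "3'UTR")
    # span equals the sum of segment lengths
    expect_identical(abs(g$tts - g$tss) + 1L,
                     sum(segs$end - segs$start + 1L))
    expect_identical(g$exonic_length,
                     sum(segs[label != "intron", end - start + 1L]))
  }
  # 100 kb flanks of adjacent genes never overlap
  o <- a$genes[order(start)]
  expect_true(all(o$start[-1] - 100000 > head(o$end, -1) + 100000))
})

test_that("truth table invariants hold and planting respects regions", {
  ds <- small_sim(seed = 6)
  tr <- ds$truth
  expect_false(any(duplicated(tr[, c("variant_id", "gene_id", "target")])))
  expect_true(all(tr$effect != 0))
  expect_true(all(tr$sex %in% c("none", "male", "female")))
  # every planted variant is inside its gene's cis window
  pr <- cis_pairs(ds$annotation, ds$genotypes)
  expect_true(all(paste(tr$variant_id, tr$gene_id) %in%
                    paste(pr$variant_id, pr$gene_id)))
})

test_that("counts match closed-form kinetic means (law of large numbers)", {
  # 2000 replicate genes, one sample, Poisson, no noise, no effects
  cfg <- sim_config(n_samples = 2, n_variants = 10, n_genes = 1, seed = 8,
                    dispersion = 0, rate_noise_sd = 0, alpha_log2_sd = 0,
                    beta_log2_sd = 0, library_size_cv = 0,
                    prop_transcription_qtl = 0, prop_stability_qtl = 0)
  g <- simulate_genotypes(cfg); a <- simulate_annotation(cfg)
  tr <- simulate_truth(g, a, cfg)
  # replicate the same gene by drawing counts repeatedly via seeds
  mu <- NULL; ex <- ix <- numeric(0)
  for (s in 1:500) {
    cfg$seed <- s
    cnt <- simulate_counts(g, a, tr, cfg)
    ex <- c(ex, cnt$exon[1, ]); ix <- c(ix, cnt$intron[1, ])
    if (is.null(mu)) mu <- list(e = attr(cnt, "mu_exon")[1, 1],
                                i = attr(cnt, "mu_intron")[1, 1])
  }
  expect_lt(abs(mean(ex) - mu$e) / mu$e, 0.01)
  expect_lt(abs(mean(ix) - mu$i) / mu$i, 0.01)
  # and the stored mu agrees with the independent closed form
  cnt <- simulate_counts(g, a, tr, cfg)
  oracle <- expected_counts(attr(cnt, "log2_alpha"), attr(cnt, "log2_beta"),
                            a$genes$exonic_length, a$genes$intronic_length,
                            lib = rep(cfg$library_size_mean, 2),
                            intron_capture = cfg$intron_capture)
  expect_equal(attr(cnt, "mu_exon"), oracle$mu_exon, tolerance = 1e-12)
})

test_that("doubling beta halves expected exon mean, leaves intron unchanged", {
  la <- matrix(0, 2, 2); lb <- matrix(c(0, 0, 1, 1), 2, 2)  # sample 2: 2x beta
  mu <- expected_counts(la, lb, exonic_length = c(1000, 1000),
                        intronic_length = c(5000, 5000), lib = c(1e6, 1e6))
  expect_equal(mu$mu_exon[, 1] / mu$mu_exon[, 2], c(2, 2))
  expect_equal(mu$mu_intron[, 1], mu$mu_intron[, 2])
})

test_that("planted decay effect -0.5/alt gives exon ratio 2 between dosage 2 and 0", {
  # dosage 2 lowers log2 beta by 1 -> beta halves -> exon mean doubles
  la <- matrix(0, 1, 2)
  lb <- matrix(c(0, -0.5 * 2), 1, 2)   # dosage 0 vs dosage 2
  mu <- expected_counts(la, lb, 1000, 5000, lib = c(1e6, 1e6))
  expect_equal(mu$mu_exon[1, 2] / mu$mu_exon[1, 1], 2.0)
  expect_equal(mu$mu_intron[1, 1], mu$mu_intron[1, 2])
})

test_that("expected trait separation grows with planted |effect|", {
  seps <- vapply(c(0.2, 0.5, 1.0), function(eff) {
    lb <- matrix(c(0, eff * 2), 1, 2)
    mu <- expected_counts(matrix(0, 1, 2), lb, 1000, 5000, c(1e6, 1e6))
    abs(log2(mu$mu_exon[1, 2]) - log2(mu$mu_exon[1, 1]))
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})

test_that("simulate_counts rejects unknown truth ids and full runs are deterministic", {
  ds <- small_sim(seed = 13, n_samples = 30, n_variants = 100, n_genes = 5)
  bad <- data.table::data.table(variant_id = "nope", gene_id = "gene0001",
                                target = "decay", effect = 1, sex = "none")
  expect_error(simulate_counts(ds$genotypes, ds$annotation, bad, ds$config),
               "unknown ids")
  ds2 <- small_sim(seed = 13, n_samples = 30, n_variants = 100, n_genes = 5)
  expect_identical(ds$counts$exon, ds2$counts$exon)
  expect_identical(ds$truth, ds2$truth)
})
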