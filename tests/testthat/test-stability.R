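test_that("hand-computed two-sample stability", {
  cnt <- toy_counts(rbind(c(200, 100)), rbind(c(50, 50)))
  st <- infer_stability(cnt, pseudocount = 0, bias_method = "none",
                        lib_exon = c(1e6, 1e6), lib_intron = c(1e6, 1e6))
  # delta-exon = (+0.5, -0.5), delta-intron = (0, 0)
  expect_equal(unname(unclass(st)[1, ]), c(0.5, -0.5))
})

test_that("stability is invariant to library-size rescaling", {
  ds <- small_sim(seed = 17, n_samples = 20, n_variants = 100, n_genes = 8)
  cnt <- ds$counts
  st1 <- infer_stability(cnt)
  cnt2 <- list(exon = cnt$exon, intron = cnt$intron)
  cnt2$exon[, 3] <- cnt2$exon[, 3] * 10L
  cnt2$intron[, 3] <- cnt2$intron[, 3] * 10L
  st2 <- infer_stability(cnt2)
  expect_equal(unclass(st1), unclass(st2), tolerance = 1e-9)
})

test_that("linear correction removes a planted expression-dependent bias", {
  set.seed(1)
  G <- 200; S <- 10
  lib <- rep(1e6, S)
  base <- 2^runif(G, 4, 12)                     # wide expression range
  exon <- matrix(rep(base * 50, S), G, S)
  intron <- matrix(rep(base * 10, S), G, S)
  rownames(exon) <- rownames(intron) <- paste0("g", 1:G)
  colnames(exon) <- colnames(intron) <- paste0("s", 1:S)
  # zero-stability dataset (identical columns); plant per-sample bias
  # b_s * xbar_g + c_s exactly in log space, pseudocount included
  xbar <- log2(exon[, 1] + 0.5)
  b <- seq(-0.05, 0.05, length.out = S); cc <- seq(-0.2, 0.2, length.out = S)
  bias <- outer(xbar, b) + matrix(cc, G, S, byrow = TRUE)
  exon_b <- (exon + 0.5) * 2^bias - 0.5
  cnt <- list(exon = exon_b, intron = intron)
  st <- infer_stability(cnt, bias_method = "linear",
                        lib_exon = lib, lib_intron = lib)
  expect_lt(max(abs(unclass(st))), 1e-6)
  st0 <- infer_stability(cnt, bias_method = "none",
                         lib_exon = lib, lib_intron = lib)
  expect_gt(max(abs(unclass(st0))), 0.1)        # bias was really there
})

test_that("rows are centered and the linear correction is idempotent", {
  ds <- small_sim(seed = 23, n_samples = 40, n_variants = 100, n_genes = 20)
  st <- infer_stability(ds$counts)
  expect_lt(max(abs(rowMeans(st))), 1e-9)
  # feed the corrected matrix back through the correction step: build a
  # synthetic counts pair whose delta equals st by construction is awkward,
  # so check idempotence algebraically: correcting st against the stored
  # covariate changes nothing
  xbar <- attr(st, "mean_log2_cpm")
  X <- cbind(1, xbar)
  coefs <- solve(crossprod(X), crossprod(X, unclass(st)))
  twice <- unclass(st) - X %*% coefs
  twice <- twice - rowMeans(twice)
  expect_equal(unclass(st), twice, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("genes without intronic reads are excluded with a reason", {
  ex <- rbind(g1 = c(100L, 200L), g2 = c(50L, 60L))
  it <- rbind(g1 = c(10L, 20L), g2 = c(0L, 0L))
  colnames(ex) <- colnames(it) <- c("s1", "s2")
  st <- infer_stability(list(exon = ex, intron = it), bias_method = "none")
  expect_false("g2" %in% rownames(st))
  expect_identical(attr(st, "excluded")$gene_id, "g2")
  expect_error(infer_stability(list(exon = ex[, 1, drop = FALSE],
                                    intron = it[, 1, drop = FALSE])),
               ">= 2 samples")
})

test_that("stringency thresholds follow the quantile definition and nest", {
  m <- c(1L, 5L, 10L, 50L, 100L)
  ex <- matrix(m, ncol = 1); it <- matrix(m + 1L, ncol = 1)
  cnt <- toy_counts(cbind(ex, ex), cbind(it, it))
  sf <- stringency_filter(cnt, sigma = 0.5)
  expect_equal(unname(sf$threshold), 10)
  expect_identical(names(sf$pass)[sf$pass], c("g3", "g4", "g5"))

  ds <- small_sim(seed = 31, n_samples = 25, n_variants = 100, n_genes = 25)
  grid <- c(0.05, 0.2, 0.5, 0.8, 0.95)
  sets <- lapply(grid, function(s)
    names(which(stringency_filter(ds$counts, s)$pass)))
  for (i in seq_along(grid)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))

  zero <- toy_counts(rbind(c(5L, 5L), c(9L, 9L)), rbind(c(0L, 0L), c(3L, 3L)))
  sfz <- stringency_filter(zero, sigma = 0.01)
  expect_false(sfz$pass[["g1"]])
  expect_true(is.na(sfz$max_stringency[["g1"]]))
  expect_error(stringency_filter(zero, sigma = 0), "\\(0, 1\\]")
})

test_that("TPM follows the length-normalized definition", {
  m <- cbind(s1 = c(10, 10))
  rownames(m) <- c("a", "b")
  tpm <- compute_tpm(m, c(a = 1000, b = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(colSums(tpm), c(s1 = 1e6))
  one <- compute_tpm(cbind(s1 = 5), 500)
  expect_equal(unname(one[1, 1]), 1e6)
  z <- cbind(s1 = c(0, 10)); rownames(z) <- c("a", "b")
  expect_equal(unname(compute_tpm(z, c(a = 100, b = 100))[1, 1]), 0)
  expect_error(compute_tpm(cbind(s1 = c(0, 0)), c(100, 100)), "all-zero")
  expect_error(compute_tpm(m, c(a = 0, b = 100)), "positive")
})

test_that("expression transform is log10(100*TPM + 1)", {
  expect_equal(transform_expression(0), 0)
  expect_equal(transform_expression(9.99), 3)
  expect_equal(transform_expression(1), log10(101))
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(transform_expression(x)) > 0))
  expect_error(transform_expression(-1), "nonnegative")
})

test_that("stability recovers the realized decay rates on clean data", {
  cfg <- sim_config(n_samples = 100, n_variants = 400, n_genes = 60,
                    seed = 77, dispersion = 0)
  ds <- simulate_dataset(cfg)
  st <- infer_stability(ds$counts)
  lb <- attr(ds$counts, "log2_beta")[rownames(st), ]
  truth_centered <- -(lb - rowMeans(lb))
  expect_gt(cor(as.vector(unclass(st)), as.vector(truth_centered)), 0.95)
})
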