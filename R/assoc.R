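#' Variant quality control
#'
#' Removes variants with realized minor allele frequency below `maf_min`
#' or a Hardy-Weinberg equilibrium chi-square p-value below `hwe_alpha`
#' (1 df test of observed genotype counts against expectations from the
#' allele frequency).  Missing dosages are mean-imputed first and the
#' affected variants flagged; HWE is computed from the hard-called
#' (non-missing) genotypes.
#'
#' @param genotypes an `stqtl_genotypes` object.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_alpha HWE chi-square p-value threshold (default 1e-6).
#' @return the filtered `stqtl_genotypes`; attributes `removed`
#'   (data.table id, reason) and `imputed` (variant ids that had missing
#'   calls).  Zero surviving variants is an error, never a silent empty
#'   object.
#' @export
variant_qc <- function(genotypes, maf_min = 0.01, hwe_alpha = 1e-6) {
  stopifnot(inherits(genotypes, "stqtl_genotypes"))
  dos <- genotypes$dosage
  imputed <- character()
  if (anyNA(dos)) {
    miss <- which(colSums(is.na(dos)) > 0L)
    imputed <- colnames(dos)[miss]
    for (j in miss) {
      m <- mean(dos[, j], na.rm = TRUE)
      dos[is.na(dos[, j]), j] <- m
    }
  }
  af <- colMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- apply(genotypes$dosage, 2L, hwe_test)
  drop_maf <- maf < maf_min
  drop_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  removed <- data.table::data.table(
    id = colnames(dos)[drop_maf | drop_hwe],
    reason = ifelse(drop_maf[drop_maf | drop_hwe], "maf", "hwe"))
  keep <- !(drop_maf | drop_hwe)
  if (!any(keep))
    stop("variant QC removed every variant (maf_min = ", maf_min,
         ", hwe_alpha = ", hwe_alpha, ")")
  out <- list(
    dosage = dos[, keep, drop = FALSE],
    variants = genotypes$variants[keep][, `:=`(maf = maf[keep],
                                               pass_qc = TRUE)],
    samples = genotypes$samples)
  class(out) <- "stqtl_genotypes"
  attr(out, "removed") <- removed
  attr(out, "imputed") <- imputed
  out
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square of the observed
#' genotype counts (0/1/2 hard calls) against Hardy-Weinberg expectations
#' at the sample allele frequency.  Monomorphic variants return `NA`.
#'
#' @param dosage vector of hard-called dosages (values 0, 1, 2; NA allowed).
#' @return two-sided upper-tail p-value.
#' @export
hwe_test <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  d <- d[d %in% c(0, 1, 2)]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) return(NA_real_)
  expc <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expc)^2 / expc)
  pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Enumerate cis variant-gene pairs
#'
#' A variant is paired with a gene when it lies between 100 kb upstream of
#' the TSS and 100 kb downstream of the TTS in transcription orientation
#' (boundaries inclusive).  For a minus-strand gene "upstream" lies at
#' higher genomic coordinates.  Signed distances to TSS and TTS are
#' positive in the direction of transcription.
#'
#' @param annotation `stqtl_annotation`.
#' @param genotypes `stqtl_genotypes`.
#' @param window flank size in bp (default 100000).
#' @return data.table (variant_id, gene_id, pos, dist_tss, dist_tts);
#'   empty when nothing pairs.
#' @export
cis_pairs <- function(annotation, genotypes, window = 100000L) {
  stopifnot(inherits(annotation, "stqtl_annotation"),
            inherits(genotypes, "stqtl_genotypes"))
  vr <- genotypes$variants
  out <- vector("list", nrow(annotation$genes))
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i]
    lo <- min(g$tss, g$tts) - window
    hi <- max(g$tss, g$tts) + window
    hit <- vr[chrom == g$chrom & pos >= lo & pos <= hi]
    if (nrow(hit) == 0L) next
    sgn <- if (g$strand == "+") 1L else -1L
    out[[i]] <- data.table::data.table(
      variant_id = hit$id, gene_id = g$gene_id, pos = hit$pos,
      dist_tss = sgn * (hit$pos - g$tss),
      dist_tts = sgn * (hit$pos - g$tts))
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table::data.table(variant_id = character(),
                                  gene_id = character(), pos = integer(),
                                  dist_tss = integer(), dist_tts = integer())
  res
}

# validate the covariate design and return the model matrix
.build_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, nrow = n, dimnames = list(NULL, "(Intercept)")))
  cv <- as.data.frame(covariates)
  if (nrow(cv) != n) stop("covariates must have one row per sample")
  for (j in seq_along(cv))
    if (is.character(cv[[j]]) || is.factor(cv[[j]]))
      cv[[j]] <- as.numeric(as.factor(cv[[j]])) - 1
  X <- cbind("(Intercept)" = 1, as.matrix(cv))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Linear dosage association scan
#'
#' For every (variant, gene) pair, ordinary least squares of the trait on
#' (intercept, dosage, covariates); the dosage coefficient's beta, standard
#' error, t statistic and two-sided p-value (t distribution with
#' `n - k` residual degrees of freedom) are reported.  The scan is computed
#' by residualizing both the trait rows and the dosage columns against the
#' covariate design once (Frisch-Waugh), which makes genome-scale scans a
#' handful of matrix products.
#'
#' Pairs whose trait or residual dosage has no variance are reported with
#' `beta = 0`, `p = 1` (kept, not dropped, so pair universes stay aligned
#' across traits); pairs with zero residual degrees of freedom are skipped
#' with a logged reason.
#'
#' @param trait genes x samples numeric matrix.
#' @param genotypes `stqtl_genotypes` (dosage already QC'ed/imputed).
#' @param covariates data.frame/data.table of per-sample covariates, or
#'   NULL; character/factor columns are coded numerically.  Must be full
#'   column rank with the intercept.
#' @param pairs data.table with variant_id and gene_id columns (e.g. from
#'   [cis_pairs()]); pairs whose gene is missing from `trait` are an error.
#' @param trait_name label stored in the `trait` column ("expression" or
#'   "stability").
#' @return an association data.table: variant_id, gene_id, trait, n_used,
#'   beta, se, t, p, q (BH within this scan), sorted as given.
#' @export
associate_linear <- function(trait, genotypes, covariates, pairs,
                             trait_name = "trait") {
  stopifnot(inherits(genotypes, "stqtl_genotypes"))
  dos <- genotypes$dosage
  n <- nrow(dos)
  if (ncol(trait) != n) stop("trait and genotypes disagree on sample count")
  miss_g <- setdiff(unique(pairs$gene_id), rownames(trait))
  if (length(miss_g))
    stop("pairs reference gene(s) absent from the trait matrix: ",
         paste(head(miss_g, 5L), collapse = ", "))
  miss_v <- setdiff(unique(pairs$variant_id), colnames(dos))
  if (length(miss_v))
    stop("pairs reference variant(s) absent from the genotypes: ",
         paste(head(miss_v, 5L), collapse = ", "))

  X <- .build_design(covariates, n)
  k <- ncol(X)
  df <- n - k - 1L
  if (df <= 0L) stop("zero residual degrees of freedom (n = ", n,
                     ", parameters = ", k + 1L, ")")
  Q <- qr.Q(qr(X))
  # residualize dosage (samples x variants) and traits (genes x samples)
  vids <- unique(pairs$variant_id)
  D <- dos[, vids, drop = FALSE]
  RD <- D - Q %*% crossprod(Q, D)
  Tm <- trait[unique(pairs$gene_id), , drop = FALSE]
  RT <- Tm - tcrossprod(Tm %*% Q, Q)
  sxx <- colSums(RD^2)
  sst <- rowSums(RT^2)

  pt_idx <- data.table::data.table(
    variant_id = pairs$variant_id, gene_id = pairs$gene_id,
    vi = match(pairs$variant_id, vids),
    gi = match(pairs$gene_id, rownames(Tm)))
  beta <- se <- tval <- pval <- numeric(nrow(pt_idx))
  # loop genes: each gene's cross-products with all its variants at once
  for (gi in unique(pt_idx$gi)) {
    rows <- which(pt_idx$gi == gi)
    vis <- pt_idx$vi[rows]
    sxy <- as.vector(RT[gi, ] %*% RD[, vis, drop = FALSE])
    sx <- sxx[vis]
    ok <- sx > 1e-12 & sst[gi] > 1e-24
    b <- ifelse(ok, sxy / sx, 0)
    sse <- pmax(sst[gi] - b^2 * sx, 0)
    s2 <- sse / df
    s_e <- ifelse(ok, sqrt(s2 / sx), NA_real_)
    tv <- ifelse(ok & s_e > 0, b / s_e, 0)
    pv <- ifelse(ok & s_e > 0, 2 * pt(-abs(tv), df), 1)
    beta[rows] <- b; se[rows] <- s_e; tval[rows] <- tv; pval[rows] <- pv
  }
  res <- data.table::data.table(
    variant_id = pt_idx$variant_id, gene_id = pt_idx$gene_id,
    trait = trait_name, n_used = n, beta = beta, se = se, t = tval,
    p = pval)
  res[, q := bh_fdr(p)]
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_(j >= i) (p_(j) * n / j)` clipped to 1 and mapped back to
#' the input order; `q < alpha` reproduces the usual FDR call set.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return the adjusted q-values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.8))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  n <- length(p)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q[order(o)]
}

#' Genotype principal components
#'
#' Covariate PCs from the dosage matrix: strand-ambiguous (A/T, C/G)
#' variants are removed, the variant set is thinned to every `thin_step`-th
#' variant (a fixed-step stand-in for LD pruning), dosages are
#' standardized, and the leading left singular vectors are returned.
#'
#' @param genotypes `stqtl_genotypes`.
#' @param n_pcs number of components (default 3).
#' @param thin_step keep every `thin_step`-th position-sorted variant.
#' @return samples x n_pcs matrix (columns PC1..).
#' @export
genotype_pcs <- function(genotypes, n_pcs = 3L, thin_step = 10L) {
  vr <- genotypes$variants
  ambig <- (vr$ref == "A" & vr$alt == "T") | (vr$ref == "T" & vr$alt == "A") |
    (vr$ref == "C" & vr$alt == "G") | (vr$ref == "G" & vr$alt == "C")
  keep <- which(!ambig)
  keep <- keep[seq(1L, length(keep), by = thin_step)]
  D <- genotypes$dosage[, keep, drop = FALSE]
  sds <- apply(D, 2L, sd)
  D <- D[, sds > 0, drop = FALSE]
  Z <- scale(D)
  n_pcs <- min(n_pcs, nrow(Z) - 1L, ncol(Z))
  sv <- svd(Z, nu = n_pcs, nv = 0)
  pcs <- sv$u[, seq_len(n_pcs), drop = FALSE] %*% diag(sv$d[seq_len(n_pcs)],
                                                       n_pcs)
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  rownames(pcs) <- rownames(genotypes$dosage)
  pcs
}
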