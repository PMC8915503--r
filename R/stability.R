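#' Infer relative mRNA stability from exon/intron counts
#'
#' Exon-intron split analysis of a cross-sectional cohort: for each gene
#' the deviation of log2 exonic abundance from its cross-sample mean
#' (delta-exon) minus the corresponding intronic deviation (delta-intron)
#' estimates the sample's mRNA stability relative to the cohort average.
#' Steps:
#' 1. `x = log2(exon / lib_exon * 1e6 + pseudocount)` and likewise `y` for
#'    introns — the pseudocount is applied on the counts-per-million scale
#'    so the result is exactly invariant to per-sample library-size
#'    rescaling of the raw counts;
#' 2. row-center both: `dx = x - rowMeans(x)`, `dy = y - rowMeans(y)`;
#' 3. `delta = dx - dy`;
#' 4. with `bias_method = "linear"`, regress each sample's delta column on
#'    the gene-wise mean log2 exonic CPM across all retained genes
#'    (ordinary least squares) and subtract the fitted line — this removes
#'    the expression-dependent bias of the exon/intron contrast;
#' 5. re-center each gene's row.
#'
#' Values are relative (log2 units): each gene's row averages zero, so a
#' positive entry means more stable than the cohort mean for that gene,
#' never an absolute decay rate.
#'
#' @param counts an `stqtl_counts` object, or a list with `exon` and
#'   `intron` integer matrices (genes x samples, identical dimnames).
#' @param pseudocount added to both CPM matrices before the log (default
#'   0.5 CPM; 0 is allowed when no retained gene has a zero count).
#' @param bias_method `"linear"` (default) or `"none"`.
#' @param lib_exon,lib_intron per-sample library sizes; default column sums
#'   of the respective matrix.
#' @return an `stqtl_stability` object: the genes x samples stability
#'   matrix with attributes `excluded` (data.table gene_id, reason) and
#'   `mean_log2_cpm` (the bias covariate).
#' @examples
#' ex <- rbind(g1 = c(200L, 100L)); int <- rbind(g1 = c(50L, 50L))
#' colnames(ex) <- colnames(int) <- c("s1", "s2")
#' # equal library sizes and no bias fit: delta-exon alone
#' infer_stability(list(exon = ex, intron = int), bias_method = "none",
#'                 lib_exon = c(1e6, 1e6), lib_intron = c(1e6, 1e6))
#' @export
infer_stability <- function(counts, pseudocount = 0.5,
                            bias_method = c("linear", "none"),
                            lib_exon = NULL, lib_intron = NULL) {
  bias_method <- match.arg(bias_method)
  exon <- counts$exon; intron <- counts$intron
  if (is.null(exon) || is.null(intron))
    stop("counts must carry exon and intron matrices")
  if (!identical(dim(exon), dim(intron)) ||
      !identical(dimnames(exon), dimnames(intron)))
    stop("exon and intron matrices must share gene and sample ordering")
  if (ncol(exon) < 2L) stop("stability needs >= 2 samples")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (is.null(lib_exon)) lib_exon <- colSums(exon)
  if (is.null(lib_intron)) lib_intron <- colSums(intron)

  keep <- rowSums(intron) > 0
  excluded <- data.table::data.table(
    gene_id = rownames(exon)[!keep],
    reason = "zero intronic counts in all samples")
  if (!any(keep)) stop("no gene has nonzero intronic counts")
  exon <- exon[keep, , drop = FALSE]
  intron <- intron[keep, , drop = FALSE]

  x <- log2(sweep(exon, 2, lib_exon, `/`) * 1e6 + pseudocount)
  y <- log2(sweep(intron, 2, lib_intron, `/`) * 1e6 + pseudocount)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite log abundance; use a positive pseudocount")
  delta <- (x - rowMeans(x)) - (y - rowMeans(y))
  xbar <- rowMeans(x)

  if (bias_method == "linear") {
    # per-sample OLS of delta on gene-mean expression; subtract fitted line
    X <- cbind(1, xbar)
    coefs <- solve(crossprod(X), crossprod(X, delta))   # 2 x samples
    delta <- delta - X %*% coefs
  }
  delta <- delta - rowMeans(delta)
  structure(delta, class = c("stqtl_stability", class(delta)),
            excluded = excluded, mean_log2_cpm = xbar,
            bias_method = bias_method)
}

#' Read-count stringency filter
#'
#' The stringency sigma maps to a minimum read count: with
#' `m_g = min_s min(exon_gs, intron_gs)` per gene, the threshold `T(sigma)`
#' is the sigma-quantile (left-continuous, type 1) of the positive `m_g`
#' values, and a gene passes at sigma iff `m_g >= T(sigma)`.  Higher sigma
#' keeps fewer, better-covered genes, and pass sets are nested.  Each
#' gene's `max_stringency` is the largest grid value (0.01, 0.1, ..., 0.9,
#' 0.99) at which it still passes, mirroring the per-gene stringency
#' reported alongside stability estimates.
#'
#' @param counts `stqtl_counts` or list with exon/intron matrices.
#' @param sigma analysis stringency in (0, 1].
#' @param grid stringency grid for `max_stringency` (11 values by default).
#' @return list with `pass` (named logical per gene), `threshold` (reads),
#'   `min_count` (the per-gene m_g) and `max_stringency` (named numeric,
#'   NA when a gene fails even the smallest grid value).
#' @export
stringency_filter <- function(counts, sigma = 0.01,
                              grid = c(0.01, seq(0.1, 0.9, by = 0.1), 0.99)) {
  if (!(is.numeric(sigma) && length(sigma) == 1L && sigma > 0 && sigma <= 1))
    stop("sigma must lie in (0, 1]")
  exon <- counts$exon; intron <- counts$intron
  m <- pmin(apply(exon, 1L, min), apply(intron, 1L, min))
  names(m) <- rownames(exon)
  pos <- m[m > 0]
  if (length(pos) == 0L) {
    thr <- Inf
  } else {
    thr <- unname(quantile(pos, sigma, type = 1))
  }
  pass <- m >= thr & m > 0
  thr_grid <- if (length(pos)) quantile(pos, grid, type = 1) else rep(Inf, length(grid))
  max_str <- vapply(m, function(mi) {
    ok <- grid[mi > 0 & mi >= thr_grid]
    if (length(ok)) max(ok) else NA_real_
  }, numeric(1L))
  list(pass = pass, threshold = thr, min_count = m, max_stringency = max_str)
}

#' Transcripts per million
#'
#' `rate_g = count_g / (length_g / 1000)`; `TPM_g = rate_g / sum(rate) * 1e6`
#' per sample, so each sample's TPM column sums to one million over the
#' gene universe supplied.
#'
#' @param exon_counts genes x samples matrix of exonic counts.
#' @param exonic_lengths per-gene exonic length in bp (> 0), recycled by
#'   name when named.
#' @return genes x samples TPM matrix.
#' @export
compute_tpm <- function(exon_counts, exonic_lengths) {
  if (!is.null(names(exonic_lengths)) && !is.null(rownames(exon_counts)))
    exonic_lengths <- exonic_lengths[rownames(exon_counts)]
  if (length(exonic_lengths) != nrow(exon_counts))
    stop("exonic_lengths must match the gene rows")
  if (any(exonic_lengths <= 0)) stop("exonic lengths must be positive")
  rate <- exon_counts / (exonic_lengths / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero))
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(exon_counts)[zero], collapse = ", "))
  sweep(rate, 2, tot, `/`) * 1e6
}

#' Expression trait transform
#'
#' `log10(100 * TPM + 1)`: strictly increasing, maps 0 to 0, compresses the
#' heavy right tail of TPM before linear-model association.
#'
#' @param tpm nonnegative TPM values (vector or matrix).
#' @return transformed values, same shape.
#' @export
transform_expression <- function(tpm) {
  if (any(tpm < 0)) stop("TPM values must be nonnegative")
  log10(100 * tpm + 1)
}
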