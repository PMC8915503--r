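#' Sex-specific and sex-biased stability QTL classification
#'
#' Two complementary routes, both restricted to genes that are *not*
#' differentially expressed between the sexes (per-gene Welch t-test on
#' the expression trait, BH across genes, genes with q > `de_fdr`
#' retained) so that apparent sex specificity cannot come from a gene
#' being expressed in only one sex:
#'
#' * **stratified** — the dosage scan ([associate_linear()] + BH) is run
#'   separately in males and females; a pair is `male_specific` when the
#'   male q < `fdr` while the female raw p > `p_other` (and symmetrically
#'   `female_specific`).
#' * **interaction** — one full-cohort model with dosage, sex, dosage x sex
#'   and the covariates; BH on the interaction p keeps pairs with
#'   interaction q <= `interaction_fdr`; those pairs are then classified by
#'   the sex-stratified calls at q < `fdr`: significant in one sex only
#'   gives `male_specific` / `female_specific`, significant in both (the
#'   interaction already certifies differing allelic effects) gives
#'   `sex_biased_both`.
#'
#' @param stability genes x samples stability matrix.
#' @param genotypes `stqtl_genotypes` (QC'ed).
#' @param covariates per-sample covariates *without* the sex column (sex
#'   enters the models explicitly), or NULL.
#' @param sex character vector per sample, values "male"/"female".
#' @param expression genes x samples expression-trait matrix used for the
#'   sex-DE filter.
#' @param pairs data.table(variant_id, gene_id) to test.
#' @param fdr stratified-call FDR threshold (default 0.05).
#' @param p_other maximum "not significant in the other sex" raw p
#'   (default 0.1).
#' @param interaction_fdr G x S interaction FDR gate (default 0.25).
#' @param de_fdr sex-DE exclusion threshold (default 0.05).
#' @return data.table of class `stqtl_sex_calls`: variant_id, gene_id,
#'   class, male_beta, male_p, male_q, female_beta, female_p, female_q,
#'   interaction_p, interaction_q, method ("stratified"/"interaction").
#'   Attribute `genes_tested` holds the post-DE-filter gene set.
#' @export
sex_specific_stqtls <- function(stability, genotypes, covariates, sex,
                                expression, pairs, fdr = 0.05,
                                p_other = 0.1, interaction_fdr = 0.25,
                                de_fdr = 0.05) {
  stopifnot(inherits(genotypes, "stqtl_genotypes"))
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex labels must be 'male' or 'female'")
  is_m <- sex == "male"
  n_cov <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (min(sum(is_m), sum(!is_m)) <= n_cov + 2L)
    stop("a sex stratum has fewer samples than model parameters")

  # (1) drop genes differentially expressed between sexes
  genes <- intersect(rownames(stability), rownames(expression))
  de_p <- vapply(genes, function(g) {
    tryCatch(t.test(expression[g, is_m], expression[g, !is_m])$p.value,
             error = function(e) 1)
  }, numeric(1L))
  de_q <- bh_fdr(de_p)
  genes_ok <- genes[de_q > de_fdr]
  pr <- pairs[gene_id %in% genes_ok, .(variant_id, gene_id)]
  if (nrow(pr) == 0L)
    return(structure(.empty_sex_calls(), genes_tested = genes_ok))

  sub_geno <- function(keep) {
    g <- list(dosage = genotypes$dosage[keep, , drop = FALSE],
              variants = genotypes$variants,
              samples = genotypes$samples[keep])
    class(g) <- "stqtl_genotypes"
    g
  }
  cov_sub <- function(keep) {
    if (is.null(covariates)) NULL
    else as.data.frame(covariates)[keep, , drop = FALSE]
  }
  # (2) stratified scans: BH within each sex's batch
  tab_m <- associate_linear(stability[, is_m, drop = FALSE], sub_geno(is_m),
                            cov_sub(is_m), pr, "stability")
  tab_f <- associate_linear(stability[, !is_m, drop = FALSE], sub_geno(!is_m),
                            cov_sub(!is_m), pr, "stability")
  both <- data.table::data.table(
    variant_id = pr$variant_id, gene_id = pr$gene_id,
    male_beta = tab_m$beta, male_p = tab_m$p, male_q = tab_m$q,
    female_beta = tab_f$beta, female_p = tab_f$p, female_q = tab_f$q)

  # (3) interaction scan on the full cohort
  it <- .interaction_scan(stability, genotypes, covariates, is_m, pr)
  both[, `:=`(interaction_p = it$p, interaction_q = bh_fdr(it$p))]

  strat <- both[(male_q < fdr & female_p > p_other) |
                  (female_q < fdr & male_p > p_other)]
  strat[, class := ifelse(male_q < fdr & female_p > p_other,
                          "male_specific", "female_specific")]
  strat[, method := "stratified"]

  inter <- both[interaction_q <= interaction_fdr]
  if (nrow(inter) > 0L) {
    sig_m <- inter$male_q < fdr
    sig_f <- inter$female_q < fdr
    inter[, class := data.table::fcase(
      sig_m & sig_f, "sex_biased_both",
      sig_m & !sig_f, "male_specific",
      !sig_m & sig_f, "female_specific",
      default = NA_character_)]
    inter <- inter[!is.na(class)]
    inter[, method := "interaction"]
  } else {
    inter <- NULL
  }
  cols <- c("variant_id", "gene_id", "class", "male_beta", "male_p",
            "male_q", "female_beta", "female_p", "female_q",
            "interaction_p", "interaction_q", "method")
  out <- data.table::rbindlist(list(
    if (nrow(strat)) strat[, ..cols],
    if (!is.null(inter) && nrow(inter)) inter[, ..cols]))
  if (nrow(out) == 0L) out <- .empty_sex_calls()
  class(out) <- c("stqtl_sex_calls", class(out))
  attr(out, "genes_tested") <- genes_ok
  out
}

.empty_sex_calls <- function() {
  data.table::data.table(
    variant_id = character(), gene_id = character(), class = character(),
    male_beta = numeric(), male_p = numeric(), male_q = numeric(),
    female_beta = numeric(), female_p = numeric(), female_q = numeric(),
    interaction_p = numeric(), interaction_q = numeric(),
    method = character())
}

# per-pair OLS with dosage, sex, dosage:sex and covariates; returns the
# interaction coefficient's two-sided p
.interaction_scan <- function(stability, genotypes, covariates, is_m, pr) {
  n <- nrow(genotypes$dosage)
  X0 <- .build_design(covariates, n)
  X0 <- cbind(X0, sex_male = as.numeric(is_m))
  qx <- qr(X0)
  if (qx$rank < ncol(X0))
    stop("covariate design with sex is rank deficient")
  p_out <- b_out <- numeric(nrow(pr))
  dos <- genotypes$dosage
  sexn <- as.numeric(is_m)
  df <- n - ncol(X0) - 2L
  if (df <= 0L) stop("zero residual df in interaction model")
  for (i in seq_len(nrow(pr))) {
    d <- dos[, pr$variant_id[i]]
    y <- stability[pr$gene_id[i], ]
    X <- cbind(X0, dosage = d, gxs = d * sexn)
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X) || sd(y) < 1e-12) { p_out[i] <- 1; next }
    rss <- sum(fit$residuals^2)
    XtXinv_kk <- chol2inv(chol(crossprod(X)))[ncol(X), ncol(X)]
    se <- sqrt(rss / df * XtXinv_kk)
    b_out[i] <- coef(fit)[["gxs"]]
    p_out[i] <- if (se > 0) 2 * pt(-abs(b_out[i] / se), df) else 1
  }
  list(p = p_out, beta = b_out)
}
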