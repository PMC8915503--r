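#' Direction-concordance summary from contingency counts
#'
#' Given the number of shared QTL pairs where both effects are positive
#' (`n_up`), both negative (`n_down`), and the total shared (`n_total`),
#' returns the percentages (round-half-even to one decimal) of
#' concordant-up, concordant-down, discordant pairs and overall
#' concordance.  Used internally by [cross_classify()] and directly when
#' only published counts are available.
#'
#' @param n_up,n_down,n_total nonnegative counts, `n_up + n_down <= n_total`.
#' @param digits decimals for the reported percentages (default 1).
#' @return list(n_up, n_down, n_discordant, n_total, pct_up, pct_down,
#'   pct_discordant, pct_concordant, defined).  When `n_total` is 0 the
#'   percentages are NA and `defined` is FALSE.
#' @examples
#' concordance_counts(31544, 36278, 70105)
#' @export
concordance_counts <- function(n_up, n_down, n_total, digits = 1L) {
  stopifnot(n_up >= 0, n_down >= 0, n_total >= 0, n_up + n_down <= n_total)
  if (n_total == 0)
    return(list(n_up = 0, n_down = 0, n_discordant = 0, n_total = 0,
                pct_up = NA_real_, pct_down = NA_real_,
                pct_discordant = NA_real_, pct_concordant = NA_real_,
                defined = FALSE))
  pct <- function(k) round(100 * k / n_total, digits)
  list(n_up = n_up, n_down = n_down, n_discordant = n_total - n_up - n_down,
       n_total = n_total,
       pct_up = pct(n_up), pct_down = pct(n_down),
       pct_discordant = pct(n_total - n_up - n_down),
       pct_concordant = pct(n_up + n_down),
       defined = TRUE)
}

#' Cross-classify expression and stability QTLs
#'
#' Joins the two association tables over their common (variant, gene) pair
#' universe, calls a pair an eQTL / stQTL when its q-value is below `fdr`
#' in the respective table, assigns each pair to
#' both / eqtl_only / stqtl_only / neither, and summarizes, among shared
#' QTLs, the direction concordance of the two effect estimates and the
#' overlap share of each QTL set.
#'
#' @param eqtl_table,stqtl_table association tables from
#'   [associate_linear()] over the same pair universe (mismatches are an
#'   error naming examples).
#' @param fdr QTL call threshold on q (default 0.05).
#' @return list of class `stqtl_cross`:
#'   * `pairs`: per-pair table with is_eqtl, is_stqtl, beta_expression,
#'     beta_stability, category;
#'   * `counts`: named counts of the four categories;
#'   * `concordance`: [concordance_counts()] output over shared QTLs;
#'   * `overlap_pct`: share of stQTLs that are eQTLs and vice versa.
#' @export
cross_classify <- function(eqtl_table, stqtl_table, fdr = 0.05) {
  ek <- paste(eqtl_table$variant_id, eqtl_table$gene_id)
  sk <- paste(stqtl_table$variant_id, stqtl_table$gene_id)
  if (length(ek) != length(sk) || !setequal(ek, sk)) {
    ex <- c(head(setdiff(ek, sk), 3L), head(setdiff(sk, ek), 3L))
    stop("pair universes differ between the two tables; examples: ",
         paste(ex, collapse = "; "))
  }
  st <- stqtl_table[match(ek, sk)]
  pairs <- data.table::data.table(
    variant_id = eqtl_table$variant_id, gene_id = eqtl_table$gene_id,
    is_eqtl = eqtl_table$q < fdr, is_stqtl = st$q < fdr,
    beta_expression = eqtl_table$beta, beta_stability = st$beta)
  pairs[, category := data.table::fcase(
    is_eqtl & is_stqtl, "both",
    is_eqtl & !is_stqtl, "eqtl_only",
    !is_eqtl & is_stqtl, "stqtl_only",
    default = "neither")]
  counts <- c(both = sum(pairs$category == "both"),
              eqtl_only = sum(pairs$category == "eqtl_only"),
              stqtl_only = sum(pairs$category == "stqtl_only"),
              neither = sum(pairs$category == "neither"))
  shared <- pairs[category == "both"]
  conc <- concordance_counts(
    n_up = sum(shared$beta_expression > 0 & shared$beta_stability > 0),
    n_down = sum(shared$beta_expression < 0 & shared$beta_stability < 0),
    n_total = nrow(shared))
  n_e <- sum(pairs$is_eqtl); n_s <- sum(pairs$is_stqtl)
  overlap_pct <- c(
    stqtl_also_eqtl = if (n_s > 0) round(100 * counts[["both"]] / n_s, 1) else NA_real_,
    eqtl_also_stqtl = if (n_e > 0) round(100 * counts[["both"]] / n_e, 1) else NA_real_)
  structure(list(pairs = pairs, counts = counts, concordance = conc,
                 overlap_pct = overlap_pct, fdr = fdr),
            class = "stqtl_cross")
}

#' @export
print.stqtl_cross <- function(x, ...) {
  cat("QTL cross-classification (FDR <", x$fdr, ")\n")
  print(x$counts)
  if (x$concordance$defined)
    cat("concordance among shared QTLs:", x$concordance$pct_concordant,
        "% (up", x$concordance$pct_up, "%, down",
        x$concordance$pct_down, "%)\n")
  else cat("concordance undefined (no shared QTLs)\n")
  invisible(x)
}

#' Greedy LD blocks and representative-QTL filtering
#'
#' LD r-squared is the squared Pearson correlation of dosage vectors
#' (composite LD on unphased genotypes), computed only for variant pairs
#' within `window_bp` base pairs and `window_count` positions of each other
#' in the position-sorted variant list.  Blocks are built greedily over the
#' position-sorted variants: a variant joins the current block iff its
#' r-squared with *every* current member exceeds `r2_min` (and each pair is
#' within the windows); otherwise it starts a new block.  The greedy rule
#' is order dependent by design — the position-sorted order is part of the
#' contract.  Per (block, gene), the QTL with the smallest q (ties: smaller
#' p, then smaller position) is kept as the representative.
#'
#' A zero-variance dosage vector has undefined correlation; its r-squared
#' is treated as 0 with a warning, so such variants always open singleton
#' blocks.
#'
#' @param genotypes `stqtl_genotypes` holding dosages for all QTL variants.
#' @param qtls association table restricted to declared QTLs (must carry
#'   variant_id, gene_id, p, q).
#' @param r2_min block membership threshold (default 0.9).
#' @param window_bp,window_count pair-evaluation windows (defaults 1e8 bp
#'   and 50 variants).
#' @return list of class `stqtl_ldblocks`: `blocks` (data.table variant_id,
#'   block), `representatives` (filtered QTL table with a block column),
#'   `r2_pairs` (computed pair cache), `params`.
#' @export
ld_blocks_and_filter <- function(genotypes, qtls, r2_min = 0.9,
                                 window_bp = 1e8, window_count = 50L) {
  stopifnot(inherits(genotypes, "stqtl_genotypes"))
  vr <- genotypes$variants[id %in% unique(qtls$variant_id)]
  miss <- setdiff(unique(qtls$variant_id), vr$id)
  if (length(miss))
    stop("dosages unavailable for QTL variant(s): ",
         paste(head(miss, 5L), collapse = ", "))
  data.table::setorder(vr, chrom, pos)
  ids <- vr$id
  dos <- genotypes$dosage[, ids, drop = FALSE]
  sds <- apply(dos, 2L, sd)
  if (any(sds == 0))
    warning("zero-variance dosage for ",
            sum(sds == 0), " variant(s); r2 treated as 0")
  r2_cache <- list()
  r2_of <- function(i, j) {
    if (sds[i] == 0 || sds[j] == 0) return(0)
    cor(dos[, i], dos[, j])^2
  }
  block <- integer(length(ids))
  cur <- 1L
  members <- 1L
  cache_rows <- list()
  if (length(ids) > 0L) block[1L] <- 1L
  for (v in seq_along(ids)[-1]) {
    join <- length(members) > 0L
    for (u in members) {
      ok <- abs(vr$pos[v] - vr$pos[u]) <= window_bp &&
        (v - u) <= window_count && vr$chrom[v] == vr$chrom[u]
      r2 <- if (ok) r2_of(u, v) else NA_real_
      if (ok) cache_rows[[length(cache_rows) + 1L]] <-
          data.table::data.table(id1 = ids[u], id2 = ids[v], r2 = r2)
      if (!ok || !(r2 > r2_min)) { join <- FALSE; break }
    }
    if (join) {
      members <- c(members, v)
    } else {
      cur <- cur + 1L
      members <- v
    }
    block[v] <- cur
  }
  blocks <- data.table::data.table(variant_id = ids, block = block,
                                   pos = vr$pos)
  qt <- merge(data.table::as.data.table(qtls), blocks, by = "variant_id")
  data.table::setorder(qt, block, gene_id, q, p, pos)
  reps <- qt[, .SD[1L], by = .(block, gene_id)]
  structure(list(blocks = blocks,
                 representatives = reps,
                 r2_pairs = if (length(cache_rows))
                   data.table::rbindlist(cache_rows) else
                     data.table::data.table(id1 = character(),
                                            id2 = character(), r2 = numeric()),
                 params = list(r2_min = r2_min, window_bp = window_bp,
                               window_count = window_count)),
            class = "stqtl_ldblocks")
}
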