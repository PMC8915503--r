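#' Assign a variant to a genic region
#'
#' Returns the label of the disjoint gene segment containing the position,
#' or `"upstream"` for positions within `flank` bp upstream of the TSS and
#' `"downstream"` for positions within `flank` bp downstream of the TTS,
#' both in transcription orientation (for a minus-strand gene upstream lies
#' genomically above the TSS).  Positions outside the cis window are an
#' error.
#'
#' @param pos 1-based genomic position (scalar).
#' @param gene one row of `annotation$genes`.
#' @param segments that gene's rows of `annotation$segments`.
#' @param flank flank size in bp (default 100000).
#' @return one of "upstream", "5'UTR", "CDS", "intron", "3'UTR",
#'   "downstream".
#' @export
assign_genic_region <- function(pos, gene, segments, flank = 100000L) {
  hit <- segments[pos >= start & pos <= end]
  if (nrow(hit) >= 1L) {
    if (nrow(hit) > 1L) {
      # user-supplied overlapping annotation: CDS > UTR > intron
      pref <- c("CDS", "5'UTR", "3'UTR", "intron")
      hit <- hit[order(match(label, pref))][1L]
    }
    return(hit$label)
  }
  sgn <- if (gene$strand == "+") 1L else -1L
  d_tss <- sgn * (pos - gene$tss)
  d_tts <- sgn * (pos - gene$tts)
  if (d_tss < 0 && d_tss >= -flank) return("upstream")
  if (d_tts > 0 && d_tts <= flank) return("downstream")
  stop("position ", pos, " outside the cis window of ", gene$gene_id)
}

#' Vectorized genic-region assignment for variant-gene pairs
#'
#' @param pairs data.table with variant_id/gene_id and pos columns (as
#'   returned by [cis_pairs()]).
#' @param annotation `stqtl_annotation`.
#' @param flank flank size in bp.
#' @return character vector of region labels aligned with `pairs` rows.
#' @export
assign_genic_regions <- function(pairs, annotation, flank = 100000L) {
  out <- character(nrow(pairs))
  seg_by_gene <- split(annotation$segments, by = "gene_id")
  gene_rows <- split(annotation$genes, by = "gene_id")
  for (gid in unique(pairs$gene_id)) {
    idx <- which(pairs$gene_id == gid)
    g <- gene_rows[[gid]]
    segs <- seg_by_gene[[gid]]
    p <- pairs$pos[idx]
    lab <- rep(NA_character_, length(p))
    for (k in seq_len(nrow(segs)))
      lab[is.na(lab) & p >= segs$start[k] & p <= segs$end[k]] <- segs$label[k]
    sgn <- if (g$strand == "+") 1L else -1L
    d_tss <- sgn * (p - g$tss); d_tts <- sgn * (p - g$tts)
    lab[is.na(lab) & d_tss < 0 & d_tss >= -flank] <- "upstream"
    lab[is.na(lab) & d_tts > 0 & d_tts <= flank] <- "downstream"
    if (anyNA(lab))
      stop("pair position outside cis window for gene ", gid)
    out[idx] <- lab
  }
  out
}

#' Region counts for enrichment
#'
#' Tabulates all tested variant-gene pairs (`N_k`) and the QTL subset
#' (`Q_k`) over the six genic regions.
#'
#' @param all_regions character region labels for every tested pair.
#' @param qtl_regions character region labels for the QTL pairs.
#' @return data.table (region, N_k, Q_k) covering the six canonical
#'   regions, plus attributes N and Q (totals).
#' @export
region_counts <- function(all_regions, qtl_regions) {
  levs <- c("upstream", "5'UTR", "CDS", "intron", "3'UTR", "downstream")
  nk <- table(factor(all_regions, levels = levs))
  qk <- table(factor(qtl_regions, levels = levs))
  out <- data.table::data.table(region = levs, N_k = as.integer(nk),
                                Q_k = as.integer(qk))
  if (any(out$Q_k > out$N_k))
    stop("QTL count exceeds background count in some region")
  structure(out, N = length(all_regions), Q = length(qtl_regions))
}

#' Genic-region enrichment of QTLs
#'
#' Per region k: enrichment ratio `ER_k = (Q_k/Q) / (N_k/N)`, a two-sided
#' Fisher exact p on the 2x2 table
#' `(Q_k, Q - Q_k; N_k - Q_k, (N - N_k) - (Q - Q_k))`, the upper-tail
#' hypergeometric p, and BH q across regions.  Regions with `N_k = 0` are
#' skipped (logged in the `note` column).
#'
#' @param counts output of [region_counts()] (or any data.table with
#'   region/N_k/Q_k plus N and Q attributes).
#' @return data.table (region, N_k, Q_k, ER, odds_ratio, p_fisher,
#'   p_hyper, q, note).
#' @export
region_enrichment <- function(counts) {
  N <- attr(counts, "N"); Q <- attr(counts, "Q")
  if (is.null(N)) N <- sum(counts$N_k)
  if (is.null(Q)) Q <- sum(counts$Q_k)
  res <- data.table::copy(counts)
  res[, `:=`(ER = NA_real_, odds_ratio = NA_real_, p_fisher = NA_real_,
             p_hyper = NA_real_, note = "")]
  for (i in seq_len(nrow(res))) {
    nk <- res$N_k[i]; qk <- res$Q_k[i]
    if (nk == 0L) { res[i, note := "skipped: N_k = 0"]; next }
    tab <- matrix(c(qk, Q - qk, nk - qk, (N - nk) - (Q - qk)), nrow = 2L)
    ft <- fisher.test(tab)
    res[i, `:=`(
      ER = (qk / Q) / (nk / N),
      odds_ratio = unname(ft$estimate),
      p_fisher = ft$p.value,
      p_hyper = phyper(qk - 1L, nk, N - nk, Q, lower.tail = FALSE))]
  }
  ok <- !is.na(res$p_fisher)
  res[, q := NA_real_]
  res[ok, q := bh_fdr(p_fisher)]
  res[]
}

#' Sliding-window positional enrichment profile
#'
#' Signed distances (transcription orientation) of all tested pairs and of
#' the QTL pairs to a common anchor are binned into sliding windows of
#' width `bin` advanced by `step`; window i covers
#' `[d_min + i*step, d_min + i*step + bin)` (half-open, so a distance on a
#' window's right edge belongs to the next window).  Each window reports
#' `ER_i = (Q_i/Q) / (N_i/N)`; windows with `N_i = 0` give NA.
#'
#' @param qtl_dist,all_dist numeric signed distances.
#' @param bin window width in bp (default 2000).
#' @param step window advance in bp (default 50).
#' @return data.table (window_start, window_end, N_i, Q_i, ER).
#' @export
positional_profile <- function(qtl_dist, all_dist, bin = 2000, step = 50) {
  if (bin <= 0 || step <= 0) stop("bin and step must be positive")
  if (length(all_dist) == 0L) stop("no background distances supplied")
  d0 <- min(all_dist); d1 <- max(all_dist)
  n_win <- max(1L, as.integer(ceiling((d1 - d0 - bin) / step)) + 1L)
  lo <- d0 + (seq_len(n_win) - 1L) * step
  count_in <- function(d) {
    ds <- sort(d)
    hi_idx <- findInterval(lo + bin - 1e-9, ds)       # < lo + bin
    lo_idx <- findInterval(lo - 1e-9, ds)             # < lo
    hi_idx - lo_idx
  }
  Ni <- count_in(all_dist)
  Qi <- count_in(qtl_dist)
  N <- length(all_dist); Q <- length(qtl_dist)
  er <- ifelse(Ni > 0 & Q > 0, (Qi / Q) / (Ni / N), NA_real_)
  data.table::data.table(window_start = lo, window_end = lo + bin,
                         N_i = Ni, Q_i = Qi, ER = er)
}

#' Two-proportion overlap comparison
#'
#' Fisher two-sided comparison of two overlap fractions `k1/n1` vs
#' `k2/n2` with percentages (round-half-even to `digits`).
#'
#' @param k1,n1,k2,n2 counts.
#' @param digits decimals in the reported percentages (default 2).
#' @return list(pct1, pct2, p).
#' @examples
#' overlap_fisher(2770, 10332, 2788, 12617)
#' @export
overlap_fisher <- function(k1, n1, k2, n2, digits = 2L) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L, byrow = TRUE)
  list(pct1 = round(100 * k1 / n1, digits),
       pct2 = round(100 * k2 / n2, digits),
       p = fisher.test(tab)$p.value)
}

# variants (1-based pos) overlapping 0-based half-open intervals
.overlap_any <- function(pos, chrom, sites) {
  if (nrow(sites) == 0L || length(pos) == 0L)
    return(rep(FALSE, length(pos)))
  v <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  s <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$start + 1L, sites$end))
  IRanges::overlapsAny(v, s)
}

#' Binding-site overlap and per-factor enrichment
#'
#' Restricts QTLs and the tested-pair background to mature-mRNA regions
#' (5'UTR, CDS, 3'UTR), deduplicates to unique variants, and computes
#' (a) the fraction of QTL variants overlapping at least one site, with a
#' two-sided Fisher test against the all-variant background, and (b) for
#' each factor a 2x2 table of QTL / non-QTL x in / out of that factor's
#' sites, with `ER = (QTL fraction in sites) / (all-variant fraction in
#' sites)`, Fisher p and BH q across factors.  A variant at 1-based
#' position `pos` overlaps a site iff `start <= pos-1 < end` (BED
#' half-open convention).
#'
#' @param qtl_pairs data.table of QTL pairs with variant_id, pos and a
#'   `region` column (see [assign_genic_regions()]).
#' @param all_pairs the tested-pair background, same columns.
#' @param sites `stqtl_sites` data.table (chrom, start, end, factor_name,
#'   type); unsorted input is sorted with a warning; an empty set returns
#'   empty results.
#' @param chrom chromosome of the variants (single-chromosome analyses).
#' @return list of class `stqtl_bse`: `overall` (n_qtl, n_qtl_in, pct_qtl,
#'   n_all, n_all_in, pct_all, p_vs_background), `per_factor` data.table
#'   (factor_name, qtl_in, qtl_out, nonqtl_in, nonqtl_out, ER, p, q).
#' @export
binding_site_enrichment <- function(qtl_pairs, all_pairs, sites,
                                    chrom = "chr1") {
  mature <- c("5'UTR", "CDS", "3'UTR")
  qv <- unique(qtl_pairs[region %in% mature, .(variant_id, pos)])
  av <- unique(all_pairs[region %in% mature, .(variant_id, pos)])
  if (nrow(sites) > 0L && is.unsorted(sites$start)) {
    warning("binding-site intervals unsorted; sorting")
    sites <- sites[order(chrom, start)]
  }
  if (nrow(sites) > 0L && any(sites$start >= sites$end))
    stop("binding-site intervals must satisfy start < end")
  q_in <- .overlap_any(qv$pos, chrom, sites)
  a_in <- .overlap_any(av$pos, chrom, sites)
  overall <- list(
    n_qtl = nrow(qv), n_qtl_in = sum(q_in),
    pct_qtl = if (nrow(qv)) round(100 * mean(q_in), 2) else NA_real_,
    n_all = nrow(av), n_all_in = sum(a_in),
    pct_all = if (nrow(av)) round(100 * mean(a_in), 2) else NA_real_,
    p_vs_background = if (nrow(qv) && nrow(av))
      overlap_fisher(sum(q_in), nrow(qv), sum(a_in), nrow(av))$p
    else NA_real_)
  if (nrow(sites) == 0L) {
    pf <- data.table::data.table(factor_name = character(),
                                 qtl_in = integer(), qtl_out = integer(),
                                 nonqtl_in = integer(), nonqtl_out = integer(),
                                 ER = numeric(), p = numeric(), q = numeric())
    return(structure(list(overall = overall, per_factor = pf),
                     class = "stqtl_bse"))
  }
  qtl_set <- qv$variant_id
  nonq <- av[!variant_id %in% qtl_set]
  rows <- lapply(unique(sites$factor_name), function(f) {
    fs <- sites[factor_name == f]
    qi <- .overlap_any(qv$pos, chrom, fs)
    ai <- .overlap_any(av$pos, chrom, fs)
    ni <- .overlap_any(nonq$pos, chrom, fs)
    er <- if (nrow(av) && sum(ai) > 0 && nrow(qv))
      (mean(qi)) / (mean(ai)) else NA_real_
    tab <- matrix(c(sum(qi), nrow(qv) - sum(qi),
                    sum(ni), nrow(nonq) - sum(ni)), nrow = 2L, byrow = TRUE)
    data.table::data.table(
      factor_name = f, qtl_in = sum(qi), qtl_out = nrow(qv) - sum(qi),
      nonqtl_in = sum(ni), nonqtl_out = nrow(nonq) - sum(ni),
      ER = er, p = fisher.test(tab)$p.value)
  })
  pf <- data.table::rbindlist(rows)
  pf[, q := bh_fdr(p)]
  structure(list(overall = overall, per_factor = pf), class = "stqtl_bse")
}
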