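#' Simulate gene models with disjoint genic segments
#'
#' Places genes on one chromosome in non-overlapping slots so that even the
#' 100 kb cis flanks of neighbouring genes never overlap.  Each gene body
#' reads, in transcription order, 5'UTR, then alternating CDS/intron, then
#' 3'UTR; segment lengths are drawn around the configured means.  Strand is
#' assigned alternately so about half the genes are on each strand; for a
#' minus-strand gene the TSS is the higher genomic coordinate.
#'
#' @param cfg an [sim_config()] object.
#' @return an object of class `stqtl_annotation`: list with
#'   * `genes`: data.table (gene_id, chrom, strand, tss, tts, start, end,
#'     exonic_length, intronic_length) where start/end are the genomic
#'     bounds of the gene body (1-based inclusive);
#'   * `segments`: data.table (gene_id, chrom, start, end, label) with
#'     labels in {5'UTR, CDS, intron, 3'UTR}, disjoint within a gene.
#' @examples
#' a <- simulate_annotation(sim_config(n_genes = 3, seed = 2))
#' a$genes
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "stqtl_config"))
  set.seed(.sub_seed(cfg, 2L))
  sp <- cfg$segment_length_params
  n <- cfg$n_genes
  slot <- cfg$gene_slot
  if (n * slot > cfg$genome_length)
    stop("cannot place ", n, " genes in genome_length ", cfg$genome_length)

  seg_list <- vector("list", n)
  genes <- vector("list", n)
  # jittered positive lengths around the configured means
  draw_len <- function(mean_len, k) pmax(20L, as.integer(round(
    mean_len * exp(rnorm(k, 0, 0.25)))))

  for (i in seq_len(n)) {
    n_int <- sp$n_introns
    lens <- c(draw_len(sp$utr5, 1L),
              as.vector(rbind(draw_len(sp$cds_exon, n_int + 1L),
                              c(draw_len(sp$intron, n_int), 0L)))[
                seq_len(2L * n_int + 1L)],
              draw_len(sp$utr3, 1L))
    labels <- c("5'UTR",
                rep(c("CDS", "intron"), length.out = 2L * n_int + 1L),
                "3'UTR")
    body_len <- sum(lens)
    if (body_len + 2L * cfg$flank + 2L > slot)
      stop("gene body exceeds its slot; increase genome_length")
    slot_start <- (i - 1L) * slot + 1L
    body_start <- as.integer(slot_start + cfg$flank +
      sample.int(slot - body_len - 2L * cfg$flank - 1L, 1L))
    strand <- if (runif(1) < 0.5) "+" else "-"

    # genomic segment coordinates in transcription order
    tx_starts <- body_start + cumsum(c(0L, head(lens, -1L)))
    tx_ends <- tx_starts + lens - 1L
    if (strand == "+") {
      g_start <- tx_starts; g_end <- tx_ends
      tss <- body_start; tts <- body_start + body_len - 1L
    } else {
      # transcription runs high -> low: first transcribed segment occupies
      # the highest genomic coordinates
      g_end <- body_start + body_len - 1L - cumsum(c(0L, head(lens, -1L)))
      g_start <- g_end - lens + 1L
      tss <- body_start + body_len - 1L; tts <- body_start
    }
    gid <- sprintf("gene%04d", i)
    seg_list[[i]] <- data.table::data.table(
      gene_id = gid, chrom = "chr1", start = g_start, end = g_end,
      label = labels)
    genes[[i]] <- data.table::data.table(
      gene_id = gid, chrom = "chr1", strand = strand,
      tss = tss, tts = tts,
      start = body_start, end = body_start + body_len - 1L,
      exonic_length = sum(lens[labels != "intron"]),
      intronic_length = sum(lens[labels == "intron"]))
  }
  out <- list(genes = data.table::rbindlist(genes),
              segments = data.table::rbindlist(seg_list))
  data.table::setkey(out$segments, gene_id, start)
  class(out) <- "stqtl_annotation"
  out
}

#' @export
print.stqtl_annotation <- function(x, ...) {
  cat("stqtl_annotation:", nrow(x$genes), "genes,",
      nrow(x$segments), "segments\n")
  invisible(x)
}

#' Plant QTL effects and build the truth table
#'
#' Selects disjoint gene subsets for transcription-rate and decay-rate QTLs
#' and assigns each chosen gene one causal cis variant with a log2 allelic
#' effect sampled from `cfg$effect_size_grid` with random sign.  By default
#' transcription effects are planted on upstream variants (promoter
#' proximal) and decay effects on CDS/3'UTR variants (where stability
#' determinants live); genes lacking a QC-pass variant in the preferred
#' region fall back to any QC-pass cis variant, and are skipped when none
#' exists.  A `cfg$prop_sex_specific` fraction of decay QTLs is restricted
#' to one sex (effect multiplied by the sex indicator downstream).
#'
#' The sign convention is stability = `-log2(beta)`: a negative `effect`
#' on target "decay" increases stability per alt allele.
#'
#' @param genotypes [simulate_genotypes()] output.
#' @param annotation [simulate_annotation()] output.
#' @param cfg an [sim_config()] object.
#' @param transcription_region,stability_region character vectors of region
#'   labels eligible for planting each effect type.
#' @param strict_region when TRUE, genes without a QC-pass variant in the
#'   preferred region are skipped instead of falling back to any cis
#'   variant (useful for region-targeted designs).
#' @return data.table of class `stqtl_truth` with columns variant_id,
#'   gene_id, target ("transcription"/"decay"), effect (log2 per alt
#'   allele, never 0), sex ("none"/"male"/"female").
#' @export
simulate_truth <- function(genotypes, annotation, cfg,
                           transcription_region = "upstream",
                           stability_region = c("CDS", "3'UTR"),
                           strict_region = FALSE) {
  stopifnot(inherits(cfg, "stqtl_config"),
            inherits(genotypes, "stqtl_genotypes"),
            inherits(annotation, "stqtl_annotation"))
  set.seed(.sub_seed(cfg, 3L))
  pairs <- cis_pairs(annotation, genotypes, window = cfg$flank)
  if (nrow(pairs) == 0L)
    return(.empty_truth())
  pairs <- merge(pairs, genotypes$variants[, .(variant_id = id, pass_qc)],
                 by = "variant_id")
  pairs <- pairs[pass_qc == TRUE]
  reg <- assign_genic_regions(pairs, annotation, flank = cfg$flank)
  pairs[, region := reg]

  g_all <- annotation$genes$gene_id
  n_tr <- round(cfg$prop_transcription_qtl * length(g_all))
  n_st <- round(cfg$prop_stability_qtl * length(g_all))
  picked <- sample(g_all, min(length(g_all), n_tr + n_st))
  g_tr <- head(picked, n_tr)
  g_st <- tail(picked, length(picked) - n_tr)

  pick_variant <- function(gid, want) {
    cand <- pairs[gene_id == gid & region %in% want]
    if (nrow(cand) == 0L && !strict_region) cand <- pairs[gene_id == gid]
    if (nrow(cand) == 0L) return(NA_character_)
    cand$variant_id[sample.int(nrow(cand), 1L)]
  }
  mk <- function(gset, want, target) {
    rows <- lapply(gset, function(gid) {
      v <- pick_variant(gid, want)
      if (is.na(v)) return(NULL)
      data.table::data.table(
        variant_id = v, gene_id = gid, target = target,
        effect = sample(cfg$effect_size_grid, 1L) * sample(c(-1, 1), 1L),
        sex = "none")
    })
    data.table::rbindlist(rows)
  }
  truth <- data.table::rbindlist(list(
    mk(g_tr, transcription_region, "transcription"),
    mk(g_st, stability_region, "decay")))
  if (nrow(truth) == 0L) return(.empty_truth())
  if (cfg$prop_sex_specific > 0) {
    dec <- which(truth$target == "decay")
    n_sx <- round(cfg$prop_sex_specific * length(dec))
    if (n_sx > 0L) {
      sel <- sample(dec, n_sx)
      truth[sel, sex := sample(c("male", "female"), n_sx, replace = TRUE)]
    }
  }
  truth <- truth[effect != 0]
  if (anyDuplicated(truth[, .(variant_id, gene_id, target)]))
    truth <- unique(truth, by = c("variant_id", "gene_id", "target"))
  class(truth) <- c("stqtl_truth", class(truth))
  truth
}

.empty_truth <- function() {
  t <- data.table::data.table(variant_id = character(), gene_id = character(),
                              target = character(), effect = numeric(),
                              sex = character())
  class(t) <- c("stqtl_truth", class(t))
  t
}

#' Simulate RBP/miRNA binding-site intervals
#'
#' Emulates a binding-site catalogue on mature mRNA: for each named factor
#' in `signal_factors`, intervals are centred on the planted decay-QTL
#' variants (so stability QTLs genuinely fall inside that factor's sites);
#' `decoy_factors` get intervals placed uniformly at random inside mature
#' mRNA segments (5'UTR/CDS/3'UTR), avoiding planted decay variants.
#'
#' @param annotation [simulate_annotation()] output.
#' @param truth [simulate_truth()] output.
#' @param genotypes [simulate_genotypes()] output (supplies variant
#'   positions for the planted decay variants).
#' @param cfg an [sim_config()] object.
#' @param signal_factors,decoy_factors character vectors of factor names.
#' @param site_halfwidth half-width in bp of each interval.
#' @param decoy_sites_per_factor number of random intervals per decoy.
#' @return data.table of class `stqtl_sites` with columns chrom, start
#'   (0-based), end (exclusive), factor_name, type.
#' @export
simulate_binding_sites <- function(annotation, truth, genotypes, cfg,
                                   signal_factors = c("RBP_A", "RBP_B"),
                                   decoy_factors = c("RBP_X", "RBP_Y"),
                                   site_halfwidth = 25L,
                                   decoy_sites_per_factor = 50L) {
  stopifnot(inherits(annotation, "stqtl_annotation"),
            inherits(genotypes, "stqtl_genotypes"))
  set.seed(.sub_seed(cfg, 4L))
  mature <- annotation$segments[label %in% c("5'UTR", "CDS", "3'UTR")]
  rows <- list()
  causal_pos <- integer()
  if (nrow(truth) > 0L) {
    dec <- truth[target == "decay"]
    causal_pos <- genotypes$variants$pos[match(dec$variant_id,
                                               genotypes$variants$id)]
    causal_pos <- causal_pos[!is.na(causal_pos)]
  }
  for (f in signal_factors) {
    if (length(causal_pos) == 0L) break
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = "chr1",
      start = pmax(0L, as.integer(causal_pos) - 1L - site_halfwidth),
      end = as.integer(causal_pos) + site_halfwidth,
      factor_name = f, type = "RBP")
  }
  for (f in decoy_factors) {
    seg <- mature[sample.int(nrow(mature), decoy_sites_per_factor,
                             replace = TRUE)]
    centre <- seg$start + floor(runif(nrow(seg)) * (seg$end - seg$start + 1L))
    if (length(causal_pos))
      centre <- centre + ifelse(
        vapply(centre, function(p) any(abs(p - causal_pos) <= 2L * site_halfwidth),
               logical(1L)),
        4L * site_halfwidth, 0L)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = "chr1",
      start = pmax(0L, as.integer(centre) - 1L - site_halfwidth),
      end = as.integer(centre) + site_halfwidth,
      factor_name = f, type = "RBP")
  }
  sites <- data.table::rbindlist(rows)
  if (nrow(sites) == 0L)
    sites <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer(), factor_name = character(),
                                    type = character())
  data.table::setorder(sites, chrom, start)
  class(sites) <- c("stqtl_sites", class(sites))
  sites
}
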