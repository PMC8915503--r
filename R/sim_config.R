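#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The generator emulates a bulk RNA-seq QTL cohort: LD-structured biallelic
#' genotypes in Hardy-Weinberg equilibrium, protein-coding gene models with
#' disjoint 5'UTR/CDS/intron/3'UTR segments, and paired exonic/intronic read
#' counts arising from a steady-state transcription/decay kinetic model with
#' genetic effects planted on the log2 transcription rate (alpha) or the
#' log2 decay rate (beta).
#'
#' Under the kinetic model, pre-mRNA abundance (hence the intronic read
#' rate) is proportional to alpha and mature-mRNA abundance (hence the
#' exonic read rate) is proportional to alpha/beta; splicing and export
#' rates are absorbed into global constants.  Relative stability is
#' `-log2(beta)`: a stability-increasing allele carries a negative effect on
#' `log2(beta)`.
#'
#' @param n_samples number of diploid samples (default 289, a lung cohort
#'   scale with 187 males and 102 females).
#' @param n_variants number of biallelic SNVs placed uniformly on one
#'   autosome.
#' @param n_genes number of genes.
#' @param n_haplotypes founder haplotype pool size; samples are mosaics of
#'   founders copied per LD segment, which induces block LD (must be >= 2).
#' @param maf_min minimum realized minor allele frequency; variants below it
#'   are flagged for removal (default 0.01).
#' @param genome_length chromosome length in bp; `NULL` sizes it so all
#'   genes fit with non-overlapping 100 kb flanks.
#' @param segment_length_params named list of mean segment lengths in bp:
#'   `utr5`, `cds_exon`, `intron`, `utr3`, and the integer `n_introns`.
#' @param ld_segment_bp founder-copying segment length in bp; variants in
#'   the same segment are copied together and so are in strong LD.
#' @param alpha_log2_mean,alpha_log2_sd baseline per-gene log2
#'   transcription rate distribution.
#' @param beta_log2_mean,beta_log2_sd baseline per-gene log2 decay rate
#'   distribution.
#' @param effect_size_grid absolute log2 allelic effects sampled (with
#'   random sign) for planted QTLs.
#' @param prop_transcription_qtl,prop_stability_qtl fraction of genes given
#'   a planted transcription-rate / decay-rate QTL.
#' @param prop_sex_specific fraction of decay QTLs whose effect is
#'   restricted to one sex.
#' @param rate_noise_sd per-gene-per-sample lognormal noise sd (log2 units)
#'   added independently to both rates.
#' @param dispersion negative-binomial dispersion phi (variance
#'   `mu + phi*mu^2`); 0 gives Poisson counts.
#' @param intron_capture fraction kappa of pre-mRNA contributing intronic
#'   reads (default 0.1; intronic reads are a minority of a library).
#' @param library_size_mean,library_size_cv per-sample library size
#'   distribution (lognormal).
#' @param prop_male probability a sample is male (default 187/289).
#' @param seed integer seed; every stochastic generator operation derives
#'   its stream from it, so identical configs give identical outputs.
#'
#' @return an object of class `stqtl_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_samples = 50, n_variants = 200, n_genes = 10, seed = 1)
#' @export
sim_config <- function(n_samples = 289L,
                       n_variants = 2000L,
                       n_genes = 200L,
                       n_haplotypes = 50L,
                       maf_min = 0.01,
                       genome_length = NULL,
                       segment_length_params = list(utr5 = 200, cds_exon = 400,
                                                    intron = 3000, utr3 = 700,
                                                    n_introns = 3L),
                       ld_segment_bp = 50000,
                       alpha_log2_mean = 0, alpha_log2_sd = 1,
                       beta_log2_mean = 0, beta_log2_sd = 0.5,
                       effect_size_grid = c(0.5, 0.8, 1.0),
                       prop_transcription_qtl = 0.15,
                       prop_stability_qtl = 0.15,
                       prop_sex_specific = 0.1,
                       rate_noise_sd = 0.15,
                       dispersion = 0.05,
                       intron_capture = 0.1,
                       library_size_mean = 2e7,
                       library_size_cv = 0.2,
                       prop_male = 187 / 289,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes), n_haplotypes = as.integer(n_haplotypes),
    maf_min = maf_min, genome_length = genome_length,
    segment_length_params = segment_length_params,
    ld_segment_bp = ld_segment_bp,
    alpha_log2_mean = alpha_log2_mean, alpha_log2_sd = alpha_log2_sd,
    beta_log2_mean = beta_log2_mean, beta_log2_sd = beta_log2_sd,
    effect_size_grid = effect_size_grid,
    prop_transcription_qtl = prop_transcription_qtl,
    prop_stability_qtl = prop_stability_qtl,
    prop_sex_specific = prop_sex_specific,
    rate_noise_sd = rate_noise_sd, dispersion = dispersion,
    intron_capture = intron_capture,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    prop_male = prop_male,
    seed = as.integer(seed),
    flank = 100000L
  )
  # mean span of one gene body given the segment means
  sp <- cfg$segment_length_params
  need <- c("utr5", "cds_exon", "intron", "utr3", "n_introns")
  if (!all(need %in% names(sp)))
    stop("segment_length_params must name: ", paste(need, collapse = ", "))
  gene_span <- sp$utr5 + sp$utr3 + (sp$n_introns + 1) * sp$cds_exon +
    sp$n_introns * sp$intron
  slot <- as.integer(2 * gene_span + 2 * cfg$flank + 10000)
  if (is.null(cfg$genome_length)) cfg$genome_length <- cfg$n_genes * slot
  cfg$gene_slot <- slot

  stopifnot(cfg$n_samples >= 2, cfg$n_variants >= 1, cfg$n_genes >= 1)
  if (cfg$n_haplotypes < 2)
    stop("n_haplotypes must be >= 2 for polymorphism")
  fracs <- c(maf_min = cfg$maf_min,
             prop_transcription_qtl = cfg$prop_transcription_qtl,
             prop_stability_qtl = cfg$prop_stability_qtl,
             prop_sex_specific = cfg$prop_sex_specific,
             intron_capture = cfg$intron_capture,
             prop_male = cfg$prop_male)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("fractions must lie in [0,1]: ", paste(names(fracs)[bad], collapse = ", "))
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$rate_noise_sd < 0) stop("rate_noise_sd must be >= 0")
  if (any(cfg$effect_size_grid <= 0))
    stop("effect_size_grid entries must be positive (sign is sampled)")
  if (cfg$genome_length < cfg$n_genes * slot)
    stop("genome_length too small to place ", cfg$n_genes,
         " genes with 100 kb flanks (need >= ", cfg$n_genes * slot, " bp)")
  if (!is.finite(cfg$seed) || abs(cfg$seed) >= 2^31 - 1000)
    stop("seed must be a 32-bit integer")
  class(cfg) <- "stqtl_config"
  cfg
}

#' @export
print.stqtl_config <- function(x, ...) {
  cat("stqtl_config:", x$n_samples, "samples,", x$n_variants, "variants,",
      x$n_genes, "genes, seed", x$seed, "\n")
  invisible(x)
}

# derived sub-seeds so generator stages are independently reproducible
.sub_seed <- function(cfg, offset) (cfg$seed * 101L + offset) %% 2000000011L
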