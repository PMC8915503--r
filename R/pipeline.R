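#' Pipeline run configuration
#'
#' Validates a named list of paths and parameters for [run_pipeline()].
#' When `simulate = TRUE` the input paths are generated into the run
#' directory from `sim` (an [sim_config()] or arguments for one);
#' otherwise `vcf`, `counts_exon`, `counts_intron`, `covariates` and `gtf`
#' must name existing files.
#'
#' @param out_dir run directory (created).
#' @param simulate generate the inputs with the bundled simulator?
#' @param sim [sim_config()] object (simulate mode).
#' @param vcf,counts_exon,counts_intron,covariates,gtf,sites_bed input
#'   paths (file mode; `sites_bed` optional in both modes).
#' @param window cis window (bp, default 100000).
#' @param stringency analysis stringency in (0,1] (default 0.01).
#' @param fdr QTL FDR threshold (default 0.05).
#' @param r2_min LD block threshold (default 0.9).
#' @param bin,step positional-profile window parameters.
#' @param seed integer seed recorded in the provenance block.
#' @return validated list of class `stqtl_runconfig`.
#' @export
run_config <- function(out_dir, simulate = TRUE, sim = sim_config(),
                       vcf = NULL, counts_exon = NULL, counts_intron = NULL,
                       covariates = NULL, gtf = NULL, sites_bed = NULL,
                       window = 100000L, stringency = 0.01, fdr = 0.05,
                       r2_min = 0.9, bin = 2000, step = 50, seed = 1L) {
  if (!simulate) {
    need <- c(vcf = vcf, counts_exon = counts_exon,
              counts_intron = counts_intron, gtf = gtf)
    missing <- names(need)[!vapply(need, function(p)
      !is.null(p) && file.exists(p), logical(1L))]
    if (length(missing))
      stop("missing input path(s): ", paste(missing, collapse = ", "))
    if (!is.null(covariates) && !file.exists(covariates))
      stop("missing input path(s): covariates")
  }
  if (!is.null(sites_bed) && !file.exists(sites_bed))
    stop("missing input path(s): sites_bed")
  stopifnot(window > 0, stringency > 0, stringency <= 1, fdr > 0, fdr < 1,
            r2_min > 0, r2_min <= 1, bin > 0, step > 0)
  structure(list(out_dir = out_dir, simulate = simulate, sim = sim,
                 vcf = vcf, counts_exon = counts_exon,
                 counts_intron = counts_intron, covariates = covariates,
                 gtf = gtf, sites_bed = sites_bed, window = window,
                 stringency = stringency, fdr = fdr, r2_min = r2_min,
                 bin = bin, step = step, seed = as.integer(seed)),
            class = "stqtl_runconfig")
}

#' Run the full QTL workflow
#'
#' Executes: (optional) simulate -> stability inference -> association on
#' both traits -> cross-classification -> LD filtering -> genic-region
#' enrichment -> binding-site overlap (when sites are supplied) ->
#' sex-specific stQTLs.  Every stage writes its table into the run
#' directory; a machine-readable `summary.json` records stage counts and a
#' provenance block (config hash, seed, package version).  A stage failure
#' aborts with the stage name; earlier outputs are kept.
#'
#' @param config an [run_config()] object.
#' @param quiet suppress progress messages.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "stqtl_runconfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[stabilityqtl] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  summary <- list()

  if (config$simulate) {
    say("simulate")
    ds <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- config$seed
      cfg <- do.call(sim_config, cfg[setdiff(names(cfg),
                                             c("gene_slot", "flank"))])
      simulate_dataset(cfg)
    })
    geno <- ds$genotypes; anno <- ds$annotation
    counts <- ds$counts; truth <- ds$truth
    stage("write-inputs", {
      write_vcf(geno, file.path(config$out_dir, "genotypes.vcf"))
      write_annotation(anno, file.path(config$out_dir, "annotation.gtf"),
                       file.path(config$out_dir, "segments.bed"))
      write_matrix_tsv(counts$exon, file.path(config$out_dir, "exon_counts.tsv"))
      write_matrix_tsv(counts$intron,
                       file.path(config$out_dir, "intron_counts.tsv"))
      data.table::fwrite(counts$covariates,
                         file.path(config$out_dir, "covariates.tsv"), sep = "\t")
      data.table::fwrite(truth, file.path(config$out_dir, "truth.tsv"),
                         sep = "\t")
    })
    covars <- counts$covariates
  } else {
    say("load inputs")
    covars_path <- config$covariates
    geno <- stage("load-genotypes", {
      sm <- if (!is.null(covars_path))
        data.table::fread(covars_path, sep = "\t") else NULL
      read_vcf_dosage(config$vcf, samples = sm)
    })
    anno <- stage("load-annotation", read_annotation_gtf(config$gtf))
    counts <- stage("load-counts", {
      ex <- read_matrix_tsv(config$counts_exon)
      it <- read_matrix_tsv(config$counts_intron)
      el <- setNames(anno$genes$exonic_length, anno$genes$gene_id)
      il <- setNames(anno$genes$intronic_length, anno$genes$gene_id)
      list(exon = ex, intron = it, lib_exon = colSums(ex),
           lib_intron = colSums(it),
           exonic_length = el[rownames(ex)],
           intronic_length = il[rownames(ex)],
           covariates = geno$samples)
    })
    covars <- geno$samples
    truth <- NULL
  }

  say("variant QC")
  geno_qc <- stage("variant-qc", variant_qc(geno))
  summary$n_variants_qc <- ncol(geno_qc$dosage)

  say("stability")
  stab_all <- stage("stability", infer_stability(counts))
  sf <- stage("stringency", stringency_filter(counts, config$stringency))
  keep <- intersect(rownames(stab_all), names(sf$pass)[sf$pass])
  stab <- stab_all[keep, , drop = FALSE]
  stab_out <- cbind(data.table::data.table(
    gene_id = keep, max_stringency = sf$max_stringency[keep]),
    data.table::as.data.table(unclass(stab)))
  data.table::fwrite(stab_out, file.path(config$out_dir, "stability.tsv"),
                     sep = "\t")
  summary$n_genes_stability <- nrow(stab)

  say("expression")
  tpm <- stage("tpm", compute_tpm(counts$exon, counts$exonic_length))
  expr <- transform_expression(tpm)

  say("cis pairs")
  pairs <- stage("cis-pairs", cis_pairs(anno, geno_qc, config$window))
  pairs <- pairs[gene_id %in% rownames(stab)]
  summary$n_pairs <- nrow(pairs)

  say("association scans")
  cov_df <- .pipeline_covariates(covars, geno_qc)
  etab <- stage("assoc-expression",
                associate_linear(expr, geno_qc, cov_df, pairs, "expression"))
  stab_tab <- stage("assoc-stability",
                    associate_linear(stab, geno_qc, cov_df, pairs, "stability"))
  data.table::fwrite(etab[order(p)], file.path(config$out_dir, "eqtl.tsv"),
                     sep = "\t")
  data.table::fwrite(stab_tab[order(p)],
                     file.path(config$out_dir, "stqtl.tsv"), sep = "\t")
  summary$n_eqtl <- sum(etab$q < config$fdr)
  summary$n_stqtl <- sum(stab_tab$q < config$fdr)

  say("cross-classification")
  cross <- stage("compare", cross_classify(etab, stab_tab, config$fdr))
  data.table::fwrite(cross$pairs, file.path(config$out_dir, "cross.tsv"),
                     sep = "\t")
  summary$categories <- as.list(cross$counts)
  summary$concordance <- cross$concordance

  say("LD filter")
  qtls <- stab_tab[q < config$fdr]
  if (nrow(qtls) > 0L) {
    lds <- stage("ld-filter",
                 ld_blocks_and_filter(geno_qc, qtls, config$r2_min))
    data.table::fwrite(lds$representatives,
                       file.path(config$out_dir, "stqtl_ld_representatives.tsv"),
                       sep = "\t")
    summary$n_ld_blocks <- length(unique(lds$blocks$block))
    summary$n_stqtl_representatives <- nrow(lds$representatives)
  }

  say("region enrichment")
  regs <- stage("regions", assign_genic_regions(pairs, anno, config$window))
  pairs[, region := regs]
  enr_st <- stage("enrich-st", region_enrichment(region_counts(
    regs, regs[stab_tab$q < config$fdr])))
  enr_e <- stage("enrich-e", region_enrichment(region_counts(
    regs, regs[etab$q < config$fdr])))
  data.table::fwrite(enr_st, file.path(config$out_dir,
                                       "region_enrichment_stqtl.tsv"), sep = "\t")
  data.table::fwrite(enr_e, file.path(config$out_dir,
                                      "region_enrichment_eqtl.tsv"), sep = "\t")
  summary$region_er_stqtl <- setNames(as.list(enr_st$ER), enr_st$region)
  summary$region_er_eqtl <- setNames(as.list(enr_e$ER), enr_e$region)

  if (!is.null(config$sites_bed) || config$simulate) {
    say("binding sites")
    sites <- if (!is.null(config$sites_bed)) read_sites_bed(config$sites_bed)
    else stage("sim-sites",
               simulate_binding_sites(anno, truth, geno, .cfg_from_run(config)))
    write_sites_bed(sites, file.path(config$out_dir, "sites.bed"))
    bse <- stage("rbp-overlap", binding_site_enrichment(
      pairs[stab_tab$q < config$fdr], pairs, sites))
    data.table::fwrite(bse$per_factor,
                       file.path(config$out_dir, "rbp_enrichment.tsv"),
                       sep = "\t")
    summary$rbp_overlap <- bse$overall
  }

  say("sex-specific stQTLs")
  if (!is.null(covars$sex) && !anyNA(covars$sex) &&
      length(unique(covars$sex)) == 2L) {
    cov_nosex <- cov_df[, setdiff(colnames(cov_df), "sex"), drop = FALSE]
    sx <- stage("sex-qtl", tryCatch(
      sex_specific_stqtls(stab, geno_qc, cov_nosex, covars$sex, expr, pairs,
                          fdr = config$fdr),
      error = function(e) { warning(conditionMessage(e)); NULL }))
    if (!is.null(sx)) {
      data.table::fwrite(sx, file.path(config$out_dir, "sex_stqtl.tsv"),
                         sep = "\t")
      summary$n_sex_calls <- nrow(sx)
    }
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "sim")], cfg_path,
                       auto_unbox = TRUE, null = "null", force = TRUE)
  summary$provenance <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("stabilityqtl")))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_from_run <- function(config) {
  cfg <- config$sim
  cfg$seed <- config$seed
  do.call(sim_config, cfg[setdiff(names(cfg), c("gene_slot", "flank"))])
}

# sex/age (+ genotype PCs when enough variants) as the covariate frame
.pipeline_covariates <- function(covars, geno_qc, n_pcs = 3L) {
  cv <- data.frame(row.names = covars$sample_id)
  if (!is.null(covars$sex) && !anyNA(covars$sex))
    cv$sex <- as.numeric(covars$sex == "male")
  if (!is.null(covars$age) && !anyNA(covars$age)) cv$age <- covars$age
  if (ncol(geno_qc$dosage) >= 50L) {
    pcs <- genotype_pcs(geno_qc, n_pcs = n_pcs)
    cv <- cbind(cv, as.data.frame(pcs))
  }
  if (ncol(cv) == 0L) NULL else cv
}
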