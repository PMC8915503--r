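#' Simulate exon and intron read counts from the kinetic model
#'
#' For gene g and sample s the log2 transcription rate is
#' `log2 alpha_gs = a0_g + sum(transcription effects * dosage) + noise`
#' and the log2 decay rate is
#' `log2 beta_gs = b0_g + sum(decay effects * dosage * sex indicator) + noise`,
#' with independent `N(0, rate_noise_sd^2)` noise on each rate.  At steady
#' state pre-mRNA abundance is proportional to alpha and mature mRNA to
#' alpha/beta, so the expected counts are
#' `mu_intron = L_s * kappa * alpha_gs * intronic_length_g * C` and
#' `mu_exon   = L_s * (alpha_gs / beta_gs) * exonic_length_g * C`,
#' where `L_s` is the library size and `C` a single global normalizer
#' chosen so the mean per-sample expected total equals the library size.
#' Counts are negative binomial with dispersion `cfg$dispersion`
#' (variance `mu + phi mu^2`), or Poisson when the dispersion is 0.
#'
#' @param genotypes [simulate_genotypes()] output.
#' @param annotation [simulate_annotation()] output.
#' @param truth [simulate_truth()] output (may have zero rows).
#' @param cfg an [sim_config()] object.
#' @return an object of class `stqtl_counts`: list with integer matrices
#'   `exon` and `intron` (genes x samples), per-sample `lib_exon` /
#'   `lib_intron` (column sums), vectors `exonic_length` /
#'   `intronic_length`, a `covariates` data.table (sample_id, sex, age),
#'   and attributes `log2_alpha`, `log2_beta`, `mu_exon`, `mu_intron`
#'   (realized rates and expected means, genes x samples) for
#'   parameter-recovery tests.
#' @examples
#' cfg <- sim_config(n_samples = 8, n_variants = 50, n_genes = 4, seed = 3)
#' g <- simulate_genotypes(cfg)
#' a <- simulate_annotation(cfg)
#' tr <- simulate_truth(g, a, cfg)
#' cnt <- simulate_counts(g, a, tr, cfg)
#' dim(cnt$exon)
#' @export
simulate_counts <- function(genotypes, annotation, truth, cfg) {
  stopifnot(inherits(cfg, "stqtl_config"),
            inherits(genotypes, "stqtl_genotypes"),
            inherits(annotation, "stqtl_annotation"))
  if (nrow(truth) > 0L) {
    bad_v <- setdiff(truth$variant_id, genotypes$variants$id)
    bad_g <- setdiff(truth$gene_id, annotation$genes$gene_id)
    if (length(bad_v) || length(bad_g))
      stop("truth table references unknown ids: ",
           paste(c(bad_v, bad_g), collapse = ", "))
  }
  set.seed(.sub_seed(cfg, 5L))
  G <- nrow(annotation$genes); N <- nrow(genotypes$dosage)
  gid <- annotation$genes$gene_id
  sid <- rownames(genotypes$dosage)
  male <- as.numeric(genotypes$samples$sex == "male")
  female <- 1 - male

  a0 <- rnorm(G, cfg$alpha_log2_mean, cfg$alpha_log2_sd)
  b0 <- rnorm(G, cfg$beta_log2_mean, cfg$beta_log2_sd)
  la <- matrix(a0, nrow = G, ncol = N)              # log2 alpha
  lb <- matrix(b0, nrow = G, ncol = N)              # log2 beta
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth))) {
      gi <- match(truth$gene_id[i], gid)
      dos <- genotypes$dosage[, truth$variant_id[i]]
      w <- switch(truth$sex[i], none = 1, male = male, female = female)
      add <- truth$effect[i] * dos * w
      if (truth$target[i] == "transcription") la[gi, ] <- la[gi, ] + add
      else lb[gi, ] <- lb[gi, ] + add
    }
  }
  if (cfg$rate_noise_sd > 0) {
    la <- la + matrix(rnorm(G * N, 0, cfg$rate_noise_sd), G, N)
    lb <- lb + matrix(rnorm(G * N, 0, cfg$rate_noise_sd), G, N)
  }
  alpha <- 2^la; beta <- 2^lb

  iL <- annotation$genes$intronic_length
  eL <- annotation$genes$exonic_length
  lib <- if (cfg$library_size_cv > 0) {
    sdl <- sqrt(log(1 + cfg$library_size_cv^2))
    rlnorm(N, log(cfg$library_size_mean) - sdl^2 / 2, sdl)
  } else rep(cfg$library_size_mean, N)

  intens_i <- cfg$intron_capture * alpha * iL       # genes x samples
  intens_e <- (alpha / beta) * eL
  C <- 1 / mean(colSums(intens_i + intens_e))
  mu_i <- sweep(intens_i * C, 2, lib, `*`)
  mu_e <- sweep(intens_e * C, 2, lib, `*`)

  draw <- function(mu) {
    n <- length(mu)
    cnt <- if (cfg$dispersion == 0) rpois(n, mu)
           else rnbinom(n, size = 1 / cfg$dispersion, mu = mu)
    matrix(as.integer(cnt), nrow = G,
           dimnames = list(gid, sid))
  }
  exon <- draw(mu_e)
  intron <- draw(mu_i)

  out <- list(
    exon = exon, intron = intron,
    lib_exon = colSums(exon), lib_intron = colSums(intron),
    exonic_length = setNames(eL, gid),
    intronic_length = setNames(iL, gid),
    covariates = data.table::copy(genotypes$samples))
  dimnames(mu_e) <- dimnames(mu_i) <- dimnames(la) <- dimnames(lb) <-
    list(gid, sid)
  attr(out, "log2_alpha") <- la
  attr(out, "log2_beta") <- lb
  attr(out, "mu_exon") <- mu_e
  attr(out, "mu_intron") <- mu_i
  class(out) <- "stqtl_counts"
  out
}

#' Expected counts under the kinetic model (closed form)
#'
#' Returns the expected exon and intron count matrices for given realized
#' log2 rates, lengths and library sizes — the closed-form means the
#' sampler draws around.  Exposed so tests and users can reason about the
#' model without re-deriving the normalizer.
#'
#' @param log2_alpha,log2_beta genes x samples matrices of realized rates.
#' @param exonic_length,intronic_length per-gene lengths (bp).
#' @param lib per-sample library sizes.
#' @param intron_capture fraction kappa of pre-mRNA read capture.
#' @return list(mu_exon, mu_intron).
#' @export
expected_counts <- function(log2_alpha, log2_beta, exonic_length,
                            intronic_length, lib, intron_capture = 0.1) {
  alpha <- 2^log2_alpha; beta <- 2^log2_beta
  intens_i <- intron_capture * alpha * intronic_length
  intens_e <- (alpha / beta) * exonic_length
  C <- 1 / mean(colSums(intens_i + intens_e))
  list(mu_exon = sweep(intens_e * C, 2, lib, `*`),
       mu_intron = sweep(intens_i * C, 2, lib, `*`))
}

#' Build one full synthetic dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_annotation()], [simulate_truth()] and [simulate_counts()].
#'
#' @param cfg an [sim_config()] object.
#' @param ... passed to [simulate_truth()].
#' @return list(genotypes, annotation, truth, counts, config).
#' @export
simulate_dataset <- function(cfg, ...) {
  g <- simulate_genotypes(cfg)
  a <- simulate_annotation(cfg)
  tr <- simulate_truth(g, a, cfg, ...)
  cnt <- simulate_counts(g, a, tr, cfg)
  list(genotypes = g, annotation = a, truth = tr, counts = cnt, config = cfg)
}
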