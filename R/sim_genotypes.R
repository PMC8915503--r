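#' Simulate LD-structured genotypes
#'
#' Draws each sample as two haplotype mosaics copied from a founder pool:
#' the chromosome is cut into fixed-length LD segments
#' (`cfg$ld_segment_bp`), and each haplotype picks one founder uniformly at
#' random per segment.  Random, independent founder picks for the two
#' haplotypes give Hardy-Weinberg equilibrium; whole-segment copying gives
#' strong within-segment LD and near-independence across segments.
#'
#' Variants whose realized minor allele frequency falls below
#' `cfg$maf_min` are flagged (`pass_qc = FALSE`) but kept in the returned
#' object; [variant_qc()] removes them.
#'
#' @param cfg an [sim_config()] object.
#' @param founders optional founder haplotype matrix
#'   (`n_haplotypes x n_variants`, values 0/1).  By default founder alleles
#'   are Bernoulli draws with per-variant frequencies uniform on
#'   (0.05, 0.95).
#' @return an object of class `stqtl_genotypes`: a list with
#'   * `dosage`: `n_samples x n_variants` integer matrix (0/1/2),
#'     dimnames sample x variant ids;
#'   * `variants`: data.table (id, chrom, pos, ref, alt, maf, pass_qc,
#'     ld_segment);
#'   * `samples`: data.table (sample_id, sex, age).
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples = 20, n_variants = 50,
#'                                    n_genes = 2, seed = 7))
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(cfg, founders = NULL) {
  stopifnot(inherits(cfg, "stqtl_config"))
  if (cfg$n_haplotypes < 2) stop("n_haplotypes must be >= 2")
  set.seed(.sub_seed(cfg, 1L))
  V <- cfg$n_variants; N <- cfg$n_samples; H <- cfg$n_haplotypes

  pos <- sort(sample.int(cfg$genome_length, V, replace = FALSE))
  seg <- as.integer(pos %/% cfg$ld_segment_bp)
  if (is.null(founders)) {
    f <- runif(V, 0.05, 0.95)
    founders <- matrix(rbinom(H * V, 1L, rep(f, each = H)), nrow = H)
  } else {
    founders <- as.matrix(founders)
    if (ncol(founders) != V) stop("founders must have n_variants columns")
    H <- nrow(founders)
    if (H < 2) stop("founder pool must hold >= 2 haplotypes")
  }

  segs <- unique(seg)
  seg_of <- match(seg, segs)              # variant -> segment index
  n_seg <- length(segs)
  # founder choice per (haplotype copy, sample, segment)
  pick1 <- matrix(sample.int(H, N * n_seg, replace = TRUE), nrow = N)
  pick2 <- matrix(sample.int(H, N * n_seg, replace = TRUE), nrow = N)
  hap1 <- founders[cbind(rep(pick1[, seg_of], 1), rep(seq_len(V), each = N))]
  hap2 <- founders[cbind(rep(pick2[, seg_of], 1), rep(seq_len(V), each = N))]
  dosage <- matrix(as.integer(hap1 + hap2), nrow = N)

  af <- colMeans(dosage) / 2
  maf <- pmin(af, 1 - af)
  ids <- sprintf("var%05d", seq_len(V))
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, V, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  rownames(dosage) <- sprintf("S%04d", seq_len(N))
  colnames(dosage) <- ids

  sex <- ifelse(runif(N) < cfg$prop_male, "male", "female")
  age <- round(pmin(pmax(rnorm(N, 52, 12), 21), 70))

  out <- list(
    dosage = dosage,
    variants = data.table::data.table(
      id = ids, chrom = "chr1", pos = pos, ref = unname(ref),
      alt = unname(alt), maf = maf, pass_qc = maf >= cfg$maf_min,
      ld_segment = seg_of),
    samples = data.table::data.table(
      sample_id = rownames(dosage), sex = sex, age = as.numeric(age))
  )
  class(out) <- "stqtl_genotypes"
  out
}

#' @export
print.stqtl_genotypes <- function(x, ...) {
  cat("stqtl_genotypes:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants (", sum(x$variants$pass_qc), "pass MAF flag )\n")
  invisible(x)
}
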