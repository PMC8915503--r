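# Independent oracles and tiny fixture builders used across test files.

# two-sided Fisher p by exhaustive enumeration over fixed margins
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up straight from the definition (quadratic scan, no cummin)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(p[o][i:n] * n / (i:n)))
  }, numeric(1))
  q_sorted[order(o)]
}

# greedy LD blocks re-implemented naively (no windows; small instances)
greedy_blocks_oracle <- function(dosage_by_variant, r2_min = 0.9) {
  V <- ncol(dosage_by_variant)
  block <- integer(V); cur <- 1L; members <- 1L; block[1] <- 1L
  for (v in seq_len(V)[-1]) {
    ok <- all(vapply(members, function(u) {
      s1 <- sd(dosage_by_variant[, u]); s2 <- sd(dosage_by_variant[, v])
      r2 <- if (s1 == 0 || s2 == 0) 0
            else cor(dosage_by_variant[, u], dosage_by_variant[, v])^2
      r2 > r2_min
    }, logical(1)))
    if (ok) members <- c(members, v) else { cur <- cur + 1L; members <- v }
    block[v] <- cur
  }
  block
}

# minimal counts object (plain list) accepted by the stability functions
toy_counts <- function(exon, intron) {
  storage.mode(exon) <- "integer"; storage.mode(intron) <- "integer"
  if (is.null(rownames(exon)))
    rownames(exon) <- rownames(intron) <- paste0("g", seq_len(nrow(exon)))
  if (is.null(colnames(exon)))
    colnames(exon) <- colnames(intron) <- paste0("s", seq_len(ncol(exon)))
  list(exon = exon, intron = intron)
}

# genotypes object from an explicit dosage matrix (samples x variants)
toy_genotypes <- function(dosage, pos = NULL, chrom = "chr1",
                          sex = NULL, age = NULL) {
  n <- nrow(dosage); V <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("v%03d", 1:V)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("s%03d", 1:n)
  if (is.null(pos)) pos <- seq_len(V) * 1000L
  af <- colMeans(dosage, na.rm = TRUE) / 2
  g <- list(
    dosage = dosage,
    variants = data.table::data.table(
      id = colnames(dosage), chrom = chrom, pos = as.integer(pos),
      ref = "A", alt = "G", maf = pmin(af, 1 - af), pass_qc = TRUE,
      ld_segment = NA_integer_),
    samples = data.table::data.table(
      sample_id = rownames(dosage),
      sex = if (is.null(sex)) rep(NA_character_, n) else sex,
      age = if (is.null(age)) rep(NA_real_, n) else age))
  class(g) <- "stqtl_genotypes"
  g
}

# one plus-strand gene annotation with explicit segments
toy_annotation <- function(gene_id = "gA", strand = "+",
                           body_start = 200000L, lens = c(100L, 300L, 200L,
                                                          300L, 150L)) {
  labels <- c("5'UTR", "CDS", "intron", "CDS", "3'UTR")
  tx_start <- body_start + cumsum(c(0L, head(lens, -1L)))
  tx_end <- tx_start + lens - 1L
  if (strand == "+") {
    start <- tx_start; end <- tx_end
    tss <- body_start; tts <- body_start + sum(lens) - 1L
  } else {
    end <- body_start + sum(lens) - 1L - cumsum(c(0L, head(lens, -1L)))
    start <- end - lens + 1L
    tss <- body_start + sum(lens) - 1L; tts <- body_start
  }
  a <- list(
    genes = data.table::data.table(
      gene_id = gene_id, chrom = "chr1", strand = strand, tss = tss,
      tts = tts, start = body_start, end = body_start + sum(lens) - 1L,
      exonic_length = sum(lens[labels != "intron"]),
      intronic_length = sum(lens[labels == "intron"])),
    segments = data.table::data.table(
      gene_id = gene_id, chrom = "chr1", start = start, end = end,
      label = labels))
  data.table::setkey(a$segments, gene_id, start)
  class(a) <- "stqtl_annotation"
  a
}

# small simulated dataset shared by several test files
small_sim <- function(seed = 42, n_samples = 120, n_variants = 600,
                      n_genes = 30, ...) {
  simulate_dataset(sim_config(n_samples = n_samples, n_variants = n_variants,
                              n_genes = n_genes, seed = seed, ...))
}
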