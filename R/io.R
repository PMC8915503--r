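#' Write genotypes as minimal VCF 4.2
#'
#' GT-only records, one sample column per cohort sample; dosage 0/1/2 is
#' written as 0/0, 0/1, 1/1 (unphased).  Output is deterministic, so two
#' writes of the same object are byte-identical.
#'
#' @param genotypes `stqtl_genotypes`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  vr <- genotypes$variants
  dos <- genotypes$dosage
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(vr)), function(i) {
    calls <- ifelse(is.na(dos[, i]), "./.", gt[round(dos[, i]) + 1L])
    paste(c(vr$chrom[i], vr$pos[i], vr$id[i], vr$ref[i], vr$alt[i],
            ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, "")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=stabilityqtl",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read GT dosages from a VCF
#'
#' Parses biallelic GT records into an `stqtl_genotypes` object (alt-allele
#' dosage; missing calls become NA).  Uses VariantAnnotation when
#' available, with a plain-text fallback for minimal GT-only files.
#'
#' @param path VCF path.
#' @param samples optional data.table (sample_id, sex, age) of covariates;
#'   default sex/age columns are NA.
#' @return `stqtl_genotypes`.
#' @export
read_vcf_dosage <- function(path, samples = NULL) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    v <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(v)$GT
    dose <- function(x) {
      a <- strsplit(x, "[/|]")
      vapply(a, function(z) {
        if (any(z == ".")) NA_real_ else sum(z == "1")
      }, numeric(1L))
    }
    dos <- apply(gt, 2L, dose)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L)
    dos <- t(matrix(dos, nrow = nrow(gt),
                    dimnames = list(rownames(gt), colnames(gt))))
    rr <- SummarizedExperiment::rowRanges(v)
    vr <- data.table::data.table(
      id = rownames(gt),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) as.character(a)[1L], ""),
      maf = NA_real_, pass_qc = TRUE, ld_segment = NA_integer_)
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#CHROM")]
    cols <- strsplit(hdr, "\t")[[1L]]
    recs <- data.table::fread(text = lines[!startsWith(lines, "#")],
                              header = FALSE)
    data.table::setnames(recs, cols)
    sample_ids <- cols[-(1:9)]
    gtmat <- as.matrix(recs[, ..sample_ids])
    dos <- t(apply(gtmat, c(1, 2), function(x) {
      z <- strsplit(sub(":.*", "", x), "[/|]")[[1L]]
      if (any(z == ".")) NA_real_ else sum(z == "1")
    }))
    rownames(dos) <- sample_ids
    colnames(dos) <- recs$ID
    vr <- data.table::data.table(
      id = recs$ID, chrom = as.character(recs$`#CHROM`), pos = recs$POS,
      ref = recs$REF, alt = recs$ALT, maf = NA_real_, pass_qc = TRUE,
      ld_segment = NA_integer_)
  }
  af <- colMeans(dos, na.rm = TRUE) / 2
  vr$maf <- pmin(af, 1 - af)
  sm <- if (!is.null(samples)) data.table::as.data.table(samples)
        else data.table::data.table(sample_id = rownames(dos),
                                    sex = NA_character_, age = NA_real_)
  out <- list(dosage = dos, variants = vr, samples = sm)
  class(out) <- "stqtl_genotypes"
  out
}

#' Write the gene annotation as GTF plus a segment BED
#'
#' The GTF (1-based inclusive) carries one `gene` feature per gene and one
#' feature per segment (types `five_prime_utr`, `CDS`, `intron`,
#' `three_prime_utr`); the companion BED (0-based half-open) lists the same
#' segments with `gene_id|label` names.
#'
#' @param annotation `stqtl_annotation`.
#' @param gtf_path,bed_path output paths (`NULL` skips that file).
#' @return invisibly, the paths written.
#' @export
write_annotation <- function(annotation, gtf_path = NULL, bed_path = NULL) {
  lab2type <- c("5'UTR" = "five_prime_utr", "CDS" = "CDS",
                "intron" = "intron", "3'UTR" = "three_prime_utr")
  if (!is.null(gtf_path)) {
    g <- annotation$genes
    gene_rows <- sprintf(
      "%s\tstabilityqtl\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      g$chrom, g$start, g$end, g$strand, g$gene_id)
    s <- merge(annotation$segments,
               g[, .(gene_id, strand)], by = "gene_id", sort = FALSE)
    seg_rows <- sprintf(
      "%s\tstabilityqtl\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      s$chrom, lab2type[s$label], s$start, s$end, s$strand, s$gene_id)
    writeLines(c(gene_rows, seg_rows), gtf_path)
  }
  if (!is.null(bed_path)) {
    s <- annotation$segments
    writeLines(sprintf("%s\t%d\t%d\t%s|%s", s$chrom, s$start - 1L, s$end,
                       s$gene_id, s$label), bed_path)
  }
  invisible(c(gtf = gtf_path, bed = bed_path))
}

#' Read a stabilityqtl GTF back into an annotation object
#'
#' Understands the feature types written by [write_annotation()]; uses
#' rtracklayer when available, else a plain-text parse.
#'
#' @param path GTF path.
#' @return `stqtl_annotation`.
#' @export
read_annotation_gtf <- function(path) {
  type2lab <- c(five_prime_utr = "5'UTR", CDS = "CDS", intron = "intron",
                three_prime_utr = "3'UTR")
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      type = as.character(gr$type), gene_id = gr$gene_id)
  } else {
    raw <- data.table::fread(path, header = FALSE, sep = "\t")
    dt <- data.table::data.table(
      chrom = raw$V1, start = raw$V4, end = raw$V5, strand = raw$V7,
      type = raw$V3, gene_id = sub('.*gene_id "([^"]+)".*', "\\1", raw$V9))
  }
  segs <- dt[type %in% names(type2lab)]
  segs <- data.table::data.table(
    gene_id = segs$gene_id, chrom = segs$chrom, start = segs$start,
    end = segs$end, label = type2lab[segs$type])
  gn <- dt[type == "gene"]
  genes <- data.table::data.table(
    gene_id = gn$gene_id, chrom = gn$chrom, strand = gn$strand,
    tss = ifelse(gn$strand == "+", gn$start, gn$end),
    tts = ifelse(gn$strand == "+", gn$end, gn$start),
    start = gn$start, end = gn$end)
  el <- segs[label != "intron", .(exonic_length = sum(end - start + 1L)),
             by = gene_id]
  il <- segs[label == "intron", .(intronic_length = sum(end - start + 1L)),
             by = gene_id]
  genes <- merge(merge(genes, el, by = "gene_id", all.x = TRUE),
                 il, by = "gene_id", all.x = TRUE)
  genes[is.na(exonic_length), exonic_length := 0L]
  genes[is.na(intronic_length), intronic_length := 0L]
  out <- list(genes = genes, segments = segs)
  data.table::setkey(out$segments, gene_id, start)
  class(out) <- "stqtl_annotation"
  out
}

#' Write / read count and covariate tables (TSV)
#'
#' Matrices go out with a `gene_id` key column and a header row.
#'
#' @param mat genes x samples matrix.
#' @param path file path.
#' @return the path (write) or the matrix / data.table (read).
#' @export
write_matrix_tsv <- function(mat, path) {
  dt <- data.table::data.table(gene_id = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1L]]
  m
}

#' Write binding sites as BED
#'
#' 0-based half-open intervals, name column `factor_name`, score 0,
#' strand ".".
#'
#' @param sites `stqtl_sites` data.table.
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", sites$chrom, sites$start,
                     sites$end, sites$factor_name), path)
  invisible(path)
}

#' @rdname write_sites_bed
#' @param type factor type recorded on read (default "RBP").
#' @export
read_sites_bed <- function(path, type = "RBP") {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    sites <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      factor_name = if (!is.null(gr$name)) gr$name else "site",
      type = type)
  } else {
    raw <- data.table::fread(path, header = FALSE)
    sites <- data.table::data.table(
      chrom = raw$V1, start = raw$V2, end = raw$V3,
      factor_name = if (ncol(raw) >= 4L) raw$V4 else "site", type = type)
  }
  class(sites) <- c("stqtl_sites", class(sites))
  sites
}
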