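# stabilityqtl

Simultaneous mapping of **expression QTLs (eQTLs)** and **mRNA-stability
QTLs (stQTLs)** from bulk RNA-seq exon/intron count matrices and
genotypes.

An eQTL can act by changing how fast a gene is transcribed or how fast
its mRNA decays. Intronic RNA-seq reads track nascent transcription while
exonic reads track mature mRNA, so the contrast
`Δexon − Δintron` (exon-intron split analysis) estimates each sample's
*relative* mRNA stability per gene. Scanning both traits against genotype
dosage in the cis window (TSS −100 kb to TTS +100 kb) separates the two
mechanisms:

- **stability**: `δ_gs = (x_gs − x̄_g) − (y_gs − ȳ_g)` with `x`, `y` the
  log2 exonic/intronic CPM, a per-sample linear bias correction on mean
  expression, and per-gene re-centering (values are relative to the
  cohort mean, in log2 units);
- **expression**: `log10(100·TPM + 1)`;
- **association**: OLS of trait on (intercept, dosage, covariates); the
  dosage coefficient's two-sided t-test feeds one Benjamini-Hochberg
  adjustment per trait; q < 0.05 defines a QTL;
- downstream: eQTL/stQTL cross-classification with direction concordance,
  greedy r² > 0.9 LD blocks with lowest-q representatives, genic-region
  and RBP/miRNA binding-site enrichment (enrichment ratio
  `ER_k = (Q_k/Q)/(N_k/N)` with Fisher exact tests), and sex-specific
  stQTL calling (sex-stratified and genotype×sex interaction models).

A negative-binomial transcription/decay simulator (LD-structured founder
haplotypes, planted allelic effects on log2 transcription or decay rates,
truth tables) generates every fixture; no protected human data are used.

## Worked example

```r
library(stabilityqtl)

cfg <- sim_config(n_samples = 200, n_variants = 2000, n_genes = 100, seed = 42)
ds  <- simulate_dataset(cfg)                      # genotypes, gene models, counts, truth
geno <- variant_qc(ds$genotypes)                  # MAF >= 1%, HWE p >= 1e-6

stab <- infer_stability(ds$counts)                # relative stability (log2)
expr <- transform_expression(
  compute_tpm(ds$counts$exon, ds$counts$exonic_length))

pairs <- cis_pairs(ds$annotation, geno)           # TSS -100 kb .. TTS +100 kb
pairs <- pairs[gene_id %in% rownames(stab)]
covs  <- data.frame(sex = as.numeric(geno$samples$sex == "male"),
                    age = geno$samples$age)
eqtl  <- associate_linear(expr, geno, covs, pairs, "expression")
stqtl <- associate_linear(stab, geno, covs, pairs, "stability")

cross <- cross_classify(eqtl, stqtl, fdr = 0.05)
print(cross)
```

```
QTL cross-classification (FDR < 0.05 )
      both  eqtl_only stqtl_only    neither
        16         28          1       1782
concordance among shared QTLs: 100 % (up 62.5 %, down 37.5 %)
```

Of 1,827 tested cis pairs, 16 are both eQTL and stQTL, 28 are eQTL only
(the planted transcription-rate effects, which cancel in the stability
contrast), and every shared QTL has the same effect direction on
expression and stability — stability-raising alleles raise expression.
Checking against the generator's truth table:

```r
truth_pairs <- ds$truth[target == "decay", paste(variant_id, gene_id)]
called <- stqtl[q < 0.05, paste(variant_id, gene_id)]
cat("planted decay QTLs recovered:", sum(truth_pairs %in% called),
    "/", length(truth_pairs), "\n")
#> planted decay QTLs recovered: 13 / 15
```

The whole workflow (simulate → stability → both scans → compare →
LD-filter → enrich → binding sites → sex-specific) is also available as a
pipeline and CLI:

```r
run_pipeline(run_config(out_dir = "demo_run",
                        sim = sim_config(n_samples = 300, n_variants = 2000,
                                         n_genes = 200, seed = 1)))
```

```sh
Rscript inst/bin/stabilityqtl run \
  --config inst/extdata/demo_config.json --out demo_run   # ~10 s, 1 CPU
```

`demo_run/` then holds `genotypes.vcf`, `annotation.gtf`, count and
covariate TSVs, `stability.tsv` (with per-gene `max_stringency`),
`eqtl.tsv` / `stqtl.tsv`, cross-classification, LD representatives,
region and binding-site enrichment tables, sex-specific calls, and a
`summary.json` with stage counts and a provenance block (seed, config
hash, package version).

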