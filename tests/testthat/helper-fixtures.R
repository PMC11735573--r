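## Shared fixtures for the test suite. Everything is generated in code.

## Genotype-likelihood matrix with indicator rows for known genotypes.
indicator_gl <- function(x) {
  dos <- rep(0:4, times = x)
  G <- matrix(0, nrow = length(dos), ncol = 5)
  G[cbind(seq_along(dos), dos + 1L)] <- 1
  G
}

## Random genotype-likelihood matrix (rows positive, max-normalized).
random_gl <- function(n) {
  G <- matrix(stats::rexp(n * 5), nrow = n)
  G / apply(G, 1, max)
}

## Minimal tetraploid VCF with GT fields; returns the path.
write_gt_vcf <- function(path, gts, samples, chrom = "1", ids = NULL) {
  n_rec <- nrow(gts)
  if (is.null(ids)) ids <- paste0("snp", seq_len(n_rec))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(n_rec), function(i) {
    paste(c(chrom, i * 100, ids[i], "A", "T", ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

## Minimal tetraploid VCF with GL fields (log10 genotype likelihoods).
write_gl_vcf <- function(path, gl_strings, samples, ids = NULL) {
  n_rec <- nrow(gl_strings)
  if (is.null(ids)) ids <- paste0("snp", seq_len(n_rec))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(n_rec), function(i) {
    paste(c("1", i * 100, ids[i], "A", "T", ".", "PASS", ".", "GT:GL",
            paste0("./././.:", gl_strings[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

gl_string <- function(lik) {
  paste(formatC(log10(pmax(lik, 1e-10)), digits = 4, format = "f"),
        collapse = ",")
}
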