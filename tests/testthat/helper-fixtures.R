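# shared builders for the test suite; everything is generated in code

snp_meta <- function(m, chrom = "1", start = 100) {
  data.frame(id = sprintf("s%03d", seq_len(m)), chrom = rep(chrom, m),
             pos = start + 100 * (seq_len(m) - 1),
             ref = rep("A", m), alt = rep("G", m), stringsAsFactors = FALSE)
}

# phased panel from a haplotype matrix (rows = haplotypes, cols = SNPs)
phased_panel <- function(h) {
  haplotype_panel(h, snp_meta(ncol(h)), phased = TRUE)
}

# unphased panel from a dosage matrix
dosage_panel <- function(d) {
  haplotype_panel(d, snp_meta(ncol(d)), phased = FALSE)
}

# independent oracle for phased r2: squared Pearson correlation of the two
# 0/1 haplotype vectors over pairwise-complete rows
r2_cor_oracle <- function(h, i, j) {
  ok <- !is.na(h[, i]) & !is.na(h[, j])
  stats::cor(h[ok, i], h[ok, j])^2
}

# random polymorphic haplotype matrix with patches of induced LD
random_ld_haplotypes <- function(n_hap, m, copy_prob = 0.5, flip = 0.15) {
  repeat {
    h <- matrix(stats::rbinom(n_hap * m, 1, stats::runif(1, 0.3, 0.7)),
                ncol = m)
    if (m > 1) {
      for (j in 2:m) {
        if (stats::runif(1) < copy_prob) {
          h[, j] <- h[, j - 1]
          fl <- stats::runif(n_hap) < flip
          h[fl, j] <- 1 - h[fl, j]
        }
      }
    }
    f <- colMeans(h)
    if (all(f > 0 & f < 1)) return(h)
  }
}

# an ld_matrix built directly from a symmetric r2 matrix
toy_ld <- function(r2, maf = NULL, pos = NULL) {
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  as_ld_matrix(r2, paste0("s", seq_len(nrow(r2))), maf = maf, pos = pos)
}

# write VCF body lines by hand (fixture-building, independent of the
# package's writer) — cols: chrom, pos, id, ref, alt, genotypes
hand_vcf <- function(path, rows, samples = c("A", "B")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(rows, function(r) paste(c(r[1:5], ".", "PASS", ".", "GT",
                                     r[-(1:5)]), collapse = "\t"),
           character(1))
  ), path)
  path
}

region_df <- function(chrom, start, end, name = "r") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

ortholog_fixture_path <- function() {
  system.file("extdata", "ortholog_table.tsv", package = "tagsel")
}

# generic eQTL table fixture
eqtl_df <- function(variant_id, tissue, p_value, nes, gene_id = "GENE1") {
  data.frame(variant_id = variant_id, gene_id = gene_id, tissue = tissue,
             p_value = p_value, nes = nes, stringsAsFactors = FALSE)
}
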