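#' Construct a haplotype panel
#'
#' The central genotype container. For phased data \code{alleles} holds one
#' row per haplotype (2N rows for N individuals) with values 0/1/NA; for
#' unphased data one row per individual with alternate-allele dosages
#' 0/1/2/NA. Columns correspond to the SNPs in \code{snps}, which must be
#' position-sorted.
#'
#' @param alleles Integer/numeric matrix, rows = haplotypes (phased) or
#'   individuals (unphased), columns = SNPs. \code{NA} marks missing calls.
#' @param snps data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, one row per SNP, positions strictly increasing
#'   within a chromosome.
#' @param phased Logical flag.
#' @param n_dropped Count of records discarded when the panel was read from a
#'   VCF (multiallelic sites, indels).
#' @return An object of class \code{haplotype_panel}.
#' @export
haplotype_panel <- function(alleles, snps, phased, n_dropped = 0L) {
  alleles <- as.matrix(alleles)
  stopifnot(is.data.frame(snps),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(snps)),
            ncol(alleles) == nrow(snps),
            is.logical(phased), length(phased) == 1)
  if (nrow(snps) > 1) {
    for (ch in unique(snps$chrom)) {
      p <- snps$pos[snps$chrom == ch]
      if (any(diff(p) <= 0))
        stop("SNP positions must be strictly increasing on chromosome ", ch)
    }
  }
  alphabet <- if (phased) c(0, 1) else c(0, 1, 2)
  vals <- alleles[!is.na(alleles)]
  if (length(vals) && !all(vals %in% alphabet))
    stop("allele values outside the declared alphabet {",
         paste(alphabet, collapse = ","), "}")
  structure(list(alleles = alleles, snps = as.data.frame(snps),
                 phased = phased, n_dropped = as.integer(n_dropped)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", ncol(x$alleles), "SNPs x", nrow(x$alleles),
      if (x$phased) "phased haplotypes" else "unphased individuals", "\n")
  if (ncol(x$alleles) > 0)
    cat("  region:", x$snps$chrom[1], paste0(min(x$snps$pos), "-",
        max(x$snps$pos)), "\n")
  if (x$n_dropped > 0)
    cat("  non-biallelic-SNP records dropped on read:", x$n_dropped, "\n")
  invisible(x)
}

n_snps <- function(panel) ncol(panel$alleles)

#' Subset a panel to a set of SNP columns
#'
#' @param panel A \code{haplotype_panel}.
#' @param keep Integer or logical index over SNP columns (order preserved).
#' @return A \code{haplotype_panel}.
#' @export
subset_panel <- function(panel, keep) {
  haplotype_panel(panel$alleles[, keep, drop = FALSE],
                  panel$snps[keep, , drop = FALSE],
                  panel$phased, panel$n_dropped)
}

#' Read biallelic SNPs from a VCF region
#'
#' Extracts records whose position falls inside a 1-based inclusive region
#' and that are biallelic single-base SNPs (exactly one REF and one ALT
#' allele, both single bases). Multiallelic sites and indels are dropped and
#' counted, not split. Genotypes are parsed into a phased haplotype matrix
#' when every non-missing call uses the \code{|} separator, otherwise into
#' unphased dosages; missing calls become \code{NA} and are handled
#' pairwise-complete downstream.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param region A one-row data.frame with \code{chrom}, \code{start},
#'   \code{end} (and optionally \code{name}), as from [apply_flanks()].
#' @return A \code{haplotype_panel}; empty (0 SNPs) with a warning if the
#'   region's chromosome has no records.
#' @export
read_vcf_region <- function(path, region) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  stopifnot(is.data.frame(region), nrow(region) == 1,
            region$start >= 1, region$start <= region$end)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) NULL)
  empty <- function(n_dropped = 0L) haplotype_panel(
    matrix(integer(), nrow = 0, ncol = 0),
    data.frame(id = character(), chrom = character(), pos = numeric(),
               ref = character(), alt = character()),
    phased = TRUE, n_dropped = n_dropped)
  if (is.null(vcf) || nrow(vcf@fix) == 0) return(empty())

  fix <- as.data.frame(vcf@fix[, 1:5, drop = FALSE],
                       stringsAsFactors = FALSE)
  names(fix) <- c("CHROM", "POS", "ID", "REF", "ALT")
  fix$POS <- as.numeric(fix$POS)
  if (!as.character(region$chrom) %in% fix$CHROM) {
    warning("chromosome ", region$chrom, " absent from VCF ", path)
    return(empty())
  }
  in_reg <- fix$CHROM == as.character(region$chrom) &
    fix$POS >= region$start & fix$POS <= region$end
  if (!any(in_reg)) return(empty())

  snp_ok <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep <- in_reg & snp_ok
  n_dropped <- sum(in_reg & !snp_ok)
  if (!any(keep)) return(empty(n_dropped))

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ord <- order(fix$POS)
  fix <- fix[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]

  calls <- as.vector(gt)
  nonmiss <- !is.na(calls) & !calls %in% c(".", "./.", ".|.")
  phased <- length(calls) > 0 &&
    all(grepl("|", calls[nonmiss], fixed = TRUE) |
          !grepl("/", calls[nonmiss], fixed = TRUE))

  snps <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS, "_", fix$REF, "_", fix$ALT),
                fix$ID),
    chrom = fix$CHROM, pos = fix$POS, ref = fix$REF, alt = fix$ALT,
    stringsAsFactors = FALSE)

  parse_allele <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out[a == "."] <- NA_integer_
    out
  }
  m <- nrow(gt); nind <- ncol(gt)
  split_gt <- strsplit(as.vector(gt), "[/|]")
  a1 <- vapply(split_gt, function(x) if (length(x) >= 1) x[1] else ".", "")
  a2 <- vapply(split_gt, function(x) if (length(x) >= 2) x[2] else ".", "")
  a1 <- matrix(parse_allele(a1), nrow = m, ncol = nind)
  a2 <- matrix(parse_allele(a2), nrow = m, ncol = nind)

  if (phased) {
    # rows: haplotype 1 of each sample, then haplotype 2
    alleles <- rbind(t(a1), t(a2))
    hap_ord <- as.vector(rbind(seq_len(nind), nind + seq_len(nind)))
    alleles <- alleles[hap_ord, , drop = FALSE]
  } else {
    dos <- a1 + a2
    dos[is.na(a1) | is.na(a2)] <- NA_integer_
    alleles <- t(dos)
  }
  haplotype_panel(alleles, snps, phased = phased, n_dropped = n_dropped)
}

#' Minor allele frequency
#'
#' Computed over non-missing alleles (haplotypes when phased, dosages when
#' unphased): the alternate-allele frequency p is folded to min(p, 1 - p).
#'
#' @param panel A \code{haplotype_panel}.
#' @param snp_index Column index of one SNP, or \code{NULL} for all SNPs.
#' @return Frequency in [0, 0.5]; a vector when \code{snp_index} is
#'   \code{NULL}. An all-missing column is an error for a single index and
#'   \code{NA} in the vectorized form.
#' @export
maf <- function(panel, snp_index = NULL) {
  one <- function(j) {
    x <- panel$alleles[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    tot <- if (panel$phased) length(x) else 2 * length(x)
    p <- sum(x) / tot
    min(p, 1 - p)
  }
  if (is.null(snp_index))
    return(vapply(seq_len(n_snps(panel)), one, numeric(1)))
  f <- one(snp_index)
  if (is.na(f))
    stop("undefined frequency: SNP ", panel$snps$id[snp_index],
         " has no non-missing alleles")
  f
}

#' Filter SNPs on minor allele frequency
#'
#' Keeps SNPs whose MAF is strictly greater than the threshold ("higher
#' than" the cutoff, so a SNP at exactly the threshold is removed). SNP
#' order is preserved; an empty result is allowed.
#'
#' @param panel A \code{haplotype_panel}.
#' @param threshold MAF cutoff in [0, 0.5); default 0.10.
#' @return A \code{haplotype_panel} with the retained SNPs.
#' @export
filter_maf <- function(panel, threshold = 0.10) {
  stopifnot(threshold >= 0, threshold < 0.5)
  if (n_snps(panel) == 0) return(panel)
  f <- maf(panel)
  keep <- !is.na(f) & f > threshold
  subset_panel(panel, keep)
}
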