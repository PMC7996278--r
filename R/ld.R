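#' Pairwise r-squared from phased haplotypes
#'
#' Haplotype-counting estimator: over haplotypes non-missing at both sites,
#' r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B)), where p_A and
#' p_B are the alternate-allele frequencies and p_AB the frequency of the
#' haplotype carrying the alternate allele at both sites.
#'
#' @param panel A phased \code{haplotype_panel}.
#' @param i,j SNP column indices.
#' @return r-squared in [0, 1].
#' @export
r2_phased <- function(panel, i, j) {
  if (!panel$phased) stop("r2_phased requires a phased panel")
  x <- panel$alleles[, i]
  y <- panel$alleles[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0) stop("no pairwise-complete haplotypes for SNPs ", i, ", ", j)
  pA <- mean(x); pB <- mean(y)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("undefined LD: zero variance at SNP ",
         panel$snps$id[if (pA <= 0 || pA >= 1) i else j])
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  min(max(r2, 0), 1)
}

# Two-locus EM over unphased dosage pairs. Returns the four haplotype
# frequencies (p11, p10, p01, p00) or NULL on non-convergence.
two_locus_em <- function(x, y, tol = 1e-8, max_iter = 1000) {
  # 3x3 genotype counts
  n <- table(factor(x, levels = 0:2), factor(y, levels = 0:2))
  ntot <- sum(n)
  pA <- mean(x) / 2; pB <- mean(y) / 2
  # linkage-equilibrium initialization
  h <- c(p11 = pA * pB, p10 = pA * (1 - pB),
         p01 = (1 - pA) * pB, p00 = (1 - pA) * (1 - pB))
  loglik <- function(h) {
    # genotype probabilities from haplotype frequencies (HWE)
    g <- matrix(0, 3, 3)
    g[3, 3] <- h[1]^2;            g[3, 2] <- 2 * h[1] * h[2]
    g[3, 1] <- h[2]^2;            g[2, 3] <- 2 * h[1] * h[3]
    g[2, 2] <- 2 * (h[1] * h[4] + h[2] * h[3])
    g[2, 1] <- 2 * h[2] * h[4];   g[1, 3] <- h[3]^2
    g[1, 2] <- 2 * h[3] * h[4];   g[1, 1] <- h[4]^2
    sum(n[g > 0] * log(g[g > 0])) + if (any(n[g == 0] > 0)) -Inf else 0
  }
  ll_old <- loglik(h)
  n_dh <- n[2, 2]  # double heterozygotes: the only ambiguous class
  for (it in seq_len(max_iter)) {
    # E step: split double hets between cis (11/00) and trans (10/01)
    denom <- h[1] * h[4] + h[2] * h[3]
    cis <- if (denom > 0) n_dh * h[1] * h[4] / denom else n_dh / 2
    trans <- n_dh - cis
    # M step: expected haplotype counts
    c11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3] + cis
    c10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1] + trans
    c01 <- 2 * n[1, 3] + n[2, 3] + n[1, 2] + trans
    c00 <- 2 * n[1, 1] + n[1, 2] + n[2, 1] + cis
    h <- c(c11, c10, c01, c00) / (2 * ntot)
    ll <- loglik(h)
    if (is.finite(ll) && is.finite(ll_old) && abs(ll - ll_old) < tol)
      return(h)
    ll_old <- ll
  }
  NULL
}

#' Pairwise r-squared from unphased genotypes
#'
#' Two estimators for dosage data: \code{"em"} fits two-locus haplotype
#' frequencies by maximum likelihood (EM, linkage-equilibrium start,
#' log-likelihood tolerance 1e-8, 1000-iteration cap) and applies the phased
#' formula; \code{"composite"} is the squared Pearson correlation of the two
#' dosage vectors. If the EM fails to converge the composite value is
#' returned with a warning.
#'
#' @param panel An unphased \code{haplotype_panel} (dosages 0/1/2).
#' @param i,j SNP column indices.
#' @param method \code{"em"} (default) or \code{"composite"}.
#' @return r-squared in [0, 1].
#' @export
r2_unphased <- function(panel, i, j, method = c("em", "composite")) {
  method <- match.arg(method)
  if (panel$phased) stop("r2_unphased requires an unphased panel")
  x <- panel$alleles[, i]
  y <- panel$alleles[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no pairwise-complete individuals for SNPs ",
                           i, ", ", j)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined LD: zero variance at SNP ",
         panel$snps$id[if (stats::var(x) == 0) i else j])
  composite <- min(max(stats::cor(x, y)^2, 0), 1)
  if (method == "composite") return(composite)
  h <- two_locus_em(x, y)
  if (is.null(h)) {
    warning("two-locus EM did not converge for SNPs ", panel$snps$id[i],
            ", ", panel$snps$id[j], "; falling back to composite r2")
    return(composite)
  }
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(composite)
  D <- h[1] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  min(max(unname(r2), 0), 1)
}

#' Construct an LD matrix object
#'
#' Wraps a symmetric r-squared matrix together with SNP labels and the
#' per-SNP minor allele frequencies and positions used by the deterministic
#' tie-breaking rules of the tagging algorithms.
#'
#' @param r2 Symmetric numeric matrix with entries in [0, 1], unit diagonal.
#' @param snp_ids Character labels, one per row/column.
#' @param maf Optional per-SNP minor allele frequencies (tie-breaking).
#' @param pos Optional per-SNP positions (tie-breaking).
#' @return An object of class \code{ld_matrix}.
#' @export
as_ld_matrix <- function(r2, snp_ids = NULL, maf = NULL, pos = NULL) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids))
    snp_ids <- if (!is.null(rownames(r2))) rownames(r2)
               else paste0("snp", seq_len(nrow(r2)))
  stopifnot(nrow(r2) == ncol(r2), length(snp_ids) == nrow(r2),
            all(r2 >= 0 & r2 <= 1),
            isTRUE(all.equal(r2, t(r2))))
  r2 <- (r2 + t(r2)) / 2  # enforce exact symmetry
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(r2 = r2, snp_ids = snp_ids, maf = maf, pos = pos),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix:", length(x$snp_ids), "SNPs; mean off-diagonal r2 =",
      if (length(x$snp_ids) > 1)
        round(mean(x$r2[upper.tri(x$r2)]), 4) else NA, "\n")
  invisible(x)
}

#' Pairwise LD matrix for a panel
#'
#' Computes all pairwise r-squared values with the phase-appropriate
#' estimator (haplotype counting when phased, EM or composite when
#' unphased). SNPs with zero variance are excluded beforehand with a warning
#' naming them; their ids are attached as attribute \code{"excluded"}.
#'
#' @param panel A \code{haplotype_panel} with at least one SNP.
#' @param method Estimator for unphased panels, see [r2_unphased()].
#' @return An \code{ld_matrix}.
#' @export
ld_matrix <- function(panel, method = c("em", "composite")) {
  method <- match.arg(method)
  if (n_snps(panel) == 0) stop("cannot compute LD for an empty panel")
  f <- maf(panel)
  mono <- is.na(f) | f == 0
  if (any(mono)) {
    warning("excluding ", sum(mono), " zero-variance SNP(s) from LD: ",
            paste(panel$snps$id[mono], collapse = ", "))
  }
  excluded <- panel$snps$id[mono]
  panel <- subset_panel(panel, !mono)
  f <- f[!mono]
  m <- n_snps(panel)
  if (m == 0) stop("no SNPs with nonzero variance remain")
  r2 <- diag(1, m)
  pair_fun <- if (panel$phased) r2_phased else
    function(p, i, j) r2_unphased(p, i, j, method = method)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        v <- pair_fun(panel, i, j)
        r2[i, j] <- v
        r2[j, i] <- v
      }
    }
  }
  out <- as_ld_matrix(r2, panel$snps$id, maf = f, pos = panel$snps$pos)
  attr(out, "excluded") <- excluded
  out
}

#' Write an LD matrix as TSV
#'
#' @param ld An \code{ld_matrix}.
#' @param path Output path.
#' @param format \code{"square"} (labelled matrix) or \code{"long"}
#'   (\code{id_i}, \code{id_j}, \code{r2} triples, upper triangle).
#' @return \code{path}, invisibly.
#' @export
write_ld_matrix <- function(ld, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    utils::write.table(ld$r2, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    idx <- which(upper.tri(ld$r2), arr.ind = TRUE)
    long <- data.frame(id_i = ld$snp_ids[idx[, 1]],
                       id_j = ld$snp_ids[idx[, 2]],
                       r2 = ld$r2[idx])
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a square LD matrix written by [write_ld_matrix()]
#'
#' @param path TSV path (square format, labelled rows and columns).
#' @return An \code{ld_matrix}.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  as_ld_matrix(m, rownames(m))
}
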