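# run code under a local RNG state so simulators are reproducible under
# their own seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Configuration for the block-LD haplotype simulator
#'
#' Defaults emulate a European-ancestry reference panel of the size used for
#' tag selection (99 individuals, the 1000 Genomes CEU sample size) over a
#' gene-sized region organised in LD blocks: four blocks of ten SNPs, four
#' founder haplotypes per block, a 10\% founder-switch probability at block
#' boundaries, 1\% allele-flip noise and a 10\% founder-level MAF floor
#' matching the pipeline's common-variant focus.
#'
#' @param n_individuals Number of diploid individuals (2N haplotypes).
#' @param blocks A list of \code{c(n_snps, n_founders)} pairs, one per block.
#' @param recomb_between_blocks Probability of re-drawing the founder at each
#'   block boundary (1 makes blocks independent).
#' @param mutation_rate Per-allele flip probability after founder copying.
#' @param maf_floor Minimum per-SNP minor-allele frequency among the
#'   founder haplotypes.
#' @param seed Integer seed; fixed seed implies fixed output.
#' @return A list of class \code{block_sim_config}.
#' @export
block_sim_config <- function(n_individuals = 99,
                             blocks = list(c(10, 4), c(10, 4),
                                           c(10, 4), c(10, 4)),
                             recomb_between_blocks = 0.1,
                             mutation_rate = 0.01,
                             maf_floor = 0.1,
                             seed = 1L) {
  stopifnot(n_individuals >= 1,
            length(blocks) >= 1,
            recomb_between_blocks >= 0, recomb_between_blocks <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            maf_floor >= 0, maf_floor < 0.5)
  blocks <- lapply(blocks, function(b) {
    stopifnot(length(b) == 2, b[1] >= 1, b[2] >= 1)
    as.integer(b)
  })
  for (b in blocks) {
    nf <- b[2]
    # feasibility: some founder count k must give k/nf and (nf-k)/nf >= floor
    k <- ceiling(nf * maf_floor)
    if (maf_floor > 0 && (nf < 2 || k > nf - ceiling(nf * maf_floor)))
      stop("config error: ", nf, " founder(s) cannot satisfy maf_floor ",
           maf_floor)
  }
  structure(list(n_individuals = as.integer(n_individuals), blocks = blocks,
                 recomb_between_blocks = recomb_between_blocks,
                 mutation_rate = mutation_rate, maf_floor = maf_floor,
                 seed = seed),
            class = "block_sim_config")
}

#' Simulate phased haplotypes with block LD structure
#'
#' Founder-resampling model: per block, founder haplotypes are drawn with
#' per-SNP allele frequencies respecting the founder-level MAF floor; each
#' of the 2N panel haplotypes picks a founder uniformly for the first block
#' and, at every block boundary, re-draws the founder uniformly with the
#' between-block recombination probability (otherwise keeping the same
#' founder index); finally each allele flips with the mutation rate. With
#' zero mutation and one block, the panel is a mixture of founder haplotypes
#' — two founders give perfect within-block LD (r2 = 1 everywhere).
#' Positions are strictly increasing: 1 kb spacing from position 10000,
#' blocks contiguous.
#'
#' @param config A \code{block_sim_config}.
#' @return A phased \code{haplotype_panel}; the ground truth (per-SNP block
#'   membership and the haplotype-by-block founder indices) is attached as
#'   attribute \code{"truth"}.
#' @export
simulate_block_haplotypes <- function(config) {
  stopifnot(inherits(config, "block_sim_config"))
  with_local_seed(config$seed, {
    n_hap <- 2L * config$n_individuals
    n_blocks <- length(config$blocks)
    n_snps_total <- sum(vapply(config$blocks, `[`, integer(1), 1))

    founders <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      n_snp <- config$blocks[[b]][1]
      n_fnd <- config$blocks[[b]][2]
      fm <- matrix(0L, n_fnd, n_snp)
      for (s in seq_len(n_snp)) {
        repeat {
          f <- stats::runif(1, config$maf_floor, 1 - config$maf_floor)
          col <- as.integer(stats::rbinom(n_fnd, 1, f))
          m <- min(mean(col), 1 - mean(col))
          if (config$maf_floor == 0 || m >= config$maf_floor) break
        }
        fm[, s] <- col
      }
      founders[[b]] <- fm
    }

    # founder choice per haplotype per block with boundary switching
    founder_idx <- matrix(0L, n_hap, n_blocks)
    founder_idx[, 1] <- sample.int(config$blocks[[1]][2], n_hap,
                                   replace = TRUE)
    if (n_blocks > 1) {
      for (b in 2:n_blocks) {
        n_fnd <- config$blocks[[b]][2]
        switch_f <- stats::runif(n_hap) < config$recomb_between_blocks
        carried <- pmin(founder_idx[, b - 1], n_fnd)
        founder_idx[, b] <- ifelse(switch_f,
                                   sample.int(n_fnd, n_hap, replace = TRUE),
                                   carried)
      }
    }

    alleles <- matrix(0L, n_hap, n_snps_total)
    block_of <- integer(n_snps_total)
    col0 <- 0L
    for (b in seq_len(n_blocks)) {
      n_snp <- config$blocks[[b]][1]
      alleles[, col0 + seq_len(n_snp)] <-
        founders[[b]][founder_idx[, b], , drop = FALSE]
      block_of[col0 + seq_len(n_snp)] <- b
      col0 <- col0 + n_snp
    }
    if (config$mutation_rate > 0) {
      flips <- matrix(stats::runif(length(alleles)) < config$mutation_rate,
                      nrow = n_hap)
      alleles[flips] <- 1L - alleles[flips]
    }

    pos <- 10000 + 1000 * (seq_len(n_snps_total) - 1)
    snps <- data.frame(id = sprintf("snp%04d", seq_len(n_snps_total)),
                       chrom = "1", pos = pos,
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
    panel <- haplotype_panel(alleles, snps, phased = TRUE)
    attr(panel, "truth") <- list(block = block_of,
                                 founder_idx = founder_idx,
                                 founders = founders,
                                 config = config)
    panel
  })
}

#' Collapse a phased panel to unphased dosages
#'
#' Pairs consecutive haplotypes (2i - 1, 2i) into individuals and sums the
#' alleles; a missing allele on either haplotype gives a missing dosage.
#'
#' @param panel A phased \code{haplotype_panel} with an even number of rows.
#' @return An unphased \code{haplotype_panel}.
#' @export
erase_phase <- function(panel) {
  stopifnot(panel$phased, nrow(panel$alleles) %% 2 == 0)
  n <- nrow(panel$alleles) / 2
  dos <- panel$alleles[2 * seq_len(n) - 1, , drop = FALSE] +
    panel$alleles[2 * seq_len(n), , drop = FALSE]
  haplotype_panel(dos, panel$snps, phased = FALSE, panel$n_dropped)
}

#' Write a panel as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype fields: \code{a|b} calls
#' for phased panels (missing haplotype alleles written as \code{./.}) and
#' \code{0/0}, \code{0/1}, \code{1/1}, \code{./.} for unphased dosages.
#' Reading the file back with [read_vcf_region()] over the covering region
#' reproduces the panel exactly.
#'
#' @param panel A \code{haplotype_panel}.
#' @param path Output path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_synthetic_vcf <- function(panel, path) {
  m <- n_snps(panel)
  if (panel$phased) {
    stopifnot(nrow(panel$alleles) %% 2 == 0)
    n_ind <- nrow(panel$alleles) / 2
  } else n_ind <- nrow(panel$alleles)
  samples <- sprintf("S%03d", seq_len(n_ind))
  header <- c("##fileformat=VCFv4.2",
              "##source=tagsel-synthetic",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              if (m > 0) paste0("##contig=<ID=", unique(panel$snps$chrom), ">"),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- header
  if (m > 0) {
    gt_of <- function(j) {
      if (panel$phased) {
        a1 <- panel$alleles[2 * seq_len(n_ind) - 1, j]
        a2 <- panel$alleles[2 * seq_len(n_ind), j]
        out <- paste0(a1, "|", a2)
        out[is.na(a1) | is.na(a2)] <- "./."
        out[is.na(a1) & !is.na(a2)] <- paste0(".|", a2[is.na(a1) & !is.na(a2)])
        out[!is.na(a1) & is.na(a2)] <- paste0(a1[!is.na(a1) & is.na(a2)], "|.")
        out
      } else {
        d <- panel$alleles[, j]
        c("0/0", "0/1", "1/1")[d + 1][seq_along(d)] -> out
        out[is.na(d)] <- "./."
        out
      }
    }
    body <- vapply(seq_len(m), function(j) {
      paste(c(panel$snps$chrom[j],
              format(panel$snps$pos[j], scientific = FALSE, trim = TRUE),
              panel$snps$id[j], panel$snps$ref[j], panel$snps$alt[j],
              ".", "PASS", ".", "GT", gt_of(j)), collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Covering region of a panel
#'
#' @param panel A non-empty \code{haplotype_panel}.
#' @param name Region label.
#' @return A one-row region data.frame spanning all the panel's SNPs.
#' @export
panel_region <- function(panel, name = "region") {
  stopifnot(n_snps(panel) > 0)
  data.frame(chrom = panel$snps$chrom[1], start = min(panel$snps$pos),
             end = max(panel$snps$pos), name = name,
             stringsAsFactors = FALSE)
}

#' Simulate a significant-eQTL fixture table
#'
#' A random fraction of the panel's SNPs receive one eQTL record each, in a
#' tissue drawn uniformly from \code{tissues}, with log-uniform p-values in
#' [1e-50, 1e-5] and normalized effect sizes uniform on [-0.5, 0.5]
#' excluding 0. Deterministic under \code{seed}.
#'
#' @param panel A \code{haplotype_panel}.
#' @param gene Gene id to attach to every record.
#' @param tissues Character vector of tissue names to draw from.
#' @param fraction_eqtl Probability that a SNP receives a record.
#' @param seed Integer seed.
#' @return eQTL data.frame (\code{variant_id}, \code{gene_id}, \code{tissue},
#'   \code{p_value}, \code{nes}), possibly empty.
#' @export
simulate_eqtl_table <- function(panel, gene,
                                tissues = c("Brain_Cortex", "Artery_Aorta",
                                            "Whole_Blood"),
                                fraction_eqtl = 0.5, seed = 1L) {
  stopifnot(fraction_eqtl >= 0, fraction_eqtl <= 1, length(tissues) >= 1)
  with_local_seed(seed, {
    take <- stats::runif(n_snps(panel)) < fraction_eqtl
    ids <- panel$snps$id[take]
    n <- length(ids)
    nes_mag <- stats::runif(n, 0, 0.5)
    nes_mag[nes_mag == 0] <- .Machine$double.eps
    data.frame(
      variant_id = ids,
      gene_id = rep(gene, n),
      tissue = if (n) tissues[sample.int(length(tissues), n, replace = TRUE)]
               else character(0),
      p_value = 10^stats::runif(n, -50, -5),
      nes = nes_mag * sample(c(-1, 1), n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}
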