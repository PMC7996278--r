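test_that("both eQTL table dialects parse, including scientific-notation p-values", {
  generic <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tgene_id\ttissue\tp_value\tnes",
               "rs1234\tCCR1\tBrain_Cortex\t1e-47\t-0.40"), generic)
  rec <- read_eqtl_table(generic)
  expect_equal(rec$p_value, 1e-47)
  expect_equal(rec$nes, -0.40)

  gtex <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gencode Id\tGene Symbol\tVariant Id\tSNP Id\tP-Value\tNES\tTissue",
               paste("ENSG1.1", "CCR1", "chr3_46243200_G_A_b38", "rs1234",
                     "1e-47", "-0.40", "Brain_Cortex", sep = "\t")), gtex)
  rec2 <- read_eqtl_table(gtex)
  expect_equal(rec2$p_value, 1e-47)
  expect_equal(rec2$tissue, "Brain_Cortex")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("variant_id\tgene_id\ttissue\tp_value\tnes", empty)
  expect_equal(nrow(read_eqtl_table(empty)), 0)

  bad_p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tgene_id\ttissue\tp_value\tnes",
               "rs1\tG\tLiver\t1.5\t0.1"), bad_p)
  expect_error(read_eqtl_table(bad_p), "\\[0, 1\\]")

  unknown <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "1\t2"), unknown)
  expect_error(read_eqtl_table(unknown), "Recognized layouts")
})

test_that("tissue filtering is case-insensitive substring matching", {
  recs <- eqtl_df(paste0("rs", 1:4),
                  c("Brain_Cortex", "Whole_Blood", "Liver",
                    "Artery_Tibial"),
                  rep(1e-10, 4), rep(0.2, 4))
  kept <- filter_tissues(recs, c("Brain", "Artery", "Nerve", "Blood",
                                 "Heart"))
  expect_setequal(kept$tissue, c("Brain_Cortex", "Whole_Blood",
                                 "Artery_Tibial"))
  expect_equal(nrow(filter_tissues(recs, "brain cortex")), 1)
})

test_that("tag/eQTL intersection assigns priority classes per tag", {
  full <- toy_ld(matrix(1, 3, 3))
  tags <- greedy_tag(full, 0.8)  # single tag s1 capturing s1..s3
  recs <- eqtl_df(c("s1", "s1", "s9"),
                  c("Brain_Cortex", "Artery_Aorta", "Whole_Blood"),
                  c(1e-20, 1e-8, 1e-5), c(0.3, -0.1, 0.2))
  cand <- intersect_tags_eqtls(tags, recs, "GENE1")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_hits, 2)
  expect_equal(cand$priority_class, "brain_first_priority")
  expect_equal(cand$best_p, 1e-20)
  expect_equal(cand$best_abs_nes, 0.3)

  # no matching record -> no_eqtl; empty record list -> all no_eqtl
  cand2 <- intersect_tags_eqtls(tags, recs[3, , drop = FALSE], "GENE1")
  expect_equal(cand2$priority_class, "no_eqtl")
  cand3 <- intersect_tags_eqtls(tags, recs[0, , drop = FALSE], "GENE1")
  expect_equal(cand3$priority_class, "no_eqtl")

  # only cis records count: other genes are ignored
  recs_other <- eqtl_df("s1", "Brain_Cortex", 1e-30, 0.4,
                        gene_id = "OTHER")
  expect_equal(intersect_tags_eqtls(tags, recs_other,
                                    "GENE1")$priority_class, "no_eqtl")
})

test_that("positional variant ids match tags through SNP metadata, allele-order-insensitively", {
  full <- toy_ld(matrix(1, 2, 2), maf = c(0.4, 0.3), pos = c(100, 200))
  tags <- greedy_tag(full, 0.8)
  snps <- data.frame(id = c("s1", "s2"), chrom = "3",
                     pos = c(100, 200), ref = "G", alt = "A",
                     stringsAsFactors = FALSE)
  recs <- eqtl_df(c("chr3_100_A_G_b38", "chr3_100_G_A_b38",
                    "chr3_999_G_A_b38"),
                  rep("Brain_Cortex", 3), rep(1e-9, 3), rep(0.2, 3))
  cand <- intersect_tags_eqtls(tags, recs, "GENE1", snps = snps)
  expect_equal(cand$n_hits[cand$snp_id == "s1"], 2)
})

test_that("filtering before intersecting equals intersecting then filtering hits", {
  set.seed(9)
  panel <- simulate_block_haplotypes(block_sim_config(
    n_individuals = 40, blocks = list(c(6, 2), c(6, 2)), seed = 9))
  ld <- ld_matrix(panel)
  tags <- greedy_tag(ld, 0.8)
  recs <- simulate_eqtl_table(panel, "GENE1",
                              tissues = c("Brain_Cortex", "Liver",
                                          "Whole_Blood", "Pancreas"),
                              fraction_eqtl = 0.8, seed = 10)
  keywords <- c("Brain", "Blood")
  route_a <- intersect_tags_eqtls(tags, filter_tissues(recs, keywords),
                                  "GENE1")
  full <- intersect_tags_eqtls(tags, recs, "GENE1")
  hits <- attr(full, "hits")
  for (t in tags$tags) {
    h <- filter_tissues(hits[[t]], keywords)
    a <- route_a[route_a$snp_id == t, ]
    expect_equal(a$n_hits, nrow(h))
    if (nrow(h)) {
      expect_equal(a$best_p, min(h$p_value))
      expect_equal(a$best_abs_nes, max(abs(h$nes)))
    } else {
      expect_equal(a$priority_class, "no_eqtl")
    }
  }
})

test_that("ranking orders by priority class, then |NES|, p-value, id, deterministically", {
  cand <- data.frame(
    snp_id = c("rs_brain", "rs_artery_big", "rs_artery_small", "rs_none"),
    gene = "G",
    priority_class = c("brain_first_priority", "other_tissue",
                       "other_tissue", "no_eqtl"),
    n_hits = c(1, 1, 1, 0),
    tissues = c("Brain_Cortex", "Artery_Aorta", "Artery_Aorta", ""),
    best_p = c(1e-5, 1e-47, 1e-8, NA),
    best_abs_nes = c(0.05, 0.40, 0.10, NA),
    stringsAsFactors = FALSE)
  ranked <- rank_candidates(cand)
  # brain first even though the artery candidate has the larger |NES|
  expect_equal(ranked$snp_id,
               c("rs_brain", "rs_artery_big", "rs_artery_small", "rs_none"))
  expect_identical(rank_candidates(cand), ranked)
  # every first-priority candidate has a brain hit
  expect_true(all(grepl("Brain", ranked$tissues[
    ranked$priority_class == "brain_first_priority"])))

  # all-no_eqtl: ordered by snp_id
  none <- cand[c(4, 4), ]
  none$snp_id <- c("rs_b", "rs_a")
  expect_equal(rank_candidates(none)$snp_id, c("rs_a", "rs_b"))
  # ties on |NES| broken by ascending p
  tie <- cand[2:3, ]
  tie$best_abs_nes <- 0.2
  expect_equal(rank_candidates(tie)$snp_id[1], "rs_artery_big")
})
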