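# build a complete synthetic workflow bundle: 2 genes with known block
# structure, an orthologue table pointing at them, a VCF per gene region,
# and an eQTL table
workflow_fixture <- function(dir, fraction_eqtl = 0.5, seed = 1) {
  blocks <- list(c(6, 2), c(6, 2), c(6, 2))
  panels <- list(
    GENE1 = simulate_block_haplotypes(block_sim_config(
      n_individuals = 60, blocks = blocks, recomb_between_blocks = 1,
      mutation_rate = 0, seed = seed)),
    GENE2 = simulate_block_haplotypes(block_sim_config(
      n_individuals = 60, blocks = blocks[1:2], recomb_between_blocks = 1,
      mutation_rate = 0, seed = seed + 1)))
  # place the two genes on different chromosomes
  panels$GENE2$snps$chrom <- "2"
  vcf1 <- file.path(dir, "chr1.vcf"); vcf2 <- file.path(dir, "chr2.vcf")
  write_synthetic_vcf(panels$GENE1, vcf1)
  write_synthetic_vcf(panels$GENE2, vcf2)

  orth <- file.path(dir, "orthologs.tsv")
  span <- function(p) range(p$snps$pos)
  writeLines(c(
    paste(c("rat_gene", "rat_chrom", "rat_start", "rat_end", "human_gene",
            "human_chrom", "human_start", "human_end", "pct_id_target",
            "pct_id_query", "goc_score", "wga_coverage", "confidence"),
          collapse = "\t"),
    paste(c("Rg1", "1", 100, 200, "GENE1", "1", span(panels$GENE1)[1],
            span(panels$GENE1)[2], 80, 80, 100, 100, 1), collapse = "\t"),
    paste(c("Rg2", "2", 100, 200, "GENE2", "2", span(panels$GENE2)[1],
            span(panels$GENE2)[2], 80, 80, 100, 100, 1), collapse = "\t"),
    paste(c("Rg3", "3", 100, 200, "*"), collapse = "\t")), orth)

  eqtl <- rbind(
    simulate_eqtl_table(panels$GENE1, "GENE1",
                        tissues = c("Brain_Cortex", "Artery_Aorta", "Liver"),
                        fraction_eqtl = fraction_eqtl, seed = seed + 10),
    simulate_eqtl_table(panels$GENE2, "GENE2",
                        tissues = c("Brain_Cortex", "Whole_Blood"),
                        fraction_eqtl = fraction_eqtl, seed = seed + 11))
  eqtl_path <- file.path(dir, "eqtl.tsv")
  write_eqtl_table(eqtl, eqtl_path)
  list(orth = orth, vcf_template = file.path(dir, "chr{chrom}.vcf"),
       eqtl = eqtl_path, panels = panels)
}

test_that("the full workflow reproduces the simulator's ground truth", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir, fraction_eqtl = 0.5, seed = 101)
  cfg <- workflow_config(ortholog_table = fx$orth, vcf = fx$vcf_template,
                         eqtl_table = fx$eqtl, flank = 0,
                         output_dir = file.path(dir, "out"))
  report <- run_workflow(cfg)

  expect_equal(report$per_gene$gene, c("GENE1", "GENE2"))
  # stage counts match the simulated truth: all SNPs extracted (floor 0.1
  # founder MAF with 2 founders makes every SNP common), blocks = tags
  expect_equal(report$per_gene$n_extracted, c(18, 12))
  expect_true(all(report$per_gene$n_post_maf <=
                    report$per_gene$n_extracted))
  expect_equal(report$per_gene$n_tags_greedy, c(3, 2))
  expect_equal(report$per_gene$n_tags_cluster, c(3, 2))
  # stage monotonicity
  expect_true(all(report$per_gene$n_post_maf >=
                    report$per_gene$n_tags_greedy))
  # chosen method is the argmax of mean capture r2, recomputable from the
  # stored assignments (ties to greedy)
  for (gene in report$per_gene$gene) {
    a <- report$assignments[[gene]]
    expected <- if (mean_capture_r2(a$cluster, a$ld) >
                      mean_capture_r2(a$greedy, a$ld)) "cluster" else "greedy"
    expect_equal(a$chosen, expected)
  }
  # every first-priority candidate carries a brain hit
  expect_true(all(grepl("Brain", report$first_priority$tissues)))
  # candidate tags are exactly the chosen assignments' tags
  for (gene in report$per_gene$gene) {
    a <- report$assignments[[gene]]
    expect_setequal(report$candidates$snp_id[report$candidates$gene == gene],
                    a[[a$chosen]]$tags)
  }
})

test_that("workflow runs are deterministic: identical configs give identical outputs", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir, seed = 7)
  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  cfg1 <- workflow_config(fx$orth, fx$vcf_template, fx$eqtl, flank = 0,
                          output_dir = out1)
  cfg2 <- workflow_config(fx$orth, fx$vcf_template, fx$eqtl, flank = 0,
                          output_dir = out2)
  run_workflow(cfg1); run_workflow(cfg2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("the pipeline stops after tagging when no eQTL table is given", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir, seed = 15)
  report <- run_workflow(workflow_config(fx$orth, fx$vcf_template,
                                         eqtl_table = NULL, flank = 0))
  expect_null(report$candidates)
  expect_null(report$first_priority)
  expect_false(any(grepl("priority", names(report$per_gene))))
  expect_equal(report$per_gene$n_tags_greedy, c(3, 2))
})

test_that("a gene with no post-MAF SNPs is reported empty and the run continues", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir, seed = 23)
  # make every GENE1 SNP rare: monomorphic except one haplotype
  p <- fx$panels$GENE1
  p$alleles[] <- 0L
  p$alleles[1, ] <- 1L
  write_synthetic_vcf(p, file.path(dir, "chr1.vcf"))
  report <- run_workflow(workflow_config(fx$orth, fx$vcf_template,
                                         fx$eqtl, flank = 0))
  g1 <- report$per_gene[report$per_gene$gene == "GENE1", ]
  expect_equal(g1$n_post_maf, 0)
  expect_true(is.na(g1$chosen_method))
  expect_equal(report$per_gene$n_tags_greedy[2], 2)
  codes <- vapply(report$log, `[[`, "", "code")
  expect_true("no_snps_after_maf" %in% codes)
})

test_that("an unreadable VCF aborts with a stage-named error", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir, seed = 31)
  file.remove(file.path(dir, "chr2.vcf"))
  expect_error(run_workflow(workflow_config(fx$orth, fx$vcf_template,
                                            fx$eqtl, flank = 0)),
               "extract stage.*GENE2")
})

test_that("YAML configs round-trip and reject unknown keys", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir, seed = 41)
  yml <- file.path(dir, "wf.yaml")
  yaml::write_yaml(list(ortholog_table = fx$orth, vcf = fx$vcf_template,
                        eqtl_table = fx$eqtl, flank = 0,
                        r2_threshold = 0.8), yml)
  cfg <- read_workflow_config(yml)
  expect_s3_class(cfg, "workflow_config")
  expect_equal(cfg$maf_threshold, 0.10)
  expect_equal(cfg$tissue_keywords,
               c("Brain", "Artery", "Nerve", "Blood", "Heart"))
  yaml::write_yaml(list(ortholog_table = fx$orth, vcf = fx$vcf_template,
                        typo_key = 1), yml)
  expect_error(read_workflow_config(yml), "typo_key")
})
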