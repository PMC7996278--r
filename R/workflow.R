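#' Workflow configuration
#'
#' Bundles and validates every parameter of the end-to-end tag-selection
#' run. Defaults are the study conditions of the pipeline: 5000 bp flanks,
#' MAF > 0.10, r2 >= 0.8, tissue keywords Brain, Artery, Nerve, Blood,
#' Heart, and the captured-per-tag TE convention.
#'
#' @param ortholog_table Path to the orthologue TSV.
#' @param vcf Path to a VCF, or a per-chromosome template containing
#'   \code{{chrom}}.
#' @param eqtl_table Optional path to an eQTL TSV; when \code{NULL} the
#'   pipeline stops after tagging and reports no priority classes.
#' @param flank Flank length in bp.
#' @param maf_threshold MAF cutoff (strict).
#' @param r2_threshold Capture threshold.
#' @param tissue_keywords Tissue filter keywords.
#' @param te_convention See [tagging_effectiveness()].
#' @param method_selection \code{"max_mean_r2"} picks, per gene, the
#'   assignment with the larger mean capture r2 (ties to greedy) for eQTL
#'   annotation; \code{"greedy"} forces the greedy/Tagger result.
#' @param min_confidence Optional orthology-confidence requirement passed to
#'   [validate_orthologs()].
#' @param output_dir Optional directory for reports and intermediates.
#' @param seed Seed for any stochastic fixtures (unused by the deterministic
#'   pipeline itself).
#' @return A list of class \code{workflow_config}.
#' @export
workflow_config <- function(ortholog_table, vcf, eqtl_table = NULL,
                            flank = 5000, maf_threshold = 0.10,
                            r2_threshold = 0.8,
                            tissue_keywords = c("Brain", "Artery", "Nerve",
                                                "Blood", "Heart"),
                            te_convention = c("captured_per_tag",
                                              "tags_per_captured"),
                            method_selection = c("max_mean_r2", "greedy"),
                            min_confidence = NULL,
                            output_dir = NULL, seed = 1L) {
  te_convention <- match.arg(te_convention)
  method_selection <- match.arg(method_selection)
  stopifnot(flank >= 0, maf_threshold >= 0, maf_threshold < 0.5,
            r2_threshold > 0, r2_threshold <= 1,
            length(tissue_keywords) >= 1)
  structure(list(ortholog_table = ortholog_table, vcf = vcf,
                 eqtl_table = eqtl_table, flank = flank,
                 maf_threshold = maf_threshold, r2_threshold = r2_threshold,
                 tissue_keywords = tissue_keywords,
                 te_convention = te_convention,
                 method_selection = method_selection,
                 min_confidence = min_confidence,
                 output_dir = output_dir, seed = seed),
            class = "workflow_config")
}

#' Read a workflow configuration from YAML
#'
#' Keys mirror the arguments of [workflow_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A \code{workflow_config}.
#' @export
read_workflow_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(workflow_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown workflow config key(s): ", paste(bad, collapse = ", "))
  do.call(workflow_config, y)
}

vcf_path_for <- function(vcf, chrom) {
  if (grepl("{chrom}", vcf, fixed = TRUE))
    gsub("{chrom}", chrom, vcf, fixed = TRUE)
  else vcf
}

#' Run the full tag-selection workflow
#'
#' Orchestrates the whole pipeline: parse and validate the orthologue table,
#' build flanked regions, extract biallelic SNPs from the VCF per gene,
#' filter on MAF, compute the LD matrix, run both tagging algorithms,
#' compare them by tagging effectiveness and mean capture r2, choose the
#' assignment for annotation (maximal mean capture r2 by default, greedy on
#' ties), intersect its tags with the tissue-filtered eQTL table and rank
#' the marker candidates. Every dropped record and divergence is logged with
#' a reason code. A gene whose region yields no post-MAF SNPs is reported
#' with empty stages and the run continues.
#'
#' @param config A \code{workflow_config}.
#' @return A \code{marker_report}: list with \code{per_gene} (stage counts
#'   and method comparison per gene), \code{candidates} (ranked marker
#'   table, when an eQTL table was given), \code{first_priority} (its
#'   brain-tissue subset), \code{assignments} (per-gene
#'   \code{tag_assignment}s and \code{ld_matrix}es), \code{log} and
#'   \code{config}. Written to \code{output_dir} when set.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  log <- list()
  note <- function(stage, code, detail) {
    log[[length(log) + 1]] <<- list(stage = stage, code = code,
                                    detail = detail)
  }

  orth <- read_ortholog_table(config$ortholog_table)
  val <- validate_orthologs(orth, min_confidence = config$min_confidence)
  for (i in seq_len(nrow(val$rejected)))
    note("orthologs", val$rejected$reason[i], val$rejected$rat_gene[i])
  regions <- gene_regions(val$accepted, flank = config$flank)

  eqtl <- NULL
  if (!is.null(config$eqtl_table)) {
    eqtl <- filter_tissues(read_eqtl_table(config$eqtl_table),
                           config$tissue_keywords)
  }

  per_gene <- list(); assignments <- list(); candidates <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, , drop = FALSE]
    gene <- region$name
    vcf_path <- vcf_path_for(config$vcf, region$chrom)
    if (!file.exists(vcf_path))
      stop("extract stage: unreadable VCF for gene ", gene, ": ", vcf_path)
    panel <- read_vcf_region(vcf_path, region)
    if (panel$n_dropped > 0)
      note("extract", "non_biallelic_snp_dropped",
           paste0(gene, ":", panel$n_dropped))
    n_extracted <- n_snps(panel)
    post <- filter_maf(panel, config$maf_threshold)
    n_post <- n_snps(post)
    if (n_extracted > n_post)
      note("maf_filter", "below_maf_threshold",
           paste0(gene, ":", n_extracted - n_post))

    row <- data.frame(gene = gene, n_extracted = n_extracted,
                      n_post_maf = n_post, n_ld_snps = 0L,
                      n_tags_greedy = NA_integer_, n_tags_cluster = NA_integer_,
                      te_greedy = NA_real_, te_cluster = NA_real_,
                      mean_r2_greedy = NA_real_, mean_r2_cluster = NA_real_,
                      chosen_method = NA_character_,
                      stringsAsFactors = FALSE)
    if (n_post == 0) {
      note("tagging", "no_snps_after_maf", gene)
      per_gene[[gene]] <- row
      next
    }
    ld <- withCallingHandlers(
      ld_matrix(post),
      warning = function(w) {
        note("ld", "zero_variance_excluded", paste0(gene, ": ",
                                                    conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    cmp <- compare_methods(ld, config$r2_threshold, config$te_convention)
    chosen <- if (config$method_selection == "greedy") "greedy"
      else if (cmp$cluster$mean_capture_r2 > cmp$greedy$mean_capture_r2)
        "cluster" else "greedy"
    row$n_ld_snps <- length(ld$snp_ids)
    row$n_tags_greedy <- length(cmp$greedy$tags)
    row$n_tags_cluster <- length(cmp$cluster$tags)
    row$te_greedy <- cmp$greedy$te
    row$te_cluster <- cmp$cluster$te
    row$mean_r2_greedy <- cmp$greedy$mean_capture_r2
    row$mean_r2_cluster <- cmp$cluster$mean_capture_r2
    row$chosen_method <- chosen
    per_gene[[gene]] <- row
    assignments[[gene]] <- list(ld = ld, greedy = cmp$greedy,
                                cluster = cmp$cluster, chosen = chosen)
    if (!is.null(eqtl)) {
      cand <- intersect_tags_eqtls(cmp[[chosen]], eqtl, gene,
                                   snps = post$snps)
      candidates[[gene]] <- cand
    }
  }

  per_gene <- do.call(rbind, per_gene)
  rownames(per_gene) <- NULL
  report <- list(per_gene = per_gene, config = config, log = log)
  if (!is.null(eqtl)) {
    cand <- if (length(candidates)) rank_candidates(
      do.call(rbind, c(candidates, list(make.row.names = FALSE))))
      else NULL
    report$candidates <- cand
    report$first_priority <-
      cand[cand$priority_class == "brain_first_priority", , drop = FALSE]
  }
  report$assignments <- assignments
  class(report) <- "marker_report"
  if (!is.null(config$output_dir)) write_marker_report(report)
  report
}

#' @export
print.marker_report <- function(x, ...) {
  cat("marker_report:", nrow(x$per_gene), "gene regions\n")
  print(x$per_gene)
  if (!is.null(x$candidates)) {
    cat("\nranked marker candidates:\n")
    print(x$candidates)
    cat("\nfirst-priority (brain) markers:",
        nrow(x$first_priority), "\n")
  } else {
    cat("\nno eQTL table supplied: run stopped after tagging\n")
  }
  invisible(x)
}

#' Write a marker report to its output directory
#'
#' Emits \code{per_gene.tsv}, \code{candidates.tsv} and
#' \code{first_priority.tsv} (when eQTL annotation ran), per-gene tag and LD
#' tables, and \code{run_log.json} with the config echo and every logged
#' drop. Output is deterministic: re-running an identical config reproduces
#' the files byte for byte.
#'
#' @param report A \code{marker_report} whose config has \code{output_dir}.
#' @return The output directory, invisibly.
#' @export
write_marker_report <- function(report) {
  dir <- report$config$output_dir
  stopifnot(!is.null(dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$per_gene, file.path(dir, "per_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$candidates)) {
    utils::write.table(report$candidates, file.path(dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$first_priority,
                       file.path(dir, "first_priority.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (gene in names(report$assignments)) {
    a <- report$assignments[[gene]]
    write_ld_matrix(a$ld, file.path(dir, paste0(gene, "_ld.tsv")))
    write_tags(a[[a$chosen]], a$ld, file.path(dir, paste0(gene, "_tags.tsv")))
  }
  cfg <- report$config
  cfg$output_dir <- NULL  # keep files location-independent
  jsonlite::write_json(list(config = unclass(cfg), log = report$log),
                       file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
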