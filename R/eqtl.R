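#' Read a significant single-tissue eQTL table
#'
#' Accepts two tab-separated dialects, auto-detected from the header: a
#' minimal generic layout with columns \code{variant_id}, \code{gene_id},
#' \code{tissue}, \code{p_value}, \code{nes}; or a GTEx single-tissue export
#' with recognizable column names (e.g. \code{Variant Id}/\code{SNP Id},
#' \code{Gencode Id}/\code{Gene Symbol}, \code{Tissue}, \code{P-Value},
#' \code{NES}). Header matching is case-insensitive and ignores
#' spaces/dots/dashes. P-values are parsed from scientific notation and must
#' lie in [0, 1].
#'
#' @param path Path to a TSV file with a header.
#' @return A data.frame with columns \code{variant_id}, \code{gene_id},
#'   \code{tissue}, \code{p_value}, \code{nes}.
#' @export
read_eqtl_table <- function(path) {
  if (!file.exists(path)) stop("eQTL table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  norm <- function(x) gsub("[ .\\-]+", "_", tolower(trimws(x)))
  hdr <- norm(names(raw))
  pick <- function(aliases) {
    hit <- which(hdr %in% aliases)
    if (length(hit)) hit[1] else NA_integer_
  }
  cols <- c(
    variant_id = pick(c("variant_id", "snp_id", "variant", "rs_id", "rsid")),
    gene_id = pick(c("gene_id", "gene", "gene_symbol", "gencode_id")),
    tissue = pick("tissue"),
    p_value = pick(c("p_value", "pvalue", "pval", "pval_nominal", "p")),
    nes = pick(c("nes", "slope", "normalized_effect_size")))
  if (anyNA(cols))
    stop("unrecognized eQTL table header: ", paste(names(raw), collapse = ", "),
         ". Recognized layouts: generic (variant_id, gene_id, tissue, ",
         "p_value, nes) or GTEx single-tissue export (Variant Id/SNP Id, ",
         "Gencode Id/Gene Symbol, Tissue, P-Value, NES).")
  out <- data.frame(variant_id = as.character(raw[[cols["variant_id"]]]),
                    gene_id = as.character(raw[[cols["gene_id"]]]),
                    tissue = as.character(raw[[cols["tissue"]]]),
                    p_value = as.numeric(raw[[cols["p_value"]]]),
                    nes = as.numeric(raw[[cols["nes"]]]),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (anyNA(out$p_value) ||
        any(out$p_value < 0 | out$p_value > 1))
      stop("eQTL table validation error: p-values must lie in [0, 1]")
    if (any(is.na(out$tissue) | out$tissue == ""))
      stop("eQTL table validation error: empty tissue name")
  }
  out
}

#' Write an eQTL table in the generic layout
#'
#' @param records eQTL data.frame as from [read_eqtl_table()].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_eqtl_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# normalize a tissue or keyword for substring matching
norm_tissue <- function(x) tolower(gsub("_", " ", x))

#' Filter eQTL records by tissue keywords
#'
#' A record is kept iff its tissue name contains any keyword,
#' case-insensitively and treating underscores as spaces — so the keyword
#' \code{"Blood"} reaches GTEx's \code{"Whole_Blood"} and \code{"Brain"}
#' reaches every \code{"Brain_*"} sub-tissue.
#'
#' @param records eQTL data.frame.
#' @param keywords Non-empty character vector of tissue keywords; default
#'   the ischemic-stroke-relevant set Brain, Artery, Nerve, Blood, Heart.
#' @return The retained rows.
#' @export
filter_tissues <- function(records,
                           keywords = c("Brain", "Artery", "Nerve",
                                        "Blood", "Heart")) {
  stopifnot(length(keywords) > 0)
  tn <- norm_tissue(records$tissue)
  keep <- Reduce(`|`, lapply(norm_tissue(keywords),
                             function(k) grepl(k, tn, fixed = TRUE)),
                 accumulate = FALSE, right = FALSE,
                 init = rep(FALSE, length(tn)))
  records[keep, , drop = FALSE]
}

# parse GTEx-style positional variant ids: chr3_46243200_G_A[_b38]
parse_positional_id <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) >= 4 &&
                 grepl("^[0-9]+$", p[2]) &&
                 all(p[3:4] %in% c("A", "C", "G", "T")), logical(1))
  data.frame(ok = ok,
             chrom = vapply(parts, function(p) sub("^chr", "", p[1]), ""),
             pos = vapply(parts, function(p)
               suppressWarnings(as.numeric(p[2])), numeric(1)),
             a1 = vapply(parts, function(p)
               if (length(p) >= 3) p[3] else NA_character_, ""),
             a2 = vapply(parts, function(p)
               if (length(p) >= 4) p[4] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

# does eQTL variant_id match this tag? exact id first, then positional
# (chrom, pos, {ref, alt}) comparison, allele-order-insensitive
variant_matches <- function(variant_ids, tag_id, tag_meta = NULL) {
  hit <- variant_ids == tag_id
  if (!is.null(tag_meta)) {
    pp <- parse_positional_id(variant_ids)
    pos_hit <- pp$ok &
      pp$chrom == sub("^chr", "", as.character(tag_meta$chrom)) &
      pp$pos == tag_meta$pos &
      ((pp$a1 == tag_meta$ref & pp$a2 == tag_meta$alt) |
         (pp$a1 == tag_meta$alt & pp$a2 == tag_meta$ref))
    hit <- hit | pos_hit
  }
  hit
}

#' Intersect tagSNPs with eQTL records
#'
#' Builds one marker candidate per tag SNP, attaching the cis eQTL records
#' (gene_id must match the target gene) whose variant matches the tag —
#' by identical id, or by (chrom, pos, ref/alt) when positional variant ids
#' and SNP metadata are available. Each candidate receives a priority class:
#' \code{brain_first_priority} if any hit is in a brain tissue,
#' \code{other_tissue} if it has hits but none in brain, \code{no_eqtl}
#' otherwise.
#'
#' @param tags A \code{tag_assignment}.
#' @param records eQTL data.frame, typically already tissue-filtered with
#'   [filter_tissues()].
#' @param gene Target gene symbol or id; only records whose \code{gene_id}
#'   matches (case-insensitively) are considered (cis only).
#' @param snps Optional SNP metadata data.frame (\code{id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}) enabling positional matching.
#' @return A data.frame with one row per tag: \code{snp_id}, \code{gene},
#'   \code{priority_class}, \code{n_hits}, \code{tissues}, \code{best_p},
#'   \code{best_abs_nes}; the matched records are attached as attribute
#'   \code{"hits"} (a named list).
#' @export
intersect_tags_eqtls <- function(tags, records, gene, snps = NULL) {
  stopifnot(inherits(tags, "tag_assignment"))
  cis <- records[tolower(records$gene_id) == tolower(gene), , drop = FALSE]
  hits <- list()
  rows <- lapply(tags$tags, function(tid) {
    meta <- if (!is.null(snps) && tid %in% snps$id)
      snps[snps$id == tid, , drop = FALSE] else NULL
    h <- cis[variant_matches(cis$variant_id, tid, meta), , drop = FALSE]
    hits[[tid]] <<- h
    brain <- nrow(h) > 0 && any(grepl("brain", norm_tissue(h$tissue),
                                      fixed = TRUE))
    data.frame(
      snp_id = tid, gene = gene,
      priority_class = if (nrow(h) == 0) "no_eqtl"
                       else if (brain) "brain_first_priority"
                       else "other_tissue",
      n_hits = nrow(h),
      tissues = paste(sort(unique(h$tissue)), collapse = ","),
      best_p = if (nrow(h)) min(h$p_value) else NA_real_,
      best_abs_nes = if (nrow(h)) max(abs(h$nes)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "hits") <- hits
  out
}

#' Rank marker candidates
#'
#' Deterministic total order implementing the final prioritization:
#' brain-tissue candidates first, then candidates with eQTL evidence in
#' other tissues (where the strongest absolute normalized effect size wins,
#' mirroring the selection of the CCR1 marker by the greatest absolute
#' eQTL statistics), then candidates with no eQTL. Within a class, the order
#' is descending best |NES|, ascending best p-value, then lexicographic
#' SNP id.
#'
#' @param candidates data.frame as from [intersect_tags_eqtls()] (possibly
#'   row-bound over genes).
#' @return The same data.frame, reordered.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0) return(candidates)
  cls <- match(candidates$priority_class,
               c("brain_first_priority", "other_tissue", "no_eqtl"))
  nes <- ifelse(is.na(candidates$best_abs_nes), -Inf, candidates$best_abs_nes)
  p <- ifelse(is.na(candidates$best_p), Inf, candidates$best_p)
  ord <- order(cls, -nes, p, candidates$snp_id)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
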