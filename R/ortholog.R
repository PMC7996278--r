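#' Read a rat-to-human orthologue table
#'
#' Parses a tab-separated orthologue table in the 13-column layout: rat gene
#' symbol, rat chromosome, rat start, rat end, human gene symbol, human
#' chromosome, human start, human end, then five orthology metrics (percent
#' identity target-to-query, percent identity query-to-target, gene-order
#' conservation score, whole-genome alignment coverage, orthology confidence
#' flag). Columns are mapped by position so that any header naming convention
#' in that order is accepted. Rat genes without a human orthologue (human
#' fields empty or marked \code{*}) are retained with the human fields set to
#' \code{NA}; no rows are dropped.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame of class \code{ortholog_table}, one row per rat gene,
#'   with columns \code{rat_gene}, \code{rat_chrom}, \code{rat_start},
#'   \code{rat_end}, \code{human_gene}, \code{human_chrom},
#'   \code{human_start}, \code{human_end}, \code{pct_id_target},
#'   \code{pct_id_query}, \code{goc_score}, \code{wga_coverage},
#'   \code{confidence}.
#' @export
#' @examples
#' tbl <- read_ortholog_table(
#'   system.file("extdata", "ortholog_table.tsv", package = "tagsel"))
#' sum(!is.na(tbl$human_gene))
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stop("orthologue table not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, colClasses = "character",
                      fill = TRUE, strip.white = TRUE,
                      check.names = FALSE, blank.lines.skip = TRUE),
    error = function(e) stop("orthologue table format error in '", path,
                             "': ", conditionMessage(e)))
  if (nrow(raw) == 0 && ncol(raw) == 0)
    stop("orthologue table format error: file '", path,
         "' is empty (no header row)")
  if (ncol(raw) < 8)
    stop("orthologue table format error: expected 13 columns ",
         "(rat gene/chrom/start/end, human gene/chrom/start/end, ",
         "5 orthology metrics); found ", ncol(raw))
  # pad optional metric columns absent from minimal tables
  while (ncol(raw) < 13) raw[[ncol(raw) + 1L]] <- NA_character_
  raw <- raw[, 1:13]
  names(raw) <- c("rat_gene", "rat_chrom", "rat_start", "rat_end",
                  "human_gene", "human_chrom", "human_start", "human_end",
                  "pct_id_target", "pct_id_query", "goc_score",
                  "wga_coverage", "confidence")

  blank <- function(x) is.na(x) | x == "" | x == "*"
  num_or_fail <- function(x, col, allow_na) {
    miss <- blank(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!miss & is.na(out))
    if (length(bad))
      stop("orthologue table parse error in column '", col, "', row ",
           bad[1], " (gene ", raw$rat_gene[bad[1]], "): non-numeric value '",
           x[bad[1]], "'")
    if (!allow_na && any(miss))
      stop("orthologue table parse error in column '", col, "', row ",
           which(miss)[1], ": value missing")
    out[miss] <- NA_real_
    out
  }

  out <- data.frame(
    rat_gene = raw$rat_gene,
    rat_chrom = raw$rat_chrom,
    rat_start = num_or_fail(raw$rat_start, "rat_start", FALSE),
    rat_end = num_or_fail(raw$rat_end, "rat_end", FALSE),
    human_gene = ifelse(blank(raw$human_gene), NA_character_, raw$human_gene),
    human_chrom = ifelse(blank(raw$human_chrom), NA_character_,
                         raw$human_chrom),
    human_start = num_or_fail(raw$human_start, "human_start", TRUE),
    human_end = num_or_fail(raw$human_end, "human_end", TRUE),
    pct_id_target = num_or_fail(raw$pct_id_target, "pct_id_target", TRUE),
    pct_id_query = num_or_fail(raw$pct_id_query, "pct_id_query", TRUE),
    goc_score = num_or_fail(raw$goc_score, "goc_score", TRUE),
    wga_coverage = num_or_fail(raw$wga_coverage, "wga_coverage", TRUE),
    confidence = num_or_fail(raw$confidence, "confidence", TRUE),
    stringsAsFactors = FALSE
  )

  has_h <- !is.na(out$human_gene)
  if (any(out$rat_start >= out$rat_end))
    stop("orthologue table invariant violated: rat_start >= rat_end for ",
         out$rat_gene[which(out$rat_start >= out$rat_end)[1]])
  if (any(has_h & (is.na(out$human_start) | is.na(out$human_end))))
    stop("orthologue table parse error: human orthologue named but ",
         "coordinates missing for ",
         out$rat_gene[which(has_h & is.na(out$human_start))[1]])
  if (any(has_h & out$human_start >= out$human_end))
    stop("orthologue table invariant violated: human_start >= human_end for ",
         out$rat_gene[which(has_h & out$human_start >= out$human_end)[1]])
  pc <- c("pct_id_target", "pct_id_query", "goc_score", "wga_coverage")
  for (col in pc)
    if (any(out[[col]] < 0 | out[[col]] > 100, na.rm = TRUE))
      stop("orthologue table invariant violated: ", col, " outside [0,100]")
  if (any(!out$confidence %in% c(0, 1) & !is.na(out$confidence)))
    stop("orthologue table invariant violated: confidence not in {0,1}")

  class(out) <- c("ortholog_table", "data.frame")
  out
}

#' Write an orthologue table
#'
#' Inverse of [read_ortholog_table()]: absent human orthologues are written
#' with a \code{*} in the human gene column and empty remaining fields, so a
#' write/read round trip reproduces the rows exactly.
#'
#' @param tbl An \code{ortholog_table}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_ortholog_table <- function(tbl, path) {
  out <- as.data.frame(tbl)
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  out[] <- lapply(out, fmt)
  out$human_gene[out$human_gene == ""] <- "*"
  out$human_gene[is.na(tbl$human_gene)] <- "*"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition orthologue rows into accepted and rejected
#'
#' Makes the implicit one-to-one and confidence requirements of a tagging
#' study explicit: rows with no human orthologue are rejected with reason
#' \code{no_orthologue}; when \code{min_confidence} is given, rows whose
#' orthology-confidence flag falls below it are rejected with reason
#' \code{low_confidence}; and when two rat genes map to the same human
#' symbol, all rows involved are rejected with reason
#' \code{duplicate_mapping}. The union of accepted and rejected rows is the
#' input; nothing is dropped silently.
#'
#' @param rows An \code{ortholog_table} from [read_ortholog_table()].
#' @param min_confidence Optional minimum confidence flag (0 or 1). \code{NULL}
#'   (default) disables the confidence check.
#' @return A list with elements \code{accepted} (an \code{ortholog_table})
#'   and \code{rejected} (the same columns plus a \code{reason} column).
#' @export
validate_orthologs <- function(rows, min_confidence = NULL) {
  stopifnot(is.data.frame(rows))
  reason <- rep(NA_character_, nrow(rows))
  reason[is.na(rows$human_gene)] <- "no_orthologue"
  if (!is.null(min_confidence)) {
    low <- !is.na(rows$human_gene) &
      (is.na(rows$confidence) | rows$confidence < min_confidence)
    reason[low & is.na(reason)] <- "low_confidence"
  }
  cand <- is.na(reason)
  dup_sym <- rows$human_gene[cand][duplicated(rows$human_gene[cand])]
  dup <- cand & rows$human_gene %in% dup_sym
  reason[dup] <- "duplicate_mapping"

  rejected <- rows[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  accepted <- rows[is.na(reason), , drop = FALSE]
  class(accepted) <- class(rows)
  rownames(accepted) <- rownames(rejected) <- NULL
  list(accepted = accepted, rejected = as.data.frame(rejected))
}

#' Build a flanked region around a human orthologue
#'
#' Extends the human gene coordinates by a symmetric flank (5000 bp by
#' default, covering the 5' and 3' regulatory neighbourhood), clamping the
#' start at position 1. Coordinates are 1-based inclusive.
#'
#' @param row A single-row \code{ortholog_table} (or any data.frame row with
#'   \code{human_gene}, \code{human_chrom}, \code{human_start},
#'   \code{human_end}).
#' @param flank Flank length in base pairs on each side.
#' @return A one-row data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}.
#' @export
#' @examples
#' tbl <- read_ortholog_table(
#'   system.file("extdata", "ortholog_table.tsv", package = "tagsel"))
#' apply_flanks(tbl[tbl$rat_gene == "Ptx3", ], flank = 5000)
apply_flanks <- function(row, flank = 5000) {
  stopifnot(is.data.frame(row), nrow(row) == 1, flank >= 0)
  if (is.na(row$human_gene))
    stop("rat gene ", row$rat_gene, " has no human orthologue; ",
         "no region can be built")
  data.frame(chrom = row$human_chrom,
             start = max(1, row$human_start - flank),
             end = row$human_end + flank,
             name = row$human_gene,
             stringsAsFactors = FALSE)
}

#' Flanked regions for every mapped orthologue in a table
#'
#' @param rows An \code{ortholog_table}; rows without a human orthologue are
#'   skipped.
#' @param flank Flank length in base pairs.
#' @return A data.frame of regions (\code{chrom}, \code{start}, \code{end},
#'   \code{name}).
#' @export
gene_regions <- function(rows, flank = 5000) {
  mapped <- rows[!is.na(rows$human_gene), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(mapped)), function(i)
    apply_flanks(mapped[i, , drop = FALSE], flank)))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character())
  rownames(out) <- NULL
  out
}

#' Write regions as BED
#'
#' Converts 1-based inclusive regions to BED's 0-based half-open convention
#' at this writer boundary only.
#'
#' @param regions A data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{name} (1-based inclusive).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom,
                    format(regions$start - 1, scientific = FALSE, trim = TRUE),
                    format(regions$end, scientific = FALSE, trim = TRUE),
                    regions$name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
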