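# capture comparisons tolerate tiny floating-point shortfall (an exact
# rational r2 like 1/2 may be stored a few ulp below the threshold)
R2_EPS <- 1e-9

# Deterministic SNP preference order used by all tie-breaks:
# higher MAF first, then lower genomic position, then lexicographic id.
snp_preference_order <- function(ld, candidates) {
  maf <- if (!is.null(ld$maf)) ld$maf[candidates] else rep(0, length(candidates))
  pos <- if (!is.null(ld$pos)) ld$pos[candidates] else rep(0, length(candidates))
  ids <- ld$snp_ids[candidates]
  candidates[order(-maf, pos, ids)]
}

new_tag_assignment <- function(tags, captured, method, threshold, ld,
                               te_convention = "captured_per_tag") {
  obj <- structure(list(tags = ld$snp_ids[tags],
                        captured = stats::setNames(
                          lapply(captured, function(s) ld$snp_ids[s]),
                          ld$snp_ids[tags]),
                        method = method, threshold = threshold,
                        n_snps = length(ld$snp_ids),
                        te_convention = te_convention),
                   class = "tag_assignment")
  obj$te <- tagging_effectiveness(obj, convention = te_convention)
  obj$mean_capture_r2 <- mean_capture_r2(obj, ld)
  obj
}

#' @export
print.tag_assignment <- function(x, ...) {
  cat("tag_assignment (", x$method, "): ", length(x$tags), " tags for ",
      x$n_snps, " SNPs at r2 >= ", x$threshold, "\n", sep = "")
  cat("  TE (", x$te_convention, ") = ", round(x$te, 4),
      "; mean capture r2 = ", round(x$mean_capture_r2, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tag_assignment <- function(object, ...) {
  data.frame(method = object$method, threshold = object$threshold,
             n_snps = object$n_snps, n_tags = length(object$tags),
             te = object$te, mean_capture_r2 = object$mean_capture_r2,
             te_convention = object$te_convention,
             stringsAsFactors = FALSE)
}

#' Greedy set-cover tagging
#'
#' Pairwise tagging in the style of Haploview's Tagger: iteratively select
#' the SNP that captures (r2 >= threshold) the largest number of
#' yet-uncovered SNPs, until every SNP is covered. Ties between equally
#' covering SNPs are broken deterministically by higher MAF, then lower
#' genomic position, then lexicographic id. A SNP capturable by several
#' chosen tags is assigned to the tag with the highest r2 to it, ties going
#' to the earlier-chosen tag; every tag captures itself.
#'
#' @param ld An \code{ld_matrix}.
#' @param threshold r-squared capture threshold in (0, 1]; default 0.8.
#' @param te_convention TE convention recorded on the result, see
#'   [tagging_effectiveness()].
#' @return A \code{tag_assignment} with \code{method = "greedy"}.
#' @export
greedy_tag <- function(ld, threshold = 0.8,
                       te_convention = c("captured_per_tag",
                                         "tags_per_captured")) {
  te_convention <- match.arg(te_convention)
  stopifnot(inherits(ld, "ld_matrix"), threshold > 0, threshold <= 1)
  m <- length(ld$snp_ids)
  cover <- ld$r2 >= threshold - R2_EPS
  diag(cover) <- TRUE  # a SNP always captures itself
  uncovered <- rep(TRUE, m)
  tags <- integer()
  while (any(uncovered)) {
    gain <- colSums(cover & uncovered)
    best <- which(gain == max(gain))
    best <- snp_preference_order(ld, best)[1]
    tags <- c(tags, best)
    uncovered[cover[, best]] <- FALSE
  }
  # final assignment: each SNP to the capturing tag with highest r2,
  # ties to the earlier-chosen tag; tags always belong to themselves
  assigned <- integer(m)
  for (s in seq_len(m)) {
    if (s %in% tags) { assigned[s] <- s; next }
    capt <- tags[cover[s, tags]]
    r2s <- ld$r2[s, capt]
    assigned[s] <- capt[which.max(r2s)]  # which.max: first (earlier) on ties
  }
  captured <- lapply(tags, function(t) which(assigned == t))
  new_tag_assignment(tags, captured, "greedy", threshold, ld, te_convention)
}

#' Complete-linkage clustering tagging
#'
#' Minimax clustering tagging in the style of CLUSTAG: agglomerative
#' complete-linkage clustering on the distance 1 - r2, cut at height
#' 1 - threshold, so that every pair of SNPs inside a cluster satisfies
#' r2 >= threshold. Clusters are disjoint and exhaustive. Within each
#' cluster the tag is the minimax SNP — the one minimizing its maximum
#' 1 - r2 to the other members — with ties broken by higher MAF, lower
#' position, lexicographic id.
#'
#' @inheritParams greedy_tag
#' @return A \code{tag_assignment} with \code{method = "cluster"}.
#' @export
cluster_tag <- function(ld, threshold = 0.8,
                        te_convention = c("captured_per_tag",
                                          "tags_per_captured")) {
  te_convention <- match.arg(te_convention)
  stopifnot(inherits(ld, "ld_matrix"), threshold > 0, threshold <= 1)
  m <- length(ld$snp_ids)
  if (m == 1) {
    return(new_tag_assignment(1L, list(1L), "cluster", threshold, ld,
                              te_convention))
  }
  d <- stats::as.dist(1 - ld$r2)
  hc <- stats::hclust(d, method = "complete")
  # small epsilon keeps pairs at exactly r2 == threshold together
  groups <- stats::cutree(hc, h = 1 - threshold + R2_EPS)
  tags <- integer(); captured <- list()
  for (g in sort(unique(groups))) {
    members <- which(groups == g)
    if (length(members) == 1) {
      tag <- members
    } else {
      sub <- 1 - ld$r2[members, members, drop = FALSE]
      diag(sub) <- 0
      worst <- apply(sub, 1, max)
      best <- members[worst == min(worst)]
      tag <- snp_preference_order(ld, best)[1]
    }
    tags <- c(tags, tag)
    captured <- c(captured, list(members))
  }
  new_tag_assignment(tags, captured, "cluster", threshold, ld, te_convention)
}

#' Tagging effectiveness
#'
#' Run-level efficiency of a tagging result. Under the default
#' \code{captured_per_tag} convention, TE is the number of SNPs captured
#' divided by the number of tags (higher is better; a run where every SNP is
#' its own tag scores 1). The literal inverse, \code{tags_per_captured}, is
#' available as the alternative convention.
#'
#' @param assignment A \code{tag_assignment}.
#' @param convention \code{"captured_per_tag"} (default) or
#'   \code{"tags_per_captured"}.
#' @return A positive real number.
#' @export
tagging_effectiveness <- function(assignment,
                                  convention = c("captured_per_tag",
                                                 "tags_per_captured")) {
  convention <- match.arg(convention)
  n_tags <- length(assignment$tags)
  if (n_tags == 0) stop("tagging effectiveness undefined: zero tags")
  n_captured <- length(unique(unlist(assignment$captured)))
  if (convention == "captured_per_tag") n_captured / n_tags
  else n_tags / n_captured
}

#' Mean capture r-squared
#'
#' The mean r2 between each non-tag captured SNP and its assigned tag; 1.0
#' when every SNP is its own tag (nothing is proxied).
#'
#' @param assignment A \code{tag_assignment}.
#' @param ld The \code{ld_matrix} the assignment was computed from.
#' @return A value in [0, 1].
#' @export
mean_capture_r2 <- function(assignment, ld) {
  vals <- numeric()
  for (t in names(assignment$captured)) {
    members <- setdiff(assignment$captured[[t]], t)
    if (length(members))
      vals <- c(vals, ld$r2[members, t])
  }
  if (length(vals) == 0) return(1.0)
  mean(vals)
}

#' Exhaustive minimum tag count
#'
#' Brute-force oracle: the size of the smallest SNP subset such that every
#' SNP has r2 >= threshold with some subset member (a SNP covers itself).
#' Exhaustive subset search, refused above 20 SNPs.
#'
#' @inheritParams greedy_tag
#' @param max_snps Refusal cap on the exhaustive search.
#' @return The minimum number of tags (integer).
#' @export
brute_force_min_tags <- function(ld, threshold = 0.8, max_snps = 20) {
  m <- length(ld$snp_ids)
  if (m > max_snps)
    stop("brute_force_min_tags refuses ", m, " SNPs (cap ", max_snps, ")")
  cover <- ld$r2 >= threshold - R2_EPS
  diag(cover) <- TRUE
  for (k in seq_len(m)) {
    subsets <- utils::combn(m, k)
    for (c_i in seq_len(ncol(subsets))) {
      sel <- subsets[, c_i]
      if (all(rowSums(cover[, sel, drop = FALSE]) > 0)) return(k)
    }
  }
  m
}

#' Run and compare both tagging algorithms
#'
#' Runs greedy set-cover and complete-linkage clustering on the same LD
#' matrix and threshold, and tabulates tag count, tagging effectiveness and
#' mean capture r2 per method. Deterministic given the input.
#'
#' @inheritParams greedy_tag
#' @return A list with elements \code{greedy} and \code{cluster} (the two
#'   \code{tag_assignment}s) and \code{summary} (a two-row data.frame).
#' @export
compare_methods <- function(ld, threshold = 0.8,
                            te_convention = c("captured_per_tag",
                                              "tags_per_captured")) {
  te_convention <- match.arg(te_convention)
  g <- greedy_tag(ld, threshold, te_convention)
  cl <- cluster_tag(ld, threshold, te_convention)
  list(greedy = g, cluster = cl,
       summary = rbind(summary(g), summary(cl)))
}

#' Write a tag assignment as TSV
#'
#' One row per tag: tag id, comma-separated captured ids, comma-separated
#' capture r2 values.
#'
#' @param assignment A \code{tag_assignment}.
#' @param ld The matching \code{ld_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tags <- function(assignment, ld, path) {
  rows <- lapply(names(assignment$captured), function(t) {
    members <- assignment$captured[[t]]
    data.frame(tag = t,
               captured = paste(members, collapse = ","),
               capture_r2 = paste(
                 formatC(ld$r2[members, t], digits = 6, format = "g"),
                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
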