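#' Per-sample alpha diversity
#'
#' Richness counts taxa with at least one read; Shannon entropy uses the
#' natural logarithm; evenness is Pielou's J = H / ln(richness), undefined
#' (NA) below 2 taxa. Counts are used as observed — no rarefaction — so any
#' depth normalization must happen upstream (see [filter_min_reads()]).
#'
#' @param table an [otu_table()].
#' @return data frame: `sample_id`, `richness`, `shannon`, `pielou`.
#' @export
alpha_diversity <- function(table) {
  m <- count_matrix(table)
  richness <- colSums(m >= 1)
  shannon <- vegan::diversity(t(m), index = "shannon")
  pielou <- ifelse(richness >= 2, shannon / log(richness), NA_real_)
  data.frame(sample_id = colnames(m), richness = as.integer(richness),
             shannon = unname(shannon), pielou = unname(pielou),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Thin, validated wrapper around [stats::kruskal.test()] (tie-corrected H,
#' chi-square p with k - 1 df). All-identical values are the degenerate
#' no-signal case: H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; every group must be non-empty.
#' @return list: `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- if (is.factor(groups)) groups else factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0))
    stop("empty group(s): ",
         paste(levels(g)[table(g) == 0], collapse = ", "))
  df <- nlevels(g) - 1L
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = df))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg control
#'
#' One rank-sum test per unordered pair of groups, exact when both groups
#' have <= 8 observations (and no ties), the tie-corrected normal
#' approximation otherwise; the BH step-up adjustment is applied across all
#' pairs as one family.
#'
#' @inheritParams kruskal_wallis
#' @return data frame: `group1`, `group2`, `W`, `p`, `p_adj`.
#' @export
pairwise_wilcoxon_bh <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  prs <- utils::combn(levels(g), 2L)
  res <- apply(prs, 2L, function(pr) {
    x <- values[g == pr[1L]]
    y <- values[g == pr[2L]]
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, exact = length(x) <= 8 && length(y) <= 8, correct = TRUE))
    c(W = unname(wt$statistic), p = wt$p.value)
  })
  data.frame(group1 = prs[1L, ], group2 = prs[2L, ],
             W = res["W", ], p = res["p", ],
             p_adj = bh_adjust(res["p", ]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Genus-level differential abundance across groups
#'
#' Collapses OTU counts by genus (sum), converts to relative abundance
#' against whole-sample totals, runs a Kruskal-Wallis test per genus across
#' the groups, and BH-adjusts across genera. `direction` names the group
#' with the highest median relative abundance.
#'
#' @param table an [otu_table()].
#' @param taxonomy named character vector mapping OTU IDs to genus names;
#'   OTUs without an assignment are dropped with a message.
#' @param metadata data frame with `sample_id` and a grouping column.
#' @param group_col name of the grouping column (default `"group"`).
#' @return data frame ordered by adjusted p: `genus`, `H`, `p`, `p_adj`,
#'   `direction`.
#' @export
genus_differential_abundance <- function(table, taxonomy, metadata,
                                         group_col = "group") {
  if (!length(taxonomy)) stop("empty taxonomy map")
  covered <- intersect(rownames(table), names(taxonomy))
  if (!length(covered)) stop("taxonomy covers no OTUs in the table")
  dropped <- setdiff(rownames(table), covered)
  if (length(dropped))
    message(length(dropped), " OTU(s) without genus assignment dropped")
  gm <- rowsum(count_matrix(table)[covered, , drop = FALSE],
               taxonomy[covered])
  empty <- rowSums(gm) == 0
  if (any(empty)) {
    message("zero-total genus(era) skipped: ",
            paste(rownames(gm)[empty], collapse = ", "))
    gm <- gm[!empty, , drop = FALSE]
  }
  rel <- sweep(gm, 2L, colSums(table), "/")
  groups <- metadata[[group_col]][match(colnames(table), metadata$sample_id)]
  if (anyNA(groups)) stop("metadata lacks entries for some samples")
  res <- t(vapply(seq_len(nrow(rel)), function(i) {
    kw <- kruskal_wallis(rel[i, ], groups)
    c(H = kw$H, p = kw$p)
  }, numeric(2)))
  med <- t(apply(rel, 1L, function(v) tapply(v, groups, stats::median)))
  out <- data.frame(genus = rownames(rel), H = res[, "H"], p = res[, "p"],
                    p_adj = bh_adjust(res[, "p"]),
                    direction = colnames(med)[max.col(med, ties.method = "first")],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_adj, out$p, out$genus), , drop = FALSE]
}
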