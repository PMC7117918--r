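#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' @param tree an [ape::phylo] with >= 2 tips and non-negative branch
#'   lengths.
#' @return symmetric matrix of tip-to-tip path-length distances.
#' @export
cophenetic_matrix <- function(tree) {
  if (length(tree$tip.label) < 2) stop("tree needs at least 2 tips")
  validate_tree(tree)
  ape::cophenetic.phylo(tree)
}

#' Mean pairwise distance among present taxa
#'
#' Presence-based (unweighted): the mean cophenetic distance over all
#' unordered pairs of taxa in the community. Undefined (NA) below 2 taxa.
#'
#' @param taxa_present character vector of taxa.
#' @param dist cophenetic distance matrix covering them.
#' @return numeric scalar, or `NA_real_` when fewer than 2 taxa.
#' @export
mpd <- function(taxa_present, dist) {
  taxa <- unique(as.character(taxa_present))
  miss <- setdiff(taxa, rownames(dist))
  if (length(miss)) stop("taxa absent from distance matrix: ",
                         paste(miss, collapse = ", "))
  if (length(taxa) < 2) return(NA_real_)
  d <- dist[taxa, taxa]
  mean(d[upper.tri(d)])
}

#' Mean nearest-taxon distance among present taxa
#'
#' The mean, over present taxa, of the distance to the closest other
#' present taxon.
#'
#' @inheritParams mpd
#' @return numeric scalar, or `NA_real_` when fewer than 2 taxa.
#' @export
mntd <- function(taxa_present, dist) {
  taxa <- unique(as.character(taxa_present))
  miss <- setdiff(taxa, rownames(dist))
  if (length(miss)) stop("taxa absent from distance matrix: ",
                         paste(miss, collapse = ", "))
  if (length(taxa) < 2) return(NA_real_)
  d <- dist[taxa, taxa]
  diag(d) <- Inf
  mean(row_mins(d))
}

# fast row minima via max.col on the negated matrix
row_mins <- function(d) {
  d[cbind(seq_len(nrow(d)), max.col(-d, ties.method = "first"))]
}

#' Standardized effect sizes of phylogenetic dispersion (NRI/NTI)
#'
#' Per sample, compares the observed MPD or MNTD of the taxa present
#' (count >= 1) with a null distribution obtained by redrawing the same
#' number of taxa uniformly without replacement from the table's full taxon
#' pool (the taxa observed anywhere in the table), `runs` times. The
#' standardized effect size is `ses = (obs - null_mean) / null_sd`; the
#' conventional indices negate it — `NRI = -SES(MPD)`, `NTI = -SES(MNTD)` —
#' so positive values indicate phylogenetic clustering (habitat filtering)
#' and negative values overdispersion. Communities assembled neutrally
#' should sit near zero. Both the signed `ses` and the negated `index` are
#' reported to leave no sign ambiguity.
#'
#' Null draws depend only on community richness, so the null distribution
#' is computed once per distinct richness value and shared across samples
#' (identical in law, and deterministic under `seed`).
#'
#' @param table an [otu_table()]; every taxon with a nonzero count must be
#'   a tip of `tree`.
#' @param tree an [ape::phylo] phylogeny.
#' @param metric `"MPD"` or `"MNTD"`.
#' @param runs number of null draws (default 999).
#' @param seed integer seed; same seed, bit-identical output.
#' @return data frame, one row per sample: `sample_id`, `metric`,
#'   `n_taxa`, `obs`, `null_mean`, `null_sd`, `ses`, `index`, `runs`,
#'   `defined`, `reason`. `defined` is `FALSE` (with `ses`/`index` NA) for
#'   samples with < 2 taxa or a degenerate null (`null_sd = 0`, e.g. a
#'   sample containing the entire pool).
#' @export
ses_dispersion <- function(table, tree, metric = c("MPD", "MNTD"),
                           runs = 999, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(runs >= 1)
  pres <- count_matrix(table) >= 1
  pool <- rownames(table)[rowSums(pres) > 0]
  check_taxa_on_tree(pool, tree)
  D <- cophenetic_matrix(tree)[pool, pool, drop = FALSE]
  P <- length(pool)
  metric_fun <- if (metric == "MPD") {
    function(i) { d <- D[i, i]; mean(d[upper.tri(d)]) }
  } else {
    function(i) { d <- D[i, i]; diag(d) <- Inf; mean(row_mins(d)) }
  }
  n_taxa <- colSums(pres[pool, , drop = FALSE])
  out <- data.frame(sample_id = colnames(table), metric = metric,
                    n_taxa = as.integer(n_taxa), obs = NA_real_,
                    null_mean = NA_real_, null_sd = NA_real_,
                    ses = NA_real_, index = NA_real_, runs = as.integer(runs),
                    defined = FALSE, reason = "", stringsAsFactors = FALSE)
  with_seed(seed, {
    null_cache <- list()
    for (j in seq_len(ncol(table))) {
      n <- n_taxa[j]
      if (n < 2) { out$reason[j] <- "too few taxa"; next }
      idx <- which(pres[pool, j])
      out$obs[j] <- metric_fun(idx)
      key <- as.character(n)
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- replicate(runs, metric_fun(sample.int(P, n)))
      nv <- null_cache[[key]]
      out$null_mean[j] <- mean(nv)
      out$null_sd[j] <- stats::sd(nv)
      if (out$null_sd[j] == 0) { out$reason[j] <- "degenerate null"; next }
      out$ses[j] <- (out$obs[j] - out$null_mean[j]) / out$null_sd[j]
      out$index[j] <- -out$ses[j]
      out$defined[j] <- TRUE
    }
  })
  out
}

#' Compare dispersion indices across sample groups
#'
#' Kruskal-Wallis across all groups, then pairwise Wilcoxon rank-sum tests
#' with Benjamini-Hochberg adjustment, on the (negated) index values of the
#' defined samples.
#'
#' @param results a [ses_dispersion()] data frame.
#' @param metadata data frame with `sample_id` and a grouping column.
#' @param group_col name of the grouping column (default `"group"`).
#' @param value which column to compare: `"index"` (default) or `"ses"`.
#' @return list: `kruskal` (H, p, df), `pairwise` (group1, group2, W, p,
#'   p_adj), `n_per_group`.
#' @export
compare_dispersion <- function(results, metadata, group_col = "group",
                               value = c("index", "ses")) {
  value <- match.arg(value)
  df <- merge(results, metadata[, c("sample_id", group_col)], by = "sample_id")
  df$group <- df[[group_col]]
  n_def <- tapply(df$defined, df$group, sum)
  drop_g <- names(n_def)[n_def < 2]
  if (length(drop_g)) {
    warning("group(s) with < 2 defined samples excluded: ",
            paste(drop_g, collapse = ", "))
    df <- df[!df$group %in% drop_g, , drop = FALSE]
  }
  df <- df[df$defined, , drop = FALSE]
  if (length(unique(df$group)) < 2)
    stop("need at least 2 groups with >= 2 defined samples")
  list(kruskal = kruskal_wallis(df[[value]], df$group),
       pairwise = pairwise_wilcoxon_bh(df[[value]], df$group),
       n_per_group = table(df$group))
}
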