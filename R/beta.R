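#' Generalized UniFrac distances between samples
#'
#' For each pair of samples (A, B) and each branch b with length L_b, let
#' p_A, p_B be the summed relative abundances of the tips descending from
#' b. The generalized UniFrac distance with weighting exponent `alpha` is
#'
#'   d = sum_b L_b (p_A + p_B)^alpha |p_A - p_B| / (p_A + p_B)
#'       / sum_b L_b (p_A + p_B)^alpha
#'
#' over branches with p_A + p_B > 0. `alpha = 1` reproduces the
#' weighted-normalized UniFrac; `alpha = 0.5` (the default) damps the
#' dominance of highly abundant lineages. Branch-length rescaling cancels.
#'
#' @param table an [otu_table()]; all taxa must be tips of `tree` and all
#'   samples must have positive totals.
#' @param tree an [ape::phylo] phylogeny (tips may be a superset of the
#'   table's taxa; extra tips carry zero abundance).
#' @param alpha weighting exponent in \[0, 1\].
#' @return symmetric distance matrix with entries in \[0, 1\], zero
#'   diagonal, sample IDs as dimnames.
#' @export
gunifrac <- function(table, tree, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  check_taxa_on_tree(rownames(table), tree)
  rel <- to_relative_abundance(table)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nsamp <- ncol(rel)
  cum <- matrix(0, ntip + tr$Nnode, nsamp)
  hit <- match(rownames(rel), tr$tip.label)
  cum[hit, ] <- rel
  for (e in seq_len(nrow(tr$edge)))  # postorder: children before parents
    cum[tr$edge[e, 1L], ] <- cum[tr$edge[e, 1L], ] + cum[tr$edge[e, 2L], ]
  B <- cum[tr$edge[, 2L], , drop = FALSE]  # branch abundance per sample
  L <- tr$edge.length
  D <- matrix(0, nsamp, nsamp,
              dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(nsamp - 1L)) {
    pa <- B[, i]
    for (j in seq((i + 1L), nsamp)) {
      pb <- B[, j]
      s <- pa + pb
      k <- s > 0
      w <- L[k] * s[k]^alpha
      den <- sum(w)
      D[i, j] <- D[j, i] <-
        if (den > 0) sum(w * abs(pa[k] - pb[k]) / s[k]) / den else 0
    }
  }
  pmin(pmax(D, 0), 1)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix via the Gower/Huygens
#' decomposition of squared distances: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within` summed per group analogously, and
#' `F = (SS_between / (k - 1)) / (SS_within / (n - k))`. Significance comes
#' from seeded random label permutations with the +1 correction, or from
#' exhaustive enumeration of all distinct label assignments when
#' `exhaustive = TRUE` (then p is the exact fraction of assignments, the
#' observed one included, with F at least as large).
#'
#' @param dist symmetric distance matrix (or `dist`).
#' @param groups group labels, one per sample; >= 2 groups, n >= 4.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all distinct assignments instead (error
#'   above 20000 assignments).
#' @return a `permanova_fit` list: `pseudo_F`, `R2`, `p`, `n_perm`,
#'   `seed`, `method`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  dmat <- as.matrix(dist)
  n <- nrow(dmat)
  g <- factor(groups)
  stopifnot(length(g) == n, n >= 4)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("empty group(s) in design")
  d2 <- dmat^2
  k <- nlevels(g)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(gg) {
    s <- 0
    for (lv in levels(gg)) {
      i <- which(gg == lv)
      s <- s + sum(d2[i, i]) / (2 * length(i))
    }
    s
  }
  f_stat <- function(gg) {
    w <- ss_within(gg)
    ((ss_total - w) / (k - 1)) / (w / (n - k))
  }
  F_obs <- f_stat(g)
  if (exhaustive) {
    perms <- multiset_permutations(as.character(g))
    Fs <- vapply(perms, function(v) f_stat(factor(v, levels = levels(g))),
                 numeric(1))
    p <- mean(Fs >= F_obs)
    n_perm_used <- length(perms)
    method <- "exhaustive"
  } else {
    Fs <- with_seed(seed, replicate(n_perm, f_stat(sample(g))))
    p <- (1 + sum(Fs >= F_obs)) / (1 + n_perm)
    n_perm_used <- n_perm
    method <- "permutation"
  }
  structure(list(pseudo_F = F_obs,
                 R2 = (ss_total - ss_within(g)) / ss_total,
                 p = p, n_perm = n_perm_used, seed = seed, method = method),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations): pseudo-F = %.4g, R2 = %.4f, p = %.4g\n",
              x$method, x$n_perm, x$pseudo_F, x$R2, x$p))
  invisible(x)
}

# all distinct arrangements of a label multiset (small n only)
multiset_permutations <- function(labels, limit = 20000) {
  cnt <- table(labels)
  total <- factorial(length(labels)) / prod(factorial(cnt))
  if (total > limit)
    stop("too many distinct assignments (", format(total), ") for exhaustive enumeration")
  gen <- function(remaining) {
    if (sum(remaining) == 0) return(list(character(0)))
    out <- list()
    for (lv in names(remaining)[remaining > 0]) {
      r2 <- remaining
      r2[lv] <- r2[lv] - 1
      for (tail in gen(r2)) out[[length(out) + 1L]] <- c(lv, tail)
    }
    out
  }
  gen(stats::setNames(as.integer(cnt), names(cnt)))
}

#' Classical principal coordinates analysis
#'
#' Classical scaling (double-centred -d^2/2 via [stats::cmdscale()]) of a
#' distance matrix. Coordinates are returned for the top `k` positive
#' eigenvalues; negative eigenvalues (from non-Euclidean distances) are
#' reported, not corrected.
#'
#' @param dist symmetric distance matrix (or `dist`).
#' @param k number of axes requested (default 2); fewer are returned with
#'   a warning when fewer positive eigenvalues exist.
#' @return list: `points` (samples x axes), `eig` (all eigenvalues),
#'   `share` (per-axis fraction of the positive-eigenvalue sum),
#'   `negative_eig`.
#' @export
pcoa_ord <- function(dist, k = 2) {
  dmat <- as.matrix(dist)
  n <- nrow(dmat)
  stopifnot(n >= 2, k >= 1)
  sc <- stats::cmdscale(stats::as.dist(dmat), k = n - 1L, eig = TRUE)
  eig <- sc$eig
  tol <- sqrt(.Machine$double.eps) * max(abs(eig), 1e-300)
  npos <- sum(eig > tol)
  if (k > npos) {
    warning("only ", npos, " positive-eigenvalue axes available")
    k <- npos
  }
  pts <- sc$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(k))
  rownames(pts) <- rownames(dmat)
  list(points = pts,
       eig = eig,
       share = (pmax(eig, 0) / sum(pmax(eig, 0)))[seq_len(k)],
       negative_eig = eig[eig < -tol])
}
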