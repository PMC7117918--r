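#' Configuration for a synthetic community-assembly study
#'
#' Describes a source metacommunity sampled by faithful environmental
#' replicates, a set of local (target) communities assembled neutrally from
#' it with migration-size product `Nm`, and optional controlled departures
#' from neutrality: "above" taxa forced into every target sample at a fixed
#' relative abundance (the host-selected signature), "below" taxa capped to
#' a low occurrence (selected-against), and a clade-restricted sample group
#' (phylogenetic filtering).
#'
#' @param S number of taxa (>= 2).
#' @param n_source,n_target numbers of source and target samples.
#' @param N mean reads per sample; per-sample totals are jittered uniformly
#'   by `depth_jitter`.
#' @param Nm positive migration-size product of the generating model.
#' @param meta_dist metacommunity abundance law: `list(type = "lognormal",
#'   meanlog, sdlog)` or `list(type = "geometric", k)`.
#' @param selected_above list of `list(taxon = i, rel_abundance = a)` specs.
#' @param selected_below list of `list(taxon = i, occupancy = q)` specs,
#'   `q` in \[0, 1).
#' @param clade_filter optional `list(fraction, n_samples, label)`: simulate
#'   `n_samples` extra samples drawn only from a random monophyletic clade
#'   containing `fraction` of the taxa.
#' @param n_shallow number of extra low-depth target samples (totals drawn
#'   uniformly in \[1000, 7999\]) emulating samples that fail the 8000-read
#'   depth filter.
#' @param depth_jitter half-width of the uniform relative jitter on sample
#'   totals (default 0.2, i.e. totals in \[0.8 N, 1.2 N\]).
#' @param seed integer master seed; every stage derives a sub-seed from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(S = 300, n_source = 10, n_target = 50, N = 10000,
                       Nm = 1000,
                       meta_dist = list(type = "lognormal", meanlog = 0, sdlog = 1),
                       selected_above = list(), selected_below = list(),
                       clade_filter = NULL, n_shallow = 0,
                       depth_jitter = 0.2, seed = 1) {
  stopifnot(S >= 2, Nm > 0, n_source >= 1, n_target >= 1, N >= 1,
            depth_jitter >= 0, depth_jitter < 1, n_shallow >= 0)
  ia <- vapply(selected_above, function(s) as.integer(s$taxon), integer(1))
  ib <- vapply(selected_below, function(s) as.integer(s$taxon), integer(1))
  if (length(intersect(ia, ib)))
    stop("selected_above and selected_below must be disjoint")
  if (length(c(ia, ib)) && (any(c(ia, ib) < 1) || any(c(ia, ib) > S)))
    stop("selected taxon index out of range")
  structure(list(S = S, n_source = n_source, n_target = n_target, N = N,
                 Nm = Nm, meta_dist = meta_dist,
                 selected_above = selected_above,
                 selected_below = selected_below,
                 clade_filter = clade_filter, n_shallow = n_shallow,
                 depth_jitter = depth_jitter, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a metacommunity relative-abundance vector
#'
#' @param S number of taxa (>= 2).
#' @param meta_dist abundance law, see [sim_config()].
#' @param seed integer seed (ignored by the deterministic geometric series).
#' @return numeric vector of length `S`, strictly positive, summing to 1,
#'   sorted in decreasing order.
#' @export
#' @examples
#' make_metacommunity(2, list(type = "geometric", k = 0.5))  # 2/3, 1/3
make_metacommunity <- function(S,
                               meta_dist = list(type = "lognormal",
                                                meanlog = 0, sdlog = 1),
                               seed = NULL) {
  if (S < 2) stop("need at least 2 taxa")
  w <- switch(meta_dist$type,
    lognormal = with_seed(seed,
      stats::rlnorm(S, meta_dist$meanlog, meta_dist$sdlog)),
    geometric = {
      k <- meta_dist$k
      stopifnot(k > 0, k <= 1)
      k^(seq_len(S) - 1)
    },
    stop("unknown meta_dist type: ", meta_dist$type)
  )
  p <- sort(w, decreasing = TRUE)
  p / sum(p)
}

#' Simulate neutrally assembled local communities
#'
#' Per sample, a community composition is drawn from Dirichlet(`Nm` * `p`)
#' — so each taxon's marginal relative abundance is exactly
#' Beta(`Nm` p_i, `Nm` (1 - p_i)), the distribution the neutral model fits —
#' and reads are then drawn multinomially at the requested depth.
#'
#' @param p metacommunity relative abundances (positive, summing to 1).
#' @param Nm positive migration-size product; large values give faithful
#'   copies of `p`, small values strong drift.
#' @param sample_totals integer vector of per-sample read depths.
#' @param seed integer seed; same seed, same table.
#' @param taxon_ids,sample_ids optional ID vectors.
#' @return an [otu_table()] whose column sums equal `sample_totals`.
#' @export
simulate_neutral_samples <- function(p, Nm, sample_totals, seed = NULL,
                                     taxon_ids = sprintf("OTU_%04d", seq_along(p)),
                                     sample_ids = sprintf("SAMPLE_%03d", seq_along(sample_totals))) {
  stopifnot(Nm > 0, all(p > 0), abs(sum(p) - 1) < 1e-9,
            all(sample_totals >= 1))
  S <- length(p)
  counts <- with_seed(seed, vapply(sample_totals, function(n) {
    g <- stats::rgamma(S, shape = Nm * p)
    if (sum(g) <= 0) g <- p  # all-underflow guard at extreme drift
    drop(stats::rmultinom(1L, size = n, prob = g))
  }, numeric(S)))
  dimnames(counts) <- list(taxon_ids, sample_ids)
  otu_table(counts)
}

#' Overwrite selected taxa with non-neutral occurrence patterns
#'
#' "Above" taxa are planted in 100% of samples at a forced relative
#' abundance (counts of the remaining taxa are rescaled so column totals are
#' preserved). "Below" taxa are zeroed in a `1 - q` fraction of samples
#' chosen without replacement, their reads redistributed within the sample.
#'
#' @param x an [otu_table()].
#' @param selected_above,selected_below specs as in [sim_config()].
#' @param seed integer seed for the below-occupancy sample choice.
#' @return `list(table = otu_table, truth = character)` where `truth` labels
#'   every taxon `"neutral"`, `"above"`, or `"below"`.
#' @export
inject_selected <- function(x, selected_above = list(),
                            selected_below = list(), seed = NULL) {
  m <- count_matrix(x)
  S <- nrow(m); n <- ncol(m)
  truth <- rep("neutral", S)
  ia <- vapply(selected_above, function(s) as.integer(s$taxon), integer(1))
  ib <- vapply(selected_below, function(s) as.integer(s$taxon), integer(1))
  if (length(intersect(ia, ib))) stop("selection specs overlap")
  abund <- vapply(selected_above, function(s) as.numeric(s$rel_abundance),
                  numeric(1))
  if (length(abund) && sum(abund) > 0.9)
    stop("selection spec exceeds community capacity")
  totals <- colSums(m)
  if (length(ia)) {
    free <- setdiff(seq_len(S), ia)
    for (j in seq_len(n)) {
      forced <- pmax(1L, round(abund * totals[j]))  # occurrence must be 1
      m[ia, j] <- forced
      m[free, j] <- scale_to_total(m[free, j], totals[j] - sum(forced))
    }
    truth[ia] <- "above"
  }
  if (length(ib)) {
    qs <- vapply(selected_below, function(s) as.numeric(s$occupancy), numeric(1))
    stopifnot(all(qs >= 0), all(qs < 1))
    free <- setdiff(seq_len(S), c(ia, ib))
    with_seed(seed, for (k in seq_along(ib)) {
      i <- ib[k]
      keep <- sample.int(n, round(qs[k] * n))
      for (j in setdiff(seq_len(n), keep)) {
        removed <- m[i, j]
        m[i, j] <- 0
        if (removed > 0)  # re-spread the removed reads; totals stay fixed
          m[free, j] <- scale_to_total(m[free, j], sum(m[free, j]) + removed)
      }
    })
    truth[ib] <- "below"
  }
  list(table = otu_table(m), truth = stats::setNames(truth, rownames(m)))
}

#' Simulate a random rooted binary phylogeny
#'
#' Builds a tree by sequential random joins of lineages, each join drawing
#' exponential(1) branch increments. An optional clade constraint makes the
#' listed taxa monophyletic with branch lengths scaled by `clade_scale`, so
#' clade members sit much closer to each other than to the rest of the tree
#' — the fixture for phylogenetic-clustering signals.
#'
#' @param taxon_ids character vector of >= 2 tip labels.
#' @param seed integer seed; same seed, same newick string.
#' @param clade_taxa optional character subset (>= 2) to force monophyletic.
#' @param clade_scale branch-length multiplier inside the clade (default 0.1).
#' @return an [ape::phylo] rooted binary tree.
#' @export
simulate_tree <- function(taxon_ids, seed = NULL, clade_taxa = NULL,
                          clade_scale = 0.1) {
  n <- length(taxon_ids)
  if (n < 2) stop("need at least 2 taxa")
  if (anyDuplicated(taxon_ids)) stop("taxon IDs must be unique")
  join_all <- function(nodes, scale) {
    while (length(nodes) > 1L) {
      i <- sample.int(length(nodes), 2L)
      e <- stats::rexp(2L) * scale
      merged <- sprintf("(%s:%.10g,%s:%.10g)",
                        nodes[i[1L]], e[1L], nodes[i[2L]], e[2L])
      nodes <- c(nodes[-i], merged)
    }
    nodes
  }
  txt <- with_seed(seed, {
    if (!is.null(clade_taxa)) {
      stopifnot(length(clade_taxa) >= 2, all(clade_taxa %in% taxon_ids))
      clade <- join_all(clade_taxa, clade_scale)
      join_all(c(setdiff(taxon_ids, clade_taxa), clade), 1)
    } else {
      join_all(taxon_ids, 1)
    }
  })
  validate_tree(ape::read.tree(text = paste0(txt, ";")))
}

#' Simulate a complete source/target study with ground truth
#'
#' Source samples are generated at `Nm = 1e8` (faithful metacommunity
#' replicates, mimicking pooled environmental samples); target samples at
#' the configured `Nm`; selected taxa are then injected and a phylogeny
#' simulated over all taxa.
#'
#' @param config a [sim_config()].
#' @return a `sim_study` list: `source_table`, `target_table`, `tree`,
#'   `metadata` (sample_id, group), `truth` (named per-taxon labels),
#'   `p` (true metacommunity), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  seed <- cfg$seed
  p <- make_metacommunity(cfg$S, cfg$meta_dist,
                          seed = derive_seed(seed, "metacommunity"))
  taxon_ids <- sprintf("OTU_%04d", seq_len(cfg$S))
  jit <- function(n, tag) with_seed(derive_seed(seed, tag),
    round(cfg$N * stats::runif(n, 1 - cfg$depth_jitter, 1 + cfg$depth_jitter)))

  src <- simulate_neutral_samples(
    p, 1e8, jit(cfg$n_source, "source_totals"),
    seed = derive_seed(seed, "source"), taxon_ids = taxon_ids,
    sample_ids = sprintf("SRC_%03d", seq_len(cfg$n_source)))

  tgt_totals <- jit(cfg$n_target, "target_totals")
  if (cfg$n_shallow > 0)
    tgt_totals <- c(tgt_totals, with_seed(derive_seed(seed, "shallow"),
      sample(1000:7999, cfg$n_shallow, replace = TRUE)))
  tgt <- simulate_neutral_samples(
    p, cfg$Nm, tgt_totals, seed = derive_seed(seed, "target"),
    taxon_ids = taxon_ids,
    sample_ids = sprintf("TGT_%03d", seq_along(tgt_totals)))
  inj <- inject_selected(tgt, cfg$selected_above, cfg$selected_below,
                         seed = derive_seed(seed, "inject"))

  clade_taxa <- NULL
  clade_tbl <- NULL
  if (!is.null(cfg$clade_filter)) {
    cf <- cfg$clade_filter
    n_clade_taxa <- max(2L, ceiling(cf$fraction * cfg$S))
    clade_taxa <- with_seed(derive_seed(seed, "clade_taxa"),
                            sort(sample(taxon_ids, n_clade_taxa)))
    p_cl <- stats::setNames(rep(.Machine$double.xmin, cfg$S), taxon_ids)
    p_cl[clade_taxa] <- p[match(clade_taxa, taxon_ids)]
    p_cl <- p_cl / sum(p_cl)
    clade_tbl <- simulate_neutral_samples(
      p_cl, cfg$Nm, jit(cf$n_samples, "clade_totals"),
      seed = derive_seed(seed, "clade"), taxon_ids = taxon_ids,
      sample_ids = sprintf("CLD_%03d", seq_len(cf$n_samples)))
  }

  target_table <- inj$table
  groups <- c(rep("source", cfg$n_source), rep("target", ncol(target_table)))
  ids <- c(colnames(src), colnames(target_table))
  if (!is.null(clade_tbl)) {
    target_table <- otu_table(cbind(count_matrix(target_table),
                                    count_matrix(clade_tbl)))
    lbl <- if (is.null(cfg$clade_filter$label)) "clade_filtered"
           else cfg$clade_filter$label
    groups <- c(groups, rep(lbl, ncol(clade_tbl)))
    ids <- c(ids, colnames(clade_tbl))
  }
  structure(list(
    source_table = src, target_table = target_table,
    tree = simulate_tree(taxon_ids, derive_seed(seed, "tree"), clade_taxa),
    metadata = data.frame(sample_id = ids, group = groups,
                          stringsAsFactors = FALSE),
    truth = inj$truth, p = p, clade_taxa = clade_taxa, config = cfg),
    class = "sim_study")
}
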