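#' Configure a full community-assembly pipeline run
#'
#' Describes a multi-group study — an environmental source group followed
#' by an ordered chain of host groups (gut compartments or life-cycle
#' stages) — together with every analysis parameter. The default group
#' labels and sizes mirror a farmed-salmon compartment survey: combined
#' feed-and-water source (FW), stomach (S), pyloric cecum (PC), midgut
#' (MG), bile duct (BD).
#'
#' Either supply `tables` (a named list of [otu_table()]s in chain order,
#' first = source) plus `tree`, or leave them `NULL` to self-generate a
#' synthetic study from the simulation parameters.
#'
#' @param outdir output directory for the report bundle.
#' @param labels ordered group labels; the first is the source community.
#' @param n_samples per-group sample counts (recycled if length 1).
#' @param mode `"stepping_stone"` (each group seeds the next) or
#'   `"common_source"` (every group compared to the first).
#' @param tables,tree optional observed inputs (see above).
#' @param S,N,Nm,meta_dist,depth_jitter,n_shallow simulation parameters as
#'   in [sim_config()], used when self-generating.
#' @param inject optional `list(stage = label, above = list(...),
#'   below = list(...))` selection spec applied to one simulated stage.
#' @param min_total depth filter threshold (default 8000 reads).
#' @param ncm_bootstrap bootstrap resamples per NCM fit (default 1000).
#' @param dispersion_runs null draws for NRI/NTI (default 999).
#' @param gunifrac_alpha UniFrac weighting exponent (default 0.5).
#' @param permanova_perms label permutations (default 999).
#' @param level confidence level of the OTU partition (default 0.95).
#' @param seed global integer seed; every stochastic stage derives its own
#'   sub-seed via [derive_seed()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            labels = c("FW", "S", "PC", "MG", "BD"),
                            n_samples = c(27, 42, 31, 39, 23),
                            mode = c("stepping_stone", "common_source"),
                            tables = NULL, tree = NULL,
                            S = 300, N = 10000, Nm = 1000,
                            meta_dist = list(type = "lognormal",
                                             meanlog = 0, sdlog = 1),
                            depth_jitter = 0.2, n_shallow = 0,
                            inject = NULL,
                            min_total = 8000, ncm_bootstrap = 1000,
                            dispersion_runs = 999, gunifrac_alpha = 0.5,
                            permanova_perms = 999, level = 0.95,
                            seed = 42) {
  mode <- match.arg(mode)
  if (length(n_samples) == 1L) n_samples <- rep(n_samples, length(labels))
  stopifnot(length(labels) >= 2, length(n_samples) == length(labels),
            all(n_samples >= 2), min_total >= 0)
  if (!is.null(inject) && !inject$stage %in% labels)
    stop("inject$stage must be one of the design labels")
  structure(list(outdir = outdir, labels = labels, n_samples = n_samples,
                 mode = mode, tables = tables, tree = tree, S = S, N = N,
                 Nm = Nm, meta_dist = meta_dist,
                 depth_jitter = depth_jitter, n_shallow = n_shallow,
                 inject = inject, min_total = min_total,
                 ncm_bootstrap = ncm_bootstrap,
                 dispersion_runs = dispersion_runs,
                 gunifrac_alpha = gunifrac_alpha,
                 permanova_perms = permanova_perms, level = level,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full community-assembly pipeline
#'
#' Executes, in order: data generation (or loading), the global depth
#' filter, the chained neutral-model fits with per-OTU partitions, NRI/NTI
#' dispersion with group tests, alpha diversity with rank tests, and
#' generalized UniFrac with PERMANOVA, pairwise beta comparisons and PCoA.
#' Every output is written as TSV or JSON into `config$outdir` together
#' with a run manifest; given a fixed seed the bundle is byte-identical
#' across reruns.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the in-memory report: `tables`, `metadata`, `tree`,
#'   `ncm`, `neutral_fractions`, `dispersion`, `dispersion_tests`,
#'   `alpha`, `alpha_tests`, `gunifrac`, `permanova`, `beta_summary`,
#'   `pcoa`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  seed <- cfg$seed
  t0 <- proc.time()[["elapsed"]]
  say <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                              paste0(...)))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  if (is.null(cfg$tables)) {
    say("simulate", "generating ", length(cfg$labels), " groups, S = ",
        cfg$S, ", Nm = ", cfg$Nm)
    p <- make_metacommunity(cfg$S, cfg$meta_dist,
                            seed = derive_seed(seed, "metacommunity"))
    taxon_ids <- sprintf("OTU_%04d", seq_len(cfg$S))
    tables <- list()
    for (i in seq_along(cfg$labels)) {
      lab <- cfg$labels[i]
      n <- cfg$n_samples[i]
      totals <- with_seed(derive_seed(seed, paste0("totals_", lab)),
        round(cfg$N * stats::runif(n, 1 - cfg$depth_jitter,
                                   1 + cfg$depth_jitter)))
      if (i == 2L && cfg$n_shallow > 0)  # shallow samples sit in the first target group
        totals <- c(totals, with_seed(derive_seed(seed, "shallow"),
                                      sample(1000:7999, cfg$n_shallow,
                                             replace = TRUE)))
      tbl <- simulate_neutral_samples(
        p, if (i == 1L) 1e8 else cfg$Nm, totals,
        seed = derive_seed(seed, paste0("table_", lab)),
        taxon_ids = taxon_ids,
        sample_ids = sprintf("%s_%03d", lab, seq_along(totals)))
      if (!is.null(cfg$inject) && identical(cfg$inject$stage, lab)) {
        inj <- inject_selected(tbl,
                               cfg$inject$above %||% list(),
                               cfg$inject$below %||% list(),
                               seed = derive_seed(seed, "inject"))
        tbl <- inj$table
      }
      tables[[lab]] <- tbl
    }
    tree <- simulate_tree(taxon_ids, derive_seed(seed, "tree"))
  } else {
    tables <- cfg$tables
    tree <- cfg$tree
    if (is.null(tree)) stop("tree required with observed tables")
  }
  metadata <- data.frame(
    sample_id = unlist(lapply(tables, colnames), use.names = FALSE),
    group = rep(names(tables), vapply(tables, ncol, integer(1))),
    stringsAsFactors = FALSE)

  # --- depth filter -------------------------------------------------------
  full <- otu_table(do.call(cbind, lapply(tables, count_matrix)))
  n_before <- ncol(full)
  filtered <- withCallingHandlers(
    filter_min_reads(full, cfg$min_total),
    message = function(m) { say("filter", conditionMessage(m)); invokeRestart("muffleMessage") })
  say("filter", n_before - ncol(filtered), " of ", n_before,
      " samples dropped below ", cfg$min_total, " reads")
  metadata <- metadata[metadata$sample_id %in% colnames(filtered), ]
  tables <- lapply(stats::setNames(nm = names(tables)), function(lab)
    otu_table(count_matrix(filtered)[,
      metadata$sample_id[metadata$group == lab], drop = FALSE]))

  # --- neutral model chain ------------------------------------------------
  say("ncm", "fitting ", length(tables) - 1L, " ", cfg$mode, " links")
  chain <- sequential_chain(
    if (cfg$mode == "stepping_stone") tables else tables[-1L],
    mode = cfg$mode,
    common_source = if (cfg$mode == "common_source") tables[[1L]] else NULL,
    common_source_label = cfg$labels[1L],
    bootstrap = cfg$ncm_bootstrap, level = cfg$level,
    seed = derive_seed(seed, "ncm"))
  neutral_fractions <- do.call(rbind, lapply(names(chain), function(key) {
    fr <- neutral_fraction(chain[[key]]$records)
    data.frame(comparison = key, m = chain[[key]]$m, Nm = chain[[key]]$Nm,
               R2 = chain[[key]]$R2, pct_neutral = fr[["neutral"]],
               pct_above = fr[["above"]], pct_below = fr[["below"]],
               stringsAsFactors = FALSE)
  }))

  # --- phylogenetic dispersion --------------------------------------------
  say("dispersion", "NRI/NTI, ", cfg$dispersion_runs, " null draws")
  disp <- rbind(
    ses_dispersion(filtered, tree, "MPD", runs = cfg$dispersion_runs,
                   seed = derive_seed(seed, "disp_MPD")),
    ses_dispersion(filtered, tree, "MNTD", runs = cfg$dispersion_runs,
                   seed = derive_seed(seed, "disp_MNTD")))
  disp_tests <- lapply(stats::setNames(nm = c("MPD", "MNTD")), function(mt)
    compare_dispersion(disp[disp$metric == mt, ], metadata))

  # --- alpha diversity ----------------------------------------------------
  say("alpha", "richness/evenness + rank tests")
  alpha <- alpha_diversity(filtered)
  groups <- metadata$group[match(alpha$sample_id, metadata$sample_id)]
  alpha_tests <- list(
    richness = list(kruskal = kruskal_wallis(alpha$richness, groups),
                    pairwise = pairwise_wilcoxon_bh(alpha$richness, groups)),
    pielou = local({
      ok <- !is.na(alpha$pielou)
      list(kruskal = kruskal_wallis(alpha$pielou[ok], groups[ok]),
           pairwise = pairwise_wilcoxon_bh(alpha$pielou[ok], groups[ok]))
    }))

  # --- beta diversity -----------------------------------------------------
  say("beta", "GUniFrac (alpha = ", cfg$gunifrac_alpha, ") + PERMANOVA")
  D <- gunifrac(filtered, tree, alpha = cfg$gunifrac_alpha)
  perm <- permanova(D, groups, n_perm = cfg$permanova_perms,
                    seed = derive_seed(seed, "permanova"))
  beta_summary <- make_report_tables(D, metadata,
                                     n_perm = cfg$permanova_perms,
                                     seed = derive_seed(seed, "permanova_pairs"))
  ord <- pcoa_ord(D, k = 2)

  # --- write bundle -------------------------------------------------------
  wt <- function(df, name) utils::write.table(
    df, file.path(cfg$outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(metadata, "metadata.tsv")
  write_otu_table(filtered, file.path(cfg$outdir, "filtered_table.tsv"))
  ape::write.tree(tree, file.path(cfg$outdir, "tree.nwk"))
  wt(neutral_fractions, "neutral_fractions.tsv")
  for (key in names(chain))
    wt(chain[[key]]$records,
       paste0("ncm_records_", gsub("->", "_to_", key, fixed = TRUE), ".tsv"))
  jsonlite::write_json(
    lapply(chain, function(fit)
      fit[c("m", "Nm", "N", "d", "R2", "m_ci", "level", "n_otus",
            "saturated")]),
    file.path(cfg$outdir, "ncm_fits.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wt(disp, "dispersion.tsv")
  wt(do.call(rbind, lapply(names(disp_tests), function(mt)
    cbind(metric = mt, disp_tests[[mt]]$pairwise))), "dispersion_tests.tsv")
  wt(alpha, "alpha.tsv")
  wt(do.call(rbind, lapply(names(alpha_tests), function(ix)
    cbind(index = ix, alpha_tests[[ix]]$pairwise))), "alpha_tests.tsv")
  wt(data.frame(sample_id = rownames(D), D, check.names = FALSE),
     "gunifrac.tsv")
  jsonlite::write_json(unclass(perm), file.path(cfg$outdir, "permanova.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wt(beta_summary, "beta_summary.tsv")
  wt(data.frame(sample_id = rownames(ord$points), ord$points,
                check.names = FALSE), "pcoa.tsv")
  manifest <- list(
    package = "ncmtools",
    version = as.character(utils::packageVersion("ncmtools")),
    seed = seed,
    parameters = cfg[c("labels", "n_samples", "mode", "S", "N", "Nm",
                       "min_total", "ncm_bootstrap", "dispersion_runs",
                       "gunifrac_alpha", "permanova_perms", "level",
                       "n_shallow", "depth_jitter")],
    samples_in = n_before, samples_kept = ncol(filtered))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", sprintf("%.1f s, bundle in %s",
                      proc.time()[["elapsed"]] - t0, cfg$outdir))
  invisible(list(tables = tables, metadata = metadata, tree = tree,
                 ncm = chain, neutral_fractions = neutral_fractions,
                 dispersion = disp, dispersion_tests = disp_tests,
                 alpha = alpha, alpha_tests = alpha_tests, gunifrac = D,
                 permanova = perm, beta_summary = beta_summary, pcoa = ord,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise beta-diversity comparison table
#'
#' One row per unordered pair of groups: mean between-group distance,
#' pairwise PERMANOVA pseudo-F and p, and a Benjamini-Hochberg adjusted p
#' across all pairs as one family.
#'
#' @param dist symmetric distance matrix over all samples.
#' @param metadata data frame with `sample_id` and `group`.
#' @param n_perm permutations per pairwise test.
#' @param seed integer; per-pair sub-seeds are derived from it.
#' @return data frame: `group1`, `group2`, `mean_dist`, `pseudo_F`, `p`,
#'   `p_adj` (empty with the same columns when < 2 groups).
#' @export
make_report_tables <- function(dist, metadata, n_perm = 999, seed = NULL) {
  dmat <- as.matrix(dist)
  groups <- metadata$group[match(rownames(dmat), metadata$sample_id)]
  lv <- unique(groups)
  empty <- data.frame(group1 = character(), group2 = character(),
                      mean_dist = numeric(), pseudo_F = numeric(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lv) < 2) return(empty)
  prs <- utils::combn(lv, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(q) {
    a <- prs[1L, q]; b <- prs[2L, q]
    ia <- which(groups == a); ib <- which(groups == b)
    sub <- dmat[c(ia, ib), c(ia, ib)]
    pm <- permanova(sub, c(rep(a, length(ia)), rep(b, length(ib))),
                    n_perm = n_perm,
                    seed = if (is.null(seed)) NULL
                           else derive_seed(seed, paste(a, b)))
    data.frame(group1 = a, group2 = b,
               mean_dist = mean(dmat[ia, ib]),
               pseudo_F = pm$pseudo_F, p = pm$p, p_adj = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}
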