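#' Assemble the inputs of a neutral community model fit
#'
#' For one source-to-target comparison: `p_i` is the mean over source
#' samples of the per-sample relative abundance of taxon i (so deep samples
#' do not dominate the metacommunity estimate); `f_obs_i` is the fraction of
#' target samples where the taxon is detected (count >= 1); `N` is the mean
#' target read depth, and the detection limit defaults to `d = 1/N` (one
#' read at the typical depth).
#'
#' Taxa with `p = 0` (never seen in the source) cannot be fit and are
#' reported in `excluded_taxa`.
#'
#' @param source,target [otu_table()]s sharing a taxon namespace.
#' @param detection `"auto"` for `1/N`, or a numeric relative-abundance
#'   threshold in (0, 1).
#' @return an `ncm_input` list: `otu_ids`, `p`, `f_obs`, `n_samples`, `N`,
#'   `d`, `excluded_taxa`.
#' @export
build_ncm_input <- function(source, target, detection = "auto") {
  if (ncol(target) < 2) stop("need at least 2 target samples")
  all_taxa <- union(rownames(source), rownames(target))
  if (!length(intersect(rownames(source), rownames(target))))
    stop("source and target tables share no taxa")
  srel <- to_relative_abundance(source)
  p <- rowMeans(srel)[match(all_taxa, rownames(source))]
  p[is.na(p)] <- 0
  occ <- rowMeans(count_matrix(target) >= 1)[match(all_taxa, rownames(target))]
  occ[is.na(occ)] <- 0
  N <- round(mean(colSums(target)))
  d <- if (identical(detection, "auto")) 1 / N else {
    d0 <- as.numeric(detection)
    stopifnot(d0 > 0, d0 < 1)
    d0
  }
  keep <- p > 0
  structure(list(otu_ids = all_taxa[keep], p = unname(p[keep]),
                 f_obs = unname(occ[keep]), n_samples = ncol(target),
                 N = N, d = d, excluded_taxa = all_taxa[!keep]),
            class = "ncm_input")
}

#' Neutral-model predicted occurrence frequency
#'
#' Under the neutral model, the relative abundance of a taxon with
#' metacommunity abundance `p` follows Beta(`Nm` p, `Nm` (1 - p)) across
#' local communities; the probability of detecting it above the limit `d`
#' is therefore the upper tail of that beta distribution:
#' `f = 1 - I_d(Nm p, Nm (1 - p))` with `I` the regularized incomplete beta
#' function.
#'
#' @param p metacommunity relative abundance(s), strictly in (0, 1).
#' @param Nm positive migration-size product.
#' @param d detection limit in (0, 1).
#' @return predicted occurrence frequency in \[0, 1\], vectorized over `p`.
#' @export
predict_frequency <- function(p, Nm, d) {
  stopifnot(length(Nm) == 1L, Nm > 0, length(d) == 1L, d > 0, d < 1)
  if (any(p <= 0 | p >= 1))
    stop("p must lie strictly between 0 and 1")
  1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
}

#' Fit the neutral community model
#'
#' Estimates the migration rate `m` by nonlinear least squares: minimizes
#' the sum of squared differences between observed occurrence frequencies
#' and the beta-tail prediction at `Nm = N m`, over `m` in (0, 1\], with a
#' bounded scalar (Brent) search at tolerance 1e-10. Goodness of fit is
#' `R^2 = 1 - SSE / SS_tot` (can be negative). Uncertainty on `m` comes
#' from a seeded nonparametric bootstrap over OTUs (percentile 2.5/97.5).
#'
#' @param input an [build_ncm_input()] result.
#' @param bootstrap number of bootstrap resamples (0 skips the interval).
#' @param level confidence level for the per-OTU partition (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return an `ncm_fit`: `m`, `Nm`, `N`, `d`, `R2`, `m_ci`, `records`
#'   (see [partition_otus()]), `excluded_taxa`, `saturated` flag.
#' @export
fit_ncm <- function(input, bootstrap = 1000, level = 0.95, seed = NULL) {
  stopifnot(inherits(input, "ncm_input"))
  p <- input$p; f <- input$f_obs; N <- input$N; d <- input$d
  if (length(p) < 10)
    stop("need at least 10 OTUs with positive source abundance")
  if (length(p) < 50)
    warning("fewer than 50 OTUs in fit; estimates may be unstable")
  sse_m <- function(m, idx = seq_along(p))
    sum((f[idx] - predict_frequency(p[idx], N * m, d))^2)
  fit_one <- function(idx)
    stats::optimize(function(m) sse_m(m, idx),
                    interval = c(1e-8, 1), tol = 1e-10)$minimum
  m_hat <- fit_one(seq_along(p))
  saturated <- FALSE
  if (m_hat > 1 - 1e-6 && sse_m(1) <= sse_m(1 - 1e-4)) {
    saturated <- TRUE
    warning("migration saturated: optimum at the m = 1 boundary")
  }
  sse <- sse_m(m_hat)
  ss_tot <- sum((f - mean(f))^2)
  R2 <- if (ss_tot > 0) 1 - sse / ss_tot else if (sse < 1e-12) 1 else -Inf
  m_ci <- c(NA_real_, NA_real_)
  if (bootstrap > 0) {
    ms <- with_seed(seed, replicate(bootstrap,
      fit_one(sample.int(length(p), replace = TRUE))))
    m_ci <- unname(stats::quantile(ms, c((1 - level) / 2, 1 - (1 - level) / 2)))
    m_ci <- c(min(m_ci[1L], m_hat), max(m_ci[2L], m_hat))
  }
  fit <- structure(list(m = m_hat, Nm = N * m_hat, N = N, d = d, R2 = R2,
                        m_ci = m_ci, level = level, bootstrap = bootstrap,
                        n_otus = length(p),
                        excluded_taxa = input$excluded_taxa,
                        saturated = saturated),
                   class = "ncm_fit")
  fit$records <- partition_otus(input, fit, level)
  fit
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Neutral community model fit: %d OTUs\n", x$n_otus))
  cat(sprintf("  m = %.5g (Nm = %.5g, N = %d, d = %.3g)\n",
              x$m, x$Nm, x$N, x$d))
  if (!anyNA(x$m_ci))
    cat(sprintf("  bootstrap %g%% CI for m: [%.5g, %.5g]\n",
                100 * x$level, x$m_ci[1L], x$m_ci[2L]))
  cat(sprintf("  R2 = %.4f\n", x$R2))
  fr <- neutral_fraction(x$records)
  cat(sprintf("  partition: %.1f%% neutral, %.1f%% above, %.1f%% below\n",
              fr[["neutral"]], fr[["above"]], fr[["below"]]))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param phat proportion(s) in \[0, 1\].
#' @param n number of trials.
#' @param level confidence level.
#' @return data frame with columns `lower`, `upper`, clamped to \[0, 1\].
#' @export
#' @examples
#' wilson_interval(0.5, 10)  # (0.2366, 0.7634)
wilson_interval <- function(phat, n, level = 0.95) {
  stopifnot(all(phat >= 0), all(phat <= 1), n >= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  z2 <- z^2
  denom <- 1 + z2 / n
  center <- (phat + z2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z2 / (4 * n^2)) / denom
  data.frame(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Partition OTUs against the fitted neutral prediction
#'
#' Each OTU's predicted frequency gets a 95% band with `n` = number of
#' target samples; OTUs whose observed frequency falls above (below) the
#' band are classified `"above"` (`"below"`), otherwise `"neutral"`.
#'
#' The default band is the binomial quantile prediction band
#' `qbinom(alpha/2, n, f_pred) / n` to `qbinom(1 - alpha/2, n, f_pred) / n`,
#' compared on the count scale — the exact reference distribution of an
#' observed occurrence count when the prediction holds, which keeps its
#' nominal pointwise error rate at saturated occupancy (where f_pred is
#' near 1 and the observation f_obs = 1 carries large probability, yet
#' falls outside a Wilson score band around f_pred). The Wilson band is
#' available via `ci_method = "wilson"` for compatibility with the common
#' convention.
#'
#' @param input the [build_ncm_input()] used for the fit.
#' @param fit the matching [fit_ncm()] result (or any list with `Nm`).
#' @param level confidence level (default 0.95).
#' @param ci_method `"binomial"` (default) or `"wilson"`.
#' @return data frame: `otu_id`, `p`, `f_obs`, `f_pred`, `ci_low`,
#'   `ci_high`, `partition`.
#' @export
partition_otus <- function(input, fit, level = 0.95,
                           ci_method = c("binomial", "wilson")) {
  ci_method <- match.arg(ci_method)
  f_pred <- predict_frequency(input$p, fit$Nm, input$d)
  n <- input$n_samples
  if (ci_method == "binomial") {
    a2 <- (1 - level) / 2
    k_lo <- stats::qbinom(a2, n, f_pred)
    k_hi <- stats::qbinom(1 - a2, n, f_pred)
    k_obs <- round(input$f_obs * n)
    partition <- ifelse(k_obs > k_hi, "above",
                        ifelse(k_obs < k_lo, "below", "neutral"))
    ci <- data.frame(lower = k_lo / n, upper = k_hi / n)
  } else {
    ci <- wilson_interval(f_pred, n, level)
    partition <- ifelse(input$f_obs > ci$upper, "above",
                        ifelse(input$f_obs < ci$lower, "below", "neutral"))
  }
  data.frame(otu_id = input$otu_ids, p = input$p, f_obs = input$f_obs,
             f_pred = f_pred, ci_low = ci$lower, ci_high = ci$upper,
             partition = partition, stringsAsFactors = FALSE)
}

#' Percentages of neutral / above / below OTUs
#'
#' @param records a [partition_otus()] data frame.
#' @return named numeric: `neutral`, `above`, `below` percentages summing
#'   to 100.
#' @export
neutral_fraction <- function(records) {
  if (!nrow(records)) stop("no OTU records")
  n <- nrow(records)
  c(neutral = 100 * sum(records$partition == "neutral") / n,
    above   = 100 * sum(records$partition == "above") / n,
    below   = 100 * sum(records$partition == "below") / n)
}

#' Chain neutral-model fits through an ordered study design
#'
#' `"stepping_stone"` fits every consecutive pair in order (compartments
#' along the digestive tract: the upstream compartment is the source of the
#' next); `"common_source"` fits every table against one fixed external
#' source (e.g. water for each life-cycle stage).
#'
#' @param tables named, ordered list of [otu_table()]s (>= 2).
#' @param mode `"stepping_stone"` or `"common_source"`.
#' @param common_source the fixed source [otu_table()] (common-source mode).
#' @param common_source_label label used in output keys (default "source").
#' @param detection,bootstrap,level passed to the fit.
#' @param seed integer; each link derives its own sub-seed.
#' @return named list of `ncm_fit`s keyed `"A->B"`.
#' @export
sequential_chain <- function(tables,
                             mode = c("stepping_stone", "common_source"),
                             common_source = NULL,
                             common_source_label = "source",
                             detection = "auto", bootstrap = 1000,
                             level = 0.95, seed = NULL) {
  mode <- match.arg(mode)
  if (length(tables) < 2) stop("need at least 2 tables in the design")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be named")
  if (mode == "common_source" && is.null(common_source))
    stop("common_source table required in common_source mode")
  fits <- list()
  links <- if (mode == "stepping_stone") {
    lapply(seq_len(length(tables) - 1L), function(k)
      list(src = tables[[k]], key = paste0(names(tables)[k], "->",
                                           names(tables)[k + 1L]),
           tgt = tables[[k + 1L]]))
  } else {
    lapply(seq_along(tables), function(k)
      list(src = common_source, key = paste0(common_source_label, "->",
                                             names(tables)[k]),
           tgt = tables[[k]]))
  }
  for (ln in links) {
    input <- build_ncm_input(ln$src, ln$tgt, detection = detection)
    fits[[ln$key]] <- fit_ncm(input, bootstrap = bootstrap, level = level,
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, ln$key))
  }
  fits
}
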