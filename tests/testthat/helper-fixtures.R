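# Shared in-code fixtures: everything is built at test time, nothing on disk.

# 3 taxa x 2 samples literal table used across the IO tests
toy_counts <- function() {
  matrix(c(5, 0,
           2, 8,
           0, 1),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("S1", "S2")))
}

# the worked 3-tip tree: d(A,B) = 2, d(A,C) = d(B,C) = 3
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")

# presence/absence table of random communities over a fixed taxon pool;
# the last sample contains the whole pool so the pool is pinned
random_presence_table <- function(S, n, sizes = 5:50, seed = 1,
                                  pin_pool = TRUE) {
  withr::with_seed(seed, {
    m <- matrix(0L, S, n + pin_pool,
                dimnames = list(sprintf("t%03d", seq_len(S)),
                                sprintf("s%03d", seq_len(n + pin_pool))))
    for (j in seq_len(n)) m[sample(S, sample(sizes, 1L)), j] <- 1L
    if (pin_pool) m[, n + 1L] <- 1L
    otu_table(m)
  })
}

# independent quadrature oracle for the beta-tail occurrence prediction
quadrature_frequency <- function(p, Nm, d) {
  a <- Nm * p
  b <- Nm * (1 - p)
  if (a > 1) {
    1 - stats::integrate(function(x) stats::dbeta(x, a, b), 0, d,
                         rel.tol = 1e-12, abs.tol = 1e-14)$value
  } else {  # integrable singularity at 0: integrate the smooth side
    stats::integrate(function(x) stats::dbeta(x, a, b), d, 1,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
}

# a valid ncm_input built directly (bypasses tables) for boundary cases
manual_ncm_input <- function(p, f_obs, n_samples, N, d = 1 / N) {
  structure(list(otu_ids = sprintf("OTU_%03d", seq_along(p)), p = p,
                 f_obs = f_obs, n_samples = n_samples, N = N, d = d,
                 excluded_taxa = character()),
            class = "ncm_input")
}
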