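test_that("GUniFrac reproduces hand-worked toy distances", {
  # identical samples -> 0
  m <- matrix(c(3, 3, 5, 5, 2, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  D <- gunifrac(otu_table(m), toy_tree(), alpha = 0.5)
  expect_equal(D["s1", "s2"], 0)
  expect_equal(diag(D), c(s1 = 0, s2 = 0))

  # completely disjoint 2-tip communities -> 1
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  m2 <- matrix(c(10, 0, 0, 7), 2, 2,
               dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(gunifrac(otu_table(m2), tr2, 0.5)["x", "y"], 1)

  # 3-tip worked example against explicit branch-by-branch arithmetic
  m3 <- matrix(c(60, 20,
                 40, 10,
                 0, 70), 3, 2, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  a <- 0.5
  branches <- rbind(  # L, pa, pb for the 4 branches of ((A:1,B:1):0.5,C:1.5);
    c(1.0, 0.6, 0.2),   # A
    c(1.0, 0.4, 0.1),   # B
    c(0.5, 1.0, 0.3),   # internal A+B
    c(1.5, 0.0, 0.7))   # C
  s <- branches[, 2] + branches[, 3]
  w <- branches[, 1] * s^a
  oracle <- sum(w * abs(branches[, 2] - branches[, 3]) / s) / sum(w)
  D3 <- gunifrac(otu_table(m3), toy_tree(), alpha = a)
  expect_equal(D3["s1", "s2"], oracle, tolerance = 1e-12)
})

test_that("GUniFrac is scale-invariant, order-equivariant, and validated", {
  st <- simulate_study(sim_config(S = 20, n_source = 2, n_target = 6,
                                  N = 2000, seed = 81))
  tb <- st$target_table
  tr <- st$tree
  D <- gunifrac(tb, tr, 0.5)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 & D <= 1))

  # branch-length rescaling cancels
  tr_scaled <- tr
  tr_scaled$edge.length <- tr_scaled$edge.length * 3.7
  expect_equal(gunifrac(tb, tr_scaled, 0.5), D, tolerance = 1e-12)

  # taxon row order is irrelevant; sample relabeling permutes the matrix
  perm_taxa <- otu_table(unclass(tb)[rev(rownames(tb)), ])
  expect_equal(gunifrac(perm_taxa, tr, 0.5), D, tolerance = 1e-12)
  perm_samp <- otu_table(unclass(tb)[, rev(colnames(tb))])
  expect_equal(gunifrac(perm_samp, tr, 0.5),
               D[rev(colnames(tb)), rev(colnames(tb))], tolerance = 1e-12)

  rogue <- otu_table(matrix(1, 1, 2, dimnames = list("nowhere", c("u", "v"))))
  expect_error(gunifrac(rogue, tr, 0.5), "missing from tree: nowhere")
})

test_that("GUniFrac at alpha = 1 equals weighted-normalized UniFrac (phyloseq)", {
  st <- simulate_study(sim_config(S = 25, n_source = 2, n_target = 6,
                                  N = 2000, seed = 82))
  tb <- st$target_table
  D1 <- gunifrac(tb, st$tree, alpha = 1)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(unclass(tb)[, ], taxa_are_rows = TRUE),
    phyloseq::phy_tree(st$tree))
  D2 <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(D1, D2[rownames(D1), colnames(D1)], tolerance = 1e-8)
})

test_that("PERMANOVA recovers the exact exhaustive p on perfect separation", {
  d <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0
  out <- permanova(d, c("g1", "g1", "g2", "g2"), exhaustive = TRUE)
  expect_equal(out$p, 1 / 3)
  expect_equal(out$R2, 1)
  expect_identical(out$n_perm, 6L)
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2 and p is seeded and bounded", {
  withr::with_seed(83, {
    pts <- matrix(rnorm(20 * 3), 20, 3)
    pts[11:20, 1] <- pts[11:20, 1] + 1.5
  })
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  g <- rep(c("a", "b"), each = 10)
  out <- permanova(d, g, n_perm = 199, seed = 4)
  ad <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 19)
  expect_equal(out$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(out$R2, ad$R2[1], tolerance = 1e-10)
  expect_identical(out$p, permanova(d, g, n_perm = 199, seed = 4)$p)
  expect_gte(out$p, 1 / 200)

  # all-equal distances: finite F, no separation signal
  deq <- matrix(1, 8, 8); diag(deq) <- 0
  dimnames(deq) <- list(paste0("s", 1:8), paste0("s", 1:8))
  oeq <- permanova(deq, rep(c("a", "b"), each = 4), n_perm = 99, seed = 1)
  expect_true(is.finite(oeq$pseudo_F))
  expect_gt(oeq$p, 0.5)

  expect_error(permanova(d, rep("a", 20)), "at least 2 groups")
})

test_that("PCoA reproduces simple geometries", {
  # three equidistant samples: an equilateral triangle in 2 axes
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoa_ord(d3, k = 2)
  expect_equal(ord$share, c(0.5, 0.5), tolerance = 1e-9)
  cd <- as.matrix(stats::dist(ord$points))
  expect_equal(cd[upper.tri(cd)], rep(1, 3), tolerance = 1e-9)

  # points on a line: axis 1 recovers the ordering
  x <- c(0, 1, 3, 6, 10)
  dl <- abs(outer(x, x, "-"))
  dimnames(dl) <- list(paste0("p", 1:5), paste0("p", 1:5))
  ordl <- pcoa_ord(dl, k = 1)
  expect_equal(abs(stats::cor(ordl$points[, 1], x)), 1, tolerance = 1e-9)

  # two samples: one axis, separation equals the distance
  d2 <- matrix(c(0, 0.42, 0.42, 0), 2, 2,
               dimnames = list(c("u", "v"), c("u", "v")))
  expect_warning(ord2 <- pcoa_ord(d2, k = 2), "positive-eigenvalue axes")
  expect_equal(abs(ord2$points["u", 1] - ord2$points["v", 1]), 0.42,
               tolerance = 1e-9)
})
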