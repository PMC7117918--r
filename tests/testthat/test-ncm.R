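test_that("NCM inputs are assembled from source and target tables", {
  src <- otu_table(matrix(c(20, 40,
                            80, 60,
                            0, 0),
                          nrow = 3, byrow = TRUE,
                          dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  tgt_counts <- matrix(0, 3, 10,
                       dimnames = list(c("a", "b", "c"), paste0("t", 1:10)))
  tgt_counts[1, 1:3] <- 5           # detected in 3 of 10 samples
  tgt_counts[2, ] <- c(8995, 10995, rep(900, 8))
  tgt_counts[3, ] <- 1              # target-only taxon: p = 0
  tgt <- otu_table(tgt_counts)
  inp <- build_ncm_input(src, tgt)
  expect_equal(inp$f_obs[inp$otu_ids == "a"], 0.3)
  # p is the mean of per-sample relative abundances: (0.2 + 0.4) / 2
  expect_equal(inp$p[inp$otu_ids == "a"], 0.3)
  expect_identical(inp$excluded_taxa, "c")

  tgt2 <- otu_table(matrix(c(9000, 11000), 1, 2,
                           dimnames = list("a", c("t1", "t2"))))
  inp2 <- build_ncm_input(src, tgt2)
  expect_equal(inp2$N, 10000)
  expect_equal(inp2$d, 1e-4)

  expect_error(build_ncm_input(src, tgt[, 1, drop = FALSE]),
               "at least 2 target samples")
  disjoint <- otu_table(matrix(1, 1, 2, dimnames = list("zz", c("x", "y"))))
  expect_error(build_ncm_input(src, disjoint), "share no taxa")
})

test_that("predicted occurrence matches independent quadrature and is monotone", {
  grid <- expand.grid(p = exp(seq(log(1e-4), log(0.2), length.out = 10)),
                      Nm = c(50, 200, 1000, 5000, 20000),
                      d = c(1e-4, 1e-3))
  err <- mapply(function(p, Nm, d)
    abs(predict_frequency(p, Nm, d) - quadrature_frequency(p, Nm, d)),
    grid$p, grid$Nm, grid$d)
  expect_lt(max(err), 1e-8)

  # limits and monotonicity
  expect_equal(predict_frequency(0.3, 10, 1e-12), 1, tolerance = 1e-6)
  ps <- seq(1e-4, 0.5, length.out = 40)
  expect_true(all(diff(predict_frequency(ps, 500, 1e-3)) >= 0))
  f_by_nm <- vapply(c(10, 100, 1000, 1e4, 1e6), function(nm)
    predict_frequency(0.01, nm, 1e-3), numeric(1))
  expect_true(all(diff(f_by_nm) >= -1e-12))
  expect_equal(f_by_nm[5], 1, tolerance = 1e-6)   # Nm -> Inf with p > d
  expect_equal(predict_frequency(1e-4, 1e8, 1e-3), 0, tolerance = 1e-6)

  expect_error(predict_frequency(0, 100, 1e-3), "strictly between")
  expect_error(predict_frequency(1, 100, 1e-3), "strictly between")
})

test_that("the fit recovers an exact self-consistent migration rate", {
  p <- make_metacommunity(300, seed = 41)
  N <- 10000
  m_star <- 0.1
  f <- predict_frequency(p, N * m_star, 1 / N)
  inp <- manual_ncm_input(p, f, n_samples = 50, N = N)
  fit <- fit_ncm(inp, bootstrap = 0)
  expect_equal(fit$m, m_star, tolerance = 1e-6)
  expect_equal(fit$Nm, fit$N * fit$m)
  expect_gt(fit$R2, 1 - 1e-9)
})

test_that("degenerate observed frequencies do not break the fit", {
  p <- make_metacommunity(100, seed = 42)
  inp <- manual_ncm_input(p, rep(0.5, 100), n_samples = 10, N = 1000)
  fit <- suppressWarnings(fit_ncm(inp, bootstrap = 0))
  expect_lte(fit$R2, 0)
  expect_error(fit_ncm(manual_ncm_input(p[1:5] / sum(p[1:5]), rep(1, 5),
                                        10, 1000), bootstrap = 0),
               "at least 10 OTUs")
})

test_that("bootstrap intervals are seeded, ordered, and contain the estimate", {
  st <- simulate_study(sim_config(S = 120, n_target = 30, seed = 43))
  inp <- build_ncm_input(st$source_table, st$target_table)
  f1 <- fit_ncm(inp, bootstrap = 100, seed = 7)
  f2 <- fit_ncm(inp, bootstrap = 100, seed = 7)
  expect_identical(f1$m_ci, f2$m_ci)
  expect_lte(f1$m_ci[1], f1$m)
  expect_gte(f1$m_ci[2], f1$m)
})

test_that("Wilson intervals match the closed-form oracle", {
  w <- wilson_interval(0.5, 10)
  expect_equal(round(w$lower, 4), 0.2366)
  expect_equal(round(w$upper, 4), 0.7634)
  # contains phat across the range, clamped to [0, 1]
  ph <- seq(0, 1, by = 0.05)
  w2 <- wilson_interval(ph, 25)
  expect_true(all(w2$lower <= ph & ph <= w2$upper))
  expect_true(all(w2$lower >= 0 & w2$upper <= 1))
})

test_that("the partition is neutral when observations equal predictions", {
  p <- make_metacommunity(200, seed = 44)
  N <- 10000
  n <- 50
  f_exact <- predict_frequency(p, N * 0.1, 1 / N)
  f_obs <- round(f_exact * n) / n   # observable occurrence on the k/n grid
  inp <- manual_ncm_input(p, f_obs, n_samples = n, N = N)
  fit <- fit_ncm(inp, bootstrap = 0)
  expect_true(all(fit$records$partition == "neutral"))
  expect_true(all(fit$records$ci_low <= fit$records$ci_high))
})

test_that("injected non-neutral taxa are recovered from simulated studies", {
  p <- make_metacommunity(300, seed = derive_seed(51, "metacommunity"))
  ia <- order(abs(p - 2e-4))[1:3]
  ib <- setdiff(order(abs(p - 0.005)), ia)[1:3]
  cfg <- sim_config(seed = 51,
    selected_above = lapply(ia, function(i) list(taxon = i, rel_abundance = 0.01)),
    selected_below = lapply(ib, function(i) list(taxon = i, occupancy = 0.1)))
  st <- simulate_study(cfg)
  fit <- suppressWarnings(
    fit_ncm(build_ncm_input(st$source_table, st$target_table), bootstrap = 0))
  part <- fit$records$partition[match(names(st$truth), fit$records$otu_id)]
  expect_true(all(part[st$truth == "above"] == "above"))
  expect_true(all(part[st$truth == "below"] == "below"))
})

test_that("neutral_fraction reports percentages that sum to 100", {
  rec <- data.frame(partition = c(rep("neutral", 8), "above", "below"))
  fr <- neutral_fraction(rec)
  expect_equal(unname(fr), c(80, 10, 10))
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  expect_equal(neutral_fraction(data.frame(partition = rep("neutral", 4)))[["neutral"]], 100)
  expect_error(neutral_fraction(data.frame(partition = character())), "no OTU")
})

test_that("sequential chains fit the right source-target pairs", {
  st <- simulate_study(sim_config(S = 80, n_source = 6, n_target = 6, seed = 52))
  p <- st$p
  mk <- function(s) simulate_neutral_samples(p, 1000, rep(9000, 6), seed = s,
                                             taxon_ids = rownames(st$source_table))
  tables <- list(FW = st$source_table, S = mk(1), PC = mk(2), MG = mk(3), BD = mk(4))
  fits <- suppressWarnings(sequential_chain(tables, "stepping_stone", bootstrap = 0))
  expect_identical(names(fits), c("FW->S", "S->PC", "PC->MG", "MG->BD"))

  stages <- list(Pa = mk(5), Sm = mk(6), MA = mk(7), RA = mk(8))
  fits2 <- suppressWarnings(sequential_chain(
    stages, "common_source", common_source = st$source_table,
    common_source_label = "water", bootstrap = 0))
  expect_identical(names(fits2), c("water->Pa", "water->Sm", "water->MA", "water->RA"))

  expect_error(sequential_chain(tables[1], "stepping_stone"), "at least 2")
  expect_error(sequential_chain(tables[1:2], "common_source"),
               "common_source table required")
})
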