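test_that("p_to_z matches the inverse-normal anchors and rejects bad input", {
  expect_identical(p_to_z(0.5), 0)
  expect_equal(round(p_to_z(0.05), 2), 1.64)
  expect_equal(round(p_to_z(0.95), 2), -1.64)
  expect_equal(p_to_z(0.05), -p_to_z(0.95))  # standard-normal symmetry
  # clipping keeps extreme P values finite
  expect_true(is.finite(p_to_z(0)) && p_to_z(0) > 7)
  expect_true(is.finite(p_to_z(1)) && p_to_z(1) < -7)
  # strictly decreasing
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(p_to_z(p)) < 0))
  expect_error(p_to_z(-0.1), class = "koreporter_validation_error")
  expect_error(p_to_z(1.1), class = "koreporter_validation_error")
  expect_error(p_to_z(NA_real_), class = "koreporter_validation_error")
})

test_that("aggregate_z is the size-independent 1/sqrt(k) sum", {
  expect_identical(aggregate_z(1), 1)
  expect_identical(aggregate_z(c(1, 1, 1, 1)), 2)
  expect_equal(aggregate_z(c(0, 1, 2)), 1.7321, tolerance = 1e-4)  # 3/sqrt(3)
  expect_error(aggregate_z(numeric(0)), class = "koreporter_validation_error")
  expect_error(aggregate_z(c(1, Inf)), class = "koreporter_validation_error")
})

test_that("background_stats: exhaustive enumeration, constants, determinism", {
  # constant universe: aggregate is c*sqrt(k) always, sigma 0
  b <- background_stats(rep(1.5, 8), k = 3)
  expect_equal(b$mu_k, 1.5 * sqrt(3))
  expect_equal(b$sigma_k, 0)
  # exhaustive worked example: subsets of {0,1,2} of size 2 aggregate to
  # {1,2,3}/sqrt(2); population sd oracle
  b <- background_stats(c(0, 1, 2), k = 2)
  expect_identical(b$method, "exhaustive")
  expect_identical(b$n_samples, 3L)
  expect_equal(b$mu_k, 1.4142, tolerance = 1e-4)
  expect_equal(b$sigma_k, 0.5774, tolerance = 1e-4)
  # Monte Carlo is forced above the cap and is seed-deterministic
  z <- qnorm(1 - seq(0.01, 0.99, length.out = 60))
  m1 <- background_stats(z, k = 5, n_samples = 200, seed = 11,
                         exhaustive_cap = 10)
  m2 <- background_stats(z, k = 5, n_samples = 200, seed = 11,
                         exhaustive_cap = 10)
  expect_identical(m1$method, "monte_carlo")
  expect_identical(m1[c("mu_k", "sigma_k")], m2[c("mu_k", "sigma_k")])
  expect_error(background_stats(z, k = 100),
               class = "koreporter_validation_error")
})

test_that("corrected_score centres and scales; degenerate background errors", {
  expect_identical(corrected_score(2, 2, 0.5), 0)
  expect_identical(corrected_score(2.5, 0.5, 1), 2)
  expect_equal(corrected_score(2.1213, 1.4142, 0.5774), 1.2247,
               tolerance = 1e-4)
  expect_error(corrected_score(1, 0, 0), class = "koreporter_validation_error")
  expect_error(corrected_score(1, 0, -1), class = "koreporter_validation_error")
})

test_that("score_to_p is the upper tail and inverts p_to_z", {
  expect_identical(score_to_p(0), 0.5)
  expect_equal(round(score_to_p(1.6449), 2), 0.05)
  z <- seq(-6, 6, by = 0.5)
  expect_equal(p_to_z(score_to_p(z)), z, tolerance = 1e-8)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(score_to_p(p_to_z(p)), p, tolerance = 1e-10)
})

test_that("split_directional implements the one-tailed halving rule", {
  expect_equal(split_directional(0.04, +1), list(p_up = 0.02, p_down = 0.98))
  expect_equal(split_directional(0.04, -1), list(p_up = 0.98, p_down = 0.02))
  expect_equal(split_directional(1, 1), list(p_up = 0.5, p_down = 0.5))
  expect_equal(split_directional(0.3, 0), list(p_up = 0.5, p_down = 0.5))
  # p_up + p_down = 1 always, and the split is sign-antisymmetric
  p <- runif(50); s <- sample(c(-1, 0, 1), 50, replace = TRUE)
  d <- split_directional(p, s)
  expect_equal(d$p_up + d$p_down, rep(1, 50))
  d_flip <- split_directional(p, -s)
  expect_equal(d_flip$p_up, d$p_down)
})

test_that("reporter_score: near-null P values give near-zero scores", {
  set.seed(3)
  n <- 60
  stats_df <- data.frame(ko = sprintf("K%05d", 1:n),
                         p_value = runif(n, 0.45, 0.55))
  ps <- make_pathways(stats_df$ko, sizes = c(5, 8, 12), seed = 4)
  fit <- reporter_score(stats_df, ps, seed = 9)
  expect_true(all(abs(fit$reporter_score) < 3))
  expect_false(any(fit$significant))
})

test_that("reporter_score: constant P values give a degenerate background", {
  stats_df <- data.frame(ko = sprintf("K%05d", 1:20),
                         p_value = rep(0.5, 20))
  ps <- make_pathways(stats_df$ko, sizes = c(4, 6), seed = 5)
  expect_warning(fit <- reporter_score(stats_df, ps, seed = 1),
                 "degenerate background")
  expect_true(all(is.na(fit$reporter_score)))
  expect_true(all(fit$z_pathway == 0))
  expect_false(any(fit$significant))
})

test_that("undirected scores are sign-flip invariant (bit-identical)", {
  sim <- simulate_pvalues(seed = 5)
  flipped <- sim$ko_stats
  flipped$statistic <- -flipped$statistic
  f1 <- reporter_score(sim$ko_stats, sim$pathways, seed = 17)
  f2 <- reporter_score(flipped, sim$pathways, seed = 17)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  # randomised signs too
  set.seed(99)
  flipped$statistic <- abs(flipped$statistic) * sample(c(-1, 1), 200, TRUE)
  f3 <- reporter_score(flipped, sim$pathways, seed = 17)
  expect_identical(as.data.frame(f1), as.data.frame(f3))
})

test_that("lowering member P values never decreases the pathway aggregate", {
  set.seed(21)
  for (rep in 1:5) {
    stats_df <- make_ko_stats(n = 50, seed = rep)
    ps <- make_pathways(stats_df$ko, sizes = c(6, 10), seed = rep + 100)
    fit1 <- reporter_score(stats_df, ps, seed = 7)
    target <- fit1$pathway[1]
    stats2 <- stats_df
    i <- stats2$ko %in% ps[[target]]
    stats2$p_value[i] <- stats2$p_value[i] * runif(sum(i), 0, 1)
    fit2 <- reporter_score(stats2, ps, seed = 7)
    expect_gte(fit2$z_pathway[fit2$pathway == target],
               fit1$z_pathway[fit1$pathway == target])
  }
})

test_that("directed mode scores up and down separately and coherently", {
  set.seed(31)
  n <- 60
  stats_df <- data.frame(ko = sprintf("K%05d", 1:n),
                         p_value = runif(n),
                         statistic = abs(rnorm(n)))  # everything moved up
  ps <- make_pathways(stats_df$ko, sizes = c(8, 10, 12), seed = 32)
  fit <- reporter_score(stats_df, ps, mode = "directed", seed = 41)
  expect_identical(sort(unique(fit$mode)), c("down", "up"))
  expect_identical(nrow(fit), 2L * length(ps))
  for (id in names(ps)) {
    p_mem <- stats_df$p_value[stats_df$ko %in% ps[[id]]]
    z_up <- fit$z_pathway[fit$pathway == id & fit$mode == "up"]
    z_down <- fit$z_pathway[fit$pathway == id & fit$mode == "down"]
    if (mean(p_mem) < 0.5) expect_gte(z_up, z_down)
  }
  # q values are adjusted within mode
  for (m in c("up", "down")) {
    i <- fit$mode == m
    expect_equal(fit$q_value[i], p.adjust(fit$p_equiv[i], "BH"))
  }
})

test_that("results are deterministically ordered and pathway-order invariant", {
  stats_df <- make_ko_stats(n = 50, seed = 8)
  ps <- make_pathways(stats_df$ko, sizes = c(5, 7, 9, 11), seed = 9)
  f1 <- reporter_score(stats_df, ps, seed = 3)
  ps_rev <- ps[rev(seq_along(ps))]
  f2 <- reporter_score(stats_df, ps_rev, seed = 3)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  sc <- f1$reporter_score
  expect_true(all(diff(sc) <= 0))
})

test_that("pathways below min_k are dropped with a notice; empty sets error", {
  stats_df <- make_ko_stats(n = 30, seed = 2)
  ps <- pathway_set(list(big = stats_df$ko[1:10],
                         tiny = stats_df$ko[1:2],
                         alien = c("KX0001", "KX0002", "KX0003")))
  expect_message(fit <- reporter_score(stats_df, ps, seed = 1),
                 "dropping 2 pathway")
  expect_identical(fit$pathway, "big")
  expect_error(
    suppressMessages(
      reporter_score(stats_df, pathway_set(list(a = c("KX1", "KX2", "KX3"))),
                     seed = 1)),
    class = "koreporter_validation_error")
  expect_error(reporter_score(stats_df[0, ], ps),
               class = "koreporter_validation_error")
})
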