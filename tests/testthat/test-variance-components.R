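test_that("one-way ANOVA matches the hand-worked two-genotype case", {
  panel <- manual_panel(list(A = c(1, 2), B = c(3, 4)))
  a <- anova_one_way(panel, "y")
  # grand mean 2.5; between-SS = 2*(1^2 + 1^2) = 4 on 1 df;
  # within-SS = 4 * 0.25 = 1 on 2 df
  expect_equal(a$MSG, 4)
  expect_equal(a$MSE, 0.5)
  expect_equal(a$F, 8)
  expect_equal(a$p_value, pf(8, 1, 2, lower.tail = FALSE))
})

test_that("ANOVA mean squares agree with stats::aov on simulated data", {
  panel <- simulate_panel(scalar_config(seed = 61, g = 25))
  a <- anova_one_way(panel, "y", "cold")
  sub <- panel[panel$treatment == "cold", ]
  fit <- summary(stats::aov(value ~ genotype, data = sub))[[1]]
  expect_equal(a$MSG, fit["genotype", "Mean Sq"], tolerance = 1e-10)
  expect_equal(a$MSE, fit["Residuals", "Mean Sq"], tolerance = 1e-10)
  expect_equal(a$p_value, fit["genotype", "Pr(>F)"], tolerance = 1e-10)

  # sum-of-squares decomposition: total = between + within
  y <- sub$value
  total_ss <- sum((y - mean(y))^2)
  expect_equal(total_ss, a$df1 * a$MSG + a$df2 * a$MSE, tolerance = 1e-8)
})

test_that("constant data yields zero mean squares and NaN F with warning", {
  panel <- manual_panel(list(A = c(2, 2), B = c(2, 2)))
  expect_warning(a <- anova_one_way(panel, "y"), "identical")
  expect_equal(a$MSG, 0)
  expect_equal(a$MSE, 0)
  expect_true(is.nan(a$F))
})

test_that("single-replicate or single-genotype designs are refused", {
  expect_error(anova_one_way(manual_panel(list(A = 1, B = 2)), "y"),
               "at least 2 replication units")
  expect_error(anova_one_way(manual_panel(list(A = c(1, 2))), "y"),
               "at least 2 genotypes")
})

test_that("heritability follows the entry-mean closed form", {
  expect_equal(heritability(MSG = 4, MSE = 0.5, r = 2), 87.5)
  expect_equal(heritability(MSG = 3, MSE = 0, r = 3), 100)
  expect_warning(h0 <- heritability(MSG = 0.5, MSE = 1, r = 3), "floored")
  expect_equal(h0, 0)
  # plot basis is never above entry-mean basis for r > 1
  expect_lt(heritability(4, 0.5, 2, basis = "plot"),
            heritability(4, 0.5, 2))

  # monotone in MSG at fixed MSE, r; monotone in r at fixed components
  msg <- seq(1, 10, by = 0.5)
  h <- heritability(msg, MSE = 1, r = 3)
  expect_true(all(diff(h) > 0))
  s2g <- 2; s2e <- 1
  h_by_r <- vapply(2:8, function(r) {
    heritability(r * s2g + s2e, s2e, r)
  }, numeric(1))
  expect_true(all(diff(h_by_r) > 0))
  expect_true(all(h >= 0 & h <= 100))
})

test_that("genetic advance follows GA = k H2 sigma_p", {
  expect_equal(genetic_advance(87.5, sqrt(2), k = 2.06),
               2.06 * 0.875 * sqrt(2))
  expect_equal(genetic_advance(0, 3), 0)
  # H2 = 100 collapses to k * sigma_g (sigma_p = sigma_g)
  expect_equal(genetic_advance(100, 1.7, k = 2.06), 2.06 * 1.7)
  expect_error(genetic_advance(50, -1), "non-negative")
  expect_error(genetic_advance(50, 1, k = 0), "positive")
})

test_that("descriptive statistics summarise genotype entry means", {
  panel <- manual_panel(list(A = c(1, 1), B = c(3, 3)))
  st <- trait_stats(panel, "cold")
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2))
  expect_equal(st$min, 1)
  expect_equal(st$max, 3)

  const <- manual_panel(list(A = c(4, 4), B = c(4, 4)))
  expect_warning(stc <- trait_stats(const, "cold"))
  expect_equal(stc$sd, 0)
  expect_equal(stc$min, stc$max)
})

test_that("simulated control qL mean lands in the observed control band", {
  cfg <- panel_config(n_genotypes = 100, seed = 71)
  panel <- simulate_panel(cfg)
  st <- trait_stats(panel, "control", traits = "qL")
  expect_gt(st$mean, 0.963)
  expect_lt(st$mean, 0.993)
})

test_that("genotypic covariance reduces to variance and is bilinear", {
  panel <- simulate_panel(scalar_config(seed = 81, g = 40))
  dup <- panel
  dup$trait <- "y2"
  neg <- panel
  neg$trait <- "y3"
  neg$value <- -neg$value
  scaled <- panel
  scaled$trait <- "y4"
  scaled$value <- 2.5 * scaled$value
  full <- stack_panels(panel, dup, neg, scaled)

  s2g <- max(0, (anova_one_way(panel, "y")$MSG -
                   anova_one_way(panel, "y")$MSE) / 3)
  expect_equal(as.numeric(genotypic_covariance(full, "y", "y2")), s2g,
               tolerance = 1e-10)
  expect_equal(as.numeric(genotypic_covariance(full, "y", "y3")), -s2g,
               tolerance = 1e-10)
  expect_equal(as.numeric(genotypic_covariance(full, "y", "y4")),
               2.5 * s2g, tolerance = 1e-10)
})

test_that("mean cross-products agree with the stats::manova SSCP oracle", {
  cfg <- panel_config(
    n_genotypes = 15, n_replicates = 3, traits = c("u", "v"),
    control_means = c(u = 0, v = 0), cold_shift = c(u = 0, v = 0),
    G_cov = matrix(c(5, -2, -2, 3), 2, 2), E_cov = diag(2), seed = 91
  )
  panel <- simulate_panel(cfg)
  cg <- genotypic_covariance(panel, "u", "v")

  wide <- tidyr::pivot_wider(panel[panel$treatment == "cold", ],
                             names_from = "trait", values_from = "value")
  fit <- summary(stats::manova(cbind(u, v) ~ genotype, data = wide))
  SSg <- fit$SS$genotype
  SSe <- fit$SS$Residuals
  g <- 15; r <- 3
  expect_equal(attr(cg, "MPG"), SSg["u", "v"] / (g - 1), tolerance = 1e-8)
  expect_equal(attr(cg, "MPE"), SSe["u", "v"] / (g * (r - 1)),
               tolerance = 1e-8)
})

test_that("index matrices are consistent with the per-trait ANOVA", {
  panel <- simulate_panel(panel_config(n_genotypes = 60, seed = 101))
  traits <- c("LI", "qL", "FvFm")
  M <- build_index_matrices(panel, traits)
  expect_equal(M$P, t(M$P))
  expect_equal(M$G, t(M$G))
  expect_true(all(diag(M$P) >= diag(M$G)))
  for (tr in traits) {
    a <- anova_one_way(panel, tr, "cold")
    expect_equal(M$G[tr, tr], (a$MSG - a$MSE) / a$r, tolerance = 1e-10)
    expect_equal(M$P[tr, tr], a$MSG / a$r, tolerance = 1e-10)
  }

  # scalar case: 1x1 matrices
  a <- anova_one_way(panel, "qL", "cold")
  M1 <- build_index_matrices(panel, "qL")
  expect_equal(as.numeric(M1$P), a$MSG / a$r, tolerance = 1e-10)
  expect_false(M1$singular)
})

test_that("duplicated trait columns flag P as singular", {
  panel <- simulate_panel(scalar_config(seed = 111, g = 30))
  dup <- panel
  dup$trait <- "y2"
  M <- build_index_matrices(stack_panels(panel, dup), c("y", "y2"))
  expect_true(M$singular)
  expect_equal(M$flagged_pair, c("y", "y2"))
  expect_error(smith_hazel_coefficients(M), "singular")
})

test_that("multi-trial panels can average trials as replication units", {
  cfg <- panel_config(n_genotypes = 12, n_trials = 2, n_replicates = 3,
                      trial_sd = 0.5, seed = 121)
  panel <- simulate_panel(cfg)
  avg <- anova_one_way(panel, "qL", "cold", trials = "average")
  pool <- anova_one_way(panel, "qL", "cold", trials = "pool")
  expect_equal(avg$r, 2)   # two trial means per genotype
  expect_equal(pool$r, 6)  # all trial x replicate observations
  expect_true(is.finite(avg$F) && is.finite(pool$F))
})
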