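test_that("identity-P systems return G a directly", {
  M <- list(traits = c("LI", "qL", "FvFm"), P = diag(3),
            G = diag(c(0.967, 0.505, 0.335)))
  cf <- smith_hazel_coefficients(M)
  expect_equal(unname(cf$b), c(0.967, 0.505, 0.335), tolerance = 1e-14)
  expect_equal(cf$solve_residual, 0)

  M2 <- list(traits = c("x1", "x2"),
             P = diag(c(2, 4)), G = diag(c(1, 2)))
  expect_equal(unname(smith_hazel_coefficients(M2)$b), c(0.5, 0.5),
               tolerance = 1e-14)
})

test_that("rank-deficient P raises an error naming the collinear pair", {
  M <- list(traits = c("x1", "x2"),
            P = matrix(1, 2, 2), G = diag(2))
  expect_error(smith_hazel_coefficients(M), "x1 ~ x2")
})

test_that("dimension mismatches are rejected", {
  M <- list(traits = c("x1", "x2"), P = diag(2), G = diag(2))
  expect_error(smith_hazel_coefficients(M, a = c(1, 1, 1)),
               "one entry per trait")
  expect_error(index_coefficients(c(1, 2), traits = "only_one"),
               "same length")
})

test_that("solve residual stays below 1e-8 on well-conditioned systems", {
  set.seed(42)
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3)
    P <- crossprod(A) + diag(3)
    B <- matrix(rnorm(9), 3)
    G <- crossprod(B)
    cf <- smith_hazel_coefficients(list(traits = letters[1:3], P = P, G = G))
    expect_lt(max(abs(P %*% cf$b - G %*% rep(1, 3))), 1e-8)
  }
})

test_that("CTI is the exact dot product of weights and trait values", {
  cf <- index_coefficients(c(0.967, 0.505, 0.335))
  expect_equal(compute_cti(cf, c(LI = 0, qL = 0, FvFm = 0)), 0)
  expect_equal(compute_cti(cf, c(LI = 1, qL = 1, FvFm = 1)), 1.807,
               tolerance = 1e-12)
  # a severely injured, photoinhibited genotype
  expect_equal(compute_cti(cf, c(LI = 8, qL = 0.353, FvFm = 0.219)),
               7.98763, tolerance = 1e-12)
})

test_that("CTI is linear in the trait matrix", {
  cf <- index_coefficients(c(0.967, 0.505, 0.335))
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, c("LI", "qL", "FvFm")))
  Y <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, c("LI", "qL", "FvFm")))
  expect_equal(compute_cti(cf, 3 * X), 3 * compute_cti(cf, X))
  expect_equal(compute_cti(cf, X + Y),
               compute_cti(cf, X) + compute_cti(cf, Y))
})

test_that("missing index-trait values are reported with genotype and trait", {
  cf <- index_coefficients(c(1, 1, 1))
  X <- tibble::tibble(genotype = c("g1", "g2"), LI = c(1, 2),
                      qL = c(0.5, NA), FvFm = c(0.7, 0.6))
  expect_error(compute_cti(cf, X), "g2.*qL")
  expect_error(compute_cti(cf, tibble::tibble(genotype = "g1", LI = 1)),
               "missing index trait")
})

test_that("equal-width bins place one of five spread scores in each class", {
  out <- rank_and_categorize(c(a = 1, b = 2, c = 3, d = 4, e = 5))
  expect_equal(as.character(out$category), c("T", "MT", "MS", "S", "SS"))
  expect_equal(out$rank, 1:5)
  expect_equal(out$genotype, letters[1:5])
})

test_that("tied minima share the tolerant class with id-ordered ranks", {
  out <- rank_and_categorize(c(z = 1, a = 1, m = 3, q = 4, b = 5))
  expect_equal(out$genotype[1:2], c("a", "z"))
  expect_equal(out$rank[1:2], 1:2)
  expect_equal(as.character(out$category[1:2]), c("T", "T"))
})

test_that("identical scores collapse to the middle class with a warning", {
  expect_warning(
    out <- rank_and_categorize(setNames(rep(2, 6), letters[1:6])),
    "middle"
  )
  expect_true(all(out$category == "MS"))
  expect_equal(sort(out$rank), 1:6)
})

test_that("categories partition the panel and ranks are a permutation", {
  panel <- simulate_panel(panel_config(n_genotypes = 100, seed = 7))
  M <- build_index_matrices(panel)
  cf <- smith_hazel_coefficients(M)
  tab <- cti_table(panel, cf)
  expect_equal(sort(tab$rank), 1:100)
  expect_equal(anyDuplicated(tab$genotype), 0L)
  counts <- category_counts(tab)
  expect_equal(names(counts), c("T", "MT", "MS", "S", "SS"))
  expect_equal(sum(counts), 100L)
  # monotone: every genotype in an earlier class scores below later classes
  expect_true(all(diff(tab$CTI[order(tab$rank)]) >= 0))
  by_cat <- split(tab$CTI, tab$category)
  by_cat <- by_cat[lengths(by_cat) > 0]
  if (length(by_cat) > 1) {
    maxima <- vapply(by_cat, max, numeric(1))
    minima <- vapply(by_cat, min, numeric(1))
    expect_true(all(head(maxima, -1) <= minima[-1]))
  }
})

test_that("permuting panel rows leaves CTI and categories unchanged", {
  panel <- simulate_panel(panel_config(n_genotypes = 30, seed = 13))
  cf <- index_coefficients(c(0.967, 0.505, 0.335))
  tab1 <- cti_table(panel, cf)
  set.seed(1)
  shuffled <- panel[sample(nrow(panel)), ]
  tab2 <- cti_table(shuffled, cf)
  expect_equal(tab1, tab2)
})

test_that("quantile scheme and manual breakpoints are honoured", {
  scores <- setNames(1:20, sprintf("g%02d", 1:20))
  q <- rank_and_categorize(scores, scheme = "quantile")
  expect_equal(unname(category_counts(q)), rep(4L, 5))
  m <- rank_and_categorize(scores, breaks = c(2.5, 5.5, 10.5, 18.5))
  expect_equal(unname(category_counts(m)), c(2L, 3L, 5L, 8L, 2L))
})
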