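test_that("membership hits its boundaries and is dual", {
  expect_equal(membership(0, 0, 2, "positive"), 0)
  expect_equal(membership(2, 0, 2, "positive"), 1)
  expect_equal(membership(1, 0, 2, "positive"), 0.5)
  expect_equal(membership(1, 0, 2, "negative"), 0.5)
  expect_equal(membership(0.3, 0.3, 0.3, "positive"), 0.5)
  expect_error(membership(3, 0, 2, "positive"), "outside")
  set.seed(3)
  for (i in 1:20) {
    lo <- runif(1, -5, 0); hi <- lo + runif(1, 0.1, 5)
    x <- runif(50, lo, hi)
    expect_equal(membership(x, lo, hi, "positive") +
                   membership(x, lo, hi, "negative"), rep(1, 50))
  }
})

test_that("pca_weights handles the rank-1 and arithmetic cases", {
  set.seed(4)
  base <- rnorm(10)
  # two perfectly correlated traits: one component carries everything
  m <- cbind(t1 = base, t2 = 2 * base + 3)
  expect_warning(model <- pca_weights(m), regexp = NA)
  expect_equal(model$k_selected, 1)
  expect_equal(model$weights, 1)
  # eigenvalue shares (0.75, 0.25, 0, 0) with target 0.80 keep two components
  f1 <- rnorm(50)
  f2 <- stats::residuals(stats::lm(rnorm(50) ~ f1))  # exactly orthogonal
  x <- cbind(t1 = f1, t2 = 2 * f1 + 1, t3 = 0.5 * f1 - 3, t4 = f2)
  model2 <- pca_weights(x)
  expect_equal(model2$contribution, c(0.75, 0.25, 0, 0), tolerance = 1e-9)
  expect_equal(model2$k_selected, 2)
  expect_equal(unname(model2$weights), c(0.75, 0.25), tolerance = 1e-9)
  # constant columns are dropped with a warning
  expect_warning(pca_weights(cbind(m, flat = rep(1, 10))), "constant")
  expect_error(suppressWarnings(pca_weights(cbind(a = rep(1, 5),
                                                  b = rep(2, 5)))),
               "2 varying traits")
})

test_that("fixture eigenvalues, scores and CSTI match the eigen oracle", {
  m <- sti_fixture()
  dirs <- default_directions(colnames(m))
  oracle <- csti_oracle(m, dirs)
  model <- pca_weights(m)
  expect_equal(model$eigenvalues, oracle$eigenvalues, tolerance = 1e-9)
  expect_equal(model$k_selected, oracle$k)
  expect_equal(unname(model$scores[, 1:model$k_selected]),
               unname(oracle$scores[, 1:oracle$k]), tolerance = 1e-9)
  res <- csti(model, directions = dirs)
  expect_equal(res$csti, unname(oracle$csti), tolerance = 1e-9)
  expect_equal(sum(attr(res, "weights")), 1)
  expect_true(all(res$csti >= 0 & res$csti <= 1))
})

test_that("CSTI is invariant to positive affine trait rescaling", {
  m <- sti_fixture()
  dirs <- default_directions(colnames(m))
  base <- csti(pca_weights(m), directions = dirs)
  m2 <- sweep(sweep(m, 2, c(3, 0.5, 10, 2), `*`), 2, c(1, -2, 0.3, 5), `+`)
  scaled <- csti(pca_weights(m2), directions = dirs)
  expect_equal(scaled$csti, base$csti, tolerance = 1e-9)
  expect_equal(scaled$rank, base$rank)
})

test_that("permuting genotype rows permutes CSTI identically", {
  m <- sti_fixture()
  dirs <- default_directions(colnames(m))
  perm <- c(4, 1, 6, 2, 5, 3)
  a <- csti(pca_weights(m), directions = dirs)
  b <- csti(pca_weights(m[perm, ]), directions = dirs)
  expect_equal(b$csti[match(a$genotype, b$genotype)], a$csti,
               tolerance = 1e-9)
})

test_that("degenerate cases: single effective component and identical genotypes", {
  set.seed(5)
  base <- seq(0.5, 1.5, length.out = 8)
  m <- cbind(t1 = base, t2 = base * 1.3 + 0.1)
  model <- pca_weights(m)
  res <- csti(model, directions = c(t1 = "positive", t2 = "positive"))
  expect_equal(model$k_selected, 1)
  # one component: CSTI equals the single membership value, best 1, worst 0
  expect_equal(max(res$csti), 1)
  expect_equal(min(res$csti), 0)
  # and the CSTI ordering equals the trait ordering (monotonicity)
  expect_equal(order(res$csti), order(base))
})

test_that("trait-level membership reading also yields a convex score", {
  m <- sti_fixture()
  dirs <- default_directions(colnames(m))
  model <- pca_weights(m)
  res <- csti(model, directions = dirs, membership_level = "trait", sti = m)
  expect_true(all(res$csti >= 0 & res$csti <= 1))
  expect_equal(sum(attr(res, "weights")), 1)
})

test_that("classification grades well-separated CSTI values and rejects ties", {
  res <- data.frame(genotype = paste0("G", 1:5),
                    csti = c(0.95, 0.9, 0.5, 0.45, 0.1))
  cls <- classify(res)
  expect_equal(as.character(cls$class),
               c("salt-resistant", "salt-resistant", "salt-tolerant",
                 "salt-tolerant", "salt-sensitive"))
  flat <- data.frame(genotype = paste0("G", 1:4), csti = rep(0.5, 4))
  expect_error(classify(flat), "degenerate")
})

test_that("zero-noise planted panels are classified exactly", {
  panel <- gen_trait_panel(noise_sd = 0, replicate_sd = 0, seed = 11)
  ev <- evaluate_panel(panel$trait_table, directions = panel$directions)
  expect_equal(as.character(ev$result$class), panel$truth$class)
})
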