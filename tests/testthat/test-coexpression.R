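make_block_matrix <- function(module_sizes, n_samples = 12, block_cor = 1,
                              n_background = 0, seed = 1) {
  gen_expression(module_sizes = module_sizes, n_background = n_background,
                 groups = rep(paste0("grp", seq_len(n_samples %/% 3)),
                              each = 3),
                 block_cor = block_cor, linked_groups = rep(NA, length(module_sizes)),
                 seed = seed)
}

test_that("expression filtering drops low-abundance genes", {
  set.seed(8)
  fpkm <- matrix(runif(600, 0, 10), 100, 6,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("S", 1:6)))
  fpkm[1:40, ] <- fpkm[1:40, ] * 0.49  # max < 4.9
  kept <- filter_expression(fpkm, fpkm_min = 5)
  expect_true(all(apply(kept, 1, max) >= 5))
  expect_identical(filter_expression(fpkm, fpkm_min = 0), fpkm)
  expect_error(filter_expression(fpkm, fpkm_min = 1e6), "empty")
  sub <- filter_expression(fpkm, fpkm_min = 0, deg_set = c("g001", "g002"))
  expect_equal(rownames(sub), c("g001", "g002"))
})

test_that("soft-power adjacency obeys its identities and bounds", {
  s <- seq_len(8)
  x <- rbind(a = s, b = 2 * s + 1, c = -s + 10, d = s^2)
  net <- build_adjacency(x, soft_power = 12, transform = "none")
  a <- net$adjacency
  expect_equal(unname(a["a", "b"]), 1)          # cor  1 -> 1
  expect_equal(unname(a["a", "c"]), 1)          # cor -1 -> |.|^beta = 1
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, t(a))
  expect_equal(unname(diag(a)), rep(1, 4))
  # cor -0.5 at beta = 12 -> 0.5^12
  y <- rbind(u = c(1, -1, 0, 1, -1, 0), v = c(-1, 0, 1, 0, 1, -1))
  expect_equal(stats::cor(y["u", ], y["v", ]), -0.5)
  net2 <- build_adjacency(y, soft_power = 12, transform = "none")
  expect_equal(unname(net2$adjacency["u", "v"]), 0.000244140625)
  # raising beta never increases off-diagonal entries
  net6 <- build_adjacency(x, soft_power = 6, transform = "none")
  off <- upper.tri(a)
  expect_true(all(a[off] <= net6$adjacency[off] + 1e-15))
  # zero-variance genes are dropped with a warning
  expect_warning(build_adjacency(rbind(x, flat = rep(2, 8)),
                                 transform = "none"), "zero-variance")
})

test_that("eigengene matches a brute-force eigen-decomposition", {
  set.seed(9)
  block <- matrix(rnorm(30 * 8), 30, 8,
                  dimnames = list(sprintf("g%02d", 1:30), paste0("S", 1:8)))
  me <- eigengene(block)
  expect_equal(stats::sd(me), 1)
  # oracle: first eigenvector of the sample covariance of standardized genes
  z <- t(scale(t(block)))
  eg <- eigen(crossprod(z) / (nrow(z) - 1), symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  v1 <- v1 / stats::sd(v1)
  if (stats::cor(v1, colMeans(z)) < 0) v1 <- -v1
  expect_equal(unname(me), v1, tolerance = 1e-9)
  # rank-1 module: ME equals the standardized common profile
  common <- matrix(rep(block[1, ], 5), 5, byrow = TRUE,
                   dimnames = list(paste0("r", 1:5), colnames(block)))
  me1 <- eigengene(common)
  expect_equal(unname(stats::cor(me1, block[1, ])), 1, tolerance = 1e-12)
  # orientation is stable under negating every profile
  expect_equal(eigengene(-block), -me, tolerance = 1e-12)
  expect_equal(stats::cor(eigengene(block), me), 1, tolerance = 1e-12)
  expect_error(eigengene(matrix(1, 3, 4)), "constant")
})

test_that("planted orthogonal blocks are detected exactly", {
  ex <- make_block_matrix(c(40, 40), block_cor = 1, seed = 31)
  net <- build_adjacency(ex$fpkm)
  mods <- detect_modules(net, min_module_size = 30)
  expect_equal(sum(mods$modules == "grey"), 0)
  expect_equal(partition_agreement(mods$modules, ex$truth), 1)
  # too few genes per cluster: everything grey
  small <- make_block_matrix(c(10, 10), block_cor = 1, seed = 32)
  net_s <- build_adjacency(small$fpkm)
  expect_warning(grey <- detect_modules(net_s, min_module_size = 30),
                 "no module")
  expect_true(all(grey$modules == "grey"))
})

test_that("near-identical blocks merge into one module", {
  # two blocks driven by the same latent factor
  ex <- gen_expression(module_sizes = c(40, 40), n_background = 0,
                       groups = rep(paste0("grp", 1:4), each = 3),
                       block_cor = 0.95,
                       linked_groups = c("grp1", "grp1"),
                       group_shift = 8, seed = 33)
  net <- build_adjacency(ex$fpkm)
  mods <- detect_modules(net, min_module_size = 30, merge_cutoff = 0.25)
  expect_equal(length(setdiff(unique(mods$modules), "grey")), 1)
})

test_that("module-group correlation matches the direct Pearson formula", {
  ex <- make_block_matrix(c(40, 40), block_cor = 1, seed = 34)
  net <- build_adjacency(ex$fpkm)
  mods <- detect_modules(net, min_module_size = 30)
  groups <- c(rep("A", 3), rep("B", 3), rep("C", 3), rep("D", 3))
  mt <- module_trait_correlation(mods, groups)
  n <- length(groups)
  for (i in seq_len(nrow(mt))) {
    me <- mods$eigengenes[, mt$module[i]]
    ind <- as.numeric(groups == mt$group[i])
    r_hand <- sum((me - mean(me)) * (ind - mean(ind))) /
      sqrt(sum((me - mean(me))^2) * sum((ind - mean(ind))^2))
    expect_equal(mt$r[i], r_hand, tolerance = 1e-12)
    t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
    expect_equal(mt$p[i], 2 * stats::pt(-abs(t_hand), n - 2),
                 tolerance = 1e-12)
    expect_equal(mt$selected[i], abs(mt$r[i]) > 0.6 & mt$p[i] < 0.05)
  }
  expect_warning(module_trait_correlation(mods, c(groups[-1], "solo")),
                 "< 2 samples")
})

test_that("group-linked planted modules are selected for exactly their groups", {
  # defaults link each planted module to one sample group with a large shift
  ex <- gen_expression(seed = 35)
  net <- build_adjacency(filter_expression(ex$fpkm, 0))
  mods <- detect_modules(net, min_module_size = 30)
  mt <- module_trait_correlation(mods, unname(ex$groups))
  linked <- unique(unname(ex$groups))[1:4]
  want <- vapply(seq_along(linked), function(m) {
    detected <- unique(mods$modules[names(ex$truth)[ex$truth ==
                                                      paste0("planted", m)]])
    expect_length(detected, 1)
    paste(detected, linked[m])
  }, character(1))
  got <- paste(mt$module[mt$selected], mt$group[mt$selected])
  expect_setequal(got, want)
})

test_that("hub genes equal the row-sum oracle and break ties by identifier", {
  # star topology: one center correlated with independent leaves
  set.seed(36)
  n <- 24
  center <- rnorm(n)
  leaves <- sapply(1:9, function(i) 0.8 * center + 0.6 * rnorm(n))
  x <- rbind(hub = center, t(leaves))
  rownames(x) <- c("hub", paste0("leaf", 1:9))
  colnames(x) <- paste0("S", 1:n)
  net <- build_adjacency(x, soft_power = 6, transform = "none")
  mods <- structure(list(modules = stats::setNames(rep("m1", 10), rownames(x)),
                         eigengenes = NULL, sizes = c(m1 = 10)),
                    class = "module_set")
  hb <- hub_genes(net, mods, which_modules = "m1", top_edges = 5)
  expect_equal(hb$hubs$gene, "hub")
  # oracle: argmax of brute-force row sums of the adjacency submatrix
  k <- rowSums(net$adjacency) - 1
  expect_equal(hb$hubs$gene, names(which.max(k)))
  expect_equal(hb$hubs$connectivity, unname(max(k)))
  expect_true(all(table(hb$edges$source) <= 5))
  # identical genes tie; the first identifier wins
  y <- rbind(b_gene = seq_len(6), a_gene = seq_len(6), c_gene = seq_len(6))
  colnames(y) <- paste0("S", 1:6)
  net_t <- build_adjacency(y, soft_power = 2, transform = "none")
  mods_t <- structure(list(modules = stats::setNames(rep("m", 3), rownames(y)),
                           eigengenes = NULL, sizes = c(m = 3)),
                      class = "module_set")
  expect_equal(hub_genes(net_t, mods_t)$hubs$gene, "a_gene")
  expect_warning(
    hub_genes(net_t, structure(list(modules = c(a_gene = "solo"),
                                    eigengenes = NULL, sizes = c(solo = 1)),
                               class = "module_set"),
              which_modules = "solo"),
    "fewer than 2")
})
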