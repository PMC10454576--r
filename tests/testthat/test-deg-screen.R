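test_that("DEG calls use inclusive FDR and fold-change thresholds", {
  de <- data.frame(
    contrast = "X", gene = c("g1", "g2", "g3"),
    log2fc = c(1.0, 0.99, -2.0), fdr = c(0.05, 0.001, 0.20),
    stringsAsFactors = FALSE
  )
  out <- call_degs(de)
  expect_equal(out$gene, "g1")
  expect_equal(out$direction, "up")
  expect_equal(nrow(call_degs(de[0, ])), 0)
})

test_that("rules 3 and 4 apply the log2FC gap as specified", {
  spec <- contrast_spec("NY2", "GP2", timepoints = "05")
  mk <- function(gene, tol, sen, btw = 0, fdr = 0.01) {
    rbind(
      data.frame(contrast = "NY2-05_vs_NY2-00", gene = gene, log2fc = tol,
                 fdr = fdr, stringsAsFactors = FALSE),
      data.frame(contrast = "GP2-05_vs_GP2-00", gene = gene, log2fc = sen,
                 fdr = fdr, stringsAsFactors = FALSE),
      data.frame(contrast = "GP2-05_vs_NY2-05", gene = gene, log2fc = btw,
                 fdr = 0.9, stringsAsFactors = FALSE)
    )
  }
  # up in both, gap 1.0 > 0.6 -> rule 3
  r <- salt_tolerance_screen(mk("gA", 2.0, 1.0), spec)$per_timepoint[["05"]]
  expect_true(r$rule3[r$gene == "gA"])
  # gap 0.2 -> rule 3 not satisfied (rule 2 still catches the tolerant DEG)
  r <- salt_tolerance_screen(mk("gB", 1.2, 1.0), spec)$per_timepoint[["05"]]
  expect_false(r$rule3[r$gene == "gB"])
  # down in both, sensitive - tolerant = -1.0 < -0.6 -> rule 4
  r <- salt_tolerance_screen(mk("gC", -2.0, -3.0), spec)$per_timepoint[["05"]]
  expect_true(r$rule4[r$gene == "gC"])
  expect_equal(r$direction[r$gene == "gC"], "down")
  # missing contrast is a configuration error naming it
  de <- mk("gD", 1, 1)
  expect_error(
    salt_tolerance_screen(de[de$contrast != "GP2-05_vs_GP2-00", ], spec),
    "GP2-05_vs_GP2-00"
  )
})

test_that("screen equals an independent per-gene brute-force loop", {
  spec <- contrast_spec("NY2", "GP2", timepoints = c("05", "3", "12"))
  for (seed in 1:10) {
    de <- random_de_table(spec, n_genes = 200, seed = seed)
    got <- salt_tolerance_screen(de, spec)
    want <- brute_screen(de, spec)
    for (tp in spec$timepoints) {
      expect_equal(got$per_timepoint[[tp]]$gene, want[[tp]])
    }
  }
})

test_that("screen is monotone in delta and fdr_max and empty without rules", {
  spec <- contrast_spec("NY2", "GP2", timepoints = c("05", "3"))
  de <- random_de_table(spec, n_genes = 300, seed = 99)
  r34 <- function(delta) {
    res <- salt_tolerance_screen(de, spec, delta = delta, rules = c(3, 4))
    lapply(res$per_timepoint, function(d) d$gene)
  }
  small <- r34(0.3); big <- r34(1.2)
  for (tp in spec$timepoints) {
    expect_true(all(big[[tp]] %in% small[[tp]]))
  }
  sets <- function(fdr_max) {
    res <- salt_tolerance_screen(de, spec, fdr_max = fdr_max)
    lapply(res$per_timepoint, function(d) d$gene)
  }
  strict <- sets(0.01); lax <- sets(0.2)
  for (tp in spec$timepoints) {
    expect_true(all(strict[[tp]] %in% lax[[tp]]))
  }
  none <- salt_tolerance_screen(de, spec, rules = integer(0))
  expect_true(all(none$counts == 0))
})

test_that("planted screen genes are recovered with precision and recall 1", {
  degs <- gen_de_tables(n_genes = 500, seed = 21)
  scr <- salt_tolerance_screen(degs$de_table, degs$spec)
  for (tp in degs$spec$timepoints) {
    planted <- sort(unique(unlist(degs$truth[[tp]])))
    expect_equal(scr$per_timepoint[[tp]]$gene, planted)
    tab <- scr$per_timepoint[[tp]]
    expect_equal(sort(tab$gene[tab$rule3]), degs$truth[[tp]]$r3)
    expect_equal(sort(tab$gene[tab$rule4]), degs$truth[[tp]]$r4)
  }
})

test_that("intersection accounting matches per-gene enumeration", {
  s <- list(A = c("g1", "g2"), B = c("g2", "g3"))
  tab <- intersect_across(s)
  expect_equal(tab$size[tab$region == "A"], 1)       # A only
  expect_equal(tab$size[tab$region == "B"], 1)       # B only
  expect_equal(tab$size[tab$region == "A&B"], 1)
  disjoint <- intersect_across(list(A = "g1", B = "g2", C = "g3"))
  expect_equal(disjoint$size[disjoint$region == "A&B&C"], 0)
  expect_error(intersect_across(list(A = "g1")), ">= 2")
  expect_error(intersect_across(stats::setNames(list("g1", "g2"), c("A", "A"))),
               "duplicate")
  # brute-force oracle: enumerate each gene's exclusive membership pattern
  set.seed(7)
  universe <- sprintf("g%03d", 1:200)
  sets <- lapply(1:4, function(i) sample(universe, 50))
  names(sets) <- LETTERS[1:4]
  tab <- intersect_across(sets)
  pattern <- vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$size[i], sum(pattern == tab$region[i]))
  }
})
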