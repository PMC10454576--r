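# Shared fixtures and independent oracles used across test files.

# fixed 6-genotype x 4-trait STI matrix (values chosen once; 6 significant
# digits so tables round-trip exactly through the writers)
sti_fixture <- function() {
  matrix(c(
    1.10, 0.95, 0.80, 1.05,
    0.90, 0.85, 1.10, 0.95,
    1.20, 1.10, 0.70, 1.15,
    0.60, 0.55, 1.30, 0.70,
    1.00, 0.90, 0.90, 1.00,
    0.75, 0.70, 1.20, 0.85
  ), nrow = 6, byrow = TRUE,
  dimnames = list(paste0("G", 1:6),
                  c("FW_shoot", "RWC_leaf", "Na_leaf", "ratio_K_Na_leaf")))
}

# independent CSTI oracle: explicit eigen-decomposition of the correlation
# matrix plus direct matrix algebra, applying the documented sign and
# direction conventions; shares no code path with pca_weights()/csti()
csti_oracle <- function(m, directions, variance_target = 0.80) {
  z <- scale(m)
  eg <- eigen(stats::cor(m), symmetric = TRUE)
  ev <- eg$values
  contrib <- ev / sum(ev)
  k <- which(cumsum(contrib) >= variance_target - 1e-12)[1]
  V <- eg$vectors
  for (i in seq_len(ncol(V))) {
    top <- which.max(abs(V[, i]))
    if (V[top, i] < 0) V[, i] <- -V[, i]
  }
  scores <- z %*% V
  sgn <- ifelse(directions[colnames(m)] == "negative", -1, 1)
  w <- contrib[seq_len(k)] / sum(contrib[seq_len(k)])
  mu <- sapply(seq_len(k), function(i) {
    s <- scores[, i] * (if (sum(sgn * V[, i]) >= 0) 1 else -1)
    (s - min(s)) / (max(s) - min(s))
  })
  list(eigenvalues = ev, scores = scores, k = k, weights = w,
       csti = drop(mu %*% w))
}

# independent brute-force re-implementation of the four-rule screen:
# loops per gene and per rule on raw table rows
brute_screen <- function(de, spec, fdr_max = 0.05, min_abs_log2fc = 1,
                         delta = 0.6, rules = 1:4) {
  out <- list()
  for (tp in spec$timepoints) {
    c_tol <- sprintf("%s-%s_vs_%s-%s", spec$tolerant, tp,
                     spec$tolerant, spec$baseline)
    c_sen <- sprintf("%s-%s_vs_%s-%s", spec$sensitive, tp,
                     spec$sensitive, spec$baseline)
    c_btw <- sprintf("%s-%s_vs_%s-%s", spec$sensitive, tp,
                     spec$tolerant, tp)
    genes <- unique(de$gene)
    hit <- character()
    for (g in genes) {
      pick <- function(cc) de[de$contrast == cc & de$gene == g, , drop = FALSE]
      rt <- pick(c_tol); rs <- pick(c_sen); rb <- pick(c_btw)
      is_deg <- function(r) {
        nrow(r) == 1 && r$fdr <= fdr_max && abs(r$log2fc) >= min_abs_log2fc
      }
      sel <- FALSE
      if (1 %in% rules && is_deg(rb)) sel <- TRUE
      if (2 %in% rules && is_deg(rt)) sel <- TRUE
      if (3 %in% rules && is_deg(rt) && is_deg(rs) &&
          rt$log2fc > 0 && rs$log2fc > 0 &&
          rt$log2fc - rs$log2fc > delta) sel <- TRUE
      if (4 %in% rules && is_deg(rt) && is_deg(rs) &&
          rt$log2fc < 0 && rs$log2fc < 0 &&
          rs$log2fc - rt$log2fc < -delta) sel <- TRUE
      if (sel) hit <- c(hit, g)
    }
    out[[tp]] <- sort(hit)
  }
  out
}

# random DE table over all contrasts of a spec (no values near thresholds
# are excluded on purpose: ties have probability zero under the continuous
# draws)
random_de_table <- function(spec, n_genes, seed) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  contrasts <- unlist(lapply(spec$timepoints, function(tp) {
    c(sprintf("%s-%s_vs_%s-%s", spec$tolerant, tp, spec$tolerant, spec$baseline),
      sprintf("%s-%s_vs_%s-%s", spec$sensitive, tp, spec$sensitive, spec$baseline),
      sprintf("%s-%s_vs_%s-%s", spec$sensitive, tp, spec$tolerant, tp))
  }))
  do.call(rbind, lapply(contrasts, function(cc) {
    data.frame(contrast = cc, gene = genes,
               log2fc = stats::rnorm(n_genes, 0, 1.5),
               fdr = stats::runif(n_genes), stringsAsFactors = FALSE)
  }))
}

# tiny three-replicate trait table builder
toy_trait_table <- function() {
  expand_tt <- expand.grid(
    genotype = c("A", "B", "C"), trait = c("FW_shoot", "DW_shoot"),
    condition = c("control", "salt"), timepoint = "24h", replicate = 1:2,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  set.seed(42)
  expand_tt$value <- signif(stats::runif(nrow(expand_tt), 0.5, 2), 6)
  expand_tt
}
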