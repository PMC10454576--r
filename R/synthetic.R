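#' @title Synthetic-data generators with planted ground truth
#' @description Generators that emulate the statistical structure each
#'   pipeline stage assumes -- a genotype panel with three planted tolerance
#'   classes, a two-genotype by four-timepoint contrast set with planted
#'   screen-positive genes, and an expression matrix with planted
#'   co-expression modules tied to sample groups. All generators are pure
#'   functions of their arguments including the seed: identical calls give
#'   identical output. The planted truth is returned alongside, never
#'   consumed by the pipeline.
#' @name saltscreen-synthetic
NULL

#' Default trait panel for the synthetic genotype generator
#'
#' Sixteen traits mirroring a seedling salt-tolerance panel: organ fresh and
#' dry weights, leaf relative water content, root-shoot ratio, organ Na
#' content (direction negative), K and Mg content, and K/Na selectivity
#' ratios. Baselines are control-condition means in trait-specific units.
#'
#' @return `data.frame` with trait, direction, baseline.
#' @export
default_panel_traits <- function() {
  data.frame(
    trait = c("FW_shoot", "DW_shoot", "FW_root", "DW_root", "RWC_leaf",
              "RS_ratio", "Na_root", "Na_stem", "Na_leaf", "K_root",
              "K_stem", "K_leaf", "Mg_leaf", "ratio_K_Na_root",
              "ratio_K_Na_leaf", "ISC_K_root_stem"),
    direction = c("positive", "positive", "positive", "positive", "positive",
                  "positive", "negative", "negative", "negative", "positive",
                  "positive", "positive", "positive", "positive",
                  "positive", "positive"),
    baseline = c(8, 1.2, 2.5, 0.35, 85, 0.3, 4, 5, 6, 30, 25, 20, 8,
                 7.5, 3.3, 1.1),
    stringsAsFactors = FALSE
  )
}

#' Generate a genotype trait panel with planted tolerance classes
#'
#' Control values are drawn around each trait's baseline (5% genotype
#' spread); salt values are `control x STI`, where the genotype-level STI is
#' normal around a class mean and truncated to `(0, 2]` to keep trait values
#' physical. For positive-direction traits the sensitive class sits at
#' `sti_base` and each class step up adds `class_effect` standard deviations
#' (`class_effect * noise_sd`; when `noise_sd = 0` a nominal scale of 0.05
#' replaces the SD so the classes still separate); negative-direction traits
#' get the inverted ordering around `2 - sti_base`. Replicates add small
#' multiplicative measurement noise.
#'
#' @param n_genotypes panel size, default 46.
#' @param class_sizes named integer vector (resistant, tolerant, sensitive)
#'   summing to `n_genotypes`; the default 2/19/25 mirrors a published
#'   seedling panel split.
#' @param traits a data.frame as from [default_panel_traits()].
#' @param class_effect per-class mean shift of the STI, in SD units.
#' @param noise_sd genotype-level STI standard deviation.
#' @param replicate_sd multiplicative replicate noise SD.
#' @param n_replicates biological replicates per cell, default 3.
#' @param sti_base sensitive-class mean STI for positive traits.
#' @param timepoint timepoint label stamped on all records.
#' @param seed RNG seed.
#' @return list with `trait_table`, `truth` (genotype, class),
#'   `directions`.
#' @export
gen_trait_panel <- function(n_genotypes = 46,
                            class_sizes = c(resistant = 2, tolerant = 19,
                                            sensitive = 25),
                            traits = default_panel_traits(),
                            class_effect = 4, noise_sd = 0.05,
                            replicate_sd = 0.02, n_replicates = 3,
                            sti_base = 0.6, timepoint = "24h", seed = 1) {
  if (sum(class_sizes) != n_genotypes) {
    stop("class sizes must sum to n_genotypes", call. = FALSE)
  }
  if (!all(c("resistant", "tolerant", "sensitive") %in% names(class_sizes))) {
    stop("class_sizes needs resistant, tolerant and sensitive entries",
         call. = FALSE)
  }
  with_rng(seed, {
    genotype <- sprintf("G%02d", seq_len(n_genotypes))
    class <- rep(c("salt-resistant", "salt-tolerant", "salt-sensitive"),
                 times = class_sizes[c("resistant", "tolerant", "sensitive")])
    step <- class_effect * if (noise_sd > 0) noise_sd else 0.05
    class_idx <- c("salt-sensitive" = 0, "salt-tolerant" = 1,
                   "salt-resistant" = 2)[class]
    rows <- list()
    for (ti in seq_len(nrow(traits))) {
      tr <- traits$trait[ti]
      positive <- traits$direction[ti] == "positive"
      mu <- if (positive) sti_base + class_idx * step
            else (2 - sti_base) - class_idx * step
      sti_g <- stats::rnorm(n_genotypes, mu, noise_sd)
      sti_g <- pmin(pmax(sti_g, 1e-3), 2)
      ctrl_g <- traits$baseline[ti] *
        exp(stats::rnorm(n_genotypes, 0, 0.05))
      for (cond in c("control", "salt")) {
        base_val <- if (cond == "control") ctrl_g else ctrl_g * sti_g
        for (r in seq_len(n_replicates)) {
          val <- base_val * exp(stats::rnorm(n_genotypes, 0, replicate_sd))
          rows[[length(rows) + 1L]] <- data.frame(
            genotype = genotype, trait = tr, condition = cond,
            timepoint = timepoint, replicate = r, value = val,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    tt <- do.call(rbind, rows)
    rownames(tt) <- NULL
    list(
      trait_table = validate_trait_table(tt),
      truth = data.frame(genotype = genotype, class = class,
                         stringsAsFactors = FALSE),
      directions = stats::setNames(traits$direction, traits$trait)
    )
  })
}

#' Generate DE tables with planted screen-positive genes
#'
#' For every timepoint, emits the three contrasts the four-rule screen
#' requires. Planted rule-3 genes are up-regulated versus baseline in both
#' genotypes with a tolerant-minus-sensitive log2FC gap of at least
#' `delta_gap`; rule-4 genes mirror this downwards; rule-1 genes differ only
#' between genotypes. Null genes get near-zero log2FC (clipped at 0.8) and
#' FDR drawn from `[0.2, 1]`, so no gene sits on a decision boundary.
#'
#' @param n_genes universe size per timepoint, default 2000.
#' @param timepoints,tolerant,sensitive,baseline contrast layout; defaults
#'   follow a two-genotype, four-timepoint salt time course.
#' @param n_planted_r1,n_planted_r3,n_planted_r4 planted genes per rule and
#'   timepoint.
#' @param delta_gap minimum log2FC gap for planted rule-3/4 genes, default 1.
#' @param seed RNG seed.
#' @return list with `de_table` (all contrasts stacked), `spec` (the
#'   matching [contrast_spec()]) and `truth` (per-timepoint list of
#'   `r1`/`r3`/`r4` gene id vectors).
#' @export
gen_de_tables <- function(n_genes = 2000,
                          timepoints = c("05", "3", "12", "24"),
                          tolerant = "NY2", sensitive = "GP2",
                          baseline = "00",
                          n_planted_r1 = 30, n_planted_r3 = 40,
                          n_planted_r4 = 30, delta_gap = 1.0, seed = 1) {
  n_planted <- n_planted_r1 + n_planted_r3 + n_planted_r4
  if (n_planted > n_genes) {
    stop("planted counts exceed n_genes", call. = FALSE)
  }
  spec <- contrast_spec(tolerant, sensitive, timepoints, baseline)
  with_rng(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    tabs <- list(); truth <- list()
    null_fc <- function(n) pmin(pmax(stats::rnorm(n, 0, 0.2), -0.8), 0.8)
    null_fdr <- function(n) stats::runif(n, 0.2, 1)
    sig_fdr <- function(n) stats::runif(n, 1e-6, 0.01)
    for (tp in timepoints) {
      planted <- sample(genes, n_planted)
      r1 <- sort(planted[seq_len(n_planted_r1)])
      r3 <- sort(planted[n_planted_r1 + seq_len(n_planted_r3)])
      r4 <- sort(planted[n_planted_r1 + n_planted_r3 + seq_len(n_planted_r4)])
      lfc_tol <- null_fc(n_genes); lfc_sen <- null_fc(n_genes)
      fdr_tol <- null_fdr(n_genes); fdr_sen <- null_fdr(n_genes)
      names(lfc_tol) <- names(lfc_sen) <- genes
      names(fdr_tol) <- names(fdr_sen) <- genes
      # rule 3: both up, tolerant leads by > delta_gap
      lfc_sen[r3] <- stats::runif(length(r3), 1.2, 2)
      lfc_tol[r3] <- lfc_sen[r3] + stats::runif(length(r3), delta_gap, delta_gap + 1)
      fdr_tol[r3] <- sig_fdr(length(r3)); fdr_sen[r3] <- sig_fdr(length(r3))
      # rule 4: both down, sensitive falls by > delta_gap more
      lfc_tol[r4] <- -stats::runif(length(r4), 1.2, 2)
      lfc_sen[r4] <- lfc_tol[r4] - stats::runif(length(r4), delta_gap, delta_gap + 1)
      fdr_tol[r4] <- sig_fdr(length(r4)); fdr_sen[r4] <- sig_fdr(length(r4))
      # between-genotype contrast: consistent with the planted responses
      lfc_btw <- null_fc(n_genes); fdr_btw <- null_fdr(n_genes)
      names(lfc_btw) <- names(fdr_btw) <- genes
      lfc_btw[r1] <- sample(c(-1, 1), length(r1), replace = TRUE) *
        stats::runif(length(r1), 1.5, 3)
      fdr_btw[r1] <- sig_fdr(length(r1))
      lfc_btw[r3] <- lfc_sen[r3] - lfc_tol[r3]
      fdr_btw[r3] <- sig_fdr(length(r3))
      lfc_btw[r4] <- lfc_sen[r4] - lfc_tol[r4]
      fdr_btw[r4] <- sig_fdr(length(r4))
      tabs[[tp]] <- rbind(
        data.frame(contrast = contrast_vs_baseline(tolerant, tp, baseline),
                   gene = genes, log2fc = unname(lfc_tol),
                   fdr = unname(fdr_tol), stringsAsFactors = FALSE),
        data.frame(contrast = contrast_vs_baseline(sensitive, tp, baseline),
                   gene = genes, log2fc = unname(lfc_sen),
                   fdr = unname(fdr_sen), stringsAsFactors = FALSE),
        data.frame(contrast = contrast_between(sensitive, tolerant, tp),
                   gene = genes, log2fc = unname(lfc_btw),
                   fdr = unname(fdr_btw), stringsAsFactors = FALSE)
      )
      truth[[tp]] <- list(r1 = r1, r3 = r3, r4 = r4)
    }
    de <- do.call(rbind, tabs)
    rownames(de) <- NULL
    list(de_table = validate_de_table(de), spec = spec, truth = truth)
  })
}

#' Generate an FPKM matrix with planted co-expression modules
#'
#' Each module is built from a latent per-sample factor: member genes are
#' `sqrt(block_cor) * factor + sqrt(1 - block_cor) * noise` on the log2
#' scale, giving an expected within-module correlation of `block_cor`.
#' Modules mapped to a sample group in `linked_groups` have their factor
#' shifted by `group_shift` in that group, tying the module to the group.
#' Background genes are independent noise. Log2 expression is exponentiated
#' around per-gene abundance levels, so FPKM is non-negative.
#'
#' @param module_sizes integer vector of module sizes.
#' @param n_background independent background genes.
#' @param groups character vector of sample group labels, one per sample;
#'   default 8 groups (two genotypes x four timepoints) of 3 replicates.
#' @param block_cor target within-module correlation, default 0.9.
#' @param linked_groups optional character vector mapping module index to a
#'   group label (`NA` for unlinked modules); default links each module to
#'   the corresponding group in order.
#' @param group_shift latent factor shift in the linked group, default 3.
#' @param seed RNG seed.
#' @return list with `fpkm` (gene x sample matrix), `groups`, and `truth`
#'   (planted module label per gene, background as `"grey"`).
#' @export
gen_expression <- function(module_sizes = rep(60, 4), n_background = 120,
                           groups = rep(paste0(rep(c("NY2", "GP2"), each = 4),
                                               "-", c("05", "3", "12", "24")),
                                        each = 3),
                           block_cor = 0.9, linked_groups = NULL,
                           group_shift = 3, seed = 1) {
  stopifnot(all(module_sizes >= 2), block_cor >= 0, block_cor <= 1)
  n_samples <- length(groups)
  n_mod <- length(module_sizes)
  if (is.null(linked_groups)) {
    linked_groups <- unique(groups)[seq_len(min(n_mod, length(unique(groups))))]
    if (n_mod > length(linked_groups)) {
      linked_groups <- c(linked_groups, rep(NA, n_mod - length(linked_groups)))
    }
  }
  with_rng(seed, {
    n_genes <- sum(module_sizes) + n_background
    genes <- sprintf("gene%05d", seq_len(n_genes))
    samples <- sprintf("S%02d", seq_len(n_samples))
    truth <- rep("grey", n_genes)
    logx <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
    idx <- 0
    for (m in seq_len(n_mod)) {
      f <- stats::rnorm(n_samples)
      if (!is.na(linked_groups[m])) {
        f <- f + group_shift * (groups == linked_groups[m])
      }
      for (g in seq_len(module_sizes[m])) {
        idx <- idx + 1
        e <- stats::rnorm(n_samples)
        logx[idx, ] <- sqrt(block_cor) * f + sqrt(1 - block_cor) * e
        truth[idx] <- paste0("planted", m)
      }
    }
    if (n_background > 0) {
      bg <- matrix(stats::rnorm(n_background * n_samples), n_background)
      logx[idx + seq_len(n_background), ] <- bg
    }
    level <- stats::rnorm(n_genes, 5, 1)
    fpkm <- 2^(logx + level)
    list(fpkm = fpkm, groups = stats::setNames(groups, samples),
         truth = stats::setNames(truth, genes))
  })
}

#' Agreement between two partitions of the same genes
#'
#' Fraction of items whose detected label matches the planted label under
#' the best greedy one-to-one matching of label pairs (largest overlaps
#' first). Used to score module and class recovery against planted truth.
#'
#' @param detected,planted label vectors of equal length (aligned by
#'   position, or by names when both are named).
#' @return agreement in `[0, 1]`.
#' @export
partition_agreement <- function(detected, planted) {
  if (!is.null(names(detected)) && !is.null(names(planted))) {
    detected <- detected[names(planted)]
  }
  stopifnot(length(detected) == length(planted))
  tab <- table(detected, planted)
  matched <- 0
  while (nrow(tab) > 0 && ncol(tab) > 0 && max(tab) > 0) {
    idx <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    matched <- matched + tab[idx[1], idx[2]]
    tab <- tab[-idx[1], -idx[2], drop = FALSE]
  }
  matched / length(planted)
}
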