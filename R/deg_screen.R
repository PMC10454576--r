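#' Contrast specification for the genotype-contrast screen
#'
#' Names the tolerant and sensitive genotypes, the ordered salt-treatment
#' timepoints, and the untreated baseline label. The screen expects, for each
#' timepoint `t`, three contrasts named by [contrast_vs_baseline()] and
#' [contrast_between()]: tolerant-t vs tolerant-baseline, sensitive-t vs
#' sensitive-baseline, and sensitive-t vs tolerant-t.
#'
#' @param tolerant,sensitive genotype labels (distinct).
#' @param timepoints ordered timepoint labels, e.g. `c("05","3","12","24")`.
#' @param baseline baseline label, not among `timepoints`.
#' @return a list of class `contrast_spec`.
#' @export
contrast_spec <- function(tolerant, sensitive,
                          timepoints = c("05", "3", "12", "24"),
                          baseline = "00") {
  if (identical(tolerant, sensitive)) {
    stop("tolerant and sensitive genotypes must be distinct", call. = FALSE)
  }
  if (baseline %in% timepoints) {
    stop("baseline must not be among the timepoints", call. = FALSE)
  }
  if (anyDuplicated(timepoints)) {
    stop("duplicate timepoint labels", call. = FALSE)
  }
  structure(list(tolerant = tolerant, sensitive = sensitive,
                 timepoints = as.character(timepoints),
                 baseline = as.character(baseline)),
            class = "contrast_spec")
}

#' @rdname contrast_spec
#' @param genotype genotype label.
#' @param timepoint timepoint label.
#' @export
contrast_vs_baseline <- function(genotype, timepoint, baseline = "00") {
  sprintf("%s-%s_vs_%s-%s", genotype, timepoint, genotype, baseline)
}

#' @rdname contrast_spec
#' @export
contrast_between <- function(sensitive, tolerant, timepoint) {
  sprintf("%s-%s_vs_%s-%s", sensitive, timepoint, tolerant, timepoint)
}

#' Call differentially expressed genes in one contrast
#'
#' A gene is a DEG iff `fdr <= fdr_max` and `|log2fc| >= min_abs_log2fc`
#' (both thresholds inclusive; the defaults encode "FDR below 5% and at
#' least a two-fold change"). The sign of the log2 fold change gives the
#' direction.
#'
#' @param table a DE table (`contrast`, `gene`, `log2fc`, `fdr`); rows of
#'   all contrasts may be stacked, see `contrast`.
#' @param fdr_max,min_abs_log2fc inclusive thresholds, positive.
#' @param contrast optional contrast label to restrict to.
#' @return `data.frame` with columns `gene`, `log2fc`, `direction`
#'   (`"up"`/`"down"`); empty input yields an empty frame.
#' @export
call_degs <- function(table, fdr_max = 0.05, min_abs_log2fc = 1,
                      contrast = NULL) {
  stopifnot(fdr_max > 0, min_abs_log2fc > 0)
  df <- validate_de_table(table)
  if (!is.null(contrast)) df <- df[df$contrast == contrast, , drop = FALSE]
  sel <- df$fdr <= fdr_max & abs(df$log2fc) >= min_abs_log2fc
  out <- df[sel, c("gene", "log2fc"), drop = FALSE]
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

get_contrast <- function(de, label) {
  sub <- de[de$contrast == label, , drop = FALSE]
  if (!nrow(sub)) {
    stop("required contrast absent from DE table: ", label, call. = FALSE)
  }
  sub
}

#' Four-rule screen for salt-tolerance-related DEGs
#'
#' Per timepoint `t`, with DEG calls at (`fdr_max`, `min_abs_log2fc`):
#' * rule 1: genes differentially expressed between the sensitive and
#'   tolerant genotypes at `t`;
#' * rule 2: genes differentially expressed in the tolerant genotype at `t`
#'   versus its baseline;
#' * rule 3: genes up-regulated versus baseline in both genotypes whose
#'   tolerant log2FC exceeds the sensitive log2FC by more than `delta`;
#' * rule 4: genes down-regulated versus baseline in both genotypes whose
#'   sensitive log2FC is more than `delta` below the tolerant log2FC
#'   (sensitive - tolerant < -delta).
#'
#' The per-timepoint result is the union of the enabled rule sets, with
#' per-gene provenance flags.
#'
#' @param de a DE table containing all required contrasts.
#' @param spec a [contrast_spec()].
#' @param fdr_max,min_abs_log2fc DEG thresholds (inclusive).
#' @param delta log2 fold-change gap for rules 3 and 4 (strict).
#' @param rules integer subset of `1:4`; disabling all rules yields empty
#'   sets.
#' @return list of class `screen_result`: `per_timepoint` (named list of
#'   data.frames with gene, rule flags, direction and the two
#'   versus-baseline log2FCs), `counts`, and `intersections` across
#'   timepoints (see [intersect_across()]).
#' @export
salt_tolerance_screen <- function(de, spec, fdr_max = 0.05,
                                  min_abs_log2fc = 1, delta = 0.6,
                                  rules = 1:4) {
  stopifnot(inherits(spec, "contrast_spec"))
  rules <- as.integer(rules)
  if (!all(rules %in% 1:4)) stop("rules must be a subset of 1:4", call. = FALSE)
  de <- validate_de_table(de)
  per_tp <- list()
  for (tp in spec$timepoints) {
    c_tol <- contrast_vs_baseline(spec$tolerant, tp, spec$baseline)
    c_sen <- contrast_vs_baseline(spec$sensitive, tp, spec$baseline)
    c_btw <- contrast_between(spec$sensitive, spec$tolerant, tp)
    tol <- get_contrast(de, c_tol)
    sen <- get_contrast(de, c_sen)
    btw <- get_contrast(de, c_btw)

    deg_tol <- call_degs(tol, fdr_max, min_abs_log2fc)
    deg_sen <- call_degs(sen, fdr_max, min_abs_log2fc)
    deg_btw <- call_degs(btw, fdr_max, min_abs_log2fc)

    lfc_tol <- stats::setNames(tol$log2fc, tol$gene)
    lfc_sen <- stats::setNames(sen$log2fc, sen$gene)

    r1 <- deg_btw$gene
    r2 <- deg_tol$gene
    both_up <- intersect(deg_tol$gene[deg_tol$direction == "up"],
                         deg_sen$gene[deg_sen$direction == "up"])
    r3 <- both_up[lfc_tol[both_up] - lfc_sen[both_up] > delta]
    both_dn <- intersect(deg_tol$gene[deg_tol$direction == "down"],
                         deg_sen$gene[deg_sen$direction == "down"])
    r4 <- both_dn[lfc_sen[both_dn] - lfc_tol[both_dn] < -delta]

    sets <- list(`1` = r1, `2` = r2, `3` = r3, `4` = r4)
    genes <- sort(unique(unlist(sets[as.character(rules)], use.names = FALSE)))
    flag <- function(r) genes %in% sets[[as.character(r)]] & r %in% rules
    tab <- data.frame(
      gene = genes,
      rule1 = flag(1), rule2 = flag(2), rule3 = flag(3), rule4 = flag(4),
      log2fc_tolerant = unname(lfc_tol[genes]),
      log2fc_sensitive = unname(lfc_sen[genes]),
      stringsAsFactors = FALSE
    )
    # direction: from the tolerant-vs-baseline response when available,
    # else from the between-genotype contrast (rule-1-only genes)
    dir_btw <- stats::setNames(deg_btw$direction, deg_btw$gene)
    tab$direction <- ifelse(!is.na(tab$log2fc_tolerant),
                            ifelse(tab$log2fc_tolerant >= 0, "up", "down"),
                            unname(dir_btw[genes]))
    per_tp[[tp]] <- tab
  }
  gene_sets <- lapply(per_tp, function(d) d$gene)
  structure(list(
    per_timepoint = per_tp,
    counts = vapply(per_tp, nrow, integer(1)),
    intersections = if (length(gene_sets) >= 2) intersect_across(gene_sets)
                    else NULL
  ), class = "screen_result")
}

#' Intersection accounting across labelled gene sets
#'
#' For up to six sets, tabulates the cardinality of every non-empty Venn
#' region (each exclusive combination of set memberships); for more sets,
#' reports pairwise intersections and the full intersection only.
#'
#' @param sets named list (>= 2, unique labels) of character vectors.
#' @return `data.frame` with columns `region` (labels joined by `&`) and
#'   `size`; for > 6 sets, columns `region`, `size` covering pairs and the
#'   full intersection.
#' @export
intersect_across <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("S", seq_along(sets))
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set labels", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  k <- length(sets)
  if (k <= 6) {
    universe <- unique(unlist(sets, use.names = FALSE))
    member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    if (length(universe) == 1) member <- matrix(member, nrow = 1)
    pattern <- apply(member, 1, function(row) {
      paste(names(sets)[row], collapse = "&")
    })
    combos <- unlist(lapply(seq_len(k), function(m) {
      utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)
    }))
    size <- vapply(combos, function(cb) sum(pattern == cb), integer(1))
    data.frame(region = combos, size = unname(size),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    pairs <- utils::combn(names(sets), 2, simplify = FALSE)
    out <- data.frame(
      region = vapply(pairs, paste, character(1), collapse = "&"),
      size = vapply(pairs, function(p) {
        length(intersect(sets[[p[1]]], sets[[p[2]]]))
      }, integer(1)),
      stringsAsFactors = FALSE
    )
    rbind(out, data.frame(
      region = paste(names(sets), collapse = "&"),
      size = length(Reduce(intersect, sets)),
      stringsAsFactors = FALSE
    ))
  }
}
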