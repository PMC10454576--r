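#' @title Lightweight co-expression stage
#' @description A desk-scale co-expression analysis built from the stated
#'   construction choices: soft-power adjacency on absolute correlations
#'   (beta = 12), average-linkage clustering of the adjacency dissimilarity
#'   with a static cut, a minimum module size of 30, iterative merging of
#'   modules whose eigengene dissimilarity falls below 0.25, first-PC module
#'   eigengenes, module-group Pearson correlation screening at |r| > 0.6 and
#'   p < 0.05, and hub genes by intramodular connectivity. The full
#'   topological-overlap / dynamic tree cut machinery of large-scale network
#'   packages is deliberately not reproduced.
#' @name saltscreen-coexpression
NULL

# labels assigned to detected modules by decreasing size, as is conventional
# for co-expression modules; "grey" is reserved for unassigned genes
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta"
)

#' Filter an expression matrix before network construction
#'
#' Keeps genes whose maximum FPKM across samples reaches `fpkm_min` and,
#' optionally, that belong to a supplied set of differentially expressed
#' genes.
#'
#' @param fpkm gene x sample FPKM matrix (non-negative).
#' @param fpkm_min minimum of the per-gene maximum FPKM; `0` keeps all.
#' @param deg_set optional character vector; when given, only these genes
#'   are retained.
#' @return the filtered matrix.
#' @export
filter_expression <- function(fpkm, fpkm_min = 5, deg_set = NULL) {
  stopifnot(is.matrix(fpkm), fpkm_min >= 0)
  keep <- apply(fpkm, 1, max) >= fpkm_min
  if (!is.null(deg_set)) keep <- keep & rownames(fpkm) %in% deg_set
  if (!any(keep)) stop("empty expression set after filtering", call. = FALSE)
  fpkm[keep, , drop = FALSE]
}

#' Soft-power co-expression adjacency
#'
#' Expression is transformed as `log2(FPKM + 1)` (configurable), genes with
#' zero variance are dropped with a warning, and the adjacency is
#' `a_ij = |cor(g_i, g_j)|^beta`. The matrix is symmetric with unit diagonal
#' and entries in `[0, 1]`; raising `beta` suppresses weak correlations,
#' pushing the network towards a scale-free topology.
#'
#' @param fpkm gene x sample FPKM matrix with >= 4 samples.
#' @param soft_power the exponent beta, default 12.
#' @param transform `"log2"` (default) or `"none"`.
#' @return list of class `coexpression_network`: `adjacency`, `expr` (the
#'   transformed matrix used for correlations), `soft_power`, `genes`.
#' @export
build_adjacency <- function(fpkm, soft_power = 12,
                            transform = c("log2", "none")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(fpkm), soft_power >= 1)
  if (ncol(fpkm) < 4) stop("need >= 4 samples", call. = FALSE)
  x <- if (transform == "log2") log2(fpkm + 1) else fpkm
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)", call. = FALSE)
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 variable genes", call. = FALSE)
  a <- abs(stats::cor(t(x)))^soft_power
  diag(a) <- 1
  structure(list(adjacency = a, expr = x, soft_power = soft_power,
                 genes = rownames(x)),
            class = "coexpression_network")
}

#' Module eigengene
#'
#' First principal component of a module's standardized gene x sample
#' expression block, scaled to unit variance and oriented so that it
#' correlates non-negatively with the module's mean standardized expression
#' (making the sign deterministic and interpretable as "module activity").
#'
#' @param expr_block numeric gene x sample matrix of one module (>= 2
#'   samples, no constant rows after standardization... a fully constant
#'   block is an error).
#' @return numeric per-sample vector with unit variance.
#' @export
eigengene <- function(expr_block) {
  stopifnot(is.matrix(expr_block))
  if (ncol(expr_block) < 2) stop("need >= 2 samples", call. = FALSE)
  sds <- apply(expr_block, 1, stats::sd)
  if (all(sds == 0)) stop("constant expression block", call. = FALSE)
  z <- t(scale(t(expr_block[sds > 0, , drop = FALSE])))
  sv <- svd(t(z), nu = 1, nv = 0)
  me <- sv$u[, 1]
  me <- me / stats::sd(me)
  if (stats::cor(me, colMeans(z)) < 0) me <- -me
  stats::setNames(me, colnames(expr_block))
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the adjacency dissimilarity
#' `1 - a_ij`, cut statically at `cut_height` times the largest merge
#' height. Clusters smaller than `min_module_size` go to the unassigned
#' `"grey"` pool. Modules whose eigengene dissimilarity `1 - cor(ME_i,
#' ME_j)` falls below `merge_cutoff` are merged iteratively (closest pair
#' first) until no pair qualifies. Surviving modules are labelled by
#' decreasing size with conventional module colors.
#'
#' @param net a `coexpression_network` from [build_adjacency()].
#' @param min_module_size smallest allowed module, default 30.
#' @param merge_cutoff eigengene dissimilarity below which modules merge,
#'   default 0.25.
#' @param cut_height fraction of the maximum merge height at which the tree
#'   is cut, default 0.99.
#' @return list of class `module_set`: `modules` (character vector named by
#'   gene), `eigengenes` (sample x module matrix), `sizes`.
#' @export
detect_modules <- function(net, min_module_size = 30, merge_cutoff = 0.25,
                           cut_height = 0.99) {
  stopifnot(inherits(net, "coexpression_network"))
  d <- stats::as.dist(1 - net$adjacency)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height * max(hc$height))
  sizes <- table(cl)
  assign <- ifelse(cl %in% as.integer(names(sizes)[sizes >= min_module_size]),
                   as.character(cl), "grey")
  names(assign) <- net$genes
  if (all(assign == "grey")) {
    warning("no module survives the size filter; all genes unassigned",
            call. = FALSE)
    return(structure(list(modules = assign,
                          eigengenes = NULL,
                          sizes = c(grey = length(assign))),
                     class = "module_set"))
  }
  mes <- module_eigengenes(net$expr, assign)
  # iterative merge: closest eigengene pair below the cutoff first
  repeat {
    mods <- colnames(mes)
    if (length(mods) < 2) break
    cm <- stats::cor(mes)
    diss <- 1 - cm
    diag(diss) <- Inf
    idx <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[idx[1], idx[2]] >= merge_cutoff) break
    keep <- mods[min(idx)]
    drop <- mods[max(idx)]
    assign[assign == drop] <- keep
    mes <- module_eigengenes(net$expr, assign)
  }
  # relabel by decreasing size, deterministic tie-break on old label
  tab <- table(assign[assign != "grey"])
  ord <- names(tab)[order(-tab, names(tab))]
  labels <- stats::setNames(MODULE_COLORS[seq_along(ord)], ord)
  assign[assign != "grey"] <- labels[assign[assign != "grey"]]
  mes <- module_eigengenes(net$expr, assign)
  structure(list(modules = assign, eigengenes = mes,
                 sizes = c(sort(table(assign[assign != "grey"]),
                                decreasing = TRUE),
                           grey = sum(assign == "grey"))),
            class = "module_set")
}

module_eigengenes <- function(expr, assign) {
  mods <- sort(setdiff(unique(assign), "grey"))
  mes <- vapply(mods, function(m) {
    eigengene(expr[names(assign)[assign == m], , drop = FALSE])
  }, numeric(ncol(expr)))
  colnames(mes) <- mods
  rownames(mes) <- colnames(expr)
  mes
}

#' Module-group correlation screening
#'
#' Pearson correlation between each module eigengene and a one-hot sample
#' group indicator, with the two-sided p-value from the t distribution on
#' `n - 2` degrees of freedom. A (module, group) pair is `selected` when
#' `|r| > r_min` and `p < p_max`.
#'
#' @param modules a `module_set` with eigengenes.
#' @param groups character vector of group labels, one per sample (same
#'   order as the eigengene rows); groups with fewer than 2 samples are
#'   excluded with a warning.
#' @param r_min,p_max selection thresholds, defaults 0.6 and 0.05.
#' @return `data.frame` with module, group, r, p, selected.
#' @export
module_trait_correlation <- function(modules, groups, r_min = 0.6,
                                     p_max = 0.05) {
  stopifnot(inherits(modules, "module_set"))
  mes <- modules$eigengenes
  if (is.null(mes)) stop("module set has no eigengenes", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != nrow(mes)) {
    stop("one group label per sample required", call. = FALSE)
  }
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  glev <- setdiff(sort(unique(groups)), small)
  n <- nrow(mes)
  out <- expand.grid(module = colnames(mes), group = glev,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- mapply(function(m, g) {
    stats::cor(mes[, m], as.numeric(groups == g))
  }, out$module, out$group)
  tstat <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out$selected <- abs(out$r) > r_min & out$p < p_max
  out
}

#' Hub genes by intramodular connectivity
#'
#' Within each module, each gene's intramodular connectivity is the sum of
#' its adjacency weights to the other module members; the gene with maximal
#' connectivity is the module hub (ties broken by gene identifier). For
#' export, each gene's `top_edges` strongest within-module edges are also
#' returned.
#'
#' @param net the `coexpression_network` the modules were detected in.
#' @param modules a `module_set`.
#' @param which_modules modules to process (default: all non-grey); modules
#'   of size 1 are skipped with a warning.
#' @param top_edges number of strongest edges kept per gene, default 5.
#' @return list with `hubs` (module, gene, connectivity) and `edges`
#'   (module, source, target, weight).
#' @export
hub_genes <- function(net, modules, which_modules = NULL, top_edges = 5) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(modules, "module_set"))
  assign <- modules$modules
  mods <- if (is.null(which_modules)) {
    sort(setdiff(unique(assign), "grey"))
  } else which_modules
  hubs <- list(); edges <- list()
  for (m in mods) {
    genes <- names(assign)[assign == m]
    if (length(genes) < 2) {
      warning("module ", m, " has fewer than 2 genes; skipped", call. = FALSE)
      next
    }
    a <- net$adjacency[genes, genes]
    k <- rowSums(a) - diag(a)
    ord <- order(-k, genes)
    hubs[[m]] <- data.frame(module = m, gene = genes[ord[1]],
                            connectivity = unname(k[ord[1]]),
                            stringsAsFactors = FALSE)
    ee <- lapply(genes, function(g) {
      w <- a[g, setdiff(genes, g)]
      top <- order(-w, names(w))[seq_len(min(top_edges, length(w)))]
      data.frame(module = m, source = g, target = names(w)[top],
                 weight = unname(w[top]), stringsAsFactors = FALSE)
    })
    edges[[m]] <- do.call(rbind, ee)
  }
  list(hubs = do.call(rbind, c(hubs, list(make.row.names = FALSE))),
       edges = do.call(rbind, c(edges, list(make.row.names = FALSE))))
}
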