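#' Membership function
#'
#' Min-max normalization of a value into `[0, 1]`. For traits (or component
#' scores) positively associated with salt tolerance the membership is
#' `(x - xmin) / (xmax - xmin)`; for negatively associated ones it is
#' `(xmax - x) / (xmax - xmin)`, so that larger membership always means more
#' tolerant. The two readings are complementary: `mu_pos + mu_neg = 1`.
#'
#' @param x value(s) to transform, each within `[xmin, xmax]`.
#' @param xmin,xmax range over which to normalize (typically the min and max
#'   across genotypes).
#' @param direction `"positive"` or `"negative"`.
#' @return membership value(s) in `[0, 1]`; if `xmax == xmin` the value
#'   carries no ranking information and 0.5 is returned.
#' @export
membership <- function(x, xmin, xmax, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (any(!is.finite(c(x, xmin, xmax)))) {
    stop("membership inputs must be finite", call. = FALSE)
  }
  if (xmax < xmin) stop("xmax must be >= xmin", call. = FALSE)
  if (any(x < xmin | x > xmax)) {
    stop("x outside [xmin, xmax]", call. = FALSE)
  }
  if (xmax == xmin) return(rep(0.5, length(x)))
  mu <- (x - xmin) / (xmax - xmin)
  if (direction == "negative") mu <- 1 - mu
  mu
}

#' Principal-component weights for the comprehensive index
#'
#' PCA on the column-standardized STI matrix (correlation-matrix PCA).
#' Component `i` contributes `P_i = eigenvalue_i / sum(eigenvalues)`;
#' components are retained until the cumulative contribution reaches
#' `variance_target` (default 80%), and the weights
#' `W_i = P_i / sum_(j<=k) P_j` are renormalized over the retained
#' components so they sum to one.
#'
#' Eigenvector signs are arbitrary; for determinism each component is
#' oriented so that its largest-magnitude loading is positive.
#'
#' @param sti an `sti_matrix` (see [sti_matrix()]) or a plain genotype x
#'   trait numeric matrix.
#' @param variance_target cumulative contribution at which to stop retaining
#'   components, in `(0, 1]`.
#' @return list of class `pca_model`: `eigenvalues`, `contribution`,
#'   `loadings` (trait x component), `scores` (genotype x component),
#'   `k_selected`, `weights` (length `k_selected`, summing to 1) and
#'   `directions` (trait directions, when available).
#' @export
pca_weights <- function(sti, variance_target = 0.80) {
  directions <- NULL
  if (inherits(sti, "sti_matrix")) {
    directions <- sti$directions
    sti <- sti$sti
  }
  stopifnot(is.matrix(sti), is.numeric(sti))
  if (variance_target <= 0 || variance_target > 1) {
    stop("variance_target must be in (0, 1]", call. = FALSE)
  }
  if (nrow(sti) < 3) stop("PCA needs >= 3 genotypes", call. = FALSE)
  sds <- apply(sti, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(sti)[sds == 0], collapse = ", "), call. = FALSE)
    sti <- sti[, sds > 0, drop = FALSE]
    directions <- directions[colnames(sti)]
  }
  if (ncol(sti) < 2) stop("PCA needs >= 2 varying traits", call. = FALSE)
  pc <- stats::prcomp(sti, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  contribution <- ev / sum(ev)
  k <- which(cumsum(contribution) >= variance_target - 1e-12)[1]
  loadings <- pc$rotation
  scores <- pc$x
  for (i in seq_len(ncol(loadings))) {
    top <- which.max(abs(loadings[, i]))
    if (loadings[top, i] < 0) {
      loadings[, i] <- -loadings[, i]
      scores[, i] <- -scores[, i]
    }
  }
  structure(list(
    eigenvalues = ev,
    contribution = contribution,
    loadings = loadings,
    scores = scores,
    k_selected = k,
    weights = contribution[seq_len(k)] / sum(contribution[seq_len(k)]),
    directions = directions
  ), class = "pca_model")
}

# Orient each retained component so that larger scores mean more tolerant:
# positive if the summed loadings of positive-direction traits minus those of
# negative-direction traits are >= 0, else the score sign is flipped.
component_orientation <- function(model, directions) {
  traits <- rownames(model$loadings)
  if (is.null(directions)) directions <- model$directions
  if (is.null(directions)) directions <- default_directions(traits)
  dirs <- directions[sub("@.*$", "", traits)]
  sign_vec <- ifelse(dirs == "negative", -1, 1)
  vapply(seq_len(model$k_selected), function(i) {
    s <- sum(sign_vec * model$loadings[, i])
    if (s >= 0) 1 else -1
  }, numeric(1))
}

#' Comprehensive salt tolerance index (CSTI)
#'
#' Maps each retained principal-component score through the membership
#' function (min/max taken over genotypes, after orienting the component
#' towards tolerance) and combines them as the weighted sum
#' `CSTI = sum_i mu_i * W_i`. Being a convex combination of memberships, the
#' CSTI lies in `[0, 1]`; genotypes are ranked in descending order.
#'
#' The alternative trait-level reading (`membership_level = "trait"`) applies
#' the membership function to each STI trait directly (using its direction)
#' and weights traits by their share of explained variance over the retained
#' components (eigenvalue-weighted squared loadings).
#'
#' @param model a `pca_model` from [pca_weights()].
#' @param directions optional named trait-direction vector overriding the one
#'   stored in the model.
#' @param membership_level `"component"` (default) or `"trait"`.
#' @param sti required for `membership_level = "trait"`: the genotype x trait
#'   STI matrix the model was fitted on.
#' @return a `data.frame` with genotype, one `mu_*` column per retained
#'   component (or per trait), `csti` and `rank`; weights are attached as
#'   attribute `"weights"`.
#' @export
csti <- function(model, directions = NULL,
                 membership_level = c("component", "trait"), sti = NULL) {
  stopifnot(inherits(model, "pca_model"))
  membership_level <- match.arg(membership_level)
  if (membership_level == "trait") {
    if (is.null(sti)) {
      if (inherits(directions, "sti_matrix")) sti <- directions$sti
      else stop("membership_level = 'trait' needs the STI matrix", call. = FALSE)
    }
    if (inherits(sti, "sti_matrix")) sti <- sti$sti
    traits <- rownames(model$loadings)
    sti <- sti[, traits, drop = FALSE]
    dirs <- if (is.null(directions)) model$directions else directions
    if (is.null(dirs)) dirs <- default_directions(traits)
    dirs <- dirs[sub("@.*$", "", traits)]
    k <- model$k_selected
    contrib <- vapply(seq_along(traits), function(j) {
      sum(model$eigenvalues[seq_len(k)] * model$loadings[j, seq_len(k)]^2)
    }, numeric(1))
    w <- contrib / sum(contrib)
    mu <- vapply(seq_along(traits), function(j) {
      membership(sti[, j], min(sti[, j]), max(sti[, j]), dirs[j])
    }, numeric(nrow(sti)))
    colnames(mu) <- paste0("mu_", traits)
    score <- drop(mu %*% w)
    names(w) <- traits
  } else {
    orient <- component_orientation(model, directions)
    k <- model$k_selected
    sc <- sweep(model$scores[, seq_len(k), drop = FALSE], 2, orient, `*`)
    mu <- vapply(seq_len(k), function(i) {
      membership(sc[, i], min(sc[, i]), max(sc[, i]), "positive")
    }, numeric(nrow(sc)))
    colnames(mu) <- paste0("mu_PC", seq_len(k))
    w <- model$weights
    score <- drop(mu %*% w)
  }
  genotype <- rownames(model$scores)
  if (is.null(genotype)) genotype <- paste0("g", seq_along(score))
  out <- data.frame(genotype = genotype, mu, csti = score,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$rank <- rank_descending(out$csti, out$genotype)
  attr(out, "weights") <- w
  rownames(out) <- NULL
  out
}

# descending rank with deterministic tie-break by genotype identifier
rank_descending <- function(x, id) {
  ord <- order(-x, id)
  rk <- integer(length(x))
  rk[ord] <- seq_along(x)
  rk
}

#' Grade genotypes from their CSTI values
#'
#' Agglomerative hierarchical clustering (Euclidean distance; Ward linkage by
#' default) on the one-dimensional CSTI values, cut into `n_classes` groups.
#' Groups are labelled by descending mean CSTI; with three classes the labels
#' are `salt-resistant` > `salt-tolerant` > `salt-sensitive`.
#'
#' @param results data.frame from [csti()] (needs `genotype` and `csti`).
#' @param n_classes number of grades, default 3.
#' @param linkage `"ward"` (Ward's minimum variance, `ward.D2`),
#'   `"average"` or `"complete"`.
#' @return `results` with a `class` column added (factor ordered from most
#'   to least tolerant).
#' @export
classify <- function(results, n_classes = 3,
                     linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.data.frame(results), all(c("genotype", "csti") %in% names(results)))
  if (nrow(results) < n_classes) {
    stop("need at least n_classes genotypes", call. = FALSE)
  }
  if (length(unique(results$csti)) == 1) {
    stop("degenerate clustering: all CSTI values identical", call. = FALSE)
  }
  # deterministic input order: by genotype identifier
  ord <- order(results$genotype)
  x <- results$csti[ord]
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[linkage]
  hc <- stats::hclust(stats::dist(x), method = method)
  grp <- stats::cutree(hc, k = n_classes)
  means <- tapply(x, grp, mean)
  lab_order <- order(-means)
  labels <- if (n_classes == 3) {
    c("salt-resistant", "salt-tolerant", "salt-sensitive")
  } else {
    paste0("class-", seq_len(n_classes))
  }
  lab_map <- stats::setNames(labels, names(means)[lab_order])
  cls <- lab_map[as.character(grp)]
  results$class <- NA_character_
  results$class[ord] <- unname(cls)
  results$class <- factor(results$class, levels = labels)
  results
}

#' Full panel evaluation
#'
#' Convenience wrapper chaining [sti_matrix()], [pca_weights()], [csti()]
#' and [classify()].
#'
#' @param trait_table validated trait table of control and salt measurements.
#' @param directions optional named trait-direction vector.
#' @param config a [run_config()]; supplies `variance_target`,
#'   `membership_level` and `linkage`.
#' @param n_classes number of tolerance grades.
#' @return list with `sti` (the `sti_matrix`), `model` (the `pca_model`) and
#'   `result` (graded CSTI table).
#' @export
evaluate_panel <- function(trait_table, directions = NULL,
                           config = run_config(), n_classes = 3) {
  sm <- sti_matrix(trait_table, directions)
  model <- pca_weights(sm, variance_target = config$variance_target)
  res <- csti(model, directions = sm$directions,
              membership_level = config$membership_level, sti = sm$sti)
  res <- classify(res, n_classes = n_classes, linkage = config$linkage)
  list(sti = sm, model = model, result = res)
}
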