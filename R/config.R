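#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults follow the evaluation and screening protocol the package
#' implements: differentially expressed genes require `fdr <= 0.05` and
#' `|log2FC| >= 1` (a two-fold change), the genotype-contrast screen uses a
#' log2 fold-change gap of 0.6, co-expression networks are built with a soft
#' power of 12, modules need at least 30 genes and are merged at an eigengene
#' dissimilarity of 0.25, module-group correlations are called at
#' `|r| > 0.6` and `p < 0.05`, and principal components are retained up to a
#' cumulative variance contribution of 80%.
#'
#' @param fdr_max maximum FDR for a differentially expressed gene.
#' @param min_abs_log2fc minimum absolute log2 fold change for a DEG.
#' @param delta_log2fc log2 fold-change gap between tolerant and sensitive
#'   genotypes required by screen rules 3 and 4.
#' @param fpkm_min genes whose maximum FPKM across samples falls below this
#'   value are removed before network construction.
#' @param soft_power exponent applied to absolute correlations to form the
#'   network adjacency.
#' @param min_module_size smallest gene count for a co-expression module;
#'   smaller clusters are assigned to the unassigned ("grey") pool.
#' @param merge_cutoff eigengene dissimilarity (1 - cor) below which two
#'   modules are merged.
#' @param module_r_min,module_p_max thresholds for flagging a module-group
#'   correlation as selected.
#' @param variance_target cumulative variance contribution at which principal
#'   components stop being retained for the CSTI.
#' @param membership_level `"component"` applies the membership function to
#'   principal-component scores (the default composite-score reading);
#'   `"trait"` applies it to each salt-tolerance index first and weights
#'   traits by their PCA variance contribution.
#' @param linkage linkage used when grading genotypes from CSTI values.
#' @param rules integer subset of `1:4`, the screen rules to apply.
#' @param seed integer seed recorded in output headers and used by the
#'   synthetic-data generators.
#'
#' @return a named list of class `saltscreen_config`.
#' @seealso [read_run_config()]
#' @export
run_config <- function(fdr_max = 0.05,
                       min_abs_log2fc = 1,
                       delta_log2fc = 0.6,
                       fpkm_min = 5,
                       soft_power = 12,
                       min_module_size = 30,
                       merge_cutoff = 0.25,
                       module_r_min = 0.6,
                       module_p_max = 0.05,
                       variance_target = 0.80,
                       membership_level = c("component", "trait"),
                       linkage = c("ward", "average", "complete"),
                       rules = 1:4,
                       seed = 1L) {
  membership_level <- match.arg(membership_level)
  linkage <- match.arg(linkage)
  cfg <- list(
    fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc,
    delta_log2fc = delta_log2fc, fpkm_min = fpkm_min,
    soft_power = soft_power, min_module_size = min_module_size,
    merge_cutoff = merge_cutoff, module_r_min = module_r_min,
    module_p_max = module_p_max, variance_target = variance_target,
    membership_level = membership_level, linkage = linkage,
    rules = as.integer(rules), seed = as.integer(seed)
  )
  validate_run_config(cfg)
  class(cfg) <- "saltscreen_config"
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(
    cfg$fdr_max > 0, cfg$fdr_max <= 1,
    cfg$min_abs_log2fc >= 0,
    cfg$delta_log2fc >= 0,
    cfg$fpkm_min >= 0,
    cfg$soft_power >= 1,
    cfg$min_module_size >= 1,
    cfg$merge_cutoff >= 0, cfg$merge_cutoff < 1,
    cfg$module_r_min >= 0, cfg$module_r_min <= 1,
    cfg$module_p_max > 0, cfg$module_p_max <= 1,
    cfg$variance_target > 0, cfg$variance_target <= 1
  )
  if (!all(cfg$rules %in% 1:4)) {
    stop("screen rules must be a subset of 1:4", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override the package defaults; unknown keys are
#' an error so typos do not silently fall back to a default.
#'
#' @param path path to a YAML file of `run_config()` fields.
#' @return a `saltscreen_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @keywords internal
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

# Append one JSON-lines record to a run log. Returns the record invisibly.
log_jsonl <- function(path, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  line <- as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(rec)
}

# Evaluate expr under a fixed RNG state without disturbing the caller's.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
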