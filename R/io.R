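#' @title Tabular readers and writers
#' @description Readers validate the core tabular types; the writer emits
#'   deterministic CSV/TSV with a comment header recording config hash and
#'   seed so any output can be traced back to the run that produced it.
#' @name saltscreen-io
NULL

TRAIT_COLS <- c("genotype", "trait", "condition", "timepoint", "replicate", "value")
DE_COLS <- c("contrast", "gene", "log2fc", "fdr")

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t",
         stop("cannot infer delimiter from extension '.", ext,
              "'; pass `delim`", call. = FALSE))
}

read_delim_file <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = delim_for(path, delim), header = TRUE,
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

coerce_numeric <- function(x, col) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad)) {
    stop("non-numeric value in column '", col, "' at row ", bad[1],
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  out
}

#' Read a genotype-by-trait measurement table
#'
#' The table holds one measured value per (genotype, trait, condition,
#' timepoint, replicate) tuple; conditions are `control` and `salt`. Column
#' names in the file can be remapped through `schema`, since panel trait
#' tables rarely share a fixed layout.
#'
#' @param path CSV/TSV file path.
#' @param schema optional named character vector mapping required column
#'   names to the names used in the file, e.g.
#'   `c(genotype = "line", value = "measurement")`.
#' @param delim field delimiter; inferred from the extension when `NULL`.
#' @param allow_missing if `TRUE`, rows with missing values are dropped
#'   (replicate averaging later uses whatever replicates remain) and only a
#'   completely empty (genotype, trait, condition, timepoint) cell is an
#'   error; if `FALSE` (default) any missing value is an error.
#' @return a validated `data.frame` with columns
#'   genotype, trait, condition, timepoint, replicate, value.
#' @export
read_trait_table <- function(path, schema = NULL, delim = NULL,
                             allow_missing = FALSE) {
  df <- read_delim_file(path, delim)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df)) {
        stop("schema maps '", std, "' to absent column '", schema[[std]], "'",
             call. = FALSE)
      }
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  require_columns(df, TRAIT_COLS, "trait table")
  df <- df[TRAIT_COLS]
  df$value <- coerce_numeric(df$value, "value")
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$value)) {
    if (!allow_missing) {
      stop("missing trait values at row(s) ",
           paste(utils::head(which(is.na(df$value)), 5), collapse = ", "),
           "; use allow_missing = TRUE to average remaining replicates",
           call. = FALSE)
    }
    cells_before <- unique(df[c("genotype", "trait", "condition", "timepoint")])
    df <- df[!is.na(df$value), , drop = FALSE]
    cells_after <- unique(df[c("genotype", "trait", "condition", "timepoint")])
    if (nrow(cells_after) < nrow(cells_before)) {
      stop("a (genotype, trait, condition, timepoint) cell is entirely empty",
           call. = FALSE)
    }
  }
  validate_trait_table(df)
}

#' @keywords internal
validate_trait_table <- function(df) {
  require_columns(df, TRAIT_COLS, "trait table")
  if (!all(df$condition %in% c("control", "salt"))) {
    stop("condition must be 'control' or 'salt'", call. = FALSE)
  }
  if (!all(is.finite(df$value))) {
    stop("trait values must be finite", call. = FALSE)
  }
  if (any(df$replicate < 1)) stop("replicate must be >= 1", call. = FALSE)
  key <- do.call(paste, c(df[c("genotype", "trait", "condition",
                               "timepoint", "replicate")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (genotype, trait, condition, timepoint, replicate) key",
         call. = FALSE)
  }
  # STI is undefined for a salt cell with no matching control cell
  cell <- unique(df[c("genotype", "trait", "timepoint", "condition")])
  salt <- cell[cell$condition == "salt", 1:3]
  ctrl <- cell[cell$condition == "control", 1:3]
  k_salt <- do.call(paste, c(salt, sep = "\r"))
  k_ctrl <- do.call(paste, c(ctrl, sep = "\r"))
  orphan <- setdiff(k_salt, k_ctrl)
  if (length(orphan)) {
    stop("salt measurements without control counterpart: ",
         gsub("\r", "/", orphan[1]), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a differential-expression table
#'
#' One record per (contrast, gene): the log2 fold change and FDR of a gene in
#' a named contrast, i.e. the output format of a count-based DE fit.
#'
#' @inheritParams read_trait_table
#' @return a validated `data.frame` with columns contrast, gene, log2fc, fdr.
#' @export
read_de_table <- function(path, delim = NULL) {
  df <- read_delim_file(path, delim)
  require_columns(df, DE_COLS, "DE table")
  df <- df[DE_COLS]
  df$log2fc <- coerce_numeric(df$log2fc, "log2fc")
  df$fdr <- coerce_numeric(df$fdr, "fdr")
  validate_de_table(df)
}

#' @keywords internal
validate_de_table <- function(df) {
  require_columns(df, DE_COLS, "DE table")
  if (!all(is.finite(df$log2fc))) stop("log2fc must be finite", call. = FALSE)
  if (anyNA(df$fdr) || any(df$fdr < 0 | df$fdr > 1)) {
    stop("fdr must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(paste(df$contrast, df$gene, sep = "\r"))) {
    stop("duplicate (contrast, gene) key", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read an FPKM expression matrix with sample groups
#'
#' @param path CSV/TSV with a `gene` column and one numeric column per sample.
#' @param sample_sheet path to a CSV/TSV with columns `sample` and `group`
#'   (genotype x timepoint label), or a data.frame of the same shape.
#' @param delim field delimiter; inferred from the extensions when `NULL`.
#' @return a list with `fpkm` (gene x sample numeric matrix) and `groups`
#'   (character vector named by sample).
#' @export
read_expression_matrix <- function(path, sample_sheet, delim = NULL) {
  df <- read_delim_file(path, delim)
  require_columns(df, "gene", "expression matrix")
  genes <- df$gene
  mat <- as.matrix(df[setdiff(names(df), "gene")])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop("FPKM values must be finite and non-negative", call. = FALSE)
  }
  sheet <- if (is.data.frame(sample_sheet)) sample_sheet else
    read_delim_file(sample_sheet, delim)
  require_columns(sheet, c("sample", "group"), "sample sheet")
  if (anyDuplicated(sheet$sample)) {
    stop("duplicate sample in sample sheet", call. = FALSE)
  }
  missing <- setdiff(colnames(mat), sheet$sample)
  if (length(missing)) {
    stop("sample(s) without group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- stats::setNames(as.character(sheet$group), sheet$sample)
  list(fpkm = mat, groups = groups[colnames(mat)])
}

format_num <- function(x) {
  ifelse(is.na(x), "NA",
         vapply(signif(x, 6), function(v) format(v, scientific = FALSE,
                                                 trim = TRUE, digits = 15),
                character(1)))
}

#' Write a tabular result deterministically
#'
#' Columns are written in their existing order, numeric columns at six
#' significant digits, preceded by comment lines (`#`) recording the package
#' version, config hash and seed. Identical input and config produce a
#' byte-identical file.
#'
#' @param obj a data.frame.
#' @param path destination; `.csv` writes comma-separated, `.tsv`
#'   tab-separated.
#' @param config optional `saltscreen_config` whose hash is recorded.
#' @param seed optional integer recorded in the header (defaults to
#'   `config$seed`).
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, config = NULL, seed = NULL) {
  stopifnot(is.data.frame(obj))
  sep <- delim_for(path)
  if (is.null(seed) && !is.null(config)) seed <- config$seed
  out <- obj
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    paste0("# saltscreen v", as.character(utils::packageVersion("saltscreen"))),
    if (!is.null(config)) paste0("# config_hash=", config_hash(config)),
    if (!is.null(seed)) paste0("# seed=", as.integer(seed))
  )
  writeLines(hdr, con, useBytes = TRUE)
  writeLines(paste(names(out), collapse = sep), con, useBytes = TRUE)
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = sep))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}
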