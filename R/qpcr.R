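#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` normalizes the target gene to the
#' housekeeping gene within a sample; `ddCt = dCt - dCt_calibrator`
#' normalizes to the calibrator sample; the relative expression is
#' `2^-ddCt`. Self-calibration is the identity: `ddct(a, b, a, b) = 1`.
#'
#' @param ct_target,ct_reference threshold cycles of the target and
#'   reference gene in the sample of interest.
#' @param ct_target_cal,ct_reference_cal the same in the calibrator sample.
#' @return fold change(s) relative to the calibrator.
#' @export
ddct <- function(ct_target, ct_reference, ct_target_cal, ct_reference_cal) {
  cts <- list(ct_target, ct_reference, ct_target_cal, ct_reference_cal)
  if (any(vapply(cts, function(x) any(!is.finite(x) | x <= 0), logical(1)))) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  dct <- ct_target - ct_reference
  dct_cal <- ct_target_cal - ct_reference_cal
  2^-(dct - dct_cal)
}

#' Fold changes from a qPCR record table
#'
#' Technical replicates of a (gene, sample) pair are averaged on the Ct
#' scale before `dCt`. The per-gene calibrator `dCt` is either the mean over
#' calibrator rows (`calibration = "mean"`) or the first calibrator
#' replicate, whose relative expression is then exactly 1
#' (`calibration = "replicate1"`).
#'
#' @param qpcr `data.frame` with columns gene, sample, ct_target,
#'   ct_reference, is_calibrator (logical); one calibrator condition per
#'   gene required.
#' @param calibration `"mean"` (default) or `"replicate1"`.
#' @return `data.frame` with gene, sample, fold (2^-ddCt).
#' @export
qpcr_fold_changes <- function(qpcr, calibration = c("mean", "replicate1")) {
  calibration <- match.arg(calibration)
  req <- c("gene", "sample", "ct_target", "ct_reference", "is_calibrator")
  require_columns(qpcr, req, "qPCR table")
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~
                            gene + sample + is_calibrator,
                          data = qpcr, FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference
  out <- list()
  for (g in sort(unique(agg$gene))) {
    sub <- agg[agg$gene == g, , drop = FALSE]
    cal <- sub[sub$is_calibrator, , drop = FALSE]
    if (!nrow(cal)) {
      stop("gene ", g, " has no calibrator sample", call. = FALSE)
    }
    cal <- cal[order(cal$sample), , drop = FALSE]
    dct_cal <- if (calibration == "mean") mean(cal$dct) else cal$dct[1]
    out[[g]] <- data.frame(gene = g, sample = sub$sample,
                           fold = 2^-(sub$dct - dct_cal),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' qPCR / RNA-seq concordance
#'
#' Pearson correlation between paired log2 fold changes from the two
#' platforms, with the two-sided p-value of the correlation test. Symmetric
#' in its two arguments.
#'
#' @param qpcr_fc,rnaseq_fc paired fold changes (linear scale, > 0), at
#'   least 3 pairs; names, when present on both, are used to align the
#'   pairs.
#' @return list with `r`, `p`, `n` and `table` (the paired log2 values).
#' @export
concordance <- function(qpcr_fc, rnaseq_fc) {
  if (!is.null(names(qpcr_fc)) && !is.null(names(rnaseq_fc))) {
    common <- intersect(names(qpcr_fc), names(rnaseq_fc))
    qpcr_fc <- qpcr_fc[common]
    rnaseq_fc <- rnaseq_fc[common]
  }
  if (length(qpcr_fc) != length(rnaseq_fc)) {
    stop("fold-change vectors must be paired", call. = FALSE)
  }
  if (length(qpcr_fc) < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (any(qpcr_fc <= 0) || any(rnaseq_fc <= 0)) {
    stop("fold changes must be > 0 for the log2 scale", call. = FALSE)
  }
  x <- log2(qpcr_fc); y <- log2(rnaseq_fc)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       table = data.frame(log2_qpcr = unname(x), log2_rnaseq = unname(y),
                          row.names = NULL))
}
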