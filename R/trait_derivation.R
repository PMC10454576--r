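#' Relative water content (RWC)
#'
#' Percent water of a tissue: `(FW - DW) / FW * 100`, where FW and DW are the
#' fresh and dry weights. Scale-invariant: multiplying both weights by a
#' positive constant leaves RWC unchanged.
#'
#' @param fw fresh weight(s), > 0.
#' @param dw dry weight(s), >= 0.
#' @param clip if `TRUE`, a dry weight exceeding the fresh weight (a
#'   measurement artefact) is clipped to RWC = 0 with a warning instead of
#'   raising an error.
#' @return RWC in percent, in `[0, 100]` whenever `dw <= fw`.
#' @export
relative_water_content <- function(fw, dw, clip = FALSE) {
  if (any(!is.finite(fw)) || any(!is.finite(dw))) {
    stop("weights must be finite", call. = FALSE)
  }
  if (any(fw <= 0)) stop("fresh weight must be > 0", call. = FALSE)
  if (any(dw < 0)) stop("dry weight must be >= 0", call. = FALSE)
  over <- dw > fw
  if (any(over)) {
    if (!clip) {
      stop("dry weight exceeds fresh weight; set clip = TRUE to clip to 0",
           call. = FALSE)
    }
    warning("dry weight exceeds fresh weight in ", sum(over),
            " case(s); RWC clipped to 0", call. = FALSE)
    dw <- pmin(dw, fw)
  }
  (fw - dw) / fw * 100
}

#' Root-shoot ratio
#'
#' Ratio of root dry weight to shoot dry weight.
#'
#' @param dw_root root dry weight(s), >= 0.
#' @param dw_shoot shoot dry weight(s), > 0.
#' @return `dw_root / dw_shoot`.
#' @export
root_shoot_ratio <- function(dw_root, dw_shoot) {
  if (any(!is.finite(dw_root)) || any(!is.finite(dw_shoot))) {
    stop("dry weights must be finite", call. = FALSE)
  }
  if (any(dw_shoot <= 0)) stop("shoot dry weight must be > 0", call. = FALSE)
  if (any(dw_root < 0)) stop("root dry weight must be >= 0", call. = FALSE)
  dw_root / dw_shoot
}

#' Ion-selective transport coefficient (ISC)
#'
#' Selectivity of ion transport between two adjacent compartments, e.g. root
#' to stem or stem to leaf: the K/Na (or Mg/Na) ratio in the destination
#' compartment divided by the same ratio in the source compartment. Values
#' above 1 mean the plant preferentially moves K (or Mg) over Na towards the
#' destination. Invariant under common rescaling of all four concentrations.
#'
#' @param k_source,na_source ion and Na concentration in the source
#'   compartment (e.g. root), > 0.
#' @param k_dest,na_dest ion and Na concentration in the destination
#'   compartment (e.g. stem), > 0.
#' @return `(k_dest / na_dest) / (k_source / na_source)`.
#' @export
ion_selective_coefficient <- function(k_source, na_source, k_dest, na_dest) {
  conc <- list(k_source, na_source, k_dest, na_dest)
  if (any(vapply(conc, function(x) any(!is.finite(x) | x <= 0), logical(1)))) {
    stop("all concentrations must be finite and > 0", call. = FALSE)
  }
  (k_dest / na_dest) / (k_source / na_source)
}

#' Per-trait salt tolerance index (STI)
#'
#' Ratio of the trait value under salt treatment to the value under control
#' conditions, applied per genotype and trait after replicate averaging. A
#' genotype unaffected by the treatment has STI = 1 for every trait.
#'
#' @param value_salt replicate-averaged trait value under salt.
#' @param value_control replicate-averaged trait value under control.
#' @return `value_salt / value_control`; a zero control value yields `NA`
#'   with a warning (the trait is flagged for exclusion).
#' @export
salt_tolerance_index <- function(value_salt, value_control) {
  if (any(!is.finite(value_salt)) || any(!is.finite(value_control))) {
    stop("trait values must be finite", call. = FALSE)
  }
  zero <- value_control == 0
  if (any(zero)) {
    warning(sum(zero), " control value(s) are zero; STI set to NA ",
            "and flagged for exclusion", call. = FALSE)
  }
  out <- value_salt / value_control
  out[zero] <- NA_real_
  out
}

# raw-trait naming convention used by derive_traits():
#   FW_<organ>, DW_<organ>    fresh / dry weight per organ
#   <Ion>_<organ>             ion concentration per organ (Na, K, Mg, ...)
TRAIT_ORGANS <- c("root", "stem", "leaf", "shoot")
ISC_PATHS <- list(c("root", "stem"), c("stem", "leaf"))

#' Derive physiological traits from raw measurements
#'
#' Appends, wherever the required raw traits exist for a (genotype,
#' condition, timepoint, replicate) cell:
#' * `RWC_<organ>` from `FW_<organ>` and `DW_<organ>`;
#' * `RS_ratio` from `DW_root` and `DW_shoot`;
#' * `ratio_<ion>_Na_<organ>` for ions in `ions` with `Na_<organ>` present;
#' * `ISC_<ion>_<src>_<dst>` for the root-to-stem and stem-to-leaf paths.
#'
#' @param trait_table a validated trait table (see [read_trait_table()]).
#' @param ions numerator ions for selectivity ratios; the study design uses
#'   K/Na and, optionally, Mg/Na.
#' @param clip passed to [relative_water_content()].
#' @return the trait table with derived records appended.
#' @export
derive_traits <- function(trait_table, ions = c("K", "Mg"), clip = FALSE) {
  tt <- validate_trait_table(trait_table)
  wide <- stats::reshape(
    tt, idvar = c("genotype", "condition", "timepoint", "replicate"),
    timevar = "trait", direction = "wide"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  has <- function(x) x %in% names(wide)
  derived <- list()
  add <- function(trait, value, ok) {
    keep <- ok & !is.na(value)
    if (!any(keep)) return(invisible(NULL))
    derived[[length(derived) + 1L]] <<- data.frame(
      genotype = wide$genotype[keep], trait = trait,
      condition = wide$condition[keep], timepoint = wide$timepoint[keep],
      replicate = wide$replicate[keep], value = value[keep],
      stringsAsFactors = FALSE
    )
  }
  for (organ in TRAIT_ORGANS) {
    fw <- paste0("FW_", organ); dw <- paste0("DW_", organ)
    if (has(fw) && has(dw)) {
      ok <- !is.na(wide[[fw]]) & !is.na(wide[[dw]])
      val <- rep(NA_real_, nrow(wide))
      val[ok] <- relative_water_content(wide[[fw]][ok], wide[[dw]][ok],
                                        clip = clip)
      add(paste0("RWC_", organ), val, ok)
    }
  }
  if (has("DW_root") && has("DW_shoot")) {
    ok <- !is.na(wide$DW_root) & !is.na(wide$DW_shoot)
    val <- rep(NA_real_, nrow(wide))
    val[ok] <- root_shoot_ratio(wide$DW_root[ok], wide$DW_shoot[ok])
    add("RS_ratio", val, ok)
  }
  for (ion in ions) {
    for (organ in TRAIT_ORGANS) {
      ic <- paste0(ion, "_", organ); na <- paste0("Na_", organ)
      if (has(ic) && has(na)) {
        ok <- !is.na(wide[[ic]]) & !is.na(wide[[na]]) & wide[[na]] > 0
        add(paste0("ratio_", ion, "_Na_", organ), wide[[ic]] / wide[[na]], ok)
      }
    }
    for (path in ISC_PATHS) {
      src <- path[1]; dst <- path[2]
      cols <- c(paste0(ion, "_", src), paste0("Na_", src),
                paste0(ion, "_", dst), paste0("Na_", dst))
      if (all(vapply(cols, has, logical(1)))) {
        vals <- lapply(cols, function(cl) wide[[cl]])
        ok <- Reduce(`&`, lapply(vals, function(v) !is.na(v) & v > 0))
        val <- rep(NA_real_, nrow(wide))
        val[ok] <- ion_selective_coefficient(vals[[1]][ok], vals[[2]][ok],
                                             vals[[3]][ok], vals[[4]][ok])
        add(paste0("ISC_", ion, "_", src, "_", dst), val, ok)
      }
    }
  }
  if (length(derived)) tt <- rbind(tt, do.call(rbind, derived))
  validate_trait_table(tt)
}

#' Default trait direction assignment
#'
#' Na accumulates under stress and is negatively associated with tolerance,
#' so Na content traits (`Na_<organ>`) and Na-numerator ratios
#' (`ratio_Na_*`) default to direction `"negative"`; everything else
#' (biomass, water content, K/Na and Mg/Na selectivity) is `"positive"`.
#' Fully overridable via the `directions` argument of [sti_matrix()].
#'
#' @param traits character vector of trait names.
#' @return named character vector, `"positive"` or `"negative"` per trait.
#' @export
default_directions <- function(traits) {
  neg <- grepl("^Na_", traits) | grepl("^ratio_Na_", traits)
  stats::setNames(ifelse(neg, "negative", "positive"), traits)
}

#' Salt-tolerance index matrix
#'
#' Averages replicates per (genotype, trait, condition, timepoint) cell,
#' computes the salt/control STI, and arranges it as a genotype x trait
#' matrix. When several timepoints are present, each (trait, timepoint) pair
#' becomes its own column named `trait@timepoint`.
#'
#' @param trait_table a validated trait table.
#' @param directions optional named direction vector; defaults to
#'   [default_directions()] on the trait names.
#' @return list of class `sti_matrix`: `sti` (genotype x trait matrix,
#'   traits with a zero control mean dropped with a warning) and
#'   `directions` (aligned to the matrix columns).
#' @export
sti_matrix <- function(trait_table, directions = NULL) {
  tt <- validate_trait_table(trait_table)
  agg <- stats::aggregate(value ~ genotype + trait + timepoint + condition,
                          data = tt, FUN = mean)
  multi_tp <- length(unique(agg$timepoint)) > 1
  agg$column <- if (multi_tp) paste0(agg$trait, "@", agg$timepoint) else agg$trait
  ctrl <- agg[agg$condition == "control", ]
  salt <- agg[agg$condition == "salt", ]
  key <- function(d) paste(d$genotype, d$column, sep = "\r")
  m <- match(key(salt), key(ctrl))
  if (anyNA(m)) stop("salt cell without control counterpart", call. = FALSE)
  sti_long <- data.frame(genotype = salt$genotype, column = salt$column,
                         trait = salt$trait,
                         sti = salt_tolerance_index(salt$value, ctrl$value[m]),
                         stringsAsFactors = FALSE)
  bad_cols <- unique(sti_long$column[is.na(sti_long$sti)])
  if (length(bad_cols)) {
    warning("dropping trait column(s) with zero control mean: ",
            paste(bad_cols, collapse = ", "), call. = FALSE)
    sti_long <- sti_long[!sti_long$column %in% bad_cols, , drop = FALSE]
  }
  genotypes <- sort(unique(sti_long$genotype))
  columns <- sort(unique(sti_long$column))
  mat <- matrix(NA_real_, length(genotypes), length(columns),
                dimnames = list(genotypes, columns))
  mat[cbind(match(sti_long$genotype, genotypes),
            match(sti_long$column, columns))] <- sti_long$sti
  if (anyNA(mat)) {
    stop("STI matrix has missing entries: not every genotype was measured ",
         "for every trait", call. = FALSE)
  }
  base_trait <- sub("@.*$", "", columns)
  if (is.null(directions)) {
    dir <- default_directions(base_trait)
  } else {
    missing <- setdiff(base_trait, names(directions))
    if (length(missing)) {
      stop("no direction for trait(s): ",
           paste(unique(missing), collapse = ", "), call. = FALSE)
    }
    dir <- directions[base_trait]
  }
  if (!all(dir %in% c("positive", "negative"))) {
    stop("directions must be 'positive' or 'negative'", call. = FALSE)
  }
  structure(list(sti = mat,
                 directions = stats::setNames(unname(dir), columns)),
            class = "sti_matrix")
}
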