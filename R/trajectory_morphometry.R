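# Gene-set z-score maturation trajectories and morphometry statistics
# (cytoplasm/nucleus ratios, mitochondria counts).

#' Gene-set z-score trajectory across ordered conditions
#'
#' Each retained gene is z-scored across all samples; the trajectory value
#' of a condition is the mean z over (genes x samples in that condition).
#' Genes absent from the matrix or with zero variance are dropped and
#' recorded in the `dropped_genes` attribute.
#'
#' @param x `normalized_counts` or numeric feature-by-sample matrix.
#' @param gene_set Character vector of gene ids.
#' @param design Sample design table.
#' @param condition_order Ordered condition labels (values of
#'   `condition_col`); defaults to order of appearance.
#' @param condition_col Design column holding the condition (default
#'   "population").
#' @param label Gene-set label carried into the result.
#' @return Object of class `trajectory_profile`: label, conditions,
#'   mean_z (named by condition), z (gene x sample matrix).
#' @export
zscore_trajectory <- function(x, gene_set, design, condition_order = NULL,
                              condition_col = "population",
                              label = "custom") {
  values <- if (inherits(x, "normalized_counts")) x$values else x
  .assert(is.matrix(values) && is.numeric(values), "need a numeric matrix")
  design <- design_for(design, values)
  cond <- design[[condition_col]]
  .assert(!is.null(cond), "design lacks column ", condition_col)
  if (is.null(condition_order)) condition_order <- unique(cond)
  .assert(all(cond %in% condition_order), "condition_order must cover all samples")
  present <- intersect(gene_set, rownames(values))
  .assert(length(present) > 0, "no gene of the set is present in the matrix")
  sub <- values[present, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  dropped <- c(setdiff(gene_set, rownames(values)), present[sds == 0])
  keep <- sds > 0
  .assert(any(keep), "all genes in the set have zero variance")
  z <- (sub[keep, , drop = FALSE] - rowMeans(sub[keep, , drop = FALSE])) /
    sds[keep]
  mean_z <- vapply(condition_order,
                   function(cc) mean(z[, cond == cc, drop = FALSE]), 0)
  structure(list(
    label = label,
    conditions = condition_order,
    mean_z = setNames(mean_z, condition_order),
    z = z
  ), class = "trajectory_profile", dropped_genes = dropped)
}

#' @export
print.trajectory_profile <- function(x, ...) {
  cat("trajectory_profile [", x$label, "]: ", nrow(x$z), " genes\n", sep = "")
  print(signif(x$mean_z, 3))
  invisible(x)
}

#' Cytoplasm and nucleus area ratios for one cell
#'
#' Cell and nucleus areas are each averaged over their repeated
#' measurements first; the cytoplasm area is the difference of the means.
#' The primary ratio is cytoplasm/nucleus; the inverted nucleus/cytoplasm
#' variant is also returned.
#'
#' @param cell_areas Numeric vector of repeated whole-cell area
#'   measurements (> 0).
#' @param nucleus_areas Numeric vector of repeated nucleus area
#'   measurements (> 0).
#' @return List: cell_area, nucleus_area, cytoplasm_area,
#'   cytoplasm_nucleus_ratio, nucleus_cytoplasm_ratio.
#' @export
cytoplasm_nucleus_ratio <- function(cell_areas, nucleus_areas) {
  .assert(is.numeric(cell_areas) && length(cell_areas) >= 1 &&
            all(cell_areas > 0), "cell_areas must be positive")
  .assert(is.numeric(nucleus_areas) && length(nucleus_areas) >= 1 &&
            all(nucleus_areas > 0), "nucleus_areas must be positive")
  mc <- mean(cell_areas)
  mn <- mean(nucleus_areas)
  .assert(mn < mc, "mean nucleus area (", signif(mn, 4),
          ") must be smaller than mean cell area (", signif(mc, 4), ")")
  cyt <- mc - mn
  list(cell_area = mc, nucleus_area = mn, cytoplasm_area = cyt,
       cytoplasm_nucleus_ratio = cyt / mn,
       nucleus_cytoplasm_ratio = mn / cyt)
}

#' Poisson log-linear comparison of per-cell counts between groups
#'
#' Fits count ~ group with a Poisson GLM per pair of groups; p-values are
#' likelihood-ratio chi-square tests (df 1), Benjamini-Hochberg corrected
#' across pairs. Rate ratios are the ratios of group means (infinite when
#' contrasting against an all-zero group, flagged but still tested).
#'
#' @param counts Integer vector of per-cell counts (e.g. mitochondria per
#'   cell).
#' @param groups Factor/character of group labels, same length.
#' @return data.frame: group_a, group_b, comparison, rate_a, rate_b,
#'   rate_ratio, lrt_stat, p_raw, q_bh.
#' @export
poisson_group_test <- function(counts, groups) {
  .assert(is.numeric(counts) && all(counts >= 0) &&
            all(abs(counts - round(counts)) < 1e-8),
          "counts must be non-negative integers")
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else sort(unique(groups))
  groups <- as.character(groups)
  .assert(length(groups) == length(counts), "groups must match counts")
  .assert(length(lev) >= 2, "need at least 2 groups")
  .assert(all(table(groups) >= 2), "every group needs >= 2 cells")
  pairs <- combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    idx <- groups %in% c(ga, gb)
    y <- counts[idx]
    g <- factor(groups[idx], levels = c(ga, gb))
    m1 <- suppressWarnings(glm(y ~ g, family = poisson()))
    m0 <- suppressWarnings(glm(y ~ 1, family = poisson()))
    lrt <- as.numeric(m0$deviance - m1$deviance)
    ra <- mean(y[g == ga]); rb <- mean(y[g == gb])
    data.frame(
      group_a = ga, group_b = gb,
      comparison = paste0(gb, "_vs_", ga),
      rate_a = ra, rate_b = rb,
      rate_ratio = rb / ra,
      lrt_stat = lrt,
      p_raw = pchisq(lrt, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$rate_ratio))) {
    warning("infinite rate ratio for contrasts against an all-zero group")
  }
  out$q_bh <- bh_fdr(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Mixed-model ANOVA with Tukey-Kramer contrasts on a scalar readout
#'
#' Applies the per-feature mixed model (population fixed, donor/patient
#' random) to a single measured quantity such as mean cell area or the
#' cytoplasm/nucleus ratio.
#'
#' @param values Numeric vector, one value per sample/cell.
#' @param design Sample design table aligned with `values`.
#' @return data.frame of pairwise statistics with q_bh across the pairs.
#' @export
mixed_anova_on_scalar <- function(values, design) {
  fit <- fit_mixed_anova(values, design, feature_id = "scalar")
  stats <- tukey_kramer(fit)
  stats$q_bh <- bh_fdr(stats$p_raw)
  stats
}

#' Built-in apoptosis-axis gene sets
#'
#' Editable seed lists for the ER-stress, pro-survival and pro-apoptotic
#' programs (representative genes of each class; substitute full pathway
#' rosters via [read_gmt()] for real analyses).
#'
#' @return Named list of character vectors.
#' @export
apoptosis_gene_sets <- function() {
  read_gmt(system.file("extdata", "apoptosis_gene_sets.gmt",
                       package = "ascmature", mustWork = TRUE))
}
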