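# Negative-binomial two-group testing on peak counts. The test statistic
# is a conditional exact test: group sums are modelled as NB with size
# parameters proportional to the group's (normalized) library size, so the
# conditional distribution of one group's sum given the total is free of
# the nuisance mean, and reduces to the binomial test in the Poisson
# (dispersion -> 0) limit. edgeR's exact test (rejection.region =
# "smallp") reproduces these p-values and serves as the independent
# cross-check in the test suite.

#' Estimate peak dispersions by pooled method of moments
#'
#' Normalized counts z = y / s have approximate variance mu + phi * mu^2.
#' The common dispersion pools within-group means and variances across all
#' peaks; per-peak estimates are shrunk toward the common value with
#' weight w = prior_df / (prior_df + df_peak).
#'
#' @param counts Integer peak-by-sample matrix.
#' @param design Sample design table (grouping via `group_col`).
#' @param size_factors Per-sample factors; median-of-ratios when NULL.
#' @param group_col Design column defining the groups (default
#'   "population").
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @return Numeric vector of per-peak dispersions (>= 0) with attributes
#'   `common` (pooled estimate) and `flagged_all_zero` (peak ids with no
#'   counts, assigned dispersion 0).
#' @export
estimate_dispersions <- function(counts, design, size_factors = NULL,
                                 group_col = "population", prior_df = 10) {
  check_count_matrix(counts)
  design <- design_for(design, counts)
  groups <- design[[group_col]]
  .assert(!is.null(groups), "design lacks grouping column ", group_col)
  .assert(all(table(groups) >= 2), "every group needs >= 2 samples")
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  s <- size_factors / exp(mean(log(size_factors)))
  z <- sweep(counts, 2, s, "/")
  num <- rep(0, nrow(counts))
  den <- rep(0, nrow(counts))
  df <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    mg <- rowMeans(z[, idx, drop = FALSE])
    vg <- apply(z[, idx, drop = FALSE], 1, var)
    hg <- mean(1 / s[idx])          # E[var of y/s] = mu * mean(1/s) + phi mu^2
    num <- num + (ng - 1) * (vg - mg * hg)
    den <- den + (ng - 1) * mg^2
    df <- df + (ng - 1)
  }
  ok <- den > 0
  common <- max(0, sum(num[ok]) / sum(den[ok]))
  tagwise <- rep(common, nrow(counts))
  raw <- ifelse(ok, pmax(0, num / ifelse(den > 0, den, 1)), 0)
  w <- prior_df / (prior_df + df)
  tagwise <- w * common + (1 - w) * raw
  tagwise[!ok] <- 0                  # all-zero peaks
  names(tagwise) <- rownames(counts)
  structure(tagwise,
            common = common,
            flagged_all_zero = rownames(counts)[rowSums(counts) == 0])
}

# log-sum-exp
.lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Negative-binomial conditional exact test for one peak
#'
#' Raw group sums a and b are conditioned on their total t. Under the
#' null the conditional pmf of a is negative-hypergeometric with size
#' parameters L_A / phi and L_B / phi (L = sum of normalized size factors
#' per group); the two-sided p-value sums all outcomes whose conditional
#' probability does not exceed that of the observed split (binom.test's
#' convention), and at phi = 0 reduces exactly to the binomial test of a
#' in t trials at proportion L_A / (L_A + L_B). The fold change is
#' log2((mean_b + c) / (mean_a + c)) on normalized per-sample means with
#' prior count c.
#'
#' @param peak_counts Integer count vector across samples.
#' @param groups Two-level factor/character of the same length.
#' @param size_factors Per-sample positive factors.
#' @param dispersion NB dispersion phi >= 0 (0 = Poisson).
#' @param prior_count Prior count for the fold change (default 0.125).
#' @return List: log2fc, p_raw, dispersion_used, mean_a, mean_b,
#'   group_a, group_b.
#' @export
nb_exact_test <- function(peak_counts, groups, size_factors,
                          dispersion = 0, prior_count = 0.125) {
  .assert(is.numeric(peak_counts) && all(peak_counts >= 0) &&
            all(abs(peak_counts - round(peak_counts)) < 1e-8),
          "peak_counts must be non-negative integers")
  # orientation follows the label order (factor levels, else sorted), so
  # that swapping the labels of the same samples negates the fold change
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else sort(unique(groups))
  groups <- as.character(groups)
  .assert(length(lev) == 2, "exactly two groups are required")
  .assert(all(table(groups) >= 1), "one group is empty")
  .assert(length(size_factors) == length(peak_counts) &&
            all(size_factors > 0), "need one positive size factor per sample")
  .assert(is.numeric(dispersion) && dispersion >= 0, "dispersion must be >= 0")
  s <- size_factors / exp(mean(log(size_factors)))
  ia <- groups == lev[1]
  ib <- groups == lev[2]
  mean_a <- mean(peak_counts[ia] / s[ia])
  mean_b <- mean(peak_counts[ib] / s[ib])
  log2fc <- log2((mean_b + prior_count) / (mean_a + prior_count))

  a_obs <- sum(peak_counts[ia])
  t_tot <- a_obs + sum(peak_counts[ib])
  if (t_tot == 0) {
    return(list(log2fc = 0, p_raw = 1, dispersion_used = dispersion,
                mean_a = mean_a, mean_b = mean_b,
                group_a = lev[1], group_b = lev[2]))
  }
  la <- sum(s[ia])
  lb <- sum(s[ib])
  a <- 0:t_tot
  if (dispersion < 1e-10) {
    logf <- dbinom(a, t_tot, la / (la + lb), log = TRUE)
  } else {
    ra <- la / dispersion
    rb <- lb / dispersion
    logf <- lgamma(a + ra) - lgamma(a + 1) +
      lgamma(t_tot - a + rb) - lgamma(t_tot - a + 1)
    logf <- logf - .lse(logf)
  }
  f <- exp(logf)
  p <- min(1, sum(f[f <= f[a_obs + 1] * (1 + 1e-7)]))
  list(log2fc = log2fc, p_raw = p, dispersion_used = dispersion,
       mean_a = mean_a, mean_b = mean_b,
       group_a = lev[1], group_b = lev[2])
}

#' Differential accessibility testing across all population pairs
#'
#' Size factors (median-of-ratios, full matrix) and moment-based
#' dispersions are estimated once; each population pair is then tested
#' peak by peak with the conditional exact test, with Benjamini-Hochberg
#' correction across peaks within each comparison.
#'
#' @param counts Integer peak-by-sample matrix.
#' @param design Sample design table.
#' @param group_col Design column defining populations.
#' @param prior_df Dispersion shrinkage prior df (see
#'   [estimate_dispersions()]).
#' @return data.frame: peak_id, group_a, group_b, comparison, log2fc,
#'   p_raw, q_bh, dispersion_used.
#' @export
run_nb_dar <- function(counts, design, group_col = "population",
                       prior_df = 10) {
  check_count_matrix(counts)
  design <- design_for(design, counts)
  groups <- design[[group_col]]
  sf <- size_factors_median_ratio(counts)
  disp <- estimate_dispersions(counts, design, size_factors = sf,
                               group_col = group_col, prior_df = prior_df)
  lev <- unique(groups)
  .assert(length(lev) >= 2, "need at least two populations")
  pairs <- combn(lev, 2)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    idx <- groups %in% c(ga, gb)
    sub_groups <- factor(groups[idx], levels = c(ga, gb))
    res <- lapply(seq_len(nrow(counts)), function(i) {
      r <- nb_exact_test(counts[i, idx], sub_groups, sf[idx],
                         dispersion = disp[i])
      c(log2fc = r$log2fc, p_raw = r$p_raw)
    })
    res <- do.call(rbind, res)
    out[[j]] <- data.frame(
      peak_id = rownames(counts),
      group_a = ga, group_b = gb,
      comparison = paste0(gb, "_vs_", ga),
      log2fc = res[, "log2fc"],
      p_raw = res[, "p_raw"],
      q_bh = bh_fdr(res[, "p_raw"]),
      dispersion_used = as.numeric(disp),
      stringsAsFactors = FALSE
    )
  }
  stats <- do.call(rbind, out)
  rownames(stats) <- NULL
  stats
}

#' Call differentially accessible regions (DARs)
#'
#' A peak is a DAR for a comparison when |log2fc| > `min_abs_log2fc` and
#' q < `fdr_threshold`, both strict, with direction "up"/"down" by the
#' sign of the fold change.
#'
#' @param stats Peak statistics with columns peak_id, comparison, log2fc,
#'   q_bh.
#' @param min_abs_log2fc Absolute log2 fold-change cutoff (strict >;
#'   default 1).
#' @param fdr_threshold FDR cutoff (strict <; default 0.05).
#' @return List with `per_comparison` (named list of peak id vectors),
#'   `union`, and `table` (peak_id, comparison, direction).
#' @export
call_dars <- function(stats, min_abs_log2fc = 1, fdr_threshold = 0.05) {
  .assert(min_abs_log2fc >= 0 && fdr_threshold >= 0, "thresholds must be >= 0")
  if (nrow(stats) == 0) {
    return(list(per_comparison = list(), union = character(0),
                table = data.frame(peak_id = character(0),
                                   comparison = character(0),
                                   direction = character(0))))
  }
  hit <- abs(stats$log2fc) > min_abs_log2fc & stats$q_bh < fdr_threshold
  tab <- data.frame(
    peak_id = stats$peak_id[hit],
    comparison = stats$comparison[hit],
    direction = ifelse(stats$log2fc[hit] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  cmps <- unique(stats$comparison)
  per <- setNames(lapply(cmps, function(cmp) {
    unique(tab$peak_id[tab$comparison == cmp])
  }), cmps)
  list(per_comparison = per,
       union = unique(tab$peak_id),
       table = tab)
}

#' Write DARs of one comparison to BED
#'
#' Score is -10 * log10(q) capped at 1000; strand is ".".
#'
#' @param stats Peak statistics (one comparison) with peak coordinates
#'   joined in columns chrom, start, end.
#' @param path Output path.
#' @export
write_dar_bed <- function(stats, path) {
  .assert(all(c("chrom", "start", "end", "peak_id", "q_bh") %in% names(stats)),
          "stats need chrom/start/end/peak_id/q_bh columns")
  gr <- peaks_as_granges(stats[, c("chrom", "start", "end", "peak_id")])
  gr$score <- pmin(-10 * log10(pmax(stats$q_bh, 1e-100)), 1000)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
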