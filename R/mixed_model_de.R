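# Per-feature linear mixed-effects ANOVA: population as fixed effect,
# patient as random intercept, fitted by profiled REML on the variance
# ratio lambda = sigma_b^2 / sigma_e^2. The same eigendecomposition of the
# patient relatedness matrix Z Z' serves every feature, which keeps
# transcriptome-wide fitting fast; lme4 reproduces these fits and is used
# as an independent cross-check in the test suite.

#' Precompute the shared design structure for mixed-model fits
#'
#' @param design Sample design table (sample_id, population, patient).
#' @return An object of class `mixed_design` reused by [fit_mixed_anova()].
#' @export
mixed_design <- function(design) {
  check_design(design)
  pop <- factor(design$population, levels = unique(design$population))
  pat <- factor(design$patient, levels = unique(design$patient))
  .assert(nlevels(pop) >= 2, "need at least 2 populations")
  n_per <- table(pop)
  .assert(all(n_per >= 2), "every population needs at least 2 observations; ",
          "drop populations with a single sample first")
  X <- model.matrix(~ 0 + pop)           # cell-means coding: beta = means
  colnames(X) <- levels(pop)
  Z <- model.matrix(~ 0 + pat)
  n <- nrow(X)
  p <- ncol(X)
  eig <- eigen(tcrossprod(Z), symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  rank_xz <- qr(cbind(X, Z))$rank
  df_containment <- n - rank_xz
  # degenerate structure (e.g. one observation per patient): the random
  # intercept is confounded with the residual; collapse to one-way ANOVA df
  if (df_containment <= 0) df_containment <- n - p
  structure(list(
    populations = levels(pop), pop = pop, patient = pat,
    X = X, Z = Z, U = U, d = d, Xs = crossprod(U, X),
    n = n, p = p, df_error = df_containment,
    n_per_population = as.integer(n_per)
  ), class = "mixed_design")
}

# -2 * profiled REML log-likelihood (up to a constant) at variance ratio
# lambda, in the rotated basis where V0 = I + lambda * diag(d)
.reml_objective <- function(lambda, Xs, ys, d, n, p) {
  w <- 1 / (1 + lambda * d)
  sw <- sqrt(w)
  Xw <- Xs * sw
  yw <- ys * sw
  A <- crossprod(Xw)
  beta <- solve(A, crossprod(Xw, yw))
  rss <- sum((yw - Xw %*% beta)^2)
  crit <- (n - p) * log(max(rss, 1e-300)) + sum(log1p(lambda * d)) +
    as.numeric(determinant(A, logarithm = TRUE)$modulus)
  list(crit = crit, beta = drop(beta), rss = rss, A = A)
}

#' Fit the per-feature mixed-effects ANOVA by profiled REML
#'
#' Model: y = mu + alpha_population + b_patient + e with b ~ N(0, sigma_b^2)
#' and e ~ N(0, sigma_e^2). REML is profiled down to the one-dimensional
#' variance ratio, optimized to tolerance 1e-8 with sigma_b^2 floored at
#' zero. Population means are model-based (generalized least squares)
#' means; their variances come from the fitted covariance. The error
#' degrees of freedom use the containment (residual) convention,
#' n - rank([X Z]), collapsing to one-way ANOVA df when patients are
#' confounded with residuals.
#'
#' @param values Numeric vector of one feature's values (log2 scale),
#'   ordered as `design`.
#' @param design Sample design table, or a precomputed [mixed_design()].
#' @param feature_id Optional label carried into the result.
#' @return An object of class `mixed_fit`: population_means, var_patient,
#'   var_resid, df_error, n_per_population, mean_variances, lambda.
#' @export
fit_mixed_anova <- function(values, design, feature_id = NA_character_) {
  md <- if (inherits(design, "mixed_design")) design else mixed_design(design)
  .assert(is.numeric(values) && length(values) == md$n,
          "values must match the design rows")
  .assert(all(is.finite(values)), "values must be finite")
  ys <- drop(crossprod(md$U, values))
  n <- md$n; p <- md$p; d <- md$d; Xs <- md$Xs

  if (var(values) < 1e-24) {
    # perfectly constant feature: zero variance components, equal means
    means <- setNames(rep(values[1], p), md$populations)
    return(structure(list(
      feature_id = feature_id, population_means = means,
      var_patient = 0, var_resid = 0, df_error = md$df_error,
      n_per_population = setNames(md$n_per_population, md$populations),
      mean_variances = setNames(rep(0, p), md$populations),
      lambda = 0, populations = md$populations
    ), class = "mixed_fit"))
  }

  obj <- function(theta) .reml_objective(exp(theta), Xs, ys, d, n, p)$crit
  opt <- optimize(obj, interval = c(-14, 14), tol = 1e-8)
  at0 <- .reml_objective(0, Xs, ys, d, n, p)
  if (at0$crit <= opt$objective + 1e-7) {
    lambda <- 0
    fit <- at0
  } else {
    lambda <- exp(opt$minimum)
    fit <- .reml_objective(lambda, Xs, ys, d, n, p)
  }
  sigma_e2 <- fit$rss / (n - p)
  sigma_b2 <- max(lambda * sigma_e2, 0)
  vcov_means <- sigma_e2 * solve(fit$A)
  structure(list(
    feature_id = feature_id,
    population_means = setNames(fit$beta, md$populations),
    var_patient = sigma_b2, var_resid = sigma_e2,
    df_error = md$df_error,
    n_per_population = setNames(md$n_per_population, md$populations),
    mean_variances = setNames(diag(vcov_means), md$populations),
    lambda = lambda, populations = md$populations
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("mixed_fit", if (!is.na(x$feature_id)) paste0("[", x$feature_id, "]"),
      ": sigma_b^2 =", signif(x$var_patient, 4),
      ", sigma_e^2 =", signif(x$var_resid, 4),
      ", df_error =", x$df_error, "\n")
  print(signif(x$population_means, 4))
  invisible(x)
}

#' Tukey-Kramer pairwise contrasts from a mixed-model fit
#'
#' For each population pair (a, b): q = |m_b - m_a| / sqrt((v_a + v_b)/2)
#' with v the estimated variance of each model-based mean, referred to the
#' studentized range distribution with k = number of populations and the
#' fit's error degrees of freedom. log2fc is m_b - m_a for the comparison
#' labelled "b_vs_a".
#'
#' @param fit A `mixed_fit`.
#' @return data.frame: feature_id, group_a, group_b, comparison, log2fc,
#'   p_raw.
#' @export
tukey_kramer <- function(fit) {
  .assert(inherits(fit, "mixed_fit"), "fit must come from fit_mixed_anova()")
  pops <- fit$populations
  k <- length(pops)
  pairs <- combn(pops, 2)
  m <- fit$population_means
  v <- fit$mean_variances
  out <- data.frame(
    feature_id = fit$feature_id,
    group_a = pairs[1, ], group_b = pairs[2, ],
    comparison = paste0(pairs[2, ], "_vs_", pairs[1, ]),
    log2fc = m[pairs[2, ]] - m[pairs[1, ]],
    p_raw = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  se <- sqrt((v[pairs[1, ]] + v[pairs[2, ]]) / 2)
  q <- abs(out$log2fc) / se
  p <- ifelse(is.finite(q), ptukey(q, nmeans = k, df = fit$df_error,
                                   lower.tail = FALSE), 1)
  bad <- !is.finite(se) | se <= 0
  if (any(bad & abs(out$log2fc) > 0)) {
    warning("non-finite standard error for some contrasts; p set to 1")
  }
  p[bad] <- 1
  out$p_raw <- pmin(pmax(p, 0), 1)
  out
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, mapped back to input
#' order. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  .assert(is.numeric(p_values), "p_values must be numeric")
  .assert(all(is.finite(p_values)) && all(p_values >= 0) && all(p_values <= 1),
          "p_values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Mixed-model differential expression across a whole matrix
#'
#' Fits [fit_mixed_anova()] per feature, computes Tukey-Kramer pairwise
#' contrasts, and applies Benjamini-Hochberg correction across features
#' separately within each pairwise comparison (set `pool_comparisons =
#' TRUE` to correct across all comparisons jointly).
#'
#' @param x `normalized_counts` or a numeric feature-by-sample matrix
#'   (log2 scale).
#' @param design Sample design table covering the matrix's samples.
#' @param pool_comparisons Pool all comparisons into one BH family?
#' @return data.frame of pairwise statistics: feature_id, group_a,
#'   group_b, comparison, log2fc, p_raw, q_bh.
#' @export
run_mixed_de <- function(x, design, pool_comparisons = FALSE) {
  values <- if (inherits(x, "normalized_counts")) x$values else x
  .assert(is.matrix(values) && is.numeric(values), "need a numeric matrix")
  design <- design_for(design, values)
  n_per <- table(design$population)
  thin <- names(n_per)[n_per < 2]
  if (length(thin) > 0) {
    message("populations with < 2 observations dropped from the fit: ",
            paste(thin, collapse = ", "))
    design <- design[!design$population %in% thin, , drop = FALSE]
    values <- values[, design$sample_id, drop = FALSE]
  }
  md <- mixed_design(design)
  res <- vector("list", nrow(values))
  for (i in seq_len(nrow(values))) {
    fit <- fit_mixed_anova(values[i, ], md, feature_id = rownames(values)[i])
    res[[i]] <- tukey_kramer(fit)
  }
  stats <- do.call(rbind, res)
  rownames(stats) <- NULL
  if (pool_comparisons) {
    stats$q_bh <- bh_fdr(stats$p_raw)
  } else {
    stats$q_bh <- NA_real_
    for (cmp in unique(stats$comparison)) {
      idx <- stats$comparison == cmp
      stats$q_bh[idx] <- bh_fdr(stats$p_raw[idx])
    }
  }
  stats
}

#' Call differentially expressed features from pairwise statistics
#'
#' A feature is differentially expressed for a comparison when
#' q < `fdr_threshold` and |log2fc| >= `min_abs_log2fc`. The ex vivo rule
#' uses FDR alone (min_abs_log2fc = 0); the in vitro rule additionally
#' requires a fold change of 2 (min_abs_log2fc = 1). The union across
#' comparisons reproduces the "differential in at least one pairwise
#' comparison" construction.
#'
#' @param stats Pairwise statistics with columns feature_id, comparison,
#'   log2fc, q_bh.
#' @param fdr_threshold FDR cutoff (strict <; default 0.05).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 0).
#' @return List with `per_comparison` (named list of feature id vectors)
#'   and `union`.
#' @export
call_degs <- function(stats, fdr_threshold = 0.05, min_abs_log2fc = 0) {
  .assert(fdr_threshold >= 0 && min_abs_log2fc >= 0, "thresholds must be >= 0")
  if (nrow(stats) == 0) {
    return(list(per_comparison = list(), union = character(0)))
  }
  hit <- stats$q_bh < fdr_threshold & abs(stats$log2fc) >= min_abs_log2fc
  per <- lapply(split(stats$feature_id[hit], stats$comparison[hit]), unique)
  cmps <- unique(stats$comparison)
  per <- setNames(lapply(cmps, function(cmp) {
    if (cmp %in% names(per)) per[[cmp]] else character(0)
  }), cmps)
  list(per_comparison = per, union = unique(unlist(per, use.names = FALSE)))
}
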