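test_that("REML variance components and means agree with lme4 on simulated features", {
  design <- nested_design(c("P1", "P2", "P3"),
                          c(P1 = "blood", P2 = "blood", P3 = "bm"), 6)
  set.seed(101)
  for (rep in 1:5) {
    y <- sim_mixed_feature(design, pop_effects = c(P1 = 0, P2 = 1, P3 = -0.5),
                           sigma_b = 0.8, sigma_e = 0.6)
    fit <- fit_mixed_anova(y, design)
    lmm <- lme4::lmer(y ~ 0 + population + (1 | patient),
                      data = cbind(design, y = y), REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(lmm))
    expect_equal(fit$var_patient, vc$vcov[vc$grp == "patient"], tolerance = 1e-4)
    expect_equal(fit$var_resid, vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
    expect_equal(unname(fit$population_means),
                 unname(lme4::fixef(lmm)), tolerance = 1e-5)
    expect_equal(unname(fit$mean_variances),
                 unname(diag(as.matrix(vcov(lmm)))), tolerance = 1e-4)
  }
})

test_that("REML recovers planted variance components over replicates", {
  # 20 patients per compartment, 3 populations, sigma_b^2 = sigma_e^2 = 1
  design <- nested_design(c("P1", "P2", "P3"),
                          c(P1 = "bm", P2 = "bm", P3 = "bm"), 20)
  set.seed(202)
  vb <- ve <- numeric(200)
  for (i in 1:200) {
    y <- sim_mixed_feature(design, sigma_b = 1, sigma_e = 1)
    fit <- fit_mixed_anova(y, design)
    vb[i] <- fit$var_patient
    ve[i] <- fit$var_resid
  }
  expect_lt(abs(median(vb) - 1), 0.3)
  expect_lt(abs(median(ve) - 1), 0.3)
})

test_that("degenerate structures collapse gracefully", {
  design <- nested_design(c("P1", "P2"), c(P1 = "blood", P2 = "bm"), 4)

  # constant feature: zero variance components, all contrasts p = 1
  fit <- fit_mixed_anova(rep(3.5, nrow(design)), design)
  expect_equal(fit$var_patient, 0)
  expect_equal(fit$var_resid, 0)
  expect_equal(unname(fit$population_means), c(3.5, 3.5))
  tk <- tukey_kramer(fit)
  expect_equal(tk$log2fc, 0)
  expect_equal(tk$p_raw, 1)

  # one observation per patient, patients unshared across populations:
  # random intercept unidentifiable; means must equal group means
  set.seed(33)
  y <- rnorm(nrow(design))
  fit2 <- fit_mixed_anova(y, design)
  gm <- tapply(y, design$population, mean)
  expect_equal(unname(fit2$population_means),
               as.numeric(gm[unique(design$population)]), tolerance = 1e-8)
  expect_equal(fit2$df_error, nrow(design) - 2)
})

test_that("Tukey-Kramer with two balanced groups equals the pooled t-test", {
  # one sample per patient makes the model a one-way ANOVA exactly
  design <- nested_design(c("A", "B"), c(A = "blood", B = "bm"), 8)
  set.seed(44)
  y <- rnorm(nrow(design)) + ifelse(design$population == "B", 0.8, 0)
  fit <- fit_mixed_anova(y, design)
  tk <- tukey_kramer(fit)
  tt <- t.test(y[design$population == "B"], y[design$population == "A"],
               var.equal = TRUE)
  expect_equal(tk$p_raw, tt$p.value, tolerance = 1e-8)
  expect_equal(tk$log2fc, unname(diff(tapply(y, design$population, mean)[c("A", "B")])),
               tolerance = 1e-10)
})

test_that("Tukey-Kramer p-values are invariant to population relabeling", {
  design <- nested_design(c("P1", "P2", "P3"),
                          c(P1 = "bm", P2 = "bm", P3 = "bm"), 5)
  set.seed(55)
  y <- sim_mixed_feature(design, pop_effects = c(P1 = 0, P2 = 0.7, P3 = -0.2),
                         sigma_b = 0.5, sigma_e = 0.5)
  tk1 <- tukey_kramer(fit_mixed_anova(y, design))
  relab <- design
  relab$population <- c(P1 = "Z9", P2 = "A1", P3 = "M5")[design$population]
  tk2 <- tukey_kramer(fit_mixed_anova(y, relab))
  key1 <- setNames(tk1$p_raw, paste(pmin(tk1$group_a, tk1$group_b),
                                    pmax(tk1$group_a, tk1$group_b)))
  map <- c(P1 = "Z9", P2 = "A1", P3 = "M5")
  ga <- map[tk1$group_a]; gb <- map[tk1$group_b]
  key2 <- setNames(tk2$p_raw, paste(pmin(tk2$group_a, tk2$group_b),
                                    pmax(tk2$group_a, tk2$group_b)))
  expect_equal(unname(key2[paste(pmin(ga, gb), pmax(ga, gb))]),
               unname(key1), tolerance = 1e-10)
})

test_that("a planted three-residual-SD shift is detected with high power", {
  design <- nested_design(c("P1", "P2", "P3"),
                          c(P1 = "bm", P2 = "bm", P3 = "bm"), 8)
  set.seed(66)
  hits <- 0
  for (i in 1:100) {
    y <- sim_mixed_feature(design, pop_effects = c(P1 = 0, P2 = 0, P3 = 3),
                           sigma_b = 0, sigma_e = 1)
    tk <- tukey_kramer(fit_mixed_anova(y, design))
    shifted <- tk[tk$group_a == "P3" | tk$group_b == "P3", ]
    if (all(shifted$p_raw < 0.01)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("Benjamini-Hochberg adjustment matches the step-up arithmetic and is monotone", {
  # step-up oracle computed by hand: q_(i) = min_{j>=i} p_(j) m / j
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), rep(0.04, 4))

  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))

  # independent step-up oracle on random vectors
  set.seed(77)
  for (i in 1:20) {
    m <- sample(1:30, 1)
    pv <- runif(m)
    o <- order(pv)
    qs <- pv[o] * m / seq_len(m)
    qs <- rev(cummin(rev(qs)))
    oracle <- pmin(qs, 1)[order(o)]
    expect_equal(bh_fdr(pv), oracle)
    expect_true(all(bh_fdr(pv) >= pv))
  }

  # monotone: raising one p never lowers any q
  pv <- runif(15)
  q1 <- bh_fdr(pv)
  pv2 <- pv
  pv2[4] <- min(1, pv2[4] + 0.3)
  expect_true(all(bh_fdr(pv2) >= q1 - 1e-12))

  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling applies the FDR and fold-change rules per comparison", {
  stats <- data.frame(
    feature_id = c("g1", "g2", "g3"),
    comparison = "B_vs_A",
    log2fc = c(0.1, 0.9, 1.4),
    q_bh = c(0.049, 0.01, 0.2)
  )
  ex_vivo <- call_degs(stats, fdr_threshold = 0.05, min_abs_log2fc = 0)
  expect_equal(ex_vivo$per_comparison$B_vs_A, c("g1", "g2"))

  in_vitro <- call_degs(stats, fdr_threshold = 0.05, min_abs_log2fc = 1)
  expect_equal(in_vitro$per_comparison$B_vs_A, character(0))

  empty <- call_degs(stats[0, ])
  expect_equal(empty$union, character(0))
})

test_that("whole-matrix mixed DE controls the false-positive rate under the null", {
  design <- nested_design(c("P1", "P2", "P3"),
                          c(P1 = "blood", P2 = "bm", P3 = "bm"), 6)
  set.seed(88)
  n_feat <- 300
  vals <- t(replicate(n_feat, sim_mixed_feature(design, sigma_b = 0.5,
                                                sigma_e = 0.7)))
  rownames(vals) <- sprintf("g%03d", seq_len(n_feat))
  colnames(vals) <- design$sample_id
  stats <- run_mixed_de(vals, design)
  degs <- call_degs(stats)
  expect_lte(length(degs$union) / n_feat, 0.07)
})
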