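toy_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    start = c(0, 20000),
    end = c(10000, 22000),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
}

test_that("peaks map to genes through gene bodies and promoter windows", {
  genes <- toy_genes()
  peaks <- data.frame(
    chrom = "chr1",
    start = c(500, 1000, 50000),
    end = c(700, 1200, 50100),
    peak_id = c("body", "prom", "nowhere"),
    stringsAsFactors = FALSE
  )
  map <- assign_peaks_to_genes(peaks, genes, window = 2000)
  expect_equal(map$body, "gA")
  expect_equal(map$nowhere, character(0))

  # promoter-window assignment: peak upstream of a TSS at 2500 (+ strand)
  genes2 <- data.frame(gene_id = "gP", chrom = "chr1", start = 2500,
                       end = 9000, strand = "+", stringsAsFactors = FALSE)
  peak2 <- data.frame(chrom = "chr1", start = 1000, end = 1200,
                      peak_id = "upstream", stringsAsFactors = FALSE)
  expect_equal(assign_peaks_to_genes(peak2, genes2, window = 2000)$upstream, "gP")

  # unknown chromosome: warned, unassigned
  peak3 <- data.frame(chrom = "chrX", start = 10, end = 20, peak_id = "off",
                      stringsAsFactors = FALSE)
  expect_warning(m3 <- assign_peaks_to_genes(peak3, genes, window = 2000),
                 "unassigned")
  expect_equal(m3$off, character(0))
})

test_that("peak-gene assignment equals a brute-force all-pairs overlap oracle", {
  # half-open overlap oracle over body union promoter window
  overlaps_halfopen <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  set.seed(501)
  for (rep in 1:100) {
    ng <- sample(3:8, 1)
    np <- sample(5:15, 1)
    w <- sample(c(100, 500, 2000), 1)
    gs <- sort(sample(0:50000, ng))
    genes <- data.frame(
      gene_id = sprintf("g%02d", 1:ng), chrom = sample(c("c1", "c2"), ng, TRUE),
      start = gs, end = gs + sample(500:5000, ng, TRUE),
      strand = sample(c("+", "-"), ng, TRUE), stringsAsFactors = FALSE
    )
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    ps <- sample(0:60000, np)
    peaks <- data.frame(
      chrom = sample(c("c1", "c2"), np, TRUE), start = ps,
      end = ps + sample(50:1000, np, TRUE),
      peak_id = sprintf("p%02d", 1:np), stringsAsFactors = FALSE
    )
    got <- suppressWarnings(assign_peaks_to_genes(peaks, genes, window = w))
    for (i in seq_len(np)) {
      hits <- character(0)
      for (j in seq_len(ng)) {
        if (peaks$chrom[i] != genes$chrom[j]) next
        body <- overlaps_halfopen(peaks$start[i], peaks$end[i],
                                  genes$start[j], genes$end[j])
        prom <- overlaps_halfopen(peaks$start[i], peaks$end[i],
                                  max(genes$tss[j] - w, 0), genes$tss[j] + w)
        if (body || prom) hits <- c(hits, genes$gene_id[j])
      }
      expect_equal(got[[peaks$peak_id[i]]], sort(unique(hits)))
    }
  }
})

test_that("DAG construction unions genes over DAR peaks with set semantics", {
  map <- list(p1 = c("gA"), p2 = c("gA"), p3 = character(0),
              p4 = c("gB", "gC"), p5 = c("gD"))
  dags <- dags_from_dars(list(cmp1 = c("p1", "p2", "p3", "p4")), map)
  expect_equal(dags$cmp1, c("gA", "gB", "gC"))

  # hand-enumerated toy instance: 5 peaks / 4 genes
  dags2 <- dags_from_dars(list(x = c("p1", "p4", "p5")), map)
  expect_equal(dags2$x, c("gA", "gB", "gC", "gD"))

  expect_message(dags_from_dars(list(x = c("p1", "ghost")), map), "dropped")
})

test_that("Venn overlap counts partition the DEG and DAG sets exactly", {
  expect_equal(unname(overlap_sets(c("a", "b", "c"), c("b", "c", "d"))),
               c(1, 2, 1))
  expect_equal(unname(overlap_sets(c("a", "b"), c("x", "y", "z"))), c(2, 0, 3))
  expect_equal(unname(overlap_sets(c("a", "b"), c("a", "b"))), c(0, 2, 0))
  ov <- overlap_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov[["n_deg_only"]] + ov[["n_overlap"]], 3)
})

test_that("concordance classification applies the strict 0.585 rule with sign equivariance", {
  expect_equal(classify_concordance(1.0, 0.8), "concordant_up")
  expect_equal(classify_concordance(1.0, -0.9), "discordant")
  expect_equal(classify_concordance(-1.0, -0.7), "concordant_down")
  # exactly at the threshold is below_threshold (strict >)
  expect_equal(classify_concordance(0.585, 2.0), "below_threshold")
  expect_equal(classify_concordance(2.0, -0.585), "below_threshold")

  # sign equivariance: negating both swaps up/down and fixes discordant
  set.seed(61)
  e <- runif(50, -2, 2)
  a <- runif(50, -2, 2)
  k1 <- classify_concordance(e, a)
  k2 <- classify_concordance(-e, -a)
  swap <- c(concordant_up = "concordant_down",
            concordant_down = "concordant_up",
            discordant = "discordant",
            below_threshold = "below_threshold")
  expect_equal(k2, unname(swap[k1]))
})

test_that("per-gene concordance tables summarize accessibility by the most significant peak", {
  expr <- data.frame(feature_id = c("gA", "gB"), log2fc = c(1.2, -0.9))
  acc <- data.frame(
    peak_id = c("p1", "p2", "p3"),
    log2fc = c(0.9, -2.0, -1.1),
    p_raw = c(0.001, 0.2, 0.01),
    q_bh = c(0.01, 0.5, 0.04)
  )
  map <- list(p1 = "gA", p2 = "gA", p3 = "gB")
  tab <- concordance_table(expr, acc, map)
  # gA takes p1 (min q), not p2 despite its larger |lfc|
  expect_equal(tab$peak_id[tab$gene_id == "gA"], "p1")
  expect_equal(tab$klass[tab$gene_id == "gA"], "concordant_up")
  expect_equal(tab$klass[tab$gene_id == "gB"], "concordant_down")

  tab2 <- concordance_table(expr, acc, map, summary = "max_abs_lfc")
  expect_equal(tab2$peak_id[tab2$gene_id == "gA"], "p2")
})

test_that("hypergeometric over-representation matches direct tail summation", {
  universe <- sprintf("u%02d", 1:20)
  hits <- universe[1:5]
  gene_sets <- list(
    setA = universe[c(1, 2, 3, 10)],     # K = 4, k = 3
    setB = universe[11:14],              # K = 4, k = 0
    ghost = c("x1", "x2")                # disjoint from universe
  )
  expect_message(res <- ora_enrichment(hits, universe, gene_sets), "skipped")
  # direct summation: sum_{x=3..4} C(4,x) C(16,5-x) / C(20,5)
  direct <- (choose(4, 3) * choose(16, 2) + choose(4, 4) * choose(16, 1)) /
    choose(20, 5)
  expect_equal(direct, 496 / 15504, tolerance = 1e-12)  # = 0.03199174
  expect_equal(res$p_hypergeom[res$set == "setA"], direct, tolerance = 1e-12)
  expect_equal(res$p_hypergeom[res$set == "setB"], 1)
  expect_false("ghost" %in% res$set)

  expect_error(ora_enrichment(c("zz"), universe, gene_sets), "outside the universe")
})
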