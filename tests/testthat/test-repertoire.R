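test_that("clone assignment respects V/J/length partitions and the 70% boundary", {
  # 3 mismatches over length 10 = identity exactly 0.70 -> same clone
  rec <- data.frame(
    sequence_id = c("s1", "s2"),
    v_call = "IGHV1-2*02", j_call = "IGHJ4*02",
    junction = c("AAAAAAAAAA", "AAAAAAATTT"),
    stringsAsFactors = FALSE
  )
  ct <- assign_clones(rec)
  expect_equal(ct$clone_id[1], ct$clone_id[2])

  # 4 mismatches (identity 0.6) -> different clones
  rec$junction[2] <- "AAAAAATTTT"
  ct2 <- assign_clones(rec)
  expect_false(ct2$clone_id[1] == ct2$clone_id[2])

  # identical CDR3 but different V gene -> different clones
  rec3 <- data.frame(
    sequence_id = c("s1", "s2"),
    v_call = c("IGHV1-2*02", "IGHV3-23*01"), j_call = "IGHJ4*02",
    junction = "AAAAAAAAAA", stringsAsFactors = FALSE
  )
  ct3 <- assign_clones(rec3)
  expect_false(ct3$clone_id[1] == ct3$clone_id[2])

  # allele stripping: same gene, different alleles -> same partition
  rec4 <- rec3
  rec4$v_call <- c("IGHV1-2*02", "IGHV1-2*04")
  ct4 <- assign_clones(rec4)
  expect_equal(ct4$clone_id[1], ct4$clone_id[2])
})

test_that("clone assignment equals the brute-force single-linkage oracle", {
  set.seed(701)
  for (rep in 1:30) {
    rec <- random_partition_records(sample(10:50, 1), len = sample(c(12, 21), 1))
    ct <- assign_clones(rec)
    oracle <- oracle_clusters(rec$junction, 0.70)
    expect_true(same_partition(ct$clone_id, oracle))
  }
})

test_that("clone assignment is invariant to input order", {
  set.seed(702)
  rec <- random_partition_records(40, len = 12)
  ct1 <- assign_clones(rec)
  perm <- sample(nrow(rec))
  ct2 <- assign_clones(rec[perm, ])
  expect_equal(ct2$clone_id[order(ct2$sequence_id)],
               ct1$clone_id[order(ct1$sequence_id)])
})

test_that("every intra-clone pair is chained by links at or above the threshold", {
  sim <- generate_repertoire(repertoire_sim_config(
    n_clones_t1 = 40, seqs_per_sample = 200, seed = 9
  ))
  ct <- assign_clones(rbind(sim$airr_t1, sim$airr_t2))
  for (id in unique(ct$clone_id)) {
    seqs <- ct$junction[ct$clone_id == id]
    if (length(seqs) == 1) next
    expect_true(same_partition(oracle_clusters(seqs, 0.70),
                               rep(1L, length(seqs))))
  }
})

test_that("the size spectrum ranks clones with exact cumulative percentages", {
  summ <- data.frame(clone_id = c("c1", "c2", "c3"), size = c(30, 50, 20))
  spec <- clone_size_spectrum(summ)
  expect_equal(spec$clone_id, c("c2", "c1", "c3"))
  expect_equal(spec$cumulative_pct, c(50, 80, 100))

  single <- clone_size_spectrum(data.frame(clone_id = "c1", size = 7))
  expect_equal(single$cumulative_pct, 100)

  # ties broken by clone_id: deterministic
  tied <- data.frame(clone_id = c("z", "a", "m"), size = c(5, 5, 5))
  expect_equal(clone_size_spectrum(tied)$clone_id, c("a", "m", "z"))
})

test_that("Simpson diversity variants obey their closed forms", {
  d <- simpson_diversity(rep(10, 4))
  expect_equal(d$simpson_lambda, 0.25)
  expect_equal(d$gini_simpson, 0.75)
  expect_equal(d$inv_simpson, 4)

  expect_equal(simpson_diversity(42)$gini_simpson, 0)

  d2 <- simpson_diversity(c(2, 1, 1))
  expect_equal(d2$simpson_lambda, 0.375)
  expect_equal(d2$gini_simpson, 0.625)

  # S equal clones: gini = 1 - 1/S
  for (S in 1:10) {
    expect_equal(simpson_diversity(rep(3, S))$gini_simpson, 1 - 1 / S)
  }

  # cross-check against vegan on a random abundance vector
  set.seed(71)
  sizes <- sample(1:50, 12)
  expect_equal(simpson_diversity(sizes)$gini_simpson,
               unname(vegan::diversity(sizes, index = "simpson")),
               tolerance = 1e-12)

  expect_error(simpson_diversity(numeric(0)), "non-empty")
})

test_that("persistence counts shared clones over first-timepoint clones", {
  rec <- data.frame(
    sequence_id = sprintf("q%02d", 1:8),
    v_call = "IGHV1-2*02", j_call = "IGHJ4*02",
    junction = c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG",
                 "AAAAAAAAA", "CCCCCCCCC", "TTTTTTTTT",
                 "GGGGGGGGT", "TTTTTTTTA"),
    timepoint = c("Y1", "Y1", "Y1", "Y2", "Y2", "Y2", "Y1", "Y2"),
    stringsAsFactors = FALSE
  )
  # clones: A* (t1+t2), C* (t1+t2), G* (t1 only, q3+q7 within 1 mismatch),
  # T* (t2 only, q6+q8)
  ct <- assign_clones(rec)
  pers <- clone_persistence(ct, "Y1", "Y2")
  expect_equal(pers$n_t1_clones, 3)
  expect_equal(pers$clone_persistence, 2 / 3)

  # no shared clones
  rec2 <- rec[c(1, 6), ]
  pers2 <- clone_persistence(assign_clones(rec2), "Y1", "Y2")
  expect_equal(pers2$clone_persistence, 0)

  # pooled-clustering precondition: missing timepoint column rejected
  expect_error(clone_persistence(assign_clones(rec[, 1:4])), "timepoint")
})

test_that("synthetic repertoires yield unbiased persistence recovery across seeds", {
  errs <- vapply(1:10, function(s) {
    sim <- generate_repertoire(repertoire_sim_config(
      n_clones_t1 = 100, seqs_per_sample = 300,
      persistence_fraction = 0.3, seed = 1000 + s
    ))
    ct <- assign_clones(rbind(sim$airr_t1, sim$airr_t2))
    clone_persistence(ct, "Y1", "Y2")$clone_persistence -
      sim$truth$persistence_fraction
  }, 0)
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("isotype stratification maps constant-region prefixes and excludes the rest", {
  rec <- data.frame(
    sequence_id = sprintf("i%d", 1:4),
    v_call = "IGHV1-2*02", j_call = "IGHJ4*02",
    junction = "AAAAAAAAA",
    c_call = c("IGHG3", "IGHM", "IGHA2", "IGHE"),
    stringsAsFactors = FALSE
  )
  expect_warning(strata <- stratify_by_isotype(rec), "IGHE")
  expect_equal(strata$IgG$sequence_id, "i1")
  expect_equal(strata$IgM$sequence_id, "i2")
  expect_equal(strata$IgA$sequence_id, "i3")
  expect_false(any(vapply(strata, function(s) "i4" %in% s$sequence_id, TRUE)))
})

test_that("mutation load counts unambiguous substitutions and skips gaps", {
  expect_equal(mutation_load("ACGT", "ACGT"), 0)
  expect_equal(mutation_load("ACGT", "ATGA"), 2)
  expect_equal(mutation_load("AC-G", "ACTG"), 0)
  expect_equal(mutation_load("ACNG", "ACTG"), 0)
  expect_error(mutation_load("ACG", "ACGT"), "lengths differ")
})

test_that("repertoire generation is deterministic and honours persistence extremes", {
  cfg <- repertoire_sim_config(n_clones_t1 = 25, seqs_per_sample = 80,
                               persistence_fraction = 0, seed = 77)
  a <- generate_repertoire(cfg)
  b <- generate_repertoire(cfg)
  expect_identical(a$airr_t1, b$airr_t1)
  expect_identical(a$airr_t2, b$airr_t2)

  # zero persistence: no t1 truth clone reappears at t2
  t1c <- unique(a$truth$clone_truth[a$airr_t1$sequence_id])
  t2c <- unique(a$truth$clone_truth[a$airr_t2$sequence_id])
  expect_equal(length(intersect(t1c, t2c)), 0)

  # full persistence flows through clustering to an estimate of exactly 1
  sim1 <- generate_repertoire(repertoire_sim_config(
    n_clones_t1 = 25, seqs_per_sample = 80, persistence_fraction = 1, seed = 78
  ))
  ct <- assign_clones(rbind(sim1$airr_t1, sim1$airr_t2))
  expect_equal(clone_persistence(ct, "Y1", "Y2")$clone_persistence, 1.0)
})

test_that("per-isotype diversity drivers produce valid indices per group", {
  sim <- generate_repertoire(repertoire_sim_config(
    n_clones_t1 = 30, seqs_per_sample = 150, seed = 80
  ))
  rec <- rbind(sim$airr_t1, sim$airr_t2)
  rec$population <- rec$timepoint
  div <- diversity_by_isotype(rec)
  expect_true(all(div$simpson_lambda > 0 & div$simpson_lambda <= 1))
  expect_true(all(div$gini_simpson >= 0 & div$gini_simpson < 1))
  expect_true(all(div$inv_simpson >= 1))
  expect_setequal(unique(div$isotype), c("IgM", "IgG", "IgA"))
})
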