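# fixtures built in code, shared across test files

# small balanced count matrix with named dims
tiny_counts <- function(values, n_features = NULL, n_samples = NULL) {
  m <- matrix(values, nrow = n_features %||% nrow(values),
              ncol = n_samples %||% (length(values) / (n_features %||% 1)))
  rownames(m) <- sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# design with each patient contributing one sample per population of its
# compartment (nested structure)
nested_design <- function(populations, comp_of_pop, patients_per_comp) {
  rows <- list()
  for (cm in unique(comp_of_pop)) {
    for (pt in seq_len(patients_per_comp)) {
      for (pp in populations[comp_of_pop[populations] == cm]) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_%s%02d", pp, cm, pt),
          population = pp, patient = sprintf("%s%02d", cm, pt),
          compartment = cm, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

# simulate one mixed-model feature: y = alpha_pop + b_patient + e
sim_mixed_feature <- function(design, pop_effects = NULL, sigma_b = 1,
                              sigma_e = 1) {
  pops <- unique(design$population)
  if (is.null(pop_effects)) pop_effects <- setNames(rep(0, length(pops)), pops)
  b <- setNames(rnorm(length(unique(design$patient)), 0, sigma_b),
                unique(design$patient))
  pop_effects[design$population] + b[design$patient] +
    rnorm(nrow(design), 0, sigma_e)
}

# random AIRR records within one V/J/length partition
random_partition_records <- function(n, len = 30, prefix = "s") {
  data.frame(
    sequence_id = sprintf("%s%03d", prefix, seq_len(n)),
    v_call = "IGHV1-2*02", j_call = "IGHJ4*02",
    junction = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, ""),
    stringsAsFactors = FALSE
  )
}

# independent brute-force single-linkage oracle: adjacency + BFS over
# components (distinct code path from the package's union-find)
oracle_clusters <- function(seqs, threshold) {
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- (1 - sum(mat[i, ] != mat[j, ]) / ncol(mat)) >= threshold
    }
  }
  labels <- rep(NA_integer_, n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    comp <- comp + 1L
    frontier <- i
    while (length(frontier) > 0) {
      labels[frontier] <- comp
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(labels))
      frontier <- nb
    }
  }
  labels
}

# compare two clusterings as partitions (label-invariant)
same_partition <- function(a, b) {
  identical(
    sort(unname(vapply(split(seq_along(a), a), paste, "", collapse = ","))),
    sort(unname(vapply(split(seq_along(b), b), paste, "", collapse = ",")))
  )
}
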