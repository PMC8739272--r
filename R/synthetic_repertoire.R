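# Two-timepoint repertoire generator with clone-structured truth. Every
# clone has one founder junction; members are founder copies carrying a
# bounded number of point mutations, so within-clone identity to the
# founder stays >= 90% and single-linkage clustering at 70% recovers the
# planted partition exactly. Founders sharing a (V, J, CDR3-length)
# partition are rejection-sampled to be mutually divergent; the guard is
# floor(0.3 L) + 2 * m_cap mismatches with m_cap = floor(0.1 L), which is
# stricter than 30% divergence and guarantees that no pair of mutated
# members from different clones can reach the 70% threshold.

#' Configuration for the repertoire simulator
#'
#' @param n_clones_t1 Clones present at the first timepoint.
#' @param seqs_per_sample Sequences sampled per timepoint (scaled-down
#'   bulk VDJ depth).
#' @param persistence_fraction Fraction of first-timepoint clones that
#'   reappear at the second timepoint.
#' @param clone_size_power Zipf exponent for clone-size sampling (> 0).
#' @param v_genes,j_genes Gene-call labels (alleles included).
#' @param cdr3_length_range Junction length bounds in nucleotides
#'   (min >= 6; lengths are drawn as multiples of 3).
#' @param isotype_probs Named fractions for IgM/IgG/IgA summing to 1.
#' @param within_clone_mutation_rate Per-base mutation probability for
#'   clone members (mutation counts are capped at 10% of the junction).
#' @param seed Integer seed.
#' @return List of class `repertoire_sim_config`.
#' @export
repertoire_sim_config <- function(n_clones_t1 = 200,
                                  seqs_per_sample = 1000,
                                  persistence_fraction = 0.3,
                                  clone_size_power = 1.5,
                                  v_genes = c("IGHV1-2*02", "IGHV3-23*01",
                                              "IGHV4-34*01", "IGHV5-51*01"),
                                  j_genes = c("IGHJ4*02", "IGHJ6*01"),
                                  cdr3_length_range = c(30, 60),
                                  isotype_probs = c(IgM = 0.2, IgG = 0.5, IgA = 0.3),
                                  within_clone_mutation_rate = 0.02,
                                  seed = 1L) {
  cfg <- list(
    n_clones_t1 = n_clones_t1, seqs_per_sample = seqs_per_sample,
    persistence_fraction = persistence_fraction,
    clone_size_power = clone_size_power,
    v_genes = v_genes, j_genes = j_genes,
    cdr3_length_range = cdr3_length_range,
    isotype_probs = isotype_probs,
    within_clone_mutation_rate = within_clone_mutation_rate,
    seed = as.integer(seed)
  )
  .assert(n_clones_t1 >= 1, "need at least one clone")
  .assert(seqs_per_sample >= n_clones_t1,
          "seqs_per_sample must be >= n_clones_t1 so every clone is observed")
  .assert(persistence_fraction >= 0 && persistence_fraction <= 1,
          "persistence_fraction must be in [0, 1]")
  .assert(clone_size_power > 0, "clone_size_power must be > 0")
  .assert(length(v_genes) >= 1 && length(j_genes) >= 1, "need V and J genes")
  .assert(length(cdr3_length_range) == 2 &&
            cdr3_length_range[1] >= 6 &&
            cdr3_length_range[1] <= cdr3_length_range[2],
          "cdr3_length_range invalid (min >= 6 required)")
  .assert(abs(sum(isotype_probs) - 1) < 1e-9 &&
            all(c("IgM", "IgG", "IgA") %in% names(isotype_probs)),
          "isotype_probs must be named IgM/IgG/IgA and sum to 1")
  .assert(within_clone_mutation_rate >= 0 && within_clone_mutation_rate < 1,
          "within_clone_mutation_rate must be in [0, 1)")
  structure(cfg, class = "repertoire_sim_config")
}

.NT <- c("A", "C", "G", "T")

# founder junction that differs from every existing same-partition founder
# at more than floor(0.3 L) + 2 * floor(0.1 L) positions
.draw_founder <- function(len, existing, max_tries = 2000) {
  need <- floor(0.3 * len) + 2 * floor(0.1 * len) + 1
  for (i in seq_len(max_tries)) {
    cand <- sample(.NT, len, replace = TRUE)
    ok <- TRUE
    for (e in existing) {
      if (sum(cand != e) < need) { ok <- FALSE; break }
    }
    if (ok) return(cand)
  }
  stop("could not place a sufficiently divergent founder; ",
       "too many clones share one V/J/length partition", call. = FALSE)
}

# mutate a founder with a capped number of substitutions
.mutate <- function(founder, rate) {
  len <- length(founder)
  n_mut <- min(rbinom(1, len, rate), floor(0.1 * len))
  if (n_mut == 0) return(founder)
  pos <- sample.int(len, n_mut)
  out <- founder
  for (p in pos) out[p] <- sample(setdiff(.NT, out[p]), 1)
  out
}

.translate_or_na <- function(junction) {
  if (nchar(junction) %% 3 != 0) return(NA_character_)
  as.character(Biostrings::translate(Biostrings::DNAString(junction),
                                     no.init.codon = TRUE))
}

.isotype_c_call <- function(iso) {
  switch(iso, IgM = "IGHM", IgG = sample(c("IGHG1", "IGHG2", "IGHG3"), 1),
         IgA = sample(c("IGHA1", "IGHA2"), 1))
}

#' Generate a two-timepoint synthetic repertoire with clone truth
#'
#' @param config A [repertoire_sim_config()].
#' @return List: airr_t1, airr_t2 (AIRR data.frames), truth (list with
#'   clone_truth mapping sequence_id to true clone, persistent_clone_ids,
#'   persistence_fraction, founders, config).
#' @export
generate_repertoire <- function(config = repertoire_sim_config()) {
  .assert(inherits(config, "repertoire_sim_config"),
          "config must come from repertoire_sim_config()")
  set.seed(config$seed)
  n1 <- config$n_clones_t1
  n_pers <- round(config$persistence_fraction * n1)
  n_new <- n1 - n_pers                    # fresh clones appearing at t2

  lens <- seq(config$cdr3_length_range[1], config$cdr3_length_range[2])
  lens <- lens[lens %% 3 == 0]
  if (length(lens) == 0) lens <- config$cdr3_length_range[1]

  n_total <- n1 + n_new
  clone_v <- config$v_genes[sample.int(length(config$v_genes), n_total,
                                       replace = TRUE)]
  clone_j <- config$j_genes[sample.int(length(config$j_genes), n_total,
                                       replace = TRUE)]
  clone_len <- lens[sample.int(length(lens), n_total, replace = TRUE)]
  part_key <- paste(strip_allele(clone_v), strip_allele(clone_j), clone_len,
                    sep = "|")
  founders <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    same <- founders[seq_len(i - 1)][part_key[seq_len(i - 1)] == part_key[i]]
    founders[[i]] <- .draw_founder(clone_len[i], same)
  }
  truth_ids <- sprintf("tclone_%04d", seq_len(n_total))
  persistent <- if (n_pers > 0) sort(sample.int(n1, n_pers)) else integer(0)

  sample_timepoint <- function(clone_idx, tp_label, prefix) {
    n_clones <- length(clone_idx)
    n_seq <- config$seqs_per_sample
    # one guaranteed (unmutated founder) sequence per clone, remainder Zipf
    assignment <- clone_idx
    if (n_seq > n_clones) {
      probs <- (seq_len(n_clones))^(-config$clone_size_power)
      extra <- clone_idx[sample.int(n_clones, n_seq - n_clones, replace = TRUE,
                                    prob = probs / sum(probs))]
      assignment <- c(assignment, extra)
    }
    founder_copy <- c(rep(TRUE, n_clones), rep(FALSE, max(0, n_seq - n_clones)))
    iso <- sample(names(config$isotype_probs), n_seq, replace = TRUE,
                  prob = config$isotype_probs)
    junction <- character(n_seq)
    for (s in seq_len(n_seq)) {
      f <- founders[[assignment[s]]]
      junction[s] <- paste(
        if (founder_copy[s]) f else .mutate(f, config$within_clone_mutation_rate),
        collapse = ""
      )
    }
    data.frame(
      sequence_id = sprintf("%s_seq_%05d", prefix, seq_len(n_seq)),
      v_call = clone_v[assignment],
      j_call = clone_j[assignment],
      junction = junction,
      junction_aa = vapply(junction, .translate_or_na, ""),
      c_call = vapply(iso, .isotype_c_call, ""),
      duplicate_count = 1L + rgeom(n_seq, 0.5),
      sample_id = paste0("BM_", tp_label),
      timepoint = tp_label,
      true_clone = truth_ids[assignment],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }

  airr_t1 <- sample_timepoint(seq_len(n1), "Y1", "t1")
  t2_clones <- c(persistent, if (n_new > 0) seq(n1 + 1, n1 + n_new))
  airr_t2 <- sample_timepoint(t2_clones, "Y2", "t2")

  clone_truth <- setNames(
    c(airr_t1$true_clone, airr_t2$true_clone),
    c(airr_t1$sequence_id, airr_t2$sequence_id)
  )
  truth <- list(
    clone_truth = clone_truth,
    persistent_clone_ids = truth_ids[persistent],
    persistence_fraction = if (n1 > 0) n_pers / n1 else NA_real_,
    founders = setNames(vapply(founders, paste, "", collapse = ""), truth_ids),
    config = config
  )
  airr_t1$true_clone <- NULL
  airr_t2$true_clone <- NULL
  list(airr_t1 = airr_t1, airr_t2 = airr_t2, truth = truth)
}
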