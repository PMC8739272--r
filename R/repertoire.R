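# Clonal lineage assignment from AIRR rearrangement records: sequences
# sharing V gene, J gene and CDR3 length are clustered by single linkage
# at >= 70% CDR3 (junction) Hamming identity. Diversity and longitudinal
# persistence summaries operate on the resulting clone table.

#' Strip allele suffixes and resolve ambiguous gene calls
#'
#' "IGHV1-2*02" becomes "IGHV1-2"; for multi-gene calls separated by
#' commas the first listed gene is used.
#'
#' @param calls Character vector of V/J calls.
#' @return Character vector of gene-level calls.
#' @export
strip_allele <- function(calls) {
  first <- sub(",.*$", "", calls)
  sub("\\*.*$", "", first)
}

# Hamming identity between equal-length strings, as a fraction of length
.hamming_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  1 - sum(av != bv) / length(av)
}

# union-find with path compression
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# single-linkage partition of equal-length strings at identity >= threshold
.cluster_single <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 1) return(1L)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  len <- ncol(mat)
  parent <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ident <- 1 - sum(mat[i, ] != mat[j, ]) / len
      if (ident >= threshold) {
        ri <- .uf_find(parent, i)
        rj <- .uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
}

# complete-linkage variant via hclust on Hamming distance
.cluster_complete <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 1) return(1L)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  len <- ncol(mat)
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dm[i, j] <- dm[j, i] <- sum(mat[i, ] != mat[j, ]) / len
    }
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "complete")
  stats::cutree(hc, h = (1 - threshold) + 1e-9)
}

#' Assign clonal lineages to AIRR records
#'
#' Records are partitioned by (V gene, J gene, CDR3 length) after allele
#' stripping; within each partition, sequences are joined into one clone
#' when their junction identity (1 - Hamming distance / length) meets the
#' threshold, chained by single linkage (complete linkage available).
#' Clone ids are deterministic: the lexicographically smallest member
#' sequence_id.
#'
#' @param records AIRR data.frame (sequence_id, v_call, j_call, junction;
#'   junction_aa required for `metric = "aa"`).
#' @param homology_threshold Identity threshold in (0, 1\]; inclusive >=
#'   (default 0.70).
#' @param metric Compare nucleotide junctions ("nt", default) or amino
#'   acid junctions ("aa").
#' @param linkage "single" (default) or "complete".
#' @return The records with a clone_id column, class `clone_table`.
#' @export
assign_clones <- function(records, homology_threshold = 0.70,
                          metric = c("nt", "aa"),
                          linkage = c("single", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  .assert(is.data.frame(records), "records must be a data.frame")
  needed <- c("sequence_id", "v_call", "j_call", "junction")
  .assert(all(needed %in% names(records)),
          "records need columns: ", paste(needed, collapse = ", "))
  .assert(anyDuplicated(records$sequence_id) == 0, "sequence_id must be unique")
  .assert(homology_threshold > 0 && homology_threshold <= 1,
          "homology_threshold must be in (0, 1]")
  seq_col <- if (metric == "nt") "junction" else "junction_aa"
  .assert(seq_col %in% names(records), "records lack column ", seq_col)
  seqs <- as.character(records[[seq_col]])
  .assert(all(nchar(seqs) > 0) && !anyNA(seqs), "junctions must be non-empty")
  v <- strip_allele(records$v_call)
  j <- strip_allele(records$j_call)
  if (any(grepl(",", records$v_call, fixed = TRUE))) {
    message("ambiguous multi-gene v_call values resolved to the first listed gene")
  }
  key <- paste(v, j, nchar(seqs), sep = "|")
  clone_id <- character(nrow(records))
  cluster_fun <- if (linkage == "single") .cluster_single else .cluster_complete
  for (k in unique(key)) {
    idx <- which(key == k)
    labels <- cluster_fun(seqs[idx], homology_threshold)
    for (cl in unique(labels)) {
      members <- idx[labels == cl]
      clone_id[members] <- min(records$sequence_id[members])
    }
  }
  out <- records
  out$v_gene <- v
  out$j_gene <- j
  out$cdr3_length <- nchar(seqs)
  out$clone_id <- clone_id
  class(out) <- c("clone_table", "data.frame")
  out
}

#' Summarize clones from a clone table
#'
#' @param clones `clone_table` from [assign_clones()].
#' @param size Count unique member sequences ("sequences", default) or sum
#'   duplicate_count ("duplicates").
#' @return data.frame per clone: clone_id, v_gene, j_gene, cdr3_length,
#'   size, isotypes, timepoints.
#' @export
clone_summary <- function(clones, size = c("sequences", "duplicates")) {
  size <- match.arg(size)
  .assert(inherits(clones, "clone_table"), "clones must come from assign_clones()")
  if (size == "duplicates") {
    .assert("duplicate_count" %in% names(clones),
            "duplicate_count column required for size = 'duplicates'")
  }
  sp <- split(seq_len(nrow(clones)), clones$clone_id)
  rows <- lapply(names(sp), function(id) {
    idx <- sp[[id]]
    sz <- if (size == "sequences") length(idx) else sum(clones$duplicate_count[idx])
    data.frame(
      clone_id = id,
      v_gene = clones$v_gene[idx[1]],
      j_gene = clones$j_gene[idx[1]],
      cdr3_length = clones$cdr3_length[idx[1]],
      size = sz,
      isotypes = if ("c_call" %in% names(clones)) {
        paste(sort(unique(clones$c_call[idx])), collapse = ",")
      } else NA_character_,
      timepoints = if ("timepoint" %in% names(clones)) {
        paste(sort(unique(clones$timepoint[idx])), collapse = ",")
      } else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$clone_id), ]
}

#' Size-ranked clone spectrum with cumulative percentages
#'
#' Clones are ranked by descending size (ties broken by clone_id); the
#' cumulative percentage of sequences reaches 100 at the last clone.
#'
#' @param clones `clone_table` or a clone summary data.frame with
#'   clone_id and size.
#' @param size Passed to [clone_summary()] when a clone table is given.
#' @return data.frame: clone_id, size, rank, cumulative_pct.
#' @export
clone_size_spectrum <- function(clones, size = "sequences") {
  summ <- if (inherits(clones, "clone_table")) clone_summary(clones, size) else clones
  .assert(nrow(summ) >= 1, "need at least one clone")
  ord <- order(-summ$size, summ$clone_id)
  summ <- summ[ord, ]
  data.frame(
    clone_id = summ$clone_id,
    size = summ$size,
    rank = seq_len(nrow(summ)),
    cumulative_pct = cumsum(summ$size) / sum(summ$size) * 100,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Simpson diversity of a clone-size distribution
#'
#' With clone proportions p_i: lambda = sum p_i^2 (Simpson concentration),
#' Gini-Simpson = 1 - lambda, inverse Simpson = 1 / lambda. The headline
#' `reported_index` defaults to the Gini-Simpson index (see the methods
#' vignette for the reporting rationale); all three are returned.
#'
#' @param clone_sizes Positive numeric vector of clone sizes.
#' @param reported_index Which variant to report as `reported`.
#' @return List: simpson_lambda, gini_simpson, inv_simpson, reported,
#'   reported_index.
#' @export
simpson_diversity <- function(clone_sizes,
                              reported_index = c("gini_simpson",
                                                 "simpson_lambda",
                                                 "inv_simpson")) {
  reported_index <- match.arg(reported_index)
  .assert(is.numeric(clone_sizes) && length(clone_sizes) > 0,
          "clone_sizes must be a non-empty numeric vector")
  .assert(all(clone_sizes >= 0) && sum(clone_sizes) > 0,
          "total clone size must be > 0")
  p <- clone_sizes / sum(clone_sizes)
  lambda <- sum(p^2)
  out <- list(simpson_lambda = lambda,
              gini_simpson = 1 - lambda,
              inv_simpson = 1 / lambda)
  out$reported <- out[[reported_index]]
  out$reported_index <- reported_index
  out
}

#' Longitudinal clone persistence between two timepoints
#'
#' Requires a clone table built by running [assign_clones()] on the pooled
#' records of both timepoints, so clone ids are directly comparable.
#' clone_persistence = clones present at both timepoints / clones with any
#' first-timepoint member; sequence_persistence = duplicate-count-weighted
#' share of second-timepoint sequences that fall in persistent clones.
#'
#' @param clones Pooled `clone_table` with a timepoint column.
#' @param t1,t2 Timepoint labels (defaults: first two in order of
#'   appearance).
#' @return List: clone_persistence, sequence_persistence, n_t1_clones,
#'   n_shared_clones, shared_clone_ids.
#' @export
clone_persistence <- function(clones, t1 = NULL, t2 = NULL) {
  .assert(inherits(clones, "clone_table"), "clones must come from assign_clones()")
  .assert("timepoint" %in% names(clones),
          "pooled clone table needs a timepoint column; run assign_clones() ",
          "on the pooled records of both timepoints")
  tps <- unique(clones$timepoint)
  if (is.null(t1)) t1 <- tps[1]
  if (is.null(t2)) t2 <- tps[2]
  .assert(all(c(t1, t2) %in% tps), "timepoints not present in the clone table")
  c1 <- unique(clones$clone_id[clones$timepoint == t1])
  c2 <- unique(clones$clone_id[clones$timepoint == t2])
  shared <- intersect(c1, c2)
  idx2 <- clones$timepoint == t2
  w2 <- if ("duplicate_count" %in% names(clones)) {
    clones$duplicate_count[idx2]
  } else rep(1, sum(idx2))
  seq_pers <- if (sum(w2) > 0) {
    sum(w2[clones$clone_id[idx2] %in% shared]) / sum(w2)
  } else NA_real_
  list(
    clone_persistence = if (length(c1) > 0) length(shared) / length(c1) else NA_real_,
    sequence_persistence = seq_pers,
    n_t1_clones = length(c1),
    n_shared_clones = length(shared),
    shared_clone_ids = sort(shared)
  )
}

#' Partition records by immunoglobulin isotype
#'
#' c_call values are mapped by prefix: IGHM -> IgM, IGHG* -> IgG,
#' IGHA* -> IgA. Records with any other constant region are excluded with
#' a warning.
#'
#' @param records AIRR data.frame (or `clone_table`) with a c_call column.
#' @return Named list of record subsets per isotype.
#' @export
stratify_by_isotype <- function(records) {
  .assert("c_call" %in% names(records), "records need a c_call column")
  iso <- rep(NA_character_, nrow(records))
  iso[startsWith(records$c_call, "IGHM")] <- "IgM"
  iso[startsWith(records$c_call, "IGHG")] <- "IgG"
  iso[startsWith(records$c_call, "IGHA")] <- "IgA"
  if (anyNA(iso)) {
    warning(sum(is.na(iso)), " record(s) with unmappable c_call excluded: ",
            paste(unique(records$c_call[is.na(iso)]), collapse = ", "))
  }
  keep <- !is.na(iso)
  split(records[keep, , drop = FALSE], iso[keep])
}

#' Count V-region mutations against an aligned germline
#'
#' Counts positions where both the observed and germline characters are
#' unambiguous nucleotides (A/C/G/T) and differ; positions opposite a gap
#' or ambiguity code are ignored.
#'
#' @param sequence Aligned observed V-region string (gaps as "-").
#' @param germline_v Aligned germline string of equal length.
#' @return Integer mutation count.
#' @export
mutation_load <- function(sequence, germline_v) {
  .assert(is.character(sequence) && length(sequence) == 1 &&
            is.character(germline_v) && length(germline_v) == 1,
          "sequence and germline_v must be single strings")
  .assert(nchar(sequence) == nchar(germline_v),
          "sequence and germline alignment lengths differ")
  a <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(germline_v), "", fixed = TRUE)[[1]]
  nt <- c("A", "C", "G", "T")
  sum(a %in% nt & b %in% nt & a != b)
}

#' Per-isotype diversity table across samples or populations
#'
#' Convenience driver: stratifies records by isotype, assigns clones
#' within each stratum of each group, and reports Simpson diversity
#' variants.
#'
#' @param records AIRR data.frame with c_call and a grouping column.
#' @param group_col Column defining groups (default "population").
#' @param homology_threshold Passed to [assign_clones()].
#' @param size Clone size rule (see [clone_summary()]).
#' @return data.frame: group, isotype, n_clones, simpson_lambda,
#'   gini_simpson, inv_simpson.
#' @export
diversity_by_isotype <- function(records, group_col = "population",
                                 homology_threshold = 0.70,
                                 size = "sequences") {
  .assert(group_col %in% names(records), "records lack column ", group_col)
  strata <- stratify_by_isotype(records)
  rows <- list()
  for (iso in names(strata)) {
    sub <- strata[[iso]]
    for (g in unique(sub[[group_col]])) {
      rec <- sub[sub[[group_col]] == g, , drop = FALSE]
      ct <- assign_clones(rec, homology_threshold)
      sizes <- clone_summary(ct, size)$size
      div <- simpson_diversity(sizes)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, isotype = iso, n_clones = length(sizes),
        simpson_lambda = div$simpson_lambda,
        gini_simpson = div$gini_simpson,
        inv_simpson = div$inv_simpson,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
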