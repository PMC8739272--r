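# DAR-to-gene mapping, DEG/DAG overlap, expression/accessibility
# concordance at the log2(1.5) = 0.585 threshold, and hypergeometric
# gene-set over-representation.

#' Validate a gene annotation data.frame
#'
#' Gene bodies are 0-based half-open; strand is "+" or "-". A tss column
#' is derived when absent: start for "+" genes, end for "-" genes.
#'
#' @param genes data.frame with gene_id, chrom, start, end, strand.
#' @return Validated data.frame with a tss column.
#' @export
check_gene_annotation <- function(genes) {
  .assert(is.data.frame(genes), "genes must be a data.frame")
  .assert(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
          "genes need columns gene_id, chrom, start, end, strand")
  .assert(all(genes$start < genes$end), "gene start must be < end")
  .assert(all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
  .assert(anyDuplicated(genes$gene_id) == 0, "gene ids must be unique")
  if (is.null(genes$tss)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  }
  genes
}

#' Assign peaks to genes via gene body or promoter window overlap
#'
#' A peak is assigned to every gene whose body \[start, end) or promoter
#' window \[tss - window, tss + window) overlaps it (half-open overlap).
#' Peaks on chromosomes absent from the annotation are left unassigned
#' with a warning.
#'
#' @param peaks Peak data.frame (0-based half-open) or GRanges.
#' @param genes Gene annotation data.frame.
#' @param window Promoter half-width in bases around the TSS (default
#'   2000).
#' @return Named list mapping peak_id to a character vector of gene ids
#'   (possibly empty).
#' @export
assign_peaks_to_genes <- function(peaks, genes, window = 2000) {
  genes <- check_gene_annotation(genes)
  pk <- if (methods::is(peaks, "GRanges")) granges_as_peaks(peaks) else check_peaks(peaks)
  unknown <- setdiff(unique(pk$chrom), unique(genes$chrom))
  if (length(unknown) > 0) {
    warning("peaks on chromosomes absent from the annotation are unassigned: ",
            paste(unknown, collapse = ", "))
  }
  pk_gr <- peaks_as_granges(pk)
  # gene region = body union promoter window, as two interval sets
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  prom_start <- pmax(genes$tss - window, 0)
  prom_end <- genes$tss + window
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(prom_start + 1L, prom_end))
  # seqlevel mismatches are already reported above; silence the internal
  # Seqinfo merge notice
  hits_body <- suppressWarnings(GenomicRanges::findOverlaps(pk_gr, body))
  hits_prom <- suppressWarnings(GenomicRanges::findOverlaps(pk_gr, prom))
  from <- c(S4Vectors::queryHits(hits_body), S4Vectors::queryHits(hits_prom))
  to <- c(S4Vectors::subjectHits(hits_body), S4Vectors::subjectHits(hits_prom))
  out <- setNames(vector("list", nrow(pk)), pk$peak_id)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (length(from) > 0) {
    sp <- split(genes$gene_id[to], pk$peak_id[from])
    sp <- lapply(sp, function(g) sort(unique(g)))
    out[names(sp)] <- sp
  }
  out
}

#' Differentially accessible genes (DAGs) from DAR peak sets
#'
#' Union of the genes mapped to each comparison's DAR peaks. DAR peaks
#' missing from the mapping are dropped, with the count recorded in the
#' `n_unmapped` attribute.
#'
#' @param dar_sets Named list of peak id vectors per comparison (e.g.
#'   `call_dars()$per_comparison`).
#' @param peak_gene_map Mapping from [assign_peaks_to_genes()].
#' @return Named list of gene id vectors per comparison.
#' @export
dags_from_dars <- function(dar_sets, peak_gene_map) {
  n_unmapped <- 0L
  out <- lapply(dar_sets, function(peaks) {
    known <- peaks %in% names(peak_gene_map)
    n_unmapped <<- n_unmapped + sum(!known)
    sort(unique(unlist(peak_gene_map[peaks[known]], use.names = FALSE)))
  })
  if (n_unmapped > 0) {
    message(n_unmapped, " DAR peak id(s) absent from the peak-gene map were dropped")
  }
  structure(out, n_unmapped = n_unmapped)
}

#' Overlap counts for a DEG/DAG Venn diagram
#'
#' @param deg_set,dag_set Character vectors of gene ids.
#' @return Named integer vector: n_deg_only, n_overlap, n_dag_only.
#' @export
overlap_sets <- function(deg_set, dag_set) {
  deg_set <- unique(deg_set)
  dag_set <- unique(dag_set)
  ov <- length(intersect(deg_set, dag_set))
  c(n_deg_only = length(deg_set) - ov,
    n_overlap = ov,
    n_dag_only = length(dag_set) - ov)
}

#' Classify expression/accessibility concordance
#'
#' A gene is concordant when both its expression and accessibility log2
#' fold changes strictly exceed the threshold in absolute value with the
#' same sign ("concordant_up" / "concordant_down"), discordant when both
#' exceed it with opposite signs, and below_threshold otherwise. The
#' default threshold 0.585 = log2(1.5) corresponds to a 1.5-fold change.
#'
#' @param expr_lfc,acc_lfc Numeric vectors of log2 fold changes.
#' @param lfc_threshold Strict absolute threshold (default 0.585).
#' @return Character vector in \{concordant_up, concordant_down,
#'   discordant, below_threshold\}.
#' @export
classify_concordance <- function(expr_lfc, acc_lfc, lfc_threshold = 0.585) {
  .assert(length(expr_lfc) == length(acc_lfc), "lfc vectors must match")
  .assert(all(is.finite(expr_lfc)) && all(is.finite(acc_lfc)),
          "fold changes must be finite")
  .assert(lfc_threshold > 0, "lfc_threshold must be > 0")
  both <- abs(expr_lfc) > lfc_threshold & abs(acc_lfc) > lfc_threshold
  same <- sign(expr_lfc) == sign(acc_lfc)
  out <- rep("below_threshold", length(expr_lfc))
  out[both & same & expr_lfc > 0] <- "concordant_up"
  out[both & same & expr_lfc < 0] <- "concordant_down"
  out[both & !same] <- "discordant"
  out
}

#' Per-gene concordance table for one comparison
#'
#' Joins expression fold changes with a per-gene accessibility summary:
#' by default the fold change of the gene's most significant DAR-tested
#' peak (minimum q, ties by minimum p then peak id); `summary =
#' "max_abs_lfc"` takes the peak with the largest absolute fold change
#' instead.
#'
#' @param expr_stats Expression pairwise statistics for one comparison
#'   (feature_id, log2fc).
#' @param acc_stats Accessibility statistics for the same comparison
#'   (peak_id, log2fc, p_raw, q_bh).
#' @param peak_gene_map Mapping from [assign_peaks_to_genes()].
#' @param lfc_threshold Concordance threshold (default 0.585).
#' @param summary Per-gene accessibility summary rule.
#' @return data.frame: gene_id, expr_lfc, acc_lfc, peak_id, klass.
#' @export
concordance_table <- function(expr_stats, acc_stats, peak_gene_map,
                              lfc_threshold = 0.585,
                              summary = c("min_q", "max_abs_lfc")) {
  summary <- match.arg(summary)
  map_df <- data.frame(
    peak_id = rep(names(peak_gene_map), lengths(peak_gene_map)),
    gene_id = unlist(peak_gene_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  acc <- merge(acc_stats, map_df, by = "peak_id")
  if (nrow(acc) == 0) {
    return(data.frame(gene_id = character(0), expr_lfc = numeric(0),
                      acc_lfc = numeric(0), peak_id = character(0),
                      klass = character(0)))
  }
  ord <- if (summary == "min_q") {
    order(acc$gene_id, acc$q_bh, acc$p_raw, acc$peak_id)
  } else {
    order(acc$gene_id, -abs(acc$log2fc), acc$peak_id)
  }
  acc <- acc[ord, ]
  acc <- acc[!duplicated(acc$gene_id), ]
  joined <- merge(
    data.frame(gene_id = expr_stats$feature_id, expr_lfc = expr_stats$log2fc,
               stringsAsFactors = FALSE),
    data.frame(gene_id = acc$gene_id, acc_lfc = acc$log2fc,
               peak_id = acc$peak_id, stringsAsFactors = FALSE),
    by = "gene_id"
  )
  joined$klass <- classify_concordance(joined$expr_lfc, joined$acc_lfc,
                                       lfc_threshold)
  joined[order(joined$gene_id), ]
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided tail p = P\[X >= k\] for X ~ hypergeometric(N = |universe|,
#' K = |set in universe|, n = |hits|), Benjamini-Hochberg corrected across
#' the tested sets. Sets disjoint from the universe are skipped (recorded
#' in the `skipped` attribute).
#'
#' @param hit_genes Character vector of hit gene ids (subset of the
#'   universe).
#' @param universe_genes Character vector defining the universe.
#' @param gene_sets Named list of gene id vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame: set, n_set, n_overlap, p_hypergeom, q_bh.
#' @export
ora_enrichment <- function(hit_genes, universe_genes, gene_sets) {
  universe_genes <- unique(universe_genes)
  hit_genes <- unique(hit_genes)
  outside <- setdiff(hit_genes, universe_genes)
  .assert(length(outside) == 0,
          "hit genes outside the universe: ", paste(head(outside, 5), collapse = ", "))
  n <- length(hit_genes)
  N <- length(universe_genes)
  K <- vapply(gene_sets, function(g) length(intersect(g, universe_genes)), 0L)
  keep <- K > 0
  skipped <- names(gene_sets)[!keep]
  if (length(skipped) > 0) {
    message("gene sets disjoint from the universe skipped: ",
            paste(skipped, collapse = ", "))
  }
  sets <- gene_sets[keep]
  k <- vapply(sets, function(g) length(intersect(intersect(g, universe_genes),
                                                 hit_genes)), 0L)
  Kk <- K[keep]
  p <- phyper(k - 1, Kk, N - Kk, n, lower.tail = FALSE)
  out <- data.frame(
    set = names(sets), n_set = as.integer(Kk), n_overlap = as.integer(k),
    p_hypergeom = as.numeric(p),
    q_bh = bh_fdr(as.numeric(p)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, skipped = skipped)
}
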