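# Preprocessing: low-count filtering, consensus peaks, median-of-ratios
# normalization, PCA. Interval work is delegated to GenomicRanges/IRanges;
# all user-facing peak coordinates are 0-based half-open (BED convention).

#' Validate a peak data.frame (0-based half-open)
#'
#' @param peaks data.frame with columns chrom, start, end and optionally
#'   peak_id.
#' @return The validated data.frame, with a peak_id column added if absent.
#' @export
check_peaks <- function(peaks) {
  .assert(is.data.frame(peaks), "peaks must be a data.frame")
  .assert(all(c("chrom", "start", "end") %in% names(peaks)),
          "peaks need columns chrom, start, end")
  bad <- which(!(peaks$start < peaks$end))
  if (length(bad) > 0) {
    stop("malformed interval (start >= end) at row ", bad[1], ": ",
         peaks$chrom[bad[1]], ":", peaks$start[bad[1]], "-", peaks$end[bad[1]],
         call. = FALSE)
  }
  .assert(all(peaks$start >= 0), "peak starts must be >= 0")
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  .assert(anyDuplicated(peaks$peak_id) == 0, "peak ids must be unique")
  peaks
}

#' Convert a 0-based half-open peak data.frame to GRanges
#'
#' @param peaks Peak data.frame or GRanges (returned unchanged).
#' @return GRanges (1-based closed, as GenomicRanges requires).
#' @export
peaks_as_granges <- function(peaks) {
  if (methods::is(peaks, "GRanges")) return(peaks)
  peaks <- check_peaks(peaks)
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  names(gr) <- peaks$peak_id
  gr
}

#' Convert GRanges back to a 0-based half-open peak data.frame
#'
#' @param gr GRanges.
#' @param ids Optional peak ids; defaults to names(gr) or generated ids.
#' @return Peak data.frame.
#' @export
granges_as_peaks <- function(gr, ids = NULL) {
  if (is.null(ids)) ids <- names(gr)
  if (is.null(ids) && !is.null(gr$name)) ids <- gr$name
  if (is.null(ids)) ids <- sprintf("peak_%05d", seq_along(gr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    peak_id = ids,
    stringsAsFactors = FALSE
  )
}

#' Remove features whose total count is below a threshold
#'
#' Keeps exactly the features with row sum >= `min_total`, preserving
#' order. The ex vivo RNA default removes genes with fewer than 150 counts
#' summed over all samples; the in vitro culture design uses 1000.
#'
#' @param counts Integer feature-by-sample matrix.
#' @param min_total Minimum total count across samples (>= 0).
#' @return Filtered count matrix.
#' @export
filter_low_count <- function(counts, min_total = 150) {
  check_count_matrix(counts)
  .assert(is.numeric(min_total) && length(min_total) == 1 && min_total >= 0,
          "min_total must be a single number >= 0")
  if (nrow(counts) == 0) return(counts)
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Merge per-sample peak sets into a consensus (union) peak set
#'
#' Returns the minimal set of disjoint intervals covering every input
#' interval, sorted by (chrom, start) — the union peak model used when
#' counting reads over all possible peaks.
#'
#' @param per_sample_peaks A peak data.frame, a GRanges, or a list of
#'   either.
#' @return Peak data.frame (0-based half-open) with fresh peak ids.
#' @export
consensus_peaks <- function(per_sample_peaks) {
  if (!is.list(per_sample_peaks) || is.data.frame(per_sample_peaks)) {
    per_sample_peaks <- list(per_sample_peaks)
  }
  .assert(length(per_sample_peaks) > 0, "no peak sets supplied")
  grl <- lapply(per_sample_peaks, peaks_as_granges)
  merged <- GenomicRanges::reduce(GenomicRanges::sort(do.call(c, unname(grl))))
  granges_as_peaks(merged, ids = sprintf("peak_%05d", seq_along(merged)))
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with strictly positive counts in every sample) of the ratio
#' of that sample's count to the feature's geometric mean across samples.
#'
#' @param counts Integer feature-by-sample matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  check_count_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  .assert(any(pos),
          "no feature has positive counts in every sample; cannot compute median-of-ratios factors")
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(median(x - geo)))
  .assert(all(is.finite(sf) & sf > 0), "size factors must be positive and finite")
  sf
}

#' Log2 normalization of counts by size factors
#'
#' value_ij = log2(count_ij / factor_j + pseudocount). This variance-
#' stabilized log scale replaces regularized-log transforms: the downstream
#' mixed-model statistics only require a log-scale matrix with library-size
#' effects removed.
#'
#' @param counts Integer feature-by-sample matrix.
#' @param size_factors Per-sample positive factors; computed by
#'   median-of-ratios when NULL.
#' @param pseudocount Positive offset added before the log (default 1).
#' @return An object of class `normalized_counts`: list with `values`
#'   (log2 matrix), `size_factors`, `pseudocount`.
#' @export
normalize_log2 <- function(counts, size_factors = NULL, pseudocount = 1) {
  check_count_matrix(counts)
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  .assert(length(size_factors) == ncol(counts),
          "need one size factor per sample")
  .assert(all(size_factors > 0), "size factors must be > 0")
  .assert(is.numeric(pseudocount) && length(pseudocount) == 1 && pseudocount > 0,
          "pseudocount must be a single positive number")
  values <- log2(sweep(counts, 2, size_factors, "/") + pseudocount)
  structure(
    list(values = values, size_factors = size_factors, pseudocount = pseudocount),
    class = "normalized_counts"
  )
}

#' @export
print.normalized_counts <- function(x, ...) {
  cat("normalized_counts: ", nrow(x$values), " features x ", ncol(x$values),
      " samples (log2, pseudocount ", x$pseudocount, ")\n", sep = "")
  invisible(x)
}

#' Principal component analysis of samples
#'
#' Samples are projected onto the principal components of the centered
#' feature space. Variance fractions are non-increasing and sum to at most
#' one.
#'
#' @param x `normalized_counts` object or a numeric feature-by-sample
#'   matrix.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components) and
#'   `variance_fraction`.
#' @export
pca_samples <- function(x, n_components = 2) {
  values <- if (inherits(x, "normalized_counts")) x$values else x
  .assert(is.matrix(values) && is.numeric(values), "need a numeric matrix")
  .assert(ncol(values) >= 2, "PCA needs at least 2 samples")
  .assert(n_components >= 1 && n_components <= min(dim(values)),
          "n_components must be between 1 and min(n_features, n_samples)")
  pr <- prcomp(t(values), center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  k <- min(n_components, ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  vf <- (pr$sdev^2 / tot)[seq_len(k)]
  list(scores = scores, variance_fraction = vf)
}

#' Flag candidate outlier samples in PC1-2 space
#'
#' Quantitative stand-in for visual outlier screening: a sample is flagged
#' when its Euclidean distance from its population centroid in the first
#' two components exceeds the population median distance by more than
#' `k` median absolute deviations. Flagging is advisory; removal is left
#' to the caller.
#'
#' @param scores Sample score matrix (>= 2 columns) from [pca_samples()].
#' @param design Sample design table covering the score rownames.
#' @param k MAD multiplier (default 3).
#' @return Logical vector named by sample.
#' @export
flag_pca_outliers <- function(scores, design, k = 3) {
  .assert(is.matrix(scores) && ncol(scores) >= 2, "need >= 2 score columns")
  design <- check_design(design, rownames(scores))
  pop <- design$population[match(rownames(scores), design$sample_id)]
  flag <- setNames(rep(FALSE, nrow(scores)), rownames(scores))
  for (p in unique(pop)) {
    idx <- which(pop == p)
    ctr <- colMeans(scores[idx, 1:2, drop = FALSE])
    d <- sqrt(rowSums((scores[idx, 1:2, drop = FALSE] -
                         matrix(ctr, length(idx), 2, byrow = TRUE))^2))
    m <- median(d)
    s <- mad(d)
    if (s > 0) flag[idx] <- d > m + k * s
  }
  flag
}
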