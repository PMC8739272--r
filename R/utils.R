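# internal validation helpers; kept terse and reused across modules

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# counts: non-negative integer matrix, unique feature/sample ids as dimnames
check_count_matrix <- function(counts, what = "counts") {
  .assert(is.matrix(counts) && is.numeric(counts), what, " must be a numeric matrix")
  .assert(all(is.finite(counts)), what, " must be finite")
  .assert(all(counts >= 0), what, " must be non-negative")
  .assert(all(abs(counts - round(counts)) < 1e-8), what, " must hold integer counts")
  .assert(nrow(counts) == 0 ||
            (!is.null(rownames(counts)) && anyDuplicated(rownames(counts)) == 0),
          what, " needs unique feature ids as rownames")
  .assert(ncol(counts) == 0 ||
            (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)) == 0),
          what, " needs unique sample ids as colnames")
  invisible(counts)
}

# sample design table: sample_id, population, patient (+ optional timepoint,
# compartment); must cover the sample ids of any matrix it is joined to
check_design <- function(design, sample_ids = NULL) {
  .assert(is.data.frame(design), "design must be a data.frame")
  needed <- c("sample_id", "population", "patient")
  .assert(all(needed %in% names(design)),
          "design needs columns: ", paste(needed, collapse = ", "))
  .assert(anyDuplicated(design$sample_id) == 0, "design sample_id must be unique")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, design$sample_id)
    .assert(length(missing) == 0,
            "design is missing samples: ", paste(head(missing, 5), collapse = ", "))
  }
  invisible(design)
}

# align a design to the columns of a matrix (same order)
design_for <- function(design, counts) {
  check_design(design, colnames(counts))
  design[match(colnames(counts), design$sample_id), , drop = FALSE]
}

# derive a bounded child seed from a user seed (stays < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
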