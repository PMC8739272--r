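# Synthetic multi-omic experiment generator. Emulates the nested study
# design: blood and bone-marrow samples come from disjoint patient sets
# (patients nested within compartment), each patient contributing one
# sample per population of their compartment. Counts are negative
# binomial with per-patient log2-scale random effects, planted population
# log2 fold changes for a fraction of features, and log-uniform library
# sizes. Peaks live on a toy genome laid out so that each linked peak
# falls inside exactly one gene body and every unlinked peak is farther
# than the promoter window from any gene, making the peak-to-gene truth
# self-consistent with assign_peaks_to_genes().

#' Configuration for the multi-omic simulator
#'
#' Defaults mirror the emulated study design: two blood populations
#' (Pop2, Pop3) and three bone-marrow populations (PopA, PopB, PopD),
#' with patients nested in compartment.
#'
#' @param n_genes,n_peaks Feature counts.
#' @param populations Ordered population labels.
#' @param compartment_of_population Named vector mapping population to
#'   "blood" or "bm".
#' @param patients_per_compartment Patients per compartment (each gives
#'   one sample per population of their compartment).
#' @param baseline_log_mean_range Range of per-feature baseline log2
#'   means.
#' @param nb_dispersion NB dispersion phi > 0 (variance = mu + phi mu^2).
#' @param patient_sd SD of the per-patient log2 random effect (>= 0).
#' @param frac_de Fraction of features given a planted effect.
#' @param planted_lfc_magnitude Absolute planted log2 fold change.
#' @param library_size_range Range of per-sample library factors
#'   (log-uniform draw).
#' @param promoter_window_bp Promoter half-width used in the toy genome
#'   layout.
#' @param frac_peaks_linked Fraction of peaks placed inside gene bodies.
#' @param seed Integer seed; the same config is bit-reproducible.
#' @return List of class `multiomic_sim_config`.
#' @export
multiomic_sim_config <- function(n_genes = 2000,
                                 n_peaks = 2000,
                                 populations = c("Pop2", "Pop3", "PopA", "PopB", "PopD"),
                                 compartment_of_population = c(
                                   Pop2 = "blood", Pop3 = "blood",
                                   PopA = "bm", PopB = "bm", PopD = "bm"),
                                 patients_per_compartment = 11,
                                 baseline_log_mean_range = c(3, 9),
                                 nb_dispersion = 0.15,
                                 patient_sd = 0.5,
                                 frac_de = 0.1,
                                 planted_lfc_magnitude = 2,
                                 library_size_range = c(0.5, 2),
                                 promoter_window_bp = 2000,
                                 frac_peaks_linked = 0.6,
                                 seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_peaks = n_peaks, populations = populations,
    compartment_of_population = compartment_of_population,
    patients_per_compartment = patients_per_compartment,
    baseline_log_mean_range = baseline_log_mean_range,
    nb_dispersion = nb_dispersion, patient_sd = patient_sd,
    frac_de = frac_de, planted_lfc_magnitude = planted_lfc_magnitude,
    library_size_range = library_size_range,
    promoter_window_bp = promoter_window_bp,
    frac_peaks_linked = frac_peaks_linked,
    seed = as.integer(seed)
  )
  .assert(length(populations) >= 2, "need at least 2 populations")
  .assert(all(populations %in% names(compartment_of_population)),
          "every population needs a compartment")
  .assert(all(compartment_of_population[populations] %in% c("blood", "bm")),
          "compartments must be 'blood' or 'bm'")
  .assert(nb_dispersion > 0, "nb_dispersion must be > 0")
  .assert(patient_sd >= 0, "patient_sd must be >= 0")
  .assert(frac_de >= 0 && frac_de <= 1, "frac_de must be in [0, 1]")
  .assert(planted_lfc_magnitude > 0, "planted_lfc_magnitude must be > 0")
  .assert(all(library_size_range > 0) && length(library_size_range) == 2,
          "library_size_range must be two positive numbers")
  .assert(frac_peaks_linked >= 0 && frac_peaks_linked <= 1,
          "frac_peaks_linked must be in [0, 1]")
  structure(cfg, class = "multiomic_sim_config")
}

# planted effect table: each affected feature gets one target population
# and a sign; alpha is the feature x population log2 effect matrix
.plant_effects <- function(n_features, populations, frac_de, magnitude) {
  n_de <- round(frac_de * n_features)
  alpha <- matrix(0, n_features, length(populations),
                  dimnames = list(NULL, populations))
  if (n_de > 0) {
    de_idx <- sample.int(n_features, n_de)
    target <- sample(populations, n_de, replace = TRUE)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    alpha[cbind(de_idx, match(target, populations))] <- sgn * magnitude
  }
  alpha
}

# all ordered pairwise true lfcs from the effect matrix (b_vs_a = b - a)
.true_lfc_table <- function(alpha, populations) {
  pairs <- combn(populations, 2)
  lfc <- alpha[, pairs[2, ], drop = FALSE] - alpha[, pairs[1, ], drop = FALSE]
  colnames(lfc) <- paste0(pairs[2, ], "_vs_", pairs[1, ])
  lfc
}

# NB counts for one modality given effects and shared design
.simulate_counts <- function(feature_ids, baselines, alpha, design,
                             patient_sd, dispersion, lib) {
  n_f <- length(feature_ids)
  patients <- unique(design$patient)
  b <- matrix(rnorm(n_f * length(patients), 0, patient_sd),
              n_f, length(patients), dimnames = list(NULL, patients))
  log2mu <- outer(baselines, rep(1, nrow(design))) +
    alpha[, design$population, drop = FALSE] +
    b[, design$patient, drop = FALSE]
  mu <- sweep(2^log2mu, 2, lib, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_f, nrow(design),
                   dimnames = list(feature_ids, design$sample_id))
  storage.mode(counts) <- "double"
  counts
}

#' Generate a synthetic multi-omic experiment with planted truth
#'
#' @param config A [multiomic_sim_config()].
#' @return List: rna_counts, atac_counts (feature x sample integer
#'   matrices), design (sample table), genes (annotation data.frame),
#'   peaks (peak data.frame, 0-based half-open), truth (list with
#'   true_lfc_rna, de_flags_rna, true_lfc_atac, de_flags_atac,
#'   peak_gene_truth, config).
#' @export
generate_multiomic <- function(config = multiomic_sim_config()) {
  .assert(inherits(config, "multiomic_sim_config"),
          "config must come from multiomic_sim_config()")
  set.seed(config$seed)
  pops <- config$populations
  comp <- config$compartment_of_population

  # design: patients nested within compartment
  rows <- list()
  for (cm in unique(comp[pops])) {
    cpops <- pops[comp[pops] == cm]
    for (pt in seq_len(config$patients_per_compartment)) {
      patient <- sprintf("%s_pt%02d", cm, pt)
      for (pp in cpops) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = paste0(pp, "_", patient), population = pp,
          patient = patient, timepoint = NA_character_, compartment = cm,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  design <- do.call(rbind, rows)
  # keep population blocks in the configured order
  design <- design[order(match(design$population, pops), design$patient), ]
  rownames(design) <- NULL
  lib <- exp(runif(nrow(design), log(config$library_size_range[1]),
                   log(config$library_size_range[2])))

  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
  peak_ids <- sprintf("peak_%05d", seq_len(config$n_peaks))

  # RNA
  base_rna <- runif(config$n_genes, config$baseline_log_mean_range[1],
                    config$baseline_log_mean_range[2])
  alpha_rna <- .plant_effects(config$n_genes, pops, config$frac_de,
                              config$planted_lfc_magnitude)
  rna <- .simulate_counts(gene_ids, base_rna, alpha_rna, design,
                          config$patient_sd, config$nb_dispersion, lib)

  # ATAC
  base_atac <- runif(config$n_peaks, config$baseline_log_mean_range[1],
                     config$baseline_log_mean_range[2])
  alpha_atac <- .plant_effects(config$n_peaks, pops, config$frac_de,
                               config$planted_lfc_magnitude)
  lib_atac <- exp(runif(nrow(design), log(config$library_size_range[1]),
                        log(config$library_size_range[2])))
  atac <- .simulate_counts(peak_ids, base_atac, alpha_atac, design,
                           config$patient_sd, config$nb_dispersion, lib_atac)

  # toy genome: one chromosome, genes on a fixed stride wide enough that
  # a gene body plus its promoter window can never touch a neighbour's
  # window or an intergenic peak slot
  w <- config$promoter_window_bp
  peak_len <- 400L
  slot_w <- 450L
  n_linked <- round(config$frac_peaks_linked * config$n_peaks)
  n_unlinked <- config$n_peaks - n_linked
  slots_linked <- max(1L, ceiling(n_linked / config$n_genes))
  slots_unlinked <- max(1L, ceiling(n_unlinked / config$n_genes))
  gene_len <- max(2000L, 200L + slots_linked * slot_w + 100L)
  dead <- max(3L * peak_len + 2000L,
              2000L + slots_unlinked * slot_w)
  stride <- gene_len + 2L * w + dead
  offset <- w + 1000L
  gstart <- offset + (seq_len(config$n_genes) - 1) * stride
  strand <- rep(c("+", "-"), length.out = config$n_genes)
  genes <- data.frame(
    gene_id = gene_ids, chrom = "chrT", start = gstart,
    end = gstart + gene_len, strand = strand,
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)

  peak_gene_truth <- setNames(rep(NA_character_, config$n_peaks), peak_ids)
  pstart <- integer(config$n_peaks)
  if (n_linked > 0) {
    gi <- ((seq_len(n_linked) - 1) %% config$n_genes) + 1
    slot <- (seq_len(n_linked) - 1) %/% config$n_genes
    pstart[seq_len(n_linked)] <- gstart[gi] + 100L + slot * slot_w
    .assert(all(pstart[seq_len(n_linked)] + peak_len <= gstart[gi] + gene_len),
            "linked peak slot escapes its gene body")
    peak_gene_truth[seq_len(n_linked)] <- gene_ids[gi]
  }
  if (n_unlinked > 0) {
    free <- seq(n_linked + 1, config$n_peaks)
    gi <- ((seq_along(free) - 1) %% config$n_genes) + 1
    slot <- (seq_along(free) - 1) %/% config$n_genes
    # dead zone after gene gi's promoter window, > window from both genes
    pstart[free] <- gstart[gi] + gene_len + w + 1000L + slot * slot_w
    .assert(all(pstart[free] + peak_len <= gstart[gi] + stride - w - 100L),
            "intergenic peak slot overlaps the next promoter window")
  }
  peaks <- data.frame(
    chrom = "chrT", start = pstart, end = pstart + peak_len,
    peak_id = peak_ids, stringsAsFactors = FALSE
  )

  truth <- list(
    true_lfc_rna = `rownames<-`(.true_lfc_table(alpha_rna, pops), gene_ids),
    true_lfc_atac = `rownames<-`(.true_lfc_table(alpha_atac, pops), peak_ids),
    peak_gene_truth = peak_gene_truth,
    config = config
  )
  truth$de_flags_rna <- abs(truth$true_lfc_rna) > 0
  truth$de_flags_atac <- abs(truth$true_lfc_atac) > 0

  list(rna_counts = rna, atac_counts = atac, design = design,
       genes = genes, peaks = peaks, truth = truth)
}

#' Write a synthetic multi-omic experiment to plain-text files
#'
#' Writes counts TSVs, the design TSV, peaks BED, gene annotation TSV and
#' truth tables into a directory.
#'
#' @param sim Output of [generate_multiomic()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_multiomic <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(sim$rna_counts, file.path(dir, "rna_counts.tsv"), "gene_id")
  write_matrix_tsv(sim$atac_counts, file.path(dir, "atac_counts.tsv"), "peak_id")
  write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_peaks_bed(sim$peaks, file.path(dir, "peaks.bed"))
  write_matrix_tsv(sim$truth$true_lfc_rna, file.path(dir, "truth_lfc_rna.tsv"),
                   "gene_id")
  write_matrix_tsv(sim$truth$true_lfc_atac, file.path(dir, "truth_lfc_atac.tsv"),
                   "peak_id")
  write.table(
    data.frame(peak_id = names(sim$truth$peak_gene_truth),
               gene_id = unname(sim$truth$peak_gene_truth)),
    file.path(dir, "truth_peak_gene.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
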