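#' Configuration for the synthetic ribosome-profiling experiment
#'
#' Holds every tunable of the synthetic-data generator. The defaults emulate
#' the structure of the profiled experiment: two conditions (WT, KO) with
#' four biological replicates each and a two-level batch factor, per-nucleotide
#' ribosome-protected-fragment (RPF) profiles with negative-binomial replicate
#' noise over Poisson-gamma codon rates, injected pause sites of known class,
#' an optional 5'-ward occupancy ramp in the KO condition, paired total-RNA
#' counts, and per-layer differential effects with recorded ground truth.
#'
#' @param n_genes number of genes to simulate.
#' @param isoforms_per_gene isoforms per gene (>= 1); exactly one per gene is
#'   designated most abundant.
#' @param utr5_len_range,cds_len_range,utr3_len_range (min, max) region lengths
#'   in nt; CDS lengths are forced to multiples of 3.
#' @param n_replicates_per_condition biological replicates per condition.
#' @param batch_levels number of batch levels; replicates are assigned to
#'   batches in rotation, balanced across conditions.
#' @param mean_cds_depth expected RPF read count over a CDS for a transcript of
#'   average expression, per sample.
#' @param rna_mean_depth expected total-RNA count per transcript per sample.
#' @param rna_nb_dispersion negative-binomial size parameter of the RNA layer.
#'   The RNA default is deeper and less dispersed than the RPF layer: the RNA
#'   counts serve as the mRNA-abundance normalizer of pause classification,
#'   whose per-condition means must be estimated more precisely than any
#'   single RPF position.
#' @param base_rate_shape gamma shape of per-codon base rates (mean 1); smaller
#'   values give more heterogeneous codon dwell times.
#' @param base_rate_cap cap on the per-codon base rate (in units of the mean);
#'   keeps chance rate outliers below the pause-detection regime so that the
#'   injected pauses are the complete set of super-threshold peaks and the
#'   recorded ground truth is exhaustive.
#' @param frame_weights length-3 probabilities splitting each codon's rate over
#'   its three nucleotides; the first entry is the in-frame (frame 0) share and
#'   sets the triplet periodicity the offset QC measures.
#' @param init_boost multiplicative elevation of the initiation codon's rate;
#'   produces the start-codon peak that anchors P-site offset calibration.
#' @param utr_background UTR per-nt rate as a fraction of the mean CDS per-nt
#'   rate.
#' @param pause_fraction fraction of transcripts receiving one injected pause.
#' @param pause_factor multiplicative amplification of the paused position
#'   (> 1).
#' @param frac_induced,frac_resolved fractions of injected pauses assigned to
#'   the induced / resolved classes (the remainder is maintained);
#'   `frac_induced + frac_resolved <= 1`.
#' @param pause_region relative CDS interval (0-1 scale) within which pause
#'   positions are drawn.
#' @param pause_edge_nt pause positions are kept at least this many nt away
#'   from the CDS start and stop, so start-site exclusion logic is exercised by
#'   dedicated fixtures rather than by the generator.
#' @param ramp_strength slope of the linear 5'-to-3' occupancy tilt applied to
#'   the KO condition only (0 = none; must be < 1). The per-nt multiplier is
#'   `1 + ramp_strength * (1 - 2x)` at relative CDS position `x`.
#' @param nb_dispersion negative-binomial size parameter of replicate noise
#'   (larger = less extra-Poisson noise). Realized as a per-transcript
#'   per-sample gamma expression factor shared between the RPF and RNA layers,
#'   mixed with per-position Poisson sampling: positions and CDS sums are
#'   marginally negative binomial, and mRNA normalization can cancel the
#'   shared biological component, as it does in real data.
#' @param de_fraction fraction of transcripts that are truly differential per
#'   layer; a scalar or a named vector with entries `rna` and `rpf`.
#' @param de_lfc absolute log2 fold change of truly differential transcripts.
#' @param expr_sd_log2 sd of the per-transcript log2 expression multiplier.
#' @param batch_effect multiplicative library-size factor applied per batch
#'   level (level b is scaled by `batch_effect^(b-1)`).
#' @param protein_base_mean,protein_base_sd,protein_noise_sd log2-scale
#'   location, between-gene sd and residual sd of simulated protein
#'   intensities.
#' @param read_lengths simulated RPF read lengths.
#' @param read_length_weights sampling weights over `read_lengths`.
#' @param p_site_offset true P-site offset (nt from the read 5' end) used to
#'   back-compute read starts; written out so offset calibration can be
#'   validated against truth.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       isoforms_per_gene = 3,
                       utr5_len_range = c(60, 240),
                       cds_len_range = c(300, 1800),
                       utr3_len_range = c(90, 450),
                       n_replicates_per_condition = 4,
                       batch_levels = 2,
                       mean_cds_depth = 500,
                       rna_mean_depth = 500,
                       rna_nb_dispersion = 1000,
                       base_rate_shape = 2,
                       base_rate_cap = 5,
                       frame_weights = c(0.95, 0.03, 0.02),
                       init_boost = 5,
                       utr_background = 0.05,
                       pause_fraction = 0.2,
                       pause_factor = 30,
                       frac_induced = 0.4,
                       frac_resolved = 0.3,
                       pause_region = c(0, 1),
                       pause_edge_nt = 30,
                       ramp_strength = 0.3,
                       nb_dispersion = 20,
                       de_fraction = c(rna = 0, rpf = 0.15),
                       de_lfc = 1,
                       expr_sd_log2 = 0.5,
                       batch_effect = 1.3,
                       protein_base_mean = 20,
                       protein_base_sd = 2,
                       protein_noise_sd = 0.3,
                       read_lengths = 28:32,
                       read_length_weights = c(0.1, 0.2, 0.4, 0.2, 0.1),
                       p_site_offset = 12,
                       seed = 1) {
  assert_range(utr5_len_range, "utr5_len_range")
  assert_range(cds_len_range, "cds_len_range")
  assert_range(utr3_len_range, "utr3_len_range")
  assert_frac(pause_fraction, "pause_fraction")
  assert_frac(frac_induced, "frac_induced")
  assert_frac(frac_resolved, "frac_resolved")
  if (frac_induced + frac_resolved > 1) {
    stop("frac_induced + frac_resolved must not exceed 1", call. = FALSE)
  }
  if (pause_factor <= 1) stop("pause_factor must be > 1", call. = FALSE)
  if (ramp_strength < 0 || ramp_strength >= 1) {
    stop("ramp_strength must lie in [0, 1)", call. = FALSE)
  }
  assert_range(pause_region, "pause_region")
  assert_frac(pause_region, "pause_region")
  if (n_genes < 0 || isoforms_per_gene < 1) {
    stop("n_genes must be >= 0 and isoforms_per_gene >= 1", call. = FALSE)
  }
  if (abs(sum(frame_weights) - 1) > 1e-8 || length(frame_weights) != 3) {
    stop("frame_weights must be 3 probabilities summing to 1", call. = FALSE)
  }
  if (length(read_length_weights) != length(read_lengths)) {
    stop("read_length_weights must match read_lengths", call. = FALSE)
  }
  if (p_site_offset < 0 || p_site_offset >= min(read_lengths)) {
    stop("p_site_offset must lie in [0, min(read_lengths))", call. = FALSE)
  }
  if (is.null(names(de_fraction))) {
    de_fraction <- c(rna = de_fraction[[1]],
                     rpf = if (length(de_fraction) > 1) de_fraction[[2]] else de_fraction[[1]])
  }
  if (!all(c("rna", "rpf") %in% names(de_fraction))) {
    stop("de_fraction must be a scalar or a named vector with entries 'rna' and 'rpf'",
         call. = FALSE)
  }
  assert_frac(de_fraction, "de_fraction")

  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_genes, "genes x", x$isoforms_per_gene, "isoforms;",
      x$n_replicates_per_condition, "replicates/condition,",
      x$batch_levels, "batches\n")
  cat("  CDS depth", x$mean_cds_depth,
      "| pause_fraction", x$pause_fraction, "x factor", x$pause_factor,
      "| ramp", x$ramp_strength,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Sample sheet implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return data.frame with columns sample_id, condition, replicate, batch.
#'   Batches rotate over replicate indices, identically in both conditions,
#'   so batch is never confounded with condition.
#' @export
sim_sample_sheet <- function(config) {
  reps <- seq_len(config$n_replicates_per_condition)
  batch <- ((reps - 1) %% config$batch_levels) + 1
  data.frame(
    sample_id = c(paste0("WT_", reps), paste0("KO_", reps)),
    condition = rep(c("WT", "KO"), each = length(reps)),
    replicate = rep(reps, 2),
    batch = rep(batch, 2),
    stringsAsFactors = FALSE
  )
}
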