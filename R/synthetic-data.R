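# Synthetic ribosome-profiling experiment with recorded ground truth.
#
# Rates are built per transcript and condition as:
#   per-codon gamma base rate (mean 1, shape base_rate_shape)
#   x initiation boost on codon 1
#   x triplet frame weights per nucleotide
#   x KO-only linear 5'->3' ramp
#   x pause factor at the injected position (condition set by pause class)
# and then rescaled so the CDS rate sum equals the transcript's expected CDS
# count (pausing redistributes footprints; total ribosome load is conserved).
#
# Replicate noise is gamma-Poisson: a per-transcript per-sample expression
# factor (gamma with shape = nb_dispersion, shared between the RPF and RNA
# layers, as biological expression variation is) mixed with per-position
# Poisson sampling, so every position and the CDS sum are marginally
# negative binomial around rate x batch library factor. The RNA layer adds
# assay-specific negative-binomial noise (size rna_nb_dispersion) on top.

resample <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

#' Generate a synthetic transcript catalog and isoform abundance table
#'
#' Produces `n_genes` genes with `isoforms_per_gene` isoforms each; one
#' isoform per gene is designated most abundant and dominates the abundance
#' table in every sample. Region lengths are drawn within the configured
#' ranges, with CDS lengths forced to multiples of 3.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` (a `transcript_catalog` restricted to the MATs,
#'   built through [select_mat()] + [build_catalog()]), `regions` (all
#'   isoforms), `abundance` (per-sample TPM for all isoforms) and
#'   `designated_mat` (the generator's own gene -> transcript truth).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_genes
    k <- config$isoforms_per_gene
    samples <- sim_sample_sheet(config)$sample_id

    if (n == 0) {
      regions <- data.frame(transcript_id = character(0), gene_id = character(0),
                            gene_symbol = character(0), utr5_len = integer(0),
                            cds_len = integer(0), utr3_len = integer(0))
      abundance <- cbind(regions[, c("transcript_id", "gene_id")],
                         as.data.frame(matrix(numeric(0), 0, length(samples),
                                              dimnames = list(NULL, samples))))
      catalog <- build_catalog(regions, stats::setNames(character(0), character(0)))
      return(list(catalog = catalog, regions = regions, abundance = abundance,
                  designated_mat = stats::setNames(character(0), character(0))))
    }

    gene_id <- sprintf("gene%05d", seq_len(n))
    gene_symbol <- sprintf("Sym%05d", seq_len(n))
    tx <- expand.grid(iso = seq_len(k), gene = seq_len(n))[, 2:1]
    ntx <- nrow(tx)

    cds_codons <- seq(ceiling(config$cds_len_range[1] / 3),
                      floor(config$cds_len_range[2] / 3))
    if (length(cds_codons) == 0 || max(cds_codons) < 1) {
      stop("configuration error: cds_len_range admits no CDS length that is a positive multiple of 3")
    }
    regions <- data.frame(
      transcript_id = sprintf("%s.t%d", gene_id[tx$gene], tx$iso),
      gene_id = gene_id[tx$gene],
      gene_symbol = gene_symbol[tx$gene],
      utr5_len = resample(seq(config$utr5_len_range[1], config$utr5_len_range[2]), ntx),
      cds_len = 3L * resample(cds_codons, ntx),
      utr3_len = resample(seq(config$utr3_len_range[1], config$utr3_len_range[2]), ntx),
      stringsAsFactors = FALSE
    )

    # abundance: the designated isoform gets the gene's full expression scale,
    # the rest a fraction well below 1 so the MAT is unambiguous
    mat_iso <- resample(seq_len(k), n)
    gene_tpm <- stats::rlnorm(n, meanlog = 3, sdlog = 1)
    frac <- ifelse(tx$iso == mat_iso[tx$gene], 1, stats::runif(ntx, 0.05, 0.6))
    base_tpm <- gene_tpm[tx$gene] * frac
    tpm <- matrix(base_tpm * exp(stats::rnorm(ntx * length(samples), 0, 0.1)),
                  nrow = ntx, ncol = length(samples),
                  dimnames = list(NULL, samples))
    abundance <- cbind(regions[, c("transcript_id", "gene_id")], as.data.frame(tpm))

    designated <- stats::setNames(
      sprintf("%s.t%d", gene_id, mat_iso), gene_id)
    catalog <- build_catalog(regions, select_mat(abundance, regions))
    list(catalog = catalog, regions = regions, abundance = abundance,
         designated_mat = designated[order(names(designated))])
  })
}

# per-transcript, per-condition rate vectors over the whole transcript
.tx_rates <- function(rec, lfc_rpf, pause, config) {
  cds_len <- rec$cds_len
  ncod <- cds_len %/% 3
  # base codon rates are capped so that chance outliers stay well below the
  # pause-detection regime: injected pauses are the complete set of
  # super-threshold features, by construction
  g <- pmin(stats::rgamma(ncod, shape = config$base_rate_shape,
                          rate = config$base_rate_shape),
            config$base_rate_cap)
  gbar <- mean(g)
  g[1] <- g[1] * config$init_boost
  cds_base <- rep(g, each = 3) * rep(config$frame_weights, ncod)

  make_cond <- function(cond) {
    r <- cds_base
    if (cond == "KO" && config$ramp_strength > 0) {
      x <- (seq_len(cds_len) - 0.5) / cds_len
      r <- r * (1 + config$ramp_strength * (1 - 2 * x))
    }
    if (!is.null(pause)) {
      hit <- switch(pause$class,
                    induced = cond == "KO",
                    resolved = cond == "WT",
                    maintained = TRUE)
      # the peak is amplified relative to the transcript's average in-frame
      # peak height -- the same scale the 10x detection rule thresholds on
      if (hit) {
        r[pause$cds_position + 1L] <-
          config$pause_factor * config$frame_weights[1] * gbar
      }
    }
    expected <- config$mean_cds_depth * rec$expr_mult *
      (if (cond == "KO") 2^lfc_rpf else 1)
    r <- r * (expected / sum(r))
    utr_rate <- config$utr_background * expected / cds_len
    full <- c(rep(utr_rate, rec$utr5_len), r, rep(utr_rate, rec$utr3_len))
    # a footprint must fit inside the transcript around its P-site
    lo <- config$p_site_offset
    hi <- rec$tx_len - max(config$read_lengths) + config$p_site_offset
    if (lo > 0) full[seq_len(min(lo, length(full)))] <- 0
    if (hi < length(full) - 1) full[(hi + 2):length(full)] <- 0
    full
  }
  list(WT = make_cond("WT"), KO = make_cond("KO"))
}

#' Simulate a ribosome-profiling experiment with known ground truth
#'
#' Generates per-sample RPF read tables (5' start + length, in transcript
#' coordinates, back-computed from P-sites with a fixed known offset), a
#' paired total-RNA count matrix, the pre-noise rate vectors, and the ground
#' truth (injected pauses with class, per-layer true log2 fold changes).
#'
#' @param catalog a `transcript_catalog` (the MAT catalog from
#'   [generate_catalog()]).
#' @param config a [sim_config()].
#' @return list with elements `reads` (data.frame sample_id, transcript_id,
#'   start, length), `rna_counts` (a `count_matrix`, assay "RNA"),
#'   `sample_info`, `truth` (class `ground_truth`), `offset_table`
#'   (the true per-length P-site offsets), `rates` (per-transcript list of
#'   WT/KO pre-noise rate vectors) and `expected_cds` (per-transcript expected
#'   CDS count per condition; the pre-noise CDS rate sum equals it exactly).
#' @export
simulate_riboseq_experiment <- function(catalog, config) {
  stopifnot(inherits(catalog, "transcript_catalog"), inherits(config, "sim_config"))
  rec <- catalog$records
  if (nrow(rec) == 0) stop("catalog is empty")
  if (config$utr5_len_range[1] < config$p_site_offset ||
      config$utr3_len_range[1] < max(config$read_lengths) - config$p_site_offset) {
    stop("UTR length ranges must cover the footprint overhang around the P-site ",
         "(utr5 >= p_site_offset, utr3 >= max read length - p_site_offset)")
  }
  samples <- sim_sample_sheet(config)

  withr::with_seed(derive_seed(config$seed, 2L), {
    n <- nrow(rec)
    rec$expr_mult <- 2^stats::rnorm(n, 0, config$expr_sd_log2)

    draw_lfc <- function(frac) {
      ifelse(stats::runif(n) < frac,
             sample(c(-1, 1), n, replace = TRUE) * config$de_lfc, 0)
    }
    lfc_rna <- draw_lfc(config$de_fraction[["rna"]])
    lfc_rpf <- draw_lfc(config$de_fraction[["rpf"]])

    # pause injection: one site per selected transcript, frame-0, away from
    # the CDS edges, within the configured relative window
    edge <- config$pause_edge_nt
    eligible <- rec$cds_len > 2 * edge + 3
    paused <- stats::runif(n) < config$pause_fraction & eligible
    p_maint <- 1 - config$frac_induced - config$frac_resolved
    classes <- sample(c("induced", "resolved", "maintained"), n, replace = TRUE,
                      prob = c(config$frac_induced, config$frac_resolved, p_maint))
    pause_pos <- rep(NA_integer_, n)
    for (i in which(paused)) {
      lo <- max(edge, floor(config$pause_region[1] * rec$cds_len[i]))
      hi <- min(rec$cds_len[i] - edge, ceiling(config$pause_region[2] * rec$cds_len[i]))
      cod <- seq(ceiling(lo / 3), floor((hi - 1) / 3))
      cod <- cod[cod >= 1 & cod < rec$cds_len[i] / 3]
      if (length(cod) == 0) { paused[i] <- FALSE; next }
      pause_pos[i] <- 3L * resample(cod, 1)
    }

    lib_factor <- config$batch_effect^(samples$batch - 1)
    is_ko <- samples$condition == "KO"

    reads_list <- vector("list", n)
    rates <- vector("list", n)
    names(rates) <- rec$transcript_id
    rna_counts <- matrix(0L, n, nrow(samples),
                         dimnames = list(rec$transcript_id, samples$sample_id))

    for (i in seq_len(n)) {
      pause <- if (paused[i]) {
        list(cds_position = pause_pos[i], class = classes[i])
      } else NULL
      r <- .tx_rates(list(cds_len = rec$cds_len[i], utr5_len = rec$utr5_len[i],
                          utr3_len = rec$utr3_len[i], tx_len = rec$tx_len[i],
                          expr_mult = rec$expr_mult[i]),
                     lfc_rpf[i], pause, config)
      rates[[i]] <- r
      # offset rates into CDS coordinates happens downstream; counts per sample
      L <- rec$tx_len[i]
      # biological expression factor per sample, shared between the RPF and
      # RNA layers; with per-position Poisson sampling this makes every
      # position (and the CDS sum) marginally negative binomial with size
      # nb_dispersion
      e_bio <- stats::rgamma(nrow(samples), shape = config$nb_dispersion,
                             rate = config$nb_dispersion)
      per_sample <- vector("list", nrow(samples))
      for (s in seq_len(nrow(samples))) {
        mu <- (if (is_ko[s]) r$KO else r$WT) * lib_factor[s] * e_bio[s]
        cnt <- stats::rpois(L, mu)
        nz <- which(cnt > 0)
        if (length(nz) == 0) next
        pos <- rep(nz - 1L, cnt[nz])      # 0-based P-site positions
        len <- resample(config$read_lengths, length(pos),
                        prob = config$read_length_weights)
        per_sample[[s]] <- data.table::data.table(
          sample_id = samples$sample_id[s],
          transcript_id = rec$transcript_id[i],
          start = pos - as.integer(config$p_site_offset),
          length = as.integer(len))
      }
      reads_list[[i]] <- data.table::rbindlist(per_sample)

      mu_rna <- config$rna_mean_depth * rec$expr_mult[i] *
        ifelse(is_ko, 2^lfc_rna[i], 1) * lib_factor * e_bio
      rna_counts[i, ] <- stats::rnbinom(nrow(samples), mu = mu_rna,
                                        size = config$rna_nb_dispersion)
    }
    reads <- as.data.frame(data.table::rbindlist(reads_list))

    truth <- structure(list(
      injected_pauses = data.frame(
        transcript_id = rec$transcript_id[paused],
        cds_position = pause_pos[paused],
        class = classes[paused],
        stringsAsFactors = FALSE),
      de_truth = data.frame(
        transcript_id = rec$transcript_id,
        gene_id = rec$gene_id,
        gene_symbol = rec$gene_symbol,
        lfc_rna = lfc_rna,
        lfc_rpf = lfc_rpf,
        lfc_protein = lfc_rpf,
        stringsAsFactors = FALSE),
      flipped_sets = character(0)
    ), class = "ground_truth")

    list(
      reads = reads,
      rna_counts = count_matrix(rna_counts, samples, assay = "RNA"),
      sample_info = samples,
      truth = truth,
      offset_table = data.frame(length = config$read_lengths,
                                offset = as.integer(config$p_site_offset)),
      rates = rates,
      expected_cds = data.frame(
        transcript_id = rec$transcript_id,
        wt = config$mean_cds_depth * rec$expr_mult,
        ko = config$mean_cds_depth * rec$expr_mult * 2^lfc_rpf,
        stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a proteome intensity matrix tied to the translatome truth
#'
#' Log-normal protein intensities (log2 scale) for the same samples, with each
#' gene's true protein effect equal to its RPF effect, except for genes in
#' `flipped_sets`, whose protein log2FC is the sign-flip of their RPF log2FC.
#' One designated protein group carries two gene symbols to exercise tied
#' ranking downstream.
#'
#' @param truth a `ground_truth` from [simulate_riboseq_experiment()].
#' @param gene_sets named list of gene-symbol vectors; genes unknown to the
#'   truth are skipped with a warning.
#' @param config a [sim_config()].
#' @param flipped_sets names of entries of `gene_sets` whose protein effect is
#'   sign-flipped relative to the RPF effect.
#' @return list with `intensity` (log2 intensity matrix, rows = protein
#'   groups), `protein_groups` (group_id -> semicolon-joined gene symbols),
#'   `truth` (updated `lfc_protein` and `flipped_sets`) and `sample_info`.
#' @export
simulate_proteome <- function(truth, gene_sets = list(), config,
                              flipped_sets = character(0)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  de <- truth$de_truth
  samples <- sim_sample_sheet(config)

  known <- de$gene_symbol
  gene_sets <- lapply(gene_sets, function(g) {
    unknown <- setdiff(g, known)
    if (length(unknown) > 0) {
      warning("skipping ", length(unknown), " gene(s) absent from the simulated truth")
    }
    intersect(g, known)
  })
  bad <- setdiff(flipped_sets, names(gene_sets))
  if (length(bad) > 0) stop("flipped_sets not found in gene_sets: ", paste(bad, collapse = ", "))

  flip_genes <- unique(unlist(gene_sets[flipped_sets], use.names = FALSE))
  de$lfc_protein <- ifelse(de$gene_symbol %in% flip_genes, -de$lfc_rpf, de$lfc_rpf)

  withr::with_seed(derive_seed(config$seed, 3L), {
    n <- nrow(de)
    base <- stats::rnorm(n, config$protein_base_mean, config$protein_base_sd)
    is_ko <- samples$condition == "KO"
    ns <- nrow(samples)
    intensity <- matrix(stats::rnorm(n * ns, 0, config$protein_noise_sd), n, ns,
                        dimnames = list(NULL, samples$sample_id)) +
      base + outer(de$lfc_protein, as.numeric(is_ko))

    group_id <- de$gene_symbol
    symbols <- de$gene_symbol
    if (n > 0) {
      # first gene hosts the multi-gene group (a paralog sharing the peptides)
      group_id[1] <- paste0(de$gene_symbol[1], ";", de$gene_symbol[1], "ps")
      symbols[1] <- group_id[1]
    }
    rownames(intensity) <- group_id

    truth$de_truth <- de
    truth$flipped_sets <- flipped_sets
    list(intensity = intensity,
         protein_groups = data.frame(group_id = group_id, gene_symbols = symbols,
                                     stringsAsFactors = FALSE),
         truth = truth,
         sample_info = samples)
  })
}

#' Gene sets anchored on the simulated truth
#'
#' Builds a GMT-style collection from a `ground_truth`: one set of truly
#' RPF-up genes, one of truly RPF-down genes, and `n_random` sets sampled
#' uniformly from all simulated genes (the null sets used for enrichment
#' calibration).
#'
#' @param truth a `ground_truth`.
#' @param n_random number of random sets.
#' @param set_size target set size.
#' @param seed RNG seed.
#' @return named list of gene-symbol vectors.
#' @export
simulate_gene_sets <- function(truth, n_random = 8, set_size = 25, seed = 1) {
  de <- truth$de_truth
  withr::with_seed(seed, {
    sets <- list()
    up <- de$gene_symbol[de$lfc_rpf > 0]
    dn <- de$gene_symbol[de$lfc_rpf < 0]
    if (length(up) > 0) sets$RPF_UP_TRUTH <- resample_noreplace(up, min(set_size, length(up)))
    if (length(dn) > 0) sets$RPF_DOWN_TRUTH <- resample_noreplace(dn, min(set_size, length(dn)))
    for (i in seq_len(n_random)) {
      sets[[sprintf("RANDOM_%02d", i)]] <-
        resample_noreplace(de$gene_symbol, min(set_size, nrow(de)))
    }
    sets
  })
}

resample_noreplace <- function(x, n) sort(x[sample.int(length(x), n)])

#' Write a simulated dataset to disk as plain-text pipeline inputs
#'
#' @param catalog_out result of [generate_catalog()].
#' @param sim result of [simulate_riboseq_experiment()].
#' @param outdir output directory (created if needed).
#' @param proteome optional result of [simulate_proteome()].
#' @param gene_sets optional named list written as GMT.
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_dataset <- function(catalog_out, sim, outdir, proteome = NULL,
                              gene_sets = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(
    regions = write_tsv_file(catalog_out$regions, p("regions.tsv")),
    abundance = write_tsv_file(catalog_out$abundance, p("abundance.tsv")),
    reads = write_tsv_file(sim$reads, p("reads.tsv")),
    sample_sheet = write_tsv_file(sim$sample_info, p("sample_sheet.tsv")),
    rna_counts = write_counts_tsv(sim$rna_counts$counts, p("rna_counts.tsv")),
    offsets = write_tsv_file(sim$offset_table, p("true_offsets.tsv"))
  )
  jsonlite::write_json(
    list(injected_pauses = sim$truth$injected_pauses,
         de_truth = sim$truth$de_truth,
         flipped_sets = sim$truth$flipped_sets),
    p("truth.json"), dataframe = "columns", digits = NA)
  paths <- c(paths, truth = p("truth.json"))
  if (!is.null(proteome)) {
    paths <- c(paths,
               protein = write_counts_tsv(proteome$intensity, p("protein_intensity.tsv")),
               protein_groups = write_tsv_file(proteome$protein_groups, p("protein_groups.tsv")))
  }
  if (!is.null(gene_sets)) {
    paths <- c(paths, gene_sets = write_gmt(gene_sets, p("gene_sets.gmt")))
  }
  invisible(paths)
}

write_counts_tsv <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_sim_dataset
#' @param sets named list of gene-symbol vectors.
#' @param path GMT output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
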