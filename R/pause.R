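#' Configuration of pause calling, classification and metagene profiling
#'
#' @param fold_threshold fold over the transcript average used by both the
#'   calling rule (peak height vs mean nonzero peak height) and the
#'   classification rule (peak-height change vs mean absolute change).
#' @param start_exclusion_nt candidates within this many nt of the CDS start
#'   (the translation start site) are excluded from the output.
#' @param min_nonzero_positions minimum number of nonzero CDS positions for a
#'   transcript's condition profile to be evaluable.
#' @param bins named vector of metagene bin counts per region
#'   (utr5, cds, utr3).
#' @param metagene_min_mean_cds metagene inclusion filter: transcripts with
#'   mean raw CDS reads across all samples strictly greater than this value.
#' @param class_labels labels used for the three pause classes; "sustained" is
#'   accepted as an alias for "maintained".
#' @return object of class `pause_config`.
#' @export
pause_config <- function(fold_threshold = 10,
                         start_exclusion_nt = 3,
                         min_nonzero_positions = 10,
                         bins = c(utr5 = 25L, cds = 100L, utr3 = 25L),
                         metagene_min_mean_cds = 50,
                         class_labels = c("induced", "resolved", "maintained")) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (any(bins < 1) || !all(c("utr5", "cds", "utr3") %in% names(bins))) {
    stop("bins must be >= 1 and named utr5, cds, utr3")
  }
  class_labels[class_labels == "sustained"] <- "maintained"
  if (!setequal(class_labels, c("induced", "resolved", "maintained"))) {
    stop("class_labels must name the induced/resolved/maintained classes")
  }
  structure(list(fold_threshold = fold_threshold,
                 start_exclusion_nt = start_exclusion_nt,
                 min_nonzero_positions = min_nonzero_positions,
                 bins = bins,
                 metagene_min_mean_cds = metagene_min_mean_cds),
            class = "pause_config")
}

#' Call pause sites on one condition profile
#'
#' A pause site is a CDS position whose count is at least `fold_threshold`
#' times the mean of the nonzero CDS counts on the same transcript. A
#' transcript is evaluable only if it has at least `min_nonzero_positions`
#' nonzero CDS positions; otherwise no positions are returned and the
#' `evaluable` attribute is FALSE.
#'
#' @param cds_counts per-nt counts over the CDS, replicate-pooled within one
#'   condition (position 0 = CDS start).
#' @param config a [pause_config()].
#' @return integer vector of 0-based CDS positions, in transcript order, with
#'   attribute `evaluable`.
#' @export
call_pauses <- function(cds_counts, config = pause_config()) {
  nz <- cds_counts > 0
  if (sum(nz) < config$min_nonzero_positions) {
    return(structure(integer(0), evaluable = FALSE))
  }
  thr <- config$fold_threshold * mean(cds_counts[nz])
  structure(which(cds_counts >= thr) - 1L, evaluable = TRUE)
}

#' Classify candidate pause sites between conditions
#'
#' The change in peak height is the difference between mRNA-normalized pooled
#' heights, `delta(i) = ko(i)/m_ko - wt(i)/m_wt`. A candidate is induced
#' (resolved) if its increase (decrease) is at least `fold_threshold` times
#' the transcript's average change, taken as the mean absolute delta over CDS
#' positions with a nonzero pooled count in either condition; everything else
#' is maintained. Candidates inside the start-exclusion window are removed
#' from the output.
#'
#' @param cds_wt,cds_ko replicate-pooled per-nt CDS counts per condition.
#' @param m_wt,m_ko mRNA abundance of the transcript per condition (positive).
#' @param candidates 0-based candidate CDS positions (union of per-condition
#'   [call_pauses()] calls). Positions outside the CDS are a caller bug and
#'   raise an error.
#' @param config a [pause_config()].
#' @return data.frame with cds_position, height_wt, height_ko, norm_wt,
#'   norm_ko, delta, class.
#' @export
classify_pauses <- function(cds_wt, cds_ko, m_wt, m_ko, candidates,
                            config = pause_config()) {
  stopifnot(length(cds_wt) == length(cds_ko))
  if (m_wt <= 0 || m_ko <= 0) stop("mRNA abundance must be positive in both conditions")
  if (any(candidates < 0 | candidates >= length(cds_wt))) {
    stop("candidate position outside the CDS (caller bug)")
  }
  delta_all <- cds_ko / m_ko - cds_wt / m_wt
  # reference scale: mean |delta| over positions occupied in both pooled
  # condition profiles -- positions where a height change is measurable.
  # Positions seen in only one condition sit at the single-read floor and
  # would drag the reference below the noise scale of any genuine peak.
  nz <- cds_wt > 0 & cds_ko > 0
  ref <- if (any(nz)) mean(abs(delta_all[nz])) else 0

  i <- candidates + 1L
  delta <- delta_all[i]
  cls <- rep("maintained", length(i))
  cls[delta > 0 & delta >= config$fold_threshold * ref] <- "induced"
  cls[delta < 0 & -delta >= config$fold_threshold * ref] <- "resolved"

  out <- data.frame(cds_position = candidates,
                    height_wt = cds_wt[i], height_ko = cds_ko[i],
                    norm_wt = cds_wt[i] / m_wt, norm_ko = cds_ko[i] / m_ko,
                    delta = delta, class = cls, stringsAsFactors = FALSE)
  out <- out[out$cds_position >= config$start_exclusion_nt, , drop = FALSE]
  out[order(out$cds_position), , drop = FALSE]
}

#' Per-condition mRNA abundance from an RNA count matrix
#'
#' Size-factor-normalized (median-of-ratios) mean RNA count per transcript and
#' condition; the normalizer used when comparing pause peak heights across
#' conditions.
#'
#' @param rna a `count_matrix` with assay "RNA" (or any count matrix).
#' @return data.frame transcript_id, m_wt, m_ko (columns named m_<condition>
#'   for each condition present).
#' @export
rna_condition_abundance <- function(rna) {
  stopifnot(inherits(rna, "count_matrix"))
  sf <- DESeq2::estimateSizeFactorsForMatrix(rna$counts)
  norm <- sweep(rna$counts, 2, sf, "/")
  conds <- unique(rna$sample_info$condition)
  out <- data.frame(transcript_id = rownames(norm), stringsAsFactors = FALSE)
  for (cc in conds) {
    ids <- rna$sample_info$sample_id[rna$sample_info$condition == cc]
    out[[paste0("m_", tolower(cc))]] <- rowMeans(norm[, ids, drop = FALSE])
  }
  out
}

#' Detect and classify pause sites across the transcriptome
#'
#' Replicate-pooled condition profiles per transcript (library-size-normalized
#' by median-of-ratios RPF size factors before pooling) are scanned with
#' [call_pauses()]; the candidate set is the union of the two per-condition
#' calls, so a pause present in only one condition can still be labeled; the
#' union is classified with [classify_pauses()]. Transcripts lacking positive
#' mRNA abundance in either condition, or evaluable in neither condition, are
#' skipped and counted.
#'
#' @param profiles an `occupancy_profiles`.
#' @param rna a `count_matrix` of RNA counts for the same samples.
#' @param config a [pause_config()].
#' @param conditions the (reference, test) condition pair; deltas are
#'   test - reference.
#' @return data.frame of pause sites (transcript_id, cds_position, heights,
#'   normalized heights, delta, class), with attribute `skipped` recording
#'   per-reason skip counts.
#' @export
find_pause_sites <- function(profiles, rna, config = pause_config(),
                             conditions = c("WT", "KO")) {
  ab <- rna_condition_abundance(rna)
  m_ref <- ab[[paste0("m_", tolower(conditions[1]))]]
  m_test <- ab[[paste0("m_", tolower(conditions[2]))]]
  tx_ids <- intersect(unique(profiles$counts$transcript_id), ab$transcript_id)

  # RPF library size factors (median-of-ratios on the filtered CDS matrix):
  # heights are depth-normalized before pooling so that condition deltas
  # reflect occupancy, not sequencing depth
  sf <- tryCatch({
    cmf <- cds_count_matrix(profiles, min_mean_reads = 10)
    DESeq2::estimateSizeFactorsForMatrix(cmf$counts)
  }, error = function(e) NULL)
  if (is.null(sf) || anyNA(sf) || any(sf <= 0)) {
    sf <- stats::setNames(rep(1, nrow(profiles$sample_info)),
                          profiles$sample_info$sample_id)
  }

  skipped <- c(no_rna = 0L, not_evaluable = 0L)
  res <- vector("list", length(tx_ids))
  for (k in seq_along(tx_ids)) {
    tx <- tx_ids[k]
    j <- match(tx, ab$transcript_id)
    if (is.na(m_ref[j]) || is.na(m_test[j]) || m_ref[j] <= 0 || m_test[j] <= 0) {
      skipped["no_rna"] <- skipped["no_rna"] + 1L
      next
    }
    wt <- pooled_cds_profile(profiles, tx, conditions[1], size_factors = sf)
    ko <- pooled_cds_profile(profiles, tx, conditions[2], size_factors = sf)
    c_wt <- call_pauses(wt, config)
    c_ko <- call_pauses(ko, config)
    if (!attr(c_wt, "evaluable") && !attr(c_ko, "evaluable")) {
      skipped["not_evaluable"] <- skipped["not_evaluable"] + 1L
      next
    }
    cand <- sort(union(c_wt, c_ko))
    if (length(cand) == 0) next
    cls <- classify_pauses(wt, ko, m_ref[j], m_test[j], cand, config)
    if (nrow(cls) > 0) {
      res[[k]] <- cbind(transcript_id = tx, cls, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), cds_position = integer(0),
                      height_wt = numeric(0), height_ko = numeric(0),
                      norm_wt = numeric(0), norm_ko = numeric(0),
                      delta = numeric(0), class = character(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Positional distribution of pause sites over the CDS
#'
#' Histograms of relative CDS position (`cds_position / cds_len`, in [0, 1))
#' per pause class, with per-class densities summing to 1; optionally
#' stratified by gene subsets (e.g. shared / only-protein / only-RPF
#' leading-edge gene lists).
#'
#' @param pauses pause table from [find_pause_sites()].
#' @param catalog a `transcript_catalog`.
#' @param n_bins number of equal-width bins over [0, 1].
#' @param subsets optional named list of gene-symbol vectors; each produces
#'   its own per-class distribution. The unstratified distribution is labeled
#'   "all".
#' @return data.frame subset, class, bin, lower, upper, count, density.
#' @export
pause_position_distribution <- function(pauses, catalog, n_bins = 20,
                                        subsets = NULL) {
  rec <- catalog$records
  idx <- match(pauses$transcript_id, rec$transcript_id)
  if (anyNA(idx)) stop("pause table contains transcripts absent from the catalog")
  rel <- pauses$cds_position / rec$cds_len[idx]
  sym <- rec$gene_symbol[idx]
  breaks <- seq(0, 1, length.out = n_bins + 1)

  one <- function(label, keep) {
    out <- lapply(c("induced", "resolved", "maintained"), function(cl) {
      r <- rel[keep & pauses$class == cl]
      cnt <- if (length(r) == 0) rep(0L, n_bins) else {
        tabulate(pmin(n_bins, findInterval(r, breaks, rightmost.closed = TRUE)),
                 nbins = n_bins)
      }
      data.frame(subset = label, class = cl, bin = seq_len(n_bins) - 1L,
                 lower = breaks[-length(breaks)], upper = breaks[-1],
                 count = cnt,
                 density = if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, n_bins),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- list(one("all", rep(TRUE, nrow(pauses))))
  for (nm in names(subsets)) res[[nm]] <- one(nm, sym %in% subsets[[nm]])
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# average per-nt values into equal-width scaled bins; returns length-n_bins
# vector with NA for bins not covered (region shorter than the bin count)
.bin_region <- function(values, n_bins) {
  L <- length(values)
  if (L == 0) return(rep(NA_real_, n_bins))
  bin <- pmin(n_bins - 1L, floor((seq_len(L) - 1) / L * n_bins))
  out <- rep(NA_real_, n_bins)
  agg <- tapply(values, bin, mean)
  out[as.integer(names(agg)) + 1L] <- agg
  out
}

#' Metagene delta-occupancy profiles over 5'UTR, CDS and 3'UTR
#'
#' For every transcript whose mean raw CDS read count across all samples
#' exceeds the configured floor (strictly), each sample's profile is
#' normalized to counts-per-million and then to the transcript's own mean,
#' and binned region-wise into equal-width scaled bins. The per-replicate
#' delta (KO replicate minus the matching WT replicate) is averaged over
#' transcripts, and the per-bin mean and standard deviation across replicate
#' pairs are reported.
#'
#' @param profiles an `occupancy_profiles`.
#' @param config a [pause_config()].
#' @param conditions the (reference, test) condition pair.
#' @return data.frame region, bin, mean_delta, sd, n (transcripts
#'   contributing to the region).
#' @export
metagene_delta <- function(profiles, config = pause_config(),
                           conditions = c("WT", "KO")) {
  rec <- profiles$catalog$records
  si <- profiles$sample_info
  cm_all <- cds_count_matrix(profiles, min_mean_reads = 0)
  means <- rowMeans(cm_all$counts)
  keep_tx <- names(means)[means > config$metagene_min_mean_cds]
  if (length(keep_tx) == 0) stop("no transcript passes the metagene coverage filter")

  cpm_factor <- 1e6 / pmax(profiles$totals, 1)
  reps <- sort(unique(si$replicate))
  ref_ids <- vchr(reps, function(r)
    si$sample_id[si$condition == conditions[1] & si$replicate == r])
  test_ids <- vchr(reps, function(r)
    si$sample_id[si$condition == conditions[2] & si$replicate == r])

  regions <- c("utr5", "cds", "utr3")
  n_bins <- config$bins[regions]
  # accumulators: per region, bins x replicates sum over transcripts + count
  acc <- lapply(regions, function(rg) matrix(0, n_bins[[rg]], length(reps)))
  names(acc) <- regions
  bin_n <- lapply(regions, function(rg) rep(0L, n_bins[[rg]]))
  names(bin_n) <- regions
  n_tx <- stats::setNames(rep(0L, 3), regions)

  for (tx in keep_tx) {
    i <- match(tx, rec$transcript_id)
    m <- profile_matrix(profiles, tx)
    norm <- sweep(m, 2, cpm_factor[colnames(m)], "*")
    mu <- colMeans(norm)
    norm <- sweep(norm, 2, ifelse(mu > 0, mu, 1), "/")
    delta <- norm[, test_ids, drop = FALSE] - norm[, ref_ids, drop = FALSE]

    spans <- list(utr5 = seq_len(rec$utr5_len[i]),
                  cds = rec$cds_start[i] + seq_len(rec$cds_len[i]),
                  utr3 = rec$cds_end[i] + seq_len(rec$utr3_len[i]))
    for (rg in regions) {
      if (length(spans[[rg]]) == 0) next
      binned <- apply(delta[spans[[rg]], , drop = FALSE], 2, .bin_region,
                      n_bins = n_bins[[rg]])
      covered <- !is.na(binned[, 1])
      binned[is.na(binned)] <- 0
      acc[[rg]] <- acc[[rg]] + binned
      bin_n[[rg]] <- bin_n[[rg]] + covered
      n_tx[rg] <- n_tx[rg] + 1L
    }
  }

  out <- lapply(regions, function(rg) {
    if (n_tx[rg] == 0) return(NULL)
    # per-bin mean over the transcripts whose (scaled) region covers the bin
    per_rep <- acc[[rg]] / pmax(bin_n[[rg]], 1)
    per_rep[bin_n[[rg]] == 0, ] <- NA
    data.frame(region = rg, bin = seq_len(nrow(per_rep)) - 1L,
               mean_delta = rowMeans(per_rep),
               sd = apply(per_rep, 1, stats::sd),
               n = unname(n_tx[rg]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
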