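#' Count matrix with sample metadata
#'
#' Container for one assay's transcripts x samples integer counts together
#' with the sample sheet (condition, replicate, batch). Column order is fixed
#' by the sample sheet.
#'
#' @param counts integer matrix, rownames = transcript_id.
#' @param sample_info data.frame with sample_id, condition, replicate, batch;
#'   one row per count column, matched by sample_id.
#' @param assay assay tag, e.g. "RPF_CDS" or "RNA".
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_info, assay = "RPF_CDS") {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  req <- c("sample_id", "condition", "replicate", "batch")
  if (!all(req %in% names(sample_info)) || anyNA(sample_info[req])) {
    stop("sample_info must provide complete sample_id, condition, replicate, batch")
  }
  if (!setequal(colnames(counts), sample_info$sample_id)) {
    stop("count columns and sample_info$sample_id disagree")
  }
  if (any(counts < 0)) stop("negative counts are not allowed")
  sample_info <- sample_info[match(colnames(counts), sample_info$sample_id), , drop = FALSE]
  rownames(sample_info) <- sample_info$sample_id
  structure(list(counts = counts, sample_info = sample_info, assay = assay),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix [", x$assay, "]: ", nrow(x$counts), " transcripts x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Read a transcript-space read table
#'
#' @param path TSV with columns `transcript_id`, `start` (0-based 5' end) or
#'   `start_0based`, `length`, and optionally `sample_id`.
#' @param sample_id sample label to attach when the file has none.
#' @return data.frame of aligned reads.
#' @export
read_read_table <- function(path, sample_id = NULL) {
  df <- read_tsv_file(path)
  if ("start_0based" %in% names(df)) names(df)[names(df) == "start_0based"] <- "start"
  stopifnot(all(c("transcript_id", "start", "length") %in% names(df)))
  if (!"sample_id" %in% names(df)) {
    if (is.null(sample_id)) stop("read table has no sample_id column; supply one")
    df$sample_id <- sample_id
  }
  df
}

#' Read transcript-space alignments from SAM/BAM
#'
#' Reference names must be transcript IDs. Only primary, mapped records are
#' used; the read's recorded alignment start and query width define its
#' transcript-space interval (no soft-clip arithmetic, transcript space is
#' contiguous).
#'
#' @param path SAM or BAM file (SAM is converted via [Rsamtools::asBam()]).
#' @param sample_id sample label to attach.
#' @return data.frame with transcript_id, start (0-based), length, sample_id.
#' @export
read_transcript_alignments <- function(path, sample_id) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("rname", "pos", "qwidth"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  data.frame(transcript_id = as.character(b$rname),
             start = b$pos - 1L,
             length = b$qwidth,
             sample_id = sample_id,
             stringsAsFactors = FALSE)
}

#' A fixed P-site offset table
#'
#' Bypasses calibration when offsets are known (e.g. supplied with a
#' simulated dataset).
#'
#' @param lengths read lengths to keep.
#' @param offset P-site offset applied to every length (or one per length).
#' @return an offset table as produced by [calibrate_offsets()].
#' @export
fixed_offset_table <- function(lengths, offset = 12) {
  data.frame(length = as.integer(lengths),
             offset = as.integer(rep(offset, length.out = length(lengths))),
             n_reads = NA_integer_, frame0_frac = NA_real_,
             keep = TRUE, reason = "", stringsAsFactors = FALSE)
}

#' Calibrate P-site offsets from the start-codon metaprofile
#'
#' For each read length within the window, the offset is the shift that places
#' the modal 5' end at the initiation P-site: the most frequent 5'-end
#' position relative to the CDS start, among reads whose 5' end lies within
#' one read length upstream of (or at) the start codon, negated. A length is
#' kept only if it is supported by at least `min_reads` reads and its in-frame
#' (frame 0) P-site fraction reaches `frame_threshold`; uniform positional
#' noise gives a frame-0 fraction near 1/3 and is rejected at the default 0.5.
#'
#' @param reads read data.frame (transcript_id, start, length, sample_id).
#' @param catalog a `transcript_catalog`.
#' @param length_window inclusive read-length window; reads outside it are
#'   ignored entirely.
#' @param frame_threshold minimum frame-0 fraction to keep a length.
#' @param min_reads minimum number of reads for a length to be calibratable.
#' @return data.frame with columns length, offset, n_reads, frame0_frac,
#'   keep, reason.
#' @export
calibrate_offsets <- function(reads, catalog, length_window = c(27, 38),
                              frame_threshold = 0.5, min_reads = 100) {
  rec <- catalog$records
  dt <- data.table::as.data.table(reads)
  dt <- dt[dt$length >= length_window[1] & dt$length <= length_window[2], ]
  if (nrow(dt) == 0) stop("no reads within the read-length window")
  unknown <- setdiff(unique(dt$transcript_id), rec$transcript_id)
  if (length(unknown) > 0) {
    stop("reads reference transcripts absent from the catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  idx <- match(dt$transcript_id, rec$transcript_id)
  dt$rel <- dt$start - rec$cds_start[idx]

  out <- lapply(sort(unique(dt$length)), function(L) {
    sub <- dt[dt$length == L, ]
    n <- nrow(sub)
    row <- data.frame(length = L, offset = NA_integer_, n_reads = n,
                      frame0_frac = NA_real_, keep = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    if (n < min_reads) { row$reason <- "insufficient"; return(row) }
    near <- sub$rel[sub$rel > -L & sub$rel <= 0]
    if (length(near) == 0) { row$reason <- "no_start_signal"; return(row) }
    tab <- table(near)
    mode_rel <- as.integer(names(tab)[which.max(tab)])
    offset <- -mode_rel
    psite_rel <- sub$rel + offset
    cds_len <- rec$cds_len[match(sub$transcript_id, rec$transcript_id)]
    in_cds <- psite_rel >= 0 & psite_rel < cds_len
    f0 <- mean(psite_rel[in_cds] %% 3 == 0)
    row$offset <- offset
    row$frame0_frac <- f0
    if (is.na(f0) || f0 < frame_threshold) { row$reason <- "aperiodic"; return(row) }
    row$keep <- TRUE
    row
  })
  do.call(rbind, out)
}

#' Build per-nucleotide P-site occupancy profiles
#'
#' Each read of a kept length contributes +1 at `start + offset(length)`.
#' Reads of non-kept lengths are discarded; P-sites falling outside the
#' transcript are dropped and counted, never written out of bounds.
#'
#' @param reads read data.frame (transcript_id, start, length, sample_id).
#' @param offsets offset table ([calibrate_offsets()] or
#'   [fixed_offset_table()]).
#' @param catalog a `transcript_catalog`.
#' @param sample_info sample sheet (sample_id, condition, replicate, batch).
#' @return object of class `occupancy_profiles`: sparse counts
#'   (`data.table` transcript_id, sample_id, pos, count), the sample sheet,
#'   the catalog, per-sample totals and drop counters.
#' @export
build_profiles <- function(reads, offsets, catalog, sample_info) {
  rec <- catalog$records
  kept <- offsets[offsets$keep, , drop = FALSE]
  if (nrow(kept) == 0) stop("no read lengths kept by the offset table")
  dt <- data.table::as.data.table(reads)
  n_in <- nrow(dt)
  dt <- dt[dt$length %in% kept$length, ]
  n_dropped_length <- n_in - nrow(dt)

  unknown <- setdiff(unique(dt$transcript_id), rec$transcript_id)
  if (length(unknown) > 0) {
    stop("reads reference transcripts absent from the catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  dt$pos <- dt$start + kept$offset[match(dt$length, kept$length)]
  tx_len <- rec$tx_len[match(dt$transcript_id, rec$transcript_id)]
  oob <- dt$pos < 0 | dt$pos >= tx_len
  n_dropped_oob <- sum(oob)
  dt <- dt[!oob, ]

  counts <- dt[, list(count = .N), by = c("transcript_id", "sample_id", "pos")]
  data.table::setorderv(counts, c("transcript_id", "sample_id", "pos"))
  data.table::setkeyv(counts, "transcript_id")
  totals <- stats::setNames(rep(0L, nrow(sample_info)), sample_info$sample_id)
  obs <- tapply(counts$count, counts$sample_id, sum)
  totals[names(obs)] <- as.integer(obs)

  structure(list(counts = counts, sample_info = sample_info, catalog = catalog,
                 totals = totals, n_dropped_length = n_dropped_length,
                 n_dropped_oob = n_dropped_oob),
            class = "occupancy_profiles")
}

#' @export
print.occupancy_profiles <- function(x, ...) {
  cat("occupancy_profiles:", length(unique(x$counts$transcript_id)),
      "transcripts,", sum(x$totals), "P-sites over",
      nrow(x$sample_info), "samples\n")
  invisible(x)
}

#' Dense per-transcript profile matrix
#'
#' @param profiles an `occupancy_profiles`.
#' @param transcript_id one transcript.
#' @param sample_ids samples to include (default: all, in sample-sheet order).
#' @return integer matrix transcript length x samples.
#' @export
profile_matrix <- function(profiles, transcript_id, sample_ids = NULL) {
  rec <- profiles$catalog$records
  L <- rec$tx_len[match(transcript_id, rec$transcript_id)]
  if (is.na(L)) stop("unknown transcript: ", transcript_id)
  if (is.null(sample_ids)) sample_ids <- profiles$sample_info$sample_id
  m <- matrix(0L, L, length(sample_ids), dimnames = list(NULL, sample_ids))
  key_dt <- data.table::data.table(transcript_id = transcript_id)
  sub <- profiles$counts[key_dt, on = "transcript_id", nomatch = NULL]
  sub <- sub[which(sub$sample_id %in% sample_ids), ]
  if (nrow(sub) > 0) {
    m[cbind(sub$pos + 1L, match(sub$sample_id, sample_ids))] <- sub$count
  }
  m
}

#' Replicate-pooled per-condition CDS profile
#'
#' Sums the condition's replicate profiles over the CDS, optionally after
#' dividing each sample by its library size factor so that cross-condition
#' height comparisons are not driven by sequencing depth.
#'
#' @param profiles an `occupancy_profiles`.
#' @param transcript_id one transcript.
#' @param condition condition label.
#' @param size_factors optional named per-sample normalization factors.
#' @return numeric vector over CDS positions (0-based CDS coordinates).
#' @export
pooled_cds_profile <- function(profiles, transcript_id, condition,
                               size_factors = NULL) {
  rec <- profiles$catalog$records
  i <- match(transcript_id, rec$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  ids <- profiles$sample_info$sample_id[profiles$sample_info$condition == condition]
  m <- profile_matrix(profiles, transcript_id, ids)
  if (!is.null(size_factors)) m <- sweep(m, 2, size_factors[ids], "/")
  v <- rowSums(m)
  v[(rec$cds_start[i] + 1L):rec$cds_end[i]]
}

#' CDS count matrix with the minimum-coverage filter
#'
#' Sums P-site counts over each transcript's CDS per sample and removes
#' transcripts whose mean count across all samples is lower than
#' `min_mean_reads` (strictly lower: a mean of exactly 10 is retained).
#'
#' @param profiles an `occupancy_profiles`.
#' @param catalog a `transcript_catalog` (defaults to the one carried by
#'   `profiles`).
#' @param min_mean_reads coverage threshold.
#' @return a `count_matrix` with assay "RPF_CDS"; attribute `n_filtered`
#'   records how many transcripts the filter removed.
#' @export
cds_count_matrix <- function(profiles, catalog = profiles$catalog,
                             min_mean_reads = 10) {
  rec <- catalog$records
  cnt <- profiles$counts
  unknown <- setdiff(unique(cnt$transcript_id), rec$transcript_id)
  if (length(unknown) > 0) {
    stop("profiles contain transcripts absent from the catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  idx <- match(cnt$transcript_id, rec$transcript_id)
  in_cds <- cnt$pos >= rec$cds_start[idx] & cnt$pos < rec$cds_end[idx]
  sub <- cnt[in_cds, ]
  agg <- sub[, list(n = sum(count)), by = c("transcript_id", "sample_id")]

  samples <- profiles$sample_info$sample_id
  m <- matrix(0L, nrow(rec), length(samples),
              dimnames = list(rec$transcript_id, samples))
  m[cbind(match(agg$transcript_id, rec$transcript_id),
          match(agg$sample_id, samples))] <- as.integer(agg$n)

  out <- filter_min_mean(m, min_mean_reads)
  cm <- count_matrix(out, profiles$sample_info, assay = "RPF_CDS")
  attr(cm, "n_filtered") <- nrow(m) - nrow(out)
  cm
}

#' Minimum mean-count filter
#'
#' Removes rows whose mean across all samples is lower than the threshold.
#' Idempotent: filtering a filtered matrix changes nothing.
#'
#' @param counts matrix or `count_matrix`.
#' @param min_mean_reads threshold (rows with mean strictly below are
#'   removed).
#' @return object of the same kind with offending rows removed.
#' @export
filter_min_mean <- function(counts, min_mean_reads = 10) {
  if (inherits(counts, "count_matrix")) {
    counts$counts <- filter_min_mean(counts$counts, min_mean_reads)
    return(counts)
  }
  counts[rowMeans(counts) >= min_mean_reads, , drop = FALSE]
}
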