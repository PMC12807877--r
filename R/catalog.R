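#' Select the most abundant transcript (MAT) per gene
#'
#' For each gene, picks the isoform with the highest mean abundance (TPM)
#' across all samples. Ties (including genes whose isoforms are all zero, for
#' which a warning is logged) are broken by longer CDS when a region table is
#' supplied, then by lexicographically smallest transcript_id. The result is
#' invariant under sample reordering and under rescaling all abundances by a
#' positive constant.
#'
#' @param abundance data.frame with columns `transcript_id`, `gene_id` and one
#'   or more numeric abundance columns (per-sample TPM, or a single `TPM`
#'   column as in RSEM `*.isoforms.results`).
#' @param regions optional region table (see [build_catalog()]) providing
#'   `cds_len` for the tie-break.
#' @return named character vector: gene_id -> transcript_id.
#' @export
select_mat <- function(abundance, regions = NULL) {
  stopifnot(all(c("transcript_id", "gene_id") %in% names(abundance)))
  num_cols <- setdiff(names(abundance)[vapply(abundance, is.numeric, logical(1))],
                      c("transcript_id", "gene_id"))
  if (length(num_cols) == 0) stop("abundance table has no numeric abundance columns")
  if (any(as.matrix(abundance[, num_cols, drop = FALSE]) < 0)) {
    stop("abundances must be non-negative")
  }
  mean_ab <- rowMeans(abundance[, num_cols, drop = FALSE])

  cds_len <- rep(0L, nrow(abundance))
  if (!is.null(regions)) {
    cds_len <- regions$cds_len[match(abundance$transcript_id, regions$transcript_id)]
    cds_len[is.na(cds_len)] <- 0L
  }

  # order so the first row per gene is the MAT under the declared rules
  ord <- order(abundance$gene_id, -mean_ab, -cds_len, abundance$transcript_id)
  first <- !duplicated(abundance$gene_id[ord])
  mat <- abundance$transcript_id[ord][first]
  names(mat) <- abundance$gene_id[ord][first]

  zero_genes <- tapply(mean_ab, abundance$gene_id, function(v) all(v == 0))
  if (any(zero_genes)) {
    warning(sum(zero_genes), " gene(s) with all-zero abundance; MAT chosen by tie-break rule")
  }
  mat[order(names(mat))]
}

#' Build a validated transcript catalog
#'
#' Assembles the transcript-coordinate model used by all positional analyses.
#' Coordinates are transcript-space, 0-based, half-open; the CDS occupies
#' `[utr5_len, utr5_len + cds_len)`. Transcripts present in `regions` but not
#' named by `mat_map` are dropped (count logged as a message).
#'
#' @param regions data.frame with columns `transcript_id`, `gene_id`,
#'   `utr5_len`, `cds_len`, `utr3_len` and optionally `gene_symbol`.
#' @param mat_map named character vector gene_id -> transcript_id, as returned
#'   by [select_mat()].
#' @return an object of class `transcript_catalog`: list with `records`
#'   (one row per MAT, with derived `tx_len`, `cds_start`, `cds_end`) and
#'   `mat` (the gene -> transcript map).
#' @export
build_catalog <- function(regions, mat_map) {
  req <- c("transcript_id", "gene_id", "utr5_len", "cds_len", "utr3_len")
  stopifnot(all(req %in% names(regions)))
  missing <- setdiff(mat_map, regions$transcript_id)
  if (length(missing) > 0) {
    stop("MAT transcript(s) missing from region table: ",
         paste(missing, collapse = ", "))
  }
  if (any(regions$utr5_len < 0 | regions$cds_len < 0 | regions$utr3_len < 0)) {
    stop("negative region lengths in region table")
  }

  keep <- regions$transcript_id %in% mat_map
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " non-MAT transcript(s) dropped from region table")
  rec <- regions[keep, , drop = FALSE]
  if (!"gene_symbol" %in% names(rec)) rec$gene_symbol <- rec$gene_id
  if (any(rec$cds_len < 3)) stop("cds_len must be >= 3 for every MAT transcript")
  off_frame <- sum(rec$cds_len %% 3 != 0)
  if (off_frame > 0) {
    warning(off_frame, " transcript(s) with CDS length not divisible by 3")
  }

  rec <- rec[order(rec$transcript_id),
             c("transcript_id", "gene_id", "gene_symbol",
               "utr5_len", "cds_len", "utr3_len")]
  rec$tx_len <- rec$utr5_len + rec$cds_len + rec$utr3_len
  rec$cds_start <- rec$utr5_len
  rec$cds_end <- rec$utr5_len + rec$cds_len
  rownames(rec) <- rec$transcript_id

  if (anyDuplicated(names(mat_map))) stop("mat_map assigns multiple transcripts to one gene")
  structure(list(records = rec, mat = mat_map[order(names(mat_map))]),
            class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat("transcript_catalog:", nrow(x$records), "MAT transcripts /",
      length(x$mat), "genes\n")
  invisible(x)
}

#' @rdname build_catalog
#' @param path file path for catalog TSV serialization.
#' @param catalog a `transcript_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv_file(catalog$records[, c("transcript_id", "gene_id", "gene_symbol",
                                     "utr5_len", "cds_len", "utr3_len")], path)
}

#' @rdname build_catalog
#' @export
read_catalog <- function(path) {
  rec <- read_tsv_file(path)
  mat <- rec$transcript_id
  names(mat) <- rec$gene_id
  build_catalog(rec, mat)
}

#' Read transcript region extents
#'
#' `read_regions` reads either the plain region TSV
#' (`transcript_id, gene_id[, gene_symbol], utr5_len, cds_len, utr3_len`) or a
#' Gencode-dialect GTF, from which per-transcript region lengths are derived as
#' the summed widths of `five_prime_utr`, `CDS` and `three_prime_utr` features.
#'
#' @param path path to a region TSV or a `.gtf` file.
#' @return region data.frame suitable for [build_catalog()].
#' @export
read_regions <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    df <- df[df$type %in% c("five_prime_utr", "CDS", "three_prime_utr"), ]
    if (nrow(df) == 0) stop("GTF contains no five_prime_utr/CDS/three_prime_utr features")
    agg <- stats::aggregate(width ~ transcript_id + gene_id + type, data = df, FUN = sum)
    wide <- stats::reshape(agg, idvar = c("transcript_id", "gene_id"),
                           timevar = "type", direction = "wide")
    get0_col <- function(nm) {
      v <- wide[[paste0("width.", nm)]]
      if (is.null(v)) rep(0L, nrow(wide)) else ifelse(is.na(v), 0L, v)
    }
    out <- data.frame(
      transcript_id = wide$transcript_id,
      gene_id = wide$gene_id,
      utr5_len = as.integer(get0_col("five_prime_utr")),
      cds_len = as.integer(get0_col("CDS")),
      utr3_len = as.integer(get0_col("three_prime_utr")),
      stringsAsFactors = FALSE
    )
    if ("gene_name" %in% names(df)) {
      out$gene_symbol <- df$gene_name[match(out$transcript_id, df$transcript_id)]
    }
    out
  } else {
    read_tsv_file(path)
  }
}

#' Read an isoform abundance table
#'
#' Accepts RSEM-style `*.isoforms.results` (columns `transcript_id`, `gene_id`,
#' `TPM`) or the generic abundance TSV with per-sample TPM columns.
#'
#' @param path path to the TSV.
#' @return abundance data.frame for [select_mat()].
#' @export
read_abundance <- function(path) {
  ab <- read_tsv_file(path)
  if (!all(c("transcript_id", "gene_id") %in% names(ab))) {
    stop("abundance table must have transcript_id and gene_id columns")
  }
  ab
}
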