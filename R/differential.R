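#' Negative-binomial Wald differential test with a batch covariate
#'
#' Fits a negative-binomial GLM per transcript on `~ batch + condition`
#' (batch dropped when it has a single level), tests the condition
#' coefficient with a Wald test and adjusts p-values by Benjamini-Hochberg
#' across all tested transcripts. Size factors come from the median-of-ratios
#' method. No independent filtering and no fold-change shrinkage are applied;
#' transcripts with all-zero counts are reported with undefined (NA) p/padj.
#'
#' @param cm a `count_matrix` (or an integer matrix plus `sample_info`).
#' @param sample_info sample sheet when `cm` is a bare matrix.
#' @param ref_level reference condition (the denominator of the fold change).
#' @return data.frame transcript_id, base_mean, log2fc, lfc_se, stat, pvalue,
#'   padj, ordered as the input rows.
#' @export
nb_differential <- function(cm, sample_info = NULL, ref_level = "WT") {
  if (inherits(cm, "count_matrix")) {
    counts <- cm$counts
    sample_info <- cm$sample_info
  } else {
    counts <- cm
    if (is.null(sample_info)) stop("sample_info required with a bare matrix")
    sample_info <- sample_info[match(colnames(counts), sample_info$sample_id), ]
  }
  cond <- as.character(sample_info$condition)
  if (!ref_level %in% cond) ref_level <- sort(unique(cond))[1]
  if (length(unique(cond)) != 2 || min(table(cond)) < 2) {
    stop("need two conditions with >= 2 samples each")
  }
  col <- data.frame(condition = stats::relevel(factor(cond), ref = ref_level),
                    batch = factor(sample_info$batch))
  design <- if (nlevels(col$batch) > 1) ~ batch + condition else ~ condition
  mm <- stats::model.matrix(design, col)
  if (qr(mm)$rank < ncol(mm)) {
    stop("design is confounded: batch and condition are collinear")
  }

  dds <- DESeq2::DESeqDataSetFromMatrix(round(counts), col, design)
  dds <- DESeq2::DESeq(dds, test = "Wald", quiet = TRUE)
  test_level <- setdiff(levels(col$condition), ref_level)
  res <- DESeq2::results(dds,
                         name = paste0("condition_", test_level, "_vs_", ref_level),
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  data.frame(transcript_id = rownames(counts),
             base_mean = res$baseMean,
             log2fc = res$log2FoldChange,
             lfc_se = res$lfcSE,
             stat = res$stat,
             pvalue = res$pvalue,
             padj = res$padj,
             stringsAsFactors = FALSE)
}

TE_CATEGORIES <- c("both_up", "both_down", "rpf_up", "rpf_down",
                   "rna_up", "rna_down", "ns")

#' Joint translational-efficiency categorization
#'
#' Intersects the RNA and RPF differential tables on their common transcript
#' set and assigns each transcript exactly one category at `padj < alpha`:
#' `both_up`/`both_down` when both layers are significant with the same sign,
#' `rpf_up`/`rpf_down` when only the RPF layer is significant, `rna_up`/
#' `rna_down` when only the RNA layer is, and `ns` otherwise. Transcripts
#' significant on both layers with discordant signs are labeled by the RPF
#' sign, with a warning.
#'
#' @param de_rna,de_rpf outputs of [nb_differential()] for the RNA and RPF
#'   assays.
#' @param alpha adjusted-significance threshold.
#' @return list with `classes` (transcript_id, category) and `counts`
#'   (named integer vector over all categories, summing to the joint set
#'   size); attribute `n_dropped` counts transcripts present in only one
#'   table.
#' @export
classify_te <- function(de_rna, de_rpf, alpha = 0.1) {
  common <- intersect(de_rna$transcript_id, de_rpf$transcript_id)
  n_dropped <- length(de_rna$transcript_id) + length(de_rpf$transcript_id) -
    2 * length(common)
  rna <- de_rna[match(common, de_rna$transcript_id), ]
  rpf <- de_rpf[match(common, de_rpf$transcript_id), ]

  sig_rna <- !is.na(rna$padj) & rna$padj < alpha
  sig_rpf <- !is.na(rpf$padj) & rpf$padj < alpha
  up_rna <- rna$log2fc > 0
  up_rpf <- rpf$log2fc > 0

  cat <- rep("ns", length(common))
  cat[sig_rpf & !sig_rna & up_rpf] <- "rpf_up"
  cat[sig_rpf & !sig_rna & !up_rpf] <- "rpf_down"
  cat[sig_rna & !sig_rpf & up_rna] <- "rna_up"
  cat[sig_rna & !sig_rpf & !up_rna] <- "rna_down"
  both <- sig_rna & sig_rpf
  cat[both & up_rna & up_rpf] <- "both_up"
  cat[both & !up_rna & !up_rpf] <- "both_down"
  discordant <- both & (up_rna != up_rpf)
  if (any(discordant)) {
    warning(sum(discordant),
            " transcript(s) significant on both layers with discordant signs;",
            " labeled by the RPF sign")
    cat[discordant & up_rpf] <- "both_up"
    cat[discordant & !up_rpf] <- "both_down"
  }

  counts <- stats::setNames(vapply(TE_CATEGORIES, function(x) sum(cat == x),
                                   integer(1)), TE_CATEGORIES)
  out <- list(classes = data.frame(transcript_id = common, category = cat,
                                   stringsAsFactors = FALSE),
              counts = counts)
  attr(out, "n_dropped") <- n_dropped
  out
}
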