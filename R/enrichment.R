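#' Build a ranked gene list
#'
#' Orders gene symbols by score, descending; ties are broken by symbol
#' (lexicographic) so the order is fully deterministic. Entries whose symbol
#' field holds several semicolon-separated symbols (multi-gene protein
#' groups) are expanded so every member symbol carries the group's score as a
#' recorded tie group. Duplicate symbols collapse to the score of largest
#' magnitude with a warning.
#'
#' @param scores data.frame with columns `symbol` and `score` (symbol may be
#'   "A;B" for a tied group).
#' @return object of class `ranked_list`: data.frame symbol, score,
#'   tie_group.
#' @export
rank_genes <- function(scores) {
  stopifnot(all(c("symbol", "score") %in% names(scores)))
  scores <- scores[!is.na(scores$score) & !is.na(scores$symbol), ]
  if (nrow(scores) == 0) stop("empty score table")

  syms <- strsplit(as.character(scores$symbol), ";", fixed = TRUE)
  n_per <- lengths(syms)
  df <- data.frame(symbol = unlist(syms),
                   score = rep(scores$score, n_per),
                   tie_group = rep(seq_len(nrow(scores)), n_per),
                   stringsAsFactors = FALSE)

  if (anyDuplicated(df$symbol)) {
    warning(sum(duplicated(df$symbol)),
            " duplicate symbol(s); keeping the score of largest magnitude")
    df <- df[order(-abs(df$score), df$symbol), ]
    df <- df[!duplicated(df$symbol), ]
  }
  df <- df[order(-df$score, df$symbol), ]
  rownames(df) <- NULL
  structure(df, class = c("ranked_list", "data.frame"))
}

#' RPF ranking from a differential-translation table
#'
#' @param de output of [nb_differential()] on the RPF assay.
#' @param catalog a `transcript_catalog` (maps transcripts to gene symbols).
#' @param metric ranking metric: the Wald statistic (default) or the log2
#'   fold change.
#' @return a `ranked_list`.
#' @export
rpf_ranking <- function(de, catalog, metric = c("stat", "log2fc")) {
  metric <- match.arg(metric)
  rec <- catalog$records
  sym <- rec$gene_symbol[match(de$transcript_id, rec$transcript_id)]
  rank_genes(data.frame(symbol = sym, score = de[[metric]],
                        stringsAsFactors = FALSE))
}

#' Proteome ranking by between-condition test difference
#'
#' Scores each protein group by the difference of condition means of its
#' log2 intensities (test minus reference); multi-gene groups keep all member
#' symbols tied.
#'
#' @param intensity log2 intensity matrix, rownames = protein-group ids
#'   (possibly semicolon-joined symbols).
#' @param sample_info sample sheet matching the columns.
#' @param conditions the (reference, test) condition pair.
#' @return a `ranked_list`.
#' @export
proteome_ranking <- function(intensity, sample_info, conditions = c("WT", "KO")) {
  sample_info <- sample_info[match(colnames(intensity), sample_info$sample_id), ]
  ref <- sample_info$condition == conditions[1]
  tst <- sample_info$condition == conditions[2]
  score <- rowMeans(intensity[, tst, drop = FALSE]) -
    rowMeans(intensity[, ref, drop = FALSE])
  rank_genes(data.frame(symbol = rownames(intensity), score = score,
                        stringsAsFactors = FALSE))
}

# enrichment score of one set: weighted KS running sum evaluated only at its
# extrema candidates (hit tops and pre-hit bottoms)
.gsea_es <- function(w, hits, N) {
  nh <- length(hits)
  nm <- N - nh
  wh <- w[hits]
  W <- sum(wh)
  if (W == 0) { wh <- rep(1, nh); W <- nh }
  cum <- cumsum(wh) / W
  if (nm == 0) {
    return(list(es = 1, peak = nh))
  }
  top <- cum - (hits - seq_len(nh)) / nm
  bot <- top - wh / W
  i_max <- which.max(top)
  i_min <- which.min(bot)
  if (top[i_max] >= -bot[i_min]) {
    list(es = top[i_max], peak = i_max)
  } else {
    list(es = bot[i_min], peak = i_min)
  }
}

#' Preranked GSEA with a gene-label permutation null
#'
#' Enrichment scores use the weighted Kolmogorov-Smirnov running sum: hit
#' increments proportional to `|score|^weight` (normalized to sum 1 over the
#' set's members), miss decrements `1/(N - n_hits)`. The null distribution
#' comes from random gene-label permutations (random sets of the same size);
#' the normalized score divides ES by the mean |null ES| of matching sign and
#' the permutation p-value counts same-sign null scores at least as extreme,
#' with the `(1 + k)/(1 + n)` correction, so p is floored at
#' `1/(n_perm + 1)`. BH adjustment is across tested pathways. The leading
#' edge contains the set members at or before the score-attaining position
#' for positive ES, and at or after it for negative ES.
#'
#' @param ranked a `ranked_list`.
#' @param sets named list of gene-symbol vectors (see [read_gmt()]).
#' @param weight KS weight exponent (1 = classic weighted statistic).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation null.
#' @param min_size sets with fewer ranked members are skipped (recorded in
#'   the `skipped` attribute).
#' @return data.frame pathway, size, es, nes, pvalue, padj, leading_edge
#'   (comma-joined symbols).
#' @export
gsea_prerank <- function(ranked, sets, weight = 1, n_perm = 10000, seed = 1,
                         min_size = 5) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- nrow(ranked)
  w <- abs(ranked$score)^weight

  hit_idx <- lapply(sets, function(g) sort(match(unique(g), ranked$symbol)))
  hit_idx <- lapply(hit_idx, function(i) i[!is.na(i)])
  sizes <- lengths(hit_idx)
  skipped <- names(sets)[sizes < min_size]
  keep <- sizes >= min_size
  hit_idx <- hit_idx[keep]
  sizes <- sizes[keep]
  if (length(hit_idx) == 0) stop("no gene set reaches min_size in the ranking")

  es <- numeric(length(hit_idx))
  peaks <- integer(length(hit_idx))
  for (j in seq_along(hit_idx)) {
    r <- .gsea_es(w, hit_idx[[j]], N)
    es[j] <- r$es
    peaks[j] <- r$peak
  }

  # shared null per distinct set size
  null_by_size <- withr::with_seed(seed, {
    lapply(stats::setNames(nm = sort(unique(sizes))), function(k) {
      vapply(seq_len(n_perm), function(p) {
        .gsea_es(w, sort(sample.int(N, k)), N)$es
      }, numeric(1))
    })
  })

  nes <- pval <- rep(NA_real_, length(es))
  for (j in seq_along(es)) {
    null <- null_by_size[[as.character(sizes[j])]]
    same <- if (es[j] >= 0) null[null >= 0] else null[null < 0]
    if (length(same) > 0) {
      nes[j] <- es[j] / mean(abs(same))
      pval[j] <- (1 + sum(abs(same) >= abs(es[j]))) / (1 + length(same))
    } else {
      pval[j] <- 1 / (n_perm + 1)
    }
  }

  le <- vchr(seq_along(hit_idx), function(j) {
    idx <- hit_idx[[j]]
    genes <- if (es[j] >= 0) idx[seq_len(peaks[j])] else idx[peaks[j]:length(idx)]
    paste(ranked$symbol[genes], collapse = ",")
  })

  out <- data.frame(pathway = names(hit_idx), size = as.integer(sizes),
                    es = es, nes = nes, pvalue = pval,
                    padj = stats::p.adjust(pval, method = "BH"),
                    leading_edge = le, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Leading-edge partition between two enrichment results
#'
#' Splits the leading edges of one pathway tested on two rankings (RPF and
#' proteome) into shared / only-RPF / only-protein genes and, when abundance
#' matrices are supplied, returns per-gene z-scaled values per modality and
#' sample (the substrate of per-condition violin summaries).
#'
#' @param res_rpf,res_prot [gsea_prerank()] tables for the two rankings.
#' @param pathway pathway name, present in both tables.
#' @param rpf_abundance,protein_abundance optional matrices (rows keyed by
#'   gene symbol) of normalized RPF counts and protein intensities.
#' @param sample_info sample sheet for the abundance columns.
#' @return list with `shared`, `only_rpf`, `only_protein`, `counts`, and
#'   (when abundances are given) `abundance`: data.frame gene, modality,
#'   sample_id, condition, z.
#' @export
leading_edge_overlap <- function(res_rpf, res_prot, pathway,
                                 rpf_abundance = NULL, protein_abundance = NULL,
                                 sample_info = NULL) {
  get_le <- function(res, side) {
    i <- match(pathway, res$pathway)
    if (is.na(i)) stop("pathway '", pathway, "' missing from the ", side, " results")
    le <- res$leading_edge[i]
    if (is.na(le) || le == "") character(0) else strsplit(le, ",", fixed = TRUE)[[1]]
  }
  le_rpf <- get_le(res_rpf, "RPF")
  le_prot <- get_le(res_prot, "protein")
  shared <- sort(intersect(le_rpf, le_prot))
  only_rpf <- sort(setdiff(le_rpf, le_prot))
  only_prot <- sort(setdiff(le_prot, le_rpf))
  out <- list(shared = shared, only_rpf = only_rpf, only_protein = only_prot,
              counts = c(shared = length(shared), only_rpf = length(only_rpf),
                         only_protein = length(only_prot)))

  if (!is.null(rpf_abundance) && !is.null(protein_abundance) &&
      length(shared) > 0) {
    zscale <- function(mat, genes, modality) {
      genes <- intersect(genes, rownames(mat))
      if (length(genes) == 0) return(NULL)
      sub <- mat[genes, , drop = FALSE]
      z <- t(scale(t(sub)))  # per gene across all samples
      df <- data.frame(gene = rep(genes, ncol(sub)),
                       modality = modality,
                       sample_id = rep(colnames(sub), each = length(genes)),
                       z = as.vector(z), stringsAsFactors = FALSE)
      if (!is.null(sample_info)) {
        df$condition <- sample_info$condition[match(df$sample_id,
                                                    sample_info$sample_id)]
      }
      df
    }
    out$abundance <- rbind(zscale(rpf_abundance, shared, "rpf"),
                           zscale(protein_abundance, shared, "protein"))
  }
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric test with both margins fixed: the two-sided
#' p-value sums the probabilities of all tables at most as probable as the
#' observed one. Also returns the sample odds ratio `(a*d)/(b*c)` (0 or
#' infinite when a margin cell is empty) and the row-1 proportion
#' `a/(a+b)`.
#'
#' @param tab 2x2 matrix, or a length-4 vector (a, b, c, d) filled by row.
#' @return list with `odds_ratio`, `p_value`, `row1_proportion`, `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  k1 <- a + b          # row-1 margin (draws)
  col1 <- a + cc       # column-1 margin (white balls)
  col2 <- b + d
  support <- max(0, k1 - col2):min(k1, col1)
  probs <- stats::dhyper(support, col1, col2, k1)
  p_obs <- stats::dhyper(a, col1, col2, k1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * cc)
  list(odds_ratio = or, p_value = p,
       row1_proportion = if (k1 > 0) a / k1 else NaN,
       table = matrix(c(a, b, cc, d), 2, 2, byrow = TRUE))
}
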