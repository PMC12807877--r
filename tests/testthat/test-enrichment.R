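test_that("rankings expand protein groups, break ties and collapse duplicates", {
  rk <- rank_genes(data.frame(symbol = c("Npm1;Npm1ps", "A", "B"),
                              score = c(2, 3, -1)))
  expect_equal(rk$symbol, c("A", "Npm1", "Npm1ps", "B"))
  expect_equal(rk$score[rk$symbol == "Npm1"], 2)
  expect_equal(rk$tie_group[rk$symbol == "Npm1"],
               rk$tie_group[rk$symbol == "Npm1ps"])

  # zero sits between positive and negative; ties ordered lexicographically
  rk2 <- rank_genes(data.frame(symbol = c("A", "B", "C"), score = c(3, -1, 0)))
  expect_equal(rk2$symbol, c("A", "C", "B"))

  # row order of the input is irrelevant
  df <- data.frame(symbol = letters[1:10], score = rnorm(10))
  expect_equal(rank_genes(df)$symbol, rank_genes(df[sample(10), ])$symbol)

  expect_warning(dup <- rank_genes(data.frame(symbol = c("A", "A"),
                                              score = c(1, -5))),
                 "duplicate")
  expect_equal(dup$score, -5)
  expect_error(rank_genes(data.frame(symbol = character(0),
                                     score = numeric(0))), "empty")
})

test_that("proteome ranking scores groups by the condition mean difference", {
  si <- toy_sample_sheet(2)
  m <- rbind("G1" = c(10, 10, 12, 12), "G2;G2ps" = c(5, 5, 4, 4))
  colnames(m) <- si$sample_id
  rk <- proteome_ranking(m, si)
  expect_equal(rk$score[rk$symbol == "G1"], 2)
  expect_equal(rk$score[rk$symbol == "G2ps"], -1)
  expect_equal(nrow(rk), 3)
})

test_that("enrichment scores match the brute-force running sum and fgsea", {
  set.seed(77)
  for (i in seq_len(200)) {
    N <- sample(50:400, 1)
    scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    rk <- rank_genes(data.frame(symbol = sprintf("g%04d", seq_len(N)),
                                score = scores))
    k <- sample(3:25, 1)
    hit_syms <- sample(rk$symbol, k)
    res <- gsea_prerank(rk, list(S = hit_syms), n_perm = 10, seed = 1,
                        min_size = 3)
    idx <- sort(match(hit_syms, rk$symbol))
    expect_equal(res$es, brute_force_es(rk$score, idx), tolerance = 1e-12)
    expect_equal(res$es, fgsea::calcGseaStat(rk$score, idx, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("a singleton set holding the top gene attains the maximal score", {
  rk <- rank_genes(data.frame(symbol = letters[1:20], score = 20:1))
  res <- gsea_prerank(rk, list(top = rk$symbol[1]), n_perm = 100, seed = 1,
                      min_size = 1)
  expect_equal(res$es, 1.0)
  expect_equal(res$leading_edge, rk$symbol[1])
})

test_that("unweighted scores are antisymmetric under ranking reversal", {
  # skip instances where the running sum's positive and negative extrema tie
  # exactly (steps are rational at weight 0): the tie-break convention then
  # legitimately picks the positive extremum in both directions
  extrema_tied <- function(scores, idx) {
    N <- length(scores)
    step_hit <- 1 / length(idx)
    step_miss <- 1 / (N - length(idx))
    run <- cumsum(ifelse(seq_len(N) %in% idx, step_hit, -step_miss))
    abs(max(run) + min(run)) < 1e-9
  }
  set.seed(9)
  for (i in seq_len(50)) {
    N <- 100
    scores <- sort(rnorm(N), decreasing = TRUE)
    syms <- sprintf("g%03d", seq_len(N))
    rk <- rank_genes(data.frame(symbol = syms, score = scores))
    rk_rev <- rank_genes(data.frame(symbol = syms, score = -scores))
    set_syms <- sample(syms, 10)
    if (extrema_tied(scores, match(set_syms, rk$symbol))) next
    es <- gsea_prerank(rk, list(S = set_syms), weight = 0, n_perm = 10,
                       seed = 1)$es
    es_rev <- gsea_prerank(rk_rev, list(S = set_syms), weight = 0, n_perm = 10,
                           seed = 1)$es
    expect_equal(es, -es_rev, tolerance = 1e-12)
  }
})

test_that("permutation p-values are seeded, floored and sets below min_size skipped", {
  set.seed(4)
  rk <- rank_genes(data.frame(symbol = sprintf("g%03d", 1:200),
                              score = rnorm(200)))
  sets <- list(big = rk$symbol[c(1:6, 50)], tiny = rk$symbol[1:3])
  a <- gsea_prerank(rk, sets, n_perm = 200, seed = 99)
  b <- gsea_prerank(rk, sets, n_perm = 200, seed = 99)
  expect_identical(a, b)
  expect_equal(attr(a, "skipped"), "tiny")
  expect_gte(min(a$pvalue), 1 / 201)
  expect_true(all(a$padj >= a$pvalue))
})

test_that("leading-edge partitions behave on identical and disjoint edges", {
  mk_res <- function(le) {
    data.frame(pathway = "P", size = 10, es = 0.5, nes = 1.5, pvalue = 0.01,
               padj = 0.02, leading_edge = paste(le, collapse = ","))
  }
  same <- leading_edge_overlap(mk_res(c("A", "B", "C")), mk_res(c("A", "B", "C")), "P")
  expect_equal(same$shared, c("A", "B", "C"))
  expect_length(same$only_rpf, 0)
  expect_length(same$only_protein, 0)

  disj <- leading_edge_overlap(mk_res(c("A", "B")), mk_res(c("C", "D")), "P")
  expect_length(disj$shared, 0)
  expect_equal(disj$counts[["only_rpf"]], 2)

  expect_error(leading_edge_overlap(mk_res("A"), mk_res("B"), "missing"),
               "RPF")

  # z-scaled abundance substrate for shared genes
  si <- toy_sample_sheet(2)
  mat <- matrix(rnorm(12), 3, 4, dimnames = list(c("A", "B", "C"), si$sample_id))
  ov <- leading_edge_overlap(mk_res(c("A", "B")), mk_res(c("B", "C")), "P",
                             rpf_abundance = mat, protein_abundance = mat,
                             sample_info = si)
  expect_setequal(unique(ov$abundance$gene), "B")
  expect_equal(as.numeric(tapply(ov$abundance$z, ov$abundance$modality, mean)),
               c(0, 0), tolerance = 1e-12)
})

test_that("a sign-flipped gene set yields opposite enrichment in the two omics", {
  s <- default_sim()
  sets <- simulate_gene_sets(s$sim$truth, n_random = 4, set_size = 15, seed = 21)
  prot <- simulate_proteome(s$sim$truth, sets, s$cfg,
                            flipped_sets = "RPF_UP_TRUTH")
  truth <- prot$truth$de_truth
  # ranking straight from the truth effects plus mild noise: isolates the
  # enrichment machinery from the differential-test machinery
  set.seed(8)
  rk_rpf <- rank_genes(data.frame(symbol = truth$gene_symbol,
                                  score = truth$lfc_rpf + rnorm(nrow(truth), 0, 0.2)))
  rk_prot <- proteome_ranking(prot$intensity, prot$sample_info)
  res_rpf <- gsea_prerank(rk_rpf, sets, n_perm = 500, seed = 3)
  res_prot <- gsea_prerank(rk_prot, sets, n_perm = 500, seed = 3)
  i <- match("RPF_UP_TRUTH", res_rpf$pathway)
  j <- match("RPF_UP_TRUTH", res_prot$pathway)
  expect_gt(res_rpf$nes[i], 0)
  expect_lt(res_prot$nes[j], 0)
  expect_lt(res_prot$padj[j], 0.1)
})

test_that("Fisher 2x2 matches enumeration, fisher.test and the printed example", {
  ex <- fisher_exact_2x2(matrix(c(69, 7, 177, 122), 2, 2, byrow = TRUE))
  expect_equal(round(100 * ex$row1_proportion, 1), 90.8)
  expect_equal(ex$odds_ratio, 69 * 122 / (7 * 177))
  expect_equal(ex$p_value, enumerate_fisher_p(69, 7, 177, 122))

  flat <- fisher_exact_2x2(c(1, 1, 1, 1))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  diag <- fisher_exact_2x2(c(5, 0, 0, 5))
  expect_equal(diag$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(diag$odds_ratio, Inf)

  set.seed(12)
  for (i in seq_len(100)) {
    tab <- matrix(rpois(4, sample(c(3, 10, 25), 1)), 2, 2)
    ours <- fisher_exact_2x2(tab)
    expect_equal(ours$p_value,
                 enumerate_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(ours$p_value, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
})
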