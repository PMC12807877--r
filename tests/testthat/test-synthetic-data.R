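test_that("catalog generation respects configuration and edge cases", {
  empty <- generate_catalog(sim_config(n_genes = 0, seed = 1))
  expect_equal(nrow(empty$catalog$records), 0)
  expect_equal(nrow(empty$abundance), 0)

  cfg <- sim_config(n_genes = 25, isoforms_per_gene = 3,
                    cds_len_range = c(300, 300), seed = 3)
  co <- suppressMessages(generate_catalog(cfg))
  expect_equal(nrow(co$catalog$records), 25)
  expect_true(all(co$catalog$records$cds_len == 300))
  expect_true(all(co$regions$cds_len %% 3 == 0))
  expect_equal(nrow(co$regions), 75)
  # the designated most-abundant isoform is the one MAT selection recovers
  expect_equal(co$catalog$mat[names(co$designated_mat)], co$designated_mat)

  expect_error(sim_config(cds_len_range = c(600, 300)), "min <= max")
  expect_error(sim_config(pause_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(frac_induced = 0.7, frac_resolved = 0.6), "exceed 1")
  expect_error(sim_config(pause_factor = 1), "pause_factor")
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 8, seed = 42, de_fraction = c(rna = 0, rpf = 0.6))
  a <- suppressMessages(generate_catalog(cfg))
  b <- suppressMessages(generate_catalog(cfg))
  expect_identical(a, b)

  sim_a <- simulate_riboseq_experiment(a$catalog, cfg)
  sim_b <- simulate_riboseq_experiment(b$catalog, cfg)
  expect_identical(sim_a$reads, sim_b$reads)
  expect_identical(sim_a$rna_counts$counts, sim_b$rna_counts$counts)
  expect_identical(sim_a$truth, sim_b$truth)

  sets <- simulate_gene_sets(sim_a$truth, seed = 5)
  p_a <- simulate_proteome(sim_a$truth, sets, cfg, flipped_sets = "RPF_UP_TRUTH")
  p_b <- simulate_proteome(sim_b$truth, sets, cfg, flipped_sets = "RPF_UP_TRUTH")
  expect_identical(p_a$intensity, p_b$intensity)
})

test_that("pre-noise rates carry the configured structure", {
  cfg <- sim_config(n_genes = 12, seed = 9, expr_sd_log2 = 0)
  co <- suppressMessages(generate_catalog(cfg))
  sim <- simulate_riboseq_experiment(co$catalog, cfg)
  rec <- co$catalog$records

  for (i in seq_len(nrow(rec))) {
    tx <- rec$transcript_id[i]
    span <- (rec$cds_start[i] + 1):rec$cds_end[i]
    exp_row <- sim$expected_cds[sim$expected_cds$transcript_id == tx, ]
    # CDS rate sums equal the expected CDS count exactly, both conditions
    expect_equal(sum(sim$rates[[tx]]$WT[span]), exp_row$wt, tolerance = 1e-10)
    expect_equal(sum(sim$rates[[tx]]$KO[span]), exp_row$ko, tolerance = 1e-10)
    # with ramp_strength > 0 the KO 5'/3' half ratio exceeds the WT one
    half <- span[seq_len(floor(length(span) / 2))]
    rest <- setdiff(span, half)
    ratio <- function(r) sum(r[half]) / sum(r[rest])
    expect_gt(ratio(sim$rates[[tx]]$KO) / ratio(sim$rates[[tx]]$WT), 1)
  }
})

test_that("nothing is injected when the corresponding fraction is zero", {
  cfg <- sim_config(n_genes = 10, seed = 2, pause_fraction = 0,
                    de_fraction = 0)
  co <- suppressMessages(generate_catalog(cfg))
  sim <- simulate_riboseq_experiment(co$catalog, cfg)
  expect_equal(nrow(sim$truth$injected_pauses), 0)
  expect_true(all(sim$truth$de_truth$lfc_rna == 0))
  expect_true(all(sim$truth$de_truth$lfc_rpf == 0))
})

test_that("injected pauses lie inside the CDS, away from the edges, in frame", {
  s <- default_sim()
  truth <- s$sim$truth$injected_pauses
  rec <- s$catalog$records
  cds_len <- rec$cds_len[match(truth$transcript_id, rec$transcript_id)]
  expect_true(all(truth$cds_position >= s$cfg$pause_edge_nt))
  expect_true(all(truth$cds_position < cds_len - s$cfg$pause_edge_nt))
  expect_true(all(truth$cds_position %% 3 == 0))
  expect_true(all(truth$class %in% c("induced", "resolved", "maintained")))
})

test_that("observed depth matches the configured rate (law of large numbers)", {
  cfg <- sim_config(n_genes = 50, seed = 13, expr_sd_log2 = 0,
                    pause_fraction = 0, de_fraction = 0, ramp_strength = 0,
                    batch_effect = 1)
  co <- suppressMessages(generate_catalog(cfg))
  sim <- simulate_riboseq_experiment(co$catalog, cfg)
  prof <- suppressMessages(toy_profiles(sim$reads, co$catalog, sim$sample_info))
  cm <- cds_count_matrix(prof, min_mean_reads = 0)
  expect_lt(abs(mean(cm$counts) - 500) / 500, 0.1)
})

test_that("under the null the between-condition occupancy difference is centred", {
  cfg <- sim_config(n_genes = 200, seed = 17, ramp_strength = 0,
                    de_fraction = 0, pause_fraction = 0, batch_effect = 1,
                    mean_cds_depth = 100, cds_len_range = c(300, 600),
                    isoforms_per_gene = 1)
  co <- generate_catalog(cfg)
  sim <- simulate_riboseq_experiment(co$catalog, cfg)
  prof <- suppressMessages(toy_profiles(sim$reads, co$catalog, sim$sample_info))
  cm <- cds_count_matrix(prof, min_mean_reads = 0)
  si <- sim$sample_info
  ko <- rowMeans(cm$counts[, si$sample_id[si$condition == "KO"]])
  wt <- rowMeans(cm$counts[, si$sample_id[si$condition == "WT"]])
  rel <- (ko - wt) / pmax((ko + wt) / 2, 1)
  se <- stats::sd(rel) / sqrt(length(rel))
  expect_lt(abs(mean(rel)), 3 * se)
})

test_that("proteome truth mirrors or flips the RPF truth as designated", {
  s <- default_sim()
  sets <- simulate_gene_sets(s$sim$truth, n_random = 2, set_size = 10, seed = 5)

  noflip <- simulate_proteome(s$sim$truth, sets, s$cfg)
  expect_equal(noflip$truth$de_truth$lfc_protein, noflip$truth$de_truth$lfc_rpf)

  flip <- simulate_proteome(s$sim$truth, sets, s$cfg,
                            flipped_sets = "RPF_UP_TRUTH")
  de <- flip$truth$de_truth
  in_set <- de$gene_symbol %in% sets$RPF_UP_TRUTH
  expect_equal(de$lfc_protein[in_set], -de$lfc_rpf[in_set])
  expect_equal(de$lfc_protein[!in_set], de$lfc_rpf[!in_set])
  expect_true(all(de$lfc_rpf[in_set] > 0))

  # the designated multi-gene protein group carries two tied symbols
  multi <- grep(";", flip$protein_groups$group_id, value = TRUE)
  expect_length(multi, 1)

  expect_warning(
    simulate_proteome(s$sim$truth, list(BAD = c("NotAGene1", "NotAGene2")),
                      s$cfg),
    "absent from the simulated truth")
})
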