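test_that("pause calling follows the 10x nonzero-mean rule on hand-built profiles", {
  # 99 positions of 1 and one of 60: nonzero mean 1.59, threshold 15.9
  prof <- c(rep(1, 99), 60)
  expect_equal(as.integer(call_pauses(prof)), 99L)
  expect_equal(10 * mean(prof[prof > 0]), 15.9)

  # a strictly uniform profile can never satisfy a >1 fold rule
  expect_length(call_pauses(rep(7, 120)), 0)

  # all-zero profile: no pauses, not evaluable
  z <- call_pauses(numeric(100))
  expect_length(z, 0)
  expect_false(attr(z, "evaluable"))

  # below min_nonzero_positions the transcript is not evaluable
  sparse <- c(rep(0, 95), rep(5, 5))
  expect_false(attr(call_pauses(sparse), "evaluable"))
})

test_that("pause calling agrees with a brute-force scan on random profiles", {
  set.seed(101)
  for (i in seq_len(1000)) {
    n <- sample(30:300, 1)
    prof <- rpois(n, lambda = sample(c(0.2, 1, 5), 1))
    if (runif(1) < 0.3) prof[sample(n, 1)] <- prof[sample(n, 1)] + rpois(1, 80)
    called <- call_pauses(prof)
    expect_identical(as.integer(called),
                     brute_force_pauses(prof))
  }
})

test_that("raising the fold threshold never increases the number of calls", {
  set.seed(7)
  for (i in seq_len(50)) {
    prof <- rpois(200, 2) + rbinom(200, 1, 0.02) * rpois(200, 100)
    n_calls <- vapply(c(2, 5, 10, 20, 50), function(f) {
      length(call_pauses(prof, pause_config(fold_threshold = f)))
    }, numeric(1))
    expect_true(all(diff(n_calls) <= 0))
  }
})

test_that("classification partitions candidates and applies the 10x change rule", {
  # identical profiles, equal abundance: every candidate is maintained
  prof <- c(rep(2, 50), 80, rep(2, 49))
  out <- classify_pauses(prof, prof, 1, 1, candidates = c(10L, 50L))
  expect_equal(out$class, c("maintained", "maintained"))
  expect_equal(out$delta, c(0, 0))

  # reference mean |delta| 0.5 from background positions, candidate delta +75
  wt <- c(5, rep(2, 20), rep(0, 79))
  ko <- c(80, rep(2.5, 20), rep(0, 79))
  out_up <- classify_pauses(wt, ko, 1, 1, candidates = 0L,
                            config = pause_config(start_exclusion_nt = 0))
  expect_equal(out_up$delta, 75)
  expect_equal(out_up$class, "induced")
  out_dn <- classify_pauses(ko, wt, 1, 1, candidates = 0L,
                            config = pause_config(start_exclusion_nt = 0))
  expect_equal(out_dn$class, "resolved")

  # start-site exclusion removes candidates in the first codon
  excl <- classify_pauses(wt, ko, 1, 1, candidates = c(0L, 2L, 50L))
  expect_false(any(excl$cds_position < 3))

  # candidates outside the CDS are a caller bug
  expect_error(classify_pauses(wt, ko, 1, 1, candidates = 150L), "outside")
  expect_error(classify_pauses(wt, ko, 0, 1, candidates = 10L), "positive")

  # the three labels partition every candidate exactly once
  set.seed(11)
  for (i in seq_len(200)) {
    a <- rpois(80, 3)
    b <- rpois(80, 3)
    cand <- sort(sample(3:79, 8))
    res <- classify_pauses(a, b, runif(1, 0.5, 2), runif(1, 0.5, 2), cand)
    expect_equal(nrow(res), length(cand))
    expect_true(all(res$class %in% c("induced", "resolved", "maintained")))
  }
})

test_that("pause position histograms are per-class densities on [0, 1)", {
  catalog <- toy_catalog(cds = 300, n = 3)
  pauses <- data.frame(
    transcript_id = c("tx01", "tx02", "tx03"),
    cds_position = c(150L, 30L, 60L),
    class = c("induced", "induced", "resolved"))
  d <- pause_position_distribution(pauses, catalog, n_bins = 10)
  ind <- d[d$subset == "all" & d$class == "induced", ]
  expect_equal(sum(ind$density), 1)
  expect_equal(ind$count[ind$lower <= 0.5 & ind$upper > 0.5], 1)  # rel 0.5
  expect_equal(ind$count[ind$bin == 1], 1)                        # rel 0.1
  # empty class gives an all-zero histogram, not an error
  expect_true(all(d$count[d$class == "maintained"] == 0))
  # gene-subset stratification
  d2 <- pause_position_distribution(pauses, catalog, n_bins = 10,
                                    subsets = list(only = "Sym03"))
  expect_equal(sum(d2$count[d2$subset == "only" & d2$class == "resolved"]), 1)
  expect_equal(sum(d2$count[d2$subset == "only" & d2$class == "induced"]), 0)
})

test_that("pauses injected in the first CDS half are recovered there", {
  cfg <- sim_config(n_genes = 80, seed = 23, pause_region = c(0, 0.5),
                    pause_fraction = 0.5, ramp_strength = 0, de_fraction = 0)
  co <- suppressMessages(generate_catalog(cfg))
  sim <- simulate_riboseq_experiment(co$catalog, cfg)
  prof <- toy_profiles(sim$reads, co$catalog, sim$sample_info)
  pauses <- find_pause_sites(prof, sim$rna_counts)
  truth <- sim$truth$injected_pauses
  rec <- co$catalog$records
  expect_true(all(truth$cds_position / rec$cds_len[
    match(truth$transcript_id, rec$transcript_id)] < 0.5))
  d <- pause_position_distribution(pauses[pauses$class == "induced", ],
                                   co$catalog, n_bins = 10)
  first_half <- sum(d$density[d$class == "induced" & d$upper <= 0.5])
  expect_gte(first_half, 0.9)
})

test_that("metagene deltas vanish when the two conditions are identical", {
  catalog <- toy_catalog(utr5 = 25, cds = 120, utr3 = 25, n = 4)
  si <- toy_sample_sheet(2)
  set.seed(3)
  base <- do.call(rbind, lapply(catalog$records$transcript_id, function(tx) {
    data.frame(transcript_id = tx, start = sample(5:130, 400, replace = TRUE),
               length = 28L, stringsAsFactors = FALSE)
  }))
  reads <- do.call(rbind, lapply(si$sample_id, function(s) {
    r <- base
    r$sample_id <- s
    r
  }))
  prof <- toy_profiles(reads, catalog, si, offsets = fixed_offset_table(28, 12))
  mg <- metagene_delta(prof, pause_config(bins = c(utr5 = 5, cds = 20, utr3 = 5),
                                          metagene_min_mean_cds = 50))
  expect_true(all(abs(mg$mean_delta) < 1e-12))
  expect_true(all(mg$sd < 1e-12))
})

test_that("metagene recovers the simulated 5' occupancy tilt", {
  s <- default_sim()   # ramp_strength 0.3 by default
  mg <- metagene_delta(s$profiles)
  cds <- mg[mg$region == "cds", ]
  expect_gt(mean(cds$mean_delta[cds$bin < 10]), 0)
  expect_lt(mean(cds$mean_delta[cds$bin >= 90]), 0)
})

test_that("the metagene filter excludes transcripts at mean CDS reads <= 50", {
  catalog <- toy_catalog(utr5 = 20, cds = 90, utr3 = 30, n = 2)
  si <- toy_sample_sheet(1)   # two samples
  mk <- function(tx, n_per_sample) {
    do.call(rbind, lapply(si$sample_id, function(s) {
      data.frame(transcript_id = tx,
                 start = rep(seq(10, 89, by = 2), length.out = n_per_sample),
                 length = 28L, sample_id = s, stringsAsFactors = FALSE)
    }))
  }
  reads <- rbind(mk("tx01", 49), mk("tx02", 60))   # means 49 and 60
  prof <- toy_profiles(reads, catalog, si, offsets = fixed_offset_table(28, 12))
  mg <- metagene_delta(prof, pause_config(bins = c(utr5 = 2, cds = 10, utr3 = 2)))
  expect_equal(unique(mg$n[mg$region == "cds"]), 1)
})
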