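# Shared simulated fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small but complete experiment under the default study conditions
default_sim <- function() {
  cached("default_sim", {
    cfg <- sim_config(n_genes = 60, seed = 7)
    co <- generate_catalog(cfg)
    sim <- simulate_riboseq_experiment(co$catalog, cfg)
    prof <- suppressMessages(
      build_profiles(sim$reads, fixed_offset_table(cfg$read_lengths,
                                                   cfg$p_site_offset),
                     co$catalog, sim$sample_info))
    list(cfg = cfg, catalog = co$catalog, catalog_out = co, sim = sim,
         profiles = prof)
  })
}

# a tiny hand-made catalog: one gene, one transcript, utr5 20 / cds 60 / utr3 20
toy_catalog <- function(utr5 = 20, cds = 60, utr3 = 20, n = 1) {
  regions <- data.frame(
    transcript_id = sprintf("tx%02d", seq_len(n)),
    gene_id = sprintf("g%02d", seq_len(n)),
    gene_symbol = sprintf("Sym%02d", seq_len(n)),
    utr5_len = utr5, cds_len = cds, utr3_len = utr3,
    stringsAsFactors = FALSE)
  mat <- regions$transcript_id
  names(mat) <- regions$gene_id
  build_catalog(regions, mat)
}

toy_sample_sheet <- function(n_rep = 2) {
  reps <- seq_len(n_rep)
  data.frame(sample_id = c(paste0("WT_", reps), paste0("KO_", reps)),
             condition = rep(c("WT", "KO"), each = n_rep),
             replicate = rep(reps, 2), batch = 1L,
             stringsAsFactors = FALSE)
}

# occupancy_profiles built from an explicit read table on a toy catalog
toy_profiles <- function(reads, catalog = toy_catalog(),
                         sample_info = toy_sample_sheet(),
                         offsets = fixed_offset_table(28:32, 12)) {
  build_profiles(reads, offsets, catalog, sample_info)
}
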